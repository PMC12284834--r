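# Stepwise assembly stoichiometry in the strong-binding limit:
# F2 + F4 -> dimer; dimer + F3 -> trimer; trimer + F1 -> tetramer.
# Affinities are taken as effectively infinite (complexation runs to
# completion), so amounts follow a min() cascade with exact mass balance.

species_names <- c("F1", "F2", "F3", "F4", "F2F4", "F2F3F4", "F1F2F3F4")

# greedy re-equilibration of a pot: complexes form to completion in the
# fixed pathway order until nothing changes
equilibrate_pot <- function(pot) {
  repeat {
    d <- min(pot["F2"], pot["F4"])
    pot["F2"] <- pot["F2"] - d; pot["F4"] <- pot["F4"] - d
    pot["F2F4"] <- pot["F2F4"] + d
    t3 <- min(pot["F2F4"], pot["F3"])
    pot["F2F4"] <- pot["F2F4"] - t3; pot["F3"] <- pot["F3"] - t3
    pot["F2F3F4"] <- pot["F2F3F4"] + t3
    t4 <- min(pot["F2F3F4"], pot["F1"])
    pot["F2F3F4"] <- pot["F2F3F4"] - t4; pot["F1"] <- pot["F1"] - t4
    pot["F1F2F3F4"] <- pot["F1F2F3F4"] + t4
    if (d + t3 + t4 == 0) break
  }
  pot
}

#' Assemble the hetero-oligomer species mix
#'
#' Strong-binding sequential assembly: the F2+F4 dimer nucleates, F3 binds
#' the dimer to give the F2F3F4 trimer, and F1 completes the F1F2F3F4
#' tetramer. In the infinite-affinity limit the final amounts are the min()
#' cascade `dimer0 = min(F2, F4)`, `trimer0 = min(dimer0, F3)`,
#' `tetramer = min(trimer0, F1)` with residual intermediates and free
#' monomers fixed by mass balance. An equilibrium per-step Kd extension is
#' deliberately not parameterized (no binding constants are available for
#' this system); the strong-binding limit matches the observed essentially
#' complete complexation.
#'
#' @param f1,f2,f3,f4 Molar amounts of the four monomers (>= 0).
#' @return One-row tibble of class `cc_species_mix` with free monomer and
#'   complex amounts: `F1`, `F2`, `F3`, `F4`, `F2F4`, `F2F3F4`,
#'   `F1F2F3F4`.
#' @export
#' @examples
#' assemble(1, 1.2, 1, 1.2)   # 20% excess of F2 and F4
assemble <- function(f1, f2, f3, f4) {
  amounts <- c(f1, f2, f3, f4)
  if (any(amounts < 0) || any(!is.finite(amounts))) {
    abort("monomer amounts must be finite and non-negative")
  }
  dimer0 <- min(f2, f4)
  trimer0 <- min(dimer0, f3)
  tetramer <- min(trimer0, f1)
  out <- tibble(
    F1 = f1 - tetramer,
    F2 = f2 - dimer0,
    F3 = f3 - trimer0,
    F4 = f4 - dimer0,
    F2F4 = dimer0 - trimer0,
    F2F3F4 = trimer0 - tetramer,
    F1F2F3F4 = tetramer
  )
  class(out) <- c("cc_species_mix", class(out))
  out
}

#' Check assembly is independent of the order of addition
#'
#' Simulates adding the four proteins to a pot one at a time in the given
#' order, re-equilibrating the strong-binding pathway after each addition,
#' and verifies the final mix equals [assemble()] for every requested
#' permutation.
#'
#' @param f1,f2,f3,f4 Molar amounts.
#' @param orders Matrix of addition orders (rows of permutations of 1:4) or
#'   `"all"` for all 24.
#' @param tol Equality tolerance.
#' @return The [assemble()] mix, invisibly errors if any order disagrees.
#' @export
order_invariance_check <- function(f1, f2, f3, f4, orders = "all",
                                   tol = 1e-12) {
  target <- assemble(f1, f2, f3, f4)
  if (identical(orders, "all")) {
    perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
    perms <- as.matrix(perms[apply(perms, 1, function(r) length(unique(r)) == 4), ])
  } else {
    perms <- as.matrix(orders)
  }
  amounts <- c(F1 = f1, F2 = f2, F3 = f3, F4 = f4)
  for (i in seq_len(nrow(perms))) {
    pot <- setNames(numeric(length(species_names)), species_names)
    for (j in perms[i, ]) {
      pot[names(amounts)[j]] <- pot[names(amounts)[j]] + amounts[j]
      pot <- equilibrate_pot(pot)
    }
    if (max(abs(pot[species_names] - unlist(target[species_names]))) > tol) {
      abort(sprintf("addition order %s gave a different mix",
                    paste(names(amounts)[perms[i, ]], collapse = ",")))
    }
  }
  target
}

#' Default SEC calibration from the silk system
#'
#' Elution centers for the species with published analytical SEC volumes:
#' tetramer 8.71, F2+F4 dimer 9.75, F1 10.12, F2 10.34, F3 11.22 and
#' F4 11.31 mL. The trimer has no published volume and therefore no default
#' entry; supply one to predict profiles of trimer-containing mixes.
#'
#' @param width Common Gaussian peak width (standard deviation), mL.
#' @return Tibble with columns `species`, `center`, `width`.
#' @export
sec_calibration <- function(width = 0.12) {
  tibble(
    species = c("F1F2F3F4", "F2F4", "F1", "F2", "F3", "F4"),
    center = c(8.71, 9.75, 10.12, 10.34, 11.22, 11.31),
    width = width
  )
}

#' Predict an analytical SEC profile from a species mix
#'
#' Sums one Gaussian peak per nonzero species, centered at its calibrated
#' elution volume. With `size_weighting` the peak area is amount times
#' subunit count (UV absorbance scales with mass for proteins of similar
#' size); otherwise area equals amount.
#'
#' @param mix A `cc_species_mix` from [assemble()].
#' @param calibration Tibble `species`, `center`, `width`; default
#'   [sec_calibration()].
#' @param size_weighting Weight areas by subunit count (default TRUE).
#' @param grid Elution volume grid, mL.
#' @return Object of class `cc_sec_profile`: list with `profile` (tibble
#'   `volume`, `signal`) and `peaks` (tibble `species`, `center`, `area`).
#' @export
predict_sec <- function(mix, calibration = sec_calibration(),
                        size_weighting = TRUE,
                        grid = seq(6, 13, by = 0.005)) {
  sizes <- c(F1 = 1, F2 = 1, F3 = 1, F4 = 1, F2F4 = 2, F2F3F4 = 3,
             F1F2F3F4 = 4)
  amounts <- unlist(mix[1, species_names])
  nz <- names(amounts)[amounts > 0]
  missing <- setdiff(nz, calibration$species)
  if (length(missing) > 0) {
    abort(paste0("no SEC calibration entry for nonzero species: ",
                 paste(missing, collapse = ", ")))
  }
  signal <- numeric(length(grid))
  peaks <- list()
  for (sp in nz) {
    cal <- calibration[calibration$species == sp, ][1, ]
    area <- amounts[[sp]] * if (size_weighting) sizes[[sp]] else 1
    signal <- signal + area / (cal$width * sqrt(2 * pi)) *
      exp(-(grid - cal$center)^2 / (2 * cal$width^2))
    peaks[[length(peaks) + 1]] <- tibble(species = sp, center = cal$center,
                                         area = unname(area))
  }
  peaks <- if (length(peaks) > 0) {
    bind_rows(peaks) |> arrange(.data$center)
  } else {
    tibble(species = character(), center = double(), area = double())
  }
  structure(list(profile = tibble(volume = grid, signal = signal),
                 peaks = peaks),
            class = "cc_sec_profile")
}

#' @export
print.cc_sec_profile <- function(x, ...) {
  cat("<cc_sec_profile>\n")
  print(x$peaks)
  invisible(x)
}

#' @rdname predict_sec
#' @param object A `cc_sec_profile`.
#' @param ... Unused.
#' @export
autoplot.cc_sec_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$volume, y = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = object$peaks,
                        ggplot2::aes(xintercept = .data$center),
                        linetype = "dotted", colour = "grey50") +
    ggplot2::labs(x = "elution volume (mL)", y = "signal") +
    ggplot2::theme_minimal()
}
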