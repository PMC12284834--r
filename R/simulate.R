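# Simulators with known ground truth: crosslink tables sampled from a
# structure, two-state thermal melts, and additive alpha-helical CD spectra.

#' Sample a synthetic crosslink table from a structure
#'
#' Emulates an amine-crosslinker experiment on a known structure: true links
#' are drawn from linkable residue pairs whose mapped distance is at most
#' `max_dist`, decoys from pairs beyond it. Linkable residues are lysines
#' plus each chain's first residue (the N-terminus) when residue identities
#' are available, otherwise every residue. Distances use the same atom rule
#' as [map_crosslinks()] so the emitted table maps back exactly.
#'
#' @param model A `cc_structure`.
#' @param n_links Number of links to emit.
#' @param max_dist Linker distance bound, Angstrom (default 30).
#' @param decoy_fraction Fraction of links drawn from violating pairs.
#' @param seed Integer seed.
#' @param scope `"both"`, `"inter"` or `"intra"` chain pairs.
#' @return Tibble with columns `chain_a`, `res_a`, `chain_b`, `res_b`,
#'   `count`, `truth_satisfied` (the generative label).
#' @export
sample_crosslinks <- function(model, n_links, max_dist = 30,
                              decoy_fraction = 0, seed = 1L,
                              scope = c("both", "inter", "intra")) {
  scope <- match.arg(scope)
  if (n_links == 0) {
    return(tibble(chain_a = character(), res_a = integer(),
                  chain_b = character(), res_b = integer(),
                  count = integer(), truth_satisfied = logical()))
  }
  anchors <- link_anchor_atoms(model)
  res <- residue_table(model)
  linkable <- res$aa == "K" | !duplicated(res$chain)
  if (all(res$aa == "X")) linkable <- rep(TRUE, nrow(res))
  anchors <- anchors |>
    dplyr::semi_join(res[linkable, c("chain", "seq_id")],
                     by = c("chain", "seq_id"))
  if (nrow(anchors) < 2) abort("no linkable residue pairs in structure")
  ij <- t(utils::combn(nrow(anchors), 2))
  a <- anchors[ij[, 1], ]; b <- anchors[ij[, 2], ]
  keep <- switch(scope,
    both = rep(TRUE, nrow(ij)),
    inter = a$chain != b$chain,
    intra = a$chain == b$chain
  )
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  pairs <- tibble(chain_a = a$chain, res_a = a$seq_id,
                  chain_b = b$chain, res_b = b$seq_id, distance = d)[keep, ]
  sat <- which(pairs$distance <= max_dist)
  vio <- which(pairs$distance > max_dist)
  n_decoy <- round(n_links * decoy_fraction)
  n_true <- n_links - n_decoy
  if (length(sat) < n_true || length(vio) < n_decoy) {
    abort("not enough eligible residue pairs for the requested link counts")
  }
  withr::with_seed(seed, {
    pick <- c(sample(sat, n_true), sample(vio, n_decoy))
  })
  out <- pairs[pick, c("chain_a", "res_a", "chain_b", "res_b")]
  out$count <- 1L
  out$truth_satisfied <- rep(c(TRUE, FALSE), c(n_true, n_decoy))
  out
}

#' Simulate a two-state thermal melt curve
#'
#' Ellipticity versus temperature under a two-state unfolding model with
#' linear folded/unfolded baselines: the folded fraction is
#' `f(T) = 1 / (1 + exp((T - tm) / width))` and the signal is
#' `f * B_F(T) + (1 - f) * B_U(T)` plus Gaussian noise.
#'
#' @param tm Midpoint temperature, deg C.
#' @param width Transition width parameter, deg C (> 0).
#' @param folded_baseline,unfolded_baseline Numeric `c(intercept, slope)` of
#'   ellipticity versus temperature. Defaults emulate a 222 nm helix melt
#'   (deep negative folded signal relaxing to a shallow unfolded one).
#' @param t_grid Increasing temperature grid, deg C.
#' @param noise_sd Gaussian noise standard deviation, ellipticity units.
#' @param seed Integer seed.
#' @return Tibble with columns `temperature`, `ellipticity`.
#' @export
simulate_melt <- function(tm, width = 2,
                          folded_baseline = c(-22000, 25),
                          unfolded_baseline = c(-6000, 10),
                          t_grid = seq(30, 80, by = 1),
                          noise_sd = 0, seed = 1L) {
  if (width <= 0) abort("width must be positive")
  if (is.unsorted(t_grid, strictly = TRUE)) abort("t_grid must be increasing")
  f <- 1 / (1 + exp((t_grid - tm) / width))
  bf <- folded_baseline[1] + folded_baseline[2] * t_grid
  bu <- unfolded_baseline[1] + unfolded_baseline[2] * t_grid
  y <- f * bf + (1 - f) * bu
  if (noise_sd > 0) {
    withr::with_seed(seed, y <- y + rnorm(length(y), sd = noise_sd))
  }
  tibble(temperature = t_grid, ellipticity = y)
}

#' Simulate an alpha-helical CD spectrum
#'
#' Phenomenological helix spectrum built from three Gaussian bands: negative
#' bands at 209 and 222 nm and a positive band at 192 nm. The 222 nm band
#' amplitude is solved exactly (a linear one-unknown problem, since the
#' bands overlap) so that the ellipticity ratio at 222 versus 209 nm equals
#' `ratio_222_209`. A ratio near 0.8 is the isolated single-helix regime; a
#' ratio above 0.9 is the coiled-coil regime.
#'
#' @param kind `"single_helix"` or `"coiled_coil"`; sets the default ratio
#'   (0.8 versus 0.95) and the 192 nm band weight.
#' @param ratio_222_209 Requested 222/209 ellipticity ratio (> 0).
#' @param wavelengths Wavelength grid, nm; must cover 190-260 nm.
#' @param amplitude_209 Depth of the 209 nm band (negative, mean residue
#'   ellipticity units).
#' @return Tibble with columns `wavelength`, `ellipticity` and attribute
#'   `label`.
#' @export
simulate_cd <- function(kind = c("single_helix", "coiled_coil"),
                        ratio_222_209 = NULL,
                        wavelengths = seq(190, 260, by = 1),
                        amplitude_209 = -20000) {
  kind <- match.arg(kind)
  if (min(wavelengths) > 190 || max(wavelengths) < 260) {
    abort("wavelength grid must cover 190-260 nm")
  }
  r <- ratio_222_209 %||% if (kind == "single_helix") 0.8 else 0.95
  if (r <= 0) abort("ratio_222_209 must be positive")
  g <- function(l, mu, sig) exp(-(l - mu)^2 / (2 * sig^2))
  s192 <- 6; s209 <- 7; s222 <- 10
  a209 <- amplitude_209
  a192 <- abs(amplitude_209) * if (kind == "single_helix") 2.0 else 2.6
  # solve a222 so that total(222) = r * total(209)
  num <- r * (a209 * g(209, 209, s209) + a192 * g(209, 192, s192)) -
    (a209 * g(222, 209, s209) + a192 * g(222, 192, s192))
  den <- g(222, 222, s222) - r * g(209, 222, s222)
  a222 <- num / den
  y <- a192 * g(wavelengths, 192, s192) +
    a209 * g(wavelengths, 209, s209) +
    a222 * g(wavelengths, 222, s222)
  out <- tibble(wavelength = wavelengths, ellipticity = y)
  attr(out, "label") <- kind
  out
}
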