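# Core packing and interhelical electrostatics: knobs-into-holes contacts
# and salt bridges, classified by heptad position.

# side-chain centers: mean of non-backbone heavy atoms; CB when only CB is
# present; residues with neither are skipped
side_chain_centers <- function(model) {
  backbone <- c("N", "CA", "C", "O", "OXT")
  sc <- model[!(model$atom %in% backbone) & model$element != "H", , drop = FALSE]
  if (nrow(sc) == 0) {
    return(tibble(chain = character(), seq_id = integer(),
                  x = double(), y = double(), z = double()))
  }
  sc |>
    group_by(.data$chain, .data$seq_id) |>
    summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
              .groups = "drop")
}

#' Detect knobs-into-holes core packing
#'
#' A residue is a knob when its side-chain center has at least four
#' side-chain centers of one other chain within `center_cutoff`; the four
#' nearest of these form the hole. This is a side-chain-center
#' simplification of the classic all-atom packing criterion sufficient for
#' core topology. Contacts are reported sorted along the superhelical axis.
#'
#' @param model A `cc_structure`.
#' @param fit Optional `cc_fit` supplying registers and the axis for
#'   sorting; without it knob registers are `"?"` and contacts sort by z.
#' @param center_cutoff Center-center cutoff, Angstrom (default 7).
#' @return Tibble with one row per knob-hole contact: `chain`, `seq_id`,
#'   `knob_register`, `hole_chain`, `hole_res` (list column of 4 residue
#'   numbers), `center_distances` (list column), `axial` (position along
#'   the axis).
#' @export
detect_kih <- function(model, fit = NULL, center_cutoff = 7.0) {
  ctr <- side_chain_centers(model)
  if (nrow(ctr) == 0) abort("no side-chain information in structure")
  reg <- if (!is.null(fit)) fit$residues else NULL
  fr <- if (!is.null(fit)) axis_frame(fit$axis) else NULL
  xyz <- as.matrix(ctr[, c("x", "y", "z")])
  axial <- if (!is.null(fr)) frame_coords(xyz, fr)$s else ctr$z
  rows <- list()
  for (i in seq_len(nrow(ctr))) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    for (ch in setdiff(unique(ctr$chain), ctr$chain[i])) {
      sel <- which(ctr$chain == ch & sqrt(d2) <= center_cutoff)
      if (length(sel) >= 4) {
        nearest <- sel[order(d2[sel])][1:4]
        r <- if (!is.null(reg)) {
          hit <- reg$register[reg$chain == ctr$chain[i] &
                                reg$seq_id == ctr$seq_id[i]]
          if (length(hit) == 1) hit else "?"
        } else "?"
        rows[[length(rows) + 1]] <- tibble(
          chain = ctr$chain[i], seq_id = ctr$seq_id[i], knob_register = r,
          hole_chain = ch,
          hole_res = list(ctr$seq_id[nearest]),
          center_distances = list(sqrt(d2[nearest])),
          axial = axial[i]
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(chain = character(), seq_id = integer(),
                  knob_register = character(), hole_chain = character(),
                  hole_res = list(), center_distances = list(),
                  axial = double()))
  }
  bind_rows(rows) |> arrange(.data$axial, .data$chain, .data$seq_id)
}

#' Summarise knob layers along the axis
#'
#' Groups knob contacts into layers by their axial coordinate (a new layer
#' starts when the gap to the previous contact exceeds `gap`), reports the
#' register composition of each layer and whether consecutive layer types
#' alternate between `a` and `d`.
#'
#' @param kih Output of [detect_kih()].
#' @param gap Axial gap opening a new layer, Angstrom (default 2).
#' @param core_only Restrict to `a`/`d` knobs (default), the layers whose
#'   alternation defines canonical core packing; set `FALSE` to stratify
#'   every knob.
#' @return List with `layers` (tibble: layer, axial_center, n_knobs,
#'   registers, type) and `alternating` (flag; `NA` when any layer type is
#'   mixed or unknown).
#' @export
layer_summary <- function(kih, gap = 2.0, core_only = TRUE) {
  if (core_only) kih <- kih |> filter(.data$knob_register %in% c("a", "d", "?"))
  if (nrow(kih) == 0) abort("no knob contacts to summarise")
  k <- kih |> distinct(.data$chain, .data$seq_id, .data$knob_register,
                       .data$axial) |> arrange(.data$axial)
  layer <- cumsum(c(1, diff(k$axial) > gap))
  layers <- k |>
    mutate(layer = layer) |>
    group_by(layer) |>
    summarise(
      axial_center = mean(.data$axial), n_knobs = dplyr::n(),
      registers = paste(sort(unique(.data$knob_register)), collapse = ""),
      .groups = "drop"
    ) |>
    mutate(type = dplyr::case_when(
      .data$registers == "a" ~ "a",
      .data$registers == "d" ~ "d",
      TRUE ~ "mixed"
    ))
  alternating <- if (nrow(layers) == 1) {
    TRUE
  } else if (any(layers$type == "mixed")) {
    NA
  } else {
    all(layers$type[-1] != layers$type[-nrow(layers)])
  }
  list(layers = layers, alternating = alternating)
}

# charged-group atoms per residue type
basic_atoms <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"))
acidic_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Detect salt bridges between charged residues
#'
#' One bridge per basic/acidic residue pair whose minimal distance between
#' charged heavy atoms (Lys NZ; Arg NH1/NH2/NE; Asp OD1/OD2; Glu OE1/OE2)
#' is within `cutoff`. Histidine is not counted as basic. The position
#' class joins the two heptad registers, basic residue first (e.g.
#' `"c-c"`, `"g-c"`, `"b-b"`); without a fit it is `"?-?"`.
#'
#' @param model A `cc_structure`.
#' @param fit Optional `cc_fit` for register lookup.
#' @param cutoff Charged-atom distance cutoff, Angstrom (default 4).
#' @param scope `"inter"`, `"intra"` or `"both"` chain pairs (default
#'   inter; intramolecular bridges are a separate question).
#' @return Tibble with one row per bridge: basic and acidic residue ids,
#'   `min_distance`, `type` (inter/intra) and `position_class`.
#' @export
detect_salt_bridges <- function(model, fit = NULL, cutoff = 4.0,
                                scope = c("inter", "intra", "both")) {
  scope <- match.arg(scope)
  pick <- function(spec) {
    out <- model[model$res_name %in% names(spec), , drop = FALSE]
    keep <- mapply(function(rn, at) at %in% spec[[rn]], out$res_name, out$atom)
    out[as.logical(keep), , drop = FALSE]
  }
  bas <- pick(basic_atoms)
  aci <- pick(acidic_atoms)
  if (nrow(bas) == 0 || nrow(aci) == 0) {
    return(tibble(chain_basic = character(), res_basic = integer(),
                  name_basic = character(), chain_acidic = character(),
                  res_acidic = integer(), name_acidic = character(),
                  min_distance = double(), type = character(),
                  position_class = character()))
  }
  reg <- if (!is.null(fit)) fit$residues else NULL
  if (is.null(reg)) warn("no geometry fit supplied; position classes are '?-?'")
  lookup_reg <- function(ch, id) {
    if (is.null(reg)) return("?")
    hit <- reg$register[reg$chain == ch & reg$seq_id == id]
    if (length(hit) == 1) hit else "?"
  }
  bx <- coords_matrix(bas); ax <- coords_matrix(aci)
  rows <- list()
  bres <- unique(bas[, c("chain", "seq_id", "res_name")])
  ares <- unique(aci[, c("chain", "seq_id", "res_name")])
  for (i in seq_len(nrow(bres))) {
    bi <- bas$chain == bres$chain[i] & bas$seq_id == bres$seq_id[i]
    for (j in seq_len(nrow(ares))) {
      same <- bres$chain[i] == ares$chain[j]
      if ((scope == "inter" && same) || (scope == "intra" && !same)) next
      aj <- aci$chain == ares$chain[j] & aci$seq_id == ares$seq_id[j]
      dm <- sqrt(outer(rowSums(bx[bi, , drop = FALSE]^2), rep(1, sum(aj))) +
                   outer(rep(1, sum(bi)), rowSums(ax[aj, , drop = FALSE]^2)) -
                   2 * bx[bi, , drop = FALSE] %*% t(ax[aj, , drop = FALSE]))
      mind <- min(dm)
      if (mind <= cutoff) {
        rows[[length(rows) + 1]] <- tibble(
          chain_basic = bres$chain[i], res_basic = bres$seq_id[i],
          name_basic = bres$res_name[i],
          chain_acidic = ares$chain[j], res_acidic = ares$seq_id[j],
          name_acidic = ares$res_name[j],
          min_distance = mind,
          type = if (same) "intra" else "inter",
          position_class = paste0(
            lookup_reg(bres$chain[i], bres$seq_id[i]), "-",
            lookup_reg(ares$chain[j], ares$seq_id[j]))
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(chain_basic = character(), res_basic = integer(),
                  name_basic = character(), chain_acidic = character(),
                  res_acidic = integer(), name_acidic = character(),
                  min_distance = double(), type = character(),
                  position_class = character()))
  }
  bind_rows(rows) |> arrange(.data$chain_basic, .data$res_basic)
}
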