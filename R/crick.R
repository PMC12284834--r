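# Ideal coiled-coil bundle construction from Crick parameters.
#
# The builder is the package's ground-truth generator: every geometric
# quantity the fitting module recovers (radius, pitch, handedness,
# orientation, stagger, register) is known exactly by construction.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
wrap180 <- function(x) ((x + 180) %% 360) - 180

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) abort("cannot normalize a zero vector")
  v / n
}

#' Crick parameters for an ideal coiled-coil bundle
#'
#' Parameter set for the closed-form Crick backbone parameterization of a
#' 2-4 helix bundle. Defaults are the canonical heptad coiled coil
#' (helix radius 2.26 Angstrom, rise 1.51 Angstrom per residue, 3.5
#' residues per turn in the supercoil frame, left-handed supercoil) at the
#' honeybee-silk superhelical radius and pitch.
#'
#' @param n_chains Number of helices (2-4).
#' @param orientations Per-chain `"U"`/`"D"` along the supercoil axis.
#' @param r0 Superhelical radius, Angstrom (> 0).
#' @param pitch Superhelical pitch, Angstrom (> 0; handedness is separate).
#' @param handedness `"left"` or `"right"` supercoil.
#' @param r1 Alpha-helix (minor) radius, Angstrom.
#' @param rise Rise per residue along the helix axis, Angstrom.
#' @param res_per_turn Residues per helical turn in the supercoil frame.
#' @param n_res Residues per chain (>= 8).
#' @param phase0 Per-chain supercoil azimuth of residue 1, degrees
#'   (recycled; default equally spaced around the bundle).
#' @param phase1 Per-chain Crick phase offset of residue 1, degrees
#'   (recycled). The default threads heptad position `a` at residue 1 with
#'   the a/d core facing the bundle axis.
#' @param stagger Per-chain axial offset, Angstrom (recycled).
#' @return A list of class `crick_params`.
#' @export
crick_params <- function(n_chains = 4,
                         orientations = rep(c("U", "D"), length.out = n_chains),
                         r0 = 5.8, pitch = 153, handedness = c("left", "right"),
                         r1 = 2.26, rise = 1.51, res_per_turn = 3.5,
                         n_res = 168,
                         phase0 = seq(0, 360, length.out = n_chains + 1)[seq_len(n_chains)],
                         phase1 = 180 + rad2deg(atan2(sin(deg2rad(360 / res_per_turn / 2)), 1 + cos(deg2rad(360 / res_per_turn / 2)))),
                         stagger = 0) {
  handedness <- match.arg(handedness)
  if (r0 <= 0) abort("r0 must be positive")
  if (pitch <= 0) abort("pitch must be positive")
  if (n_res < 8) abort("n_res must be at least 8")
  if (!n_chains %in% 2:4) abort("n_chains must be 2, 3 or 4")
  orientations <- rep(orientations, length.out = n_chains)
  if (!all(orientations %in% c("U", "D"))) abort("orientations must be 'U' or 'D'")
  p <- list(
    n_chains = n_chains, orientations = orientations, r0 = r0, pitch = pitch,
    handedness = handedness, r1 = r1, rise = rise, res_per_turn = res_per_turn,
    n_res = as.integer(n_res),
    phase0 = rep(phase0, length.out = n_chains),
    phase1 = rep(phase1, length.out = n_chains),
    stagger = rep(stagger, length.out = n_chains)
  )
  structure(p, class = "crick_params")
}

#' @export
print.crick_params <- function(x, ...) {
  cat(sprintf(
    "<crick_params> %d chains (%s), r0 %.2f A, pitch %.1f A (%s), %d res/chain\n",
    x$n_chains, paste(x$orientations, collapse = ""), x$r0, x$pitch,
    x$handedness, x$n_res))
  invisible(x)
}

#' Silk-tetramer parameter preset
#'
#' The antiparallel four-helix bundle preset matching the honeybee silk
#' heterotetramer: chains F1(U), F2(U), F3(D), F4(D) placed so the cyclic
#' arrangement viewed from the positive axis end is clockwise F1-F3-F2-F4,
#' at superhelical radius 5.8 Angstrom and pitch 153 Angstrom with
#' 168-residue (24-heptad) chains.
#'
#' @param ... Overrides passed to [crick_params()].
#' @return A `crick_params` object carrying chain ids F1-F4.
#' @export
silk_params <- function(...) {
  args <- utils::modifyList(list(
    n_chains = 4, orientations = c("U", "U", "D", "D"),
    r0 = 5.8, pitch = 153, n_res = 168,
    phase0 = c(0, 180, 270, 90)
  ), list(...))
  p <- do.call(crick_params, args)
  attr(p, "chain_ids") <- c("F1", "F2", "F3", "F4")
  p
}

# core Crick coordinate engine for one U chain (no stagger):
# returns list of CA (n x 3), CB (n x 3), axis path (n x 3)
crick_chain_xyz <- function(p, phase0_deg, phase1_deg) {
  i <- seq_len(p$n_res) - 1
  alpha <- atan(2 * pi * p$r0 / p$pitch)
  sgn <- if (p$handedness == "left") -1 else 1
  w0 <- sgn * 2 * pi * (p$rise * cos(alpha)) / p$pitch   # rad per residue
  w1 <- 2 * pi / p$res_per_turn                          # rad per residue
  h <- p$rise * cos(alpha)                               # axial rise per residue
  th <- w0 * i + deg2rad(phase0_deg)
  ph <- w1 * i + deg2rad(phase1_deg)
  ca <- cbind(
    p$r0 * cos(th) + p$r1 * (cos(th) * cos(ph) - cos(alpha) * sin(th) * sin(ph)),
    p$r0 * sin(th) + p$r1 * (sin(th) * cos(ph) + cos(alpha) * cos(th) * sin(ph)),
    h * i - p$r1 * sin(alpha) * sin(ph)
  )
  axis <- cbind(p$r0 * cos(th), p$r0 * sin(th), h * i)
  # local axis tangent (analytic derivative of the supercoil path)
  tang <- cbind(-p$r0 * w0 * sin(th), p$r0 * w0 * cos(th), rep(h, length(i)))
  tang <- tang / sqrt(rowSums(tang^2))
  # CB pseudo-atom: 1.53 A from CA along the outward radial direction from
  # the local helix axis (purely radial; no tetrahedral tilt)
  u <- if (p$r1 > 0) ca - axis else cbind(cos(th), sin(th), 0 * th)
  u <- u - tang * rowSums(u * tang)
  u <- u / sqrt(rowSums(u^2))
  cb <- ca + 1.53 * u
  list(ca = ca, cb = cb, axis = axis, w0 = w0, h = h, alpha = alpha)
}

rot_x180 <- function(m) cbind(m[, 1], -m[, 2], -m[, 3])
rot_z <- function(m, ang) {
  cbind(cos(ang) * m[, 1] - sin(ang) * m[, 2],
        sin(ang) * m[, 1] + cos(ang) * m[, 2], m[, 3])
}

#' Ground-truth register implied by a Crick phase offset
#'
#' Given the true per-residue Crick phase (angle about the local helix axis,
#' 0 = pointing at the supercoil axis), picks the cyclic heptad offset whose
#' a/d positions face the core most directly (maximal mean cosine), ties to
#' the smallest offset, and returns the per-residue register letters.
#'
#' @param phase1_deg Crick phase offset of residue 1 in the builder's
#'   convention (0 = pointing away from the supercoil axis).
#' @param n_res Number of residues.
#' @param res_per_turn Residues per turn in the supercoil frame.
#' @return Character vector of register letters, length `n_res`.
#' @export
register_from_phase <- function(phase1_deg, n_res, res_per_turn = 3.5) {
  i <- seq_len(n_res) - 1
  # builder phase measures from the outward radial; Crick phase from inward
  psi <- wrap180(360 / res_per_turn * i + phase1_deg - 180)
  assign_offsets(psi)$register
}

# shared 7-offset register search: psi in degrees (0 = core-facing),
# NA allowed; returns list(register (letters for all indices), offset, score)
assign_offsets <- function(psi) {
  idx <- seq_along(psi) - 1
  scores <- vapply(0:6, function(k) {
    sel <- ((idx + k) %% 7) %in% c(0, 3) & !is.na(psi)
    if (!any(sel)) return(-Inf)
    mean(cos(deg2rad(psi[sel])))
  }, numeric(1))
  k <- which.max(scores) - 1L  # which.max returns the first max: smallest offset
  list(register = heptad_letters()[((idx + k) %% 7) + 1],
       offset = k, scores = scores)
}

#' Build an ideal coiled-coil bundle
#'
#' Generates CA coordinates (plus radial CB pseudo-atoms) for an ideal
#' bundle following the Crick parameterization, threads a sequence, and
#' attaches the generative ground truth (parameters, per-residue register,
#' sequences). Chains with orientation `D` are built as `U` and rigidly
#' rotated 180 degrees about an in-plane axis, which preserves both the
#' alpha-helix chirality and the supercoil handedness; the rotated chain is
#' then replaced on the same superhelical track so that `phase0` and
#' `stagger` keep their meaning.
#'
#' @param params A [crick_params()] object.
#' @param sequence Optional per-chain one-letter sequences (recycled). By
#'   default a silk-like alanine-rich sequence is drawn with
#'   [silk_sequence()] using `seed`.
#' @param chain_ids Chain identifiers; default `A`, `B`, ... or the ids
#'   attached by [silk_params()].
#' @param seed Seed for the default sequence draw.
#' @return A `cc_structure` with attribute `ground_truth` (see
#'   [ground_truth()]).
#' @export
build_bundle <- function(params, sequence = NULL, chain_ids = NULL, seed = 1L) {
  stopifnot(inherits(params, "crick_params"))
  p <- params
  ids <- chain_ids %||% attr(params, "chain_ids") %||% LETTERS[seq_len(p$n_chains)]
  registers <- lapply(seq_len(p$n_chains), function(c) {
    register_from_phase(p$phase1[c], p$n_res, p$res_per_turn)
  })
  if (is.null(sequence)) {
    sequence <- vapply(seq_len(p$n_chains), function(c) {
      silk_sequence(registers[[c]], seed = seed + c - 1L)
    }, character(1))
  }
  sequence <- rep(sequence, length.out = p$n_chains)
  if (any(nchar(sequence) != p$n_res)) {
    abort("each sequence must have exactly n_res residues")
  }
  chains <- lapply(seq_len(p$n_chains), function(c) {
    xyz <- crick_chain_xyz(p, p$phase0[c], p$phase1[c])
    ca <- xyz$ca; cb <- xyz$cb
    if (p$orientations[c] == "D") {
      delta <- 2 * deg2rad(p$phase0[c]) + xyz$w0 * (p$n_res - 1)
      shift <- (p$n_res - 1) * xyz$h
      ca <- rot_z(rot_x180(ca), delta); ca[, 3] <- ca[, 3] + shift
      cb <- rot_z(rot_x180(cb), delta); cb[, 3] <- cb[, 3] + shift
    }
    ca[, 3] <- ca[, 3] + p$stagger[c]
    cb[, 3] <- cb[, 3] + p$stagger[c]
    aa <- strsplit(sequence[c], "")[[1]]
    res3 <- unname(aa_one_to_three[aa])
    res3[is.na(res3)] <- "UNK"
    n <- p$n_res
    tibble(
      chain = ids[c],
      seq_id = rep(seq_len(n), each = 2),
      res_name = rep(res3, each = 2),
      atom = rep(c("CA", "CB"), n),
      element = "C",
      x = as.vector(rbind(ca[, 1], cb[, 1])),
      y = as.vector(rbind(ca[, 2], cb[, 2])),
      z = as.vector(rbind(ca[, 3], cb[, 3]))
    )
  })
  model <- cc_structure(bind_rows(chains), title = "ideal Crick bundle")
  truth <- list(
    params = p,
    chain_ids = ids,
    register = bind_rows(lapply(seq_len(p$n_chains), function(c) {
      tibble(chain = ids[c], seq_id = seq_len(p$n_res), register = registers[[c]])
    })),
    sequence = setNames(sequence, ids)
  )
  attr(model, "ground_truth") <- truth
  model
}

#' Ground truth attached to a synthetic structure
#'
#' @param model A structure produced by [build_bundle()].
#' @return List with elements `params`, `chain_ids`, `register` (tibble of
#'   chain, seq_id, register) and `sequence` (named character vector), or
#'   `NULL` if the structure carries no ground truth.
#' @export
ground_truth <- function(model) attr(model, "ground_truth")

#' Draw a silk-like sequence for a given register
#'
#' Samples residues position-by-position with alanine strongly enriched at
#' the core (`a`, `d`) and core-flanking (`e`, `g`) heptad positions, and
#' polar/charged residues (including the lysines an amine crosslinker needs)
#' at the outward-facing `b`, `c`, `f` positions -- the composition pattern
#' of the silk coiled-coil domain.
#'
#' @param register Character vector of heptad letters, one per residue.
#' @param seed Integer seed.
#' @return One-letter sequence string.
#' @export
silk_sequence <- function(register, seed = 1L) {
  pools <- list(
    core = c(A = 0.55, S = 0.12, V = 0.10, L = 0.08, I = 0.05, T = 0.05, M = 0.05),
    surf = c(K = 0.18, E = 0.18, D = 0.08, Q = 0.12, N = 0.10, S = 0.12,
             T = 0.08, R = 0.08, L = 0.03, A = 0.03)
  )
  withr::with_seed(seed, {
    vapply(register, function(r) {
      pool <- if (r %in% c("a", "d", "e", "g")) pools$core else pools$surf
      sample(names(pool), 1, prob = pool)
    }, character(1)) |> paste(collapse = "")
  })
}

#' Add isotropic coordinate noise
#'
#' Displaces every atom by an isotropic Gaussian with the given per-axis
#' standard deviation; reproducible under `seed`.
#'
#' @param model A `cc_structure`.
#' @param noise_sd Per-axis displacement standard deviation, Angstrom (>= 0).
#' @param seed Integer seed.
#' @return The perturbed `cc_structure` (ground truth, if any, is kept).
#' @export
perturb <- function(model, noise_sd, seed = 1L) {
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (noise_sd == 0) return(model)
  n <- nrow(model)
  withr::with_seed(seed, {
    model$x <- model$x + rnorm(n, sd = noise_sd)
    model$y <- model$y + rnorm(n, sd = noise_sd)
    model$z <- model$z + rnorm(n, sd = noise_sd)
  })
  model
}
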