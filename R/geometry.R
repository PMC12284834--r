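# Coiled-coil geometry fitting: local helix axes, superhelical axis line,
# radius/pitch/handedness, chain orientations, cyclic arrangement, axial
# stagger, per-residue Crick phase and heptad register.

#' Local helix axis points of each chain
#'
#' Smooths each chain's CA trace with a sliding window of `window`
#' consecutive residues: the window centroid lies exactly on the local helix
#' axis for an ideal helix with 3.5 residues per turn (window 7), and very
#' nearly so under noise. Tangents are normalized central differences of
#' neighbouring centroids. The first and last `(window - 1) / 2` residues
#' have no full window and are omitted.
#'
#' @param model A `cc_structure`.
#' @param window Odd window length (default 7).
#' @return Tibble with columns `chain`, `seq_id` (window-centre residue),
#'   `ax`, `ay`, `az` (axis point) and `tx`, `ty`, `tz` (unit tangent; `NA`
#'   for a single-point chain).
#' @export
local_axis <- function(model, window = 7) {
  if (window %% 2 != 1 || window < 3) abort("window must be odd and >= 3")
  out <- lapply(chain_ids(model), function(ch) {
    ca <- ca_trace(model, ch)
    n <- nrow(ca)
    if (n < window) {
      abort(sprintf("chain %s has %d CA atoms; need at least %d", ch, n, window))
    }
    if (any(diff(ca$seq_id) != 1)) {
      abort(sprintf("chain %s has gaps in its CA trace", ch))
    }
    xyz <- coords_matrix(ca)
    m <- n - window + 1
    # window centroids via cumulative sums
    cs <- rbind(0, apply(xyz, 2, cumsum))
    cen <- (cs[(window + 1):(n + 1), , drop = FALSE] -
              cs[1:m, , drop = FALSE]) / window
    half <- (window - 1) / 2
    tang <- matrix(NA_real_, m, 3)
    if (m >= 2) {
      for (j in seq_len(m)) {
        lo <- max(1, j - 1); hi <- min(m, j + 1)
        v <- cen[hi, ] - cen[lo, ]
        tang[j, ] <- v / sqrt(sum(v^2))
      }
    }
    tibble(chain = ch, seq_id = ca$seq_id[(half + 1):(n - half)],
           ax = cen[, 1], ay = cen[, 2], az = cen[, 3],
           tx = tang[, 1], ty = tang[, 2], tz = tang[, 3])
  })
  bind_rows(out)
}

#' Total-least-squares superhelical axis line
#'
#' First principal direction of the pooled axis-point cloud, anchored at the
#' centroid. The direction is signed so that the first chain runs N to C
#' along the positive axis.
#'
#' @param axis_points Output of [local_axis()].
#' @return List with unit `direction`, `origin` and the residual RMS
#'   perpendicular distance `rms`.
#' @export
fit_axis_line <- function(axis_points) {
  pts <- as.matrix(axis_points[, c("ax", "ay", "az")])
  if (nrow(pts) < 3) abort("need at least 3 axis points")
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  if (max(abs(cen)) < 1e-9) abort("axis points are degenerate (coincident)")
  sv <- svd(cen, nu = 0, nv = 3)
  d <- sv$v[, 1]
  first <- axis_points[axis_points$chain == axis_points$chain[1], ]
  nc <- as.numeric(first[nrow(first), c("ax", "ay", "az")]) -
    as.numeric(first[1, c("ax", "ay", "az")])
  if (sum(nc * d) < 0) d <- -d
  perp <- cen - outer(as.vector(cen %*% d), d)
  list(direction = d, origin = ctr, rms = sqrt(mean(rowSums(perp^2))))
}

# right-handed frame (u, v, d): azimuth = atan2(.v, .u), axial = .d
axis_frame <- function(line) {
  d <- unit(line$direction)
  e <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit(e - sum(e * d) * d)
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v, d = d, origin = line$origin)
}

# axial coordinate and azimuth (radians) of points (n x 3) in a frame
frame_coords <- function(pts, fr) {
  rel <- sweep(pts, 2, fr$origin)
  list(s = as.vector(rel %*% fr$d),
       theta = atan2(as.vector(rel %*% fr$v), as.vector(rel %*% fr$u)),
       radial = sqrt(as.vector(rel %*% fr$u)^2 + as.vector(rel %*% fr$v)^2))
}

unwrap <- function(theta) {
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(theta[1], d))
}

#' Superhelical radius, pitch and handedness
#'
#' Radius is the mean perpendicular distance of the axis points to the
#' fitted line, corrected for the radial shrinkage of a `window`-point
#' centroid on a curved track (the analytic factor
#' `(1 + 2 * sum cos(k * w0)) / window` estimated from the fitted azimuth
#' slope). Pitch comes from regressing the unwrapped azimuth on the axial
#' coordinate per chain and averaging `2 * pi / |slope|`. Handedness is the
#' slope sign in a right-handed frame whose third vector is the positive
#' axis: decreasing azimuth with increasing axial coordinate is left-handed.
#' Below `slope_min` (default the slope of a 2000 Angstrom pitch) the bundle
#' is called straight: handedness `"none"`, pitch `NA`.
#'
#' @param axis_points Output of [local_axis()].
#' @param line Output of [fit_axis_line()].
#' @param window Window used in [local_axis()] (for the radius correction).
#' @param slope_min Minimum |dtheta/ds| (rad per Angstrom) for a supercoil.
#' @return List with `r0`, `pitch`, `handedness`, per-chain tibble `chains`
#'   (slope, pitch, turns spanned) and `low_confidence` flag (less than two
#'   turns of axial extent).
#' @export
fit_radius_pitch <- function(axis_points, line, window = 7,
                             slope_min = 2 * pi / 2000) {
  fr <- axis_frame(line)
  per_chain <- lapply(split(axis_points, axis_points$chain), function(apc) {
    fc <- frame_coords(as.matrix(apc[, c("ax", "ay", "az")]), fr)
    th <- unwrap(fc$theta)
    fit <- lm(th ~ fc$s)
    tibble(chain = apc$chain[1], slope = coef(fit)[2],
           turns = abs(diff(range(th))) / (2 * pi),
           mean_radial = mean(fc$radial),
           spacing = abs(coef(lm(fc$s ~ seq_along(fc$s)))[2]))
  })
  pc <- bind_rows(per_chain)
  mean_slope <- mean(pc$slope)
  straight <- all(abs(pc$slope) < slope_min)
  if (straight) {
    return(list(r0 = mean(pc$mean_radial), pitch = NA_real_,
                handedness = "none", chains = pc, low_confidence = FALSE))
  }
  pitch <- 2 * pi / mean(abs(pc$slope))
  handed <- if (mean_slope < 0) "left" else "right"
  # centroid shrinkage correction: per-residue angular step on the track
  w0 <- mean(abs(pc$slope) * pc$spacing)
  k <- seq_len((window - 1) / 2)
  shrink <- (1 + 2 * sum(cos(k * w0))) / window
  list(r0 = mean(pc$mean_radial) / shrink, pitch = pitch,
       handedness = handed, chains = pc,
       low_confidence = any(pc$turns < 2))
}

#' Chain orientation along the axis
#'
#' `U` if the chain's CA trace runs N to C with positive projection on the
#' axis direction, `D` otherwise.
#'
#' @param model A `cc_structure`.
#' @param line Axis line (list with `direction`), e.g. from
#'   [fit_axis_line()].
#' @return Tibble with columns `chain`, `orientation`.
#' @export
chain_orientation <- function(model, line) {
  d <- unit(line$direction)
  out <- lapply(chain_ids(model), function(ch) {
    ca <- ca_trace(model, ch)
    v <- as.numeric(ca[nrow(ca), c("x", "y", "z")]) -
      as.numeric(ca[1, c("x", "y", "z")])
    pr <- sum(v * d)
    if (abs(pr) < 1e-6 * sqrt(sum(v^2))) {
      abort(sprintf("chain %s runs perpendicular to the axis", ch))
    }
    tibble(chain = ch, orientation = if (pr > 0) "U" else "D")
  })
  bind_rows(out)
}

#' Cyclic chain arrangement viewed from the positive axis end
#'
#' Chains are ordered by clockwise azimuth of their axis-point centroids as
#' seen by an observer on the positive axis end looking back along the axis
#' (in the right-handed frame this is decreasing azimuth), starting at the
#' first chain.
#'
#' @param axis_points Output of [local_axis()].
#' @param line Axis line.
#' @return Character vector: the cyclic chain order.
#' @export
arrangement_order <- function(axis_points, line) {
  chains <- unique(axis_points$chain)
  if (length(chains) < 3) return(chains)
  fr <- axis_frame(line)
  az <- vapply(chains, function(ch) {
    apc <- axis_points[axis_points$chain == ch, ]
    ctr <- colMeans(as.matrix(apc[, c("ax", "ay", "az")]))
    fc <- frame_coords(matrix(ctr, 1), fr)
    fc$theta
  }, numeric(1))
  if (any(duplicated(round(az, 6)))) {
    abort("two chains sit at identical azimuth; arrangement undefined")
  }
  rel <- (az[1] - az) %% (2 * pi)  # clockwise angle from chain 1
  chains[order(rel)]
}

#' Axial stagger of each chain
#'
#' Projection of each chain's axis-point midpoint (mean of the extreme
#' axial coordinates) onto the axis, reported relative to the first chain.
#'
#' @param axis_points Output of [local_axis()].
#' @param line Axis line.
#' @return Tibble with columns `chain`, `stagger` (Angstrom).
#' @export
axial_stagger <- function(axis_points, line) {
  fr <- axis_frame(line)
  mids <- vapply(unique(axis_points$chain), function(ch) {
    apc <- axis_points[axis_points$chain == ch, ]
    s <- frame_coords(as.matrix(apc[, c("ax", "ay", "az")]), fr)$s
    (max(s) + min(s)) / 2
  }, numeric(1))
  tibble(chain = unique(axis_points$chain),
         stagger = unname(mids - mids[1]))
}

#' Axial extent of the coiled coil
#'
#' Span between the extreme axis points over all chains, along the axis.
#'
#' @param axis_points Output of [local_axis()].
#' @param line Axis line.
#' @return Length in Angstrom.
#' @export
coil_extent <- function(axis_points, line) {
  fr <- axis_frame(line)
  s <- frame_coords(as.matrix(axis_points[, c("ax", "ay", "az")]), fr)$s
  diff(range(s))
}

# per-residue Crick phase (degrees): signed angle, in the plane normal to
# the local tangent, from (helix axis point -> superhelix axis) to
# (helix axis point -> CA); 0 = side chain pointing at the supercoil axis
crick_phases <- function(model, axis_points, line) {
  fr <- axis_frame(line)
  out <- lapply(unique(axis_points$chain), function(ch) {
    apc <- axis_points[axis_points$chain == ch, ]
    ca <- ca_trace(model, ch)
    ca <- ca[match(apc$seq_id, ca$seq_id), ]
    A <- as.matrix(apc[, c("ax", "ay", "az")])
    Tg <- as.matrix(apc[, c("tx", "ty", "tz")])
    P <- sweep(outer(as.vector(sweep(A, 2, fr$origin) %*% fr$d), fr$d), 2,
               -fr$origin)  # projection of A onto the line
    v1 <- P - A
    v2 <- coords_matrix(ca) - A
    proj_out <- function(M) M - Tg * rowSums(M * Tg)
    v1 <- proj_out(v1); v2 <- proj_out(v2)
    n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
    v1 <- v1 / n1; v2 <- v2 / n2
    crossp <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
                    v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
                    v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
    psi <- atan2(rowSums(crossp * Tg), rowSums(v1 * v2))
    tibble(chain = ch, seq_id = apc$seq_id, crick_phase = rad2deg(psi))
  })
  bind_rows(out)
}

#' Assign heptad register from fitted Crick phases
#'
#' For each chain, all seven cyclic offsets of the periodic `a`-`g`
#' assignment are scored by the mean cosine of the Crick phase over the
#' residues labelled `a` or `d` (the core must face the supercoil axis); the
#' maximizing offset wins, ties going to the smallest offset. The winning
#' periodic assignment is extended over the whole chain, including the
#' window-trimmed ends where no Crick phase is defined. `n_heptads` counts
#' complete consecutive `a`-to-`g` periods.
#'
#' @param model A `cc_structure`.
#' @param axis_points Output of [local_axis()].
#' @param line Axis line.
#' @return List with `residues` (tibble: chain, seq_id, crick_phase,
#'   register), `n_heptads` (named integer per chain) and `offsets` (named
#'   integer per chain).
#' @export
assign_register <- function(model, axis_points, line) {
  phases <- crick_phases(model, axis_points, line)
  res <- residue_table(model)
  out <- lapply(chain_ids(model), function(ch) {
    resc <- res[res$chain == ch, ]
    if (nrow(resc) < 7) abort(sprintf("chain %s shorter than one heptad", ch))
    ph <- phases[phases$chain == ch, ]
    psi <- rep(NA_real_, nrow(resc))
    psi[match(ph$seq_id, resc$seq_id)] <- ph$crick_phase
    fit <- assign_offsets(psi)
    reg <- fit$register
    first_a <- match("a", reg)
    nhep <- if (is.na(first_a)) 0L else as.integer((nrow(resc) - first_a + 1) %/% 7)
    list(residues = tibble(chain = ch, seq_id = resc$seq_id,
                           crick_phase = psi, register = reg),
         n_heptads = nhep, offset = fit$offset)
  })
  list(
    residues = bind_rows(lapply(out, `[[`, "residues")),
    n_heptads = setNames(vapply(out, `[[`, integer(1), "n_heptads"),
                         chain_ids(model)),
    offsets = setNames(vapply(out, `[[`, integer(1), "offset"),
                       chain_ids(model))
  )
}

#' Fit the full coiled-coil geometry of a bundle
#'
#' Convenience wrapper chaining [local_axis()], [fit_axis_line()],
#' [fit_radius_pitch()], [chain_orientation()], [arrangement_order()],
#' [axial_stagger()], [assign_register()] and [coil_extent()].
#'
#' @param model A `cc_structure`.
#' @param window Sliding-window length for the local axis (default 7).
#' @return An object of class `cc_fit`: a list with elements `r0`, `pitch`,
#'   `handedness`, `axis` (origin/direction/rms), `chains` (tibble with
#'   orientation and stagger per chain), `arrangement`, `extent`,
#'   `n_heptads`, `residues` (per-residue Crick phase and register) and
#'   `low_confidence`.
#' @export
fit_coiled_coil <- function(model, window = 7) {
  ap <- local_axis(model, window = window)
  line <- fit_axis_line(ap)
  rp <- fit_radius_pitch(ap, line, window = window)
  ori <- chain_orientation(model, line)
  arr <- if (length(chain_ids(model)) >= 3) arrangement_order(ap, line) else chain_ids(model)
  stag <- axial_stagger(ap, line)
  reg <- assign_register(model, ap, line)
  chains <- ori |> left_join(stag, by = "chain")
  chains$n_heptads <- unname(reg$n_heptads[chains$chain])
  structure(list(
    r0 = rp$r0, pitch = rp$pitch, handedness = rp$handedness,
    axis = line, chains = chains, arrangement = arr,
    extent = coil_extent(ap, line),
    n_heptads = reg$n_heptads, offsets = reg$offsets,
    residues = reg$residues, axis_points = ap,
    low_confidence = rp$low_confidence, window = window
  ), class = "cc_fit")
}

#' @export
print.cc_fit <- function(x, ...) {
  cat("<cc_fit> coiled-coil geometry fit\n")
  cat(sprintf("  radius %.2f A, pitch %s, handedness %s\n", x$r0,
              if (is.na(x$pitch)) "NA (straight)" else sprintf("%.1f A", x$pitch),
              x$handedness))
  cat(sprintf("  chains: %s\n", paste0(
    x$chains$chain, "(", x$chains$orientation, ")", collapse = " ")))
  cat(sprintf("  arrangement (clockwise from +axis): %s\n",
              paste(x$arrangement, collapse = "-")))
  cat(sprintf("  extent %.1f A, heptads per chain: %s\n", x$extent,
              paste(x$n_heptads, collapse = ", ")))
  invisible(x)
}

#' @rdname fit_coiled_coil
#' @param x A `cc_fit` object.
#' @param ... Unused.
#' @export
tidy.cc_fit <- function(x, ...) x$residues

#' @rdname fit_coiled_coil
#' @export
glance.cc_fit <- function(x, ...) {
  tibble(
    r0 = x$r0, pitch = x$pitch, handedness = x$handedness,
    n_chains = nrow(x$chains), extent = x$extent,
    arrangement = paste(x$arrangement, collapse = "-"),
    axis_rms = x$axis$rms, low_confidence = x$low_confidence
  )
}

#' Export a geometry fit as JSON
#'
#' @param fit A `cc_fit`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    r0 = fit$r0, pitch = fit$pitch, handedness = fit$handedness,
    axis_origin = fit$axis$origin, axis_direction = fit$axis$direction,
    chains = fit$chains, arrangement = fit$arrangement,
    extent = fit$extent, n_heptads = as.list(fit$n_heptads),
    residues = fit$residues
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
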