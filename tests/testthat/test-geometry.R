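test_that("local axis points sit on the true helix axis", {
  # straight alpha-helix (negligible supercoil): axis points colinear
  straight <- build_bundle(crick_params(n_chains = 2, r0 = 0.001,
                                        pitch = 5e5, n_res = 30), seed = 1)
  ap <- local_axis(straight)
  a1 <- ap[ap$chain == "A", c("ax", "ay", "az")]
  cen <- sweep(as.matrix(a1), 2, colMeans(as.matrix(a1)))
  resid <- sqrt(sum(svd(cen)$d[-1]^2) / nrow(a1))
  expect_lt(resid, 0.01)

  # ideal bundle: axis points at distance ~r0 from the generator z-axis
  # (the window centroid sits ~0.8% inside the true track, with a small
  # residual wobble from the finite supercoil curvature)
  ap2 <- local_axis(small_model)
  r <- sqrt(ap2$ax^2 + ap2$ay^2)
  expect_lt(abs(mean(r) - 5.8) / 5.8, 0.01)
  expect_true(all(abs(r - 5.8) / 5.8 < 0.03))

  # 7-residue chain gives exactly one axis point
  seven <- cc_structure(silk_model[silk_model$chain == "F1" &
                                     silk_model$seq_id <= 7, ])
  expect_equal(nrow(local_axis(seven)), 1)
  expect_error(local_axis(cc_structure(
    silk_model[silk_model$chain == "F1" & silk_model$seq_id <= 6, ])),
    "at least 7")
})

test_that("axis line fit recovers the generator axis", {
  ap <- local_axis(small_model)
  line <- fit_axis_line(ap)
  ang <- acos(abs(sum(line$direction * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 0.5)
  # direction is signed so chain 1 (a U chain) runs N->C positive
  expect_gt(line$direction[3], 0)
  exact <- tibble::tibble(chain = "A", seq_id = 1:5, ax = 0, ay = 0,
                          az = as.numeric(1:5), tx = 0, ty = 0, tz = 1)
  lf <- fit_axis_line(exact)
  expect_equal(lf$rms, 0, tolerance = 1e-12)
  expect_error(fit_axis_line(exact |> dplyr::mutate(az = 1)), "degenerate")
})

test_that("radius and pitch are recovered and straight bundles flagged", {
  ap <- local_axis(silk_model)
  line <- fit_axis_line(ap)
  rp <- fit_radius_pitch(ap, line)
  expect_equal(rp$r0, 5.8, tolerance = 0.01)
  expect_equal(rp$pitch, 153, tolerance = 0.02 * 153)
  expect_equal(rp$handedness, "left")

  straight <- build_bundle(crick_params(n_chains = 2, r0 = 5, pitch = 5e5,
                                        n_res = 60), seed = 1)
  aps <- local_axis(straight)
  rps <- fit_radius_pitch(aps, fit_axis_line(aps))
  expect_equal(rps$handedness, "none")
  expect_true(is.na(rps$pitch))
})

test_that("chain orientation tracks the terminus direction and is antisymmetric", {
  expect_equal(silk_fit$chains$orientation, c("U", "U", "D", "D"))
  rev_model <- silk_model |>
    dplyr::group_by(chain) |>
    dplyr::mutate(seq_id = max(seq_id) + 1L - seq_id) |>
    dplyr::ungroup() |>
    dplyr::arrange(chain, seq_id)
  ori <- chain_orientation(cc_structure(rev_model), silk_fit$axis)
  expect_equal(ori$orientation, c("D", "D", "U", "U"))
})

test_that("arrangement order is clockwise from the positive axis end", {
  # chains placed counterclockwise at 0/90/180/270 read clockwise as 1,4,3,2
  p <- crick_params(n_chains = 4, orientations = rep("U", 4),
                    phase0 = c(0, 90, 180, 270), n_res = 35)
  m <- build_bundle(p, seed = 1)
  ap <- local_axis(m)
  line <- fit_axis_line(ap)
  expect_equal(arrangement_order(ap, line), c("A", "D", "C", "B"))
  # silk preset reproduces the published clockwise order
  expect_equal(silk_fit$arrangement, c("F1", "F3", "F2", "F4"))
  # rigid rotation leaves the cyclic order invariant
  m2 <- rigid_move(m, seed = 5)
  ap2 <- local_axis(m2)
  expect_equal(arrangement_order(ap2, fit_axis_line(ap2)), c("A", "D", "C", "B"))
})

test_that("axial stagger is recovered relative to chain 1", {
  p <- crick_params(n_chains = 3, orientations = c("U", "D", "U"),
                    n_res = 42, stagger = c(0, 3, -1.5))
  m <- build_bundle(p, seed = 1)
  ap <- local_axis(m)
  st <- axial_stagger(ap, fit_axis_line(ap))
  expect_equal(st$stagger, c(0, 3, -1.5), tolerance = 0.1)
  # invariant under rigid translation
  mt <- m; mt$z <- mt$z + 25; mt$x <- mt$x - 4
  apt <- local_axis(mt)
  expect_equal(axial_stagger(apt, fit_axis_line(apt))$stagger,
               st$stagger, tolerance = 1e-6)
})

test_that("register assignment recovers the threaded ground truth", {
  expect_equal(silk_fit$residues$register,
               truth_register_for(silk_model, silk_fit))
  expect_equal(unname(silk_fit$n_heptads), rep(24L, 4))
  # every cyclic relabeling of the truth scores strictly worse
  ap <- local_axis(silk_model)
  line <- fit_axis_line(ap)
  phases <- coilspect:::crick_phases(silk_model, ap, line)
  psi <- phases$crick_phase[phases$chain == "F1"]
  scores <- coilspect:::assign_offsets(psi)$scores
  best <- which.max(scores)
  expect_true(all(scores[-best] < scores[best]))
})

test_that("coil extent behaves under stagger and matches single-chain span", {
  one <- cc_structure(silk_model[silk_model$chain == "F1", ])
  ap1 <- local_axis(one)
  l1 <- fit_axis_line(ap1)
  e1 <- coil_extent(ap1, l1)
  # two fully overlapping chains span the same extent
  p <- crick_params(n_chains = 2, orientations = c("U", "U"), n_res = 168,
                    phase0 = c(0, 180))
  m2 <- build_bundle(p, seed = 1)
  ap2 <- local_axis(m2)
  e2 <- coil_extent(ap2, fit_axis_line(ap2))
  expect_equal(e2, e1, tolerance = 1e-3)
  # staggering one chain by s grows the span by s
  p3 <- crick_params(n_chains = 2, orientations = c("U", "U"), n_res = 168,
                     phase0 = c(0, 180), stagger = c(0, 4))
  m3 <- build_bundle(p3, seed = 1)
  ap3 <- local_axis(m3)
  e3 <- coil_extent(ap3, fit_axis_line(ap3))
  expect_equal(e3, e2 + 4, tolerance = 0.05)
})

test_that("geometric outputs are invariant under rigid motion", {
  f1 <- small_fit
  m2 <- rigid_move(small_model, seed = 21)
  f2 <- fit_coiled_coil(m2)
  expect_equal(f2$r0, f1$r0, tolerance = 1e-6)
  expect_equal(f2$pitch, f1$pitch, tolerance = 1e-6)
  expect_equal(f2$extent, f1$extent, tolerance = 1e-6)
  expect_identical(f2$residues$register, f1$residues$register)
  expect_identical(f2$chains$orientation, f1$chains$orientation)
  expect_equal(f2$chains$stagger, f1$chains$stagger, tolerance = 1e-6)
  expect_identical(f2$arrangement, f1$arrangement)
})

test_that("mirror reflection flips handedness and axis-referred orientations", {
  m <- small_model
  mir <- m; mir$z <- -mir$z
  fmir <- fit_coiled_coil(cc_structure(as.data.frame(mir) |>
                                         dplyr::arrange(match(chain, chain_ids(m)))))
  expect_equal(fmir$handedness, "right")
  ori <- chain_orientation(mir, small_fit$axis)
  expect_true(all(ori$orientation != small_fit$chains$orientation))
})

test_that("noisy bundles still yield accurate radius and register", {
  noisy <- perturb(silk_model, 0.3, seed = 17)
  f <- fit_coiled_coil(noisy)
  expect_lt(abs(f$r0 - 5.8) / 5.8, 0.05)
  recovery <- mean(f$residues$register ==
                     truth_register_for(silk_model, f))
  expect_gte(recovery, 0.95)
})

test_that("fit object tidiers and JSON export are consistent", {
  expect_equal(nrow(tidy(silk_fit)), 168 * 4)
  g <- glance(silk_fit)
  expect_equal(g$arrangement, "F1-F3-F2-F4")
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(silk_fit, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$r0, silk_fit$r0, tolerance = 1e-9)
  expect_equal(j$n_heptads$F1, 24)
})
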