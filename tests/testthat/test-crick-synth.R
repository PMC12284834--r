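test_that("builder follows the Crick parameterization", {
  # degenerate minor helix: all CA exactly at distance r0 from the z-axis
  p0 <- crick_params(n_chains = 2, r1 = 0, r0 = 6, pitch = 150, n_res = 30)
  m0 <- build_bundle(p0, sequence = strrep("A", 30), seed = 1)
  ca <- m0[m0$atom == "CA" & m0$chain == "A", ]
  expect_equal(sqrt(ca$x^2 + ca$y^2), rep(6, 30), tolerance = 1e-12)

  # axial extent of a U chain matches the closed-form z equation
  p <- crick_params(n_chains = 2, orientations = c("U", "U"), n_res = 60)
  m <- build_bundle(p, seed = 1)
  alpha <- atan(2 * pi * p$r0 / p$pitch)
  expected <- p$rise * cos(alpha) * (p$n_res - 1)
  ca <- m[m$atom == "CA" & m$chain == "A", ]
  expect_lt(abs(diff(range(ca$z)) - expected), 2 * p$r1)
})

test_that("generated helices are right-handed and supercoil handedness is honoured", {
  for (hand in c("left", "right")) {
    m <- build_bundle(crick_params(n_chains = 2, handedness = hand, n_res = 30),
                      seed = 1)
    ca <- as.matrix(m[m$atom == "CA" & m$chain == "A", c("x", "y", "z")])
    # signed dihedral of 4 consecutive CA: positive for a right-handed helix
    dihedrals <- vapply(seq_len(nrow(ca) - 3), function(i) {
      b1 <- ca[i + 1, ] - ca[i, ]; b2 <- ca[i + 2, ] - ca[i + 1, ]
      b3 <- ca[i + 3, ] - ca[i + 2, ]
      n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
      atan2(sum(cross3(n1, n2) * b2 / sqrt(sum(b2^2))), sum(n1 * n2))
    }, numeric(1))
    expect_true(all(dihedrals > 0), label = paste("right-handed helix,", hand))
    expect_equal(fit_coiled_coil(m)$handedness, hand)
  }
})

test_that("crick parameter round trip holds over 50 random draws", {
  withr::with_seed(42, {
    draws <- lapply(1:50, function(i) {
      nc <- sample(2:4, 1)
      list(i = i, params = crick_params(
        n_chains = nc,
        orientations = c("U", sample(c("U", "D"), nc - 1, replace = TRUE)),
        r0 = runif(1, 4, 9), pitch = runif(1, 100, 250),
        n_res = sample(35:175, 1),
        handedness = sample(c("left", "right"), 1),
        stagger = c(0, runif(nc - 1, -3, 3))))
    })
  })
  for (d in draws) {
    p <- d$params
    m <- build_bundle(p, seed = d$i)
    f <- fit_coiled_coil(m)
    expect_lt(abs(f$r0 - p$r0) / p$r0, 0.01)
    expect_lt(abs(f$pitch - p$pitch) / p$pitch, 0.02)
    expect_equal(f$handedness, p$handedness)
    expect_equal(f$chains$orientation, p$orientations)
    expect_equal(f$residues$register, truth_register_for(m, f))
  }
})

test_that("perturb is seeded, isotropic and exact at zero noise", {
  m <- silk_model
  expect_identical(perturb(m, 0, seed = 1), m)
  p1 <- perturb(m, 0.4, seed = 11)
  p2 <- perturb(m, 0.4, seed = 11)
  expect_identical(p1$x, p2$x)
  expect_false(identical(p1$x, perturb(m, 0.4, seed = 12)$x))
  # 3D RMS displacement ~ noise_sd * sqrt(3) (Monte-Carlo over ~10^4 atoms)
  big <- cc_structure(dplyr::bind_rows(lapply(1:8, function(k) {
    mm <- as.data.frame(m); mm$chain <- paste0(LETTERS[k], mm$chain); mm
  })))
  pb <- perturb(big, 0.5, seed = 3)
  disp <- sqrt((pb$x - big$x)^2 + (pb$y - big$y)^2 + (pb$z - big$z)^2)
  expect_equal(sqrt(mean(disp^2)), 0.5 * sqrt(3), tolerance = 0.05)
})

test_that("sampled crosslinks honour the decoy split and match brute-force distances", {
  expect_equal(nrow(sample_crosslinks(silk_model, 0)), 0)
  xl <- sample_crosslinks(silk_model, n_links = 40, decoy_fraction = 0,
                          seed = 4)
  mp <- map_crosslinks(xl, silk_model, silk_fit)
  expect_true(all(mp$distance <= 30))
  xl2 <- sample_crosslinks(silk_model, n_links = 40, decoy_fraction = 0.5,
                           seed = 4)
  mp2 <- map_crosslinks(xl2, silk_model, silk_fit)
  # emitted truth labels agree with an independent brute-force distance scan
  anchors <- silk_model[silk_model$atom == "CA", ]
  brute <- vapply(seq_len(nrow(xl2)), function(i) {
    a <- anchors[anchors$chain == xl2$chain_a[i] &
                   anchors$seq_id == xl2$res_a[i], ]
    b <- anchors[anchors$chain == xl2$chain_b[i] &
                   anchors$seq_id == xl2$res_b[i], ]
    sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  }, numeric(1))
  expect_equal(mp2$distance, brute, tolerance = 1e-12)
  expect_equal(xl2$truth_satisfied, brute <= 30)
})

test_that("simulated melts follow the two-state law", {
  flat <- simulate_melt(tm = 50, width = 2, folded_baseline = c(-10, 0),
                        unfolded_baseline = c(-2, 0),
                        t_grid = c(30, 50, 80))
  # at T = tm the signal is midway between flat baselines
  expect_equal(flat$ellipticity[2], -6)
  # far below tm the folded baseline dominates
  expect_equal(flat$ellipticity[1], -10, tolerance = 1e-3)
  # noise-free self-consistency with the fitter
  fit <- fit_two_state_melt(simulate_melt(tm = 55.3, width = 3, noise_sd = 0))
  expect_lt(abs(fit$tm - 55.3), 0.01)
})

test_that("simulated CD spectra hit the requested 222/209 ratio", {
  for (r in c(0.8, 0.95, 1.0)) {
    s <- simulate_cd("single_helix", ratio_222_209 = r)
    expect_equal(ratio_222_209(s)$ratio_222_209, r, tolerance = 0.01)
  }
  # amplitude scaling leaves the ratio unchanged
  s <- simulate_cd("coiled_coil")
  s2 <- s; s2$ellipticity <- 2 * s2$ellipticity
  expect_equal(ratio_222_209(s2)$ratio_222_209,
               ratio_222_209(s)$ratio_222_209, tolerance = 1e-12)
  expect_error(simulate_cd(wavelengths = seq(200, 260)), "190-260")
})

test_that("silk-like sequences enrich alanine at a/d/e/g", {
  reg <- rep(heptad_letters(), 24)
  seqs <- vapply(1:6, function(s) silk_sequence(reg, seed = s), character(1))
  df <- tibble::tibble(aa = unlist(strsplit(seqs, "")),
                       register = rep(reg, 6))
  stats <- per_position_stats(df)
  top4 <- stats$register[order(-stats$ala_fraction)][1:4]
  expect_setequal(top4, c("a", "d", "e", "g"))
  expect_true(any(grepl("K", seqs)))  # lysines available for crosslinking
})
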