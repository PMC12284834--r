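test_that("knobs on an ideal silk tetramer sit at core-side positions", {
  kih <- detect_kih(silk_model, silk_fit)
  expect_gt(nrow(kih), 0)
  # no knob at the solvent-facing b, c, f positions; the antiparallel
  # tetramer packs with a/d core knobs and e/g flanking knobs
  expect_true(all(kih$knob_register %in% c("a", "d", "e", "g")))
  expect_true(all(c("a", "d") %in% kih$knob_register))
  # every hole is exactly 4 residues on a single foreign chain
  expect_true(all(vapply(kih$hole_res, length, integer(1)) == 4))
  expect_true(all(kih$hole_chain != kih$chain))
  # distances within the default cutoff
  expect_true(all(unlist(kih$center_distances) <= 7.0))
})

test_that("knob/hole relations are reciprocal on a symmetric dimer", {
  p <- crick_params(n_chains = 2, orientations = c("U", "U"), r0 = 4.9,
                    pitch = 140, n_res = 35, phase0 = c(0, 180))
  m <- build_bundle(p, seed = 2)
  kih <- detect_kih(m, fit_coiled_coil(m))
  tab <- table(kih$chain)
  expect_equal(unname(tab["A"]), unname(tab["B"]))
  # exchange symmetry: knob registers identical between chains
  expect_equal(sort(kih$knob_register[kih$chain == "A"]),
               sort(kih$knob_register[kih$chain == "B"]))
})

test_that("helices beyond the cutoff yield no knobs", {
  far <- build_bundle(crick_params(n_chains = 2, r0 = 12, pitch = 200,
                                   n_res = 35), seed = 3)
  expect_equal(nrow(detect_kih(far)), 0)
})

test_that("core layers alternate between a and d along the axis", {
  kih <- detect_kih(silk_model, silk_fit)
  ls <- layer_summary(kih)
  expect_true(ls$alternating)
  expect_true(all(ls$layers$type %in% c("a", "d")))
  expect_gt(nrow(ls$layers), 10)
  # shuffled input gives the identical report
  shuffled <- kih[withr::with_seed(1, sample(nrow(kih))), ]
  expect_equal(layer_summary(shuffled)$layers, ls$layers)
  # single core contact trivially alternates
  one_a <- kih[kih$knob_register == "a", ][1, ]
  expect_true(layer_summary(one_a)$alternating)
})

test_that("salt bridges match an engineered fixture and a brute-force scan", {
  toy <- cc_structure(tibble::tibble(
    chain = c("A", "A", "B", "B", "B"),
    seq_id = c(10L, 10L, 20L, 20L, 20L),
    res_name = c("LYS", "LYS", "GLU", "GLU", "GLU"),
    atom = c("CA", "NZ", "CA", "OE1", "OE2"),
    element = c("C", "N", "C", "O", "O"),
    x = c(0, 1, 8, 4.5, 6), y = 0, z = 0))
  expect_warning(sb <- detect_salt_bridges(toy, fit = NULL, scope = "inter"),
                 "position classes")
  expect_equal(nrow(sb), 1)
  expect_equal(sb$min_distance, 3.5)
  expect_equal(sb$position_class, "?-?")
  # register-aware class from a hand-made fit lookup
  fake_fit <- list(residues = tibble::tibble(
    chain = c("A", "B"), seq_id = c(10L, 20L), register = c("g", "c")))
  sb2 <- detect_salt_bridges(toy, fit = fake_fit, scope = "inter")
  expect_equal(sb2$position_class, "g-c")
  # brute-force all-pairs oracle on a decorated bundle
  m <- decorate_charges(small_model, small_fit)
  sb3 <- detect_salt_bridges(m, small_fit, cutoff = 4.0, scope = "both")
  brute <- brute_force_bridges(m, cutoff = 4.0)
  expect_equal(nrow(sb3), nrow(brute))
  if (nrow(brute) > 0) {
    key <- function(d) sort(paste(d$chain_basic, d$res_basic,
                                  d$chain_acidic, d$res_acidic))
    expect_equal(key(sb3), key(brute))
    expect_equal(sort(sb3$min_distance), sort(brute$min_distance),
                 tolerance = 1e-12)
  }
  # poly-alanine has no charged groups
  polyA <- build_bundle(crick_params(n_chains = 2, n_res = 21),
                        sequence = strrep("A", 21), seed = 1)
  expect_equal(nrow(detect_salt_bridges(polyA, scope = "both")), 0)
})

test_that("silk-parameter bundles yield peripheral bridge classes", {
  m <- decorate_charges(silk_model, silk_fit)
  # coarse pseudo side chains need a looser cutoff than real atoms
  sb <- detect_salt_bridges(m, silk_fit, cutoff = 7.0, scope = "inter")
  expect_gt(nrow(sb), 0)
  pos <- unlist(strsplit(sb$position_class, "-"))
  # interhelical electrostatics live outside the a/d core
  expect_false(any(pos %in% c("a", "d")))
})
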