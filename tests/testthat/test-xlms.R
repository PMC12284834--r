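test_that("crosslink CSV reading validates rows and carries counts", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("chain_a,res_a,chain_b,res_b,count",
               "F1,12,F2,30,1", "F1,12,F3,44,5", "F2,8,F2,61,1"), path)
  recs <- read_crosslinks(path)
  expect_equal(nrow(recs), 3)
  expect_equal(recs$count, c(1L, 5L, 1L))
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("chain_a,res_a,chain_b,res_b", "F1,K12a,F2,30"), bad)
  expect_error(read_crosslinks(bad), "row 1")
  nohead <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), nohead)
  expect_error(read_crosslinks(nohead), "missing column")
})

test_that("mapping measures distances, types and registers correctly", {
  recs <- tibble::tibble(
    chain_a = c("F1", "F1", "F1"), res_a = c(10L, 10L, 10L),
    chain_b = c("F1", "F2", "F9"), res_b = c(10L, 50L, 1L),
    count = 1L)
  mp <- map_crosslinks(recs, silk_model, silk_fit)
  # self link: distance 0, satisfied, intra
  expect_equal(mp$distance[1], 0)
  expect_true(mp$satisfied[1])
  expect_equal(mp$type[1:2], c("intra", "inter"))
  # unresolvable residue yields an error entry, run continues
  expect_match(mp$error[3], "F9:1")
  expect_true(is.na(mp$distance[3]))
  # registers come from the fit
  reg <- silk_fit$residues
  expect_equal(mp$register_a[1],
               reg$register[reg$chain == "F1" & reg$seq_id == 10])
})

test_that("the 30 A restraint is strict and monotone in the cutoff", {
  # engineered pair at exactly 30.0 A
  toy <- cc_structure(tibble::tibble(
    chain = c("A", "B"), seq_id = c(1L, 1L), res_name = "ALA",
    atom = "CA", element = "C", x = c(0, 30), y = 0, z = 0))
  rec <- tibble::tibble(chain_a = "A", res_a = 1L, chain_b = "B", res_b = 1L,
                        count = 1L)
  expect_false(map_crosslinks(rec, toy, cutoff = 30)$satisfied)
  expect_true(map_crosslinks(rec, toy, cutoff = 30.0001)$satisfied)
  # satisfied set at 25 A is a subset of the set at 30 A
  xl <- sample_crosslinks(silk_model, n_links = 80, decoy_fraction = 0.3,
                          seed = 9)
  m25 <- map_crosslinks(xl, silk_model, cutoff = 25)
  m30 <- map_crosslinks(xl, silk_model, cutoff = 30)
  expect_true(all(!(m25$satisfied & !m30$satisfied)))
  # symmetry: swapped endpoints map identically
  swapped <- xl |>
    dplyr::rename(chain_a = chain_b, chain_b = chain_a,
                  res_a = res_b, res_b = res_a)
  msw <- map_crosslinks(swapped, silk_model, silk_fit)
  mfw <- map_crosslinks(xl, silk_model, silk_fit)
  expect_equal(msw$distance, mfw$distance, tolerance = 1e-12)
  expect_equal(msw$satisfied, mfw$satisfied)
  expect_equal(msw$type, mfw$type)
})

test_that("lysine side chains anchor at NZ with CA fallback", {
  toy <- cc_structure(tibble::tibble(
    chain = c("A", "A", "B"), seq_id = c(5L, 5L, 9L),
    res_name = c("LYS", "LYS", "LYS"),
    atom = c("CA", "NZ", "CA"), element = c("C", "N", "C"),
    x = c(0, 2, 10), y = 0, z = 0))
  rec <- tibble::tibble(chain_a = "A", res_a = 5L, chain_b = "B", res_b = 9L,
                        count = 1L)
  # NZ on A (x=2), CA fallback on B (x=10) -> distance 8
  expect_equal(map_crosslinks(rec, toy)$distance, 8)
})

test_that("restraint report deduplicates pairs and matches generator bookkeeping", {
  recs <- tibble::tibble(
    chain_a = c("F1", "F2"), res_a = c(10L, 50L),
    chain_b = c("F2", "F1"), res_b = c(50L, 10L), count = c(2L, 3L))
  rep <- restraint_report(map_crosslinks(recs, silk_model, silk_fit))
  expect_equal(rep$summary$n_unique, 1L)
  expect_equal(rep$links$observations, 5L)
  # synthetic table with known decoy fraction
  xl <- sample_crosslinks(silk_model, n_links = 100, decoy_fraction = 0.25,
                          seed = 5)
  rep2 <- restraint_report(map_crosslinks(xl, silk_model, silk_fit))
  expect_equal(rep2$summary$satisfied_fraction, 0.75)
  expect_equal(nrow(rep2$violations), 25)
  # all-decoy table
  xl3 <- sample_crosslinks(silk_model, n_links = 20, decoy_fraction = 1,
                           seed = 6)
  rep3 <- restraint_report(map_crosslinks(xl3, silk_model, silk_fit))
  expect_equal(rep3$summary$satisfied_fraction, 0)
})

test_that("surface annotation flags links at exposed heptad positions", {
  xl <- sample_crosslinks(silk_model, n_links = 60, decoy_fraction = 0,
                          seed = 8)
  mp <- map_crosslinks(xl, silk_model, silk_fit)
  expect_true(all(!is.na(mp$surface_ok)))
  # lysines in the silk-like sequence live at b/c/f, so sampled links sit
  # at surface positions (N-terminal residue 1 links can be at any register)
  nterm <- mp$res_a == 1 | mp$res_b == 1
  expect_true(all(mp$surface_ok[!nterm]))
  mp_nofit <- map_crosslinks(xl, silk_model)
  expect_true(all(is.na(mp_nofit$surface_ok)))
  expect_true(all(mp_nofit$register_a == "?"))
})
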