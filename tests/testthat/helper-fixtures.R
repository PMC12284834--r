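# Shared fixtures, built once per test run.

# the silk-parameter antiparallel tetramer (ideal, zero noise)
silk_model <- build_bundle(silk_params(), seed = 1)
silk_fit <- fit_coiled_coil(silk_model)

# a small generic tetramer for cheap tests
small_model <- build_bundle(silk_params(n_res = 63), seed = 2)
small_fit <- fit_coiled_coil(small_model)

# tiny hand-written PDB fixture: 1 chain, 2 residues, 2 atoms each
mini_pdb_lines <- c(
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
  "ATOM      3  CA  LYS A   2      12.345   7.000  -4.000  1.00  0.00           C",
  "ATOM      4  CB  LYS A   2      13.000   7.500  -3.000  1.00  0.00           C",
  "END"
)

write_mini_pdb <- function(lines = mini_pdb_lines) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# minimal mmCIF with distinct author numbering/chain ids
mini_cif_lines <- c(
  "data_test", "loop_",
  paste0("_atom_site.",
         c("group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
           "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
           "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
           "B_iso_or_equiv", "auth_seq_id", "auth_comp_id", "auth_asym_id",
           "auth_atom_id", "pdbx_PDB_model_num")),
  "ATOM 1 N N . ALA A 1 1 ? 11.104 6.134 -6.504 1.00 0.00 101 ALA F2 N 1",
  "ATOM 2 C CA . ALA A 1 1 ? 11.639 6.071 -5.147 1.00 0.00 101 ALA F2 CA 1",
  "ATOM 3 C CA . LYS A 1 2 ? 12.345 7.000 -4.000 1.00 0.00 102 LYS F2 CA 1"
)

# random rigid motion applied to a structure
rigid_move <- function(model, seed = 1) {
  withr::with_seed(seed, {
    th <- runif(3, 0, 2 * pi)
    tr <- runif(3, -20, 20)
  })
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                 0, -sin(th[1]), cos(th[1])), 3)
  Ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0,
                 sin(th[2]), 0, cos(th[2])), 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0,
                 0, 0, 1), 3)
  R <- Rz %*% Ry %*% Rx
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(R)
  model$x <- xyz[, 1] + tr[1]
  model$y <- xyz[, 2] + tr[2]
  model$z <- xyz[, 3] + tr[3]
  model
}

# ground-truth register lookup aligned to a fit's residue table
truth_register_for <- function(model, fit) {
  gt <- ground_truth(model)
  key <- paste(fit$residues$chain, fit$residues$seq_id)
  gkey <- paste(gt$register$chain, gt$register$seq_id)
  gt$register$register[match(key, gkey)]
}

# cross product (for chirality dihedrals)
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# place NZ/OE1 pseudo charged atoms 2.2 A beyond CB along the CA->CB
# direction for every Lys/Glu/Asp/Arg in a CA/CB bundle
decorate_charges <- function(model, fit) {
  res <- residue_table(model)
  add <- list()
  for (i in seq_len(nrow(res))) {
    at <- switch(res$res_name[i], LYS = "NZ", ARG = "NH1",
                 GLU = "OE1", ASP = "OD1", NULL)
    if (is.null(at)) next
    sub <- model[model$chain == res$chain[i] & model$seq_id == res$seq_id[i], ]
    ca <- sub[sub$atom == "CA", ]; cb <- sub[sub$atom == "CB", ]
    v <- c(cb$x - ca$x, cb$y - ca$y, cb$z - ca$z)
    v <- v / sqrt(sum(v^2))
    add[[length(add) + 1]] <- tibble::tibble(
      chain = res$chain[i], seq_id = res$seq_id[i],
      res_name = res$res_name[i], atom = at,
      element = substr(at, 1, 1),
      x = cb$x + 2.2 * v[1], y = cb$y + 2.2 * v[2], z = cb$z + 2.2 * v[3])
  }
  out <- dplyr::bind_rows(as.data.frame(model), dplyr::bind_rows(add)) |>
    dplyr::arrange(match(chain, chain_ids(model)), seq_id)
  cc_structure(out)
}

brute_force_bridges <- function(model, cutoff) {
  bas <- model[(model$res_name == "LYS" & model$atom == "NZ") |
                 (model$res_name == "ARG" & model$atom %in% c("NH1", "NH2", "NE")), ]
  aci <- model[(model$res_name == "GLU" & model$atom %in% c("OE1", "OE2")) |
                 (model$res_name == "ASP" & model$atom %in% c("OD1", "OD2")), ]
  rows <- list()
  for (i in seq_len(nrow(bas))) {
    for (j in seq_len(nrow(aci))) {
      d <- sqrt((bas$x[i] - aci$x[j])^2 + (bas$y[i] - aci$y[j])^2 +
                  (bas$z[i] - aci$z[j])^2)
      if (d <= cutoff) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          chain_basic = bas$chain[i], res_basic = bas$seq_id[i],
          chain_acidic = aci$chain[j], res_acidic = aci$seq_id[j],
          min_distance = d)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(chain_basic = character(), res_basic = integer(),
                          chain_acidic = character(), res_acidic = integer(),
                          min_distance = double()))
  }
  dplyr::bind_rows(rows) |>
    dplyr::group_by(chain_basic, res_basic, chain_acidic, res_acidic) |>
    dplyr::summarise(min_distance = min(min_distance), .groups = "drop")
}
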