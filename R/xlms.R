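# Crosslinking-MS restraint mapping: read crosslink tables, measure mapped
# distances on a model, apply the linker cutoff, annotate heptad context.

# anchor atom per residue for crosslink distances: NZ for lysines when
# present, the backbone N for a chain's first residue (the N-terminus),
# else CA
link_anchor_atoms <- function(model) {
  res <- residue_table(model)
  first_res <- res |>
    group_by(.data$chain) |>
    summarise(seq_id = min(.data$seq_id), .groups = "drop")
  pick_one <- function(ch, id) {
    sub <- model[model$chain == ch & model$seq_id == id, , drop = FALSE]
    rn <- sub$res_name[1]
    at <- if (rn == "LYS" && "NZ" %in% sub$atom) {
      "NZ"
    } else if (any(first_res$chain == ch & first_res$seq_id == id) &&
               "N" %in% sub$atom) {
      "N"
    } else if ("CA" %in% sub$atom) {
      "CA"
    } else {
      NA_character_
    }
    if (is.na(at)) return(NULL)
    row <- sub[sub$atom == at, ][1, ]
    tibble(chain = ch, seq_id = id, atom = at,
           x = row$x, y = row$y, z = row$z)
  }
  bind_rows(mapply(pick_one, res$chain, res$seq_id, SIMPLIFY = FALSE))
}

#' Read a crosslink table from CSV
#'
#' Expects header columns `chain_a,res_a,chain_b,res_b` with an optional
#' `count` column (default 1 observation per row).
#'
#' @param path CSV file path.
#' @return Tibble with columns `chain_a`, `res_a`, `chain_b`, `res_b`,
#'   `count`, `source`.
#' @export
read_crosslinks <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  needed <- c("chain_a", "res_a", "chain_b", "res_b")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(paste0("crosslink CSV is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (col in c("res_a", "res_b")) {
    bad <- which(is.na(suppressWarnings(as.integer(raw[[col]]))) |
                   grepl("[^0-9]", raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("non-integer residue id '%s' in column %s, row %d",
                    raw[[col]][bad[1]], col, bad[1]))
    }
  }
  cnt <- if ("count" %in% names(raw)) {
    bad <- which(grepl("[^0-9]", raw$count))
    if (length(bad) > 0) {
      abort(sprintf("non-integer count in row %d", bad[1]))
    }
    as.integer(raw$count)
  } else {
    rep(1L, nrow(raw))
  }
  tibble(
    chain_a = raw$chain_a, res_a = as.integer(raw$res_a),
    chain_b = raw$chain_b, res_b = as.integer(raw$res_b),
    count = cnt, source = path
  )
}

#' Map crosslinks onto a structural model
#'
#' Measures the mapped distance of each crosslink record on the model (Lys
#' NZ-NZ when both side chains are present, N-terminal backbone N for a
#' chain's first residue, CA fallback otherwise), applies the strict
#' `distance < cutoff` linker restraint, and annotates heptad registers and
#' surface exposure when a geometry fit is supplied. Records referencing
#' residues absent from the model get an `error` entry and the run
#' continues.
#'
#' @param records Crosslink tibble (see [read_crosslinks()]; a `count` or
#'   `truth_satisfied` column is carried through).
#' @param model A `cc_structure`.
#' @param fit Optional `cc_fit` for register lookup.
#' @param cutoff Linker distance restraint, Angstrom (default 30; strictly
#'   less-than).
#' @return Tibble: the records plus `distance`, `satisfied`, `type`
#'   (intra/inter), `register_a`, `register_b`, `surface_ok`, `error`.
#' @export
map_crosslinks <- function(records, model, fit = NULL, cutoff = 30) {
  anchors <- link_anchor_atoms(model)
  reg <- if (!is.null(fit)) fit$residues else NULL
  lookup <- function(ch, id) {
    hit <- which(anchors$chain == ch & anchors$seq_id == id)
    if (length(hit) == 0) NULL else anchors[hit[1], ]
  }
  lookup_reg <- function(ch, id) {
    if (is.null(reg)) return("?")
    hit <- reg$register[reg$chain == ch & reg$seq_id == id]
    if (length(hit) == 1) hit else "?"
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    a <- lookup(r$chain_a, r$res_a)
    b <- lookup(r$chain_b, r$res_b)
    if (is.null(a) || is.null(b)) {
      bad <- if (is.null(a)) sprintf("%s:%d", r$chain_a, r$res_a)
      else sprintf("%s:%d", r$chain_b, r$res_b)
      return(mutate(r, distance = NA_real_, satisfied = NA,
                    type = NA_character_, register_a = NA_character_,
                    register_b = NA_character_, surface_ok = NA,
                    error = sprintf("residue %s not in model", bad)))
    }
    d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
    ra <- lookup_reg(r$chain_a, r$res_a)
    rb <- lookup_reg(r$chain_b, r$res_b)
    mutate(r, distance = d, satisfied = d < cutoff,
           type = if (r$chain_a == r$chain_b) "intra" else "inter",
           register_a = ra, register_b = rb,
           surface_ok = if (ra == "?" || rb == "?") NA else
             ra %in% surface_positions && rb %in% surface_positions,
           error = NA_character_)
  })
  bind_rows(rows)
}

#' Summarise mapped crosslink restraints
#'
#' Collapses mapped links to unique unordered residue pairs (observations
#' summed), then reports unique inter/intra counts, the satisfied fraction,
#' the surface-position fraction (over links with known registers) and the
#' violating links.
#'
#' @param mapped Output of [map_crosslinks()].
#' @return List with `summary` (one-row tibble), `links` (unique pairs) and
#'   `violations` (unsatisfied unique links).
#' @export
restraint_report <- function(mapped) {
  ok <- mapped |> filter(is.na(.data$error))
  if (nrow(ok) == 0) {
    return(list(summary = tibble(n_unique = 0L, n_inter = 0L, n_intra = 0L,
                                 satisfied_fraction = NA_real_,
                                 surface_fraction = NA_real_,
                                 n_errors = nrow(mapped)),
                links = ok, violations = ok))
  }
  key_a <- paste0(ok$chain_a, ":", ok$res_a)
  key_b <- paste0(ok$chain_b, ":", ok$res_b)
  ok$pair <- ifelse(key_a <= key_b, paste(key_a, key_b, sep = "--"),
                    paste(key_b, key_a, sep = "--"))
  links <- ok |>
    group_by(.data$pair) |>
    summarise(
      chain_a = .data$chain_a[1], res_a = .data$res_a[1],
      chain_b = .data$chain_b[1], res_b = .data$res_b[1],
      observations = sum(.data$count),
      distance = .data$distance[1], satisfied = .data$satisfied[1],
      type = .data$type[1], register_a = .data$register_a[1],
      register_b = .data$register_b[1], surface_ok = .data$surface_ok[1],
      .groups = "drop"
    ) |>
    select(-"pair")
  known <- links |> filter(!is.na(.data$surface_ok))
  list(
    summary = tibble(
      n_unique = nrow(links),
      n_inter = sum(links$type == "inter"),
      n_intra = sum(links$type == "intra"),
      satisfied_fraction = mean(links$satisfied),
      surface_fraction = if (nrow(known) > 0) mean(known$surface_ok) else NA_real_,
      n_errors = sum(!is.na(mapped$error))
    ),
    links = links,
    violations = links |> filter(!.data$satisfied)
  )
}
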