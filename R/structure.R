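# Atomic structure container and PDB/mmCIF I/O.
#
# A structure is a tidy atom table: one row per atom, ordered as in the
# source file. Author residue numbering is the single residue coordinate
# system throughout the package (label_seq in mmCIF is ignored).

#' Construct a structure table
#'
#' Builds the atom-table representation used by all analysis functions:
#' one row per atom with chain id, author residue number, residue name,
#' atom name, element and Cartesian coordinates in Angstrom.
#'
#' @param atoms Data frame with columns `chain`, `seq_id`, `res_name`,
#'   `atom`, `element`, `x`, `y`, `z`.
#' @param title Optional title string.
#' @return A tibble of class `cc_structure`.
#' @export
cc_structure <- function(atoms, title = "") {
  atoms <- as_tibble(atoms)
  needed <- c("chain", "seq_id", "res_name", "atom", "element", "x", "y", "z")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("atoms is missing column(s): ", paste(missing, collapse = ", ")))
  }
  atoms$seq_id <- as.integer(atoms$seq_id)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("atom coordinates must be finite")
  }
  dup <- atoms |>
    dplyr::count(.data$chain, .data$seq_id, .data$atom) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate atom '%s' in chain %s residue %d",
                  dup$atom[1], dup$chain[1], dup$seq_id[1]))
  }
  # seq_id strictly increasing within each chain (order-preserving contract)
  bad <- atoms |>
    group_by(.data$chain) |>
    summarise(ok = all(diff(rle(.data$seq_id)$values) > 0), .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(sprintf("residue numbering not strictly increasing in chain %s", bad$chain[1]))
  }
  structure(atoms, class = c("cc_structure", class(tibble())), title = title)
}

#' @export
print.cc_structure <- function(x, ...) {
  ttl <- attr(x, "title")
  cat(sprintf("<cc_structure> %d atoms, %d chain(s)%s\n",
              nrow(x), dplyr::n_distinct(x$chain),
              if (nzchar(ttl)) paste0(" - ", ttl) else ""))
  NextMethod()
}

#' List chain identifiers of a structure
#' @param model A `cc_structure`.
#' @return Character vector of chain ids in file order.
#' @export
chain_ids <- function(model) unique(model$chain)

#' Read an atomic structure
#'
#' Reads PDB or mmCIF coordinate files into the tidy atom table. Only the
#' first model of a multi-model file is used. Author chain ids and author
#' residue numbers are kept; mmCIF `label_seq_id` is ignored. Files with
#' insertion codes or alternate locations are rejected.
#'
#' @param path File path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @return A `cc_structure` tibble.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- if (format == "pdb") {
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  } else {
    suppressWarnings(bio3d::read.cif(path, multi = FALSE, verbose = FALSE))
  }
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(at) == 0) abort(sprintf("no coordinate records in %s", path))
  if (any(!is.na(at$insert) & nzchar(at$insert))) {
    abort(sprintf("insertion codes are not supported (found in %s)", path))
  }
  alt <- at$alt[!is.na(at$alt) & nzchar(at$alt)]
  if (length(alt) > 0) {
    abort(sprintf("alternate locations are not supported (found in %s)", path))
  }
  chain <- ifelse(is.na(at$chain), " ", at$chain)
  elem <- at$elesy
  if (is.null(elem)) elem <- NA_character_
  elem <- ifelse(is.na(elem) | !nzchar(elem),
                 substr(gsub("[0-9]", "", at$elety), 1, 1), elem)
  cc_structure(
    tibble(
      chain = chain,
      seq_id = as.integer(at$resno),
      res_name = at$resid,
      atom = at$elety,
      element = elem,
      x = at$x, y = at$y, z = at$z
    ),
    title = basename(path)
  )
}

#' Write a structure as PDB
#'
#' Serializes the atom table to PDB ATOM records with chain-terminating TER
#' lines. Coordinates are written with three decimals (the PDB fixed-column
#' precision); chain ids must be a single character as the format requires.
#'
#' @param model A `cc_structure`.
#' @param path Output file path.
#' @param format Only `"pdb"` is supported.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path, format = "pdb") {
  if (!identical(format, "pdb")) abort("only PDB output is supported")
  if (nrow(model) == 0) abort("refusing to write a structure with no atoms")
  if (any(nchar(model$chain) > 1)) {
    abort("PDB chain ids must be a single character; rename chains first")
  }
  per_res <- model |> dplyr::count(.data$chain, .data$seq_id)
  if (any(per_res$n < 1)) abort("every residue needs at least one atom")
  lines <- character(0)
  ttl <- attr(model, "title")
  if (!is.null(ttl) && nzchar(ttl)) {
    lines <- c(lines, sprintf("TITLE     %s", substr(ttl, 1, 60)))
  }
  serial <- 0L
  for (ch in chain_ids(model)) {
    sub <- model[model$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1L
      a <- sub[i, ]
      name <- a$atom
      # PDB atom-name column convention: element right-justified in 13-14
      name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
      lines <- c(lines, sprintf(
        "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, name_fmt, a$res_name, ch, a$seq_id,
        a$x, a$y, a$z, 1, 0, a$element
      ))
    }
    serial <- serial + 1L
    last <- sub[nrow(sub), ]
    lines <- c(lines, sprintf("TER   %5d      %-3s %1s%4d",
                              serial %% 100000L, last$res_name, ch, last$seq_id))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Extract one-letter sequences per chain
#'
#' Translates residue names to one-letter codes, one sequence per chain.
#' Non-standard residue names map to `X` with a warning.
#'
#' @param model A `cc_structure`.
#' @param chain Optional single chain id; default all chains.
#' @return Tibble with columns `chain`, `sequence`, `n_res`, `n_unknown`.
#' @export
extract_sequences <- function(model, chain = NULL) {
  if (!is.null(chain)) model <- model[model$chain %in% chain, , drop = FALSE]
  res <- model |>
    distinct(.data$chain, .data$seq_id, .data$res_name)
  res$aa <- unname(aa_three_to_one[res$res_name])
  n_unk <- sum(is.na(res$aa))
  if (n_unk > 0) {
    warn(sprintf("%d residue(s) with non-standard names mapped to X", n_unk))
    res$aa[is.na(res$aa)] <- "X"
  }
  res |>
    group_by(.data$chain) |>
    summarise(
      sequence = paste(.data$aa, collapse = ""),
      n_res = dplyr::n(),
      n_unknown = sum(.data$aa == "X"),
      .groups = "drop"
    ) |>
    arrange(match(.data$chain, chain_ids(model)))
}

#' @rdname extract_sequences
#' @export
extract_sequence <- function(model, chain) {
  out <- extract_sequences(model, chain = chain)
  if (nrow(out) == 0) return("")
  out$sequence[[1]]
}

#' Read protein sequences from FASTA
#'
#' Sequence-mode input for the composition statistics: reads a FASTA file
#' into a tibble of named one-letter sequences.
#'
#' @param path FASTA file path.
#' @return Tibble with columns `chain` (record name) and `sequence`.
#' @export
read_fasta_sequences <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required to read FASTA files")
  }
  ss <- Biostrings::readAAStringSet(path)
  tibble(chain = sub("\\s.*$", "", names(ss)), sequence = as.character(ss))
}

#' Per-residue table of a structure
#'
#' One row per residue with the one-letter code, in chain/residue order.
#'
#' @param model A `cc_structure`.
#' @return Tibble with columns `chain`, `seq_id`, `res_name`, `aa`.
#' @export
residue_table <- function(model) {
  res <- model |> distinct(.data$chain, .data$seq_id, .data$res_name)
  res$aa <- unname(aa_three_to_one[res$res_name])
  res$aa[is.na(res$aa)] <- "X"
  res
}

# internal: n x 3 coordinate matrix for a set of rows
coords_matrix <- function(model) {
  cbind(x = model$x, y = model$y, z = model$z)
}

# internal: CA trace for one chain, in residue order
ca_trace <- function(model, chain) {
  sub <- model[model$chain == chain & model$atom == "CA", , drop = FALSE]
  if (nrow(sub) == 0) abort(sprintf("chain %s has no CA atoms", chain))
  sub[order(sub$seq_id), , drop = FALSE]
}
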