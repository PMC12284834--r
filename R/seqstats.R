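# Per-heptad-position composition statistics: hydropathy, residue volume
# and alanine content at each register position, pooled over chains.

#' Per-residue register table
#'
#' Joins a structure's sequence with a geometry fit's register assignment,
#' producing the registered-residue input for [per_position_stats()].
#'
#' @param model A `cc_structure`.
#' @param fit A `cc_fit` from [fit_coiled_coil()].
#' @return Tibble with columns `chain`, `seq_id`, `aa`, `register`.
#' @export
register_table <- function(model, fit) {
  residue_table(model) |>
    select("chain", "seq_id", "aa") |>
    left_join(fit$residues |> select("chain", "seq_id", "register"),
              by = c("chain", "seq_id"))
}

#' Composition statistics per heptad position
#'
#' Arithmetic means of Kyte-Doolittle hydropathy and Zamyatnin residue
#' volume, plus the alanine fraction, at each heptad position `a`-`g`,
#' pooled over all chains. Residues with unknown amino-acid codes or
#' missing register labels are excluded with a warning.
#'
#' @param registered Data frame with columns `aa` (one-letter code) and
#'   `register` (heptad letter); e.g. from [register_table()], or built
#'   from user-supplied sequences and alignments.
#' @return Tibble with 7 rows: `register`, `n_residues`, `mean_hydropathy`,
#'   `mean_volume`, `ala_fraction`.
#' @export
per_position_stats <- function(registered) {
  registered <- as_tibble(registered)
  if (nrow(registered) == 0) abort("no registered residues supplied")
  scales <- aa_scales()
  bad <- !(registered$aa %in% scales$aa) | !(registered$register %in% heptad_letters())
  if (any(bad)) {
    warn(sprintf("excluding %d residue(s) with unknown code or register", sum(bad)))
    registered <- registered[!bad, , drop = FALSE]
  }
  if (nrow(registered) == 0) abort("no scorable residues after exclusions")
  registered |>
    left_join(scales, by = "aa") |>
    mutate(register = factor(.data$register, levels = heptad_letters())) |>
    group_by(.data$register, .drop = FALSE) |>
    summarise(
      n_residues = dplyr::n(),
      mean_hydropathy = mean(.data$hydropathy),
      mean_volume = mean(.data$volume),
      ala_fraction = mean(.data$aa == "A"),
      .groups = "drop"
    ) |>
    mutate(register = as.character(.data$register))
}

#' Export a composition table as CSV (radar-plot data)
#'
#' Writes the 7-position composition table; with `normalize = TRUE` each
#' metric column is scaled by its maximum absolute value so all metrics
#' share a unit range.
#'
#' @param table Output of [per_position_stats()].
#' @param path Output CSV path.
#' @param normalize Scale each metric to max |value| 1.
#' @return Invisibly, the (possibly normalized) tibble written.
#' @export
radar_export <- function(table, path, normalize = FALSE) {
  out <- table
  if (normalize) {
    for (col in c("mean_hydropathy", "mean_volume", "ala_fraction")) {
      m <- max(abs(out[[col]]))
      if (m > 0) out[[col]] <- out[[col]] / m
    }
  }
  readr::write_csv(out, path)
  invisible(out)
}

#' Radar-style plot of per-position composition
#'
#' @param table Output of [per_position_stats()].
#' @return A ggplot: the three metrics (max-|value|-scaled) on a polar
#'   heptad-position axis.
#' @export
plot_composition_radar <- function(table) {
  long <- table |>
    mutate(across(c("mean_hydropathy", "mean_volume", "ala_fraction"),
                  ~ .x / max(abs(.x)))) |>
    tidyr::pivot_longer(c("mean_hydropathy", "mean_volume", "ala_fraction"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$register, y = .data$value,
                                     group = .data$metric,
                                     colour = .data$metric)) +
    ggplot2::geom_polygon(fill = NA) +
    ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::labs(x = "heptad position", y = "scaled value") +
    ggplot2::theme_minimal()
}
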