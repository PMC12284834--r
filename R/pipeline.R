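# End-to-end pipeline: build or load a structure, fit geometry, detect
# packing, map crosslinks, compute composition statistics, analyse CD and
# melts, predict assembly, and write a report bundle.

default_config <- function() {
  list(
    seed = 1L,
    structure = list(synthetic = TRUE, n_res = 168, r0 = 5.8, pitch = 153,
                     noise_sd = 0),
    crosslinks = list(synthetic = TRUE, n_links = 50, decoy_fraction = 0.1,
                      cutoff = 30),
    packing = list(kih_cutoff = 7.0, bridge_cutoff = 4.0),
    cd = list(single_ratio = 0.8, mix_ratio = 0.95),
    melt = list(tm = 63, width = 2, noise_sd = 0),
    assembly = list(F1 = 1, F2 = 1.2, F3 = 1, F4 = 1.2)
  )
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]])) {
      merge_config(base[[k]], user[[k]])
    } else {
      user[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$seed)) abort("config: seed must be numeric")
  st <- cfg$structure
  if (!isTRUE(st$synthetic) && is.null(st$path)) {
    abort("config: structure needs synthetic: true or a path")
  }
  xl <- cfg$crosslinks
  if (!isTRUE(xl$synthetic) && is.null(xl$path) && !isFALSE(xl$enabled %||% TRUE)) {
    abort("config: crosslinks need synthetic: true, a path, or enabled: false")
  }
  invisible(cfg)
}

#' Run the full coiled-coil analysis pipeline
#'
#' Chains build/load, geometry fit, packing detection, crosslink mapping,
#' composition statistics, CD ratio analysis, melt fitting and assembly
#' prediction, writing a report bundle (`fit.json`, `kih.tsv`,
#' `bridges.tsv`, `xlms_report.tsv`, `composition.csv`, `cd.json`,
#' `melt.json`, `assembly.tsv`, `summary.txt`) to `out_dir`. Fully
#' deterministic given the config and its seed; every effective parameter
#' is echoed in the summary.
#'
#' @param config Path to a YAML config file, or a config list. Omitted
#'   fields fall back to a self-contained synthetic default.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all intermediate results.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("coilspect_")) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- validate_config(merge_config(default_config(), cfg))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  seed <- as.integer(cfg$seed)

  model <- stage("structure", {
    st <- cfg$structure
    if (isTRUE(st$synthetic)) {
      p <- silk_params(n_res = as.integer(st$n_res), r0 = st$r0,
                       pitch = st$pitch)
      m <- build_bundle(p, seed = seed)
      if (st$noise_sd > 0) m <- perturb(m, st$noise_sd, seed = seed)
      m
    } else {
      read_structure(st$path)
    }
  })
  fit <- stage("geometry", fit_coiled_coil(model))
  write_fit_json(fit, file.path(out_dir, "fit.json"))
  writeLines(register_fasta(fit, model), file.path(out_dir, "register.txt"))

  kih <- stage("packing", detect_kih(model, fit,
                                     center_cutoff = cfg$packing$kih_cutoff))
  kih_flat <- kih |>
    mutate(hole_res = vapply(.data$hole_res, paste, character(1), collapse = "+"),
           center_distances = vapply(.data$center_distances, function(d)
             paste(sprintf("%.2f", d), collapse = "+"), character(1)))
  readr::write_tsv(kih_flat, file.path(out_dir, "kih.tsv"))
  bridges <- stage("packing", detect_salt_bridges(
    model, fit, cutoff = cfg$packing$bridge_cutoff, scope = "inter"))
  readr::write_tsv(bridges, file.path(out_dir, "bridges.tsv"))

  xl_report <- NULL
  if (!isFALSE(cfg$crosslinks$enabled %||% TRUE)) {
    xl <- stage("xlms", {
      if (isTRUE(cfg$crosslinks$synthetic)) {
        sample_crosslinks(model, n_links = cfg$crosslinks$n_links,
                          max_dist = cfg$crosslinks$cutoff,
                          decoy_fraction = cfg$crosslinks$decoy_fraction,
                          seed = seed)
      } else {
        read_crosslinks(cfg$crosslinks$path)
      }
    })
    mapped <- stage("xlms", map_crosslinks(xl, model, fit,
                                           cutoff = cfg$crosslinks$cutoff))
    xl_report <- restraint_report(mapped)
    readr::write_tsv(xl_report$links, file.path(out_dir, "xlms_report.tsv"))
  }

  comp <- stage("seqstats", per_position_stats(register_table(model, fit)))
  radar_export(comp, file.path(out_dir, "composition.csv"))

  cd <- stage("cd", {
    singles <- lapply(seq_len(4), function(i)
      simulate_cd("single_helix", ratio_222_209 = cfg$cd$single_ratio))
    mix <- simulate_cd("coiled_coil", ratio_222_209 = cfg$cd$mix_ratio)
    sim <- combine_spectra(singles, rep(0.25, 4))
    list(single_ratio = ratio_222_209(singles[[1]]),
         simulated_sum_ratio = ratio_222_209(sim),
         mixture_ratio = ratio_222_209(mix))
  })
  jsonlite::write_json(lapply(cd, as.list), file.path(out_dir, "cd.json"),
                       auto_unbox = TRUE, digits = NA)

  melt <- stage("melt", {
    curve <- simulate_melt(tm = cfg$melt$tm, width = cfg$melt$width,
                           noise_sd = cfg$melt$noise_sd, seed = seed)
    fit_two_state_melt(curve)
  })
  jsonlite::write_json(as.list(glance(melt)), file.path(out_dir, "melt.json"),
                       auto_unbox = TRUE, digits = NA)

  mix <- stage("assembly", do.call(assemble, unname(cfg$assembly[c("F1", "F2", "F3", "F4")])))
  readr::write_tsv(as_tibble(mix), file.path(out_dir, "assembly.tsv"))

  summary_lines <- c(
    "coilspect pipeline summary",
    paste0("seed: ", seed),
    paste0("config: ", gsub("\n", " ", yaml::as.yaml(cfg))),
    sprintf("geometry: r0 %.3f A, pitch %s, handedness %s, extent %.1f A",
            fit$r0, ifelse(is.na(fit$pitch), "NA", sprintf("%.2f A", fit$pitch)),
            fit$handedness, fit$extent),
    sprintf("arrangement: %s", paste(fit$arrangement, collapse = "-")),
    sprintf("heptads per chain: %s",
            paste(names(fit$n_heptads), fit$n_heptads, sep = "=", collapse = " ")),
    sprintf("knob contacts: %d; salt bridges: %d", nrow(kih), nrow(bridges)),
    if (!is.null(xl_report)) {
      sprintf("crosslinks: %d unique, satisfied fraction %.3f",
              xl_report$summary$n_unique, xl_report$summary$satisfied_fraction)
    },
    sprintf("melt: Tm %.2f degC (%s)", melt$tm,
            if (melt$cooperative) "cooperative" else "non-cooperative"),
    sprintf("assembly: tetramer %.3f, trimer %.3f, dimer %.3f",
            mix$F1F2F3F4, mix$F2F3F4, mix$F2F4)
  )
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(list(config = cfg, model = model, fit = fit, kih = kih,
                 bridges = bridges, xlms = xl_report, composition = comp,
                 cd = cd, melt = melt, assembly = mix, out_dir = out_dir))
}

# per-chain register annotation in a FASTA-like two-line layout
register_fasta <- function(fit, model) {
  seqs <- extract_sequences(model)
  unlist(lapply(seqs$chain, function(ch) {
    reg <- fit$residues[fit$residues$chain == ch, ]
    c(paste0(">", ch),
      seqs$sequence[seqs$chain == ch],
      paste(reg$register, collapse = ""))
  }))
}

#' Crick-phase and register plot for a geometry fit
#'
#' @param object A `cc_fit`.
#' @param ... Unused.
#' @return A ggplot of per-residue Crick phase coloured by register,
#'   faceted by chain.
#' @export
autoplot.cc_fit <- function(object, ...) {
  df <- object$residues |> filter(!is.na(.data$crick_phase))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$seq_id, y = .data$crick_phase,
                                   colour = .data$register)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~chain) +
    ggplot2::labs(x = "residue", y = "Crick phase (deg)") +
    ggplot2::theme_minimal()
}
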