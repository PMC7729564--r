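# Pipeline orchestration: configuration, file I/O, and the
# simulate -> gate -> fit -> cluster -> enrich run with a human-readable
# report. Every output table carries the configuration hash in a header
# comment for provenance.

#' Build a validated run configuration
#'
#' @param simulation A `screen_config` (see [default_screen_config()]) to
#'   simulate input data, or `NULL` when `event_dir` is given.
#' @param event_dir Directory of per-well event tables plus a
#'   `layout.csv` (`strain_id`, `well`, `day`), used instead of simulation.
#' @param catalog_path Optional category-catalog file ([read_catalog()]);
#'   when absent the enrichment stage is skipped with a logged notice.
#' @param background_path Optional background gene list for the catalog.
#' @param gate [gate_params()].
#' @param fit [fit_options()].
#' @param k_range Candidate cluster numbers.
#' @param standardize Z-score features before clustering.
#' @param seed Integer seed for all randomness in the run.
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = default_screen_config(),
                       event_dir = NULL, catalog_path = NULL,
                       background_path = NULL,
                       gate = gate_params(), fit = fit_options(),
                       k_range = 2:15, standardize = TRUE, seed = 1) {
  if (is.null(simulation) && is.null(event_dir)) {
    stop("either a simulation config or an event_dir is required")
  }
  structure(list(simulation = simulation, event_dir = event_dir,
                 catalog_path = catalog_path,
                 background_path = background_path, gate = gate, fit = fit,
                 k_range = k_range, standardize = standardize,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Unknown top-level keys are rejected. Recognized keys mirror the
#' [run_config()] arguments; `simulation: default` requests
#' [default_screen_config()] with optional `n_strains`, `n_events`,
#' `noise_sd`, `doublet_rate` overrides.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("simulation", "event_dir", "catalog_path", "background_path",
             "gate", "fit", "k_range", "standardize", "seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  sim <- NULL
  if (!is.null(y$simulation)) {
    s <- y$simulation
    sim_args <- s[setdiff(names(s), "kind")]
    sim <- do.call(default_screen_config, sim_args)
  }
  gate <- do.call(gate_params, as.list(y$gate %||% list()))
  fit <- do.call(fit_options, as.list(y$fit %||% list()))
  kr <- if (is.null(y$k_range)) 2:15 else y$k_range[1]:y$k_range[2]
  run_config(simulation = sim, event_dir = y$event_dir,
             catalog_path = y$catalog_path,
             background_path = y$background_path,
             gate = gate, fit = fit, k_range = kr,
             standardize = y$standardize %||% TRUE, seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hash a configuration for provenance
#'
#' FNV-1a hash of the deparsed configuration, reported as 8 hex digits in the
#' header comment of every output file.
#'
#' @param config Any R object.
#' @return Character scalar, e.g. `"a1b2c3d4"`.
#' @export
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "\n")
  h <- 2166136261
  for (code in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2^31), code)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Write an event table
#'
#' Canonical delimited-text form: a `# quiescreen` header comment (carrying
#' the config hash when given), one header row, and exactly the columns
#' `event_id, FSC_A, FSC_H, SSC_A, VIAB, DNA_A, DNA_W`. The simulator's
#' `true_pop` ground-truth column is dropped on export.
#'
#' @param events Event table data frame.
#' @param path Output path.
#' @param hash Optional config hash string for the header.
#' @export
write_event_table <- function(events, path, hash = NULL) {
  cols <- c("event_id", EVENT_CHANNELS)
  .check_event_table(events)
  if (!"event_id" %in% names(events)) events$event_id <- seq_len(nrow(events))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# quiescreen event table",
                    if (!is.null(hash)) paste0(" config_hash=", hash)), con)
  utils::write.csv(events[, cols], con, row.names = FALSE, quote = FALSE)
}

#' Read an event table
#'
#' Reads the delimited-text event format (comment lines starting with `#`
#' are skipped), checks that all six channels are present, and drops rows
#' with missing or negative intensities, tallying them as anomalies.
#'
#' @param path File path.
#' @param channel_map Optional named character vector mapping file column
#'   names to the canonical channel names (`c(FL3A = "VIAB")` renames an
#'   `FL3A` column to `VIAB`).
#' @return Validated event table; the number of dropped rows is in the
#'   `"n_anomalies"` attribute.
#' @export
read_event_table <- function(path, channel_map = NULL) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(channel_map)) {
    for (from in names(channel_map)) {
      names(tab)[names(tab) == from] <- channel_map[[from]]
    }
  }
  miss <- setdiff(EVENT_CHANNELS, names(tab))
  if (length(miss) > 0) {
    stop("event table ", path, " lacks channel(s): ",
         paste(miss, collapse = ", "))
  }
  vals <- as.matrix(tab[, EVENT_CHANNELS])
  bad <- rowSums(!is.finite(vals) | vals < 0) > 0
  out <- tab[!bad, , drop = FALSE]
  if (nrow(out) == 0) stop("no valid events in ", path)
  attr(out, "n_anomalies") <- sum(bad)
  out
}

.write_table <- function(df, path, hash, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# quiescreen %s config_hash=%s", what, hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

.load_event_dir <- function(event_dir) {
  layout <- utils::read.csv(file.path(event_dir, "layout.csv"),
                            comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("strain_id", "well", "day") %in% names(layout)))
  wells <- lapply(layout$well, function(w) {
    read_event_table(file.path(event_dir, paste0(gsub("[|]", "_", w), ".csv")))
  })
  names(wells) <- layout$well
  list(wells = wells, layout = layout)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) per-well event tables, gates every well, fits and
#' selects mortality models per strain, assembles and clusters the
#' five-feature phenotype matrix, computes cluster enrichment when a catalog
#' is configured, and writes all stage tables plus a run report to `outdir`.
#' Identical configuration and seed give identical outputs.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed); `NULL` returns results
#'   without writing files.
#' @return (Invisibly) a list with `well_summaries`, `fit_table`,
#'   `phenotypes`, `clustering`, `enrichment` (`NULL` when skipped),
#'   `ground_truth` (simulated runs), and `report` (character lines).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  # --- input stage ---------------------------------------------------------
  ground_truth <- NULL
  if (!is.null(config$event_dir)) {
    say("stage load: reading event tables from %s", config$event_dir)
    screen <- .load_event_dir(config$event_dir)
  } else {
    say("stage simulate: %d strains x %d days, %d events/well, seed %d",
        nrow(config$simulation$strains), length(config$simulation$timepoints),
        config$simulation$n_events, config$seed)
    screen <- simulate_screen(config$simulation, seed = config$seed)
    ground_truth <- screen$ground_truth
  }

  # --- gating --------------------------------------------------------------
  ws <- summarize_screen(screen$wells, screen$layout, config$gate)
  n_fail <- sum(!ws$qc_pass)
  say("stage gate: %d wells summarized, %d failed the %d-singlet QC cutoff",
      nrow(ws), n_fail, config$gate$min_singlets)
  if (n_fail > 0) {
    for (i in which(!ws$qc_pass)) {
      say("  QC fail: %s day %s (%d singlets)", ws$strain_id[i], ws$day[i],
          ws$n_singlets[i])
    }
  }

  # --- fitting -------------------------------------------------------------
  fit_tab <- fit_screen(ws, config$fit, seed = config$seed)
  say("stage fit: %d/%d strains fittable", sum(fit_tab$fittable),
      nrow(fit_tab))

  # --- clustering ----------------------------------------------------------
  phen <- build_phenotype_matrix(fit_tab, ws)
  excl <- attr(phen, "exclusions")
  say("stage cluster: %d phenotype records (%d excluded)", nrow(phen),
      nrow(excl))
  for (i in seq_len(nrow(excl))) {
    say("  excluded: %s (%s)", excl$strain_id[i], excl$reason[i])
  }
  clus <- NULL
  if (nrow(phen) >= 3) {
    clus <- cluster_phenotypes(phen, config$k_range, config$standardize)
    say("stage cluster: chosen k = %d (max CCC %.2f)", clus$chosen_k,
        max(clus$ccc_by_k$ccc[is.finite(clus$ccc_by_k$ccc)], -Inf))
  } else {
    say("stage cluster: skipped, fewer than 3 records")
  }

  # --- enrichment ----------------------------------------------------------
  enr <- NULL
  if (!is.null(config$catalog_path) && !is.null(clus)) {
    catalog <- read_catalog(config$catalog_path, config$background_path)
    enr <- cluster_enrichment(clus$assignments, catalog)
    say("stage enrich: %d (cluster, category) pairs reported", nrow(enr))
  } else {
    say("stage enrich: skipped (no catalog configured)")
  }

  # --- outputs -------------------------------------------------------------
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    .write_table(ws, file.path(outdir, "well_summaries.csv"), hash,
                 "well summaries")
    .write_table(fit_tab, file.path(outdir, "fit_table.csv"), hash,
                 "fit table")
    .write_table(phen, file.path(outdir, "phenotype_matrix.csv"), hash,
                 "phenotype matrix")
    if (!is.null(clus)) {
      .write_table(clus$assignments,
                   file.path(outdir, "cluster_assignments.csv"), hash,
                   "cluster assignments")
      .write_table(clus$ccc_by_k, file.path(outdir, "ccc_by_k.csv"), hash,
                   "ccc by k")
      profile <- stats::aggregate(
        phen[, PHENOTYPE_FEATURES],
        by = list(cluster = clus$assignments$cluster), FUN = mean)
      .write_table(profile, file.path(outdir, "cluster_profiles.csv"), hash,
                   "cluster profiles")
    }
    if (!is.null(enr)) {
      .write_table(enr, file.path(outdir, "enrichment.csv"), hash,
                   "enrichment")
    }
    if (!is.null(ground_truth)) {
      yaml::write_yaml(ground_truth, file.path(outdir, "ground_truth.yaml"))
    }
    yaml::write_yaml(list(config_hash = hash, seed = config$seed),
                     file.path(outdir, "run_provenance.yaml"))
    writeLines(c(sprintf("# quiescreen run report config_hash=%s", hash),
                 log_lines), file.path(outdir, "report.txt"))
  }

  invisible(list(well_summaries = ws, fit_table = fit_tab, phenotypes = phen,
                 clustering = clus, enrichment = enr,
                 ground_truth = ground_truth, report = log_lines,
                 config_hash = hash))
}
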