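#' Packaged threshold table
#'
#' Literature toxic-effect thresholds and adequate/high reference bands for
#' stable elements in liver, kidney and bone (mg/kg dry mass). Values
#' originally published on a wet-mass basis carry the dry-mass factor that
#' was applied in `dry_mass_factor_applied`. Users can edit a copy and pass
#' it to [screen_thresholds()].
#'
#' @return data.frame of threshold entries.
#' @export
default_thresholds <- function() {
  utils::read.csv(system.file("extdata", "thresholds.csv", package = "radecol"),
                  stringsAsFactors = FALSE)
}

#' Packaged soil reference table
#'
#' Two literature soil 137Cs activities (109 and 141 Bq/kg dry mass) with
#' assumed mid-survey reference dates, plus synthetic placeholder values for
#' 210Pb and the stable elements (real soil concentrations are site-specific
#' and must be supplied by the user).
#'
#' @return data.frame usable as `soil_table` in [cr_table()].
#' @export
default_soil_table <- function() {
  utils::read.csv(system.file("extdata", "soil_synthetic.csv", package = "radecol"),
                  stringsAsFactors = FALSE)
}

# measurement units to mg/kg (dry basis assumed preserved)
to_mg_per_kg <- function(value, unit) {
  switch(unit,
         "mg/kg" = value,
         "ug/kg" = value / 1000,
         "g/kg" = value * 1000,
         stop_radecol(paste0("cannot convert unit to mg/kg: ", unit),
                      "radecol_unit_error"))
}

#' Screen measured ranges against literature thresholds
#'
#' Compares the observed detected min-max per analyte and tissue (converted
#' to mg/kg dry mass) with the threshold entries. Wet-mass thresholds are
#' converted to the dry basis by multiplying by the entry's
#' `dry_mass_factor_applied` before comparison; a wet-mass entry without a
#' factor is a configuration error. Flags: for `toxic`/`high` entries,
#' `"exceeds"` or `"within"`; for `adequate` bands, any combination of
#' `"below"`, `"within"` and `"above"` the band that the observed range
#' touches, joined with `"+"`.
#'
#' @param dataset a [cohort_dataset] with dry-basis stable element data.
#' @param thresholds data.frame as [default_thresholds()].
#' @return data.frame: analyte, tissue, observed_min, observed_max,
#'   threshold_value, threshold_high, threshold_kind, flag.
#' @export
screen_thresholds <- function(dataset, thresholds = default_thresholds()) {
  m <- dataset$measurements
  rows <- list()
  for (i in seq_len(nrow(thresholds))) {
    th <- thresholds[i, ]
    sub <- m[m$analyte == th$analyte & m$tissue == th$tissue & !m$censored, ]
    if (nrow(sub) == 0) next
    if (any(sub$basis != "dry"))
      stop_radecol("screening expects dry-basis measurements", "radecol_config_error")
    vals <- vapply(seq_len(nrow(sub)),
                   function(j) to_mg_per_kg(sub$value[j], sub$unit[j]), 0)
    lo_th <- th$threshold_value
    hi_th <- if (!is.na(th$threshold_high)) th$threshold_high else NA_real_
    if (identical(th$threshold_basis, "wet")) {
      if (is.na(th$dry_mass_factor_applied))
        stop_radecol(paste0("wet-mass threshold without dry-mass factor: ",
                            th$analyte, "/", th$tissue), "radecol_config_error")
      lo_th <- lo_th * th$dry_mass_factor_applied
      hi_th <- hi_th * th$dry_mass_factor_applied
    }
    omin <- min(vals); omax <- max(vals)
    flag <- if (th$threshold_kind %in% c("toxic", "high")) {
      if (omax > lo_th) "exceeds" else "within"
    } else {  # adequate band
      band_hi <- if (is.na(hi_th)) lo_th else hi_th
      parts <- c(if (omin < lo_th) "below",
                 if (omax >= lo_th && omin <= band_hi) "within",
                 if (omax > band_hi) "above")
      paste(parts, collapse = "+")
    }
    rows[[length(rows) + 1L]] <-
      data.frame(analyte = th$analyte, tissue = th$tissue,
                 observed_min = omin, observed_max = omax,
                 threshold_value = lo_th, threshold_high = hi_th,
                 threshold_kind = th$threshold_kind, flag = flag)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run configuration for the full pipeline
#'
#' @param animal_csv,measurement_csv input CSVs; if `NULL` a synthetic cohort
#'   is generated from `sim` instead.
#' @param sim a [sim_params()] object for the simulate branch.
#' @param output_dir directory for the report CSVs.
#' @param seed master seed, recorded in every output's header comment.
#' @param censoring censoring policy for summaries (`"drop"` or `"half_lod"`).
#' @param mcmc an [mcmc_settings()] for the analogue correlations.
#' @param n_permutations Monte-Carlo permutation count.
#' @param analogue_pairs 2-column matrix of radionuclide/analogue pairs.
#' @param cr_analytes analytes for the concentration-ratio table.
#' @param soil_table soil reference table (default packaged synthetic table).
#' @param transfer a [transfer_config()].
#' @param thresholds threshold table for screening.
#' @return List of class `run_config`.
#' @export
run_config <- function(animal_csv = NULL, measurement_csv = NULL,
                       sim = sim_params(), output_dir = tempfile("radecol_run_"),
                       seed = 1, censoring = "drop",
                       mcmc = mcmc_settings(n_chains = 2, n_draws = 500,
                                            n_tune = 300, seed = seed),
                       n_permutations = 10000,
                       analogue_pairs = cbind(c("Cs137"), c("Cs")),
                       cr_analytes = c("Cs137", "Pb210", "Cd", "Pb"),
                       soil_table = default_soil_table(),
                       transfer = transfer_config(),
                       thresholds = default_thresholds()) {
  structure(list(animal_csv = animal_csv, measurement_csv = measurement_csv,
                 sim = sim, output_dir = output_dir, seed = seed,
                 censoring = censoring, mcmc = mcmc,
                 n_permutations = n_permutations,
                 analogue_pairs = analogue_pairs, cr_analytes = cr_analytes,
                 soil_table = soil_table, transfer = transfer,
                 thresholds = thresholds),
            class = "run_config")
}

write_report_csv <- function(df, path, seed) {
  con <- file(path, "w")
  writeLines(paste0("# seed=", seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate-or-load, validation, descriptive summaries,
#' relative-to-muscle distribution with paired sign-flip tests, Spearman
#' inter-tissue matrices, robust analogue correlations, concentration ratios
#' and threshold screening. Each stage writes a CSV headed by a
#' `# seed=` comment, a log line records row counts per stage, and a JSON
#' manifest records the configuration. Two runs with the same configuration
#' produce byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return The output directory path, invisibly; errors name the failing
#'   stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log_stage <- function(stage, n_in, n_out, dropped = 0) {
    log_lines <<- c(log_lines,
                    sprintf("%s: in=%d out=%d dropped=%d", stage, n_in, n_out, dropped))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_radecol(paste0("stage ", name, " failed: ", conditionMessage(e)),
                   "radecol_pipeline_error"))
  }

  dataset <- stage("load", {
    if (!is.null(config$animal_csv)) {
      if (!file.exists(config$animal_csv))
        stop_radecol(paste0("missing input file: ", config$animal_csv),
                     "radecol_config_error")
      read_cohort(config$animal_csv, config$measurement_csv)
    } else generate_cohort(config$sim)
  })
  n_meas <- nrow(dataset$measurements)
  log_stage("load", n_meas, n_meas)

  stage("summaries", {
    ts <- tissue_summary(dataset)
    write_report_csv(ts, file.path(out, "summary.csv"), config$seed)
    log_stage("summaries", n_meas, nrow(ts),
              n_meas - sum(ts$n_detected + ts$n_censored))
  })

  stage("relative", {
    rows <- list()
    for (r in seq_len(nrow(config$analogue_pairs))) {
      for (an in config$analogue_pairs[r, ]) {
        rel <- relative_to_muscle(dataset, an, config$censoring)
        rows[[an]] <- data.frame(analyte = an,
                                 tissue = names(rel$mean_percent),
                                 mean_percent = unname(rel$mean_percent))
      }
      rad <- config$analogue_pairs[r, 1]; sta <- config$analogue_pairs[r, 2]
      rel_r <- relative_to_muscle(dataset, rad, config$censoring)
      rel_s <- relative_to_muscle(dataset, sta, config$censoring)
      shared <- intersect(rownames(rel_r$percent), rownames(rel_s$percent))
      tst <- lapply(setdiff(colnames(rel_r$percent), "muscle"), function(ti) {
        d <- rel_r$percent[shared, ti] - rel_s$percent[shared, ti]
        d <- d[!is.na(d)]
        res <- paired_signflip_test(d, config$n_permutations,
                                    seed = derive_seed(config$seed, ti))
        data.frame(tissue = ti, delta_mean = res$statistic_observed,
                   p_value = res$p_value, method = res$method,
                   n_permutations_used = res$n_permutations_used)
      })
      write_report_csv(do.call(rbind, tst),
                       file.path(out, paste0("signflip_", rad, "_vs_", sta, ".csv")),
                       config$seed)
    }
    rel_df <- do.call(rbind, rows)
    write_report_csv(rel_df, file.path(out, "relative_to_muscle.csv"), config$seed)
    log_stage("relative", n_meas, nrow(rel_df))
  })

  stage("spearman", {
    for (an in unique(as.vector(config$analogue_pairs))) {
      sm <- spearman_matrix(dataset, an)
      write_report_csv(as.data.frame(sm),
                       file.path(out, paste0("spearman_", an, ".csv")), config$seed)
    }
    log_stage("spearman", n_meas, length(unique(as.vector(config$analogue_pairs))))
  })

  stage("robust_correlation", {
    rows <- list()
    for (r in seq_len(nrow(config$analogue_pairs))) {
      tab <- analogue_correlation_table(dataset, config$analogue_pairs[r, 1],
                                        config$analogue_pairs[r, 2], config$mcmc)
      tab$pair <- paste0(config$analogue_pairs[r, 1], ":", config$analogue_pairs[r, 2])
      rows[[r]] <- tab
    }
    rc <- do.call(rbind, rows)
    write_report_csv(rc, file.path(out, "robust_correlation.csv"), config$seed)
    log_stage("robust_correlation", n_meas, nrow(rc))
  })

  stage("concentration_ratios", {
    if (is.null(config$soil_table))
      stop_radecol("missing soil table for CR stage", "radecol_config_error")
    crt <- cr_table(dataset, intersect(config$cr_analytes,
                                       unique(dataset$measurements$analyte)),
                    config$transfer, config$soil_table)
    write_report_csv(crt, file.path(out, "cr_table.csv"), config$seed)
    log_stage("concentration_ratios", n_meas, nrow(crt))
  })

  stage("screening", {
    sc <- screen_thresholds(dataset, config$thresholds)
    if (is.null(sc)) sc <- data.frame()
    write_report_csv(sc, file.path(out, "screening.csv"), config$seed)
    log_stage("screening", n_meas, nrow(sc))
  })

  writeLines(log_lines, file.path(out, "pipeline.log"))
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("radecol")),
                   n_animals = nrow(dataset$animals),
                   n_measurements = n_meas,
                   censoring = config$censoring,
                   mcmc = unclass(config$mcmc),
                   n_permutations = config$n_permutations)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
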