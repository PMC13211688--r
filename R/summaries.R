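#' Censoring-aware descriptive summary
#'
#' Arithmetic mean, sample SD, geometric mean, median and range of the
#' detected values in a vector; censored entries (reported thresholds) are
#' excluded from every statistic and only counted. The GM is
#' `exp(mean(log(detected)))` and requires strictly positive detections.
#'
#' @param values numeric vector of detections and censored thresholds.
#' @param censored logical vector marking below-threshold entries.
#' @return One-row data.frame: `n_detected`, `n_censored`, `am`, `sd`, `gm`,
#'   `median`, `min`, `max`.
#' @export
#' @examples
#' summarize_values(c(1, 10, 100))
summarize_values <- function(values, censored = rep(FALSE, length(values))) {
  stopifnot(length(values) == length(censored))
  det <- values[!censored]
  if (length(det) == 0)
    stop_radecol("no detected values to summarize", "radecol_empty_summary_error")
  if (any(det <= 0))
    stop_radecol("geometric mean undefined for nonpositive detected values",
                 "radecol_domain_error")
  data.frame(n_detected = length(det), n_censored = sum(censored),
             am = mean(det),
             sd = if (length(det) > 1) stats::sd(det) else 0,
             gm = exp(mean(log(det))),
             median = stats::median(det),
             min = min(det), max = max(det))
}

#' Per-tissue summary table for a cohort
#'
#' Applies [summarize_values()] to every analyte-by-tissue cell, producing the
#' conventional reporting layout (AM +- SD, GM, median, min-max, with detected
#' and censored counts).
#'
#' @param dataset a [cohort_dataset].
#' @param analytes analytes to include (default: all present).
#' @return data.frame, one row per analyte x tissue with data.
#' @export
tissue_summary <- function(dataset, analytes = NULL) {
  m <- dataset$measurements
  analytes <- analytes %||% unique(m$analyte)
  rows <- list()
  for (an in analytes) {
    for (ti in intersect(tissue_vocabulary(), unique(m$tissue[m$analyte == an]))) {
      sub <- m[m$analyte == an & m$tissue == ti, ]
      if (all(sub$censored)) next
      s <- summarize_values(sub$value, sub$censored)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(analyte = an, tissue = ti,
                         unit = sub$unit[1], basis = sub$basis[1]), s)
    }
  }
  do.call(rbind, rows)
}

#' Tissue distribution relative to muscle
#'
#' For each animal with a detected muscle value, expresses every other
#' tissue's concentration as a percentage of that animal's own muscle value,
#' then averages the per-animal percentages per tissue. Averaging per-animal
#' ratios (rather than taking a ratio of means) keeps the values paired, which
#' downstream paired sign-flip tests require. Animals without a detected
#' muscle value are dropped with a warning.
#'
#' @param dataset a [cohort_dataset].
#' @param analyte the analyte to profile.
#' @param censoring `"drop"` (default; censored values excluded) or
#'   `"half_lod"` (censored thresholds halved and used).
#' @return Object of class `relative_distribution`: list with `analyte`,
#'   `percent` (animal x tissue matrix, muscle column all 100) and
#'   `mean_percent` (named vector).
#' @export
relative_to_muscle <- function(dataset, analyte, censoring = c("drop", "half_lod")) {
  censoring <- match.arg(censoring)
  m <- dataset$measurements[dataset$measurements$analyte == analyte, ]
  if (censoring == "half_lod") {
    m$value[m$censored] <- m$value[m$censored] / 2
    m$censored <- FALSE
  }
  m <- m[!m$censored, ]
  musc <- m[m$tissue == "muscle", ]
  if (nrow(musc) == 0)
    stop_radecol(paste0("no animal with a detected muscle value for ", analyte),
                 "radecol_empty_result_error")
  dropped <- setdiff(unique(m$animal_id), musc$animal_id)
  if (length(dropped))
    warning("dropping animals without a detected muscle value: ",
            paste(dropped, collapse = ", "))
  ids <- musc$animal_id
  tissues <- intersect(tissue_vocabulary(), unique(m$tissue))
  pct <- matrix(NA_real_, length(ids), length(tissues),
                dimnames = list(ids, tissues))
  for (i in seq_along(ids)) {
    base <- musc$value[musc$animal_id == ids[i]][1]
    sub <- m[m$animal_id == ids[i], ]
    pct[i, ] <- 100 * sub$value[match(tissues, sub$tissue)] / base
  }
  structure(list(analyte = analyte, percent = pct,
                 mean_percent = colMeans(pct, na.rm = TRUE)),
            class = "relative_distribution")
}

#' @export
print.relative_distribution <- function(x, ...) {
  cat("Distribution of", x$analyte, "relative to muscle (mean %):\n")
  print(round(x$mean_percent, 1))
  invisible(x)
}

#' Spearman rank correlation matrix between tissues
#'
#' Tie-aware Spearman correlations (Pearson on midranks) between all tissue
#' pairs for one analyte, using pairwise-complete detected values. Entries
#' with fewer than three complete pairs are reported as `NA`, never as 0.
#'
#' @param dataset a [cohort_dataset].
#' @param analyte the analyte.
#' @param tissues tissues to include (default the full vocabulary).
#' @return Symmetric matrix with unit diagonal.
#' @export
spearman_matrix <- function(dataset, analyte, tissues = tissue_vocabulary()) {
  m <- dataset$measurements
  m <- m[m$analyte == analyte & !m$censored & m$tissue %in% tissues, ]
  ids <- unique(dataset$animals$animal_id)
  wide <- matrix(NA_real_, length(ids), length(tissues),
                 dimnames = list(ids, tissues))
  wide[cbind(match(m$animal_id, ids), match(m$tissue, tissues))] <- m$value
  k <- length(tissues)
  out <- diag(1, k); dimnames(out) <- list(tissues, tissues)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- stats::complete.cases(wide[, c(i, j)])
      r <- if (sum(ok) < 3) NA_real_ else
        stats::cor(rank(wide[ok, i]), rank(wide[ok, j]))
      out[i, j] <- out[j, i] <- r
    }
  }
  out
}

#' Body condition index as an OLS residual
#'
#' Fits ordinary least squares of body mass on body length over a reference
#' population and returns each animal's residual (observed minus predicted
#' mass). Animals missing either biometric get `NA`.
#'
#' @param mass_kg,length_cm biometrics of the animals to score (vectorised).
#' @param reference_pairs data.frame with columns `body_mass_kg` and
#'   `body_length_cm`; needs >= 3 rows and nonzero length variance.
#' @return Numeric vector of residuals (kg).
#' @export
compute_bci <- function(mass_kg, length_cm, reference_pairs) {
  ref <- reference_pairs[stats::complete.cases(
    reference_pairs[, c("body_mass_kg", "body_length_cm")]), ]
  if (nrow(ref) < 3)
    stop_radecol("reference needs at least 3 complete pairs", "radecol_fit_error")
  if (stats::var(ref$body_length_cm) == 0)
    stop_radecol("degenerate reference: constant body length", "radecol_fit_error")
  fit <- stats::lm(body_mass_kg ~ body_length_cm, data = ref)
  pred <- stats::predict(fit, newdata = data.frame(body_length_cm = length_cm))
  as.numeric(mass_kg - pred)
}

#' Attach BCI to the animal table of a cohort
#'
#' @param dataset a [cohort_dataset].
#' @param reference_pairs reference population for [compute_bci()]; defaults
#'   to the cohort's own animals.
#' @return The dataset with a `bci` column on `animals`.
#' @export
add_bci <- function(dataset, reference_pairs = dataset$animals) {
  a <- dataset$animals
  a$bci <- compute_bci(a$body_mass_kg, a$body_length_cm, reference_pairs)
  dataset$animals <- a
  dataset
}
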