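#' Transfer configuration for whole-organism concentrations
#'
#' Maps each analyte to the proxy tissue assumed to represent the whole
#' organism, with the tissue dry-to-wet conversion factors, the bone
#' dry-to-wet mass ratio (0.8) and the bone-to-whole-organism factor for Pb
#' (0.16, which already embeds the 0.8 ratio).
#'
#' @param proxy_tissue named character: analyte -> tissue.
#' @param tissue_factor named numeric dry-to-wet factors in (0, 1].
#' @param bone_dry_wet_ratio dry-to-wet bone mass ratio.
#' @param pb_bone_to_wo bone-to-whole-organism conversion for Pb routes.
#' @return List of class `transfer_config`.
#' @export
transfer_config <- function(proxy_tissue = c(Cs137 = "muscle", Ca = "muscle",
                                             Cd = "muscle", Cu = "muscle",
                                             Mn = "bone", Zn = "liver",
                                             Pb210 = "bone", Pb = "bone"),
                            tissue_factor = default_tissue_factors(),
                            bone_dry_wet_ratio = 0.8,
                            pb_bone_to_wo = 0.16) {
  if (any(tissue_factor <= 0 | tissue_factor > 1))
    stop_radecol("tissue factors must lie in (0, 1]", "radecol_config_error")
  structure(list(proxy_tissue = proxy_tissue, tissue_factor = tissue_factor,
                 bone_dry_wet_ratio = bone_dry_wet_ratio,
                 pb_bone_to_wo = pb_bone_to_wo),
            class = "transfer_config")
}

#' Whole-organism wet-mass concentration for one animal
#'
#' Converts the animal's proxy-tissue dry-mass value to a wet-mass
#' whole-organism concentration: the proxy value times the tissue's
#' dry-to-wet factor, except for Pb routed through bone, where the dry bone
#' value is multiplied by the bone-to-whole-organism factor (0.16) directly.
#'
#' @param dataset a [cohort_dataset].
#' @param analyte the analyte.
#' @param config a [transfer_config()].
#' @param animal_id the animal.
#' @return Scalar wet-mass concentration, or `NA` (with a warning) when the
#'   animal has only censored proxy values.
#' @export
whole_organism_concentration <- function(dataset, analyte, config, animal_id) {
  proxy <- config$proxy_tissue[analyte]
  if (is.na(proxy))
    stop_radecol(paste0("no proxy tissue configured for ", analyte),
                 "radecol_config_error")
  m <- dataset$measurements
  row <- m[m$analyte == analyte & m$tissue == proxy & m$animal_id == animal_id, ]
  if (nrow(row) == 0) return(NA_real_)
  if (all(row$censored)) {
    warning("animal ", animal_id, " has only censored ", analyte,
            " proxy values; skipped")
    return(NA_real_)
  }
  v <- row$value[!row$censored][1]
  if (row$basis[1] != "dry")
    stop_radecol("proxy measurements must be on a dry basis", "radecol_config_error")
  if (analyte %in% c("Pb", "Pb210") && proxy == "bone")
    return(v * config$pb_bone_to_wo)
  f <- config$tissue_factor[proxy]
  if (is.na(f))
    stop_radecol(paste0("no conversion factor for tissue ", proxy),
                 "radecol_config_error")
  to_wet_basis(v, unname(f))
}

#' Concentration ratio
#'
#' `CR = c_wo / c_soil`: wet-mass whole-organism concentration over dry-mass
#' soil concentration, dimensionless once both carry the same unit.
#'
#' @param c_wo_wet whole-organism wet-mass concentration (>= 0).
#' @param c_soil_dry soil dry-mass concentration (> 0).
#' @param unit_wo,unit_soil optional unit labels, checked for identity.
#' @return Dimensionless CR.
#' @export
concentration_ratio <- function(c_wo_wet, c_soil_dry,
                                unit_wo = NULL, unit_soil = NULL) {
  if (!is.null(unit_wo) && !is.null(unit_soil) && unit_wo != unit_soil)
    stop_radecol(paste0("unit mismatch: ", unit_wo, " vs ", unit_soil),
                 "radecol_unit_error")
  if (any(c_soil_dry <= 0))
    stop_radecol("soil concentration must be positive", "radecol_domain_error")
  if (any(c_wo_wet < 0))
    stop_radecol("whole-organism concentration must be non-negative",
                 "radecol_domain_error")
  c_wo_wet / c_soil_dry
}

#' Soil reference concentration for an analyte
#'
#' Stable elements return the tabulated value unchanged. Radionuclides return
#' the arithmetic mean of the available entries, each decay-corrected from its
#' own reference date to the sampling date before averaging (entries may stem
#' from surveys of different vintage).
#'
#' @param analyte the analyte.
#' @param sampling_date date the animal was sampled.
#' @param soil_table data.frame with columns `analyte`, `value`, `unit`,
#'   `basis`, `reference_date` (radionuclides only), `source`.
#' @param nuclide_specs data.frame as [radionuclide_specs()].
#' @return List with `value` and `unit`.
#' @export
soil_reference_for <- function(analyte, sampling_date, soil_table,
                               nuclide_specs = radionuclide_specs()) {
  sub <- soil_table[soil_table$analyte == analyte, ]
  if (nrow(sub) == 0)
    stop_radecol(paste0("analyte absent from soil table: ", analyte),
                 "radecol_config_error")
  spec <- nuclide_specs[nuclide_specs$name == analyte, ]
  if (nrow(spec) == 0)
    return(list(value = mean(sub$value), unit = sub$unit[1]))
  rd <- as.Date(sub$reference_date)
  if (any(is.na(rd)))
    stop_radecol(paste0("radionuclide soil entry without reference_date: ", analyte),
                 "radecol_config_error")
  corrected <- decay_correct(sub$value, spec$half_life_years,
                             delta_years = decay_delta_years(rd, sampling_date))
  list(value = mean(corrected), unit = sub$unit[1])
}

#' Concentration-ratio table for a cohort
#'
#' For each analyte: per-animal CRs (each animal's whole-organism wet-mass
#' concentration over the soil reference decay-corrected to that animal's own
#' sampling date), then AM +- SD, GM and range. Radionuclides and their
#' stable analogues (e.g. 210Pb and Pb) appear as separate rows. Analytes
#' with no eligible animal are omitted with a warning.
#'
#' @param dataset a [cohort_dataset].
#' @param analytes analytes to tabulate.
#' @param config a [transfer_config()].
#' @param soil_table soil reference table (see [soil_reference_for()]).
#' @return data.frame: `analyte`, `proxy_tissue`, `n`, `am`, `sd`, `gm`,
#'   `min`, `max`, `soil_value_used` (mean over animals for radionuclides,
#'   whose soil value moves with each sampling date); per-animal CRs in
#'   attribute `"per_animal"`.
#' @export
cr_table <- function(dataset, analytes, config = transfer_config(),
                     soil_table) {
  rows <- list(); per_animal <- list()
  for (an in analytes) {
    crs <- c(); soils <- c()
    unit_an <- dataset$measurements$unit[dataset$measurements$analyte == an][1]
    for (i in seq_len(nrow(dataset$animals))) {
      aid <- dataset$animals$animal_id[i]
      cwo <- whole_organism_concentration(dataset, an, config, aid)
      if (is.na(cwo)) next
      soil <- soil_reference_for(an, dataset$animals$sampling_date[i], soil_table)
      crs[aid] <- concentration_ratio(cwo, soil$value,
                                      unit_wo = unit_an, unit_soil = soil$unit)
      soils[aid] <- soil$value
    }
    if (length(crs) == 0) {
      warning("no eligible animals for analyte ", an, "; row omitted")
      next
    }
    s <- summarize_values(crs)
    rows[[an]] <- data.frame(analyte = an,
                             proxy_tissue = unname(config$proxy_tissue[an]),
                             n = s$n_detected, am = s$am, sd = s$sd, gm = s$gm,
                             min = s$min, max = s$max,
                             soil_value_used = mean(soils))
    per_animal[[an]] <- crs
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_animal") <- per_animal
  out
}
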