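#' Radionuclide specifications
#'
#' Physical half-lives and stable-analogue pairings for the radionuclides the
#' workflow handles: 137Cs (30.0 y, analogue Cs), 210Pb (22.2 y, analogue Pb)
#' and 40K (1.248e9 y, analogue K). The decay constant is always derived as
#' `log(2) / half_life_years`, never stored.
#'
#' @return data.frame with columns `name`, `half_life_years`, `stable_analogue`.
#' @export
#' @examples
#' radionuclide_specs()
radionuclide_specs <- function() {
  data.frame(name = c("Cs137", "Pb210", "K40"),
             half_life_years = c(30.0, 22.2, 1.248e9),
             stable_analogue = c("Cs", "Pb", "K"),
             stringsAsFactors = FALSE)
}

#' Elapsed time between two dates in years
#'
#' Uses a fixed 365.25-day year, a sub-0.1% approximation that keeps decay
#' corrections reproducible across calendar conventions.
#'
#' @param reference_date,target_date `Date`s (or ISO-8601 strings).
#' @return Signed elapsed time in years (`target - reference`).
#' @export
decay_delta_years <- function(reference_date, target_date) {
  as.numeric(as.Date(target_date) - as.Date(reference_date)) / 365.25
}

#' Decay-correct an activity
#'
#' Rescales a massic activity to another date via the decay law
#' `A = A0 * 2^(-dt / T1/2)`. Negative `dt` back-corrects with the same
#' formula. Supply either `delta_years` directly or a pair of dates.
#'
#' @param activity activity in Bq/kg (vectorised, non-negative).
#' @param half_life_years physical half-life in years (> 0).
#' @param delta_years elapsed time in years; if `NULL`, computed from the dates.
#' @param reference_date,target_date dates bracketing the correction.
#' @return Corrected activity, same units as the input.
#' @export
#' @examples
#' decay_correct(125, 30.0, delta_years = 10)   # 125 * 2^(-1/3)
decay_correct <- function(activity, half_life_years, delta_years = NULL,
                          reference_date = NULL, target_date = NULL) {
  if (any(activity < 0)) stop_radecol("activity must be non-negative", "radecol_domain_error")
  if (half_life_years <= 0) stop_radecol("half_life_years must be positive", "radecol_domain_error")
  if (is.null(delta_years)) {
    if (is.null(reference_date) || is.null(target_date))
      stop_radecol("supply delta_years or both dates", "radecol_domain_error")
    delta_years <- decay_delta_years(reference_date, target_date)
  }
  activity * 2^(-delta_years / half_life_years)
}

#' Dry-to-wet conversion factor from moisture content
#'
#' The factor multiplying a dry-mass concentration to express it on a wet-mass
#' basis is the dry-matter fraction, `f = 1 - moisture`. A muscle moisture of
#' 75% gives f = 0.25; heart at 76% gives f = 0.24.
#'
#' @param moisture_fraction moisture as a fraction in `[0, 1)` (vectorised).
#' @return Conversion factor `f` in `(0, 1]`.
#' @export
moisture_to_factor <- function(moisture_fraction) {
  if (any(moisture_fraction < 0 | moisture_fraction >= 1))
    stop_radecol("moisture_fraction must lie in [0, 1)", "radecol_domain_error")
  1 - moisture_fraction
}

#' Moisture content from freeze-drying masses
#'
#' Moisture fraction determined gravimetrically from a tissue aliquot weighed
#' before and after freeze-drying.
#'
#' @param mass_before,mass_after_freeze_dry masses in the same units;
#'   `0 < mass_after <= mass_before`.
#' @return Moisture fraction in `[0, 1)`.
#' @export
compute_moisture <- function(mass_before, mass_after_freeze_dry) {
  if (any(mass_after_freeze_dry <= 0) || any(mass_after_freeze_dry > mass_before))
    stop_radecol("require 0 < mass_after <= mass_before", "radecol_validation_error")
  (mass_before - mass_after_freeze_dry) / mass_before
}

#' Convert a dry-basis concentration to wet basis
#'
#' Multiplies a dry-mass concentration by the tissue's conversion factor
#' (dry-matter fraction). Pure unit bookkeeping: linear, unit-preserving, and
#' applied to censored thresholds exactly as to detections.
#'
#' @param value_dry concentration on a dry-mass basis (vectorised, >= 0).
#' @param factor conversion factor `f` in `(0, 1]`.
#' @return Concentration on a wet-mass basis.
#' @export
#' @examples
#' to_wet_basis(6.49, moisture_to_factor(0.75))  # muscle median, dm -> wm
to_wet_basis <- function(value_dry, factor) {
  if (any(factor <= 0 | factor > 1))
    stop_radecol("factor must lie in (0, 1]", "radecol_domain_error")
  if (any(value_dry < 0))
    stop_radecol("value_dry must be non-negative", "radecol_domain_error")
  value_dry * factor
}

#' Default tissue dry-to-wet conversion factors
#'
#' Dry-matter fractions per tissue: muscle 0.25, heart 0.24, lungs 0.23 and
#' liver 0.30 follow measured moisture contents; bone uses the conventional
#' 0.8 dry-to-wet mass ratio. Spleen (0.23) and kidney (0.25) moisture values
#' are configuration placeholders, not measured values, and should be replaced
#' when study-specific moistures exist.
#'
#' @return Named numeric vector over [tissue_vocabulary()].
#' @export
default_tissue_factors <- function() {
  c(muscle = 0.25, heart = 0.24, spleen = 0.23, lungs = 0.23,
    liver = 0.30, kidney = 0.25, bone = 0.8)
}

#' Convert a measurement table between mass bases
#'
#' Applies per-tissue conversion factors to all dry-basis rows (direction
#' `"wet"`) or divides wet-basis rows back (direction `"dry"`). Censored
#' thresholds are converted like values and keep their flag.
#'
#' @param measurements measurement data.frame (see [cohort_dataset()]).
#' @param tissue_factor named factor vector, e.g. [default_tissue_factors()].
#' @param direction `"wet"` (default) or `"dry"`.
#' @return The measurement data.frame with `value` rescaled and `basis` flipped.
#' @export
convert_basis <- function(measurements, tissue_factor = default_tissue_factors(),
                          direction = c("wet", "dry")) {
  direction <- match.arg(direction)
  f <- tissue_factor[measurements$tissue]
  if (any(is.na(f)))
    stop_radecol("no conversion factor for some tissues", "radecol_config_error")
  from <- if (direction == "wet") "dry" else "wet"
  idx <- measurements$basis == from
  measurements$value[idx] <- if (direction == "wet")
    measurements$value[idx] * f[idx] else measurements$value[idx] / f[idx]
  measurements$basis[idx] <- direction
  measurements
}
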