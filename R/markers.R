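#' Spectral Hounsfield-unit curve slope
#'
#' The slope of the virtual-monoenergetic attenuation curve between 40 keV
#' and 100 keV, `(HU40 - HU100) / 60`, in HU/keV. Iodine attenuates strongly
#' at low keV, so iodine-rich tissue has a steep (large) slope.
#'
#' @param hu40,hu100 Attenuation (HU) on the 40 keV and 100 keV
#'   virtual-monoenergetic images. Vectorized.
#' @return Numeric vector of slopes (HU/keV).
#' @examples
#' lambda_hu(100, 40)      # 1
#' lambda_hu(327.18, 60)   # 4.453
#' @export
lambda_hu <- function(hu40, hu100) {
  if (!all(is.finite(hu40)) || !all(is.finite(hu100))) {
    abort("Monoenergetic HU values must be finite.",
          class = "spectraef_invalid_measurement")
  }
  (hu40 - hu100) / 60
}

#' Normalize a nodule measurement to its same-phase carotid reference
#'
#' Used for both the normalized iodine concentration (NIC) and the normalized
#' effective atomic number (NZeff): the nodule value divided by the value
#' measured in the carotid artery on the same phase, which removes inter-scan
#' contrast-timing variability.
#'
#' @param nodule_value Nodule measurement (mg/mL for iodine, unitless for
#'   effective atomic number). Vectorized.
#' @param carotid_value Same-phase carotid measurement; must be strictly
#'   positive.
#' @return Numeric vector of normalized values.
#' @examples
#' normalize_to_carotid(1.86, 5) # 0.372
#' @export
normalize_to_carotid <- function(nodule_value, carotid_value) {
  if (!all(is.finite(carotid_value)) || any(carotid_value <= 0)) {
    abort("Carotid reference values must be finite and strictly positive.",
          class = "spectraef_invalid_reference")
  }
  nodule_value / carotid_value
}

#' Arterial enhancement fraction from blended single-energy images
#'
#' `AEF_S = (HU_a - HU_u) / (HU_v - HU_u)`: the fraction of a nodule's total
#' contrast enhancement (venous minus non-contrast) already present in the
#' arterial phase. When the venous and non-contrast attenuations are closer
#' than `epsilon` the ratio is numerically meaningless; those records return
#' `NA` and are flagged so downstream stages can exclude and count them.
#' Negative fractions (arterial below non-contrast attenuation) are retained
#' unclipped but flagged.
#'
#' @param hu_u,hu_a,hu_v Non-contrast, arterial-phase and venous-phase
#'   attenuation (HU) on the 120-kVp-equivalent blended image. Vectorized.
#' @param epsilon Minimum absolute denominator `|HU_v - HU_u|` (HU) for a
#'   stable ratio; defaults to 1 HU, below typical measurement noise.
#' @return Numeric vector with attribute `flags`, a character vector per
#'   element ("" for clean, `"unstable_denominator"` or `"negative_aef"`).
#' @examples
#' aef_single(60.70, 186.60, 140.40) # 1.58 (benign worked example)
#' aef_single(65.90, 139.90, 148.30) # 0.90 (malignant worked example)
#' @export
aef_single <- function(hu_u, hu_a, hu_v, epsilon = 1) {
  if (!all(is.finite(c(hu_u, hu_a, hu_v)))) {
    abort("Blended-image HU values must be finite.",
          class = "spectraef_invalid_measurement")
  }
  stopifnot(epsilon > 0)
  den <- hu_v - hu_u
  out <- (hu_a - hu_u) / den
  flags <- rep("", length(out))
  unstable <- abs(den) < epsilon
  out[unstable] <- NA_real_
  flags[unstable] <- "unstable_denominator"
  neg <- !unstable & out < 0
  flags[neg] <- "negative_aef"
  structure(out, flags = flags)
}

#' Arterial enhancement fraction from dual-layer iodine maps
#'
#' `AEF_D = IC_a / IC_v`: the arterial-to-venous ratio of the nodule iodine
#' concentration measured on spectral iodine-density maps.
#'
#' @param ic_a,ic_v Arterial- and venous-phase nodule iodine concentration
#'   (mg/mL); `ic_v` must be strictly positive. Vectorized.
#' @return Numeric vector of ratios.
#' @examples
#' aef_dual(5.28, 3.77) # 1.40 (benign worked example)
#' aef_dual(2.81, 3.02) # 0.93 (malignant worked example)
#' @export
aef_dual <- function(ic_a, ic_v) {
  if (!all(is.finite(c(ic_a, ic_v))) || any(ic_v <= 0)) {
    abort("Iodine concentrations must be finite and the venous value positive.",
          class = "spectraef_invalid_measurement")
  }
  ic_a / ic_v
}

#' Derive all spectral markers for a table of nodule records
#'
#' Takes a nodule-record table (one row per nodule with raw per-phase
#' measurements, as produced by [simulate_cohort()] or read from CSV) and
#' appends the eight derived markers: per-phase spectral slope
#' (`ap_lambda_hu`, `vp_lambda_hu`), carotid-normalized iodine concentration
#' (`ap_nic`, `vp_nic`) and effective atomic number (`ap_nzeff`, `vp_nzeff`),
#' and the two arterial enhancement fractions (`aef_s`, `aef_d`). A `flags`
#' column records per-record quality flags; marker failures are flagged, not
#' fatal, so one degenerate record does not abort a cohort.
#'
#' @param records A data frame with the raw measurement columns
#'   (`hu_u`, `hu_a`, `hu_v`, `ap_hu40`, `ap_hu100`, `vp_hu40`, `vp_hu100`,
#'   `ap_ic`, `vp_ic`, `ap_zeff`, `vp_zeff`, and the four carotid
#'   references).
#' @param epsilon Stability threshold (HU) for the `aef_s` denominator,
#'   passed to [aef_single()].
#' @return The input as a tibble with the eight marker columns and `flags`
#'   appended (existing columns of those names are replaced).
#' @examples
#' fig2 <- worked_example_records()
#' derive_markers(fig2)[, c("nodule_id", "aef_s", "aef_d")]
#' @export
derive_markers <- function(records, epsilon = 1) {
  records <- as_tibble(records)
  aef_s <- aef_single(records$hu_u, records$hu_a, records$hu_v, epsilon)
  dplyr::mutate(
    records,
    ap_lambda_hu = lambda_hu(.data$ap_hu40, .data$ap_hu100),
    vp_lambda_hu = lambda_hu(.data$vp_hu40, .data$vp_hu100),
    ap_nic = normalize_to_carotid(.data$ap_ic, .data$ap_carotid_ic),
    vp_nic = normalize_to_carotid(.data$vp_ic, .data$vp_carotid_ic),
    ap_nzeff = normalize_to_carotid(.data$ap_zeff, .data$ap_carotid_zeff),
    vp_nzeff = normalize_to_carotid(.data$vp_zeff, .data$vp_carotid_zeff),
    aef_s = as.numeric(!!aef_s),
    aef_d = aef_dual(.data$ap_ic, .data$vp_ic),
    flags = attr(!!aef_s, "flags")
  )
}

#' Mean measurement over a region of interest
#'
#' Minimal stand-in for workstation ROI measurement: the arithmetic mean of a
#' 2-D value map (HU or mg/mL) under a logical mask.
#'
#' @param values Numeric matrix (a slice of a parametric map).
#' @param mask Logical matrix of the same shape selecting at least one cell.
#' @return The mean value inside the ROI.
#' @examples
#' measure_roi(matrix(1:4, 2), matrix(TRUE, 2, 2)) # 2.5
#' @export
measure_roi <- function(values, mask) {
  if (!is.matrix(values) || !is.logical(mask) || !identical(dim(values), dim(mask))) {
    abort("`values` must be a numeric matrix and `mask` a logical matrix of the same shape.",
          class = "spectraef_invalid_roi")
  }
  if (!any(mask)) {
    abort("ROI mask selects no cells.", class = "spectraef_invalid_roi")
  }
  mean(values[mask])
}

#' Worked-example nodule records
#'
#' The two published worked-example nodules: a benign micronodule with
#' non-contrast/arterial/venous attenuation 60.70 / 186.60 / 140.40 HU and
#' iodine concentrations 5.28 / 3.77 mg/mL, and a malignant micronodule with
#' 65.90 / 139.90 / 148.30 HU and 2.81 / 3.02 mg/mL. Spectral monoenergetic
#' and effective-atomic-number fields are filled with plausible placeholder
#' values (the worked example only exercises the AEF formulas).
#'
#' @return A two-row nodule-record tibble.
#' @export
worked_example_records <- function() {
  tibble(
    nodule_id = c("example_benign", "example_malignant"),
    cohort = c("benign", "malignant"),
    hu_u = c(60.70, 65.90),
    hu_a = c(186.60, 139.90),
    hu_v = c(140.40, 148.30),
    ap_hu40 = c(327.2, 265.6),
    ap_hu70 = c(160.0, 140.0),
    ap_hu100 = c(60.0, 65.9),
    vp_hu40 = c(267.4, 274.8),
    vp_hu70 = c(150.0, 150.0),
    vp_hu100 = c(60.0, 66.0),
    ap_ic = c(5.28, 2.81),
    vp_ic = c(3.77, 3.02),
    ap_zeff = c(8.2, 7.9),
    vp_zeff = c(9.4, 9.5),
    ap_carotid_ic = c(14.2, 9.9),
    vp_carotid_ic = c(5.5, 4.2),
    ap_carotid_zeff = c(10, 10),
    vp_carotid_zeff = c(10, 10),
    calcification = c("absent", "micro"),
    enhanced_blurring = c(FALSE, TRUE),
    age_ge50 = c(TRUE, FALSE),
    female = c(TRUE, TRUE),
    max_diameter_mm = c(7, 6)
  )
}
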