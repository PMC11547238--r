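#' Cell concentration
#'
#' @param count Cells counted.
#' @param volume_mL Volume analyzed in mL.
#' @return Cells per mL.
#' @export
concentration <- function(count, volume_mL) {
  if (any(volume_mL <= 0)) stop("volume must be positive")
  count / volume_mL
}

#' Theoretically expected CTCs in the leukapheresis product
#'
#' Extrapolates the peripheral-blood CellSearch count (per 7.5 mL) to the
#' total blood volume processed during leukapheresis:
#' `(count / 7.5 mL) * processed liters * 1000`.
#'
#' @param pb_count_per_7_5mL CTC count in 7.5 mL peripheral blood.
#' @param processed_blood_L Blood volume processed, liters.
#' @param pb_volume_mL Peripheral-blood draw volume (default 7.5 mL).
#' @return Expected total CTCs in the product.
#' @export
expected_ctc_in_dla <- function(pb_count_per_7_5mL, processed_blood_L,
                                pb_volume_mL = 7.5) {
  if (any(pb_count_per_7_5mL < 0) || any(processed_blood_L < 0)) {
    stop("inputs must be nonnegative")
  }
  (pb_count_per_7_5mL / pb_volume_mL) * processed_blood_L * 1000
}

#' Leukapheresis recovery
#'
#' The product is assayed as an aliquot; the measured product total is the
#' aliquot concentration extrapolated to the full product volume, and
#' recovery is measured over expected, as a percentage. Recovery may exceed
#' 100% through counting noise. When the expected total is zero (no CTCs in
#' peripheral blood) recovery is undefined and reported as not evaluable
#' (`NA`), never as 0%.
#'
#' @param measured_concentration Cells per mL measured in the product
#'   aliquot.
#' @param product_volume_mL Total product volume, mL.
#' @param expected_total Expected total cells from [expected_ctc_in_dla()].
#' @return List of class `recovery_result`: `expected_total_in_product`,
#'   `measured_total_in_product`, `recovery_pct` (`NA` when not evaluable).
#' @export
recovery <- function(measured_concentration, product_volume_mL,
                     expected_total) {
  if (product_volume_mL <= 0) stop("product volume must be positive")
  measured_total <- measured_concentration * product_volume_mL
  pct <- if (expected_total > 0) 100 * measured_total / expected_total
         else NA_real_
  structure(
    list(expected_total_in_product = expected_total,
         measured_total_in_product = measured_total,
         recovery_pct = pct),
    class = "recovery_result"
  )
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("<recovery_result> measured %.1f / expected %.1f = %s\n",
              x$measured_total_in_product, x$expected_total_in_product,
              if (is.na(x$recovery_pct)) "not evaluable"
              else sprintf("%.1f%%", x$recovery_pct)))
  invisible(x)
}

#' Per-platform detection summary
#'
#' @param measurements Long `data.frame` with columns `patient_id`,
#'   `platform`, `ctc_count` (one row per patient per platform).
#' @param positivity_threshold Minimum count called positive (inclusive).
#' @return `data.frame` per platform: `n_positive`, `n_total`, `rate`.
#' @export
detection_summary <- function(measurements, positivity_threshold = 1) {
  key <- paste(measurements$patient_id, measurements$platform)
  if (anyDuplicated(key)) {
    stop("duplicate patient/platform rows: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  rows <- lapply(split(measurements, measurements$platform), function(d) {
    pos <- sum(d$ctc_count >= positivity_threshold)
    data.frame(platform = d$platform[1], n_positive = pos,
               n_total = nrow(d), rate = pos / nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort-level CTC metrics
#'
#' From a clinical table (one row per patient, as produced by
#' [simulate_cohort()]), derives the long measurement table, per-platform
#' detection summaries and per-patient leukapheresis recovery. Patients
#' without CTCs in peripheral blood have undefined recovery and are
#' excluded from recovery statistics (not set to 0).
#'
#' @param clinical `data.frame` with columns `patient_id`, `pb_ctc`,
#'   `dla_cs_ctc`, `dla_cs_aliquot_mL`, `dla_fcm_ctc`, `product_volume_mL`,
#'   `processed_blood_L`.
#' @param positivity_threshold Minimum count called positive.
#' @return List with `measurements` (long table), `detection`
#'   (per-platform summary), `recovery` (per-patient, flow-cytometry
#'   measurement), `median_recovery_pct` (over evaluable patients).
#' @export
cohort_ctc_metrics <- function(clinical, positivity_threshold = 1) {
  meas <- rbind(
    data.frame(patient_id = clinical$patient_id, platform = "PB_CellSearch",
               ctc_count = clinical$pb_ctc, volume_analyzed_mL = 7.5,
               product_volume_mL = NA_real_,
               processed_blood_L = NA_real_, stringsAsFactors = FALSE),
    data.frame(patient_id = clinical$patient_id, platform = "DLA_CellSearch",
               ctc_count = clinical$dla_cs_ctc,
               volume_analyzed_mL = clinical$dla_cs_aliquot_mL,
               product_volume_mL = clinical$product_volume_mL,
               processed_blood_L = clinical$processed_blood_L,
               stringsAsFactors = FALSE),
    data.frame(patient_id = clinical$patient_id, platform = "DLA_FCM",
               ctc_count = clinical$dla_fcm_ctc,
               volume_analyzed_mL = clinical$product_volume_mL,
               product_volume_mL = clinical$product_volume_mL,
               processed_blood_L = clinical$processed_blood_L,
               stringsAsFactors = FALSE)
  )
  detection <- detection_summary(meas, positivity_threshold)
  rec <- lapply(seq_len(nrow(clinical)), function(i) {
    expected <- expected_ctc_in_dla(clinical$pb_ctc[i],
                                    clinical$processed_blood_L[i])
    conc <- concentration(clinical$dla_fcm_ctc[i],
                          clinical$product_volume_mL[i])
    r <- recovery(conc, clinical$product_volume_mL[i], expected)
    data.frame(patient_id = clinical$patient_id[i],
               expected_total = r$expected_total_in_product,
               measured_total = r$measured_total_in_product,
               recovery_pct = r$recovery_pct, stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rec)
  rownames(rec) <- NULL
  list(measurements = meas, detection = detection, recovery = rec,
       median_recovery_pct = stats::median(rec$recovery_pct, na.rm = TRUE))
}
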