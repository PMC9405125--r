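# Per-sample quality control on intensity profiles.

#' Sample quality control from LRR dispersion and BAF drift
#'
#' A sample passes QC iff its genome-wide LRR standard deviation is at most
#' `lrr_sd_max` and its BAF drift is at most `baf_drift_max` (defaults are
#' the conventional 0.3 / 0.01 thresholds for Illumina-array CNV calling).
#'
#' BAF drift is estimated from the occupancy of the windows
#' `(0.10, 0.20)` and `(0.80, 0.90)`, which lie between the legitimate
#' genotype clusters of every modeled copy-number state (at least 3.3
#' cluster standard deviations from the diploid clusters at the default
#' `baf_sd` of 0.03, and clear of the CN3/CN4 clusters at 1/3, 0.25 and
#' their mirror images). Because uniformly drifted BAF values land in those
#' windows with probability equal to their total width (0.2), the occupancy
#' is divided by 0.2 (and clamped to `[0, 1]`) so that the reported value
#' estimates the fraction of drifted markers itself rather than the window
#' hit rate.
#'
#' @param profile An `intensity_profile` (list with `sample_id`, `lrr`,
#'   `baf`).
#' @param lrr_sd_max,baf_drift_max QC thresholds.
#' @return A one-row data.frame: `sample_id`, `lrr_sd`, `baf_drift`,
#'   `passed`, plus the thresholds used.
#' @export
sample_qc <- function(profile, lrr_sd_max = 0.3, baf_drift_max = 0.01) {
  lrr <- profile$lrr[!is.na(profile$lrr)]
  baf <- profile$baf[!is.na(profile$baf)]
  if (length(lrr) < 2L || length(baf) == 0L) {
    stop("profile has no usable LRR/BAF values")
  }
  lrr_sd <- sd(lrr)
  in_win <- (baf > 0.10 & baf < 0.20) | (baf > 0.80 & baf < 0.90)
  baf_drift <- min(1, mean(in_win) / 0.2)
  data.frame(
    sample_id = profile$sample_id,
    lrr_sd = lrr_sd,
    baf_drift = baf_drift,
    passed = lrr_sd <= lrr_sd_max && baf_drift <= baf_drift_max,
    lrr_sd_max = lrr_sd_max,
    baf_drift_max = baf_drift_max,
    stringsAsFactors = FALSE
  )
}

#' QC every profile of a cohort
#'
#' @param profiles Named list of `intensity_profile`s.
#' @inheritParams sample_qc
#' @return A data.frame with one [sample_qc()] row per profile.
#' @export
qc_cohort <- function(profiles, lrr_sd_max = 0.3, baf_drift_max = 0.01) {
  out <- do.call(rbind, lapply(profiles, sample_qc,
                               lrr_sd_max = lrr_sd_max,
                               baf_drift_max = baf_drift_max))
  rownames(out) <- NULL
  out
}
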