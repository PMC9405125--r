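# Recovery evaluation of final CNVRs against the spiked truth regions of a
# synthetic cohort.

# Reciprocal overlap of [s1,e1] and [s2,e2] (1-based closed): the shared
# width divided by each interval's width must reach `min_reciprocal`.
.reciprocal_match <- function(s1, e1, s2, e2, min_reciprocal) {
  ov <- pmin(e1, e2) - pmax(s1, s2) + 1
  ov >= min_reciprocal * (e1 - s1 + 1) & ov >= min_reciprocal * (e2 - s2 + 1)
}

#' Recovery of spiked regions in the final CNVR set
#'
#' Matches the designed recurrent truth regions of a synthetic cohort
#' against the final CNVRs by reciprocal overlap. A single-type truth region
#' counts as recovered when a final region labeled specific to that type
#' matches it at `min_reciprocal` (default 50%) reciprocal overlap; a
#' cross-type truth region must match a `"shared"` final region. Precision
#' is the fraction of type-specific final regions that match a single-type
#' truth region of their type.
#'
#' @param final Final region data.frame from [classify_specificity()].
#' @param truth_regions `shared_regions` table of [simulate_cohort()] /
#'   [spike_events()].
#' @param min_reciprocal Reciprocal overlap threshold.
#' @return A list: `recall`, `precision`, `n_truth_specific`,
#'   `n_final_specific`, `shared_truth_recalled` (fraction of cross-type
#'   truths matched by a shared final region), and
#'   `specific_matches_cross_type` (count of type-specific final regions
#'   that reciprocally match a cross-type truth region — should be 0).
#' @export
recovery_stats <- function(final, truth_regions, min_reciprocal = 0.5) {
  cross <- grepl(",", truth_regions$cattle_type)
  truth_spec <- truth_regions[!cross, , drop = FALSE]
  truth_shared <- truth_regions[cross, , drop = FALSE]
  final_spec <- final[final$label != "shared", , drop = FALSE]
  final_shared <- final[final$label == "shared", , drop = FALSE]

  match_any <- function(t_row, f_df, label = NULL) {
    if (nrow(f_df) == 0L) return(FALSE)
    sel <- f_df$chrom == t_row$chrom
    if (!is.null(label)) sel <- sel & f_df$label == label
    if (!any(sel)) return(FALSE)
    any(.reciprocal_match(f_df$start_bp[sel], f_df$end_bp[sel],
                          t_row$start_bp, t_row$end_bp, min_reciprocal))
  }

  recalled <- vapply(seq_len(nrow(truth_spec)), function(i) {
    t_row <- truth_spec[i, ]
    match_any(t_row, final_spec, paste0(t_row$cattle_type, "_specific"))
  }, logical(1))

  shared_rec <- vapply(seq_len(nrow(truth_shared)), function(i) {
    match_any(truth_shared[i, ], final_shared)
  }, logical(1))

  spec_matched <- vapply(seq_len(nrow(final_spec)), function(i) {
    f <- final_spec[i, ]
    ty <- sub("_specific$", "", f$label)
    t_df <- truth_spec[truth_spec$cattle_type == ty &
                         truth_spec$chrom == f$chrom, , drop = FALSE]
    nrow(t_df) > 0L && any(.reciprocal_match(
      f$start_bp, f$end_bp, t_df$start_bp, t_df$end_bp, min_reciprocal))
  }, logical(1))

  spec_vs_cross <- vapply(seq_len(nrow(final_spec)), function(i) {
    f <- final_spec[i, ]
    t_df <- truth_shared[truth_shared$chrom == f$chrom, , drop = FALSE]
    nrow(t_df) > 0L && any(.reciprocal_match(
      f$start_bp, f$end_bp, t_df$start_bp, t_df$end_bp, min_reciprocal))
  }, logical(1))

  list(
    recall = if (nrow(truth_spec)) mean(recalled) else NA_real_,
    precision = if (nrow(final_spec)) mean(spec_matched) else NA_real_,
    n_truth_specific = nrow(truth_spec),
    n_final_specific = nrow(final_spec),
    shared_truth_recalled = if (nrow(truth_shared)) mean(shared_rec)
                            else NA_real_,
    specific_matches_cross_type = sum(spec_vs_cross)
  )
}
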