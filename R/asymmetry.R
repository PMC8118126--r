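# Cohort-scale volumetric asymmetry index (AI) and z-score outlier flagging:
# ground-truth-free quality control for hemisphere splits.

#' Volumetric asymmetry index
#'
#' `AI = |V_L - V_R| / (V_L + V_R)`. Scale-invariant, 0 for a perfectly
#' balanced split, 1 when one hemisphere is empty. Under a correct midline
#' the cerebral hemispheres are nearly balanced, so a large AI signals a
#' failed split rather than anatomy.
#'
#' @param v_left,v_right hemispheric volumes in mL (vectorized).
#' @return asymmetry index in \[0, 1\].
#' @export
asymmetry_index <- function(v_left, v_right) {
  tot <- v_left + v_right
  if (any(tot <= 0)) stop("v_left + v_right must be positive")
  abs(v_left - v_right) / tot
}

#' Flag asymmetry-index outliers in a cohort
#'
#' z-scores the AI over the cohort (population standard deviation) and flags
#' records with `z > z_cut`. Flagging is one-sided: a low AI means good
#' symmetry and is never anomalous.
#'
#' @param records data frame with columns `v_left` and `v_right` (mL), or an
#'   `ai` column directly; typically built by [cohort_asymmetry()].
#' @param z_cut z-score cut-off (default 3; strictly greater flags).
#' @return the input as a tibble with columns `ai`, `z` and `flagged`.
#' @export
flag_outliers <- function(records, z_cut = 3) {
  df <- as_tibble(records)
  if (!"ai" %in% names(df)) {
    if (!all(c("v_left", "v_right") %in% names(df))) {
      stop("records need either `ai` or both `v_left` and `v_right`")
    }
    df$ai <- asymmetry_index(df$v_left, df$v_right)
  }
  if (sum(is.finite(df$ai)) < 3) stop("need at least 3 records with finite AI")
  mu <- mean(df$ai)
  sd_pop <- sqrt(mean((df$ai - mu)^2))
  if (sd_pop == 0) {
    warning("zero AI spread in cohort; no outliers flagged")
    df$z <- 0
  } else {
    df$z <- (df$ai - mu) / sd_pop
  }
  df$flagged <- df$z > z_cut
  df
}

#' Cohort asymmetry table from hemisphere splits
#'
#' Convenience wrapper: computes hemispheric volumes, AI, z-scores and
#' outlier flags for a list of `hemisphere_pair` objects.
#'
#' @param hemis_list list of `hemisphere_pair` objects.
#' @param spacing voxel spacing `c(dz, dy, dx)` in mm (shared, or a list).
#' @param subject_id optional identifiers.
#' @param z_cut z-score cut-off.
#' @return tibble with `subject_id`, `v_left`, `v_right`, `ai`, `z`, `flagged`.
#' @export
cohort_asymmetry <- function(hemis_list, spacing, subject_id = NULL, z_cut = 3) {
  n <- length(hemis_list)
  if (is.null(subject_id)) subject_id <- sprintf("s%03d", seq_len(n))
  sp <- if (is.list(spacing)) spacing else rep(list(spacing), n)
  vols <- t(vapply(seq_len(n), function(i) {
    hemisphere_volumes(hemis_list[[i]], sp[[i]])
  }, numeric(2)))
  flag_outliers(tibble(subject_id = subject_id,
                       v_left = vols[, 1], v_right = vols[, 2]),
                z_cut = z_cut)
}
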