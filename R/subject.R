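#' Simulate one subject's ROI data for decoding
#'
#' Convenience wrapper tying the generators together: builds an ROI mask,
#' draws exemplar-specific clustered patterns, generates a test-session
#' trial sequence (the standard 20 trials per RefTC exemplar + 60 RTC +
#' 120 NTC unless one is supplied) and produces a trial-by-voxel
#' [beta_set()] either directly or via a BOLD time series followed by
#' trial-wise GLM estimation.
#'
#' @param sequence Optional [trial_sequence]; defaults to
#'   [generate_test_session()].
#' @param roi_voxels Mask size in voxels.
#' @param shape Grid dimensions for the mask.
#' @param amplitude,noise_sd Signal scale and noise standard deviation; the
#'   effective SNR is `amplitude / noise_sd`.
#' @param n_clusters,cluster_radius Informative-cluster geometry (voxels).
#' @param baseline Mean activity.
#' @param subject_id,roi Identifiers.
#' @param route `"betas"` simulates trial betas directly; `"timeseries"`
#'   simulates BOLD at the scanner TR and estimates betas by GLM.
#' @param tr_s Repetition time for the time-series route (s).
#' @return A list with `betas` ([beta_set()] over all trials), `mask`,
#'   `patterns` and `sequence`.
#' @export
simulate_roi_subject <- function(sequence = NULL, roi_voxels = 160,
                                 shape = c(12, 12, 12),
                                 amplitude = 1, noise_sd = 1,
                                 n_clusters = 3, cluster_radius = 2,
                                 baseline = 0, subject_id = NA, roi = "ROI",
                                 route = c("betas", "timeseries"), tr_s = 4.2) {
  route <- match.arg(route)
  if (is.null(sequence)) sequence <- generate_test_session()
  mask <- make_roi_mask(shape, roi_voxels, name = roi)
  patterns <- make_exemplar_patterns(mask, n_clusters = n_clusters,
                                     cluster_radius = cluster_radius,
                                     amplitude = amplitude, baseline = baseline)
  if (route == "betas") {
    betas <- simulate_trial_betas(sequence, patterns, noise_sd = noise_sd,
                                  subject_id = subject_id)
  } else {
    scan <- scans_for_sequence(sequence, tr_s = tr_s)
    Y <- simulate_bold_timeseries(sequence, patterns, scan, noise_sd = noise_sd)
    X <- build_design_matrix(sequence, scan = scan)
    betas <- estimate_trial_betas(Y, X, labels = sequence$category,
                                  subject_id = subject_id, roi = roi)
  }
  list(betas = betas, mask = mask, patterns = patterns, sequence = sequence)
}

#' Subset a beta set by trial label
#'
#' @param betas A [beta_set()].
#' @param categories Labels to keep (exact match), e.g.
#'   `c("RefTC-1", "RefTC-2", "RefTC-3")` or `"RTC"`.
#' @return A [beta_set()] restricted to the matching trials.
#' @export
subset_trials <- function(betas, categories) {
  stopifnot(inherits(betas, "beta_set"))
  keep <- betas$labels %in% categories
  beta_set(betas$betas[keep, , drop = FALSE], betas$labels[keep],
           subject_id = betas$subject_id, roi = betas$roi)
}

reftc_labels <- c("RefTC-1", "RefTC-2", "RefTC-3")
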