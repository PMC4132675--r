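#' Canonical haemodynamic response function parameters
#'
#' The canonical HRF is modelled as a difference of two gamma densities: a
#' positive response peaking about 5 s after the event and an undershoot
#' peaking later, weighted by `undershoot_ratio`. Delays and dispersions
#' are in seconds; gamma shape = delay / dispersion, scale = dispersion.
#'
#' @param peak_delay,peak_dispersion Delay and dispersion of the peak (s).
#' @param undershoot_delay,undershoot_dispersion Delay and dispersion of
#'   the undershoot (s).
#' @param undershoot_ratio Relative amplitude of the undershoot (< 1).
#' @param kernel_length Support of the sampled kernel (s).
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       undershoot_ratio = 1 / 6, kernel_length = 32) {
  vals <- c(peak_delay, undershoot_delay, peak_dispersion,
            undershoot_dispersion, kernel_length)
  if (any(vals <= 0) || undershoot_ratio < 0 || undershoot_ratio >= 1)
    stop("invalid spec: HRF parameters must be positive, undershoot_ratio in [0, 1)",
         call. = FALSE)
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio,
                 kernel_length = kernel_length),
            class = "hrf_params")
}

#' Sample the canonical HRF kernel
#'
#' Evaluates the double-gamma kernel on `[0, kernel_length]` at resolution
#' `dt` and normalises it to unit peak.
#'
#' @param params An [hrf_params()].
#' @param dt Sampling interval (s).
#' @return An object of class `hrf_kernel`: numeric kernel values with
#'   attribute `dt`.
#' @export
canonical_hrf <- function(params = hrf_params(), dt = 0.1) {
  stopifnot(inherits(params, "hrf_params"), dt > 0)
  t <- seq(0, params$kernel_length, by = dt)
  h <- dgamma(t, shape = params$peak_delay / params$peak_dispersion,
              scale = params$peak_dispersion) -
    params$undershoot_ratio *
      dgamma(t, shape = params$undershoot_delay / params$undershoot_dispersion,
             scale = params$undershoot_dispersion)
  h <- h / max(h)
  structure(h, dt = dt, class = "hrf_kernel")
}

#' Build a trial-wise design matrix
#'
#' One regressor per trial: a boxcar over the trial's listening time,
#' convolved with the HRF at microtime resolution `dt`, then sampled at the
#' scan times `0, TR, 2 TR, ...`. An intercept and any confound columns are
#' appended.
#'
#' @param sequence A [trial_sequence].
#' @param hrf An [canonical_hrf()] kernel (its `dt` must match `dt`).
#' @param scan A [scan_params()].
#' @param confounds Optional matrix of nuisance regressors
#'   (`n_scans` rows), e.g. movement parameters.
#' @param dt Microtime resolution (s).
#' @param intercept Append an intercept column.
#' @return A scans x regressors matrix with column names `trial_<index>`,
#'   confound names and `intercept`, plus attribute `trial_columns`.
#' @export
build_design_matrix <- function(sequence, hrf = NULL, scan, confounds = NULL,
                                dt = 0.1, intercept = TRUE) {
  stopifnot(inherits(scan, "scan_params"))
  if (is.null(hrf)) hrf <- canonical_hrf(dt = dt)
  if (abs(attr(hrf, "dt") - dt) > 1e-12)
    stop("hrf kernel resolution does not match dt", call. = FALSE)
  run_s <- (scan$n_scans - 1) * scan$tr_s
  if (any(sequence$onset_s < 0) || any(sequence$onset_s > run_s))
    stop("coverage error: trial onsets outside the scanned interval", call. = FALSE)
  n_fine <- ceiling((run_s + attr(hrf, "dt") * length(hrf)) / dt) + 1L
  n <- nrow(sequence)
  X <- matrix(0, scan$n_scans, n)
  scan_idx <- round((seq_len(scan$n_scans) - 1) * scan$tr_s / dt) + 1L
  h <- as.numeric(hrf)
  for (i in seq_len(n)) {
    box <- numeric(n_fine)
    a <- floor(sequence$onset_s[i] / dt) + 1L
    b <- min(ceiling((sequence$onset_s[i] + sequence$duration_s[i]) / dt), n_fine)
    box[a:b] <- 1
    reg <- convolve(box, rev(h), type = "open")[seq_len(n_fine)]
    X[, i] <- reg[scan_idx]
  }
  colnames(X) <- sprintf("trial_%03d", sequence$index)
  trial_cols <- seq_len(n)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    stopifnot(nrow(confounds) == scan$n_scans)
    if (is.null(colnames(confounds)))
      colnames(confounds) <- sprintf("confound_%d", seq_len(ncol(confounds)))
    X <- cbind(X, confounds)
  }
  if (intercept) X <- cbind(X, intercept = 1)
  attr(X, "trial_columns") <- trial_cols
  X
}

#' Estimate trial-wise betas by ordinary least squares
#'
#' Fits all trial regressors (plus intercept/confounds) in a single model
#' per voxel and returns the trial coefficients as a [beta_set()].
#'
#' @param timeseries Scans x voxels matrix.
#' @param design Design matrix from [build_design_matrix()].
#' @param labels Per-trial labels to attach (defaults to trial column
#'   names).
#' @param subject_id,roi Identifiers stored on the result.
#' @return A [beta_set()] of trials x voxels coefficients.
#' @export
estimate_trial_betas <- function(timeseries, design, labels = NULL,
                                 subject_id = NA, roi = NA) {
  timeseries <- as.matrix(timeseries)
  stopifnot(nrow(timeseries) == nrow(design))
  qrd <- qr(design)
  if (qrd$rank < ncol(design))
    stop("estimation error: design matrix is rank deficient", call. = FALSE)
  coefs <- qr.coef(qrd, timeseries)
  trial_cols <- attr(design, "trial_columns")
  if (is.null(trial_cols)) trial_cols <- seq_len(ncol(design))
  B <- coefs[trial_cols, , drop = FALSE]
  if (is.null(labels)) labels <- colnames(design)[trial_cols]
  beta_set(B, labels, subject_id = subject_id, roi = roi)
}
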