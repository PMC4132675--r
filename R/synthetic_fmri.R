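#' ROI voxel masks
#'
#' A mask is a single 6-connected blob of voxels inside a 3D grid,
#' representing an anatomical region of interest in one hemisphere. Masks
#' are sized in voxels; [roi_voxel_target()] converts the region volumes
#' (mm^3, summed across hemispheres) reported for this paradigm's six
#' regions into voxel counts at 1.5 mm isotropic resolution.
#'
#' @param shape Integer grid dimensions, e.g. `c(24, 24, 24)`.
#' @param target_voxels Number of member voxels to grow.
#' @param name Region label (free text; conventional labels are `"HC"`,
#'   `"EPC"`, `"PHC"`, `"HG"`, `"PT"`, `"STS"`).
#' @param hemisphere `"left"`, `"right"` or `NA`.
#' @param voxel_size_mm Isotropic voxel edge length (mm).
#' @return An object of class `roi_mask`: list with `shape`, `voxels`
#'   (matrix of integer xyz coordinates, one row per member voxel, in fixed
#'   order), `name`, `hemisphere`, `voxel_size_mm`.
#' @export
make_roi_mask <- function(shape, target_voxels, name = "ROI",
                          hemisphere = NA_character_, voxel_size_mm = 1.5) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  if (target_voxels < 1 || target_voxels > prod(shape))
    stop("capacity error: target_voxels must be in [1, prod(shape)]", call. = FALSE)
  occupied <- array(FALSE, dim = shape)
  seed <- sapply(shape, function(s) sample.int(s, 1))
  occupied[seed[1], seed[2], seed[3]] <- TRUE
  members <- matrix(seed, nrow = 1)
  frontier <- neighbours6(seed, shape)
  while (nrow(members) < target_voxels) {
    if (nrow(frontier) == 0)
      stop("capacity error: grid exhausted before reaching target_voxels", call. = FALSE)
    keep <- !occupied[frontier]
    frontier <- frontier[keep, , drop = FALSE]
    frontier <- frontier[!duplicated(frontier), , drop = FALSE]
    if (nrow(frontier) == 0)
      stop("capacity error: grid exhausted before reaching target_voxels", call. = FALSE)
    pick <- sample.int(nrow(frontier), 1)
    v <- frontier[pick, ]
    occupied[v[1], v[2], v[3]] <- TRUE
    members <- rbind(members, v)
    frontier <- rbind(frontier[-pick, , drop = FALSE], neighbours6(v, shape))
  }
  dimnames(members) <- list(NULL, c("x", "y", "z"))
  structure(list(shape = shape, voxels = members, name = name,
                 hemisphere = hemisphere, voxel_size_mm = voxel_size_mm),
            class = "roi_mask")
}

neighbours6 <- function(v, shape) {
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  nb <- sweep(offs, 2, v, "+")
  ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
        nb[, 2] >= 1 & nb[, 2] <= shape[2] &
        nb[, 3] >= 1 & nb[, 3] <= shape[3]
  nb[ok, , drop = FALSE]
}

#' @rdname make_roi_mask
#' @details `roi_voxel_target()` uses reference mean segmented volumes
#'   (mm^3, both hemispheres summed): HC 4188.8, EPC 5026.04, PHC 1799.29,
#'   HG 2317.93, PT 3967.07, STS 14396.07.
#' @param roi One of `"HC"`, `"EPC"`, `"PHC"`, `"HG"`, `"PT"`, `"STS"`.
#' @export
roi_voxel_target <- function(roi, voxel_size_mm = 1.5) {
  volumes <- c(HC = 4188.8, EPC = 5026.04, PHC = 1799.29,
               HG = 2317.93, PT = 3967.07, STS = 14396.07)
  roi <- match.arg(roi, names(volumes))
  round(volumes[[roi]] / voxel_size_mm^3)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s%s: %d voxels in %s grid (%.1f mm iso)\n",
              x$name, if (!is.na(x$hemisphere)) paste0(" (", x$hemisphere, ")") else "",
              nrow(x$voxels), paste(x$shape, collapse = "x"), x$voxel_size_mm))
  invisible(x)
}

#' Exemplar-specific multivoxel patterns
#'
#' Generates the generative patterns for the three RefTC exemplars inside an
#' ROI. Informative voxels are arranged in `n_clusters` spatial clusters
#' (all mask voxels within `cluster_radius` of randomly chosen cluster
#' centres); within them each exemplar gets independent standard-normal
#' deviations scaled by `amplitude`, while outside them the three patterns
#' are identical (baseline only). The signal-to-noise ratio of simulated
#' data is `amplitude / noise_sd`.
#'
#' @param mask An [make_roi_mask()] result.
#' @param n_clusters Number of informative clusters.
#' @param cluster_radius Cluster radius in voxel units (Euclidean).
#' @param amplitude Scale of exemplar-specific signal.
#' @param baseline Mean activity added to every voxel.
#' @param n_exemplars Number of exemplar patterns (3 in the standard design).
#' @return An object of class `exemplar_patterns`: list with `patterns`
#'   (`n_exemplars` x voxels matrix), `informative` (voxel row indices into
#'   `mask$voxels`), `amplitude`, `baseline`, `mask`.
#' @export
make_exemplar_patterns <- function(mask, n_clusters = 3, cluster_radius = 2,
                                   amplitude = 1, baseline = 0, n_exemplars = 3) {
  stopifnot(inherits(mask, "roi_mask"))
  nv <- nrow(mask$voxels)
  centres <- mask$voxels[sample.int(nv, n_clusters), , drop = FALSE]
  informative <- integer(0)
  for (i in seq_len(n_clusters)) {
    d2 <- rowSums(sweep(mask$voxels, 2, centres[i, ], "-")^2)
    informative <- union(informative, which(d2 <= cluster_radius^2))
  }
  informative <- sort(informative)
  patterns <- matrix(baseline, n_exemplars, nv)
  patterns[, informative] <- baseline +
    amplitude * matrix(rnorm(n_exemplars * length(informative)),
                       n_exemplars, length(informative))
  structure(list(patterns = patterns, informative = informative,
                 cluster_centres = centres, amplitude = amplitude,
                 baseline = baseline, mask = mask),
            class = "exemplar_patterns")
}

#' Trial-by-voxel beta sets
#'
#' Container for the activity estimates fed to the decoder: a numeric
#' matrix of trials x voxels plus per-trial labels.
#'
#' @param betas Trials x voxels matrix.
#' @param labels Character labels per trial (e.g. `"RefTC-1"`).
#' @param subject_id,roi Identifiers carried along for bookkeeping.
#' @return An object of class `beta_set`.
#' @export
beta_set <- function(betas, labels, subject_id = NA, roi = NA) {
  betas <- as.matrix(betas)
  stopifnot(nrow(betas) == length(labels), !anyNA(betas))
  structure(list(betas = betas, labels = as.character(labels),
                 subject_id = subject_id, roi = roi),
            class = "beta_set")
}

#' @export
print.beta_set <- function(x, ...) {
  cat(sprintf("<beta_set> %d trials x %d voxels (%s)\n",
              nrow(x$betas), ncol(x$betas),
              paste(names(table(x$labels)), table(x$labels),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

#' Simulate trial-wise betas directly
#'
#' Each trial's row is `baseline + pattern(label) + N(0, noise_sd)` per
#' voxel. RefTC trials reuse the fixed exemplar patterns; RTC and NTC
#' trials receive trial-unique fresh patterns on the informative voxels
#' (drawn at the same amplitude), mirroring stimuli that are generated anew
#' each trial and therefore carry no stable multivoxel representation.
#'
#' @param sequence A [trial_sequence].
#' @param patterns An [make_exemplar_patterns()] result.
#' @param noise_sd Standard deviation of additive iid Gaussian noise.
#' @param subject_id Identifier stored on the result.
#' @return A [beta_set()].
#' @export
simulate_trial_betas <- function(sequence, patterns, noise_sd = 1, subject_id = NA) {
  stopifnot(inherits(patterns, "exemplar_patterns"))
  nv <- ncol(patterns$patterns)
  info <- patterns$informative
  n <- nrow(sequence)
  betas <- matrix(rnorm(n * nv, sd = noise_sd), n, nv)
  for (i in seq_len(n)) {
    row <- rep(patterns$baseline, nv)
    if (grepl("^RefTC-", sequence$category[i])) {
      row <- patterns$patterns[sequence$exemplar_id[i], ]
    } else if (length(info) > 0) {
      row[info] <- patterns$baseline +
        patterns$amplitude * rnorm(length(info))
    }
    betas[i, ] <- betas[i, ] + row
  }
  beta_set(betas, sequence$category, subject_id = subject_id,
           roi = patterns$mask$name)
}

#' Scan parameters
#'
#' @param tr_s Repetition time (s); the acquisition default is 4.2 s.
#' @param n_scans Number of volumes.
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(tr_s = 4.2, n_scans) {
  stopifnot(tr_s > 0, n_scans >= 1)
  structure(list(tr_s = tr_s, n_scans = as.integer(n_scans)),
            class = "scan_params")
}

#' Number of scans needed to cover a trial sequence
#'
#' Covers the last trial's listening event plus the HRF tail.
#'
#' @param sequence A [trial_sequence].
#' @param tr_s Repetition time (s).
#' @param hrf_tail_s Kernel length to allow after the last event (s).
#' @return A [scan_params()].
#' @export
scans_for_sequence <- function(sequence, tr_s = 4.2, hrf_tail_s = 32) {
  t_end <- max(sequence$onset_s + sequence$duration_s) + hrf_tail_s
  scan_params(tr_s = tr_s, n_scans = ceiling(t_end / tr_s) + 1L)
}

#' Simulate BOLD time series from a trial sequence
#'
#' Per voxel, the series is the sum over trials of the trial's pattern
#' value times an HRF-convolved boxcar of the listening event, sampled at
#' the TR, plus iid Gaussian noise (optionally AR(1)-filtered). Trial
#' amplitudes are generated with the same label rules as
#' [simulate_trial_betas()] but without measurement noise, so a noise-free
#' series followed by [estimate_trial_betas()] recovers the injected
#' amplitudes exactly. The per-trial amplitude matrix used is attached as
#' attribute `amplitudes`.
#'
#' @param sequence A [trial_sequence].
#' @param patterns An [make_exemplar_patterns()] result.
#' @param scan A [scan_params()].
#' @param hrf HRF kernel sampled at `dt` (default [canonical_hrf()]).
#' @param noise_sd Gaussian noise standard deviation on the sampled series.
#' @param ar1 AR(1) coefficient for temporally autocorrelated noise
#'   (0 = white).
#' @param dt Microtime resolution for the convolution (s).
#' @return A scans x voxels matrix with attribute `amplitudes`
#'   (trials x voxels).
#' @export
simulate_bold_timeseries <- function(sequence, patterns, scan,
                                     hrf = NULL, noise_sd = 1, ar1 = 0,
                                     dt = 0.1) {
  stopifnot(inherits(patterns, "exemplar_patterns"), inherits(scan, "scan_params"))
  if (is.null(hrf)) hrf <- canonical_hrf(dt = dt)
  nv <- ncol(patterns$patterns)
  info <- patterns$informative
  n <- nrow(sequence)
  amps <- matrix(patterns$baseline, n, nv)
  for (i in seq_len(n)) {
    if (grepl("^RefTC-", sequence$category[i])) {
      amps[i, ] <- patterns$patterns[sequence$exemplar_id[i], ]
    } else if (length(info) > 0) {
      amps[i, info] <- patterns$baseline + patterns$amplitude * rnorm(length(info))
    }
  }
  X <- build_design_matrix(sequence, hrf = hrf, scan = scan, dt = dt,
                           intercept = FALSE)
  Y <- X %*% amps
  noise <- matrix(rnorm(scan$n_scans * nv, sd = noise_sd), scan$n_scans, nv)
  if (ar1 != 0) {
    noise <- apply(noise, 2, function(e) as.numeric(stats::filter(e, ar1,
                                                    method = "recursive")))
    noise <- noise * sqrt(1 - ar1^2)  # keep marginal variance at noise_sd^2
  }
  Y <- Y + noise
  attr(Y, "amplitudes") <- amps
  Y
}
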