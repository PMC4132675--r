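test_that("ROI masks are single 6-connected blobs of the requested size", {
  set.seed(51)
  mask <- make_roi_mask(c(12, 12, 12), 300, name = "PT")
  expect_equal(nrow(mask$voxels), 300)
  expect_equal(nrow(unique(mask$voxels)), 300)
  # connectivity check by BFS over the member set
  key <- function(v) paste(v, collapse = ",")
  members <- new.env()
  for (i in seq_len(nrow(mask$voxels))) assign(key(mask$voxels[i, ]), i, members)
  seen <- rep(FALSE, 300)
  queue <- 1L; seen[1] <- TRUE
  offs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  while (length(queue) > 0) {
    v <- mask$voxels[queue[1], ]; queue <- queue[-1]
    for (o in seq_len(6)) {
      k <- key(v + offs[o, ])
      if (exists(k, members, inherits = FALSE)) {
        idx <- get(k, members)
        if (!seen[idx]) { seen[idx] <- TRUE; queue <- c(queue, idx) }
      }
    }
  }
  expect_true(all(seen))
  expect_error(make_roi_mask(c(4, 4, 4), 65), "capacity")
})

test_that("ROI voxel targets follow the printed volumes at 1.5 mm isotropic", {
  # e.g. planum temporale: 3967.07 mm^3 / 3.375 mm^3 per voxel
  expect_equal(roi_voxel_target("PT"), round(3967.07 / 1.5^3))
  expect_true(abs(roi_voxel_target("PT") - 1176) <= 1)
  expect_equal(roi_voxel_target("HC"), round(4188.8 / 3.375))
  expect_error(roi_voxel_target("XX"))
})

test_that("exemplar patterns differ only on clustered informative voxels", {
  set.seed(52)
  mask <- make_roi_mask(c(10, 10, 10), 250)
  pat <- make_exemplar_patterns(mask, n_clusters = 3, cluster_radius = 2,
                                amplitude = 1.5, baseline = 0.4)
  expect_true(all(pat$informative %in% seq_len(250)))
  # all informative voxels lie within cluster_radius of a centre
  for (v in pat$informative) {
    d <- sqrt(rowSums(sweep(pat$cluster_centres, 2,
                            mask$voxels[v, ], "-")^2))
    expect_lte(min(d), 2)
  }
  # identical outside the clusters
  outside <- setdiff(seq_len(250), pat$informative)
  expect_equal(pat$patterns[1, outside], pat$patterns[2, outside])
  expect_equal(pat$patterns[1, outside], rep(0.4, length(outside)))

  flat <- make_exemplar_patterns(mask, amplitude = 0)
  expect_equal(flat$patterns[1, ], flat$patterns[3, ])
})

test_that("exemplar patterns are uncorrelated over informative voxels", {
  set.seed(53)
  mask <- make_roi_mask(c(10, 10, 10), 250)
  cors <- replicate(150, {
    p <- make_exemplar_patterns(mask, n_clusters = 3, cluster_radius = 3)
    cor(p$patterns[1, p$informative], p$patterns[2, p$informative])
  })
  expect_lt(abs(mean(cors)), 0.05)
})

test_that("trial betas carry fixed RefTC patterns and trial-unique RTC rows", {
  set.seed(54)
  mask <- make_roi_mask(c(8, 8, 8), 60)
  pat <- make_exemplar_patterns(mask, amplitude = 1)
  seqn <- generate_test_session(4, 6, 4)
  b0 <- simulate_trial_betas(seqn, pat, noise_sd = 0)
  ref1 <- b0$betas[b0$labels == "RefTC-1", , drop = FALSE]
  for (i in seq_len(nrow(ref1))) expect_equal(ref1[i, ], ref1[1, ])
  rtc <- b0$betas[b0$labels == "RTC", , drop = FALSE]
  expect_equal(nrow(unique(rtc)), nrow(rtc))  # unique even without noise

  # class means converge to the injected pattern
  seq_big <- generate_test_session(120, 0, 0)
  bb <- simulate_trial_betas(seq_big, pat, noise_sd = 0.5)
  m1 <- colMeans(bb$betas[bb$labels == "RefTC-1", ])
  expect_lt(max(abs(m1 - pat$patterns[1, ])), 0.35)
  expect_lt(mean(abs(m1 - pat$patterns[1, ])), 0.12)
})

test_that("BOLD simulation plus GLM recovers injected amplitudes", {
  set.seed(55)
  mask <- make_roi_mask(c(6, 6, 6), 25)
  pat <- make_exemplar_patterns(mask, amplitude = 1)
  seqn <- generate_test_session(3, 2, 2)
  scan <- scans_for_sequence(seqn)
  Y <- simulate_bold_timeseries(seqn, pat, scan, noise_sd = 0)
  X <- build_design_matrix(seqn, scan = scan)
  bet <- estimate_trial_betas(Y, X, labels = seqn$category)
  amps <- attr(Y, "amplitudes")
  rel <- abs(bet$betas - amps) / pmax(abs(amps), 1e-8)
  expect_lt(max(rel[abs(amps) > 1e-6]), 1e-6)

  # zero-amplitude patterns give pure noise about the baseline
  flat <- make_exemplar_patterns(mask, amplitude = 0, baseline = 0)
  Y2 <- simulate_bold_timeseries(seqn, flat, scan, noise_sd = 1)
  expect_lt(abs(mean(Y2)), 0.1)

  set.seed(88); a <- simulate_bold_timeseries(seqn, pat, scan, noise_sd = 1)
  set.seed(88); b <- simulate_bold_timeseries(seqn, pat, scan, noise_sd = 1)
  expect_identical(a, b)
})

test_that("direct-beta and timeseries+GLM routes give similar decoding", {
  set.seed(56)
  seqn <- generate_test_session(20, 0, 0)
  # overlapping trial regressors inflate beta noise; scale the scanner noise
  # so the GLM-estimated betas carry unit noise, matching the direct route
  scan <- scans_for_sequence(seqn)
  X <- build_design_matrix(seqn, scan = scan)
  infl <- sqrt(mean(diag(solve(crossprod(X)))[attr(X, "trial_columns")]))
  accs <- matrix(NA_real_, 3, 2)
  for (s in 1:3) {
    for (r in 1:2) {
      route <- c("betas", "timeseries")[r]
      sub <- simulate_roi_subject(sequence = seqn, roi_voxels = 48,
                                  shape = c(8, 8, 8), amplitude = 1.2,
                                  noise_sd = if (r == 1) 1 else 1 / infl,
                                  route = route)
      ref <- subset_trials(sub$betas, reftc3)
      accs[s, r] <- cross_validated_accuracy(ref, sub$mask,
                                             decoding_config())$accuracy
    }
  }
  # both routes decode well above chance at matched effective SNR and agree
  expect_gt(mean(accs[, 1]), 0.6)
  expect_gt(mean(accs[, 2]), 0.6)
  expect_lt(abs(mean(accs[, 1]) - mean(accs[, 2])), 0.15)
})
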