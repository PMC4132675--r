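test_that("searchlight neighbourhoods match brute-force lattice enumeration", {
  mask <- cube_mask(9)
  centre <- which(mask$voxels[, 1] == 5 & mask$voxels[, 2] == 5 &
                  mask$voxels[, 3] == 5)
  nb <- searchlight_neighbourhood(centre, 3, mask)
  # independent oracle: enumerate integer offsets with x^2+y^2+z^2 <= 9
  offs <- expand.grid(x = -3:3, y = -3:3, z = -3:3)
  n_oracle <- sum(offs$x^2 + offs$y^2 + offs$z^2 <= 9)
  expect_equal(length(nb), n_oracle)
  expect_equal(length(nb), 123)
  expect_true(centre %in% nb)

  corner <- which(mask$voxels[, 1] == 1 & mask$voxels[, 2] == 1 &
                  mask$voxels[, 3] == 1)
  expect_lt(length(searchlight_neighbourhood(corner, 3, mask)), 123)
  expect_equal(searchlight_neighbourhood(centre, 0, mask), centre)
  expect_error(searchlight_neighbourhood(0, 3, mask), "invalid centre")
})

test_that("stratified folds balance classes and partition the trials", {
  set.seed(81)
  labels <- rep(c("a", "b", "c"), each = 20)
  f <- stratified_folds(labels, 10)
  expect_equal(sort(unique(f)), 1:10)
  for (k in 1:10) expect_equal(as.integer(table(labels[f == k])), rep(2L, 3))
  expect_error(stratified_folds(rep(c("a", "b"), c(5, 20)), 10),
               "fold infeasible")
})

test_that("feature selection finds the informative cluster", {
  set.seed(82)
  hits <- 0; n_sim <- 15
  for (r in seq_len(n_sim)) {
    mask <- make_roi_mask(c(9, 9, 9), 64)
    pat <- make_exemplar_patterns(mask, n_clusters = 1, cluster_radius = 2,
                                  amplitude = 2)
    seqn <- generate_test_session(18, 0, 0)
    b <- simulate_trial_betas(seqn, pat, noise_sd = 1)
    sel <- select_features(b$betas, b$labels, mask, decoding_config())
    overlap <- length(intersect(sel$voxels, pat$informative)) /
      length(sel$voxels)
    chance <- length(pat$informative) / nrow(mask$voxels)
    hits <- hits + (overlap > chance)
  }
  expect_gte(hits / n_sim, 0.9)
})

test_that("feature selection returns a legal neighbourhood on pure noise", {
  set.seed(83)
  mask <- make_roi_mask(c(8, 8, 8), 40)
  x <- matrix(rnorm(30 * 40), 30, 40)
  labels <- rep(c("a", "b", "c"), each = 10)
  sel <- select_features(x, labels, mask, decoding_config())
  expect_true(all(sel$voxels %in% seq_len(40)))
  expect_identical(sel$voxels,
                   searchlight_neighbourhood(sel$centre, 3, mask))
  expect_error(select_features(x[1:3, ], labels[c(1, 11, 21)], mask,
                               decoding_config()),
               ">= 2 training trials")
})

test_that("score ties are broken by the lowest centre index", {
  set.seed(84)
  mask <- make_roi_mask(c(6, 6, 6), 20)
  x <- matrix(rnorm(30 * 20), 30, 20)
  labels <- rep(c("a", "b", "c"), 10)
  # a radius larger than the mask makes every neighbourhood the full ROI,
  # so all scores tie and the first centre must win
  cfg <- decoding_config(radius_voxels = 50)
  sel <- select_features(x, labels, mask, cfg)
  expect_equal(sel$centre, 1L)
  expect_equal(sel$voxels, seq_len(20))
})

test_that("noiseless separable betas decode perfectly and folds partition", {
  set.seed(85)
  sub <- small_subject(n_per_exemplar = 10, roi_voxels = 40, noise_sd = 0,
                       amplitude = 1)
  ref <- subset_trials(sub$betas, reftc3)
  res <- cross_validated_accuracy(ref, sub$mask, decoding_config())
  expect_equal(res$accuracy, 1.0)
  # every trial tested exactly once
  expect_equal(sort(unique(res$folds)), 1:10)
  expect_equal(length(res$predicted), nrow(ref$betas))
  expect_equal(res$chance, 1 / 3)
  expect_error(cross_validated_accuracy(
    beta_set(ref$betas[1:9, ], ref$labels[1:9]), sub$mask,
    decoding_config()), "fold infeasible")
})

test_that("feature selection never touches held-out data", {
  set.seed(86)
  sub <- small_subject(n_per_exemplar = 10, roi_voxels = 40,
                       amplitude = 1.5, noise_sd = 1)
  ref <- subset_trials(sub$betas, reftc3)
  cls <- as.integer(factor(ref$labels))
  set.seed(300); folds <- stratified_folds(cls, 10)

  run_fold1_selection <- function(x) {
    tr <- which(folds != 1)
    std <- tcmvpa:::fold_standardizer(x[tr, , drop = FALSE])
    set.seed(301)  # fixed inner-fold stream
    select_features(std(x[tr, , drop = FALSE]), ref$labels[tr], sub$mask,
                    decoding_config())$voxels
  }
  clean <- run_fold1_selection(ref$betas)
  poisoned <- ref$betas
  poisoned[folds == 1, ] <- poisoned[folds == 1, ] + 100  # corrupt test fold
  expect_identical(run_fold1_selection(poisoned), clean)

  # and the full pipeline: poisoning fold f leaves that fold's selection
  # unchanged when the RNG stream is replayed
  set.seed(302); r_clean <- cross_validated_accuracy(ref, sub$mask,
                                                     decoding_config())
  x2 <- ref$betas
  x2[r_clean$folds == 3, ] <- matrix(rnorm(sum(r_clean$folds == 3) *
                                           ncol(x2), sd = 50),
                                     sum(r_clean$folds == 3), ncol(x2))
  set.seed(302); r_pois <- cross_validated_accuracy(
    beta_set(x2, ref$labels), sub$mask, decoding_config())
  expect_identical(r_pois$selected[[3]], r_clean$selected[[3]])
})

test_that("the pipeline equals a naive reimplementation on a small fixture", {
  library(e1071)
  # 12 trials x 10 voxels, clearly separable three-class structure
  set.seed(87)
  proto <- matrix(rnorm(3 * 10, sd = 3), 3, 10)
  labels <- rep(c("e1", "e2", "e3"), each = 4)
  x <- proto[rep(1:3, each = 4), ] + matrix(rnorm(12 * 10, sd = 0.3), 12, 10)
  mask <- cube_mask(3)
  mask$voxels <- mask$voxels[1:10, , drop = FALSE]
  cfg <- decoding_config(radius_voxels = 1, n_folds = 4, n_inner_folds = 2,
                         standardize = FALSE,
                         score_tol = 1e-5, score_max_iter = 100000)

  cls <- as.integer(factor(labels))
  set.seed(310); folds <- stratified_folds(cls, 4)
  set.seed(311)
  res <- cross_validated_accuracy(beta_set(x, labels), mask, cfg, folds = folds)

  # naive path: plain R loops, e1071/LIBSVM binaries, same folds and RNG
  nbs <- lapply(1:10, function(ctr) searchlight_neighbourhood(ctr, 1, mask))
  naive_margins <- function(xtr, ytr, xte) {
    sapply(1:3, function(k) {
      yb <- ifelse(ytr == k, 1, -1)
      fit <- svm(xtr, factor(yb), kernel = "linear", cost = 1, scale = FALSE)
      w <- drop(t(fit$coefs) %*% fit$SV); b <- -fit$rho
      d_tr <- as.numeric(xtr %*% w + b)
      sgn <- if (sum(sign(d_tr) * yb) >= 0) 1 else -1  # orient towards class k
      sgn * (as.matrix(xte) %*% w + b)
    })
  }
  set.seed(311)
  correct <- 0
  for (f in 1:4) {
    tr <- which(folds != f); te <- which(folds == f)
    # naive selection: score each centre by 2-fold inner CV accuracy
    inner <- stratified_folds(cls[tr], 2)
    scores <- sapply(nbs, function(nb) {
      ok <- 0
      for (g in 1:2) {
        itr <- tr[inner != g]; ite <- tr[inner == g]
        m <- naive_margins(x[itr, nb, drop = FALSE], cls[itr],
                           x[ite, nb, drop = FALSE])
        pred <- sapply(seq_along(ite), function(u) {
          s <- ifelse(m[u, ] >= 0, 1, -1)
          h <- sapply(1:3, function(k) sum(s != (2 * (1:3 == k) - 1)))
          cand <- which(h == min(h))
          if (length(cand) > 1) {
            sm <- sapply(cand, function(k) sum((2 * (1:3 == k) - 1) * m[u, ]))
            cand <- cand[order(-sm, cand)]
          }
          cand[1]
        })
        ok <- ok + sum(pred == cls[ite])
      }
      ok / length(tr)
    })
    best <- which.max(scores)   # which.max takes the lowest index on ties
    nb <- nbs[[best]]
    m <- naive_margins(x[tr, nb, drop = FALSE], cls[tr],
                       x[te, nb, drop = FALSE])
    pred <- sapply(seq_along(te), function(u) {
      s <- ifelse(m[u, ] >= 0, 1, -1)
      h <- sapply(1:3, function(k) sum(s != (2 * (1:3 == k) - 1)))
      cand <- which(h == min(h))
      if (length(cand) > 1) {
        sm <- sapply(cand, function(k) sum((2 * (1:3 == k) - 1) * m[u, ]))
        cand <- cand[order(-sm, cand)]
      }
      cand[1]
    })
    correct <- correct + sum(pred == cls[te])
  }
  expect_equal(res$accuracy, correct / 12)
})
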