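#' Decoding configuration
#'
#' Settings for the exemplar-decoding pipeline: searchlight radius for
#' feature selection, inner cross-validation folds used to score candidate
#' searchlights, outer folds, SVM regularisation (fixed at C = 1 in the
#' study design), ECOC code type and standardisation.
#'
#' @param radius_voxels Searchlight radius in voxel units.
#' @param n_inner_folds Inner CV folds used to score searchlights on
#'   training data.
#' @param n_folds Outer cross-validation folds.
#' @param C SVM soft-margin penalty.
#' @param code ECOC code: `"onevsrest"` (default) or `"exhaustive"`.
#' @param standardize Z-score each voxel using training-fold statistics.
#' @param n_best Number of top-scoring searchlights whose union forms the
#'   feature set (1 = the single best searchlight).
#' @param svm_tol,svm_max_iter Dual tolerance and iteration cap for the
#'   per-fold classifiers.
#' @param score_tol,score_max_iter Looser solver settings used when scoring
#'   the many candidate searchlights during feature selection (accuracy
#'   scoring does not need tightly converged duals).
#' @return An object of class `decoding_config`.
#' @export
decoding_config <- function(radius_voxels = 3, n_inner_folds = 5, n_folds = 10,
                            C = 1, code = c("onevsrest", "exhaustive"),
                            standardize = TRUE, n_best = 1,
                            svm_tol = 1e-5, svm_max_iter = 100000L,
                            score_tol = 1e-2, score_max_iter = 2000L) {
  stopifnot(radius_voxels >= 0, n_inner_folds >= 2, n_folds >= 2, C > 0,
            n_best >= 1)
  structure(list(radius_voxels = radius_voxels, n_inner_folds = n_inner_folds,
                 n_folds = n_folds, C = C, code = match.arg(code),
                 standardize = standardize, n_best = n_best,
                 svm_tol = svm_tol, svm_max_iter = as.integer(svm_max_iter),
                 score_tol = score_tol,
                 score_max_iter = as.integer(score_max_iter)),
            class = "decoding_config")
}

#' Searchlight neighbourhood of a voxel
#'
#' All mask voxels whose Euclidean distance (in voxel-index units) from the
#' centre voxel is at most `radius_voxels`. Spheres are restricted to the
#' ROI, so their size shrinks near the mask border.
#'
#' @param centre Row index of the centre voxel in `mask$voxels`.
#' @param radius_voxels Sphere radius (voxel units).
#' @param mask An [make_roi_mask()] result.
#' @return Integer vector of voxel row indices (centre included).
#' @export
searchlight_neighbourhood <- function(centre, radius_voxels, mask) {
  stopifnot(inherits(mask, "roi_mask"))
  if (centre < 1 || centre > nrow(mask$voxels))
    stop("invalid centre: not a mask voxel", call. = FALSE)
  d2 <- rowSums(sweep(mask$voxels, 2, mask$voxels[centre, ], "-")^2)
  which(d2 <= radius_voxels^2 + 1e-9)
}

# Neighbourhoods for every mask voxel, as a list of index vectors.
all_neighbourhoods <- function(mask, radius_voxels) {
  lapply(seq_len(nrow(mask$voxels)), searchlight_neighbourhood,
         radius_voxels = radius_voxels, mask = mask)
}

#' Stratified fold assignment
#'
#' Assigns each trial to one of `k` folds, balancing classes: within each
#' class, fold labels are dealt in shuffled round-robin order. Uses the R
#' random number generator.
#'
#' @param labels Class label per trial.
#' @param k Number of folds.
#' @return Integer fold id (1..k) per trial.
#' @export
stratified_folds <- function(labels, k) {
  n <- length(labels)
  fold <- integer(n)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("fold infeasible: fewer trials than folds in class ", cl, call. = FALSE)
    fold[sample(idx)] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

#' Train a soft-margin linear SVM
#'
#' Solves the standard C-SVC dual (hinge loss, penalty `C`, linear kernel)
#' by sequential minimal optimisation. The decision value for a pattern `x`
#' is `weights . x + bias`; its sign gives the class.
#'
#' @param x Trials x features matrix.
#' @param y Labels in `{-1, +1}` (or a two-level factor).
#' @param C Soft-margin penalty.
#' @param tol Dual KKT violation tolerance.
#' @return An object of class `linear_svm`: `weights`, `bias`, `alpha`,
#'   `C`, `dual_objective`, `primal_objective`, `levels`.
#' @export
train_linear_svm <- function(x, y, C = 1, tol = 1e-6) {
  x <- as.matrix(x)
  if (is.factor(y) || is.character(y)) {
    lev <- sort(unique(as.character(y)))
    if (length(lev) != 2) stop("invalid labels: need exactly two classes", call. = FALSE)
    yy <- ifelse(as.character(y) == lev[2], 1, -1)
  } else {
    lev <- c("-1", "1")
    yy <- as.numeric(y)
    if (!all(yy %in% c(-1, 1))) stop("invalid labels: need -1/+1", call. = FALSE)
  }
  if (length(unique(yy)) < 2)
    stop("invalid labels: both classes must be present", call. = FALSE)
  fit <- smo_train_cpp(x, yy, C = C, tol = tol)
  margin <- as.numeric(x %*% fit$weights + fit$bias)
  primal <- 0.5 * sum(fit$weights^2) + C * sum(pmax(0, 1 - yy * margin))
  structure(list(weights = as.numeric(fit$weights), bias = fit$bias,
                 alpha = as.numeric(fit$alpha), C = C,
                 dual_objective = fit$dual_objective,
                 primal_objective = primal, levels = lev),
            class = "linear_svm")
}

#' @export
#' @rdname train_linear_svm
#' @param object A `linear_svm`.
#' @param newdata Trials x features matrix.
#' @param ... Unused.
#' @return `predict()` returns decision values (attribute `class` holds the
#'   signed class labels).
predict.linear_svm <- function(object, newdata, ...) {
  d <- as.numeric(as.matrix(newdata) %*% object$weights + object$bias)
  structure(d, class_label = ifelse(d >= 0, object$levels[2], object$levels[1]))
}

#' ECOC code matrix
#'
#' Rows are classes, columns binary problems, entries +/-1. The
#' one-vs-rest code for `k` classes has `k` columns; the exhaustive code
#' enumerates all `2^(k-1) - 1` distinct non-constant dichotomies.
#'
#' @param n_classes Number of classes.
#' @param type `"onevsrest"` or `"exhaustive"`.
#' @return Integer matrix (classes x problems) of +/-1.
#' @export
ecoc_code <- function(n_classes, type = c("onevsrest", "exhaustive")) {
  type <- match.arg(type)
  if (type == "onevsrest") {
    code <- matrix(-1L, n_classes, n_classes)
    diag(code) <- 1L
  } else {
    cols <- list()
    for (m in seq_len(2^(n_classes - 1) - 1)) {
      bits <- as.integer(intToBits(m))[seq_len(n_classes)]
      cols[[length(cols) + 1]] <- ifelse(bits == 1, 1L, -1L)
    }
    code <- do.call(cbind, cols)
  }
  code
}

#' Classify by ECOC Hamming decoding
#'
#' Turns per-problem decision values into a codeword of signs and assigns
#' the class whose code row has minimum Hamming distance. Ties are broken
#' by the larger summed signed margin (`sum(code[k, ] * margins)`), then by
#' the lower class index.
#'
#' @param margins Trials x problems matrix of decision values (or a single
#'   trial's vector).
#' @param code An [ecoc_code()] matrix.
#' @return Integer class index per trial.
#' @export
ecoc_classify <- function(margins, code) {
  if (is.null(dim(margins))) margins <- matrix(margins, nrow = 1)
  if (ncol(margins) != ncol(code))
    stop("configuration error: one margin column per code column required",
         call. = FALSE)
  as.integer(ecoc_decode_cpp(as.matrix(margins), code))
}

# Fit one SVM per ECOC column on (x, integer classes); returns list of fits.
fit_ecoc_svms <- function(x, cls, code, C, tol = 1e-6) {
  lapply(seq_len(ncol(code)), function(l) {
    yb <- code[cls, l]
    if (length(unique(yb)) < 2) return(NULL)  # degenerate dichotomy
    train_linear_svm(x, yb, C = C, tol = tol)
  })
}

ecoc_margins <- function(models, x) {
  x <- as.matrix(x)
  vapply(models, function(m) {
    if (is.null(m)) rep(0, nrow(x)) else as.numeric(predict(m, x))
  }, numeric(nrow(x)))
}

# Standardise columns by training statistics; zero-variance voxels pass
# through unscaled.
fold_standardizer <- function(train_x) {
  mu <- colMeans(train_x)
  sdv <- apply(train_x, 2, sd)
  sdv[sdv < 1e-12] <- 1
  function(x) sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
}

#' Searchlight feature selection
#'
#' Scores every candidate searchlight (one per mask voxel, radius
#' `config$radius_voxels`, restricted to the ROI) by the inner
#' cross-validated accuracy of the same ECOC linear-SVM classifier on the
#' training data only, and returns the voxel set of the highest-scoring
#' searchlight (or the union of the `n_best` best). Ties are broken by the
#' lowest centre voxel index. Inner folds are drawn from the R random
#' number generator, so results are deterministic given the seed.
#'
#' @param x Training trials x mask voxels matrix (standardised by the
#'   caller if desired).
#' @param labels Class label per training trial.
#' @param mask An [make_roi_mask()] result with one row per column of `x`.
#' @param config A [decoding_config()].
#' @param neighbourhoods Optional precomputed [all_neighbourhoods()] list.
#' @return List with `voxels` (selected voxel indices), `centre`,
#'   `score`, and `scores` (per-centre accuracies).
#' @export
select_features <- function(x, labels, mask, config = decoding_config(),
                            neighbourhoods = NULL) {
  stopifnot(inherits(mask, "roi_mask"))
  if (nrow(mask$voxels) == 0) stop("invalid input: empty mask", call. = FALSE)
  cls <- as.integer(factor(labels, levels = sort(unique(labels))))
  if (min(table(cls)) < 2)
    stop("invalid input: need >= 2 training trials per class", call. = FALSE)
  if (is.null(neighbourhoods))
    neighbourhoods <- all_neighbourhoods(mask, config$radius_voxels)
  code <- ecoc_code(length(unique(cls)), config$code)
  inner <- stratified_folds(cls, min(config$n_inner_folds, min(table(cls))))
  scores <- score_neighbourhoods_cpp(as.matrix(x), cls, code, neighbourhoods,
                                     inner, config$C,
                                     tol = config$score_tol,
                                     max_iter = config$score_max_iter)
  ord <- order(-scores, seq_along(scores))  # ties: lowest centre index first
  best <- ord[seq_len(min(config$n_best, length(ord)))]
  list(voxels = sort(unique(unlist(neighbourhoods[best]))),
       centre = best[1], score = scores[best[1]], scores = scores)
}

#' Cross-validated exemplar decoding for one ROI
#'
#' The full decoding pipeline: stratified `n_folds`-fold cross-validation
#' where, within each fold, voxels are standardised by training statistics,
#' a searchlight feature set is selected on the training portion only, one
#' linear SVM (C = `config$C`) is trained per ECOC binary problem, and the
#' held-out trials are classified by Hamming decoding. Accuracy is the
#' proportion of correct guesses pooled across all folds; chance for three
#' balanced classes is 1/3.
#'
#' @param betas A [beta_set()] (or trials x voxels matrix with `labels`).
#' @param mask The [make_roi_mask()] the beta columns live in.
#' @param config A [decoding_config()].
#' @param labels Labels (taken from `betas$labels` when `betas` is a
#'   `beta_set`).
#' @param folds Optional precomputed fold assignment (1..n_folds per
#'   trial); drawn by [stratified_folds()] otherwise.
#' @param neighbourhoods Optional precomputed [all_neighbourhoods()].
#' @return An object of class `decoding_result`: `accuracy`,
#'   `fold_accuracy`, `folds`, `predicted`, `true`, `selected` (voxel sets
#'   per fold), `chance`.
#' @export
cross_validated_accuracy <- function(betas, mask, config = decoding_config(),
                                     labels = NULL, folds = NULL,
                                     neighbourhoods = NULL) {
  if (inherits(betas, "beta_set")) {
    x <- betas$betas
    if (is.null(labels)) labels <- betas$labels
  } else x <- as.matrix(betas)
  stopifnot(length(labels) == nrow(x), ncol(x) == nrow(mask$voxels))
  lev <- sort(unique(labels))
  cls <- as.integer(factor(labels, levels = lev))
  if (min(table(cls)) < config$n_folds)
    stop("fold infeasible: need >= n_folds trials per class", call. = FALSE)
  if (is.null(folds)) folds <- stratified_folds(cls, config$n_folds)
  if (is.null(neighbourhoods))
    neighbourhoods <- all_neighbourhoods(mask, config$radius_voxels)
  code <- ecoc_code(length(lev), config$code)

  predicted <- integer(length(cls))
  selected <- vector("list", config$n_folds)
  fold_acc <- numeric(config$n_folds)
  for (f in seq_len(config$n_folds)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    std <- if (config$standardize) fold_standardizer(x[tr, , drop = FALSE])
           else identity
    xtr <- std(x[tr, , drop = FALSE])
    xte <- std(x[te, , drop = FALSE])
    sel <- select_features(xtr, labels[tr], mask, config,
                           neighbourhoods = neighbourhoods)
    selected[[f]] <- sel$voxels
    models <- fit_ecoc_svms(xtr[, sel$voxels, drop = FALSE], cls[tr], code,
                            C = config$C, tol = config$svm_tol)
    marg <- ecoc_margins(models, xte[, sel$voxels, drop = FALSE])
    predicted[te] <- ecoc_classify(marg, code)
    fold_acc[f] <- mean(predicted[te] == cls[te])
  }
  structure(list(accuracy = mean(predicted == cls), fold_accuracy = fold_acc,
                 folds = folds, predicted = lev[predicted], true = labels,
                 selected = selected, chance = 1 / length(lev)),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> accuracy %.3f (chance %.3f) over %d folds\n",
              x$accuracy, x$chance, length(x$fold_accuracy)))
  invisible(x)
}

#' Label-shuffle control
#'
#' Repeats the full decoding pipeline with labels randomly shuffled across
#' trials. With shuffled labels no exemplar information is available and
#' pooled accuracy is expected at chance.
#'
#' @inheritParams cross_validated_accuracy
#' @param n_shuffles Number of shuffles.
#' @return Numeric vector of per-shuffle pooled accuracies.
#' @export
label_shuffle_control <- function(betas, mask, config = decoding_config(),
                                  labels = NULL, n_shuffles = 20,
                                  neighbourhoods = NULL) {
  if (inherits(betas, "beta_set") && is.null(labels)) labels <- betas$labels
  if (is.null(neighbourhoods))
    neighbourhoods <- all_neighbourhoods(mask, config$radius_voxels)
  vapply(seq_len(n_shuffles), function(s) {
    cross_validated_accuracy(betas, mask, config, labels = sample(labels),
                             neighbourhoods = neighbourhoods)$accuracy
  }, numeric(1))
}

#' Pseudo-class control on trial-unique stimuli
#'
#' Divides trials of a trial-unique condition (the 60 RTC trials in the
#' standard design) randomly into three equal pseudo-classes and runs the
#' same decoding pipeline. Because the stimulus is generated anew every
#' trial, no stable representation exists and accuracy is expected at
#' chance.
#'
#' @inheritParams cross_validated_accuracy
#' @param n_classes Number of pseudo-classes.
#' @return A `decoding_result`.
#' @export
rtc_split_control <- function(betas, mask, config = decoding_config(),
                              n_classes = 3, neighbourhoods = NULL) {
  x <- if (inherits(betas, "beta_set")) betas$betas else as.matrix(betas)
  n <- nrow(x)
  sizes <- rep(n %/% n_classes, n_classes)
  extra <- n %% n_classes
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  pseudo <- sample(rep(paste0("pseudo-", seq_len(n_classes)), sizes))
  cross_validated_accuracy(x, mask, config, labels = pseudo,
                           neighbourhoods = neighbourhoods)
}
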