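#' Group-level test result
#'
#' Uniform container for the group statistics: test name, statistic (t or
#' F), degrees of freedom, p-value, tail and effect direction.
#'
#' @param test Test name.
#' @param statistic Observed statistic.
#' @param df Degrees of freedom (length 1 for t, 2 for F).
#' @param p P-value.
#' @param tail `"one"` or `"two"`.
#' @param direction Sign of the observed effect (`"greater"`, `"less"`,
#'   `"none"`).
#' @return An object of class `group_result`.
#' @export
group_result <- function(test, statistic, df, p, tail, direction = "none") {
  stopifnot(p >= 0, p <= 1)
  structure(list(test = test, statistic = statistic, df = df, p = p,
                 tail = tail, direction = direction),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result> %s: stat = %.4f, df = %s, p = %.4g (%s-tailed)\n",
              x$test, x$statistic, paste(x$df, collapse = ","), x$p, x$tail))
  invisible(x)
}

#' One-sample t-test against a fixed level
#'
#' Used to test per-subject decoding accuracies against the chance level
#' (1/3 for three balanced classes); accuracy questions are directional, so
#' the default alternative is `"greater"`.
#'
#' @param values One value per subject.
#' @param mu0 Null level (default chance = 1/3).
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return A [group_result()] with df = n - 1.
#' @export
one_sample_t <- function(values, mu0 = 1 / 3,
                         alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(values) < 2) stop("invalid input: need n >= 2", call. = FALSE)
  if (sd(values) < 1e-10 * max(1, abs(mean(values))))
    stop("undefined statistic: zero variance in values", call. = FALSE)
  tt <- t.test(values, mu = mu0, alternative = alternative)
  group_result("one-sample t", unname(tt$statistic), unname(tt$parameter),
               tt$p.value, if (alternative == "two.sided") "two" else "one",
               if (mean(values) > mu0) "greater"
               else if (mean(values) < mu0) "less" else "none")
}

#' Paired t-test
#'
#' A one-sample t-test on within-subject differences `a - b`; used for the
#' region and hemisphere comparisons (two-tailed by default).
#'
#' @param a,b Paired per-subject values.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return A [group_result()] with df = n - 1.
#' @export
paired_t <- function(a, b, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b) || length(a) < 2)
    stop("invalid input: need equal-length vectors, n >= 2", call. = FALSE)
  d <- a - b
  if (sd(d) < 1e-10 * max(1, abs(mean(d))))
    stop("undefined statistic: zero variance of paired differences", call. = FALSE)
  tt <- t.test(a, b, paired = TRUE, alternative = alternative)
  group_result("paired t", unname(tt$statistic), unname(tt$parameter),
               tt$p.value, if (alternative == "two.sided") "two" else "one",
               if (mean(d) > 0) "greater" else if (mean(d) < 0) "less" else "none")
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject ANOVA on a complete subjects x conditions table (e.g.
#' decoding accuracy per region). The F statistic is
#' `MS_condition / MS_(condition x subject)` with degrees of freedom
#' `(r - 1, (r - 1)(n - 1))`; no sphericity correction is applied (a
#' Greenhouse-Geisser epsilon is reported alongside for reference).
#'
#' @param table Numeric matrix or data frame, subjects in rows, conditions
#'   in columns; no missing cells.
#' @return A [group_result()]; the Greenhouse-Geisser epsilon is attached
#'   as attribute `gg_epsilon`.
#' @export
rm_anova <- function(table) {
  table <- as.matrix(table)
  if (anyNA(table)) stop("invalid input: missing cells", call. = FALSE)
  n <- nrow(table); r <- ncol(table)
  if (n < 2 || r < 2) stop("invalid input: need >= 2 subjects and >= 2 conditions",
                           call. = FALSE)
  long <- data.frame(y = as.vector(table),
                     subject = factor(rep(seq_len(n), times = r)),
                     condition = factor(rep(seq_len(r), each = n)))
  fit <- aov(y ~ condition + Error(subject / condition), data = long)
  s <- summary(fit)[["Error: subject:condition"]][[1]]
  Fval <- s["condition", "F value"]
  p <- s["condition", "Pr(>F)"]
  df <- c(s["condition", "Df"], s["Residuals", "Df"])
  # Greenhouse-Geisser epsilon from the double-centred covariance matrix
  S <- stats::cov(table)
  Sc <- sweep(sweep(S, 1, rowMeans(S), "-"), 2, colMeans(S), "-") + mean(S)
  eps <- sum(diag(Sc))^2 / ((r - 1) * sum(Sc^2))
  out <- group_result("repeated-measures ANOVA", unname(Fval), unname(df),
                      unname(p), "two")
  attr(out, "gg_epsilon") <- eps
  out
}

#' Hemisphere comparison and collapse
#'
#' For each ROI, compares left- and right-hemisphere accuracies with a
#' paired two-tailed t-test. If no ROI shows a significant difference at
#' `alpha`, hemisphere-collapsed accuracies (the per-subject mean of left
#' and right) are returned; otherwise the collapse is withheld and the
#' significant ROIs are flagged.
#'
#' @param left,right Numeric matrices, subjects x ROIs, with matching
#'   column names.
#' @param alpha Significance threshold.
#' @return A list with `tests` (one [group_result()] per ROI), `collapse`
#'   (logical), `flagged` (ROIs with significant asymmetry) and
#'   `collapsed` (subjects x ROIs matrix, `NULL` when withheld).
#' @export
hemisphere_collapse_check <- function(left, right, alpha = 0.05) {
  left <- as.matrix(left); right <- as.matrix(right)
  if (!all(dim(left) == dim(right)))
    stop("invalid input: left/right must be paired per subject and ROI",
         call. = FALSE)
  rois <- colnames(left)
  if (is.null(rois)) rois <- sprintf("roi_%d", seq_len(ncol(left)))
  tests <- lapply(seq_len(ncol(left)), function(j) {
    if (sd(left[, j] - right[, j]) < 1e-10)
      group_result("paired t", 0, nrow(left) - 1, 1, "two")
    else paired_t(left[, j], right[, j])
  })
  names(tests) <- rois
  p <- vapply(tests, function(t) t$p, numeric(1))
  flagged <- rois[p < alpha]
  collapse <- length(flagged) == 0
  list(tests = tests, collapse = collapse, flagged = flagged,
       collapsed = if (collapse) (left + right) / 2 else NULL)
}

#' Tidy results table and stats report across subjects and ROIs
#'
#' `decoding_table()` assembles a tidy data frame (subject, roi,
#' hemisphere, analysis, accuracy) from nested result lists;
#' `group_report()` runs the one-tailed accuracy-vs-chance test per ROI and
#' the across-region repeated-measures ANOVA on such a table.
#'
#' @param results Named list (by subject) of named lists (by ROI) of
#'   accuracies or `decoding_result`s.
#' @param hemisphere,analysis Annotation columns.
#' @return A data frame (`decoding_table`); a list with `per_roi`
#'   [group_result()]s and `anova` (`group_report`).
#' @export
decoding_table <- function(results, hemisphere = NA, analysis = "reftc") {
  rows <- list()
  for (s in names(results))
    for (r in names(results[[s]])) {
      v <- results[[s]][[r]]
      acc <- if (inherits(v, "decoding_result")) v$accuracy else as.numeric(v)
      rows[[length(rows) + 1]] <-
        data.frame(subject = s, roi = r, hemisphere = hemisphere,
                   analysis = analysis, accuracy = acc, stringsAsFactors = FALSE)
    }
  do.call(rbind, rows)
}

#' @rdname decoding_table
#' @param table Tidy data frame with columns `subject`, `roi`, `accuracy`.
#' @param chance Null accuracy level.
#' @export
group_report <- function(table, chance = 1 / 3) {
  wide <- tapply(table$accuracy, list(table$subject, table$roi), mean)
  per_roi <- lapply(colnames(wide), function(r) one_sample_t(wide[, r], chance))
  names(per_roi) <- colnames(wide)
  anova <- if (ncol(wide) >= 2) rm_anova(wide) else NULL
  list(per_roi = per_roi, anova = anova)
}
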