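#' Linear regression against identity
#'
#' Ordinary least squares of y (method under evaluation) on x (reference),
#' with the squared Pearson correlation as R^2. Used to compare a method's
#' read-outs with reference values next to the identity line y = x.
#'
#' @param x reference values
#' @param y method values, same length
#' @return list with `slope`, `intercept`, `r_squared`, `n`
#' @export
regress_identity <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_lungmorph("need equal-length vectors with n >= 3", "lungmorph_stat_error")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_lungmorph("non-finite values in regression input", "lungmorph_stat_error")
  if (stats::var(x) == 0)
    stop_lungmorph("x has no variance", "lungmorph_stat_error")
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 0 else cor(x, y)^2
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, n = length(x))
}

#' Bland-Altman analysis on relative differences
#'
#' Paired relative differences r_i = (a_i - b_i) / ((a_i + b_i) / 2); bias
#' is their mean and the limits of agreement are bias +/- 1.96 * sd(r).
#' With the method under evaluation passed as `a` and the reference as `b`,
#' underestimation by the method yields a negative bias.
#'
#' @param a,b paired values; all pairwise averages must be positive
#' @param percent report bias and limits in percent (default FALSE)
#' @return list with `bias`, `loa_low`, `loa_high`, `rel_diff`, `n`
#' @export
bland_altman <- function(a, b, percent = FALSE) {
  if (length(a) != length(b) || length(a) < 1L)
    stop_lungmorph("need equal-length paired vectors", "lungmorph_stat_error")
  avg <- (a + b) / 2
  if (any(!is.finite(avg)) || any(avg <= 0)) {
    bad <- which(!is.finite(avg) | avg <= 0)[1]
    stop_lungmorph(sprintf("pair %d has non-positive average; relative difference undefined",
                           bad), "lungmorph_stat_error")
  }
  r <- (a - b) / avg
  bias <- mean(r)
  s <- if (length(r) >= 2L) sd(r) else NA_real_
  k <- if (percent) 100 else 1
  list(bias = k * bias, loa_low = k * (bias - 1.96 * s),
       loa_high = k * (bias + 1.96 * s), rel_diff = k * r, n = length(r))
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' ICC(2,1): single-measurement absolute agreement under a two-way random
#' effects model (rows = subjects, columns = raters), computed from the
#' two-way ANOVA mean squares as
#' (MSR - MSE) / (MSR + (k - 1) MSE + (k / n)(MSC - MSE)).
#' Penalizes systematic rater offsets as well as loss of correlation.
#'
#' @param ratings complete numeric matrix, subjects x raters (n >= 2, k >= 2)
#' @return ICC estimate in \[-1, 1\]
#' @export
icc_absolute <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (any(!is.finite(ratings)))
    stop_lungmorph("ratings matrix must be complete and finite", "lungmorph_stat_error")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L)
    stop_lungmorph("need >= 2 subjects and >= 2 raters", "lungmorph_stat_error")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Welch's two-sample t-test
#'
#' Two-sided t-test with Welch's correction for unequal variances
#' (Satterthwaite degrees of freedom); the comparison used for
#' normoxia-vs-hyperoxia group read-outs.
#'
#' @param a,b numeric group vectors (each n >= 2, at least one with
#'   positive variance)
#' @return list with `t`, `df`, `p`
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop_lungmorph("each group needs n >= 2", "lungmorph_stat_error")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop_lungmorph("both groups are constant", "lungmorph_stat_error")
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

# Regression + Bland-Altman bundle for one read-out; computed (method under
# evaluation) vs reference (theory or gold standard).
agreement_result <- function(reference, computed, label = "") {
  structure(list(label = label,
                 regression = regress_identity(reference, computed),
                 bland_altman = bland_altman(computed, reference, percent = TRUE),
                 n = length(reference)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  r <- x$regression; ba <- x$bland_altman
  cat(sprintf("<agreement_result> %s (n = %d)\n", x$label, x$n))
  cat(sprintf("  regression: y = %.4f x + %.4g, R^2 = %.4f\n",
              r$slope, r$intercept, r$r_squared))
  cat(sprintf("  Bland-Altman: bias %.2f%% [%.2f%%, %.2f%%]\n",
              ba$bias, ba$loa_low, ba$loa_high))
  invisible(x)
}
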