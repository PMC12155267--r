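#' Spearman rank correlation between two measurement methods
#'
#' Pearson correlation of mid-ranks (average ranks on ties), as used to
#' validate an automated angle measurement against a clinical reference.
#' The p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom;
#' an exact permutation p-value is available for small samples.
#'
#' @param x,y paired numeric vectors, length >= 3, no missing values.
#' @param p_method `"t"` (default) or `"exact"` (delegates to
#'   [stats::cor.test()]'s exact Spearman distribution; small n only).
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_rho <- function(x, y, p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) stop("paired vectors differ in length", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant column: rank correlation undefined", call. = FALSE)
  rho <- stats::cor(x, y, method = "spearman")
  p <- if (p_method == "t") {
    if (abs(rho) >= 1) 0 else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  }
  list(rho = rho, p = p, n = n)
}

#' Intraclass correlation coefficient with 95% confidence interval
#'
#' Two-way ANOVA decomposition of an n-subjects by k-raters table into
#' between-subject (MSR), between-rater (MSC) and residual (MSE) mean
#' squares, then the single-measurement ICC in the requested form:
#'
#' * `"agreement"` (default) -- two-way random effects, absolute agreement,
#'   ICC(A,1): `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'   Sensitive to systematic offsets between raters.
#' * `"consistency"` -- two-way, consistency, ICC(C,1):
#'   `(MSR - MSE) / (MSR + (k-1) MSE)`. Ignores constant offsets.
#'
#' Confidence bounds follow the standard F-distribution constructions for
#' these forms (Satterthwaite degrees of freedom for the agreement form).
#'
#' @param ratings numeric matrix or data frame, subjects in rows, raters or
#'   methods in columns (k >= 2, n >= 3, no missing cells).
#' @param form `"agreement"` or `"consistency"`.
#' @param conf_level confidence level (default 0.95).
#' @return list with `icc`, `ci_low`, `ci_high`, `form`, `n`, `k` and the
#'   mean squares `MSR`, `MSC`, `MSE`.
#' @export
icc <- function(ratings, form = c("agreement", "consistency"),
                conf_level = 0.95) {
  form <- match.arg(form)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("missing cells not allowed", call. = FALSE)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (k < 2L) stop("need at least 2 raters/methods", call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((ratings - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR <= 0)
    stop("zero between-subject variance: ICC degenerate", call. = FALSE)
  alpha <- 1 - conf_level
  if (form == "consistency") {
    est <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    if (MSE == 0) {
      lo <- hi <- 1
    } else {
      Fobs <- MSR / MSE
      FL <- Fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      FU <- Fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      lo <- (FL - 1) / (FL + k - 1)
      hi <- (FU - 1) / (FU + k - 1)
    }
  } else {
    est <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    if (MSE == 0 && MSC == 0) {
      lo <- hi <- 1
    } else {
      a <- k * est / (n * (1 - est))
      b <- 1 + k * est * (n - 1) / (n * (1 - est))
      v <- (a * MSC + b * MSE)^2 /
        ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
      FL <- stats::qf(1 - alpha / 2, n - 1, v)
      FU <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (MSR - FL * MSE) /
        (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
      hi <- n * (FU * MSR - MSE) /
        (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    }
  }
  list(icc = est, ci_low = min(lo, est), ci_high = max(hi, est),
       form = form, n = n, k = k, MSR = MSR, MSC = MSC, MSE = MSE)
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' \deqn{\alpha = \frac{k}{k-1}\left(1 -
#'   \frac{\sum_i s_i^2}{s_{total}^2}\right)}
#' where `s_i^2` are the sample variances of the k item (method) columns
#' and `s_total^2` the variance of the per-subject total score. Values
#' above 0.9 indicate high internal consistency between methods.
#'
#' @param items numeric matrix or data frame, subjects in rows, items in
#'   columns (k >= 2, n >= 3, no missing cells).
#' @return alpha coefficient (<= 1; can be negative for discordant items).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (anyNA(items)) stop("missing cells not allowed", call. = FALSE)
  n <- nrow(items); k <- ncol(items)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (k < 2L) stop("need at least 2 items", call. = FALSE)
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) stop("zero total-score variance", call. = FALSE)
  item_var <- sum(apply(items, 2, stats::var))
  k / (k - 1) * (1 - item_var / total_var)
}

#' Mean and sample standard deviation
#'
#' Descriptive summary of a measurement series; SD uses the n-1
#' denominator. A single value yields an `NA` SD.
#'
#' @param values numeric vector, nonempty.
#' @return named vector `c(mean, sd)`.
#' @export
describe_values <- function(values) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  c(mean = mean(values),
    sd = if (length(values) < 2L) NA_real_ else stats::sd(values))
}

#' Method-agreement reliability report
#'
#' Bundles the validation statistics comparing an automated measurement
#' (method B) against a clinical reference (method A): Spearman rho with
#' p-value, ICC with 95% CI, Cronbach's alpha across the two methods, and
#' the mean +/- SD of each method.
#'
#' @param reference,predicted paired numeric vectors of angles (degrees).
#' @param icc_form passed to [icc()].
#' @return object of class `reliability_report`.
#' @export
reliability_report <- function(reference, predicted,
                               icc_form = "agreement") {
  if (length(reference) != length(predicted))
    stop("methods differ in length", call. = FALSE)
  rho <- spearman_rho(reference, predicted)
  tab <- cbind(reference, predicted)
  ic <- icc(tab, form = icc_form)
  structure(list(
    n = length(reference),
    spearman_rho = rho$rho,
    spearman_p = rho$p,
    icc = ic$icc, icc_ci_low = ic$ci_low, icc_ci_high = ic$ci_high,
    icc_form = ic$form,
    cronbach_alpha = cronbach_alpha(tab),
    reference_mean = mean(reference), reference_sd = stats::sd(reference),
    predicted_mean = mean(predicted), predicted_sd = stats::sd(predicted)),
    class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("Method-agreement reliability (n =", x$n, "subjects)\n")
  cat(sprintf("  Spearman rho    %.3f  (p = %.3g)\n", x$spearman_rho,
              x$spearman_p))
  cat(sprintf("  ICC [%s]  %.3f  (95%% CI %.3f-%.3f)\n", x$icc_form,
              x$icc, x$icc_ci_low, x$icc_ci_high))
  cat(sprintf("  Cronbach alpha  %.3f\n", x$cronbach_alpha))
  cat(sprintf("  reference  %.2f +/- %.2f deg\n", x$reference_mean,
              x$reference_sd))
  cat(sprintf("  predicted  %.2f +/- %.2f deg\n", x$predicted_mean,
              x$predicted_sd))
  invisible(x)
}
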