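#' Intraclass correlation coefficient, two-way random effects, absolute agreement
#'
#' Computes ICC(2,1) (single measures) or ICC(2,k) (average measures)
#' from the standard two-way ANOVA decomposition with rows as targets and
#' columns as raters.
#'
#' @param a numeric vector (first rater) or an `n x k` matrix of ratings.
#' @param b numeric vector (second rater) when `a` is a vector.
#' @param form `"2,1"` (single measures, default) or `"2,k"` (average measures).
#' @return the ICC value.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(20); icc(x, x + rnorm(20, sd = 0.1))
icc <- function(a, b = NULL, form = c("2,1", "2,k")) {
  form <- match.arg(form)
  m <- if (is.null(b)) as.matrix(a) else cbind(a, b)
  if (!is.numeric(m) || any(!is.finite(m)))
    gf_stop("gf_bad_input", "ratings must be finite numeric")
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2)
    gf_stop("gf_bad_input", "need >= 3 targets and >= 2 raters")
  if (all(apply(m, 2, var) == 0))
    gf_stop("gf_undefined_icc", "zero variance in all raters: ICC undefined")
  gm <- mean(m)
  rm_ <- rowMeans(m); cm <- colMeans(m)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  sse <- sum((m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (form == "2,1") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (msc - mse) / n)
  }
}

#' Mean absolute error
#' @param reference,estimated numeric vectors of equal length.
#' @return mean of `|estimated - reference|`.
#' @export
mae <- function(reference, estimated) {
  stopifnot(length(reference) == length(estimated))
  mean(abs(estimated - reference))
}

#' Adjusted coefficient of determination
#' @param y observed values.
#' @param fitted fitted values from a linear model with `p` predictors.
#' @param p number of predictors (excluding the intercept).
#' @return adjusted R-squared.
#' @export
adjusted_r2 <- function(y, fitted, p) {
  n <- length(y)
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Qualitative interpretation bands
#'
#' Standard interpretation guidelines: ICC agreement is "poor" below
#' 0.400, "fair" to 0.599, "good" to 0.749 and "excellent" above 0.750;
#' correlation magnitude is "none" below 0.100, "small" to 0.299,
#' "medium" to 0.499 and "large" above; R-squared is "none" below 0.02,
#' "small" to 0.13, "medium" to 0.26 and "large" above.
#'
#' @param v the statistic to interpret (for `interpret_r` the absolute
#'   value is banded).
#' @return a band label.
#' @export
#' @examples
#' interpret_icc(0.978)  # "excellent"
interpret_icc <- function(v) {
  stopifnot(is.finite(v))
  if (v < 0.400) "poor" else if (v < 0.600) "fair"
  else if (v <= 0.750) "good" else "excellent"
}

#' @rdname interpret_icc
#' @export
interpret_r <- function(v) {
  stopifnot(is.finite(v))
  v <- abs(v)
  if (v < 0.100) "none" else if (v < 0.300) "small"
  else if (v <= 0.499) "medium" else "large"
}

#' @rdname interpret_icc
#' @export
interpret_r2 <- function(v) {
  stopifnot(is.finite(v))
  if (v < 0.02) "none" else if (v < 0.14) "small"
  else if (v <= 0.26) "medium" else "large"
}

#' Bland-Altman agreement analysis with confidence limits of the LoA
#'
#' Differences (`estimated - reference`) are tested for normality
#' (Kolmogorov-Smirnov); if plausible, a one-sample t-test probes fixed
#' bias and a Pearson test of differences against means probes
#' proportional bias.  The 95% limits of agreement are the mean
#' difference +/- 1.96 sigma; each limit additionally receives a
#' large-sample confidence band of half-width `1.96 * sigma * sqrt(3/n)`,
#' yielding the outer limits UULoA/LULoA (around ULoA) and ULLoA/LLLoA
#' (around LLoA).
#'
#' @param reference,estimated paired measurements (n >= 8).
#' @return an object of class `gf_ba`: a list with the bias, its t-test
#'   p-value, `sd_diff`, the six limit lines, the proportional-bias
#'   correlation/fit, the KS p-value and the residuals (differences).
#' @export
bland_altman <- function(reference, estimated) {
  stopifnot(length(reference) == length(estimated))
  n <- length(reference)
  if (n < 8) gf_stop("gf_bad_input", "Bland-Altman needs n >= 8 pairs")
  d <- estimated - reference
  m <- (estimated + reference) / 2
  s <- sd(d)
  bias <- mean(d)
  degenerate <- s < .Machine$double.eps^0.5
  if (degenerate) {
    ks_p <- NA_real_; bias_p <- NA_real_
    prop <- list(estimate = NA_real_, p.value = NA_real_)
    slope <- NA_real_; intercept <- NA_real_
  } else {
    ks_p <- suppressWarnings(ks.test(d, "pnorm", bias, s)$p.value)
    bias_p <- t.test(d)$p.value
    if (sd(m) < .Machine$double.eps^0.5) {
      prop <- list(estimate = NA_real_, p.value = NA_real_)
      slope <- NA_real_; intercept <- NA_real_
    } else {
      prop <- suppressWarnings(cor.test(m, d))
      fit <- coef(lm(d ~ m))
      slope <- unname(fit[2]); intercept <- unname(fit[1])
    }
  }
  uloa <- bias + 1.96 * s
  lloa <- bias - 1.96 * s
  hw <- 1.96 * s * sqrt(3 / n)
  structure(list(
    n = n, bias = bias, bias_p = bias_p, sd_diff = s,
    uloa = uloa, lloa = lloa,
    uuloa = uloa + hw, luloa = uloa - hw,
    ulloa = lloa + hw, llloa = lloa - hw,
    prop_r = unname(prop$estimate), prop_p = prop$p.value,
    prop_slope = slope, prop_intercept = intercept,
    ks_p = ks_p, degenerate = degenerate, residuals = d
  ), class = "gf_ba")
}

#' @export
print.gf_ba <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d)\n", x$n))
  cat(sprintf("  bias %.4g (t-test p = %.3g), sd of differences %.4g\n",
              x$bias, x$bias_p, x$sd_diff))
  cat(sprintf("  LoA  [%.4g, %.4g];  outer limits [%.4g, %.4g]\n",
              x$lloa, x$uloa, x$llloa, x$uuloa))
  if (is.finite(x$prop_r))
    cat(sprintf("  proportional bias r = %.3f (p = %.3g), d = %.4g %+.4g m\n",
                x$prop_r, x$prop_p, x$prop_intercept, x$prop_slope))
  invisible(x)
}

#' Probability-based bounds on the measurement success rate K_A
#'
#' The success rate K_A is the probability mass of the test-residual
#' distribution N(mu_T, sigma_T^2) inside the training agreement
#' interval +/- 1.96 sigma_AU, divided by the nominal inlier fraction
#' (0.95) and clipped at 1.  Because the residual-distribution
#' parameters are estimated from limited data, mu_T (t-based) and
#' sigma_A, sigma_T (chi-square-based) are replaced by confidence
#' intervals; the maximal and minimal mass over the (mu_T, sigma_T)
#' confidence rectangle give the upper and lower bounds K_AU and K_AL.
#'
#' @param train_res training residuals (model residuals, mean zero in theory).
#' @param test_res test residuals.
#' @param conf confidence level for all interval estimates and the
#'   nominal inlier fraction (default 0.95).
#' @param grid_n grid resolution per axis for the rectangle search.
#' @return an object of class `gf_ka`: list with `K_AL`, `K_AU`, the point
#'   estimate `K_A`, the agreement interval and the parameter CIs.
#' @export
ka_bounds <- function(train_res, test_res, conf = 0.95, grid_n = 201) {
  n_a <- length(train_res); n_t <- length(test_res)
  if (n_a < 3 || n_t < 3)
    gf_stop("gf_bad_input", "ka_bounds needs >= 3 residuals in each set")
  a2 <- (1 - conf) / 2
  s_a <- sd(train_res)
  sigma_a_ci <- s_a * sqrt((n_a - 1) / qchisq(c(1 - a2, a2), n_a - 1))
  mu_t <- mean(test_res); s_t <- sd(test_res)
  mu_t_ci <- mu_t + qt(c(a2, 1 - a2), n_t - 1) * s_t / sqrt(n_t)
  sigma_t_ci <- s_t * sqrt((n_t - 1) / qchisq(c(1 - a2, a2), n_t - 1))
  half <- 1.96 * sigma_a_ci[2]   # optimistic interval, +/- 1.96 sigma_AU
  mass <- function(mu, sg) pnorm((half - mu) / sg) - pnorm((-half - mu) / sg)
  mus <- seq(mu_t_ci[1], mu_t_ci[2], length.out = grid_n)
  sgs <- seq(sigma_t_ci[1], sigma_t_ci[2], length.out = grid_n)
  mm <- outer(mus, sgs, mass)
  structure(list(
    K_AL = min(min(mm) / conf, 1),
    K_AU = min(max(mm) / conf, 1),
    K_A = min(mass(mu_t, s_t) / conf, 1),
    interval = c(-half, half),
    mu_t_ci = mu_t_ci, sigma_a_ci = sigma_a_ci, sigma_t_ci = sigma_t_ci,
    conf = conf
  ), class = "gf_ka")
}

#' @export
print.gf_ka <- function(x, ...) {
  cat(sprintf("K_A success-rate bounds: %.1f%% - %.1f%% (point %.1f%%)\n",
              100 * x$K_AL, 100 * x$K_AU, 100 * x$K_A))
  cat(sprintf("  agreement interval [%.4g, %.4g] at conf %.2f\n",
              x$interval[1], x$interval[2], x$conf))
  invisible(x)
}

#' Full agreement report between reference and estimated values
#'
#' @param reference,estimated paired vectors.
#' @param p number of model predictors for the adjusted R-squared
#'   (default 1).
#' @return list with ICC(2,1), ICC(2,k), MAE, adjusted R-squared,
#'   Pearson r and their qualitative bands.
#' @export
agreement_report <- function(reference, estimated, p = 1) {
  icc21 <- icc(reference, estimated, "2,1")
  icc2k <- icc(reference, estimated, "2,k")
  r <- cor(reference, estimated)
  ar2 <- adjusted_r2(reference, estimated, p)
  list(icc21 = icc21, icc21_band = interpret_icc(icc21),
       icc2k = icc2k,
       mae = mae(reference, estimated),
       adj_r2 = ar2,
       r = r, r_band = interpret_r(r))
}
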