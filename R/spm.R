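#' Sidak-corrected significance level
#'
#' Per-test level that keeps the family-wise error at `alpha` over `m`
#' independent tests: `1 - (1 - alpha)^(1/m)`.
#'
#' @param m number of tests (here, the 9 signal channels).
#' @param alpha family-wise level in (0, 1).
#' @return corrected per-test level.
#' @export
#' @examples
#' sidak_alpha(9, 0.05)  # 0.005683...
sidak_alpha <- function(m, alpha) {
  if (m < 1) gf_stop("gf_bad_input", "m must be >= 1")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    gf_stop("gf_bad_input", "alpha must lie in (0, 1)")
  1 - (1 - alpha)^(1 / m)
}

# Smoothness (FWHM, in node units) of a residual field, estimated from the
# node-wise gradient of the normalized residuals.  `R` is an n x Q matrix
# whose rows are residual curves; fields from several channels may be
# stacked row-wise for a pooled estimate.
estimate_fwhm <- function(R) {
  R <- as.matrix(R)
  Q <- ncol(R)
  ssq <- colSums(R^2)
  G <- R[, -1, drop = FALSE] - R[, -Q, drop = FALSE]
  gsq <- colSums(G^2)
  den <- (ssq[-1] + ssq[-Q]) / 2
  ok <- den > 0
  if (!any(ok)) return(Q)  # flat residuals: treat as maximally smooth
  v <- mean(gsq[ok] / den[ok])
  fwhm <- sqrt(4 * log(2) / v)
  max(min(fwhm, 10 * Q), 1)  # clamp to [grid resolution, 10 * domain]
}

# 1D Euler-characteristic densities, i.e. the expected number of
# upcrossings of level `u` per resel.  Derived from the Rice formula for
# fields built from i.i.d. unit-variance Gaussian component fields; the
# t and chi-square forms agree with the classical results, and the
# Hotelling T2 form (p response components, nu error df) reduces to the
# two-sided t density at p = 1 and to the chi-square density as
# nu -> Inf.  For "t2", `dof` is c(p, nu).
gf_ec_density <- function(kind, u, dof) {
  switch(kind,
    t = sqrt(4 * log(2)) / (2 * pi) *
      (1 + u^2 / dof)^(-(dof - 1) / 2),
    chi2 = sqrt(4 * log(2) / pi) * u^((dof - 1) / 2) * exp(-u / 2) /
      (2^((dof - 1) / 2) * gamma(dof / 2)),
    t2 = {
      p <- dof[1]; nu <- dof[2]
      sqrt(4 * log(2) / pi) *
        exp(lgamma((nu + 1) / 2) - lgamma(p / 2) - lgamma((nu - p + 2) / 2)) *
        (u / nu)^((p - 1) / 2) * (1 + u / nu)^(-(nu - 1) / 2)
    },
    gf_stop("gf_bad_input", "unknown field kind '%s'", kind))
}

# upper-tail probability of the field's marginal distribution
gf_tail_p <- function(kind, u, dof) {
  switch(kind,
    t = pt(u, dof, lower.tail = FALSE),
    chi2 = pchisq(u, dof, lower.tail = FALSE),
    t2 = {
      p <- dof[1]; nu <- dof[2]
      stats::pf(u * (nu - p + 1) / (nu * p), p, nu - p + 1,
                lower.tail = FALSE)
    })
}

#' Random-field-theory critical threshold for a 1D statistic field
#'
#' Smallest height `u` at which the expected Euler characteristic of the
#' excursion set of a smooth 1D t- or chi-square field equals `alpha`.
#' The expected EC is `P(S > u) + resels * rho1(u)` with
#' `resels = (n_nodes - 1) / fwhm`; as `fwhm` grows the threshold falls
#' to the pointwise critical value.
#'
#' @param kind `"t"`, `"chi2"`, or `"t2"` (Hotelling T-squared, the
#'   field arising from node-wise canonical correlation of a
#'   multivariate response with a scalar target).
#' @param dof degrees of freedom of the field; for `"t2"`, `c(p, nu)`
#'   with `p` response components and `nu` error degrees of freedom.
#' @param n_nodes number of domain nodes (here 100 %GC nodes).
#' @param fwhm field smoothness in node units (clamped to >= 1).
#' @param alpha target excursion probability.  For a two-sided t test
#'   pass `alpha/2` and threshold `|t|`.
#' @return the critical threshold.
#' @export
rft_threshold <- function(kind = c("t", "chi2", "t2"), dof, n_nodes, fwhm,
                          alpha) {
  kind <- match.arg(kind)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    gf_stop("gf_bad_input", "alpha must lie in (0, 1)")
  fwhm <- max(fwhm, 1)
  resels <- (n_nodes - 1) / fwhm
  eec <- function(u) gf_tail_p(kind, u, dof) +
    resels * gf_ec_density(kind, u, dof)
  u0 <- switch(kind,  # pointwise critical value: root lies at or above it
    t = qt(alpha, dof, lower.tail = FALSE),
    chi2 = qchisq(alpha, dof, lower.tail = FALSE),
    t2 = {
      p <- dof[1]; nu <- dof[2]
      stats::qf(alpha, p, nu - p + 1, lower.tail = FALSE) * nu * p /
        (nu - p + 1)
    })
  if (eec(u0) <= alpha) return(u0)
  hi <- u0 + 1
  while (eec(hi) > alpha && hi < 1e6) hi <- hi * 2
  uniroot(function(u) eec(u) - alpha, c(u0, hi), tol = 1e-10)$root
}

#' SPM canonical-correlation curve over the gait cycle
#'
#' At each %GC node the canonical correlation between the 9-channel
#' foot-motion response vector and the scalar target (here HGS) is
#' computed -- equivalently the multiple R-squared of regressing the
#' target on the nine channels -- and converted to a chi-square-type
#' statistic via the Bartlett-Wilks transform
#' `X2 = -(N - (p + q + 3)/2) log(1 - r^2)` with `p = 9`, `q = 1`,
#' `dof = 9`.  The random-field-theory threshold at `alpha` is attached,
#' with the field smoothness estimated from the channel-wise regression
#' residuals pooled across channels.
#'
#' @param grids array `N x 9 x Q` of normalized stride grids
#'   (datasets x channels x %GC nodes), e.g. `$grids` of
#'   [process_cohort()] output.
#' @param y numeric target of length `N`.
#' @param alpha significance level (default 0.05).
#' @return object of class `gf_spm`: list with `stat` (length Q),
#'   `kind`, `dof`, `fwhm`, `threshold`, `alpha`, `n` and the logical
#'   `supra` excursion mask.
#' @export
spm_cca_curve <- function(grids, y, alpha = 0.05) {
  stopifnot(length(dim(grids)) == 3, dim(grids)[1] == length(y))
  N <- dim(grids)[1]; P <- dim(grids)[2]; Q <- dim(grids)[3]
  if (N < 20) gf_stop("gf_bad_input", "SPM-CCA needs N >= 20 datasets")
  yc <- y - mean(y)
  syy <- sum(yc^2)
  stat <- r2s <- numeric(Q)
  res <- matrix(0, N * P, Q)  # channel-wise residuals, stacked
  warned <- FALSE
  for (q in seq_len(Q)) {
    Y <- grids[, , q, drop = TRUE]
    Yc <- sweep(Y, 2, colMeans(Y))
    C <- crossprod(Yc)
    b <- crossprod(Yc, yc)
    beta <- tryCatch(solve(C, b), error = function(e) NULL)
    if (is.null(beta)) {
      if (!warned) {
        warning("rank-deficient response at one or more nodes; using pseudo-inverse")
        warned <- TRUE
      }
      sv <- svd(C)
      pos <- sv$d > max(sv$d) * 1e-10
      beta <- sv$v[, pos, drop = FALSE] %*%
        ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos])
    }
    r2 <- min(sum(b * beta) / syy, 1 - 1e-12)
    r2s[q] <- r2
    stat[q] <- -(N - (P + 1 + 3) / 2) * log(1 - r2)
    # residuals of each channel regressed on y (for smoothness estimation)
    g <- crossprod(Yc, yc) / syy
    res[, q] <- as.vector(Yc - outer(yc, as.vector(g)))
  }
  fwhm <- estimate_fwhm(res)
  # The field is a Hotelling T2 field (p channels, nu = N - 2 error df):
  # T2 = nu r^2 / (1 - r^2).  The threshold is found on that scale and
  # mapped through the monotone Bartlett transform onto the reported
  # chi-square-type statistic, whose excursion set is identical.
  nu <- N - 2
  thr_t2 <- rft_threshold("t2", c(P, nu), Q, fwhm, alpha)
  r2_crit <- (thr_t2 / nu) / (1 + thr_t2 / nu)
  thr <- -(N - (P + 1 + 3) / 2) * log(1 - r2_crit)
  structure(list(stat = stat, kind = "chi2", dof = P, fwhm = fwhm,
                 threshold = thr, threshold_t2 = thr_t2, nu = nu,
                 alpha = alpha, n = N,
                 supra = stat > thr),
            class = "gf_spm")
}

#' Post hoc per-channel SPM Pearson-correlation curves
#'
#' For each channel the node-wise Pearson correlation with the target is
#' converted to `t = r * sqrt((N - 2) / (1 - r^2))` and thresholded
#' (two-sided) at the random-field-theory critical value for the
#' Sidak-corrected level `sidak_alpha(m, alpha)`.  Statistics are
#' computed over the full domain but reported (and eligible for
#' excursions) only inside `mask` -- the significant nodes of the
#' preceding vector-field test.
#'
#' @param grids array `N x 9 x Q` as in [spm_cca_curve()].
#' @param y numeric target.
#' @param mask logical length-Q node mask (e.g. `$supra` of the CCA
#'   curve); `NULL` means all nodes.
#' @param alpha family-wise level before Sidak correction.
#' @param m number of channels for the correction (default `dim(grids)[2]`).
#' @return named list of `gf_spm` objects, one per channel.
#' @export
spm_pearson_curves <- function(grids, y, mask = NULL, alpha = 0.05, m = NULL) {
  stopifnot(length(dim(grids)) == 3, dim(grids)[1] == length(y))
  N <- dim(grids)[1]; P <- dim(grids)[2]; Q <- dim(grids)[3]
  if (is.null(m)) m <- P
  if (is.null(mask)) mask <- rep(TRUE, Q)
  stopifnot(length(mask) == Q)
  a_c <- sidak_alpha(m, alpha)
  chn <- dimnames(grids)[[2]]
  if (is.null(chn)) chn <- GF_CHANNELS[seq_len(P)]
  yc <- y - mean(y); syy <- sum(yc^2)
  out <- vector("list", P); names(out) <- chn
  for (p in seq_len(P)) {
    W <- grids[, p, , drop = TRUE]                   # N x Q
    Wc <- sweep(W, 2, colMeans(W))
    sww <- colSums(Wc^2)
    r <- as.vector(crossprod(Wc, yc)) / sqrt(pmax(sww * syy, .Machine$double.xmin))
    r[sww == 0] <- 0
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    tt <- r * sqrt((N - 2) / (1 - r^2))
    res <- Wc - outer(yc, colSums(Wc * yc) / syy)    # residuals channel ~ y
    fwhm <- estimate_fwhm(res)
    thr <- rft_threshold("t", N - 2, Q, fwhm, a_c / 2)  # two-sided
    stat <- tt; stat[!mask] <- NA_real_
    out[[p]] <- structure(list(stat = stat, kind = "t", dof = N - 2,
                               fwhm = fwhm, threshold = thr,
                               alpha = a_c, n = N,
                               supra = mask & abs(tt) > thr),
                          class = "gf_spm")
  }
  out
}

#' @export
print.gf_spm <- function(x, ...) {
  cat(sprintf("SPM %s-field curve: dof %s, FWHM %.2f, threshold %.3f (alpha %.4g)\n",
              x$kind, format(x$dof), x$fwhm, x$threshold, x$alpha))
  cat(sprintf("  %d of %d nodes supra-threshold\n", sum(x$supra), length(x$stat)))
  invisible(x)
}

#' Extract gait phase clusters (GPCs) from thresholded SPM curves
#'
#' A GPC is a maximal run of consecutive supra-threshold %GC nodes in a
#' channel's post hoc curve, reported as a closed interval.
#'
#' @param curves a single `gf_spm` object or a named list of them (one
#'   per channel, as returned by [spm_pearson_curves()]).
#' @return data.frame with columns `channel`, `t_s`, `t_e`,
#'   `peak_stat`, `threshold` (zero rows if nothing is supra-threshold).
#' @export
extract_gpcs <- function(curves) {
  if (inherits(curves, "gf_spm")) curves <- list(channel = curves)
  rows <- list()
  for (ch in names(curves)) {
    cv <- curves[[ch]]
    r <- rle(as.logical(cv$supra))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      idx <- starts[i]:ends[i]
      rows[[length(rows) + 1]] <- data.frame(
        channel = ch, t_s = starts[i], t_e = ends[i],
        peak_stat = max(abs(cv$stat[idx])), threshold = cv$threshold,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(channel = character(), t_s = integer(),
                      t_e = integer(), peak_stat = numeric(),
                      threshold = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Quadriceps-activation %GC windows
#'
#' The fixed filter windows `{1-16, 48-70, 92-100}` %GC in which the
#' quadriceps are mostly active during gait; GPCs are intersected with
#' these windows before predictors are formed.
#'
#' @return data.frame with columns `t_s`, `t_e`.
#' @export
qt_windows <- function() {
  data.frame(t_s = c(1L, 48L, 92L), t_e = c(16L, 70L, 100L))
}

#' Intersect GPCs with the quadriceps-activation windows
#'
#' Each GPC is intersected with each window; empty intersections are
#' dropped and a GPC spanning two windows yields two rows.
#'
#' @param gpcs data.frame from [extract_gpcs()].
#' @param qt data.frame of windows (default [qt_windows()]).
#' @return filtered GPC data.frame.
#' @export
#' @examples
#' g <- data.frame(channel = "Ay", t_s = 60, t_e = 95)
#' intersect_qt(g)  # [60, 70] and [92, 95]
intersect_qt <- function(gpcs, qt = qt_windows()) {
  rows <- list()
  for (i in seq_len(nrow(gpcs))) {
    for (j in seq_len(nrow(qt))) {
      ts <- max(gpcs$t_s[i], qt$t_s[j])
      te <- min(gpcs$t_e[i], qt$t_e[j])
      if (ts <= te) {
        r <- gpcs[i, , drop = FALSE]
        r$t_s <- ts; r$t_e <- te
        rows[[length(rows) + 1]] <- r
      }
    }
  }
  if (!length(rows)) return(gpcs[0, , drop = FALSE])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Integral-average IMS predictor over a GPC
#'
#' Trapezoidal average of a channel's normalized waveform over the
#' closed %GC interval `[t_s, t_e]` with unit node step; a single-node
#' interval returns the node value itself.
#'
#' @param stride a 9 x 100 normalized stride grid (rows named by
#'   channel) or a `gf_stride` object.
#' @param channel channel name, one of `Ax..Ez`.
#' @param t_s,t_e integer %GC bounds, `1 <= t_s <= t_e <= 100`.
#' @return the scalar predictor value.
#' @export
ims_predictor_value <- function(stride, channel, t_s, t_e) {
  grid <- if (is.list(stride) && !is.null(stride$grid)) stride$grid else stride
  if (!channel %in% rownames(grid))
    gf_stop("gf_bad_input", "unknown channel '%s'", channel)
  Q <- ncol(grid)
  if (t_s < 1 || t_e > Q || t_s > t_e)
    gf_stop("gf_bad_input", "interval [%d, %d] outside 1..%d", t_s, t_e, Q)
  w <- grid[channel, ]
  if (t_e == t_s) return(unname(w[t_e]))
  idx <- t_s:t_e
  unname(sum((w[idx[-length(idx)]] + w[idx[-1]]) / 2) / (t_e - t_s))
}

# Permutation-based FWER threshold: max-statistic null distribution under
# random relabeling of y.  Used in tests as an independent oracle for
# rft_threshold, never on the default analysis path.
perm_fwer_threshold <- function(grids, y, alpha = 0.05, n_perm = 500,
                                kind = c("chi2", "t"), channel = 1) {
  kind <- match.arg(kind)
  N <- dim(grids)[1]
  mx <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    yp <- sample(y)
    if (kind == "chi2") {
      cv <- spm_cca_curve(grids, yp, alpha = alpha)
      mx[b] <- max(cv$stat)
    } else {
      W <- grids[, channel, , drop = TRUE]
      ypc <- yp - mean(yp)
      Wc <- sweep(W, 2, colMeans(W))
      r <- as.vector(crossprod(Wc, ypc)) /
        sqrt(colSums(Wc^2) * sum(ypc^2))
      r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
      mx[b] <- max(abs(r * sqrt((N - 2) / (1 - r^2))))
    }
  }
  unname(quantile(mx, 1 - alpha, type = 8))
}
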