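# Independent oracles and fixture builders shared across test files.
# Oracles deliberately avoid the code paths they check.

# Brute-force LASSO oracle: enumerate all 3^C sign patterns, solve the
# stationarity system for each, keep the one whose KKT conditions hold.
# Objective: (1/2N) sum (y - b0 - x'b)^2 + lambda * ||b||_1.
lasso_oracle <- function(X, y, lambda, tol = 1e-8) {
  X <- as.matrix(X); N <- nrow(X); C <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  G <- crossprod(Xc) / N
  g <- crossprod(Xc, yc) / N
  signs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), C)))
  for (i in seq_len(nrow(signs))) {
    s <- signs[i, ]
    A <- which(s != 0)
    b <- numeric(C)
    if (length(A)) {
      bA <- try(solve(G[A, A, drop = FALSE],
                      g[A] - lambda * s[A]), silent = TRUE)
      if (inherits(bA, "try-error")) next
      b[A] <- bA
      if (any(sign(b[A]) != s[A])) next
    }
    grad <- g - G %*% b
    if (length(A) && any(abs(grad[A] - lambda * s[A]) > tol)) next
    inA <- setdiff(seq_len(C), A)
    if (length(inA) && any(abs(grad[inA]) > lambda + tol)) next
    return(list(beta = b, beta0 = ym - sum(b * xm)))
  }
  stop("lasso oracle found no KKT point")
}

# Dense numeric-integration oracle for the K_A bounds: Riemann-integrate
# the normal density over the agreement interval for every (mu, sigma)
# on a fine grid over the confidence rectangle.
ka_oracle <- function(train_res, test_res, conf = 0.95, grid_n = 101,
                      int_n = 20001) {
  a2 <- (1 - conf) / 2
  n_a <- length(train_res); n_t <- length(test_res)
  s_a <- sd(train_res)
  sigma_au <- s_a * sqrt((n_a - 1) / qchisq(a2, n_a - 1))
  mu_t <- mean(test_res); s_t <- sd(test_res)
  mu_ci <- mu_t + qt(c(a2, 1 - a2), n_t - 1) * s_t / sqrt(n_t)
  sg_ci <- s_t * sqrt((n_t - 1) / qchisq(c(1 - a2, a2), n_t - 1))
  half <- 1.96 * sigma_au
  xs <- seq(-half, half, length.out = int_n)
  dx <- xs[2] - xs[1]
  mass <- function(mu, sg) {
    d <- exp(-(xs - mu)^2 / (2 * sg^2)) / (sqrt(2 * pi) * sg)
    (sum(d) - (d[1] + d[int_n]) / 2) * dx
  }
  vals <- outer(seq(mu_ci[1], mu_ci[2], length.out = grid_n),
                seq(sg_ci[1], sg_ci[2], length.out = grid_n), Vectorize(mass))
  list(K_AL = min(min(vals) / conf, 1), K_AU = min(max(vals) / conf, 1))
}

# ICC oracle from aov() mean squares (two-way, absolute agreement).
icc_oracle <- function(m, form = "2,1") {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(v = as.vector(m),
                  row = factor(rep(seq_len(n), k)),
                  col = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(v ~ row + col, data = d))[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  if (form == "2,1")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (msc - mse) / n)
}

# Smooth Gaussian null fields: N datasets x P channels x Q nodes with
# known FWHM (Gaussian-kernel-filtered white noise, unit variance).
smooth_null_grids <- function(N, P = 9, Q = 100, fwhm = 10) {
  sd_k <- fwhm / sqrt(8 * log(2))
  ker <- dnorm(seq(-25, 25), 0, sd_k)
  ker <- ker / sqrt(sum(ker^2))
  a <- array(0, c(N, P, Q))
  for (i in seq_len(N)) for (p in seq_len(P)) {
    w <- rnorm(Q + 50)
    s <- as.numeric(stats::filter(w, ker, sides = 2, circular = TRUE))
    a[i, p, ] <- s[26:(Q + 25)]
  }
  dimnames(a) <- list(NULL, paste0("C", seq_len(P)), NULL)
  a
}

# Predictor-level synthetic table: U subjects x n_trials rows, planted
# linear dependence of y on the first `planted` predictors (subject-level
# signal), remaining predictors noise.  Effect sizes are in SD-of-y per
# SD-of-x units.
predictor_table_fixture <- function(U = 35, n_trials = 4, n_pred = 20,
                                    planted = 3, effect = 1.2,
                                    noise_sd = 0.5) {
  n <- U * n_trials
  subj <- rep(sprintf("S%03d", seq_len(U)), each = n_trials)
  subj_level <- matrix(rnorm(U * n_pred), U, n_pred)
  X <- subj_level[rep(seq_len(U), each = n_trials), ] +
    matrix(rnorm(n * n_pred, sd = 0.2), n, n_pred)
  colnames(X) <- sprintf("x%02d", seq_len(n_pred))
  y_subj <- as.vector(subj_level[, seq_len(planted), drop = FALSE] %*%
                        rep(effect, planted)) + rnorm(U, sd = noise_sd)
  d <- data.frame(subject = subj, y = y_subj[rep(seq_len(U),
                                                 each = n_trials)],
                  X, stringsAsFactors = FALSE)
  d
}

# Small noise-free single-window cohort used by several contracts.
noise_free_spec <- function(n_subjects = 10, channel = "Gz",
                            t_s = 12L, t_e = 16L, effect = 5,
                            seed = 99, n_trials = 2) {
  cohort_spec(n_subjects, "male", n_trials = n_trials, seed = seed,
              planted_windows = list(list(channel = channel,
                                          t_s = t_s, t_e = t_e)),
              effect_sizes = effect, noise_sd = rep(0, 9),
              gs_dist = c(1.29, 0), strides_per_trial = 10,
              duration_dist = c(1.05, 0), stride_jitter_sd = 0)
}
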