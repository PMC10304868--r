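test_that("lasso_fit recovers OLS at lambda 0 and the null model at lambda_max", {
  set.seed(60)
  X <- matrix(rnorm(40 * 4), 40, 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  y <- X %*% c(1, -2, 0, 0.5) + rnorm(40, sd = 0.3)
  f0 <- lasso_fit(X, y, 0)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(f0$beta), unname(ols[-1]), tolerance = 1e-8)
  expect_equal(f0$beta0, unname(ols[1]), tolerance = 1e-8)
  # lambda above the zero-support bound kills every coefficient
  st <- gaitfrail:::gf_standardize(X)
  lmax <- max(abs(crossprod(st$X, y - mean(y)))) / nrow(X)
  f1 <- lasso_fit(X, y, lmax * 1.01)
  expect_equal(unname(f1$beta), rep(0, 4))
  expect_equal(f1$beta0, mean(y), tolerance = 1e-8)
  expect_error(lasso_fit(X, y, -1), class = "gf_bad_input")
})

test_that("lasso_fit matches the sign-enumeration oracle", {
  set.seed(61)
  for (i in 1:20) {
    X <- matrix(rnorm(30 * 5), 30, 5)
    X <- scale(X)  # oracle and fit share the same (standardized) problem
    y <- as.vector(X %*% runif(5, -2, 2)) + rnorm(30)
    st <- gaitfrail:::gf_standardize(X)
    lmax <- max(abs(crossprod(st$X, y - mean(y)))) / 30
    lam <- runif(1, 0.05, 0.8) * lmax
    fit <- lasso_fit(X, y, lam, standardize = FALSE)
    oracle <- lasso_oracle(X, y, lam)
    expect_equal(unname(fit$beta), unname(oracle$beta), tolerance = 1e-4)
    expect_equal(fit$beta0, oracle$beta0, tolerance = 1e-4)
  }
})

test_that("lasso_fit back-transforms standardized coefficients correctly", {
  set.seed(62)
  X <- matrix(rnorm(50 * 3), 50, 3) %*% diag(c(1, 10, 100))
  y <- rnorm(50)
  f <- lasso_fit(X, y, 0.01)
  # the fitted values must be invariant to the internal standardization
  fs <- lasso_fit(scale(X), y, 0.01, standardize = FALSE)
  expect_equal(as.vector(X %*% f$beta + f$beta0),
               as.vector(scale(X) %*% fs$beta + fs$beta0),
               tolerance = 1e-6)
})

test_that("make_lambda_path is a length-100 geometric sequence", {
  set.seed(63)
  X <- matrix(rnorm(60 * 8), 60, 8)
  y <- rnorm(60)
  lam <- make_lambda_path(X, y)
  expect_length(lam, 100)
  expect_true(all(diff(lam) < 0))
  ratios <- lam[-1] / lam[-100]
  expect_equal(max(ratios) - min(ratios), 0, tolerance = 1e-10)
  expect_equal(lam[100] / lam[1], 1e-4, tolerance = 1e-10)
  # lambda_1 zeroes all coefficients
  f <- lasso_fit(X, y, lam[1])
  expect_equal(unname(f$beta), rep(0, 8))
  # selected-support size is non-increasing in lambda on this fixture
  supp <- gaitfrail:::gf_lasso_path_support(X, y, lam)
  expect_true(all(diff(colSums(supp)) >= 0))  # lam decreasing along path
  expect_error(make_lambda_path(matrix(1, 10, 2), rnorm(10)),
               class = "gf_config_error")
})

test_that("loso_lasso reproduces the printed thresholds and finds a dominant predictor", {
  set.seed(64)
  for (U in c(27, 35)) {
    d <- predictor_table_fixture(U = U, n_trials = 2, n_pred = 5,
                                 planted = 1, effect = 2, noise_sd = 0.01)
    lab <- loso_lasso(d, predictors = paste0("x0", 1:5))
    expect_equal(lab$threshold, if (U == 27) 25 else 33)
    expect_equal(lab$U, U)
    expect_true(all(lab$B0 >= 0 & lab$B0 <= U))
    expect_identical(lab$B, (lab$B0 >= lab$threshold) * 1L)
    # the dominant (planted, near-noise-free) predictor reaches B
    expect_gt(sum(lab$B["x01", ]), 0)
  }
  d <- predictor_table_fixture(U = 8)
  expect_error(loso_lasso(d, predictors = "x01"), class = "gf_bad_input")
  d <- predictor_table_fixture(U = 12)
  d <- d[-1, ]  # subject with missing rows
  expect_error(loso_lasso(d, predictors = "x01"), class = "gf_bad_input")
})

test_that("select_optimal_model recovers planted supports with high ICC", {
  set.seed(65)
  d <- predictor_table_fixture(U = 35, n_trials = 4, n_pred = 20,
                               planted = 3, effect = 1.5, noise_sd = 0.3)
  lab <- loso_lasso(d, predictors = sprintf("x%02d", 1:20))
  m <- select_optimal_model(d, lab)
  expect_true(all(sprintf("x%02d", 1:3) %in% m$predictors))
  expect_gt(m$icc, 0.95)
  expect_equal(m$icc_band, "excellent")
  # reported coefficients are refit on all rows
  refit <- coef(lm(reformulate(m$predictors, "y"), data = d))
  expect_equal(unname(m$coefficients), unname(refit[-1]), tolerance = 1e-8)
  expect_equal(m$intercept, unname(refit[1]), tolerance = 1e-8)
  # predictions work on new data and complain about missing columns
  p <- predict(m, d)
  expect_length(p, nrow(d))
  expect_error(predict(m, d[, 1:3]), class = "gf_predictor_mismatch")
})

test_that("pure-noise predictors give a poor model on average", {
  # Selecting the max-ICC candidate induces a winner's-curse lift above
  # zero even with honest LOSOCV (chance subject-level correlations
  # survive fold removal), so the null is tested on replicate cohorts:
  # the mean selected ICC must sit well inside the "poor" band.
  set.seed(66)
  iccs <- replicate(5, {
    d <- predictor_table_fixture(U = 35, n_trials = 4, n_pred = 15,
                                 planted = 0, effect = 0, noise_sd = 1)
    d$y <- rnorm(35)[match(d$subject, unique(d$subject))]
    lab <- loso_lasso(d, predictors = sprintf("x%02d", 1:15))
    m <- tryCatch(select_optimal_model(d, lab),
                  gf_no_model = function(e) NULL)
    if (is.null(m)) 0 else m$icc
  })
  expect_lt(mean(iccs), 0.4)
  expect_equal(interpret_icc(mean(iccs)), "poor")
})

test_that("LOSOCV predictions never use the held-out subject", {
  set.seed(67)
  d <- predictor_table_fixture(U = 12, n_trials = 3, n_pred = 5,
                               planted = 2, effect = 1)
  X <- as.matrix(d[, sprintf("x%02d", 1:5)])
  pred <- gaitfrail:::gf_losocv_predict(X, d$y, d$subject, 1:5)
  u <- d$subject == "S001"
  y2 <- d$y
  y2[u] <- y2[u] + 100  # poison the held-out subject's target
  pred2 <- gaitfrail:::gf_losocv_predict(X, y2, d$subject, 1:5)
  expect_equal(pred[u], pred2[u])          # unchanged where held out
  expect_false(isTRUE(all.equal(pred[!u], pred2[!u])))
})

test_that("duplicate label columns share one evaluation consistently", {
  set.seed(68)
  d <- predictor_table_fixture(U = 12, n_trials = 2, n_pred = 4,
                               planted = 1, effect = 2)
  lab <- loso_lasso(d, predictors = sprintf("x%02d", 1:4))
  m <- select_optimal_model(d, lab)
  # candidates are unique supports; every lambda column maps onto one
  expect_lte(nrow(m$candidates), ncol(lab$B))
  expect_false(any(duplicated(m$candidates$lambda_index)))
})

test_that("comparison pools obey their definitions and expected ordering", {
  set.seed(69)
  # signal lives only in the IMS predictors; GPs and IPAs are noise
  U <- 20; n <- U * 4
  subj <- rep(sprintf("S%03d", 1:U), each = 4)
  base <- data.frame(subject = subj, sex = "male", stringsAsFactors = FALSE)
  for (g in sprintf("gp%02d", 1:20)) base[[g]] <- rnorm(n)
  for (ipa in c("age", "height", "weight", "bmi"))
    base[[ipa]] <- rnorm(U)[match(subj, unique(subj))]
  sig <- rnorm(U)
  base$y <- 30 + 5 * sig[match(subj, unique(subj))] + rnorm(n, sd = 0.2)
  base$IMS_Gz_12_16 <- sig[match(subj, unique(subj))] +
    rnorm(n, sd = 0.05)
  base$IMS_Ax_97_98 <- rnorm(n)
  pools <- list(M1 = "gp02",
                M2 = sprintf("gp%02d", 1:20),
                M3 = c(sprintf("gp%02d", 1:20), "age", "height", "weight",
                       "bmi"),
                Mo = c(sprintf("gp%02d", 1:20), "age", "height", "weight",
                       "bmi", "IMS_Gz_12_16", "IMS_Ax_97_98"))
  expect_length(pools$M3, 24)
  cm <- comparison_models(base, pools)
  expect_lte(length(cm$models$M1$predictors), 1)
  expect_gt(cm$summary$icc[cm$summary$pool == "Mo"],
            cm$summary$icc[cm$summary$pool == "M3"])
  expect_gt(cm$summary$icc[cm$summary$pool == "Mo"],
            cm$summary$icc[cm$summary$pool == "M1"])
})
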