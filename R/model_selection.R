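# ---- predictor table --------------------------------------------------------

#' Assemble the predictor table for model selection
#'
#' One row per trial-average dataset; predictor columns are the four
#' individual physical attributes (age, height, weight, BMI), the 20
#' gait parameters, and one integral-average IMS predictor per GPC
#' (named `IMS_<channel>_<t_s>_<t_e>`).  The target `y` is the
#' reference grip strength.  Pool definitions for the comparison models
#' (`M1` gait speed only, `M2` all GPs, `M3` GPs + IPAs, `Mo`
#' everything) are attached as the `"pools"` attribute.
#'
#' @param tavg a `gf_trial_averages` from [process_cohort()].
#' @param gpcs data.frame of GPC intervals (`channel`, `t_s`, `t_e`),
#'   e.g. from [intersect_qt()]; may have zero rows.
#' @return object of class `gf_predictor_table` (a data.frame).
#' @export
build_predictor_table <- function(tavg, gpcs) {
  stopifnot(inherits(tavg, "gf_trial_averages"))
  ipa <- data.frame(age = tavg$meta$age, height = tavg$meta$height_cm,
                    weight = tavg$meta$weight_kg, bmi = tavg$meta$bmi)
  out <- cbind(data.frame(subject = tavg$meta$subject,
                          sex = tavg$meta$sex,
                          y = tavg$meta$hgs_kg,
                          stringsAsFactors = FALSE),
               ipa, tavg$gps)
  ims_names <- character()
  if (!is.null(gpcs) && nrow(gpcs)) {
    for (i in seq_len(nrow(gpcs))) {
      nm <- sprintf("IMS_%s_%d_%d", gpcs$channel[i], gpcs$t_s[i], gpcs$t_e[i])
      vals <- vapply(seq_len(nrow(tavg$meta)), function(r)
        ims_predictor_value(tavg$grids[r, , ], gpcs$channel[i],
                            gpcs$t_s[i], gpcs$t_e[i]), 0)
      out[[nm]] <- vals
      ims_names <- c(ims_names, nm)
    }
  }
  if (any(!is.finite(as.matrix(out[, -(1:2)]))))
    gf_stop("gf_bad_input", "predictor table contains non-finite values")
  gp_names <- sprintf("gp%02d", 1:20)
  attr(out, "pools") <- list(
    M1 = "gp02",
    M2 = gp_names,
    M3 = c(gp_names, names(ipa)),
    Mo = c(gp_names, names(ipa), ims_names))
  attr(out, "ims") <- if (nrow(gpcs)) gpcs[, c("channel", "t_s", "t_e")] else
    gpcs
  class(out) <- c("gf_predictor_table", "data.frame")
  out
}

# standardize columns to zero mean / unit SD; constant columns get SD 1
gf_standardize <- function(X) {
  mu <- colMeans(X)
  sg <- apply(X, 2, sd)
  sg[sg == 0] <- 1
  list(X = sweep(sweep(X, 2, mu), 2, sg, "/"), mu = mu, sd = sg)
}

# ---- LASSO ------------------------------------------------------------------

#' LASSO fit at a single regularization value
#'
#' Minimizes `(1/2N) sum (y_k - b0 - x_k' b)^2 + lambda * ||b||_1`.
#' Predictors are standardized internally (the penalty is
#' scale-sensitive and the candidate predictors mix units) and the
#' coefficients are transformed back to the original scale;
#' `standardize = FALSE` fits on the columns as given.  `lambda = 0`
#' falls back to ordinary least squares.
#'
#' @param X numeric matrix (N x C).
#' @param y numeric response.
#' @param lambda non-negative penalty.
#' @param standardize standardize columns before penalizing.
#' @return list with `beta` (length C, original scale) and `beta0`.
#' @export
lasso_fit <- function(X, y, lambda, standardize = TRUE) {
  X <- as.matrix(X)
  if (any(!is.finite(X)) || any(!is.finite(y)) || !is.finite(lambda) ||
      lambda < 0)
    gf_stop("gf_bad_input", "non-finite inputs to lasso_fit")
  N <- nrow(X)
  st <- if (standardize) gf_standardize(X) else
    list(X = X, mu = rep(0, ncol(X)), sd = rep(1, ncol(X)))
  if (lambda == 0) {
    fit <- lm.fit(cbind(1, st$X), y)
    b <- fit$coefficients[-1]; b[is.na(b)] <- 0
    b0 <- fit$coefficients[1]
  } else if (ncol(st$X) == 1) {
    # single predictor: soft-threshold closed form
    x <- st$X[, 1]; xc <- x - mean(x)
    z <- sum(xc * (y - mean(y))) / N
    d <- sum(xc^2) / N
    b <- sign(z) * max(abs(z) - lambda, 0) / d
    b0 <- mean(y) - b * mean(x)
  } else {
    lmax <- max(abs(crossprod(st$X, y - mean(y)))) / N
    lams <- if (lambda >= lmax) lambda else
      exp(seq(log(lmax), log(lambda), length.out = 30))
    g <- glmnet::glmnet(st$X, y, lambda = lams, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-12, maxit = 1e6)
    cf <- coef(g, s = lambda, exact = FALSE)
    b <- as.numeric(cf)[-1]
    b0 <- as.numeric(cf)[1]
  }
  beta <- b / st$sd
  list(beta = setNames(beta, colnames(X)),
       beta0 = unname(b0 - sum(beta * st$mu)))
}

#' Geometric regularization path for LOSO-LASSO
#'
#' 100 lambda values in geometric progression from the smallest value
#' that zeroes every coefficient on the full data down to `ratio` times
#' it.
#'
#' @param X predictor matrix (standardized internally for the bound).
#' @param y response.
#' @param length path length (default 100).
#' @param ratio dynamic range `lambda_min / lambda_max` (default 1e-4).
#' @return decreasing numeric vector of length `length`.
#' @export
make_lambda_path <- function(X, y, length = 100, ratio = 1e-4) {
  X <- as.matrix(X)
  if (all(apply(X, 2, sd) == 0))
    gf_stop("gf_config_error", "all predictors are constant")
  st <- gf_standardize(X)
  lmax <- max(abs(crossprod(st$X, y - mean(y)))) / nrow(X)
  exp(seq(log(lmax), log(lmax * ratio), length.out = length))
}

# Support matrix (C x n_lambda) of a LASSO path fit on standardized data.
gf_lasso_path_support <- function(X, y, lambda) {
  st <- gf_standardize(X)
  if (ncol(X) == 1) {
    xc <- st$X[, 1] - mean(st$X[, 1])
    z <- abs(sum(xc * (y - mean(y)))) / nrow(X)
    return(matrix(as.integer(z > lambda), 1, length(lambda),
                  dimnames = list(colnames(X), NULL)))
  }
  g <- glmnet::glmnet(st$X, y, lambda = lambda, standardize = FALSE,
                      intercept = TRUE, thresh = 1e-9, maxit = 1e6)
  b <- as.matrix(g$beta)
  # glmnet may drop trailing path entries on early convergence; pad
  if (ncol(b) < length(lambda)) {
    pad <- matrix(b[, ncol(b)], nrow(b), length(lambda) - ncol(b))
    b <- cbind(b, pad)
  }
  (b != 0) * 1L
}

#' Leave-one-subject-out LASSO label matrices
#'
#' For each left-out subject `u`, the LASSO path over the common
#' 100-value lambda sequence is fit on the remaining subjects' rows and
#' the nonzero pattern of the coefficient matrix is recorded as the
#' binary label matrix `B_u` (C predictors x 100 lambdas).  Summing
#' over `u` gives the counter `B_0`; entries reaching the threshold
#' `floor(0.95 U)` (25 of 27 subjects, 33 of 35) are kept in the final
#' binary label matrix `B`.
#'
#' @param table a `gf_predictor_table` (or data.frame with `subject`,
#'   `y` and predictor columns).
#' @param predictors character vector of predictor columns to use
#'   (default: the `Mo` pool).
#' @param lambda optional pre-computed lambda path.
#' @return object of class `gf_label_matrix`: list with `B` , `B0`,
#'   `B_u` (C x 100 x U array), `threshold`, `U`, `lambda`,
#'   `predictors`.
#' @export
loso_lasso <- function(table, predictors = NULL, lambda = NULL) {
  if (is.null(predictors)) predictors <- attr(table, "pools")$Mo
  subj <- table$subject
  ids <- unique(subj)
  U <- length(ids)
  if (U < 10) gf_stop("gf_bad_input", "LOSO-LASSO needs >= 10 subjects")
  counts <- table(subj)
  if (length(unique(counts)) != 1)
    gf_stop("gf_bad_input",
            "every subject must contribute the same number of rows")
  X <- as.matrix(table[, predictors, drop = FALSE])
  y <- table$y
  if (is.null(lambda)) lambda <- make_lambda_path(X, y)
  C <- ncol(X)
  B_u <- array(0L, c(C, length(lambda), U),
               dimnames = list(predictors, NULL, ids))
  for (u in seq_len(U)) {
    keep <- subj != ids[u]
    B_u[, , u] <- gf_lasso_path_support(X[keep, , drop = FALSE], y[keep],
                                        lambda)
  }
  B0 <- apply(B_u, c(1, 2), sum)
  thr <- floor(0.95 * U)
  structure(list(B = (B0 >= thr) * 1L, B0 = B0, B_u = B_u,
                 threshold = thr, U = U, lambda = lambda,
                 predictors = predictors),
            class = "gf_label_matrix")
}

#' @export
print.gf_label_matrix <- function(x, ...) {
  cat(sprintf("LOSO-LASSO label matrix: %d predictors x %d lambdas, U = %d, threshold %d\n",
              nrow(x$B), ncol(x$B), x$U, x$threshold))
  cat(sprintf("  stable predictors (selected at some lambda): %d\n",
              sum(rowSums(x$B) > 0)))
  invisible(x)
}

# LOSOCV predictions of an OLS model with the given predictor subset.
gf_losocv_predict <- function(X, y, subj, cols) {
  pred <- numeric(length(y))
  for (id in unique(subj)) {
    hold <- subj == id
    fit <- lm.fit(cbind(1, X[!hold, cols, drop = FALSE]), y[!hold])
    cf <- fit$coefficients; cf[is.na(cf)] <- 0
    pred[hold] <- cbind(1, X[hold, cols, drop = FALSE]) %*% cf
  }
  pred
}

#' Evaluate the 100 candidate models and select the optimal one
#'
#' Each lambda column of the final label matrix defines a candidate
#' predictor subset; duplicated subsets are evaluated once and shared.
#' For every subset an ordinary multivariate linear regression is
#' evaluated by leave-one-subject-out cross-validation and scored by the
#' ICC(2,1) between cross-validated predictions and the reference
#' values; the subset with the highest ICC wins (ties: fewer predictors,
#' then smaller lambda index).  The reported coefficients are refit on
#' all rows.
#'
#' @param table a `gf_predictor_table`.
#' @param labels a `gf_label_matrix` from [loso_lasso()].
#' @return object of class `gf_model`: list with `predictors`,
#'   `coefficients`, `intercept`, `icc`, `icc_band`, `mae`, `adj_r2`,
#'   `lambda_index`, `lambda`, `cv_pred`, `y`, `candidates`
#'   (per-unique-subset summary) and the IMS predictor definitions
#'   carried over from the table.
#' @export
select_optimal_model <- function(table, labels) {
  stopifnot(inherits(labels, "gf_label_matrix"))
  X <- as.matrix(table[, labels$predictors, drop = FALSE])
  y <- table$y
  subj <- table$subject
  nl <- ncol(labels$B)
  keys <- apply(labels$B, 2, paste, collapse = "")
  first_idx <- match(unique(keys), keys)
  cand <- list()
  for (i in first_idx) {
    cols <- which(labels$B[, i] == 1)
    if (!length(cols)) next
    pred <- gf_losocv_predict(X, y, subj, cols)
    full <- lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
    cf <- full$coefficients; cf[is.na(cf)] <- 0
    cand[[keys[i]]] <- list(
      lambda_index = i, cols = cols, cv_pred = pred,
      icc = icc(y, pred, "2,1"), mae = mae(y, pred),
      adj_r2 = adjusted_r2(y, cbind(1, X[, cols, drop = FALSE]) %*% cf,
                           length(cols)),
      coefficients = cf)
  }
  if (!length(cand))
    gf_stop("gf_no_model", "no lambda column selects any predictor")
  iccs <- vapply(cand, `[[`, 0, "icc")
  sizes <- vapply(cand, function(c) length(c$cols), 0L)
  idxs <- vapply(cand, `[[`, 0L, "lambda_index")
  best <- order(-iccs, sizes, idxs)[1]
  b <- cand[[best]]
  structure(list(
    predictors = labels$predictors[b$cols],
    coefficients = setNames(b$coefficients[-1], labels$predictors[b$cols]),
    intercept = unname(b$coefficients[1]),
    icc = b$icc, icc_band = interpret_icc(b$icc),
    mae = b$mae, adj_r2 = b$adj_r2,
    lambda_index = b$lambda_index, lambda = labels$lambda[b$lambda_index],
    cv_pred = b$cv_pred, y = y,
    candidates = data.frame(
      lambda_index = idxs, n_predictors = sizes, icc = iccs,
      mae = vapply(cand, `[[`, 0, "mae"),
      adj_r2 = vapply(cand, `[[`, 0, "adj_r2"), row.names = NULL),
    ims = attr(table, "ims")
  ), class = "gf_model")
}

#' @export
print.gf_model <- function(x, ...) {
  cat(sprintf("Optimal HGS model: %d predictors, LOSOCV ICC(2,1) = %.3f (%s)\n",
              length(x$predictors), x$icc, x$icc_band))
  cat(sprintf("  MAE %.2f kg, adjusted R^2 %.3f, lambda index %d\n",
              x$mae, x$adj_r2, x$lambda_index))
  cat("  predictors:", paste(x$predictors, collapse = ", "), "\n")
  invisible(x)
}

#' Predict grip strength for new data
#' @param object a `gf_model`.
#' @param newdata data.frame containing the model's predictor columns.
#' @param ... unused.
#' @export
predict.gf_model <- function(object, newdata, ...) {
  miss <- setdiff(object$predictors, names(newdata))
  if (length(miss))
    gf_stop("gf_predictor_mismatch", "missing predictors: %s",
            paste(miss, collapse = ", "))
  Xn <- as.matrix(newdata[, object$predictors, drop = FALSE])
  as.vector(object$intercept + Xn %*% object$coefficients)
}

#' Fit and compare the standard predictor pools
#'
#' Runs the identical LOSO-LASSO + ICC selection on each comparison
#' pool: `M1` (gait speed only), `M2` (all gait parameters), `M3` (GPs
#' plus physical attributes) and `Mo` (everything including IMS
#' predictors).
#'
#' @param table a `gf_predictor_table`.
#' @param pools named list of predictor pools (default: the table's
#'   `"pools"` attribute).
#' @return list with `models` (one `gf_model` per pool) and `summary`
#'   (data.frame of ICC / MAE / adjusted R-squared per pool).
#' @export
comparison_models <- function(table, pools = NULL) {
  if (is.null(pools)) pools <- attr(table, "pools")
  models <- lapply(pools, function(p) {
    lab <- loso_lasso(table, predictors = p)
    select_optimal_model(table, lab)
  })
  summary <- data.frame(
    pool = names(models),
    n_predictors = vapply(models, function(m) length(m$predictors), 0L),
    icc = vapply(models, `[[`, 0, "icc"),
    icc_band = vapply(models, `[[`, "", "icc_band"),
    mae = vapply(models, `[[`, 0, "mae"),
    adj_r2 = vapply(models, `[[`, 0, "adj_r2"),
    row.names = NULL)
  list(models = models, summary = summary)
}
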