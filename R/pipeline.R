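# ---- configuration ----------------------------------------------------------

#' Default run configuration for the full study replica
#'
#' A nested list describing the construction cohort (the model-building
#' group), the test cohort (agreement testing), the frailty-evaluation
#' cohort, SPM/LASSO settings, the synthetic expert-rater model, and
#' per-stage seeds split deterministically from one master seed.  The
#' default construction cohort mirrors the model-building group of the
#' motivating study design: 27 male subjects, 4 trials each (108
#' datasets), with three planted waveform windows inside the
#' quadriceps-activation filter.
#'
#' @param seed master seed; all per-stage seeds are derived from it.
#' @param sex cohort sex.
#' @param n_construction,n_test,n_frailty subject counts per cohort.
#' @param effect_scale multiplies the default planted effect sizes
#'   (`0` gives a null world with no HGS-waveform dependence).
#' @param alpha SPM significance level.
#' @return a named list (class `gf_config`).
#' @export
default_config <- function(seed = 1, sex = "male",
                           n_construction = 27, n_test = 12,
                           n_frailty = 12, effect_scale = 1,
                           alpha = 0.05) {
  set.seed(seed)
  stage_seeds <- sample.int(2^31 - 10, 4)
  planted <- list(list(channel = "Ax", t_s = 97L, t_e = 98L),
                  list(channel = "Ay", t_s = 59L, t_e = 61L),
                  list(channel = "Gz", t_s = 12L, t_e = 16L))
  effects <- c(0.05, 0.10, 6) * effect_scale
  structure(list(
    sex = sex, alpha = alpha,
    seeds = list(construction = stage_seeds[1], test = stage_seeds[2],
                 frailty = stage_seeds[3], rater = stage_seeds[4]),
    planted_windows = planted, effect_sizes = effects,
    n_construction = n_construction, n_test = n_test,
    n_frailty = n_frailty,
    rater = list(n_raters = 6, noise_sd = 10, bias_sd = 5),
    norms = population_norms()
  ), class = "gf_config")
}

gf_spec_from_config <- function(config, n, seed) {
  cohort_spec(n, config$sex, seed = seed,
              planted_windows = config$planted_windows,
              effect_sizes = config$effect_sizes)
}

# ---- construction -----------------------------------------------------------

#' Model construction run: cohort to optimal HGS model
#'
#' Generates the construction cohort, processes it into trial averages,
#' runs the SPM stage (vector-field curve, Sidak-corrected post hoc
#' per-channel curves, GPC extraction, quadriceps-window filtering),
#' builds the predictor table and selects the optimal model by
#' LOSO-LASSO; optionally also fits the comparison pools M1-M3.
#'
#' @param config a [default_config()] list.
#' @param out_dir optional directory for JSON/CSV reports.
#' @param pools also fit the M1/M2/M3 comparison pools (default FALSE;
#'   the optimal pool `Mo` is always fit).
#' @return list with `model` (`gf_model`), `gpcs`, `table`, `tavg`,
#'   `cohort`, `labels`, optional `pools`, and a run `manifest`.
#' @export
run_construction <- function(config = default_config(), out_dir = NULL,
                             pools = FALSE) {
  t0 <- Sys.time()
  spec <- gf_spec_from_config(config, config$n_construction,
                              config$seeds$construction)
  cohort <- generate_cohort(spec)
  tavg <- process_cohort(cohort)
  y <- tavg$meta$hgs_kg
  cca <- spm_cca_curve(tavg$grids, y, alpha = config$alpha)
  pec <- spm_pearson_curves(tavg$grids, y, mask = cca$supra,
                            alpha = config$alpha)
  gpcs <- intersect_qt(extract_gpcs(pec))
  table <- build_predictor_table(tavg, gpcs)
  labels <- loso_lasso(table)
  model <- select_optimal_model(table, labels)
  pool_fits <- if (pools)
    comparison_models(table, attr(table, "pools")[c("M1", "M2", "M3")])
  else NULL
  manifest <- list(
    stage = "construction", seed = config$seeds$construction,
    n_subjects = config$n_construction, n_datasets = nrow(table),
    n_gpcs = nrow(gpcs), n_predictors = length(attr(table, "pools")$Mo),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out <- list(model = model, gpcs = gpcs, table = table, tavg = tavg,
              cohort = cohort, labels = labels, pools = pool_fits,
              cca = cca, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(predictors = model$predictors,
           coefficients = as.list(model$coefficients),
           intercept = model$intercept, icc = model$icc,
           icc_band = model$icc_band, mae = model$mae,
           adj_r2 = model$adj_r2, lambda_index = model$lambda_index),
      file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(gpcs, file.path(out_dir, "gpcs.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(labels$B, file.path(out_dir, "label_matrix.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# Apply a construction result to a fresh cohort: trial averages,
# predictor table with the training GPC definitions, HGS predictions and
# per-trial IMS-measured gait speed.
gf_apply_model <- function(construction, cohort) {
  tavg <- process_cohort(cohort)
  table <- build_predictor_table(tavg, construction$model$ims)
  list(tavg = tavg, table = table,
       hgs_ref = table$y,
       hgs_est = predict(construction$model, table),
       gs_ref = tavg$meta$gait_speed_mps,
       gs_est = tavg$gps$gp02,
       subject = table$subject)
}

#' Test-1 analogue: agreement of the trained model on a held-out cohort
#'
#' Generates an independent test cohort, applies the trained model, and
#' reports Bland-Altman agreement plus the probability-based success
#' rate bounds K_AL-K_AU for both the HGS estimate and the IMS-measured
#' gait speed.  Training residuals come from the construction LOSOCV
#' predictions (HGS) and the construction gait-speed differences.
#'
#' @param config a [default_config()].
#' @param construction result of [run_construction()].
#' @return list with `hgs` and `gait_speed` sub-reports (agreement,
#'   `gf_ba`, `gf_ka`) and the applied test data.
#' @export
run_test1 <- function(config, construction) {
  spec <- gf_spec_from_config(config, config$n_test, config$seeds$test)
  if (config$n_test < 3)
    gf_stop("gf_bad_input", "test cohort too small for interval estimates")
  applied <- gf_apply_model(construction, generate_cohort(spec))
  # training residuals
  train_hgs_res <- construction$model$cv_pred - construction$model$y
  train_gs_res <- construction$tavg$gps$gp02 -
    construction$tavg$meta$gait_speed_mps
  rep_for <- function(ref, est, train_res) {
    list(agreement = agreement_report(ref, est),
         ba = bland_altman(ref, est),
         ka = ka_bounds(train_res, est - ref))
  }
  list(hgs = rep_for(applied$hgs_ref, applied$hgs_est, train_hgs_res),
       gait_speed = rep_for(applied$gs_ref, applied$gs_est, train_gs_res),
       applied = applied)
}

#' Test-2 analogue: frailty risk scores against a synthetic expert rater
#'
#' Generates a frailty-evaluation cohort, computes the analog frailty
#' risk score from (a) the reference HGS / gait speed and (b) the
#' model-estimated HGS and IMS-measured gait speed, and compares both
#' against a declared synthetic expert rating: each of `n_raters`
#' experts scores `100 - true P_fr` plus a rater-specific bias and
#' Gaussian noise, clamped to 0-100 (experts rate *risk*, so their
#' scores fall as performance rises).
#'
#' @param config a [default_config()].
#' @param construction result of [run_construction()].
#' @return list with the per-subject score table, Pearson correlations
#'   (with bands) of expert score vs estimated / reference `P_fr`, and
#'   the inter-rater ICC(2,1) / ICC(2,k).
#' @export
run_test2 <- function(config, construction) {
  spec <- gf_spec_from_config(config, config$n_frailty,
                              config$seeds$frailty)
  applied <- gf_apply_model(construction, generate_cohort(spec))
  sex <- config$sex
  # per-subject means of the per-dataset estimates
  agg <- function(v) tapply(v, applied$subject, mean)
  hgs_ref <- agg(applied$hgs_ref); hgs_est <- agg(applied$hgs_est)
  gs_ref <- agg(applied$gs_ref); gs_est <- agg(applied$gs_est)
  fs_ref <- frailty_scores(hgs_ref, gs_ref, sex, config$norms)
  fs_est <- frailty_scores(hgs_est, gs_est, sex, config$norms)
  set.seed(config$seeds$rater)
  nr <- config$rater$n_raters
  ns <- length(hgs_ref)
  bias <- rnorm(nr, 0, config$rater$bias_sd)
  raters <- sapply(seq_len(nr), function(k)
    pmin(pmax(100 - fs_ref$P_fr + bias[k] +
                rnorm(ns, 0, config$rater$noise_sd), 0), 100))
  expert <- rowMeans(raters)
  cor_with <- function(p) {
    ct <- suppressWarnings(cor.test(expert, p))
    list(r = unname(ct$estimate), p = ct$p.value,
         band = interpret_r(ct$estimate))
  }
  list(
    scores = data.frame(subject = names(hgs_ref),
                        hgs_ref = as.numeric(hgs_ref),
                        hgs_est = as.numeric(hgs_est),
                        gs_ref = as.numeric(gs_ref),
                        gs_est = as.numeric(gs_est),
                        P_fr_ref = fs_ref$P_fr, P_fr_est = fs_est$P_fr,
                        expert = expert, row.names = NULL),
    cor_est = cor_with(fs_est$P_fr),
    cor_ref = cor_with(fs_ref$P_fr),
    icc_raters = list(icc21 = icc(raters, form = "2,1"),
                      icc2k = icc(raters, form = "2,k")),
    frailty_ref = fs_ref, frailty_est = fs_est)
}

#' Run the full study replica
#'
#' Construction, Test 1 and Test 2 in sequence under one configuration.
#'
#' @param config a [default_config()].
#' @param out_dir optional report directory (passed to
#'   [run_construction()]).
#' @return list with `construction`, `test1`, `test2`.
#' @export
run_all <- function(config = default_config(), out_dir = NULL) {
  con <- run_construction(config, out_dir = out_dir)
  list(construction = con,
       test1 = run_test1(config, con),
       test2 = run_test2(config, con))
}

# ---- command-line interface -------------------------------------------------

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort), `score` (frailty
#' score for one subject), `construct`, `test1`, `test2`, `all`.
#' Invoke from a shell as
#' `Rscript -e 'gaitfrail::gaitfrail_cli()' score --hgs 28 --gs 1.0 --sex male`.
#'
#' @param args character vector of CLI arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return invisibly, the result of the dispatched command.
#' @export
gaitfrail_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: gaitfrail <simulate|score|construct|test1|test2|all> [options]\n")
    return(invisible(NULL))
  }
  cmd <- args[1]; rest <- args[-1]
  opt <- function(name, default = NULL) {
    i <- which(rest == paste0("--", name))
    if (length(i) && i < length(rest)) rest[i + 1] else default
  }
  seed <- as.integer(opt("seed", "1"))
  out <- opt("out", "gaitfrail_out")
  result <- switch(cmd,
    score = {
      sc <- frailty_scores(as.numeric(opt("hgs")), as.numeric(opt("gs")),
                           opt("sex", "male"))
      cat(jsonlite::toJSON(as.list(sc), auto_unbox = TRUE, digits = NA), "\n")
      sc
    },
    simulate = {
      spec <- gf_spec_from_config(default_config(seed, opt("sex", "male")),
                                  as.integer(opt("n", "10")), seed)
      write_cohort(generate_cohort(spec), out)
      cat("cohort written to", out, "\n")
      out
    },
    construct = run_construction(default_config(seed, opt("sex", "male")),
                                 out_dir = out),
    test1 = {
      cfg <- default_config(seed, opt("sex", "male"))
      run_test1(cfg, run_construction(cfg))
    },
    test2 = {
      cfg <- default_config(seed, opt("sex", "male"))
      run_test2(cfg, run_construction(cfg))
    },
    all = run_all(default_config(seed, opt("sex", "male")), out_dir = out),
    gf_stop("gf_bad_input", "unknown subcommand '%s'", cmd))
  invisible(result)
}
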