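# one deterministic single-subject cohort shared across this file
local_cohort <- generate_cohort(cohort_spec(1, "male", n_trials = 1,
                                            seed = 33,
                                            strides_per_trial = 12))
local_trial <- local_cohort$trials[[1]]
local_gt <- local_cohort$ground_truth$trials[[1]]

test_that("heel strikes are detected within +/- 3 samples of ground truth", {
  hs <- detect_heel_strikes(local_trial)
  expect_length(hs, length(local_gt$hs))   # 12 strides -> 13 heel strikes
  expect_lte(max(abs(hs - local_gt$hs)), 3)
})

test_that("toe offs are detected near truth and keep the event ordering", {
  hs <- detect_heel_strikes(local_trial)
  to <- detect_toe_offs(local_trial, hs)
  expect_lte(max(abs(to - local_gt$to)), 3)
  ns <- length(to)
  expect_true(all(hs[seq_len(ns)] < to & to < hs[seq_len(ns) + 1]))
})

test_that("degenerate trials are rejected, not silently processed", {
  flat <- local_trial
  flat[gaitfrail:::GF_CHANNELS] <- 0
  expect_error(detect_heel_strikes(flat), class = "gf_no_strides")
  # time-reversed trial: events come out implausible and raise
  rev_trial <- local_trial[rev(seq_len(nrow(local_trial))), ]
  rev_trial$t <- local_trial$t
  expect_error({
    hs <- detect_heel_strikes(rev_trial)
    detect_toe_offs(rev_trial, hs)
  }, class = "gaitfrail_error")
  expect_error(detect_heel_strikes(local_trial[1:50, ]),
               class = "gf_bad_input")
})

test_that("normalize_stride removes bias and is identity on a 60/40 stride", {
  hs <- detect_heel_strikes(local_trial)
  to <- detect_toe_offs(local_trial, hs)
  st <- normalize_stride(local_trial, hs[4], to[4], hs[5])
  expect_equal(dim(st$grid), c(9, 100))
  expect_equal(unname(rowMeans(st$grid[, 21:25])), rep(0, 9),
               tolerance = 1e-12)
  expect_true(st$bias_removed && st$velocity_normalized)
  # stance of exactly 60 samples, swing of 40: resampling is the identity
  set.seed(50)
  n <- 120
  sig <- as.data.frame(matrix(rnorm(n * 9), n,
                              dimnames = list(NULL,
                                              gaitfrail:::GF_CHANNELS)))
  sig$t <- (seq_len(n) - 1) / 100
  st <- normalize_stride(sig, 1, 60, 100, velocity_normalize = FALSE)
  raw <- t(as.matrix(sig[1:100, gaitfrail:::GF_CHANNELS]))
  raw <- raw - rowMeans(raw[, 21:25])
  expect_equal(unname(st$grid), unname(raw), tolerance = 1e-12)
  expect_error(normalize_stride(sig, 60, 10, 100), class = "gf_event_order")
})

test_that("v_max matches closed-form integration of constant acceleration", {
  n <- 400
  sig <- as.data.frame(matrix(0, n, 9,
                              dimnames = list(NULL,
                                              gaitfrail:::GF_CHANNELS)))
  sig$t <- (seq_len(n) - 1) / 100
  a <- 2
  sig$Ay <- -a  # forward = -Ay
  st <- normalize_stride(sig, 1, 240, 400, velocity_normalize = FALSE)
  i_n <- round(0.23 * 240)
  expect_equal(st$v_max, a * (400 - i_n) / 100, tolerance = 0.02)
  # zero forward acceleration: degenerate for velocity normalization
  sig$Ay <- 0
  expect_error(normalize_stride(sig, 1, 240, 400),
               class = "gf_degenerate_stride")
})

test_that("filter_strides drops lead-in/out strides and gross outliers", {
  mk <- function(d, v = 5) list(duration = d, v_max = v)
  s13 <- lapply(rep(1.0, 13), mk)
  expect_length(filter_strides(s13), 7)
  # 10 strides, one gross interior outlier -> 4 - 1 = 3 retained
  durs <- c(1, 1.02, 0.98, 1.01, 2.5, 0.99, 1.03, 1, 1.01, 0.97)
  s10 <- lapply(durs, mk)
  expect_length(filter_strides(s10), 3)
  expect_error(filter_strides(lapply(rep(1, 6), mk)),
               class = "gf_insufficient_strides")
  # outliers in v_max are caught too
  s10 <- lapply(rep(1, 10), mk)
  s10[[6]]$v_max <- 50
  expect_length(filter_strides(s10), 3)
})

test_that("gait parameters follow their definitions and normalizations", {
  hs <- detect_heel_strikes(local_trial)
  to <- detect_toe_offs(local_trial, hs)
  h <- local_cohort$subjects$height_cm[1] / 100
  gp <- compute_gait_parameters(local_trial, hs[4], to[4], hs[5], h)
  expect_length(gp, 20)
  expect_true(all(is.finite(gp)))
  raw <- attr(gp, "raw")
  dur <- raw[["duration"]]
  # stance + swing equals the stride duration before normalization
  expect_equal(raw[["stance_time"]] + raw[["swing_time"]], dur)
  expect_equal(gp[["gp11"]] + gp[["gp12"]], 1)
  expect_equal(gp[["gp10"]], 120 / dur)
  expect_lte(gp[["gp02"]], gp[["gp17"]])
  # 60/40 split by construction of the generator
  expect_equal(gp[["gp11"]], 0.6, tolerance = 0.02)
  expect_error(compute_gait_parameters(local_trial, hs[4], to[4], hs[5],
                                       NULL),
               class = "gf_config_error")
})

test_that("noise-free processing recovers generator truth", {
  co <- generate_cohort(noise_free_spec(n_subjects = 4, effect = 0))
  ta <- process_cohort(co)
  # gait parameters against known template properties
  expect_equal(mean(ta$gps$gp02), mean(ta$meta$gait_speed_mps),
               tolerance = 0.03)
  expect_lt(max(abs(ta$gps$gp02 - ta$meta$gait_speed_mps) /
                  ta$meta$gait_speed_mps), 0.03)
  phi <- seq(0, 1, length.out = 10001)
  gp03_true <- max(-gaitfrail:::GF_TEMPLATES$Ex(phi))
  expect_equal(mean(ta$gps$gp03), gp03_true, tolerance = 0.02)
  # recovered mean grid vs the generator template normalized identically
  tmpl <- matrix(0, 9, 100,
                 dimnames = list(gaitfrail:::GF_CHANNELS, NULL))
  cols <- gaitfrail:::gf_col_phase(1:100)
  gs <- ta$meta$gait_speed_mps[1]
  for (ch in gaitfrail:::GF_CHANNELS)
    tmpl[ch, ] <- gaitfrail:::gf_channel_template(ch, cols, gs, 1.05)
  tmpl <- tmpl - rowMeans(tmpl[, 21:25, drop = FALSE])
  v_max <- gs * co$ground_truth$v_max_factor
  tmpl[gaitfrail:::GF_INERTIAL, ] <- tmpl[gaitfrail:::GF_INERTIAL, ] / v_max
  rec <- apply(ta$grids, c(2, 3), mean)
  rel_rms <- sqrt(mean((rec - tmpl)^2)) / sqrt(mean(tmpl^2))
  expect_lt(rel_rms, 0.01)
})

test_that("average_trial averages feet and falls back to one foot", {
  co <- generate_cohort(cohort_spec(1, "male", n_trials = 1, seed = 12,
                                    strides_per_trial = 10))
  h <- co$subjects$height_cm[1] / 100
  pl <- process_trial(co$trials[[1]], h)
  pr <- process_trial(co$trials[[2]], h)
  av <- average_trial(pl, pr)
  expect_equal(av$grid, (Reduce(`+`, lapply(pl$strides, `[[`, "grid")) /
                           length(pl$strides) +
                         Reduce(`+`, lapply(pr$strides, `[[`, "grid")) /
                           length(pr$strides)) / 2)
  # identical inputs -> output equals either input's mean
  av2 <- average_trial(pl, pl)
  expect_equal(av2$grid,
               Reduce(`+`, lapply(pl$strides, `[[`, "grid")) /
                 length(pl$strides))
  # mirrored grids cancel
  neg <- pl
  neg$strides <- lapply(neg$strides, function(s) {
    s$grid <- -s$grid; s
  })
  neg$gps <- -neg$gps
  expect_equal(max(abs(average_trial(pl, neg)$grid)), 0)
  expect_warning(av3 <- average_trial(pl, NULL), "single-foot")
  expect_equal(av3$grid, av2$grid)
  expect_error(average_trial(NULL, NULL), class = "gf_insufficient_strides")
})

test_that("process_cohort yields n_subjects x n_trials datasets and round-trips", {
  co <- generate_cohort(cohort_spec(3, "female", n_trials = 4, seed = 14,
                                    strides_per_trial = 10))
  ta <- process_cohort(co)
  expect_equal(nrow(ta$meta), 12)
  expect_equal(dim(ta$grids), c(12, 9, 100))
  expect_length(ta$provenance, 12)
  d <- file.path(tempdir(), "tavg")
  write_trial_averages(ta, d)
  ta2 <- read_trial_averages(d)
  expect_equal(ta2$grids, ta$grids, tolerance = 1e-7)
  expect_equal(ta2$meta$subject, ta$meta$subject)
  unlink(d, recursive = TRUE)
})
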