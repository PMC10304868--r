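test_that("cohort_spec validates its invariants", {
  expect_error(cohort_spec(0, "male"), class = "gf_bad_spec")
  expect_error(cohort_spec(5, "male", strides_per_trial = 6),
               class = "gf_bad_spec")
  expect_error(cohort_spec(5, "male", noise_sd = c(-1, rep(1, 8))),
               class = "gf_bad_spec")
  # planted window must lie inside a quadriceps-activation window
  expect_error(cohort_spec(5, "male",
                           planted_windows = list(list(channel = "Ax",
                                                       t_s = 30L, t_e = 35L)),
                           effect_sizes = 1),
               class = "gf_window_outside_qt")
  expect_error(cohort_spec(5, "male",
                           planted_windows = list(list(channel = "Ax",
                                                       t_s = 12L, t_e = 20L)),
                           effect_sizes = 1),
               class = "gf_window_outside_qt")
  expect_error(cohort_spec(5, "male",
                           planted_windows = list(list(channel = "Ax",
                                                       t_s = 12L, t_e = 14L)),
                           effect_sizes = c(1, 2)),
               class = "gf_bad_spec")
  # sex-specific default grip-strength norms
  expect_equal(cohort_spec(5, "male")$hgs_dist, c(34.7, 7.1))
  expect_equal(cohort_spec(5, "female")$hgs_dist, c(21.9, 4.8))
})

test_that("identical (spec, seed) gives a bit-identical cohort on disk", {
  spec <- cohort_spec(2, "female", n_trials = 1, seed = 123,
                      strides_per_trial = 10)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(c1, d1); write_cohort(c2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("ground truth satisfies the event invariants", {
  spec <- cohort_spec(2, "male", n_trials = 2, seed = 5,
                      strides_per_trial = 11)
  co <- generate_cohort(spec)
  expect_length(co$trials, 2 * 2 * 2)  # subjects x trials x feet
  for (gt in co$ground_truth$trials) {
    expect_length(gt$hs, spec$strides_per_trial + 1)
    ns <- length(gt$to)
    expect_true(all(gt$hs[seq_len(ns)] < gt$to))
    expect_true(all(gt$to < gt$hs[seq_len(ns) + 1]))
  }
})

test_that("noise-free planted window gives |r| = 1 with the Eq.-style predictor", {
  co <- generate_cohort(noise_free_spec(n_subjects = 8, effect = 5))
  ta <- process_cohort(co)
  vals <- vapply(seq_len(nrow(ta$meta)), function(r)
    ims_predictor_value(ta$grids[r, , ], "Gz", 12, 16), 0)
  expect_gt(cor(vals, ta$meta$hgs_kg), 1 - 1e-6)
})

test_that("planted-signal strength is monotone in the effect size", {
  rs <- vapply(c(0.5, 2, 8), function(e) {
    spec <- cohort_spec(10, "male", n_trials = 2, seed = 77,
                        planted_windows = list(list(channel = "Gz",
                                                    t_s = 12L, t_e = 16L)),
                        effect_sizes = e, strides_per_trial = 10)
    ta <- process_cohort(generate_cohort(spec))
    vals <- vapply(seq_len(nrow(ta$meta)), function(r)
      ims_predictor_value(ta$grids[r, , ], "Gz", 12, 16), 0)
    abs(cor(vals, ta$meta$hgs_kg))
  }, 0)
  expect_true(all(diff(rs) > 0))
})

test_that("subject-level draws match the requested distributions", {
  # the truncated-normal sampler used for all subject-level quantities
  set.seed(41)
  x <- gaitfrail:::gf_rtnorm(1e4, 34.7, 7.1, 0)
  # sampling error of the mean: 7.1/sqrt(1e4) ~ 0.07 kg (0.2%); the 2%
  # band is ~10 standard errors wide
  expect_lt(abs(mean(x) - 34.7) / 34.7, 0.02)
  expect_lt(abs(sd(x) - 7.1) / 7.1, 0.02)
  expect_true(all(x > 0))
  # and end-to-end on a generated cohort (wider band at n = 400)
  spec <- cohort_spec(400, "female", n_trials = 1, seed = 42,
                      strides_per_trial = 10)
  set.seed(spec$seed)
  n <- spec$n_subjects
  hgs <- gaitfrail:::gf_rtnorm(n, spec$hgs_dist[1], spec$hgs_dist[2], 0)
  co <- generate_cohort(cohort_spec(30, "female", n_trials = 1, seed = 43,
                                    strides_per_trial = 10))
  expect_true(all(co$subjects$hgs_kg > 0))
  expect_lt(abs(mean(hgs) - 21.9), 4.8 * 4 / sqrt(n))
})

test_that("cohorts round-trip through CSV/JSON exactly", {
  co <- generate_cohort(cohort_spec(2, "male", n_trials = 1, seed = 9,
                                    strides_per_trial = 10,
                                    planted_windows = list(
                                      list(channel = "Gy", t_s = 50L,
                                           t_e = 55L)),
                                    effect_sizes = 2))
  d <- file.path(tempdir(), "rt")
  write_cohort(co, d)
  co2 <- read_cohort(d)
  expect_equal(co2$subjects, co$subjects)
  expect_equal(co2$trials, co$trials)
  expect_equal(co2$spec, co$spec)
  expect_equal(co2$ground_truth$hgs, co$ground_truth$hgs)
  expect_equal(co2$ground_truth$trials[[1]]$hs,
               co$ground_truth$trials[[1]]$hs)
  unlink(d, recursive = TRUE)
})

test_that("malformed trial files raise typed parse errors", {
  co <- generate_cohort(cohort_spec(1, "male", n_trials = 1, seed = 10,
                                    strides_per_trial = 10))
  d <- file.path(tempdir(), "bad")
  write_cohort(co, d)
  f <- list.files(file.path(d, "trials"), full.names = TRUE)[1]
  # corrupt one cell -> error naming the offending row
  lines <- readLines(f)
  lines[102] <- sub("^[^,]*,[^,]*", "0.99,NaN", lines[102])
  writeLines(lines, f)
  err <- tryCatch(read_cohort(d), error = identity)
  expect_s3_class(err, "gf_parse_error")
  expect_match(conditionMessage(err), "row 101")
  # malformed header
  write_cohort(co, d)
  lines <- readLines(f)
  lines[1] <- sub("Ax", "XX", lines[1])
  writeLines(lines, f)
  expect_error(read_cohort(d), class = "gf_parse_error")
  # wrong sampling rate metadata
  write_cohort(co, d)
  lines <- readLines(f)
  d2 <- read.csv(f); d2$t <- d2$t * 2
  write.csv(d2, f, row.names = FALSE)
  expect_error(read_cohort(d), class = "gf_parse_error")
  unlink(d, recursive = TRUE)
})
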