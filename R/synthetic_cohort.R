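# ---- waveform templates -----------------------------------------------------
#
# Base one-stride shapes for the nine channels, defined on stride phase
# phi in [0, 1) with heel strike at phi = 0 and toe off at phi = 0.6
# (stance/swing fixed at 60/40 by construction).  Shapes are sums of a
# few periodic Gaussian bumps and low harmonics that loosely mimic real
# foot-motion waveforms; their exact form is a free choice of the
# generator -- downstream correctness does not depend on biomechanical
# realism.  Constraints that DO matter:
#   * Az has a dominant positive spike at phi = 0 (heel-strike detector),
#   * Gx crosses zero upward at exactly phi = 0.6 and is negative in the
#     preceding late stance (toe-off detector), near zero at foot flat,
#   * Ay is the negated forward acceleration of a velocity profile that
#     is ~0 at the 21-25%GC neutral posture and integrates to the
#     subject's gait speed over the stride.

# periodic Gaussian bump centred at `c` with width `w`
gf_bump <- function(phi, c, w) {
  exp(-((phi - c) / w)^2) + exp(-((phi - c - 1) / w)^2) +
    exp(-((phi - c + 1) / w)^2)
}

gf_dbump <- function(phi, c, w) {  # d/dphi of gf_bump
  -2 * ((phi - c) / w^2) * exp(-((phi - c) / w)^2) -
    2 * ((phi - c - 1) / w^2) * exp(-((phi - c - 1) / w)^2) -
    2 * ((phi - c + 1) / w^2) * exp(-((phi - c + 1) / w)^2)
}

# forward-velocity weight: ~0 through mid stance, peaking in mid swing,
# normalized to unit mean so that v(phi) = gait_speed * gf_vweight(phi)
GF_VW_C <- 0.8
GF_VW_W <- 0.12
GF_VW_MEAN <- local({
  phi <- seq(0, 1, length.out = 20001)[-20001]
  mean(gf_bump(phi, GF_VW_C, GF_VW_W))
})
gf_vweight <- function(phi) gf_bump(phi, GF_VW_C, GF_VW_W) / GF_VW_MEAN
gf_dvweight <- function(phi) gf_dbump(phi, GF_VW_C, GF_VW_W) / GF_VW_MEAN

# channel templates excluding Ay (units: A m/s^2, G deg/s, E deg)
GF_TEMPLATES <- list(
  Ax = function(phi) 0.8 * sin(2 * pi * phi) + 0.5 * gf_bump(phi, 0.05, 0.04) -
    0.6 * gf_bump(phi, 0.75, 0.10),
  Az = function(phi) 5.0 * gf_bump(phi, 0.00, 0.025) +
    1.0 * gf_bump(phi, 0.62, 0.06) + 0.5 * sin(4 * pi * phi),
  Gx = function(phi) 200 * gf_bump(phi, 0.70, 0.08) -
    200 * gf_bump(phi, 0.45, 0.12) - 60 * gf_bump(phi, 0.05, 0.04) -
    120 * gf_bump(phi, 0.93, 0.05),
  Gy = function(phi) 60 * gf_bump(phi, 0.10, 0.08) -
    90 * gf_bump(phi, 0.65, 0.10) + 40 * sin(2 * pi * phi),
  Gz = function(phi) 50 * sin(2 * pi * phi) - 70 * gf_bump(phi, 0.68, 0.09) +
    30 * gf_bump(phi, 0.10, 0.10),
  Ex = function(phi) 28 * gf_bump(phi, 0.68, 0.09) -
    30 * gf_bump(phi, 0.97, 0.06),
  Ey = function(phi) 8 * sin(2 * pi * phi) - 6 * gf_bump(phi, 0.60, 0.10),
  Ez = function(phi) 10 * gf_bump(phi, 0.03, 0.05) -
    8 * gf_bump(phi, 0.70, 0.12) + 4 * sin(2 * pi * phi + 0.5)
)

# Template value of a channel; Ay depends on gait speed and stride duration.
gf_channel_template <- function(channel, phi, gait_speed = NULL,
                                duration = NULL) {
  if (channel == "Ay") {
    # Ay is posterior-positive: forward acceleration enters negated
    -gait_speed * gf_dvweight(phi) / duration
  } else {
    GF_TEMPLATES[[channel]](phi)
  }
}

# phase of the centre of %GC column c under the 60/40 convention used by
# normalize_stride (column 1 = heel strike, column 60 = toe off)
gf_col_phase <- function(col) {
  ifelse(col <= 60, 0.6 * (col - 1) / 59, 0.6 + 0.4 * (col - 60) / 40)
}

# ---- cohort specification ---------------------------------------------------

#' Specification of a synthetic gait cohort
#'
#' Describes a seeded synthetic cohort of one sex: subject-level grip
#' strength and gait-speed distributions, trial layout, waveform noise
#' and the planted linear dependence of waveform amplitude on grip
#' strength inside chosen %GC windows.  Planted windows must lie inside
#' the quadriceps-activation filter windows [qt_windows()] so that the
#' signal survives the downstream GPC filtering and recovery is
#' possible.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param sex `"male"` or `"female"` (one cohort is single-sex; runs are
#'   sex-stratified throughout).
#' @param n_trials walking trials per subject (default 4).
#' @param seed integer RNG seed; identical (spec, seed) reproduces the
#'   cohort bit-identically.
#' @param planted_windows list of `list(channel=, t_s=, t_e=)` windows.
#' @param effect_sizes numeric, one per window: waveform amplitude added
#'   per kg of grip strength above the cohort mean (channel units / kg).
#' @param noise_sd length-9 non-negative per-channel noise SD (channel
#'   units, before the smoothing that gives the noise its ~5-sample
#'   correlation length).
#' @param hgs_dist `c(mean, sd)` of grip strength in kg; defaults to the
#'   sex-specific population norms (34.7/7.1 male, 21.9/4.8 female).
#' @param gs_dist `c(mean, sd)` of gait speed in m/s (default 1.29/0.24).
#' @param strides_per_trial strides recorded per trial (>= 10; the first
#'   and last three are discarded downstream).
#' @param duration_dist `c(mean, sd)` of the subject-level base stride
#'   duration in seconds (sd 0 makes all subjects share one duration).
#' @param stride_jitter_sd within-subject stride-to-stride duration SD
#'   in seconds (0 makes every stride of a subject identical, which the
#'   noise-free contracts rely on).
#' @return object of class `gf_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, sex = c("male", "female"),
                        n_trials = 4, seed = 1,
                        planted_windows = list(), effect_sizes = numeric(),
                        noise_sd = c(0.3, 0.3, 0.3, 8, 8, 8, 1, 1, 1),
                        hgs_dist = NULL, gs_dist = c(1.29, 0.24),
                        strides_per_trial = 16,
                        duration_dist = c(1.05, 0.06),
                        stride_jitter_sd = 0.015) {
  sex <- match.arg(sex)
  if (n_subjects < 1 || n_trials < 1)
    gf_stop("gf_bad_spec", "n_subjects and n_trials must be positive")
  if (strides_per_trial < 10)
    gf_stop("gf_bad_spec", "strides_per_trial must be >= 10")
  if (is.null(hgs_dist))
    hgs_dist <- if (sex == "male") c(34.7, 7.1) else c(21.9, 4.8)
  if (hgs_dist[2] < 0 || gs_dist[2] < 0 || duration_dist[2] < 0 ||
      stride_jitter_sd < 0)
    gf_stop("gf_bad_spec", "distribution sd must be non-negative")
  noise_sd <- rep_len(noise_sd, 9)
  if (any(noise_sd < 0))
    gf_stop("gf_bad_spec", "noise_sd must be non-negative")
  if (length(effect_sizes) != length(planted_windows))
    gf_stop("gf_bad_spec", "need one effect size per planted window")
  qt <- qt_windows()
  for (w in planted_windows) {
    if (!all(c("channel", "t_s", "t_e") %in% names(w)) ||
        !w$channel %in% GF_CHANNELS)
      gf_stop("gf_bad_spec", "planted window needs channel/t_s/t_e")
    inside <- any(w$t_s >= qt$t_s & w$t_e <= qt$t_e)
    if (!inside || w$t_s > w$t_e)
      gf_stop("gf_window_outside_qt",
              "planted window %s [%d, %d] not inside a Q_t window",
              w$channel, w$t_s, w$t_e)
  }
  structure(list(n_subjects = as.integer(n_subjects), sex = sex,
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 planted_windows = planted_windows,
                 effect_sizes = as.numeric(effect_sizes),
                 noise_sd = as.numeric(noise_sd),
                 hgs_dist = as.numeric(hgs_dist),
                 gs_dist = as.numeric(gs_dist),
                 strides_per_trial = as.integer(strides_per_trial),
                 duration_dist = as.numeric(duration_dist),
                 stride_jitter_sd = as.numeric(stride_jitter_sd)),
            class = "gf_cohort_spec")
}

# normal draw truncated below at `lo` (resampling)
gf_rtnorm <- function(n, mean, sd, lo) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= lo)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

# ---- generation -------------------------------------------------------------

#' Generate a seeded synthetic cohort with ground truth
#'
#' Draws subjects (grip strength truncated at 0 kg, gait speed, simple
#' demographics and J-CHS questionnaire answers), then synthesizes raw
#' 100 Hz 9-channel foot-motion trials for both feet.  Each stride is a
#' smooth template plus, inside each planted %GC window, `effect_size *
#' (HGS - cohort HGS mean)`, plus Gaussian noise smoothed with a
#' 5-sample moving average (so the noise field has non-degenerate
#' smoothness, FWHM >= 3 %GC).  Heel-strike/toe-off sample indices and
#' all subject-level truths are returned alongside.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `gf_cohort`: list with `spec`, `subjects`
#'   (data.frame), `trials` (named list of data.frames with columns
#'   `t, Ax..Ez`) and `ground_truth` (per-trial `hs`/`to` indices,
#'   planted support, subject truths).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "gf_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  male <- spec$sex == "male"
  subjects <- data.frame(
    id = sprintf("S%03d", seq_len(n)),
    sex = spec$sex,
    age = round(gf_rtnorm(n, if (male) 70.3 else 70.9,
                          if (male) 7.7 else 5.9, 60)),
    height_cm = round(gf_rtnorm(n, if (male) 166.7 else 154.9,
                                if (male) 4.2 else 6.6, 120), 1),
    weight_kg = round(gf_rtnorm(n, if (male) 66.8 else 54.7,
                                if (male) 8.8 else 9.4, 35), 1),
    hgs_kg = round(gf_rtnorm(n, spec$hgs_dist[1], spec$hgs_dist[2], 0), 2),
    gait_speed_mps = round(gf_rtnorm(n, spec$gs_dist[1], spec$gs_dist[2],
                                     0.2), 3),
    q1 = runif(n) < 0.10, q2 = runif(n) < 0.20,
    q3 = runif(n) < 0.60, q4 = runif(n) < 0.50,
    stringsAsFactors = FALSE)
  subjects$bmi <- round(subjects$weight_kg / (subjects$height_cm / 100)^2, 1)
  hgs_centre <- spec$hgs_dist[1]

  # planted windows in stride-phase coordinates (with half-column margins
  # so the full effect lands on the intended grid columns)
  plant <- lapply(spec$planted_windows, function(w) {
    sp_lo <- if (w$t_s <= 60) 0.6 / 59 else 0.4 / 40
    sp_hi <- if (w$t_e <= 60) 0.6 / 59 else 0.4 / 40
    list(channel = w$channel,
         lo = max(gf_col_phase(w$t_s) - sp_lo / 2, 0),
         hi = min(gf_col_phase(w$t_e) + sp_hi / 2, 1))
  })

  trials <- list()
  gt_trials <- list()
  pad <- 50L
  for (s in seq_len(n)) {
    sub <- subjects[s, ]
    d0 <- gf_rtnorm(1, spec$duration_dist[1], spec$duration_dist[2], 0.8)
    dhgs <- sub$hgs_kg - hgs_centre
    for (tr in seq_len(spec$n_trials)) {
      for (side in c("left", "right")) {
        ns <- spec$strides_per_trial
        dur <- gf_rtnorm(ns, d0, spec$stride_jitter_sd, 0.7)
        L <- round(dur * 100)
        hs <- pad + c(0L, cumsum(L)) + 1L       # ns + 1 heel strikes
        to <- hs[seq_len(ns)] + round(0.6 * L)
        total <- pad + sum(L) + 30L + pad       # 30 samples of a final stride
        sig <- matrix(0, total, 9, dimnames = list(NULL, GF_CHANNELS))
        for (i in seq_len(ns)) {
          idx <- hs[i]:(hs[i + 1] - 1L)
          phi <- (seq_along(idx) - 1) / L[i]
          for (ch in GF_CHANNELS) {
            v <- gf_channel_template(ch, phi, sub$gait_speed_mps, dur[i])
            sig[idx, ch] <- v
          }
          for (k in seq_along(plant)) {
            p <- plant[[k]]
            in_w <- phi >= p$lo & phi <= p$hi
            sig[idx[in_w], p$channel] <-
              sig[idx[in_w], p$channel] + spec$effect_sizes[k] * dhgs
          }
        }
        # final heel-strike spike at the start of the (n_s + 1)-th stride
        idx <- hs[ns + 1]:(hs[ns + 1] + 29L)
        phi <- (seq_along(idx) - 1) / L[ns]
        for (ch in GF_CHANNELS)
          sig[idx, ch] <- gf_channel_template(ch, phi, sub$gait_speed_mps,
                                              dur[ns])
        for (j in seq_len(9)) {
          if (spec$noise_sd[j] > 0) {
            e <- rnorm(total, 0, spec$noise_sd[j])
            e <- as.numeric(stats::filter(e, rep(1 / 5, 5), sides = 2))
            e[is.na(e)] <- 0
            sig[, j] <- sig[, j] + e
          }
        }
        nm <- sprintf("%s_T%d_%s", sub$id, tr, side)
        trials[[nm]] <- data.frame(t = round((seq_len(total) - 1) / 100, 2),
                                   round(sig, 6))
        gt_trials[[nm]] <- list(subject = sub$id, trial = tr, side = side,
                                hs = hs, to = to)
      }
    }
  }
  structure(list(
    spec = spec, subjects = subjects, trials = trials,
    ground_truth = list(
      trials = gt_trials,
      planted = spec$planted_windows,
      effect_sizes = spec$effect_sizes,
      hgs = setNames(subjects$hgs_kg, subjects$id),
      gait_speed = setNames(subjects$gait_speed_mps, subjects$id),
      v_max_factor = max(gf_vweight(seq(0, 1, by = 1e-4))))
  ), class = "gf_cohort")
}

#' @export
print.gf_cohort <- function(x, ...) {
  cat(sprintf("Synthetic gait cohort: %d %s subjects x %d trials (%d trial files)\n",
              x$spec$n_subjects, x$spec$sex, x$spec$n_trials,
              length(x$trials)))
  invisible(x)
}

# ---- persistence ------------------------------------------------------------

#' Write / read a cohort as plain CSV + JSON
#'
#' `write_cohort()` creates `subjects.csv`, `ground_truth.json` and one
#' `trials/<subject>_T<k>_<side>.csv` per trial (columns `t, Ax..Ez`,
#' 100 Hz).  `read_cohort()` reconstructs the identical `gf_cohort`
#' object; malformed files raise a typed `gf_parse_error` naming the
#' offending file and row.
#'
#' @param cohort a `gf_cohort`.
#' @param path directory to create/read.
#' @return `write_cohort` returns `path` invisibly; `read_cohort`
#'   returns the `gf_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "gf_cohort"))
  dir.create(file.path(path, "trials"), recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$subjects, file.path(path, "subjects.csv"),
            row.names = FALSE)
  meta <- list(spec = unclass(cohort$spec),
               ground_truth = cohort$ground_truth,
               sampling_hz = 100)
  jsonlite::write_json(meta, file.path(path, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(cohort$trials))
    write.csv(cohort$trials[[nm]],
              file.path(path, "trials", paste0(nm, ".csv")),
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  sfile <- file.path(path, "subjects.csv")
  gfile <- file.path(path, "ground_truth.json")
  if (!file.exists(sfile) || !file.exists(gfile))
    gf_stop("gf_parse_error", "not a cohort directory: %s", path)
  subjects <- read.csv(sfile, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(gfile, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  if (!identical(as.numeric(meta$sampling_hz), 100))
    gf_stop("gf_parse_error", "cohort metadata is not 100 Hz")
  sp <- meta$spec
  spec <- cohort_spec(sp$n_subjects, sp$sex, sp$n_trials, sp$seed,
                      lapply(sp$planted_windows, function(w)
                        list(channel = w$channel, t_s = as.integer(w$t_s),
                             t_e = as.integer(w$t_e))),
                      as.numeric(sp$effect_sizes), as.numeric(sp$noise_sd),
                      as.numeric(sp$hgs_dist), as.numeric(sp$gs_dist),
                      sp$strides_per_trial, as.numeric(sp$duration_dist),
                      as.numeric(sp$stride_jitter_sd))
  files <- sort(list.files(file.path(path, "trials"), full.names = TRUE))
  trials <- list()
  for (f in files) {
    nm <- sub("\\.csv$", "", basename(f))
    trials[[nm]] <- read_trial_csv(f)
  }
  gt <- meta$ground_truth
  gt$trials <- lapply(gt$trials, function(x) {
    x$hs <- as.integer(unlist(x$hs)); x$to <- as.integer(unlist(x$to)); x
  })
  gt$hgs <- setNames(as.numeric(unlist(gt$hgs)), subjects$id)
  gt$gait_speed <- setNames(as.numeric(unlist(gt$gait_speed)), subjects$id)
  gt$effect_sizes <- as.numeric(unlist(gt$effect_sizes))
  structure(list(spec = spec, subjects = subjects, trials = trials,
                 ground_truth = gt), class = "gf_cohort")
}

# Read and validate one raw trial CSV (t + nine channel columns, 100 Hz).
read_trial_csv <- function(file) {
  d <- tryCatch(read.csv(file, stringsAsFactors = FALSE),
                error = function(e)
                  gf_stop("gf_parse_error", "cannot read %s: %s",
                          file, conditionMessage(e)))
  need <- c("t", GF_CHANNELS)
  if (!identical(names(d), need))
    gf_stop("gf_parse_error",
            "%s: malformed header (expected %s)", basename(file),
            paste(need, collapse = ","))
  bad <- which(!stats::complete.cases(d) |
                 rowSums(!sapply(d, is.finite)) > 0)
  if (length(bad))
    gf_stop("gf_parse_error", "%s: non-finite or truncated value at row %d",
            basename(file), bad[1])
  if (nrow(d) > 1) {
    dt <- median(diff(d$t))
    if (abs(dt - 0.01) > 1e-6)
      gf_stop("gf_parse_error", "%s: sampling interval %.4g s is not 100 Hz",
              basename(file), dt)
  }
  d
}
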