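# ---- event detection --------------------------------------------------------

#' Detect heel-strike events in a raw trial
#'
#' Heel strikes are taken as prominent local maxima of the superior
#' acceleration `Az` (the landing spike), with a 0.4 s refractory period
#' between events.  The candidate threshold is half the trial maximum.
#'
#' @param signal data.frame with columns `t, Ax..Ez` at `fs` Hz.
#' @param fs sampling rate in Hz (default 100).
#' @return integer vector of heel-strike sample indices (>= 2 events).
#' @export
detect_heel_strikes <- function(signal, fs = 100) {
  az <- signal$Az
  n <- length(az)
  if (n < 200) gf_stop("gf_bad_input", "trial too short (< 200 samples)")
  thr <- 0.5 * max(az)
  if (!is.finite(thr) || thr <= 0)
    gf_stop("gf_no_strides", "no detectable strides (flat or non-positive Az)")
  loc <- which(az > thr)
  loc <- loc[loc > 1 & loc < n]
  loc <- loc[az[loc] >= az[loc - 1] & az[loc] >= az[loc + 1]]
  if (!length(loc)) gf_stop("gf_no_strides", "no detectable strides")
  # greedy refractory pruning, strongest peaks first
  loc <- loc[order(az[loc], decreasing = TRUE)]
  keep <- integer()
  gap <- round(0.4 * fs)
  for (p in loc) if (!length(keep) || all(abs(keep - p) >= gap))
    keep <- c(keep, p)
  hs <- sort(keep)
  if (length(hs) < 2) gf_stop("gf_no_strides", "fewer than two heel strikes")
  hs
}

#' Detect toe-off events between consecutive heel strikes
#'
#' Within each stride the sagittal angular velocity `Gx` shows a large
#' positive (plantarflexion) swing peak; toe off is located as the
#' upward zero crossing of `Gx` immediately preceding that peak, searched
#' after 25% of the stride.  Detected events must satisfy
#' `hs[i] < to[i] < hs[i+1]` with a stance fraction in (0.45, 0.75);
#' anything else raises a typed error rather than returning silently
#' implausible events.
#'
#' @param signal raw trial data.frame.
#' @param hs heel-strike indices from [detect_heel_strikes()].
#' @return integer vector of toe-off indices, one per stride.
#' @export
detect_toe_offs <- function(signal, hs) {
  gx <- signal$Gx
  to <- integer(length(hs) - 1)
  for (i in seq_len(length(hs) - 1)) {
    L <- hs[i + 1] - hs[i]
    lo <- hs[i] + round(0.25 * L)
    seg <- gx[lo:(hs[i + 1] - 1)]
    pk <- which.max(seg)
    j <- pk
    while (j > 1 && seg[j - 1] > 0) j <- j - 1
    if (j == 1 || seg[pk] <= 0)
      gf_stop("gf_event_order",
              "stride %d: no upward Gx zero crossing before the swing peak", i)
    # j is the first positive sample; take whichever side is closer to zero
    if (abs(seg[j - 1]) <= abs(seg[j])) j <- j - 1
    to[i] <- lo + j - 1L
    frac <- (to[i] - hs[i]) / L
    if (frac <= 0.45 || frac >= 0.75)
      gf_stop("gf_event_order",
              "stride %d: implausible stance fraction %.2f", i, frac)
  }
  to
}

# ---- normalization ----------------------------------------------------------

#' Temporally normalize, de-bias and velocity-normalize one stride
#'
#' The stance phase (`hs_i .. to_i`) is linearly resampled to %GC
#' columns 1-60 and the swing phase (`to_i .. hs_next`) to columns
#' 61-100.  Per channel, the mean over 21-25%GC (foot flat, neutral
#' posture) is subtracted.  The maximum instantaneous walking velocity
#' `v_max` is obtained by trapezoidal integration of the forward
#' acceleration (`-Ay`; posterior is positive) from the neutral posture
#' to the end of the stride, and the six inertial channels are divided
#' by it; the Euler-angle channels are left untouched.
#'
#' @param signal raw trial data.frame.
#' @param hs_i,to_i,hs_next sample indices of the stride events.
#' @param fs sampling rate (Hz).
#' @param velocity_normalize divide inertial channels by `v_max`
#'   (default `TRUE`).
#' @return object of class `gf_stride`: list with the 9 x 100 `grid`
#'   (rows named `Ax..Ez`), `v_max` (m/s), `duration`, `stance_time`,
#'   `swing_time` (s) and normalization flags.
#' @export
normalize_stride <- function(signal, hs_i, to_i, hs_next, fs = 100,
                             velocity_normalize = TRUE) {
  if (!(hs_i < to_i && to_i < hs_next))
    gf_stop("gf_event_order", "events must satisfy hs < to < next hs")
  mat <- t(as.matrix(signal[hs_i:hs_next, GF_CHANNELS]))
  L <- hs_next - hs_i + 1L
  ito <- to_i - hs_i + 1L
  x <- seq_len(L)
  stance_x <- seq(1, ito, length.out = 60)
  swing_x <- seq(ito, L, length.out = 41)[-1]
  grid <- matrix(0, 9, 100, dimnames = list(GF_CHANNELS, NULL))
  for (ch in GF_CHANNELS)
    grid[ch, ] <- approx(x, mat[ch, ], xout = c(stance_x, swing_x))$y
  # neutral-posture bias removal: zero mean over 21-25%GC per channel
  grid <- grid - rowMeans(grid[, 21:25, drop = FALSE])
  # v_max from the raw (un-debiased) forward acceleration
  i_n <- round(0.23 * ito)  # neutral posture ~23%GC of stance
  a_fwd <- -mat["Ay", i_n:L]
  v <- c(0, cumsum((a_fwd[-1] + a_fwd[-length(a_fwd)]) / 2)) / fs
  v_max <- max(abs(v))
  if (velocity_normalize) {
    if (v_max <= 0.05)
      gf_stop("gf_degenerate_stride",
              "v_max %.4f m/s too small for velocity normalization", v_max)
    grid[GF_INERTIAL, ] <- grid[GF_INERTIAL, ] / v_max
  }
  structure(list(grid = grid, v_max = v_max,
                 duration = (hs_next - hs_i) / fs,
                 stance_time = (to_i - hs_i) / fs,
                 swing_time = (hs_next - to_i) / fs,
                 bias_removed = TRUE,
                 velocity_normalized = velocity_normalize),
            class = "gf_stride")
}

#' Drop lead-in/lead-out and outlier strides of a trial
#'
#' The first and last three strides of a trial (not uniform in speed)
#' are always discarded; among the remainder a stride is an outlier if
#' its duration or `v_max` deviates from the leave-one-out mean of its
#' peers by more than `max(3 leave-one-out SDs, 10%)`.  The
#' leave-one-out form is required because with few retained strides a
#' gross outlier dominates the plain mean and SD and could never exceed
#' 3 SDs computed with itself included.
#'
#' @param strides list of `gf_stride` objects in stride order.
#' @return the retained sub-list (possibly re-indexed).
#' @export
filter_strides <- function(strides) {
  ns <- length(strides)
  if (ns < 7)
    gf_stop("gf_insufficient_strides",
            "need >= 7 strides, got %d", ns)
  mid <- strides[4:(ns - 3)]
  feats <- cbind(duration = vapply(mid, `[[`, 0, "duration"),
                 v_max = vapply(mid, `[[`, 0, "v_max"))
  m <- nrow(feats)
  if (m < 3) return(mid)
  keep <- rep(TRUE, m)
  for (i in seq_len(m)) {
    for (j in 1:2) {
      others <- feats[-i, j]
      thr <- max(3 * sd(others), 0.10 * abs(mean(others)), 1e-12)
      if (abs(feats[i, j] - mean(others)) > thr) keep[i] <- FALSE
    }
  }
  mid[keep]
}

# ---- gait parameters --------------------------------------------------------

# trapezoidal cumulative integral with unit step dt
gf_cumtrapz <- function(x, dt) c(0, cumsum((x[-1] + x[-length(x)]) / 2)) * dt

# remove a linear trend pinned to zero at both ends (per-stride drift removal)
gf_detrend <- function(x) {
  n <- length(x)
  x - (x[1] + (x[n] - x[1]) * (seq_len(n) - 1) / (n - 1))
}

#' Compute the 20 spatiotemporal gait parameters of one stride
#'
#' Operational definitions on the raw stride signal (before temporal
#' normalization), with the conventional normalizations applied: GP01,
#' GP05 and GP06 by subject height; GP11-GP14, GP19 and GP20 by stride
#' duration; GP15, GP16 and GP18 by the maximum instantaneous walking
#' velocity.  The unnormalized timing values are kept in the `"raw"`
#' attribute.
#'
#' \describe{
#'   \item{gp01/gp02}{stride length (forward-velocity integral) and
#'     one-stride gait velocity}
#'   \item{gp03/gp04}{extreme roll angle `Ex` in dorsi-/plantarflexion}
#'   \item{gp05/gp06}{max lateral / vertical excursion from detrended
#'     double integration of `Ax` / `Az`}
#'   \item{gp07}{toe in/out: mean yaw `Ez` at foot flat (21-25%GC)}
#'   \item{gp08/gp09}{pitch `Ey` at heel strike / toe off}
#'   \item{gp10}{cadence (2 steps per stride)}
#'   \item{gp11-gp14}{stance, swing and the two double-support times}
#'   \item{gp15/gp16}{extreme sagittal angular velocity `Gx` in swing}
#'   \item{gp17}{maximum instantaneous walking velocity}
#'   \item{gp18}{max superior acceleration in swing (in g)}
#'   \item{gp19/gp20}{heel strike to foot flat, and foot-flat duration}
#' }
#'
#' @param signal raw trial data.frame.
#' @param hs_i,to_i,hs_next stride event sample indices.
#' @param height_m subject height in metres (required for GP01/05/06).
#' @param fs sampling rate (Hz).
#' @return named numeric vector `gp01..gp20` with attribute `"raw"`
#'   (unnormalized stance/swing/double-support/foot-flat times and
#'   stride length).
#' @export
compute_gait_parameters <- function(signal, hs_i, to_i, hs_next,
                                    height_m, fs = 100) {
  if (missing(height_m) || is.null(height_m) || !is.finite(height_m))
    gf_stop("gf_config_error", "subject height is required for GP01/05/06")
  seg <- as.matrix(signal[hs_i:hs_next, GF_CHANNELS])
  L <- nrow(seg)
  dt <- 1 / fs
  dur <- (hs_next - hs_i) / fs
  stance <- (to_i - hs_i) / fs
  swing <- dur - stance
  ito <- to_i - hs_i + 1L
  i_n <- round(0.23 * ito)

  v_fwd <- gf_cumtrapz(-seg[i_n:L, "Ay"], dt)       # forward velocity, m/s
  v_max <- max(abs(v_fwd))
  stride_len <- sum((v_fwd[-1] + v_fwd[-length(v_fwd)]) / 2) * dt
  v_lat <- gf_detrend(gf_cumtrapz(seg[, "Ax"], dt))
  d_lat <- gf_detrend(gf_cumtrapz(v_lat, dt))
  v_ver <- gf_detrend(gf_cumtrapz(seg[, "Az"], dt))
  d_ver <- gf_detrend(gf_cumtrapz(v_ver, dt))

  ff_win <- max(i_n - round(0.02 * ito), 1):min(i_n + round(0.02 * ito), ito)
  gx_st <- abs(seg[seq_len(ito), "Gx"])
  thr <- max(0.05 * max(abs(seg[, "Gx"])), quantile(gx_st, 0.2))
  flat <- gx_st <= thr
  # contiguous foot-flat run containing the neutral-posture sample
  ctr <- i_n
  if (!flat[ctr]) ctr <- which(flat)[which.min(abs(which(flat) - ctr))]
  a <- ctr; while (a > 1 && flat[a - 1]) a <- a - 1
  b <- ctr; while (b < ito && flat[b + 1]) b <- b + 1
  ff_start <- (a - 1) / fs
  ff_dur <- (b - a + 1) / fs

  sw <- ito:L
  ds <- max(stance - dur / 2, 0)  # symmetric-gait double support estimate

  gp <- c(
    gp01 = stride_len / height_m,
    gp02 = stride_len / dur,
    gp03 = max(-seg[, "Ex"]),
    gp04 = max(seg[, "Ex"]),
    gp05 = max(abs(d_lat)) / height_m,
    gp06 = max(abs(d_ver)) / height_m,
    gp07 = mean(seg[ff_win, "Ez"]),
    gp08 = seg[1, "Ey"],
    gp09 = seg[ito, "Ey"],
    gp10 = 120 / dur,
    gp11 = stance / dur,
    gp12 = swing / dur,
    gp13 = ds / dur,
    gp14 = ds / dur,
    gp15 = max(seg[sw, "Gx"]) / v_max,
    gp16 = min(seg[sw, "Gx"]) / v_max,
    gp17 = v_max,
    gp18 = max(seg[sw, "Az"]) / 9.8 / v_max,
    gp19 = ff_start / dur,
    gp20 = ff_dur / dur
  )
  if (any(!is.finite(gp)))
    gf_stop("gf_degenerate_stride", "non-finite gait parameter computed")
  attr(gp, "raw") <- c(stance_time = stance, swing_time = swing,
                       duration = dur, stride_length = stride_len,
                       double_support = ds, foot_flat_start = ff_start,
                       foot_flat_dur = ff_dur)
  gp
}

# ---- trial processing and averaging -----------------------------------------

#' Process one raw trial into retained normalized strides and GPs
#'
#' Detects events, normalizes every stride, computes its gait
#' parameters, then applies [filter_strides()] (lead-in/out and outlier
#' removal, paired with the GP rows).
#'
#' @param signal raw trial data.frame.
#' @param height_m subject height in metres.
#' @param fs sampling rate.
#' @param velocity_normalize passed to [normalize_stride()].
#' @return list with `strides` (retained `gf_stride`s), `gps` (matrix,
#'   one row per retained stride), `n_detected`, `n_retained`.
#' @export
process_trial <- function(signal, height_m, fs = 100,
                          velocity_normalize = TRUE) {
  hs <- detect_heel_strikes(signal, fs)
  to <- detect_toe_offs(signal, hs)
  ns <- length(hs) - 1
  strides <- vector("list", ns)
  gps <- matrix(NA_real_, ns, 20,
                dimnames = list(NULL, sprintf("gp%02d", 1:20)))
  for (i in seq_len(ns)) {
    strides[[i]] <- normalize_stride(signal, hs[i], to[i], hs[i + 1], fs,
                                     velocity_normalize)
    gps[i, ] <- compute_gait_parameters(signal, hs[i], to[i], hs[i + 1],
                                        height_m, fs)
  }
  kept <- filter_strides(strides)
  # recover which original indices survived (match on object identity)
  keep_idx <- vapply(kept, function(s)
    which(vapply(strides, identical, NA, s))[1], 0L)
  list(strides = kept, gps = gps[keep_idx, , drop = FALSE],
       n_detected = ns, n_retained = length(kept))
}

#' Average retained strides of the left and right foot into one trial record
#'
#' Element-wise mean of the normalized grids and of the GP vectors,
#' first within each foot and then across the two feet.  If one foot
#' contributed no retained strides the other foot's average is used
#' alone, with a warning.
#'
#' @param left,right lists as returned by [process_trial()] (fields
#'   `strides`, `gps`), or `NULL`.
#' @return list with `grid` (9 x 100), `gps` (length-20 vector),
#'   `n_strides` (left/right counts).
#' @export
average_trial <- function(left, right) {
  foot_mean <- function(pr) {
    if (is.null(pr) || !length(pr$strides)) return(NULL)
    g <- Reduce(`+`, lapply(pr$strides, `[[`, "grid")) / length(pr$strides)
    list(grid = g, gps = colMeans(pr$gps), n = length(pr$strides))
  }
  l <- foot_mean(left); r <- foot_mean(right)
  if (is.null(l) && is.null(r))
    gf_stop("gf_insufficient_strides", "no retained strides on either foot")
  if (is.null(l) || is.null(r)) {
    warning("one foot has no retained strides; using single-foot average")
    one <- if (is.null(l)) r else l
    return(list(grid = one$grid, gps = one$gps,
                n_strides = c(left = if (is.null(l)) 0L else l$n,
                              right = if (is.null(r)) 0L else r$n)))
  }
  list(grid = (l$grid + r$grid) / 2, gps = (l$gps + r$gps) / 2,
       n_strides = c(left = l$n, right = r$n))
}

#' Process a whole synthetic cohort into trial averages
#'
#' Runs [process_trial()] on every trial of every subject and foot and
#' [average_trial()] across feet, yielding one row per (subject, trial):
#' the data sets entering SPM and model selection.
#'
#' @param cohort a `gf_cohort`.
#' @param velocity_normalize passed through to [normalize_stride()].
#' @return object of class `gf_trial_averages`: list with `grids`
#'   (array N x 9 x 100), `gps` (N x 20 data.frame), `meta` (subject,
#'   trial, sex, hgs and covariates per row) and a `provenance` list of
#'   per-trial stride counts.
#' @export
process_cohort <- function(cohort, velocity_normalize = TRUE) {
  stopifnot(inherits(cohort, "gf_cohort"))
  sub <- cohort$subjects
  n_rows <- nrow(sub) * cohort$spec$n_trials
  grids <- array(NA_real_, c(n_rows, 9, 100),
                 dimnames = list(NULL, GF_CHANNELS, NULL))
  gps <- matrix(NA_real_, n_rows, 20,
                dimnames = list(NULL, sprintf("gp%02d", 1:20)))
  meta <- vector("list", n_rows)
  prov <- list()
  row <- 0L
  for (s in seq_len(nrow(sub))) {
    h <- sub$height_cm[s] / 100
    for (tr in seq_len(cohort$spec$n_trials)) {
      pr <- lapply(c(left = "left", right = "right"), function(side) {
        nm <- sprintf("%s_T%d_%s", sub$id[s], tr, side)
        process_trial(cohort$trials[[nm]], h, velocity_normalize =
                        velocity_normalize)
      })
      av <- average_trial(pr$left, pr$right)
      row <- row + 1L
      grids[row, , ] <- av$grid
      gps[row, ] <- av$gps
      meta[[row]] <- data.frame(subject = sub$id[s], trial = tr,
                                sex = sub$sex[s], hgs_kg = sub$hgs_kg[s],
                                gait_speed_mps = sub$gait_speed_mps[s],
                                age = sub$age[s], height_cm = sub$height_cm[s],
                                weight_kg = sub$weight_kg[s], bmi = sub$bmi[s],
                                stringsAsFactors = FALSE)
      prov[[sprintf("%s_T%d", sub$id[s], tr)]] <-
        c(detected_left = pr$left$n_detected,
          retained_left = pr$left$n_retained,
          detected_right = pr$right$n_detected,
          retained_right = pr$right$n_retained)
    }
  }
  structure(list(grids = grids, gps = as.data.frame(gps),
                 meta = do.call(rbind, meta), provenance = prov),
            class = "gf_trial_averages")
}

#' @export
print.gf_trial_averages <- function(x, ...) {
  cat(sprintf("Trial averages: %d datasets (%d subjects x %d trials)\n",
              nrow(x$meta), length(unique(x$meta$subject)),
              max(x$meta$trial)))
  invisible(x)
}

#' Write / read trial averages as CSV (flattened grids) plus provenance JSON
#'
#' @param tavg a `gf_trial_averages`.
#' @param path output directory.
#' @return `write_trial_averages` returns `path` invisibly;
#'   `read_trial_averages` reconstructs the object (without provenance
#'   counts if the sidecar is absent).
#' @export
write_trial_averages <- function(tavg, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  N <- nrow(tavg$meta)
  flat <- matrix(aperm(tavg$grids, c(1, 3, 2)), nrow = N)  # channel-major
  colnames(flat) <- as.vector(t(outer(GF_CHANNELS, 1:100, paste, sep = "_")))
  df <- cbind(tavg$meta, round(as.data.frame(flat), 8),
              round(tavg$gps, 8))
  write.csv(df, file.path(path, "trial_averages.csv"), row.names = FALSE)
  jsonlite::write_json(tavg$provenance,
                       file.path(path, "processing_provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trial_averages
#' @export
read_trial_averages <- function(path) {
  f <- file.path(path, "trial_averages.csv")
  if (!file.exists(f)) gf_stop("gf_parse_error", "missing %s", f)
  df <- read.csv(f, stringsAsFactors = FALSE)
  meta_cols <- c("subject", "trial", "sex", "hgs_kg", "gait_speed_mps",
                 "age", "height_cm", "weight_kg", "bmi")
  grid_cols <- as.vector(t(outer(GF_CHANNELS, 1:100, paste, sep = "_")))
  gp_cols <- sprintf("gp%02d", 1:20)
  if (!all(c(meta_cols, grid_cols, gp_cols) %in% names(df)))
    gf_stop("gf_parse_error", "trial_averages.csv: missing columns")
  N <- nrow(df)
  grids <- aperm(array(as.matrix(df[, grid_cols]), c(N, 100, 9)), c(1, 3, 2))
  dimnames(grids) <- list(NULL, GF_CHANNELS, NULL)
  pfile <- file.path(path, "processing_provenance.json")
  prov <- if (file.exists(pfile))
    jsonlite::read_json(pfile, simplifyVector = TRUE) else list()
  structure(list(grids = grids, gps = df[, gp_cols], meta = df[, meta_cols],
                 provenance = prov), class = "gf_trial_averages")
}
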