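#' Population norms for grip strength and gait speed
#'
#' Reference means and standard deviations used to standardize grip
#' strength (sex-specific) and gait speed (sex-pooled) in older Asian
#' adults.  The defaults are large-sample population values: HGS 34.7
#' (7.1) kg for males, 21.9 (4.8) kg for females, and gait speed 1.29
#' (0.24) m/s for both sexes.
#'
#' @param hgs_male,hgs_female numeric length-2 `c(mean, sd)` in kg.
#' @param gait_speed numeric length-2 `c(mean, sd)` in m/s.
#' @return An object of class `gf_norms`.
#' @export
#' @examples
#' population_norms()
population_norms <- function(hgs_male = c(34.7, 7.1),
                             hgs_female = c(21.9, 4.8),
                             gait_speed = c(1.29, 0.24)) {
  for (v in list(hgs_male, hgs_female, gait_speed)) {
    if (length(v) != 2 || !all(is.finite(v)) || v[2] <= 0)
      gf_stop("gf_bad_norms", "norms must be c(mean, sd) with sd > 0")
  }
  structure(list(hgs_male = unname(hgs_male),
                 hgs_female = unname(hgs_female),
                 gait_speed = unname(gait_speed)),
            class = "gf_norms")
}

#' Z-scores of grip strength and gait speed against population norms
#'
#' @param hgs grip strength in kg (vectorized).
#' @param gs gait speed in m/s (vectorized).
#' @param sex `"male"` or `"female"` (recycled against `hgs`).
#' @param norms a [population_norms()] object.
#' @return list with components `Z_HGS` and `Z_GS`.
#' @export
#' @examples
#' z_scores(34.7, 1.53, "male")  # Z_HGS = 0, Z_GS = 1
z_scores <- function(hgs, gs, sex, norms = population_norms()) {
  stopifnot(inherits(norms, "gf_norms"))
  sex <- rep_len(as.character(sex), length(hgs))
  if (!all(sex %in% c("male", "female")))
    gf_stop("gf_bad_sex", "sex must be 'male' or 'female'")
  mu <- ifelse(sex == "male", norms$hgs_male[1], norms$hgs_female[1])
  sg <- ifelse(sex == "male", norms$hgs_male[2], norms$hgs_female[2])
  list(Z_HGS = (hgs - mu) / sg,
       Z_GS  = (gs - norms$gait_speed[1]) / norms$gait_speed[2])
}

#' Cumulative-normal performance score
#'
#' Maps a Z-score to the cumulative percentage of the standard normal
#' distribution, i.e. the percentile of the population performing worse.
#'
#' @param z finite Z-score (vectorized).
#' @param scale `"percent"` (0-100, default) or `"unit"` (0-1).
#' @return performance score on the requested scale.
#' @export
#' @examples
#' performance_score(0)    # 50
#' performance_score(1)    # 84.13
performance_score <- function(z, scale = c("percent", "unit")) {
  scale <- match.arg(scale)
  if (any(!is.finite(z))) gf_stop("gf_bad_z", "Z-scores must be finite")
  p <- pnorm(z)
  if (scale == "percent") 100 * p else p
}

#' Analog frailty risk score
#'
#' Equal-weight mean of the grip-strength and gait-speed performance
#' scores, reflecting the equal weight the two criteria carry in the
#' J-CHS frailty assessment.  Higher values indicate better performance
#' (lower frailty risk).
#'
#' @param p_hgs,p_gs performance scores in `[0, 100]` (vectorized).
#' @return `(p_hgs + p_gs) / 2`.
#' @export
frailty_risk <- function(p_hgs, p_gs) {
  if (any(p_hgs < 0 | p_hgs > 100 | p_gs < 0 | p_gs > 100, na.rm = TRUE) ||
      any(!is.finite(p_hgs)) || any(!is.finite(p_gs)))
    gf_stop("gf_bad_score", "performance scores must lie in [0, 100]")
  (p_hgs + p_gs) / 2
}

#' Score the revised J-CHS frailty questionnaire
#'
#' Four questionnaire items plus instrumented criteria: one point for a
#' "yes" on Q1 (weight loss) or Q2 (exhaustion); one point if both Q3 and
#' Q4 (exercise habit items) are "no"; one point if grip strength falls
#' below the sex-specific cut-off (28 kg male / 18 kg female); one point
#' if gait speed is below 1.0 m/s.  Scores 0, 1-2 and >2 map to
#' "Robust", "Pre-frail" and "Frail".
#'
#' @param q1,q2,q3,q4 logical answers (`TRUE` = yes).
#' @param hgs grip strength in kg.
#' @param gs gait speed in m/s.
#' @param sex `"male"` or `"female"`.
#' @return list with `score` (0-5) and `category`.
#' @export
#' @examples
#' jchs_score(FALSE, FALSE, TRUE, TRUE, hgs = 30, gs = 1.2, sex = "male")
jchs_score <- function(q1, q2, q3, q4, hgs, gs, sex) {
  args <- list(q1, q2, q3, q4, hgs, gs, sex)
  if (any(vapply(args, function(a) length(a) != 1 || is.na(a), logical(1))))
    gf_stop("gf_missing_answer", "all J-CHS inputs must be single non-missing values")
  if (!sex %in% c("male", "female"))
    gf_stop("gf_bad_sex", "sex must be 'male' or 'female'")
  pts <- as.integer(q1) + as.integer(q2) + as.integer(!q3 && !q4)
  hgs_cut <- if (sex == "male") 28 else 18
  pts <- pts + as.integer(hgs < hgs_cut) + as.integer(gs < 1.0)
  category <- if (pts == 0) "Robust" else if (pts <= 2) "Pre-frail" else "Frail"
  list(score = pts, category = category)
}

#' Frailty scores for a table of subjects
#'
#' Convenience wrapper applying [z_scores()], [performance_score()] and
#' [frailty_risk()] row-wise.
#'
#' @param hgs,gs,sex vectors (see [z_scores()]).
#' @param norms a [population_norms()] object.
#' @param scale passed to [performance_score()].
#' @return data.frame with `Z_HGS`, `Z_GS`, `P_HGS`, `P_GS`, `P_fr` and a
#'   `scale` attribute recording the score scale in use.
#' @export
frailty_scores <- function(hgs, gs, sex, norms = population_norms(),
                           scale = c("percent", "unit")) {
  scale <- match.arg(scale)
  z <- z_scores(hgs, gs, sex, norms)
  p_hgs <- performance_score(z$Z_HGS, scale)
  p_gs <- performance_score(z$Z_GS, scale)
  mult <- if (scale == "percent") 1 else 100
  out <- data.frame(Z_HGS = z$Z_HGS, Z_GS = z$Z_GS,
                    P_HGS = p_hgs, P_GS = p_gs,
                    P_fr = frailty_risk(p_hgs * mult, p_gs * mult) / mult)
  attr(out, "scale") <- scale
  out
}
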