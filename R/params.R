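#' Published per-child sitting counts
#'
#' The per-child mean accelerometer counts (counts per minute) recorded
#' during the seated computer-game activity of the calibration study this
#' package models: 35 children with all-zero series, fourteen small
#' positive values, and three large outlying values. This vector anchors
#' both the sedentary 100-cpm threshold and the zero-inflated sitting
#' generator.
#'
#' @return Numeric vector of 52 counts-per-minute values, sorted ascending.
#' @examples
#' adjusted_boxplot_outliers(reference_sitting_counts())
#' @export
reference_sitting_counts <- function() {
  c(
    rep(0, 35),
    1.5, 3.0, 3.0, 3.0, 4.5, 5.5, 5.5, 6.0, 10.5, 11.0, 11.0,
    71.5, 94.5, 96.5,
    251.0, 292.5, 483.0
  )
}

#' Default per-activity generator parameters
#'
#' One row per protocol activity, holding the class means and standard
#' deviations (across children) of counts per minute and energy
#' expenditure, the zero-inflation fraction for the two sedentary
#' activities, the within-child epoch-stability target (an intraclass
#' correlation), and the child-level correlation between count level and
#' energy expenditure.
#'
#' Count and energy-expenditure means/SDs are the published class summaries
#' of the calibration sample. Sedentary activities have no published count
#' mean; their counts come from a zero-inflated mixture calibrated to
#' [reference_sitting_counts()] (see [sitting_mixture_params()]).
#'
#' @return A tibble with columns `activity`, `intensity`, `mean_cpm`,
#'   `sd_cpm`, `mean_ee`, `sd_ee`, `zero_fraction`, `icc_target`,
#'   `ee_count_corr`.
#' @export
default_activity_params <- function() {
  tibble(
    activity = c(
      "lying", "sitting", "slow_walk", "brisk_walk", "jog",
      "hopscotch", "basketball"
    ),
    intensity = c(
      "sedentary", "sedentary", "light", "moderate", "vigorous",
      "vigorous", "vigorous"
    ),
    mean_cpm = c(NA, NA, 1592, 2879, 4835, 4299, 3301),
    sd_cpm = c(NA, NA, 783, 1042, 1424, 1162, 1079),
    mean_ee = c(2.01, 2.25, 4.74, 6.50, 10.59, 8.96, 10.67),
    sd_ee = c(0.54, 0.74, 1.06, 1.51, 1.58, 1.31, 1.98),
    zero_fraction = c(0.62, 0.66, 0, 0, 0, 0, 0),
    icc_target = c(0.85, 0.85, 0.80, 0.85, 0.90, 0.77, 0.80),
    ee_count_corr = c(0, 0, 0.6, 0.6, 0.2, 0.5, 0.5)
  )
}

#' Sedentary sitting-count mixture parameters
#'
#' The non-zero part of the sedentary count distribution is modelled as a
#' two-component log-normal mixture: a body of small values and a rare
#' outlier component, with weights and log-scale moments calibrated to the
#' published sitting vector (14 small and 3 outlying values among 17
#' non-zero children).
#'
#' @return Named list with `outlier_prob`, `body_meanlog`, `body_sdlog`,
#'   `outlier_meanlog`, `outlier_sdlog`.
#' @export
sitting_mixture_params <- function() {
  v <- reference_sitting_counts()
  body <- v[v > 0 & v < 200]
  out <- v[v >= 200]
  list(
    outlier_prob = length(out) / (length(body) + length(out)),
    body_meanlog = mean(log(body)),
    body_sdlog = sd(log(body)),
    outlier_meanlog = mean(log(out)),
    outlier_sdlog = sd(log(out))
  )
}

#' Default cohort anthropometry parameters
#'
#' Means and SDs of height and weight of the calibration sample (ages 7-8),
#' the assumed height-weight correlation, and the morning/afternoon session
#' split.
#'
#' @return Named list with `height_mean_cm`, `height_sd_cm`,
#'   `weight_mean_kg`, `weight_sd_kg`, `hw_corr`, `age_min`, `age_max`,
#'   `morning_fraction`.
#' @export
default_anthro_params <- function() {
  list(
    height_mean_cm = 132.9,
    height_sd_cm = 6.5,
    weight_mean_kg = 31.3,
    weight_sd_kg = 6.8,
    hw_corr = 0.7,
    age_min = 7,
    age_max = 8,
    morning_fraction = 39 / 53
  )
}

#' Schofield BMR prediction coefficients (ages 3-10)
#'
#' Sex-specific weight-and-height Schofield equations predicting basal
#' metabolic rate in MJ per day for children aged 3-10:
#' `bmr = weight_coef * W + height_coef * H + intercept` with weight in kg
#' and height in metres.
#'
#' @return A tibble with columns `sex`, `weight_coef`, `height_coef`,
#'   `intercept`, `age_min`, `age_max`.
#' @export
schofield_coefficients <- function() {
  tibble(
    sex = c("male", "female"),
    weight_coef = c(0.082, 0.071),
    height_coef = c(0.545, 0.677),
    intercept = c(1.736, 1.553),
    age_min = 3,
    age_max = 10
  )
}

#' Kilocalories per litre of oxygen
#'
#' Caloric equivalent used to convert oxygen uptake to energy expenditure.
#' @return 4.825 (kcal per litre O2).
#' @export
kcal_per_litre_o2 <- function() 4.825

#' Kilocalories per megajoule
#'
#' Thermochemical conversion used when expressing Schofield-predicted BMR
#' (MJ/day) in kilocalories.
#' @return 239.006 (kcal per MJ).
#' @export
kcal_per_mj <- function() 239.006

#' Study configuration
#'
#' Bundles every tunable of the synthetic study and downstream analysis
#' into one validated list: cohort size and composition, anthropometry,
#' per-activity generator parameters, epoch and oxygen-uptake sampling
#' settings, activity durations, analysis windows, and the thresholding
#' options used at calibration time.
#'
#' @param n_children Number of children in the cohort.
#' @param n_male Number of male children.
#' @param anthro Anthropometry parameters, see [default_anthro_params()].
#' @param activities Per-activity parameters, see
#'   [default_activity_params()].
#' @param epoch_length_s Accelerometer epoch length in seconds (must divide
#'   60).
#' @param vo2_interval_s Spacing of oxygen-uptake records in seconds.
#' @param vo2_tau_s Time constant of the rise-to-plateau oxygen-uptake
#'   profile in seconds.
#' @param lying_duration_s Duration of the lying activity in seconds.
#' @param activity_duration_s Duration of every other activity in seconds.
#' @param grubbs_alpha Significance level for iterative Grubbs outlier
#'   removal.
#' @param normality_alpha Significance level of the Shapiro-Wilk gate that
#'   chooses between Pearson and Spearman correlation.
#' @param round_to Rounding grain (cpm) of the sedentary threshold.
#' @param boundary_round Rounding grain (cpm) applied to the two
#'   discriminant boundaries; `NULL` keeps them unrounded.
#' @param prior `"observed"` (class frequencies) or `"equal"` priors for
#'   the discriminant fit.
#' @param csv_digits Decimal places used when writing CSV output.
#' @return A list of class `accelcal_config`.
#' @export
study_config <- function(n_children = 53,
                         n_male = 29,
                         anthro = default_anthro_params(),
                         activities = default_activity_params(),
                         epoch_length_s = 15,
                         vo2_interval_s = 5,
                         vo2_tau_s = 30,
                         lying_duration_s = 1800,
                         activity_duration_s = 300,
                         grubbs_alpha = 0.05,
                         normality_alpha = 0.05,
                         round_to = 100,
                         boundary_round = 10,
                         prior = c("observed", "equal"),
                         csv_digits = 3) {
  prior <- match.arg(prior)
  cfg <- list(
    n_children = n_children, n_male = n_male, anthro = anthro,
    activities = activities, epoch_length_s = epoch_length_s,
    vo2_interval_s = vo2_interval_s, vo2_tau_s = vo2_tau_s,
    lying_duration_s = lying_duration_s,
    activity_duration_s = activity_duration_s,
    grubbs_alpha = grubbs_alpha, normality_alpha = normality_alpha,
    round_to = round_to, boundary_round = boundary_round, prior = prior,
    csv_digits = csv_digits
  )
  class(cfg) <- "accelcal_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_children < 0) abort("`n_children` must be non-negative.")
  if (cfg$n_male < 0 || cfg$n_male > cfg$n_children) {
    abort("`n_male` must lie in [0, n_children].")
  }
  if (60 %% cfg$epoch_length_s != 0) {
    abort("`epoch_length_s` must divide 60.")
  }
  if (cfg$activity_duration_s < cfg$epoch_length_s) {
    abort("`activity_duration_s` is shorter than one epoch.")
  }
  act <- cfg$activities
  check_columns(act, c(
    "activity", "intensity", "mean_cpm", "sd_cpm", "mean_ee", "sd_ee",
    "zero_fraction", "icc_target", "ee_count_corr"
  ), "`activities`")
  sed <- act$zero_fraction > 0
  if (any(act$zero_fraction < 0 | act$zero_fraction > 1)) {
    abort("`zero_fraction` must lie in [0, 1].")
  }
  if (any(!sed & (is.na(act$sd_cpm) | act$sd_cpm < 0))) {
    abort("Non-sedentary activities need `sd_cpm` >= 0.")
  }
  if (any(act$sd_ee < 0)) abort("`sd_ee` must be >= 0.")
  if (any(act$icc_target <= 0 | act$icc_target >= 1)) {
    abort("`icc_target` must lie strictly within (0, 1).")
  }
  if (any(abs(act$ee_count_corr) > 1)) {
    abort("`ee_count_corr` must lie in [-1, 1].")
  }
  an <- cfg$anthro
  if (an$height_sd_cm < 0 || an$weight_sd_kg < 0) {
    abort("Anthropometry SDs must be >= 0.")
  }
  if (abs(an$hw_corr) > 1) abort("`hw_corr` must lie in [-1, 1].")
  invisible(cfg)
}
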