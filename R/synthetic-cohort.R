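#' Generate a synthetic cohort of children
#'
#' Draws anthropometrics for a cohort of 7-8-year-olds: height and weight
#' from a correlated bivariate normal truncated to positive values, age
#' uniform over the study band, a fixed number of male profiles, and a
#' morning/afternoon session assignment matching the configured split.
#'
#' @param n_children Number of children.
#' @param n_male Number of male children (`0 <= n_male <= n_children`).
#' @param anthro Anthropometry parameters, see [default_anthro_params()].
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `child_id`, `sex`, `age_years`,
#'   `height_cm`, `weight_kg`, `session`.
#' @examples
#' generate_cohort(5, 3, seed = 1)
#' @export
generate_cohort <- function(n_children = 53, n_male = 29,
                            anthro = default_anthro_params(),
                            seed = NULL) {
  if (n_children < 0) abort("`n_children` must be non-negative.")
  if (n_male < 0 || n_male > n_children) {
    abort("`n_male` must lie in [0, n_children].")
  }
  if (anthro$height_sd_cm < 0 || anthro$weight_sd_kg < 0) {
    abort("Anthropometry SDs must be >= 0.")
  }
  with_seed(seed, {
    n <- as.integer(n_children)
    if (n == 0L) {
      return(tibble(
        child_id = character(), sex = character(), age_years = numeric(),
        height_cm = numeric(), weight_kg = numeric(), session = character()
      ))
    }
    z <- rnorm_pair(n, anthro$hw_corr)
    height <- anthro$height_mean_cm + anthro$height_sd_cm * z[, 1]
    weight <- anthro$weight_mean_kg + anthro$weight_sd_kg * z[, 2]
    # redraw the (rare) non-positive pairs, preserving the correlation
    bad <- height <= 0 | weight <= 0
    iter <- 0L
    while (any(bad)) {
      iter <- iter + 1L
      if (iter > 1000L) abort("Impossible truncation bounds for anthropometry.")
      z2 <- rnorm_pair(sum(bad), anthro$hw_corr)
      height[bad] <- anthro$height_mean_cm + anthro$height_sd_cm * z2[, 1]
      weight[bad] <- anthro$weight_mean_kg + anthro$weight_sd_kg * z2[, 2]
      bad <- height <= 0 | weight <= 0
    }
    n_morning <- round(n * anthro$morning_fraction)
    tibble(
      child_id = sprintf("c%03d", seq_len(n)),
      sex = rep(c("male", "female"), c(n_male, n - n_male)),
      age_years = runif(n, anthro$age_min, anthro$age_max),
      height_cm = height,
      weight_kg = weight,
      session = rep(c("morning", "afternoon"), c(n_morning, n - n_morning))
    )
  })
}

# Variance decomposition behind the epoch generator: per-epoch values (on
# the cpm scale) split into a child-level effect and epoch noise such that
# (a) the within-child ICC over epochs equals `icc` and (b) the per-child
# mean over `k` epochs has SD `sd_mean` across children.
epoch_variance_components <- function(sd_mean, icc, k) {
  total <- k * sd_mean^2 / ((k - 1) * icc + 1)
  c(between = icc * total, within = (1 - icc) * total)
}

#' Generate an epoch-level accelerometer count series
#'
#' For locomotor and games activities, per-epoch counts (expressed on the
#' counts-per-minute scale) are a child-level Gaussian effect plus epoch
#' noise, with the variance split chosen so that the per-child 2-minute
#' mean is distributed `Normal(mean_cpm, sd_cpm)` across children while the
#' within-child epoch ICC matches `icc_target`. Values are clipped at zero
#' and rounded half-up to integer counts per epoch.
#'
#' For sedentary activities (`zero_fraction > 0`) a zero-inflated model is
#' used instead: with probability `zero_fraction` the whole series is zero;
#' otherwise a child-level count rate is drawn from the log-normal mixture
#' of [sitting_mixture_params()] and epoch counts are Poisson at that rate.
#'
#' @param child_id Identifier recorded on every row.
#' @param params One row of [default_activity_params()] (or a list with the
#'   same fields).
#' @param duration_s Series duration in seconds.
#' @param epoch_length_s Epoch length in seconds (divides 60).
#' @param seed Optional seed.
#' @param child_z Optional pre-drawn standard-normal child effect, used by
#'   [generate_study()] to correlate counts with oxygen uptake.
#' @param mixture Sedentary mixture parameters, see
#'   [sitting_mixture_params()].
#' @return A tibble with columns `child_id`, `activity`, `epoch_index`,
#'   `epoch_length_s`, `start_offset_s`, `counts`.
#' @export
generate_epoch_counts <- function(child_id, params, duration_s = 300,
                                  epoch_length_s = 15, seed = NULL,
                                  child_z = NULL,
                                  mixture = sitting_mixture_params()) {
  params <- as.list(params)
  if (duration_s < epoch_length_s) {
    abort("`duration_s` must cover at least one epoch.")
  }
  if (params$zero_fraction == 0 &&
      (params$icc_target <= 0 || params$icc_target >= 1)) {
    abort("`icc_target` must lie strictly within (0, 1).")
  }
  with_seed(seed, {
    n_epochs <- floor(duration_s / epoch_length_s)
    scale <- epoch_length_s / 60
    if (params$zero_fraction > 0) {
      # zero-inflated sedentary model
      if (runif(1) < params$zero_fraction) {
        counts <- rep(0L, n_epochs)
      } else {
        rate_cpm <- if (runif(1) < mixture$outlier_prob) {
          stats::rlnorm(1, mixture$outlier_meanlog, mixture$outlier_sdlog)
        } else {
          stats::rlnorm(1, mixture$body_meanlog, mixture$body_sdlog)
        }
        counts <- rpois(n_epochs, rate_cpm * scale)
      }
    } else {
      vc <- epoch_variance_components(params$sd_cpm, params$icc_target,
                                      k = 120 / epoch_length_s)
      z <- child_z %||% rnorm(1)
      child_cpm <- params$mean_cpm + sqrt(vc[["between"]]) * z
      epoch_cpm <- child_cpm + sqrt(vc[["within"]]) * rnorm(n_epochs)
      counts <- as.integer(round_half_up(pmax(epoch_cpm, 0) * scale))
    }
    tibble(
      child_id = child_id,
      activity = params$activity,
      epoch_index = seq_len(n_epochs),
      epoch_length_s = epoch_length_s,
      start_offset_s = (seq_len(n_epochs) - 1) * epoch_length_s,
      counts = as.integer(counts)
    )
  })
}

#' Generate an oxygen-uptake series
#'
#' Oxygen uptake follows a smooth rise-to-plateau profile
#' `vo2(t) = plateau * (1 - exp(-t / tau))`, the standard mono-exponential
#' kinetics of the onset of steady-state exercise. The plateau, expressed
#' as energy expenditure, is distributed `Normal(mean_ee, sd_ee)` across
#' children (clipped at zero); a shared child effect lets
#' [generate_study()] correlate it with the same child's count level.
#'
#' @param child_id Identifier recorded on every row.
#' @param params One row of [default_activity_params()].
#' @param duration_s Series duration in seconds.
#' @param interval_s Record spacing in seconds.
#' @param tau_s Rise time constant in seconds; `0` gives a flat series at
#'   the plateau.
#' @param seed Optional seed.
#' @param child_z Optional pre-drawn standard-normal effect for the
#'   plateau.
#' @return A tibble with columns `child_id`, `activity`, `time_s`,
#'   `vo2_ml_kg_min`, plus attribute-free plateau column `plateau_ee` is
#'   not stored; recover it via the final records.
#' @export
generate_vo2 <- function(child_id, params, duration_s = 300,
                         interval_s = 5, tau_s = 30, seed = NULL,
                         child_z = NULL) {
  params <- as.list(params)
  if (duration_s <= 0) abort("`duration_s` must be positive.")
  with_seed(seed, {
    z <- child_z %||% rnorm(1)
    plateau_ee <- max(params$mean_ee + params$sd_ee * z, 0)
    plateau_vo2 <- ee_to_vo2(plateau_ee)
    times <- seq(interval_s, duration_s, by = interval_s)
    profile <- if (tau_s <= 0) 1 else 1 - exp(-times / tau_s)
    tibble(
      child_id = child_id,
      activity = params$activity,
      time_s = times,
      vo2_ml_kg_min = plateau_vo2 * profile
    )
  })
}

#' Generate a complete synthetic study
#'
#' Produces the three tables of a full laboratory session for every child:
#' anthropometrics, epoch-level counts, and oxygen-uptake records for all
#' seven activities (30 minutes lying, 5 minutes each otherwise). Count
#' and oxygen-uptake child effects are drawn jointly with correlation
#' `ee_count_corr`, so children who move more also burn more energy.
#'
#' @param config Study configuration from [study_config()].
#' @param seed Optional integer seed; fixing it makes the whole study
#'   byte-reproducible.
#' @return A list of class `accelcal_study` with tibbles `anthro`,
#'   `epochs`, `vo2` and the `config` used.
#' @examples
#' study <- generate_study(study_config(n_children = 4, n_male = 2), seed = 1)
#' dplyr::count(study$epochs, activity)
#' @export
generate_study <- function(config = study_config(), seed = NULL) {
  validate_config(config)
  with_seed(seed, {
    cohort <- generate_cohort(config$n_children, config$n_male,
                              config$anthro)
    acts <- config$activities
    mixture <- sitting_mixture_params()
    epochs_list <- list()
    vo2_list <- list()
    for (i in seq_len(nrow(cohort))) {
      for (j in seq_len(nrow(acts))) {
        p <- acts[j, ]
        dur <- if (p$activity == "lying") config$lying_duration_s else
          config$activity_duration_s
        z <- rnorm_pair(1, p$ee_count_corr)
        epochs_list[[length(epochs_list) + 1L]] <- generate_epoch_counts(
          cohort$child_id[i], p, dur,
          epoch_length_s = config$epoch_length_s,
          child_z = z[1, 1], mixture = mixture
        )
        vo2_list[[length(vo2_list) + 1L]] <- generate_vo2(
          cohort$child_id[i], p, dur,
          interval_s = config$vo2_interval_s, tau_s = config$vo2_tau_s,
          child_z = z[1, 2]
        )
      }
    }
    epochs <- if (length(epochs_list)) bind_rows(epochs_list) else
      tibble(child_id = character(), activity = character(),
             epoch_index = integer(), epoch_length_s = numeric(),
             start_offset_s = numeric(), counts = integer())
    vo2 <- if (length(vo2_list)) bind_rows(vo2_list) else
      tibble(child_id = character(), activity = character(),
             time_s = numeric(), vo2_ml_kg_min = numeric())
    structure(
      list(anthro = cohort, epochs = epochs, vo2 = vo2, config = config),
      class = "accelcal_study"
    )
  })
}

#' Write a synthetic study to CSV files
#'
#' Writes `anthro.csv`, `epochs.csv` and `vo2.csv` into `dir`, with floats
#' formatted at the configured number of decimal places so repeated runs
#' under the same seed are byte-identical.
#'
#' @param study Result of [generate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "accelcal_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  digits <- study$config$csv_digits
  fmt <- function(df) {
    for (nm in names(df)) {
      if (is.double(df[[nm]])) {
        df[[nm]] <- formatC(df[[nm]], digits = digits, format = "f")
      }
    }
    df
  }
  paths <- c(
    anthro = file.path(dir, "anthro.csv"),
    epochs = file.path(dir, "epochs.csv"),
    vo2 = file.path(dir, "vo2.csv")
  )
  readr::write_csv(fmt(study$anthro), paths[["anthro"]])
  readr::write_csv(
    fmt(study$epochs[, c("child_id", "activity", "epoch_index",
                         "epoch_length_s", "counts")]),
    paths[["epochs"]]
  )
  readr::write_csv(fmt(study$vo2), paths[["vo2"]])
  invisible(paths)
}
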