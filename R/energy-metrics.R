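#' Analysis window bounds for an activity
#'
#' The 2-minute steady-state sampling window: minutes 2.5-4.5 of each
#' activity bout, except lying where minutes 22.5-24.5 are used so the
#' child has fully settled. Windows are half-open `[start, end)` in
#' seconds from the start of the bout.
#'
#' @param activity Activity name.
#' @return Numeric vector `c(start_s, end_s)`.
#' @export
window_bounds <- function(activity) {
  if (identical(activity, "lying")) c(22.5 * 60, 24.5 * 60) else
    c(2.5 * 60, 4.5 * 60)
}

#' Restrict series to their steady-state analysis window
#'
#' Keeps the records of each child-by-activity series that fall inside the
#' activity's sampling window (see [window_bounds()]). Epoch rows are
#' assigned to the window by their start time (`start_offset_s`, computed
#' from `epoch_index` if absent); oxygen-uptake rows by their record time
#' `time_s`. Series that do not cover the whole window raise an
#' "incomplete window" error naming the child and activity.
#'
#' @param series A tibble of epoch counts (columns `child_id`, `activity`,
#'   `epoch_index`, `epoch_length_s`, `counts`) or oxygen-uptake records
#'   (columns `child_id`, `activity`, `time_s`, `vo2_ml_kg_min`).
#' @return The input restricted to window rows, same columns.
#' @export
extract_window <- function(series) {
  is_epoch <- "counts" %in% names(series)
  if (is_epoch) {
    check_columns(series, c("child_id", "activity", "epoch_index",
                            "epoch_length_s", "counts"), "epoch series")
    if (!"start_offset_s" %in% names(series)) {
      series <- mutate(series,
        start_offset_s = (.data$epoch_index - 1) * .data$epoch_length_s)
    }
  } else {
    check_columns(series, c("child_id", "activity", "time_s",
                            "vo2_ml_kg_min"), "oxygen-uptake series")
  }
  time_col <- if (is_epoch) "start_offset_s" else "time_s"
  grouped <- dplyr::group_split(group_by(series, .data$child_id,
                                         .data$activity))
  out <- purrr::map(grouped, function(g) {
    w <- window_bounds(g$activity[[1]])
    t <- g[[time_col]]
    step <- if (is_epoch) g$epoch_length_s[[1]] else min(diff(sort(unique(t))))
    covered <- min(t) <= w[1] && max(t) + (if (is_epoch) step else 0) >= w[2] - 1e-9
    if (!covered) {
      abort(sprintf(
        "incomplete window: series for child '%s', activity '%s' does not cover [%g, %g) s",
        g$child_id[[1]], g$activity[[1]], w[1], w[2]
      ))
    }
    g[t >= w[1] & t < w[2], , drop = FALSE]
  })
  bind_rows(out)
}

#' Counts per minute from a windowed epoch series
#'
#' Implements the sum-then-mean reduction: epoch counts are summed within
#' each whole minute of the window (four 15-second epochs per minute) and
#' the per-minute sums are averaged, yielding one mean counts-per-minute
#' value. The window must contain a whole number of minutes (8 epochs for
#' the standard 2-minute window at 15-second epochs).
#'
#' @param window Epoch rows for a single child and activity, in time
#'   order, as returned by [extract_window()].
#' @return A single counts-per-minute value.
#' @examples
#' w <- tibble::tibble(
#'   child_id = "c1", activity = "slow_walk", epoch_index = 1:8,
#'   epoch_length_s = 15, counts = c(0, 0, 0, 0, 100, 100, 100, 100)
#' )
#' epochs_to_cpm(w) # mean of minute sums 0 and 400
#' @export
epochs_to_cpm <- function(window) {
  check_columns(window, c("epoch_length_s", "counts"), "epoch window")
  epoch_len <- window$epoch_length_s[[1]]
  per_min <- 60 / epoch_len
  if (per_min != round(per_min)) abort("Epoch length must divide 60.")
  n <- nrow(window)
  if (n %% per_min != 0) {
    abort("Window must contain a whole number of minutes of epochs.")
  }
  minute <- rep(seq_len(n / per_min), each = per_min)
  mean(tapply(window$counts, minute, sum))
}

#' Convert oxygen uptake to energy expenditure
#'
#' `EE = vo2 * 60 * 4.825 / 1000`: millilitres of oxygen per kg per minute
#' to kilocalories per kg per hour at the caloric equivalent of
#' [kcal_per_litre_o2()].
#'
#' @param vo2_ml_kg_min Oxygen uptake in ml O2 per kg per minute (>= 0).
#' @return Energy expenditure in kcal per kg per hour.
#' @examples
#' vo2_to_ee(5.46) # ~1.58, the cohort's mean predicted BMR
#' @export
vo2_to_ee <- function(vo2_ml_kg_min) {
  if (any(vo2_ml_kg_min < 0, na.rm = TRUE)) {
    abort("Oxygen uptake must be non-negative.")
  }
  vo2_ml_kg_min * 60 * kcal_per_litre_o2() / 1000
}

#' Inverse of [vo2_to_ee()]
#'
#' @param ee_kcal_kg_hr Energy expenditure in kcal per kg per hour (>= 0).
#' @return Oxygen uptake in ml O2 per kg per minute.
#' @export
ee_to_vo2 <- function(ee_kcal_kg_hr) {
  if (any(ee_kcal_kg_hr < 0, na.rm = TRUE)) {
    abort("Energy expenditure must be non-negative.")
  }
  ee_kcal_kg_hr * 1000 / (60 * kcal_per_litre_o2())
}

#' Schofield-predicted basal metabolic rate
#'
#' Applies the sex-specific Schofield weight-and-height equations for ages
#' 3-10 (see [schofield_coefficients()]) to each child, returning the
#' prediction in kcal per day and, normalised by body weight, in kcal per
#' kg per hour — the denominator of the child-specific MET.
#'
#' @param anthro Tibble with columns `child_id`, `sex`, `age_years`,
#'   `height_cm`, `weight_kg`.
#' @param coefs Coefficient table, see [schofield_coefficients()].
#' @return A tibble with columns `child_id`, `bmr_kcal_day`,
#'   `bmr_kcal_kg_hr`.
#' @examples
#' kid <- tibble::tibble(child_id = "c1", sex = "male", age_years = 7.5,
#'                       height_cm = 132.9, weight_kg = 31.3)
#' schofield_bmr(kid)
#' @export
schofield_bmr <- function(anthro, coefs = schofield_coefficients()) {
  check_columns(anthro, c("child_id", "sex", "age_years", "height_cm",
                          "weight_kg"), "anthropometry table")
  if (any(anthro$height_cm <= 0) || any(anthro$weight_kg <= 0)) {
    abort("Height and weight must be positive.")
  }
  bad_sex <- setdiff(unique(anthro$sex), coefs$sex)
  if (length(bad_sex)) {
    abort(sprintf("Unknown sex value(s): %s", paste(bad_sex, collapse = ", ")))
  }
  joined <- left_join(anthro, coefs, by = "sex")
  out_of_band <- joined$age_years < joined$age_min |
    joined$age_years > joined$age_max
  if (any(out_of_band)) {
    abort(sprintf(
      "Age outside the %g-%g y Schofield band for child(ren): %s",
      coefs$age_min[[1]], coefs$age_max[[1]],
      paste(joined$child_id[out_of_band], collapse = ", ")
    ))
  }
  mj_day <- joined$weight_coef * joined$weight_kg +
    joined$height_coef * (joined$height_cm / 100) + joined$intercept
  kcal_day <- mj_day * kcal_per_mj()
  tibble(
    child_id = joined$child_id,
    bmr_kcal_day = kcal_day,
    bmr_kcal_kg_hr = kcal_day / (joined$weight_kg * 24)
  )
}

#' MET values from energy expenditure and predicted BMR
#'
#' The child-specific MET: activity energy expenditure divided by the
#' child's predicted basal metabolic rate, both in kcal per kg per hour.
#' The adult 3.5 ml/kg/min convention is deliberately not used — resting
#' oxygen uptake in young children is substantially higher.
#'
#' @param ee_kcal_kg_hr Activity energy expenditure (>= 0).
#' @param bmr_kcal_kg_hr Predicted BMR (> 0), recycled as needed.
#' @return MET values.
#' @export
compute_mets <- function(ee_kcal_kg_hr, bmr_kcal_kg_hr) {
  if (any(bmr_kcal_kg_hr <= 0)) abort("BMR must be positive.")
  if (any(ee_kcal_kg_hr < 0)) abort("Energy expenditure must be >= 0.")
  ee_kcal_kg_hr / bmr_kcal_kg_hr
}

#' Reduce a study to per-child activity summaries
#'
#' The full data-reduction step: both streams are restricted to the
#' steady-state window, epoch counts are reduced to one mean
#' counts-per-minute value per child and activity ([epochs_to_cpm()]),
#' oxygen uptake is averaged over the window and converted to energy
#' expenditure ([vo2_to_ee()]), and METs are formed against each child's
#' Schofield-predicted BMR. Child-activity pairs present in one stream but
#' not the other are reported as an error, never silently dropped.
#'
#' @param epochs Epoch-level count tibble (see [generate_study()]).
#' @param vo2 Oxygen-uptake tibble.
#' @param anthro Anthropometry tibble.
#' @return A tibble with one row per child and activity: `child_id`,
#'   `activity`, `mean_cpm`, `ee_kcal_kg_hr`, `mets`, `n_epochs_used`.
#' @export
reduce_study <- function(epochs, vo2, anthro) {
  keys_e <- dplyr::distinct(epochs, .data$child_id, .data$activity)
  keys_v <- dplyr::distinct(vo2, .data$child_id, .data$activity)
  missing_v <- dplyr::anti_join(keys_e, keys_v,
                                by = c("child_id", "activity"))
  missing_e <- dplyr::anti_join(keys_v, keys_e,
                                by = c("child_id", "activity"))
  if (nrow(missing_v) + nrow(missing_e) > 0) {
    miss <- bind_rows(
      mutate(missing_v, stream = "vo2"),
      mutate(missing_e, stream = "epochs")
    )
    abort(c(
      "Mismatched child-activity pairs between streams:",
      sprintf("missing %s series for (%s, %s)", miss$stream, miss$child_id,
              miss$activity)
    ))
  }
  bmr <- schofield_bmr(anthro)

  epo_w <- extract_window(epochs)
  cpm <- epo_w |>
    group_by(.data$child_id, .data$activity) |>
    summarise(
      mean_cpm = epochs_to_cpm(dplyr::pick(dplyr::everything())),
      n_epochs_used = dplyr::n(),
      .groups = "drop"
    )

  vo2_w <- extract_window(vo2)
  ee <- vo2_w |>
    group_by(.data$child_id, .data$activity) |>
    summarise(ee_kcal_kg_hr = vo2_to_ee(mean(.data$vo2_ml_kg_min)),
              .groups = "drop")

  cpm |>
    left_join(ee, by = c("child_id", "activity")) |>
    left_join(bmr, by = "child_id") |>
    mutate(mets = compute_mets(.data$ee_kcal_kg_hr, .data$bmr_kcal_kg_hr)) |>
    select("child_id", "activity", "mean_cpm", "ee_kcal_kg_hr", "mets",
           "n_epochs_used") |>
    arrange(.data$child_id, .data$activity)
}
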