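# End-to-end orchestration: CSV readers with validation, the QC stage,
# and run_pipeline() tying generate -> reduce -> qc -> calibrate ->
# evaluate together with JSON/CSV artifacts.

read_validated_csv <- function(path, col_types, what) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, col_types = col_types,
                        show_col_types = FALSE)
  check_columns(df, names(col_types$cols), what)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(c(
      sprintf("Malformed rows in %s:", path),
      sprintf("line %d: %s", probs$row + 1L, probs$expected)
    ))
  }
  if (nrow(df) == 0) warn(sprintf("%s is empty (header only).", path))
  df
}

#' Read an anthropometry CSV
#'
#' Columns: `child_id`, `sex`, `age_years`, `height_cm`, `weight_kg`,
#' `session`. Non-positive heights/weights and duplicate child ids are
#' rejected with their line numbers.
#'
#' @param path CSV path.
#' @return A validated tibble.
#' @export
read_anthro <- function(path) {
  df <- read_validated_csv(path, readr::cols(
    child_id = readr::col_character(), sex = readr::col_character(),
    age_years = readr::col_double(), height_cm = readr::col_double(),
    weight_kg = readr::col_double(), session = readr::col_character()
  ), "anthropometry table")
  bad <- which(df$height_cm <= 0 | df$weight_kg <= 0)
  if (length(bad)) {
    abort(sprintf("Non-positive height/weight at line(s): %s",
                  paste(bad + 1L, collapse = ", ")))
  }
  dup <- which(duplicated(df$child_id))
  if (length(dup)) {
    abort(sprintf("Duplicate child_id at line(s): %s",
                  paste(dup + 1L, collapse = ", ")))
  }
  df
}

#' Read an epoch-level count CSV
#'
#' Columns: `child_id`, `activity`, `epoch_index`, `epoch_length_s`,
#' `counts`. Negative counts and duplicate (child, activity, epoch) keys
#' are rejected with their line numbers.
#'
#' @param path CSV path.
#' @return A validated tibble with `start_offset_s` added.
#' @export
read_epochs <- function(path) {
  df <- read_validated_csv(path, readr::cols(
    child_id = readr::col_character(), activity = readr::col_character(),
    epoch_index = readr::col_integer(),
    epoch_length_s = readr::col_double(), counts = readr::col_double()
  ), "epoch table")
  bad <- which(df$counts < 0)
  if (length(bad)) {
    abort(sprintf("Negative counts at line(s): %s",
                  paste(bad + 1L, collapse = ", ")))
  }
  dup <- which(duplicated(df[c("child_id", "activity", "epoch_index")]))
  if (length(dup)) {
    abort(sprintf("Duplicate (child, activity, epoch) at line(s): %s",
                  paste(dup + 1L, collapse = ", ")))
  }
  mutate(df, start_offset_s = (.data$epoch_index - 1) * .data$epoch_length_s)
}

#' Read an oxygen-uptake CSV
#'
#' Columns: `child_id`, `activity`, `time_s`, `vo2_ml_kg_min`. Negative
#' uptake values and non-increasing times within a series are rejected.
#'
#' @param path CSV path.
#' @return A validated tibble.
#' @export
read_vo2 <- function(path) {
  df <- read_validated_csv(path, readr::cols(
    child_id = readr::col_character(), activity = readr::col_character(),
    time_s = readr::col_double(), vo2_ml_kg_min = readr::col_double()
  ), "oxygen-uptake table")
  bad <- which(df$vo2_ml_kg_min < 0)
  if (length(bad)) {
    abort(sprintf("Negative oxygen uptake at line(s): %s",
                  paste(bad + 1L, collapse = ", ")))
  }
  nonmono <- df |>
    group_by(.data$child_id, .data$activity) |>
    summarise(ok = all(diff(.data$time_s) > 0), .groups = "drop")
  if (any(!nonmono$ok)) {
    bad_series <- nonmono[!nonmono$ok, ]
    abort(sprintf(
      "Non-increasing times in series: %s",
      paste(sprintf("(%s, %s)", bad_series$child_id, bad_series$activity),
            collapse = ", ")
    ))
  }
  df
}

#' Quality-control report for a reduced study
#'
#' Runs the statistical checks that precede calibration: per-activity
#' epoch-stability ICCs on the windowed counts, Shapiro-Wilk normality
#' verdicts and normality-gated MET-count correlations per locomotor
#' activity, iterative Grubbs outliers on brisk-walk counts,
#' adjusted-boxplot outliers on sitting counts, morning/afternoon
#' energy-expenditure comparisons, and the height-R-squared of each
#' activity. Warnings (for example a non-normal class) never abort the
#' pipeline.
#'
#' @param summaries Output of [reduce_study()].
#' @param epochs Epoch-level counts (used for the ICCs).
#' @param anthro Anthropometry table (for sessions and heights).
#' @param grubbs_alpha,normality_alpha Significance levels.
#' @return A list of class `qc_report` with elements `icc`, `normality`,
#'   `correlation`, `grubbs_brisk_walk`, `sitting_outliers`,
#'   `session_tests`, `height_r2`.
#' @export
qc_study <- function(summaries, epochs, anthro, grubbs_alpha = 0.05,
                     normality_alpha = 0.05) {
  win <- extract_window(epochs)
  icc <- win |>
    group_by(.data$activity) |>
    dplyr::group_modify(function(g, key) {
      m <- tidyr::pivot_wider(
        g[c("child_id", "epoch_index", "counts")],
        names_from = "epoch_index", values_from = "counts"
      )
      mat <- as.matrix(m[, -1])
      if (nrow(mat) < 2 || sum(var(as.vector(mat))) == 0) {
        return(tibble(estimate = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, n_subjects = nrow(mat),
                      k_measurements = ncol(mat)))
      }
      icc_oneway(mat)
    }) |>
    ungroup()

  locomotor <- c("slow_walk", "brisk_walk", "jog", "hopscotch",
                 "basketball")
  per_act <- split(summaries, summaries$activity)
  normality <- purrr::imap(per_act, function(d, act) {
    if (!(act %in% locomotor) || var(d$mean_cpm) == 0) return(NULL)
    mutate(normality_test(d$mean_cpm), activity = act)
  }) |> bind_rows()
  correlation <- purrr::imap(per_act, function(d, act) {
    if (!(act %in% locomotor) || var(d$mean_cpm) == 0) return(NULL)
    mutate(gated_correlation(d$mean_cpm, d$mets, normality_alpha),
           activity = act)
  }) |> bind_rows()

  grubbs_bw <- if ("brisk_walk" %in% names(per_act)) {
    grubbs_iterative(per_act$brisk_walk$mean_cpm, alpha = grubbs_alpha)
  }
  sitting_out <- if ("sitting" %in% names(per_act)) {
    adjusted_boxplot_outliers(per_act$sitting$mean_cpm)
  }

  with_session <- left_join(summaries,
                            anthro[c("child_id", "session", "height_cm")],
                            by = "child_id")
  session_tests <- with_session |>
    group_by(.data$activity) |>
    dplyr::group_modify(function(g, key) {
      am <- g$ee_kcal_kg_hr[g$session == "morning"]
      pm <- g$ee_kcal_kg_hr[g$session == "afternoon"]
      if (!length(am) || !length(pm)) {
        return(tibble(statistic = NA_real_, p_value = NA_real_,
                      method = "mann_whitney", n_x = length(am),
                      n_y = length(pm)))
      }
      rank_sum_test(am, pm)
    }) |>
    ungroup()
  height_r2 <- with_session |>
    group_by(.data$activity) |>
    summarise(
      r_squared = if (dplyr::n() >= 3 && var(.data$height_cm) > 0)
        height_variance_r2(.data$mean_cpm, .data$height_cm)
      else NA_real_,
      .groups = "drop"
    )

  structure(
    list(
      icc = icc, normality = normality, correlation = correlation,
      grubbs_brisk_walk = grubbs_bw, sitting_outliers = sitting_out,
      session_tests = session_tests, height_r2 = height_r2
    ),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  epoch-stability ICC range: %.2f-%.2f\n",
              min(x$icc$estimate, na.rm = TRUE),
              max(x$icc$estimate, na.rm = TRUE)))
  if (!is.null(x$grubbs_brisk_walk)) {
    cat(sprintf("  brisk-walk Grubbs outliers: %d\n",
                nrow(x$grubbs_brisk_walk)))
  }
  if (!is.null(x$sitting_outliers)) {
    cat(sprintf("  sitting adjusted-boxplot outliers: %d\n",
                nrow(x$sitting_outliers)))
  }
  invisible(x)
}

qc_as_list <- function(qc) {
  list(
    icc = qc$icc,
    normality = qc$normality,
    correlation = qc$correlation,
    grubbs_brisk_walk = if (!is.null(qc$grubbs_brisk_walk))
      as_tibble(qc$grubbs_brisk_walk),
    sitting_outliers = if (!is.null(qc$sitting_outliers))
      as_tibble(qc$sitting_outliers),
    sitting_medcouple = attr(qc$sitting_outliers, "medcouple"),
    sitting_fences = attr(qc$sitting_outliers, "fences"),
    session_tests = qc$session_tests,
    height_r2 = qc$height_r2
  )
}

#' Run the full calibration pipeline
#'
#' Executes every stage in order: synthetic-study generation (or reading
#' user-supplied CSVs), data reduction, quality control, cut-point
#' calibration, and ROC evaluation. With `out_dir` set, all intermediate
#' artifacts are written (`anthro.csv`, `epochs.csv`, `vo2.csv`,
#' `summaries.csv`, `qc_report.json`, `cutpoints.json`, `posteriors.csv`,
#' `evaluation.json`, `roc_points.csv`, `run_report.json`), each JSON
#' embedding the configuration hash for provenance. The run is
#' deterministic under a fixed seed and configuration.
#'
#' @param config A [study_config()].
#' @param seed Integer seed for the generator.
#' @param out_dir Optional output directory.
#' @param input_dir Optional directory holding user-supplied `anthro.csv`,
#'   `epochs.csv` and `vo2.csv`, bypassing the generator.
#' @return A list of class `run_report`: `config_hash`, `counts` (records
#'   per stage), `qc`, `cutpoints`, `evaluation`, `warnings`.
#' @export
run_pipeline <- function(config = study_config(), seed = NULL,
                         out_dir = NULL, input_dir = NULL) {
  validate_config(config)
  cfg_hash <- rlang::hash(config)
  warnings <- character()

  if (is.null(input_dir)) {
    study <- generate_study(config, seed = seed)
    anthro <- study$anthro
    epochs <- study$epochs
    vo2 <- study$vo2
  } else {
    anthro <- read_anthro(file.path(input_dir, "anthro.csv"))
    epochs <- read_epochs(file.path(input_dir, "epochs.csv"))
    vo2 <- read_vo2(file.path(input_dir, "vo2.csv"))
  }

  summaries <- reduce_study(epochs, vo2, anthro)
  qc <- qc_study(summaries, epochs, anthro,
                 grubbs_alpha = config$grubbs_alpha,
                 normality_alpha = config$normality_alpha)
  non_normal <- qc$normality$activity[qc$normality$p_value <
                                        config$normality_alpha]
  if (length(non_normal)) {
    warnings <- c(warnings, sprintf(
      "Class '%s' deviates from normality; discriminant fit proceeds regardless.",
      non_normal
    ))
  }
  cuts <- derive_cutpoints(summaries, round_to = config$round_to,
                           boundary_round = config$boundary_round,
                           prior = config$prior)
  evaluation <- evaluate_cutpoints(summaries, cuts)

  report <- structure(
    list(
      config_hash = cfg_hash,
      counts = list(
        children = nrow(anthro), epoch_records = nrow(epochs),
        vo2_records = nrow(vo2), summaries = nrow(summaries)
      ),
      qc = qc, cutpoints = cuts, evaluation = evaluation,
      warnings = warnings
    ),
    class = "run_report"
  )

  if (!is.null(out_dir)) {
    write_pipeline_artifacts(report, anthro, epochs, vo2, summaries,
                             config, seed, out_dir)
  }
  report
}

write_pipeline_artifacts <- function(report, anthro, epochs, vo2,
                                     summaries, config, seed, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  digits <- config$csv_digits
  prov <- list(config_hash = report$config_hash, seed = seed)
  wjson <- function(x, file) {
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", pretty = TRUE,
                         na = "null")
  }
  study <- structure(list(anthro = anthro, epochs = epochs, vo2 = vo2,
                          config = config), class = "accelcal_study")
  write_study(study, out_dir)
  readr::write_csv(
    mutate(summaries, across(c("mean_cpm", "ee_kcal_kg_hr", "mets"),
                             ~ round(.x, digits))),
    file.path(out_dir, "summaries.csv")
  )
  wjson(c(prov, qc_as_list(report$qc)), "qc_report.json")
  cuts <- report$cutpoints
  wjson(c(prov, list(
    sedentary_max = cuts$sedentary_max, light_max = cuts$light_max,
    moderate_max = cuts$moderate_max,
    raw_light_max = cuts$raw$light_max,
    raw_moderate_max = cuts$raw$moderate_max,
    model = list(class_labels = cuts$model$class_labels,
                 class_means = cuts$model$class_means,
                 pooled_sd = cuts$model$pooled_sd,
                 priors = cuts$model$priors),
    rounding = cuts$rounding
  )), "cutpoints.json")
  grid <- seq(0, max(cuts$model$class_means) + 3 * cuts$model$pooled_sd,
              by = 10)
  readr::write_csv(
    mutate(posterior_curves(cuts$model, grid),
           posterior = round(.data$posterior, 6)),
    file.path(out_dir, "posteriors.csv")
  )
  ev <- report$evaluation
  wjson(c(prov, list(
    per_intensity = tidy(ev),
    confusion = as.data.frame.matrix(ev$confusion),
    misclassification_rate = ev$misclassification_rate
  )), "evaluation.json")
  roc_pts <- purrr::imap(ev$roc, function(r, lev) {
    mutate(r$roc_points, intensity = lev)
  }) |> bind_rows()
  readr::write_csv(roc_pts, file.path(out_dir, "roc_points.csv"))
  wjson(c(prov, list(
    counts = report$counts,
    cutpoints = list(sedentary_max = cuts$sedentary_max,
                     light_max = cuts$light_max,
                     moderate_max = cuts$moderate_max),
    misclassification_rate = ev$misclassification_rate,
    warnings = report$warnings
  )), "run_report.json")
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  config hash: %s\n", x$config_hash))
  cat(sprintf("  children: %d, summaries: %d\n", x$counts$children,
              x$counts$summaries))
  cat(sprintf("  cut points: <=%g / <=%g / <=%g cpm\n",
              x$cutpoints$sedentary_max, x$cutpoints$light_max,
              x$cutpoints$moderate_max))
  cat(sprintf("  misclassification rate: %.1f%%\n",
              100 * x$evaluation$misclassification_rate))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
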