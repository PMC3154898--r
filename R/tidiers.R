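# broom-style tidiers for the package's fitted objects.

#' Tidy a univariate count discriminant model
#'
#' @param x A [fit_count_lda()] object.
#' @param ... Unused.
#' @return One row per class: `activity`, `mean_cpm`, `prior`, `n`.
#' @exportS3Method generics::tidy
tidy.count_lda <- function(x, ...) {
  tibble(
    activity = x$class_labels,
    mean_cpm = x$class_means,
    prior = x$priors,
    n = x$n_per_class
  )
}

#' Glance at a univariate count discriminant model
#'
#' @param x A [fit_count_lda()] object.
#' @param ... Unused.
#' @return One row: `pooled_sd`, `n_classes`, `n_obs`.
#' @exportS3Method generics::glance
glance.count_lda <- function(x, ...) {
  tibble(
    pooled_sd = x$pooled_sd,
    n_classes = length(x$class_labels),
    n_obs = sum(x$n_per_class)
  )
}

#' Tidy a cut-point set
#'
#' @param x A [derive_cutpoints()] object.
#' @param ... Unused.
#' @return One row per boundary: `boundary`, `cutpoint_cpm`, `raw_cpm`.
#' @exportS3Method generics::tidy
tidy.cutpoint_set <- function(x, ...) {
  tibble(
    boundary = c("sedentary_max", "light_max", "moderate_max"),
    cutpoint_cpm = c(x$sedentary_max, x$light_max, x$moderate_max),
    raw_cpm = c(NA_real_, x$raw$light_max, x$raw$moderate_max)
  )
}

#' Glance at a cut-point set
#'
#' @param x A [derive_cutpoints()] object.
#' @param ... Unused.
#' @return One row: the three cut points, pooled SD and rounding grains.
#' @exportS3Method generics::glance
glance.cutpoint_set <- function(x, ...) {
  tibble(
    sedentary_max = x$sedentary_max,
    light_max = x$light_max,
    moderate_max = x$moderate_max,
    pooled_sd = x$model$pooled_sd,
    round_to = x$rounding$round_to,
    boundary_round = x$rounding$boundary_round %||% NA_real_
  )
}

#' Tidy a cut-point evaluation
#'
#' @param x An [evaluate_cutpoints()] object.
#' @param ... Unused.
#' @return One row per intensity with AUC, its p-value, achieved and
#'   optimal sensitivity/specificity and class sizes.
#' @exportS3Method generics::tidy
tidy.cutpoint_evaluation <- function(x, ...) {
  purrr::imap(x$roc, function(r, lev) {
    tibble(
      intensity = lev,
      auc = r$auc, auc_p = r$auc_p,
      achieved_sens = r$achieved_sens, achieved_spec = r$achieved_spec,
      optimal_sens = r$optimal_sens, optimal_spec = r$optimal_spec,
      n_pos = r$n_pos, n_neg = r$n_neg
    )
  }) |> bind_rows()
}

#' Glance at a cut-point evaluation
#'
#' @param x An [evaluate_cutpoints()] object.
#' @param ... Unused.
#' @return One row: `misclassification_rate`, `n_obs`, `min_auc`,
#'   `max_auc`.
#' @exportS3Method generics::glance
glance.cutpoint_evaluation <- function(x, ...) {
  aucs <- vapply(x$roc, function(r) r$auc, numeric(1))
  tibble(
    misclassification_rate = x$misclassification_rate,
    n_obs = sum(x$confusion),
    min_auc = min(aucs),
    max_auc = max(aucs)
  )
}
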