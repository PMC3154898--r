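#' Fit a univariate Gaussian discriminant model to activity counts
#'
#' Homoscedastic (pooled-variance) linear discriminant analysis on a
#' single feature, counts per minute: each activity class is modelled as
#' Gaussian with its own mean and a common pooled SD, with priors taken
#' from class frequencies (or set equal). This is the model whose
#' posterior-probability intersections define the intensity boundaries.
#'
#' @param summaries Tibble with (at least) a score column and a class
#'   column, typically the output of [reduce_study()].
#' @param classes Activity classes to fit, in increasing intensity order.
#' @param prior `"observed"` class frequencies or `"equal"`.
#' @param score_col,class_col Column names of the score and class.
#' @return An object of class `count_lda`: list with `class_labels`,
#'   `class_means`, `pooled_sd`, `priors`, `n_per_class`.
#' @examples
#' d <- tibble::tibble(
#'   activity = rep(c("slow_walk", "brisk_walk", "jog"), each = 2),
#'   mean_cpm = c(0, 2, 4, 6, 9, 11)
#' )
#' fit_count_lda(d)
#' @export
fit_count_lda <- function(summaries,
                          classes = c("slow_walk", "brisk_walk", "jog"),
                          prior = c("observed", "equal"),
                          score_col = "mean_cpm", class_col = "activity") {
  prior <- match.arg(prior)
  check_columns(summaries, c(score_col, class_col), "summaries")
  d <- summaries[summaries[[class_col]] %in% classes, ]
  got <- unique(d[[class_col]])
  if (length(setdiff(classes, got))) {
    abort(sprintf("Missing class(es): %s",
                  paste(setdiff(classes, got), collapse = ", ")))
  }
  split_scores <- split(d[[score_col]], factor(d[[class_col]], classes))
  n_per <- vapply(split_scores, length, integer(1))
  if (any(n_per < 2)) abort("Each class needs >= 2 observations.")
  means <- vapply(split_scores, mean, numeric(1))
  ss <- sum(vapply(split_scores, function(v) sum((v - mean(v))^2),
                   numeric(1)))
  pooled_var <- ss / (sum(n_per) - length(classes))
  if (pooled_var == 0) {
    abort("All classes have zero variance; the discriminant is undefined.")
  }
  priors <- if (prior == "equal") {
    rep(1 / length(classes), length(classes))
  } else {
    n_per / sum(n_per)
  }
  structure(
    list(
      class_labels = classes,
      class_means = unname(means),
      pooled_sd = sqrt(pooled_var),
      priors = unname(priors),
      n_per_class = unname(n_per)
    ),
    class = "count_lda"
  )
}

#' @export
print.count_lda <- function(x, ...) {
  cat("<count_lda> univariate pooled-variance Gaussian discriminant\n")
  print(tidy(x))
  cat(sprintf("pooled SD: %.2f cpm\n", x$pooled_sd))
  invisible(x)
}

# Log-posterior matrix (grid x classes) by Bayes' rule, via a stabilised
# log-sum-exp so extreme grid points do not underflow.
posterior_matrix <- function(model, grid) {
  logd <- vapply(seq_along(model$class_labels), function(j) {
    dnorm(grid, model$class_means[j], model$pooled_sd, log = TRUE) +
      log(model$priors[j])
  }, numeric(length(grid)))
  logd <- matrix(logd, nrow = length(grid))
  mx <- apply(logd, 1, max)
  p <- exp(logd - mx)
  p / rowSums(p)
}

#' Posterior probability curves over a count grid
#'
#' Class posterior probabilities by Bayes' rule from the fitted class
#' Gaussians and priors, evaluated on a grid of counts-per-minute values.
#' At every grid point the posteriors sum to one.
#'
#' @param model A [fit_count_lda()] model.
#' @param grid Numeric vector of counts-per-minute values.
#' @return A tibble in long format: `cpm`, `activity`, `posterior`.
#' @export
posterior_curves <- function(model, grid) {
  stopifnot(inherits(model, "count_lda"))
  if (!length(grid)) abort("`grid` must be nonempty.")
  p <- posterior_matrix(model, grid)
  tibble(
    cpm = rep(grid, times = length(model$class_labels)),
    activity = rep(model$class_labels, each = length(grid)),
    posterior = as.vector(p)
  )
}

# Closed-form intersection of the posteriors of adjacent classes i, j:
# the midpoint of the class means shifted by sd^2 * log(pi_i/pi_j) /
# (mu_j - mu_i).  Bisection on the posterior difference cross-checks it.
boundary_closed_form <- function(mu_i, mu_j, sd, pi_i, pi_j) {
  (mu_i + mu_j) / 2 + sd^2 * log(pi_i / pi_j) / (mu_j - mu_i)
}

boundary_bisection <- function(model, i, j, lower, upper,
                               tol = 1e-9) {
  f <- function(x) {
    p <- posterior_matrix(model, x)
    p[, i] - p[, j]
  }
  stats::uniroot(f, lower = lower, upper = upper, tol = tol)$root
}

#' Boundaries between adjacent discriminant classes
#'
#' For each adjacent pair of classes, the counts-per-minute value at which
#' their posterior probabilities are equal. With a pooled variance and
#' equal priors this is exactly the midpoint of the two class means;
#' unequal priors shift it by `sd^2 * log(prior_i / prior_j) / (mu_j -
#' mu_i)`. The closed form is cross-checked internally against a
#' bisection solve of the posterior curves; an intersection falling
#' outside the open interval between the two means is an error (the model
#' is misordered).
#'
#' @param model A [fit_count_lda()] model with strictly increasing class
#'   means.
#' @return A tibble with one row per adjacent pair: `lower_class`,
#'   `upper_class`, `boundary_cpm`.
#' @export
lda_boundaries <- function(model) {
  stopifnot(inherits(model, "count_lda"))
  mu <- model$class_means
  if (any(diff(mu) <= 0)) {
    abort("Class means must be strictly increasing in intensity order.")
  }
  k <- length(mu)
  out <- purrr::map(seq_len(k - 1), function(i) {
    b <- boundary_closed_form(mu[i], mu[i + 1], model$pooled_sd,
                              model$priors[i], model$priors[i + 1])
    if (b <= mu[i] || b >= mu[i + 1]) {
      abort(sprintf(
        "Boundary between '%s' and '%s' (%.1f cpm) falls outside the class means; priors overwhelm the class separation.",
        model$class_labels[i], model$class_labels[i + 1], b
      ))
    }
    b_num <- boundary_bisection(model, i, i + 1, mu[i], mu[i + 1])
    if (abs(b - b_num) > 1e-6) {
      abort("Closed-form and bisection boundaries disagree beyond 1e-6.")
    }
    tibble(
      lower_class = model$class_labels[i],
      upper_class = model$class_labels[i + 1],
      boundary_cpm = b
    )
  })
  bind_rows(out)
}

#' Sedentary threshold from the sitting count distribution
#'
#' The sedentary boundary is taken from the empirical sitting counts, not
#' from a posterior intersection: adjusted-boxplot outliers are removed
#' and the threshold is the smallest multiple of `round_to` strictly
#' greater than the largest remaining value. The default grain of 100
#' reproduces the round-number decision rule of the calibration study
#' (maximum non-outlying value 96.5 cpm, threshold 100 cpm); `round_to =
#' 1` gives the raw empirical bound.
#'
#' @param sitting_cpm Per-child mean sitting counts per minute.
#' @param round_to Rounding grain in counts per minute.
#' @return The threshold in counts per minute.
#' @examples
#' sedentary_threshold(reference_sitting_counts()) # 100
#' @export
sedentary_threshold <- function(sitting_cpm, round_to = 100) {
  if (!length(sitting_cpm)) abort("`sitting_cpm` must be nonempty.")
  if (round_to <= 0) abort("`round_to` must be positive.")
  if (length(unique(sitting_cpm)) == 1) {
    # constant data: nothing to flag, threshold sits just above the value
    return(round_to * (floor(sitting_cpm[[1]] / round_to) + 1))
  }
  rep_out <- adjusted_boxplot_outliers(sitting_cpm)
  kept <- sitting_cpm[setdiff(seq_along(sitting_cpm), rep_out$index)]
  if (!length(kept)) abort("All sitting values were flagged as outliers.")
  mx <- max(kept)
  round_to * (floor(mx / round_to) + 1)
}

#' Derive the full intensity cut-point set
#'
#' Orchestrates calibration: the sedentary boundary from
#' [sedentary_threshold()] on the sitting counts, and the light/moderate
#' and moderate/vigorous boundaries as discriminant posterior
#' intersections over the three locomotor classes ([fit_count_lda()] +
#' [lda_boundaries()]). Raw boundaries are always retained; rounded
#' values (default: nearest 10 cpm) are the operational cut points.
#' Sitting can optionally be included as a fourth discriminant class
#' (`include_sitting = TRUE`); the sedentary boundary still comes from
#' the empirical threshold rule either way.
#'
#' @param summaries Output of [reduce_study()] covering sitting,
#'   slow_walk, brisk_walk and jog.
#' @param round_to Grain of the sedentary threshold.
#' @param boundary_round Grain for rounding the discriminant boundaries;
#'   `NULL` to keep them unrounded.
#' @param prior Prior mode for the discriminant fit.
#' @param include_sitting Include sitting as a discriminant class.
#' @return An object of class `cutpoint_set`: list with `sedentary_max`,
#'   `light_max`, `moderate_max`, `raw` (unrounded boundaries), `model`
#'   (the `count_lda` fit) and `rounding`.
#' @export
derive_cutpoints <- function(summaries, round_to = 100,
                             boundary_round = 10,
                             prior = c("observed", "equal"),
                             include_sitting = FALSE) {
  prior <- match.arg(prior)
  check_columns(summaries, c("child_id", "activity", "mean_cpm"),
                "summaries")
  need <- c("sitting", "slow_walk", "brisk_walk", "jog")
  missing <- setdiff(need, unique(summaries$activity))
  if (length(missing)) {
    abort(sprintf("Calibration requires activities: %s (missing %s)",
                  paste(need, collapse = ", "),
                  paste(missing, collapse = ", ")))
  }
  sitting <- summaries$mean_cpm[summaries$activity == "sitting"]
  sed_max <- sedentary_threshold(sitting, round_to = round_to)
  classes <- if (include_sitting) {
    c("sitting", "slow_walk", "brisk_walk", "jog")
  } else {
    c("slow_walk", "brisk_walk", "jog")
  }
  model <- fit_count_lda(summaries, classes = classes, prior = prior)
  bounds <- lda_boundaries(model)
  # the two uppermost intersections separate light/moderate and
  # moderate/vigorous regardless of whether sitting joined the fit
  upper <- tail(bounds$boundary_cpm, 2)
  rounded <- if (is.null(boundary_round)) upper else
    round(upper / boundary_round) * boundary_round
  if (!(sed_max < rounded[1] && rounded[1] < rounded[2])) {
    abort("Derived cut points are not strictly increasing.")
  }
  structure(
    list(
      sedentary_max = sed_max,
      light_max = rounded[1],
      moderate_max = rounded[2],
      raw = list(light_max = upper[1], moderate_max = upper[2],
                 boundaries = bounds),
      model = model,
      rounding = list(round_to = round_to, boundary_round = boundary_round)
    ),
    class = "cutpoint_set"
  )
}

#' @export
print.cutpoint_set <- function(x, ...) {
  cat("<cutpoint_set> intensity boundaries (counts per minute)\n")
  cat(sprintf("  sedentary <= %g < light <= %g < moderate <= %g < vigorous\n",
              x$sedentary_max, x$light_max, x$moderate_max))
  cat(sprintf("  raw discriminant intersections: %.1f, %.1f\n",
              x$raw$light_max, x$raw$moderate_max))
  invisible(x)
}

#' Classify counts per minute into intensity categories
#'
#' Partition of the non-negative count axis by a cut-point set:
#' sedentary for `cpm <= sedentary_max`, light up to `light_max`,
#' moderate up to `moderate_max`, vigorous above.
#'
#' @param cpm Numeric vector of counts per minute (>= 0).
#' @param cuts A [derive_cutpoints()] result, or any list with
#'   `sedentary_max`, `light_max`, `moderate_max`.
#' @return Factor with levels [intensity_levels()].
#' @examples
#' cuts <- list(sedentary_max = 100, light_max = 2240, moderate_max = 3840)
#' classify_intensity(c(0, 100, 101, 2240, 2241, 3840, 3841), cuts)
#' @export
classify_intensity <- function(cpm, cuts) {
  if (any(cpm < 0, na.rm = TRUE)) abort("`cpm` must be non-negative.")
  breaks <- c(-Inf, cuts$sedentary_max, cuts$light_max, cuts$moderate_max,
              Inf)
  cut(cpm, breaks = breaks, labels = intensity_levels(), right = TRUE)
}
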