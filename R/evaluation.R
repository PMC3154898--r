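# One-vs-rest ROC machinery. Scores are counts per minute; `direction`
# says which side of a threshold indicates the positive class: "high"
# (predict positive when score > threshold; locomotor intensities) or
# "low" (predict positive when score <= threshold; sedentary, whose
# counts sit below the rest).

check_two_classes <- function(labels) {
  if (!is.logical(labels)) abort("`labels` must be logical (TRUE = positive).")
  if (!any(labels) || all(labels)) {
    abort("Need at least one positive and one negative observation.")
  }
}

#' Empirical ROC curve
#'
#' One `(1 - specificity, sensitivity)` point per distinct observed
#' threshold, plus the (0, 0) and (1, 1) endpoints. For
#' `direction = "high"` the classifier predicts positive when the score
#' exceeds the threshold; for `"low"` when the score is at or below it.
#'
#' @param scores Numeric scores (counts per minute).
#' @param labels Logical vector, `TRUE` for the positive class.
#' @param direction `"high"` or `"low"`.
#' @return A tibble: `threshold`, `fpr`, `tpr`, sorted so the curve runs
#'   from (0, 0) to (1, 1).
#' @export
roc_curve <- function(scores, labels, direction = c("high", "low")) {
  direction <- match.arg(direction)
  check_two_classes(labels)
  s <- if (direction == "high") scores else -scores
  thr <- sort(unique(s), decreasing = TRUE)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  tpr <- vapply(thr, function(t) sum(s[labels] >= t), numeric(1)) / n_pos
  fpr <- vapply(thr, function(t) sum(s[!labels] >= t), numeric(1)) / n_neg
  out <- tibble(
    threshold = c(Inf, thr, -Inf) * (if (direction == "high") 1 else -1),
    fpr = c(0, fpr, 1),
    tpr = c(0, tpr, 1)
  )
  dplyr::distinct(out, .data$fpr, .data$tpr, .keep_all = TRUE)
}

trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

#' AUC via the Mann-Whitney statistic
#'
#' The probability that a random positive scores higher than a random
#' negative (ties counted one half), computed from ranks:
#' `AUC = (rank sum of positives - n_pos (n_pos + 1) / 2) / (n_pos n_neg)`.
#' Identical to the trapezoidal area under [roc_curve()].
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_mann_whitney(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE)) # 0.75
#' @export
auc_mann_whitney <- function(scores, labels, direction = c("high", "low")) {
  direction <- match.arg(direction)
  check_two_classes(labels)
  s <- if (direction == "high") scores else -scores
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  r <- rank(s)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Test of no discrimination (AUC = 1/2)
#'
#' One-sided significance test of `H0: AUC = 1/2` against `AUC > 1/2`
#' using the null distribution of the Mann-Whitney U statistic: exact
#' enumeration when the sample is tie-free and `n_pos * n_neg <= 1e4`,
#' otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @inheritParams roc_curve
#' @return A one-row tibble: `auc`, `u`, `p_value`, `method`, `n_pos`,
#'   `n_neg`.
#' @export
mason_graham_test <- function(scores, labels,
                              direction = c("high", "low")) {
  direction <- match.arg(direction)
  check_two_classes(labels)
  auc <- auc_mann_whitney(scores, labels, direction)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  u <- auc * n_pos * n_neg
  has_ties <- anyDuplicated(scores) > 0
  if (!has_ties && n_pos * n_neg <= 1e4) {
    # tie-free, so u is an integer; P(U >= u) = P(U > u - 1) exactly
    p <- pwilcox(round(u) - 1, n_pos, n_neg, lower.tail = FALSE)
    method <- "exact"
  } else {
    nn <- n_pos + n_neg
    t_tab <- table(scores)
    tie_term <- sum(t_tab^3 - t_tab) / (nn * (nn - 1))
    sigma2 <- n_pos * n_neg / 12 * (nn + 1 - tie_term)
    if (sigma2 <= 0) abort("Degenerate null variance (all scores tied).")
    z <- (u - n_pos * n_neg / 2 - 0.5) / sqrt(sigma2)
    p <- pnorm(z, lower.tail = FALSE)
    method <- "normal_tie_corrected"
  }
  tibble(auc = auc, u = u, p_value = p, method = method,
         n_pos = n_pos, n_neg = n_neg)
}

#' Optimal point of a ROC curve
#'
#' The curve point minimising the Euclidean distance to perfect
#' classification `(fpr, tpr) = (0, 1)`; ties broken toward higher
#' sensitivity.
#'
#' @param roc A [roc_curve()] tibble.
#' @return A one-row tibble: `optimal_sens`, `optimal_spec`, `threshold`.
#' @export
optimal_point <- function(roc) {
  if (!nrow(roc)) abort("Empty ROC curve.")
  d <- sqrt((1 - roc$tpr)^2 + roc$fpr^2)
  best <- which(d == min(d))
  best <- best[which.max(roc$tpr[best])]
  tibble(optimal_sens = roc$tpr[best], optimal_spec = 1 - roc$fpr[best],
         threshold = roc$threshold[best])
}

#' Sensitivity and specificity at a fixed cut point
#'
#' Dichotomises the scores at the given threshold (direction as in
#' [roc_curve()]) and reports the achieved sensitivity and specificity.
#'
#' @inheritParams roc_curve
#' @param threshold Cut point on the score scale.
#' @return A one-row tibble: `achieved_sens`, `achieved_spec`.
#' @export
achieved_at_cut <- function(scores, labels, threshold,
                            direction = c("high", "low")) {
  direction <- match.arg(direction)
  check_two_classes(labels)
  pred_pos <- if (direction == "high") scores > threshold else
    scores <= threshold
  tibble(
    achieved_sens = mean(pred_pos[labels]),
    achieved_spec = mean(!pred_pos[!labels])
  )
}

activity_intensity_map <- function() {
  c(sitting = "sedentary", slow_walk = "light", brisk_walk = "moderate",
    jog = "vigorous")
}

#' Evaluate a cut-point set by one-vs-rest ROC analysis
#'
#' For each intensity the corresponding calibration activity is the
#' positive class and the other three are pooled as negatives, giving a
#' one-vs-rest ROC, the Mann-Whitney AUC with its significance test, the
#' optimal curve point, and the sensitivity/specificity achieved at the
#' intensity's own cut point. Sedentary and light use the "low counts
#' positive" direction with the upper bound of their interval as the cut;
#' moderate and vigorous use "high counts positive" with the lower bound.
#' A 4x4 confusion matrix of [classify_intensity()] predictions against
#' the true activity classes summarises overall performance as the
#' misclassification rate (off-diagonal count over all observations).
#'
#' @param summaries Output of [reduce_study()] covering sitting,
#'   slow_walk, brisk_walk and jog.
#' @param cuts A [derive_cutpoints()] result.
#' @return An object of class `cutpoint_evaluation`: list with `roc` (a
#'   named list per intensity: `roc_points`, `auc`, `auc_p`,
#'   `achieved_sens`, `achieved_spec`, `optimal_sens`, `optimal_spec`,
#'   `n_pos`, `n_neg`), `confusion` (4x4 matrix) and
#'   `misclassification_rate`.
#' @export
evaluate_cutpoints <- function(summaries, cuts) {
  check_columns(summaries, c("child_id", "activity", "mean_cpm"),
                "summaries")
  amap <- activity_intensity_map()
  d <- summaries[summaries$activity %in% names(amap), ]
  missing <- setdiff(names(amap), unique(d$activity))
  if (length(missing)) {
    abort(sprintf("Missing calibration activities: %s",
                  paste(missing, collapse = ", ")))
  }
  truth <- factor(unname(amap[d$activity]), levels = intensity_levels())
  scores <- d$mean_cpm
  cut_for <- c(
    sedentary = cuts$sedentary_max, light = cuts$light_max,
    moderate = cuts$light_max, vigorous = cuts$moderate_max
  )
  dir_for <- c(sedentary = "low", light = "low", moderate = "high",
               vigorous = "high")
  roc_res <- purrr::map(setNames(nm = intensity_levels()), function(lev) {
    labels <- truth == lev
    direction <- dir_for[[lev]]
    roc <- roc_curve(scores, labels, direction)
    mg <- mason_graham_test(scores, labels, direction)
    opt <- optimal_point(roc)
    ach <- achieved_at_cut(scores, labels, cut_for[[lev]], direction)
    list(
      roc_points = roc,
      auc = mg$auc, auc_p = mg$p_value,
      achieved_sens = ach$achieved_sens, achieved_spec = ach$achieved_spec,
      optimal_sens = opt$optimal_sens, optimal_spec = opt$optimal_spec,
      n_pos = sum(labels), n_neg = sum(!labels)
    )
  })
  pred <- classify_intensity(scores, cuts)
  confusion <- table(truth = truth, predicted = pred)
  rate <- 1 - sum(diag(confusion)) / sum(confusion)
  structure(
    list(roc = roc_res, confusion = confusion,
         misclassification_rate = rate),
    class = "cutpoint_evaluation"
  )
}

#' @export
print.cutpoint_evaluation <- function(x, ...) {
  cat("<cutpoint_evaluation> one-vs-rest ROC analysis\n")
  print(tidy(x))
  cat(sprintf("misclassification rate: %.1f%%\n",
              100 * x$misclassification_rate))
  invisible(x)
}
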