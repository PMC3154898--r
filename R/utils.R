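# Internal numeric helpers shared across modules.

# Round half away from zero (for non-negative count data this is round
# half-up). base::round() rounds half to even, which would bias counts
# generated at .5-resolution epoch means.
round_half_up <- function(x) {
  floor(x + 0.5)
}

# Draw n correlated standard-normal pairs; returns a two-column matrix.
rnorm_pair <- function(n, rho) {
  stopifnot(abs(rho) <= 1)
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  cbind(z1, z2, deparse.level = 0)
}

# Normals truncated to be positive by resampling.  Means in this package
# sit several SDs above zero, so rejection is cheap; a hard iteration cap
# guards against impossible configurations.
rnorm_positive <- function(n, mean, sd, max_iter = 1000L) {
  if (sd == 0) {
    if (mean < 0) abort("Degenerate truncation: mean < 0 with sd = 0.")
    return(rep(mean, n))
  }
  x <- rnorm(n, mean, sd)
  iter <- 0L
  while (any(bad <- x <= 0)) {
    iter <- iter + 1L
    if (iter > max_iter) {
      abort("Truncated-normal sampler failed: mass above 0 is too small.")
    }
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      abort("`seed` must be a single number or NULL.")
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

#' Intensity category levels
#'
#' The four activity-intensity categories used throughout the package, in
#' increasing order of energy expenditure.
#'
#' @return Character vector `c("sedentary", "light", "moderate", "vigorous")`.
#' @export
intensity_levels <- function() {
  c("sedentary", "light", "moderate", "vigorous")
}
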