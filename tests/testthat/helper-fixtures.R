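# Shared fixtures and independent oracles for the test suite.

# Brute-force medcouple oracle: plain double loop over sorted positions,
# written independently of the package's vectorised kernel enumeration.
medcouple_bruteforce <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- stats::median(x)
  n_below <- sum(x < m)
  q <- sum(x == m)
  h <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (x[i] > m || x[j] < m) next
      if (x[i] == m && x[j] == m) {
        h <- c(h, sign((i - n_below) + (j - n_below) - 1 - q))
      } else {
        h <- c(h, ((x[j] - m) - (m - x[i])) / (x[j] - x[i]))
      }
    }
  }
  stats::median(h)
}

# ANOVA-table ICC oracle via stats::aov.
icc_aov_oracle <- function(m) {
  d <- data.frame(
    v = as.vector(t(m)),
    subj = factor(rep(seq_len(nrow(m)), each = ncol(m)))
  )
  tab <- summary(stats::aov(v ~ subj, data = d))[[1]]
  msb <- tab["subj", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  k <- ncol(m)
  (msb - msw) / (msb + (k - 1) * msw)
}

# Summaries table with exactly specified class scores.
make_summaries <- function(...) {
  classes <- list(...)
  purrr::imap(classes, function(v, act) {
    tibble::tibble(
      child_id = sprintf("%s_%02d", act, seq_along(v)),
      activity = act,
      mean_cpm = v
    )
  }) |> dplyr::bind_rows()
}

# A small but complete synthetic study shared by slower tests.
cached_default_study <- local({
  study <- NULL
  function() {
    if (is.null(study)) {
      study <<- generate_study(study_config(), seed = 42)
    }
    study
  }
})

cached_default_summaries <- local({
  s <- NULL
  function() {
    if (is.null(s)) {
      st <- cached_default_study()
      s <<- reduce_study(st$epochs, st$vo2, st$anthro)
    }
    s
  }
})

sitting_vector <- reference_sitting_counts()
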