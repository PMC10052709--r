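# shared fixtures, built in code

# a random valid series with strictly positive endpoints
random_series <- function(n, thickness = 0.25, subject = "S01",
                          observer = "A") {
  slice_series(runif(n, 1, 50), thickness, subject, observer)
}

# a cohort where every observer traces the same constant-area profile:
# decimation and interobserver statistics are all exactly zero on it
constant_cohort <- function(n_per_thickness = 8, n_obs = 3,
                            thicknesses = c(0.25, 0.375), n = 48) {
  series <- list()
  idx <- 0
  for (th in thicknesses) {
    for (s in seq_len(n_per_thickness)) {
      idx <- idx + 1
      for (o in seq_len(n_obs)) {
        series[[length(series) + 1]] <-
          slice_series(rep(15, n), th, sprintf("S%02d", idx), LETTERS[o])
      }
    }
  }
  slice_cohort(series)
}

# small default-shaped phantom spec with overridable fields
small_spec <- function(seed = 42, ...) {
  phantom_spec(n_subjects_per_thickness = 2, seed = seed, ...)
}
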