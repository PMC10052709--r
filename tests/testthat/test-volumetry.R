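test_that("full volume is thickness times summed area", {
  expect_equal(full_volume(slice_series(rep(10, 40), 0.25)), 100)
  expect_equal(full_volume(slice_series(7.2, 0.375)), 2.7)
  # brute-force re-summation oracle on random series
  set.seed(11)
  for (i in 1:20) {
    s <- random_series(sample(2:80, 1), thickness = runif(1, 0.1, 0.5))
    oracle <- 0
    for (a in s$areas_cm2) oracle <- oracle + a * s$thickness_cm
    expect_equal(full_volume(s), oracle)
  }
})

test_that("series constructor enforces its invariants", {
  expect_error(slice_series(numeric(0), 0.25), "at least one")
  expect_error(slice_series(c(0, 5, 3), 0.25), "first and last")
  expect_error(slice_series(c(5, 3, 0), 0.25), "first and last")
  expect_error(slice_series(c(5, -1, 3), 0.25), "non-negative")
  expect_error(slice_series(c(5, 3), 0), "positive")
  # interior zeros are allowed
  expect_s3_class(slice_series(c(5, 0, 3), 0.25), "slice_series")
})

test_that("decimation schemes require exact integer interval multiples", {
  sc <- decimation_scheme(0.25, 0.75)
  expect_equal(sc$k, 3L)
  expect_equal(sc$group_label, "2.5-7.5")
  expect_equal(decimation_scheme(0.375, 0.375)$group_label, "3.75-full")
  expect_equal(decimation_scheme(0.375, 1.125)$k, 3L)
  expect_error(decimation_scheme(0.25, 0.6), "integer multiple")
  expect_error(decimation_scheme(0.25, 0.1), ">=")
})

test_that("phase subsets partition the slices for every (N, k)", {
  s40 <- random_series(40)
  ph <- enumerate_phases(s40, decimation_scheme(0.25, 0.5))
  expect_length(ph, 2L)
  expect_equal(lengths(ph), c("0" = 20L, "1" = 20L))
  expect_equal(ph[["0"]], seq(1, 39, by = 2))
  expect_equal(ph[["1"]], seq(2, 40, by = 2))
  # full group: the single subset is everything
  expect_equal(enumerate_phases(s40, decimation_scheme(0.25, 0.25)),
               list("0" = 1:40))
  # non-divisible N keeps ceil/floor subset sizes
  s10 <- random_series(10)
  ph3 <- enumerate_phases(s10, decimation_scheme(0.25, 0.75))
  expect_equal(unname(lengths(ph3)), c(4L, 3L, 3L))
  # property: disjoint and exhaustive, with n_used = ceil((N - p)/k)
  set.seed(21)
  for (i in 1:25) {
    n <- sample(2:70, 1)
    k <- sample(seq_len(min(n, 8)), 1)
    s <- random_series(n)
    ph <- enumerate_phases(s, decimation_scheme(0.25, 0.25 * k))
    expect_length(ph, k)
    expect_equal(sort(unname(unlist(ph))), 1:n)
    expect_equal(unname(lengths(ph)),
                 ceiling((n - (seq_len(k) - 1)) / k))
  }
  expect_error(enumerate_phases(s10, decimation_scheme(0.375, 0.75)),
               "does not match")
  expect_error(enumerate_phases(random_series(3),
                                decimation_scheme(0.25, 1.5)),
               "exceeds")
})

test_that("decimated volume implements the extrapolation formula", {
  # constant profile: exact for every subset
  s <- slice_series(rep(12, 37), 0.25)
  set.seed(5)
  for (i in 1:10) {
    sub <- sample(37, sample(1:37, 1))
    expect_equal(decimated_volume(s, sub), full_volume(s))
  }
  # subset = all slices reduces to the full volume
  r <- random_series(29)
  expect_identical(decimated_volume(r, 1:29), full_volume(r))
  # brute-force oracle on random series/subsets
  set.seed(6)
  for (i in 1:20) {
    n <- sample(3:60, 1)
    s <- random_series(n, thickness = runif(1, 0.1, 0.5))
    sub <- sample(n, sample(1:n, 1))
    oracle <- 0
    for (j in sub) oracle <- oracle + s$areas_cm2[j] * s$thickness_cm
    oracle <- oracle * n / length(sub)
    expect_equal(decimated_volume(s, sub), oracle)
  }
  expect_error(decimated_volume(r, integer(0)), "non-empty")
  expect_error(decimated_volume(r, c(1, 1)), "unique")
  expect_error(decimated_volume(r, 30), "within")
})

test_that("estimators are linear in the areas", {
  set.seed(7)
  s <- random_series(31)
  s2 <- slice_series(s$areas_cm2 * 3.7, s$thickness_cm)
  sub <- sample(31, 11)
  expect_equal(full_volume(s2), 3.7 * full_volume(s))
  expect_equal(decimated_volume(s2, sub), 3.7 * decimated_volume(s, sub))
})

test_that("phase-mean equals the full volume whenever k divides N", {
  set.seed(8)
  for (k in c(2, 3, 4, 6)) {
    n <- k * sample(5:12, 1)
    s <- random_series(n)
    m <- measure_all(s, decimation_scheme(0.25, 0.25 * k))
    expect_equal(mean(m$volume_cm3), full_volume(s))
  }
})

test_that("measure_all yields one measurement per phase", {
  s <- random_series(41, thickness = 0.375, subject = "S09", observer = "B")
  m <- measure_all(s, decimation_scheme(0.375, 1.5))
  expect_equal(nrow(m), 4L)
  expect_equal(m$phase, 0:3)
  expect_equal(m$n_used, ceiling((41 - 0:3) / 4))
  expect_true(all(m$n_total == 41L))
  expect_equal(unique(m$group), "3.75-15")
  expect_equal(unique(m$subject), "S09")
  # k = 1: the single measurement is the full volume
  m1 <- measure_all(s, decimation_scheme(0.375, 0.375))
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$volume_cm3, full_volume(s))
})
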