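test_that("spec constructors validate their ranges", {
  expect_error(phantom_spec(thicknesses_cm = c(0.25, 0)), "> 0")
  expect_error(phantom_spec(slice_count_range = c(1, 40)), "minimum >= 2")
  expect_error(phantom_spec(target_volume_range = c(-5, 100)), "positive")
  expect_error(observer_noise_spec(n_observers = 0), ">= 1")
  expect_error(observer_noise_spec(per_slice_noise_sd = -0.1), ">= 0")
})

test_that("phantom spec round-trips through YAML losslessly", {
  spec <- phantom_spec(n_subjects_per_thickness = 5, seed = 99,
                       target_volume_range = c(300, 900))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_phantom_spec(spec, path)
  back <- read_phantom_spec(path)
  expect_equal(back, spec)
  # unknown keys are rejected by name
  cfg <- yaml::read_yaml(path)
  cfg$slice_gap <- 3
  yaml::write_yaml(cfg, path)
  expect_error(read_phantom_spec(path), "slice_gap")
})

test_that("generated profiles honour the spec postconditions", {
  spec <- phantom_spec()
  set.seed(101)
  for (i in 1:40) {
    th <- sample(spec$thicknesses_cm, 1)
    s <- generate_subject_profile(spec, th)
    n <- n_slices(s)
    expect_gte(n, spec$slice_count_range[1])
    expect_lte(n, spec$slice_count_range[2])
    v <- full_volume(s)
    expect_gte(v, spec$target_volume_range[1])
    expect_lte(v, spec$target_volume_range[2])
    expect_true(all(s$areas_cm2 > 0))
    # unimodal: the sign of the first difference changes at most once
    d <- sign(diff(s$areas_cm2))
    d <- d[d != 0]
    expect_lte(sum(diff(d) != 0), 1)
  }
  expect_error(generate_subject_profile(spec, 0.5), "thickness")
})

test_that("degenerate shape limit yields a constant profile", {
  spec <- phantom_spec(slice_count_range = c(40, 40),
                       profile_shape_params = list(
                         peak_frac_range = c(0.5, 0.5),
                         sharpness_range = c(0, 0)))
  set.seed(3)
  s <- generate_subject_profile(spec, 0.25)
  expect_equal(n_slices(s), 40L)
  expect_equal(s$areas_cm2, rep(s$areas_cm2[1], 40))
  expect_equal(full_volume(s), 40 * 0.25 * s$areas_cm2[1])
})

test_that("cohort mean volume matches the configured target band", {
  spec <- phantom_spec()
  set.seed(202)
  vols <- replicate(1000, full_volume(
    generate_subject_profile(spec, 0.25)))
  target_mean <- mean(spec$target_volume_range)
  mc_se <- diff(spec$target_volume_range) / sqrt(12) / sqrt(1000)
  expect_lt(abs(mean(vols) - target_mean), 4 * mc_se)
})

test_that("observer noise is multiplicative lognormal with the stated structure", {
  s <- random_series(30)
  # zero noise: identity on areas
  z <- observer_noise_spec(per_observer_bias_sd = 0, per_slice_noise_sd = 0)
  expect_equal(apply_observer(s, z, 2)$areas_cm2, s$areas_cm2)
  # bias only: every area scaled by one common factor e^b
  bias_only <- observer_noise_spec(per_observer_bias_sd = 0.1,
                                   per_slice_noise_sd = 0)
  set.seed(44)
  out <- apply_observer(s, bias_only, 1)
  ratio <- out$areas_cm2 / s$areas_cm2
  expect_equal(ratio, rep(ratio[1], 30))
  expect_equal(full_volume(out), ratio[1] * full_volume(s))
  expect_true(all(out$areas_cm2 > 0))
  expect_equal(n_slices(out), n_slices(s))
  expect_equal(out$thickness_cm, s$thickness_cm)
})

test_that("identical (spec, seed) gives a bit-identical cohort", {
  spec <- small_spec()
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_false(identical(as.data.frame(c1),
                         as.data.frame(generate_cohort(small_spec(seed = 43)))))
})

test_that("adding observers does not perturb subject profiles", {
  base <- small_spec(observer_noise = observer_noise_spec(n_observers = 2))
  more <- small_spec(observer_noise = observer_noise_spec(n_observers = 3))
  t2 <- attr(generate_cohort(base, keep_truth = TRUE), "truth")
  t3 <- attr(generate_cohort(more, keep_truth = TRUE), "truth")
  expect_identical(lapply(t2, `[[`, "areas_cm2"),
                   lapply(t3, `[[`, "areas_cm2"))
})

test_that("default observer noise lands the cohort CV in the calibrated band", {
  cvs <- vapply(1:6, function(i) {
    co <- generate_cohort(phantom_spec(seed = 1000 + i))
    summarize_interobserver(interobserver_summary(co))$mean_cv_pct
  }, numeric(1))
  expect_gt(mean(cvs), 1)
  expect_lt(mean(cvs), 4)
})

test_that("noise calibration recovers the target cohort CV", {
  spec <- phantom_spec(seed = 7)
  cal <- calibrate_observer_noise(spec, target_cv_pct = 2.5, n_cohorts = 6)
  expect_gt(cal$per_observer_bias_sd, 0)
  # applying the calibrated noise reproduces the target within MC error
  cvs <- vapply(1:6, function(i) {
    sp <- phantom_spec(seed = 2000 + i, observer_noise = cal)
    summarize_interobserver(interobserver_summary(generate_cohort(sp)))$mean_cv_pct
  }, numeric(1))
  se <- sd(cvs) / sqrt(length(cvs))
  expect_lt(abs(mean(cvs) - 2.5), 4 * se + 0.3)
})
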