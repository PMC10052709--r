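#' Observer-noise settings for the phantom generator
#'
#' Manual ROI tracing varies between observers in two ways that the phantom
#' emulates multiplicatively on each slice area: a systematic per-observer
#' scaling (one lognormal factor per observer per subject, SD
#' `per_observer_bias_sd` on the log scale) and independent per-slice jitter
#' (SD `per_slice_noise_sd`). The default bias SD was obtained by running
#' [calibrate_observer_noise()] at the default phantom settings against a
#' target cohort CV of 2.5%; the per-slice SD of 0.05 represents boundary
#' tracing jitter and contributes under 1% at the whole-volume level.
#'
#' @param n_observers Number of simulated observers (>= 1; default 3).
#' @param per_observer_bias_sd SD of the per-observer log scale factor
#'   (dimensionless, >= 0).
#' @param per_slice_noise_sd SD of the per-slice log jitter
#'   (dimensionless, >= 0).
#' @return An object of class `observer_noise_spec`.
#' @export
observer_noise_spec <- function(n_observers = 3L,
                                per_observer_bias_sd = 0.0271,
                                per_slice_noise_sd = 0.05) {
  n_observers <- as.integer(n_observers)
  if (is.na(n_observers) || n_observers < 1L) {
    stop("n_observers must be >= 1", call. = FALSE)
  }
  for (v in c(per_observer_bias_sd, per_slice_noise_sd)) {
    if (!is.finite(v) || v < 0) {
      stop("noise SDs must be finite and >= 0", call. = FALSE)
    }
  }
  structure(list(n_observers = n_observers,
                 per_observer_bias_sd = as.numeric(per_observer_bias_sd),
                 per_slice_noise_sd = as.numeric(per_slice_noise_sd)),
            class = "observer_noise_spec")
}

#' Specification of a synthetic canine-liver cohort
#'
#' All parameters of the phantom generator. The defaults mirror the study
#' design this package targets: 8 subjects at each of two slice thicknesses
#' (2.5 mm and 3.75 mm), livers spanning 36-63 slices, and full volumes
#' drawn uniformly over a range whose mean and SD match the reported cohort
#' moments (approximately 722 and 281 cm^3). Area profiles are scaled Beta
#' density curves over slice index: unimodal, smooth and strictly positive,
#' with the peak position and sharpness drawn per subject from the
#' configured ranges (a sharpness of 0 degenerates to a constant profile).
#'
#' @param n_subjects_per_thickness Subjects per slice thickness (default 8).
#' @param thicknesses_cm Slice thicknesses in cm (default 0.25 and 0.375).
#' @param slice_count_range Inclusive integer range of liver-bearing slice
#'   counts (default c(36, 63); minimum >= 2).
#' @param target_volume_range Range (cm^3) from which full volumes are drawn
#'   uniformly (default c(236, 1208), giving mean 722 and SD ~281 cm^3).
#' @param profile_shape_params List with `peak_frac_range` (peak position as
#'   a fraction of the span), `sharpness_range` (Beta concentration; 0 =
#'   flat profile) and `margin_floor` (fraction of a uniform profile mixed
#'   in, so the cranial/caudal tip slices keep a realistic minimum area
#'   instead of tapering towards zero; default 0.05).
#' @param observer_noise An [observer_noise_spec()].
#' @param seed Integer root seed; subject and observer random streams are
#'   split from it in a fixed subject-major order, so changing the number of
#'   observers never perturbs the subject profiles.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_cohort()], [read_phantom_spec()]
#' @export
phantom_spec <- function(n_subjects_per_thickness = 8L,
                         thicknesses_cm = c(0.25, 0.375),
                         slice_count_range = c(36L, 63L),
                         target_volume_range = c(236, 1208),
                         profile_shape_params = list(
                           peak_frac_range = c(0.35, 0.6),
                           sharpness_range = c(3, 8),
                           margin_floor = 0.05),
                         observer_noise = observer_noise_spec(),
                         seed = 177L) {
  n_subjects_per_thickness <- as.integer(n_subjects_per_thickness)
  slice_count_range <- as.integer(round(slice_count_range))
  if (is.na(n_subjects_per_thickness) || n_subjects_per_thickness < 1L) {
    stop("n_subjects_per_thickness must be >= 1", call. = FALSE)
  }
  if (any(!is.finite(thicknesses_cm)) || any(thicknesses_cm <= 0)) {
    stop("all thicknesses must be > 0", call. = FALSE)
  }
  if (length(slice_count_range) != 2L || slice_count_range[1] < 2L ||
      slice_count_range[2] < slice_count_range[1]) {
    stop("slice_count_range must be an increasing pair with minimum >= 2",
         call. = FALSE)
  }
  if (length(target_volume_range) != 2L ||
      any(!is.finite(target_volume_range)) || target_volume_range[1] <= 0 ||
      target_volume_range[2] < target_volume_range[1]) {
    stop("target_volume_range must be a positive increasing pair",
         call. = FALSE)
  }
  for (f in c("peak_frac_range", "sharpness_range")) {
    r <- profile_shape_params[[f]]
    if (is.null(r) || length(r) != 2L || any(!is.finite(r)) || r[2] < r[1]) {
      stop("profile_shape_params$", f, " must be an increasing pair",
           call. = FALSE)
    }
  }
  if (any(profile_shape_params$sharpness_range < 0) ||
      any(profile_shape_params$peak_frac_range < 0) ||
      any(profile_shape_params$peak_frac_range > 1)) {
    stop("sharpness must be >= 0 and peak fraction within [0, 1]",
         call. = FALSE)
  }
  if (is.null(profile_shape_params$margin_floor)) {
    profile_shape_params$margin_floor <- 0.05
  }
  mf <- profile_shape_params$margin_floor
  if (length(mf) != 1L || !is.finite(mf) || mf < 0 || mf > 1) {
    stop("profile_shape_params$margin_floor must be within [0, 1]",
         call. = FALSE)
  }
  if (!inherits(observer_noise, "observer_noise_spec")) {
    observer_noise <- do.call(observer_noise_spec, as.list(observer_noise))
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  structure(list(n_subjects_per_thickness = n_subjects_per_thickness,
                 thicknesses_cm = as.numeric(thicknesses_cm),
                 slice_count_range = slice_count_range,
                 target_volume_range = as.numeric(target_volume_range),
                 profile_shape_params = lapply(
                   profile_shape_params[c("peak_frac_range",
                                          "sharpness_range",
                                          "margin_floor")], as.numeric),
                 observer_noise = observer_noise,
                 seed = seed),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> %d subjects x %d thicknesses (%s cm), ",
                     "%d-%d slices, volumes %g-%g cm^3, %d observers, seed %d\n"),
              x$n_subjects_per_thickness, length(x$thicknesses_cm),
              paste(x$thicknesses_cm, collapse = "/"),
              x$slice_count_range[1], x$slice_count_range[2],
              x$target_volume_range[1], x$target_volume_range[2],
              x$observer_noise$n_observers, x$seed))
  invisible(x)
}

#' Serialise a phantom specification to YAML
#'
#' The on-disk form is a flat key-value YAML file with a nested
#' `observer_noise` block; [read_phantom_spec()] round-trips it losslessly
#' and rejects unknown keys by name.
#'
#' @param spec A [phantom_spec()].
#' @param path File path.
#' @return `write_phantom_spec` returns `path` invisibly;
#'   `read_phantom_spec` returns a `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  x <- unclass(spec)
  x$observer_noise <- unclass(x$observer_noise)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  known <- c("n_subjects_per_thickness", "thicknesses_cm",
             "slice_count_range", "target_volume_range",
             "profile_shape_params", "observer_noise", "seed")
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(x$observer_noise)) {
    known_noise <- c("n_observers", "per_observer_bias_sd",
                     "per_slice_noise_sd")
    extra <- setdiff(names(x$observer_noise), known_noise)
    if (length(extra)) {
      stop("unknown observer_noise keys: ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
    x$observer_noise <- do.call(observer_noise_spec, x$observer_noise)
  }
  do.call(phantom_spec, x)
}

#' Draw one synthetic liver area profile
#'
#' Draws a slice count, a target full volume and profile shape parameters
#' from the spec's ranges (using the current RNG state), and returns the
#' scaled Beta-density area profile: at slice i of N the area is
#' proportional to the Beta(1 + p s, 1 + (1 - p) s) density evaluated at the
#' slice midpoint (i - 1/2)/N, mixed with a uniform floor (`margin_floor`)
#' so the tip slices keep a realistic minimum area, and scaled so the
#' slice-summation volume equals the drawn target exactly. The profile is
#' strictly positive, smooth and unimodal (constant when the sharpness
#' s = 0).
#'
#' Randomness comes from R's global RNG; seed it (or call through
#' [generate_cohort()], which manages per-subject streams) for
#' reproducibility.
#'
#' @param spec A [phantom_spec()].
#' @param thickness_cm Slice thickness (must be one of the spec's
#'   thicknesses).
#' @param subject_id,observer_id Identifiers for the returned series.
#' @return A [slice_series()].
#' @export
generate_subject_profile <- function(spec, thickness_cm,
                                     subject_id = "S01", observer_id = "A") {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!any(abs(spec$thicknesses_cm - thickness_cm) < 1e-8)) {
    stop("thickness_cm must be one of the spec thicknesses", call. = FALSE)
  }
  n <- spec$slice_count_range[1] +
    sample.int(spec$slice_count_range[2] - spec$slice_count_range[1] + 1L,
               1L) - 1L
  vol <- stats::runif(1, spec$target_volume_range[1],
                      spec$target_volume_range[2])
  pf <- spec$profile_shape_params$peak_frac_range
  sh <- spec$profile_shape_params$sharpness_range
  p <- stats::runif(1, pf[1], pf[2])
  s <- stats::runif(1, sh[1], sh[2])
  x <- (seq_len(n) - 0.5) / n
  mf <- spec$profile_shape_params$margin_floor
  w <- (1 - mf) * stats::dbeta(x, 1 + p * s, 1 + (1 - p) * s) + mf
  areas <- vol / thickness_cm * w / sum(w)
  if (any(!is.finite(areas)) || any(areas <= 0)) {
    stop(sprintf(paste0("infeasible spec: target volume %.1f cm^3 at %d ",
                        "slices of %.3g cm yields a degenerate area profile"),
                 vol, n, thickness_cm), call. = FALSE)
  }
  slice_series(areas, thickness_cm, subject_id, observer_id)
}

#' Apply simulated observer tracing noise to a series
#'
#' Each area is multiplied by exp(b + e_i), where b ~ N(0,
#' per_observer_bias_sd) is one systematic factor for this observer on this
#' subject and e_i ~ N(0, per_slice_noise_sd) is independent per-slice
#' jitter. Slice count and thickness are unchanged and areas stay strictly
#' positive. With both SDs zero this is the identity. Uses the current RNG
#' state.
#'
#' @param series A [slice_series()] (the noiseless truth).
#' @param noise An [observer_noise_spec()].
#' @param observer_index Which observer (1-based); used only to label the
#'   output series with LETTERS[observer_index].
#' @return A [slice_series()] with the same dimensions.
#' @export
apply_observer <- function(series, noise, observer_index = 1L) {
  stopifnot(inherits(series, "slice_series"),
            inherits(noise, "observer_noise_spec"))
  n <- n_slices(series)
  b <- stats::rnorm(1, 0, noise$per_observer_bias_sd)
  eps <- stats::rnorm(n, 0, noise$per_slice_noise_sd)
  slice_series(series$areas_cm2 * exp(b + eps), series$thickness_cm,
               series$subject_id, LETTERS[observer_index])
}

# derive a stream of independent sub-seeds (< 2^31) from the root seed
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a full synthetic cohort
#'
#' Produces one traced [slice_series()] per subject x observer. Subjects are
#' laid out thickness-major (`S01..S08` at the first thickness, `S09..S16`
#' at the second, at defaults); observers are `A`, `B`, `C`, ... . All
#' randomness derives from `spec$seed` through fixed stream splitting
#' (subject-major, then observer), so identical specs give bit-identical
#' cohorts and adding observers does not perturb the subject profiles.
#'
#' @param spec A [phantom_spec()].
#' @param keep_truth If `TRUE`, attach the noiseless truth series as
#'   attribute `"truth"`.
#' @return A [slice_cohort()] with attribute `"spec"`.
#' @examples
#' cohort <- generate_cohort(phantom_spec(n_subjects_per_thickness = 2))
#' cohort
#' @export
generate_cohort <- function(spec, keep_truth = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_subj <- spec$n_subjects_per_thickness * length(spec$thicknesses_cm)
  subj_seeds <- derive_seeds(spec$seed, n_subj)
  wd <- max(2L, nchar(as.character(n_subj)))
  series <- list()
  truth <- list()
  idx <- 0L
  for (ti in seq_along(spec$thicknesses_cm)) {
    for (si in seq_len(spec$n_subjects_per_thickness)) {
      idx <- idx + 1L
      sid <- sprintf(paste0("S%0", wd, "d"), idx)
      set.seed(subj_seeds[idx])
      prof <- generate_subject_profile(spec, spec$thicknesses_cm[ti],
                                       subject_id = sid)
      obs_seeds <- sample.int(.Machine$integer.max - 1L,
                              spec$observer_noise$n_observers)
      truth[[idx]] <- prof
      for (oi in seq_len(spec$observer_noise$n_observers)) {
        set.seed(obs_seeds[oi])
        series[[length(series) + 1L]] <-
          apply_observer(prof, spec$observer_noise, oi)
      }
    }
  }
  out <- slice_cohort(series)
  attr(out, "spec") <- spec
  if (keep_truth) attr(out, "truth") <- truth
  out
}

#' Calibrate observer bias to a target cohort CV
#'
#' Searches `per_observer_bias_sd` so that the cohort mean of the
#' per-subject interobserver CV of full volumes matches a target (default
#' 2.5%). Uses common random numbers: noiseless profiles and unit-normal
#' noise draws are generated once from `spec$seed`, then rescaled by each
#' candidate SD, making the mean CV a continuous increasing function of the
#' bias SD that [stats::uniroot()] can solve.
#'
#' @param spec A [phantom_spec()] supplying all settings except the bias SD.
#' @param target_cv_pct Target cohort mean CV, percent (default 2.5).
#' @param n_cohorts Monte-Carlo replicates of the cohort (default 12).
#' @param bias_range Search interval for the bias SD.
#' @param tol Root-finding tolerance on the bias SD.
#' @return An [observer_noise_spec()] with the calibrated
#'   `per_observer_bias_sd` (other fields copied from `spec`).
#' @export
calibrate_observer_noise <- function(spec, target_cv_pct = 2.5,
                                     n_cohorts = 12L,
                                     bias_range = c(0, 0.3), tol = 1e-5) {
  stopifnot(inherits(spec, "phantom_spec"), target_cv_pct > 0)
  noise <- spec$observer_noise
  n_obs <- noise$n_observers
  if (n_obs < 2L) stop("calibration needs >= 2 observers", call. = FALSE)
  # pre-draw profiles and unit normals once (common random numbers)
  rep_seeds <- derive_seeds(spec$seed, n_cohorts)
  draws <- list()
  for (r in seq_len(n_cohorts)) {
    set.seed(rep_seeds[r])
    for (ti in seq_along(spec$thicknesses_cm)) {
      for (si in seq_len(spec$n_subjects_per_thickness)) {
        prof <- generate_subject_profile(spec, spec$thicknesses_cm[ti])
        n <- n_slices(prof)
        draws[[length(draws) + 1L]] <- list(
          areas = prof$areas_cm2,
          zb = stats::rnorm(n_obs),
          ze = matrix(stats::rnorm(n_obs * n), nrow = n_obs))
      }
    }
  }
  mean_cv <- function(bias_sd) {
    cvs <- vapply(draws, function(d) {
      v <- vapply(seq_len(n_obs), function(o) {
        sum(d$areas * exp(bias_sd * d$zb[o] +
                            noise$per_slice_noise_sd * d$ze[o, ]))
      }, numeric(1))
      stats::sd(v) / mean(v) * 100
    }, numeric(1))
    mean(cvs)
  }
  lo <- mean_cv(bias_range[1])
  if (lo >= target_cv_pct) {
    stop(sprintf(paste0("per-slice noise alone already gives mean CV %.2f%% ",
                        ">= target %.2f%%; reduce per_slice_noise_sd"),
                 lo, target_cv_pct), call. = FALSE)
  }
  root <- stats::uniroot(function(b) mean_cv(b) - target_cv_pct,
                         interval = bias_range, tol = tol)
  observer_noise_spec(n_observers = n_obs,
                      per_observer_bias_sd = root$root,
                      per_slice_noise_sd = noise$per_slice_noise_sd)
}
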