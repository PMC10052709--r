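#' Coefficient of variation, in percent
#'
#' CV = standard deviation / mean x 100, using the sample (n-1) standard
#' deviation; here the per-subject spread of full hepatic volumes across
#' observers.
#'
#' @param values Numeric vector of at least two positive-mean measurements.
#' @return CV in percent (>= 0).
#' @examples
#' cv_pct(c(90, 100, 110))   # 10
#' @export
cv_pct <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("mean of values must be > 0", call. = FALSE)
  stats::sd(values) / m * 100
}

#' Greatest percent difference among a set of measurements
#'
#' The worst-case disagreement metric: the range (largest minus smallest
#' measurement) divided by the mean of all measurements, times 100. For two
#' values it coincides with [pairwise_percent_difference()].
#'
#' @param values Numeric vector of at least two positive-mean measurements.
#' @return Greatest percent difference (>= 0).
#' @examples
#' greatest_percent_difference(c(90, 100, 110))   # 20
#' @export
greatest_percent_difference <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("mean of values must be > 0", call. = FALSE)
  (max(values) - min(values)) / m * 100
}

#' Percent difference between two observers' measurements
#'
#' Symmetric percent difference: |a - b| divided by the pair mean, times
#' 100. Vectorised over `a` and `b`.
#'
#' @param a,b Positive volumes.
#' @return Percent difference(s) (>= 0).
#' @examples
#' pairwise_percent_difference(95, 105)   # 10
#' @export
pairwise_percent_difference <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) stop("volumes must be > 0", call. = FALSE)
  abs(a - b) / ((a + b) / 2) * 100
}

#' Per-subject interobserver agreement of full volumes
#'
#' Computes, for each subject, every observer's full hepatic volume and the
#' agreement statistics: CV, greatest percent difference, and the percent
#' difference for each observer pair. Every subject must have a series from
#' every observer.
#'
#' @param cohort A [slice_cohort()] (all subjects x all observers).
#' @return A `data.frame` with one row per subject: `subject`, one
#'   `vol_<observer>` column per observer, `cv_pct`, `greatest_pct_diff`,
#'   and one `pd_<o1>_<o2>` column per observer pair.
#' @export
interobserver_summary <- function(cohort) {
  stopifnot(inherits(cohort, "slice_cohort"))
  vols <- data.frame(
    subject = vapply(cohort, `[[`, character(1), "subject_id"),
    observer = vapply(cohort, `[[`, character(1), "observer_id"),
    volume_cm3 = vapply(cohort, full_volume, numeric(1)),
    stringsAsFactors = FALSE
  )
  observers <- sort(unique(vols$observer))
  subjects <- unique(vols$subject)
  # completeness check, naming any gap
  tab <- table(vols$subject, vols$observer)
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)
    gaps <- apply(bad, 1L, function(ij)
      paste0(rownames(tab)[ij[1]], "/", colnames(tab)[ij[2]]))
    stop("incomplete cohort: subject/observer combinations missing or ",
         "duplicated: ", paste(gaps, collapse = ", "), call. = FALSE)
  }
  pairs <- if (length(observers) >= 2L) utils::combn(observers, 2L) else NULL
  rows <- lapply(subjects, function(sj) {
    v <- vols$volume_cm3[vols$subject == sj][match(observers,
           vols$observer[vols$subject == sj])]
    out <- as.data.frame(as.list(stats::setNames(v, paste0("vol_", observers))))
    out <- cbind(data.frame(subject = sj, stringsAsFactors = FALSE), out)
    if (length(observers) >= 2L) {
      out$cv_pct <- cv_pct(v)
      out$greatest_pct_diff <- greatest_percent_difference(v)
      for (j in seq_len(ncol(pairs))) {
        o1 <- pairs[1, j]; o2 <- pairs[2, j]
        out[[paste0("pd_", o1, "_", o2)]] <-
          pairwise_percent_difference(v[observers == o1], v[observers == o2])
      }
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort-level interobserver summary
#'
#' Mean and sample SD, across subjects, of each per-subject agreement
#' statistic, plus the cohort mean and SD of all full-volume measurements.
#' With a single subject the SDs are reported as `NA`.
#'
#' @param per_subject Output of [interobserver_summary()].
#' @return A one-row `data.frame`: `n_subjects`, `n_measurements`,
#'   `mean_volume_cm3`, `sd_volume_cm3`, then `mean_`/`sd_` columns for
#'   `cv_pct`, `greatest_pct_diff` and each pairwise statistic.
#' @export
summarize_interobserver <- function(per_subject) {
  stopifnot(is.data.frame(per_subject), nrow(per_subject) >= 1L)
  volcols <- grep("^vol_", names(per_subject), value = TRUE)
  statcols <- c("cv_pct", "greatest_pct_diff",
                grep("^pd_", names(per_subject), value = TRUE))
  statcols <- intersect(statcols, names(per_subject))
  allvols <- unlist(per_subject[volcols], use.names = FALSE)
  safe_sd <- function(x) if (length(x) >= 2L) stats::sd(x) else NA_real_
  out <- data.frame(n_subjects = nrow(per_subject),
                    n_measurements = length(allvols),
                    mean_volume_cm3 = mean(allvols),
                    sd_volume_cm3 = safe_sd(allvols))
  for (sc in statcols) {
    out[[paste0("mean_", sc)]] <- mean(per_subject[[sc]])
    out[[paste0("sd_", sc)]] <- safe_sd(per_subject[[sc]])
  }
  out
}
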