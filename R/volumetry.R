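#' Full hepatic volume by slice summation
#'
#' The Cavalieri-style reference estimator: the liver volume is the sum of
#' the per-slice traced areas times the slice thickness,
#' \deqn{V = t \sum_i A_i,}
#' using every slice with no inter-slice gap.
#'
#' @param series A [slice_series()].
#' @return Volume in cm^3 (strictly positive).
#' @examples
#' full_volume(slice_series(rep(10, 40), 0.25))  # 100 cm^3
#' @export
full_volume <- function(series) {
  stopifnot(inherits(series, "slice_series"))
  series$thickness_cm * sum(series$areas_cm2)
}

#' Define a slice thickness-interval decimation scheme
#'
#' A scheme pairs an acquisition slice thickness with the slice interval
#' actually used for volumetry. The interval must be an exact integer
#' multiple of the thickness; the ratio `k = interval / thickness` is the
#' decimation factor (every k-th slice is traced). `k = 1` denotes the full
#' group. Groups are labelled "thickness-interval" in millimetres
#' (e.g. "2.5-7.5"), with "-full" for k = 1.
#'
#' @param thickness_cm Slice thickness in cm.
#' @param interval_cm Slice interval in cm (integer multiple of the
#'   thickness).
#' @return An object of class `decimation_scheme` with fields
#'   `thickness_cm`, `interval_cm`, `k` and `group_label`.
#' @examples
#' decimation_scheme(0.25, 0.75)   # the 2.5-7.5 group, k = 3
#' @export
decimation_scheme <- function(thickness_cm, interval_cm) {
  thickness_cm <- as.numeric(thickness_cm)[1L]
  interval_cm <- as.numeric(interval_cm)[1L]
  if (!is.finite(thickness_cm) || thickness_cm <= 0) {
    stop("thickness_cm must be positive", call. = FALSE)
  }
  if (!is.finite(interval_cm) || interval_cm < thickness_cm) {
    stop("interval_cm must be >= thickness_cm", call. = FALSE)
  }
  ratio <- interval_cm / thickness_cm
  k <- as.integer(round(ratio))
  if (abs(ratio - k) > 1e-8) {
    stop(sprintf("interval (%g cm) is not an integer multiple of thickness (%g cm)",
                 interval_cm, thickness_cm), call. = FALSE)
  }
  label <- paste0(format(thickness_cm * 10), "-",
                  if (k == 1L) "full" else format(interval_cm * 10))
  structure(list(thickness_cm = thickness_cm, interval_cm = interval_cm,
                 k = k, group_label = label),
            class = "decimation_scheme")
}

#' @export
print.decimation_scheme <- function(x, ...) {
  cat(sprintf("<decimation_scheme> %s (k = %d)\n", x$group_label, x$k))
  invisible(x)
}

#' Enumerate the phase-offset slice subsets of a scheme
#'
#' For decimation factor k there are exactly k possible starting slices;
#' phase p (p = 0, ..., k-1) selects slices p+1, p+1+k, p+1+2k, ... . The k
#' subsets are pairwise disjoint and together cover every slice, so each
#' yields its own volume estimate (the paper-style "first set" / "second
#' set" at k = 2, generalised).
#'
#' @param series A [slice_series()].
#' @param scheme A [decimation_scheme()] with the same thickness as the
#'   series.
#' @return A list of k integer index vectors (1-based), named by phase
#'   `"0"` ... `"k-1"`.
#' @examples
#' s <- slice_series(seq(1, 10), 0.25)
#' enumerate_phases(s, decimation_scheme(0.25, 0.75))
#' @export
enumerate_phases <- function(series, scheme) {
  stopifnot(inherits(series, "slice_series"),
            inherits(scheme, "decimation_scheme"))
  if (abs(scheme$thickness_cm - series$thickness_cm) > 1e-8) {
    stop(sprintf("scheme thickness (%g cm) does not match series thickness (%g cm)",
                 scheme$thickness_cm, series$thickness_cm), call. = FALSE)
  }
  n <- n_slices(series)
  k <- scheme$k
  if (k > n) {
    stop(sprintf("decimation factor k = %d exceeds the %d-slice liver span",
                 k, n), call. = FALSE)
  }
  subsets <- lapply(seq_len(k) - 1L, function(p) seq.int(p + 1L, n, by = k))
  names(subsets) <- as.character(seq_len(k) - 1L)
  subsets
}

#' Extrapolated volume from a decimated slice subset
#'
#' The modified volume formula for a subset of traced slices: the subset's
#' slice-summation volume is scaled up by the ratio of the total
#' liver-bearing slice count N to the number of slices actually used,
#' \deqn{\hat V = t \sum_{i \in S} A_i \times N / |S|.}
#' With the full subset this reduces exactly to [full_volume()]; for a
#' constant area profile it is exact for every subset.
#'
#' @param series A [slice_series()].
#' @param subset Integer vector of 1-based slice indices (non-empty, unique,
#'   within 1..N), typically one element of [enumerate_phases()].
#' @return Estimated volume in cm^3.
#' @export
decimated_volume <- function(series, subset) {
  stopifnot(inherits(series, "slice_series"))
  n <- n_slices(series)
  subset <- as.integer(subset)
  if (length(subset) == 0L) stop("subset must be non-empty", call. = FALSE)
  if (anyNA(subset) || any(subset < 1L) || any(subset > n) ||
      anyDuplicated(subset)) {
    stop("subset indices must be unique and within 1..N", call. = FALSE)
  }
  series$thickness_cm * sum(series$areas_cm2[subset]) * n / length(subset)
}

#' All phase-offset volume estimates of a series under one scheme
#'
#' Runs [enumerate_phases()] and [decimated_volume()] for every phase,
#' producing one measurement row per phase (k rows).
#'
#' @param series A [slice_series()].
#' @param scheme A [decimation_scheme()].
#' @return A `data.frame` with columns `subject`, `observer`, `group`,
#'   `thickness_cm`, `interval_cm`, `k`, `phase` (0-based), `n_used`,
#'   `n_total`, `volume_cm3`.
#' @export
measure_all <- function(series, scheme) {
  subsets <- enumerate_phases(series, scheme)
  n <- n_slices(series)
  data.frame(
    subject = series$subject_id,
    observer = series$observer_id,
    group = scheme$group_label,
    thickness_cm = scheme$thickness_cm,
    interval_cm = scheme$interval_cm,
    k = scheme$k,
    phase = seq_along(subsets) - 1L,
    n_used = vapply(subsets, length, integer(1)),
    n_total = n,
    volume_cm3 = vapply(subsets, function(s) decimated_volume(series, s),
                        numeric(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
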