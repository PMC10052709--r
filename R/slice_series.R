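#' Per-slice liver area series
#'
#' A `slice_series` is the unit of all volumetry in this package: the ordered
#' liver cross-sectional areas (cm^2) of one subject as traced by one
#' observer, at a fixed slice thickness. The series covers exactly the
#' liver-bearing slices, from the cranial to the caudal margin: the first and
#' last areas must be strictly positive and there is no zero padding.
#' Interior zeros are permitted (with a warning at mask extraction time) but
#' are not expected for real livers.
#'
#' @param areas_cm2 Numeric vector of per-slice areas in cm^2, in axial
#'   order. Length >= 1, all values finite and >= 0, first and last > 0.
#' @param thickness_cm Slice thickness in cm (> 0).
#' @param subject_id,observer_id Identifiers carried through all outputs.
#' @return An object of class `slice_series`.
#' @examples
#' s <- slice_series(c(5, 12, 20, 14, 6), thickness_cm = 0.25)
#' full_volume(s)
#' @seealso [full_volume()], [measure_all()], [generate_subject_profile()]
#' @export
slice_series <- function(areas_cm2, thickness_cm,
                         subject_id = "S01", observer_id = "A") {
  areas_cm2 <- as.numeric(areas_cm2)
  thickness_cm <- as.numeric(thickness_cm)[1L]
  if (!is.finite(thickness_cm) || thickness_cm <= 0) {
    stop("thickness_cm must be a single positive number", call. = FALSE)
  }
  if (length(areas_cm2) < 1L) {
    stop("areas_cm2 must contain at least one slice", call. = FALSE)
  }
  if (anyNA(areas_cm2) || any(!is.finite(areas_cm2)) || any(areas_cm2 < 0)) {
    stop("areas_cm2 must be finite and non-negative", call. = FALSE)
  }
  if (areas_cm2[1L] <= 0 || areas_cm2[length(areas_cm2)] <= 0) {
    stop("first and last slice areas must be > 0 (the series covers exactly ",
         "the liver-bearing slices, with no zero padding)", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id)[1L],
         observer_id = as.character(observer_id)[1L],
         thickness_cm = thickness_cm,
         areas_cm2 = areas_cm2),
    class = "slice_series"
  )
}

#' Number of liver-bearing slices in a series
#'
#' @param series A [slice_series()].
#' @return Integer slice count N.
#' @export
n_slices <- function(series) {
  stopifnot(inherits(series, "slice_series"))
  length(series$areas_cm2)
}

#' @export
print.slice_series <- function(x, ...) {
  cat(sprintf("<slice_series> subject %s, observer %s: %d slices @ %.4g cm, volume %.1f cm^3\n",
              x$subject_id, x$observer_id, length(x$areas_cm2),
              x$thickness_cm, x$thickness_cm * sum(x$areas_cm2)))
  invisible(x)
}

#' Bundle slice series into a cohort
#'
#' A `slice_cohort` is a flat list of [slice_series()] objects, typically one
#' per subject x observer combination, as produced by [generate_cohort()] or
#' read from a long-format CSV.
#'
#' @param series A list of `slice_series` objects.
#' @return An object of class `slice_cohort`.
#' @export
slice_cohort <- function(series) {
  if (!is.list(series) || length(series) == 0L ||
      !all(vapply(series, inherits, logical(1), "slice_series"))) {
    stop("series must be a non-empty list of slice_series objects",
         call. = FALSE)
  }
  structure(series, class = "slice_cohort")
}

#' @export
print.slice_cohort <- function(x, ...) {
  subj <- unique(vapply(x, `[[`, character(1), "subject_id"))
  obs <- unique(vapply(x, `[[`, character(1), "observer_id"))
  cat(sprintf("<slice_cohort> %d series: %d subjects x %d observers\n",
              length(x), length(subj), length(obs)))
  invisible(x)
}

#' Convert a cohort to/from long format
#'
#' The long format has one row per slice with columns
#' `subject`, `observer`, `slice_index` (1-based), `area_cm2`,
#' `thickness_cm`; this is the on-disk CSV layout used throughout.
#'
#' @param x A `slice_cohort`.
#' @param row.names,optional,... Passed through for S3 compatibility; unused.
#' @return A `data.frame` in long format.
#' @export
as.data.frame.slice_cohort <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  out <- do.call(rbind, lapply(x, function(s) {
    data.frame(subject = s$subject_id,
               observer = s$observer_id,
               slice_index = seq_along(s$areas_cm2),
               area_cm2 = s$areas_cm2,
               thickness_cm = s$thickness_cm,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @rdname as.data.frame.slice_cohort
#' @param df A long-format data frame with the columns listed above.
#' @export
cohort_from_df <- function(df) {
  need <- c("subject", "observer", "slice_index", "area_cm2", "thickness_cm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("cohort data is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(df$subject, df$observer, drop = TRUE, sep = "\r")
  series <- lapply(split(df, key), function(d) {
    d <- d[order(d$slice_index), , drop = FALSE]
    if (!all(d$slice_index == seq_len(nrow(d)))) {
      stop("slice_index must be contiguous from 1 for subject ", d$subject[1],
           " observer ", d$observer[1], call. = FALSE)
    }
    th <- unique(d$thickness_cm)
    if (length(th) != 1L) {
      stop("inconsistent thickness within subject ", d$subject[1],
           " observer ", d$observer[1], call. = FALSE)
    }
    slice_series(d$area_cm2, th, d$subject[1], d$observer[1])
  })
  names(series) <- NULL
  # preserve first-appearance order of the input
  ord <- order(match(vapply(series, function(s)
    paste(s$subject_id, s$observer_id, sep = "\r"), character(1)),
    unique(as.character(key))))
  slice_cohort(series[ord])
}

#' Read and write cohort CSV files
#'
#' Long-format CSV: comma-separated, UTF-8, `.` decimal, header row, one row
#' per slice (`subject, observer, slice_index, area_cm2, thickness_cm`).
#'
#' @param path File path.
#' @return `read_cohort_csv` returns a `slice_cohort`; `write_cohort_csv`
#'   returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort_from_df(df)
}

#' @rdname read_cohort_csv
#' @param cohort A `slice_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
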