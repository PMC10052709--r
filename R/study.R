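#' Percent difference of an estimate from its reference volume
#'
#' |estimate - reference| / reference x 100; the accuracy metric comparing
#' each decimated volume to the corresponding full volume. Vectorised.
#'
#' @param estimate Estimated volume(s), cm^3.
#' @param reference Reference (full) volume(s), cm^3, > 0.
#' @return Percent difference(s), >= 0.
#' @examples
#' percent_difference(95, 100)   # 5
#' @export
percent_difference <- function(estimate, reference) {
  if (any(reference <= 0)) stop("reference volume must be > 0", call. = FALSE)
  abs(estimate - reference) / reference * 100
}

#' Design of a decimation study
#'
#' Declares which thickness-interval groups to run, how many observers are
#' expected, and the slice-count bins used to summarise accuracy by the
#' number of slices. The defaults reproduce the target study design: at
#' 2.5 mm thickness the intervals 5, 7.5, 10 and 15 mm; at 3.75 mm the
#' intervals 7.5, 11.25 and 15 mm; plus the two full (k = 1) reference
#' groups; 3 observers; and the bins <10, 10-14, 15-19, 20-24, >=25 slices.
#'
#' @param intervals_by_thickness Named-free list: one element per thickness,
#'   itself a list with `thickness_cm` and a vector `intervals_cm`
#'   (each an integer multiple of the thickness; include the thickness
#'   itself for the full group).
#' @param n_observers Expected observers per subject (default 3).
#' @param bin_breaks Increasing integer cut points on `n_used`; bin b holds
#'   `n_used` in [break(b-1), break(b)) with open outer bins, so the
#'   default `c(10, 15, 20, 25)` gives <10, 10-14, 15-19, 20-24, >=25.
#' @param bin_labels Labels, length `length(bin_breaks) + 1`.
#' @return An object of class `study_design` with a `schemes` list of
#'   [decimation_scheme()]s.
#' @export
study_design <- function(intervals_by_thickness = list(
                           list(thickness_cm = 0.25,
                                intervals_cm = c(0.25, 0.5, 0.75, 1.0, 1.5)),
                           list(thickness_cm = 0.375,
                                intervals_cm = c(0.375, 0.75, 1.125, 1.5))),
                         n_observers = 3L,
                         bin_breaks = c(10L, 15L, 20L, 25L),
                         bin_labels = c("<10", "10-14", "15-19", "20-24",
                                        ">=25")) {
  schemes <- list()
  for (blk in intervals_by_thickness) {
    for (iv in blk$intervals_cm) {
      schemes[[length(schemes) + 1L]] <- decimation_scheme(blk$thickness_cm, iv)
    }
  }
  labels <- vapply(schemes, `[[`, character(1), "group_label")
  if (anyDuplicated(labels)) {
    stop("duplicate groups in design: ",
         paste(labels[duplicated(labels)], collapse = ", "), call. = FALSE)
  }
  bin_breaks <- as.integer(bin_breaks)
  if (is.unsorted(bin_breaks, strictly = TRUE)) {
    stop("bin_breaks must be strictly increasing", call. = FALSE)
  }
  if (length(bin_labels) != length(bin_breaks) + 1L) {
    stop("need one more bin label than breaks", call. = FALSE)
  }
  n_observers <- as.integer(n_observers)
  if (is.na(n_observers) || n_observers < 1L) {
    stop("n_observers must be >= 1", call. = FALSE)
  }
  structure(list(schemes = schemes, n_observers = n_observers,
                 bin_breaks = bin_breaks, bin_labels = bin_labels),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %d groups, %d observers; bins: %s\n",
              length(x$schemes), x$n_observers,
              paste(x$bin_labels, collapse = ", ")))
  for (s in x$schemes) cat("  ", s$group_label, " (k = ", s$k, ")\n", sep = "")
  invisible(x)
}

#' Summarise the greatest percent difference by slice-count bin
#'
#' Assigns each measurement to exactly one bin by the number of slices it
#' used (`n_used`) and reports the bin's measurement count and maximum
#' percent difference. Empty bins are reported with n = 0 and no maximum.
#'
#' @param measurements A `data.frame` with columns `n_used` and `pct_diff`
#'   (as in a `decimation_study`'s `measurements` table).
#' @param bin_breaks,bin_labels As in [study_design()].
#' @return A `data.frame`: `bin`, `n_measurements`, `greatest_pct_diff`.
#' @export
bin_by_slice_count <- function(measurements,
                               bin_breaks = c(10L, 15L, 20L, 25L),
                               bin_labels = c("<10", "10-14", "15-19",
                                              "20-24", ">=25")) {
  stopifnot(all(c("n_used", "pct_diff") %in% names(measurements)),
            all(measurements$n_used >= 1L))
  idx <- findInterval(measurements$n_used, bin_breaks) + 1L
  out <- data.frame(bin = bin_labels,
                    n_measurements = 0L,
                    greatest_pct_diff = NA_real_,
                    stringsAsFactors = FALSE)
  for (b in seq_along(bin_labels)) {
    sel <- idx == b
    out$n_measurements[b] <- sum(sel)
    if (any(sel)) out$greatest_pct_diff[b] <- max(measurements$pct_diff[sel])
  }
  out
}

# mean/sd/max/n of pct_diff within groups defined by `by` (a list of factors)
summarise_pct_diff <- function(measurements, by) {
  agg <- function(f) stats::aggregate(measurements$pct_diff, by = by, FUN = f)
  m <- agg(mean); s <- agg(stats::sd); mx <- agg(max); n <- agg(length)
  out <- m
  names(out)[ncol(out)] <- "mean_pct_diff"
  out$sd_pct_diff <- s$x
  out$greatest_pct_diff <- mx$x
  out$n_measurements <- n$x
  out
}

#' Run the full decimation study on a cohort
#'
#' For every series (subject x observer) the full volume is computed; every
#' non-full design scheme matching the series' thickness is then run through
#' [measure_all()], and each decimated estimate is compared to the same
#' subject-and-observer full volume via [percent_difference()]. Results are
#' summarised per thickness-interval group (pooled and per observer), per
#' slice interval (pooling groups that share an interval), and per
#' slice-count bin; interobserver agreement of the full volumes is
#' summarised via [interobserver_summary()].
#'
#' @param cohort A [slice_cohort()]: one series per subject x observer,
#'   complete, each thickness matching a design thickness.
#' @param design A [study_design()].
#' @return An object of class `decimation_study`: a list with
#'   `measurements` (one row per decimated measurement, incl. `pct_diff`),
#'   `full_volumes`, `group_summary`, `group_summary_by_observer`,
#'   `interval_greatest`, `bin_summary`, `interobserver`,
#'   `interobserver_cohort`, and `design`.
#' @examples
#' cohort <- generate_cohort(phantom_spec(n_subjects_per_thickness = 2,
#'                                        seed = 7))
#' st <- run_study(cohort)
#' st
#' @export
run_study <- function(cohort, design = study_design()) {
  stopifnot(inherits(cohort, "slice_cohort"),
            inherits(design, "study_design"))
  design_th <- unique(vapply(design$schemes, `[[`, numeric(1),
                             "thickness_cm"))
  # completeness and thickness checks
  subj <- vapply(cohort, `[[`, character(1), "subject_id")
  obs <- vapply(cohort, `[[`, character(1), "observer_id")
  th <- vapply(cohort, `[[`, numeric(1), "thickness_cm")
  observers <- sort(unique(obs))
  if (length(observers) != design$n_observers) {
    stop(sprintf("cohort has %d observers but the design expects %d",
                 length(observers), design$n_observers), call. = FALSE)
  }
  bad_th <- unique(th[!vapply(th, function(t)
    any(abs(design_th - t) < 1e-8), logical(1))])
  if (length(bad_th)) {
    stop("series thickness not in design: ",
         paste(signif(bad_th, 4), collapse = ", "), " cm", call. = FALSE)
  }
  per_subject <- interobserver_summary(cohort)  # also validates completeness

  full <- data.frame(subject = subj, observer = obs, thickness_cm = th,
                     n_total = vapply(cohort, n_slices, integer(1)),
                     volume_cm3 = vapply(cohort, full_volume, numeric(1)),
                     stringsAsFactors = FALSE)
  group_label <- vapply(design$schemes, `[[`, character(1), "group_label")

  rows <- vector("list", 0L)
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    for (sc in design$schemes) {
      if (sc$k == 1L) next
      if (abs(sc$thickness_cm - s$thickness_cm) > 1e-8) next
      m <- measure_all(s, sc)
      m$full_volume_cm3 <- full$volume_cm3[i]
      rows[[length(rows) + 1L]] <- m
    }
  }
  if (length(rows) == 0L) {
    stop("design contains no decimated (k >= 2) group matching the cohort",
         call. = FALSE)
  }
  meas <- do.call(rbind, rows)
  meas$pct_diff <- percent_difference(meas$volume_cm3, meas$full_volume_cm3)
  glev <- group_label[vapply(design$schemes, `[[`, integer(1), "k") > 1L]
  meas$group <- factor(meas$group, levels = glev)

  group_summary <- summarise_pct_diff(meas, list(group = meas$group))
  group_summary <- group_summary[order(match(group_summary$group, glev)), ]
  rownames(group_summary) <- NULL
  gsbo <- summarise_pct_diff(meas, list(group = meas$group,
                                        observer = meas$observer))
  gsbo <- gsbo[order(match(gsbo$group, glev), gsbo$observer), ]
  rownames(gsbo) <- NULL

  ig <- stats::aggregate(meas$pct_diff,
                  by = list(interval_mm = meas$interval_cm * 10), FUN = max)
  names(ig)[2] <- "greatest_pct_diff"
  ig$n_measurements <- stats::aggregate(meas$pct_diff,
    by = list(interval_mm = meas$interval_cm * 10), FUN = length)$x
  ig$groups <- vapply(ig$interval_mm, function(iv)
    paste(unique(meas$group[meas$interval_cm * 10 == iv]), collapse = ","),
    character(1))
  ig <- ig[order(ig$interval_mm), c("interval_mm", "groups",
                                    "n_measurements", "greatest_pct_diff")]
  rownames(ig) <- NULL

  structure(list(
    measurements = meas,
    full_volumes = full,
    group_summary = group_summary,
    group_summary_by_observer = gsbo,
    interval_greatest = ig,
    bin_summary = bin_by_slice_count(meas, design$bin_breaks,
                                     design$bin_labels),
    interobserver = per_subject,
    interobserver_cohort = summarize_interobserver(per_subject),
    design = design
  ), class = "decimation_study")
}

#' @export
print.decimation_study <- function(x, ...) {
  co <- x$interobserver_cohort
  at20 <- x$measurements$pct_diff[x$measurements$n_used >= 20L]
  cat("<decimation_study>\n")
  cat(sprintf("  %d decimated measurements (%d groups), %d full volumes\n",
              nrow(x$measurements), nlevels(x$measurements$group),
              nrow(x$full_volumes)))
  cat(sprintf("  cohort full volume: %.1f (SD %.1f) cm^3\n",
              co$mean_volume_cm3, co$sd_volume_cm3))
  cat(sprintf("  interobserver CV: %.1f (SD %.1f) %%\n",
              co$mean_cv_pct, co$sd_cv_pct))
  if (length(at20)) {
    cat(sprintf("  max |pct diff| using >= 20 slices: %.1f %%\n", max(at20)))
  }
  invisible(x)
}

#' @export
summary.decimation_study <- function(object, ...) {
  r1 <- function(d) {
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], round, 1)
    d
  }
  cat("Per-group percent difference from the corresponding full volume:\n")
  print(r1(object$group_summary), row.names = FALSE)
  cat("\nGreatest percent difference per slice interval:\n")
  print(r1(object$interval_greatest), row.names = FALSE)
  cat("\nGreatest percent difference per slice-count bin:\n")
  print(r1(object$bin_summary), row.names = FALSE)
  cat("\nInterobserver agreement (cohort):\n")
  print(r1(object$interobserver_cohort), row.names = FALSE)
  invisible(object)
}

#' Plot a decimation study
#'
#' `which = "interval"` scatters each measurement's percent difference by
#' thickness-interval group; `which = "slices"` scatters it against the
#' number of slices used. Both draw the dotted 5% acceptability reference
#' line.
#'
#' @param x A `decimation_study`.
#' @param which `"interval"` or `"slices"`.
#' @param ref_pct Reference line, percent (default 5; `NA` to omit).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.decimation_study <- function(x, which = c("interval", "slices"),
                                  ref_pct = 5, ...) {
  which <- match.arg(which)
  m <- x$measurements
  if (which == "interval") {
    gi <- as.integer(m$group)
    graphics::plot(jitter(gi, amount = 0.12), m$pct_diff, xaxt = "n",
                   xlab = "thickness-interval group",
                   ylab = "percent difference from full volume (%)",
                   pch = 1, ...)
    graphics::axis(1, at = seq_len(nlevels(m$group)),
                   labels = levels(m$group), las = 2, cex.axis = 0.8)
  } else {
    graphics::plot(m$n_used, m$pct_diff,
                   xlab = "number of slices used",
                   ylab = "percent difference from full volume (%)",
                   pch = 1, ...)
  }
  if (is.finite(ref_pct)) graphics::abline(h = ref_pct, lty = 3)
  invisible(x)
}

#' Write all study tables to CSV
#'
#' Writes `measurements.csv`, `full_volumes.csv`, `group_summary.csv`,
#' `group_summary_by_observer.csv`, `interval_greatest.csv`,
#' `bin_summary.csv`, `interobserver.csv` and `interobserver_cohort.csv`
#' into a directory. Percentages are stored at full precision; tables with a
#' `pct_diff` column gain a 1-decimal presentation column
#' `pct_diff_rounded`.
#'
#' @param study A `decimation_study`.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_study_tables <- function(study, dir) {
  stopifnot(inherits(study, "decimation_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- list(measurements = study$measurements,
                 full_volumes = study$full_volumes,
                 group_summary = study$group_summary,
                 group_summary_by_observer = study$group_summary_by_observer,
                 interval_greatest = study$interval_greatest,
                 bin_summary = study$bin_summary,
                 interobserver = study$interobserver,
                 interobserver_cohort = study$interobserver_cohort)
  tables$measurements$pct_diff_rounded <- round(tables$measurements$pct_diff, 1)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
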