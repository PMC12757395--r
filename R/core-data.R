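# Data model: scan observations, pooled region series, signal
# normalization, scan-window filtering, composite-region aggregation and
# cohort summary statistics.

#' Normalize a raw regional T1 signal by a reference ROI
#'
#' Intrathecal gadobutrol shortens T1 and raises the T1-weighted signal,
#' but scanners rescale the image grayscale between sessions. Dividing
#' each region's T1 signal unit by that of a reference region of interest
#' (placed where no tracer-related enhancement is expected, e.g. the
#' posterior orbit) removes the session-level rescaling and yields the
#' dimensionless normalized T1 signal analysed throughout the package.
#'
#' @param raw_t1 numeric vector of raw regional T1 signal units (> 0).
#' @param ref_t1 numeric vector (recycled) of reference-ROI T1 signal
#'   units for the same scans; must be finite and > 0.
#' @return `raw_t1 / ref_t1`, the normalized T1 signal.
#' @examples
#' normalize_signal(100, 50) # 2
#' @export
normalize_signal <- function(raw_t1, ref_t1) {
  if (length(ref_t1) == 0L || anyNA(ref_t1) || any(!is.finite(ref_t1)) ||
      any(ref_t1 <= 0)) {
    stop_invalid_reference("reference-ROI T1 must be finite and > 0")
  }
  if (anyNA(raw_t1) || any(!is.finite(raw_t1)) || any(raw_t1 <= 0)) {
    stop_invalid_reference("raw T1 must be finite and > 0")
  }
  raw_t1 / ref_t1
}

#' Pooled observations for one (cohort, region) pair
#'
#' A region series pools the scan observations of every subject in a
#' cohort for one composite brain region; it is the unit on which the
#' segmented model is fitted (one breakpoint per region per cohort, not
#' per subject). Pre-injection scans carry negative times.
#'
#' @param time_h numeric, hours since intrathecal injection (negative for
#'   pre-injection scans).
#' @param signal numeric, normalized T1 signal (> 0).
#' @param cohort,region single strings labelling the series.
#' @param subject_id optional vector identifying the subject of each
#'   observation; used only to count subjects.
#' @return an object of class `region_series`: a list with elements
#'   `time_h`, `signal`, `cohort`, `region`, `subject_id`, `n_subjects`,
#'   `n_obs`.
#' @export
region_series <- function(time_h, signal, cohort = "", region = "",
                          subject_id = NULL) {
  time_h <- as.numeric(time_h)
  signal <- as.numeric(signal)
  if (length(time_h) != length(signal)) {
    stop("time_h and signal must have equal length")
  }
  if (anyNA(time_h) || any(!is.finite(time_h))) {
    stop("time_h must be finite")
  }
  if (anyNA(signal) || any(signal <= 0)) {
    stop("signal must be positive")
  }
  if (!is.null(subject_id) && length(subject_id) != length(time_h)) {
    stop("subject_id must match the number of observations")
  }
  structure(
    list(
      time_h = time_h, signal = signal,
      cohort = as.character(cohort)[1L], region = as.character(region)[1L],
      subject_id = subject_id,
      n_subjects = if (is.null(subject_id)) NA_integer_
                   else length(unique(subject_id)),
      n_obs = length(time_h)
    ),
    class = "region_series"
  )
}

#' @export
print.region_series <- function(x, ...) {
  cat(sprintf(
    "Region series: %s / %s  (%d observations%s, t in [%.2f, %.2f] h)\n",
    x$cohort, x$region, x$n_obs,
    if (is.na(x$n_subjects)) "" else sprintf(", %d subjects", x$n_subjects),
    min(x$time_h), max(x$time_h)
  ))
  invisible(x)
}

#' @export
as.data.frame.region_series <- function(x, ...) {
  data.frame(
    subject_id = if (is.null(x$subject_id)) NA_character_
                 else as.character(x$subject_id),
    cohort = x$cohort, region = x$region,
    time_h = x$time_h, signal = x$signal,
    stringsAsFactors = FALSE
  )
}

# TRUE when the series carries enough information for a breakpoint fit:
# at least one pre-/at-injection scan and two post-injection scans.
series_fittable <- function(series) {
  sum(series$time_h <= 0) >= 1L && sum(series$time_h > 0) >= 2L
}

#' Restrict a region series to the modelling scan window
#'
#' Scans from the first day after injection — until about 7 h — carry the
#' influx signal; next-morning (~24 h) and later scans reflect near-peak
#' enrichment and clearance and are excluded from the breakpoint model.
#' Pre-injection scans (negative times) are always retained.
#'
#' @param series a [region_series()].
#' @param max_time_h scans with `time_h` greater than this are dropped
#'   (default 7 hours).
#' @return the filtered `region_series`, with attribute `n_removed`
#'   giving the number of observations dropped.
#' @export
filter_scan_window <- function(series, max_time_h = 7.0) {
  stopifnot(inherits(series, "region_series"))
  if (!is.numeric(max_time_h) || length(max_time_h) != 1L || max_time_h <= 0) {
    stop("max_time_h must be a single positive number")
  }
  keep <- series$time_h <= max_time_h
  if (!any(keep)) {
    stop_empty_series(sprintf(
      "no observations at or before %.2f h in %s / %s",
      max_time_h, series$cohort, series$region
    ))
  }
  out <- region_series(
    series$time_h[keep], series$signal[keep],
    cohort = series$cohort, region = series$region,
    subject_id = if (is.null(series$subject_id)) NULL
                 else series$subject_id[keep]
  )
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Map atlas segments to composite regions
#'
#' @param segment,composite_region character vectors of equal length:
#'   each atlas segment name and the composite region it belongs to. A
#'   segment may appear only once.
#' @param mode how member-segment signals are combined:
#'   `"unweighted_mean"` (default) or `"volume_weighted_mean"`.
#' @return a `region_map` object.
#' @export
region_map <- function(segment, composite_region,
                       mode = c("unweighted_mean", "volume_weighted_mean")) {
  mode <- match.arg(mode)
  segment <- as.character(segment)
  composite_region <- as.character(composite_region)
  if (length(segment) != length(composite_region)) {
    stop("segment and composite_region must have equal length")
  }
  if (anyDuplicated(segment)) {
    stop_mapping("each segment must map to exactly one composite region",
                 segments = segment[duplicated(segment)])
  }
  structure(
    list(map = stats::setNames(composite_region, segment), mode = mode),
    class = "region_map"
  )
}

#' Aggregate per-segment signals into composite regions
#'
#' Atlas-level segmentations are finer than the composite regions the
#' influx analysis reports (frontal, temporal, parietal, occipital cortex
#' and white matter, etc.). For every (subject, scan time, composite
#' region) the member-segment signals are averaged — volume-weighted when
#' the map requests it and volumes are available, otherwise unweighted.
#'
#' @param rows a data frame with columns `subject_id`, `time_h`,
#'   `segment`, `signal` and optionally `cohort` and `volume_mm3`.
#' @param map a [region_map()] covering every segment in `rows`.
#' @return a data frame with one row per (subject, time, composite
#'   region): columns `subject_id`, `cohort` (if present), `region`,
#'   `time_h`, `signal`.
#' @export
aggregate_regions <- function(rows, map) {
  stopifnot(is.data.frame(rows), inherits(map, "region_map"))
  need <- c("subject_id", "time_h", "segment", "signal")
  missing_cols <- setdiff(need, names(rows))
  if (length(missing_cols)) {
    stop("rows is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  unmapped <- setdiff(unique(rows$segment), names(map$map))
  if (length(unmapped)) {
    stop_mapping(
      paste0("segments not present in the region map: ",
             paste(unmapped, collapse = ", ")),
      segments = unmapped
    )
  }
  rows$region <- unname(map$map[as.character(rows$segment)])
  use_volume <- map$mode == "volume_weighted_mean" &&
    "volume_mm3" %in% names(rows) && !anyNA(rows$volume_mm3)
  has_cohort <- "cohort" %in% names(rows)

  key_cols <- c("subject_id", if (has_cohort) "cohort", "region", "time_h")
  key <- do.call(paste, c(rows[key_cols], sep = "\r"))
  idx <- split(seq_len(nrow(rows)), factor(key, levels = unique(key)))
  out <- lapply(idx, function(i) {
    first <- rows[i[1L], key_cols, drop = FALSE]
    first$signal <- if (use_volume) {
      stats::weighted.mean(rows$signal[i], rows$volume_mm3[i])
    } else {
      mean(rows$signal[i])
    }
    first
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$subject_id, out$time_h, out$region), , drop = FALSE]
}

#' Cohort summary statistics
#'
#' Demographic comparisons between cohorts: continuous variables are
#' summarized as mean ± SD and tested with the pooled-variance two-sample
#' t-test (df = n1 + n2 − 2); categorical variables as counts, tested
#' with Pearson's chi-square without continuity correction.
#'
#' @param x,y numeric vectors (one per cohort) for a continuous variable,
#'   or `x` a matrix of non-negative integer counts (cohorts x
#'   categories) with `y` omitted.
#' @return a list with `test` ("t" or "chisq"), `statistic`, `df`, `p`,
#'   and for the t-test per-group `mean` and `sd`.
#' @examples
#' cohort_summary(c(1, 2, 3), c(1, 2, 3)) # t = 0, p = 1
#' cohort_summary(matrix(c(10, 10, 10, 10), 2)) # chi-square = 0, p = 1
#' @export
cohort_summary <- function(x, y = NULL) {
  if (is.matrix(x)) {
    if (!is.null(y)) stop("supply either two vectors or one count matrix")
    if (anyNA(x) || any(x < 0) || any(x != round(x))) {
      stop("counts must be non-negative integers")
    }
    ht <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
    return(list(test = "chisq", statistic = unname(ht$statistic),
                df = unname(ht$parameter), p = ht$p.value))
  }
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least two observations")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop_degenerate_test("both groups have zero variance; t-test undefined")
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(
    test = "t", statistic = unname(ht$statistic),
    df = unname(ht$parameter), p = ht$p.value,
    mean = c(mean(x), mean(y)), sd = c(stats::sd(x), stats::sd(y))
  )
}
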