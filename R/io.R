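# Reading and writing the tabular interfaces: long-format scan CSVs,
# region maps, fit/comparison tables and their JSON twins.

#' Read a long-format tracer scan CSV
#'
#' Expected header: `subject_id, cohort, region, time_h, signal` with
#' optional `raw_t1`, `ref_t1`, `volume_mm3`; one row per scan x region,
#' UTF-8, '.' decimal separator. When `signal` is absent but `raw_t1`
#' and `ref_t1` are present it is computed as their ratio; when all
#' three are present they are checked for consistency.
#'
#' @param path CSV file path.
#' @param segment_level if `TRUE` the rows are per atlas segment (column
#'   `segment` instead of `region`), to be aggregated with
#'   [aggregate_regions()].
#' @return a validated data frame of scan observations.
#' @export
read_tracer_csv <- function(path, segment_level = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("subject_id", "cohort", if (segment_level) "segment" else "region",
            "time_h")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("input is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  has_raw <- all(c("raw_t1", "ref_t1") %in% names(df))
  if (!"signal" %in% names(df)) {
    if (!has_raw) stop("input needs a signal column or raw_t1 + ref_t1")
    df$signal <- normalize_signal(df$raw_t1, df$ref_t1)
  } else if (has_raw) {
    ratio <- df$raw_t1 / df$ref_t1
    bad <- which(abs(df$signal - ratio) > 1e-9 * pmax(abs(ratio), 1))
    if (length(bad)) {
      stop(sprintf(
        "signal inconsistent with raw_t1/ref_t1 at data row(s) %s",
        paste(utils::head(bad, 5L), collapse = ", ")))
    }
  }
  bad <- which(!is.finite(df$time_h) | is.na(df$signal) | df$signal <= 0)
  if (length(bad)) {
    stop(sprintf("malformed values at data row(s) %s of %s",
                 paste(utils::head(bad, 5L), collapse = ", "), path))
  }
  df
}

#' Read a segment-to-composite region map CSV
#'
#' Two columns: `segment`, `composite_region`.
#'
#' @param path CSV file path.
#' @param mode aggregation mode, see [region_map()].
#' @return a [region_map()].
#' @export
read_region_map <- function(path, mode = "unweighted_mean") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment", "composite_region")
  if (!all(need %in% names(df))) {
    stop("region map needs columns segment, composite_region")
  }
  region_map(df$segment, df$composite_region, mode = mode)
}

#' Split scan observations into pooled per-(cohort, region) series
#'
#' @param df a data frame as from [read_tracer_csv()].
#' @return a named list of [region_series()], names `cohort/region`.
#' @export
split_region_series <- function(df) {
  key <- paste(df$cohort, df$region, sep = "/")
  lapply(split(df, factor(key, levels = unique(key))), function(sub) {
    region_series(sub$time_h, sub$signal, cohort = sub$cohort[1L],
                  region = sub$region[1L], subject_id = sub$subject_id)
  })
}

# One tidy row per fitted model, for fits.csv / fits.json.
fit_row <- function(fit) {
  data.frame(
    region = fit$region, cohort = fit$cohort,
    psi = fit$psi, ci_low = fit$ci_psi[1L], ci_high = fit$ci_psi[2L],
    se_psi = fit$se_psi, beta0 = fit$beta0, beta1 = fit$beta1,
    r2 = fit$r2, n_obs = fit$n_obs, converged = fit$converged,
    stringsAsFactors = FALSE
  )
}

write_table_pair <- function(df, out_dir, stem) {
  csv <- file.path(out_dir, paste0(stem, ".csv"))
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(df, file.path(out_dir, paste0(stem, ".json")),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(csv)
}
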