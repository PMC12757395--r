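# Classed error conditions so callers (and tests) can discriminate failure
# modes without matching message text.

glymph_error <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "glymph_error")))
}

stop_invalid_reference <- function(msg) glymph_error("glymph_invalid_reference", msg)
stop_empty_series <- function(msg) glymph_error("glymph_empty_series", msg)
stop_mapping <- function(msg, segments) {
  glymph_error("glymph_mapping_error", msg, segments = segments)
}
stop_degenerate_test <- function(msg) glymph_error("glymph_degenerate_test", msg)
stop_insufficient_data <- function(msg) glymph_error("glymph_insufficient_data", msg)
stop_non_convergence <- function(msg, rss_profile = NULL) {
  glymph_error("glymph_non_convergence", msg, rss_profile = rss_profile)
}
stop_unidentifiable <- function(msg) glymph_error("glymph_unidentifiable_breakpoint", msg)
stop_empty_grid <- function(msg) glymph_error("glymph_empty_grid", msg)
stop_degenerate_r2 <- function(msg) glymph_error("glymph_degenerate_r2", msg)
stop_empty_family <- function(msg) glymph_error("glymph_empty_family", msg)
stop_missing_cohort <- function(msg) glymph_error("glymph_missing_cohort", msg)
stop_invalid_scenario <- function(msg) glymph_error("glymph_invalid_scenario", msg)
stop_comparison <- function(msg) glymph_error("glymph_comparison_error", msg)
stop_collinear_baseline <- function(msg) glymph_error("glymph_collinear_baseline", msg)
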