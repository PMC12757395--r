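# Fixture builders shared across test files.

# Noiseless plateau-then-slope data with the breakpoint at an observed
# abscissa: exact recovery is possible.
noiseless_series <- function(psi = 2, beta0 = 10, beta1 = 5,
                             t = c(-1, 0, 1, 2, 3, 4, 5, 6)) {
  region_series(t, beta0 + beta1 * pmax(t - psi, 0))
}

# Published per-cohort breakpoint estimates (hours, 95% CI) shipped with
# the package; 17 regions x 2 cohorts.
published_estimates <- function() {
  utils::read.csv(system.file("extdata", "cohort_breakpoints.csv",
                              package = "glymphtime"),
                  stringsAsFactors = FALSE)
}

published_differences <- function() {
  utils::read.csv(system.file("extdata", "published_differences.csv",
                              package = "glymphtime"),
                  stringsAsFactors = FALSE)
}

# A small two-cohort, two-region scan table written to a temp CSV.
write_sim_csv <- function(path, seed = 404) {
  set.seed(seed)
  rows <- list()
  for (co in c("REF", "IIH")) {
    n_sub <- if (co == "REF") 12L else 8L
    for (rg in c("cortex", "white_matter")) {
      psi <- if (rg == "cortex") 1.0 else 3.0
      sc <- sim_scenario(true_psi = psi, beta1 = 0.05, sigma = 0.02,
                         n_subjects = n_sub)
      s <- simulate_cohort(sc, seed = NULL, cohort = co, region = rg)
      df <- as.data.frame(s)
      df$subject_id <- paste0(co, "_", df$subject_id)
      rows[[paste(co, rg)]] <- df
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
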