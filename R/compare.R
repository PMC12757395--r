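# Between-cohort comparison of first-appearance times: z-test on the
# breakpoint difference using the standard errors of the two separately
# fitted cohort models, Holm family-wise error control over the region
# family, and the expanded joint model with a common baseline but
# separate breakpoints per group.

#' Compare two cohorts' breakpoints with a z-test
#'
#' The difference in first-appearance time between two cohorts is tested
#' with a z-statistic built from the delta-method standard errors of the
#' two separately fitted segmented models:
#' `z = (psi_2 - psi_1) / sqrt(se_1^2 + se_2^2)`, with a two-sided
#' standard-normal p-value and a normal-quantile confidence interval for
#' the difference.
#'
#' @param model_ref,model_iih `segfit` objects for the reference and
#'   comparison cohorts (or any two cohorts; the difference is
#'   `model_iih` minus `model_ref`).
#' @param conf confidence level for the difference interval.
#' @return an object of class `breakpoint_comparison`: a list with
#'   `region`, `psi_ref`, `psi_iih`, `se_ref`, `se_iih`, `diff`,
#'   `se_diff`, `ci_diff`, `z`, `p` and `p_holm` (`NA` until
#'   [holm_adjust()] is applied across the family).
#' @export
compare_breakpoints <- function(model_ref, model_iih, conf = 0.95) {
  for (m in list(model_ref, model_iih)) {
    if (!inherits(m, "segfit")) stop("inputs must be segfit objects")
    if (!isTRUE(m$converged) || !is.finite(m$se_psi)) {
      stop_comparison(sprintf(
        "cohort model for %s / %s did not converge with a finite SE",
        m$cohort, m$region))
    }
  }
  d <- model_iih$psi - model_ref$psi
  se <- sqrt(model_ref$se_psi^2 + model_iih$se_psi^2)
  z <- d / se
  zq <- stats::qnorm((1 + conf) / 2)
  structure(
    list(
      region = model_ref$region,
      psi_ref = model_ref$psi, psi_iih = model_iih$psi,
      se_ref = model_ref$se_psi, se_iih = model_iih$se_psi,
      r2_ref = model_ref$r2, r2_iih = model_iih$r2,
      ci_ref = model_ref$ci_psi, ci_iih = model_iih$ci_psi,
      diff = d, se_diff = se, ci_diff = c(d - zq * se, d + zq * se),
      z = z, p = 2 * stats::pnorm(-abs(z)), p_holm = NA_real_,
      conf = conf
    ),
    class = "breakpoint_comparison"
  )
}

#' @export
print.breakpoint_comparison <- function(x, ...) {
  cat(sprintf("Breakpoint comparison%s\n",
              if (nzchar(x$region)) paste0(": ", x$region) else ""))
  cat(sprintf("  difference  %.2f h  [%.0f%% CI %.2f, %.2f]\n",
              x$diff, 100 * x$conf, x$ci_diff[1L], x$ci_diff[2L]))
  cat(sprintf("  z = %.3f, p = %.4g%s\n", x$z, x$p,
              if (is.na(x$p_holm)) "" else sprintf(", Holm p = %.4g", x$p_holm)))
  invisible(x)
}

#' Holm step-down adjustment over a family of region comparisons
#'
#' Controls the family-wise error rate across the per-region z-tests of
#' one analysis run: p-values are sorted ascending and the i-th smallest
#' is multiplied by (m - i + 1), with a running maximum enforcing
#' monotonicity and a cap at 1.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @param alpha family-wise significance level for the flags.
#' @return a list with `p_holm` (adjusted p-values, original order) and
#'   `flag` (logical, `p_holm <= alpha`).
#' @export
holm_adjust <- function(p, alpha = 0.05) {
  if (length(p) == 0L) stop_empty_family("empty p-value family")
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  adj <- stats::p.adjust(p, method = "holm")
  list(p_holm = adj, flag = adj <= alpha)
}

#' Build a comparison table across regions
#'
#' Applies [holm_adjust()] over the family of per-region comparisons and
#' assembles one row per region.
#'
#' @param comparisons a list of [compare_breakpoints()] results, one per
#'   region (the Holm family).
#' @param alpha family-wise significance level.
#' @return a data frame with columns `region`, `psi_ref`, `ci_ref_low`,
#'   `ci_ref_high`, `r2_ref`, `psi_iih`, `ci_iih_low`, `ci_iih_high`,
#'   `r2_iih`, `diff`, `ci_diff_low`, `ci_diff_high`, `z`, `p`, `p_holm`,
#'   `flag`.
#' @export
comparison_table <- function(comparisons, alpha = 0.05) {
  if (length(comparisons) == 0L) stop_empty_family("no comparisons supplied")
  stopifnot(all(vapply(comparisons, inherits, logical(1L),
                       "breakpoint_comparison")))
  holm <- holm_adjust(vapply(comparisons, `[[`, numeric(1L), "p"),
                      alpha = alpha)
  rows <- lapply(seq_along(comparisons), function(i) {
    x <- comparisons[[i]]
    data.frame(
      region = x$region,
      psi_ref = x$psi_ref, ci_ref_low = x$ci_ref[1L], ci_ref_high = x$ci_ref[2L],
      r2_ref = x$r2_ref,
      psi_iih = x$psi_iih, ci_iih_low = x$ci_iih[1L], ci_iih_high = x$ci_iih[2L],
      r2_iih = x$r2_iih,
      diff = x$diff, ci_diff_low = x$ci_diff[1L], ci_diff_high = x$ci_diff[2L],
      z = x$z, p = x$p, p_holm = holm$p_holm[i], flag = holm$flag[i],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort comparison from published estimates instead of raw data
#'
#' When only per-cohort breakpoint estimates with confidence intervals
#' are available (e.g. from a published table), the z-test can still be
#' run: each standard error is recovered from the interval half-width as
#' `(high - low) / (2 * qnorm((1 + conf) / 2))`.
#'
#' @param estimates a data frame with columns `region`, `cohort`, `psi`,
#'   `ci_low`, `ci_high` and optionally `r2`; exactly two cohorts.
#' @param ref label of the reference cohort (differences are
#'   other-minus-reference).
#' @param conf confidence level of the supplied intervals (and of the
#'   difference intervals produced).
#' @param alpha family-wise level for the Holm flags.
#' @return a comparison table as from [comparison_table()].
#' @export
compare_from_estimates <- function(estimates, ref = "REF", conf = 0.95,
                                   alpha = 0.05) {
  need <- c("region", "cohort", "psi", "ci_low", "ci_high")
  missing_cols <- setdiff(need, names(estimates))
  if (length(missing_cols)) {
    stop("estimates is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  cohorts <- unique(estimates$cohort)
  if (length(cohorts) != 2L) stop_missing_cohort("need exactly two cohorts")
  if (!ref %in% cohorts) {
    stop_missing_cohort(sprintf("reference cohort '%s' not present", ref))
  }
  alt <- setdiff(cohorts, ref)
  zq <- stats::qnorm((1 + conf) / 2)
  pseudo <- function(row) {
    se <- (row$ci_high - row$ci_low) / (2 * zq)
    structure(
      list(psi = row$psi, se_psi = se, ci_psi = c(row$ci_low, row$ci_high),
           r2 = if ("r2" %in% names(row)) row$r2 else NA_real_,
           region = row$region, cohort = row$cohort,
           converged = TRUE, conf = conf),
      class = "segfit"
    )
  }
  regions <- unique(estimates$region)
  comparisons <- lapply(regions, function(rg) {
    sub <- estimates[estimates$region == rg, , drop = FALSE]
    if (nrow(sub) != 2L) {
      stop_missing_cohort(sprintf("region '%s' lacks one of the cohorts", rg))
    }
    compare_breakpoints(pseudo(sub[sub$cohort == ref, , drop = FALSE]),
                        pseudo(sub[sub$cohort == alt, , drop = FALSE]),
                        conf = conf)
  })
  comparison_table(comparisons, alpha = alpha)
}

#' Joint two-group segmented model with a shared baseline
#'
#' The expanded model fits both cohorts together with one common
#' pre-break horizontal level but separate breakpoints and post-break
#' slopes per group: `mu_g(t) = beta0 + beta1_g * max(t - psi_g, 0)`.
#' Both breakpoints are updated simultaneously by the same iterative
#' linearization as [fit_segmented()]. Because minor systematic baseline
#' differences between cohorts are absorbed into the shared level, the
#' separate-fit z-test remains the primary comparison; this model serves
#' reporting and plotting.
#'
#' @param series_ref,series_iih [region_series()] objects for the two
#'   cohorts.
#' @param control a [seg_control()].
#' @return an object of class `segfit_joint`: `beta0`, and per group
#'   `psi`, `beta1`, `se_psi`, `ci_psi`; plus `rss`, `r2`, `converged`,
#'   `n_iter`, and the pooled data with group labels.
#' @export
fit_joint_two_group <- function(series_ref, series_iih,
                                control = seg_control()) {
  stopifnot(inherits(series_ref, "region_series"),
            inherits(series_iih, "region_series"),
            inherits(control, "seg_control"))
  sers <- list(ref = series_ref, iih = series_iih)
  m <- control$min_points_per_segment
  for (nm in names(sers)) {
    s <- sers[[nm]]
    if (s$n_obs < 4L) {
      stop_insufficient_data(sprintf("group '%s' has fewer than 4 observations", nm))
    }
    if (!series_fittable(s)) {
      stop_collinear_baseline(sprintf(
        "group '%s' lacks pre-breakpoint observations to anchor the shared baseline",
        nm))
    }
  }
  t <- c(series_ref$time_h, series_iih$time_h)
  y <- c(series_ref$signal, series_iih$signal)
  g <- rep(c(1L, 2L), c(series_ref$n_obs, series_iih$n_obs))
  bounds <- lapply(sers, function(s) psi_bounds(s$time_h, m))

  joint_rss <- function(psi) {
    u1 <- (g == 1L) * pmax(t - psi[1L], 0)
    u2 <- (g == 2L) * pmax(t - psi[2L], 0)
    f <- stats::lm.fit(cbind(1, u1, u2), y)
    sum(f$residuals^2)
  }

  # start from the separate single-group fits
  init <- vapply(sers, function(s) fit_segmented(s, control)$psi, numeric(1L))
  psi <- c(min(max(init[1L], bounds[[1L]][1L]), bounds[[1L]][2L]),
           min(max(init[2L], bounds[[2L]][1L]), bounds[[2L]][2L]))
  rss_cur <- joint_rss(psi)
  converged <- FALSE
  n_iter <- 0L
  slope_eps <- sqrt(.Machine$double.eps) * max(1, stats::sd(y))
  for (it in seq_len(control$max_iter)) {
    n_iter <- it
    u1 <- (g == 1L) * pmax(t - psi[1L], 0)
    u2 <- (g == 2L) * pmax(t - psi[2L], 0)
    v1 <- -((g == 1L) & (t > psi[1L]))
    v2 <- -((g == 2L) & (t > psi[2L]))
    wf <- stats::lm.fit(cbind(1, u1, u2, v1, v2), y)
    cf <- wf$coefficients
    if (anyNA(cf[2:3]) || any(abs(cf[2:3]) < slope_eps)) {
      stop_unidentifiable(
        "a group's post-break slope is indistinguishable from zero")
    }
    step <- c(cf[4L] / cf[2L], cf[5L] / cf[3L])
    h <- 1
    repeat {
      psi_new <- c(
        min(max(psi[1L] + h * step[1L], bounds[[1L]][1L]), bounds[[1L]][2L]),
        min(max(psi[2L] + h * step[2L], bounds[[2L]][1L]), bounds[[2L]][2L])
      )
      rss_new <- joint_rss(psi_new)
      if (rss_new <= rss_cur * (1 + 1e-12) || h < 1 / 64) break
      h <- h / 2
    }
    moved <- max(abs(psi_new - psi))
    psi <- psi_new
    rss_cur <- rss_new
    if (moved < control$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop_non_convergence("joint two-group fit did not converge")
  }

  # final parameters and delta-method SEs from the working model at psi
  u1 <- (g == 1L) * pmax(t - psi[1L], 0)
  u2 <- (g == 2L) * pmax(t - psi[2L], 0)
  v1 <- -((g == 1L) & (t > psi[1L]))
  v2 <- -((g == 2L) & (t > psi[2L]))
  X <- cbind(1, u1, u2, v1, v2)
  wf <- stats::lm.fit(X, y)
  p_rank <- wf$rank
  n <- length(y)
  sigma2 <- sum(wf$residuals^2) / (n - p_rank)
  XtX_inv <- chol2inv(chol(crossprod(X[, seq_len(p_rank), drop = FALSE])))
  se_all <- sqrt(sigma2 * diag(XtX_inv))
  delta <- wf$coefficients[2:3]
  se_psi <- se_all[4:5] / abs(delta)

  two <- stats::lm.fit(cbind(1, u1, u2), y)
  rss <- sum(two$residuals^2)
  tss <- sum((y - mean(y))^2)
  zq <- stats::qnorm((1 + control$conf) / 2)
  structure(
    list(
      beta0 = unname(two$coefficients[1L]),
      psi = stats::setNames(psi, c("ref", "iih")),
      beta1 = stats::setNames(unname(two$coefficients[2:3]), c("ref", "iih")),
      se_psi = stats::setNames(unname(se_psi), c("ref", "iih")),
      ci_psi = rbind(ref = psi[1L] + c(-1, 1) * zq * se_psi[1L],
                     iih = psi[2L] + c(-1, 1) * zq * se_psi[2L]),
      rss = rss, tss = tss, r2 = 1 - rss / tss, sigma2 = sigma2,
      n_obs = n, converged = TRUE, n_iter = n_iter, conf = control$conf,
      region = series_ref$region,
      cohorts = c(series_ref$cohort, series_iih$cohort),
      time_h = t, signal = y, group = g
    ),
    class = "segfit_joint"
  )
}

#' @export
print.segfit_joint <- function(x, ...) {
  cat(sprintf("Joint two-group segmented fit%s (shared baseline %.4f)\n",
              if (nzchar(x$region)) paste0(": ", x$region) else "", x$beta0))
  for (i in 1:2) {
    cat(sprintf("  %-4s breakpoint %.3f h [%.0f%% CI %.3f, %.3f], slope %.4f/h\n",
                c(x$cohorts[1L], x$cohorts[2L])[i], x$psi[i], 100 * x$conf,
                x$ci_psi[i, 1L], x$ci_psi[i, 2L], x$beta1[i]))
  }
  cat(sprintf("  n = %d, R^2 = %.3f, %d iterations\n", x$n_obs, x$r2, x$n_iter))
  invisible(x)
}
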