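# Plateau-then-slope segmented regression.
#
# Mean function: mu(t) = beta0                      for t <= psi
#                        beta0 + beta1 * (t - psi)  for t >  psi
# i.e. mu(t) = beta0 + beta1 * max(t - psi, 0). The breakpoint psi is the
# estimated time of first tracer appearance. The pre-break slope is fixed
# at zero by construction (no linear term before psi), so the model has
# three parameters: beta0, beta1 and psi.
#
# Estimation is by iterative linearization: at a working breakpoint
# psi_k, regress the signal on U = max(t - psi_k, 0) and
# V = -1[t > psi_k]. Writing the coefficients as (beta0, delta, gamma),
# gamma measures the first-order gap between the working breakpoint and
# the least-squares one, and the update is psi_{k+1} = psi_k +
# gamma/delta. At convergence gamma ~ 0, delta is the post-break slope,
# and SE(psi) = SE(gamma)/|delta| by the delta method.

#' Fitting controls for the segmented model
#'
#' @param psi_init starting breakpoint in hours, or `"auto"` to start
#'   from the median of the admissible breakpoint interval.
#' @param max_iter maximum linearization iterations per start.
#' @param tol convergence tolerance on the breakpoint update, in hours.
#' @param conf confidence level for the breakpoint interval.
#' @param n_restarts number of additional starting breakpoints, spread
#'   over interior quantiles of the admissible interval, tried when the
#'   first start fails to converge (all convergent solutions are kept and
#'   the minimum-RSS one reported).
#' @param min_points_per_segment minimum observations required on each
#'   side of any admissible breakpoint.
#' @param allow_psi_outside_observed if `FALSE` (default) the breakpoint
#'   is constrained to the observed time range.
#' @return a list of class `seg_control`.
#' @export
seg_control <- function(psi_init = "auto", max_iter = 50L, tol = 1e-6,
                        conf = 0.95, n_restarts = 10L,
                        min_points_per_segment = 2L,
                        allow_psi_outside_observed = FALSE) {
  stopifnot(tol > 0, max_iter >= 1, conf > 0, conf < 1,
            n_restarts >= 0, min_points_per_segment >= 1)
  structure(
    list(psi_init = psi_init, max_iter = as.integer(max_iter), tol = tol,
         conf = conf, n_restarts = as.integer(n_restarts),
         min_points_per_segment = as.integer(min_points_per_segment),
         allow_psi_outside_observed = allow_psi_outside_observed),
    class = "seg_control"
  )
}

# Admissible breakpoint interval: psi must leave >= m observations with
# t <= psi (plateau) and >= m with t > psi (slope). With sorted times
# t_(1) <= ... <= t_(n) that is [t_(m), t_(n-m+1)), shrunk slightly off
# the right endpoint so the slope segment is never empty.
psi_bounds <- function(time_h, m) {
  ts <- sort(time_h)
  n <- length(ts)
  if (n < 2L * m) {
    stop_insufficient_data(sprintf(
      "need at least %d observations for %d per segment", 2L * m, m))
  }
  lo <- ts[m]
  hi <- ts[n - m + 1L]
  if (lo >= hi) {
    stop_insufficient_data("observed times too tied to place a breakpoint")
  }
  eps <- 1e-8 * max(1, diff(range(ts)))
  c(lo, hi - eps)
}

# Profile RSS of the two-parameter least-squares fit of
# beta0 + beta1 * max(t - psi, 0), vectorized over candidate psi.
profile_rss <- function(time_h, signal, psi) {
  n <- length(time_h)
  sy <- sum(signal)
  syy <- sum(signal^2) - sy^2 / n
  vapply(psi, function(p) {
    u <- pmax(time_h - p, 0)
    su <- sum(u)
    suu <- sum(u^2) - su^2 / n
    if (suu <= 0) return(syy)  # U identically zero: intercept-only fit
    suy <- sum(u * signal) - su * sy / n
    max(syy - suy^2 / suu, 0)
  }, numeric(1L))
}

# Closed-form two-parameter fit at a fixed breakpoint.
fit_at_psi <- function(time_h, signal, psi) {
  n <- length(time_h)
  u <- pmax(time_h - psi, 0)
  su <- sum(u); sy <- sum(signal)
  suu <- sum(u^2) - su^2 / n
  syy <- sum(signal^2) - sy^2 / n
  if (suu <= 0) {
    beta1 <- 0
    beta0 <- mean(signal)
  } else {
    beta1 <- (sum(u * signal) - su * sy / n) / suu
    beta0 <- (sy - beta1 * su) / n
  }
  fitted <- beta0 + beta1 * u
  rss <- sum((signal - fitted)^2)
  list(beta0 = beta0, beta1 = beta1, rss = rss, tss = syy, fitted = fitted)
}

# One run of the linearization from a given start. Returns NULL when the
# run fails to converge; signals nothing.
linearize_from <- function(time_h, signal, psi0, bounds, control) {
  psi <- min(max(psi0, bounds[1L]), bounds[2L])
  rss_cur <- profile_rss(time_h, signal, psi)
  slope_eps <- sqrt(.Machine$double.eps) *
    max(1, stats::sd(signal) / max(diff(range(time_h)), 1e-12))
  converged <- FALSE
  n_iter <- 0L
  unident <- FALSE
  for (it in seq_len(control$max_iter)) {
    n_iter <- it
    u <- pmax(time_h - psi, 0)
    v <- -(time_h > psi)
    wf <- stats::lm.fit(cbind(1, u, v), signal)
    cf <- wf$coefficients
    if (anyNA(cf) || !is.finite(cf[2L]) || abs(cf[2L]) < slope_eps) {
      unident <- TRUE
      break
    }
    step <- cf[3L] / cf[2L]
    # step-halving: accept the first (possibly clamped) update that does
    # not increase the profile RSS; if no such step exists the current
    # breakpoint is a local minimum of the attainable profile
    h <- 1
    accepted <- FALSE
    psi_new <- psi
    rss_new <- rss_cur
    while (h >= 1 / 64) {
      cand <- min(max(psi + h * step, bounds[1L]), bounds[2L])
      rss_cand <- profile_rss(time_h, signal, cand)
      if (rss_cand <= rss_cur * (1 + 1e-12)) {
        psi_new <- cand
        rss_new <- rss_cand
        accepted <- TRUE
        break
      }
      h <- h / 2
    }
    improvement <- rss_cur - rss_new
    moved <- abs(psi_new - psi)
    psi <- psi_new
    rss_cur <- rss_new
    if (!accepted || moved < control$tol ||
        improvement <= 1e-12 * max(rss_cur, .Machine$double.xmin)) {
      converged <- TRUE
      break
    }
  }
  if (unident) return(structure(list(), class = "glymph_unident_run"))
  if (!converged) return(NULL)
  list(psi = psi, rss = rss_cur, n_iter = n_iter)
}

#' Fit the plateau-then-slope segmented model to a pooled region series
#'
#' Estimates the baseline level, the breakpoint (time of first tracer
#' appearance) and the post-break slope by iterative linearization, with
#' a delta-method standard error and normal-quantile confidence interval
#' for the breakpoint. If the first start does not converge, additional
#' starts spread over the admissible breakpoint interval are tried and
#' the minimum-RSS convergent solution is kept.
#'
#' @param series a [region_series()], or a data frame with columns
#'   `time_h` and `signal`.
#' @param control a [seg_control()] list.
#' @return an object of class `segfit`: a list with `beta0`, `psi`,
#'   `beta1`, `se_psi`, `ci_psi`, `se_beta0`, `se_beta1`, `sigma2`, `r2`,
#'   `rss`, `tss`, `n_obs`, `converged`, `n_iter`, `conf`, plus the data
#'   and series labels.
#' @examples
#' t <- c(-1, 0, 1, 2, 3, 4, 5, 6)
#' y <- 10 + 5 * pmax(t - 2, 0)
#' fit <- fit_segmented(region_series(t, y))
#' fit$psi # 2
#' @export
fit_segmented <- function(series, control = seg_control()) {
  if (is.data.frame(series)) {
    series <- region_series(series$time_h, series$signal,
                            subject_id = series[["subject_id"]])
  }
  stopifnot(inherits(series, "region_series"), inherits(control, "seg_control"))
  time_h <- series$time_h
  signal <- series$signal
  n <- length(time_h)
  if (n < 4L) {
    stop_insufficient_data(sprintf(
      "segmented fit needs at least 4 observations, got %d", n))
  }
  if (!series_fittable(series)) {
    stop_insufficient_data(
      "need at least one pre-injection (t <= 0) and two post-injection observations")
  }
  if (stats::var(signal) == 0) {
    stop_unidentifiable("constant signal: breakpoint not identifiable")
  }
  bounds <- psi_bounds(time_h, control$min_points_per_segment)
  if (control$allow_psi_outside_observed) {
    span <- diff(range(time_h))
    bounds <- c(min(time_h) - span, max(time_h) + span)
  }

  starts <- if (identical(control$psi_init, "auto")) {
    mean(bounds)
  } else {
    as.numeric(control$psi_init)
  }
  if (control$n_restarts > 0L) {
    qs <- bounds[1L] + diff(bounds) *
      seq(0.05, 0.95, length.out = control$n_restarts)
    starts <- c(starts, qs)
  }

  # every start is run and the minimum-RSS convergent solution kept: the
  # profile RSS is non-convex (piecewise quadratic with kinks at the
  # data), so a single start can converge to a poor local or boundary
  # minimum that a neighbouring start escapes
  best <- NULL
  n_unident <- 0L
  for (k in seq_along(starts)) {
    run <- linearize_from(time_h, signal, starts[k], bounds, control)
    if (inherits(run, "glymph_unident_run")) {
      n_unident <- n_unident + 1L
      next
    }
    if (is.null(run)) next
    if (is.null(best) || run$rss < best$rss) best <- run
  }
  if (is.null(best)) {
    if (n_unident == length(starts)) {
      stop_unidentifiable(
        "post-break slope indistinguishable from zero: breakpoint not identifiable")
    }
    grid <- seq(bounds[1L], bounds[2L], length.out = 101L)
    stop_non_convergence(
      "no starting breakpoint led to a convergent fit",
      rss_profile = data.frame(psi = grid,
                               rss = profile_rss(time_h, signal, grid))
    )
  }

  psi <- best$psi
  two <- fit_at_psi(time_h, signal, psi)
  if (two$tss <= 0) stop_degenerate_r2("constant signal: R^2 undefined")

  # working model at the solution for delta-method standard errors
  u <- pmax(time_h - psi, 0)
  v <- -(time_h > psi)
  X <- cbind(`(Intercept)` = 1, U = u, V = v)
  wf <- stats::lm.fit(X, signal)
  p <- wf$rank
  sigma2 <- sum(wf$residuals^2) / (n - p)
  XtX_inv <- chol2inv(chol(crossprod(X[, seq_len(p), drop = FALSE])))
  se <- sqrt(sigma2 * diag(XtX_inv))
  delta <- wf$coefficients[["U"]]
  se_gamma <- if (p >= 3L) se[3L] else NA_real_
  se_psi <- se_gamma / abs(delta)
  z <- stats::qnorm((1 + control$conf) / 2)

  structure(
    list(
      beta0 = two$beta0, psi = psi, beta1 = two$beta1,
      se_psi = se_psi, ci_psi = c(psi - z * se_psi, psi + z * se_psi),
      se_beta0 = se[1L], se_beta1 = se[2L],
      sigma2 = sigma2, rss = two$rss, tss = two$tss,
      r2 = 1 - two$rss / two$tss,
      n_obs = n, converged = TRUE, n_iter = best$n_iter,
      conf = control$conf, psi_bounds = bounds,
      cohort = series$cohort, region = series$region,
      time_h = time_h, signal = signal, fitted = two$fitted
    ),
    class = "segfit"
  )
}

#' @export
print.segfit <- function(x, ...) {
  cat(sprintf("Plateau-then-slope segmented fit: %s%s\n",
              if (nzchar(x$cohort)) paste0(x$cohort, " / ") else "",
              if (nzchar(x$region)) x$region else "(unlabelled series)"))
  cat(sprintf("  breakpoint  %.3f h  [%.0f%% CI %.3f, %.3f]  (SE %.3f)\n",
              x$psi, 100 * x$conf, x$ci_psi[1L], x$ci_psi[2L], x$se_psi))
  cat(sprintf("  baseline    %.4f\n  slope       %.4f per h\n", x$beta0, x$beta1))
  cat(sprintf("  n = %d, R^2 = %.3f, RSS = %.4g, %d iterations\n",
              x$n_obs, x$r2, x$rss, x$n_iter))
  invisible(x)
}

#' @export
coef.segfit <- function(object, ...) {
  c(beta0 = object$beta0, beta1 = object$beta1, psi = object$psi)
}

#' Predicted mean signal from a segmented fit
#'
#' @param object a `segfit` object.
#' @param newdata optional numeric vector of times (hours); defaults to
#'   the times the model was fitted to.
#' @param ... unused.
#' @return numeric vector of predicted normalized signals.
#' @export
predict.segfit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$time_h else as.numeric(newdata)
  object$beta0 + object$beta1 * pmax(t - object$psi, 0)
}

#' Brute-force grid-search oracle for the breakpoint
#'
#' Profiles the residual sum of squares of the two-parameter closed-form
#' fit of `beta0 + beta1 * max(t - psi, 0)` over a grid of candidate
#' breakpoints, returning the minimum-RSS candidate (ties broken toward
#' the smallest breakpoint, matching the first-appearance reading) and
#' the full profile. Independent of the iterative estimator; used to
#' validate it.
#'
#' @param series a [region_series()] or data frame with `time_h`,
#'   `signal`.
#' @param grid strictly increasing numeric vector of candidate
#'   breakpoints; candidates leaving fewer than `min_points_per_segment`
#'   observations on either side are dropped.
#' @param min_points_per_segment minimum observations per segment.
#' @return a list with `psi` (the minimizer), `rss` (its RSS) and
#'   `profile` (data frame of `psi`, `rss` over the admissible grid).
#' @export
grid_profile <- function(series, grid, min_points_per_segment = 2L) {
  if (is.data.frame(series)) {
    series <- region_series(series$time_h, series$signal)
  }
  stopifnot(inherits(series, "region_series"))
  grid <- as.numeric(grid)
  if (length(grid) == 0L) stop_empty_grid("candidate grid is empty")
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing")
  }
  time_h <- series$time_h
  m <- min_points_per_segment
  admissible <- vapply(grid, function(p) {
    sum(time_h <= p) >= m && sum(time_h > p) >= m
  }, logical(1L))
  if (!any(admissible)) {
    stop_empty_grid("no grid candidate leaves enough observations per segment")
  }
  grid <- grid[admissible]
  rss <- profile_rss(time_h, series$signal, grid)
  i <- which(rss <= min(rss) + 0)[1L]  # ties: smallest psi wins
  list(psi = grid[i], rss = rss[i],
       profile = data.frame(psi = grid, rss = rss))
}
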