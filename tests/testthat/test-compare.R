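# Cohort comparison: z-test arithmetic, Holm adjustment, the joint
# common-baseline model.

pseudo_fit <- function(psi, se, region = "r") {
  structure(list(psi = psi, se_psi = se, ci_psi = psi + c(-1, 1) * 1.96 * se,
                 r2 = NA_real_, region = region, cohort = "x",
                 converged = TRUE, conf = 0.95),
            class = "segfit")
}

test_that("compare_breakpoints implements the two-SE z-test", {
  a <- pseudo_fit(1.0, 0.2)
  b <- pseudo_fit(2.0, 0.3)
  cmp <- compare_breakpoints(a, b)
  expect_equal(cmp$diff, 1.0)
  expect_equal(cmp$se_diff, sqrt(0.2^2 + 0.3^2))
  expect_equal(cmp$z, 1.0 / sqrt(0.13))
  expect_equal(cmp$p, 2 * pnorm(-abs(cmp$z)))
  expect_equal(cmp$ci_diff,
               1.0 + c(-1, 1) * qnorm(0.975) * sqrt(0.13))

  # identical models: no difference
  same <- compare_breakpoints(a, a)
  expect_equal(same$diff, 0)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  # antisymmetry: swapping negates diff and z, keeps p
  rev <- compare_breakpoints(b, a)
  expect_equal(rev$diff, -cmp$diff)
  expect_equal(rev$z, -cmp$z)
  expect_equal(rev$p, cmp$p)

  bad <- pseudo_fit(1, 0.2)
  bad$converged <- FALSE
  expect_error(compare_breakpoints(bad, a), class = "glymph_comparison_error")
})

test_that("holm_adjust is step-down Holm, bounded by raw and Bonferroni", {
  expect_equal(holm_adjust(0.03)$p_holm, 0.03)       # m = 1: unchanged
  two <- holm_adjust(c(0.01, 0.04))
  expect_equal(two$p_holm, c(0.02, 0.04))
  expect_true(all(two$flag))

  # cross-check against a direct sequential-rejection implementation
  direct_holm <- function(p, alpha) {
    m <- length(p)
    o <- order(p)
    rej <- logical(m)
    for (i in seq_len(m)) {
      if (p[o[i]] <= alpha / (m - i + 1)) rej[o[i]] <- TRUE else break
    }
    rej
  }
  set.seed(301)
  for (i in 1:25) {
    m <- sample(2:20, 1)
    p <- runif(m)^sample(1:3, 1)
    adj <- holm_adjust(p, alpha = 0.05)
    expect_true(all(adj$p_holm >= p))
    expect_true(all(adj$p_holm <= pmin(1, m * p) + 1e-15))
    expect_identical(adj$flag, direct_holm(p, 0.05))
  }

  expect_error(holm_adjust(numeric(0)), class = "glymph_empty_family")
  expect_error(holm_adjust(c(0.5, 0)), "0, 1")
})

test_that("joint two-group model recovers shared-baseline truth exactly", {
  t <- c(-1, 0, 1, 2, 3, 4, 5, 6)
  s1 <- region_series(t, 10 + 4 * pmax(t - 1, 0), "REF", "r")
  s2 <- region_series(t, 10 + 2 * pmax(t - 3, 0), "IIH", "r")
  j <- fit_joint_two_group(s1, s2)
  expect_true(j$converged)
  expect_equal(j$beta0, 10, tolerance = 1e-8)
  expect_equal(unname(j$psi), c(1, 3), tolerance = 1e-8)
  expect_equal(unname(j$beta1), c(4, 2), tolerance = 1e-8)
  expect_equal(j$r2, 1)
})

test_that("joint model on identical groups matches the single-group fit", {
  s <- noiseless_series(2, 10, 5)
  single <- fit_segmented(s)
  j <- fit_joint_two_group(s, s)
  expect_equal(unname(j$psi), rep(single$psi, 2), tolerance = 1e-8)
  expect_equal(j$beta0, single$beta0, tolerance = 1e-8)
  expect_equal(unname(j$beta1), rep(single$beta1, 2), tolerance = 1e-8)

  set.seed(302)
  sim <- simulate_cohort(sim_scenario(true_psi = 1.5, n_subjects = 20),
                         seed = NULL)
  single2 <- fit_segmented(sim)
  j2 <- fit_joint_two_group(sim, sim)
  expect_equal(unname(j2$psi), rep(single2$psi, 2), tolerance = 1e-4)
  expect_equal(j2$beta0, single2$beta0, tolerance = 1e-6)
})

test_that("joint model matches a 2-D grid-search oracle on simulated data", {
  set.seed(303)
  sA <- simulate_cohort(sim_scenario(true_psi = 1.0, n_subjects = 30),
                        seed = NULL, cohort = "REF")
  sB <- simulate_cohort(sim_scenario(true_psi = 3.0, n_subjects = 15),
                        seed = NULL, cohort = "IIH")
  j <- fit_joint_two_group(sA, sB)
  t_all <- c(sA$time_h, sB$time_h)
  y_all <- c(sA$signal, sB$signal)
  g <- rep(1:2, c(sA$n_obs, sB$n_obs))
  step <- 0.01
  best <- c(NA, NA); brss <- Inf
  for (p1 in seq(0.7, 1.3, by = step)) {
    u1 <- (g == 1) * pmax(t_all - p1, 0)
    for (p2 in seq(2.7, 3.3, by = step)) {
      u2 <- (g == 2) * pmax(t_all - p2, 0)
      r <- sum(stats::lm.fit(cbind(1, u1, u2), y_all)$residuals^2)
      if (r < brss) { brss <- r; best <- c(p1, p2) }
    }
  }
  expect_lte(abs(j$psi[[1L]] - best[1L]), step + 1e-9)
  expect_lte(abs(j$psi[[2L]] - best[2L]), step + 1e-9)
})

test_that("joint model demands pre-breakpoint data in both groups", {
  t <- c(-1, 0, 1, 2, 3, 4, 5, 6)
  s1 <- region_series(t, 10 + 4 * pmax(t - 1, 0), "REF", "r")
  post_only <- region_series(c(2, 3, 4, 5), c(10, 11, 12, 13), "IIH", "r")
  expect_error(fit_joint_two_group(s1, post_only),
               class = "glymph_collinear_baseline")
})

test_that("comparison_table assembles regions and applies Holm once", {
  cmps <- list(
    compare_breakpoints(pseudo_fit(1, 0.2, "A"), pseudo_fit(2.5, 0.2, "A")),
    compare_breakpoints(pseudo_fit(1, 0.2, "B"), pseudo_fit(1.1, 0.2, "B"))
  )
  tab <- comparison_table(cmps)
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$p_holm >= tab$p))
  expect_error(comparison_table(list()), class = "glymph_empty_family")
})
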