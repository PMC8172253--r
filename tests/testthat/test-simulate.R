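# Trial generation (normal and skew-normal), truth computation and the
# performance-criteria aggregation.

test_that("generation is reproducible and respects the design", {
  sc <- baseline_scenario(n = 120)
  d1 <- generate_trial(sc, seed = 71)
  d2 <- generate_trial(sc, seed = 71)
  expect_identical(d1, d2)
  expect_equal(sum(d1$treat), 60)
  expect_true(all(d1$Y3 %in% 1:5))
  expect_true(all(d1$Y4 %in% 0:1))
})

test_that("large-sample moments match the generating model", {
  sc <- baseline_scenario(n = 2e5)
  dat <- generate_trial(sc, seed = 73)
  p <- sc$params
  r1 <- dat$Y1 - (p$alpha0 + p$alpha1 * dat$treat + p$alpha2 * dat$y10)
  r2 <- dat$Y2 - (p$beta0 + p$beta1 * dat$treat + p$beta2 * dat$y20)
  S <- make_sigma(p)
  expect_equal(stats::var(r1), S[1, 1], tolerance = 0.01)
  expect_equal(stats::var(r2), S[2, 2], tolerance = 0.01)
  expect_equal(stats::cov(r1, r2), S[1, 2], tolerance = 0.02)
  # ordinal level frequencies in the control arm follow the Phi bands
  ctrl <- dat[dat$treat == 0, ]
  tau <- c(-Inf, p$tau, Inf)
  for (w in 1:5) {
    pw <- pnorm(tau[w + 1]) - pnorm(tau[w])
    se <- sqrt(pw * (1 - pw) / nrow(ctrl))
    expect_lt(abs(mean(ctrl$Y3 == w) - pw), 3 * se + 1e-4)
  }
  # binary component: P(Y4 = 0 | control) = Phi(-psi0)
  p0 <- pnorm(-p$psi0)
  expect_lt(abs(mean(ctrl$Y4 == 0) - p0),
            3 * sqrt(p0 * (1 - p0) / nrow(ctrl)))
})

test_that("skew generator reduces to normal at slant zero and is centred", {
  sc0 <- baseline_scenario(n = 100)
  expect_identical(generate_trial(sc0, seed = 75),
                   generate_trial_skew(sc0, seed = 75))
  sc <- baseline_scenario(n = 2e5, skew = c(4, 0, 0, 0))
  dat <- generate_trial_skew(sc, seed = 77)
  p <- sc$params
  e1 <- dat$Y1 - (p$alpha0 + p$alpha1 * dat$treat + p$alpha2 * dat$y10)
  # centring: mean error ~ 0
  expect_lt(abs(mean(e1)), 3 * sd(e1) / sqrt(nrow(dat)))
  # closed-form skew-normal skewness for the slant implied by the structure
  Obar <- stats::cov2cor(make_sigma(p))
  alpha <- c(4, 0, 0, 0)
  delta <- drop(Obar %*% alpha) / sqrt(1 + drop(crossprod(alpha, Obar %*% alpha)))
  dm <- delta[1] * sqrt(2 / pi)
  gamma1 <- (4 - pi) / 2 * dm^3 / (1 - dm^2)^1.5
  samp_skew <- mean(((e1 - mean(e1)) / sd(e1))^3)
  expect_lt(abs(samp_skew - gamma1), 0.05)
  expect_gt(abs(samp_skew), 0.2)  # the skew really is there
})

test_that("exact truth equals Monte Carlo truth on the baseline fixture", {
  sc <- baseline_scenario()
  exact <- true_effect(sc, method = "exact")
  mc <- true_effect(sc, method = "mc", n_mc = 4e5, seed = 79)
  se0 <- sqrt(exact$p0 * (1 - exact$p0) / 4e5)
  se1 <- sqrt(exact$p1 * (1 - exact$p1) / 4e5)
  expect_lt(abs(exact$p0 - mc$p0), 3 * se0)
  expect_lt(abs(exact$p1 - mc$p1), 3 * se1)
  # degenerate limit: thresholds at infinity
  sc2 <- sc; sc2$criteria <- responder_criteria(Inf, Inf)
  p <- sc2$params; p$tau[4] <- 30; p$psi0 <- -30; sc2$params <- p
  te <- true_effect(sc2, method = "exact")
  expect_equal(te$p0, 1, tolerance = 1e-6)
  expect_equal(te$p1, 1, tolerance = 1e-6)
})

test_that("performance summary implements the criteria definitions", {
  reps <- tibble::tibble(
    sim = rep(1:4, each = 1), seed = 1:4, method = "m",
    log_or = c(0.5, 0.5, 0.5, 0.5), se = 0.1,
    ci_low = -Inf, ci_high = Inf, p_value = 0, converged = TRUE)
  s <- performance_summary(reps, true_log_or = 0.5)
  expect_equal(s$bias, 0)
  expect_equal(s$mse, 0)
  expect_equal(s$coverage, 1)       # infinite CIs always cover
  expect_equal(s$power, 1)          # all p below alpha
  reps$p_value <- 1
  expect_equal(performance_summary(reps, 0.5)$power, 0)
  # non-converged replicates are excluded and counted
  reps$converged[1] <- FALSE
  s2 <- performance_summary(reps, 0.5)
  expect_equal(s2$n_used, 3)
  expect_equal(s2$n_fail, 1)
})

test_that("relative precision ratios follow the variance arithmetic", {
  reps <- dplyr::bind_rows(
    tibble::tibble(sim = 1:3, seed = 1:3, method = "A", log_or = 0,
                   se = c(1, 2, 3), ci_low = 0, ci_high = 0, p_value = 0.5,
                   converged = TRUE),
    tibble::tibble(sim = 1:3, seed = 1:3, method = "B", log_or = 0,
                   se = c(2, 4, 6), ci_low = 0, ci_high = 0, p_value = 0.5,
                   converged = TRUE))
  rp <- relative_precision(reps, "A", "B")
  expect_equal(rp$ratio, c(4, 4, 4))  # doubled SE -> fourfold variance
  rp_same <- relative_precision(reps, "A", "A")
  expect_equal(rp_same$ratio, c(1, 1, 1))
  # invariant to common rescaling
  reps2 <- dplyr::mutate(reps, se = se * 10)
  expect_equal(relative_precision(reps2, "A", "B")$ratio, rp$ratio)
})

test_that("run_scenario produces a coherent result object", {
  sc <- baseline_scenario(n = 150, n_sim = 3)
  res <- run_scenario(sc, methods = c("standard_binary", "augmented_binary"),
                      seed = 83)
  expect_s3_class(res, "lv_scenario_result")
  expect_equal(nrow(res$replicates), 6)
  expect_true(all(c("bias", "coverage", "power", "mse") %in%
                    names(res$summary)))
  # determinism of the whole pipeline
  res2 <- run_scenario(sc, methods = c("standard_binary",
                                       "augmented_binary"), seed = 83)
  expect_identical(res$replicates, res2$replicates)
})
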