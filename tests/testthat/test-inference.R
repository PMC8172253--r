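# Response probabilities, marginal effects and delta-method inference.

test_that("prob_response limits, independence product and monotonicity", {
  p <- lv_params(psi0 = -0.4, tau = c(-1.2, -0.4, 0.4, 1.2))
  crit_inf <- responder_criteria(Inf, Inf)
  # with eta3 = tau4 and eta4 = 0 fixed, probabilities stay below 1, so test
  # the limit behaviour through the continuous thresholds
  expect_equal(prob_response(p, crit_inf, 0, 0, 0),
               pnorm(1.2) * pnorm(0.4), tolerance = 1e-6)
  expect_equal(prob_response(p, responder_criteria(-40, 0), 0, 0, 0), 0)
  # independence: plain product of four univariate tails
  p2 <- lv_params(alpha1 = -0.3, sigma1 = 1.5, psi0 = -0.4,
                  tau = c(-1.2, -0.4, 0.4, 1.2))
  crit <- responder_criteria(0.3, 0.1)
  expect_equal(prob_response(p2, crit, 1, 0.2, -0.1),
               pnorm((0.3 - (-0.3 + 0)) / 1.5 - 0.2 / 1.5 * 0) *
                 pnorm(0.1) * pnorm(1.2) * pnorm(0.4),
               tolerance = 1e-5)
  # monotone nondecreasing in each continuous threshold
  p3 <- random_params(19)
  probs <- vapply(seq(-2, 2, length.out = 9), function(e)
    prob_response(p3, responder_criteria(e, 0.5), 1, 0, 0), numeric(1))
  expect_true(all(diff(probs) >= -1e-9))
  probs2 <- vapply(seq(-2, 2, length.out = 9), function(e)
    prob_response(p3, responder_criteria(0.5, e), 1, 0, 0), numeric(1))
  expect_true(all(diff(probs2) >= -1e-9))
})

test_that("prob_response agrees with a Monte-Carlo responder fraction", {
  p <- baseline_scenario()$params
  crit <- baseline_scenario()$criteria
  set.seed(61)
  n <- 1e6
  e <- matrix(rnorm(n * 4), n, 4) %*% chol(make_sigma(p))
  y10 <- 0.3; y20 <- -0.1
  lp <- linear_predictors(p, 1, y10, y20)
  resp <- (lp$mu[1] + e[, 1] <= crit$eta1) &
    (lp$mu[2] + e[, 2] <= crit$eta2) &
    (lp$mu[3] + e[, 3] <= p$tau[4]) &
    (lp$mu[4] + e[, 4] <= 0)
  mc <- mean(resp)
  se <- sqrt(mc * (1 - mc) / n)
  expect_lt(abs(prob_response(p, crit, 1, y10, y20) - mc), 3 * se)
})

test_that("null effects give OR = 1, RR = 1, RD = 0 exactly", {
  sc <- null_scenario(n = 150)
  dat <- generate_trial(sc, seed = 41)
  fit <- structure(list(params = sc$params,
                        u = transform_params(sc$params),
                        cov_u = NULL, converged = TRUE, method = "latent",
                        loglik = NA, n = nrow(dat)), class = "lv_fit")
  eff <- effect_measures(fit, dat, sc$criteria)
  expect_equal(eff$odds_ratio, 1)
  expect_equal(eff$risk_ratio, 1)
  expect_equal(eff$risk_difference, 0)
})

test_that("the marginal odds ratio follows its defining arithmetic", {
  # averaged probabilities 0.38 and 0.28 give (0.38/0.62)/(0.28/0.72)
  expect_equal(exp(qlogis(0.38) - qlogis(0.28)),
               (0.38 / 0.62) / (0.28 / 0.72), tolerance = 1e-12)
  expect_equal(round((0.38 / 0.62) / (0.28 / 0.72), 2), 1.58)
})

test_that("effect_measures equals a per-patient brute-force loop", {
  sc <- baseline_scenario(n = 60)
  dat <- generate_trial(sc, seed = 43)
  fit <- fit_latent(dat, control = list(hessian = FALSE))
  eff <- effect_measures(fit, dat, sc$criteria)
  ph <- fit$params
  p1 <- vapply(seq_len(nrow(dat)), function(i)
    prob_response(ph, sc$criteria, 1, dat$y10[i], dat$y20[i]), numeric(1))
  p0 <- vapply(seq_len(nrow(dat)), function(i)
    prob_response(ph, sc$criteria, 0, dat$y10[i], dat$y20[i]), numeric(1))
  N <- nrow(dat)
  or_oracle <- (sum(p1) / (N - sum(p1))) / (sum(p0) / (N - sum(p0)))
  expect_equal(eff$p1, mean(p1), tolerance = 1e-9)
  expect_equal(eff$p0, mean(p0), tolerance = 1e-9)
  expect_equal(eff$odds_ratio, or_oracle, tolerance = 1e-9)
})

test_that("delta-method variance: trivial cases and bootstrap sanity", {
  fit <- structure(list(u = c(a = 1, b = 2),
                        cov_u = diag(c(0.5, 2))), class = "lv_fit")
  # zero gradient -> zero variance
  expect_equal(delta_method_variance(fit, function(u) 42), 0)
  # scalar chain rule: f(u) = 3 u_1 -> var = 9 * 0.5
  expect_equal(delta_method_variance(fit, function(u) 3 * u[1]), 4.5,
               tolerance = 1e-6)
})

test_that("delta-method SE is in the ballpark of a bootstrap SE", {
  sc <- baseline_scenario(n = 200)
  dat <- generate_trial(sc, seed = 47)
  res <- analyse_method(dat, sc$criteria, "augmented_binary")
  set.seed(48)
  boots <- replicate(300, {
    idx <- sample.int(nrow(dat), replace = TRUE)
    tryCatch(
      suppressWarnings(
        fit_augmented_binary(dat[idx, ], sc$criteria)$effect$log_or),
      error = function(e) NA_real_)
  })
  expect_lt(abs(res$effect$se - sd(boots, na.rm = TRUE)) / res$effect$se,
            0.25)
})

test_that("Wald interval and p-value behave at the reference points", {
  w <- wald_ci_pvalue(0, 0.04)
  expect_equal(w$p_value, 1)
  expect_equal(w$ci_low, -w$ci_high)
  expect_equal(wald_ci_pvalue(0.7, 0)$ci_low, 0.7)  # degenerate CI
  expect_equal(wald_ci_pvalue(1.96, 1)$p_value, 0.05, tolerance = 1e-3)
  # CI always contains the point estimate
  w2 <- wald_ci_pvalue(-0.4, 0.1)
  expect_true(w2$ci_low <= -0.4 && -0.4 <= w2$ci_high)
})
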