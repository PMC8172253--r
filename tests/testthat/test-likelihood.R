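# Likelihood building blocks: linear predictors, conditional moments, cell
# probabilities and the patient/total log-likelihood.

test_that("linear predictors follow the mean structure", {
  p0 <- lv_params()
  expect_equal(linear_predictors(p0, 1, 2, 3)$mu, c(0, 0, 0, 0))
  p <- lv_params(alpha0 = 1, alpha1 = 2, alpha2 = 0.5, gamma1 = 0.7)
  expect_equal(linear_predictors(p, 1, 2, 0)$mu[1], 1 + 2 + 0.5 * 2)
  # the ordinal intercept is fixed at zero
  expect_equal(linear_predictors(p, 0, 5, 5)$mu[3], 0)
  expect_equal(linear_predictors(p, 1, 5, 5)$mu[3], 0.7)
})

test_that("conditional moments equal the Schur-complement oracle", {
  for (s in 1:25) {
    p <- random_params(s)
    set.seed(3000 + s)
    treat <- rbinom(1, 1, 0.5); y10 <- rnorm(1); y20 <- rnorm(1)
    Y1 <- rnorm(1, sd = 2); Y2 <- rnorm(1, sd = 2)
    lp <- linear_predictors(p, treat, y10, y20)
    cm <- conditional_moments(p, lp, Y1, Y2)
    S <- lp$Sigma
    A <- S[1:2, 1:2]; B <- S[3:4, 1:2]
    mu_cond <- lp$mu[3:4] +
      drop(B %*% solve(A, c(Y1, Y2) - lp$mu[1:2]))
    S_cond <- S[3:4, 3:4] - B %*% solve(A, t(B))
    expect_equal(c(cm$mu3, cm$mu4), mu_cond, tolerance = 1e-10)
    expect_equal(cm$Sigma34, S_cond, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("conditioning on the mean leaves the latent means unchanged", {
  p <- random_params(7)
  lp <- linear_predictors(p, 1, 0.3, -0.2)
  cm <- conditional_moments(p, lp, lp$mu[1], lp$mu[2])
  expect_equal(c(cm$mu3, cm$mu4), lp$mu[3:4])
})

test_that("cell probabilities are coherent and factorise under independence", {
  for (s in 1:10) {
    p <- random_params(40 + s)
    set.seed(500 + s)
    lp <- linear_predictors(p, 1, rnorm(1), rnorm(1))
    cm <- conditional_moments(p, lp, rnorm(1, lp$mu[1]), rnorm(1, lp$mu[2]))
    cells <- outer(1:5, 0:1,
                   Vectorize(function(w, k) cell_probability(cm, p$tau, w, k)))
    expect_true(all(cells >= 0 & cells <= 1))
    expect_equal(sum(cells), 1, tolerance = 1e-8)
  }
  # independence: product of univariate bands
  p <- lv_params(tau = c(-1, 0, 0.5, 1.2), psi0 = 0.3)
  lp <- linear_predictors(p, 0, 0, 0)
  cm <- conditional_moments(p, lp, 0.4, -0.2)
  pr <- cell_probability(cm, p$tau, 3, 0)
  expect_equal(pr, (pnorm(0.5) - pnorm(0)) * pnorm(-0.3), tolerance = 1e-12)
})

test_that("patient log-likelihood factorises when all correlations are zero", {
  p <- lv_params(alpha0 = 0.5, alpha1 = -0.3, alpha2 = 0.4,
                 beta1 = -0.2, gamma1 = -0.25, psi0 = -0.5, psi1 = -0.3,
                 tau = c(-1.3, -0.4, 0.3, 1.1), sigma1 = 1.4, sigma2 = 0.7)
  dat <- small_trial(n = 40, seed = 5)
  for (i in c(1, 17, 40)) {
    rec <- dat[i, ]
    expect_equal(patient_loglik(p, rec), indep_loglik_oracle(p, rec),
                 tolerance = 1e-10)
  }
})

test_that("patient likelihood matches a bivariate-CDF oracle with correlation", {
  skip_if_not_installed("mvtnorm")
  p <- random_params(3)
  dat <- small_trial(n = 15, seed = 9)
  tau <- c(-Inf, p$tau, Inf)
  for (i in c(2, 8, 15)) {
    rec <- dat[i, ]
    lp <- linear_predictors(p, rec$treat, rec$y10, rec$y20)
    S <- lp$Sigma
    # oracle: f(Y1, Y2) x P(rectangle) via mvtnorm on the conditional law
    A <- S[1:2, 1:2]
    dens <- mvtnorm::dmvnorm(c(rec$Y1, rec$Y2), lp$mu[1:2], A, log = TRUE)
    B <- S[3:4, 1:2]
    mu_c <- lp$mu[3:4] + drop(B %*% solve(A, c(rec$Y1, rec$Y2) - lp$mu[1:2]))
    S_c <- S[3:4, 3:4] - B %*% solve(A, t(B))
    lo <- c(tau[rec$Y3], if (rec$Y4 == 0) -Inf else 0)
    hi <- c(tau[rec$Y3 + 1], if (rec$Y4 == 0) 0 else Inf)
    rect <- mvtnorm::pmvnorm(lower = lo - mu_c, upper = hi - mu_c,
                             sigma = S_c,
                             algorithm = mvtnorm::GenzBretz(abseps = 1e-10))
    expect_equal(patient_loglik(p, rec), dens + log(rect[1]),
                 tolerance = 1e-7)
  }
})

test_that("total negative log-likelihood is additive and order-invariant", {
  p <- random_params(12)
  u <- transform_params(p)
  dat <- small_trial(n = 60, seed = 21)
  nll <- total_negloglik(u, dat)
  expect_equal(total_negloglik(u, dplyr::bind_rows(dat, dat)), 2 * nll,
               tolerance = 1e-9)
  per_patient <- vapply(seq_len(nrow(dat)),
                        function(i) patient_loglik(p, dat[i, ]), numeric(1))
  expect_equal(nll, -sum(per_patient), tolerance = 1e-9)
  set.seed(2)
  expect_equal(total_negloglik(u, dat[sample(60), ]), nll, tolerance = 1e-9)
})

test_that("non-PD parameter regions return the documented penalty", {
  u <- transform_params(random_params(1))
  u[grep("omega1[34]|omega2[34]|omega34", names(u))] <- 6  # rho ~ 0.995
  val <- total_negloglik(u, small_trial(n = 10, seed = 1))
  expect_gte(val, 1e10)
})
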