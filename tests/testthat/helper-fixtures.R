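# Shared fixtures and oracles for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random valid parameter set: unconstrained draw pushed through the inverse
# transform, redrawn until the implied covariance is comfortably PD.
random_params <- function(seed) {
  set.seed(seed)
  repeat {
    u <- c(runif(9, -1, 1),          # coefficients
           runif(1, -2, 0), runif(3, -1.2, 0.3),  # tau1, log-increments
           runif(2, -0.5, 0.5),      # log sigmas
           runif(6, -1.2, 1.2))      # correlation logits
    p <- tryCatch(inverse_transform(u), error = function(e) NULL)
    if (!is.null(p)) {
      ev <- min(eigen(make_sigma(p), symmetric = TRUE,
                      only.values = TRUE)$values)
      if (ev > 0.05) return(p)
    }
  }
}

# Small, quickly fitted trial for smoke tests.
small_trial <- function(n = 200, seed = 101) {
  generate_trial(baseline_scenario(n = n), seed = seed)
}

# Independence log-likelihood oracle: with all correlations zero the joint
# factorises into two Gaussian densities, an ordinal band and a binary band.
indep_loglik_oracle <- function(params, rec) {
  p <- params
  mu1 <- p$alpha0 + p$alpha1 * rec$treat + p$alpha2 * rec$y10
  mu2 <- p$beta0 + p$beta1 * rec$treat + p$beta2 * rec$y20
  mu3 <- p$gamma1 * rec$treat
  mu4 <- p$psi0 + p$psi1 * rec$treat
  tau <- c(-Inf, p$tau, Inf)
  band3 <- pnorm(tau[rec$Y3 + 1] - mu3) - pnorm(tau[rec$Y3] - mu3)
  band4 <- if (rec$Y4 == 0) pnorm(0 - mu4) else 1 - pnorm(0 - mu4)
  dnorm(rec$Y1, mu1, p$sigma1, log = TRUE) +
    dnorm(rec$Y2, mu2, p$sigma2, log = TRUE) +
    log(band3) + log(band4)
}

# Scenario runs shared between acceptance tests (each is expensive); cached
# per session so several test blocks can reuse one run.
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(name, expr) {
  if (is.null(.run_cache[[name]])) .run_cache[[name]] <- force(expr)
  .run_cache[[name]]
}

baseline_run <- function() {
  cached_run("baseline", run_scenario(baseline_scenario(), n_sim = 150,
                                      seed = 904))
}
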