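# Marginal response probabilities, treatment effects and delta-method
# uncertainty for the latent-variable model.
#
# Overall response is the event that all four (observed and latent) components
# fall at or below their thresholds, an orthant probability of the 4-variate
# normal. The treatment effect is the marginal (covariate-standardised) odds
# ratio: every patient's response probability is computed under both
# counterfactual treatment assignments and averaged over the trial.

# 4-variate normal CDF, vectorised over rows; upper may be a single vector.
mvn4_cdf <- function(upper, mean, Sigma, nodes = 20L) {
  if (!is.matrix(mean)) mean <- matrix(mean, nrow = 1)
  if (!is.matrix(upper)) {
    upper <- matrix(upper, nrow = nrow(mean), ncol = 4, byrow = TRUE)
  }
  L <- t(chol(Sigma))
  g <- gl_nodes(nodes)
  mvn4_cdf_cpp(mean, upper, L, g$x, g$w)
}

#' Probability of overall response
#'
#' The orthant probability that `Y1 <= eta1`, `Y2 <= eta2` and the latent
#' ordinal and binary components fall below the top cut-point and 0
#' respectively, under the 4-variate normal implied by `params` at the given
#' covariates. Evaluated as a multivariate normal CDF by deterministic
#' separation-of-variables quadrature (absolute error around 1e-5 at the
#' default node count, decreasing with `nodes`).
#'
#' @param params an [lv_params] object.
#' @param criteria an [responder_criteria] object (continuous thresholds);
#'   the ordinal/binary thresholds are taken from `params`.
#' @param treat,y10,y20 covariates, vectorised.
#' @param nodes Gauss-Legendre nodes per outer dimension (default 20).
#' @return vector of response probabilities.
#' @export
prob_response <- function(params, criteria, treat, y10, y20, nodes = 20L) {
  lp <- linear_predictors(params, treat, y10, y20)
  mu <- lp$mu
  if (!is.matrix(mu)) mu <- matrix(mu, nrow = 1)
  upper <- c(criteria$eta1, criteria$eta2, params$tau[4], 0)
  p <- mvn4_cdf(upper, mu, lp$Sigma, nodes = nodes)
  if (any(!is.finite(p))) {
    stop("prob_response: numerical failure in CDF evaluation", call. = FALSE)
  }
  pmin(pmax(p, 0), 1)
}

# Average counterfactual response probabilities over all patients for a given
# natural-scale parameter vector (used both at the estimate and inside the
# delta-method gradient).
marginal_probs <- function(v, data, criteria, nodes = 20L) {
  n <- nrow(data)
  mu_t <- function(t) {
    cbind(v[1] + v[2] * t + v[3] * data$y10,
          v[4] + v[5] * t + v[6] * data$y20,
          rep(v[7] * t, n),
          rep(v[8] + v[9] * t, n))
  }
  S <- matrix(c(v[14]^2, v[16] * v[14] * v[15], v[17] * v[14], v[18] * v[14],
                v[16] * v[14] * v[15], v[15]^2, v[19] * v[15], v[20] * v[15],
                v[17] * v[14], v[19] * v[15], 1, v[21],
                v[18] * v[14], v[20] * v[15], v[21], 1), 4, 4)
  upper <- c(criteria$eta1, criteria$eta2, v[13], 0)
  L <- t(chol(S))
  g <- gl_nodes(nodes)
  c(p0 = mean(mvn4_cdf_cpp(mu_t(0), matrix(upper, n, 4, byrow = TRUE), L,
                           g$x, g$w)),
    p1 = mean(mvn4_cdf_cpp(mu_t(1), matrix(upper, n, 4, byrow = TRUE), L,
                           g$x, g$w)))
}

#' Marginal treatment effect from a fitted latent model
#'
#' For every patient, the response probability is computed under treatment and
#' under control at their own baselines; the averages over all patients in
#' both arms give the marginal response probabilities, from which the odds
#' ratio (the primary effect), risk ratio and risk difference follow. The
#' variance of the log odds ratio is obtained by the delta method over the
#' unconstrained parameter vector, using the fitted covariance.
#'
#' @param fit a converged `lv_fit` (with `cov_u` for standard errors).
#' @param data the trial data.
#' @param criteria an [responder_criteria] object.
#' @param level confidence level (default 0.95).
#' @param nodes quadrature nodes for the response probability.
#' @param gradient_step relative central-difference step for the delta-method
#'   gradient (default 1e-5).
#' @return an object of class `lv_effect`; see [tidy.lv_effect()].
#' @export
effect_measures <- function(fit, data, criteria, level = 0.95,
                            nodes = 20L, gradient_step = 1e-5) {
  data <- validate_trial_data(data)
  stopifnot(inherits(fit, "lv_fit"), inherits(criteria, "lv_criteria"))
  pp <- marginal_probs(as_param_vector(fit$params), data, criteria, nodes)
  if (any(pp <= .Machine$double.eps) || any(pp >= 1 - 1e-12)) {
    stop("effect_measures: averaged response probability is 0 or 1; ",
         "odds ratio undefined", call. = FALSE)
  }
  log_or_fn <- function(u) {
    v <- u_to_vector(u)
    q <- marginal_probs(v, data, criteria, nodes)
    (qlogis(q[["p1"]]) - qlogis(q[["p0"]]))
  }
  log_or <- qlogis(pp[["p1"]]) - qlogis(pp[["p0"]])
  var_log_or <- NA_real_
  if (!is.null(fit$cov_u)) {
    grad <- num_gradient(log_or_fn, fit$u, rel_step = gradient_step)
    var_log_or <- delta_quadratic(grad, fit$cov_u)
  }
  new_effect(method = "latent", p0 = pp[["p0"]], p1 = pp[["p1"]],
             log_or = log_or, var_log_or = var_log_or, level = level,
             n = nrow(data))
}

# Central-difference gradient with a relative step.
num_gradient <- function(f, x, rel_step = 1e-5) {
  g <- numeric(length(x))
  for (j in seq_along(x)) {
    h <- rel_step * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    g[j] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# g' C g with a PSD fallback if numerical noise makes it negative.
delta_quadratic <- function(grad, cov) {
  v <- drop(crossprod(grad, cov %*% grad))
  if (is.na(v)) return(NA_real_)
  if (v < 0) {
    warning("delta method produced a negative variance; ",
            "repairing the covariance to nearest PD", call. = FALSE)
    v <- max(0, drop(crossprod(grad, nearest_pd(cov) %*% grad)))
  }
  v
}

#' Delta-method variance of a scalar function of the fitted parameters
#'
#' First-order variance `g' Cov(u) g` where `g` is the central-difference
#' gradient of `effect_fn` at the unconstrained estimates.
#'
#' @param fit an `lv_fit` with `cov_u`.
#' @param effect_fn scalar function of the unconstrained 21-vector.
#' @param rel_step relative step for the gradient (default 1e-5).
#' @return non-negative variance.
#' @export
delta_method_variance <- function(fit, effect_fn, rel_step = 1e-5) {
  stopifnot(!is.null(fit$cov_u))
  delta_quadratic(num_gradient(effect_fn, fit$u, rel_step), fit$cov_u)
}

#' Wald confidence interval and p-value on the log-odds scale
#'
#' @param log_or log odds ratio estimate.
#' @param var_log_or its variance (>= 0).
#' @param level confidence level.
#' @return a list with `ci_low`, `ci_high` (log-odds scale) and `p_value`
#'   (two-sided).
#' @export
wald_ci_pvalue <- function(log_or, var_log_or, level = 0.95) {
  stopifnot(is.na(var_log_or) || var_log_or >= 0)
  se <- sqrt(var_log_or)
  z <- qnorm(1 - (1 - level) / 2)
  p <- if (is.na(se)) {
    NA_real_
  } else if (se == 0) {
    if (log_or == 0) 1 else 0
  } else {
    2 * pnorm(-abs(log_or) / se)
  }
  list(ci_low = log_or - z * se, ci_high = log_or + z * se, p_value = p)
}

new_effect <- function(method, p0, p1, log_or, var_log_or, level, n) {
  wd <- wald_ci_pvalue(log_or, var_log_or, level)
  structure(list(method = method, p0 = p0, p1 = p1,
                 odds_ratio = exp(log_or), risk_ratio = p1 / p0,
                 risk_difference = p1 - p0,
                 log_or = log_or, var_log_or = var_log_or,
                 se = sqrt(var_log_or),
                 ci_low = wd$ci_low, ci_high = wd$ci_high,
                 p_value = wd$p_value, level = level, n = n),
            class = "lv_effect")
}

#' @export
print.lv_effect <- function(x, ...) {
  cat("<lv_effect> method:", x$method, "\n")
  cat(sprintf("  p0 = %.4f, p1 = %.4f\n", x$p0, x$p1))
  cat(sprintf("  log-OR = %.4f (SE %.4f), %d%% CI [%.4f, %.4f], p = %.4g\n",
              x$log_or, x$se, round(100 * x$level), x$ci_low, x$ci_high,
              x$p_value))
  cat(sprintf("  OR = %.3f, RR = %.3f, RD = %.3f\n",
              x$odds_ratio, x$risk_ratio, x$risk_difference))
  invisible(x)
}
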