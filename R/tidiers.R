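# broom-style tidiers for fitted objects and results.

#' Tidy a fitted latent model
#'
#' One row per natural-scale parameter with estimate and, when the parameter
#' covariance is available, a delta-method standard error (Jacobian of the
#' unconstrained-to-natural map applied to the unconstrained covariance).
#'
#' @param x an `lv_fit` object.
#' @param ... unused.
#' @return a tibble with columns `term`, `estimate`, `std.error`.
#' @export
#' @exportS3Method generics::tidy
tidy.lv_fit <- function(x, ...) {
  if (x$method != "latent") {
    est <- x$params
    se <- sqrt(diag(x$cov_u))[seq_along(est)]
    return(tibble::tibble(term = names(est), estimate = unname(est),
                          std.error = unname(se)))
  }
  est <- as_param_vector(x$params)
  se <- rep(NA_real_, length(est))
  if (!is.null(x$cov_u)) {
    J <- numDeriv::jacobian(u_to_vector, x$u)
    se <- sqrt(pmax(0, diag(J %*% x$cov_u %*% t(J))))
  }
  tibble::tibble(term = param_names, estimate = unname(est),
                 std.error = unname(se))
}

#' Model-level summary of a fitted latent model
#'
#' @param x an `lv_fit` object.
#' @param ... unused.
#' @return a one-row tibble with `logLik`, `n`, `converged`, `n_iter`,
#'   `cov_repaired`, `method`.
#' @export
#' @exportS3Method generics::glance
glance.lv_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n = x$n, converged = x$converged,
                 n_iter = x$n_iter %||% NA_integer_,
                 cov_repaired = x$cov_repaired %||% FALSE,
                 method = x$method)
}

#' Tidy an effect estimate
#'
#' @param x an `lv_effect` object.
#' @param ... unused.
#' @return a one-row tibble with per-arm marginal response probabilities, the
#'   odds ratio, risk ratio and risk difference, the log odds ratio with its
#'   standard error, Wald confidence limits (log-odds scale) and p-value.
#' @export
#' @exportS3Method generics::tidy
tidy.lv_effect <- function(x, ...) {
  tibble::tibble(method = x$method, p0 = x$p0, p1 = x$p1,
                 odds_ratio = x$odds_ratio, risk_ratio = x$risk_ratio,
                 risk_difference = x$risk_difference,
                 log_or = x$log_or, std.error = x$se,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 p_value = x$p_value, level = x$level)
}

#' Tidy a bootstrap bias correction
#'
#' @param x an `lv_bootstrap` object.
#' @param ... unused.
#' @return a one-row tibble with the original estimate, bootstrap mean, bias,
#'   corrected estimate and percentile interval.
#' @export
#' @exportS3Method generics::tidy
tidy.lv_bootstrap <- function(x, ...) {
  tibble::tibble(method = x$method, original = x$original,
                 boot_mean = x$boot_mean, bias = x$bias,
                 corrected = x$corrected,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 level = x$level, n_boot = x$n_boot, n_fail = x$n_fail)
}

#' Tidy a scenario result
#'
#' @param x an `lv_scenario_result` object.
#' @param ... unused.
#' @return the per-method performance summary tibble with the true log
#'   odds ratio attached.
#' @export
#' @exportS3Method generics::tidy
tidy.lv_scenario_result <- function(x, ...) {
  dplyr::mutate(x$summary, true_log_or = x$true_log_or)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
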