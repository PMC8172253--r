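# Maximum-likelihood fitting of the latent-variable model.

#' Starting values for the latent-model optimisation
#'
#' Deterministic, data-driven starts: least squares for the two continuous
#' outcomes, an ordered probit for the ordinal component (empirical-quantile
#' cut-points as fallback), a probit for the binary component, and crude
#' moment estimates for the correlations from residuals and integer-coded
#' discrete outcomes, clipped to (-0.95, 0.95).
#'
#' @param data validated trial data.
#' @return a named unconstrained 21-vector.
#' @export
initial_values <- function(data) {
  data <- validate_trial_data(data)
  for (cl in c("Y1", "Y2", "Y3", "Y4")) {
    if (length(unique(data[[cl]])) < 2L) {
      stop("initial_values: outcome `", cl, "` is constant (degenerate data)",
           call. = FALSE)
    }
  }
  f1 <- lm(Y1 ~ treat + y10, data = data)
  f2 <- lm(Y2 ~ treat + y20, data = data)
  a <- coef(f1); b <- coef(f2)
  s1 <- sd(residuals(f1)); s2 <- sd(residuals(f2))

  po <- tryCatch(
    MASS::polr(factor(Y3, levels = 1:5) ~ treat, data = data,
               method = "probit"),
    error = function(e) NULL)
  if (!is.null(po) && all(is.finite(po$zeta)) && length(po$zeta) == 4L &&
      all(diff(po$zeta) > 0)) {
    gamma1 <- unname(coef(po)[1])  # polr: P(Y <= w) = Phi(zeta_w - b * treat)
    tau <- unname(po$zeta)
  } else {
    cum <- cumsum(tabulate(data$Y3, nbins = 5L))[1:4] / nrow(data)
    cum <- pmin(pmax(cum, 1 / (2 * nrow(data))), 1 - 1 / (2 * nrow(data)))
    tau <- qnorm(cum)
    tau <- tau + cumsum(c(0, pmax(0, 1e-3 - diff(tau))))
    gamma1 <- 0
  }

  pr <- suppressWarnings(
    glm(Y4 ~ treat, family = binomial("probit"), data = data))
  psi <- coef(pr)

  r1 <- residuals(f1); r2 <- residuals(f2)
  z3 <- as.numeric(data$Y3); z4 <- as.numeric(data$Y4)
  clip <- function(x) min(max(x, -0.95), 0.95)
  rho <- c(clip(cor(r1, r2)),
           clip(cor(r1, z3)), clip(cor(r1, z4)),
           clip(cor(r2, z3)), clip(cor(r2, z4)),
           clip(cor(z3, z4)))
  p0 <- lv_params(alpha0 = a[[1]], alpha1 = a[[2]], alpha2 = a[[3]],
                  beta0 = b[[1]], beta1 = b[[2]], beta2 = b[[3]],
                  gamma1 = gamma1, psi0 = psi[[1]], psi1 = psi[[2]],
                  tau = tau, sigma1 = s1, sigma2 = s2,
                  rho12 = rho[1], rho13 = rho[2], rho14 = rho[3],
                  rho23 = rho[4], rho24 = rho[5], rho34 = rho[6])
  # back off the correlation starts if jointly inconsistent
  sh <- 1
  repeat {
    ev <- min(eigen(make_sigma(p0, check = FALSE), symmetric = TRUE,
                    only.values = TRUE)$values)
    if (ev > 1e-6) break
    sh <- sh * 0.7
    for (nm in c("rho12", "rho13", "rho14", "rho23", "rho24", "rho34")) {
      p0[[nm]] <- p0[[nm]] * 0.7
    }
  }
  transform_params(p0)
}

#' Fit the latent-variable model by maximum likelihood
#'
#' Minimises the penalised negative log-likelihood on the unconstrained scale
#' with a quasi-Newton (PORT) algorithm, then computes the covariance of the
#' estimates from the Richardson-extrapolated numerical Hessian, repaired to
#' the nearest positive semi-definite matrix when needed.
#'
#' @param data trial data (see [validate_trial_data()]).
#' @param start optional unconstrained start vector; defaults to
#'   [initial_values()].
#' @param control list of optimiser settings: `rel_tol` (objective tolerance,
#'   default 1e-8), `max_iter` (default 500), `hessian` (compute the
#'   parameter covariance, default `TRUE`).
#' @return an object of class `lv_fit` with elements `params` ([lv_params]),
#'   `u` (unconstrained estimates), `loglik`, `converged`, `n_iter`, `cov_u`
#'   (21x21 covariance, when requested), `cov_repaired`, `method`.
#' @examples
#' \donttest{
#' sc <- baseline_scenario(n = 150)
#' dat <- generate_trial(sc, seed = 1)
#' fit <- fit_latent(dat, control = list(hessian = FALSE))
#' glance(fit)
#' }
#' @export
fit_latent <- function(data, start = NULL, control = list()) {
  data <- validate_trial_data(data)
  ctl <- modifyList(list(rel_tol = 1e-8, max_iter = 500, hessian = TRUE),
                    control)
  if (length(unique(data$treat)) < 2L) {
    stop("fit_latent: both arms must be present", call. = FALSE)
  }
  lev <- tabulate(data$Y3, nbins = 5L)
  if (any(lev == 0L)) {
    warning("fit_latent: ordinal level(s) ",
            paste(which(lev == 0L), collapse = ", "),
            " unobserved; the adjacent cut-points are weakly identified",
            call. = FALSE)
  }
  if (is.null(start)) start <- initial_values(data)
  dm <- data_matrix(data)
  obj <- function(u) total_negloglik(u, dm)
  opt <- stats::nlminb(start, obj,
                       control = list(rel.tol = ctl$rel_tol,
                                      iter.max = ctl$max_iter,
                                      eval.max = 4L * ctl$max_iter))
  if (opt$convergence != 0 && !grepl("relative convergence|X-convergence|both X|singular convergence",
                                     opt$message)) {
    warning("fit_latent: optimiser did not report convergence (",
            opt$message, ")", call. = FALSE)
  }
  converged <- opt$convergence == 0 ||
    grepl("relative convergence|X-convergence|both X", opt$message)
  u_hat <- setNames(opt$par, u_names)
  fit <- structure(
    list(params = inverse_transform(u_hat), u = u_hat,
         loglik = -opt$objective, converged = converged,
         n_iter = opt$iterations, message = opt$message,
         cov_u = NULL, cov_repaired = FALSE, hessian_condition = NA_real_,
         method = "latent", n = nrow(data)),
    class = "lv_fit")
  if (isTRUE(ctl$hessian)) fit <- param_covariance(fit, data)
  fit
}

#' Covariance of the unconstrained estimates
#'
#' Numerical Hessian of the negative log-likelihood at the optimum by
#' Richardson extrapolation (`numDeriv::hessian`), inverted; a non
#' positive-semi-definite result is replaced by its nearest positive-definite
#' matrix (Higham's alternating projections, `Matrix::nearPD`) and flagged in
#' `cov_repaired`.
#'
#' @param fit an `lv_fit` object.
#' @param data the trial data the model was fitted to.
#' @return `fit` with `cov_u`, `cov_repaired` and `hessian_condition` filled.
#' @export
param_covariance <- function(fit, data) {
  data <- validate_trial_data(data)
  dm <- data_matrix(data)
  H <- numDeriv::hessian(function(u) total_negloglik(u, dm), fit$u)
  H <- (H + t(H)) / 2
  fit$hessian_condition <- kappa(H, exact = FALSE)
  cov_u <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov_u)) {
    warning("param_covariance: singular Hessian (condition number ",
            format(fit$hessian_condition, digits = 3),
            "); using pseudo-inverse", call. = FALSE)
    cov_u <- MASS::ginv(H)
  }
  cov_u <- (cov_u + t(cov_u)) / 2
  ev <- eigen(cov_u, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) {
    cov_u <- as.matrix(Matrix::nearPD(cov_u)$mat)
    fit$cov_repaired <- TRUE
  }
  dimnames(cov_u) <- list(u_names, u_names)
  fit$cov_u <- cov_u
  fit
}

#' Repair a matrix to the nearest positive-definite one
#'
#' Thin wrapper over `Matrix::nearPD` returning a plain matrix; used for
#' covariance repair and exposed for testing.
#'
#' @param m a symmetric matrix.
#' @return the nearest positive-definite matrix (Frobenius norm).
#' @export
nearest_pd <- function(m) {
  as.matrix(Matrix::nearPD((m + t(m)) / 2)$mat)
}

#' @export
print.lv_fit <- function(x, ...) {
  cat("<lv_fit> method:", x$method, " n:", x$n, "\n",
      "logLik:", format(x$loglik, digits = 6),
      " converged:", x$converged, " iterations:", x$n_iter, "\n")
  invisible(x)
}
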