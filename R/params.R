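# Model parameters and the unconstrained reparameterisation.
#
# 21 free parameters: regression coefficients for the two observed continuous
# outcomes, latent treatment effects for the ordinal and binary components,
# four ordinal cut-points, two residual scales and six correlations. The
# ordinal intercept is fixed at 0 and the binary cut-point at 0; the latent
# scales are fixed at 1 — the usual probit identifiability constraints.

param_names <- c("alpha0", "alpha1", "alpha2",
                 "beta0", "beta1", "beta2",
                 "gamma1", "psi0", "psi1",
                 "tau1", "tau2", "tau3", "tau4",
                 "sigma1", "sigma2",
                 "rho12", "rho13", "rho14", "rho23", "rho24", "rho34")

u_names <- c("alpha0", "alpha1", "alpha2",
             "beta0", "beta1", "beta2",
             "gamma1", "psi0", "psi1",
             "tau1", "zeta1", "zeta2", "zeta3",
             "omega1", "omega2",
             "omega12", "omega13", "omega14", "omega23", "omega24", "omega34")

#' Construct latent-model parameters
#'
#' Builds and validates the parameter set of the latent-variable model for a
#' composite endpoint with two continuous components (`Y1`, `Y2`), one
#' five-level ordinal component (`Y3`) and one binary component (`Y4`). The
#' latent scales for the discrete components are fixed at 1, the ordinal
#' intercept at 0 and the binary cut-point at 0 for identifiability.
#'
#' @param alpha0,alpha1,alpha2 intercept, treatment effect and baseline slope
#'   for `Y1` (outcome units).
#' @param beta0,beta1,beta2 the same for `Y2`.
#' @param gamma1 latent treatment effect for the ordinal component.
#' @param psi0,psi1 latent intercept and treatment effect for the binary
#'   component.
#' @param tau strictly increasing vector of the four ordinal cut-points.
#' @param sigma1,sigma2 residual standard deviations of `Y1`, `Y2` (> 0).
#' @param rho12,rho13,rho14,rho23,rho24,rho34 latent error correlations in
#'   (-1, 1); the implied 4x4 covariance must be positive definite.
#' @return an object of class `lv_params`.
#' @examples
#' p <- lv_params(alpha1 = -0.3, tau = c(-1.5, -0.5, 0.5, 1.5), rho12 = 0.5)
#' make_sigma(p)
#' @export
lv_params <- function(alpha0 = 0, alpha1 = 0, alpha2 = 0,
                      beta0 = 0, beta1 = 0, beta2 = 0,
                      gamma1 = 0, psi0 = 0, psi1 = 0,
                      tau = c(-1.5, -0.5, 0.5, 1.5),
                      sigma1 = 1, sigma2 = 1,
                      rho12 = 0, rho13 = 0, rho14 = 0,
                      rho23 = 0, rho24 = 0, rho34 = 0) {
  p <- structure(list(alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2,
                      beta0 = beta0, beta1 = beta1, beta2 = beta2,
                      gamma1 = gamma1, psi0 = psi0, psi1 = psi1,
                      tau = as.numeric(tau), sigma1 = sigma1, sigma2 = sigma2,
                      rho12 = rho12, rho13 = rho13, rho14 = rho14,
                      rho23 = rho23, rho24 = rho24, rho34 = rho34),
                 class = "lv_params")
  validate_lv_params(p)
  p
}

validate_lv_params <- function(p) {
  num <- unlist(p[setdiff(names(p), "tau")])
  if (!all(is.finite(num)) || !all(is.finite(p$tau))) {
    stop("lv_params: all parameters must be finite", call. = FALSE)
  }
  if (length(p$tau) != 4L || any(diff(p$tau) <= 0)) {
    stop("lv_params: `tau` must be four strictly increasing cut-points",
         call. = FALSE)
  }
  if (p$sigma1 <= 0 || p$sigma2 <= 0) {
    stop("lv_params: `sigma1` and `sigma2` must be positive", call. = FALSE)
  }
  rho <- unlist(p[c("rho12", "rho13", "rho14", "rho23", "rho24", "rho34")])
  if (any(abs(rho) >= 1)) {
    stop("lv_params: correlations must lie in (-1, 1)", call. = FALSE)
  }
  ev <- eigen(make_sigma(p, check = FALSE), symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 1e-12) {
    stop("lv_params: correlations are jointly inconsistent; ",
         "the implied covariance matrix is not positive definite",
         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.lv_params <- function(x, ...) {
  cat("<lv_params>\n")
  v <- as_param_vector(x)
  print(round(v, 4))
  invisible(x)
}

#' Flatten parameters to the canonical 21-vector
#'
#' Named vector in the fixed order used throughout the package: regression
#' coefficients, cut-points `tau1`..`tau4`, scales, correlations.
#'
#' @param p an [lv_params] object.
#' @return a named numeric 21-vector.
#' @export
as_param_vector <- function(p) {
  v <- c(p$alpha0, p$alpha1, p$alpha2, p$beta0, p$beta1, p$beta2,
         p$gamma1, p$psi0, p$psi1, p$tau, p$sigma1, p$sigma2,
         p$rho12, p$rho13, p$rho14, p$rho23, p$rho24, p$rho34)
  names(v) <- param_names
  v
}

params_from_vector <- function(v) {
  lv_params(alpha0 = v[[1]], alpha1 = v[[2]], alpha2 = v[[3]],
            beta0 = v[[4]], beta1 = v[[5]], beta2 = v[[6]],
            gamma1 = v[[7]], psi0 = v[[8]], psi1 = v[[9]],
            tau = v[10:13], sigma1 = v[[14]], sigma2 = v[[15]],
            rho12 = v[[16]], rho13 = v[[17]], rho14 = v[[18]],
            rho23 = v[[19]], rho24 = v[[20]], rho34 = v[[21]])
}

#' Assemble the latent error covariance matrix
#'
#' The 4x4 covariance of the latent errors: the observed continuous components
#' carry free scales `sigma1`, `sigma2`; the two latent components have unit
#' variance.
#'
#' @param params an [lv_params] object.
#' @param check if `TRUE`, error when the matrix is not positive definite.
#' @return a symmetric 4x4 matrix.
#' @export
make_sigma <- function(params, check = TRUE) {
  p <- params
  s1 <- p$sigma1; s2 <- p$sigma2
  S <- matrix(c(s1^2, p$rho12 * s1 * s2, p$rho13 * s1, p$rho14 * s1,
                p$rho12 * s1 * s2, s2^2, p$rho23 * s2, p$rho24 * s2,
                p$rho13 * s1, p$rho23 * s2, 1, p$rho34,
                p$rho14 * s1, p$rho24 * s2, p$rho34, 1),
              nrow = 4, byrow = TRUE)
  if (check) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12) {
      stop("make_sigma: matrix is not positive definite ",
           "(correlations jointly inconsistent)", call. = FALSE)
    }
  }
  S
}

#' Map parameters to and from the unconstrained scale
#'
#' Optimisation runs on a 21-vector over the reals: `omega1 = log(sigma1)`,
#' `omega2 = log(sigma2)`, `rho_jk = 2*expit(omega_jk) - 1` for the six
#' correlations, and the ordinal cut-points stored as `tau1` plus three
#' log-increments so the ordering constraint holds for any real vector.
#' Regression coefficients pass through unchanged.
#'
#' @param params an [lv_params] object.
#' @return `transform_params`: a named numeric 21-vector;
#'   `inverse_transform`: an [lv_params] object.
#' @export
transform_params <- function(params) {
  p <- params
  u <- c(p$alpha0, p$alpha1, p$alpha2, p$beta0, p$beta1, p$beta2,
         p$gamma1, p$psi0, p$psi1,
         p$tau[1], log(diff(p$tau)),
         log(p$sigma1), log(p$sigma2),
         qlogis((c(p$rho12, p$rho13, p$rho14, p$rho23, p$rho24, p$rho34) + 1) / 2))
  names(u) <- u_names
  u
}

#' @rdname transform_params
#' @param u a named or unnamed numeric 21-vector on the unconstrained scale.
#' @export
inverse_transform <- function(u) {
  if (!is.numeric(u) || length(u) != 21L || !all(is.finite(u))) {
    stop("inverse_transform: `u` must be a finite numeric 21-vector",
         call. = FALSE)
  }
  tau <- u[10] + c(0, cumsum(exp(u[11:13])))
  rho <- 2 * plogis(u[16:21]) - 1
  lv_params(alpha0 = u[[1]], alpha1 = u[[2]], alpha2 = u[[3]],
            beta0 = u[[4]], beta1 = u[[5]], beta2 = u[[6]],
            gamma1 = u[[7]], psi0 = u[[8]], psi1 = u[[9]],
            tau = tau, sigma1 = exp(u[[14]]), sigma2 = exp(u[[15]]),
            rho12 = rho[[1]], rho13 = rho[[2]], rho14 = rho[[3]],
            rho23 = rho[[4]], rho24 = rho[[5]], rho34 = rho[[6]])
}

# As inverse_transform but returning the plain 21-vector without the
# positive-definiteness check; used inside the optimiser where non-PD
# correlation combinations are handled by penalty, not by error.
u_to_vector <- function(u) {
  tau <- u[10] + c(0, cumsum(exp(u[11:13])))
  rho <- 2 * plogis(u[16:21]) - 1
  v <- c(u[1:9], tau, exp(u[14:15]), rho)
  names(v) <- param_names
  v
}

#' Responder criteria for the composite endpoint
#'
#' Response requires every component to fall at or below its threshold:
#' `Y1 <= eta1`, `Y2 <= eta2`, the ordinal component below its top (worst)
#' category and the binary component equal to 0. On the latent scale the
#' ordinal threshold is the top cut-point `tau4` and the binary threshold is
#' the fixed cut-point 0; both are resolved from the fitted model, so only the
#' continuous thresholds are supplied.
#'
#' @param eta1,eta2 responder thresholds for `Y1` and `Y2` (outcome units);
#'   `Inf` means the component never blocks response.
#' @return an object of class `lv_criteria`.
#' @export
responder_criteria <- function(eta1, eta2) {
  if (!is.numeric(eta1) || !is.numeric(eta2) ||
      is.na(eta1) || is.na(eta2) ||
      eta1 == -Inf || eta2 == -Inf) {
    stop("responder_criteria: `eta1` and `eta2` must be numbers (or +Inf)",
         call. = FALSE)
  }
  structure(list(eta1 = eta1, eta2 = eta2), class = "lv_criteria")
}

#' @export
print.lv_criteria <- function(x, ...) {
  cat("<lv_criteria> eta1 =", x$eta1, ", eta2 =", x$eta2,
      "; ordinal: below top category; binary: Y4 = 0\n")
  invisible(x)
}
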