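# Observed-data likelihood of the latent-variable model.
#
# Each patient contributes the bivariate normal density of the two observed
# continuous outcomes times the conditional probability of the observed
# (ordinal, binary) cell, a rectangle probability of the conditional bivariate
# normal for the latent pair given (Y1, Y2).

trial_cols <- c("treat", "y10", "y20", "Y1", "Y2", "Y3", "Y4")

#' Validate a trial dataset
#'
#' Checks that `data` holds the per-patient components of the composite
#' endpoint: `treat` (0/1), baselines `y10`, `y20`, continuous outcomes `Y1`,
#' `Y2`, ordinal `Y3` in 1..5 (1 = best grade, 5 = worst/non-responder
#' category) and binary `Y4` in 0/1 (0 = responder component).
#'
#' @param data a data frame with the columns above.
#' @param n_levels number of ordinal levels (default 5).
#' @return `data` as a tibble, invisibly usable downstream.
#' @export
validate_trial_data <- function(data, n_levels = 5L) {
  data <- tibble::as_tibble(data)
  miss <- setdiff(trial_cols, names(data))
  if (length(miss) > 0) {
    stop("trial data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) < 1L) stop("trial data has no rows", call. = FALSE)
  bad_row <- function(ok, what) {
    if (!all(ok)) {
      stop("trial data: ", what, " in row(s) ",
           paste(head(which(!ok), 5L), collapse = ", "), call. = FALSE)
    }
  }
  bad_row(data$treat %in% c(0, 1), "`treat` must be 0 or 1")
  for (cl in c("y10", "y20", "Y1", "Y2")) {
    bad_row(is.finite(data[[cl]]), paste0("`", cl, "` must be finite"))
  }
  bad_row(data$Y3 %in% seq_len(n_levels),
          paste0("`Y3` must be an integer in 1..", n_levels))
  bad_row(data$Y4 %in% c(0, 1), "`Y4` must be 0 or 1")
  data
}

data_matrix <- function(data) {
  m <- as.matrix(data[, trial_cols])
  storage.mode(m) <- "double"
  m
}

#' Linear predictors of the latent-variable model
#'
#' Means of the four (observed and latent) components at given covariates,
#' together with the latent error covariance.
#'
#' @param params an [lv_params] object.
#' @param treat treatment indicator (0/1), scalar or vector.
#' @param y10,y20 baseline measures, recycled against `treat`.
#' @return a list with `mu` (length-4 vector, or n x 4 matrix when the inputs
#'   have length > 1) and `Sigma` (4x4 covariance).
#' @export
linear_predictors <- function(params, treat, y10, y20) {
  p <- params
  mu <- cbind(p$alpha0 + p$alpha1 * treat + p$alpha2 * y10,
              p$beta0 + p$beta1 * treat + p$beta2 * y20,
              p$gamma1 * treat,
              p$psi0 + p$psi1 * treat + 0 * y10)
  if (nrow(mu) == 1L) mu <- drop(mu)
  list(mu = mu, Sigma = make_sigma(p))
}

#' Conditional moments of the latent pair given the continuous outcomes
#'
#' Closed-form conditional mean and covariance of (Y3*, Y4*) given
#' (Y1, Y2), i.e. the Schur complement of the continuous block of the latent
#' covariance.
#'
#' @param params an [lv_params] object.
#' @param moments output of [linear_predictors()] for one patient.
#' @param Y1,Y2 observed continuous outcomes.
#' @return a list with `mu3`, `mu4` (conditional means) and `Sigma34` (2x2
#'   conditional covariance).
#' @export
conditional_moments <- function(params, moments, Y1, Y2) {
  p <- params
  om <- 1 - p$rho12^2
  if (om < 1e-10) {
    stop("conditional_moments: |rho12| too close to 1 (degenerate conditioning)",
         call. = FALSE)
  }
  mu <- moments$mu
  if (is.matrix(mu)) mu <- drop(mu[1, ])
  d1 <- (Y1 - mu[1]) / p$sigma1
  d2 <- (Y2 - mu[2]) / p$sigma2
  mu3 <- mu[3] + ((p$rho13 - p$rho12 * p$rho23) * d1 +
                  (p$rho23 - p$rho12 * p$rho13) * d2) / om
  mu4 <- mu[4] + ((p$rho14 - p$rho12 * p$rho24) * d1 +
                  (p$rho24 - p$rho12 * p$rho14) * d2) / om
  v3 <- 1 - (p$rho13^2 - 2 * p$rho12 * p$rho13 * p$rho23 + p$rho23^2) / om
  v4 <- 1 - (p$rho14^2 - 2 * p$rho12 * p$rho14 * p$rho24 + p$rho24^2) / om
  c34 <- p$rho34 - (p$rho13 * p$rho14 + p$rho23 * p$rho24 -
                    p$rho12 * (p$rho13 * p$rho24 + p$rho14 * p$rho23)) / om
  list(mu3 = mu3, mu4 = mu4,
       Sigma34 = matrix(c(v3, c34, c34, v4), 2, 2))
}

#' Bivariate standard normal distribution function
#'
#' `P(X <= h, Y <= k)` for standard normal margins with correlation `r`,
#' evaluated by Gauss-Legendre quadrature over the correlation
#' (Drezner-Wesolowsky form as refined by Genz); absolute error below 1e-14.
#' Infinite limits are handled.
#'
#' @param h,k upper limits, recycled to a common length.
#' @param r correlation in (-1, 1).
#' @return vector of probabilities.
#' @export
pbvn <- function(h, k, r) {
  stopifnot(is.numeric(h), is.numeric(k), length(r) == 1L, abs(r) < 1)
  pbvn_cpp(as.numeric(h), as.numeric(k), r)
}

#' Probability of an observed (ordinal, binary) cell
#'
#' Rectangle probability of the conditional bivariate normal for the latent
#' pair, for ordinal level `w` and binary level `k`.
#'
#' @param cond output of [conditional_moments()].
#' @param cuts the four ordinal cut-points (strictly increasing).
#' @param w ordinal level in 1..5.
#' @param k binary level, 0 or 1.
#' @return a probability in \[0, 1\].
#' @export
cell_probability <- function(cond, cuts, w, k) {
  stopifnot(w %in% 1:5, k %in% 0:1, length(cuts) == 4L, all(diff(cuts) > 0))
  tau3 <- c(-Inf, cuts, Inf)
  v3 <- cond$Sigma34[1, 1]; v4 <- cond$Sigma34[2, 2]
  if (v3 <= 0 || v4 <= 0) {
    stop("cell_probability: conditional covariance is not positive definite",
         call. = FALSE)
  }
  rc <- cond$Sigma34[1, 2] / sqrt(v3 * v4)
  lo3 <- (tau3[w] - cond$mu3) / sqrt(v3)
  hi3 <- (tau3[w + 1] - cond$mu3) / sqrt(v3)
  lim4 <- (0 - cond$mu4) / sqrt(v4)
  lo4 <- if (k == 0) -Inf else lim4
  hi4 <- if (k == 0) lim4 else Inf
  p <- pbvn_cpp(hi3, hi4, rc) - pbvn_cpp(lo3, hi4, rc) -
    pbvn_cpp(hi3, lo4, rc) + pbvn_cpp(lo3, lo4, rc)
  if (!is.finite(p)) stop("cell_probability: evaluation failed", call. = FALSE)
  min(max(p, 0), 1)
}

#' Log-likelihood contribution of one patient
#'
#' Log of the bivariate normal density of (Y1, Y2) plus the log conditional
#' probability of the observed (ordinal, binary) cell. Probabilities are
#' clipped at 1e-300 before logging.
#'
#' @param params an [lv_params] object.
#' @param rec a one-row data frame with the trial columns.
#' @return scalar log-likelihood contribution.
#' @export
patient_loglik <- function(params, rec) {
  rec <- validate_trial_data(rec)
  -negloglik_cpp(as_param_vector(params), data_matrix(rec))
}

# Penalised negative log-likelihood on the unconstrained scale. When the
# implied covariance is not positive definite the optimiser receives
# 1e10 plus the distance to positive definiteness so the surface stays
# informative.
#' Total negative log-likelihood on the unconstrained scale
#'
#' @param u unconstrained 21-vector.
#' @param data validated trial data.
#' @return scalar; `1e10 + |min eigenvalue|` when the implied latent
#'   covariance is not positive definite.
#' @export
total_negloglik <- function(u, data) {
  v <- u_to_vector(u)
  S <- matrix(c(v[14]^2, v[16] * v[14] * v[15], v[17] * v[14], v[18] * v[14],
                v[16] * v[14] * v[15], v[15]^2, v[19] * v[15], v[20] * v[15],
                v[17] * v[14], v[19] * v[15], 1, v[21],
                v[18] * v[14], v[20] * v[15], v[21], 1), 4, 4)
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 1e-10) return(1e10 + abs(ev_min))
  negloglik_cpp(v, if (is.matrix(data)) data else data_matrix(data))
}
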