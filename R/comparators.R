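# Comparator analyses: the standard binary method (logistic regression on the
# collapsed responder index) and the augmented binary method (joint model
# keeping one continuous component and collapsing the rest).

#' Derive the composite responder indicators
#'
#' `S` is the overall responder index: response in every component
#' (`Y1 <= eta1`, `Y2 <= eta2`, ordinal below the top category, `Y4 = 0`).
#' `F` is the non-response indicator used by the augmented binary method,
#' combining only (`Y2`, `Y3`, `Y4`): `F = 0` iff `Y2 <= eta2`, `Y3` below the
#' top category and `Y4 = 0`.
#'
#' @param data trial data.
#' @param criteria an [responder_criteria] object.
#' @return a tibble with columns `S` and `F` (0/1).
#' @export
derive_composite <- function(data, criteria) {
  data <- validate_trial_data(data)
  resp1 <- data$Y1 <= criteria$eta1
  resp2 <- data$Y2 <= criteria$eta2
  resp3 <- data$Y3 < 5
  resp4 <- data$Y4 == 0
  tibble::tibble(S = as.integer(resp1 & resp2 & resp3 & resp4),
                 F = as.integer(!(resp2 & resp3 & resp4)))
}

check_separation <- function(model, label) {
  fv <- fitted(model)
  if (any(fv < 1e-8) || any(fv > 1 - 1e-8) ||
      any(abs(coef(model)) > 15, na.rm = TRUE)) {
    warning(label, ": possible separation; estimates may be unstable",
            call. = FALSE)
  }
  if (any(is.na(coef(model)))) {
    stop(label, ": rank-deficient fit (aliased coefficients)", call. = FALSE)
  }
  invisible(model)
}

#' Standard binary analysis of the composite endpoint
#'
#' Logistic regression of the collapsed responder index `S` on treatment and
#' the two baselines. The treatment log odds ratio and its Wald standard
#' error come directly from the maximum-likelihood fit (a conditional, not
#' covariate-standardised, odds ratio). The reported per-arm probabilities
#' are averaged counterfactual predictions, for comparability of output.
#'
#' @param data trial data.
#' @param criteria an [responder_criteria] object.
#' @param level confidence level.
#' @return a list with `fit` (an `lv_fit`-like summary) and `effect`
#'   (an `lv_effect`).
#' @export
fit_standard_binary <- function(data, criteria, level = 0.95) {
  data <- validate_trial_data(data)
  S <- derive_composite(data, criteria)$S
  if (length(unique(S)) < 2L) {
    stop("fit_standard_binary: responder index is constant ",
         "(complete separation/degenerate data)", call. = FALSE)
  }
  df <- dplyr::mutate(data, .S = S)
  m <- suppressWarnings(
    glm(.S ~ treat + y10 + y20, family = binomial(), data = df))
  check_separation(m, "fit_standard_binary")
  log_or <- unname(coef(m)["treat"])
  var_log_or <- vcov(m)["treat", "treat"]
  p1 <- mean(predict(m, newdata = dplyr::mutate(df, treat = 1),
                     type = "response"))
  p0 <- mean(predict(m, newdata = dplyr::mutate(df, treat = 0),
                     type = "response"))
  eff <- new_effect("standard_binary", p0 = p0, p1 = p1, log_or = log_or,
                    var_log_or = var_log_or, level = level, n = nrow(data))
  fit <- structure(list(params = coef(m), cov_u = vcov(m),
                        loglik = as.numeric(stats::logLik(m)),
                        converged = m$converged, n_iter = m$iter,
                        method = "standard_binary", n = nrow(data)),
                   class = "lv_fit")
  list(fit = fit, effect = eff)
}

#' Augmented binary analysis of the composite endpoint
#'
#' Joint model keeping the information in one continuous component (`Y1` by
#' default): a Gaussian linear model for the continuous outcome on treatment
#' and both baselines, and a logistic model for the collapsed non-response
#' indicator `F` of the remaining components on the same covariates. The
#' per-patient counterfactual response probability is
#' `P(Y1 <= eta1 | t) * P(F = 0 | t)`; the product form follows because the
#' fitted `F`-model does not depend on `Y1` (a documented variant adds `Y1`
#' to the `F`-model, the classical form of the method). Effects are the same
#' marginal odds ratio as the latent method, with delta-method variance over
#' the stacked parameter vector of both sub-models (block-diagonal
#' covariance).
#'
#' @param data trial data.
#' @param criteria an [responder_criteria] object.
#' @param continuous which continuous component to retain, `"Y1"` or `"Y2"`.
#' @param f_includes_y1 add the retained continuous outcome as a covariate in
#'   the `F`-model (default `FALSE`: the response probability then factorises
#'   exactly).
#' @param level confidence level.
#' @return a list with `fit` and `effect` (an `lv_effect`).
#' @export
fit_augmented_binary <- function(data, criteria, continuous = c("Y1", "Y2"),
                                 f_includes_y1 = FALSE, level = 0.95) {
  data <- validate_trial_data(data)
  continuous <- match.arg(continuous)
  if (length(unique(data$treat)) < 2L) {
    stop("fit_augmented_binary: both arms must be present", call. = FALSE)
  }
  cc <- derive_composite(data, criteria)
  if (continuous == "Y2") {
    # retain Y2: F collapses (Y1, Y3, Y4)
    eta_c <- criteria$eta2
    yc <- data$Y2
    Fi <- as.integer(!(data$Y1 <= criteria$eta1 & data$Y3 < 5 & data$Y4 == 0))
  } else {
    eta_c <- criteria$eta1
    yc <- data$Y1
    Fi <- cc$F
  }
  df <- dplyr::mutate(data, .yc = yc, .F = Fi)
  m1 <- lm(.yc ~ treat + y10 + y20, data = df)
  if (length(unique(Fi)) < 2L) {
    stop("fit_augmented_binary: non-response indicator is constant ",
         "(separation/degenerate data)", call. = FALSE)
  }
  fml <- if (f_includes_y1) .F ~ treat + y10 + y20 + .yc else
    .F ~ treat + y10 + y20
  m2 <- suppressWarnings(glm(fml, family = binomial(), data = df))
  check_separation(m2, "fit_augmented_binary")

  n <- nrow(df)
  sig <- sqrt(sum(residuals(m1)^2) / m1$df.residual)
  theta <- c(coef(m1), log_sigma = log(sig), coef(m2))
  k1 <- length(coef(m1)); k2 <- length(coef(m2))
  cov_th <- matrix(0, k1 + 1 + k2, k1 + 1 + k2)
  cov_th[seq_len(k1), seq_len(k1)] <- vcov(m1)
  cov_th[k1 + 1, k1 + 1] <- 1 / (2 * m1$df.residual)
  cov_th[(k1 + 2):(k1 + 1 + k2), (k1 + 2):(k1 + 1 + k2)] <- vcov(m2)
  dimnames(cov_th) <- list(names(theta), names(theta))

  X <- cbind(1, 0, df$y10, df$y20)   # counterfactual design, treat column 2
  probs <- function(th, t) {
    Xt <- X; Xt[, 2] <- t
    mu <- drop(Xt %*% th[seq_len(k1)])
    p_cont <- pnorm((eta_c - mu) / exp(th[k1 + 1]))
    bf <- th[(k1 + 2):(k1 + 1 + k2)]
    if (f_includes_y1) {
      # integrate P(F=0 | y1) over the fitted normal density of y1 below eta_c
      g <- gl_nodes(24L)
      sdv <- exp(th[k1 + 1])
      out <- numeric(n)
      ub <- pnorm((eta_c - mu) / sdv)
      for (i in seq_len(n)) {
        y1g <- mu[i] + sdv * qnorm(g$x * ub[i])
        lf <- bf[1] + bf[2] * t + bf[3] * df$y10[i] + bf[4] * df$y20[i] +
          bf[5] * y1g
        out[i] <- ub[i] * sum(g$w * (1 - plogis(lf)))
      }
      out
    } else {
      p_cont * (1 - plogis(drop(Xt %*% bf)))
    }
  }
  pbar <- function(th) c(p0 = mean(probs(th, 0)), p1 = mean(probs(th, 1)))
  pp <- pbar(theta)
  if (any(pp <= .Machine$double.eps) || any(pp >= 1 - 1e-12)) {
    stop("fit_augmented_binary: averaged response probability is 0 or 1",
         call. = FALSE)
  }
  log_or_fn <- function(th) {
    q <- pbar(th)
    qlogis(q[["p1"]]) - qlogis(q[["p0"]])
  }
  log_or <- qlogis(pp[["p1"]]) - qlogis(pp[["p0"]])
  grad <- num_gradient(log_or_fn, theta, rel_step = 1e-5)
  var_log_or <- delta_quadratic(grad, cov_th)
  eff <- new_effect("augmented_binary", p0 = pp[["p0"]], p1 = pp[["p1"]],
                    log_or = log_or, var_log_or = var_log_or, level = level,
                    n = n)
  fit <- structure(list(params = theta, cov_u = cov_th,
                        loglik = as.numeric(stats::logLik(m1)) +
                          as.numeric(stats::logLik(m2)),
                        converged = m2$converged, n_iter = m2$iter,
                        method = "augmented_binary", n = n),
                   class = "lv_fit")
  list(fit = fit, effect = eff)
}
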