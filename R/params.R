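#' Model parameters for the breeding-probability models
#'
#' The three competing models share a Bernoulli-logit structure for the
#' probability that a female in state `k` (F, E, or S) in year `t - 1`
#' produces a pup (enters state `E`) in year `t`:
#'
#' \deqn{\mathrm{logit}\,\psi^{kE}_{i,t} = \mu + \delta_k + \gamma_1 A_{i,t}
#'   + \gamma_2 A_{i,t}^2 + \eta_t + \alpha_i + \beta_i X_t}
#'
#' where \eqn{A_{i,t}} is standardized age in the outcome year,
#' \eqn{X_t} indicates a perturbed (iceberg) year, \eqn{\eta_t \sim
#' N(0,\sigma_\eta)} are year effects, and \eqn{\alpha_i \sim N(0,
#' \sigma_\alpha)}, \eqn{\beta_i \sim N(0,\sigma_\beta)} are latent
#' individual effects. The hypotheses differ only in which individual
#' effects exist: **H1** (no heterogeneity) has neither, **H2** (fixed
#' heterogeneity) has \eqn{\alpha_i} only, **H3** (environment-dependent
#' heterogeneity) has both. State offsets \eqn{\delta_k} sum to zero so that
#' \eqn{\mu} is the across-state mean rate on the logit scale.
#'
#' @param hypothesis One of `"H1"`, `"H2"`, `"H3"`.
#' @param mu Logit-scale mean reproductive rate.
#' @param delta Named numeric vector `c(F=,E=,S=)` of state offsets; must sum
#'   to zero (a small numerical tolerance is allowed and re-centred away).
#' @param gamma1,gamma2 Quadratic age-effect coefficients (logit scale, on
#'   standardized age).
#' @param sigma_eta,sigma_alpha,sigma_beta Hyper-SDs (logit scale) of the
#'   year and individual effects; `sigma_alpha` must be 0 under H1 and
#'   `sigma_beta` 0 under H1/H2.
#' @param age_mean,age_sd Age-standardization constants the gammas refer to.
#' @param eta,alpha,beta Optional named numeric vectors of realized year
#'   effects (names = calendar years) and individual effects (names =
#'   individual ids). Years or individuals absent from the maps contribute 0.
#' @return An object of class `model_params` (a list of the above).
#' @seealso [reference_params()], [simulate_states()], [log_likelihood()]
#' @export
model_params <- function(hypothesis = c("H2", "H1", "H3"),
                         mu,
                         delta = c(F = 0, E = 0, S = 0),
                         gamma1 = 0, gamma2 = 0,
                         sigma_eta = 0, sigma_alpha = 0, sigma_beta = 0,
                         age_mean = 11.98, age_sd = 4.39,
                         eta = numeric(), alpha = numeric(), beta = numeric()) {
  hypothesis <- match.arg(hypothesis)
  stopifnot(
    is.numeric(mu), length(mu) == 1,
    all(c("F", "E", "S") %in% names(delta)),
    sigma_eta >= 0, sigma_alpha >= 0, sigma_beta >= 0, age_sd > 0
  )
  delta <- delta[c("F", "E", "S")]
  delta <- delta - mean(delta)
  if (hypothesis == "H1" && sigma_alpha != 0) {
    abort("H1 has no individual effects: `sigma_alpha` must be 0")
  }
  if (hypothesis != "H3" && sigma_beta != 0) {
    abort("only H3 has iceberg-year individual effects: `sigma_beta` must be 0")
  }
  structure(
    list(
      hypothesis = hypothesis, mu = mu, delta = delta,
      gamma1 = gamma1, gamma2 = gamma2,
      sigma_eta = sigma_eta, sigma_alpha = sigma_alpha,
      sigma_beta = sigma_beta,
      age_mean = age_mean, age_sd = age_sd,
      eta = eta, alpha = alpha, beta = beta
    ),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> hypothesis %s\n", x$hypothesis))
  cat(sprintf(
    "  mu %.3f; delta F %.3f E %.3f S %.3f; gamma (%.3f, %.3f)\n",
    x$mu, x$delta["F"], x$delta["E"], x$delta["S"], x$gamma1, x$gamma2
  ))
  cat(sprintf(
    "  sigma_eta %.3f sigma_alpha %.3f sigma_beta %.3f; age std (%.2f, %.2f)\n",
    x$sigma_eta, x$sigma_alpha, x$sigma_beta, x$age_mean, x$age_sd
  ))
  invisible(x)
}

# Gauss-Hermite nodes/weights (probabilists', i.e. weight exp(-x^2/2)),
# computed by Golub-Welsch. Used wherever a N(0,1) expectation is needed
# deterministically (back-transformed SDs, individual-averaged rates).
gauss_hermite <- function(n = 31) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i)
  J[cbind(i + 1, i)] <- sqrt(i)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = (e$vectors[1, ]^2)[ord])
}

# E[f(mu + sigma Z)] and SD[f(mu + sigma Z)] for Z ~ N(0,1), f = inv-logit.
prob_scale_mean <- function(mu, sigma, gh = gauss_hermite()) {
  vapply(seq_along(mu), function(i) {
    sum(gh$w * inv_logit(mu[i] + sigma[i] * gh$x))
  }, numeric(1))
}

prob_scale_sd <- function(mu, sigma, gh = gauss_hermite()) {
  vapply(seq_along(mu), function(i) {
    p <- inv_logit(mu[i] + sigma[i] * gh$x)
    m <- sum(gh$w * p)
    sqrt(max(sum(gh$w * (p - m)^2), 0))
  }, numeric(1))
}

#' Convert a probability-scale SD to the logit scale
#'
#' Solves for the logit-scale SD `sigma` such that the standard deviation of
#' `plogis(mu + sigma * Z)`, `Z ~ N(0,1)`, equals `target` — the inverse of
#' the starred back-transformation used for reporting hyper-SDs (see
#' [back_transform_sd()]).
#'
#' @param target Probability-scale SD (in `[0, 0.5)`).
#' @param mu Logit-scale location around which the effect varies.
#' @return The logit-scale SD.
#' @export
invert_prob_sd <- function(target, mu) {
  stopifnot(target >= 0, target < 0.5)
  if (target == 0) return(0)
  stats::uniroot(
    function(s) prob_scale_sd(mu, s) - target,
    interval = c(1e-8, 10), tol = 1e-9
  )$root
}
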