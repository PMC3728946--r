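# Probability-scale reference values for the three hypotheses, consistent
# with published estimates for the Erebus Bay Weddell seal population:
# state-specific breeding rates (the posterior means of
# inv-logit(mu + delta_k), i.e. with the mean-zero terms — standardized
# age, year effects, individual effects — at their means), the overall mean
# rate, the back-transformed hyper-SDs, and the probability-scale quadratic
# age coefficient. These anchor the logit-scale reconstruction in
# reference_params().
.reference <- list(
  H1 = list(mu_star = 0.62, psi = c(F = 0.50, E = 0.67, S = 0.67),
            sd_eta_star = 0.12, sd_alpha_star = 0, sd_beta_star = 0,
            gamma2_star = -0.08),
  H2 = list(mu_star = 0.66, psi = c(F = 0.54, E = 0.67, S = 0.76),
            sd_eta_star = 0.14, sd_alpha_star = 0.15, sd_beta_star = 0,
            gamma2_star = -0.10),
  H3 = list(mu_star = 0.65, psi = c(F = 0.52, E = 0.67, S = 0.74),
            sd_eta_star = 0.13, sd_alpha_star = 0.13, sd_beta_star = 0.18,
            gamma2_star = -0.09)
)

# Reference age standardization (moments of age over individual-year records
# implied by the default window and recruit-age distributions) and the age
# at peak breeding probability.
.age_ref <- list(mean = 11.98, sd = 4.39, peak = 15)

#' Reference parameter values for the seal study system
#'
#' `reference_rates()` returns the probability-scale reference quantities for
#' a hypothesis: the state-specific breeding rates
#' \eqn{\psi^{FE}, \psi^{EE}, \psi^{SE}}, the mean rate, and the
#' back-transformed (probability-scale) hyper-SDs, consistent with published
#' estimates for the Erebus Bay Weddell seal population.
#' `reference_params()` returns the corresponding logit-scale
#' [model_params()], reconstructed as follows:
#'
#' * state intercepts are `qlogis()` of the reference rates — the rates are
#'   defined with all mean-zero model terms (standardized age, year
#'   effects, individual effects) at their means, so they invert exactly;
#' * hyper-SDs by exact inversion of the starred back-transformation
#'   ([invert_prob_sd()] at `mu = qlogis(mu_star)`);
#' * the quadratic age effect with curvature from a delta-method inversion
#'   of the probability-scale coefficient (divide by `p(1-p)` at the mean
#'   rate) and the linear term set so the trend peaks at age 15.
#'
#' @param hypothesis `"H1"`, `"H2"`, or `"H3"`.
#' @return `reference_rates()`: a named list; `reference_params()`: a
#'   [model_params()].
#' @export
reference_rates <- function(hypothesis = c("H2", "H1", "H3")) {
  hypothesis <- match.arg(hypothesis)
  .reference[[hypothesis]]
}

#' @rdname reference_rates
#' @export
reference_params <- function(hypothesis = c("H2", "H1", "H3")) {
  hypothesis <- match.arg(hypothesis)
  ref <- .reference[[hypothesis]]
  mu_logit <- qlogis(ref$mu_star)
  g2 <- ref$gamma2_star / (ref$mu_star * (1 - ref$mu_star))
  peak_std <- (.age_ref$peak - .age_ref$mean) / .age_ref$sd
  g1 <- -2 * g2 * peak_std
  ic <- qlogis(ref$psi)
  model_params(
    hypothesis = hypothesis,
    mu = mean(ic),
    delta = ic - mean(ic),
    gamma1 = g1, gamma2 = g2,
    sigma_eta = invert_prob_sd(ref$sd_eta_star, mu_logit),
    sigma_alpha = if (hypothesis == "H1") 0 else
      invert_prob_sd(ref$sd_alpha_star, mu_logit),
    sigma_beta = if (hypothesis == "H3")
      invert_prob_sd(ref$sd_beta_star, mu_logit) else 0,
    age_mean = .age_ref$mean, age_sd = .age_ref$sd
  )
}

#' Covariate-profile state rates under known parameters
#'
#' A record-profile companion to the theoretical state rates: for each
#' from-state `k`, the breeding probability is averaged over that state's
#' transition records (their ages and realized year effects) and over the
#' *population law* of the latent individual effects — each individual
#' weighted equally, the effect integrated over \eqn{N(0, \sigma_\alpha)}
#' (plus \eqn{N(0,\sigma_\beta)} in iceberg years) by Gauss--Hermite
#' quadrature. Unlike the theoretical rate `plogis(mu + delta_k)`, this
#' average reflects where in covariate space each state's transitions
#' actually occur (e.g. first-time breeders are young, so their
#' profile-averaged rate sits below the theoretical one).
#'
#' @param params A [model_params()] (with realized `eta` map if available).
#' @param records A record tibble from [build_design()].
#' @return A tibble with columns `from_state` and `rate`.
#' @export
state_rates <- function(params, records) {
  stopifnot(inherits(params, "model_params"))
  base <- base_predictor(params, records)
  s <- ind_sd(params, records$iceberg)
  gh <- gauss_hermite()
  p <- inv_logit(outer(base, rep(1, length(gh$x))) +
                   outer(s, gh$x))
  pbar <- as.vector(p %*% gh$w)
  tibble::tibble(from_state = records$from_state, rate = pbar) |>
    dplyr::group_by(.data$from_state) |>
    dplyr::summarise(rate = mean(.data$rate), .groups = "drop")
}

# linear predictor without the individual effects (those are integrated)
base_predictor <- function(params, records) {
  a <- (records$age - params$age_mean) / params$age_sd
  eta <- unname(params$eta[as.character(records$year)])
  if (length(params$eta) == 0) eta <- rep(0, nrow(records))
  eta[is.na(eta)] <- 0
  params$mu + unname(params$delta[records$from_state]) +
    params$gamma1 * a + params$gamma2 * a^2 + eta
}

# SD of the integrated individual effect per record (alpha, plus beta in
# iceberg years; the two are a priori independent)
ind_sd <- function(params, iceberg) {
  sqrt(params$sigma_alpha^2 +
         params$sigma_beta^2 * as.numeric(iceberg))
}
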