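#' Transition records for model fitting
#'
#' Converts a population of encounter histories into the record set the
#' Bernoulli-logit models are fitted to: one record per within-window state
#' transition, i.e. a history spanning `L` years yields exactly `L - 1`
#' records. Covariates attach to the *outcome* year `t` (the year in which a
#' pup is or is not produced): the from-state is the state in year `t - 1`,
#' the age covariate is the individual's age in year `t` (standardized with
#' the population's constants), and the iceberg flag indicates whether `t`
#' is a perturbed year. The outcome is 1 if the state in year `t` is `E`.
#'
#' @param pop A [seal_population()].
#' @return A tibble with columns `individual_id`, `year` (outcome year),
#'   `from_state`, `age`, `age_std`, `iceberg`, `y`.
#' @export
build_design <- function(pop) {
  stopifnot(inherits(pop, "seal_population"))
  ice <- pop$iceberg_years
  pop$histories |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::mutate(from_state = dplyr::lag(.data$state)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$from_state)) |>
    dplyr::transmute(
      individual_id = .data$individual_id,
      year = .data$year,
      from_state = .data$from_state,
      age = .data$age,
      age_std = (.data$age - pop$age_mean) / pop$age_sd,
      iceberg = .data$year %in% ice,
      y = as.integer(.data$state == "E")
    )
}

# Linear predictor for a record set under point-valued parameters. Ages are
# standardized with the parameters' own constants; realized eta/alpha/beta
# are looked up in the parameter maps (absent keys contribute 0).
linear_predictor <- function(params, records) {
  stopifnot(inherits(params, "model_params"))
  a <- (records$age - params$age_mean) / params$age_sd
  lookup <- function(map, keys) {
    out <- unname(map[as.character(keys)])
    out[is.na(out)] <- 0
    if (length(map) == 0) out <- rep(0, length(keys))
    out
  }
  lp <- params$mu + unname(params$delta[records$from_state]) +
    params$gamma1 * a + params$gamma2 * a^2 +
    lookup(params$eta, records$year) +
    lookup(params$alpha, records$individual_id) +
    lookup(params$beta, records$individual_id) * as.numeric(records$iceberg)
  clip_lp(lp)
}

#' Bernoulli log-likelihood of a transition record set
#'
#' Sum of `log Bernoulli(y | plogis(linear predictor))` over the records of
#' [build_design()], under point-valued parameters (including any realized
#' year/individual effects stored in the parameter maps). Under H2/H3 this is
#' the *conditional* log-likelihood given the effects, the building block of
#' the hierarchical models.
#'
#' @param params A [model_params()].
#' @param records A record tibble from [build_design()].
#' @return A finite scalar for finite parameters.
#' @export
log_likelihood <- function(params, records) {
  lp <- linear_predictor(params, records)
  # log Bernoulli via plogis log form for numerical stability
  sum(ifelse(records$y == 1,
             plogis(lp, log.p = TRUE),
             plogis(-lp, log.p = TRUE)))
}
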