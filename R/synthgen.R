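#' Configuration for the synthetic-population generator
#'
#' The generator emulates the structure of the Erebus Bay Weddell seal
#' study: 954 breeding females followed over study years 1982--2011 with a
#' perturbed (iceberg) period 2001--2005; minimal lifetime windows of 2--25
#' years with mean 7.1 and about 67% of windows of at least 5 years
#' (a truncated negative binomial calibrated to those facts); and ages at
#' first reproduction averaging 7.62 years (a shifted Poisson with minimum
#' 4, truncated at 12, calibrated to that mean). Recruit years are uniform
#' over the years in which the window fits the study period.
#'
#' @param n_individuals Number of females.
#' @param study_years Inclusive calendar range of the study.
#' @param iceberg_years Perturbed years (binary environmental covariate).
#' @param params True generating parameters, a [model_params()]; the
#'   hypothesis field decides which individual effects are drawn.
#' @param mlw List defining the truncated negative-binomial window
#'   distribution: `mu`, `size`, `min`, `max`. Windows are truncated to the
#'   study length if it is shorter than `max`.
#' @param recruit_age List defining the recruit-age distribution:
#'   `lambda` (Poisson mean before truncation), `min`, `max`.
#' @param center_year_effects If `TRUE` (default) the realized year effects
#'   are re-centred to mean zero across the study years, so that the
#'   generating intercepts are exactly the grand means of the realized
#'   process; the draws remain i.i.d. up to that single linear constraint.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_individuals = 954,
                             study_years = 1982:2011,
                             iceberg_years = 2001:2005,
                             params = reference_params("H2"),
                             mlw = list(mu = 6.4825, size = 2.7206,
                                        min = 2, max = 25),
                             recruit_age = list(lambda = 3.7009,
                                                min = 4, max = 12),
                             center_year_effects = TRUE) {
  stopifnot(
    n_individuals >= 1,
    inherits(params, "model_params"),
    mlw$min >= 1, mlw$min <= mlw$max,
    recruit_age$min <= recruit_age$max
  )
  study_years <- seq(min(study_years), max(study_years))
  if (mlw$min > length(study_years)) {
    abort("minimal window lower bound exceeds the study length")
  }
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      study_years = study_years,
      iceberg_years = sort(unique(as.integer(iceberg_years))),
      params = params,
      mlw = mlw,
      recruit_age = recruit_age,
      center_year_effects = isTRUE(center_year_effects)
    ),
    class = "generator_config"
  )
}

# Draw from a discrete distribution truncated to an integer support.
sample_truncated <- function(n, support, prob) {
  prob <- prob / sum(prob)
  support[sample.int(length(support), n, replace = TRUE, prob = prob)]
}

#' Transition probability and single-step state simulation
#'
#' `transition_prob()` evaluates the probability of producing a pup (moving
#' into state `E`) for given from-state, age, and realized effects;
#' `simulate_states()` draws the resulting next state. Both are vectorized
#' over their arguments.
#'
#' @param params A [model_params()].
#' @param from_state Character vector of states in the previous year
#'   (`"F"`, `"E"`, `"S"`).
#' @param age Integer age in the outcome year (standardized internally with
#'   the parameters' constants).
#' @param eta,alpha,beta Realized year/individual effects (numeric).
#' @param iceberg Logical; whether the outcome year is a perturbed year
#'   (gates `beta`).
#' @return `transition_prob()`: probabilities; `simulate_states()`: a
#'   character vector of `"E"`/`"S"`.
#' @export
transition_prob <- function(params, from_state, age, eta = 0, alpha = 0,
                            beta = 0, iceberg = FALSE) {
  stopifnot(inherits(params, "model_params"),
            all(from_state %in% c("F", "E", "S")))
  a <- (age - params$age_mean) / params$age_sd
  inv_logit(
    params$mu + unname(params$delta[from_state]) +
      params$gamma1 * a + params$gamma2 * a^2 +
      eta + alpha + beta * as.numeric(iceberg)
  )
}

#' @rdname transition_prob
#' @export
simulate_states <- function(params, from_state, age, eta = 0, alpha = 0,
                            beta = 0, iceberg = FALSE) {
  p <- transition_prob(params, from_state, age, eta, alpha, beta, iceberg)
  ifelse(runif(length(p)) < p, "E", "S")
}

#' Generate a synthetic population of encounter histories
#'
#' Draws a full population under the generating model of the configured
#' hypothesis: shared year effects (one per study year), latent individual
#' effects as the hypothesis dictates, a window length and recruit age/year
#' per female, and a forward-simulated state sequence starting from `F`.
#' The true latent effects are returned in a side table (not in the
#' histories) so that parameter-recovery experiments can join on
#' `individual_id`.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; the output is reproducible byte-for-byte.
#' @return A list of class `synth_population` with elements
#'   `population` (a [seal_population()]), `truth` (tibble
#'   `individual_id`, `alpha`, `beta`), `year_effects` (tibble `year`,
#'   `eta`), `config`, and `seed`.
#' @examples
#' synth <- sample_population(generator_config(n_individuals = 50), seed = 1)
#' synth$population
#' @export
sample_population <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  yrs <- config$study_years
  n_yr <- length(yrs)
  n <- config$n_individuals
  p <- config$params

  eta <- rnorm(n_yr, 0, p$sigma_eta)
  if (config$center_year_effects && p$sigma_eta > 0) eta <- eta - mean(eta)
  names(eta) <- yrs

  mlw_support <- seq(config$mlw$min, min(config$mlw$max, n_yr))
  L <- sample_truncated(
    n, mlw_support,
    dnbinom(mlw_support, mu = config$mlw$mu, size = config$mlw$size)
  )
  ra <- config$recruit_age
  age_support <- seq(ra$min, ra$max)
  recruit_age <- sample_truncated(
    n, age_support, dpois(age_support - ra$min, ra$lambda)
  )
  recruit_year <- yrs[1] + vapply(
    L, function(l) sample.int(n_yr - l + 1, 1) - 1L, integer(1)
  )

  alpha <- if (p$hypothesis %in% c("H2", "H3")) {
    rnorm(n, 0, p$sigma_alpha)
  } else {
    rep(0, n)
  }
  beta <- if (p$hypothesis == "H3") rnorm(n, 0, p$sigma_beta) else rep(0, n)

  ids <- sprintf("ind%04d", seq_len(n))
  max_l <- max(L)
  states <- matrix(NA_character_, n, max_l)
  states[, 1] <- "F"
  for (j in seq_len(max_l - 1)) {
    active <- which(L > j)
    if (!length(active)) break
    yr <- recruit_year[active] + j
    states[active, j + 1] <- simulate_states(
      p,
      from_state = states[active, j],
      age = recruit_age[active] + j,
      eta = eta[as.character(yr)],
      alpha = alpha[active],
      beta = beta[active],
      iceberg = yr %in% config$iceberg_years
    )
  }

  long <- tibble::tibble(
    individual_id = rep(ids, L),
    offset = unlist(lapply(L, seq_len)) - 1L
  ) |>
    dplyr::mutate(
      year = rep(recruit_year, L) + .data$offset,
      age = rep(recruit_age, L) + .data$offset,
      state = states[cbind(rep(seq_len(n), L), .data$offset + 1L)]
    ) |>
    dplyr::select(-"offset")

  pop <- seal_population(
    long,
    iceberg_years = config$iceberg_years,
    study_years = config$study_years
  )
  structure(
    list(
      population = pop,
      truth = tibble::tibble(individual_id = ids, alpha = alpha, beta = beta),
      year_effects = tibble::tibble(year = yrs, eta = unname(eta)),
      config = config,
      seed = seed
    ),
    class = "synth_population"
  )
}

#' @export
print.synth_population <- function(x, ...) {
  cat(sprintf(
    "<synth_population> hypothesis %s, seed %d\n",
    x$config$params$hypothesis, x$seed
  ))
  print(x$population)
  invisible(x)
}

#' Write a synthetic population to disk
#'
#' Emits the histories CSV dialect of [write_histories()], a `truth.csv`
#' side table (`individual_id,alpha,beta`), a `year_effects.csv` table, and
#' a `params.json` echo of the generator configuration including the seed.
#'
#' @param synth A `synth_population` from [sample_population()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(synth, dir) {
  stopifnot(inherits(synth, "synth_population"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_histories(synth$population, file.path(dir, "histories.csv"))
  readr::write_csv(synth$truth, file.path(dir, "truth.csv"))
  readr::write_csv(synth$year_effects, file.path(dir, "year_effects.csv"))
  cfg <- synth$config
  echo <- list(
    n_individuals = cfg$n_individuals,
    study_years = range(cfg$study_years),
    iceberg_years = cfg$iceberg_years,
    mlw = cfg$mlw,
    recruit_age = cfg$recruit_age,
    center_year_effects = cfg$center_year_effects,
    params = unclass(cfg$params)[c(
      "hypothesis", "mu", "delta", "gamma1", "gamma2",
      "sigma_eta", "sigma_alpha", "sigma_beta", "age_mean", "age_sd"
    )],
    seed = synth$seed
  )
  jsonlite::write_json(echo, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
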