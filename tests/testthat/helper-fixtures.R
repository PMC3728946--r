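# shared fixtures and independent oracles (kept deliberately naive: the
# oracles enumerate runs with explicit loops and never call package
# internals beyond constructors)

toy_histories <- function() {
  tibble::tibble(
    individual_id = c("A", "A", "B", "B", "B"),
    year = c(2000L, 2001L, 1998L, 1999L, 2000L),
    age = c(8L, 9L, 7L, 8L, 9L),
    state = c("F", "E", "F", "S", "E")
  )
}

toy_population <- function() {
  seal_population(toy_histories(), iceberg_years = integer(),
                  study_years = 1995:2005)
}

random_state_string <- function(len) {
  c("F", sample(c("E", "S"), len - 1, replace = TRUE))
}

# brute-force trajectory statistics: explicit run enumeration
oracle_trajectory <- function(states) {
  pups <- 1L
  consec <- 0L
  persist <- 0L
  run <- 0L
  for (i in seq_along(states)) {
    if (i > 1 && states[i] == "E") {
      pups <- pups + 1L
      if (states[i - 1] == "E") consec <- consec + 1L
      run <- run + 1L
    } else if (i > 1) {
      run <- 0L
    }
    persist <- max(persist, run)
  }
  list(rep_output = pups, consec_rep = consec, persist_rep = persist)
}

# build a states tibble for one individual from a state vector
states_to_history <- function(states, id = "x", recruit_year = 1990L,
                              recruit_age = 8L) {
  tibble::tibble(
    individual_id = id,
    year = recruit_year + seq_along(states) - 1L,
    age = recruit_age + seq_along(states) - 1L,
    state = states
  )
}

# a hand-assembled ih_fit whose "posterior" is exactly the draws supplied;
# lets derived-quantity code be tested against closed-form expectations
fake_fit <- function(hypothesis, fixed, eta, alpha = NULL, beta = NULL,
                     pop = toy_population(), n_chains = 2) {
  stopifnot(is.matrix(fixed))
  colnames(fixed) <- c("mu", "delta_F", "delta_E", "g1", "g2",
                       "sd_eta", "sd_alpha", "sd_beta")
  records <- build_design(pop)
  ids <- sort(unique(pop$histories$individual_id))
  windows <- pop$histories |>
    dplyr::group_by(individual_id) |>
    dplyr::summarise(
      recruit_year = min(year),
      recruit_age = age[which.min(year)],
      min_life_win = dplyr::n(), .groups = "drop"
    )
  empty <- matrix(numeric(0), nrow(fixed), 0)
  ch <- list(fixed = fixed, eta = eta,
             alpha = if (is.null(alpha)) empty else alpha,
             beta = if (is.null(beta)) empty else beta)
  fit <- structure(
    list(
      hypothesis = hypothesis, prior = "uniform-sd",
      chains = rep(list(ch), n_chains), n_chains = n_chains,
      samples = nrow(fixed), burnin = 0, thin = 1, seed = 1,
      records = records, windows = windows, individual_ids = ids,
      study_years = pop$study_years, iceberg_years = pop$iceberg_years,
      age_mean = pop$age_mean, age_sd = pop$age_sd,
      elapsed = 0, converged = TRUE, rhat_threshold = 1.05
    ),
    class = "ih_fit"
  )
  fit$rhat <- rhat(fit)
  fit
}

# small cached fits so expensive MCMC runs are shared across test files
.fit_cache <- new.env(parent = emptyenv())

cached_fit <- function(key, expr) {
  if (!exists(key, .fit_cache)) assign(key, force(expr), .fit_cache)
  get(key, .fit_cache)
}

small_synth <- function(n = 200, hypothesis = "H2", seed = 42) {
  sample_population(
    generator_config(n_individuals = n,
                     params = reference_params(hypothesis)),
    seed = seed
  )
}

# The closed-loop replicate experiment shared by the posterior-predictive
# power/calibration checks and the interval-coverage property: 20 synthetic
# populations at the study scale under H2 truth, each fitted with H1 and H2
# (scaled-down chains, convergence-gated by construction) and checked with
# 300 posterior predictive replicates. Cached so the suite pays for it once.
replicate_experiment <- function() {
  cached_fit("replicate_experiment", {
    truth <- reference_params("H2")
    purrr::map_dfr(1:20, function(r) {
      synth <- sample_population(generator_config(), seed = 300 + r)
      f1 <- suppressWarnings(
        fit_ih(synth, "H1", burnin = 600, samples = 1500, seed = r)
      )
      p1 <- run_ppc(f1, n_rep = 300, seed = r)
      f2 <- suppressWarnings(
        fit_ih(synth, "H2", burnin = 600, samples = 1500, seed = r)
      )
      p2 <- run_ppc(f2, n_rep = 300, seed = r)
      psi2 <- derive_state_rates(f2)
      sd2 <- tidy(f2)
      pick <- function(ppc) {
        ppc$p_value[ppc$statistic == "rep_output" & ppc$summary == "sd"]
      }
      tibble::tibble(
        rep = r,
        conv_h1 = f1$converged, conv_h2 = f2$converged,
        p_h1 = pick(p1), p_h2 = pick(p2),
        psi_F_l = psi2$lci2.5[psi2$from_state == "F"],
        psi_F_u = psi2$uci97.5[psi2$from_state == "F"],
        psi_E_l = psi2$lci2.5[psi2$from_state == "E"],
        psi_E_u = psi2$uci97.5[psi2$from_state == "E"],
        psi_S_l = psi2$lci2.5[psi2$from_state == "S"],
        psi_S_u = psi2$uci97.5[psi2$from_state == "S"],
        sd_a_l = sd2$lci2.5[sd2$parameter == "sd_alpha"],
        sd_a_u = sd2$uci97.5[sd2$parameter == "sd_alpha"]
      )
    })
  })
}
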