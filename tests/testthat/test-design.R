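test_that("each history of length L yields exactly L - 1 outcome records", {
  pop <- toy_population()
  rec <- build_design(pop)
  expect_equal(nrow(rec), 3)  # windows of 2 and 3 years
  a <- rec[rec$individual_id == "A", ]
  expect_equal(a$from_state, "F")
  expect_equal(a$y, 1L)
  expect_equal(a$year, 2001L)
  b <- rec[rec$individual_id == "B", ]
  expect_equal(b$from_state, c("F", "S"))
  expect_equal(b$y, c(0L, 1L))

  single <- seal_population(states_to_history("F"), iceberg_years = integer())
  expect_equal(nrow(build_design(single)), 0)
})

test_that("covariates attach to the outcome year", {
  h <- states_to_history(c("F", "E", "S"), recruit_year = 2000L,
                         recruit_age = 8L)
  pop <- seal_population(h, iceberg_years = 2001L, study_years = 1998:2005)
  rec <- build_design(pop)
  # outcome years 2001, 2002: only the first is an iceberg year
  expect_equal(rec$iceberg, c(TRUE, FALSE))
  expect_equal(rec$age, c(9L, 10L))
  expect_equal(rec$age_std, (c(9, 10) - pop$age_mean) / pop$age_sd)
})

test_that("default-scale populations give the expected record count", {
  synth <- sample_population(generator_config(), seed = 6)
  rec <- build_design(synth$population)
  n_ind <- nrow(synth$truth)
  expect_equal(nrow(rec), nrow(synth$population$histories) - n_ind)
  expect_lt(abs(nrow(rec) - 5838), 500)
})

test_that("log-likelihood matches direct Bernoulli computation", {
  # one record, all terms zero
  h <- states_to_history(c("F", "E"))
  pop <- seal_population(h, iceberg_years = integer())
  rec <- build_design(pop)
  p0 <- model_params("H1", mu = 0, age_mean = 8, age_sd = 1)
  p0$age_mean <- rec$age[1]  # zero the age covariate
  expect_equal(log_likelihood(p0, rec), log(0.5))

  # brute-force oracle on random records under a full H3 parameter set
  synth <- sample_population(
    generator_config(n_individuals = 30,
                     params = reference_params("H3")),
    seed = 13
  )
  rec <- build_design(synth$population)[1:20, ]
  par <- reference_params("H3")
  par$eta <- setNames(synth$year_effects$eta, synth$year_effects$year)
  par$alpha <- setNames(synth$truth$alpha, synth$truth$individual_id)
  par$beta <- setNames(synth$truth$beta, synth$truth$individual_id)
  direct <- 0
  for (i in seq_len(nrow(rec))) {
    r <- rec[i, ]
    a <- (r$age - par$age_mean) / par$age_sd
    lp <- par$mu + par$delta[[r$from_state]] + par$gamma1 * a +
      par$gamma2 * a^2 + par$eta[[as.character(r$year)]] +
      par$alpha[[r$individual_id]] +
      par$beta[[r$individual_id]] * as.numeric(r$iceberg)
    direct <- direct + log(ifelse(r$y == 1, plogis(lp), 1 - plogis(lp)))
  }
  expect_equal(log_likelihood(par, rec), direct, tolerance = 1e-10)
})

test_that("the model family is nested: H3 at zero beta equals H2", {
  synth <- small_synth(n = 40, seed = 21)
  rec <- build_design(synth$population)
  base <- reference_params("H2")
  h3 <- model_params(
    "H3", mu = base$mu, delta = base$delta,
    gamma1 = base$gamma1, gamma2 = base$gamma2,
    sigma_eta = base$sigma_eta, sigma_alpha = base$sigma_alpha,
    sigma_beta = 0.5,
    age_mean = base$age_mean, age_sd = base$age_sd
  )
  set.seed(88)
  shared_alpha <- setNames(rnorm(40, 0, 0.5),
                           sort(unique(rec$individual_id)))
  base$alpha <- shared_alpha
  h3$alpha <- shared_alpha
  h3$beta <- setNames(rep(0, 40), names(shared_alpha))
  expect_equal(log_likelihood(h3, rec), log_likelihood(base, rec))

  h1 <- model_params(
    "H1", mu = base$mu, delta = base$delta,
    gamma1 = base$gamma1, gamma2 = base$gamma2,
    sigma_eta = base$sigma_eta,
    age_mean = base$age_mean, age_sd = base$age_sd
  )
  base0 <- base
  base0$alpha <- numeric()
  expect_equal(log_likelihood(base0, rec), log_likelihood(h1, rec))
})
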