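test_that("probability-scale SD transformation matches a Monte-Carlo oracle", {
  # degenerate case
  expect_equal(invert_prob_sd(0, 0.5), 0)
  mu <- qlogis(0.66)
  # frozen oracle value: SD of plogis(mu + 0.67 Z) over 1e6 N(0,1) draws
  set.seed(991)
  mc <- sd(plogis(mu + 0.67 * rnorm(1e6)))
  expect_equal(mc, 0.1410, tolerance = 0.002)
  expect_equal(sealIH:::prob_scale_sd(mu, 0.67), mc, tolerance = 0.002)
  # exact inversion round-trips
  for (target in c(0.05, 0.14, 0.15, 0.3)) {
    s <- invert_prob_sd(target, mu)
    expect_equal(sealIH:::prob_scale_sd(mu, s), target, tolerance = 1e-6)
  }
  # strictly increasing in sigma at fixed mu
  grid <- seq(0.1, 2, by = 0.1)
  vals <- sealIH:::prob_scale_sd(rep(mu, length(grid)), grid)
  expect_true(all(diff(vals) > 0))
})

test_that("back-transformed hyper-SD summaries follow the draws", {
  n <- 500
  fixed <- matrix(0, n, 8)
  fixed[, 1] <- qlogis(0.66)       # mu
  fixed[, 7] <- 0.67               # sd_alpha
  fit <- fake_fit("H2", fixed, eta = matrix(0, n, 11),
                  alpha = matrix(0, n, 2))
  bt <- back_transform_sd(fit, "alpha")
  expect_equal(bt$mean, 0.1410, tolerance = 0.002)
  expect_equal(bt$lci2.5, bt$uci97.5)  # point-mass posterior
  # zero SD maps to zero
  fixed0 <- fixed
  fixed0[, 7] <- 0
  fit0 <- fake_fit("H2", fixed0, eta = matrix(0, n, 11),
                   alpha = matrix(0, n, 2))
  expect_equal(back_transform_sd(fit0, "alpha")$mean, 0)
  # beta is not part of H2
  expect_error(back_transform_sd(fit, "beta"), "has no beta effects")
})

test_that("derived state rates reduce to plogis at point-mass posteriors", {
  n <- 200
  fixed <- matrix(0, n, 8)
  fixed[, 1] <- qlogis(0.7)  # mu; deltas zero
  fit <- fake_fit("H1", fixed, eta = matrix(0, n, 11))
  rates <- derive_state_rates(fit)
  expect_equal(rates$mean, rep(0.7, 3), tolerance = 1e-9)
  expect_equal(rates$lci2.5, rates$uci97.5)

  # with state offsets the three rates separate accordingly
  fixed2 <- fixed
  fixed2[, 2] <- -0.5  # delta_F
  fixed2[, 3] <- 0.2   # delta_E
  fit2 <- fake_fit("H1", fixed2, eta = matrix(0, n, 11))
  r2 <- derive_state_rates(fit2)
  expect_equal(r2$mean[r2$from_state == "F"], plogis(qlogis(0.7) - 0.5))
  expect_equal(r2$mean[r2$from_state == "E"], plogis(qlogis(0.7) + 0.2))
  expect_equal(r2$mean[r2$from_state == "S"], plogis(qlogis(0.7) + 0.3))
})

test_that("covariate-profile rates agree with the known-parameter average", {
  # a fit whose single 'draw' equals known parameters must reproduce
  # state_rates() on the same records
  pop <- small_synth(n = 60, seed = 31)$population
  par <- reference_params("H2")
  n <- 50
  fixed <- matrix(0, n, 8)
  fixed[, 1] <- par$mu
  fixed[, 2] <- par$delta[["F"]]
  fixed[, 3] <- par$delta[["E"]]
  fixed[, 4] <- par$gamma1
  fixed[, 5] <- par$gamma2
  fixed[, 7] <- par$sigma_alpha
  n_ids <- length(unique(pop$histories$individual_id))
  fit <- fake_fit("H2", fixed,
                  eta = matrix(0, n, length(pop$study_years)),
                  alpha = matrix(0, n, n_ids), pop = pop)
  got <- derive_state_rates(fit, type = "covariate")
  par2 <- par
  par2$age_mean <- pop$age_mean
  par2$age_sd <- pop$age_sd
  want <- state_rates(par2, build_design(pop))
  for (k in c("F", "E", "S")) {
    expect_equal(got$mean[got$from_state == k],
                 want$rate[want$from_state == k], tolerance = 1e-6)
  }
  # profile averaging sits below the theoretical rate for young first-timers
  theo <- derive_state_rates(fit)
  expect_lt(got$mean[got$from_state == "F"],
            theo$mean[theo$from_state == "F"])
})

test_that("alpha-beta correlation has the right anchors and guards", {
  pop <- small_synth(n = 40, seed = 71)$population
  n_ids <- length(unique(pop$histories$individual_id))
  n <- 300
  fixed <- matrix(0.5, n, 8)
  set.seed(14)
  a <- matrix(rnorm(n * n_ids), n, n_ids)
  fit_same <- fake_fit("H3", fixed, eta = matrix(0, n, 30), alpha = a,
                       beta = a, pop = pop)
  r1 <- correlation_alpha_beta(fit_same, individuals = "all")
  expect_equal(r1$mean, 1)
  expect_equal(r1$cor_of_means, 1)

  b <- matrix(rnorm(n * n_ids), n, n_ids)
  fit_ind <- fake_fit("H3", fixed, eta = matrix(0, n, 30), alpha = a,
                      beta = b, pop = pop)
  r0 <- correlation_alpha_beta(fit_ind, individuals = "all")
  expect_lt(abs(r0$mean), 3 / sqrt(n_ids))

  fit_h2 <- fake_fit("H2", fixed, eta = matrix(0, n, 30), alpha = a,
                     pop = pop)
  expect_error(correlation_alpha_beta(fit_h2), "H3")
})

test_that("independent effects at the study scale give near-zero correlation", {
  n_ids <- 954
  n <- 100
  fixed <- matrix(0.5, n, 8)
  set.seed(24)
  a <- matrix(rnorm(n * n_ids), n, n_ids)
  b <- matrix(rnorm(n * n_ids), n, n_ids)
  pop <- sample_population(
    generator_config(params = reference_params("H3")), seed = 5
  )$population
  fit <- fake_fit("H3", fixed, eta = matrix(0, n, 30), alpha = a, beta = b,
                  pop = pop)
  r <- correlation_alpha_beta(fit, individuals = "all")
  expect_lt(abs(r$mean), 2 / sqrt(n_ids))
  r_exposed <- correlation_alpha_beta(fit)
  expect_lt(r_exposed$n_individuals, n_ids)
  expect_gt(r_exposed$n_individuals, 0)
})
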