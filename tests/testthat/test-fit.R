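test_that("fits are reproducible draw-for-draw under a fixed seed", {
  synth <- small_synth(n = 60, seed = 15)
  a <- suppressWarnings(
    fit_ih(synth, "H2", burnin = 200, samples = 300, seed = 4)
  )
  b <- suppressWarnings(
    fit_ih(synth, "H2", burnin = 200, samples = 300, seed = 4)
  )
  expect_identical(a$chains[[1]]$fixed, b$chains[[1]]$fixed)
  expect_identical(a$chains[[2]]$alpha, b$chains[[2]]$alpha)
  c <- suppressWarnings(
    fit_ih(synth, "H2", burnin = 200, samples = 300, seed = 5)
  )
  expect_false(identical(a$chains[[1]]$fixed, c$chains[[1]]$fixed))
})

test_that("potential scale reduction behaves at its anchor points", {
  n <- 100
  fixed <- matrix(0, n, 8)
  fixed[, 1] <- sin(seq_len(n))  # within-chain variance, identical chains
  fit <- fake_fit("H1", fixed, eta = matrix(0, n, 11))
  expect_lt(abs(rhat(fit, "mu") - 1), 0.01)

  # disjoint supports: between-chain variance dominates
  fit$chains[[2]]$fixed[, "mu"] <- fit$chains[[2]]$fixed[, "mu"] + 10
  expect_gt(rhat(fit, "mu"), 5)

  # textbook formula, coded independently, on the same 2 x 100 array
  x <- cbind(fit$chains[[1]]$fixed[, "mu"], fit$chains[[2]]$fixed[, "mu"])
  W <- mean(c(var(x[, 1]), var(x[, 2])))
  B <- n * var(c(mean(x[, 1]), mean(x[, 2])))
  vhat <- (n - 1) / n * W + B / n
  expect_equal(rhat(fit, "mu"), sqrt(vhat / W), tolerance = 1e-12)
})

test_that("rhat agrees with the coda implementation on real chains", {
  skip_if_not_installed("coda")
  synth <- small_synth(n = 80, seed = 33)
  fit <- suppressWarnings(
    fit_ih(synth, "H1", burnin = 800, samples = 2500, seed = 2)
  )
  ml <- coda::mcmc.list(lapply(fit$chains, function(ch) {
    coda::mcmc(ch$fixed[, c("mu", "sd_eta")])
  }))
  ref <- coda::gelman.diag(ml, autoburnin = FALSE,
                           multivariate = FALSE)$psrf[, 1]
  # coda adds a sampling-variability correction, so agreement is approximate
  # and tightest when the chains have converged
  expect_lt(abs(rhat(fit, "mu") - ref[["mu"]]), 0.02)
  expect_lt(abs(rhat(fit, "sd_eta") - ref[["sd_eta"]]), 0.02)
})

test_that("single-chain fits work but refuse a convergence diagnostic", {
  synth <- small_synth(n = 30, seed = 16)
  fit <- suppressWarnings(
    fit_ih(synth, "H1", chains = 1, burnin = 100, samples = 200, seed = 1)
  )
  expect_true(all(is.na(fit$rhat$rhat)))
  expect_error(rhat(fit), "at least 2 chains")
})

test_that("degenerate all-identical outcomes are flagged but fit", {
  par <- model_params("H1", mu = 50)
  synth <- sample_population(
    generator_config(n_individuals = 15, params = par), seed = 3
  )
  # flags non-identifiability and (unsurprisingly) fails the R-hat gate
  expect_warning(
    expect_warning(
      fit <- fit_ih(synth, "H1", burnin = 100, samples = 200, seed = 1),
      "degenerate"
    ),
    "potential scale reduction"
  )
  expect_s3_class(fit, "ih_fit")
})

test_that("H1 recovers the mean rate and year-effect scale on H1 data", {
  truth <- reference_params("H1")
  fit <- cached_fit("h1_recovery", {
    synth <- sample_population(
      generator_config(n_individuals = 400, params = truth), seed = 19
    )
    fit_ih(synth, "H1", burnin = 600, samples = 1500, seed = 6)
  })
  expect_true(fit$converged)
  rates <- derive_state_rates(fit)
  ref <- reference_rates("H1")
  for (k in c("F", "E", "S")) {
    expect_lt(abs(rates$mean[rates$from_state == k] - ref$psi[[k]]), 0.06)
  }
  sd_eta <- tidy(fit)
  expect_true(
    sd_eta$lci2.5[sd_eta$parameter == "sd_eta"] < truth$sigma_eta &&
      truth$sigma_eta < sd_eta$uci97.5[sd_eta$parameter == "sd_eta"]
  )
})

test_that("tidy and glance summarize the fit consistently", {
  synth <- small_synth(n = 50, seed = 25)
  fit <- suppressWarnings(
    fit_ih(synth, "H2", burnin = 200, samples = 400, seed = 2)
  )
  td <- tidy(fit)
  expect_setequal(
    td$parameter,
    c("mu", "delta_F", "delta_E", "g1", "g2", "sd_eta", "sd_alpha")
  )
  expect_true(all(td$lci2.5 <= td$mean & td$mean <= td$uci97.5))
  gl <- glance(fit)
  expect_equal(gl$n_individuals, 50)
  expect_equal(gl$n_draws, 800)
  expect_equal(gl$hypothesis, "H2")
  # summary table adds probability-scale derived rows
  fs <- fit_summary(fit)
  expect_true(all(c("mean_rate", "psi_FE", "psi_EE", "psi_SE",
                    "sd_alpha_star") %in% fs$parameter))
  p <- fs[fs$scale == "probability", ]
  expect_true(all(p$mean >= 0 & p$mean <= 1))
})

test_that("credible intervals cover generating parameters at nominal rate", {
  exp_res <- replicate_experiment()
  truth <- reference_params("H2")
  ref <- reference_rates("H2")
  covered <- c(
    psi_F = mean(exp_res$psi_F_l <= ref$psi[["F"]] &
                   ref$psi[["F"]] <= exp_res$psi_F_u),
    psi_E = mean(exp_res$psi_E_l <= ref$psi[["E"]] &
                   ref$psi[["E"]] <= exp_res$psi_E_u),
    psi_S = mean(exp_res$psi_S_l <= ref$psi[["S"]] &
                   ref$psi[["S"]] <= exp_res$psi_S_u),
    sd_alpha = mean(exp_res$sd_a_l <= truth$sigma_alpha &
                      truth$sigma_alpha <= exp_res$sd_a_u)
  )
  # pooled coverage of nominal-95% intervals across 20 replicates x 4
  # parameters; Monte-Carlo slack for 80 Bernoulli trials
  expect_gte(mean(covered), 0.85)
  expect_true(all(covered >= 0.7))
})
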