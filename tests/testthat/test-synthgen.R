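test_that("generation is deterministic under a fixed seed", {
  a <- sample_population(generator_config(n_individuals = 50), seed = 11)
  b <- sample_population(generator_config(n_individuals = 50), seed = 11)
  expect_identical(a$population$histories, b$population$histories)
  expect_identical(a$truth, b$truth)
  expect_identical(a$year_effects, b$year_effects)
  c <- sample_population(generator_config(n_individuals = 50), seed = 12)
  expect_false(identical(a$population$histories, c$population$histories))
})

test_that("homogeneous parameters produce fair-coin breeding outcomes", {
  par <- model_params("H1", mu = 0, delta = c(F = 0, E = 0, S = 0))
  synth <- sample_population(
    generator_config(n_individuals = 400, params = par), seed = 5
  )
  h <- synth$population$histories
  outcomes <- h$state[h$state != "F"]
  expect_equal(mean(outcomes == "E"), 0.5, tolerance = 0.05)
})

test_that("single-step simulation matches its target probability", {
  par <- model_params("H2", mu = qlogis(0.76),
                      sigma_alpha = 0.5)
  # saturation
  hi <- model_params("H1", mu = 50)
  expect_true(all(simulate_states(hi, rep("E", 200),
                                  age = hi$age_mean) == "E"))
  lo <- model_params("H1", mu = -50)
  expect_true(all(simulate_states(lo, rep("S", 200),
                                  age = lo$age_mean) == "S"))
  # all terms zero
  expect_equal(transition_prob(model_params("H1", mu = 0), "E",
                               age = 11.98), 0.5, tolerance = 1e-6)
  # Monte-Carlo oracle at logit(0.76): age at the standardization mean so
  # the quadratic term vanishes
  set.seed(77)
  draws <- simulate_states(par, rep("E", 1e6), age = par$age_mean)
  expect_equal(mean(draws == "E"), 0.76, tolerance = 0.002)
})

test_that("default population matches the study's observation count scale", {
  synth <- sample_population(generator_config(), seed = 1)
  n_obs <- nrow(synth$population$histories)
  expect_lt(abs(n_obs - 6792), 500)
  mlw <- trajectory_stats(synth$population)$min_life_win
  expect_true(all(mlw >= 2 & mlw <= 25))
  expect_lt(abs(mean(mlw) - 7.1), 0.3)
  expect_gt(mean(mlw >= 5), 0.6)
})

test_that("generated data always pass encounter-history validation", {
  for (s in 1:3) {
    synth <- sample_population(generator_config(n_individuals = 80), seed = s)
    expect_no_error(seal_population(
      synth$population$histories,
      iceberg_years = synth$population$iceberg_years,
      study_years = synth$population$study_years
    ))
    expect_true(all(synth$population$histories$year %in% 1982:2011))
  }
})

test_that("empirical breeding rates track the true individual effects", {
  synth <- sample_population(generator_config(), seed = 8)
  emp <- trajectory_stats(synth$population) |>
    dplyr::filter(min_life_win >= 8) |>
    dplyr::mutate(rate = (rep_output - 1) / (min_life_win - 1)) |>
    dplyr::inner_join(synth$truth, by = "individual_id")
  expect_gt(nrow(emp), 100)
  expect_gt(cor(emp$rate, emp$alpha, method = "spearman"), 0.2)
})

test_that("reproductive output matches exact enumeration under homogeneity", {
  # fixed 4-year windows, fixed recruit age, no year effects: the state
  # sequence is a 3-step Markov chain whose 8 paths can be enumerated
  par <- model_params(
    "H1", mu = qlogis(0.62),
    delta = c(F = -0.3, E = 0.1, S = 0.2),
    gamma1 = 0.3, gamma2 = -0.2, sigma_eta = 0
  )
  cfg <- generator_config(
    n_individuals = 5000, params = par,
    mlw = list(mu = 4, size = 1, min = 4, max = 4),
    recruit_age = list(lambda = 1, min = 8, max = 8)
  )
  p_step <- function(from, age) {
    transition_prob(par, from, age = age)
  }
  paths <- expand.grid(s1 = c("E", "S"), s2 = c("E", "S"),
                       s3 = c("E", "S"), stringsAsFactors = FALSE)
  probs <- apply(paths, 1, function(pp) {
    p1 <- p_step("F", 9)
    p2 <- p_step(pp[1], 10)
    p3 <- p_step(pp[2], 11)
    prod(ifelse(pp == "E", c(p1, p2, p3), 1 - c(p1, p2, p3)))
  })
  pups <- 1 + rowSums(paths == "E")
  mean_exact <- sum(pups * probs)
  var_exact <- sum(pups^2 * probs) - mean_exact^2

  synth <- sample_population(cfg, seed = 4)
  ro <- trajectory_stats(synth$population)$rep_output
  expect_lt(abs(mean(ro) - mean_exact), 0.04)
  expect_lt(abs(var(ro) - var_exact), 0.08)
})

test_that("infeasible window configurations are rejected", {
  expect_error(
    generator_config(study_years = 1982:1984,
                     mlw = list(mu = 6, size = 2, min = 10, max = 25)),
    "exceeds the study length"
  )
})

test_that("side tables and config echo are written alongside histories", {
  synth <- small_synth(n = 20, seed = 2)
  dir <- withr::local_tempdir()
  write_population(synth, dir)
  expect_true(all(file.exists(file.path(
    dir, c("histories.csv", "truth.csv", "year_effects.csv", "params.json")
  ))))
  echo <- jsonlite::read_json(file.path(dir, "params.json"))
  expect_equal(echo$seed, 2)
  expect_equal(echo$params$hypothesis, "H2")
  tr <- readr::read_csv(file.path(dir, "truth.csv"),
                        show_col_types = FALSE)
  expect_equal(nrow(tr), 20)
})
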