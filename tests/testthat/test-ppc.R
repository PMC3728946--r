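test_that("one-sided p-values count replicates at least as extreme", {
  expect_equal(ppc_pvalue(5, 1:10), 0.6)
  expect_equal(ppc_pvalue(5, 1:10, "less"), 0.5)
  expect_equal(ppc_pvalue(11, 1:10), 0)
  expect_equal(ppc_pvalue(0, 1:10), 1)
  # ties count as extreme (conservative)
  expect_equal(ppc_pvalue(5, rep(5, 4)), 1)
  expect_error(ppc_pvalue(1, numeric(0)), "no replicate")
})

test_that("replicates are conditional on each observed window", {
  synth <- small_synth(n = 40, seed = 61)
  fit <- cached_fit("ppc_small_fit", {
    suppressWarnings(fit_ih(small_synth(n = 40, seed = 61), "H2",
                             burnin = 300, samples = 600, seed = 3))
  })
  reps <- replicate_data(fit, n_rep = 5, seed = 9)
  obs_w <- min_life_win(synth$population) |> dplyr::arrange(individual_id)
  for (r in reps) {
    w <- min_life_win(r) |> dplyr::arrange(individual_id)
    expect_equal(w, obs_w)
    first <- r |>
      dplyr::group_by(individual_id) |>
      dplyr::slice_min(year, n = 1) |>
      dplyr::ungroup()
    expect_true(all(first$state == "F"))
    expect_true(all(table(r$individual_id[r$state == "F"]) == 1))
    # replicate years and ages coincide with the observed windows
    expect_equal(
      dplyr::arrange(r[c("individual_id", "year", "age")],
                     individual_id, year),
      dplyr::arrange(
        synth$population$histories[c("individual_id", "year", "age")],
        individual_id, year
      ),
      ignore_attr = TRUE
    )
  }
})

test_that("degenerate posteriors force all-breeding replicates", {
  pop <- small_synth(n = 20, seed = 41)$population
  n <- 50
  fixed <- matrix(0, n, 8)
  fixed[, 1] <- 50  # mu so large that P(E) ~ 1
  fit <- fake_fit("H1", fixed, eta = matrix(0, n, 30), pop = pop)
  reps <- replicate_data(fit, n_rep = 3, seed = 1)
  for (r in reps) {
    after_first <- r |>
      dplyr::group_by(individual_id) |>
      dplyr::filter(year > min(year))
    expect_true(all(after_first$state == "E"))
  }
})

test_that("fast replicate summaries agree with the tabular code path", {
  fit <- cached_fit("ppc_small_fit", {
    suppressWarnings(fit_ih(small_synth(n = 40, seed = 61), "H2",
                             burnin = 300, samples = 600, seed = 3))
  })
  reps <- replicate_data(fit, n_rep = 4, seed = 17)
  ppc <- run_ppc(fit, n_rep = 4, min_window = 3, seed = 17)
  mat <- attr(ppc, "replicates")
  for (i in seq_along(reps)) {
    tab <- population_summaries(reps[[i]], min_window = 3)
    for (j in seq_len(nrow(tab))) {
      key <- paste0(tab$summary[j], "_", tab$statistic[j])
      expect_equal(unname(mat[i, key]), tab$value[j],
                   info = sprintf("rep %d %s", i, key))
    }
  }
  # observed column agrees with population_summaries on the fitted data
  obs_tab <- population_summaries(
    small_synth(n = 40, seed = 61)$population, min_window = 3
  )
  for (j in seq_len(nrow(obs_tab))) {
    row <- ppc[ppc$statistic == obs_tab$statistic[j] &
                 ppc$summary == obs_tab$summary[j], ]
    expect_equal(row$observed, obs_tab$value[j])
  }
})

test_that("matched model replicates track the observed reproductive output", {
  fit <- cached_fit("ppc_small_fit", {
    suppressWarnings(fit_ih(small_synth(n = 40, seed = 61), "H2",
                             burnin = 300, samples = 600, seed = 3))
  })
  reps <- replicate_data(fit, n_rep = 30, seed = 23)
  obs_mean <- mean(trajectory_stats(
    small_synth(n = 40, seed = 61)$population
  )$rep_output)
  rep_means <- vapply(reps, function(r) {
    mean(trajectory_stats(r)$rep_output)
  }, numeric(1))
  expect_lt(abs(mean(rep_means) - obs_mean), 0.5)
})

test_that("run_ppc output is well-formed and both directions are stored", {
  fit <- cached_fit("ppc_small_fit", {
    suppressWarnings(fit_ih(small_synth(n = 40, seed = 61), "H2",
                             burnin = 300, samples = 600, seed = 3))
  })
  ppc <- run_ppc(fit, n_rep = 50, min_window = 3, seed = 2)
  expect_equal(nrow(ppc), 6)
  expect_true(all(ppc$p_value >= 0 & ppc$p_value <= 1))
  expect_true(all(ppc$p_less >= 0 & ppc$p_less <= 1))
  # the two directions overlap only through ties
  expect_true(all(ppc$p_value + ppc$p_less >= 1))
  expect_error(run_ppc(fit, n_rep = 10, min_window = 26), "no individual")
  # redraw mode runs and differs from the conditional default
  ppc2 <- run_ppc(fit, n_rep = 50, min_window = 3, seed = 2,
                  individual_effects = "redraw")
  expect_false(identical(attr(ppc, "replicates"),
                         attr(ppc2, "replicates")))
  p <- autoplot(ppc)
  expect_s3_class(p, "ggplot")
})
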