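#' Posterior predictive replication of encounter histories
#'
#' Simulates replicate datasets under the fitted model, each replicate using
#' one posterior draw, *conditional on every individual's observed window*:
#' the replicate history starts in state `F` in the individual's recruit
#' year and runs for exactly her observed minimal lifetime window, with the
#' draw's state, age, and year effects applied as in the fitted model. By
#' default each individual keeps the draw's own latent effects
#' \eqn{\alpha_i} (and \eqn{\beta_i}) — the replicate is a draw from the
#' joint posterior predictive of *these* females; alternatively the latent
#' effects can be re-drawn from their population law `N(0, sigma)` per
#' replicate (`individual_effects = "redraw"`).
#'
#' Draw selection: replicates use evenly spaced draws across the stacked
#' chains; when `n_rep` exceeds the available draws, draws are sampled with
#' replacement.
#'
#' @param fit An [fit_ih()] object.
#' @param n_rep Number of replicate datasets.
#' @param seed Integer seed.
#' @param individual_effects `"draw"` (default) or `"redraw"`, see above.
#' @return A list of `n_rep` tibbles in the long histories format
#'   (`individual_id`, `year`, `age`, `state`), each carrying the posterior
#'   draw index used as attribute `"draw"`.
#' @seealso [run_ppc()] for the memory-light path that reduces each
#'   replicate to its discrepancy statistics on the fly.
#' @export
replicate_data <- function(fit, n_rep, seed = 1,
                           individual_effects = c("draw", "redraw")) {
  individual_effects <- match.arg(individual_effects)
  stopifnot(inherits(fit, "ih_fit"), n_rep >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  idx <- ppc_draw_indices(fit, n_rep)
  w <- fit$windows
  lapply(idx, function(d) {
    states <- simulate_replicate_states(fit, d, individual_effects)
    out <- tibble::tibble(
      individual_id = rep(w$individual_id, w$min_life_win),
      offset = unlist(lapply(w$min_life_win, seq_len)) - 1L
    ) |>
      dplyr::mutate(
        year = rep(w$recruit_year, w$min_life_win) + .data$offset,
        age = rep(w$recruit_age, w$min_life_win) + .data$offset,
        state = states[cbind(
          rep(seq_len(nrow(w)), w$min_life_win), .data$offset + 1L
        )]
      ) |>
      dplyr::select(-"offset")
    attr(out, "draw") <- d
    out
  })
}

# evenly spaced draw indices over the stacked chains (with replacement only
# when more replicates than draws are requested)
ppc_draw_indices <- function(fit, n_rep) {
  total <- fit$n_chains * fit$samples
  if (n_rep <= total) {
    unique(round(seq(1, total, length.out = n_rep)))[seq_len(n_rep)]
  } else {
    sample.int(total, n_rep, replace = TRUE)
  }
}

# pull one stacked draw as point parameters
stacked_draw <- function(fit, d) {
  ch <- (d - 1) %/% fit$samples + 1
  i <- (d - 1) %% fit$samples + 1
  c <- fit$chains[[ch]]
  list(
    fixed = c$fixed[i, ],
    eta = c$eta[i, ],
    alpha = if (ncol(c$alpha)) c$alpha[i, ] else numeric(0),
    beta = if (ncol(c$beta)) c$beta[i, ] else numeric(0)
  )
}

# n_individuals x max-window character matrix of replicate states (NA
# beyond each individual's window), conditional on observed windows
simulate_replicate_states <- function(fit, d, individual_effects = "draw") {
  dr <- stacked_draw(fit, d)
  w <- fit$windows
  n <- nrow(w)
  f <- dr$fixed
  alpha <- if (length(dr$alpha)) {
    unname(dr$alpha[match(w$individual_id, fit$individual_ids)])
  } else {
    rep(0, n)
  }
  beta <- if (length(dr$beta)) {
    unname(dr$beta[match(w$individual_id, fit$individual_ids)])
  } else {
    rep(0, n)
  }
  if (individual_effects == "redraw") {
    if (fit$hypothesis != "H1") alpha <- rnorm(n, 0, f["sd_alpha"])
    if (fit$hypothesis == "H3") beta <- rnorm(n, 0, f["sd_beta"])
  }
  delta <- c(F = unname(f["delta_F"]), E = unname(f["delta_E"]),
             S = unname(-f["delta_F"] - f["delta_E"]))
  max_l <- max(w$min_life_win)
  states <- matrix(NA_character_, n, max_l)
  states[, 1] <- "F"
  for (j in seq_len(max_l - 1)) {
    act <- which(w$min_life_win > j)
    if (!length(act)) break
    yr <- w$recruit_year[act] + j
    a <- (w$recruit_age[act] + j - fit$age_mean) / fit$age_sd
    ice <- yr %in% fit$iceberg_years
    lp <- f["mu"] + delta[states[act, j]] + f["g1"] * a + f["g2"] * a^2 +
      dr$eta[match(yr, fit$study_years)] + alpha[act] + beta[act] * ice
    states[act, j + 1] <- ifelse(runif(length(act)) < inv_logit(lp),
                                 "E", "S")
  }
  states
}

# SD and Max of the three trajectory statistics from a state matrix,
# restricted to windows >= min_window (fast path shared by observed data
# and replicates; agrees with population_summaries() by construction and
# by test)
matrix_summaries <- function(states, win, min_window) {
  keep <- win >= min_window
  m <- states[keep, , drop = FALSE] == "E"
  n <- nrow(m)
  rep_out <- 1 + rowSums(m, na.rm = TRUE)
  if (ncol(m) > 1) {
    pair <- m[, -1, drop = FALSE] & m[, -ncol(m), drop = FALSE]
    consec <- rowSums(pair, na.rm = TRUE)
  } else {
    consec <- rep(0, n)
  }
  run <- best <- rep(0, n)
  for (j in seq_len(ncol(m))) {
    e <- m[, j]
    e[is.na(e)] <- FALSE
    run <- (run + 1) * e
    best <- pmax(best, run)
  }
  c(
    sd_rep_output = sd(rep_out), max_rep_output = max(rep_out),
    sd_consec_rep = sd(consec), max_consec_rep = max(consec),
    sd_persist_rep = sd(best), max_persist_rep = max(best)
  )
}

# observed state matrix reconstructed from the fit's windows + records
observed_state_matrix <- function(fit) {
  w <- fit$windows
  states <- matrix(NA_character_, nrow(w), max(w$min_life_win))
  states[, 1] <- "F"
  rec <- fit$records
  i <- match(rec$individual_id, w$individual_id)
  j <- rec$year - w$recruit_year[i] + 1L
  states[cbind(i, j)] <- ifelse(rec$y == 1, "E", "S")
  states
}

#' One-sided posterior predictive p-value
#'
#' The proportion of replicate discrepancy values at least as extreme as the
#' observed one. Ties count as satisfying the inequality, which makes the
#' p-value conservative.
#'
#' @param observed Observed discrepancy value.
#' @param replicates Vector of replicate values (non-empty).
#' @param direction `"greater"` for `Pr[T(rep) >= T(obs)]` (default) or
#'   `"less"` for `Pr[T(rep) <= T(obs)]`.
#' @return A value in `[0, 1]`.
#' @export
ppc_pvalue <- function(observed, replicates,
                       direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(replicates) < 1) abort("no replicate values")
  if (direction == "greater") {
    mean(replicates >= observed)
  } else {
    mean(replicates <= observed)
  }
}

#' Discrepancy statistic of one dataset
#'
#' SD or Max of a trajectory statistic over the individuals of a dataset
#' with minimal lifetime window of at least `min_window` years; delegates to
#' [population_summaries()].
#'
#' @param x A [seal_population()], long histories data frame, or
#'   [trajectory_stats()] tibble.
#' @param statistic `"rep_output"`, `"consec_rep"`, or `"persist_rep"`.
#' @param summary `"sd"` or `"max"`.
#' @param min_window Window filter (default 5).
#' @return A single numeric value.
#' @export
ppc_statistic <- function(x, statistic = c("rep_output", "consec_rep",
                                           "persist_rep"),
                          summary = c("sd", "max"), min_window = 5) {
  statistic <- match.arg(statistic)
  summary <- match.arg(summary)
  tab <- population_summaries(x, min_window = min_window)
  tab$value[tab$statistic == statistic & tab$summary == summary]
}

#' Posterior predictive check of a fitted model
#'
#' Compares the observed across-individual spread of the three trajectory
#' statistics (RepOutput, ConsecRep, PersistRep; SD and Max of each) with
#' their posterior predictive distribution over `n_rep` replicate datasets
#' simulated conditional on each individual's observed window (see
#' [replicate_data()]). A model that cannot generate as much
#' between-individual spread as observed yields small
#' `Pr[T(rep) >= T(obs)]` p-values — the signature of unmodeled individual
#' heterogeneity. Both one-sided directions are computed; ties count as
#' extreme (conservative).
#'
#' @inheritParams replicate_data
#' @param min_window Only individuals with windows of at least this many
#'   years enter the discrepancy statistics (default 5).
#' @return An `ih_ppc` object: a tibble with one row per statistic x
#'   summary (`model`, `statistic`, `summary`, `min_window`, `observed`,
#'   `p_value`, `p_less`, `n_rep`), the replicate values in attribute
#'   `"replicates"` (an `n_rep` x 6 matrix). `p_value` is the `>=`
#'   direction.
#' @export
run_ppc <- function(fit, n_rep = 1000, min_window = 5, seed = 1,
                    individual_effects = c("draw", "redraw")) {
  individual_effects <- match.arg(individual_effects)
  stopifnot(inherits(fit, "ih_fit"), n_rep >= 1)
  w <- fit$windows
  if (!any(w$min_life_win >= min_window)) {
    abort(sprintf("no individual has a window of at least %d years",
                  min_window))
  }
  obs <- matrix_summaries(observed_state_matrix(fit), w$min_life_win,
                          min_window)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  idx <- ppc_draw_indices(fit, n_rep)
  reps <- t(vapply(idx, function(d) {
    matrix_summaries(
      simulate_replicate_states(fit, d, individual_effects),
      w$min_life_win, min_window
    )
  }, numeric(6)))

  grid <- tidyr::expand_grid(
    statistic = c("rep_output", "consec_rep", "persist_rep"),
    summary = c("sd", "max")
  )
  key <- paste0(grid$summary, "_", grid$statistic)
  out <- grid |>
    dplyr::mutate(
      model = fit$hypothesis,
      min_window = min_window,
      observed = unname(obs[key]),
      p_value = vapply(key, function(k) ppc_pvalue(obs[k], reps[, k]),
                       numeric(1)),
      p_less = vapply(key, function(k)
        ppc_pvalue(obs[k], reps[, k], "less"), numeric(1)),
      n_rep = length(idx)
    ) |>
    dplyr::select("model", "statistic", "summary", "min_window",
                  "observed", "p_value", "p_less", "n_rep")
  attr(out, "replicates") <- reps
  class(out) <- c("ih_ppc", class(out))
  out
}

#' @export
#' @method autoplot ih_ppc
autoplot.ih_ppc <- function(object, ...) {
  reps <- attr(object, "replicates")
  long <- purrr::map_dfr(seq_len(nrow(object)), function(i) {
    k <- paste0(object$summary[i], "_", object$statistic[i])
    tibble::tibble(
      statistic = object$statistic[i],
      summary = object$summary[i],
      value = reps[, k]
    )
  }) |>
    dplyr::mutate(panel = paste(.data$summary, .data$statistic))
  marks <- object |>
    dplyr::mutate(
      panel = paste(.data$summary, .data$statistic),
      label = sprintf("P = %.3f", .data$p_value)
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(
      data = marks, ggplot2::aes(xintercept = .data$observed),
      linewidth = 0.8
    ) +
    ggplot2::geom_text(
      data = marks,
      ggplot2::aes(x = .data$observed, y = Inf, label = .data$label),
      hjust = -0.1, vjust = 1.5, size = 3
    ) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(
      x = "discrepancy statistic over replicates",
      y = "replicate count",
      title = sprintf("Posterior predictive check (%s)",
                      object$model[1])
    ) +
    ggplot2::theme_minimal()
}

#' Write a PPC table as CSV
#'
#' Layout: `model,statistic,summary,min_window,observed,p_value,n_rep`.
#' Optionally writes the per-replicate values in a sidecar CSV.
#'
#' @param ppc An `ih_ppc` object from [run_ppc()].
#' @param path Output CSV path.
#' @param replicates_path Optional sidecar path for per-replicate values.
#' @return The table, invisibly.
#' @export
write_ppc <- function(ppc, path, replicates_path = NULL) {
  stopifnot(inherits(ppc, "ih_ppc"))
  readr::write_csv(
    dplyr::select(tibble::as_tibble(ppc), "model", "statistic", "summary",
                  "min_window", "observed", "p_value", "n_rep"),
    path
  )
  if (!is.null(replicates_path)) {
    readr::write_csv(tibble::as_tibble(attr(ppc, "replicates")),
                     replicates_path)
  }
  invisible(ppc)
}
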