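#' Fit a hierarchical breeding-probability model
#'
#' Fits one of the three competing hypotheses to a population of encounter
#' histories by MCMC:
#'
#' * **H1** — no latent individual heterogeneity (year effects only);
#' * **H2** — fixed heterogeneity (a latent effect \eqn{\alpha_i} per female,
#'   expressed in all years);
#' * **H3** — environment-dependent heterogeneity (\eqn{\alpha_i} plus an
#'   iceberg-year effect \eqn{\beta_i}).
#'
#' Priors: the mean reproductive rate `plogis(mu)` is uniform on `[0, 1]`;
#' state and age coefficients get diffuse `N(0, 1000)` priors; hyper-SDs get
#' `U(0, 10)` priors, or (with `prior = "inv-gamma"`) an inverse-gamma(4,
#' 0.05) prior on the corresponding variance, a restrictive choice that
#' penalizes heterogeneity a priori and is used for sensitivity analysis.
#' Sampling uses a compiled adaptive Metropolis-within-Gibbs sampler
#' (proposal scales adapted during burn-in only; conjugate variance
#' updates; likelihood-invariant translation moves for the intercept).
#' Convergence is summarized by the Brooks--Gelman--Rubin potential scale
#' reduction factor on all top-level parameters; a warning state is attached
#' when any exceeds `rhat_threshold`.
#'
#' @param pop A [seal_population()] or the result of [sample_population()].
#' @param hypothesis `"H1"`, `"H2"`, or `"H3"`.
#' @param prior `"uniform-sd"` (default) or `"inv-gamma"` for the
#'   hyper-variance prior.
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param burnin Burn-in iterations per chain (discarded; adaptation happens
#'   here).
#' @param samples Posterior draws kept per chain (after thinning). The
#'   original analysis budget of 150,000 draws is reachable by raising this;
#'   the default keeps memory proportional to `samples * n_individuals`
#'   modest.
#' @param thin Thinning interval.
#' @param seed Integer seed; chain `c` uses `seed * 1000 + c`, so fits are
#'   reproducible draw-for-draw.
#' @param rhat_threshold Convergence gate for the attached warning state.
#' @return An object of class `ih_fit`. Use [tidy()][generics::tidy] /
#'   [glance()][generics::glance] for summaries, [derive_state_rates()],
#'   [back_transform_sd()], [correlation_alpha_beta()] for derived
#'   quantities, and [run_ppc()] for posterior predictive checks.
#' @export
fit_ih <- function(pop, hypothesis = c("H2", "H1", "H3"),
                   prior = c("uniform-sd", "inv-gamma"),
                   chains = 2, burnin = 1000, samples = 5000, thin = 1,
                   seed = 1, rhat_threshold = 1.05) {
  hypothesis <- match.arg(hypothesis)
  prior <- match.arg(prior)
  if (inherits(pop, "synth_population")) pop <- pop$population
  stopifnot(inherits(pop, "seal_population"),
            chains >= 1, samples > 0, burnin >= 0, thin >= 1)
  records <- build_design(pop)
  windows <- pop$histories |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(
      recruit_year = min(.data$year),
      recruit_age = .data$age[which.min(.data$year)],
      min_life_win = dplyr::n(),
      .groups = "drop"
    )
  if (nrow(records) == 0) abort("no transition records to fit")
  if (length(unique(records$y)) == 1) {
    warn("degenerate data: all transition outcomes identical; intercepts are only weakly identified by the prior")
  }

  ids <- sort(unique(pop$histories$individual_id))
  years <- pop$study_years
  dat <- list(
    y = as.integer(records$y),
    A = records$age_std,
    state = match(records$from_state, c("F", "E", "S")) - 1L,
    yr = match(records$year, years) - 1L,
    ind = match(records$individual_id, ids) - 1L,
    ice = as.integer(records$iceberg)
  )

  # clamp so degenerate all-0/all-1 outcomes still give finite inits
  p_emp <- min(max(mean(records$y), 0.02), 0.98)
  hyp_i <- match(hypothesis, c("H1", "H2", "H3"))
  run_chain <- function(ch) {
    # deterministic over-dispersed inits: chains start on opposite sides
    spread <- (ch - (chains + 1) / 2)
    inits <- list(
      mu = qlogis(p_emp) + spread * 1.0,
      dF = -spread * 0.5, dE = spread * 0.5,
      g1 = 0, g2 = 0,
      sd_eta = max(0.25, 0.5 + spread),
      sd_alpha = max(0.25, 0.5 + spread),
      sd_beta = max(0.25, 0.5 + spread)
    )
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed * 1000 + ch)
    mh_sampler(
      dat$y, dat$A, dat$state, dat$yr, dat$ind, dat$ice,
      n_year = length(years), n_ind = length(ids),
      hypothesis = hyp_i,
      prior_type = if (prior == "inv-gamma") 1L else 0L,
      n_burn = as.integer(burnin), n_keep = as.integer(samples),
      thin = as.integer(thin), inits = inits
    )
  }
  t0 <- Sys.time()
  draws <- lapply(seq_len(chains), run_chain)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  fit <- structure(
    list(
      hypothesis = hypothesis, prior = prior,
      chains = draws, n_chains = chains,
      samples = samples, burnin = burnin, thin = thin, seed = seed,
      records = records, windows = windows,
      individual_ids = ids, study_years = years,
      iceberg_years = pop$iceberg_years,
      age_mean = pop$age_mean, age_sd = pop$age_sd,
      elapsed = elapsed
    ),
    class = "ih_fit"
  )
  if (chains >= 2) {
    fit$rhat <- rhat(fit)
    fit$converged <- all(fit$rhat$rhat < rhat_threshold, na.rm = TRUE)
  } else {
    fit$rhat <- tibble::tibble(parameter = free_params(hypothesis),
                               rhat = NA_real_)
    fit$converged <- NA
  }
  fit$rhat_threshold <- rhat_threshold
  if (isFALSE(fit$converged)) {
    warn(sprintf(
      "potential scale reduction above %.3f for: %s",
      rhat_threshold,
      paste(fit$rhat$parameter[fit$rhat$rhat >= rhat_threshold],
            collapse = ", ")
    ))
  }
  fit
}

# which top-level parameters are free under each hypothesis
free_params <- function(hypothesis) {
  base <- c("mu", "delta_F", "delta_E", "g1", "g2", "sd_eta")
  switch(hypothesis,
    H1 = base,
    H2 = c(base, "sd_alpha"),
    H3 = c(base, "sd_alpha", "sd_beta")
  )
}

# stacked draws (all chains) for one fixed parameter
param_draws <- function(fit, parameter) {
  if (!parameter %in% colnames(fit$chains[[1]]$fixed)) {
    abort(sprintf("unknown parameter '%s'", parameter))
  }
  unlist(lapply(fit$chains, function(ch) ch$fixed[, parameter]))
}

# per-chain matrix (draws x chains) for one fixed parameter
param_chain_matrix <- function(fit, parameter) {
  vapply(fit$chains, function(ch) ch$fixed[, parameter],
         numeric(fit$samples))
}

#' Potential scale reduction diagnostic
#'
#' The Brooks--Gelman--Rubin potential scale reduction factor
#' \eqn{\hat R = \sqrt{\hat V / W}} with \eqn{\hat V = \frac{n-1}{n} W +
#' \frac{B}{n}}, where `W` is the mean within-chain variance and `B/n` the
#' between-chain variance of the chain means. Values near 1.00 indicate
#' convergence.
#'
#' @param fit An [fit_ih()] object (needs >= 2 chains).
#' @param parameter Optional parameter name; default computes all free
#'   top-level parameters.
#' @return A tibble (`parameter`, `rhat`), or a single value when
#'   `parameter` is given.
#' @export
rhat <- function(fit, parameter = NULL) {
  stopifnot(inherits(fit, "ih_fit"))
  if (fit$n_chains < 2) abort("rhat requires at least 2 chains")
  if (!is.null(parameter)) {
    return(psrf(param_chain_matrix(fit, parameter)))
  }
  pars <- free_params(fit$hypothesis)
  tibble::tibble(
    parameter = pars,
    rhat = vapply(pars, function(p) psrf(param_chain_matrix(fit, p)),
                  numeric(1))
  )
}

# x: n-draws x m-chains matrix
psrf <- function(x) {
  n <- nrow(x)
  W <- mean(apply(x, 2, var))
  B_over_n <- var(colMeans(x))
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt((n - 1) / n + B_over_n / W)
}

#' @export
print.ih_fit <- function(x, ...) {
  cat(sprintf(
    "<ih_fit> %s, %s prior; %d chains x %d draws (burn-in %d, thin %d)\n",
    x$hypothesis, x$prior, x$n_chains, x$samples, x$burnin, x$thin
  ))
  cat(sprintf(
    "  %d transition records, %d individuals; max rhat %s\n",
    nrow(x$records), length(x$individual_ids),
    if (all(is.na(x$rhat$rhat))) "NA (single chain)" else sprintf(
      "%.3f (%s)", max(x$rhat$rhat),
      if (isTRUE(x$converged)) "converged" else "NOT converged"
    )
  ))
  invisible(x)
}

#' Tidy posterior summaries of a model fit
#'
#' `tidy()` returns one row per free top-level parameter (logit scale):
#' posterior mean, 95% credible limits, and the convergence diagnostic.
#' `glance()` returns a one-row model overview.
#'
#' @param x An [fit_ih()] object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ih_fit
#' @export
tidy.ih_fit <- function(x, ...) {
  pars <- free_params(x$hypothesis)
  purrr::map_dfr(pars, function(p) {
    d <- param_draws(x, p)
    tibble::tibble(
      parameter = p,
      mean = mean(d),
      lci2.5 = unname(quantile(d, 0.025)),
      uci97.5 = unname(quantile(d, 0.975)),
      rhat = x$rhat$rhat[x$rhat$parameter == p],
      scale = "logit"
    )
  })
}

#' @rdname tidy.ih_fit
#' @method glance ih_fit
#' @export
glance.ih_fit <- function(x, ...) {
  tibble::tibble(
    hypothesis = x$hypothesis,
    prior = x$prior,
    n_records = nrow(x$records),
    n_individuals = length(x$individual_ids),
    n_chains = x$n_chains,
    n_draws = x$n_chains * x$samples,
    max_rhat = max(x$rhat$rhat),
    converged = x$converged,
    elapsed_s = x$elapsed
  )
}
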