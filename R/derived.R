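#' Posterior state-specific reproductive rates on the probability scale
#'
#' Posterior summaries of \eqn{\psi^{FE}, \psi^{EE}, \psi^{SE}}: the
#' probability of producing a pup given the previous year's state, averaged
#' across ages, years, and individuals. Two averaging conventions are
#' available:
#'
#' * `type = "theoretical"` (default): per draw,
#'   \eqn{\psi^{kE} = \mathrm{plogis}(\mu + \delta_k)} — every mean-zero
#'   model term (standardized age, year effects, individual effects) at its
#'   mean. This is the conventional reporting scale for this model family
#'   and the convention the package's reference rates invert.
#' * `type = "covariate"`: per draw, the breeding probability averaged over
#'   each from-state's observed transition records (their standardized ages
#'   and the draw's realized year effects) and over the population law of
#'   the latent individual effects — the draw's \eqn{N(0, \sigma_\alpha)}
#'   (plus \eqn{N(0, \sigma_\beta)} in iceberg years), integrated by
#'   Gauss--Hermite quadrature so every individual counts equally. This
#'   reflects where in covariate space the transitions actually occur; see
#'   [state_rates()].
#'
#' @param fit An [fit_ih()] object.
#' @param type Averaging convention, see above.
#' @param max_draws Cap on the number of (evenly thinned) draws used.
#' @return A tibble (`from_state`, `mean`, `lci2.5`, `uci97.5`), with the
#'   per-draw rates attached as attribute `"draws"` (a draws x 3 matrix).
#' @export
derive_state_rates <- function(fit, type = c("theoretical", "covariate"),
                               max_draws = 2000) {
  stopifnot(inherits(fit, "ih_fit"))
  type <- match.arg(type)
  keep <- thin_index(fit$samples, max_draws)
  if (type == "theoretical") {
    per_chain <- lapply(fit$chains, function(ch) {
      f <- ch$fixed[keep, , drop = FALSE]
      cbind(
        F = inv_logit(f[, "mu"] + f[, "delta_F"]),
        E = inv_logit(f[, "mu"] + f[, "delta_E"]),
        S = inv_logit(f[, "mu"] - f[, "delta_F"] - f[, "delta_E"])
      )
    })
  } else {
    gh <- gauss_hermite()
    rec <- fit$records
    state_i <- match(rec$from_state, c("F", "E", "S")) - 1L
    yr_i <- match(rec$year, fit$study_years) - 1L
    per_chain <- lapply(fit$chains, function(ch) {
      derived_rates_cpp(
        ch$fixed[keep, , drop = FALSE], ch$eta[keep, , drop = FALSE],
        rec$age_std, state_i, yr_i, as.integer(rec$iceberg),
        gh$x, gh$w
      )
    })
  }
  draws <- do.call(rbind, per_chain)
  out <- purrr::map_dfr(c("F", "E", "S"), function(k) {
    d <- draws[, k]
    tibble::tibble(
      from_state = k,
      mean = mean(d),
      lci2.5 = unname(quantile(d, 0.025)),
      uci97.5 = unname(quantile(d, 0.975))
    )
  })
  attr(out, "draws") <- draws
  out
}

thin_index <- function(n, max_draws) {
  if (n <= max_draws) seq_len(n) else
    unique(round(seq(1, n, length.out = max_draws)))
}

#' Back-transform a hyper-SD to the probability scale
#'
#' Hyper-SDs live on the logit scale; for reporting they are transformed to
#' the more interpretable probability scale as the induced SD of the rate
#' itself: for each posterior draw, \eqn{\sigma^* = \mathrm{SD}[\,
#' \mathrm{plogis}(\mu + z)\,]}, \eqn{z \sim N(0, \sigma)}, evaluated by
#' Gauss--Hermite quadrature around the draw's theoretical mean rate
#' \eqn{\mu}. [invert_prob_sd()] is the exact inverse of this map.
#'
#' @param fit An [fit_ih()] object.
#' @param which `"alpha"`, `"beta"`, or `"eta"`.
#' @param max_draws Cap on the number of draws used.
#' @return A one-row tibble (`which`, `mean`, `lci2.5`, `uci97.5`) with the
#'   per-draw values attached as attribute `"draws"`.
#' @export
back_transform_sd <- function(fit, which = c("alpha", "beta", "eta"),
                              max_draws = 5000) {
  stopifnot(inherits(fit, "ih_fit"))
  which <- match.arg(which)
  par <- paste0("sd_", which)
  if (!par %in% free_params(fit$hypothesis)) {
    abort(sprintf("%s has no %s effects", fit$hypothesis, which))
  }
  keep <- thin_index(fit$samples, max_draws)
  mu <- unlist(lapply(fit$chains, function(ch) ch$fixed[keep, "mu"]))
  sg <- unlist(lapply(fit$chains, function(ch) ch$fixed[keep, par]))
  d <- prob_scale_sd(mu, sg)
  out <- tibble::tibble(
    which = which,
    mean = mean(d),
    lci2.5 = unname(quantile(d, 0.025)),
    uci97.5 = unname(quantile(d, 0.975))
  )
  attr(out, "draws") <- d
  out
}

#' Posterior correlation between normal-year and iceberg-year effects
#'
#' The two individual effects are modeled as a priori independent; their
#' across-individual correlation \eqn{\rho_{\alpha,\beta}} is a derived
#' quantity computed directly from the joint posterior. The primary
#' definition is per-draw: for each posterior draw, the Pearson correlation
#' across individuals between the draw's \eqn{\alpha_i} and \eqn{\beta_i}.
#' The correlation of the posterior *means* is reported alongside, since
#' scatterplots of posterior means are the common graphical companion.
#'
#' @param fit An H3 [fit_ih()] object.
#' @param individuals `"exposed"` (default) restricts to individuals with at
#'   least one iceberg-year transition — for the others \eqn{\beta_i} is
#'   posterior-sampled from its prior and only dilutes the correlation —
#'   or `"all"`.
#' @param max_draws Cap on the number of draws used.
#' @return A one-row tibble (`mean`, `lci2.5`, `uci97.5`,
#'   `cor_of_means`, `n_individuals`) with per-draw correlations attached as
#'   attribute `"draws"`.
#' @export
correlation_alpha_beta <- function(fit, individuals = c("exposed", "all"),
                                   max_draws = 2000) {
  stopifnot(inherits(fit, "ih_fit"))
  individuals <- match.arg(individuals)
  if (fit$hypothesis != "H3") {
    abort("correlation_alpha_beta() requires an H3 fit (both individual effects)")
  }
  sel <- if (individuals == "exposed") {
    exposed <- unique(fit$records$individual_id[fit$records$iceberg])
    match(exposed, fit$individual_ids)
  } else {
    seq_along(fit$individual_ids)
  }
  if (length(sel) < 3) abort("too few individuals to correlate")
  keep <- thin_index(fit$samples, max_draws)
  a <- do.call(rbind, lapply(fit$chains,
                             function(ch) ch$alpha[keep, sel, drop = FALSE]))
  b <- do.call(rbind, lapply(fit$chains,
                             function(ch) ch$beta[keep, sel, drop = FALSE]))
  d <- vapply(seq_len(nrow(a)), function(i) cor(a[i, ], b[i, ]), numeric(1))
  out <- tibble::tibble(
    mean = mean(d),
    lci2.5 = unname(quantile(d, 0.025)),
    uci97.5 = unname(quantile(d, 0.975)),
    cor_of_means = cor(colMeans(a), colMeans(b)),
    n_individuals = length(sel)
  )
  attr(out, "draws") <- d
  out
}

#' Combined posterior summary table
#'
#' Binds the logit-scale top-level summaries of [tidy()] with the
#' probability-scale derived quantities (mean rate, state-specific rates,
#' back-transformed hyper-SDs, and, for H3, \eqn{\rho_{\alpha,\beta}}),
#' in the layout `parameter, mean, lci2.5, uci97.5, rhat, scale`.
#' `write_fit_summary()` writes it as CSV.
#'
#' @param fit An [fit_ih()] object.
#' @param path Output CSV path.
#' @return A tibble (invisibly for the writer).
#' @export
fit_summary <- function(fit) {
  stopifnot(inherits(fit, "ih_fit"))
  logit_part <- tidy(fit)
  mu <- param_draws(fit, "mu")
  mu_star <- inv_logit(mu)
  rows <- list(
    tibble::tibble(
      parameter = "mean_rate", mean = mean(mu_star),
      lci2.5 = unname(quantile(mu_star, 0.025)),
      uci97.5 = unname(quantile(mu_star, 0.975)),
      rhat = NA_real_, scale = "probability"
    ),
    derive_state_rates(fit) |>
      dplyr::transmute(
        parameter = paste0("psi_", .data$from_state, "E"),
        mean = .data$mean, lci2.5 = .data$lci2.5, uci97.5 = .data$uci97.5,
        rhat = NA_real_, scale = "probability"
      )
  )
  for (w in c("eta", "alpha", "beta")) {
    if (paste0("sd_", w) %in% free_params(fit$hypothesis)) {
      rows <- c(rows, list(
        back_transform_sd(fit, w) |>
          dplyr::transmute(
            parameter = paste0("sd_", .data$which, "_star"),
            mean = .data$mean, lci2.5 = .data$lci2.5,
            uci97.5 = .data$uci97.5,
            rhat = NA_real_, scale = "probability"
          )
      ))
    }
  }
  if (fit$hypothesis == "H3") {
    rows <- c(rows, list(
      correlation_alpha_beta(fit) |>
        dplyr::transmute(
          parameter = "rho_alpha_beta",
          mean = .data$mean, lci2.5 = .data$lci2.5,
          uci97.5 = .data$uci97.5,
          rhat = NA_real_, scale = "probability"
        )
    ))
  }
  dplyr::bind_rows(c(list(logit_part), rows))
}

#' @rdname fit_summary
#' @export
write_fit_summary <- function(fit, path) {
  out <- fit_summary(fit)
  readr::write_csv(out, path)
  invisible(out)
}

#' Persist posterior draws with run metadata
#'
#' Writes the top-level posterior draws to a columnar CSV (one row per
#' draw, columns `chain`, `draw`, and the free parameters) together with a
#' JSON metadata record (hypothesis, prior, chain/draw counts, seed, and a
#' hash of the fitted record set) sufficient to identify the run. Latent
#' year/individual effects are omitted by default for size; set
#' `include_eta = TRUE` to add the year effects.
#'
#' @param fit An [fit_ih()] object.
#' @param dir Output directory (created if needed).
#' @param include_eta Also write the per-year effect draws.
#' @return `dir`, invisibly.
#' @export
write_draws <- function(fit, dir, include_eta = FALSE) {
  stopifnot(inherits(fit, "ih_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pars <- free_params(fit$hypothesis)
  tab <- purrr::imap_dfr(fit$chains, function(ch, i) {
    out <- tibble::as_tibble(as.data.frame(ch$fixed[, pars, drop = FALSE]))
    if (include_eta) {
      eta <- tibble::as_tibble(as.data.frame(ch$eta))
      names(eta) <- paste0("eta_", fit$study_years)
      out <- dplyr::bind_cols(out, eta)
    }
    dplyr::mutate(out, chain = i, draw = dplyr::row_number(),
                  .before = 1)
  })
  readr::write_csv(tab, file.path(dir, "draws.csv"))
  meta <- list(
    hypothesis = fit$hypothesis, prior = fit$prior,
    chains = fit$n_chains, samples = fit$samples, burnin = fit$burnin,
    thin = fit$thin, seed = fit$seed,
    n_records = nrow(fit$records),
    records_hash = rlang::hash(fit$records),
    package_version = as.character(utils::packageVersion("sealIH"))
  )
  jsonlite::write_json(meta, file.path(dir, "draws_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
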