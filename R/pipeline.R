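#' Estimated age trend in breeding probability
#'
#' The posterior quadratic age trend evaluated at the theoretical mean
#' (all other terms at their means): `plogis(mu + g1*A + g2*A^2)` over a
#' grid of ages, with pointwise 95% credible bands and the age at peak
#' marked.
#'
#' @param object An [fit_ih()] object.
#' @param ages Integer grid of ages.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot ih_fit
autoplot.ih_fit <- function(object, ages = 5:30, ...) {
  mu <- param_draws(object, "mu")
  g1 <- param_draws(object, "g1")
  g2 <- param_draws(object, "g2")
  a <- (ages - object$age_mean) / object$age_sd
  curve <- purrr::map_dfr(seq_along(ages), function(i) {
    p <- inv_logit(mu + g1 * a[i] + g2 * a[i]^2)
    tibble::tibble(
      age = ages[i], mean = mean(p),
      lci = unname(quantile(p, 0.025)), uci = unname(quantile(p, 0.975))
    )
  })
  peak_age <- curve$age[which.max(curve$mean)]
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$age, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lci, ymax = .data$uci),
      fill = "grey80"
    ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = peak_age, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(
      x = "age (years)", y = "breeding probability",
      title = sprintf("Age trend in reproductive rate (%s)",
                      object$hypothesis)
    ) +
    ggplot2::theme_minimal()
}

#' Scatter of posterior-mean individual effects (H3)
#'
#' Posterior means of the normal-year effect \eqn{\alpha_i} against the
#' iceberg-year effect \eqn{\beta_i}, for individuals with at least one
#' iceberg-year transition. The absence of points in the off-diagonal
#' corners (very robust in one regime, very frail in the other) is the
#' qualitative signature of consistent individual quality.
#'
#' @param fit An H3 [fit_ih()] object.
#' @return A ggplot.
#' @export
plot_alpha_beta <- function(fit) {
  stopifnot(inherits(fit, "ih_fit"))
  if (fit$hypothesis != "H3") abort("plot_alpha_beta() requires an H3 fit")
  exposed <- unique(fit$records$individual_id[fit$records$iceberg])
  sel <- match(exposed, fit$individual_ids)
  a <- colMeans(do.call(rbind, lapply(fit$chains, function(ch)
    ch$alpha[, sel, drop = FALSE])))
  b <- colMeans(do.call(rbind, lapply(fit$chains, function(ch)
    ch$beta[, sel, drop = FALSE])))
  df <- tibble::tibble(alpha = a, beta = b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha, y = .data$beta)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = "individual effect, normal years (posterior mean)",
      y = "individual effect, iceberg years (posterior mean)"
    ) +
    ggplot2::theme_minimal()
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> fit (one or more hypotheses) ->
#' posterior predictive checks -> reproductive-output projections ->
#' report, writing every stage's artifacts plus a replayable metadata
#' record into `out_dir`. Configuration comes from a named list or a YAML
#' file; unspecified entries fall back to the defaults below.
#'
#' Config keys (defaults in parentheses): `seed` (1); `input` — path to a
#' histories CSV, or `NULL` to simulate; `simulate$n_individuals` (954),
#' `simulate$hypothesis` ("H2"); `fit$hypotheses` (H1, H2, H3),
#' `fit$chains` (2), `fit$burnin` (1000), `fit$samples` (3000),
#' `fit$prior` ("uniform-sd"); `ppc$n_rep` (1000), `ppc$min_window` (5);
#' `project$k` (2), `project$n_sim` (5000), `project$horizon` (10),
#' `project$start_age` (8).
#'
#' Artifacts: `histories.csv` (plus `truth.csv` when simulating),
#' `fit_<H>.csv` posterior summaries, `ppc_<H>.csv` tables,
#' `projection.csv`, `report.csv` (collated key quantities), and
#' `run_metadata.json` (config echo, seed, package version, timestamps).
#' On a stage failure the error propagates; artifacts of completed stages
#' remain on disk.
#'
#' @param config A named list, or path to a YAML file.
#' @param out_dir Output directory (created; default a tempdir run folder).
#' @return Invisibly, a list with the fitted objects, PPC tables,
#'   projection table, and the report tibble.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config))
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    seed = 1,
    input = NULL,
    simulate = list(n_individuals = 954, hypothesis = "H2"),
    fit = list(hypotheses = c("H1", "H2", "H3"), chains = 2,
               burnin = 1000, samples = 3000, prior = "uniform-sd"),
    ppc = list(n_rep = 1000, min_window = 5),
    project = list(k = 2, n_sim = 5000, horizon = 10, start_age = 8)
  )
  cfg <- utils::modifyList(defaults, config)
  if (is.null(out_dir)) {
    out_dir <- file.path(tempdir(), format(Sys.time(), "run_%Y%m%d_%H%M%S"))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    config = cfg, package_version = as.character(utils::packageVersion("sealIH")),
    started = format(Sys.time())
  )
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)

  # --- data ---------------------------------------------------------------
  if (!is.null(cfg$input)) {
    pop <- read_histories(cfg$input)
    write_histories(pop, file.path(out_dir, "histories.csv"))
  } else {
    synth <- sample_population(
      generator_config(
        n_individuals = cfg$simulate$n_individuals,
        params = reference_params(cfg$simulate$hypothesis)
      ),
      seed = cfg$seed
    )
    write_population(synth, out_dir)
    pop <- synth$population
  }

  # --- fits + checks ------------------------------------------------------
  fits <- list()
  ppcs <- list()
  for (h in cfg$fit$hypotheses) {
    fit <- fit_ih(
      pop, h, prior = cfg$fit$prior, chains = cfg$fit$chains,
      burnin = cfg$fit$burnin, samples = cfg$fit$samples,
      seed = cfg$seed
    )
    write_fit_summary(fit, file.path(out_dir, sprintf("fit_%s.csv", h)))
    ppc <- run_ppc(fit, n_rep = cfg$ppc$n_rep,
                   min_window = cfg$ppc$min_window, seed = cfg$seed)
    write_ppc(ppc, file.path(out_dir, sprintf("ppc_%s.csv", h)))
    fits[[h]] <- fit
    ppcs[[h]] <- ppc
  }

  # --- projections from the fixed-heterogeneity fit -----------------------
  proj <- NULL
  if ("H2" %in% names(fits)) {
    fit2 <- fits[["H2"]]
    post <- tidy(fit2)
    pm <- setNames(post$mean, post$parameter)
    par <- model_params(
      hypothesis = "H2",
      mu = pm["mu"],
      delta = c(F = unname(pm["delta_F"]), E = unname(pm["delta_E"]),
                S = unname(-pm["delta_F"] - pm["delta_E"])),
      gamma1 = pm["g1"], gamma2 = pm["g2"],
      sigma_eta = pm["sd_eta"], sigma_alpha = pm["sd_alpha"],
      age_mean = fit2$age_mean, age_sd = fit2$age_sd
    )
    proj <- project_typology(
      par, k = cfg$project$k, n_sim = cfg$project$n_sim,
      horizon = cfg$project$horizon, start_age = cfg$project$start_age,
      seed = cfg$seed
    )
    write_projection(proj, file.path(out_dir, "projection.csv"))
  }

  # --- report -------------------------------------------------------------
  report <- dplyr::bind_rows(
    purrr::imap_dfr(fits, function(f, h) {
      fit_summary(f) |> dplyr::mutate(section = paste0("fit_", h))
    }),
    purrr::imap_dfr(ppcs, function(p, h) {
      tibble::as_tibble(p) |>
        dplyr::transmute(
          section = paste0("ppc_", h),
          parameter = paste(.data$summary, .data$statistic),
          mean = .data$p_value, scale = "p_value"
        )
    }),
    if (!is.null(proj)) {
      tibble::as_tibble(proj) |>
        dplyr::transmute(
          section = "projection",
          parameter = .data$type, mean = .data$mean, scale = "pups"
        )
    }
  )
  readr::write_csv(report, file.path(out_dir, "report.csv"))
  invisible(list(fits = fits, ppc = ppcs, projection = proj,
                 report = report, out_dir = out_dir))
}
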