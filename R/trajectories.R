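#' Per-individual reproductive trajectory statistics
#'
#' Three statistics summarize each female's realized reproductive trajectory
#' within her minimal lifetime window:
#'
#' * **RepOutput** — total pups produced, i.e. 1 (the recruitment pup of the
#'   `F` year) plus the number of `E` years;
#' * **ConsecRep** — the total number of adjacent `E,E` pairs in the state
#'   sequence (equivalently, the sum over `E`-runs of run length minus one);
#' * **PersistRep** — the length of the longest unbroken run of `E` years.
#'
#' The `F` year contributes a pup to RepOutput but never counts towards
#' `E`-runs, and skip years break runs.
#'
#' @param x A [seal_population()] or long-format histories data frame.
#' @return A tibble with columns `individual_id`, `min_life_win`,
#'   `rep_output`, `consec_rep`, `persist_rep`.
#' @examples
#' pop <- sample_population(generator_config(n_individuals = 10), seed = 1)
#' trajectory_stats(pop$population)
#' @export
trajectory_stats <- function(x) {
  h <- if (inherits(x, "seal_population")) x$histories else tibble::as_tibble(x)
  h |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::summarise(
      min_life_win = dplyr::n(),
      rep_output = rep_output(.data$state),
      consec_rep = consec_rep(.data$state),
      persist_rep = persist_rep(.data$state),
      .groups = "drop"
    )
}

#' @rdname trajectory_stats
#' @param states A character vector of states (`"F"`, `"E"`, `"S"`) in year
#'   order for one individual.
#' @export
rep_output <- function(states) 1L + sum(states == "E")

#' @rdname trajectory_stats
#' @export
consec_rep <- function(states) {
  if (length(states) < 2) return(0L)
  e <- states == "E"
  sum(e[-1] & e[-length(e)])
}

#' @rdname trajectory_stats
#' @export
persist_rep <- function(states) {
  e <- states == "E"
  if (!any(e)) return(0L)
  r <- rle(e)
  max(r$lengths[r$values])
}

#' Population-level spread of trajectory statistics
#'
#' The across-individual standard deviation (SD) and maximum (Max) of the
#' three trajectory statistics, restricted to individuals whose minimal
#' lifetime window is at least `min_window` years. Longer windows carry more
#' stochastic state transitions, so the spread of their trajectory statistics
#' is the more informative yardstick for model checking; `min_window = 5` is
#' the conventional filter.
#'
#' @param x A [seal_population()], a long-format histories data frame, or a
#'   tibble already produced by [trajectory_stats()].
#' @param min_window Minimum window length (years) for inclusion.
#' @return A tibble with columns `statistic` (`rep_output`, `consec_rep`,
#'   `persist_rep`), `summary` (`sd`, `max`), `value`, `n_individuals`.
#' @export
population_summaries <- function(x, min_window = 5) {
  stopifnot(min_window >= 1)
  stats <- if (is.data.frame(x) && all(c("rep_output", "min_life_win") %in% names(x))) {
    tibble::as_tibble(x)
  } else {
    trajectory_stats(x)
  }
  kept <- dplyr::filter(stats, .data$min_life_win >= min_window)
  if (nrow(kept) == 0) {
    abort(sprintf(
      "no individual has a minimal lifetime window of at least %d years",
      min_window
    ))
  }
  kept |>
    tidyr::pivot_longer(
      c("rep_output", "consec_rep", "persist_rep"),
      names_to = "statistic", values_to = "value"
    ) |>
    dplyr::group_by(.data$statistic) |>
    dplyr::summarise(
      sd = sd(.data$value),
      max = as.numeric(max(.data$value)),
      n_individuals = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(
      c("sd", "max"),
      names_to = "summary", values_to = "value"
    ) |>
    dplyr::select("statistic", "summary", "value", "n_individuals") |>
    dplyr::arrange(.data$statistic, .data$summary)
}
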