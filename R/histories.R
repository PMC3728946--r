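#' Encounter-history populations
#'
#' An encounter history records one female's yearly reproductive state over
#' her *minimal lifetime window* (MinLifeWin): the span of calendar years from
#' her first reproduction (state `F`, first-time breeder) to her last
#' sighting, inclusive. Every year after the first is either `E` (experienced
#' breeder, a pup was produced) or `S` (skip-breeder). Because breeding
#' females are detected with near certainty on the ice, a non-detection
#' inside the window is a skip year by construction, so states are known for
#' every year of the window and no detection model is needed.
#'
#' `seal_population()` bundles a long-format table of individual-year records
#' with study-wide metadata: the study-year range, the set of perturbed
#' ("iceberg") years used as the binary environmental covariate, and the
#' age-standardization constants (mean and SD of age over all individual-year
#' records) used by the models.
#'
#' @param histories A data frame with columns `individual_id`, `year`, `age`,
#'   `state` (one row per individual-year; `state` in `c("F","E","S")`).
#' @param iceberg_years Integer vector of perturbed calendar years
#'   (default 2001:2005, the iceberg period of the Erebus Bay study).
#' @param study_years Inclusive range of study years; defaults to the range
#'   observed in `histories`.
#' @param age_mean,age_sd Optional age-standardization constants. By default
#'   they are computed from all individual-year records of `histories`.
#'
#' @return An object of class `seal_population`: a list with elements
#'   `histories` (a tibble sorted by individual and year), `study_years`,
#'   `iceberg_years`, `age_mean`, and `age_sd`.
#' @seealso [read_histories()], [trajectory_stats()], [build_design()]
#' @export
seal_population <- function(histories, iceberg_years = 2001:2005,
                            study_years = NULL, age_mean = NULL, age_sd = NULL) {
  histories <- validate_histories(histories)
  if (is.null(study_years)) {
    study_years <- seq(min(histories$year), max(histories$year))
  }
  study_years <- seq(min(study_years), max(study_years))
  iceberg_years <- sort(unique(as.integer(iceberg_years)))
  if (!all(range(histories$year) %in% study_years) ||
      !all(histories$year %in% study_years)) {
    abort("observed years fall outside `study_years`")
  }
  if (length(iceberg_years) && !all(iceberg_years %in% study_years)) {
    abort("`iceberg_years` must be a subset of `study_years`")
  }
  if (is.null(age_mean)) age_mean <- mean(histories$age)
  if (is.null(age_sd)) {
    age_sd <- if (length(unique(histories$age)) > 1) sd(histories$age) else 1
  }
  if (age_sd <= 0) abort("`age_sd` must be positive")
  structure(
    list(
      histories = histories,
      study_years = study_years,
      iceberg_years = iceberg_years,
      age_mean = age_mean,
      age_sd = age_sd
    ),
    class = "seal_population"
  )
}

#' @export
print.seal_population <- function(x, ...) {
  n_ind <- length(unique(x$histories$individual_id))
  cat(sprintf(
    "<seal_population> %d females, %d individual-year records\n",
    n_ind, nrow(x$histories)
  ))
  cat(sprintf(
    "  study years %d-%d; iceberg years %s\n",
    min(x$study_years), max(x$study_years),
    if (length(x$iceberg_years)) {
      paste(range(x$iceberg_years), collapse = "-")
    } else "none"
  ))
  cat(sprintf(
    "  age standardization: mean %.2f, sd %.2f\n", x$age_mean, x$age_sd
  ))
  invisible(x)
}

#' @export
#' @method as_tibble seal_population
#' @importFrom tibble as_tibble
as_tibble.seal_population <- function(x, ...) x$histories

#' @export
tibble::as_tibble

# Validate the long-format individual-year table. Errors name the offending
# individual (and year where meaningful) so malformed files are diagnosable.
validate_histories <- function(histories) {
  histories <- tibble::as_tibble(histories)
  needed <- c("individual_id", "year", "age", "state")
  missing <- setdiff(needed, names(histories))
  if (length(missing)) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(histories) == 0) abort("no individual-year records")
  histories <- histories |>
    dplyr::mutate(
      individual_id = as.character(.data$individual_id),
      year = as.integer(.data$year),
      age = as.integer(.data$age),
      state = as.character(.data$state)
    ) |>
    dplyr::arrange(.data$individual_id, .data$year)
  bad_state <- !histories$state %in% c("F", "E", "S")
  if (any(bad_state)) {
    r <- histories[which(bad_state)[1], ]
    abort(sprintf(
      "invalid state '%s' for individual %s in year %d",
      r$state, r$individual_id, r$year
    ))
  }
  check_one <- function(df) {
    id <- df$individual_id[1]
    if (anyDuplicated(df$year)) {
      abort(sprintf("individual %s has duplicated years", id))
    }
    if (nrow(df) > 1 && any(diff(df$year) != 1L)) {
      gap <- df$year[which(diff(df$year) != 1L)[1]]
      abort(sprintf(
        "individual %s has a gap in its year sequence after %d (non-detections inside the window must be recorded as state S)",
        id, gap
      ))
    }
    if (df$state[1] != "F") {
      abort(sprintf(
        "individual %s does not start with state F in year %d",
        id, df$year[1]
      ))
    }
    if (nrow(df) > 1 && any(df$state[-1] == "F")) {
      yr <- df$year[-1][which(df$state[-1] == "F")[1]]
      abort(sprintf(
        "individual %s has state F after its first year (year %d)",
        id, yr
      ))
    }
    if (nrow(df) > 1 && any(diff(df$age) != 1L)) {
      abort(sprintf("individual %s: ages do not increase by 1 with year", id))
    }
    invisible(NULL)
  }
  histories |>
    dplyr::group_split(.data$individual_id) |>
    purrr::walk(check_one)
  histories
}

#' Read and write encounter-history files
#'
#' The on-disk dialect is a long-format CSV with header
#' `individual_id,year,age,state`, one row per individual-year, states coded
#' `F`/`E`/`S`, years and ages as integers. `write_histories()` emits the
#' identical dialect, so files round-trip.
#'
#' @param path File path.
#' @param iceberg_years,study_years Passed to [seal_population()].
#' @return `read_histories()` returns a [seal_population()];
#'   `write_histories()` returns `path` invisibly.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' pop <- sample_population(generator_config(n_individuals = 20), seed = 1)
#' write_histories(pop$population, tmp)
#' read_histories(tmp)
#' @export
read_histories <- function(path, iceberg_years = 2001:2005,
                           study_years = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      individual_id = readr::col_character(),
      year = readr::col_integer(),
      age = readr::col_integer(),
      state = readr::col_character()
    )
  )
  seal_population(raw, iceberg_years = iceberg_years,
                  study_years = study_years)
}

#' @rdname read_histories
#' @param pop A [seal_population()].
#' @export
write_histories <- function(pop, path) {
  stopifnot(inherits(pop, "seal_population"))
  readr::write_csv(pop$histories, path)
  invisible(path)
}

#' Minimal lifetime window length
#'
#' The number of calendar years, inclusive of both endpoints, from an
#' individual's first reproduction to its last sighting. All modeling in the
#' package is conditional on this window.
#'
#' @param x A [seal_population()] or a long-format histories data frame.
#' @return A tibble with columns `individual_id` and `min_life_win`.
#' @export
min_life_win <- function(x) {
  h <- if (inherits(x, "seal_population")) x$histories else tibble::as_tibble(x)
  h |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(
      min_life_win = max(.data$year) - min(.data$year) + 1L,
      .groups = "drop"
    )
}
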