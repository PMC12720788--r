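#' Pooled replicate variability of relative uptake
#'
#' Estimates the experimental variability of the HDX workflow by pooling
#' replicate deviations over all (peptide, state, timepoint) groups. The
#' default (`"pooled-within"`) computes the degrees-of-freedom-weighted mean
#' of the within-group replicate variances and returns its square root, so
#' between-peptide and between-timepoint spread does not inflate the
#' estimate. `"raw"` instead takes the standard deviation of all replicate
#' values around their grand mean, which mixes biological signal into the
#' noise estimate and is provided only for comparison with that reading of
#' "the standard deviation of the pooled distribution".
#'
#' Time-zero groups are excluded (they are exact zeros by construction).
#'
#' @param records An uptake-record tibble.
#' @param sigma_mode `"pooled-within"` (default) or `"raw"`.
#' @return A one-row tibble with `sigma_pct`, `n_groups`, `n_values`.
#' @export
pooled_sigma <- function(records, sigma_mode = c("pooled-within", "raw")) {
  sigma_mode <- match.arg(sigma_mode)
  r <- dplyr::filter(records, .data$exposure_s > 0)
  groups <- r |>
    dplyr::group_by(.data$protein, .data$start, .data$end, .data$state,
                    .data$exposure_s) |>
    dplyr::summarise(n = dplyr::n(), v = var(.data$relative_uptake_pct),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= 2)
  if (nrow(groups) == 0) {
    abort(paste("No (peptide, state, time) group has >= 2 replicates;",
                "supply a sigma value from a comparable experiment instead"))
  }
  if (sigma_mode == "pooled-within") {
    df <- groups$n - 1
    sigma <- sqrt(sum(df * groups$v) / sum(df))
  } else {
    sigma <- sd(r$relative_uptake_pct)
  }
  tibble::tibble(sigma_pct = sigma, n_groups = nrow(groups),
                 n_values = sum(groups$n))
}

#' Wood's-plot table of differential uptake between two conditions
#'
#' For every peptide and non-zero timepoint present in both conditions,
#' computes the replicate-averaged difference in relative uptake,
#' `delta_pct = uptake\%(state_b) - uptake\%(state_a)`, and flags it
#' significant when `|delta_pct|` strictly exceeds
#' `multiplier * sigma_pct`. Positive significant differences are classed
#' "more flexible" (state B takes up more deuterium), negative ones "more
#' rigid". Peptides present in only one condition are reported in a warning
#' and recorded in the `missing_peptides` attribute, never dropped silently.
#'
#' @param records An uptake-record tibble containing both states.
#' @param state_a,state_b Condition labels; the difference is B minus A.
#' @param sigma A [pooled_sigma()] result, a plain number (percent), or
#'   `NULL` to estimate it from `records` with default settings.
#' @param multiplier Threshold multiplier on sigma (default 1).
#' @return A tibble with one row per (peptide, time): `start`, `end`,
#'   `sequence`, `exposure_s`, `uptake_a`, `uptake_b`, `delta_pct`,
#'   `threshold_pct`, `significant`, `direction`. Replicate counts per side
#'   are in `n_a`, `n_b`.
#' @export
woods_table <- function(records, state_a, state_b, sigma = NULL,
                        multiplier = 1) {
  stopifnot(multiplier > 0)
  present <- unique(records$state)
  for (s in c(state_a, state_b)) {
    if (!s %in% present) abort(paste0("State not present in records: ", s))
  }
  if (is.null(sigma)) sigma <- pooled_sigma(records)
  sigma_pct <- if (is.data.frame(sigma)) sigma$sigma_pct else as.numeric(sigma)
  stopifnot(is.finite(sigma_pct), sigma_pct >= 0)

  nrep <- records |>
    dplyr::filter(.data$state %in% c(state_a, state_b), .data$exposure_s > 0) |>
    dplyr::count(.data$state, .data$start, .data$end, .data$exposure_s)
  if (any(nrep$n < 2)) {
    warn("Fewer than 2 replicates in some groups; differences rest on single measurements")
  }

  side <- function(s, nm) {
    records |>
      dplyr::filter(.data$state == s, .data$exposure_s > 0) |>
      dplyr::group_by(.data$protein, .data$start, .data$end, .data$sequence,
                      .data$exposure_s) |>
      dplyr::summarise("uptake_{nm}" := mean(.data$relative_uptake_pct),
                       "n_{nm}" := dplyr::n(), .groups = "drop")
  }
  a <- side(state_a, "a"); b <- side(state_b, "b")
  joined <- dplyr::inner_join(
    a, b, by = c("protein", "start", "end", "sequence", "exposure_s"))
  if (nrow(joined) == 0) abort("No common peptide/timepoint between the two states")

  only <- dplyr::symdiff(dplyr::distinct(a, .data$start, .data$end),
                         dplyr::distinct(b, .data$start, .data$end))
  if (nrow(only)) {
    warn(sprintf("%d peptide(s) present in only one condition: %s",
                 nrow(only),
                 paste(only$start, only$end, sep = "-", collapse = ", ")))
  }

  out <- joined |>
    dplyr::mutate(
      delta_pct = .data$uptake_b - .data$uptake_a,
      threshold_pct = multiplier * sigma_pct,
      significant = abs(.data$delta_pct) > .data$threshold_pct,
      direction = dplyr::case_when(
        .data$significant & .data$delta_pct > 0 ~ "more flexible",
        .data$significant & .data$delta_pct < 0 ~ "more rigid",
        .default = "unchanged"
      )
    ) |>
    dplyr::arrange(.data$start, .data$end, .data$exposure_s)
  attr(out, "states") <- c(a = state_a, b = state_b)
  attr(out, "sigma_pct") <- sigma_pct
  attr(out, "missing_peptides") <- only
  class(out) <- c("hdx_woods", class(out))
  out
}

#' Peptides significant in a Wood's table
#'
#' @param table A [woods_table()] result.
#' @param min_timepoints Minimum number of timepoints at which a peptide
#'   must be significant to be reported (default 1).
#' @return A tibble of peptides (ordered by start coordinate) with the
#'   number of significant timepoints, the time-averaged `mean_delta_pct`,
#'   and the dominant `direction` (sign of the time-averaged difference).
#' @export
significant_peptides <- function(table, min_timepoints = 1) {
  stopifnot(nrow(table) > 0, min_timepoints >= 1)
  table |>
    dplyr::group_by(.data$protein, .data$start, .data$end, .data$sequence) |>
    dplyr::summarise(
      n_significant = sum(.data$significant),
      mean_delta_pct = mean(.data$delta_pct),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_significant >= min_timepoints) |>
    dplyr::mutate(direction = ifelse(.data$mean_delta_pct > 0,
                                     "more flexible", "more rigid")) |>
    dplyr::arrange(.data$start, .data$end)
}

#' Time-averaged uptake difference for one peptide
#'
#' Arithmetic mean of `delta_pct` over the non-zero timepoints entering the
#' Wood's analysis for the peptide at the given coordinates.
#'
#' @param table A [woods_table()] result.
#' @param start,end Peptide coordinates.
#' @return Mean difference in percent (scalar).
#' @export
mean_delta <- function(table, start, end) {
  rows <- table[table$start == start & table$end == end, ]
  if (nrow(rows) == 0) {
    abort(sprintf("Peptide %d-%d not present in the Wood's table", start, end))
  }
  mean(rows$delta_pct)
}
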