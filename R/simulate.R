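#' Construct an HDX simulation design
#'
#' A design bundles everything needed to generate a peptide-level HDX-MS
#' dataset with known ground truth: the protein and its peptide map,
#' per-residue two-state exchange parameters (`k_int`, `k_open`, `k_close`),
#' the experimental conditions (states, exposure times, replicates), the
#' condition-specific opening-equilibrium multipliers, and the noise model.
#'
#' Condition effects are modelled as multiplicative changes of the opening
#' equilibrium `K_op = k_open / k_close`, applied by scaling `k_open` with
#' `k_close` held fixed: a multiplier below 1 rigidifies (less uptake), above
#' 1 loosens (more uptake). Ligand-bearing states may be partially occupied:
#' with fractional occupancy `theta < 1` the expected uptake is the
#' theta-weighted mixture of the bound parameters and the reference apo
#' state's parameters.
#'
#' @param peptides Peptide tibble (see [peptide_table()]); all peptides must
#'   lie within `protein_length`.
#' @param protein_length Residue count of the construct.
#' @param residue_params Tibble with columns `residue`, `k_int`, `k_open`,
#'   `k_close` covering residues 1..`protein_length` (baseline condition).
#' @param states Tibble with columns `state`, and optionally `occupancy`
#'   (default 1) and `apo_state` (reference state for the unbound fraction;
#'   required when `occupancy < 1`).
#' @param multipliers Tibble with columns `state`, `residue`, `multiplier`
#'   giving the K_op multiplier for that state and residue; omitted pairs
#'   default to 1.
#' @param timepoints Exposure times in seconds; must include 0.
#' @param n_replicates Technical replicates per condition (>= 1).
#' @param noise_sd Gaussian replicate noise on relative uptake, in percent.
#' @param d2o_fraction Deuterium fraction of the labeling buffer, in (0, 1].
#' @return An object of class `hdx_design`.
#' @export
hdx_design <- function(peptides, protein_length, residue_params,
                       states = tibble::tibble(state = "A"),
                       multipliers = NULL,
                       timepoints = c(0, 30, 90, 300, 1800, 3600, 5400),
                       n_replicates = 2, noise_sd = 3.1, d2o_fraction = 0.9) {
  stopifnot(is.data.frame(peptides), nrow(peptides) >= 1)
  if (any(peptides$end > protein_length)) abort("Peptide extends past protein_length")
  stopifnot(all(c("residue", "k_int", "k_open", "k_close") %in% names(residue_params)))
  check_rates(residue_params$k_int, residue_params$k_open, residue_params$k_close)
  if (!all(seq_len(protein_length) %in% residue_params$residue)) {
    abort("residue_params must cover residues 1..protein_length")
  }
  if (!"occupancy" %in% names(states)) states$occupancy <- 1
  if (!"apo_state" %in% names(states)) states$apo_state <- NA_character_
  if (any(states$occupancy < 0 | states$occupancy > 1)) {
    abort("occupancy must be in [0, 1]")
  }
  partial <- states$occupancy < 1
  if (any(partial & (is.na(states$apo_state) |
                     !states$apo_state %in% states$state))) {
    abort("States with occupancy < 1 need an apo_state present in the design")
  }
  if (is.null(multipliers)) {
    multipliers <- tibble::tibble(state = character(), residue = integer(),
                                  multiplier = double())
  }
  if (nrow(multipliers) && any(multipliers$multiplier <= 0)) {
    abort("K_op multipliers must be positive")
  }
  if (!0 %in% timepoints) abort("timepoints must include 0")
  if (any(timepoints < 0)) abort("timepoints must be >= 0")
  stopifnot(n_replicates >= 1, noise_sd >= 0,
            d2o_fraction > 0, d2o_fraction <= 1)
  structure(list(
    peptides = peptides, protein_length = as.integer(protein_length),
    residue_params = residue_params, states = states,
    multipliers = multipliers, timepoints = sort(unique(timepoints)),
    n_replicates = as.integer(n_replicates), noise_sd = noise_sd,
    d2o_fraction = d2o_fraction
  ), class = "hdx_design")
}

#' @export
print.hdx_design <- function(x, ...) {
  cat("HDX simulation design\n")
  cat(sprintf("  protein length : %d residues, %d peptides\n",
              x$protein_length, nrow(x$peptides)))
  cat(sprintf("  states         : %s\n", paste(x$states$state, collapse = ", ")))
  cat(sprintf("  timepoints (s) : %s\n", paste(x$timepoints, collapse = ", ")))
  cat(sprintf("  replicates     : %d   noise sd: %g%%   D2O fraction: %g\n",
              x$n_replicates, x$noise_sd, x$d2o_fraction))
  invisible(x)
}

#' Draw generic per-residue exchange parameters
#'
#' Intrinsic rates are drawn log-uniformly over 0.1-100 1/s (the spread
#' typical of backbone amides near pD 7.4 at 25 C) and opening equilibria
#' log-uniformly over protection factors 1e2-1e5; `k_close` is set to
#' `1000 * k_int` so every residue sits deep in the EX2 regime.
#'
#' @param protein_length Residue count.
#' @param seed Integer seed for the draws.
#' @return A `residue_params` tibble.
#' @export
default_residue_params <- function(protein_length, seed = 1) {
  withr_seed(seed, {
    k_int <- 10^runif(protein_length, -1, 2)
    kop <- 10^runif(protein_length, -5, -2)
    k_close <- 1000 * k_int
    tibble::tibble(residue = seq_len(protein_length), k_int = k_int,
                   k_open = kop * k_close, k_close = k_close)
  })
}

# evaluate expr with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# exchangeable residue positions of a peptide: skip the first two residues,
# drop prolines
exchangeable_positions <- function(start, end, sequence, skip_n_term = 2) {
  if (end - start + 1L <= skip_n_term) return(integer(0))
  pos <- (start + skip_n_term):end
  aa <- strsplit(sequence, "")[[1]][(skip_n_term + 1L):(end - start + 1L)]
  pos[aa != "P"]
}

# per-(state, residue, time) expected exchange probability, occupancy mixture
# applied for partially bound states
state_probability_matrix <- function(design, times) {
  rp <- design$residue_params[order(design$residue_params$residue), ]
  mult_of <- function(state) {
    m <- rep(1, design$protein_length)
    mm <- design$multipliers[design$multipliers$state == state, ]
    if (nrow(mm)) m[mm$residue] <- mm$multiplier
    m
  }
  pure <- lapply(design$states$state, function(s) {
    m <- mult_of(s)
    sapply(times, function(t) {
      exchange_probability(t, rp$k_int, rp$k_open * m, rp$k_close)
    })  # residues x times
  })
  names(pure) <- design$states$state
  out <- pure
  for (i in seq_len(nrow(design$states))) {
    th <- design$states$occupancy[i]
    if (th < 1) {
      ref <- design$states$apo_state[i]
      out[[i]] <- th * pure[[i]] + (1 - th) * pure[[ref]]
    }
  }
  out
}

#' Simulate a peptide-level HDX-MS dataset
#'
#' For every peptide x state x timepoint x replicate, the expected uptake is
#' `d2o_fraction` times the sum of [exchange_probability()] over the
#' peptide's exchangeable residues (with the state's K_op multipliers and,
#' for partially occupied states, the bound/unbound occupancy mixture).
#' Gaussian noise of sd `noise_sd` (relative-uptake percent) is added
#' independently per record; time-zero records are exact zeros. A single
#' integer seed drives all draws, so equal seeds give bit-identical
#' datasets.
#'
#' @param design An [hdx_design()].
#' @param seed Integer seed.
#' @return A list of class `hdx_sim` with elements `records` (uptake-record
#'   tibble in the canonical format) and `truth` (per state x residue ground
#'   truth: effective rates, multiplier, and EX2 `k_hdx`).
#' @export
simulate_hdx <- function(design, seed = 1) {
  stopifnot(inherits(design, "hdx_design"))
  times <- design$timepoints
  probs <- state_probability_matrix(design, times)

  pep <- design$peptides
  grid <- tidyr::expand_grid(
    pep_idx = seq_len(nrow(pep)),
    state = design$states$state,
    exposure_s = times,
    replicate = seq_len(design$n_replicates)
  )
  expected_rel <- purrr::pmap_dbl(
    grid[c("pep_idx", "state", "exposure_s")],
    function(pep_idx, state, exposure_s) {
      xpos <- exchangeable_positions(pep$start[pep_idx], pep$end[pep_idx],
                                     pep$sequence[pep_idx])
      if (!length(xpos)) return(0)
      ti <- match(exposure_s, times)
      100 * design$d2o_fraction * mean(probs[[state]][xpos, ti])
    })

  rec <- withr_seed(seed, {
    noise <- rnorm(nrow(grid), 0, design$noise_sd)
    rel <- ifelse(grid$exposure_s == 0, 0, expected_rel + noise)
    tibble::tibble(
      protein = pep$protein[grid$pep_idx],
      start = pep$start[grid$pep_idx], end = pep$end[grid$pep_idx],
      sequence = pep$sequence[grid$pep_idx], state = grid$state,
      exposure_s = grid$exposure_s, replicate = grid$replicate,
      n_exchangeable = pep$n_exchangeable[grid$pep_idx],
      relative_uptake_pct = rel,
      uptake_da = rel / 100 * pep$n_exchangeable[grid$pep_idx]
    )
  })
  rec <- dplyr::arrange(rec, .data$protein, .data$start, .data$end,
                        .data$state, .data$exposure_s, .data$replicate)

  rp <- design$residue_params
  truth <- tidyr::expand_grid(state = design$states$state,
                              residue = rp$residue) |>
    dplyr::left_join(rp, by = "residue") |>
    dplyr::left_join(design$multipliers, by = c("state", "residue")) |>
    dplyr::mutate(
      multiplier = dplyr::coalesce(.data$multiplier, 1),
      k_open_eff = .data$k_open * .data$multiplier,
      k_hdx_ex2 = ifelse(.data$k_close > 0,
                         .data$k_open_eff / .data$k_close * .data$k_int, NA_real_)
    )
  structure(list(records = rec, truth = truth, design = design,
                 seed = as.integer(seed)), class = "hdx_sim")
}

#' @export
print.hdx_sim <- function(x, ...) {
  cat(sprintf("Simulated HDX dataset: %d records (seed %d)\n",
              nrow(x$records), x$seed))
  print(x$design)
  invisible(x)
}
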