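# 162-residue myoglobin-like construct: initiator Met + 153-residue globin
# + GS linker + C-terminal His6 tag. Synthetic stand-in sequence used only
# to give the simulator a realistic peptide map (amide counts, prolines).
myoglobin_construct_sequence <- function() {
  paste0(
    "M",
    "VLSEGEWQLVLHVWAKVEADVAGHGQDILIRLFKSHPETLEKFDRFKHLKTEAEMKASED",
    "LKKHGVTVLTALGAILKKKGHHEAELKPLAQSHATKHKIPIKYLEFISEAIIHVLHSRHP",
    "GDFGADAQGAMNKALELFRKDIAAKYKELGYQG",
    "GS", "HHHHHH"
  )
}

# the nine reproducible non-overlapping peptides used for detailed analysis
myoglobin_peptide_coords <- function() {
  tibble::tibble(
    start = c(3L, 12L, 30L, 41L, 56L, 70L, 87L, 107L, 130L),
    end   = c(11L, 29L, 40L, 55L, 69L, 86L, 106L, 129L, 159L)
  )
}

#' Solve for the K_op multiplier giving a target mean uptake difference
#'
#' Finds the multiplier `m` on `k_open` such that the mean over `timepoints`
#' of `100 * d2o_fraction * (p_m(t) - p_1(t))` equals `target_delta_pct`,
#' where `p_m` is [exchange_probability()] with `k_open` scaled by `m`.
#' Used to construct simulation designs whose ground-truth effect sizes
#' match stated time-averaged uptake differences.
#'
#' @inheritParams ex2_rate
#' @param target_delta_pct Desired time-averaged uptake difference, percent.
#' @param timepoints Exposure times (s) over which the mean is taken.
#' @param d2o_fraction Deuterium fraction of the labeling buffer.
#' @return The multiplier (positive scalar).
#' @export
kop_multiplier_for_delta <- function(k_int, k_open, k_close, target_delta_pct,
                                     timepoints = c(30, 90, 300, 1800),
                                     d2o_fraction = 0.9) {
  mean_delta_at <- function(log_m) {
    m <- exp(log_m)
    mean(100 * d2o_fraction *
           (exchange_probability(timepoints, k_int, k_open * m, k_close) -
              exchange_probability(timepoints, k_int, k_open, k_close)))
  }
  f <- function(lm) mean_delta_at(lm) - target_delta_pct
  uniroot(f, lower = log(1e-4), upper = log(1e4), tol = 1e-12)$root |> exp()
}

#' The default myoglobin-like simulation design
#'
#' A four-condition design mirroring a variant x ligand HDX-MS study on a
#' 162-residue myoglobin construct (His-tagged): wild-type-like (`WT`) and
#' triple-mutant (`MUT`) variants, each apo and bound to a substrate analog
#' (`holo`), measured over seven exposure times (0, 30, 90, 300, 1800, 3600,
#' 5400 s) in duplicate on nine non-overlapping peptides covering 97% of the
#' sequence.
#'
#' Ground-truth effects are encoded as K_op multipliers per peptide region:
#' \itemize{
#'   \item Mutant apo vs WT apo: peptide 12-29 rigidified to a time-averaged
#'     uptake difference of -18%, 30-40 to -13%; 41-55, 70-86 and 87-106
#'     loosened to +6%; peptide 56-69's opening equilibrium scaled so its
#'     observed EX2 rate rises from 0.0052 to 0.0447 1/s.
#'   \item WT holo vs apo: peptide 12-29 loosened to +6%; 56-69 slowed to
#'     0.0046 1/s.
#'   \item Mutant holo: ligand binding restores peptides 12-29, 30-40,
#'     41-55, 70-86 and 87-106 to the WT baseline; 56-69 exchanges at
#'     0.0263 1/s.
#' }
#' Holo states carry the fractional occupancy obtained from the quadratic
#' 1:1 binding relation at KD = 11.2, P0 = 100, I0 = 1188 (micromolar), with
#' the unbound fraction exchanging with the matching apo parameters.
#' Replicate noise defaults to a 3.1% relative-uptake standard deviation,
#' the pooled workflow variability of a typical bottom-up HDX platform, and
#' the labeling buffer to 90% deuterium.
#'
#' All residues sit deep in the EX2 regime (`k_int = 10` 1/s,
#' `k_close = 5000` 1/s; region-specific `k_open`).
#'
#' @param noise_sd Replicate noise sd on relative uptake, percent.
#' @param n_replicates Replicates per condition.
#' @param timepoints Exposure times in seconds (must include 0).
#' @return An [hdx_design()].
#' @export
hdx_design_myoglobin <- function(noise_sd = 3.1, n_replicates = 2,
                                 timepoints = c(0, 30, 90, 300, 1800, 3600, 5400)) {
  seq_full <- myoglobin_construct_sequence()
  L <- nchar(seq_full)
  coords <- myoglobin_peptide_coords()
  peptides <- peptide_table(
    protein = "MB", start = coords$start, end = coords$end,
    sequence = substring(seq_full, coords$start, coords$end)
  )

  # baseline (WT apo) observed EX2 rates per peptide region, 1/s
  k_int <- 10; k_close <- 5000
  base_khdx <- c(0.010, 0.005, 0.003, 0.008, 0.0052, 0.004, 0.006, 0.002, 0.015)
  k_open_region <- (base_khdx / k_int) * k_close

  residue_khdx <- rep(base_khdx[1], L)
  for (i in seq_len(nrow(coords))) {
    residue_khdx[coords$start[i]:coords$end[i]] <- base_khdx[i]
  }
  residue_params <- tibble::tibble(
    residue = seq_len(L), k_int = k_int,
    k_open = (residue_khdx / k_int) * k_close, k_close = k_close
  )

  occ <- complex_concentration(kd = 11.2, p0 = 100, i0 = 1188)$theta
  states <- tibble::tibble(
    state = c("WT_apo", "MUT_apo", "WT_holo", "MUT_holo"),
    occupancy = c(1, 1, occ, occ),
    apo_state = c(NA, NA, "WT_apo", "MUT_apo")
  )

  plotted <- c(30, 90, 300, 1800)
  solve_m <- function(region, target) {
    kop_multiplier_for_delta(k_int, k_open_region[region], k_close,
                             target_delta_pct = target, timepoints = plotted)
  }
  region_of <- function(i) coords$start[i]:coords$end[i]
  mult_rows <- function(state, region, m) {
    tibble::tibble(state = state, residue = region_of(region), multiplier = m)
  }
  multipliers <- dplyr::bind_rows(
    # mutant apo: calibrated time-averaged uptake differences vs WT apo
    mult_rows("MUT_apo", 2, solve_m(2, -18)),
    mult_rows("MUT_apo", 3, solve_m(3, -13)),
    mult_rows("MUT_apo", 4, solve_m(4, +6)),
    mult_rows("MUT_apo", 5, 0.0447 / 0.0052),
    mult_rows("MUT_apo", 6, solve_m(6, +6)),
    mult_rows("MUT_apo", 7, solve_m(7, +6)),
    # WT holo: modest loosening of the N-terminal helices on binding
    mult_rows("WT_holo", 2, solve_m(2, +6)),
    mult_rows("WT_holo", 5, 0.0046 / 0.0052),
    # mutant holo: binding restores all regions except 56-69 to WT baseline
    mult_rows("MUT_holo", 5, 0.0263 / 0.0052)
  )

  hdx_design(
    peptides = peptides, protein_length = L, residue_params = residue_params,
    states = states, multipliers = multipliers, timepoints = timepoints,
    n_replicates = n_replicates, noise_sd = noise_sd, d2o_fraction = 0.9
  )
}

#' A minimal two-condition design for ground-truth recovery studies
#'
#' The nine-peptide myoglobin peptide map with two states (`ctrl`,
#' `perturbed`) in which a chosen subset of peptides has its opening
#' equilibrium scaled by `effect_multiplier`; all other peptides are
#' unperturbed nulls. Useful for sensitivity/specificity benchmarking
#' against known truth.
#'
#' @param perturbed_peptides Indices (1-9, by start order) of the peptides
#'   to perturb.
#' @param effect_multiplier K_op multiplier applied to the perturbed
#'   peptides (< 1 rigidifies, > 1 loosens).
#' @param noise_sd Replicate noise sd, percent relative uptake.
#' @param n_replicates Replicates per condition.
#' @return An [hdx_design()].
#' @export
hdx_design_two_state <- function(perturbed_peptides = c(2, 5),
                                 effect_multiplier = 0.5, noise_sd = 0.5,
                                 n_replicates = 2) {
  seq_full <- myoglobin_construct_sequence()
  L <- nchar(seq_full)
  coords <- myoglobin_peptide_coords()
  peptides <- peptide_table(
    protein = "MB", start = coords$start, end = coords$end,
    sequence = substring(seq_full, coords$start, coords$end)
  )
  k_int <- 10; k_close <- 5000
  base_khdx <- c(0.010, 0.005, 0.003, 0.008, 0.0052, 0.004, 0.006, 0.002, 0.015)
  residue_khdx <- rep(base_khdx[1], L)
  for (i in seq_len(nrow(coords))) {
    residue_khdx[coords$start[i]:coords$end[i]] <- base_khdx[i]
  }
  residue_params <- tibble::tibble(
    residue = seq_len(L), k_int = k_int,
    k_open = (residue_khdx / k_int) * k_close, k_close = k_close
  )
  res <- unlist(lapply(perturbed_peptides,
                       function(i) coords$start[i]:coords$end[i]))
  multipliers <- tibble::tibble(state = "perturbed", residue = res,
                                multiplier = effect_multiplier)
  hdx_design(
    peptides = peptides, protein_length = L, residue_params = residue_params,
    states = tibble::tibble(state = c("ctrl", "perturbed")),
    multipliers = multipliers, n_replicates = n_replicates,
    noise_sd = noise_sd, d2o_fraction = 0.9
  )
}
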