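#' Run the full differential HDX analysis pipeline
#'
#' Orchestrates the standard stage order: uptake records (read or
#' simulated), pooled replicate variability, Wood's differential tables for
#' each requested contrast, significant-peptide summaries, and
#' one-exponential fits per peptide and state. Deterministic given the
#' inputs and seed.
#'
#' @param records An uptake-record tibble, or `NULL` to simulate from
#'   `design`.
#' @param design An [hdx_design()] used when `records` is `NULL`.
#' @param contrasts A list of `c(state_a, state_b)` pairs (difference is
#'   B minus A). Defaults to all ordered pairs sharing a variant or a
#'   ligand status are *not* guessed: for the four-state myoglobin design
#'   the conventional contrasts are supplied automatically.
#' @param sigma `NULL` (estimate from the data), a number, or a
#'   [pooled_sigma()] tibble.
#' @param multiplier Threshold multiplier on sigma.
#' @param min_timepoints Timepoints required for a peptide-level call.
#' @param seed Seed used when simulating.
#' @return An object of class `hdx_report`: a list with `summary`,
#'   `sigma`, `woods` (named list of Wood's tables), `significant` (named
#'   list), `fits`, and `provenance`.
#' @export
run_pipeline <- function(records = NULL, design = NULL, contrasts = NULL,
                         sigma = NULL, multiplier = 1, min_timepoints = 1,
                         seed = 1) {
  sim <- NULL
  if (is.null(records)) {
    if (is.null(design)) abort("Provide records or a design to simulate")
    sim <- simulate_hdx(design, seed = seed)
    records <- sim$records
  }
  states <- unique(records$state)
  if (is.null(contrasts)) {
    if (all(c("WT_apo", "MUT_apo", "WT_holo", "MUT_holo") %in% states)) {
      contrasts <- list(
        mutation_apo = c("WT_apo", "MUT_apo"),
        mutation_holo = c("WT_holo", "MUT_holo"),
        binding_wt = c("WT_apo", "WT_holo"),
        binding_mut = c("MUT_apo", "MUT_holo")
      )
    } else if (length(states) == 2) {
      contrasts <- stats::setNames(list(states),
                                   paste(states[2], "vs", states[1]))
    } else {
      abort("Supply contrasts: cannot infer them from the state labels")
    }
  }
  for (ctr in contrasts) {
    bad <- setdiff(ctr, states)
    if (length(bad)) abort(paste0("Contrast names missing state: ", bad[1]))
  }
  if (is.null(names(contrasts))) {
    names(contrasts) <- vapply(contrasts, function(x) paste(x[2], "vs", x[1]), "")
  }

  sig <- if (is.null(sigma)) pooled_sigma(records) else {
    if (is.data.frame(sigma)) sigma
    else tibble::tibble(sigma_pct = as.numeric(sigma), n_groups = NA_integer_,
                        n_values = NA_integer_)
  }
  woods <- lapply(contrasts, function(ctr) {
    woods_table(records, state_a = ctr[1], state_b = ctr[2],
                sigma = sig, multiplier = multiplier)
  })
  significant <- lapply(woods, significant_peptides,
                        min_timepoints = min_timepoints)
  fits <- fit_uptake_curves(records)

  peps <- peptides_of(records)
  plen <- if (!is.null(design)) design$protein_length else max(peps$end)
  summary <- tibble::tibble(
    n_peptides = nrow(peps),
    coverage = peptide_coverage(peps, plen),
    n_states = length(states),
    n_timepoints = length(unique(records$exposure_s)),
    n_replicates = max(records$replicate),
    n_records = nrow(records)
  )
  provenance <- list(
    seed = seed, multiplier = multiplier, min_timepoints = min_timepoints,
    simulated = !is.null(sim),
    package_version = as.character(utils::packageVersion("hdxdelta"))
  )
  structure(list(summary = summary, sigma = sig, woods = woods,
                 significant = significant, fits = fits,
                 truth = if (!is.null(sim)) sim$truth else NULL,
                 provenance = provenance),
            class = "hdx_report")
}

#' @export
print.hdx_report <- function(x, ...) {
  cat("Differential HDX-MS analysis report\n")
  cat(sprintf("  %d peptides, coverage %.1f%%, %d states, %d timepoints, %d replicates\n",
              x$summary$n_peptides, 100 * x$summary$coverage,
              x$summary$n_states, x$summary$n_timepoints,
              x$summary$n_replicates))
  cat(sprintf("  pooled sigma: %.2f%% (from %d replicate groups)\n",
              x$sigma$sigma_pct, x$sigma$n_groups))
  for (nm in names(x$woods)) {
    sp <- x$significant[[nm]]
    cat(sprintf("  contrast %-14s: %d significant peptide(s)%s\n", nm, nrow(sp),
                if (nrow(sp)) paste0(" [",
                  paste(sprintf("%d-%d %s", sp$start, sp$end, sp$direction),
                        collapse = "; "), "]") else ""))
  }
  invisible(x)
}

#' Write per-report tables to a directory
#'
#' Emits the dataset summary, pooled sigma, every Wood's table,
#' significant-peptide lists and the fit table as comma-separated files.
#'
#' @param report An `hdx_report`.
#' @param dir Output directory (created if needed).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$summary, file.path(dir, "summary.csv"))
  readr::write_csv(report$sigma, file.path(dir, "pooled_sigma.csv"))
  for (nm in names(report$woods)) {
    readr::write_csv(report$woods[[nm]],
                     file.path(dir, paste0("woods_", nm, ".csv")))
    readr::write_csv(report$significant[[nm]],
                     file.path(dir, paste0("significant_", nm, ".csv")))
  }
  readr::write_csv(report$fits, file.path(dir, "fits.csv"))
  invisible(report)
}

#' Map per-residue uptake differences onto a PDB structure
#'
#' Writes the mean uptake difference of the peptide covering each residue
#' into the B-factor column of a PDB file (the usual route for colouring a
#' structure by differential exchange). Residues covered by no peptide get
#' the sentinel value -99.9. Coordinates are untouched. Requires the bio3d
#' package.
#'
#' @param table A [woods_table()] result (or any tibble with `start`, `end`,
#'   `delta_pct`).
#' @param pdb_path Input PDB file.
#' @param out_path Output PDB file.
#' @param chain Chain identifier to annotate.
#' @param sentinel B-factor for uncovered residues.
#' @return Invisibly, the per-residue annotation tibble (`resno`, `bfactor`).
#' @export
export_structure_map <- function(table, pdb_path, out_path, chain = "A",
                                 sentinel = -99.9) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("export_structure_map requires the bio3d package")
  }
  per_pep <- table |>
    dplyr::group_by(.data$start, .data$end) |>
    dplyr::summarise(mean_delta = mean(.data$delta_pct), .groups = "drop")
  pdb <- bio3d::read.pdb(pdb_path)
  sel <- pdb$atom$chain == chain
  if (!any(sel)) abort(paste0("Chain not present in PDB: ", chain))
  resno <- pdb$atom$resno[sel]
  bf <- rep(sentinel, length(resno))
  for (i in seq_len(nrow(per_pep))) {
    hit <- resno >= per_pep$start[i] & resno <= per_pep$end[i]
    bf[hit] <- round(per_pep$mean_delta[i], 2)
  }
  pdb$atom$b[sel] <- bf
  bio3d::write.pdb(pdb, file = out_path)
  invisible(tibble::tibble(resno = unique(resno),
                           bfactor = bf[!duplicated(resno)]))
}
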