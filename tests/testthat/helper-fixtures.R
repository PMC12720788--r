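# small in-code fixtures shared across test files

# minimal uptake-record tibble: one protein, chosen peptides/states/times,
# uptake values supplied as a function of (start, state, time, replicate)
make_records <- function(peptides, states, times, n_rep = 2,
                         rel_uptake = function(start, state, time, rep) {
                           50 * (1 - exp(-0.005 * time))
                         }) {
  grid <- expand.grid(i = seq_len(nrow(peptides)), state = states,
                      exposure_s = times, replicate = seq_len(n_rep),
                      stringsAsFactors = FALSE)
  rel <- mapply(rel_uptake, peptides$start[grid$i], grid$state,
                grid$exposure_s, grid$replicate)
  tibble::tibble(
    protein = "P1",
    start = peptides$start[grid$i], end = peptides$end[grid$i],
    sequence = peptides$sequence[grid$i],
    state = grid$state, exposure_s = grid$exposure_s,
    replicate = grid$replicate,
    n_exchangeable = exchangeable_amides(peptides$sequence[grid$i]),
    relative_uptake_pct = ifelse(grid$exposure_s == 0, 0, rel),
    uptake_da = ifelse(grid$exposure_s == 0, 0, rel) / 100 *
      exchangeable_amides(peptides$sequence[grid$i])
  )
}

two_peptides <- function() {
  tibble::tibble(start = c(1L, 11L), end = c(10L, 20L),
                 sequence = c("GLSDGEWQLV", "LHVWAKVEAD"))
}

# exhaustive-search oracle for maximum-coverage non-overlapping subsets
brute_force_best_coverage <- function(starts, ends) {
  n <- length(starts)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) < 2 ||
        all(outer(seq_along(idx), seq_along(idx), function(a, b) {
          a >= b | starts[idx[a]] > ends[idx[b]] | ends[idx[a]] < starts[idx[b]]
        }))) {
      cov <- sum(ends[idx] - starts[idx] + 1)
      best <- max(best, cov)
    }
  }
  best
}

# five-residue single-chain PDB written as plain text
make_mini_pdb <- function(path, resnos = 1:5, chain = "A") {
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_along(resnos), chain, resnos, resnos * 1.5, 0, 0, 1, 0)
  writeLines(c(lines, "END"), path)
  path
}
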