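#' Deuterium uptake from centroid masses
#'
#' Uptake is the centroid mass of the deuterated peptide minus the centroid
#' mass of the undeuterated peptide. Small negative differences (down to
#' `-tolerance`) are treated as measurement noise and clipped to zero with a
#' warning; differences below `-tolerance` indicate a data error and are
#' rejected.
#'
#' @param centroid_deuterated Centroid mass of the deuterated peptide (Da).
#' @param centroid_undeuterated Centroid mass of the undeuterated peptide (Da).
#' @param tolerance Magnitude of negative difference still attributed to
#'   noise, in Da. Default 0.1.
#' @param label Optional record label used in error messages.
#' @return Uptake in Da (vectorised).
#' @examples
#' compute_uptake(1841.02, 1836.00)
#' @export
compute_uptake <- function(centroid_deuterated, centroid_undeuterated,
                           tolerance = 0.1, label = NULL) {
  if (any(!is.finite(centroid_deuterated)) || any(!is.finite(centroid_undeuterated))) {
    abort(paste0("Non-finite centroid mass",
                 if (!is.null(label)) paste0(" in record ", label) else ""))
  }
  if (any(centroid_deuterated <= 0) || any(centroid_undeuterated <= 0)) {
    abort("Centroid masses must be positive")
  }
  uptake <- centroid_deuterated - centroid_undeuterated
  bad <- uptake < -tolerance
  if (any(bad)) {
    abort(sprintf(
      "Uptake below -%g Da for %d record(s)%s: likely swapped or corrupt centroids",
      tolerance, sum(bad),
      if (!is.null(label)) paste0(" (", paste(label[bad], collapse = ", "), ")") else ""))
  }
  neg <- uptake < 0
  if (any(neg)) {
    warn(sprintf("Clipped %d small negative uptake value(s) to 0", sum(neg)))
    uptake[neg] <- 0
  }
  uptake
}

#' Count exchangeable backbone amides in a peptide
#'
#' The first residue has no backbone amide after digestion and the second
#' residue's amide back-exchanges too rapidly to retain label, so neither is
#' observable; prolines lack an amide hydrogen altogether. The count is
#' therefore `length - skip_n_term - (prolines beyond the skipped prefix)`,
#' floored at zero.
#'
#' @param sequence Character vector of peptide sequences (one-letter codes).
#' @param skip_n_term Number of N-terminal residues excluded from the count
#'   (default 2, the dominant community convention).
#' @return Integer vector of exchangeable-amide counts.
#' @examples
#' exchangeable_amides("GLSDGEWQL")  # 7
#' @export
exchangeable_amides <- function(sequence, skip_n_term = 2) {
  stopifnot(is.character(sequence), all(nzchar(sequence)))
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", sequence)
  if (!all(ok)) {
    abort(paste0("Unknown residue code in sequence(s): ",
                 paste(sequence[!ok], collapse = ", ")))
  }
  vapply(sequence, function(s) {
    n <- nchar(s)
    if (n <= skip_n_term) return(0L)
    body <- substring(s, skip_n_term + 1L, n)
    pro <- lengths(regmatches(body, gregexpr("P", body, fixed = TRUE)))
    max(0L, as.integer(n - skip_n_term - pro))
  }, integer(1), USE.NAMES = FALSE)
}

#' Build a validated peptide table
#'
#' @param protein,start,end,sequence Vectors defining one peptide per element;
#'   coordinates are 1-based inclusive residue numbers.
#' @return A tibble with columns `protein`, `start`, `end`, `sequence`,
#'   `n_exchangeable`, one row per distinct peptide.
#' @export
peptide_table <- function(protein, start, end, sequence) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(end < start)) abort("Peptide end must be >= start")
  if (any(nchar(sequence) != end - start + 1L)) {
    abort("Peptide sequence length must equal end - start + 1")
  }
  tibble::tibble(
    protein = as.character(protein), start = start, end = end,
    sequence = toupper(sequence),
    n_exchangeable = exchangeable_amides(toupper(sequence))
  ) |> dplyr::distinct()
}

# column-name shim: map common export variants onto the canonical names
.canonical_columns <- c(
  protein = "protein", protein_id = "protein",
  start = "start", pep_start = "start",
  end = "end", pep_end = "end", stop = "end",
  sequence = "sequence", peptide = "sequence",
  state = "state", protein_state = "state",
  exposure_s = "exposure_s", exposure = "exposure_s", time = "exposure_s",
  time_s = "exposure_s",
  replicate = "replicate", rep = "replicate",
  centroid_undeut = "centroid_undeut", centroid_undeuterated = "centroid_undeut",
  centroid_deut = "centroid_deut", centroid_deuterated = "centroid_deut",
  uptake_da = "uptake_da", uptake = "uptake_da",
  relative_uptake_pct = "relative_uptake_pct", relative_uptake = "relative_uptake_pct",
  rel_uptake = "relative_uptake_pct"
)

#' Read a long-format HDX uptake summary table
#'
#' The native layout is comma-separated, one row per peptide x state x
#' exposure x replicate, with columns `protein`, `start`, `end`, `sequence`,
#' `state`, `exposure_s`, `replicate`, and either centroid masses
#' (`centroid_undeut`, `centroid_deut`) or `uptake_da` (or both, which must
#' agree within 0.05 Da). Common column-name variants from community exports
#' (`Exposure`, `State`, `Uptake`, ...) are mapped automatically. A missing
#' replicate column defaults to replicate 1.
#'
#' @param path File path, or anything `readr::read_csv()` accepts.
#' @return A tibble of validated uptake records with computed `uptake_da`,
#'   `n_exchangeable` and `relative_uptake_pct` columns, sorted by peptide
#'   start, state and exposure.
#' @export
read_uptake_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) {
    warn("Empty uptake table")
    return(empty_uptake_records())
  }
  names(raw) <- tolower(gsub("[ .]", "_", names(raw)))
  hit <- names(raw) %in% names(.canonical_columns)
  names(raw)[hit] <- .canonical_columns[names(raw)[hit]]
  raw <- raw[!duplicated(names(raw))]
  as_uptake_records(raw)
}

#' Validate a data frame of uptake measurements
#'
#' Applies the same validation as [read_uptake_table()] to an in-memory data
#' frame already using canonical column names.
#'
#' @param data A data frame with canonical uptake-record columns.
#' @return A validated uptake-record tibble.
#' @export
as_uptake_records <- function(data) {
  needed <- c("protein", "start", "end", "sequence", "state", "exposure_s")
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    abort(paste0("Missing mandatory column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  has_centroids <- all(c("centroid_undeut", "centroid_deut") %in% names(data))
  has_uptake <- "uptake_da" %in% names(data)
  if (!has_centroids && !has_uptake) {
    abort("Need either centroid mass columns or an uptake_da column")
  }

  rec <- tibble::as_tibble(data)
  rec$start <- as.integer(rec$start); rec$end <- as.integer(rec$end)
  rec$replicate <- as.integer(rec$replicate)
  rec$exposure_s <- as.numeric(rec$exposure_s)
  rec$sequence <- toupper(as.character(rec$sequence))
  if (any(rec$exposure_s < 0)) abort("Exposure times must be >= 0")
  if (any(rec$replicate < 1)) abort("Replicate numbers must be >= 1")

  # same coordinates must always carry the same sequence
  seq_check <- rec |>
    dplyr::distinct(.data$protein, .data$start, .data$end, .data$sequence) |>
    dplyr::count(.data$protein, .data$start, .data$end)
  if (any(seq_check$n > 1)) {
    bad <- seq_check[seq_check$n > 1, ]
    abort(sprintf("Inconsistent sequence for peptide %s %d-%d",
                  bad$protein[1], bad$start[1], bad$end[1]))
  }
  if (any(nchar(rec$sequence) != rec$end - rec$start + 1L)) {
    abort("Sequence length must equal end - start + 1")
  }

  lab <- sprintf("%s %d-%d %s t=%gs rep%d", rec$protein, rec$start, rec$end,
                 rec$state, rec$exposure_s, rec$replicate)
  if (has_centroids) {
    centroid_uptake <- compute_uptake(rec$centroid_deut, rec$centroid_undeut,
                                      label = lab)
    if (has_uptake) {
      off <- abs(centroid_uptake - rec$uptake_da) > 0.05
      if (any(off, na.rm = TRUE)) {
        abort(sprintf(
          "uptake_da disagrees with centroid difference by > 0.05 Da for %s",
          lab[which(off)[1]]))
      }
    }
    rec$uptake_da <- centroid_uptake
  }
  rec$n_exchangeable <- exchangeable_amides(rec$sequence)
  rec$relative_uptake_pct <- ifelse(rec$n_exchangeable > 0,
                                    100 * rec$uptake_da / rec$n_exchangeable, 0)
  dplyr::arrange(rec, .data$protein, .data$start, .data$end, .data$state,
                 .data$exposure_s, .data$replicate)
}

empty_uptake_records <- function() {
  tibble::tibble(
    protein = character(), start = integer(), end = integer(),
    sequence = character(), state = character(), exposure_s = double(),
    replicate = integer(), uptake_da = double(), n_exchangeable = integer(),
    relative_uptake_pct = double()
  )
}

#' Write uptake records to the canonical table format
#'
#' @param records An uptake-record tibble.
#' @param path Output file path (comma-separated, UTF-8, dot decimal).
#' @return `records`, invisibly.
#' @export
write_uptake_table <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(records)
}

#' Extract the distinct peptides from uptake records
#'
#' @param records An uptake-record tibble.
#' @return A peptide tibble (one row per distinct peptide).
#' @export
peptides_of <- function(records) {
  records |>
    dplyr::distinct(.data$protein, .data$start, .data$end, .data$sequence) |>
    dplyr::mutate(n_exchangeable = exchangeable_amides(.data$sequence)) |>
    dplyr::arrange(.data$start, .data$end)
}

#' Select a non-overlapping peptide subset maximising residue coverage
#'
#' Finds the pairwise non-overlapping subset whose peptides cover the largest
#' total number of residues, by weighted interval scheduling (dynamic
#' programming over end-sorted intervals, peptide length as weight). Ties are
#' broken deterministically in favour of the leftmost (earlier-starting)
#' peptides, so the result does not depend on input order.
#'
#' @param peptides A peptide tibble (single protein).
#' @return The selected subset, ordered by start coordinate.
#' @export
select_nonoverlapping <- function(peptides) {
  stopifnot(nrow(peptides) >= 1)
  if (length(unique(peptides$protein)) > 1) {
    abort("Peptides must share a protein")
  }
  p <- dplyr::distinct(peptides, .data$start, .data$end, .keep_all = TRUE)
  p <- p[order(p$end, p$start), ]
  n <- nrow(p)
  w <- p$end - p$start + 1L
  # pred[i]: last interval ending before interval i starts (0 if none)
  pred <- vapply(seq_len(n), function(i) {
    j <- which(p$end < p$start[i])
    if (length(j)) max(j) else 0L
  }, integer(1))
  f <- numeric(n + 1L)       # f[i+1] = best coverage using intervals 1..i
  for (i in seq_len(n)) {
    f[i + 1L] <- max(f[i], w[i] + f[pred[i] + 1L])
  }
  keep <- logical(n)
  i <- n
  while (i >= 1L) {
    # strict inequality: on ties skip interval i, preferring earlier peptides
    if (w[i] + f[pred[i] + 1L] > f[i]) {
      keep[i] <- TRUE
      i <- pred[i]
    } else {
      i <- i - 1L
    }
  }
  dplyr::arrange(p[keep, ], .data$start)
}

#' Fraction of a protein covered by a peptide set
#'
#' @param peptides A peptide tibble.
#' @param protein_length Total residue count of the protein construct.
#' @return Fraction in \[0, 1\] of residues `1..protein_length` inside the
#'   union of the peptide intervals.
#' @export
peptide_coverage <- function(peptides, protein_length) {
  stopifnot(protein_length >= 1)
  if (nrow(peptides) == 0) return(0)
  if (any(peptides$end > protein_length)) {
    abort("Peptide extends past protein_length")
  }
  covered <- logical(protein_length)
  for (i in seq_len(nrow(peptides))) {
    covered[peptides$start[i]:peptides$end[i]] <- TRUE
  }
  sum(covered) / protein_length
}
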