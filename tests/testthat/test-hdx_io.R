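test_that("uptake is the centroid difference, with small negatives clipped", {
  expect_equal(compute_uptake(1841.02, 1836.00), 5.02)
  expect_equal(compute_uptake(1836.00, 1836.00), 0)
  expect_warning(u <- compute_uptake(1835.90, 1836.00), "Clipped")
  expect_equal(u, 0)
  expect_error(compute_uptake(1835.0, 1836.00), "swapped or corrupt")
  expect_error(compute_uptake(NaN, 1836.00), "Non-finite")
  expect_error(compute_uptake(Inf, 1836.00, label = "pep 1-10"), "pep 1-10")
})

test_that("exchangeable amide count skips the N-terminal pair and prolines", {
  expect_equal(exchangeable_amides("GLSDGEWQL"), 7L)
  expect_equal(exchangeable_amides("GP"), 0L)
  expect_equal(exchangeable_amides("AAPAPAA"), 3L)
  expect_equal(exchangeable_amides(c("AA", "A")), c(0L, 0L))
  # prolines in the skipped prefix are not double-counted
  expect_equal(exchangeable_amides("PPAAA"), 3L)
  expect_error(exchangeable_amides("AXZ"), "Unknown residue")
})

test_that("reading a table with centroids computes uptake and validates", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "protein,start,end,sequence,state,exposure,replicate,centroid_undeuterated,centroid_deuterated",
    "P1,1,10,GLSDGEWQLV,apo,30,1,1100.00,1103.50",
    "P1,1,10,GLSDGEWQLV,apo,0,1,1100.00,1100.00"
  ), tmp)
  rec <- read_uptake_table(tmp)
  expect_equal(nrow(rec), 2)
  expect_equal(sort(rec$uptake_da), c(0, 3.5))
  expect_equal(rec$n_exchangeable, rep(exchangeable_amides("GLSDGEWQLV"), 2))
  expect_equal(rec$relative_uptake_pct, 100 * rec$uptake_da / rec$n_exchangeable)
  # times come back sorted
  expect_equal(rec$exposure_s, c(0, 30))
})

test_that("reader rejects missing columns, inconsistent sequences and bad centroids", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("protein,start,end,sequence,exposure_s,uptake",
               "P1,1,10,GLSDGEWQLV,30,2.0"), tmp)
  expect_error(read_uptake_table(tmp), "state")

  writeLines(c(
    "protein,start,end,sequence,state,exposure_s,uptake",
    "P1,1,10,GLSDGEWQLV,apo,30,2.0",
    "P1,1,10,GLSDGEWQLW,apo,90,3.0"
  ), tmp)
  expect_error(read_uptake_table(tmp), "Inconsistent sequence")

  # uptake column disagreeing with centroid difference beyond 0.05 Da
  writeLines(c(
    "protein,start,end,sequence,state,exposure_s,centroid_undeut,centroid_deut,uptake_da",
    "P1,1,10,GLSDGEWQLV,apo,30,1100.00,1103.50,3.40"
  ), tmp)
  expect_error(read_uptake_table(tmp), "disagrees")

  # agreement within 0.05 Da passes
  writeLines(c(
    "protein,start,end,sequence,state,exposure_s,centroid_undeut,centroid_deut,uptake_da",
    "P1,1,10,GLSDGEWQLV,apo,30,1100.00,1103.50,3.48"
  ), tmp)
  expect_equal(read_uptake_table(tmp)$uptake_da, 3.5)
})

test_that("an empty table yields an empty record set with a warning", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("protein,start,end,sequence,state,exposure_s,uptake_da", tmp)
  expect_warning(rec <- read_uptake_table(tmp), "Empty")
  expect_equal(nrow(rec), 0)
})

test_that("a missing replicate column defaults to replicate 1", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("protein,start,end,sequence,state,exposure_s,uptake_da",
               "P1,1,10,GLSDGEWQLV,apo,30,2.0"), tmp)
  expect_equal(read_uptake_table(tmp)$replicate, 1L)
})

test_that("write/read round trip preserves all numeric fields", {
  sim <- simulate_hdx(hdx_design_two_state(noise_sd = 1), seed = 3)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_uptake_table(sim$records, tmp)
  back <- read_uptake_table(tmp)
  expect_equal(as.data.frame(back[names(sim$records)]),
               as.data.frame(sim$records), tolerance = 1e-12)
})

test_that("non-overlapping selection matches the exhaustive optimum", {
  # hand example: {1-10, 5-15, 16-20} -> {5-15, 16-20}, 16 residues
  p <- peptide_table("P1", c(1, 5, 16), c(10, 15, 20),
                     c(strrep("A", 10), strrep("A", 11), strrep("A", 5)))
  sel <- select_nonoverlapping(p)
  expect_equal(sel$start, c(5L, 16L))
  expect_equal(sum(sel$end - sel$start + 1), 16)

  # already non-overlapping sets come back unchanged; singletons survive
  p2 <- peptide_table("P1", c(1, 12), c(10, 20),
                      c(strrep("A", 10), strrep("A", 9)))
  expect_equal(select_nonoverlapping(p2)$start, c(1L, 12L))
  expect_equal(nrow(select_nonoverlapping(p2[1, ])), 1)

  # randomized sets of <= 8 peptides vs brute-force subset enumeration
  set.seed(101)
  for (i in 1:30) {
    n <- sample(2:8, 1)
    s <- sample(1:40, n, replace = TRUE)
    e <- s + sample(0:15, n, replace = TRUE)
    p <- peptide_table("P1", s, e, strrep("A", e - s + 1))
    sel <- select_nonoverlapping(p)
    expect_true(all(outer(seq_len(nrow(sel)), seq_len(nrow(sel)),
                          function(a, b) a >= b | sel$start[a] > sel$end[b] |
                            sel$end[a] < sel$start[b])))
    expect_equal(sum(sel$end - sel$start + 1),
                 brute_force_best_coverage(p$start, p$end))
  }
})

test_that("coverage counts the interval union and validates bounds", {
  p1 <- peptide_table("P1", 1, 50, strrep("A", 50))
  expect_equal(peptide_coverage(p1, 50), 1)
  p2 <- peptide_table("P1", c(1, 61), c(50, 162),
                      c(strrep("A", 50), strrep("A", 102)))
  expect_equal(peptide_coverage(p2, 162), 152 / 162)  # 50 + 102 residues
  expect_error(peptide_coverage(p2, 100), "past protein_length")
  # overlap is not double-counted
  p3 <- peptide_table("P1", c(1, 5), c(10, 12),
                      c(strrep("A", 10), strrep("A", 8)))
  expect_equal(peptide_coverage(p3, 20), 12 / 20)
})

test_that("selection never increases coverage", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    s <- sample(1:60, n, replace = TRUE)
    e <- pmin(s + sample(0:20, n, replace = TRUE), 80)
    p <- peptide_table("P1", s, e, strrep("A", e - s + 1))
    expect_lte(peptide_coverage(select_nonoverlapping(p), 80),
               peptide_coverage(p, 80))
  }
})

test_that("the nine-peptide myoglobin map covers 97% of the construct", {
  d <- hdx_design_myoglobin()
  expect_equal(peptide_coverage(d$peptides, d$protein_length), 0.97,
               tolerance = 0.005)
})
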