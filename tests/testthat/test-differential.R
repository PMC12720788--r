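make_sigma_records <- function(pairs) {
  # two peptides x one state x one timepoint, replicate values as given
  n <- length(pairs)
  tibble::tibble(
    protein = "P1",
    start = rep(seq_len(n), each = 2), end = rep(seq_len(n) + 9L, each = 2),
    sequence = rep(strrep("A", 10), 2 * n), state = "apo",
    exposure_s = 30, replicate = rep(1:2, n),
    n_exchangeable = 8L,
    relative_uptake_pct = unlist(pairs),
    uptake_da = unlist(pairs) * 8 / 100
  )
}

test_that("pooled sigma is the df-weighted root mean within-group variance", {
  expect_equal(pooled_sigma(make_sigma_records(list(c(10, 10), c(20, 20))))$sigma_pct, 0)
  ps <- pooled_sigma(make_sigma_records(list(c(10, 12), c(20, 26))))
  expect_equal(ps$sigma_pct, sqrt((2 + 18) / 2))  # pair variances 2 and 18
  expect_equal(ps$n_groups, 2L)
  expect_equal(ps$n_values, 4L)
  # raw mode pools values around the grand mean instead (includes signal)
  raw <- pooled_sigma(make_sigma_records(list(c(10, 12), c(20, 26))), "raw")
  expect_equal(raw$sigma_pct, sd(c(10, 12, 20, 26)))
  # single-replicate data cannot support a pooled estimate
  single <- make_sigma_records(list(c(10, 12)))[1, ]
  expect_error(pooled_sigma(single), "supply a sigma")
})

test_that("pooled sigma excludes time-zero groups", {
  r <- make_sigma_records(list(c(10, 12)))
  r0 <- r; r0$exposure_s <- 0; r0$relative_uptake_pct <- 0
  expect_equal(pooled_sigma(rbind(r, r0))$sigma_pct, sqrt(2))
})

test_that("pooled sigma recovers the injected noise level (slope 1)", {
  levels <- c(0.5, 1, 2, 4)
  est <- vapply(levels, function(ns) {
    mean(vapply(1:3, function(s) {
      pooled_sigma(simulate_hdx(hdx_design_two_state(noise_sd = ns),
                                seed = s)$records)$sigma_pct
    }, 0))
  }, 0)
  slope <- sum(est * levels) / sum(levels^2)  # regression through origin
  expect_equal(slope, 1, tolerance = 0.05)
})

test_that("Wood's table applies the threshold rule with strict inequality", {
  pep <- two_peptides()
  rec <- make_records(pep, c("A", "B"), c(0, 30, 90), n_rep = 2,
                      rel_uptake = function(start, state, time, rep) {
                        base <- 30
                        if (state == "B" && start == 1) base + 5
                        else if (state == "B") base - 2 else base
                      })
  w <- woods_table(rec, "A", "B", sigma = 3.1)
  expect_s3_class(w, "hdx_woods")
  w1 <- w[w$start == 1, ]
  expect_true(all(w1$delta_pct == 5))
  expect_true(all(w1$significant))
  expect_true(all(w1$direction == "more flexible"))
  w2 <- w[w$start == 11, ]
  expect_true(all(w2$delta_pct == -2))
  expect_false(any(w2$significant))
  expect_true(all(w2$direction == "unchanged"))
  # a difference exactly at the threshold is not significant
  wt <- woods_table(rec, "A", "B", sigma = 5)
  expect_false(any(wt$significant[wt$start == 1]))
  # time zero never enters
  expect_true(all(w$exposure_s > 0))
  expect_error(woods_table(rec, "A", "missing"), "missing")
})

test_that("Wood's tables are antisymmetric in the condition order", {
  sim <- simulate_hdx(hdx_design_two_state(noise_sd = 1), seed = 2)
  ab <- woods_table(sim$records, "ctrl", "perturbed", sigma = 1)
  ba <- woods_table(sim$records, "perturbed", "ctrl", sigma = 1)
  expect_equal(ab$delta_pct, -ba$delta_pct)
})

test_that("peptides in only one condition are reported, not silently dropped", {
  pep <- two_peptides()
  rec <- make_records(pep, c("A", "B"), c(0, 30, 90))
  rec <- rec[!(rec$state == "B" & rec$start == 11), ]
  expect_warning(w <- woods_table(rec, "A", "B", sigma = 1), "only one condition")
  expect_equal(nrow(attr(w, "missing_peptides")), 1)
  expect_equal(attr(w, "missing_peptides")$start, 11L)
})

test_that("significant_peptides honours the min_timepoints threshold", {
  pep <- two_peptides()[1, ]
  rec <- make_records(pep, c("A", "B"), c(0, 30, 90, 300, 1800),
                      rel_uptake = function(start, state, time, rep) {
                        30 + ifelse(state == "B" & time == 1800, 6, 0)
                      })
  w <- woods_table(rec, "A", "B", sigma = 3.1)
  expect_equal(nrow(significant_peptides(w, min_timepoints = 1)), 1)
  expect_equal(nrow(significant_peptides(w, min_timepoints = 2)), 0)
  none <- woods_table(rec, "A", "B", sigma = 100)
  expect_equal(nrow(significant_peptides(none)), 0)
})

test_that("mean_delta averages the Wood's-table entries for one peptide", {
  pep <- two_peptides()[1, ]
  rec <- make_records(pep, c("A", "B"), c(0, 100, 1000),
                      rel_uptake = function(start, state, time, rep) {
                        if (state == "B") 30 - ifelse(time == 100, 20, 16)
                        else 30
                      })
  w <- woods_table(rec, "A", "B", sigma = 3.1)
  expect_equal(mean_delta(w, 1, 10), -18)
  expect_error(mean_delta(w, 50, 60), "not present")
  single <- w[w$exposure_s == 100, ]
  expect_equal(mean_delta(single, 1, 10), -20)
})

test_that("null flagging at 1 sigma matches the Gaussian prediction", {
  # identical conditions, n_rep = 2: the replicate-mean difference has sd
  # sigma, so P(flag) = 2 * pnorm(-1) ~ 0.317 at the 1-sigma cutoff
  n_flag <- 0L; n_tot <- 0L
  for (s in 1:200) {
    sim <- simulate_hdx(hdx_design_two_state(effect_multiplier = 1,
                                             noise_sd = 0.5), seed = s)
    sig <- pooled_sigma(sim$records)
    w <- woods_table(sim$records, "ctrl", "perturbed", sigma = sig)
    n_flag <- n_flag + sum(w$significant)
    n_tot <- n_tot + nrow(w)
  }
  expect_gte(n_tot, 1e4)
  expected <- 2 * pnorm(-1)
  se <- sqrt(expected * (1 - expected) / n_tot)
  expect_lt(abs(n_flag / n_tot - expected), 3 * se)
})

test_that("flagging power is monotone in the true effect size", {
  mults <- c(1, 0.85, 0.7, 0.55, 0.4)
  rate <- vapply(mults, function(m) {
    flags <- vapply(1:20, function(s) {
      sim <- simulate_hdx(hdx_design_two_state(perturbed_peptides = 2,
                                               effect_multiplier = m,
                                               noise_sd = 0.5), seed = s)
      w <- woods_table(sim$records, "ctrl", "perturbed",
                       sigma = pooled_sigma(sim$records))
      mean(w$significant[w$start == 12])
    }, 0)
    mean(flags)
  }, 0)
  expect_true(all(diff(rate) >= -0.05))
  expect_gt(rate[length(rate)], rate[1])
})

test_that("a K_op-halved peptide is recovered as more rigid with nulls quiet", {
  hits <- 0L; null_flagged <- 0L; n_null <- 0L
  for (s in 1:100) {
    sim <- simulate_hdx(hdx_design_two_state(perturbed_peptides = 2,
                                             effect_multiplier = 0.5,
                                             noise_sd = 0.5), seed = 1000 + s)
    w <- woods_table(sim$records, "ctrl", "perturbed",
                     sigma = pooled_sigma(sim$records), multiplier = 2)
    sp <- significant_peptides(w, min_timepoints = 2)
    if (any(sp$start == 12 & sp$direction == "more rigid")) hits <- hits + 1L
    null_flagged <- null_flagged + sum(sp$start != 12)
    n_null <- n_null + 8L
  }
  expect_gte(hits / 100, 0.95)
  expect_gte(1 - null_flagged / n_null, 0.95)
})

test_that("the myoglobin design reproduces its calibrated -18% mean difference", {
  deltas <- vapply(1:10, function(s) {
    sim <- simulate_hdx(hdx_design_myoglobin(), seed = 200 + s)
    w <- woods_table(sim$records, "WT_apo", "MUT_apo",
                     sigma = pooled_sigma(sim$records))
    mean_delta(w[w$exposure_s %in% c(30, 90, 300, 1800), ], 12, 29)
  }, 0)
  expect_equal(mean(deltas), -18, tolerance = 0.1)  # relative: ~1.8% of 18
})
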