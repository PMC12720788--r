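# hdxdelta

Differential analysis of peptide-level hydrogen–deuterium exchange mass
spectrometry (HDX-MS) data, for structural biologists comparing protein
variants and ligand-bound states: which regions of a protein become more
flexible or more rigid when you mutate it or saturate it with a ligand, and
how fast do they exchange?

The package implements the standard comparative HDX workflow as a tidy,
fully tested pipeline:

* **Uptake tables** — readers/writers for long-format HDX summary tables
  (peptide × state × exposure × replicate), centroid-difference uptake with
  validation, exchangeable-amide accounting (first two residues and
  prolines excluded), maximum-coverage non-overlapping peptide selection,
  and sequence-coverage computation.
* **Wood's-plot statistics** — per-peptide, per-timepoint differential
  uptake ΔHDX% between two conditions, a pooled replicate-variability
  threshold σ (df-weighted root-mean within-group variance), strict
  |ΔHDX%| > m·σ significance calls with flexible/rigid direction, and
  time-averaged effect summaries.
* **Exchange kinetics** — one-exponential fits D(t) = A(1 − e^(−kt)) by
  bounded least squares with broom-style `tidy()`/`glance()`, rate reporting
  in s⁻¹ and min⁻¹, fast/intermediate/slow classification, rate-ratio
  comparisons, and EX2 back-calculation of the opening equilibrium
  K_op = k_HDX / k_int (protection factor 1/K_op).
* **Binding occupancy** — the quadratic 1:1 binding solution
  PI = ((P₀+I₀+K_D) − √((P₀+I₀+K_D)² − 4P₀I₀))/2 in a
  cancellation-safe form, its closed-form inverse for saturation planning,
  and bound/unbound mixture weights.
* **A ground-truth simulator** — residue-level Linderstrøm-Lang two-state
  exchange (closed ⇌ open → exchanged) solved in closed form across EX1/EX2
  regimes, validated against an independent event-driven stochastic
  sampler; condition effects as K_op multipliers; occupancy mixtures;
  Gaussian replicate noise; isotope-envelope diagnostics (unimodal EX2
  convolutions vs bimodal EX1 mixtures).

Everything returns tibbles, chains with the pipe, and plots via
`autoplot()` / `plot_*()`.

## Worked example

```r
library(hdxdelta)

# Will a 11.88-fold ligand excess saturate a K_D = 11.2 uM interaction?
complex_concentration(kd = 11.2, p0 = 100, i0 = 1188)
#> # A tibble: 1 × 3
#>      pi theta excess_fold
#>   <dbl> <dbl>       <dbl>
#> 1  99.0 0.990        11.9
```

θ ≈ 0.99: under the labeling conditions ~99% of protein molecules are
bound, so the holo dataset reports on the complex, not a mixture.

```r
# Reference study: 2 variants x 2 ligand states, 9 peptides, 7 timepoints,
# duplicates, 3.1% replicate noise, with known ground truth
design <- hdx_design_myoglobin()
report <- run_pipeline(design = design, seed = 1,
                       multiplier = 2, min_timepoints = 2)
report
#> Differential HDX-MS analysis report
#>   9 peptides, coverage 96.9%, 4 states, 7 timepoints, 2 replicates
#>   pooled sigma: 3.16% (from 216 replicate groups)
#>   contrast mutation_apo  : 5 significant peptide(s) [12-29 more rigid; 30-40 more rigid; 56-69 more flexible; 70-86 more flexible; 87-106 more flexible]
#>   contrast mutation_holo : 3 significant peptide(s) [12-29 more rigid; 56-69 more flexible; 130-159 more rigid]
#>   contrast binding_wt    : 1 significant peptide(s) [12-29 more flexible]
#>   contrast binding_mut   : 4 significant peptide(s) [12-29 more flexible; 30-40 more flexible; 41-55 more rigid; 70-86 more rigid]
```

The pooled σ (3.16%) recovers the injected 3.1% replicate noise; the
mutation contrast recovers the designed rigidified (12–29, 30–40) and
loosened (56–69, 70–86, 87–106) regions with correct directions.
(`multiplier = 2, min_timepoints = 2` is the benchmarking decision rule;
the default `multiplier = 1, min_timepoints = 1` mirrors how Wood's plots
are conventionally read and flags more entries by construction.)

```r
rec <- simulate_hdx(design, seed = 1)$records
fit <- fit_one_exponential(subset(rec, start == 56 & state == "MUT_apo"))
glance(fit)
#> # A tibble: 1 × 7
#>   amplitude  k_hdx k_hdx_per_min    se_k   sse n_points converged
#>       <dbl>  <dbl>         <dbl>   <dbl> <dbl>    <int> <lgl>    
#> 1      89.7 0.0486          2.91 0.00335  76.7       14 TRUE
```

Peptide 56–69 in the mutant apo state fits to k ≈ 0.049 s⁻¹ (2.9 min⁻¹)
against a ground-truth 0.0447 s⁻¹ at this noise level — an
intermediate-exchanging region (`rate_class(2.91)`), ~9-fold faster than
the same peptide's wild-type rate.

Plotting: `autoplot(report$woods$mutation_apo)` draws the Wood's plot with
dotted ±threshold lines; `autoplot(fit)` overlays the fitted curve on a
log-time axis; `export_structure_map()` writes per-residue mean ΔHDX% into
a PDB B-factor column for structure colouring.

See the vignette (`vignettes/differential-hdx-analysis.Rmd`) for the model,
threshold calibration, and what the simulator does and does not emulate.

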