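---
title: "Differential HDX-MS analysis: model, thresholds and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential HDX-MS analysis: model, thresholds and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxdelta)
```

## The measurement and the model

In a bottom-up hydrogen-deuterium exchange (HDX) MS experiment, a protein is
diluted into D~2~O buffer, quenched after a series of exposure times,
digested, and the centroid mass of each proteolytic peptide is compared with
its undeuterated value. The mass difference is the deuterium uptake; divided
by the number of exchangeable backbone amides it becomes relative uptake in
percent. The first two residues of a peptide and all prolines are not
observable (no retained amide label), so a peptide of length $L$ with $n_P$
prolines beyond position 2 carries $L - 2 - n_P$ exchangeable amides. This
denominator convention is configurable (`skip_n_term`) because vendors
differ; the package default is the dominant community choice.

Exchange at a structured amide follows the Linderstrøm-Lang two-state
scheme

$$\mathrm{closed} \underset{k_{close}}{\overset{k_{open}}{\rightleftharpoons}}
  \mathrm{open} \xrightarrow{k_{int}} \mathrm{exchanged},$$

whose unexchanged fraction is a two-exponential mixture of the chain's
eigenmodes. `exchange_probability()` evaluates this closed form exactly
(including irreversible opening, $k_{close}=0$, and the repeated-eigenvalue
boundary), using a subtraction-safe expression for the slow eigenvalue
$\lambda_{slow} = 2\,k_{open}k_{int}\,/\,(s + \sqrt{s^2 - 4\,k_{open}k_{int}})$
with $s = k_{open}+k_{close}+k_{int}$. In the EX2 regime
($k_{int} \ll k_{close}$: many opening/closing events per exchange) the
observed rate reduces to $k_{HDX} = K_{op}\,k_{int}$ with
$K_{op} = k_{open}/k_{close}$; in the EX1 regime
($k_{int} \gg k_{close}$) it approaches $k_{open}$. Both limits are tested
against the closed form, and the closed form itself is validated against an
independent event-driven sampler (`stochastic_exchange_fraction()`) that
draws a geometric number of openings and gamma waiting times per molecule —
an exact simulation of the chain, not a discretisation.

`simulate_envelope()` provides the spectral-regime diagnostic: independent
residues (EX2) give the Poisson-binomial convolution of per-residue
probabilities — unimodal, centroid equal to the summed probabilities — while
a correlated block opening on one shared clock (EX1) gives a bimodal mixture
with weights $e^{-k_{open}t}$ and $1-e^{-k_{open}t}$. The EX1 construction
is deliberately minimal (point masses at 0 and $n$ deuterons): it is a
regime caricature for diagnostics, not a model of real EX1 spectra.

## Differential analysis: the Wood's-plot threshold

For a contrast of two conditions, `woods_table()` computes per peptide and
non-zero timepoint the replicate-averaged difference in relative uptake,
$\Delta\mathrm{HDX}\% = \bar{u}_B - \bar{u}_A$, and flags entries whose
absolute value strictly exceeds a multiple of the pooled replicate
variability $\sigma$. `pooled_sigma()` estimates $\sigma$ as the
df-weighted root-mean within-group replicate variance over all
(peptide, state, time) groups. The phrase "standard deviation of the pooled
distribution" admits a second reading — the SD of all raw values around
their grand mean — but that mixes between-peptide signal into a noise
estimate and cannot represent workflow variability, so `"pooled-within"` is
the default and `"raw"` is retained only for comparison.

The null behaviour of this rule is fully analytic under the package's noise
model: with duplicate measurements and homoscedastic Gaussian noise of sd
$\sigma$ on relative uptake, each replicate mean has variance $\sigma^2/2$,
the difference has sd $\sigma$, and the flag probability of a true-null
entry at the $1\sigma$ cutoff is $2\Phi(-1) \approx 31.7\%$. The test suite
verifies this to within three binomial standard errors over more than
10^4^ simulated entries. This is also why the *peptide-level benchmark* in
the test suite uses a stricter decision rule (threshold multiplier 2,
significance required at $\ge 2$ timepoints): with a 31.7% per-entry null
rate, a six-timepoint peptide would be falsely flagged about 90% of the
time at the $1\sigma$/1-timepoint setting, so no rule that mirrors the
plotting convention alone can deliver high specificity. The package
*defaults* remain the plotting convention (multiplier 1, one timepoint),
because that is how Wood's plots are conventionally read; the stricter rule
is a choice made for ground-truth benchmarking and is exposed through the
`multiplier` and `min_timepoints` arguments. Ties at exactly the threshold
are not significant. No multiple-testing correction is applied by default,
mirroring standard fixed-threshold practice; a Bonferroni-style multiplier
can be passed explicitly.

## Uptake kinetics

`fit_one_exponential()` fits $D(t) = A\,(1 - e^{-kt})$ by bounded
Levenberg-Marquardt least squares ($k \in (10^{-6}, 10)$ s^-1^,
$A \in (0, 1.2\,\max D]$), replicates entering as individual points with
uniform weight and $t=0$ included as an exact anchor. Initialisation uses
$A_0 = \max D$ and $k_0 = \ln 2 / t_{1/2}$ with $t_{1/2}$ the earliest time
reaching $A_0/2$. Because the $t=0$ anchors carry no noise, residual
degrees of freedom for standard errors are counted over the non-zero
timepoints only; without that correction the $\pm 2$SE comparison interval
of `compare_fits()` is anti-conservative. The plateau is free by default
(peptide-level fits, where back-exchange and incomplete labeling depress
the plateau); rates are reported in both s^-1^ and min^-1^
($\times 60$ exactly) and classed fast / intermediate / slow at 10 and
0.05 min^-1^ — conventional boundaries, exposed as arguments, not measured
quantities. `kop_from_ex2()` inverts $k_{HDX} = K_{op} k_{int}$ and rejects
$k_{HDX} > k_{int}$ as an EX2-regime violation; $k_{open}$ and $k_{close}$
are not separately identifiable from peptide uptake data and are not
fitted.

## Binding occupancy

`complex_concentration()` solves the 1:1 quadratic mass balance
$[PI] = \tfrac{1}{2}\big(P_0 + I_0 + K_D - \sqrt{(P_0+I_0+K_D)^2 - 4P_0I_0}\big)$
in the algebraically equivalent form $2P_0I_0/(P_0+I_0+K_D+\sqrt{\cdot})$,
which avoids catastrophic cancellation when $4P_0I_0 \ll (P_0+I_0+K_D)^2$.
At the labeling conditions used for a micromolar-affinity substrate analog
($K_D = 11.2$, $P_0 = 100$, $I_0 = 1188$, all µM) the occupancy is
$\theta \approx 0.99$, which is why holo-state simulations default to a
99:1 bound/unbound mixture. `ligand_for_occupancy()` inverts the relation
in closed form, $I_0 = \theta P_0 + \theta K_D/(1-\theta)$.

## What the simulator emulates — and what it does not

`hdx_design_myoglobin()` is the package's reference study: a 162-residue
His-tagged myoglobin-like construct (the sequence is a synthetic stand-in;
only its length, peptide boundaries and proline positions matter), nine
non-overlapping peptides covering 97% of the sequence, four conditions
(wild-type-like and triple-mutant variants, each apo and analog-bound),
seven exposure times (0, 30, 90, 300, 1800, 3600, 5400 s) and duplicate
measurements. Ground-truth effects are encoded as per-region $K_{op}$
multipliers applied to $k_{open}$ with $k_{close}$ fixed — the minimal
mechanism by which a mutation or ligand changes EX2 uptake:

* peptide 56–69 exchanges at 0.0052 s^-1^ (WT apo), 0.0447 s^-1^ (mutant
  apo), 0.0046 and 0.0263 s^-1^ in the bound states — region-level rates
  taken as the design's kinetic ground truth;
* peptides 12–29 and 30–40 are rigidified in the mutant apo state to
  time-averaged uptake differences of −18% and −13% (averaged over the
  four plotted timepoints 30–1800 s), with `kop_multiplier_for_delta()`
  solving the required multiplier at design construction;
* the flexible regions (41–55, 70–86, 87–106) are loosened to +6%;
  ligand binding restores the mutant's perturbed regions to baseline, and
  loosens WT 12–29 by +6%.

Replicate noise is Gaussian on relative uptake, homoscedastic across
timepoints, with default sd 3.1% (a typical pooled workflow variability for
a bottom-up HDX platform); the labeling buffer is 90% D~2~O (a 1:9 dilution
into 99% D~2~O). All residues sit deep in EX2 ($k_{int}=10$ s^-1^,
$k_{close}=5000$ s^-1^), so the slow eigenvalue is within ~1% of
$K_{op}k_{int}$ throughout.

Features of real data the simulator does *not* emulate — so passing tests
bound what simulation can show, not what real data will do: back-exchange
during quench/LC (a constant-loss hook exists but defaults to off),
heteroscedastic or time-correlated noise, within-peptide rate dispersion
(residues in a region share parameters, making peptide curves exactly
one-exponential), carryover, overlapping-peptide redundancy, and intrinsic
rates derived from sequence/pH/temperature chemistry ($k_{int}$ is supplied,
not predicted).

## Numerical and design choices

* Negative uptake between −0.1 Da and 0 is clipped to zero with a warning;
  below −0.1 Da it is a data error and rejected.
* `select_nonoverlapping()` solves the maximum-coverage non-overlapping
  subset exactly (weighted interval scheduling DP, leftmost tie-break) —
  a greedy-by-length pass is not optimal on crossing interval patterns.
* One integer seed drives every stochastic draw of a simulated dataset;
  equal seeds give bit-identical tables and the caller's RNG stream is
  restored afterwards.
* Problem sizes in the validation suite — 200-seed benchmarks, 10^5^
  molecules for the stochastic oracle, 27-point rate grids — were chosen as
  the smallest designs whose Monte-Carlo error is well below the tolerances
  being checked (3 binomial SE margins throughout).

## Worked example

```{r example, eval = FALSE}
design <- hdx_design_myoglobin()
report <- run_pipeline(design = design, seed = 1)
report
autoplot(report$woods$mutation_apo)

rec <- simulate_hdx(design, seed = 1)$records
fit <- fit_one_exponential(subset(rec, start == 56 & state == "MUT_apo"))
glance(fit)
```

The same objects export to disk via `write_report()` and map onto a
structure via `export_structure_map()` (mean ΔHDX% into the PDB B-factor
column, −99.9 sentinel for uncovered residues).
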