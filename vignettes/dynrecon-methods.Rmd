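---
title: "Dynamic network reconfiguration with dynrecon: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic network reconfiguration with dynrecon: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynrecon)
```

## The problem

Resting-state fMRI yields, per subject, a matrix of ROI time series.  A
functional atlas assigns each ROI to one of a small number of canonical
networks (default mode, basal ganglia, medial frontal, ...).  The question
`dynrecon` addresses is how these predefined networks *reconfigure over
time*: whether the ROIs of a network stay together in data-driven
communities as the connectivity pattern evolves (recruitment), and how
often they co-assemble with ROIs of other networks (integration) — and
whether those quantities differ between a case and a control group across
acquisition sites.

The pipeline is:

1. **Sliding windows.** The `T`-timepoint series is cut into windows of
   length 20 TR stepping by 10 TR (50% overlap); trailing timepoints not
   filling a window are dropped.  Within each window, pairwise Pearson
   correlation gives one `K x K` layer; negative correlations are set to 0
   (their interpretation as edges is unclear) and the diagonal is zeroed.
2. **Multilayer community detection.** The layer stack is coupled
   ordinally — each node is linked to itself in adjacent layers with
   weight `omega` — and the multilayer modularity

   $$Q = \frac{1}{2\mu}\sum_{ijlr}\Big[(A_{ijl} - \gamma_l V_{ijl})\,
   \delta_{lr} + \delta_{ij}\,\omega_{jlr}\Big]\,\delta(g_{il}, g_{jr})$$

   is maximized over community assignments \(g\) by a generalized Louvain
   procedure.  \(V_{ijl} = k_{il}k_{jl}/2m_l\) is the per-layer
   Newman–Girvan configuration null, \(\gamma_l\) the structural and
   \(\omega\) the temporal resolution, and
   \(2\mu = \sum_l 2m_l + 2\omega K(L-1)\) the total intra- plus
   interlayer weight.
3. **Allegiance.** Because the optimizer is stochastic, it is run
   `n_runs = 100` times; the module-allegiance matrix \(P_{ij}\) is the
   relative frequency, over layers and runs, that nodes \(i\) and \(j\)
   share a community.
4. **Recruitment / integration.** For node \(i\) in network \(N\) of size
   \(m_N\): \(R_i = \frac{1}{m_N}\sum_{j \in N} P_{ij}\) and
   \(I_i = \frac{1}{K - m_N}\sum_{j \notin N} P_{ij}\).  Network-level
   values are unweighted means over the network's ROIs; pairwise network
   integration is the mean allegiance over cross-network node pairs.  With
   9 networks this yields the 45 parameters (9 recruitment + 36
   integration) carried into inference.
5. **Harmonization.** Parametric empirical-Bayes batch adjustment
   (ComBat) removes per-site location/scale effects from the 45-parameter
   table while protecting the diagnosis effect.
6. **Inference.** Independent-sample *t*-tests per parameter with
   Benjamini–Hochberg FDR over the joint family of 45 (`q <= 0.05`),
   exploratory ROI-level follow-up at uncorrected `p < 0.001`,
   age-stratified re-analysis, and an independent-cohort replication
   protocol.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window_length` | 20 TR | stationarity/resolution trade-off of dynamic connectivity |
| `window_step` | 10 TR | 50% overlap between contiguous windows |
| `gamma` | 1 | structural resolution; larger values favor smaller communities |
| `omega` | 0.4 | interlayer coupling; larger values persist labels through time (robustness variant: 1) |
| `n_runs` | 100 | optimizer repetitions averaged into the allegiance matrix |
| `q_threshold` | 0.05 | FDR level over the 45 network-level tests |
| `roi_p_threshold` | 0.001 | uncorrected ROI-level follow-up threshold |
| `age_bins` | 7, 12, 18, 25 | strata \([7,12)\), \([12,18)\), \([18,25]\) years |

Whether the 45 parameters are computed by averaging allegiance matrices
and then applying the recruitment/integration formulas, or by averaging
per-run metrics, is immaterial: both formulas are linear in \(P\), so the
two orders of aggregation coincide exactly (this identity is tested).

## The synthetic-cohort generator

Real multi-site cohorts are out of scope; `cohort_spec()` /
`generate_cohort()` produce a stated world with known ground truth:

* **Piecewise-stationary states.** Time is divided into equal blocks of
  `state_length` (default 40) timepoints.  Within a state each node
  belongs to one latent community; its home community is its functional
  network.  Equal-length states match the sliding-window estimator's
  assumptions and give exact per-state ground truth.
* **Detachment.** With probability `p_detach[group, network]` a node
  spends the state in one uniformly chosen foreign community — the
  simplest mechanism that lowers recruitment and raises specific pairwise
  integration.  The reference effect used by the power suite is
  `p_detach(case, DMN) = 0.4` vs `0.1` elsewhere (baseline 0.1 for both
  groups in all networks).
* **Correlation structure.** Nodes of one community share a latent signal
  so their correlation is `rho_in` (default 0.8) before observation noise
  (`noise_sd = 0.3`), which attenuates the realized within-community
  correlation to roughly `rho_in / (1 + noise_sd^2)` ≈ 0.73 — strong
  enough for reliable community recovery at window length 20, weak enough
  to leave estimation noise in the metrics.
* **Site effects** are per-node affine maps (shift `0.3·(s-1)`, scale
  `1 + 0.15·(s-1)`).  Pearson correlation is invariant to per-node affine
  maps, so these effects deliberately do *not* confound community
  detection; they model the batch structure that harmonization of derived
  metrics removes.  Harmonization's own acceptance test plants offsets
  directly on the metric table, where site effects on derived coefficients
  actually live.
* **Defaults** are a desk-scale world: 9 networks × 5 nodes (45 ROIs),
  `T = 200`, 30 subjects/group, 2 sites, ages uniform on [7, 25] per
  group so every age bin is occupied.  `T = 200` is a free default, not a
  claim about any public dataset.

What a green test does **not** establish: the generator has no
hemodynamics, motion, spatial autocorrelation, heavy-tailed noise or
site-by-covariate interactions, and its community dynamics are block
stationary.  Green means the estimator chain recovers the statistical
structure it assumes, at the stated sizes — not that it is robust to real
fMRI artefacts.

## Numerical choices

* **Louvain moves** are accepted only on strict gain (`> 1e-12`) with the
  visit order randomized per sweep; ties keep the first candidate in the
  randomized order.  Strictness guarantees termination under floating
  point.  After local convergence, communities are aggregated and the
  procedure recurses until no improving move exists.
* **Supra-matrix representation.** The optimizer's hot path works on the
  block-sparse structure (dense intralayer blocks + regular couplings);
  a dense multilevel path handles aggregated levels.  A test pins the two
  paths to the same attained quality on random instances.
* **Diagonal convention.** The intralayer null term at \(i = j\) is kept
  in \(Q\); it is constant in the partition (so the argmax is unchanged)
  and makes \(Q = 0\) exact for the single-layer one-community case.  The
  connectivity diagonal itself is zeroed before detection — self-edges
  carry no information in modularity.  The source convention is not
  stated; this choice is flagged, not attributed.
* **Seeding.** One master seed drives everything: subject `i` of a cohort
  uses a deterministic sub-seed, and optimizer run `r` uses sub-stream
  `(seed, r)` in the compiled core, so full runs are bit-reproducible
  (and verified so by checksum in the acceptance suite).
* **BH rejection** uses `q <= threshold`, the standard step-up rule (the
  strict form contradicts the worked four-rejection example).
* **ComBat** standardizes with an `n`-denominator pooled variance and,
  deliberately, an `n_b`-denominator (MLE) per-batch scale: with matching
  denominators a covariate-free adjustment is exactly idempotent, which
  the reference `n_b − 1` convention misses by a \(\sqrt{(n-B)/n}\)
  rescaling.  The EB location/scale posteriors are solved by iterated
  conditional modes to relative tolerance `1e-4` (max 100 iterations).
  Constant features pass through with a warning; a single batch returns
  the input unchanged.
* **Degenerate inputs.** A zero-variance column inside any window is an
  error naming the window and node; an all-zero network yields \(Q = 0\)
  and singleton communities; a partition whose single network contains
  every node makes integration undefined and errors.

## Design choices where the design was open

* **Pairwise network integration** is not given a formula in the source
  convention; it is declared here as the mean allegiance over
  cross-network node pairs — the only definition consistent with both the
  node-level integration formula and the 36-pair count.  The weighted
  identity \(\sum_{M \neq N} m_M I^{N,M} / (K - m_N) = \operatorname{mean}_{i \in N} I_i\)
  is enforced to `1e-12`.
* **Recruitment includes the self term** (\(j = i\), \(P_{ii} = 1\)), as
  the formula literally reads; it contributes a \(1/m_N\) floor.
* **Pooled-variance t-tests** by default (Welch behind a flag): plain
  "independent sample t-tests" reads as the classical pooled form.
* **ROI follow-up** is explicitly uncorrected and reported as
  exploratory localization, mirroring its role as a descriptive adjunct
  to the corrected network-level family.
* **Harmonization is applied to the derived 45-parameter table**, not to
  time series or edges, with diagnosis as the only protected covariate by
  default and an `harmonize_age` flag for the age-retaining variant.
* **Calibration suite scale.** The 500-replicate null calibration keeps
  the default 30 subjects/group — the t-test's finite-sample calibration
  on bounded, mildly skewed metrics is part of what the suite measures,
  and at much smaller n the two-sided test is visibly anti-conservative —
  but runs a reduced partition (27 nodes), `T = 100` and `n_runs = 5` to
  fit a single-CPU budget: under the null the group labels are
  exchangeable whatever those sizes, so they do not affect the rejection
  rate being compared to nominal.  The power suite runs at the stated
  `n = 30`/group, `T = 200`, `n_runs = 25`.

## Known limitations

* The multilayer optimizer is greedy; global optimality is only verified
  against brute force on small instances (the acceptance oracle).
* No tapered windows, coherence/wavelet connectivity, negative-weight
  modularity, categorical (all-to-all) coupling, Leiden refinement, or
  nonparametric/GAM harmonization variants.
* The pipeline starts from extracted ROI time series; no imaging
  preprocessing of any kind is performed or emulated.
* Stage outputs are verified by manifest checksums but not resumed from
  partial runs; at desk scale rerunning is cheaper than caching.

## A worked miniature

```{r toy, eval = FALSE}
part <- toy_partition(3)
spec <- cohort_spec(n_per_group = 5, n_sites = 2, n_timepoints = 100,
                    state_length = 25, partition = part,
                    p_detach = planted_detach(part, 0.1, "DMN", 0.5),
                    seed = 1)
dir <- tempfile()
write_cohort(generate_cohort(spec), spec, dir)
res <- run_pipeline(run_config(n_runs = 10L, seed = 1L), dir)
subset(res$results, reject,
       select = c(metric_type, network_1, network_2, t, q))
```

Every number shown in the README is produced by exactly this code path;
the vignette states no empirical result that the tests or the acceptance
script do not themselves compute.
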