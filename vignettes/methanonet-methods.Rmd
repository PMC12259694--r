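---
title: "Methods: from methanogen communities to methane production potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from methanogen communities to methane production potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methanonet)
```

## The scientific problem

Wetland soils are the largest natural source of atmospheric methane, and the
archaea that produce it can be profiled cheaply by sequencing the *mcrA*
marker gene (the terminal enzyme of all methanogenesis pathways). A standing
question is how much of a soil's methane production *potential* — the rate
measured when a soil slurry is incubated anaerobically in the laboratory
(PMPR, ng CH4 g^-1 dry soil day^-1) — is explained by *biotic* structure
(methanogen abundance, diversity, community composition, and the density of
co-occurrence relationships among taxa) versus *abiotic* soil chemistry.

`methanonet` implements that analysis chain as reusable, tested components:

1. **flux** — PMPR from two-time-point headspace CH4 measurements;
2. **community** — count-table hygiene, rarefaction, diversity, Bray–Curtis
   ordination, PERMANOVA, forward-selected db-RDA, PCA, ANOVA/Tukey letters;
3. **network** — thresholded Spearman co-occurrence networks, ten topological
   properties, a per-sample complexity index, Zi–Pi keystone roles;
4. **linkage** — regressions, random-forest importance, variation
   partitioning, and PLS path modeling;
5. **synth** — a generator of complete synthetic datasets with planted,
   recoverable ground truth, so every downstream stage can be verified.

## The flux equation

A vial's headspace contains `n = PA * VH / (R * T_K)` moles of gas (ideal gas
law at the incubation temperature `T_K = T_ST + T`). If the CH4 mixing ratio
changes by `dc/dt` (mole fraction per day), the production rate per gram dry
soil is

```
PMPR = (dc/dt) * MM * (VH * PA) / (R * (T_ST + T)) / Ws
```

converted to ng per gram per day. Because kPa·L = J, using `PA` in kPa and
`VH` in litres cancels exactly against `R` in J mol^-1 K^-1. The function is
linear in `dc/dt` and `VH`, inverse-linear in `Ws`, and decreasing in `T`
(warmer headspace means fewer moles per unit mixing ratio) — all asserted
numerically in the test suite. `batch_pmpr()` averages the three replicate
vials per sample and optionally subtracts an N2-only blank; whether blank
subtraction is applied is a policy flag (`"auto"` by default) because assay
protocols differ on it.

## Community processing

ASVs with fewer than 10 reads *summed over the whole dataset* are removed
("fewer than 10" is strict; an ASV with exactly 10 reads stays). All samples
are then rarefied without replacement to a common depth (default 1,016 reads,
a typical lowest-depth value for *mcrA* amplicon libraries); rarefaction is
seeded and therefore reproducible. Shannon diversity uses the natural
logarithm (the ecology convention). Bray–Curtis, PERMANOVA (Anderson's
pseudo-F with label permutations) and distance-based RDA follow the standard
vegan formulations; forward selection adds, at each step, the candidate
environmental term with the largest additional constrained inertia whose
marginal permutation p-value (conditioned on the already-selected terms) is
at most `alpha`. Negative principal-coordinate eigenvalues are left
uncorrected and this is recorded in the result, since CAP implementations
differ on Lingoes/Cailliez corrections. The community-composition index is a
PCA of centered relative abundances (no unit scaling, so abundant ASVs carry
their actual variance).

## Co-occurrence networks

Edges join ASV pairs whose Spearman correlation satisfies `|rho| > 0.6` and
`p < 0.01` (both strict; a correlation of exactly 0.6 is not an edge).
Correlations are computed on relative abundances; ASVs present in fewer than
20% of samples are excluded first, because rank correlations between
mostly-zero vectors are spurious. P-values use the t approximation with
n − 2 degrees of freedom. No multiple-testing correction is applied at the
edge filter by default (the raw-p convention of correlation-threshold
networks); a Benjamini–Hochberg option exists behind a flag. Networks are
undirected — correlation is symmetric, so a directed representation would be
an artifact of the drawing tool, not of the statistic.

Ten topological properties summarize a network: node count NN, edge count
NE, connectance, average degree AD = 2·NE/NN, global clustering coefficient
GCC (transitivity), average local clustering ACC (nodes of degree < 2
contribute 0), average neighborhood connectivity AN (mean over nodes of the
mean degree of their neighbors), average degree centrality ADC = AD/(NN−1),
Freeman degree centralization DC = Σ(kmax − ki)/((NN−1)(NN−2)), and the
number of positive edges. AN and ADC are ambiguous labels in parts of the
literature; the definitions above are the ones this package commits to, and
every metric is verified against an independent naive double-loop
implementation on random graphs. Graphs with fewer than three nodes return
0 for GCC, ACC and DC by convention, flagged in the output.

**Per-sample complexity.** Each sample induces a subnetwork on the ASVs it
actually contains; the ten properties of that subnetwork are min–max
standardized across all samples, `(x − min)/(max − min)`, and averaged with
equal weights into a complexity index in [0, 1]. The index is invariant to
affine rescaling of any raw metric, and the extreme samples attain exactly
0 and 1 per metric. Standardization pools all samples by default
(a per-habitat pooling can be had by running the chain per site).

**Keystones.** Modules are detected by greedy modularity maximization
(deterministic for a given graph; the method is recorded). Zi is the
within-module degree z-score, Pi the participation coefficient
`1 − Σ_s (k_is/k_i)²`, and nodes are classified by the conventional
thresholds (2.5 / 0.62), with boundary values falling in the "≤" class.
A geometric note: with a hard `|rho| > 0.6` edge filter and statistically
independent modules, *connectors* (Pi > 0.62) are nearly impossible to plant
in Gaussian synthetic data — a node would need correlation above the
threshold with three or more mutually independent factors, which the
correlation budget (Σ loadings² ≤ 1) forbids. Planted keystones in the
generator are therefore *module hubs* (star-like modules), and the
recovery test targets those.

## Linkage statistics

Simple regressions report both the Pearson correlation on the (optionally
log10) transformed scale and the Spearman correlation on the raw scale —
field figures mix the two conventions, so both are returned, labeled.
Random-forest importance is the percent increase in out-of-bag MSE under
feature permutation, with significance from refitting the forest on permuted
responses (distribution-free, reproducible under a seed). Variation
partitioning uses adjusted R²: pure fractions are differences against the
combined model, the shared fraction is the inclusion–exclusion remainder,
and the four fractions sum to one by construction; individual fractions may
be slightly negative (an adjusted-R² artifact) and are reported unclipped
with a clipped display copy.

**PLS path modeling** is implemented in full rather than wrapped: reflective
(mode A) outer weighting, centroid inner scheme by default (factorial behind
a flag), alternating until the maximum outer-weight change falls below 1e-6
(at most 300 iterations, with an informative error and iteration trace on
non-convergence). Path coefficients are per-endogenous-block least squares
on the standardized latent scores; indirect effects are sums of products
along directed chains; bootstrap resampling of rows yields percentile 95%
intervals, and stars mark paths whose 95/99/99.9% intervals exclude zero
(the star rule is a package convention). The goodness of fit is
`GoF = sqrt(mean communality × mean R²)`. Latent score signs are fixed so
each block correlates positively with its indicators on balance. With a
single indicator per block the model provably collapses to Pearson
correlations, which the tests assert exactly.

The default seven-block model mirrors the field design: Nutrition {TOC, TN},
Non-nutrition {pH, EC}, Abundance {log10 mcrA}, Diversity {richness,
Shannon}, Community {PC1, PC2}, Complexity {complexity index}, and CH4
{PMPR}, with soil blocks feeding the biotic blocks and all six feeding CH4.
The Community block uses PC1+PC2 by default with a `community_pc = "pc1"`
switch, since published variants of this model disagree on whether the
second component belongs in the block.

## The synthetic-data generator

The generator emulates the *post-bioinformatics* state of a wetland survey:
4 sites × 8 plots × 4 depth layers (128 samples; a `n_dropped` flag can
remove 7 to mimic failed libraries), 300 ASVs, multinomial counts at a
jittered depth of ~2,000 reads (never below 1,016), site-specific dominant
ASVs, soil chemistry drawn per site around means contrasting mineral and
peatland wetlands, and log10 *mcrA* abundances spanning the 1.6–2.0 window.

Correlation structure uses a Gaussian copula: each sample draws one latent
factor per module; module members load on their factor and the latents map
through log-normal quantiles (rank-preserving) to expected relative
abundances before multinomial sampling. Counts are therefore realistically
over-dispersed while the planted rank correlations remain analytically
known. Each 10-member module combines two tiers:

* **core** members (median relative abundance 1.8%, sdlog 1.0) with the
  exchangeable within-module correlation `rho = 0.75` — these carry the
  recoverable edges;
* **conditionally rare "satellite"** members (median 0.18%, sdlog 1.5,
  loading 0.95 on the module factor) that hover at the detection limit — a
  sample's satellite occupancy tracks its module activity.

The mean of the module factors is the planted *complexity driver*: samples
with active modules contain more satellites, hence larger and denser
subnetworks, hence a higher measured complexity index. The satellite tier's
elevated loading is deliberate: with the exchangeable loading alone the
occupancy signal is too weak for the measured complexity to recover the
driver (pilot correlation ≈ 0.25 versus ≈ 0.67 with the tier), which would
make the complexity limb of the model unverifiable.

PMPR is a known linear model on three standardized drivers,
`0.80·z(log10 mcrA) + 0.60·z(TOC,TN) + 0.58·z(complexity driver) + N(0, 0.25)`,
mapped to a realistic scale (200 ± 80 ng g^-1 d^-1). The effect sizes were
fixed once by an a-priori power analysis: large-to-medium standardized
effects in the order abundance > nutrition > complexity, sized so that at
n = 128 the weakest (complexity, further attenuated by its network
measurement channel to an observable marginal correlation near 0.32) is
detectable in ≈98% of replicate datasets and the path ordering is preserved
in ≈95%. Incubation records are *reverse-engineered* from each sample's
PMPR (three identical replicates plus a zero-change N2 blank, 0.115 L
headspace, 67 kPa — a high-plateau atmospheric pressure — 25 °C, days 1 and
15), so the flux module and the generator check each other: `batch_pmpr()`
must reproduce the planted rates to floating-point accuracy.

What the generator does **not** emulate: taxonomy, phylogeny, chimeric or
frameshifted reads, depth-specific community structure (depth layers share
their site's structure, as pooled-depth analyses assume), spatial
autocorrelation between plots, and negative co-occurrence (planted
correlations are positive; negative edges arise only from sampling noise).
Passing tests therefore demonstrate that the *chain of estimators* recovers
known structure through realistic count noise — not that any particular
field system behaves this way.

## Numerical choices and problem sizes

* Spearman p-values: t approximation (n − 2 df); tests cross-check the rank
  formula directly, including ties.
* PERMANOVA p-values: `(1 + #{F* ≥ F}) / (1 + n_perm)`; the test suite
  verifies the pseudo-F against brute-force enumeration and vegan's
  `adonis2`, nominal type-I error over 1,000 null datasets, and uniformity
  of the null p-value distribution.
* Pipeline seeds: one global seed fans out as
  `(seed·1009 + utf8 sum of stage name) mod (2^31 − 1)`, so any stage can be
  re-run in isolation.
* Min–max standardization with a zero-range metric: that metric contributes
  0 and is flagged rather than dropped, keeping the index a mean over a
  fixed set of ten metrics.
* Tie-breaks in the Tukey letter display: letters are maximal cliques of the
  non-significance graph, ordered by descending group mean.
* Test problem sizes: topology oracle on 50 random graphs (≤ 25 nodes);
  PERMANOVA calibration on 1,000 null datasets of 20 samples with 99
  permutations; edge recovery on 20 replicate datasets; full-chain recovery
  on 100 replicate datasets; bootstrap coverage on 200 replicates with 200
  resamples. These sizes make the whole suite run in a few minutes on one
  CPU while keeping Monte-Carlo error well inside the asserted bounds.

## Known limitations

* The complexity index inherits the arbitrariness of equal weighting; two of
  its ten metrics (connectance, clustering) can *fall* as sparse nodes join
  a subnetwork, partially offsetting the size metrics.
* Percentile bootstrap intervals undercover slightly at small n (a known
  property); coverage is asserted at n = 100.
* `forward_select_dbrda` tests each candidate conditioned on the selected
  terms without family-wise correction, as is conventional; with many pure
  noise candidates the selection-wise false-positive rate grows accordingly.
* PLS-PM estimates are attenuated by indicator noise; the synthetic recovery
  tolerances account for this, but users comparing path coefficients across
  datasets with different measurement error should expect the same effect.
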