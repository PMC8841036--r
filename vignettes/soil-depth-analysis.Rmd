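---
title: "Methods: depth- and time-structured soil microbiome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth- and time-structured soil microbiome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`microdepth` implements the downstream statistics used to ask how soil
prokaryotic communities are structured by soil depth and sampling time in a
replicated field design (plots x sampling occasions x soil layers, with
layers labelled S/M/D for surface, middle and deep). The substrate is a
samples x ASVs table of amplicon read counts plus sample metadata, an
optional taxonomy table and an optional soil physicochemical table.
Upstream read processing (denoising, chimera removal, taxonomic
assignment) is out of scope: the package starts at the count table.

This vignette records the models, the parameters that matter, the design
choices made where the design was genuinely open, and what the synthetic
generator does and does not emulate.

# The analysis stages

## Rarefaction and the rare/abundant partition

Rarefaction draws, per sample, a multivariate hypergeometric subsample of
exactly `depth` reads (sampling without replacement), dropping samples
whose total is below the target with a warning. Rarefying a sample to its
own total is the identity.

Rare and abundant taxa are defined on **dataset-total** relative abundance
— the ASV's reads over the grand total — not per-sample abundance: rare
strictly below 0.01% (`rare_threshold = 1e-4`), abundant strictly above
0.1% (`abundant_threshold = 1e-3`), intermediate otherwise. The partition
is exhaustive and exclusive by construction. Per-sample rare proportions
are then the share of a sample's observed richness, and of its reads,
carried by rare-class ASVs.

## Layer enrichment (ternary classification)

The classification of ASVs as enriched in one layer is not pinned to a
single canonical test in the literature; this package uses, per ASV, a
Kruskal-Wallis test of per-sample relative abundance across the three
layers, Benjamini-Hochberg correction across ASVs, and — when
q < 0.05 — assignment to the layer with the highest mean relative
abundance. ASVs with identical relative abundance in every sample are
assigned p = 1 directly rather than passing a zero-variance vector to the
test. Mean relative abundances per layer, normalised to sum to one, are
emitted as ternary-plot coordinates. An optional `times` argument
restricts the test to a subset of sampling occasions; no claim is made
that this matches any particular published stratification.

## Alpha diversity and ANOVA

Richness S is the count of ASVs with reads, Shannon entropy H uses the
natural log, and Pielou evenness is J = H / ln S (undefined and flagged
when S <= 1; J = 1 exactly for a uniform community). The two-way ANOVA
(layer, time, interaction) is **balanced-only**: with equal replication
the Type I/III ambiguity vanishes, so unbalanced input is rejected with a
pointer to permutation-based alternatives rather than silently
re-weighted. Post-hoc pairwise comparisons use Tukey's HSD — the package's
own choice of post-hoc procedure — whose two-group case reduces to the
pooled t-test.

## Fertility index and random-forest drivers

The soil fertility index is the per-sample sum of z-scores (taken across
all samples) of six nutrient variables: TC, TN, DOC, DON, NH4-N, NO3-N.
It has cohort mean zero by construction and is invariant to affine
rescaling of any input variable, so units never matter. A nutrient with
zero variance is an error, not a silent drop.

Random-forest driver analysis fits a regression forest (defaults:
500 trees, mtry = ceiling(p/3), the standard regression rule) and reports
permutation importance (% increase in MSE). Significance is calibrated by
refitting the forest on permuted copies of the **response**:

P = (1 + #{null importance >= observed}) / (1 + n_permutations).

Because each null draw refits a full forest, the default number of
response permutations is 99 (a separate knob from the 999 distance-matrix
permutations); the estimator is exact-in-expectation at any permutation
count, and the +1 convention keeps P in (0, 1].

## Distance-based ordination and tests

Bray-Curtis dissimilarity, PCoA, PERMANOVA and the Mantel test are
implemented from first principles on the distance matrix:

* d(x, y) = 1 - 2 sum(min(x_i, y_i)) / (sum x + sum y), in [0, 1].
* PCoA: Gower double-centering of -d^2/2, eigendecomposition, coordinates
  = eigenvectors scaled by the square root of the positive eigenvalues.
  Negative eigenvalues (the non-Euclidean share of Bray-Curtis) are
  reported, **not** corrected: Lingoes/Cailliez corrections alter
  coordinates silently, whereas reporting makes the non-Euclidean share
  visible. The trace identity (sum of eigenvalues = sum of squared
  distances / n) is tested.
* PERMANOVA uses sequential (Type I) sums of squares read off traces of
  hat-matrix projections of the centered Gower matrix, pseudo-F =
  (SS_term/df_term)/(SS_resid/df_resid), and free permutation of sample
  labels, P = (1 + #{F_perm >= F_obs}) / (1 + n_permutations). Terms enter
  in formula order (default layer, time, interaction), mirroring
  conventional sequential behaviour; no plot-restricted permutation is
  offered. A permuted relabelling that merely reshuffles within groups
  reproduces the observed F exactly in exact arithmetic, so the
  exceedance comparison allows a 1e-8 relative slack — without it,
  floating-point noise of order 1e-16 silently discards true ties and
  biases P downward.
* Mantel correlates strictly-upper-triangle entries and permutes the
  second matrix's rows and columns simultaneously, one-sided (greater).
  Zero off-diagonal variance is flagged as degenerate rather than
  producing a spurious correlation.

A single-level factor term contributes zero additional rank and is
reported with SS = 0 and r-squared = 0; a term genuinely confounded with
earlier terms (two or more levels but no rank gain) is an error.

## Co-occurrence networks and node roles

Per layer, candidate ASVs must have subset relative abundance strictly
above 0.5% **and** occur in strictly more than half the subset's samples.
Spearman correlations (average ranks for ties; two-sided P from the
t-approximation with n - 2 df) are thresholded: an undirected edge is kept
iff |rho| >= 0.8 and the BH-adjusted p <= 0.001. The absolute-value
reading is deliberate: thresholding signed rho would forbid the negative
links the analysis is meant to count. Edge sign is the sign of rho;
isolated nodes are excluded. A flag allows gating on raw p for
sensitivity analysis.

Modules come from greedy modularity maximisation on the unweighted,
unsigned graph (signed community detection is unstandardised). The merge
tree is cut at the modularity maximum explicitly, because the stock cut
can be suboptimal on degenerate graphs (a single clique's optimal
partition is one community at Q = 0). Per node, Zi is the within-module
degree z-score (defined as 0 when the module has fewer than 3 members or
zero spread — a z-score against no variation is meaningless) and Pi is
the participation coefficient 1 - sum_t (k_it/k_i)^2. Role thresholds
default to Zi = 2.5 and Pi = 0.62, the established module-role
convention; "keystone" is reported as any non-peripheral node, with the
full role breakdown emitted so stricter readings (hubs only) remain
recoverable. "Connectedness" is ambiguous in the field's tables, so both
connectance 2E/(N(N-1)) and the largest-component fraction are emitted.

## Functional-group mapping

Function assignment uses a deliberately miniature rules format: a
two-column TSV mapping `rank:Name` patterns (exact, case-insensitive — no
silent regex surprises) to functional-group labels. A taxon may feed
several groups and a group may aggregate several taxa; no normalisation
is applied across groups, matching how rule databases in this field
attribute reads. The packaged `function_rules.tsv` covers the functions
relevant to rare-taxon ecology (sulfate and iron respiration,
phototrophy, nitrogen fixation, cellulolysis, dark hydrogen oxidation,
methanogenesis, nitrification, fermentation). The full FAPROTAX database,
with its boolean rule language, is intentionally out of scope; only the
mechanism is reproduced. Attribution tables report, per group, the
percentage of reads contributed by each taxon at a chosen rank; the
percentages close to 100 within every group with reads. Unclassified
proportions are tallied per rank — this package's own convention.

# The synthetic generator

`simulate_dataset()` produces data with the statistical structure the
analysis assumes, so that every stage is testable without any sequencing
deposit:

* **Design**: `n_plots` x `n_times` x 3 layers (defaults 6 x 4 x 3 = 72
  samples), with plot as a random intercept on latent log-abundance
  (`plot_sd = 0.1`) — supporting the repeated-plots design without
  modelling spatial structure.
* **Species-abundance distribution**: log-normal with shape
  `sad_sigma = 2`, giving the strong rare-taxa skew of real soil surveys
  (many more rare than abundant ASVs at 2000 ASVs).
* **Effects** are multiplicative on latent (pre-multinomial) abundances,
  keeping compositional closure and making fold-change the single
  effect-size unit: a fraction of ASVs gets a `depth_effect` fold-change
  in a preferred layer (default 4-fold on 10%), and analogously for
  time (default 0 = no temporal effect, the regime the analysis is built
  to detect against). Effects are planted only on ASVs whose expected
  per-sample count is at least ~10 reads: an effect planted on an ASV
  that never appears in realised counts is unobservable by construction,
  so eligibility is restricted to realisable ASVs.
* **Planted modules**: member ASVs share a per-sample latent factor.
  `module_strength` is defined as the **target correlation** of members'
  latent log-abundances (the factor loading is its square root); the
  default 0.9 yields networks whose planted blocks survive the 0.8 edge
  gate. Module members' base abundances are boosted to ~1.5% each so they
  pass the network abundance filter.
* **Noise**: idiosyncratic latent log-noise with `latent_noise_sd = 0.5`
  — a realistic replicate-level overdispersion for amplicon data that
  leaves an 8-fold planted shift clearly detectable at 8 samples per
  layer.
* **Soil**: nutrient variables with additive depth gradients, a shared
  per-sample latent fertility factor that also loads on a designated set
  of ASVs (so the fertility-index/random-forest stage has a real signal),
  and a clay/silt/sand composition closing to 100.
* **Counts** are one multinomial draw of `library_size` reads per sample
  (default 50,000 — a desk-scale library, far below real survey depths).

What the generator does **not** emulate: sequence-level error and
chimeras, spatial autocorrelation among plots, taxon-specific copy-number
variation, overdispersion beyond the log-normal latent (no
Dirichlet-multinomial layer), and real phylogenetic structure (taxonomy
strings come from a fixed toy lineage pool that includes designated rare
phyla so phylum summaries and function mapping are exercised). Passing
tests therefore demonstrate the statistical machinery is correct and
calibrated under the assumed data-generating process — not that any
particular field result will reproduce.

# Numerical and testing choices

* All threshold comparisons in filters and classes are strict, matching
  their definitions; boundary cases are tested explicitly.
* Every function taking a `seed` restores the caller's RNG state, so
  results are reproducible per call. The pipeline derives per-stage
  sub-seeds as global seed + stage index, making stages re-runnable in
  isolation.
* Calibration and recovery tests run at reduced problem sizes chosen as
  the package's own test scale: 500 ASVs at 10,000 reads for null
  calibration (200 replicates) and depth-effect recovery (50
  replicates), 400 ASVs at 50,000 reads for enrichment recovery, 300
  ASVs at 20,000 reads over 20 seeds for module recovery, with 99-199
  permutations where only the rejection decision is needed.
* The acceptance script runs the full default-scale pipeline (72 samples,
  2000 ASVs, 50,000 reads, 999 permutations) and reports its headline
  quantities.

# Known limitations

* PERMANOVA offers free permutation only; plot-restricted permutation
  schemes are out of scope.
* Correlations are plain Spearman on relative counts; compositionality-
  aware estimators (SparCC and relatives) are out of scope, and at the
  0.8/0.001 gates compositional artefacts are unlikely to create edges
  but can attenuate true ones.
* The balanced-only ANOVA is a feature for this design but means missing
  samples (e.g. dropped by rarefaction) disable that stage rather than
  degrade it silently.
* The miniature rules format cannot express FAPROTAX's boolean logic
  (e.g. "genus A unless species B").
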