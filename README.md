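# microdepth

Downstream statistical analysis of depth- and time-structured soil
prokaryotic communities from 16S ASV count tables.

Soil microbial surveys in agroecosystems increasingly sample below the
plough layer and across seasons, asking whether community structure is
governed by soil depth, by sampling time, or both — and what the many rare
taxa contribute to soil function. `microdepth` packages the statistics such
a survey needs once reads have been denoised into a samples × ASVs count
table:

* **Rarefaction** (exact without-replacement subsampling) and
  **rare/abundant partitioning** on dataset-total relative abundance
  (rare < 0.01 %, abundant > 0.1 %), with per-sample rare richness/read
  proportions and layer-enrichment (ternary) classification.
* **Alpha diversity** — richness *S*, Shannon *H* (natural log), Pielou
  *J* = *H*/ln *S* — with balanced two-way ANOVA (layer × time) and Tukey
  post-hoc comparisons.
* A **soil fertility index** (per-sample sum of z-scores of TC, TN, DOC,
  DON, NH4-N, NO3-N) and **random-forest driver analysis** with
  response-permutation significance,
  *P* = (1 + #{null ≥ observed}) / (1 + *n*<sub>perm</sub>).
* **Beta diversity from first principles**: Bray–Curtis
  *d* = 1 − 2Σmin(*x*, *y*)/(Σ*x* + Σ*y*); PCoA via Gower double-centering
  of −*d*²/2 (negative eigenvalues reported, not corrected); sequential
  **PERMANOVA** with pseudo-*F* and label permutation; the **Mantel test**.
* **Co-occurrence networks** per soil layer: abundance (> 0.5 %) and
  occurrence (> 50 %) filters, Spearman correlations, BH-FDR, edges at
  |ρ| ≥ 0.8 and *q* ≤ 0.001, topology metrics, greedy-modularity modules,
  and **Zi–Pi node roles** (module hubs, connectors, network hubs =
  keystones; thresholds Zi 2.5, Pi 0.62).
* **Functional-group mapping** through a miniature FAPROTAX-style rules
  file, with per-taxon attribution percentages per group.
* A **synthetic-data generator** emulating the plots × times × depths
  design — log-normal abundance distribution, multiplicative layer/time
  effects, planted correlation modules, nutrient depth gradients and a
  latent fertility factor — so the whole pipeline is testable end to end,
  plus `run_pipeline()` to orchestrate every stage from one configuration.

See `vignettes/soil-depth-analysis.Rmd` for the full methods account.

## Worked example

```r
library(microdepth)

sim <- simulation_params(n_asvs = 800, library_size = 20000, seed = 42)
ds  <- simulate_dataset(sim)          # 72 samples: 6 plots x 4 times x 3 layers

d  <- bray_curtis(ds$counts)
permanova(d, ds$metadata, n_permutations = 999, seed = 42)
#> PERMANOVA (999 permutations)
#>        term df     SS      MS       F     r2     P
#>       layer  2 1.7980 0.89900 17.5400 0.3351 0.001
#>        time  3 0.1300 0.04334  0.8457 0.0242 0.690
#>  layer:time  6 0.3631 0.06052  1.1810 0.0677 0.131
#>   Residuals 60 3.0750 0.05124      NA 0.5730    NA
#>       Total 71 5.3660      NA      NA 1.0000    NA
```

The simulated 4-fold depth effect on 10 % of ASVs shows up as a strong,
significant layer term (r² = 0.34, P = 0.001) while the null temporal
effect stays non-significant — the qualitative pattern this analysis is
designed to detect.

```r
head(alpha_diversity(ds$counts), 3)
#>   sample_id   S        H         J evenness_defined
#> 1   P1_T1_S 525 4.400644 0.7025968             TRUE
#> 2   P2_T1_S 556 4.617284 0.7304942             TRUE
#> 3   P3_T1_S 564 4.460777 0.7041419             TRUE

table(classify_abundance(ds$counts)$class)
#>     abundant intermediate         rare
#>          155          274          371
```

Rare ASVs (here 371 of 800) outnumber abundant ones, the heavy-tailed
regime the rare-biosphere statistics assume. A per-layer network:

```r
samp <- ds$metadata$sample_id[ds$metadata$layer == "S"]
f    <- filter_for_network(ds$counts, samples = samp)
sp   <- spearman_matrix(f)
net  <- build_network(sp$rho, sp$p)
net
#> Co-occurrence network: 28 nodes, 55 edges ( 55 positive / 0 negative )

topo <- zi_pi(net, detect_modules(net, seed = 1))
table(topo$role)
#> peripheral
#>         28
```

The 28 surviving abundant ASVs split into the planted correlation modules;
no node exceeds the Zi/Pi role thresholds in this small example, so all
are peripheral (no keystones).

`run_pipeline(analysis_config(seed = 1), "out/", sim_params = simulation_params(seed = 1))`
runs every stage (rarefy → partition → alpha/beta → fertility/RF →
networks → functions) and writes result TSVs plus a JSON run report; a
thin command-line wrapper lives at `inst/scripts/microdepth.R`.

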