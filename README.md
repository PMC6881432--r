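# phasecore

Core transcriptional signatures of locust phase change from heterogeneous
bulk RNA-seq designs.

The migratory locust switches between solitary and gregarious phenotypes
("phases") with population density. The transcriptome datasets that bear on
this switch — developmental stages, tissue panels, and
gregarization/solitarization time courses — are dominated by their nuisance
axis (stage, tissue, time point), so ordinary PCA cannot separate phases.
`phasecore` is for researchers who need to extract a phase (or any
condition) signature from such confounded multi-design collections:

* **AC-PCA** — confounding-adjusted PCA. For unit loadings *v* it maximizes
  `v'X'Xv − λ · Σ_g Σ_{i∈g} ((x_i − x̄_g)·v)²`, captured variance minus the
  within-replicate-group scatter of the sample scores, with λ tuned on a grid
  until the residual scatter falls below tolerance. Phase is predicted for
  new samples by the sign of the projection on PC1.
* **Directional Borda aggregation** — per-dataset PC1 rankings are combined
  by median rank, once gregarious-top and once solitary-top, interleaved into
  one directional list; the top 10% is the *PhaseCore* set. Validation by
  leave-one-sample-out and cross-dataset prediction over gene bins.
* **Gene features** — specificity index τ, CpG observed/expected, gene-body
  methylation (≥ 19 CG sites), topological-overlap connectivity, and the
  Audic–Claverie no-replicate test with BH adjustment.
* **Ensemble TRN** — six network scorers (CLR, ARACNE with DPI pruning,
  signed TOM, random-forest importance, shrinkage partial correlation,
  K-means/BIC module scores) aggregated by Borda into a TF→target network
  with promiscuous-target filtering; *PhaseCoreTFs* are TFs whose targets are
  over-represented in the PhaseCore set (hypergeometric, BH, ≥ 3 overlapping
  targets).
* **P_greg** — the logistic behavior classifier
  `P_greg = e^η/(1+e^η)`, `η = −2.11 + 0.005·AI + 0.012·TDM + 0.015·TDMV`.
* **Synthetic studies** — a generator that emulates the three designs with
  planted core genes, a planted TF network, sequences, methylation tables and
  behavior records, so every stage is testable end to end.

## Worked example

```r
library(phasecore)

study <- simulate_studies(simulation_config(seed = 1))
study
#> synthetic_study: 2000 genes (50 TFs), 200 planted core genes
#>   development: 12 samples
#>   tissue: 16 samples
#>   timecourse: 24 samples

kinds <- c(development = "development", tissue = "tissue",
           timecourse = "timecourse")
models <- lapply(names(study$datasets), function(nm) {
  ds <- rpkm(study$datasets[[nm]])
  x  <- log_quantile_center(ds)
  design <- build_confounder_design(ds$samples, kinds[[nm]])
  fit_acpca(x, design, lambda = 20, phase = ds$samples$phase)
})
models[[1]]
#> acpca_model: 2000 genes, 2 components, lambda = 20
#>   variance explained: 0.00733, 0.0036

borda <- directional_borda(models)
head(borda, 4)
#>   gene_id direction rank
#> 1  g01023         G    1
#> 2  g01854         S    2
#> 3  g00279         G    3
#> 4  g00905         S    4

core <- select_core(borda, fraction = 0.10)
mean(study$truth_core$gene_id %in% core)
#> [1] 0.875
```

PC1 explains little *total* variance (0.7% here) because the confounder
dominates the matrix — yet its score sign classifies every sample's phase,
which is exactly the point of the adjustment. The directional list alternates
gregarious- and solitary-biased genes from the top, and the top-10% PhaseCore
set recovers 87.5% of the planted phase-biased genes.

The behavior classifier is a plain closed form:

```r
pgreg(100, 100, 0.41 / 0.015)   # eta solves to exactly 0
#> [1] 0.5
```

See `vignette("phasecore-methods")` for the model, its assumptions, every
tunable default, and what the synthetic generator does and does not emulate.
A thin command-line wrapper over the same functions is installed at
`inst/cli/phasecore.R` (subcommands `simulate`, `preprocess`, `acpca`,
`rank`, `behavior`).

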