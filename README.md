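# viscage

Age-trajectory analysis of the visceral adipose transcriptome, and the
predicted adipose-to-liver ligand–receptor connectome.

Visceral (omental) adipose tissue is drained by the portal vein directly
into the liver, so age-driven changes in its secretome are a plausible
lever on hepatic metabolism. `viscage` implements, as a tested R pipeline,
the analysis chain needed to study this from bulk RNA-seq counts of a
sex × ordered-age-group cohort:

1. **Differential expression vs a common youngest reference.** For each sex
   and each age group *g* ≥ 30–39, a moderated two-sample test against the
   20–29 reference on log₁₀(CPM + 1):

   t<sub>g</sub> = (x̄₂ − x̄₁) / √( s̃² (1/n₁ + 1/n₂) ),  with
   s̃² = (d₀s₀² + d s²)/(d₀ + d)

   where the prior (d₀, s₀²) is fitted empirically by matching the first
   two moments of log s² to the scaled log-F distribution (trigamma
   inversion by monotone root-finding), p-values are taken on d₀ + d df,
   BH-FDR is applied within each contrast, and a gene is significant at
   FDR < 0.05 with linear fold change ≥ 2 in either direction.
2. **Trajectory clustering.** Union DEGs are averaged per age group,
   row-z-scored (population sd), and clustered by Euclidean k-means
   (K = 11, k-means++ seeding, 50 restarts). Clusters whose centroid is
   monotone across the six age decades (Spearman |ρ| ≥ 0.9 against the
   group index) are *gradient clusters*; per sex, each member gene's
   trajectory is min–max normalized to [0, 1], averaged, and compared
   between sexes via the ratio of trapezoidal AUCs.
3. **Cell-type signatures.** A rank-based single-sample score (mean
   normalized rank of signature genes − ½) and a post-ANOVA linear trend
   contrast across age groups, per sex.
4. **Enrichment.** Local hypergeometric over-representation analysis of
   gene lists against GMT collections with BH-FDR and −log₁₀(FDR) scores.
5. **Networks.** Eigenvector centrality (power iteration, per connected
   component, max-normalized) on a supplied gene–gene edge list.
6. **Connectome.** A ligand qualifies when it (i) shows ≥ 25 TPM in at
   least 25 % of adipose samples (bounds inclusive), (ii) is annotated as
   blood-secreted, (iii) sits in a gradient cluster, and (iv) has an
   interaction partner passing the same expression filter in liver; every
   qualifying (ligand, receptor) pair becomes a connectome edge.

TMM scaling factors, CPM/TPM transforms, strict TSV/GMT readers and
deterministic writers are included. A negative binomial simulator
(`simulate_study()`) generates the whole study with planted ground truth —
trajectory templates, a SASP panel, cell-type mixing trends, and a
ligand/receptor wiring with single-filter decoys — so every stage is
testable end to end without external data.

## Worked example

```r
library(viscage)

cfg <- sim_config(seed = 42)        # default planted study conditions
sim <- simulate_study(cfg)
res <- run_pipeline(sim)

length(unique(res$de$gene[res$de$significant & res$de$sex == "male"]))
#> [1] 492
length(unique(res$de$gene[res$de$significant & res$de$sex == "female"]))
#> [1] 468

subset(res$clusters$gradient, gradient)
#>   cluster        rho gradient  direction
#> 1       A -1.0000000     TRUE decreasing
#> 2       B  1.0000000     TRUE increasing
#> 3       C -1.0000000     TRUE decreasing
#> 4       D -1.0000000     TRUE decreasing
#> 8       H  0.9428571     TRUE increasing

head(res$connectome[, c("ligand", "receptor", "ligand_cluster",
                        "ligand_direction", "ligand_median_tpm")], 4)
#>   ligand receptor ligand_cluster ligand_direction ligand_median_tpm
#> 1 G00001   G00441              A       decreasing          428.8830
#> 2 G00001   G00447              A       decreasing          428.8830
#> 3 G00002   G00445              A       decreasing          443.6142
#> 4 G00041   G00442              D       decreasing          275.7875

res$trends[res$trends$sex == "male",
           c("cell_type", "direction", "t", "p", "significant")]
#>      cell_type direction         t             p significant
#> 1    adipocyte      down -37.00484 5.340592e-100        TRUE
#> 2 preadipocyte      down -27.20017  1.498290e-74        TRUE
#> 3   fibroblast        up  32.99080  3.631032e-90        TRUE
#> 4        tcell        up  23.00874  4.027615e-62        TRUE
```

What these numbers mean: 492/468 genes pass the per-sex FDR + fold-change
gate in at least one age contrast (the planted template, marker and decoy
genes plus a handful of borderline calls). Five of the eleven clusters are
flagged as gradients — the four planted monotone templates plus the
cell-type markers, which drift monotonically by construction. The
connectome edges are exactly the planted secreted-ligand → liver-receptor
wiring (decreasing adipokine-like ligands and one increasing inflammatory
ligand); the decoys, each violating exactly one filter, are excluded. The
trend tests recover the planted mixing-trend direction for all four cell
types. Because the female trajectory onset is planted one age group later
than the male one, decreasing clusters show a male/female AUC ratio below
1 (e.g. cluster A: 0.82).

Inputs can equally come from files: `read_counts()`,
`read_sample_table()`, `read_gmt()`, `read_annotation()`,
`read_interactions()`, `read_edge_list()`; `write_study()` and
`write_pipeline()` emit every artifact as deterministic TSV.

See `vignettes/viscage-methods.Rmd` for the model, parameter and design
documentation.

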