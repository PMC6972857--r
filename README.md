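# fflnet

Co-regulation analysis for two-group expression studies: transcription
factor (TF) and microRNA (miRNA) regulation pairs, coherent TF–miRNA–gene
feed-forward loops (FFLs), subtype-specific regulatory networks with hub
detection, and FFL-based sample classification.  Written for analysts who
have paired mRNA/miRNA log2 expression matrices for a cohort split into two
groups (e.g. two tumour subtypes) plus candidate regulator–target pair
lists, and want the full chain from differential expression to classified
regulatory motifs in one tested toolchain.

## The method in brief

1. **Filter** genes (log2 < 1 in more than half the samples) and miRNAs
   (missing in >10% of samples, or log2 > 3.46 in no more than 10%).
2. **Differential expression** between the two groups with an
   empirical-Bayes moderated t: per-feature pooled variance s² (df d) shrunk
   toward a moment-fitted prior (d₀, s₀²),

   t = (x̄₁ − x̄₂) / ( s̃ √(1/n₁+1/n₂) ),  s̃² = (d₀s₀² + d s²)/(d₀ + d),

   two-sided p on d₀+d df, BH-adjusted; called at |log2FC| ≥ 1 and
   adjusted p < 0.05.
3. **Priors**: miRNA–target pairs kept when supported by ≥2 of the supplied
   databases; TF pairs from a promoter-scan list; everything restricted to
   DE features.
4. **Edges**: Pearson r per prior with p from t = r√((n−2)/(1−r²)); kept at
   p < 0.05 (optional |r| threshold); TF edges signed activation/repression,
   miRNA edges repression only (r < 0).
5. **FFLs** in three coherent categories — TRF (TF activates miRNA,
   represses gene), TAF (TF represses miRNA, activates gene), MRF (miRNA
   represses TF; TF activates gene) — with miRNA repressing the gene in all
   three.
6. **Network**: union of FFL edges; degrees, local clustering, hubs = top
   20% by out- or in-degree (ties included).  Hypergeometric upper-tail
   test (log-space) for count enrichment.
7. **Classification**: each top FFL (ranked by Σ|r| of its edges) is a
   3-feature random forest evaluated by stratified 10-fold CV × 10 repeats;
   sensitivity, specificity, precision, accuracy and fold-averaged AUC.

A seeded synthetic-data generator plants DE features, signed couplings and
ground-truth FFLs of all three categories so the entire pipeline can be
validated against a known truth manifest.  See the methods vignette
(`vignettes/ffl-methods.Rmd`) for model details and design rationale.

## Worked example

```r
library(fflnet)

sim <- simulate_dataset(simulation_config(seed = 1))   # 48 + 55 samples
res <- run_ffl_pipeline(sim$mrna, sim$mirna, sim$sheet, sim$pairs,
                        group = "NSE")                 # within-group edges
res$network
#> <regulatory_network> 90 nodes (30 TFs, 30 miRNAs, 30 genes), 90 links, mean degree 2.0

truth_recovery_report(sim$truth, res$ffls)
#>  category n_planted n_called n_recovered recall precision
#>       TRF        10       10          10      1         1
#>       TAF        10       10          10      1         1
#>       MRF        10       10          10      1         1
#>   overall        30       30          30      1         1

top <- rank_ffls(res$ffls, k = 1)
top[, c("tf_id", "mirna_id", "gene_id", "category", "score")]
#>   tf_id mirna_id gene_id category    score
#> 1 TF009  miR-009   G0009      TRF 2.836408
#> 2 TF016  miR-016   G0016      TAF 2.786406
#> 3 TF022  miR-022   G0022      MRF 2.735989

evaluate_ffl_table(top[1, ], sim$mrna, sim$mirna, sim$sheet, seed = 2)
#>   tf_id mirna_id gene_id category sensitivity specificity precision  accuracy       auc
#> 1 TF009  miR-009   G0009      TRF      0.6255   0.7526667 0.6882857 0.6940404 0.7509333
```

All 30 planted FFLs are recovered with no false calls, and the top-ranked
TRF — at the generator's default 2 log2-unit group shift against a 1.5-sd
background — classifies the two groups well above chance (accuracy 0.69,
AUC 0.75) but far from perfectly; near-perfect classification requires the
separable regime (tiny coupling noise, large shift), as discussed in the
vignette.

File-based workflows use `read_expression_matrix()`, `read_sample_sheet()`,
`read_pair_list()` (tab-separated), `write_network()` (SIF, GraphML, edge
TSV) and `write_ffl_table()`.

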