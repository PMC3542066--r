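# phosvar

Analysis of **phosphorylation variability across the cell cycle as a
function of structural context**. Given a table of phospho-sites with
six normalized SILAC phosphorylation ratios (cell-cycle phases G1,
G1/S, early S, late S, G2, M), protein sequences, and per-residue
secondary-structure (PsiPred `.ss2`), disorder (DISOPRED `.diso`) and
evolutionary-rate (rate4site) predictions, `phosvar`:

1. computes each site's **variability** — the sample standard deviation
   of its phase ratios, `v = sd(r_G1, …, r_M)` — and the completeness
   filters defining the analysis set;
2. merges structure and disorder calls into **regular** (helix/sheet,
   ordered), **irregular** (coil, ordered) and **disordered** (coil,
   disordered) site categories and compares the variability
   distributions (Kolmogorov–Smirnov for the two-level ordered vs
   disordered split, one-way ANOVA across the three levels);
3. runs **two-sample-logo** and composition-profile statistics on the
   ±6-residue flanking windows of low- vs high-variability sites;
4. tests enrichment of **proximal multi-phosphorylation** in disordered
   regions (Fisher's exact test with the conditional-MLE odds ratio, at
   neighbor distances 1–5);
5. places kinase recognition motifs in a rank-based **2D enrichment**
   space with coordinates in [−1, 1] per dimension,
   `s = 2(meanRank_members − (n+1)/2)/(n − m)`, over (variability,
   disorder), with Benjamini–Hochberg control across motifs;
6. compares **evolutionary rates** of phospho-sites against control
   S/T/Y residues of the same proteins, stratified by structural
   background (Mann–Whitney–Wilcoxon).

A calibrated synthetic-data generator (`simulate_dataset()`) emulates
all inputs jointly — class-conditional ratio variance, neighbor
clustering, motif planting, conservation structure — so the whole
pipeline is testable without running any external predictor. It is
intended for phosphoproteomics and structural-bioinformatics
researchers who want these analyses reusable on their own site tables.

## Worked example

```r
library(phosvar)

sim <- simulate_dataset(sim_config(seed = 1))   # or read_site_table()/read_fasta()/...
analysis   <- add_variability(filter_complete(sim$sites, min_timepoints = 6))
classified <- classify_sites(analysis, sim$profiles)

cmp <- compare_category_variability(classified)
cmp$by_category3
#>     category    n median
#> 1    REGULAR  147   1.64
#> 2  IRREGULAR  359   1.82
#> 3 DISORDERED 4667   2.22

neighbor_enrichment(classified, w = 1:5)[, c("w", "odds_ratio", "p_value")]
#>   w odds_ratio  p_value
#> 1 1       1.42 9.76e-02
#> 2 2       1.95 1.79e-05
#> 3 3       1.73 1.80e-05
#> 4 4       1.71 2.03e-06
#> 5 5       1.71 2.03e-06
```

The medians show variability rising with the level of structural
disorder (regular < irregular < disordered; here the planted 1.65 /
1.83 / 2.22), and the odds ratios show sites with a neighboring
phospho-site within `w` residues are consistently enriched in
disordered regions (planted odds ratio 1.9 at `w = 4`, recovered within
its confidence interval).

`run_pipeline()` chains every stage — variability, classification,
category comparison, two-sample logo, neighbor enrichment, 2D motif
enrichment, conservation — and writes a results directory
(`classified.tsv`, `summary.tsv`, `logo.tsv`, `table1.tsv`,
`enrich2d.tsv`, `cons.tsv`, a run log and a config snapshot). See the
methods vignette (`vignettes/phosvar-methods.Rmd`) for the model,
parameter and design documentation.

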