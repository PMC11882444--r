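# bescan

Analysis toolkit for **base editor scanning**: pooled screens that
tile a coding gene with cytidine/adenosine base-editor sgRNAs (SpG,
`NG` PAM), sort cells on a phenotype, and read out per-sgRNA
enrichment to map which residues of a protein a function depends on.

The package covers the whole desk-side workflow:

* **Gene models** — a genomic segment plus exon/CDS structure with
  coordinate mapping and translation (`gene_model()`,
  `map_position()`).
* **Library design** — enumeration of all windowed `NG`-PAM guides
  over exons ± 30 bp, `TTTT` exclusion, non-targeting and intergenic
  controls (`enumerate_guides()`, `attach_controls()`), and residue
  coverage reporting (`residue_coverage()`).
* **Outcome prediction** — deterministic conversion of every editable
  window base (CBE C→T, ABE A→G), retranslation, and six-class
  assignment with priority nonsense > missense > silent >
  UTR-intronic > non-editing > negative control
  (`annotate_library()`).
* **Enrichment scoring** — `log2(1 + RPM)`, plasmid normalization,
  replicate averaging, sorted − unsorted, non-targeting centring, and
  ±4 s.d. hit calling against negative controls (`score_screen()`).
* **Linear clustering** — the per-residue statistic: LOESS with span
  `20/L` (fraction of data points, tricube weights, no robustifying
  iterations), quadratic-spline interpolation to residues `1..L`, a
  score-shuffling permutation null with one-sided add-one empirical
  p-values, Benjamini–Hochberg FDR, and contiguous cluster calling
  (`residue_clustering()`).
* **Assay models** — the exact quadratic binding isotherm

  `AB = ((A_T + B_T + K_D) − √((A_T + B_T + K_D)² − 4·A_T·B_T)) / 2`

  and a K_D fitter built on it, four-parameter logistic dose–response
  fits, TR-FRET 520/490 ratios, geometric-mean reporter stability
  scores, and constrained exponential decay (`bound_complex()`,
  `fit_kd()`, `fit_4pl()`, `trfret_ratio()`, `reporter_score()`,
  `fit_decay()`), with broom-style `tidy()`/`glance()`/`augment()`
  methods and `autoplot()` views.
* **Synthetic screens** — a generator with planted residue hotspots
  and negative-binomial counts so every stage is verifiable against
  known ground truth (`simulate_screen_dataset()`,
  `evaluate_recovery()`).

Everything takes and returns tibbles and composes with the pipe; flat
files are plain TSV/FASTA/JSON (see `run_screen_pipeline()` for the
one-call version that writes every artefact).

## Worked example

Simulate a 200-residue gene with a planted 15-residue hotspot
(residues 90–104, effect 2 log2 units), score the screen, and run the
clustering statistic:

```r
library(bescan)

cfg <- sim_config(L = 200, hotspots = list(c(90L, 104L)), seed = 42)
ds  <- simulate_screen_dataset(cfg)
ds$model
#> <gene_model> simgene: 713 nt segment, 2 exon(s), strand +, protein 200 aa

scored <- score_screen(ds$counts, ds$sample_sheet, ds$library)
attr(scored, "thresholds")
#> # A tibble: 1 × 7
#>   control_category       k control_mean control_sd lower upper n_controls
#>   <chr>              <dbl>        <dbl>      <dbl> <dbl> <dbl>      <int>
#> 1 intergenic_control     4      -0.0197      0.286 -1.16  1.12         50

tr <- residue_clustering(scored, ds$model$L,
                         clustering_config(n_perm = 1000, seed = 42))
clusters(tr)
#> # A tibble: 1 × 4
#>   start_res end_res width min_p_adj
#>       <int>   <int> <int>     <dbl>
#> 1        89     105    17    0.0118

evaluate_recovery(clusters(tr), ds$hotspot_residues, ds$model$L)
#> # A tibble: 1 × 3
#>   sensitivity residue_fpr n_cluster_residues
#>         <dbl>       <dbl>              <int>
#> 1           1      0.0108                 17
```

The single called cluster (residues 89–105) recovers the planted
hotspot: 15 enriched missense guides push the smoothed track above
every permutation at those positions, the BH-adjusted empirical
p-values drop below 0.05, and the cluster boundary lands within one
smoothing bandwidth of the truth. `plot_guide_scores(scored)` and
`autoplot(tr)` draw the guide-level scatter with the ±4 s.d. band and
the −log10 adjusted-p track with clusters shaded.

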