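---
title: "Base editor scanning: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Base editor scanning: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bescan)
library(tibble)
```

# The experiment this package models

Base editor scanning tiles a coding gene with every sgRNA a
PAM-relaxed Cas9 base editor can use, introduces the library into a
reporter cell population, applies a phenotypic sort (here, cells whose
fluorescent degradation reporter survives drug treatment), and reads
out sgRNA abundances by sequencing. Because each sgRNA produces a
predictable amino-acid change, enrichment of an sgRNA in the sorted
population maps a functional requirement onto specific residues. The
package implements the complete desk-side half of such an experiment:
library design, editing-outcome prediction, enrichment scoring, a
per-residue clustering statistic, the small biophysical fitters used
in follow-up assays, and a synthetic-screen generator that makes every
stage testable with known ground truth.

# Guide design and outcome prediction

Guides are 20-nt protospacers followed by an `NG` PAM (the relaxed
SpG recognition written as G required at the second PAM position),
enumerated on both strands. A guide enters the library iff any base of
its *editing window* — protospacer positions 4–8, counted 1-based from
the 5′ (PAM-distal) end — lies within an exon or within 30 bp of an
exon boundary. The inclusion region is configurable
(`include_rule = "window" | "protospacer" | "cut_site"`) because
published library designs are not explicit on this point; the window
rule is the default on the argument that only window bases can produce
edits. Protospacers containing `TTTT` are removed (U6 terminator);
the filter is applied to the protospacer only.

Outcome prediction is deliberately deterministic: every editable base
in the window (C for CBE, A for ABE, on the protospacer strand) is
converted simultaneously, the CDS is re-spliced and retranslated, and
the guide is assigned exactly one of six classes in fixed priority:

1. **nonsense** — a new premature stop;
2. **missense** — any other amino-acid change;
3. **silent** — CDS bases edited, protein unchanged;
4. **utr_intronic** — edits only in exonic UTR or intron flank;
5. **non_editing** — no editable base in the window;
6. **negative_control** — control guides, which bypass prediction.

Two boundary conventions are ours to fix, since the class scheme has no
slot for them: loss of the start codon and readthrough edits of the
terminal stop are both classified missense (the changed codon is
recorded; a changed terminal stop is indexed `L + 1` and therefore
never enters the residue track, which is defined on `1..L`). Each
consequential guide gets a *representative residue*: the arithmetic
mean of its altered residue indices, rounded half away from zero
(configurable to first-altered-residue). Probabilistic bystander
models and editing efficiency are out of scope by design — the
scanning analysis treats prediction as a labelling step, not a
likelihood.

Coordinates are 0-based half-open for segments, exons and CDS bounds
(and in the JSON sidecar), while residues are 1-based — the former is
the common interchange convention for genome intervals, the latter
matches how protein positions are reported.

# Enrichment scoring

Counts are converted to `log2(1 + RPM)`; guides absent from the
plasmid library are excluded outright. Each sample is then normalized
to the plasmid abundance, replicates are averaged within role, sorted
is subtracted from unsorted, and the mean over non-targeting controls
is subtracted, which centres the controls at exactly zero. The chain
follows the recipe's sentence order; pairing sorted and unsorted by
replicate before averaging is available (`pair_replicates = TRUE`)
and gives identical results for matched replicate sets.

Hits are guides strictly more than `k = 4` sample standard deviations
(n − 1 denominator) from the mean of a negative-control set. The
control set defaults to intergenic controls but is configurable to
non-targeting controls — both conventions are in circulation, and the
two differ slightly because intergenic guides cut DNA while
non-targeting guides do not.

# The linear clustering statistic

Guide-level scores are noisy and unevenly spaced along the protein, so
per-residue inference proceeds in four steps, using only missense
guides:

1. **LOESS.** Locally weighted linear regression of score on residue
   position with tricube weights, **span = 20/L as a fraction of the
   data points**, and zero robustifying iterations. The span is
   implemented exactly as the fraction `20/L` rather than as a literal
   20-residue bandwidth: when the number of missense sgRNAs differs
   from `L` these are different smoothers, and the fraction form is
   the stated computation. The fit is evaluated at the observed guide
   positions; fitted values at duplicated positions are averaged.
2. **Quadratic spline interpolation** carries the smooth to every
   residue `1..L`. We use an interpolating B-spline of degree 2 with
   boundary knots tripled and interior knots at midpoints of
   consecutive data sites (dropping the outermost two midpoints) — the
   same convention as the common scientific-Python interpolator, which
   we verified against a reference instance frozen into the tests.
   Residues outside the observed position range take the nearest
   fitted value; quadratic extrapolation diverges and is never used.
3. **Permutation null.** Positions stay fixed; scores are shuffled and
   the entire track recomputed, 10,000 times by default. The
   empirical p-value is one-sided for enrichment with the add-one
   estimator `(1 + #exceedances) / (n_perm + 1)`, which cannot return
   zero. One-sidedness is a choice (the sorted phenotype is a gain
   signal); the shuffle, smooth and interpolation are identical for
   observed and null tracks, so the p-value is exact under
   exchangeability.
4. **FDR and clusters.** Benjamini–Hochberg across all `L` residues
   (including interpolated ones), clusters as maximal runs of adjusted
   p ≤ 0.05, and the plotting transform
   `-log10(p_adj + 1e-4)`.

The permutation loop precomputes everything that depends only on the
positions (the spline collocation factorization in particular), so a
10,000-permutation run on a 400-residue protein takes seconds.

## What calibration means here — and what it does not

Marginally, the empirical p-value at any fixed residue is uniform
under an exchangeable null; we verified this directly by simulating
independent null datasets and testing the p-value distribution at
fixed residues. Pooled across residues *within* one dataset, however,
p-values are strongly dependent: neighbouring residues share both the
smoothed observed track and the permutation draws. A
Kolmogorov–Smirnov test applied to the pooled values therefore
over-rejects relative to its nominal level even when the method is
perfectly calibrated — the effective number of independent values is
roughly `L` divided by the smoothing span, not `L`. The acceptance
checks report the pooled-KS pass rate as measured; it hovers around
its threshold precisely because of this dependence, while the
false-cluster rate (the quantity that matters for inference) is
essentially zero on null data.

# Assay models

* `bound_complex()` is the exact two-component equilibrium
  `AB = ((A_T + B_T + K_D) - sqrt((A_T + B_T + K_D)^2 - 4 A_T B_T)) / 2`,
  implemented in the algebraically equivalent stable form
  `2 A_T B_T / (S + sqrt(S^2 - 4 A_T B_T))` so that `K_D -> 0` does not
  cancel catastrophically. `fit_kd()` wraps it in a signal model
  `s0 + amp * AB` (baseline and amplitude may be frozen; both float by
  default, since titration data rarely come pre-normalized).
* `fit_4pl()` uses the log-symmetric parameterization
  `bottom + (top - bottom) / (1 + (ec50/x)^hill)` with quantile-based
  initialization.
* `trfret_ratio()` forms per-well 520/490 ratios after subtracting
  mean background-well intensities; `reporter_score()` is the
  reference-normalized geometric mean of per-event GFP/mCherry ratios
  (non-positive events are excluded and counted — they carry no
  information on the log scale).
* `fit_decay()` fits `exp(-k t)` with intercept 1 and plateau 0 and
  derives `V/[E] = k S0 / E0`, the first-order initial-rate
  equivalence; the derivation convention is flagged in the
  documentation because published values do not print it.

All fitters use Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with bound constraints, report Jacobian-based
standard errors via `tidy()`, and recover generating parameters on
noiseless data to at least 1e-6 relative — a property the tests
enforce.

# The synthetic screen generator

`simulate_screen_dataset()` emulates the screen design end to end: a
simulated coding gene (random sense codons, optional multi-exon
structure so the UTR-intronic class is exercised), the full enumerated
library, 199 non-targeting and 50 intergenic controls, one plasmid
sample, and three unsorted plus three sorted replicates. Counts are
negative binomial (`variance = mu + phi mu^2`, default `phi = 0.05`,
mean depth 500 reads per guide) over plasmid proportions with
log-normal skew (`sigma_lib = 0.5`). A planted hotspot (default one
15-residue interval, effect `delta = 2` log2 units) acts
multiplicatively on sorting probability for guides whose
missense/nonsense residues intersect it, so the scoring chain's
expected score equals the planted effect up to pseudocount and
renormalization bias — which is what makes recovery analytically
checkable. An `e3_mode` additionally gives every nonsense guide the
effect, mirroring screens of an E3 ligase where any loss of function
scores.

What the generator does *not* emulate: editing-efficiency
heterogeneity between guides, bystander-outcome uncertainty, sorting
impurity, PCR jackpotting beyond NB overdispersion, and positional
correlation of library skew. Passing recovery tests therefore
demonstrate the statistical machinery, not robustness to those
real-data pathologies.

# Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale chosen
to finish in a couple of minutes while keeping the statistics
meaningful: null calibration at `L = 200` with 150 guides and 1,000
permutations over 10 seeds; hotspot recovery at the generator defaults
(`L = 400`, 15-residue hotspot, `delta = 2`) with 1,000 permutations
over 10 seeds; the isotherm checked against a bisection oracle on
1,000 parameter triples. Production analyses should use the default
`n_perm = 10000`. Every stochastic stage takes an explicit integer
seed and restores the caller's RNG state, so identical inputs and
seeds give byte-identical flat-file outputs.

# Known limitations

* One transcript per gene model; no GTF/GFF ingestion.
* Outcome prediction is all-or-nothing within the window; guides with
  several editable bases are assigned their joint outcome only.
* The clustering statistic is one-sided (enrichment); depletion
  clustering would need a sign flip and is not exposed.
* The 4PL and K_D fitters assume independent homoscedastic noise;
  no weighting or bootstrap is provided.
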