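---
title: "Methods: staging, marker discovery and regulatory-network inference in vcmnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staging, marker discovery and regulatory-network inference in vcmnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcmnet)
```

`vcmnet` analyses a four-group developmental expression series —
undifferentiated human embryonic stem cells (hESC), hESC-derived
ventricular cardiomyocytes (VCMs), fetal VCMs and adult VCMs — to stage
the derived cells, find markers of cardiac identity and maturation, and
infer a transcription-factor (TF) regulatory hierarchy. This vignette
explains the models and procedures, the tunable parameters and their
defaults, the synthetic-data generator used for validation, and the
numerical and design choices that were genuinely open.

## The expression substrate

All analyses run on an `ExpressionMatrix`: log2 abundances of genes (or
probes) by samples, a sample-to-group map whose order of first
appearance fixes the developmental order, and optionally a matching
matrix of detection p-values. For linear-scale array input the
normalisation stack is fixed as

1. `log2_transform(x, offset = 1)` — `log2(value + 1)`, monotone;
2. `quantile_normalize()` — every sample forced onto the row-wise mean
   of the sorted columns (ties receive their quantile mean);
3. `collapse_probes(rule = "max_mean")` — per gene, the probe with the
   highest mean abundance represents the gene.

This is the standard stack for bead-array data; the scanner-side
preprocessing of the original instruments is proprietary, so the
package standardises on these transparent equivalents. Internally all
fold changes are computed on log2 values and reported on the linear
scale.

A gene is *present* in a group when its detection p-value is below
`alpha` (default 0.01) in a strict majority of that group's replicates;
"A-only"/"B-only" presence categories in the differential tables follow
from this call. The majority rule and `alpha` are exposed because no
universal definition of "expressed" exists for these arrays.

## Global staging

Samples are clustered with `cluster_samples()` under 1−Pearson distance
and average linkage (defaults; Euclidean and complete linkage are
available). Samples are ordered lexicographically before clustering so
ties resolve deterministically. `pca_embed()` embeds samples by PCA of
the gene-centred matrix, by default restricted to the 2000
most-variable genes to stabilise small-sample embeddings; each
component's largest-magnitude loading is forced positive so the
embedding is sign-deterministic.

The *developmental-axis linearity* statistic is the Pearson correlation
of the (PC1, PC2) coordinates of the three VCM group centroids:
`|r| = 1` exactly when the centroids are collinear. It is computed on
group centroids, not individual samples, because the question is
whether the *stages* fall on a line. Two degenerate configurations
raise documented errors rather than returning a value: coincident
centroids, and an axis-aligned line (zero variance on PC1 or PC2, where
Pearson correlation is undefined even though the points are collinear).

## Marker discovery

`top_n_abundant()` ranks genes by group-mean abundance (default
n = 200) with boundary ties broken lexicographically.
`classify_markers()` combines three ingredients:

* the three top-n lists of the VCM groups and their Venn partition;
* a tissue-specificity ratio from a multi-tissue reference table:
  mean over the target tissues (heart, skeletal muscle) divided by the
  *median* over the remaining tissues (≥3 required). The median was
  chosen over mean or max as the denominator because it is robust to a
  single aberrant tissue; the >10-fold cut is the conventional bar for
  "tissue specific". An all-zero denominator yields a flagged `Inf`
  rather than an error.
* fold changes from the derived-VCM group to the fetal and adult
  groups.

Identity markers are genes in all three top-n lists that pass the
specificity cut; depleted markers are specificity-passing genes in the
union of the lists whose fetal and/or adult fold change exceeds the
depletion cut (default 10). Both cuts are strict inequalities.

## Differential screen and enrichment

`diff_table()` reports, per gene, the linear fold change
`2^(mean log2 B − mean log2 A)`, Welch's unequal-variance t with
Welch–Satterthwaite degrees of freedom, the BH-adjusted q, a direction
call at strict thresholds (default: fold > 2 and p < 0.05) and the
presence category. Two conventions handle degenerate genes: both groups
constant and equal gives t = 0, p = 1; constant but different gives
p = 0 with an infinite statistic. Genes absent from one group are
reported categorically instead of with unbounded fold changes. A
moderated-variance test was deliberately not used: with 2–3 replicates
per group the package mirrors a plain per-gene test and exposes the
statistic so users may substitute alternatives.

`enrichment_score()` implements the weighted Kolmogorov–Smirnov-style
running sum: at gene-set members the sum increases by
`|s|^p / Σ_members |s|^p`, elsewhere it decreases by `1/(N − N_h)`; the
enrichment score is the extremum, so `|ES| ≤ 1`. The weight p = 1 and
the set-size window 15–500 are the established defaults for this
statistic. Zero-variance genes under the signal-to-noise ranking are
kept by flooring the denominator at 1e−8. `permutation_fdr()` defaults
to *gene-set permutation* because phenotype permutation is meaningless
with two or three replicates per group (requesting it with fewer than
three replicates errors with a pointer to gene-set permutation); the
mode is recorded in the run metadata. NES divides ES by the mean
same-sign null magnitude; the FDR is the ratio of normalised null to
observed exceedances, capped at 1. The RNG is always seeded explicitly
and the caller's RNG state is restored afterwards.

`hypergeometric_test()` gives the upper-tail probability of the
observed overlap for annotating gene lists (e.g. Venn regions) against
user-supplied collections.

## Co-expression network over the TF panel

The co-expression procedure correlates **4-point group-mean profiles**,
not replicate-level values: the staging question is whether a gene
tracks a TF across the four developmental stages, and group means are
the natural profile for that question (a switch to replicate-level
profiles would be a one-line change, but the group-level reading
matches the pipeline's design). An edge (TF, gene) is stored iff
Pearson r strictly exceeds 0.95. With only 4 points this threshold is a
descriptive bar, not a significance claim, and the module accordingly
reports counts without p-values. Constant profiles have undefined
correlation: constant TFs are dropped with a warning, constant genes
excluded with a logged message.

The core TF cluster is the **maximum clique** of the TF–TF edge graph —
exact, since the panel has ≤17 nodes — with ties broken by summed
pairwise correlation, then lexicographically. Per-gene joint-target
counts report links over the whole panel and over the core subset;
the core fraction is a half-up-rounded integer percentage
(5 of 8 → 63%), and a gene is "exclusive to core" when all its links
are core links. `build_network()` keeps the core TFs plus genes with at
least `min_core_links` core links (default 4).

## Promoter scanning and the regulatory hierarchy

Promoter windows run from 1000 bp upstream to 300 bp downstream of the
TSS. Coordinates are 0-based half-open with the TSS as the first
transcribed base: a + strand window is `[TSS−1000, TSS+300)`; a −
strand window is the reverse complement of `[TSS−300, TSS+1000)`.
Windows are clipped at contig edges and flagged.

Motifs are supplied as JASPAR-style count matrices; a pseudocount of
0.1 per cell gives probabilities, and each position carries an
information weight `w_i = 2 + Σ_b p_ib log2 p_ib` (bits). A window
scores `Σ w_i p_i(b_i) / Σ w_i max_b p_i(b)`, reaching 1 exactly at the
consensus; the *core similarity* applies the same formula restricted to
the 4 consecutive positions with maximal summed information (leftmost
on ties). A hit requires core similarity ≥ 0.90 and matrix similarity
≥ 0.85 — conventional defaults for this two-stage scheme. Both strands
are scanned at every offset; overlapping same-strand hits count
separately; windows with ambiguity codes are skipped; zero-information
matrices score 0 with a warning rather than erroring, keeping batch
scans total. PPARGC1A is excluded from scanning by default because it
acts as a co-factor without defined binding sites (the exclusion is a
parameter).

The bundled 27-gene × 4-TF binding-site count table
(`inst/extdata/table4_binding_sites.tsv`) exercises the summarisation
operations; because the matrix library behind the original site
predictions is proprietary, those counts serve as a transcribed fixture
for `summarize_sites()` rather than a target the scanner reproduces
from sequence.

`integrate_hierarchy()` flags a directed TF→gene edge "both" when a
co-expression edge exists *and* the gene's promoter carries ≥1
predicted site for that TF; single-source edges are labelled
`coexpression` or `binding_site`. TF self-edges are permitted via
binding evidence.

## The synthetic-data generator

No public expression data accompany this study design, so the
generator emits a fully self-contained substitute with known truth.
Defaults, chosen once as the study conditions:

| parameter | default | meaning |
|---|---|---|
| groups | hESC, hESC-VCM, hF-VCM, hA-VCM | developmental order |
| replicates_per_group | 3 | replicate count (not stated by the emulated design; 2–3 is typical for arrays) |
| noise_sd | 0.1 | additive Gaussian noise, log2 scale |
| n_core_tfs / n_distractor_tfs | 5 / 12 | the 17-TF panel |
| targets_per_module | 30 | shared targets of the core module |
| fc_gradient | 1, 16, 32 | maturation fold changes across the VCM stages |
| promoter_len | 1300 | −1000/+300 window length |

Noise is additive Gaussian on the log2 scale (log-normal in linear
scale), the standard array error model. Noiseless group-mean profiles
come from a fixed dictionary: pluripotency high only in hESC;
pan-cardiac high in all VCM groups; maturation strictly increasing with
the configured fold gradient (baseline placed so these genes are
abundant in fetal/adult cells, as maturation markers are); a depleted
cell-cycle block; one shared shape for the core TFs and their targets
(per-gene affine transforms keep within-module correlations exactly 1);
and 12 distractor shapes. All pairwise correlations in the dictionary
stay below 0.84, and background genes are rejection-sampled below 0.85
against every planted profile, so the strict 0.95 edge rule sees
planted structure only.

Every class and background profile places its between-VCM contrasts on
one gene-space direction (deltas proportional to (4, 5) relative to the
derived-VCM group): the planted developmental axis. This makes the
three VCM centroids collinear in noiseless data — the property the
staging statistic measures — while the hESC coordinate stays free. The
12 distractor TFs are deliberately off-axis; their variance share is
small, so the axis dominates PC1/PC2 and |r| stays ≥ 0.99.

Promoters are i.i.d. uniform ACGT with motif consensus instances
planted at uniform non-overlapping offsets and uniform strands in the
promoters of all module members (targets and core TFs, matching the
planted hierarchy). Synthetic motifs are 18 bp with 16 near-deterministic
positions: long and sharp enough that, at the default thresholds, the
expected number of spurious background hits across a full module scan
is well below one, so planted-site tallies are recoverable exactly on
typical seeds. The 12-tissue reference plants ~50-fold heart +
skeletal-muscle enrichment for the pan-cardiac and maturation classes.
Detection p-values are near 0 where the noiseless mean is above the
absent level (4.5 log2 units) and high otherwise, giving clean planted
presence/absence (e.g. pluripotency genes present in hESC only).

What the generator does **not** emulate: probe-level bead intensities
and detection-p physics, heteroscedastic (intensity-dependent) noise,
correlated background genes, realistic promoter composition
(GC content, repeats) and degenerate real motifs. Passing recovery
tests therefore demonstrates correctness of the procedures under the
planted model, not performance on real arrays, where the 4-point
PCC > 0.95 rule is a far looser statistical bar.

Determinism contract: the same seed yields bit-identical datasets and
fixture bundles (`write_fixture_bundle()` checksums every file); all
randomness flows through one seeded stream and the caller's RNG state
is untouched.

## Pipeline

`run_config()` collects inputs, stage toggles and every threshold;
`validate_config()` returns violations as data (field + rule) and
`run_pipeline()` refuses to start on any violation — including enabling
`hierarchy` without `coexnet` and `promoter`. Stages run in dependency
order; outputs land in `out_dir` and are manifested with MD5 checksums;
logs go to stderr, never stdout. Identical configuration and inputs
give byte-identical manifests. A thin CLI
(`inst/scripts/vcmnet-cli.R`: `simulate`, `validate`, `run`) wraps
these functions; flags override YAML config values.

## Numerical choices and limitations

* Strictness: every published-style threshold ("more than 2-fold",
  "PCC > 0.95", ">10-fold") is a strict inequality; scan thresholds
  are inclusive lower bounds on similarity scores.
* Rounding: core-fraction percentages round half-up (`floor(x+0.5)`),
  matching the 5/8 → 63% convention; analysis TSVs carry 6 significant
  digits, fixture bundles full (`%.17g`) precision so round trips are
  exact.
* Tie-breaks are always lexicographic (abundance boundaries, ranking
  scores, clique selection, clustering input order) so outputs are
  reproducible to the byte.
* Test problem sizes: recovery runs use 150–500 genes, 17 TFs and
  3 replicates; calibration uses 2000 null Welch tests and 200 random
  sets × 300 permutations. These sizes make the planted-structure
  checks sharp while keeping the suite quick.
* Known limitations: with n = 4 profile points the co-expression
  threshold has no significance interpretation; the scanner does not
  model dinucleotide background or conservation; the hierarchy is
  evidence labelling, not causal inference; phenotype permutation is
  unavailable below 3 replicates by design.
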