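---
title: "Locating sequence determinants of protein thermostability with thermodet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating sequence determinants of protein thermostability with thermodet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermodet)
```

## The problem

Within a single protein family, mesophilic and thermophilic members are
often nearly identical in sequence and structure, yet differ sharply in
the temperature they tolerate.  `thermodet` implements a multivariate
contrast of two aligned groups of homologues — one from mesophiles
(optimal growth temperature, OGT, in `[20, 40)` °C) and one from
thermophiles (OGT ≥ 50 °C) — to locate short sequence fragments whose
physico-chemical character differs systematically between the groups,
and, separately, alignment regions where the two groups differ in their
insertion/deletion behaviour.  The archetype is a PLP-dependent enzyme
family whose members share roughly 80% identity; the method itself is
family-agnostic.

Two deliberately separate signals are analysed:

1. **Substitution signal** — per-fragment differences in six amino-acid
   property scales, scored by PCA; detects positions where thermophiles
   prefer different residues.
2. **Indel signal** — per-column gap-rate contrasts (the MRT statistic);
   detects regions where thermophiles insert or delete residues.

Fragments touching any gapped column are excluded from the first
analysis precisely so that the two signals cannot masquerade as one
another.

## Inputs and coordinates

The pipeline takes two aligned FASTA files (one per thermal group), a
tab-separated metadata table (`id organism ogt group`), and an
AAindex1-format property file supplying six scales: hydrophobicity,
molecular weight, polarity, side chain, flexibility and buriability.
Accession-to-property names are read from each entry's title line, never
assumed from file order.

Both group alignments must contain a common reference (template)
sequence.  `merge_on_reference()` merges them on that anchor: columns
where the reference carries a residue are shared; insertion columns are
carried over per group (mesophilic insertions placed before thermophilic
ones within an anchor — a deterministic, order-stable rule).  Every
output carries both coordinate systems: alignment columns and reference
residue numbers.  Domains are defined on reference residues — by default
an N-terminal sub-domain (1–111), a PLP-binding domain (112–370) and a
C-terminal domain (371 onward) — and insertion columns inherit the
domain of the nearest preceding reference residue (insertions before
residue 1 go to N1); the boundaries are configurable for other families.

## The substitution model

For a window of `w = 7` columns sliding in steps of one, each sequence's
*window index* for property *k* is the mean of the property value over
the non-gap residues in the window (an alignment of `s` columns gives
`s − 6` fragments).  Gaps and non-standard residue codes are excluded
from the mean — never scored as zero — so an indel does not imitate a
property shift; a fully gapped window is undefined and drops out of the
group average.  Group profiles average the window indices across
sequences within each group (within-window mean first, then across
sequences; the two orders differ when gap counts vary per sequence, and
the chosen order keeps every sequence's fragment equally weighted).  The
reference sequence is a coordinate anchor, not a data point: it joins no
average and no gap count.

The per-fragment, per-property contrast is

$$D(i,k) = \bar P_t(i,k) - \bar P_m(i,k),$$

and `V` stacks the D rows of the *retained* fragments — those whose
seven columns all have missing number zero.  The unfiltered score track
is also computed so users can see how gap-rich regions would dominate
without the filter.

### PCA, varimax, and the fragment score

`V`'s six columns are standardized (sample SD, so results are
bit-reproducible), decomposed by PCA on the correlation structure, and
the components with standard deviation above 1 are retained.  Their
loading block, scaled by the component standard deviations, is
varimax-rotated (Kaiser normalization, convergence tolerance 1e-6) to
concentrate each component on few properties; orthogonal rotation
preserves the block's total explained variance.  Rotated components (the
factor loadings, FLs) are kept greedily by variance share until the
cumulative share reaches 80% — both knobs (`sd_threshold`, `cumvar`) are
independent and the run metadata records which components each rule
selects, because with correlated property scales the first component
alone often sits just below or above 80%.  Fragment *i*'s score is the
variance-weighted norm of its rotated component scores,

$$L(i) = \sqrt{\textstyle\sum_k v'_k f_k(i)^2},$$

with $v'_k$ the chosen FLs' variance shares renormalized to one.  This
score is non-negative, reduces to $|f_1(i)|$ when a single FL is chosen,
and is invariant to the sign indeterminacy of loadings.  The exact
published form of the score was not recoverable from the source
material, so this definition is a documented reconstruction and is
isolated in `fragment_scores()` where alternatives can be substituted.

### Significance

A fragment is a candidate when its score exceeds 1.2 **and** its p-value
is below 0.01.  P-values come from a group-label permutation null: the
thermal labels are shuffled (group sizes preserved) and the whole
group-mean → difference → PCA → varimax → score chain is recomputed, by
default 999 times.  Because the standardized score measures *relative*
outlierness among fragments, a per-fragment null would report about one
false candidate per hundred retained fragments at α = 0.01; the null is
therefore family-wise — each permutation contributes its **maximum**
fragment score, and

$$p(i) = \frac{1 + \#\{b: \max_j L_b(j) \ge L(i)\}}{1 + n_{perm}},$$

which calibrates the probability of *any* false candidate to α.  The
window profiles do not depend on labels, so permutations only re-average
them; the batched implementation makes 999 permutations on a
378-sequence, 562-column alignment take a few seconds.  A parametric
alternative (`p_method = "normal"`, upper tail of a normal fitted to the
observed scores) is available for quick looks; calibration claims rest
on the permutation null only.  With fewer than 99 permutations α = 0.01
is unattainable and a warning is raised.

### MLR validation

Each candidate fragment is validated by ordinary least squares of
thermostability on the six per-sequence window features.  The response
is the 0/1 thermal class — a linear probability model — because the
dataset design excludes the 40–50 °C band, making OGT bimodal; raw OGT
can be passed instead.  Reported are the multiple correlation
$R = \sqrt{R^2}$, the global F-test p-value, and the properties whose
coefficients pass t-tests at 0.05 (the "significant impact factors").
Collinear columns are dropped with a warning naming them.  No
multiple-testing correction is applied across fragments; with the
family-wise permutation null upstream, the MLR is a descriptive
validation, not an independent discovery step.

## Per-position analysis

Within candidate fragments, single-column property differences are
computed on z-standardized scales (across the 20 residues) so the six
properties share one unit-free axis; raw-scale output is also available
since either convention is defensible.  Residue compositions are
percentages of each group's *non-gap* sequences — including gaps in the
denominator would make compositions depend on unrelated indels.

## The indel (MRT) model

For every column, the gapped fraction of each group is computed
(reference excluded) and contrasted as

$$\mathrm{MRT}(c) = mr_{thermo}(c) - mr_{meso}(c) \in [-1, 1].$$

The name denotes the gap-rate contrast statistic; its exact published
formula was not recoverable, and the signed rate difference is the
reconstruction used here: it is zero when indel behaviour is
group-independent, antisymmetric under group swap, and bounded so that
the ±0.5 flagging thresholds are meaningful (a ratio-based alternative
would be unbounded).  Columns with |MRT| > 0.5 are "high"; the domain
summary reports, per domain, the columns with any gap, the high columns,
and each domain's share of all high columns, plus the share in the two
chain ends (N1 ∪ C) — the summary in which C-terminal indel bias is
expected for this enzyme family.

## The synthetic-data generator

Because the original 378-sequence dataset is not deposited with
accessions, every stage is tested by parameter recovery on synthetic
alignments.  `synthetic_config()` defaults emulate the study design:

* 305 mesophilic + 73 thermophilic sequences, 562 columns, with a
  gap-free consensus reference included in both groups;
* consensus-plus-noise columns with conservation ρ = 0.8, emulating the
  ~80% within-family identity; OGTs uniform in `[20, 40)` and `[50, 85]`;
* three planted determinant columns (at the scaled positions of 116, 244
  and 462) where thermophilic sequences draw from an enriched residue
  set with probability e = 0.9.  Each default pairs enriched residues
  with a property-contrasting consensus — Lys vs Gly (charge/side-chain
  gain), Val/Phe vs Ser (hydrophobicity/buriability gain), Asp/Glu vs
  Val (charge gain, hydrophobicity loss) — because a determinant *is* a
  physico-chemical contrast: a planted Lys against a property-similar
  consensus such as Glu is invisible to any property-based method, by
  construction.  The consensus pairing is configurable per column, or
  can be left to a random draw outside the enriched set;
* one thermophile-biased gap hotspot over the last five columns
  (C domain), applied as a whole-span deletion per sequence with
  probability g = 0.8, mimicking a segmental indel;
* a single seed drives all randomness; fixture files are byte-stable.

A planted column inside a same-group gap hotspot is rejected as
confounded.  What the generator does **not** emulate: phylogenetic
correlation between sequences (draws are independent given the
consensus), realistic indel length distributions, column-to-column
property correlation, or compositional skew (background is uniform by
default).  Passing recovery tests therefore demonstrate correctness of
the machinery and calibration under exchangeability — not performance on
real families, where tree structure can inflate between-group contrasts.

## Numerical and design choices

* Standardization uses the sample (n−1) SD; a zero-variance property
  column is an error naming the property, except the fully degenerate
  identical-groups case (V ≡ 0), which yields zero scores and no
  candidates rather than an error.
* Varimax: Kaiser-normalized, eps 1e-6; FL selection ties break by
  original component order; a single retained component rotates by the
  identity.
* Permutation p-values use the add-one estimator, so the smallest
  attainable p is `1/(1+n_perm)`.
* All TSV outputs print at 6 significant digits; reruns with the same
  inputs and seed are byte-identical.
* Test problem sizes: module and calibration tests use 60+20 sequences
  over 120 columns (null calibration: 20 seeds × 199 permutations;
  recovery: 999 permutations), sizes at which the permutation machinery
  is exercised end-to-end in seconds; the acceptance script runs the
  full 305+73 × 562 study-condition simulation.

## A worked example

```{r example}
aa <- system.file("extdata", "aaindex_six_synthetic.txt",
                  package = "thermodet")
cfg <- synthetic_config(n_meso = 60, n_thermo = 20, s = 100, seed = 21,
  planted_columns = list(
    list(column = 40, residues = "L", consensus = "G", e = 1.0),
    list(column = 44, residues = "F", consensus = "G", e = 1.0)),
  gap_hotspots = list(
    list(columns = 90:94, group = "thermophilic", g = 0.8)))
sim <- simulate_alignments(cfg)
run <- run_all(run_config(meso = sim$meso, thermo = sim$thermo,
                          aaindex = aa, ref_id = cfg$ref_id,
                          n_perm = 499, seed = 31,
                          partition = cfg$partition))
run
```

The report lists the candidate fragments covering the planted columns
40/44, their permutation p-values, the MLR multiple correlation for each,
and the indel summary placing all high-MRT columns in the C domain —
the planted configuration, recovered.

## Known limitations

* The fragment score and MRT formulas are documented reconstructions of
  quantities whose published definitions were not recoverable; both are
  isolated behind small functions so alternatives can be swapped in.
* The bundled AAindex file carries synthetic stand-in values (clearly
  labelled); analyses of real data should use the published entries.
* OLS on a binary response is heteroscedastic; the global F-test is used
  descriptively, with calibration verified empirically under label
  permutation.
* Alignment uncertainty is not propagated: gap columns are taken at face
  value from the input alignments.
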