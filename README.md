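# thermodet

Locating sequence determinants of protein thermostability within one
protein family, by contrasting aligned mesophilic and thermophilic
homologues.

Protein families often span organisms growing at 25 °C and at 75 °C with
members that are ~80% identical and structurally superimposable, which
makes the *sequence determinants* of the thermal difference hard to see
by eye. `thermodet` is for sequence analysts who have two multiple
alignments of one family — one of mesophiles (optimal growth temperature
in `[20, 40)` °C) and one of thermophiles (OGT ≥ 50 °C), both containing
a shared reference/template sequence — and want a ranked, significance-
tested list of short fragments whose physico-chemical character separates
the groups, plus a separate map of group-biased insertions/deletions.

## The method

For a sliding window of `w = 7` alignment columns (an alignment of `s`
columns gives `s − 6` fragments), each sequence's window index for
property *k* is the mean of the AAindex scale value over the non-gap
residues in the window. Six scales are used: hydrophobicity, molecular
weight, polarity, side chain, flexibility, buriability. Averaging within
each thermal group and subtracting gives the contrast matrix

    D(i, k) = P̄t(i, k) − P̄m(i, k),        i = 1 … s−6,  k = 1 … 6

whose rows for *retained* fragments (all 7 columns free of gaps) form the
matrix **V**. **V** is column-standardized and decomposed by PCA;
components with sd > 1 are varimax-rotated, and rotated components
(factor loadings, FLs) are kept until their cumulative variance share
reaches 80%. Fragment *i* is scored by the variance-weighted norm of its
rotated component scores,

    L(i) = sqrt( Σk v'k · fk(i)² ),

and is a **candidate** when `L(i) > 1.2` and its p-value — from a
group-label permutation null in which each of `n_perm` relabellings
contributes its *maximum* fragment score (family-wise calibration) — is
below 0.01. Candidates are validated by multivariable linear regression
of the 0/1 thermal class on the six per-sequence window features
(multiple correlation R, global F-test, per-property t-tests), and
localized within the window by per-position property differences and
residue compositions.

Independently, the per-column gap-rate contrast

    MRT(c) = mr_thermo(c) − mr_meso(c)  ∈ [−1, 1]

flags columns with |MRT| > 0.5 and summarizes them over three reference
domains (N-terminal sub-domain, PLP-binding domain, C-terminal domain).

A synthetic-alignment generator (`synthetic_config()` /
`simulate_alignments()`) plants determinant columns and gap hotspots with
known truth, so every stage is testable by parameter recovery.

## Worked example

Simulate a family with two planted critical positions (Leu and Phe
against a Gly consensus, columns 40 and 44) and a thermophile-biased gap
hotspot at columns 90–94, then run the full pipeline:

```r
library(thermodet)
aa <- system.file("extdata", "aaindex_six_synthetic.txt", package = "thermodet")
cfg <- synthetic_config(n_meso = 60, n_thermo = 20, s = 100, seed = 21,
  planted_columns = list(
    list(column = 40, residues = "L", consensus = "G", e = 1.0),
    list(column = 44, residues = "F", consensus = "G", e = 1.0)),
  gap_hotspots = list(list(columns = 90:94, group = "thermophilic", g = 0.8)))
sim <- simulate_alignments(cfg)
run <- run_all(run_config(meso = sim$meso, thermo = sim$thermo,
                          aaindex = aa, ref_id = cfg$ref_id,
                          n_perm = 499, seed = 31, partition = cfg$partition))
run
```

```
# Thermostability determinant report

Alignment: 81 sequences (60 mesophilic, 20 thermophilic), 100 columns.
Fragments: 94 (window 7); 83 retained after the gap filter.
Thresholds: PC sd > 1, cumulative variance >= 80%, score > 1.2, alpha = 0.01, |MRT| > 0.5; 499 permutations, seed 31.

Principal components: variance proportions 78.0%, 20.1%, 1.2%, 0.5%, 0.2%, 0.0%; retained 1, 2; chosen FLs (rotated) 1, 2.

## Candidate fragments

| fragment (cols) | ref span | score | p | R | overall p | significant factors |
|---|---|---|---|---|---|---|
| 38-44 | 38-44 | 6.571 | 0.004 | 0.903 | 7.55e-25 | hydrophobicity, buriability |
| 39-45 | 39-45 | 6.453 | 0.004 | 0.905 | 3.94e-25 | hydrophobicity, buriability |
| 40-46 | 40-46 | 5.911 | 0.004 | 0.899 | 2.73e-24 | hydrophobicity, buriability |

## Insertion/deletion (MRT) summary

Columns with any gap: 5; columns with |MRT| > 0.5: 5.

| domain | indel columns | high-MRT columns | share of high |
|---|---|---|---|
| N1 | 0 | 0 | 0.0% |
| N2 | 0 | 0 | 0.0% |
| C | 5 | 5 | 100.0% |

Share of high-MRT columns in the chain ends (N1 + C): 100.0%.
```

Reading it: the three candidate fragments are exactly the windows
covering both planted columns (40 and 44); their scores stand far above
the permutation null (p = 0.004 at 499 permutations), the MLR confirms a
strong class association (R ≈ 0.90) driven by hydrophobicity and
buriability — the properties that separate Leu/Phe from Gly — and the
indel track places 100% of high-|MRT| columns in the C-terminal domain,
where the hotspot was planted. With `out_dir` set, `run_all()` also
writes `fragments.tsv`, `scores.tsv`, `mlr.tsv`, `positions.tsv`,
`mrt.tsv`, `domains.tsv`, `pca.json`, `column_map.tsv` and `report.md`.

A thin command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "thermodet.R", package = "thermodet"))') \
  run --meso meso.fa --thermo thermo.fa --meta meta.tsv \
      --aaindex props.txt --ref REF_TEMPLATE --out outdir
```

Note: the bundled AAindex file carries synthetic stand-in scale values
(labelled as such in the file); for real analyses supply the published
AAindex entries.

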