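---
title: "Fluctuating-residue analysis: model, parameters and design notes"
author: "flucres authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluctuating-residue analysis: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flucres)
```

## The classification and the index scale

Amino acids differ widely in how much conformational freedom they grant
the backbone and side chain. `flucres` is built around a fixed,
three-way partition of the 20 standard residues by that mobility:

* **high** fluctuating — G, A, S, P, D (5 residues),
* **moderate** — T, E, N, K, C, Q, R, V (8 residues),
* **weak** — H, L, M, I, Y, F, W (7 residues).

Each class carries a single integer **fluctuation index**: −2 for high,
−1 for moderate and +2 for weak residues. The scale is deliberately
asymmetric: flexible residues score negative and rigid ones positive,
so a mixed scoring stream separates flexible stretches (sustained
negative runs) from well-packed ones at a glance, which a purely
positive or purely negative score cannot.

The physical quantity behind the grouping is the **carbon content** of
the residue: carbon-rich side chains are hydrophobic, pack tightly and
fluctuate little, while carbon-poor residues are small or polar and
move more. The package ships the carbon table next to the
classification (`inst/extdata/fluctuation_scale.tsv`) so the basis is
auditable:

```{r}
head(fluctuation_scale()$carbon)
```

**Convention for the carbon fraction.** A precise formula for "carbon
content" is not fixed by the underlying scheme, so the package defines
it as (number of carbon atoms) / (number of all atoms, hydrogens
included) of the residue as a chain monomer — the free amino acid minus
one water. Glycine (C2H3NO) is 2/7 ≈ 0.286; tryptophan (C11H10N2O) is
11/24 ≈ 0.458. The convention is simple, reproducible from any
molecular-formula table, and lives in a one-file data table, so an
alternative convention (e.g. heavy atoms only) is a data edit, not a
code change. The classification itself is taken as given and is *not*
re-derived from carbon thresholds; see Non-goals.

## Scoring sequences

`profile_sequence()` maps each residue to its index. Three policies
govern non-standard codes (X, B, Z, U, O, gaps):

* `skip` (default) — drop them with a warning. Original positions are
  retained, so downstream coordinates stay interpretable; composition
  denominators count classifiable residues only.
* `zero` — keep them at index 0, class `NA`, preserving length.
* `error` — fail, naming the offending positions.

The scheme itself is silent on non-standard codes; `skip` is the
default because it keeps composition fractions well defined without
inventing an index for unknown chemistry.

`smooth_profile()` applies a centered moving average with an odd window
(residues). At the ends the window shrinks symmetrically, so the output
has the same length as the input and stays within the raw range.
**The default is unsmoothed** (window 1): no particular window is part
of the method definition, so none is invented; smoothing exists for
visualization and for segment calling on noisy profiles, and the window
is an explicit, logged parameter wherever it is used.

## Segment calling

`call_segments()` reports maximal runs of consecutive positions whose
value (smoothed if present, else raw) is **at or below a threshold**,
keeping runs of at least `min_length` residues.

* `threshold = -1` by default: captures the high (−2) and moderate (−1)
  classes, i.e. exactly the residues that promote flexibility and
  disorder, while any weak residue (+2) breaks a raw run.
* `min_length = 30` by default: the conventional cutoff for a *long*
  disordered region in the disorder-prediction literature.

These two defaults make the caller a candidate-IDR screen out of the
box, but both are plain arguments (and CLI flags) because the scoring
scheme defines a per-residue index, not a calling rule; the rule here
is this package's own, stated choice. Segment coordinates are 1-based
inclusive, matching residue numbering in PDB-facing tools; the CLI
additionally writes a BED-like table with 0-based half-open starts for
genome-browser-style consumers.

`agreement()` compares segment calls with any externally produced
per-residue reference mask (e.g. a curated disorder annotation) as a
per-residue confusion matrix with sensitivity and specificity. Rates
with empty denominators are reported as `NA`, not 0, so a sequence with
no annotated positives cannot silently inflate averages.

## Composition

`composition()` pools residues across all records of a dataset and
reports per-class counts and fractions. Pooling (rather than averaging
per-chain fractions) weights every residue equally, which is the
natural reading of statements about class percentages over a dataset;
per-record summaries are a one-liner (`lapply(records, composition)`).
Fractions are over classifiable residues, so skipped unknowns never
distort the denominator.

## Ranking scales and the occupancy matrix

An AAindex scale assigns one real value per residue. `rank_residues()`
sorts the 20 residues from the highest property value to the lowest
(rank 1 = highest, following the usual presentation of hydrophobicity
rankings); `descending = FALSE` serves scales where *low* values mean
flexible. Ties break alphabetically by one-letter code — a deterministic
rule chosen so that every scale places every residue at exactly one
rank; without it the occupancy matrix would lose its marginal
invariant. Scales with missing values are rejected, not imputed:
ranking an incomplete alphabet would silently break the same invariant.

`build_occupancy_matrix()` aggregates a scale collection into a 20×20
count grid (rank positions × residues). Because each scale contributes
one permutation, **every row and column of a k-scale matrix sums to
k** — a property the tests verify for the bundled published 70-scale
matrix (all forty marginals equal 70) and for every matrix the builder
produces. The bundled matrix ships as data and is *verified*, never
rebuilt: the identities of the 70 flexibility/rigidity-related
hydrophobicity scales behind it were never published, so exact
reconstruction is not attempted (Non-goals).

The bundled AAindex1 sample file contains ten complete scales: two
transcribed published hydropathy scales (Kyte–Doolittle KYTJ820101 and
Hopp–Woods HOPT810101, cross-checked in the tests against an
independent reading of the AAindex database) and eight synthetic
flexibility-like scales, generated deterministically with
class-dependent means plus noise and labelled synthetic in their
accessions and titles. The synthetic scales exist to exercise the
parser and builder, not to stand in for real AAindex entries.

## Sequence input

FASTA reading/writing goes through Biostrings (60-column wrapped
output; round-trip identity on id and sequence). PDB files are read via
bio3d, sequence only: SEQRES is preferred when present because it
carries the full construct, including disordered residues that never
got coordinates — exactly the residues this package cares about;
`from_atoms = TRUE` forces the Cα-derived sequence. Unknown monomers
become `X`. mmCIF and any use of coordinates or B-factors are out of
scope. For multi-model NMR entries the first model is read; chains are
otherwise treated independently.

The crotamine fixture carries the published 42-residue cell-penetrating
peptide (PDB entry 1H5O) both as FASTA and as a **synthetic minimal
PDB rendering** (SEQRES plus placeholder Cα records of the same
sequence — not the deposited coordinates, as the file's header and
name state), so both input paths are exercised offline.

## The synthetic generator

`generate_sequence()` draws each residue by first sampling a
fluctuation class from the target fractions, then a residue within the
class — uniform by default, or weighted by a user-supplied 20-residue
frequency vector for more realistic backgrounds. The default class
fractions are the alphabet proportions of the scale itself (5/20, 8/20,
7/20): the composition of a uniform-residue background, a neutral
choice that favours no class. Identical seeds give identical sequences,
and the caller's RNG stream is restored afterwards.

What the generator emulates is *composition only*: i.i.d. residues with
controlled class fractions. Real sequences have positional
autocorrelation, domain structure and phylogenetic bias, none of which
are modelled — so tests built on the generator demonstrate correctness
of counting, calling and ranking machinery, not predictive performance
on real proteins. The convergence checks use n = 100000 with a ±0.01
tolerance (> 6 standard errors for a binomial fraction at that n, so
the check is sharp but not flaky); randomized suites elsewhere use
profiles up to 200 residues and 1000-sequence composition pools, sizes
at which the brute-force oracles are still instant.

## Numerical and degenerate-input choices

* Class fractions must sum to 1 within 1e-9; composition fractions sum
  to 1 exactly by construction.
* `which.max` resolves modal-position ties to the smallest rank, and
  the tie is flagged in the return value rather than hidden.
* Per-residue column correlations between matrices are `NA` for
  constant columns (zero variance), not forced to a number.
* Empty inputs fail loudly: empty FASTA, empty record lists, empty
  scale lists and sequences with no classifiable residue are all
  errors, not empty results.

## Known limitations

* The classification is fixed per the published scheme; it is not
  re-estimated from structures or B-factors.
* The published 70-scale occupancy matrix is verifiable only as shipped
  data (marginals, modal cells), not reproducible from scales, because
  the scale list was never published.
* Composition figures reported for database-derived corpora (e.g. a
  PDB query for thermonuclease structures, or a DisProt release) drift
  with database versions and are therefore not reproduction targets of
  this package; the machinery to compute them on any user-supplied
  dataset is.
* The disorder predictors used in the original comparisons (GlobPlot,
  RONN, PONDR) are neither invoked nor re-implemented;
  `agreement()` accepts their outputs, or any reference mask, as
  external data.
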