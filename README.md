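# flucres

Conformational flexibility drives protein folding and binding: residues
at interfaces and in disordered regions change conformation to do their
job, and which residues a sequence is made of already says a lot about
where that will happen. `flucres` is an R toolkit for sequence-based
flexibility analysis built on a fixed three-way classification of the
20 standard amino acids by conformational mobility:

| class    | residues                | index |
|----------|-------------------------|------:|
| high     | G, A, S, P, D           |    −2 |
| moderate | T, E, N, K, C, Q, R, V  |    −1 |
| weak     | H, L, M, I, Y, F, W     |    +2 |

The classification is grounded in the carbon content of each residue
(carbon-rich side chains are hydrophobic and rigid; carbon-poor ones
are small or polar and mobile); the carbon table ships alongside the
scale as plain text. Scoring a sequence position by position with the
integer index gives a fluctuation profile in which sustained negative
runs mark flexible, disorder-prone stretches and positive spikes mark
rigid ones.

It is aimed at structural bioinformaticians and protein scientists who
want to screen sequences for flexible/disordered candidate regions,
compare class compositions across datasets (folded proteins,
cell-penetrating peptides, intrinsically disordered proteins), or study
how flexibility-related amino-acid propensity scales order the
residues.

**What the package provides**

* the classification, index and carbon-content tables
  (`classify_residue()`, `fluctuation_index()`, `carbon_fraction()`);
* per-residue profiles with optional centered-moving-average smoothing
  (`profile_sequence()`, `smooth_profile()`);
* pooled class composition over sequence sets (`composition()`);
* flexible-segment calling — maximal runs with index ≤ threshold
  (default −1) of at least a minimum length (default 30, the
  long-disordered-region convention) — plus per-residue
  sensitivity/specificity against any reference annotation
  (`call_segments()`, `agreement()`);
* AAindex1 flat-file parsing, within-scale residue ranking
  (highest value first, alphabetical tie-breaks) and aggregation of
  many scales into a 20×20 rank-occupancy matrix whose rows and
  columns all sum to the number of scales (`parse_aaindex()`,
  `rank_residues()`, `build_occupancy_matrix()`, `modal_position()`);
  the published 70-scale matrix is bundled as data;
* FASTA and PDB (sequence-only) input via Biostrings and bio3d, a
  deterministic synthetic-sequence generator with controlled class
  composition, and a CLI (`exec/flucres`) over the same functions.

## Worked example

```r
library(flucres)

fluctuation_index(c("G", "K", "F"))
#> [1] -2 -1  2

# crotamine, a 42-residue cell-penetrating peptide (PDB entry 1H5O)
cro <- load_fixture("crotamine")
composition(cro)
#> <fluct_composition> 42 residues (0 skipped)
#>   high         13   31.0%
#>   moderate     19   45.2%
#>   weak         10   23.8%

# a disorder-like synthetic sequence: 55% high, 35% moderate, 10% weak
idp <- generate_sequence(120, c(high = 0.55, moderate = 0.35, weak = 0.10),
                         seed = 42, id = "idp_like")
call_segments(profile_sequence(idp), threshold = -1, min_length = 30)
#>   sequence_id start end length mean_index
#> 1    idp_like    63  93     31  -1.645161

# where does alanine sit when 70 flexibility-related hydrophobicity
# scales each rank the residues from highest to lowest value?
modal_position(load_fixture("table2"), "A")[c("position", "count")]
#> $position
#> [1] 10
#> $count
#> [1] 16
```

The crotamine numbers show the cell-penetrating-peptide signature:
over three quarters of its residues are high or moderate fluctuating,
consistent with a peptide that stays coil-like until it binds. The
segment call flags one 31-residue run whose mean index (−1.65) sits
between the high and moderate class values — a candidate long flexible
region. The modal position says alanine most often lands mid-table
(rank 10 of 20, in 16 of the 70 scales) when residues are ordered by
hydrophobicity-type properties.

The same operations are available from the shell:

```sh
exec/flucres profile my.fasta --out results --window 5
exec/flucres segments my.fasta --threshold -1 --min-length 30 --out results
exec/flucres compose structure.pdb --format pdb --chain A --out results
```

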