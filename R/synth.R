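# Synthetic sequence generation with controlled fluctuation-class
# composition, and access to the bundled fixtures.

#' Generate a synthetic protein sequence with controlled class composition
#'
#' Draws each residue by first sampling a fluctuation class according to
#' `class_fractions`, then a residue within that class — uniformly by
#' default, or proportionally to `residue_freqs` (a full 20-residue
#' frequency vector) for more realistic backgrounds. With a fixed
#' `seed` the output is deterministic and the caller's RNG state is left
#' untouched.
#'
#' The default class fractions are the alphabet proportions of the
#' scale itself (5/20 high, 8/20 moderate, 7/20 weak), i.e. the
#' composition of a uniform-residue background.
#'
#' @param length sequence length (>= 1).
#' @param class_fractions named numeric over high/moderate/weak;
#'   non-negative, summing to 1 (within 1e-9).
#' @param seed optional integer seed.
#' @param residue_freqs optional named non-negative frequencies over the
#'   20 residues, used as within-class weights.
#' @param id record identifier.
#' @param scale a [fluctuation_scale()].
#' @return A [seq_record()] with source `"synthetic"`.
#' @examples
#' generate_sequence(30, c(high = 1, moderate = 0, weak = 0), seed = 1)
#' @export
generate_sequence <- function(length,
                              class_fractions = c(high = 0.25,
                                                  moderate = 0.40,
                                                  weak = 0.35),
                              seed = NULL, residue_freqs = NULL,
                              id = "synthetic", scale = fluctuation_scale()) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("length must be >= 1")
  if (!setequal(names(class_fractions), FLUCT_CLASSES))
    stop("class_fractions must be named high/moderate/weak")
  cf <- as.numeric(class_fractions[FLUCT_CLASSES])
  if (any(cf < 0) || abs(sum(cf) - 1) > 1e-9)
    stop("class fractions must be non-negative and sum to 1")
  if (!is.null(residue_freqs)) {
    if (!setequal(names(residue_freqs), AA20) || any(residue_freqs < 0) ||
        sum(residue_freqs) <= 0)
      stop("residue_freqs must be non-negative frequencies over the 20 residues")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  members <- split(names(scale$class_of), scale$class_of)[FLUCT_CLASSES]
  cls <- sample(FLUCT_CLASSES, length, replace = TRUE, prob = cf)
  res <- character(length)
  for (cl in FLUCT_CLASSES) {
    at <- which(cls == cl)
    if (length(at) == 0L) next
    pool <- members[[cl]]
    w <- if (is.null(residue_freqs)) NULL else {
      wc <- residue_freqs[pool]
      if (sum(wc) <= 0) NULL else wc  # empty-weight class falls back to uniform
    }
    res[at] <- sample(pool, length(at), replace = TRUE, prob = w)
  }
  seq_record(id, paste(res, collapse = ""), source = "synthetic")
}

#' Load a bundled fixture
#'
#' Offline fixtures shipped with the package:
#' \describe{
#'   \item{table2 (alias occupancy70)}{the published 20x20 rank-occupancy
#'     matrix aggregated over 70 flexibility/rigidity-related
#'     hydrophobicity scales, as a [rank_occupancy_matrix()].}
#'   \item{crotamine}{the 42-residue crotamine cell-penetrating peptide
#'     (PDB entry 1H5O) as a [seq_record()], read from the bundled
#'     FASTA. A companion synthetic minimal PDB rendering of the same
#'     sequence is available via `load_fixture("crotamine_pdb")` (a
#'     path), exercising the PDB reader.}
#'   \item{sample_scales}{a small set of complete propensity scales in
#'     AAindex1 format (two transcribed published hydropathy scales plus
#'     synthetic flexibility-like scales), as a list of [aa_index()].}
#'   \item{mini_pdb}{path to a minimal 3-residue PDB file (Gly-Ala-Val).}
#' }
#'
#' @param name one of `"table2"`, `"crotamine"`, `"crotamine_pdb"`,
#'   `"sample_scales"`, `"mini_pdb"`.
#' @return The corresponding object (or a file path for the PDB
#'   fixtures).
#' @examples
#' load_fixture("table2")$n_indices       # 70
#' nchar(load_fixture("crotamine")$residues)  # 42
#' @export
load_fixture <- function(name) {
  ext <- function(f) system.file("extdata", f, package = "flucres",
                                 mustWork = TRUE)
  switch(match.arg(name, c("table2", "occupancy70", "crotamine",
                           "crotamine_pdb", "sample_scales", "mini_pdb")),
         table2 = ,
         occupancy70 = read_occupancy_matrix(ext("rank_occupancy_70.tsv")),
         crotamine = read_fasta(ext("crotamine_1h5o.fasta"))[[1]],
         crotamine_pdb = ext("crotamine_1h5o_synthetic.pdb"),
         sample_scales = parse_aaindex(ext("sample_scales.aaindex1")),
         mini_pdb = ext("mini_gav.pdb"))
}
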