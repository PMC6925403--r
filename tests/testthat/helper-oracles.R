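# Independent oracles used across the suite. Everything here is frozen
# or brute-force on purpose: none of it calls the code paths it checks.

# The published three-way classification, written out residue by residue
# (independent of the package's shipped data file).
TABLE1_CLASS <- c(
  G = "high", A = "high", S = "high", P = "high", D = "high",
  T = "moderate", E = "moderate", N = "moderate", K = "moderate",
  C = "moderate", Q = "moderate", R = "moderate", V = "moderate",
  H = "weak", L = "weak", M = "weak", I = "weak", Y = "weak",
  F = "weak", W = "weak"
)
TABLE1_INDEX <- c(high = -2L, moderate = -1L, weak = 2L)

# Chain-monomer molecular formulas (free amino acid minus one water).
RESIDUE_FORMULA <- c(
  A = "C3H5NO",    R = "C6H12N4O",  N = "C4H6N2O2", D = "C4H5NO3",
  C = "C3H5NOS",   Q = "C5H8N2O2",  E = "C5H7NO3",  G = "C2H3NO",
  H = "C6H7N3O",   I = "C6H11NO",   L = "C6H11NO",  K = "C6H12N2O",
  M = "C5H9NOS",   F = "C9H9NO",    P = "C5H7NO",   S = "C3H5NO2",
  T = "C4H7NO2",   W = "C11H10N2O", Y = "C9H9NO2",  V = "C5H9NO"
)

# atom-counting oracle: carbon fraction straight from the formula string
oracle_carbon_fraction <- function(formula) {
  m <- gregexpr("([A-Z])([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z])([0-9]*)", formula))[[1]]
  elem <- substr(parts, 1, 1)
  n <- as.integer(sub("^[A-Z]", "", parts))
  n[is.na(n)] <- 1L
  sum(n[elem == "C"]) / sum(n)
}

# per-letter tally oracle for class composition of a set of sequences
oracle_composition <- function(seqs) {
  chars <- unlist(strsplit(toupper(seqs), ""))
  cls <- TABLE1_CLASS[chars]
  cls <- cls[!is.na(cls)]
  counts <- vapply(c("high", "moderate", "weak"),
                   function(k) sum(cls == k), integer(1))
  list(counts = counts, fractions = counts / sum(counts), total = sum(counts))
}

# brute-force run scan: loop every position, no rle
oracle_segments <- function(values, threshold, min_length) {
  below <- values <= threshold
  segs <- list()
  i <- 1L
  n <- length(values)
  while (i <= n) {
    if (below[i]) {
      j <- i
      while (j < n && below[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_length)
        segs[[length(segs) + 1L]] <-
          c(start = i, end = j, length = j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  do.call(rbind, segs)
}

# position-by-position confusion counts
oracle_confusion <- function(pred, ref) {
  stopifnot(length(pred) == length(ref))
  tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] && ref[i]) tp <- tp + 1L
    else if (pred[i] && !ref[i]) fp <- fp + 1L
    else if (!pred[i] && !ref[i]) tn <- tn + 1L
    else fn <- fn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# selection-sort ranking oracle: highest value first, letters break ties
oracle_rank <- function(values, descending = TRUE) {
  nm <- names(values)
  out <- character(0)
  while (length(nm) > 0L) {
    v <- values[nm]
    best <- if (descending) nm[v == max(v)] else nm[v == min(v)]
    pick <- sort(best)[1]
    out <- c(out, pick)
    nm <- setdiff(nm, pick)
  }
  out
}

random_aa_sequence <- function(n, alphabet = names(TABLE1_CLASS)) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
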