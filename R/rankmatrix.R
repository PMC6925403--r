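# Ranking residues within propensity scales and aggregating rank
# positions over a scale collection into a 20x20 occupancy matrix.

#' Construct a rank-occupancy matrix
#'
#' A 20x20 count grid: rows are rank positions 1..20 (1 = highest
#' property value), columns the 20 residues (alphabetical). Because each
#' scale places every residue at exactly one rank, every row and every
#' column of a matrix built from `n_indices` complete scales sums to
#' `n_indices`.
#'
#' @param counts 20x20 non-negative integer matrix; columns must be
#'   named by the 20 standard residues.
#' @param n_indices number of scales aggregated.
#' @return Object of class `rank_occupancy`.
#' @export
rank_occupancy_matrix <- function(counts, n_indices) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(20L, 20L))) stop("counts must be 20x20")
  if (is.null(colnames(counts)) || !setequal(colnames(counts), AA20))
    stop("counts columns must be named by the 20 standard residues")
  counts <- counts[, AA20, drop = FALSE]
  storage.mode(counts) <- "integer"
  if (any(counts < 0L)) stop("counts must be non-negative")
  rownames(counts) <- as.character(1:20)
  n_indices <- as.integer(n_indices)
  if (!all(rowSums(counts) == n_indices) || !all(colSums(counts) == n_indices))
    stop("every row and column must sum to n_indices (", n_indices, ")")
  structure(list(counts = counts, n_indices = n_indices),
            class = "rank_occupancy")
}

#' @export
print.rank_occupancy <- function(x, ...) {
  cat(sprintf("<rank_occupancy> 20 rank positions x 20 residues, %d scales\n",
              x$n_indices))
  print(x$counts)
  invisible(x)
}

#' Rank the 20 residues within one propensity scale
#'
#' Sorts residues by property value, highest first by default (set
#' `descending = FALSE` for scales where low values mean flexible).
#' Ties are broken alphabetically by one-letter code, so the ranking is
#' deterministic and each residue occupies exactly one rank.
#'
#' @param index a complete [aa_index()] (no missing values).
#' @param descending rank 1 = highest value (default) or lowest.
#' @return Character vector of the 20 residues, rank 1 first.
#' @export
rank_residues <- function(index, descending = TRUE) {
  stopifnot(inherits(index, "aa_index"))
  if (length(index$missing) > 0L)
    stop("index ", index$accession, " has missing values for: ",
         paste(index$missing, collapse = ", "))
  v <- index$values[AA20]
  ord <- order(if (descending) -v else v, names(v))
  names(v)[ord]
}

#' Build a rank-occupancy matrix from a scale collection
#'
#' For each scale the residue at rank p increments cell (p, residue).
#' The result is invariant to the order of the scales, and its row and
#' column marginals all equal the number of scales.
#'
#' @param indices non-empty list of complete [aa_index()] objects.
#' @param descending passed to [rank_residues()].
#' @return A [rank_occupancy_matrix()].
#' @export
build_occupancy_matrix <- function(indices, descending = TRUE) {
  if (inherits(indices, "aa_index")) indices <- list(indices)
  if (length(indices) == 0L) stop("need at least one index")
  counts <- matrix(0L, 20L, 20L, dimnames = list(as.character(1:20), AA20))
  for (idx in indices) {
    ranked <- rank_residues(idx, descending = descending)
    counts[cbind(1:20, match(ranked, AA20))] <-
      counts[cbind(1:20, match(ranked, AA20))] + 1L
  }
  rank_occupancy_matrix(counts, length(indices))
}

#' Modal rank position of a residue
#'
#' The rank position where the residue is observed most often across the
#' aggregated scales. Ties resolve to the smallest position, with the
#' tie reported.
#'
#' @param matrix a [rank_occupancy_matrix()].
#' @param residue one-letter residue code.
#' @return List with `position`, `count` and logical `tie`.
#' @examples
#' m <- load_fixture("table2")
#' modal_position(m, "A")  # position 10, count 16
#' @export
modal_position <- function(matrix, residue) {
  stopifnot(inherits(matrix, "rank_occupancy"))
  residue <- .norm_aa(residue)
  if (length(residue) != 1L || !residue %in% AA20)
    stop_unknown_residue(residue, "modal_position")
  col <- matrix$counts[, residue]
  pos <- which.max(col)  # smallest index on ties
  list(position = as.integer(pos), count = as.integer(col[pos]),
       tie = sum(col == col[pos]) > 1L)
}

#' Compare two rank-occupancy matrices
#'
#' @param a,b [rank_occupancy_matrix()] objects of the same shape.
#' @return List with `max_abs_diff`, `total_abs_diff` (both symmetric in
#'   `a`, `b`), `column_correlation` (per-residue Pearson correlation,
#'   `NA` for constant columns) and `n_indices_mismatch`. A mismatch in
#'   `n_indices` additionally raises a warning.
#' @export
compare_matrices <- function(a, b) {
  stopifnot(inherits(a, "rank_occupancy"), inherits(b, "rank_occupancy"))
  d <- a$counts - b$counts
  mismatch <- a$n_indices != b$n_indices
  if (mismatch)
    warning("matrices aggregate different numbers of scales (",
            a$n_indices, " vs ", b$n_indices, ")", call. = FALSE)
  cors <- vapply(AA20, function(r) {
    suppressWarnings(stats::cor(a$counts[, r], b$counts[, r]))
  }, numeric(1))
  list(max_abs_diff = max(abs(d)), total_abs_diff = sum(abs(d)),
       column_correlation = cors, n_indices_mismatch = mismatch)
}

#' Write a rank-occupancy matrix as TSV
#'
#' 21x21 grid: a header row of residues, a first column of positions
#' 1..20, preceded by a `# n_indices=` comment. [read_occupancy_matrix()]
#' round-trips it bit-exactly.
#'
#' @param matrix a [rank_occupancy_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occupancy_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "rank_occupancy"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_indices=%d", matrix$n_indices), con)
  writeLines(paste(c("position", AA20), collapse = "\t"), con)
  for (p in 1:20)
    writeLines(paste(c(p, matrix$counts[p, ]), collapse = "\t"), con)
  invisible(path)
}

#' Read a rank-occupancy matrix from TSV
#'
#' @param path a file written by [write_occupancy_matrix()] (or any TSV
#'   in the same layout; `n_indices` is inferred from the marginals when
#'   the comment line is absent).
#' @return A [rank_occupancy_matrix()].
#' @export
read_occupancy_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  n_ind <- if (grepl("^#\\s*n_indices=", first))
    as.integer(sub("^#\\s*n_indices=", "", first)) else NA_integer_
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  if (names(tab)[1] != "position" || nrow(tab) != 20L)
    stop("expected a 20-row table with a 'position' first column")
  counts <- as.matrix(tab[, -1, drop = FALSE])
  if (is.na(n_ind)) {
    rs <- unique(rowSums(counts))
    if (length(rs) != 1L)
      stop("cannot infer n_indices: rows have unequal sums")
    n_ind <- rs
  }
  rank_occupancy_matrix(counts, n_ind)
}
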