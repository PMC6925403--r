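# Fluctuation classification of the 20 standard amino acids and the
# integer index scale built on it.

#' The 20 standard amino acids (one-letter codes, alphabetical)
#'
#' @format Character vector of length 20.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Fluctuation class labels
#'
#' The three-way partition of residues by conformational mobility:
#' `high`, `moderate` and `weak` fluctuating.
#'
#' @format Character vector of length 3.
#' @export
FLUCT_CLASSES <- c("high", "moderate", "weak")

# integer index attached to each class; fixed by the method
.CLASS_INDEX <- c(high = -2L, moderate = -1L, weak = 2L)

.flucres_cache <- new.env(parent = emptyenv())

#' Signal an unknown-residue condition
#'
#' @param aa offending residue code(s)
#' @param what short description of the operation that failed
#' @noRd
stop_unknown_residue <- function(aa, what = "residue lookup") {
  stop(errorCondition(
    sprintf("unknown residue code(s) in %s: %s (standard one-letter codes only)",
            what, paste(unique(aa), collapse = ", ")),
    class = c("flucres_unknown_residue", "error"),
    residues = unique(aa)
  ))
}

#' Fluctuation scale: residue classes, indices and carbon content
#'
#' Builds the scale object used throughout the package: the partition of
#' the 20 standard amino acids into high (G, A, S, P, D), moderate
#' (T, E, N, K, C, Q, R, V) and weak (H, L, M, I, Y, F, W) fluctuating
#' residues, the integer fluctuation index per class (-2 high, -1
#' moderate, +2 weak), and the carbon-content table underlying the
#' classification. The scale ships as a plain-text table
#' (`extdata/fluctuation_scale.tsv`: residue, class, index,
#' carbon_atoms, total_atoms) so it is auditable and can be overridden
#' via `path`.
#'
#' Atom counts are for the residue as a chain monomer, i.e. the free
#' amino acid minus one water; the carbon fraction is
#' carbon_atoms / total_atoms with hydrogens included.
#'
#' @param path optional path to an alternative scale table with the same
#'   five columns. The default reads the bundled table (cached).
#' @return An object of class `fluct_scale`: a list with `class_of`
#'   (named character), `index_of` (named integer), `carbon` (data frame
#'   with carbon_atoms, total_atoms, carbon_fraction per residue) and
#'   `table` (the raw table).
#' @examples
#' sc <- fluctuation_scale()
#' sc$index_of[c("G", "K", "F")]
#' @export
fluctuation_scale <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.flucres_cache$default_scale)) return(.flucres_cache$default_scale)
    path <- system.file("extdata", "fluctuation_scale.tsv", package = "flucres",
                        mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("residue", "class", "index", "carbon_atoms", "total_atoms")
  if (!all(need %in% names(tab)))
    stop("scale table must have columns: ", paste(need, collapse = ", "))
  tab$residue <- toupper(tab$residue)
  if (!setequal(tab$residue, AA20) || anyDuplicated(tab$residue))
    stop("scale table must cover exactly the 20 standard residues, once each")
  if (!all(tab$class %in% FLUCT_CLASSES))
    stop("scale classes must be one of: ", paste(FLUCT_CLASSES, collapse = ", "))
  # one index per class: the index is a function of the class alone
  idx_by_class <- tapply(tab$index, tab$class, function(x) length(unique(x)))
  if (any(idx_by_class != 1L))
    stop("all residues of a class must share one index")
  if (any(tab$carbon_atoms <= 0L | tab$carbon_atoms >= tab$total_atoms))
    stop("carbon_atoms must be strictly between 0 and total_atoms")
  ord <- match(AA20, tab$residue)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  carbon <- data.frame(
    residue = tab$residue,
    carbon_atoms = as.integer(tab$carbon_atoms),
    total_atoms = as.integer(tab$total_atoms),
    carbon_fraction = tab$carbon_atoms / tab$total_atoms,
    stringsAsFactors = FALSE
  )
  scale <- structure(
    list(
      class_of = stats::setNames(tab$class, tab$residue),
      index_of = stats::setNames(as.integer(tab$index), tab$residue),
      carbon = carbon,
      table = tab
    ),
    class = "fluct_scale"
  )
  if (cache) .flucres_cache$default_scale <- scale
  scale
}

#' @export
print.fluct_scale <- function(x, ...) {
  cnt <- scale_summary(x)
  cat("Fluctuation scale over the 20 standard amino acids\n")
  for (cl in FLUCT_CLASSES) {
    res <- names(x$class_of)[x$class_of == cl]
    cat(sprintf("  %-8s (index %+d, n=%d): %s\n", cl,
                x$index_of[res[1]], cnt[[cl]], paste(res, collapse = " ")))
  }
  invisible(x)
}

# normalize residue input to single upper-case letters; no validity check here
.norm_aa <- function(aa) {
  aa <- toupper(as.character(aa))
  if (any(nchar(aa) != 1L))
    stop("residue codes must be single characters; split sequences first")
  aa
}

#' Classify residues into fluctuation classes
#'
#' @param aa character vector of one-letter residue codes
#'   (case-insensitive).
#' @param scale a [fluctuation_scale()] object.
#' @return Character vector of class labels (`high`/`moderate`/`weak`),
#'   same length as `aa`.
#' @examples
#' classify_residue(c("G", "V", "W"))
#' @export
classify_residue <- function(aa, scale = fluctuation_scale()) {
  aa <- .norm_aa(aa)
  cls <- scale$class_of[aa]
  if (anyNA(cls)) stop_unknown_residue(aa[is.na(cls)], "classify_residue")
  unname(cls)
}

#' Fluctuation index of residues
#'
#' Returns the integer fluctuation index: -2 for high, -1 for moderate
#' and +2 for weak fluctuating residues.
#'
#' @inheritParams classify_residue
#' @return Integer vector, same length as `aa`.
#' @examples
#' fluctuation_index(c("G", "K", "F"))  # -2 -1  2
#' @export
fluctuation_index <- function(aa, scale = fluctuation_scale()) {
  aa <- .norm_aa(aa)
  idx <- scale$index_of[aa]
  if (anyNA(idx)) stop_unknown_residue(aa[is.na(idx)], "fluctuation_index")
  unname(idx)
}

#' Carbon fraction of residues
#'
#' Proportion of carbon atoms among all atoms of the residue as a chain
#' monomer (free amino acid minus one water, hydrogens included) — the
#' physical quantity the fluctuation classification is based on.
#'
#' @inheritParams classify_residue
#' @return Numeric vector of fractions in (0, 1), same length as `aa`.
#' @examples
#' carbon_fraction("G")  # glycine, C2H3NO: 2/7
#' @export
carbon_fraction <- function(aa, scale = fluctuation_scale()) {
  aa <- .norm_aa(aa)
  i <- match(aa, scale$carbon$residue)
  if (anyNA(i)) stop_unknown_residue(aa[is.na(i)], "carbon_fraction")
  scale$carbon$carbon_fraction[i]
}

#' Residue counts per fluctuation class
#'
#' @param scale a [fluctuation_scale()] object.
#' @return Named integer vector over `high`, `moderate`, `weak`.
#' @examples
#' scale_summary()  # 5 8 7
#' @export
scale_summary <- function(scale = fluctuation_scale()) {
  cnt <- table(factor(scale$class_of, levels = FLUCT_CLASSES))
  stats::setNames(as.integer(cnt), FLUCT_CLASSES)
}
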