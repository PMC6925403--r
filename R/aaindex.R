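# Parser for AAindex1 flat files (one numeric property value per
# residue per entry). No installed package parses this format, so the
# reader is implemented here against the documented record layout.

# fixed residue order of the two I-block value rows, per the AAindex
# documentation (not inferred from the file)
.AAINDEX_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct an amino-acid index (propensity scale)
#'
#' @param accession entry identifier.
#' @param title free-text description.
#' @param values named numeric vector over (a subset of) the 20 standard
#'   residues; residues with `NA` are moved to `missing`.
#' @return Object of class `aa_index` with fields `accession`, `title`,
#'   `values` (complete residues only) and `missing` (residues without a
#'   value). `values` plus `missing` cover exactly the 20 residues.
#' @export
aa_index <- function(accession, title = "", values) {
  stopifnot(is.character(accession), length(accession) == 1L, nzchar(accession))
  if (!setequal(names(values), AA20) || anyDuplicated(names(values)))
    stop("values must be named by exactly the 20 standard residues")
  values <- values[AA20]
  missing <- names(values)[is.na(values)]
  structure(list(accession = accession, title = title,
                 values = values[!is.na(values)], missing = missing),
            class = "aa_index")
}

#' @export
print.aa_index <- function(x, ...) {
  cat(sprintf("<aa_index> %s: %s (%d values%s)\n", x$accession, x$title,
              length(x$values),
              if (length(x$missing)) paste0(", missing ",
                                            paste(x$missing, collapse = ""))
              else ""))
  invisible(x)
}

#' Parse an AAindex1 flat file
#'
#' Reads entries in the AAindex1 format: keyed record lines (`H`
#' accession, `D` description, ..., `I` the value block) with
#' continuation lines indented, entries terminated by `//`. The `I`
#' block holds two rows of ten values in the documented residue order
#' A/R/N/D/C/Q/E/G/H/I then L/K/M/F/P/S/T/W/Y/V; literal `NA` values are
#' recorded as missing residues.
#'
#' @param path path to an AAindex1 flat file.
#' @return List of [aa_index()] objects, in file order.
#' @export
parse_aaindex <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^//", lines)
  if (length(ends) == 0L) stop("not an AAindex1 file (no '//' terminator): ", path)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- vector("list", length(ends))
  for (k in seq_along(ends)) {
    entry <- lines[starts[k]:(ends[k] - 1L)]
    entry <- entry[nzchar(trimws(entry))]
    key <- substr(entry, 1L, 1L)
    cont <- key == " "  # continuation of the previous record
    for (i in seq_along(key)) if (cont[i]) key[i] <- key[i - 1L]
    get_field <- function(k0) {
      sel <- key == k0
      if (!any(sel)) return("")
      trimws(paste(trimws(substring(entry[sel], 2L)), collapse = " "))
    }
    acc <- get_field("H")
    if (!nzchar(acc)) stop("entry ", k, " has no H (accession) record")
    ival <- entry[key == "I"]
    if (length(ival) < 2L)
      stop("entry ", acc, ": I block must have a header and value rows")
    tokens <- unlist(strsplit(trimws(ival[-1L]), "[[:space:]]+"))
    if (length(tokens) != 20L)
      stop("entry ", acc, ": I block has ", length(tokens),
           " value fields, expected 20")
    vals <- suppressWarnings(as.numeric(tokens))
    bad <- is.na(vals) & toupper(tokens) != "NA"
    if (any(bad))
      stop("entry ", acc, ": non-numeric value(s): ",
           paste(tokens[bad], collapse = ", "))
    out[[k]] <- aa_index(acc, get_field("D"),
                         stats::setNames(vals, .AAINDEX_ORDER))
  }
  out
}
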