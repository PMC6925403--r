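# Sequence records, FASTA I/O and PDB sequence extraction.

#' Construct a sequence record
#'
#' Lightweight container for one protein sequence: an identifier, an
#' optional chain, the one-letter residue string, and the source it came
#' from (`fasta`, `pdb` or `synthetic`).
#'
#' @param id non-empty identifier.
#' @param residues non-empty one-letter residue string (uppercased).
#' @param chain optional chain identifier.
#' @param source one of `"fasta"`, `"pdb"`, `"synthetic"`.
#' @return Object of class `seq_record`.
#' @export
seq_record <- function(id, residues, chain = NA_character_, source = "fasta") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(gsub("[[:space:]]", "", as.character(residues)))
  if (length(residues) != 1L || !nzchar(residues))
    stop("residues must be a non-empty string")
  source <- match.arg(source, c("fasta", "pdb", "synthetic"))
  structure(list(id = id, chain = chain, residues = residues, source = source),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s%s (%d aa, %s)\n", x$id,
              if (!is.na(x$chain)) paste0(" chain ", x$chain) else "",
              nchar(x$residues), x$source))
  invisible(x)
}

# accept a seq_record, a plain string, or a list of either
.as_records <- function(x) {
  if (inherits(x, "seq_record")) return(list(x))
  if (is.character(x)) {
    ids <- if (is.null(names(x))) paste0("seq", seq_along(x)) else names(x)
    return(mapply(seq_record, ids, x, SIMPLIFY = FALSE))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "seq_record"))) return(x)
  stop("expected a seq_record, a character vector, or a list of seq_record")
}

#' Read protein sequences from a FASTA file
#'
#' The record id is the header token up to the first whitespace;
#' sequences are uppercased with whitespace stripped.
#'
#' @param path path to a FASTA file.
#' @return List of [seq_record()] objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("no sequences in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i)
    seq_record(ids[i], as.character(set[[i]]), source = "fasta"))
}

#' Write sequence records to a FASTA file
#'
#' Standard FASTA, 60-column wrapped. `write_fasta()` followed by
#' [read_fasta()] is the identity on (id, residues).
#'
#' @param records non-empty list of [seq_record()] objects (or character
#'   vector of sequences).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- .as_records(records)
  if (length(records) == 0L) stop("no records to write")
  set <- Biostrings::AAStringSet(vapply(records, `[[`, character(1), "residues"))
  names(set) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Extract protein sequences from a PDB file
#'
#' Returns one record per protein chain. The sequence is taken from
#' SEQRES records when present (the full construct, including residues
#' without coordinates); set `from_atoms = TRUE` to force the
#' ATOM-CA-derived sequence instead. Three-letter codes are translated
#' to one-letter; unknown monomers become `X`. For multi-model (NMR)
#' entries only the first model is read.
#'
#' @param path path to a PDB-format file.
#' @param chain optional chain identifier; all protein chains if `NULL`.
#' @param from_atoms use ATOM CA records even when SEQRES is present.
#' @return List of [seq_record()] objects (source `"pdb"`, chain set).
#' @export
extract_pdb_sequence <- function(path, chain = NULL, from_atoms = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE))
  seqs <- list()
  if (!from_atoms && length(pdb$seqres) > 0L) {
    seqs <- split(unname(pdb$seqres), names(pdb$seqres))
  } else {
    at <- pdb$atom[pdb$atom$type == "ATOM" & pdb$atom$elety == "CA", , drop = FALSE]
    if (nrow(at) > 0L) {
      key <- paste(at$chain, at$resno, at$insert)
      at <- at[!duplicated(key), , drop = FALSE]
      seqs <- split(at$resid, at$chain)
    }
  }
  if (length(seqs) == 0L)
    stop("no sequence-bearing records (SEQRES or ATOM) in ", path)
  one <- lapply(seqs, function(res3) {
    aa <- suppressWarnings(bio3d::aa321(res3))
    aa[is.na(aa) | !nzchar(aa)] <- "X"
    paste(aa, collapse = "")
  })
  # protein chains: at least one residue translates to a standard code
  is_prot <- vapply(one, function(s)
    any(strsplit(s, "")[[1]] %in% AA20), logical(1))
  one <- one[is_prot]
  if (length(one) == 0L) stop("no protein chains in ", path)
  if (!is.null(chain)) {
    if (!chain %in% names(one))
      stop("chain '", chain, "' not found; available: ",
           paste(names(one), collapse = ", "))
    one <- one[chain]
  }
  base <- tools::file_path_sans_ext(basename(path))
  lapply(names(one), function(ch)
    seq_record(paste0(base, "_", ch), one[[ch]], chain = ch, source = "pdb"))
}
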