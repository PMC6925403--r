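# Per-residue fluctuation profiles, smoothing, composition over
# sequence sets, flexible-segment calling and per-residue agreement
# against reference annotations.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-residue fluctuation profile of a sequence
#'
#' Assigns every residue its integer fluctuation index (-2 high, -1
#' moderate, +2 weak). Residues outside the 20-letter standard alphabet
#' (X, B, Z, U, O, gaps, ...) are handled per `unknown_policy`:
#' \describe{
#'   \item{skip}{drop them (with a warning); positions are retained so
#'     outputs still refer to the original numbering.}
#'   \item{zero}{keep them with index 0 and class `NA`.}
#'   \item{error}{fail, naming the offending positions.}
#' }
#'
#' @param record a [seq_record()] or a plain sequence string.
#' @param scale a [fluctuation_scale()].
#' @param unknown_policy `"skip"` (default), `"zero"` or `"error"`.
#' @return Object of class `fluct_profile`: `sequence_id`, `positions`
#'   (original 1-based positions retained), `residues`, `classes`,
#'   `values` (integer indices), `smoothed` (`NULL` until
#'   [smooth_profile()]), `window`, `skipped`.
#' @examples
#' p <- profile_sequence("GTW")
#' p$values  # -2 -1  2
#' @export
profile_sequence <- function(record, scale = fluctuation_scale(),
                             unknown_policy = c("skip", "zero", "error")) {
  unknown_policy <- match.arg(unknown_policy)
  rec <- .as_records(record)[[1]]
  chars <- strsplit(rec$residues, "")[[1]]
  cls <- scale$class_of[chars]
  unknown <- is.na(cls)
  pos <- seq_along(chars)
  skipped <- 0L
  if (any(unknown)) {
    if (unknown_policy == "error") {
      stop("unknown residue(s) at position(s) ",
           paste(pos[unknown], collapse = ", "), " in '", rec$id, "': ",
           paste(unique(chars[unknown]), collapse = ", "))
    } else if (unknown_policy == "skip") {
      skipped <- sum(unknown)
      warning(skipped, " unknown residue(s) skipped in '", rec$id, "'",
              call. = FALSE)
      keep <- !unknown
      chars <- chars[keep]; cls <- cls[keep]; pos <- pos[keep]
      unknown <- unknown[keep]
    }
  }
  values <- ifelse(is.na(cls), 0L, scale$index_of[chars])
  structure(list(sequence_id = rec$id, positions = pos, residues = chars,
                 classes = unname(cls), values = as.integer(unname(values)),
                 smoothed = NULL, window = 1L, skipped = skipped),
            class = "fluct_profile")
}

#' @export
print.fluct_profile <- function(x, ...) {
  cat(sprintf("<fluct_profile> %s: %d residues%s%s\n", x$sequence_id,
              length(x$values),
              if (x$skipped) sprintf(" (%d skipped)", x$skipped) else "",
              if (!is.null(x$smoothed)) sprintf(", smoothed (window %d)", x$window)
              else ""))
  invisible(x)
}

#' @export
as.data.frame.fluct_profile <- function(x, ...) {
  data.frame(position = x$positions, residue = x$residues, class = x$classes,
             index = x$values,
             smoothed = x$smoothed %||% as.numeric(x$values),
             stringsAsFactors = FALSE)
}

#' Smooth a fluctuation profile with a centered moving average
#'
#' At the sequence ends the window shrinks symmetrically, so the
#' smoothed series has the same length as the raw one and every smoothed
#' value lies within the range of the raw values. `window = 1` leaves
#' the profile unsmoothed.
#'
#' @param profile a [profile_sequence()] result.
#' @param window odd integer window length in residues, between 1 and
#'   the profile length.
#' @return The profile with `smoothed` and `window` set.
#' @export
smooth_profile <- function(profile, window) {
  stopifnot(inherits(profile, "fluct_profile"))
  n <- length(profile$values)
  if (length(window) != 1L || is.na(window) || window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd integer")
  if (window > n) stop("window (", window, ") exceeds profile length (", n, ")")
  v <- as.numeric(profile$values)
  half <- (as.integer(window) - 1L) %/% 2L
  profile$smoothed <- vapply(seq_len(n), function(i) {
    k <- min(half, i - 1L, n - i)
    mean(v[(i - k):(i + k)])
  }, numeric(1))
  profile$window <- as.integer(window)
  profile
}

#' Fluctuation-class composition of a sequence set
#'
#' Pools residues over all records and counts each fluctuation class.
#' Unknown residues are skipped (counted in `skipped`), keeping the
#' denominator well defined.
#'
#' @param records a [seq_record()], list of them, or character vector of
#'   sequences.
#' @param scale a [fluctuation_scale()].
#' @return Object of class `fluct_composition`: `counts` and `fractions`
#'   (named over high/moderate/weak), `total` classifiable residues,
#'   `skipped`.
#' @examples
#' composition("GASPD")$fractions  # all high
#' @export
composition <- function(records, scale = fluctuation_scale()) {
  records <- .as_records(records)
  chars <- unlist(strsplit(vapply(records, `[[`, character(1), "residues"), ""))
  cls <- scale$class_of[chars]
  skipped <- sum(is.na(cls))
  cls <- cls[!is.na(cls)]
  if (length(cls) == 0L) stop("no classifiable residues in input")
  counts <- table(factor(cls, levels = FLUCT_CLASSES))
  counts <- stats::setNames(as.integer(counts), FLUCT_CLASSES)
  structure(list(counts = counts, fractions = counts / sum(counts),
                 total = sum(counts), skipped = skipped),
            class = "fluct_composition")
}

#' @export
print.fluct_composition <- function(x, ...) {
  cat(sprintf("<fluct_composition> %d residues (%d skipped)\n", x$total, x$skipped))
  for (cl in FLUCT_CLASSES)
    cat(sprintf("  %-8s %6d  %5.1f%%\n", cl, x$counts[[cl]],
                100 * x$fractions[[cl]]))
  invisible(x)
}

#' @export
as.data.frame.fluct_composition <- function(x, ...) {
  data.frame(class = FLUCT_CLASSES, count = unname(x$counts),
             fraction = unname(x$fractions), stringsAsFactors = FALSE)
}

#' Call contiguous flexible segments from a profile
#'
#' Reports maximal runs of consecutive positions whose profile value
#' (smoothed if present, else raw) is at or below `threshold`, keeping
#' runs of at least `min_length` residues. The defaults — threshold -1,
#' capturing the high and moderate classes, and minimum length 30, the
#' conventional cutoff for long disordered regions — target candidate
#' long flexible/disordered segments.
#'
#' Positions are 1-based inclusive in the profile's own coordinates
#' (identical to sequence coordinates unless residues were skipped).
#'
#' @param profile a [profile_sequence()] result.
#' @param threshold call positions with value <= threshold.
#' @param min_length minimum run length in residues (>= 1).
#' @return Data frame with columns `sequence_id`, `start`, `end`,
#'   `length`, `mean_index`, sorted by `start`.
#' @export
call_segments <- function(profile, threshold = -1, min_length = 30L) {
  stopifnot(inherits(profile, "fluct_profile"),
            is.finite(threshold), min_length >= 1L)
  v <- profile$smoothed %||% as.numeric(profile$values)
  runs <- rle(v <= threshold)
  end <- cumsum(runs$lengths)
  start <- end - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_length
  start <- start[keep]; end <- end[keep]
  data.frame(
    sequence_id = rep(profile$sequence_id, length(start)),
    start = as.integer(start), end = as.integer(end),
    length = as.integer(end - start + 1L),
    mean_index = vapply(seq_along(start),
                        function(i) mean(v[start[i]:end[i]]), numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Per-residue agreement with a reference annotation
#'
#' Treats membership in any called segment as a positive per-residue
#' prediction and compares it with a binary reference mask, yielding a
#' confusion matrix with sensitivity and specificity.
#'
#' @param segments data frame from [call_segments()] (columns `start`,
#'   `end`), all within `[1, length]`.
#' @param reference_mask logical (or 0/1) vector of length `length`;
#'   `TRUE` = annotated positive (e.g. disordered).
#' @param length sequence length.
#' @return Object of class `fluct_agreement`: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity` (tp/(tp+fn)), `specificity` (tn/(tn+fp)); rates are
#'   `NA` when their denominator is 0.
#' @export
agreement <- function(segments, reference_mask, length) {
  length <- as.integer(length)
  ref <- as.logical(reference_mask)
  if (base::length(ref) != length || anyNA(ref))
    stop("reference_mask must be a complete binary vector of length ", length)
  pred <- rep(FALSE, length)
  if (nrow(segments) > 0L) {
    if (any(segments$start < 1L | segments$end > length |
            segments$start > segments$end))
      stop("segment out of range [1, ", length, "]")
    for (i in seq_len(nrow(segments)))
      pred[segments$start[i]:segments$end[i]] <- TRUE
  }
  tp <- sum(pred & ref); fp <- sum(pred & !ref)
  tn <- sum(!pred & !ref); fn <- sum(!pred & ref)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  ), class = "fluct_agreement")
}

#' @export
print.fluct_agreement <- function(x, ...) {
  cat(sprintf("<fluct_agreement> tp=%d fp=%d tn=%d fn=%d  sens=%.3f spec=%.3f\n",
              x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity))
  invisible(x)
}
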