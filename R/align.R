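as_dna_string <- function(x) {
  if (methods::is(x, "DNAString")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(Biostrings::DNAString(toupper(x)))
  }
  stop("sequence must be a single character string or a DNAString")
}

#' Global pairwise alignment of a query to a reference
#'
#' Needleman-Wunsch optimal global alignment with affine gaps and
#' un-penalized terminal gaps (ends-free/overlap mode), the appropriate mode
#' for near-identical amplicon sequences of slightly different trimmed
#' lengths. Default scoring: match +2, mismatch -1, gap open -5, gap extend
#' -2 (a gap of length L costs `open + L * extend`).
#'
#' @param query,reference DNA sequences (character strings or `DNAString`s);
#'   IUPAC ambiguity codes are allowed.
#' @param match,mismatch,gap_opening,gap_extension Scoring parameters
#'   (penalties given as positive magnitudes for the gap terms).
#' @return An object of class `pairwise_alignment`: a list with the gapped
#'   `query_aln`/`ref_aln` strings (equal length), `query_start`/`ref_start`
#'   (1-based positions of the first aligned residue in each original
#'   sequence) and the alignment `score`.
#' @export
global_align <- function(query, reference, match = 2, mismatch = -1,
                         gap_opening = 5, gap_extension = 2) {
  q <- as_dna_string(query)
  r <- as_dna_string(reference)
  if (length(q) == 0L || length(r) == 0L) stop("sequences must be non-empty")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    q, r, type = "overlap", substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  structure(list(
    query_aln = as.character(Biostrings::alignedPattern(al)),
    ref_aln = as.character(Biostrings::alignedSubject(al)),
    query_start = BiocGenerics::start(Biostrings::pattern(al)),
    ref_start = BiocGenerics::start(Biostrings::subject(al)),
    query_length = length(q),
    ref_length = length(r),
    score = Biostrings::score(al)
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment: %d columns, score %.1f\n",
              nchar(x$query_aln), x$score))
  invisible(x)
}

#' Call nucleotide substitutions from a pairwise alignment
#'
#' One call per aligned column where the query and reference carry two
#' unambiguous, unequal bases and both positions are quality-trusted.
#' Columns containing a gap or an IUPAC ambiguity code are skipped, never
#' called. Coordinates are 1-based in the original (ungapped) sequences.
#'
#' @param alignment A [global_align()] result (query = sample sequence,
#'   reference = the sequence substitutions are called against).
#' @param query_mask,ref_mask Optional logical vectors over the full original
#'   sequences (`TRUE` = trusted position); `NULL` trusts everything.
#' @return A data.frame with columns `query_position`, `ref_position`,
#'   `ref_base`, `alt_base` (the base observed in the query).
#' @export
call_substitutions <- function(alignment, query_mask = NULL, ref_mask = NULL) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  qc <- strsplit(alignment$query_aln, "", fixed = TRUE)[[1]]
  rc <- strsplit(alignment$ref_aln, "", fixed = TRUE)[[1]]
  if (!is.null(query_mask) && length(query_mask) != alignment$query_length) {
    stop("query_mask length must equal the query sequence length")
  }
  if (!is.null(ref_mask) && length(ref_mask) != alignment$ref_length) {
    stop("ref_mask length must equal the reference sequence length")
  }
  qpos <- alignment$query_start - 1L + cumsum(qc != "-")
  rpos <- alignment$ref_start - 1L + cumsum(rc != "-")
  plain <- c("A", "C", "G", "T")
  callable <- qc %in% plain & rc %in% plain & qc != rc
  if (!is.null(query_mask)) callable <- callable & query_mask[qpos]
  if (!is.null(ref_mask)) callable <- callable & ref_mask[rpos]
  idx <- which(callable)
  data.frame(query_position = qpos[idx], ref_position = rpos[idx],
             ref_base = rc[idx], alt_base = qc[idx])
}

#' Translate sequence positions into another sequence's coordinates
#'
#' Aligns `from_seq` to `to_seq` and maps each position through the aligned
#' columns; positions falling in a gap of `to_seq` (no homologous base) map
#' to `NA`.
#'
#' @param positions 1-based positions in `from_seq`.
#' @param from_seq,to_seq DNA sequences.
#' @param ... Scoring parameters passed to [global_align()].
#' @return Integer vector of 1-based positions in `to_seq` (`NA` where
#'   unmapped).
#' @export
translate_positions <- function(positions, from_seq, to_seq, ...) {
  al <- global_align(from_seq, to_seq, ...)
  qc <- strsplit(al$query_aln, "", fixed = TRUE)[[1]]
  rc <- strsplit(al$ref_aln, "", fixed = TRUE)[[1]]
  qpos <- al$query_start - 1L + cumsum(qc != "-")
  rpos <- al$ref_start - 1L + cumsum(rc != "-")
  vapply(positions, function(p) {
    col <- which(qpos == p & qc != "-")
    if (!length(col) || rc[col[1]] == "-") return(NA_integer_)
    as.integer(rpos[col[1]])
  }, integer(1))
}
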