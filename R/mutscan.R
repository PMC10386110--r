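#' Scan a weekly 16S sequence series for nucleotide substitutions
#'
#' Each weekly consensus sequence is globally aligned to the series
#' reference (by default the first, week-1 sequence) and substitutions are
#' called per [call_substitutions()]. Reference positions are then expressed
#' in the coordinate system of `coord_ref` (e.g. the E. coli 16S reference)
#' when one is supplied — via [translate_positions()] — and labelled with
#' their variable region.
#'
#' For near-identical amplicon series, pairwise alignment of every weekly
#' sequence to the week-1 sequence is equivalent to a multiple alignment for
#' substitution calling and far easier to audit.
#'
#' @param sequences A named character vector / list / `DNAStringSet` of
#'   weekly sequences, in chronological order.
#' @param reference The sequence substitutions are called against; defaults
#'   to the first element of `sequences`.
#' @param coord_ref Optional coordinate reference sequence; when `NULL`,
#'   reference coordinates are used directly for region mapping (appropriate
#'   when `reference` is already in the region map's numbering, as for the
#'   bundled synthetic series).
#' @param region_map Variable-region table, see [default_region_map()].
#' @param masks Optional named list of per-sequence logical quality masks.
#' @return A data.frame with one row per substitution: `sample`,
#'   `query_position`, `ref_position`, `coord_position` (reference numbering
#'   after translation), `ref_base`, `alt_base`, `region`.
#' @export
scan_16s_series <- function(sequences, reference = NULL, coord_ref = NULL,
                            region_map = default_region_map(), masks = NULL) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  sequences <- vapply(sequences, as.character, character(1))
  if (!length(sequences)) stop("no sequences supplied")
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("sample", seq_along(sequences))
  if (is.null(reference)) reference <- sequences[[1]]
  reference <- as.character(reference)

  translate <- if (is.null(coord_ref)) {
    identity
  } else {
    function(p) translate_positions(p, reference, coord_ref)
  }

  out <- lapply(seq_along(sequences), function(k) {
    al <- global_align(sequences[[k]], reference)
    calls <- call_substitutions(
      al,
      query_mask = if (!is.null(masks)) masks[[ids[k]]] else NULL)
    if (!nrow(calls)) return(NULL)
    coord <- translate(calls$ref_position)
    data.frame(sample = ids[k], calls, coord_position = coord,
               region = ifelse(is.na(coord), NA_character_,
                               map_to_regions(coord, region_map)))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(sample = character(0), query_position = integer(0),
                      ref_position = integer(0), ref_base = character(0),
                      alt_base = character(0), coord_position = integer(0),
                      region = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readDNAStringSet()` returning a named
#' character vector in the form the scanning functions accept.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(s)), names(s))
}
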