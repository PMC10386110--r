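#' Variable-region map of the 16S rRNA gene
#'
#' Loads the bundled V1-V9 interval table (E. coli numbering, 1-based
#' inclusive). Interval boundaries differ between published conventions;
#' the bundled table is one common convention and is an editable CSV
#' resource, replaceable via `path`.
#'
#' @param path Optional path to an alternative CSV with columns `region`,
#'   `start`, `end`.
#' @return A data.frame with ascending, non-overlapping intervals.
#' @export
default_region_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "regions_16s.csv", package = "oxyderep")
  }
  map <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("region", "start", "end") %in% names(map))) {
    stop("region map must have columns 'region', 'start', 'end'")
  }
  map <- map[order(map$start), , drop = FALSE]
  if (any(map$end < map$start)) stop("region intervals must have start <= end")
  if (nrow(map) > 1 && any(map$start[-1] <= map$end[-nrow(map)])) {
    stop("region intervals must not overlap")
  }
  if (anyDuplicated(map$region)) stop("duplicate region labels")
  rownames(map) <- NULL
  map
}

#' Map a reference position to its 16S region label
#'
#' @param ref_position 1-based position(s) in reference coordinates.
#' @param region_map A region map (see [default_region_map()]).
#' @param ref_length Optional reference length for range checking; positions
#'   beyond it (or `< 1`) are an error.
#' @return Character vector of region labels (`"V1"`..`"V9"` or
#'   `"conserved"`).
#' @export
map_to_regions <- function(ref_position, region_map = default_region_map(),
                           ref_length = NULL) {
  if (any(ref_position < 1)) stop("position out of range (< 1)")
  if (!is.null(ref_length) && any(ref_position > ref_length)) {
    stop("position out of range (beyond reference length)")
  }
  vapply(ref_position, function(p) {
    hit <- region_map$start <= p & p <= region_map$end
    if (any(hit)) region_map$region[which(hit)[1]] else "conserved"
  }, character(1))
}
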