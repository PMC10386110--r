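#' Dereplication parameters
#'
#' The identification rule is conjunctive: a library record is accepted for a
#' feature only when the absolute Dalton difference is strictly below
#' `max_delta_da` AND the absolute ppm difference is strictly below
#' `max_delta_ppm` AND the record's biological source matches the filter,
#' simultaneously. Defaults are 0.001 Da and 10 ppm.
#'
#' @param max_delta_da Dalton tolerance (strict upper bound, `> 0`).
#' @param max_delta_ppm ppm tolerance (strict upper bound, `> 0`).
#' @param adducts Adduct table used when matching raw m/z values.
#' @param source_filter Producing genus to require (case-insensitive exact
#'   match), or `"any"` to disable the source rule.
#' @return A list of class `derep_params`.
#' @export
derep_params <- function(max_delta_da = 0.001, max_delta_ppm = 10,
                         adducts = default_adducts(), source_filter = "any") {
  if (max_delta_da <= 0 || max_delta_ppm <= 0) {
    stop("tolerances must be positive")
  }
  if (!nrow(adducts)) stop("adduct set must be non-empty")
  structure(list(max_delta_da = max_delta_da, max_delta_ppm = max_delta_ppm,
                 adducts = adducts, source_filter = source_filter),
            class = "derep_params")
}

match_one_mass <- function(neutral_mass, library, params, adduct_label) {
  # the Da bound is a superset of every conjunctive match; ppm filtered below
  hits <- mass_range_query(library, neutral_mass, params$max_delta_da)
  if (!nrow(hits)) return(NULL)
  err <- mass_error(neutral_mass, hits$monoisotopic_mass)
  keep <- abs(err$delta_da) < params$max_delta_da &
    abs(err$delta_ppm) < params$max_delta_ppm
  if (params$source_filter != "any") {
    keep <- keep & tolower(hits$biological_source) ==
      tolower(params$source_filter)
  }
  if (!any(keep)) return(NULL)
  data.frame(compound = hits$name[keep],
             biological_source = hits$biological_source[keep],
             activities = hits$activities[keep],
             adduct = adduct_label,
             library_mass = hits$monoisotopic_mass[keep],
             delta_da = err$delta_da[keep],
             delta_ppm = err$delta_ppm[keep])
}

#' Dereplicate feature clusters against a compound library
#'
#' Assigns library identities to feature clusters under the conjunctive
#' Dalton + ppm tolerance and biological-source rule. Cluster consensus
#' masses are compared to library masses directly when they are neutral
#' (deconvoluted) masses; when `mz_mode = TRUE` the cluster masses are taken
#' as raw m/z values and every adduct in the parameter set is tried, each
#' candidate neutral mass being matched against the library.
#'
#' @param clusters A `feature_clusters` object from [align_features()], or a
#'   data.frame with columns `cluster_id` and `consensus_mass`.
#' @param library A [compound_library()].
#' @param params A [derep_params()] object.
#' @param mz_mode Match at the adduct m/z level instead of neutral masses.
#' @return A data.frame of matches with one row per (cluster, compound,
#'   adduct) assignment: `cluster_id`, `compound`, `adduct`, `library_mass`,
#'   `delta_da`, `delta_ppm`, `rank` (1 = smallest absolute ppm error within
#'   the cluster). Clusters with no match do not appear (they are the
#'   unknowns).
#' @export
dereplicate <- function(clusters, library, params = derep_params(),
                        mz_mode = FALSE) {
  if (inherits(clusters, "feature_clusters")) clusters <- clusters$clusters
  stopifnot(all(c("cluster_id", "consensus_mass") %in% names(clusters)))
  if (!nrow(library)) stop("library must be non-empty")

  out <- vector("list", nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    if (mz_mode) {
      cand <- list()
      for (k in seq_len(nrow(params$adducts))) {
        a <- params$adducts[k, ]
        nm <- clusters$consensus_mass[i] * a$charge - a$mass_shift
        if (nm <= 0) next
        cand[[length(cand) + 1L]] <-
          match_one_mass(nm, library, params, a$label)
      }
      hits <- if (length(cand)) do.call(rbind, cand) else NULL
    } else {
      hits <- match_one_mass(clusters$consensus_mass[i], library, params,
                             "neutral")
    }
    if (!is.null(hits) && nrow(hits)) {
      hits <- hits[order(abs(hits$delta_ppm), hits$compound), , drop = FALSE]
      hits$rank <- seq_len(nrow(hits))
      hits <- cbind(cluster_id = clusters$cluster_id[i], hits)
      out[[i]] <- hits
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(cluster_id = integer(0), compound = character(0),
                      biological_source = character(0),
                      activities = character(0), adduct = character(0),
                      library_mass = numeric(0), delta_da = numeric(0),
                      delta_ppm = numeric(0), rank = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize a dereplication run
#'
#' @param matches The data.frame returned by [dereplicate()].
#' @param clusters The clusters that were dereplicated (to count unknowns).
#' @return A list with `identified`, `unknown`, `total` counts
#'   (`identified + unknown == total`) and `activity_counts`, a table of how
#'   many clusters have a rank-1 match carrying each activity annotation.
#' @export
summarize_identification <- function(matches, clusters) {
  if (inherits(clusters, "feature_clusters")) clusters <- clusters$clusters
  total <- nrow(clusters)
  identified_ids <- unique(matches$cluster_id)
  identified <- length(identified_ids)
  top <- matches[matches$rank == 1, , drop = FALSE]
  acts <- unlist(lapply(strsplit(top$activities, ";", fixed = TRUE),
                        function(x) unique(trimws(x[nzchar(trimws(x))]))))
  activity_counts <- if (length(acts)) table(acts) else table(character(0))
  list(identified = identified, unknown = total - identified, total = total,
       activity_counts = activity_counts)
}
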