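#' Build a presence/absence matrix over a sampling design
#'
#' A presence matrix records, for every feature cluster (row) and every
#' designed sample (column), whether the cluster was observed in that sample
#' with intensity strictly above a floor. Designed samples with no data at
#' all yield all-false columns with a warning.
#'
#' @param clusters A `feature_clusters` object from [align_features()].
#' @param design A data.frame with columns `strain`, `condition`, `week`,
#'   `fraction`, one row per designed sample; defaults to the samples present
#'   in the data. Duplicate design rows are an error.
#' @param intensity_floor Detection floor (default 0: any positive intensity
#'   counts as presence).
#' @return An object of class `presence_matrix`: a list with `presence`
#'   (logical matrix, rows = cluster ids, columns = sample ids), `clusters`
#'   (cluster summary with consensus mass/RT) and `design`.
#' @export
build_presence_matrix <- function(clusters, design = NULL,
                                  intensity_floor = 0) {
  stopifnot(inherits(clusters, "feature_clusters"))
  members <- clusters$members
  if (is.null(design)) {
    design <- unique(members[c("strain", "condition", "week", "fraction")])
    design <- design[order(match(design$condition, CONDITIONS),
                           design$fraction, design$week), , drop = FALSE]
  }
  ids <- sample_id(design$strain, design$condition, design$week,
                   design$fraction)
  if (anyDuplicated(ids)) stop("duplicate design columns")
  orphan <- setdiff(ids, members$sample_id)
  if (length(orphan)) {
    warning(sprintf("design sample(s) with no data: %s",
                    paste(orphan, collapse = ", ")))
  }

  pres <- matrix(FALSE, nrow = nrow(clusters$clusters), ncol = length(ids),
                 dimnames = list(clusters$clusters$cluster_id, ids))
  observed <- members[members$intensity > intensity_floor &
                        members$sample_id %in% ids, , drop = FALSE]
  if (nrow(observed)) {
    pres[cbind(match(observed$cluster_id, clusters$clusters$cluster_id),
               match(observed$sample_id, ids))] <- TRUE
  }
  design$sample_id <- ids
  structure(list(presence = pres, clusters = clusters$clusters,
                 design = design),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d clusters x %d samples (%d conditions)\n",
              nrow(x$presence), ncol(x$presence),
              length(unique(x$design$condition))))
  invisible(x)
}

control_columns <- function(pm) which(pm$design$condition == "C")
experimental_columns <- function(pm) which(pm$design$condition != "C")

#' Clusters synthesized only under experimental conditions
#'
#' Returns the clusters with zero presence across every control (natural
#' aeration, `C`) column and at least one presence in an experimental (`O2`
#' or `O3`) column — the presence-level notion of "synthesized only under
#' experimental conditions".
#'
#' @param pm A [build_presence_matrix()] result.
#' @return The cluster ids (same type as `pm$clusters$cluster_id`).
#' @export
detect_only_experimental <- function(pm) {
  stopifnot(inherits(pm, "presence_matrix"))
  ctrl <- control_columns(pm)
  expc <- experimental_columns(pm)
  if (!length(ctrl)) stop("design has no control (C) columns")
  if (!length(expc)) stop("design has no experimental columns")
  no_ctrl <- rowSums(pm$presence[, ctrl, drop = FALSE]) == 0
  any_exp <- rowSums(pm$presence[, expc, drop = FALSE]) > 0
  pm$clusters$cluster_id[no_ctrl & any_exp]
}

#' Clusters induced within a retention-time window
#'
#' Returns the clusters whose consensus retention time falls inside
#' `[rt_low, rt_high]` and whose number of experimental-column presences
#' strictly exceeds the number of control-column presences — a
#' presence-count notion of induction relative to natural aeration.
#'
#' @param pm A [build_presence_matrix()] result.
#' @param rt_low,rt_high Window bounds in minutes, `rt_low < rt_high`.
#' @return The cluster ids.
#' @export
induced_in_window <- function(pm, rt_low, rt_high) {
  stopifnot(inherits(pm, "presence_matrix"))
  if (!(rt_low < rt_high)) stop("rt_low must be < rt_high")
  ctrl <- control_columns(pm)
  expc <- experimental_columns(pm)
  in_window <- pm$clusters$consensus_rt >= rt_low &
    pm$clusters$consensus_rt <= rt_high
  n_exp <- rowSums(pm$presence[, expc, drop = FALSE])
  n_ctrl <- rowSums(pm$presence[, ctrl, drop = FALSE])
  pm$clusters$cluster_id[in_window & n_exp > n_ctrl]
}

#' Concordance between a presence pattern and an activity pattern
#'
#' Simple matching coefficient: the proportion of samples (in identical
#' column order) where the two boolean vectors agree. 1 means the metabolite
#' presence pattern and the bioassay pattern coincide exactly.
#'
#' @param cluster_row Logical vector of per-sample presence.
#' @param activity_row Logical vector of per-sample activity, same length and
#'   order.
#' @return A fraction in `[0, 1]`.
#' @export
presence_activity_concordance <- function(cluster_row, activity_row) {
  if (length(cluster_row) != length(activity_row)) {
    stop("presence and activity vectors must have the same length")
  }
  if (!length(cluster_row)) stop("vectors must be non-empty")
  mean(as.logical(cluster_row) == as.logical(activity_row))
}
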