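CONDITIONS <- c("C", "O2", "O3")
FRACTIONS <- c("biomass", "cultural_liquid")

# One canonical id per sample so clusters/presence columns line up everywhere.
sample_id <- function(strain, condition, week, fraction) {
  paste(strain, condition, week, fraction, sep = "|")
}

#' Validate an LC-MS feature table
#'
#' A feature table has one row per detected feature per sample with columns
#' `rt_min` (retention time, minutes), `neutral_mass` (Da), `intensity`
#' (arbitrary units, `>= 0`) and the sample metadata `strain`, `condition`
#' (one of `C`, `O2`, `O3`: natural aeration / elevated oxygen / elevated
#' oxygen + ozone), `week` (integer `>= 1`) and `fraction` (`biomass` or
#' `cultural_liquid`).
#'
#' @param features A data.frame with the columns above.
#' @param rt_window Allowed retention-time range in minutes (the
#'   chromatographic run window); default `c(0, 18)`.
#' @return The validated data.frame with an added `sample_id` column.
#' @export
feature_table <- function(features, rt_window = c(0, 18)) {
  required <- c("rt_min", "neutral_mass", "intensity", "strain", "condition",
                "week", "fraction")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols)) {
    stop(sprintf("missing feature-table column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(features)) {
    if (!all(features$condition %in% CONDITIONS)) {
      stop(sprintf("unknown condition token(s): %s",
                   paste(unique(setdiff(features$condition, CONDITIONS)),
                         collapse = ", ")))
    }
    if (!all(features$fraction %in% FRACTIONS)) {
      stop(sprintf("unknown fraction token(s): %s",
                   paste(unique(setdiff(features$fraction, FRACTIONS)),
                         collapse = ", ")))
    }
    if (any(features$week < 1 | features$week != round(features$week))) {
      stop("week must be an integer >= 1")
    }
    if (any(features$neutral_mass <= 0)) stop("neutral_mass must be positive")
    if (any(features$intensity < 0)) stop("intensity must be >= 0")
    if (any(features$rt_min < rt_window[1] | features$rt_min > rt_window[2])) {
      stop(sprintf("rt_min outside the run window [%g, %g]",
                   rt_window[1], rt_window[2]))
    }
  }
  features$sample_id <- sample_id(features$strain, features$condition,
                                  features$week, features$fraction)
  features
}

#' Read a feature table from CSV
#'
#' Rows may carry a `neutral_mass` directly, or an `mz` plus `adduct_label`
#' pair which is converted via [neutral_from_mz()]. If both are given they
#' must agree within 1e-4 Da.
#'
#' @param path Path to a CSV file (`#` lines are comments).
#' @param adducts Adduct table used to resolve `adduct_label`.
#' @param rt_window Passed to [feature_table()].
#' @return A validated feature table.
#' @export
read_feature_table <- function(path, adducts = default_adducts(),
                               rt_window = c(0, 18)) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  has_mz <- "mz" %in% names(raw) && "adduct_label" %in% names(raw)
  if (!"neutral_mass" %in% names(raw)) {
    if (!has_mz) stop("need either a neutral_mass column or mz + adduct_label")
    raw$neutral_mass <- NA_real_
  }
  if (has_mz) {
    for (i in seq_len(nrow(raw))) {
      if (is.na(raw$mz[i])) next
      nm <- neutral_from_mz(raw$mz[i], raw$adduct_label[i], adducts)
      if (!is.na(raw$neutral_mass[i]) && abs(raw$neutral_mass[i] - nm) > 1e-4) {
        stop(sprintf(
          "row %d: neutral_mass %.6f inconsistent with mz-derived %.6f",
          i, raw$neutral_mass[i], nm))
      }
      raw$neutral_mass[i] <- nm
    }
  }
  feature_table(raw, rt_window = rt_window)
}

#' Align features across samples into clusters
#'
#' Greedy single-pass centroid clustering on (mass, retention time): features
#' are sorted by mass (then RT, then sample id, so the result is invariant to
#' input row order), and each feature joins the best existing cluster whose
#' consensus mass is within `mass_tol_ppm`, whose consensus RT is within
#' `rt_tol_min`, and which has no member from the same sample yet; otherwise
#' it founds a new cluster. Ties are broken by smaller mass gap, then smaller
#' RT gap. Consensus values are member medians, updated as members join.
#'
#' @param features A feature table (see [feature_table()]).
#' @param mass_tol_ppm Mass tolerance in ppm (default 5).
#' @param rt_tol_min Retention-time tolerance in minutes (default 0.2).
#' @return An object of class `feature_clusters`: a list with `clusters`
#'   (data.frame: `cluster_id`, `consensus_mass`, `consensus_rt`, `n_members`)
#'   and `members` (the input features with a `cluster_id` column).
#' @export
align_features <- function(features, mass_tol_ppm = 5, rt_tol_min = 0.2) {
  if (mass_tol_ppm <= 0 || rt_tol_min <= 0) stop("tolerances must be positive")
  features <- feature_table(features, rt_window = c(-Inf, Inf))
  ord <- order(features$neutral_mass, features$rt_min, features$sample_id)
  features <- features[ord, , drop = FALSE]
  n <- nrow(features)

  cl_mass <- numeric(0)   # consensus masses
  cl_rt <- numeric(0)     # consensus RTs
  members <- list()       # per-cluster member row indices
  member_samples <- list()
  assignment <- integer(n)

  for (i in seq_len(n)) {
    m <- features$neutral_mass[i]
    rt <- features$rt_min[i]
    smp <- features$sample_id[i]
    best <- 0L
    if (length(cl_mass)) {
      dppm <- abs(m - cl_mass) / cl_mass * 1e6
      drt <- abs(rt - cl_rt)
      ok <- which(dppm <= mass_tol_ppm & drt <= rt_tol_min)
      ok <- ok[!vapply(member_samples[ok], function(s) smp %in% s, logical(1))]
      if (length(ok)) {
        best <- ok[order(dppm[ok], drt[ok])][1]
      }
    }
    if (best == 0L) {
      cl_mass <- c(cl_mass, m)
      cl_rt <- c(cl_rt, rt)
      members <- c(members, list(i))
      member_samples <- c(member_samples, list(smp))
      best <- length(cl_mass)
    } else {
      members[[best]] <- c(members[[best]], i)
      member_samples[[best]] <- c(member_samples[[best]], smp)
      cl_mass[best] <- stats::median(features$neutral_mass[members[[best]]])
      cl_rt[best] <- stats::median(features$rt_min[members[[best]]])
    }
    assignment[i] <- best
  }

  clusters <- data.frame(
    cluster_id = seq_along(cl_mass),
    consensus_mass = cl_mass,
    consensus_rt = cl_rt,
    n_members = lengths(members)
  )
  features$cluster_id <- assignment
  structure(list(clusters = clusters, members = features),
            class = "feature_clusters")
}

#' @export
print.feature_clusters <- function(x, ...) {
  cat(sprintf("feature_clusters: %d clusters from %d features in %d samples\n",
              nrow(x$clusters), nrow(x$members),
              length(unique(x$members$sample_id))))
  invisible(x)
}
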