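#' Call DPPH antioxidant activity from plate absorbances
#'
#' The DPPH radical absorbs at 517 nm; scavenging by antioxidants bleaches
#' it. The scavenging fraction is `1 - A_sample / A_control` and a sample is
#' called `"+"` when that fraction reaches the threshold. The underlying
#' assay readout is qualitative (a pink-to-yellow colour change); the 20%
#' default threshold is a configurable operationalization, not a measured
#' constant.
#'
#' @param absorbance Sample absorbance(s) at 517 nm (`>= 0`).
#' @param control_absorbance Negative-control absorbance(s) (`> 0`; DPPH plus
#'   solvent, no extract).
#' @param threshold Scavenging fraction at or above which the call is `"+"`
#'   (default 0.2).
#' @return A data.frame with `scavenging_fraction` and `call` (`"+"`/`"-"`).
#' @export
call_dpph <- function(absorbance, control_absorbance, threshold = 0.2) {
  if (any(control_absorbance <= 0)) {
    stop("control absorbance must be positive")
  }
  if (any(absorbance < 0)) stop("absorbance must be >= 0")
  s <- 1 - absorbance / control_absorbance
  data.frame(scavenging_fraction = s,
             call = ifelse(s >= threshold, "+", "-"))
}

#' Call antibiotic activity from a disk-diffusion zone
#'
#' A sample is active (`"+"`) when the measured inhibition-zone diameter
#' exceeds the paper-disk diameter, i.e. when any halo extends beyond the
#' disk itself.
#'
#' @param zone_mm Zone diameter(s) in mm (`>= 0`).
#' @param disk_mm Disk diameter in mm (default 6).
#' @return Character vector of `"+"`/`"-"` calls.
#' @export
call_zone <- function(zone_mm, disk_mm = 6) {
  if (any(zone_mm < 0)) stop("zone diameter must be >= 0")
  ifelse(zone_mm > disk_mm, "+", "-")
}

#' Lay out activity calls as a condition-by-week grid
#'
#' @param calls A data.frame with columns `condition`, `week`, `fraction` and
#'   `call` (`"+"`/`"-"`), at most one row per (condition, week, fraction)
#'   cell. Missing cells become `NA` (absence of a measurement is not a
#'   negative call).
#' @return A data.frame with one row per (condition, fraction) and one `w<k>`
#'   column per week, cells in `{"+", "-", NA}`.
#' @export
activity_table <- function(calls) {
  required <- c("condition", "week", "fraction", "call")
  if (!all(required %in% names(calls))) {
    stop(sprintf("calls must have columns %s", paste(required, collapse = ", ")))
  }
  key <- paste(calls$condition, calls$week, calls$fraction)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate cell(s): %s",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  if (!nrow(calls)) {
    return(data.frame(condition = character(0), fraction = character(0)))
  }
  weeks <- sort(unique(calls$week))
  rows <- unique(calls[c("condition", "fraction")])
  rows <- rows[order(rows$fraction, match(rows$condition, CONDITIONS)), ,
               drop = FALSE]
  grid <- rows
  for (w in weeks) {
    col <- rep(NA_character_, nrow(rows))
    sel <- calls$week == w
    idx <- match(paste(calls$condition[sel], calls$fraction[sel]),
                 paste(rows$condition, rows$fraction))
    col[idx] <- calls$call[sel]
    grid[[paste0("w", w)]] <- col
  }
  rownames(grid) <- NULL
  grid
}

#' Parse an activity grid back into a call list
#'
#' Inverse of [activity_table()]: `NA` cells are dropped, not turned into
#' negative calls.
#'
#' @param grid A grid as produced by [activity_table()] (or read from the
#'   bundled reference CSVs).
#' @return A data.frame with columns `condition`, `week`, `fraction`, `call`.
#' @export
parse_activity_table <- function(grid) {
  week_cols <- grep("^w[0-9]+$", names(grid), value = TRUE)
  out <- do.call(rbind, lapply(week_cols, function(cn) {
    data.frame(condition = grid$condition,
               week = as.integer(sub("^w", "", cn)),
               fraction = grid$fraction,
               call = grid[[cn]])
  }))
  out <- out[!is.na(out$call), , drop = FALSE]
  out <- out[order(out$fraction, match(out$condition, CONDITIONS), out$week), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bundled reference activity grids
#'
#' `dpph_reference_grid()` is the DPPH (antioxidant) grid and
#' `zone_reference_grid()` the disk-diffusion (antibiotic, vs *Bacillus
#' subtilis*) grid for the Streptomyces strain across conditions C/O2/O3,
#' weeks 1,3,5,7,9,11 and both extract fractions.
#'
#' @return A grid data.frame (see [activity_table()]).
#' @export
dpph_reference_grid <- function() {
  utils::read.csv(system.file("extdata", "dpph_reference_grid.csv",
                              package = "oxyderep"),
                  comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE)
}

#' @rdname dpph_reference_grid
#' @export
zone_reference_grid <- function() {
  utils::read.csv(system.file("extdata", "zone_reference_grid.csv",
                              package = "oxyderep"),
                  comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE)
}
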