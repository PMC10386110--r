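#' Construct and validate a compound library
#'
#' A compound library is an ordered collection of natural-product records,
#' each with a name, an optional molecular formula, a monoisotopic mass, a
#' biological source (producing genus) and a set of activity annotations.
#' When a formula is present the mass is computed from it; a stored mass, if
#' also given, must agree within 1e-6 Da.
#'
#' @param records A data.frame with columns `name`, `formula` (may be NA or
#'   empty), `monoisotopic_mass` (may be NA when a formula is given),
#'   `biological_source`, `activities` (semicolon-separated string, may be
#'   empty).
#' @param provenance Free-text description of where the records come from.
#' @param elements Element table used to compute masses from formulas.
#' @return An object of class `compound_library`: the validated data.frame,
#'   sorted by mass, with a `provenance` attribute and a list column
#'   `activity_set`.
#' @export
compound_library <- function(records, provenance = "user-supplied",
                             elements = element_table()) {
  required <- c("name", "biological_source")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"formula" %in% names(records)) records$formula <- NA_character_
  if (!"monoisotopic_mass" %in% names(records)) {
    records$monoisotopic_mass <- NA_real_
  }
  if (!"activities" %in% names(records)) records$activities <- ""
  records$activities[is.na(records$activities)] <- ""

  if (anyDuplicated(records$name)) {
    stop(sprintf("duplicate compound name(s): %s",
                 paste(unique(records$name[duplicated(records$name)]),
                       collapse = ", ")))
  }
  if (any(is.na(records$biological_source) | !nzchar(records$biological_source))) {
    stop("biological_source must be non-empty for every record")
  }

  has_formula <- !is.na(records$formula) & nzchar(records$formula)
  for (i in which(has_formula)) {
    m <- tryCatch(monoisotopic_mass(records$formula[i], elements),
                  error = function(e) {
                    stop(sprintf("row %d (%s): %s", i, records$name[i],
                                 conditionMessage(e)))
                  })
    if (!is.na(records$monoisotopic_mass[i]) &&
        abs(records$monoisotopic_mass[i] - m) > 1e-6) {
      stop(sprintf(
        "row %d (%s): stored mass %.6f disagrees with formula mass %.6f",
        i, records$name[i], records$monoisotopic_mass[i], m))
    }
    records$monoisotopic_mass[i] <- m
  }
  if (any(is.na(records$monoisotopic_mass))) {
    bad <- which(is.na(records$monoisotopic_mass))[1]
    stop(sprintf("row %d (%s): neither formula nor stored mass",
                 bad, records$name[bad]))
  }
  if (any(records$monoisotopic_mass <= 0)) stop("masses must be positive")

  records$activity_set <- lapply(strsplit(records$activities, ";", fixed = TRUE),
                                 function(x) trimws(x[nzchar(trimws(x))]))
  records <- records[order(records$monoisotopic_mass, records$name), ,
                     drop = FALSE]
  rownames(records) <- NULL
  attr(records, "provenance") <- provenance
  class(records) <- c("compound_library", class(records))
  records
}

#' Load a compound library from CSV or JSON
#'
#' The CSV schema has columns `name, formula, monoisotopic_mass,
#' biological_source, activities` (activities semicolon-separated); the JSON
#' mirror is an array of objects with the same fields. `#`-prefixed lines in
#' CSV files are treated as comments.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @param provenance Provenance string; defaults to the file path.
#' @return A [compound_library()] object.
#' @export
read_compound_library <- function(path, provenance = path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  records <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = c(monoisotopic_mass = "numeric"))
  }
  compound_library(records, provenance = provenance)
}

#' Bundled actinobacterial reference library
#'
#' Loads the fixture library shipped with the package: named natural
#' products of *Streptomyces* and *Rhodococcus* plus synthetic mass decoys.
#'
#' @return A [compound_library()] object.
#' @export
baikal_reference_library <- function() {
  read_compound_library(
    system.file("extdata", "compound_library.csv", package = "oxyderep"),
    provenance = "bundled actinobacterial reference fixture")
}

#' Query library records within a mass window
#'
#' @param library A [compound_library()].
#' @param center Query mass in Da.
#' @param window Half-width of the window in Da (`>= 0`; `Inf` returns all).
#' @return Records with `|monoisotopic_mass - center| <= window`, sorted by
#'   absolute mass difference (ties by name).
#' @export
mass_range_query <- function(library, center, window) {
  stopifnot(inherits(library, "compound_library"))
  if (length(window) != 1L || is.na(window) || window < 0) {
    stop("window must be a single non-negative number")
  }
  # records are sorted by mass: binary-search the window bounds
  masses <- library$monoisotopic_mass
  lo <- findInterval(center - window, masses, left.open = TRUE) + 1L
  hi <- findInterval(center + window, masses)
  if (hi < lo) {
    out <- library[0, , drop = FALSE]
  } else {
    out <- library[lo:hi, , drop = FALSE]
    out <- out[abs(out$monoisotopic_mass - center) <= window, , drop = FALSE]
    out <- out[order(abs(out$monoisotopic_mass - center), out$name), ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' @export
print.compound_library <- function(x, ...) {
  cat(sprintf("compound_library: %d records (%s)\n", nrow(x),
              attr(x, "provenance")))
  print.data.frame(utils::head(as.data.frame(x)[
    c("name", "monoisotopic_mass", "biological_source", "activities")]), ...)
  invisible(x)
}
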