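#' Monoisotopic element mass table
#'
#' Loads the bundled table of per-atom monoisotopic masses (the mass of the
#' most abundant isotope, in Da). The table is a plain CSV resource so that
#' additional elements can be added without touching code.
#'
#' @param path Optional path to an alternative CSV with columns
#'   `symbol` and `monoisotopic_mass`. Defaults to the bundled table.
#' @return A data.frame with columns `symbol` (character, unique) and
#'   `monoisotopic_mass` (positive numeric, Da).
#' @export
element_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "elements.csv", package = "oxyderep")
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("symbol", "monoisotopic_mass") %in% names(tab))) {
    stop("element table must have columns 'symbol' and 'monoisotopic_mass'")
  }
  if (anyDuplicated(tab$symbol)) stop("duplicate element symbols in table")
  if (any(tab$monoisotopic_mass <= 0)) stop("element masses must be positive")
  tab
}

#' Parse a molecular formula in Hill notation
#'
#' Accepts formulas such as `"C27H48N6O9"` or `"H2O"`: element symbols
#' (one capital letter optionally followed by one lowercase letter) each
#' followed by an optional positive integer count (implicit 1). Isotope
#' labels and charge states are not supported.
#'
#' @param text A single non-empty formula string.
#' @param elements Element table used to validate symbols.
#' @return A named integer vector mapping element symbol to count.
#' @examples
#' parse_formula("H2O")
#' parse_formula("C27H48N6O9")
#' @export
parse_formula <- function(text, elements = element_table()) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("formula must be a single non-empty string")
  }
  pos <- 1L
  n <- nchar(text)
  comp <- integer(0)
  while (pos <= n) {
    m <- regmatches(
      substr(text, pos, n),
      regexec("^([A-Z][a-z]?)([0-9]*)", substr(text, pos, n))
    )[[1]]
    if (length(m) == 0L || !nzchar(m[1])) {
      stop(sprintf("malformed formula '%s' at position %d", text, pos))
    }
    sym <- m[2]
    cnt <- m[3]
    if (!sym %in% elements$symbol) {
      # a two-letter guess may swallow the next element's capital; retry 1-letter
      if (nchar(sym) == 2L && substr(sym, 1, 1) %in% elements$symbol) {
        stop(sprintf("unknown element symbol '%s' in formula '%s'", sym, text))
      }
      stop(sprintf("unknown element symbol '%s' in formula '%s'", sym, text))
    }
    count <- if (nzchar(cnt)) suppressWarnings(as.integer(cnt)) else 1L
    if (is.na(count) || count < 1L) {
      stop(sprintf("malformed count in formula '%s' at position %d", text, pos))
    }
    comp[sym] <- if (sym %in% names(comp)) comp[[sym]] + count else count
    pos <- pos + nchar(m[1])
  }
  comp
}

#' Monoisotopic mass of a formula
#'
#' Sums count times per-atom monoisotopic mass over all elements. An empty
#' composition (the explicit "unknown formula" sentinel) has mass 0.
#'
#' @param formula A named integer vector as returned by [parse_formula()],
#'   or a formula string (parsed on the fly).
#' @param elements Element table providing per-atom masses.
#' @return Monoisotopic mass in Da (non-negative scalar).
#' @examples
#' monoisotopic_mass("H2O") # 18.010565
#' @export
monoisotopic_mass <- function(formula, elements = element_table()) {
  if (is.character(formula)) formula <- parse_formula(formula, elements)
  if (length(formula) == 0L) return(0)
  syms <- names(formula)
  idx <- match(syms, elements$symbol)
  if (anyNA(idx)) {
    stop(sprintf("unknown element symbol '%s'", syms[which(is.na(idx))[1]]))
  }
  if (any(formula < 0)) stop("element counts must be non-negative")
  sum(as.numeric(formula) * elements$monoisotopic_mass[idx])
}

#' Default ESI adduct set
#'
#' Positive-mode adducts with electron-corrected mass shifts (e.g. the
#' `[M+H]+` shift is the proton mass, not the hydrogen atom mass). Shipped
#' as an editable CSV resource.
#'
#' @param path Optional path to an alternative adduct CSV with columns
#'   `label`, `mass_shift`, `charge`.
#' @return A data.frame with columns `label`, `mass_shift` (Da), `charge`.
#' @export
default_adducts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "adducts.csv", package = "oxyderep")
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("label", "mass_shift", "charge") %in% names(tab))) {
    stop("adduct table must have columns 'label', 'mass_shift', 'charge'")
  }
  if (anyDuplicated(tab$label)) stop("duplicate adduct labels")
  if (any(tab$charge < 1)) stop("adduct charge must be >= 1")
  tab
}

# Resolve an adduct given as a label (looked up in a table), a one-row
# data.frame, or a list with mass_shift and charge.
resolve_adduct <- function(adduct, adducts = default_adducts()) {
  if (is.character(adduct) && length(adduct) == 1L) {
    i <- match(adduct, adducts$label)
    if (is.na(i)) stop(sprintf("unknown adduct label '%s'", adduct))
    return(list(label = adduct, mass_shift = adducts$mass_shift[i],
                charge = adducts$charge[i]))
  }
  adduct <- as.list(adduct)
  if (is.null(adduct$mass_shift) || is.null(adduct$charge)) {
    stop("adduct must provide mass_shift and charge")
  }
  if (adduct$charge < 1) stop("adduct charge must be >= 1")
  if (is.null(adduct$label)) adduct$label <- "custom"
  adduct
}

#' m/z of an adduct ion
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (must be positive).
#' @param adduct An adduct label (e.g. `"[M+H]+"`), or a list/one-row
#'   data.frame with `mass_shift` and `charge`.
#' @param adducts Adduct table used to resolve labels.
#' @return The ion m/z: `(neutral_mass + mass_shift) / charge`.
#' @export
adduct_mz <- function(neutral_mass, adduct, adducts = default_adducts()) {
  if (any(neutral_mass <= 0)) stop("neutral mass must be positive")
  a <- resolve_adduct(adduct, adducts)
  (neutral_mass + a$mass_shift) / a$charge
}

#' Neutral mass from an adduct m/z
#'
#' Exact algebraic inverse of [adduct_mz()].
#'
#' @inheritParams adduct_mz
#' @param mz Observed ion m/z.
#' @return Neutral mass in Da: `mz * charge - mass_shift`.
#' @export
neutral_from_mz <- function(mz, adduct, adducts = default_adducts()) {
  a <- resolve_adduct(adduct, adducts)
  m <- mz * a$charge - a$mass_shift
  if (any(m <= 0)) stop("inferred neutral mass is non-positive")
  m
}

#' Mass error between an observed and a reference mass
#'
#' Computes the signed Dalton and parts-per-million differences used by the
#' dereplication tolerance rule. The ppm denominator is the reference
#' (library) mass: the tolerance is a property of the library assignment.
#'
#' @param observed Observed mass/masses in Da.
#' @param reference Reference mass(es) in Da; must be positive.
#' @return A data.frame with columns `delta_da` (`observed - reference`) and
#'   `delta_ppm` (`delta_da / reference * 1e6`); signs always agree.
#' @examples
#' mass_error(600.3486, monoisotopic_mass("C27H48N6O9"))
#' @export
mass_error <- function(observed, reference) {
  if (any(reference <= 0)) stop("reference mass must be positive")
  delta_da <- observed - reference
  data.frame(delta_da = delta_da, delta_ppm = delta_da / reference * 1e6)
}
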