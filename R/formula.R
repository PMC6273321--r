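# Elemental-formula arithmetic and ion m/z.
#
# Formulas are restricted to C/H/N/O, the element set of aconitane
# lipo-alkaloid chemistry. Monoisotopic atomic masses are frozen constants
# so every computed m/z is bit-stable across platforms.

.ATOMIC_MASS <- c(C = 12, H = 1.0078250319, N = 14.0030740, O = 15.9949146)

# Adduct mass for +/-H ionization under the two conventions in use:
# proton mass when the electron is accounted for, hydrogen-atom mass when
# it is not. Both occur in published reference tables, so the convention
# is always an explicit argument, never implicit.
.PROTON_MASS <- 1.007276
.HYDROGEN_ATOM_MASS <- 1.007825

#' Create an elemental formula
#'
#' An `elemental_formula` is a named integer vector of element counts in
#' canonical form: zero counts dropped, elements ordered C, H, then
#' alphabetically (Hill order). Only C, H, N and O are supported.
#'
#' @param counts Named numeric vector of non-negative integer element counts.
#' @return An object of class `elemental_formula`.
#' @examples
#' elemental_formula(c(C = 31, H = 43, N = 1, O = 10))
#' @export
elemental_formula <- function(counts = integer(0)) {
  if (length(counts) == 0) {
    counts <- integer(0)
  } else {
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      stop("element counts must be named", call. = FALSE)
    }
    unknown <- setdiff(names(counts), names(.ATOMIC_MASS))
    if (length(unknown)) {
      stop("UnknownElement: unsupported element(s) ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (any(is.na(counts)) || any(counts != round(counts))) {
      stop("element counts must be integers", call. = FALSE)
    }
    if (any(counts < 0)) {
      stop("NegativeCount: element counts must be non-negative", call. = FALSE)
    }
    counts <- stats::setNames(as.integer(round(counts)), names(counts))
    counts <- counts[counts > 0L]
    if (anyDuplicated(names(counts))) {
      counts <- tapply(counts, names(counts), sum)
      counts <- stats::setNames(as.integer(counts), names(counts))
    }
    ord <- c(intersect(c("C", "H"), names(counts)),
             sort(setdiff(names(counts), c("C", "H"))))
    counts <- counts[ord]
  }
  structure(counts, class = "elemental_formula")
}

#' Parse a Hill-notation formula string
#'
#' @param x Formula string such as `"C49H73NO11"`. An empty string gives the
#'   empty formula.
#' @return An `elemental_formula`.
#' @examples
#' parse_formula("C18H32O2")
#' @export
parse_formula <- function(x) {
  if (inherits(x, "elemental_formula")) return(x)
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x <- trimws(x)
  if (!nzchar(x)) return(elemental_formula())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x, perl = TRUE)[[1]]
  tokens <- regmatches(x, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x)) {
    stop("cannot parse formula string: ", x, call. = FALSE)
  }
  els <- sub("[0-9]*$", "", tokens)
  ns <- sub("^[A-Za-z]+", "", tokens)
  counts <- ifelse(nzchar(ns), suppressWarnings(as.integer(ns)), 1L)
  elemental_formula(stats::setNames(counts, els))
}

.as_formula <- function(x) {
  if (inherits(x, "elemental_formula")) x else parse_formula(x)
}

#' @export
format.elemental_formula <- function(x, ...) {
  if (length(x) == 0) return("")
  n <- unclass(x)
  paste0(names(n), ifelse(n == 1L, "", n), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ",
      if (length(x)) format(x) else "(empty)", "\n", sep = "")
  invisible(x)
}

#' @export
as.character.elemental_formula <- function(x, ...) format(x)

#' Add two elemental formulas
#'
#' Element-wise sum in canonical form; the composition step of the
#' lipo-alkaloid construction rule (skeleton + fatty acid - H2O).
#'
#' @param a,b Formulas (`elemental_formula` or string).
#' @return An `elemental_formula`.
#' @examples
#' formula_add("C31H43NO10", "C18H32O2")
#' @export
formula_add <- function(a, b) {
  a <- unclass(.as_formula(a)); b <- unclass(.as_formula(b))
  els <- union(names(a), names(b))
  out <- stats::setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  elemental_formula(out)
}

#' Subtract one elemental formula from another
#'
#' Errors with `NegativeCount` if the subtraction would drive any element
#' negative -- the signal for a chemically impossible neutral loss.
#'
#' @param a,b Formulas (`elemental_formula` or string); `b` must be
#'   element-wise contained in `a`.
#' @return An `elemental_formula`.
#' @examples
#' formula_subtract("C49H75NO12", "H2O")
#' @export
formula_subtract <- function(a, b) {
  a <- unclass(.as_formula(a)); b <- unclass(.as_formula(b))
  els <- union(names(a), names(b))
  out <- stats::setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0)) {
    stop("NegativeCount: loss ", paste0(names(b), ifelse(b == 1, "", b), collapse = ""),
         " is not contained in the parent formula", call. = FALSE)
  }
  elemental_formula(out)
}

#' @export
Ops.elemental_formula <- function(e1, e2) {
  switch(.Generic,
         "+" = formula_add(e1, e2),
         "-" = formula_subtract(e1, e2),
         "==" = identical(unclass(.as_formula(e1)), unclass(.as_formula(e2))),
         "!=" = !identical(unclass(.as_formula(e1)), unclass(.as_formula(e2))),
         stop("operation '", .Generic, "' not defined for elemental_formula",
              call. = FALSE))
}

#' Monoisotopic mass of a formula
#'
#' Sum of frozen monoisotopic atomic masses (C = 12 exact,
#' H = 1.0078250319, N = 14.0030740, O = 15.9949146 Da).
#'
#' @param f Formula (`elemental_formula` or string).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")   # 18.010565
#' @export
monoisotopic_mass <- function(f) {
  f <- unclass(.as_formula(f))
  if (length(f) == 0) return(0)
  sum(.ATOMIC_MASS[names(f)] * f)
}

#' m/z of a singly charged +/-H ion
#'
#' In positive mode the adduct mass is added to the neutral monoisotopic
#' mass; in negative mode it is subtracted. With
#' `electron_corrected = TRUE` the adduct is the proton mass (1.007276 Da,
#' physically correct for an ion); with `FALSE` it is the hydrogen-atom
#' mass (1.007825 Da), the convention used by some published fragment
#' tables. Only charge 1 is supported.
#'
#' @param f Formula of the neutral species (`elemental_formula` or string).
#' @param mode `"positive"` or `"negative"`.
#' @param electron_corrected Logical; see Details.
#' @param charge Must be 1.
#' @return m/z in Th (Da/e), full precision.
#' @examples
#' ion_mz("C49H73NO11", "positive")                            # 852.5256...
#' ion_mz("C31H41NO9", "positive", electron_corrected = FALSE) # 572.2860...
#' @export
ion_mz <- function(f, mode = c("positive", "negative"),
                   electron_corrected = TRUE, charge = 1L) {
  mode <- match.arg(mode)
  if (!identical(as.integer(charge), 1L)) {
    stop("UnsupportedCharge: only singly charged ions are supported",
         call. = FALSE)
  }
  adduct <- if (isTRUE(electron_corrected)) .PROTON_MASS else .HYDROGEN_ATOM_MASS
  m <- monoisotopic_mass(f)
  if (mode == "positive") m + adduct else m - adduct
}
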