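# Fatty-acid side-chain space.
#
# A side chain is the point (c, o, dbe): carbon count, oxygen count and
# degrees of unsaturation. dbe counts the carboxyl carbonyl, so a
# saturated acid has dbe = 1 and linoleic acid (two C=C) has dbe = 3. The
# formula is fully determined: C_c H_(2c+2-2*dbe) O_o. Oxygenation is
# carried only as the oxygen count; hydroxy/oxo/epoxy positional forms are
# not distinguishable at MS1 and are represented by candidate names.

#' Fatty-acid side-chain specification
#'
#' @param c Carbon count.
#' @param o Oxygen count (>= 2: at least the carboxyl oxygens).
#' @param dbe Degrees of unsaturation including the carboxyl C=O (>= 1).
#' @param name Optional trivial name(s).
#' @param abbreviation Optional short code (e.g. `"lino"`).
#' @return A `fatty_acid` object: the (c, o, dbe) triple plus its formula
#'   and monoisotopic mass.
#' @examples
#' fatty_acid(18, 2, 3)   # linoleic acid, C18H32O2
#' @export
fatty_acid <- function(c, o, dbe, name = NA_character_,
                       abbreviation = NA_character_) {
  c <- as.integer(c); o <- as.integer(o); dbe <- as.integer(dbe)
  if (dbe < 1L) stop("dbe must be >= 1 (the carboxyl C=O)", call. = FALSE)
  if (o < 2L) stop("a carboxylic acid needs o >= 2", call. = FALSE)
  h <- 2L * c + 2L - 2L * dbe
  if (h < 2L) {
    stop("infeasible fatty acid: ", c, " carbons cannot carry ", dbe,
         " degrees of unsaturation", call. = FALSE)
  }
  f <- elemental_formula(c(C = c, H = h, O = o))
  structure(list(c = c, o = o, dbe = dbe, h = h, formula = format(f),
                 mass = monoisotopic_mass(f), name = name,
                 abbreviation = abbreviation),
            class = "fatty_acid")
}

#' @export
print.fatty_acid <- function(x, ...) {
  cat("<fatty_acid> ", x$formula,
      sprintf(" (c=%d, o=%d, dbe=%d, %.6f Da)", x$c, x$o, x$dbe, x$mass),
      if (!is.na(x$abbreviation)) paste0(" [", x$abbreviation, "]"),
      "\n", sep = "")
  invisible(x)
}

#' Constraint box for the fatty-acid space
#'
#' Defaults are the side-chain space used when hypothesizing
#' lipo-alkaloids: 3-25 carbons, 2-6 oxygens, 1-7 degrees of unsaturation.
#'
#' @param c_min,c_max,o_min,o_max,dbe_min,dbe_max Integer bounds.
#' @return A `fa_constraints` list.
#' @export
fa_constraints <- function(c_min = 3L, c_max = 25L, o_min = 2L, o_max = 6L,
                           dbe_min = 1L, dbe_max = 7L) {
  con <- lapply(list(c_min = c_min, c_max = c_max, o_min = o_min,
                     o_max = o_max, dbe_min = dbe_min, dbe_max = dbe_max),
                as.integer)
  if (con$c_min > con$c_max || con$o_min > con$o_max ||
      con$dbe_min > con$dbe_max) {
    stop("InvalidConstraints: inverted bounds", call. = FALSE)
  }
  if (con$o_min < 2L || con$dbe_min < 1L || con$c_min < 1L) {
    stop("InvalidConstraints: o >= 2, dbe >= 1, c >= 1 required", call. = FALSE)
  }
  structure(con, class = "fa_constraints")
}

#' Enumerate all fatty acids in a constraint box
#'
#' All (c, o, dbe) triples in the box whose hydrogen count
#' 2c + 2 - 2*dbe is at least 2, in deterministic (c, o, dbe) order.
#'
#' @param con A [fa_constraints()] box.
#' @return Data frame with columns `c`, `o`, `dbe`, `h`, `formula`, `mass`.
#' @examples
#' nrow(enumerate_fatty_acids(fa_constraints()))
#' @export
enumerate_fatty_acids <- function(con = fa_constraints()) {
  if (!inherits(con, "fa_constraints")) con <- do.call(fa_constraints, as.list(con))
  g <- expand.grid(dbe = con$dbe_min:con$dbe_max,
                   o = con$o_min:con$o_max,
                   c = con$c_min:con$c_max)
  g <- g[, c("c", "o", "dbe")]
  g$h <- 2L * g$c + 2L - 2L * g$dbe
  g <- g[g$h >= 2L, , drop = FALSE]
  g <- g[order(g$c, g$o, g$dbe), , drop = FALSE]
  if (nrow(g) == 0) {
    g$formula <- character(0)
    g$mass <- numeric(0)
    rownames(g) <- NULL
    return(g)
  }
  g$formula <- paste0("C", g$c, "H", g$h, ifelse(g$o == 1L, "O", paste0("O", g$o)))
  g$mass <- g$c * .ATOMIC_MASS[["C"]] + g$h * .ATOMIC_MASS[["H"]] +
    g$o * .ATOMIC_MASS[["O"]]
  rownames(g) <- NULL
  g
}

#' Named side-chain glossary
#'
#' The abbreviation glossary of literature-attested side chains (fmr, bte,
#' ..., lino, hodd, ole, ..., gvl, gcf, gfr) mapped to molecular formulas.
#' Used to parse compound display names such as `"8-lino-BMA"` and to
#' prioritize attested chains during side-chain inference.
#'
#' @param path CSV config file; `NULL` for the shipped default.
#' @return Data frame with columns `abbreviation`, `name`, `formula`, `c`,
#'   `o`, `dbe`, `h`, `mass`.
#' @examples
#' gl <- named_side_chains()
#' gl[gl$abbreviation == "lino", ]
#' @export
named_side_chains <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "side_chains.csv", package = "lipoannot",
                        mustWork = TRUE)
  }
  gl <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("abbreviation", "name", "formula") %in% names(gl)))
  if (anyDuplicated(gl$abbreviation)) {
    stop("duplicate abbreviations in side-chain glossary", call. = FALSE)
  }
  parsed <- lapply(gl$formula, parse_formula)
  counts <- function(el) vapply(parsed, function(p) {
    n <- unclass(p); if (el %in% names(n)) n[[el]] else 0L
  }, integer(1))
  gl$c <- counts("C"); gl$h <- counts("H"); gl$o <- counts("O")
  gl$dbe <- (2L * gl$c + 2L - gl$h) %/% 2L
  gl$mass <- vapply(parsed, monoisotopic_mass, numeric(1))
  gl
}

#' Look up one named side chain by abbreviation
#'
#' @param abbreviation Short code, e.g. `"lino"`.
#' @param glossary Glossary table from [named_side_chains()].
#' @return A [fatty_acid()] object.
#' @examples
#' side_chain("lino")$formula
#' @export
side_chain <- function(abbreviation, glossary = named_side_chains()) {
  i <- match(abbreviation, glossary$abbreviation)
  if (is.na(i)) {
    stop("UnknownAbbreviation: '", abbreviation,
         "' is not in the side-chain glossary", call. = FALSE)
  }
  fatty_acid(glossary$c[i], glossary$o[i], glossary$dbe[i],
             name = glossary$name[i], abbreviation = glossary$abbreviation[i])
}

#' Literature catalog of fatty-acid side chains
#'
#' The reported catalog of side-chain formulas with candidate structures
#' and the number of lipo-alkaloids each was detected in (`NA` = reported
#' in earlier literature but not detected).
#'
#' @return Data frame with columns `formula`, `name`, `n_lipo_alkaloids`,
#'   `first_detected`.
#' @export
fatty_acid_catalog <- function() {
  utils::read.csv(system.file("extdata", "fatty_acid_catalog.csv",
                              package = "lipoannot", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
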