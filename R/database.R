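# Combinatorial accurate-mass database of hypothetical lipo-alkaloids.
#
# Every (skeleton, fatty acid) pair composes to one molecular formula by
# the esterification rule
#     MF(lipo-alkaloid) = MF(skeleton) + MF(fatty acid) - H2O,
# and the database is keyed by molecular formula: LC-MS alone cannot
# resolve isomeric (skeleton, side chain) combinations, so all generating
# pairs are retained as members of one entry and disambiguated later by
# MS/MS.

#' Compose a lipo-alkaloid molecular formula
#'
#' Skeleton formula + fatty-acid formula - H2O (loss of water on
#' esterification of the C-8 hydroxyl).
#'
#' @param skeleton Skeleton (`skeleton_spec`, `elemental_formula` or
#'   formula string).
#' @param fatty_acid Side chain (`fatty_acid`, `elemental_formula` or
#'   formula string).
#' @return An `elemental_formula`.
#' @examples
#' compose_formula("C31H43NO10", "C18H32O2")  # C49H73NO11
#' @export
compose_formula <- function(skeleton, fatty_acid) {
  s <- if (inherits(skeleton, "skeleton_spec")) skeleton$formula else skeleton
  fa <- if (inherits(fatty_acid, "fatty_acid")) fatty_acid$formula else fatty_acid
  formula_subtract(formula_add(s, fa), "H2O")
}

.chno_string <- function(C, H, N, O) {
  paste0("C", C, "H", H,
         ifelse(N == 0L, "", ifelse(N == 1L, "N", paste0("N", N))),
         ifelse(O == 0L, "", ifelse(O == 1L, "O", paste0("O", O))))
}

#' Build the lipo-alkaloid accurate-mass database
#'
#' Crosses every registry skeleton with the enumerated fatty-acid box
#' (plus, by default, the named glossary chains that fall outside the box,
#' such as the glucosyl phenolic acids) and groups the compositions by
#' molecular formula.
#'
#' @param registry A [skeleton_registry()].
#' @param constraints A [fa_constraints()] box.
#' @param glossary Named side-chain glossary, used for display names and
#'   (when `include_named = TRUE`) to extend the side-chain space.
#' @param include_named Also compose the attested named chains that lie
#'   outside the constraint box (default `TRUE`).
#' @return An `la_database` data frame sorted by neutral mass with columns
#'   `formula`, `neutral_mass`, `mz_pos` (electron-corrected \[M+H\]+),
#'   `n_members`, `members` (semicolon-joined `"skeleton|FAformula"`) and
#'   `display_names`; attributes `n_combinations` and `n_formulas` report
#'   the total composition count and the distinct-formula count.
#' @examples
#' db <- build_database()
#' attr(db, "n_formulas")
#' @export
build_database <- function(registry = skeleton_registry(),
                           constraints = fa_constraints(),
                           glossary = named_side_chains(),
                           include_named = TRUE) {
  stopifnot(nrow(registry) > 0)
  fas <- enumerate_fatty_acids(constraints)
  if (include_named && nrow(glossary)) {
    extra <- glossary[!(glossary$formula %in% fas$formula),
                      c("c", "o", "dbe", "h", "formula", "mass")]
    fas <- rbind(fas, extra)
  }
  fas$abbreviation <- glossary$abbreviation[match(fas$formula, glossary$formula)]

  h2o <- monoisotopic_mass("H2O")
  pieces <- lapply(seq_len(nrow(registry)), function(i) {
    sk <- unclass(parse_formula(registry$formula[i]))
    n_s <- if ("N" %in% names(sk)) sk[["N"]] else 0L
    data.frame(
      formula = .chno_string(sk[["C"]] + fas$c, sk[["H"]] + fas$h - 2L,
                             n_s, sk[["O"]] + fas$o - 1L),
      neutral_mass = monoisotopic_mass(registry$formula[i]) + fas$mass - h2o,
      member = paste0(registry$name[i], "|", fas$formula),
      display = ifelse(is.na(fas$abbreviation), NA_character_,
                       paste0("8-", fas$abbreviation, "-", registry$name[i])),
      stringsAsFactors = FALSE
    )
  })
  all <- do.call(rbind, pieces)
  grp <- split(seq_len(nrow(all)), all$formula)
  db <- data.frame(
    formula = names(grp),
    neutral_mass = vapply(grp, function(j) all$neutral_mass[j[1]], numeric(1)),
    n_members = lengths(grp),
    members = vapply(grp, function(j) paste(all$member[j], collapse = ";"),
                     character(1)),
    display_names = vapply(grp, function(j) {
      d <- all$display[j]
      paste(d[!is.na(d)], collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  db$mz_pos <- db$neutral_mass + .PROTON_MASS
  db <- db[order(db$neutral_mass),
           c("formula", "neutral_mass", "mz_pos", "n_members", "members",
             "display_names")]
  rownames(db) <- NULL
  attr(db, "n_combinations") <- nrow(all)
  attr(db, "n_formulas") <- nrow(db)
  class(db) <- c("la_database", "data.frame")
  db
}

#' Look up database entries by accurate mass
#'
#' Binary-search window lookup: entries whose electron-corrected \[M+H\]+
#' lies within `tol_ppm` of the observed m/z, ordered by |ppm error|.
#'
#' @param db An `la_database` (sorted by mass, as built).
#' @param mz Observed m/z.
#' @param tol_ppm Mass tolerance in ppm (default 10).
#' @return The matching rows of `db` with an added `ppm_error` column
#'   (zero rows if nothing matches).
#' @examples
#' db <- build_database()
#' find_by_formula(db, 852.5254)$formula
#' @export
find_by_formula <- function(db, mz, tol_ppm = 10) {
  stopifnot(is.numeric(mz), length(mz) == 1L, tol_ppm > 0)
  tol <- mz * tol_ppm * 1e-6
  lo <- findInterval(mz - tol, db$mz_pos) + 1L
  hi <- findInterval(mz + tol, db$mz_pos)
  if (hi < lo) {
    out <- db[0, , drop = FALSE]
    out$ppm_error <- numeric(0)
    return(out)
  }
  out <- db[lo:hi, , drop = FALSE]
  out$ppm_error <- (mz - out$mz_pos) / out$mz_pos * 1e6
  out <- out[order(abs(out$ppm_error)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split a database entry's members into (skeleton, fatty acid) pairs
#'
#' @param entry One row of an `la_database` (or its `members` string).
#' @return Data frame with columns `skeleton` and `fa_formula`.
#' @export
database_members <- function(entry) {
  members <- if (is.character(entry)) entry else entry$members
  stopifnot(length(members) == 1L)
  parts <- strsplit(strsplit(members, ";", fixed = TRUE)[[1]], "|", fixed = TRUE)
  data.frame(skeleton = vapply(parts, `[`, character(1), 1L),
             fa_formula = vapply(parts, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Export / import the database as CSV
#'
#' @param db An `la_database`.
#' @param path CSV file path.
#' @return `read_database` returns the `la_database`; `write_database`
#'   returns `path` invisibly.
#' @export
write_database <- function(db, path) {
  utils::write.csv(as.data.frame(db), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_database
#' @export
read_database <- function(path) {
  db <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(display_names = "character"))
  db$display_names[is.na(db$display_names)] <- ""
  db <- db[order(db$neutral_mass), , drop = FALSE]
  rownames(db) <- NULL
  attr(db, "n_formulas") <- nrow(db)
  attr(db, "n_combinations") <- sum(db$n_members)
  class(db) <- c("la_database", "data.frame")
  db
}
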