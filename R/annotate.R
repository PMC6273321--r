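# Identification pipeline: MS1 formula match -> MS/MS skeleton
# classification -> side-chain inference; plus the negative-mode rules for
# locating the hydroxyl of oxygenated C18 side chains.

#' Centroided peak list
#'
#' @param mz Numeric vector of peak m/z values (will be sorted ascending;
#'   exact duplicates are an error).
#' @param intensity Peak intensities (>= 0); defaults to 1 for every peak.
#' @param precursor_mz Precursor m/z (`NA` for MS1-only contexts).
#' @param mode `"positive"` or `"negative"`.
#' @param id Optional spectrum identifier.
#' @return A `peak_list` object.
#' @export
peak_list <- function(mz, intensity = NULL, precursor_mz = NA_real_,
                      mode = c("positive", "negative"), id = NULL) {
  mode <- match.arg(mode)
  mz <- as.numeric(mz)
  if (is.null(intensity)) intensity <- rep(1, length(mz))
  intensity <- as.numeric(intensity)
  stopifnot(length(intensity) == length(mz))
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (length(mz) > 1 && any(diff(mz) <= 0)) {
    stop("peak m/z values must be strictly ascending", call. = FALSE)
  }
  structure(list(precursor_mz = as.numeric(precursor_mz), mode = mode,
                 mz = mz, intensity = intensity, id = id),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat("<peak_list> ", if (!is.null(x$id)) paste0(x$id, ": "),
      length(x$mz), " peaks, ", x$mode, " mode, precursor ",
      formatC(x$precursor_mz, digits = 4, format = "f"), "\n", sep = "")
  invisible(x)
}

#' Matching tolerances and identification thresholds
#'
#' @param ms1_tol_ppm MS1 (precursor/feature) tolerance in ppm (default 10,
#'   typical for Q-TOF data).
#' @param ms2_tol Absolute MS/MS fragment tolerance in Da (default 0.01;
#'   absolute rather than ppm because fragments span roughly 100-900 m/z).
#' @param min_diagnostic_ions Minimum matched diagnostic ions for a
#'   confident identification (default 3).
#' @param score_threshold Minimum diagnostic score of the top candidate
#'   (default 0.5; a declared default, no community standard exists).
#' @return A `match_config` list.
#' @export
match_config <- function(ms1_tol_ppm = 10, ms2_tol = 0.01,
                         min_diagnostic_ions = 3L, score_threshold = 0.5) {
  if (ms1_tol_ppm <= 0 || ms2_tol <= 0) {
    stop("tolerances must be positive", call. = FALSE)
  }
  structure(list(ms1_tol_ppm = ms1_tol_ppm, ms2_tol = ms2_tol,
                 min_diagnostic_ions = as.integer(min_diagnostic_ions),
                 score_threshold = score_threshold),
            class = "match_config")
}

#' Infer the fatty-acid side chain from a neutral-loss mass
#'
#' The skeleton ion \eqn{[M+H-FA]^+} is the MS/MS base peak of a
#' lipo-alkaloid, so the precursor-minus-base-peak difference is the
#' neutral monoisotopic mass of the intact side chain. Candidates are all
#' fatty acids in the constraint box (plus named glossary chains) whose
#' mass matches within a tolerance scaled to the precursor.
#'
#' @param precursor_mz Precursor ([M+H]+) m/z.
#' @param base_peak_mz m/z of the skeleton ion located in the spectrum.
#' @param constraints A [fa_constraints()] box.
#' @param config A [match_config()]; the window is
#'   `ms2_tol + ms1_tol_ppm * 1e-6 * precursor_mz` (both measurements
#'   contribute error).
#' @param glossary Named side-chain glossary.
#' @return Data frame of candidate fatty acids (columns of
#'   [enumerate_fatty_acids()] plus `error_da`, `abbreviation`, `named`),
#'   named chains first, then by |error|. Zero rows if nothing matches.
#' @examples
#' infer_fatty_acid(852.5254, 572.2863)   # linoleic acid, C18H32O2
#' @export
infer_fatty_acid <- function(precursor_mz, base_peak_mz,
                             constraints = fa_constraints(),
                             config = match_config(),
                             glossary = named_side_chains()) {
  if (base_peak_mz >= precursor_mz) {
    stop("NonPositiveLoss: precursor m/z must exceed the skeleton ion m/z",
         call. = FALSE)
  }
  delta <- precursor_mz - base_peak_mz
  tol <- config$ms2_tol + config$ms1_tol_ppm * 1e-6 * precursor_mz
  fas <- enumerate_fatty_acids(constraints)
  extra <- glossary[!(glossary$formula %in% fas$formula),
                    c("c", "o", "dbe", "h", "formula", "mass")]
  fas <- rbind(fas, extra)
  fas$error_da <- fas$mass - delta
  fas <- fas[abs(fas$error_da) <= tol, , drop = FALSE]
  fas$abbreviation <- glossary$abbreviation[match(fas$formula, glossary$formula)]
  fas$named <- !is.na(fas$abbreviation)
  fas <- fas[order(-fas$named, abs(fas$error_da)), , drop = FALSE]
  rownames(fas) <- NULL
  fas
}

.display_name <- function(skeleton, abbreviation) {
  if (is.na(abbreviation)) NA_character_ else paste0("8-", abbreviation, "-", skeleton)
}

#' Annotate one MS1 feature
#'
#' Runs the full identification logic on a feature: (1) accurate-mass
#' lookup of candidate molecular formulas in the database; (2) if an MS/MS
#' spectrum is available, scoring of every member (skeleton, fatty acid)
#' pair of every matching formula against the skeleton's predicted
#' diagnostic ions, and side-chain inference from the located skeleton ion;
#' (3) status assignment: `"identified"` when a unique top candidate scores
#' at least `score_threshold` with at least `min_diagnostic_ions` matched
#' ions, `"ambiguous"` when several candidates tie at the top (after
#' preferring literature-attested side chains) or when no MS/MS is
#' available, `"unidentified"` otherwise.
#'
#' @param mz Feature (quasi-molecular ion) m/z, positive mode.
#' @param msms Optional [peak_list()] of the feature's MS/MS spectrum.
#' @param db An `la_database` from [build_database()].
#' @param registry The [skeleton_registry()] the database was built from.
#' @param config A [match_config()].
#' @param constraints,glossary Side-chain space used for inference and
#'   display names.
#' @return An `annotation` object: `feature_mz`, `status`, `candidates`
#'   (ranked data frame with skeleton, fatty-acid formula, diagnostic score,
#'   matched-ion count, ppm error and display name), `matches` (matched-ion
#'   table of the top candidate) and `side_chain` (inference table for the
#'   top candidate's skeleton ion, when located).
#' @examples
#' db <- build_database()
#' reg <- skeleton_registry()
#' a1 <- reference_spectra()$A1
#' annotate_feature(a1$precursor_mz, a1, db, reg)
#' @export
annotate_feature <- function(mz, msms = NULL, db, registry,
                             config = match_config(),
                             constraints = fa_constraints(),
                             glossary = named_side_chains()) {
  empty <- data.frame(skeleton = character(0), fa_formula = character(0),
                      abbreviation = character(0), display_name = character(0),
                      score = numeric(0), n_matched = integer(0),
                      ppm_error = numeric(0), named_fa = logical(0),
                      stringsAsFactors = FALSE)
  result <- function(status, candidates = empty, matches = NULL,
                     side_chain = NULL) {
    structure(list(feature_mz = mz, status = status, candidates = candidates,
                   matches = matches, side_chain = side_chain),
              class = "annotation")
  }
  hits <- find_by_formula(db, mz, config$ms1_tol_ppm)
  if (nrow(hits) == 0) return(result("unidentified"))

  cand <- do.call(rbind, lapply(seq_len(nrow(hits)), function(i) {
    m <- database_members(hits$members[i])
    m$ppm_error <- hits$ppm_error[i]
    m$formula <- hits$formula[i]
    m
  }))
  cand$abbreviation <- glossary$abbreviation[match(cand$fa_formula, glossary$formula)]
  cand$named_fa <- !is.na(cand$abbreviation)
  cand$display_name <- ifelse(cand$named_fa,
                              paste0("8-", cand$abbreviation, "-", cand$skeleton),
                              paste0(cand$fa_formula, "-", cand$skeleton))

  if (is.null(msms)) {
    cand$score <- NA_real_
    cand$n_matched <- NA_integer_
    cand <- cand[order(-cand$named_fa, abs(cand$ppm_error)), , drop = FALSE]
    rownames(cand) <- NULL
    return(result("ambiguous", cand[, names(empty)]))
  }

  preds <- new.env(parent = emptyenv())
  scored <- lapply(seq_len(nrow(cand)), function(i) {
    sk <- cand$skeleton[i]
    if (is.null(preds[[sk]])) preds[[sk]] <- predict_fragments(get_skeleton(registry, sk))
    diagnostic_score(preds[[sk]], msms, config$ms2_tol)
  })
  cand$score <- vapply(scored, `[[`, numeric(1), "score")
  cand$n_matched <- vapply(scored, `[[`, integer(1), "n_matched")
  ord <- order(-cand$score, -cand$named_fa, abs(cand$ppm_error))
  cand <- cand[ord, , drop = FALSE]
  scored <- scored[ord]
  rownames(cand) <- NULL

  top_tie <- cand$score >= cand$score[1] - 1e-12 &
    cand$named_fa == cand$named_fa[1]
  unique_top <- sum(top_tie) == 1L

  # side-chain inference from the top skeleton's [M+H-FA]+ ion
  side_chain <- NULL
  pred_top <- preds[[cand$skeleton[1]]]
  base_mz_pred <- pred_top$mz[pred_top$losses == "FA"]
  in_win <- abs(msms$mz - base_mz_pred) <= config$ms2_tol
  if (any(in_win)) {
    base_obs <- msms$mz[in_win][which.max(msms$intensity[in_win])]
    prec <- if (!is.na(msms$precursor_mz)) msms$precursor_mz else mz
    if (prec > base_obs) {
      side_chain <- infer_fatty_acid(prec, base_obs, constraints, config, glossary)
    }
  }

  status <- if (unique_top &&
                cand$score[1] >= config$score_threshold &&
                cand$n_matched[1] >= config$min_diagnostic_ions) {
    "identified"
  } else if (!unique_top &&
             cand$score[1] >= config$score_threshold &&
             cand$n_matched[1] >= config$min_diagnostic_ions) {
    "ambiguous"
  } else {
    "unidentified"
  }
  result(status, cand[, names(empty)], matches = scored[[1]]$matches,
         side_chain = side_chain)
}

#' @export
print.annotation <- function(x, ...) {
  cat("<annotation> feature m/z ", formatC(x$feature_mz, digits = 4, format = "f"),
      " -- ", x$status, "\n", sep = "")
  if (nrow(x$candidates)) {
    top <- x$candidates[1, ]
    cat("  top candidate: ", top$display_name,
        sprintf(" (skeleton %s, side chain %s, score %.3f, %d ions, %+.1f ppm)\n",
                top$skeleton, top$fa_formula, top$score, top$n_matched,
                top$ppm_error), sep = "")
    if (nrow(x$candidates) > 1) {
      cat("  ", nrow(x$candidates) - 1L, " further candidate(s)\n", sep = "")
    }
  }
  invisible(x)
}

# neutral losses diagnostic for hydroxyl position in negative mode
.HYDROXY_RULES <- list(
  "10-OH" = c("H2O", "C8H16", "CO"),
  "13-OH" = c("H2O", "C6H12O"),
  "9-OH"  = c("H2O", "C9H16")
)

#' Assign the hydroxyl position of an oxygenated fatty acid
#'
#' Negative-mode MS/MS of free hydroxy fatty acids (e.g. after alkaline
#' hydrolysis of the lipo-alkaloid) shows position-specific chain-cleavage
#' losses from \eqn{[M-H]^-}: water plus C6H12O for a 13-hydroxyl, water
#' plus C8H16 plus CO for a 10-hydroxyl, water plus C9H16 for a
#' 9-hydroxyl. Anything else is reported `"unknown"`.
#'
#' @param fa_msms Negative-mode [peak_list()] of the free fatty acid.
#' @param fa_formula Neutral formula of the fatty acid (checked against the
#'   precursor).
#' @param config A [match_config()].
#' @return One of `"13-OH"`, `"10-OH"`, `"9-OH"`, `"unknown"`.
#' @examples
#' fx <- reference_spectra()
#' assign_hydroxy_position(fx$hydrolysis_13OH, "C18H32O3")
#' @export
assign_hydroxy_position <- function(fa_msms, fa_formula,
                                    config = match_config()) {
  if (!inherits(fa_msms, "peak_list")) stop("fa_msms must be a peak_list",
                                            call. = FALSE)
  if (fa_msms$mode != "negative") {
    stop("WrongMode: hydroxyl-position rules apply to negative-mode spectra",
         call. = FALSE)
  }
  prec <- fa_msms$precursor_mz
  theo <- ion_mz(fa_formula, "negative", electron_corrected = TRUE)
  if (is.na(prec) ||
      abs(prec - theo) > config$ms2_tol + config$ms1_tol_ppm * 1e-6 * theo) {
    stop("precursor m/z does not match [M-H]- of ", format(.as_formula(fa_formula)),
         call. = FALSE)
  }
  losses <- prec - fa_msms$mz
  has_loss <- function(f) any(abs(losses - monoisotopic_mass(f)) <= config$ms2_tol)
  for (pos in names(.HYDROXY_RULES)) {
    if (all(vapply(.HYDROXY_RULES[[pos]], has_loss, logical(1)))) return(pos)
  }
  "unknown"
}

#' Parse a compound display name
#'
#' Splits names like `"8-lino-BMA"` (and the acetylated variant
#' `"3-Acetyl-8-lino-BMA"`) into the side-chain abbreviation and the
#' skeleton, resolving skeleton aliases.
#'
#' @param name Display name.
#' @param registry A [skeleton_registry()].
#' @param glossary Named side-chain glossary.
#' @return List with `skeleton` (registry name), `abbreviation`,
#'   `fatty_acid` (a [fatty_acid()]) and `formula` (the composed
#'   lipo-alkaloid `elemental_formula`).
#' @examples
#' parse_display_name("8-lino-BMA")$formula
#' @export
parse_display_name <- function(name, registry = skeleton_registry(),
                               glossary = named_side_chains()) {
  x <- name
  if (startsWith(x, "3-Acetyl-8-")) {
    rest <- sub("^3-Acetyl-8-", "", x)
    ab <- strsplit(rest, "-", fixed = TRUE)[[1]][1]
    sk_name <- "3-Ac-BMA"
  } else if (startsWith(x, "8-")) {
    rest <- sub("^8-", "", x)
    ab <- strsplit(rest, "-", fixed = TRUE)[[1]][1]
    sk_name <- substring(rest, nchar(ab) + 2L)
  } else {
    stop("cannot parse display name: ", name, call. = FALSE)
  }
  fa <- side_chain(ab, glossary)
  sk <- get_skeleton(registry, sk_name)
  list(skeleton = sk$name, abbreviation = ab, fatty_acid = fa,
       formula = compose_formula(sk, fa))
}
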