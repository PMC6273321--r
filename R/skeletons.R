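# Aconitane skeleton registry and the neutral-loss fragment grammar.
#
# Each skeleton is a named C19-aconitane core (neutral formula) plus the
# substitution flags that determine which diagnostic neutral losses its
# [M+H]+ ions undergo after ejecting the fatty-acid side chain:
#   * methoxy count (n_ome): up to n_ome - 1 sequential CH3OH losses are
#     observed (the C18 methoxy is retained);
#   * 3-OH: H2O loss after the first and second CH3OH losses;
#   * 15-OH-16-OMe (all registered skeletons): CO loss after the first and
#     second CH3OH losses;
#   * 13-OH-14-OBz: benzoic acid (BzOH) loss after n_ome - 1 CH3OH losses,
#     plus a weak BzOH loss one CH3OH earlier on tetramethoxy skeletons,
#     plus the benzoyl cation [C6H5CO]+;
#   * 3-OAc: acetic acid loss appended to the BzOH-loss ion.
# A few flag-licensed ions are not observed in practice; those are listed
# per skeleton in `absent_losses` and suppressed.

.LOSS_FORMULA <- c(CH3OH = "CH4O", H2O = "H2O", CO = "CO",
                   BzOH = "C7H6O2", AcOH = "C2H4O2")

# canonical key for a multiset of unit losses, e.g. "FA+2CH3OH+CO"
.combo_key <- function(losses) {
  if (length(losses) == 0) return("FA")
  tab <- table(factor(losses, levels = names(.LOSS_FORMULA)))
  tab <- tab[tab > 0]
  paste(c("FA", paste0(ifelse(tab == 1, "", tab), names(tab))), collapse = "+")
}

.combo_label <- function(key) {
  if (key == "C6H5CO") return("[C6H5CO]+")
  parts <- strsplit(key, "+", fixed = TRUE)[[1]]
  paste0("[M + H - ", paste(parts, collapse = " - "), "]+")
}

#' Load the aconitane skeleton registry
#'
#' Reads a skeleton registry from a CSV config file. The shipped default
#' contains the 12 literature-characterized skeletons (BMA, BA, BHA,
#' 3-Ac-BMA, 10-OH-BA, 10-OH-BMA, DBA, 3,13-DDBA, 3-DMDBA, 13-DMDBA,
#' DMBHA, 3,13-DMDDBA); user registries with additional skeletons use the
#' same column layout.
#'
#' @param path CSV file; `NULL` for the shipped default.
#' @return A `skeleton_registry` data frame, one row per skeleton, with the
#'   neutral formula, methoxy count and substitution flags.
#' @examples
#' reg <- skeleton_registry()
#' reg$name
#' @export
skeleton_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "skeletons.csv", package = "lipoannot",
                        mustWork = TRUE)
  }
  reg <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(absent_losses = "character",
                                        aliases = "character"))
  required <- c("name", "formula", "n_ome", "has_3_oh", "has_13_oh_14_obz",
                "has_15_oh_16_ome", "has_3_oac", "n_substituent",
                "absent_losses", "aliases")
  missing <- setdiff(required, names(reg))
  if (length(missing)) {
    stop("skeleton registry lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(reg$name)) stop("skeleton names must be unique", call. = FALSE)
  if (!all(reg$n_ome %in% c(3L, 4L))) {
    stop("n_ome must be 3 or 4 for C19-aconitane skeletons", call. = FALSE)
  }
  if (!all(reg$n_substituent %in% c("Me", "Et"))) {
    stop("n_substituent must be 'Me' or 'Et'", call. = FALSE)
  }
  for (f in reg$formula) parse_formula(f)  # validates
  reg$absent_losses[is.na(reg$absent_losses)] <- ""
  reg$aliases[is.na(reg$aliases)] <- ""
  class(reg) <- c("skeleton_registry", "data.frame")
  reg
}

#' Look up one skeleton by name or alias
#'
#' @param registry A `skeleton_registry`.
#' @param name Skeleton name (or alias, e.g. `"DMDDBA"`).
#' @return A one-row list (`skeleton_spec`) with the registry fields.
#' @export
get_skeleton <- function(registry, name) {
  i <- match(name, registry$name)
  if (is.na(i)) {
    hit <- vapply(strsplit(registry$aliases, ";", fixed = TRUE),
                  function(a) name %in% trimws(a), logical(1))
    if (sum(hit) == 1L) i <- which(hit)
  }
  if (is.na(i)) {
    stop("UnknownSkeleton: '", name, "' is not in the registry", call. = FALSE)
  }
  structure(as.list(registry[i, , drop = FALSE]), class = "skeleton_spec")
}

.as_skeleton <- function(s, registry = NULL) {
  if (inherits(s, "skeleton_spec")) return(s)
  if (is.character(s) && length(s) == 1L) {
    if (is.null(registry)) registry <- skeleton_registry()
    return(get_skeleton(registry, s))
  }
  if (is.list(s) && !is.null(s$name) && !is.null(s$formula)) {
    return(structure(as.list(s), class = "skeleton_spec"))
  }
  stop("cannot interpret skeleton specification", call. = FALSE)
}

# loss combos (character vectors of unit losses) licensed by the flags
.grammar_combos <- function(s) {
  n <- s$n_ome
  combos <- list(character(0))
  weak <- FALSE
  for (k in seq_len(n - 1L)) combos <- c(combos, list(rep("CH3OH", k)))
  weak <- c(weak, rep(FALSE, n - 1L))
  if (isTRUE(s$has_3_oh)) {
    combos <- c(combos, list(c("CH3OH", "H2O"), c("CH3OH", "CH3OH", "H2O")))
    weak <- c(weak, FALSE, FALSE)
  }
  if (isTRUE(s$has_15_oh_16_ome)) {
    combos <- c(combos, list(c("CH3OH", "CO"), c("CH3OH", "CH3OH", "CO")))
    weak <- c(weak, FALSE, FALSE)
  }
  if (isTRUE(s$has_13_oh_14_obz)) {
    combos <- c(combos, list(c(rep("CH3OH", n - 1L), "BzOH")))
    weak <- c(weak, FALSE)
    if (n == 4L) {
      combos <- c(combos, list(c(rep("CH3OH", n - 2L), "BzOH")))
      weak <- c(weak, TRUE)
    }
    if (isTRUE(s$has_3_oac)) {
      combos <- c(combos, list(c(rep("CH3OH", n - 1L), "BzOH", "AcOH")))
      weak <- c(weak, FALSE)
    }
  }
  keys <- vapply(combos, .combo_key, character(1))
  absent <- trimws(strsplit(s$absent_losses %||% "", ";", fixed = TRUE)[[1]])
  keep <- !(keys %in% absent)
  list(combos = combos[keep], weak = weak[keep], keys = keys[keep])
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Predict diagnostic fragment ions for a skeleton
#'
#' Applies the neutral-loss grammar to a skeleton and returns the expected
#' diagnostic ion table. The fragment series starts at the skeleton ion
#' \eqn{[M+H-FA]^+} (loss of the intact fatty acid from the protonated
#' lipo-alkaloid), which is independent of the side chain, so the grid is
#' the same for every fatty acid; when `fatty_acid` is supplied the
#' precursor \eqn{[M+H]^+} m/z is attached as attribute `precursor_mz`
#' (electron-corrected).
#'
#' @param skeleton A `skeleton_spec`, or a skeleton name resolved against
#'   `registry`.
#' @param fatty_acid Optional side chain (`fatty_acid`, formula or string)
#'   used only to compute the precursor m/z.
#' @param electron_corrected Convention for the fragment m/z values;
#'   defaults to `FALSE` (hydrogen-atom convention, the one used by the
#'   published diagnostic-ion grid).
#' @param registry Registry used when `skeleton` is given by name.
#' @return Data frame with columns `label`, `losses` (canonical key such as
#'   `"FA+2CH3OH+CO"`), `formula` (neutral-composition formula of the
#'   fragment, i.e. the protonated ion minus the adduct), `mz` and `weak`,
#'   ordered by decreasing m/z.
#' @examples
#' reg <- skeleton_registry()
#' predict_fragments(get_skeleton(reg, "BMA"))
#' @export
predict_fragments <- function(skeleton, fatty_acid = NULL,
                              electron_corrected = FALSE, registry = NULL) {
  s <- .as_skeleton(skeleton, registry)
  g <- .grammar_combos(s)
  base <- formula_subtract(s$formula, "H2O")  # neutral composition of [M+H-FA]+ minus adduct
  frag <- lapply(g$combos, function(losses) {
    f <- base
    for (l in losses) f <- formula_subtract(f, .LOSS_FORMULA[[l]])
    f
  })
  keys <- g$keys
  weak <- g$weak
  if (isTRUE(s$has_13_oh_14_obz)) {
    frag <- c(frag, list(parse_formula("C7H4O")))  # benzoyl cation, neutral composition
    keys <- c(keys, "C6H5CO")
    weak <- c(weak, FALSE)
  }
  mz <- vapply(frag, ion_mz, numeric(1), mode = "positive",
               electron_corrected = electron_corrected)
  out <- data.frame(
    label = vapply(keys, .combo_label, character(1)),
    losses = keys,
    formula = vapply(frag, format, character(1)),
    mz = mz,
    weak = weak,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(-out$mz), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skeleton") <- s$name
  if (!is.null(fatty_acid)) {
    fa_formula <- if (inherits(fatty_acid, "fatty_acid")) fatty_acid$formula else fatty_acid
    attr(out, "precursor_mz") <- ion_mz(compose_formula(s$formula, fa_formula),
                                        "positive", electron_corrected = TRUE)
  }
  out
}

#' Score an observed spectrum against predicted fragments
#'
#' Fraction of predicted diagnostic ions found in the observed peak list
#' within an absolute m/z tolerance; weak ions carry weight 0.5. Observed
#' peaks that match nothing are not penalized (real spectra contain ions
#' outside the diagnostic grammar).
#'
#' @param predicted Output of [predict_fragments()].
#' @param peaks A [peak_list()] (centroided, m/z ascending).
#' @param ms2_tol Absolute matching tolerance in Da (default 0.01).
#' @return List with `score` in \[0, 1\], `n_matched`, and `matches`, a data
#'   frame of matched ions with observed m/z and ppm errors.
#' @export
diagnostic_score <- function(predicted, peaks, ms2_tol = 0.01) {
  stopifnot(is.data.frame(predicted), nrow(predicted) > 0, ms2_tol > 0)
  obs <- if (inherits(peaks, "peak_list")) peaks$mz else as.numeric(peaks)
  if (length(obs) == 0) {
    stop("EmptySpectrum: observed peak list has no peaks", call. = FALSE)
  }
  idx <- vapply(predicted$mz, function(m) which.min(abs(obs - m)), integer(1))
  d <- obs[idx] - predicted$mz
  matched <- abs(d) <= ms2_tol
  w <- ifelse(predicted$weak, 0.5, 1)
  matches <- data.frame(
    label = predicted$label[matched],
    losses = predicted$losses[matched],
    mz_pred = predicted$mz[matched],
    mz_obs = obs[idx][matched],
    ppm = (d[matched] / predicted$mz[matched]) * 1e6,
    weak = predicted$weak[matched],
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(score = sum(w[matched]) / sum(w),
       n_matched = sum(matched),
       matches = matches)
}
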