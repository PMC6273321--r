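# Seeded synthetic Q-TOF-like spectra for end-to-end testing without
# instrument data. Intensities are synthetic conveniences (scoring uses
# presence and weak-ion weighting only) and are not physical.

#' Simulation configuration
#'
#' Defaults are the benchmark conditions of the recovery experiment:
#' 5 ppm Gaussian m/z jitter, 20 decoy peaks, 10% dropout of non-base
#' diagnostic ions. The same seed and configuration always give
#' bit-identical output.
#'
#' @param seed Integer RNG seed.
#' @param mz_jitter_ppm Gaussian sigma of the per-peak mass error, ppm.
#' @param n_decoy_peaks Number of uniform decoy peaks added per spectrum.
#' @param decoy_mz_range Range the decoys are drawn from.
#' @param intensity_range Intensity range for non-base diagnostic ions
#'   (the base peak is fixed at 100).
#' @param decoy_intensity_max Intensity ceiling for decoy peaks.
#' @param dropout_prob Probability that a non-base diagnostic ion is
#'   omitted.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, mz_jitter_ppm = 5, n_decoy_peaks = 20L,
                       decoy_mz_range = c(100, 900),
                       intensity_range = c(5, 60),
                       decoy_intensity_max = 20, dropout_prob = 0.1) {
  stopifnot(mz_jitter_ppm >= 0, n_decoy_peaks >= 0,
            dropout_prob >= 0, dropout_prob <= 1,
            length(decoy_mz_range) == 2, decoy_mz_range[1] < decoy_mz_range[2])
  structure(list(seed = as.integer(seed), mz_jitter_ppm = mz_jitter_ppm,
                 n_decoy_peaks = as.integer(n_decoy_peaks),
                 decoy_mz_range = decoy_mz_range,
                 intensity_range = intensity_range,
                 decoy_intensity_max = decoy_intensity_max,
                 dropout_prob = dropout_prob),
            class = "sim_config")
}

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate one lipo-alkaloid MS/MS spectrum
#'
#' Jitters the skeleton's predicted diagnostic ions, drops non-base ions
#' at the configured rate, and adds decoy peaks drawn uniformly but
#' excluded from a +/-0.03 Da guard zone around every true ion so that the
#' ground truth stays unambiguous. The precursor is the jittered
#' electron-corrected \[M+H\]+ of the composed lipo-alkaloid.
#'
#' @param skeleton A `skeleton_spec` (or name, resolved via `registry`).
#' @param fatty_acid A [fatty_acid()], formula or formula string.
#' @param config A [sim_config()].
#' @param registry Registry used when `skeleton` is a name.
#' @return List with `spectrum` (a [peak_list()]) and `truth` (list with
#'   the generating skeleton name, side-chain formula and true \[M+H\]+).
#' @examples
#' sim <- simulate_spectrum("BMA", side_chain("lino"),
#'                          sim_config(seed = 42))
#' sim$truth$skeleton
#' @export
simulate_spectrum <- function(skeleton, fatty_acid, config = sim_config(),
                              registry = NULL) {
  s <- .as_skeleton(skeleton, registry)
  fa_formula <- if (inherits(fatty_acid, "fatty_acid")) fatty_acid$formula else
    format(.as_formula(fatty_acid))
  pred <- predict_fragments(s)
  mz_true <- pred$mz
  base_i <- which(pred$losses == "FA")
  precursor_true <- ion_mz(compose_formula(s$formula, fa_formula),
                           "positive", electron_corrected = TRUE)
  guard <- 0.03  # 3x the default MS/MS matching tolerance

  .with_seed(config$seed, {
    keep <- rep(TRUE, length(mz_true))
    nb <- setdiff(seq_along(mz_true), base_i)
    keep[nb] <- stats::runif(length(nb)) >= config$dropout_prob
    mz <- mz_true[keep]
    mz_obs <- mz * (1 + stats::rnorm(length(mz), 0, config$mz_jitter_ppm) * 1e-6)
    int <- stats::runif(length(mz), config$intensity_range[1],
                        config$intensity_range[2])
    int[match(base_i, which(keep))] <- 100
    decoys <- numeric(0)
    while (length(decoys) < config$n_decoy_peaks) {
      cand <- stats::runif(config$n_decoy_peaks - length(decoys),
                           config$decoy_mz_range[1], config$decoy_mz_range[2])
      ok <- vapply(cand, function(x) all(abs(x - mz_true) > guard), logical(1))
      decoys <- c(decoys, cand[ok])
    }
    dint <- stats::runif(length(decoys), 0, config$decoy_intensity_max)
    precursor_obs <- precursor_true *
      (1 + stats::rnorm(1, 0, config$mz_jitter_ppm) * 1e-6)
    spec <- peak_list(c(mz_obs, decoys), c(int, dint),
                      precursor_mz = precursor_obs, mode = "positive")
    list(spectrum = spec,
         truth = list(skeleton = s$name, fa_formula = fa_formula,
                      mz = precursor_true, seed = config$seed))
  })
}

#' Simulate a batch of spectra with ground truth
#'
#' Each spectrum gets its own derived seed (`config$seed + i`), so the
#' batch is reproducible and individual spectra can be regenerated.
#'
#' @param pairs Data frame with columns `skeleton` and `fa_formula`.
#' @param config A [sim_config()]; `config$seed` anchors the batch.
#' @param registry A [skeleton_registry()].
#' @return List with `spectra` (list of [peak_list()]) and `truth` (data
#'   frame with `id`, `skeleton`, `fa_formula`, `mz`).
#' @export
simulate_spectra <- function(pairs, config = sim_config(),
                             registry = skeleton_registry()) {
  stopifnot(all(c("skeleton", "fa_formula") %in% names(pairs)))
  n <- nrow(pairs)
  spectra <- vector("list", n)
  truth <- data.frame(id = sprintf("sim-%04d", seq_len(n)),
                      skeleton = pairs$skeleton,
                      fa_formula = pairs$fa_formula,
                      mz = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    sim <- simulate_spectrum(get_skeleton(registry, pairs$skeleton[i]),
                             pairs$fa_formula[i], cfg_i)
    sim$spectrum$id <- truth$id[i]
    spectra[[i]] <- sim$spectrum
    truth$mz[i] <- sim$truth$mz
  }
  list(spectra = spectra, truth = truth)
}
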