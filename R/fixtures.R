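# Worked-example spectra and reference tables.
#
# The spectra below are transcriptions of literature-reported peak values
# for characterized lipo-alkaloids: A1 (8-O-linoleoyl-14-benzoylmesaconine,
# the canonical BMA x linoleic worked example), A7 (its hydroxylated-side-
# chain analogue), a BHA-skeleton isomer observed at the same nominal mass
# as A1, and the negative-mode spectra of hydroxyoctadecadienoic acids
# released by alkaline hydrolysis. Peak intensities are synthetic ordering
# conveniences -- only the m/z values are reported measurements.

#' Literature worked-example spectra
#'
#' @return Named list of [peak_list()] objects: `A1`, `A7`, `compound71`
#'   (positive mode) and `hydrolysis_13OH`, `hydrolysis_10OH`,
#'   `hydrolysis_9OH`, `hydrolysis_unknown` (negative-mode free fatty
#'   acids).
#' @examples
#' names(reference_spectra())
#' @export
reference_spectra <- function() {
  list(
    # quasi-molecular ion 852.5254; base peak 572.2863 = loss of C18H32O2;
    # MeOH/H2O/CO/BzOH-loss series; 105.0340 benzoyl cation; 390.2271 is a
    # reported ion outside the diagnostic grammar (FA+CH3OH+CO+BzOH).
    A1 = peak_list(
      mz = c(105.0340, 390.2271, 480.2385, 490.2226, 508.2335, 512.2649,
             522.2493, 540.2600, 572.2863),
      intensity = c(18, 12, 22, 25, 40, 28, 30, 45, 100),
      precursor_mz = 852.5254, mode = "positive", id = "A1"),
    # one oxygen more than A1, same BMA skeleton series
    A7 = peak_list(
      mz = c(105.0340, 480.2385, 490.2226, 508.2335, 512.2649, 522.2493,
             540.2600, 572.2863),
      intensity = c(15, 20, 24, 38, 26, 28, 42, 100),
      precursor_mz = 868.5228, mode = "positive", id = "A7"),
    # isomer of A1's formula with base peak 556.2919, one oxygen less than
    # A1's skeleton ions and no CO-loss ions: BHA skeleton
    compound71 = peak_list(
      mz = c(105.0340, 338.1756, 460.2124, 492.2386, 524.2651, 556.2919),
      intensity = c(20, 12, 15, 35, 40, 100),
      precursor_mz = 852.5264, mode = "positive", id = "compound71"),
    # free C18H32O3 acids at [M-H]- 295.2279 after alkaline hydrolysis
    hydrolysis_13OH = peak_list(
      mz = c(195.1407, 277.2191), intensity = c(100, 60),
      precursor_mz = 295.2279, mode = "negative", id = "hydrolysis_13OH"),
    hydrolysis_10OH = peak_list(
      mz = c(183.1027, 267.2330, 277.2173), intensity = c(100, 40, 50),
      precursor_mz = 295.2279, mode = "negative", id = "hydrolysis_10OH"),
    hydrolysis_9OH = peak_list(
      mz = c(171.1027, 277.2173), intensity = c(100, 55),
      precursor_mz = 295.2279, mode = "negative", id = "hydrolysis_9OH"),
    # losses of H2O and C5H12O do not fit any hydroxyl-position rule
    hydrolysis_unknown = peak_list(
      mz = c(207.1391, 277.2173), intensity = c(100, 60),
      precursor_mz = 295.2279, mode = "negative", id = "hydrolysis_unknown")
  )
}

#' Reported diagnostic-ion grid
#'
#' The literature-reported calculated m/z grid of skeleton diagnostic ions
#' (hydrogen-atom convention, 4 decimals), one row per non-empty cell.
#' `weak` marks ions reported as present but low-abundance (no printed
#' value); `misprint` marks the cells whose printed value is inconsistent
#' with their own row's methanol-loss arithmetic.
#'
#' @return Data frame with columns `skeleton`, `losses`, `printed_mz`,
#'   `weak`, `misprint`.
#' @export
reported_fragment_grid <- function() {
  utils::read.csv(system.file("extdata", "reported_fragment_grid.csv",
                              package = "lipoannot", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Reported lipo-alkaloid identifications
#'
#' The 148 literature-reported identifications: retention time, calculated
#' and observed \[M+H\]+ and the display name (side-chain abbreviation plus
#' skeleton). `calcd_consistent = FALSE` flags rows whose printed
#' calculated m/z is internally inconsistent with the rest of the table
#' (cross-row arithmetic) or whose skeleton code matches no registry entry;
#' those rows are excluded from reproduction checks.
#'
#' @return Data frame with columns `no`, `rt_min`, `calcd_mz`, `obs_mz`,
#'   `name`, `first_report`, `calcd_consistent`.
#' @export
reported_annotations <- function() {
  utils::read.csv(system.file("extdata", "reported_annotations.csv",
                              package = "lipoannot", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
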