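---
title: "Annotating aconitane lipo-alkaloids: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating aconitane lipo-alkaloids: model, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipoannot)
```

## The identification problem

Lipo-alkaloids are C19-norditerpenoid alkaloids of *Aconitum* species in
which a fatty acid is esterified to C-8 of an aconitane core (benzoylmesaconine,
benzoylaconine, benzoylhypaconine and their deoxy/demethoxy/hydroxy/acetyl
variants). They are too similar to purify at scale, so identification is done
by high-resolution LC-MS/MS: an accurate MS1 mass proposes molecular formulas,
and the MS/MS spectrum resolves which (skeleton, side chain) combination
produced them. `lipoannot` implements that workflow as code: a combinatorial
formula database, a rule-based fragment predictor, a matcher/scorer, and a
synthetic-spectrum generator that makes the whole pipeline testable without
instrument data.

## The composition model

Every hypothetical lipo-alkaloid is a molecular-formula sum

$$\mathrm{MF}_{lipo\text{-}alkaloid} \;=\; \mathrm{MF}_{skeleton} \;+\;
\mathrm{MF}_{fatty\ acid} \;-\; \mathrm{H_2O},$$

the water being lost on esterification. Side chains are points
$(c, o, d)$ — carbon count, oxygen count, degrees of unsaturation — with
formula $\mathrm{C}_c\mathrm{H}_{2c+2-2d}\mathrm{O}_o$. The default
constraint box is $c \in [3, 25]$, $o \in [2, 6]$, $d \in [1, 7]$; $d$
counts the carboxyl C=O, so a saturated acid has $d = 1$ and linoleic acid
(two C=C) has $d = 3$. This convention is the only one under which the
box's stated unsaturation range and the attested chains (e.g.
C~18~H~32~O~2~) are mutually consistent. Oxygenation is carried only as
the oxygen count: hydroxy, oxo, epoxy and hydroperoxy forms are not
distinguishable at MS1 and are represented by candidate names in the
glossary.

`build_database()` crosses the 12-skeleton registry with the box and
groups compositions by molecular formula, because LC-MS alone cannot
resolve isomeric compositions; all generating pairs stay attached to the
entry for MS/MS disambiguation. One deliberate extension: the abbreviation
glossary contains three glucosyl phenolic acids (o = 9) that fall outside
the box yet are attested side chains, so the composed space is the box
*union* the named glossary (`include_named = TRUE`). Without this, known
compounds would be invisible to the MS1 lookup.

With the default registry and box this gives
`r attr(build_database(), "n_formulas")` distinct formulas from
`r attr(build_database(), "n_combinations")` compositions. The original
in-house database figure (484 formulas) was built from a 13-skeleton,
51-chain list that is not fully printed anywhere, so the size is reported
informationally and never asserted.

## The fragment grammar

Collision-induced dissociation of a protonated lipo-alkaloid first ejects
the intact fatty acid, giving the skeleton ion $[M+H-FA]^+$ — the base
peak, and the reason side-chain identity can be read off as
`precursor − base peak`. The subsequent neutral losses are determined by
the skeleton's substitution pattern:

* **Methanol.** Up to $n_{OMe} - 1$ sequential CH~3~OH losses; the
  C-18 methoxy is bound too strongly to leave, so tetramethoxy skeletons
  show at most three and trimethoxy skeletons at most two.
* **Water** after the first and second methanol loss marks a 3-OH.
* **CO** after the first and second methanol loss marks the 15-OH-16-OMe
  pair (present in all registered skeletons).
* **Benzoic acid** after $n_{OMe}-1$ methanol losses marks 13-OH-14-OBz,
  with a weak variant one methanol earlier on tetramethoxy skeletons, and
  the benzoyl cation [C~6~H~5~CO]^+^ at m/z 105.034.
* **Acetic acid** appended to the benzoate-loss ion marks a 3-OAc.

The registry is data, not code (`inst/extdata/skeletons.csv`): each row is
a name, neutral formula, methoxy count and these flags, so new skeletons
are added without touching the grammar. Three flag-licensed ions are not
observed in practice (the plain triple-methanol ion of 3-Ac-BMA and DBA,
and the single-methanol-plus-CO ion of DMBHA); they are listed per
skeleton as `absent_losses` and suppressed, so the predictor emits exactly
the empirically observed grid. Two cells of the published reference grid
are internally inconsistent with their own row's methanol arithmetic
(the DMDBA rows' 448.2448, implied 448.2488; and 524.3014, implied
524.3012); they are flagged `misprint` in the shipped reference table and
checked against the implied values.

Two ionization conventions coexist in the reference tables: the fragment
grid matches hydrogen-atom addition (+1.007825 Da, no electron
correction), while the identification table's calculated $[M+H]^+$ matches
proton addition (+1.007276 Da). `ion_mz()` therefore takes the convention
as an explicit argument; fragment prediction defaults to the hydrogen-atom
convention and the database stores electron-corrected m/z. The 0.00055 Da
gap is far below every matching tolerance, but keeping it explicit makes
table reproduction exact. Atomic masses are frozen constants
(C = 12, H = 1.0078250319, N = 14.003074, O = 15.9949146 Da) so results
are bit-stable; table comparisons round half-to-even to 4 decimals while
internal computation keeps full precision.

## Matching and scoring

* **MS1**: 10 ppm window (Q-TOF-typical; the original workflow used vendor
  defaults that are not printed). Lookup is a binary-search window over
  the mass-sorted database.
* **MS/MS**: 0.01 Da absolute window — absolute rather than ppm because
  fragments span roughly 100–900 m/z and centroid accuracy there is
  dominated by calibration, not relative error.
* **Score**: matched predicted ions over total predicted ions, weak ions
  weighted 0.5 on both sides. Observed peaks that match nothing are not
  penalized: real spectra contain ions outside the grammar (e.g. the
  reported 390.2271 ion of the linoleoyl-BMA worked example combines
  methanol, CO and benzoate losses in a pattern the grid does not list).
* **Status**: `identified` needs a unique top candidate with score ≥ 0.5
  and ≥ 3 matched diagnostic ions; both thresholds are declared defaults
  (`match_config()`), not literature values, since none are published.
  Ties prefer glossary-attested side chains over hypothetical $(c,o,d)$
  points; remaining ties are reported `ambiguous`, never silently broken.
  MS1-only features are at best `ambiguous` — a skeleton cannot be
  confirmed without MS/MS.
* **Side-chain inference** (`infer_fatty_acid()`) matches
  `precursor − base peak` against the chain space within
  `ms2_tol + ms1_tol_ppm × precursor`, since both measurements contribute
  error.

Negative-mode spectra of free hydroxy fatty acids (obtained by alkaline
hydrolysis) are classified by position-specific chain-cleavage losses from
$[M-H]^-$: {H~2~O, C~6~H~12~O} → 13-OH, {H~2~O, C~8~H~16~, CO} → 10-OH,
{H~2~O, C~9~H~16~} → 9-OH, anything else `unknown`. The 10-OH rule is
checked first as the most specific.

## The synthetic-spectrum generator

`simulate_spectrum()` emulates centroided Q-TOF output for a known
(skeleton, side chain) pair: the predicted diagnostic ions with Gaussian
per-peak m/z jitter, dropout of non-base ions, and uniform decoy peaks,
plus a jittered electron-corrected precursor. Defaults are the benchmark
conditions used throughout the tests: 5 ppm jitter (routine Q-TOF mass
accuracy), 20 decoys, 10% dropout. Decoys are rejection-sampled outside a
±0.03 Da guard zone (3× the MS/MS tolerance) around true ions so ground
truth stays unambiguous. Intensities are synthetic ordering conveniences
(base peak 100, others uniform) — scoring uses presence only, so no
physical intensity model is attempted. Each spectrum's RNG stream is
derived from the configured seed and restored afterwards; the same seed
and configuration give bit-identical spectra.

What the simulation does *not* emulate: profile-mode peak shape, isotope
envelopes, co-isolation chimerism, intensity-dependent mass error, and
retention time. Passing the recovery benchmark therefore shows the
matcher's logic is sound under calibrated mass error and spectral
contamination, not that real chromatographic data of arbitrary quality
will annotate at the same rate.

The benchmark itself: all 12 registry skeletons × all 56 named chains
(672 spectra). At zero noise, annotation must recover every generating
pair exactly with score 1. Under benchmark noise, top-1 recovery must stay
≥ 95%; the residual failures are dominated by precursors jittered past the
10 ppm MS1 window (a 2σ event at 5 ppm jitter), which is the physically
expected failure mode, not a matcher defect.

## Numerical and degenerate-input choices

* Formula subtraction that would drive an element negative errors
  (`NegativeCount`) — a chemically impossible loss should never be silent.
* The empty formula is a valid identity element (mass 0).
* `peak_list()` requires strictly ascending m/z and non-negative
  intensities; an empty observed spectrum is an error (`EmptySpectrum`)
  rather than a zero score, because it indicates an upstream extraction
  problem.
* Skeleton aliases (`DMDBA`, `DMDDBA`, `3-DBA`) resolve the abbreviated
  names used in published identification lists; the two DMDBA isomers
  share a formula, so alias choice never changes a computed mass.
* Problem sizes in the shipped tests: the full 672-pair recovery benchmark
  twice (noiseless and benchmark noise), 1,000 randomized lookup queries,
  100 frozen oracle formulas, ~11,000 jitter draws — sizes chosen so each
  property is exercised exhaustively where the space is finite and with
  comfortable margins where it is stochastic.

## Known limitations

* Isomer resolution is only as good as the grammar: skeletons outside the
  registry, or side-chain positional isomers, are indistinguishable.
* Retention time is carried as metadata only; the orthogonal RT evidence
  used in manual workflows is not modeled.
* Only ±H adducts of singly charged ions are computed; no isotope-pattern
  scoring.
* The headline census figures of the source workflow (148 identifications
  from plant extract) depend on unreleased instrument data and cannot be
  recomputed here; the package reproduces the calculable quantities — the
  diagnostic-ion grid, the calculated $[M+H]^+$ table, and the worked
  examples — and demonstrates the pipeline on synthetic data.
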