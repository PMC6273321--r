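# lipoannot

Accurate-mass annotation of **lipo-alkaloids** — C19-norditerpenoid
alkaloids of *Aconitum* species carrying a fatty-acid ester at C-8 of an
aconitane skeleton — from high-resolution LC-MS/MS data. The package is
aimed at natural-product and metabolomics researchers who need to identify
these compounds without purifying them.

## What it does

Every hypothetical lipo-alkaloid is a molecular-formula composition

```
MF(lipo-alkaloid) = MF(skeleton) + MF(fatty acid) − H2O
```

over a registry of 12 aconitane skeletons (BMA, BA, BHA, 3-Ac-BMA,
10-OH-BA, 10-OH-BMA, DBA, 3,13-DDBA, 3-DMDBA, 13-DMDBA, DMBHA,
3,13-DMDDBA) and a fatty-acid space C_c H_(2c+2−2d) O_o with c ∈ [3, 25],
o ∈ [2, 6], d ∈ [1, 7]. The composed formulas form an accurate-mass
database; MS1 features are matched by ppm window, and MS/MS spectra are
scored against a rule-based fragment grammar in which the neutral losses
(CH3OH, H2O, CO, benzoic acid, acetic acid) after ejection of the intact
fatty acid are determined by the skeleton's substitution flags. The side
chain is inferred from the precursor-minus-base-peak mass, and
negative-mode spectra of hydrolysed hydroxy fatty acids are classified to
9-/10-/13-OH by position-specific chain-cleavage losses.

A seeded synthetic-spectrum generator (jitter, decoys, dropout) and MGF
I/O make the pipeline fully testable without instrument data.

## Worked example

The canonical worked example: a feature at m/z 852.5254 whose MS/MS base
peak 572.2863 corresponds to the benzoylmesaconine skeleton ion, with a
neutral loss matching linoleic acid.

```r
library(lipoannot)
db  <- build_database()
reg <- skeleton_registry()
a1  <- reference_spectra()$A1
annotate_feature(a1$precursor_mz, a1, db, reg)
#> <annotation> feature m/z 852.5254 -- identified
#>   top candidate: 8-lino-BMA (skeleton BMA, side chain C18H32O2, score 0.762, 8 ions, -0.3 ppm)
#>   8 further candidate(s)
```

The feature is identified as 8-*O*-linoleoyl-14-benzoylmesaconine: 8 of
the skeleton's predicted diagnostic ions matched within 0.01 Da, the
precursor sits 0.3 ppm from the calculated [M+H]+ of C49H73NO11, and the
isomeric alternative (BHA skeleton with a hydroxylated C18H32O3 chain,
which shares the molecular formula) scores far lower because its fragment
series is one oxygen short of the observed ions.

Hydroxyl-position assignment of a released side chain:

```r
fx <- reference_spectra()
assign_hydroxy_position(fx$hydrolysis_13OH, "C18H32O3")
#> [1] "13-OH"
```

Simulation round trip:

```r
sim <- simulate_spectrum("BMA", side_chain("lino"), sim_config(seed = 42),
                         registry = reg)
annotate_feature(sim$spectrum$precursor_mz, sim$spectrum, db, reg)$candidates[1, 1:2]
#>   skeleton fa_formula
#> 1      BMA   C18H32O2
```

A command-line wrapper with `build-db`, `annotate` and `simulate`
subcommands is installed under `inst/scripts/lipoannot`.

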