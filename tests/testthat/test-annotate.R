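fx <- reference_spectra()

test_that("side-chain inference recovers the neutral-loss composition", {
  cand <- infer_fatty_acid(852.5254, 572.2863)
  expect_equal(cand$formula[1], "C18H32O2")
  expect_true(cand$named[1])
  expect_equal(cand$abbreviation[1], "lino")

  cand7 <- infer_fatty_acid(868.5228, 572.2863)
  expect_equal(cand7$formula[1], "C18H32O3")

  expect_error(infer_fatty_acid(572.2863, 572.2863), "NonPositiveLoss")
  expect_error(infer_fatty_acid(500, 572.2863), "NonPositiveLoss")
})

test_that("worked-example spectra annotate to the characterized structures", {
  a1 <- annotate_feature(fx$A1$precursor_mz, fx$A1, db_default, reg)
  expect_equal(a1$status, "identified")
  expect_equal(a1$candidates$skeleton[1], "BMA")
  expect_equal(a1$candidates$fa_formula[1], "C18H32O2")
  expect_equal(a1$candidates$display_name[1], "8-lino-BMA")
  expect_gte(a1$candidates$n_matched[1], 8)
  # the isomeric hydroxy-chain alternative is present but outscored
  expect_true(any(a1$candidates$skeleton == "BHA" &
                    a1$candidates$fa_formula == "C18H32O3"))
  # side-chain inference from the located base peak agrees
  expect_equal(a1$side_chain$formula[1], "C18H32O2")

  c71 <- annotate_feature(fx$compound71$precursor_mz, fx$compound71,
                          db_default, reg)
  expect_equal(c71$status, "identified")
  expect_equal(c71$candidates$skeleton[1], "BHA")
  expect_equal(c71$candidates$fa_formula[1], "C18H32O3")

  a7 <- annotate_feature(fx$A7$precursor_mz, fx$A7, db_default, reg)
  expect_equal(a7$candidates$skeleton[1], "BMA")
  expect_equal(a7$candidates$fa_formula[1], "C18H32O3")

  far <- annotate_feature(437.0000, fx$A1, db_default, reg)
  expect_equal(far$status, "unidentified")
  expect_equal(nrow(far$candidates), 0)
})

test_that("MS1-only features are reported ambiguous, not silently resolved", {
  a <- annotate_feature(852.5254, NULL, db_default, reg)
  expect_equal(a$status, "ambiguous")
  expect_gt(nrow(a$candidates), 1)
  expect_true(all(is.na(a$candidates$score)))
})

test_that("negative-mode rules assign hydroxyl positions of free fatty acids", {
  expect_equal(assign_hydroxy_position(fx$hydrolysis_13OH, "C18H32O3"), "13-OH")
  expect_equal(assign_hydroxy_position(fx$hydrolysis_10OH, "C18H32O3"), "10-OH")
  expect_equal(assign_hydroxy_position(fx$hydrolysis_9OH, "C18H32O3"), "9-OH")
  expect_equal(assign_hydroxy_position(fx$hydrolysis_unknown, "C18H32O3"),
               "unknown")
  expect_error(assign_hydroxy_position(fx$A1, "C18H32O3"), "WrongMode")
})

test_that("isomeric entries resolve by skeleton series (three-way case)", {
  # same molecular formula class, three different (skeleton, chain) readings
  triple <- data.frame(
    skeleton = c("BHA", "BMA", "10-OH-BMA"),
    fa_formula = c("C18H34O4", "C18H34O3", "C18H34O2"),
    stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 99, mz_jitter_ppm = 0, n_decoy_peaks = 0,
                    dropout_prob = 0)
  fml <- unique(vapply(seq_len(3), function(i)
    format(compose_formula(get_skeleton(reg, triple$skeleton[i]),
                           triple$fa_formula[i])), character(1)))
  expect_equal(fml, "C49H75NO12")
  for (i in seq_len(3)) {
    sim <- simulate_spectrum(get_skeleton(reg, triple$skeleton[i]),
                             triple$fa_formula[i], cfg)
    a <- annotate_feature(sim$spectrum$precursor_mz, sim$spectrum,
                          db_default, reg)
    expect_equal(a$candidates$skeleton[1], triple$skeleton[i])
    expect_equal(a$candidates$fa_formula[1], triple$fa_formula[i])
  }
})

test_that("noiseless spectra round-trip through annotation with score 1", {
  chains <- c("lino", "ole", "pal", "hodd", "act", "gvl")
  cfg <- sim_config(seed = 5, mz_jitter_ppm = 0, n_decoy_peaks = 0,
                    dropout_prob = 0)
  for (sk in reg$name) for (ab in chains) {
    sim <- simulate_spectrum(get_skeleton(reg, sk), side_chain(ab), cfg)
    a <- annotate_feature(sim$spectrum$precursor_mz, sim$spectrum,
                          db_default, reg)
    expect_equal(a$candidates$skeleton[1], sk)
    expect_equal(a$candidates$fa_formula[1], side_chain(ab)$formula)
    expect_equal(a$candidates$score[1], 1.0)
    expect_equal(a$status, "identified")
  }
})

test_that("display names parse back into skeleton and side chain", {
  p <- parse_display_name("8-lino-BMA", reg, gloss)
  expect_equal(p$skeleton, "BMA")
  expect_equal(p$fatty_acid$formula, "C18H32O2")
  expect_equal(format(p$formula), "C49H73NO11")
  p2 <- parse_display_name("3-Acetyl-8-lino-BMA", reg, gloss)
  expect_equal(p2$skeleton, "3-Ac-BMA")
  p3 <- parse_display_name("8-pal-DMDBA", reg, gloss)  # alias resolution
  expect_equal(p3$skeleton, "3-DMDBA")
  expect_error(parse_display_name("lino-BMA", reg, gloss), "cannot parse")
})
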