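test_that("the built-in registry holds the 12 characterized skeletons", {
  expect_equal(nrow(reg), 12)
  expect_equal(anyDuplicated(reg$name), 0)
  expect_setequal(reg$name,
                  c("BMA", "BA", "BHA", "3-Ac-BMA", "10-OH-BA", "10-OH-BMA",
                    "DBA", "3,13-DDBA", "3-DMDBA", "13-DMDBA", "DMBHA",
                    "3,13-DMDDBA"))
  expect_equal(reg$formula[reg$name == "BMA"], "C31H43NO10")
  # the demethoxy isomer pair shares a formula but differs in flags
  a <- get_skeleton(reg, "3-DMDBA"); b <- get_skeleton(reg, "13-DMDBA")
  expect_equal(a$formula, b$formula)
  expect_false(a$has_3_oh == b$has_3_oh)
  expect_false(a$has_13_oh_14_obz == b$has_13_oh_14_obz)
  expect_error(get_skeleton(reg, "nope"), "UnknownSkeleton")
  expect_equal(get_skeleton(reg, "DMDDBA")$name, "3,13-DMDDBA")  # alias
})

test_that("the fragment grammar emits the expected diagnostic series", {
  bma <- predict_fragments(get_skeleton(reg, "BMA"))
  expect_true(all(round(c(572.2860, 540.2597, 522.2492, 512.2648, 508.2335,
                          490.2230, 480.2386, 476.2073, 354.1705), 4) %in%
                    round(bma$mz, 4)))
  # benzoyl cation for 13-OH-14-OBz skeletons
  expect_true("C6H5CO" %in% bma$losses)
  # no 3-OH and no 13-OBz: no water losses, no benzoate chemistry
  dd <- predict_fragments(get_skeleton(reg, "3,13-DMDDBA"))
  expect_false(any(grepl("H2O", dd$losses)))
  expect_false(any(grepl("BzOH", dd$losses)))
  expect_false("C6H5CO" %in% dd$losses)
  # acetylated skeleton ends in the combined BzOH + AcOH loss
  ac <- predict_fragments(get_skeleton(reg, "3-Ac-BMA"))
  expect_equal(round(min(ac$mz[ac$losses != "C6H5CO"]), 4), 336.1600)
  # side chain does not change the grid, only the precursor attribute
  ac2 <- predict_fragments(get_skeleton(reg, "3-Ac-BMA"), side_chain("lino"))
  expect_equal(ac2$mz, ac$mz)
  expect_equal(round(attr(ac2, "precursor_mz"), 4), 894.5362)
})

test_that("loss chains are mass-additive and strictly decreasing", {
  for (nm in reg$name) {
    pred <- predict_fragments(get_skeleton(reg, nm))
    ions <- pred[pred$losses != "C6H5CO", ]
    base_mz <- ions$mz[ions$losses == "FA"]
    for (i in seq_len(nrow(ions))) {
      expect_equal(ions$mz[i], base_mz - loss_key_mass(ions$losses[i]),
                   tolerance = 1e-9)
      if (ions$losses[i] != "FA") expect_lt(ions$mz[i], base_mz)
    }
    expect_false(is.unsorted(rev(pred$mz), strictly = TRUE))
  }
})

test_that("isomeric skeletons predict distinguishable diagnostic sets", {
  same_formula <- split(reg$name, reg$formula)
  pairs <- Filter(function(x) length(x) > 1, same_formula)
  expect_gt(length(pairs), 0)
  for (group in pairs) {
    for (i in seq_along(group)) for (j in seq_along(group)) {
      if (i >= j) next
      mi <- round(predict_fragments(get_skeleton(reg, group[i]))$mz, 4)
      mj <- round(predict_fragments(get_skeleton(reg, group[j]))$mz, 4)
      expect_false(setequal(mi, mj))
    }
  }
})

test_that("diagnostic scoring matches ions and never rewards peak removal", {
  pred <- predict_fragments(get_skeleton(reg, "BMA"))
  perfect <- peak_list(sort(pred$mz), precursor_mz = 852.5256)
  expect_equal(diagnostic_score(pred, perfect)$score, 1.0)

  a1 <- reference_spectra()$A1
  sc <- diagnostic_score(pred, a1)
  expect_equal(sc$n_matched, 8)
  expect_true(all(c(572.2863, 540.2600, 522.2493, 512.2649, 508.2335,
                    490.2226, 480.2385, 105.0340) %in% sc$matches$mz_obs))
  expect_true(all(abs(sc$matches$ppm) < 10))
  # the wrong skeleton scores strictly lower on the same spectrum
  sc_wrong <- diagnostic_score(predict_fragments(get_skeleton(reg, "13-DMDBA")), a1)
  expect_lt(sc_wrong$score, sc$score)

  expect_error(diagnostic_score(pred, peak_list(numeric(0))), "EmptySpectrum")

  # monotonicity: dropping any one observed peak never increases the score
  for (k in seq_along(a1$mz)) {
    reduced <- peak_list(a1$mz[-k], a1$intensity[-k],
                         precursor_mz = a1$precursor_mz)
    expect_lte(diagnostic_score(pred, reduced)$score, sc$score)
  }
})
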