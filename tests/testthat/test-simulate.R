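test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 123)
  s1 <- simulate_spectrum(get_skeleton(reg, "BMA"), side_chain("lino"), cfg)
  s2 <- simulate_spectrum(get_skeleton(reg, "BMA"), side_chain("lino"), cfg)
  expect_identical(s1$spectrum$mz, s2$spectrum$mz)
  expect_identical(s1$spectrum$intensity, s2$spectrum$intensity)
  expect_identical(s1$spectrum$precursor_mz, s2$spectrum$precursor_mz)
  s3 <- simulate_spectrum(get_skeleton(reg, "BMA"), side_chain("lino"),
                          sim_config(seed = 124))
  expect_false(identical(s1$spectrum$mz, s3$spectrum$mz))
  # the caller's RNG stream is left untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_spectrum("BMA", side_chain("lino"), cfg,
                                           registry = reg))
  expect_identical(runif(1), before)
})

test_that("a noiseless simulation reproduces the predicted ions exactly", {
  cfg <- sim_config(seed = 1, mz_jitter_ppm = 0, n_decoy_peaks = 0,
                    dropout_prob = 0)
  pred <- predict_fragments(get_skeleton(reg, "BA"))
  sim <- simulate_spectrum(get_skeleton(reg, "BA"), side_chain("ole"), cfg)
  expect_equal(sim$spectrum$mz, sort(pred$mz))
  expect_equal(sim$spectrum$precursor_mz, sim$truth$mz)
  expect_equal(round(sim$truth$mz, 4), 868.5569)
  # base peak carries the maximum intensity
  base_mz <- pred$mz[pred$losses == "FA"]
  expect_equal(sim$spectrum$mz[which.max(sim$spectrum$intensity)], base_mz)
})

test_that("mass jitter is centred and decoys avoid the true peaks", {
  cfg0 <- sim_config(seed = 0, mz_jitter_ppm = 5, n_decoy_peaks = 0,
                     dropout_prob = 0)
  pred_mz <- sort(predict_fragments(get_skeleton(reg, "BMA"))$mz)
  ppm <- c()
  for (i in seq_len(1100)) {
    cfg0$seed <- i
    sim <- simulate_spectrum(get_skeleton(reg, "BMA"), side_chain("lino"), cfg0)
    ppm <- c(ppm, (sim$spectrum$mz - pred_mz) / pred_mz * 1e6)
  }
  expect_gte(length(ppm), 10000)
  expect_lt(abs(mean(ppm)), 3 * 5 / sqrt(length(ppm)))
  expect_equal(sd(ppm), 5, tolerance = 0.1)

  cfgd <- sim_config(seed = 3, mz_jitter_ppm = 0, n_decoy_peaks = 50,
                     dropout_prob = 0)
  sim <- simulate_spectrum(get_skeleton(reg, "BMA"), side_chain("lino"), cfgd)
  decoys <- setdiff(sim$spectrum$mz, pred_mz)
  expect_equal(length(decoys), 50)
  expect_true(all(vapply(decoys, function(d) min(abs(d - pred_mz)) > 0.03,
                         logical(1))))
})

test_that("MGF files round-trip simulated spectra", {
  pairs <- data.frame(skeleton = rep(c("BMA", "BHA"), 5),
                      fa_formula = rep(c("C18H32O2", "C18H32O3"), 5),
                      stringsAsFactors = FALSE)
  batch <- simulate_spectra(pairs, sim_config(seed = 7), reg)
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(batch$spectra, path)
  back <- read_mgf(path)
  expect_length(back, 10)
  for (i in seq_len(10)) {
    expect_equal(back[[i]]$mz, batch$spectra[[i]]$mz, tolerance = 1e-6)
    expect_equal(back[[i]]$precursor_mz, batch$spectra[[i]]$precursor_mz,
                 tolerance = 1e-6)
    expect_equal(back[[i]]$mode, batch$spectra[[i]]$mode)
    expect_equal(back[[i]]$id, batch$spectra[[i]]$id)
  }
  # negative-mode charge header round-trips too
  neg <- reference_spectra()$hydrolysis_13OH
  write_mgf(neg, path)
  expect_equal(read_mgf(path)[[1]]$mode, "negative")
})

test_that("malformed MGF input fails with a located parse error", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(character(0), path)
  expect_length(read_mgf(path), 0)

  writeLines(c("BEGIN IONS", "TITLE=x", "100.1 5", "END IONS"), path)
  expect_error(read_mgf(path), "line 1.*PEPMASS")

  writeLines(c("100.0 1"), path)
  expect_error(read_mgf(path), "line 1.*BEGIN IONS")

  writeLines(c("BEGIN IONS", "PEPMASS=500", "abc def", "END IONS"), path)
  expect_error(read_mgf(path), "line 3")
})

test_that("reference spectra carry the reported peak values", {
  fx <- reference_spectra()
  expect_equal(fx$A1$precursor_mz, 852.5254)
  expect_true(all(c(105.0340, 572.2863) %in% fx$A1$mz))
  expect_equal(fx$A7$precursor_mz, 868.5228)
  expect_true(all(c(277.2191, 195.1407) %in% fx$hydrolysis_13OH$mz))
  expect_true(all(vapply(fx, inherits, logical(1), "peak_list")))
})
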