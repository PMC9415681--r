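# FTMS quantification: peak picking, assignment, natural-abundance
# correction and spiked-standard quantification.

test_that("peak picking centroids a noiseless Gaussian to its center", {
  cfg <- ftms_synth_config(noise_sd = 0, seed = 1)
  sp <- synthesize_ftms_spectrum(c("M+0" = 10), config = cfg)
  pk <- pick_peaks(sp)
  main <- pk[which.max(pk$intensity), ]
  expect_equal(main$mz, 181.07066, tolerance = 1e-4)
  expect_error(pick_peaks(data.frame(mz = numeric(0),
                                     intensity = numeric(0))), "empty")
})

test_that("a flat zero spectrum yields no peaks", {
  sp <- data.frame(mz = seq(180, 190, by = 0.001), intensity = 0)
  expect_equal(nrow(pick_peaks(sp)), 0)
})

test_that("two resolvable species yield exactly two principal peaks", {
  cfg <- ftms_synth_config(noise_sd = 0, seed = 1)
  sp <- synthesize_ftms_spectrum(c("13C1" = 10, "2H1" = 10), config = cfg)
  pk <- pick_peaks(sp)
  principal <- pk[pk$intensity > 0.5 * max(pk$intensity), ]
  expect_equal(nrow(principal), 2)
})

test_that("assignment finds the nearest species within tolerance", {
  species <- enumerate_species("13C")
  pk <- data.frame(mz = c(181.07066, 185.0), intensity = c(100, 5))
  asg <- assign_peaks(pk, species)
  expect_equal(asg$label[1], "M+0")
  expect_lt(abs(asg$error_ppm[1]), 0.1)
  expect_true(is.na(asg$label[2]))   # 185.0 is far from every channel
  expect_error(assign_peaks(pk, species, tolerance_ppm = -1), "positive")
})

test_that("13C1 and 2H1 peaks get distinct assignments at R = 500k", {
  cfg <- ftms_synth_config(noise_sd = 0, seed = 1)
  sp <- synthesize_ftms_spectrum(c("13C1" = 10, "2H1" = 10), config = cfg)
  species <- enumerate_species(c("13C", "2H"))
  asg <- assign_peaks(pick_peaks(sp), species)
  big <- asg[asg$intensity > 0.5 * max(asg$intensity), ]
  expect_setequal(big$label, c("13C1", "2H1"))
})

test_that("species within tolerance of each other raise an ambiguity error", {
  species <- enumerate_species("13C")[1:2, ]
  species$exact_mass[2] <- species$exact_mass[1] + 1e-4  # ~0.5 ppm apart
  pk <- data.frame(mz = 181.07, intensity = 1)
  expect_error(assign_peaks(pk, species), "ambiguous")
})

test_that("correction matrix columns are probability masses (sum <= 1)", {
  species <- enumerate_species("13C")
  C <- correction_matrix(species)
  expect_true(all(colSums(C) <= 1 + 1e-9))
  expect_true(all(diag(C) > 0.9))  # all-light line dominates each channel
})

test_that("identity correction matrix returns the input unchanged", {
  obs <- c("M+0" = 10, "13C6" = 5)
  C <- diag(2); dimnames(C) <- list(names(obs), names(obs))
  expect_equal(as.numeric(correct_natural_abundance(obs, C)),
               as.numeric(obs))
})

test_that("natural abundance round-trips: pure unlabeled and 50:50 mix", {
  species <- enumerate_species("13C")
  C <- correction_matrix(species)
  # observed = C %*% truth is exactly what the synthesizer produces per
  # channel; correction must invert it
  truth <- c(1, 0, 0, 0, 0, 0, 0)
  obs <- as.numeric(C %*% truth); names(obs) <- species$label
  x <- correct_natural_abundance(obs, C)
  expect_gt(x[["M+0"]] / sum(x), 0.99)
  truth5050 <- c(0.5, 0, 0, 0, 0, 0, 0.5)
  obs2 <- as.numeric(C %*% truth5050); names(obs2) <- species$label
  x2 <- correct_natural_abundance(obs2, C)
  expect_equal(as.numeric(x2 / sum(x2)), truth5050, tolerance = 0.005)
})

test_that("ill-conditioned correction matrices are rejected", {
  species <- enumerate_species("13C")
  C <- correction_matrix(species)
  C[, 2] <- C[, 1] * (1 + 1e-12)  # nearly collinear channels
  obs <- rep(1, 7); names(obs) <- species$label
  expect_error(correct_natural_abundance(obs, C), "ill-conditioned")
})

test_that("spiked-standard quantification is proportional and excludes the spike", {
  corrected <- c("M+0" = 2, "13C6" = 0, "13C6.2H7" = 1)
  q <- quantify_with_standard(corrected, "13C6.2H7", 10)
  expect_equal(q$amount_nmol[["M+0"]], 20)
  expect_equal(q$total_nmol, 20)
  expect_false("13C6.2H7" %in% names(q$amount_nmol))
  zero <- c("M+0" = 0, "13C6.2H7" = 1)
  expect_equal(quantify_with_standard(zero, "13C6.2H7", 10)$total_nmol, 0)
})

test_that("a spike that is also an analyte species is rejected", {
  corrected <- c("M+0" = 2, "13C6" = 3)
  expect_error(
    quantify_with_standard(corrected, "13C6", 10,
                           analyte_labels = c("M+0", "13C6")),
    "dual-labeled")
})

test_that("quantification is invariant to uniform intensity scaling", {
  cfg <- ftms_synth_config(noise_sd = 0, seed = 1)
  fr <- simulate_labeling(labeling_scenario(0.4, 0.5, 0.1, p = 0.5))
  sp <- synthesize_ftms_spectrum(30 * fr,
                                 spike = list(label = "13C6.2H7", nmol = 20),
                                 cfg)
  species <- enumerate_species("13C")
  q1 <- ftms_quantify(sp, species, "13C6.2H7", 20)
  sp$intensity <- sp$intensity * 7.3
  q2 <- ftms_quantify(sp, species, "13C6.2H7", 20)
  expect_equal(q1$amount_nmol, q2$amount_nmol, tolerance = 1e-9)
})

test_that("PDTX-liver-like composition is recovered end to end", {
  # pool fractions chosen so the observable isotopologue split (M+0 :
  # 13C6 : partially labeled) is 46.3 : 37.6 : 16.1 — the scrambled
  # Binomial(6, 0.5) also deposits a little mass on M+0 and 13C6
  fr <- simulate_labeling(labeling_scenario(0.46041, 0.37341, 0.16618,
                                            p = 0.5))
  expect_equal(100 * fr[["M+0"]], 46.3, tolerance = 1e-3)
  cfg <- ftms_synth_config(seed = 424)
  sp <- synthesize_ftms_spectrum(40 * fr,
                                 spike = list(label = "13C6.2H7", nmol = 30),
                                 cfg)
  q <- ftms_quantify(sp, enumerate_species("13C"), "13C6.2H7", 30)
  f_un <- q$fraction[["M+0"]]
  f_full <- q$fraction[["13C6"]]
  f_scr <- 1 - f_un - f_full
  expect_lt(abs(100 * f_un - 46.3), 0.75)
  expect_lt(abs(100 * f_full - 37.6), 0.75)
  expect_lt(abs(100 * f_scr - 16.1), 0.75)
})

test_that("end-to-end recovery holds across random scenarios at default noise", {
  for (seed in 1:10) {
    r <- run_recovery_scenario(seed)
    expect_lt(max(abs(r$recovered_fraction - r$truth_fraction)), 0.01)
    expect_lt(abs(r$recovered_glycogen - r$truth_glycogen) /
                r$truth_glycogen, 0.05)
  }
})
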