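# Synthetic-data generators: labeling, hydrolysis kinetics, FTMS and NMR
# spectrum synthesis.

test_that("labeling fractions are a proper distribution over species", {
  fr <- simulate_labeling(labeling_scenario(0.46, 0.38, 0.16, p = 0.4))
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_named(fr, enumerate_species("13C")$label)
  expect_error(labeling_scenario(0.5, 0.4, 0.2), "sum to 1")
  expect_error(labeling_scenario(0.5, 0.5, 0, p = 1.5), "retention")
})

test_that("direct incorporation puts all mass on the fully labeled species", {
  fr <- simulate_labeling(labeling_scenario(0, 1, 0))
  expect_equal(fr[["13C6"]], 1)
  # a 55.1/44.9 unlabeled/direct split reports 44.9% fully labeled
  fr2 <- simulate_labeling(labeling_scenario(0.551, 0.449, 0))
  expect_equal(fr2[["13C6"]], 0.449)
  expect_equal(fr2[["M+0"]], 0.551)
})

test_that("scrambling follows the per-position Bernoulli brute-force oracle", {
  p <- 0.5
  fr <- simulate_labeling(labeling_scenario(0, 0, 1, p = p))
  # oracle: enumerate all 2^6 per-position labeling patterns
  patterns <- as.matrix(expand.grid(rep(list(0:1), 6)))
  k <- rowSums(patterns)
  w <- p^k * (1 - p)^(6 - k)
  oracle <- vapply(0:6, function(j) sum(w[k == j]), numeric(1))
  expect_equal(unname(fr), oracle, tolerance = 1e-12)
  expect_equal(fr[["13C3"]], 0.3125)
  # 2H tracer spreads over 7 labelable positions
  fr2 <- simulate_labeling(labeling_scenario(0, 0, 1, p = 0.3,
                                             tracer = "2H7"))
  expect_length(fr2, 8)
  expect_equal(unname(fr2), dbinom(0:7, 7, 0.3), tolerance = 1e-12)
})

test_that("default hydrolysis model satisfies the calibration anchors", {
  r110_10 <- simulate_hydrolysis(10, 110, 10)$recovery_fraction
  r105_10 <- simulate_hydrolysis(10, 105, 10)$recovery_fraction
  r115_10 <- simulate_hydrolysis(10, 115, 10)$recovery_fraction
  r110_30 <- simulate_hydrolysis(10, 110, 30)$recovery_fraction
  expect_gt(r110_10, 0.90)
  expect_gte(r105_10, 0.71)
  expect_gt(r115_10, 0.90)      # broad plateau over 105-115 C
  expect_lt(r110_30, r110_10)   # over-digestion degrades glucose
})

test_that("recovery is unimodal in temperature and HMF rises beyond the peak", {
  Ts <- seq(20, 200, by = 2)
  rec <- vapply(Ts, function(T)
    simulate_hydrolysis(10, T, 10)$recovery_fraction, numeric(1))
  expect_lte(sum(diff(sign(diff(rec))) != 0), 1)
  hmf_hot <- simulate_hydrolysis(10, 150, 10)$hmf_nmol
  hmf_opt <- simulate_hydrolysis(10, 110, 10)$hmf_nmol
  expect_gt(hmf_hot, hmf_opt)
})

test_that("without degradation recovery tends to 1 and glucose follows 6.17", {
  m <- hydrolysis_model(k_deg_ref = 0)
  r <- simulate_hydrolysis(10, 110, 500, m)
  expect_equal(r$recovery_fraction, 1, tolerance = 1e-6)
  expect_equal(r$glucose_nmol, 10 * 6.17, tolerance = 1e-4)
  expect_error(simulate_hydrolysis(-1, 110, 10), "non-negative")
  expect_error(simulate_hydrolysis(10, 250, 10), "temperature")
})

test_that("noiseless FTMS synthesis puts the tallest peak at 181.0707", {
  cfg <- ftms_synth_config(noise_sd = 0, seed = 1)
  sp <- synthesize_ftms_spectrum(c("M+0" = 10), config = cfg)
  expect_equal(sp$mz[which.max(sp$intensity)], 181.07066, tolerance = 1e-4)
})

test_that("zero amounts give a flat noise-only spectrum", {
  cfg <- ftms_synth_config(seed = 5)
  sp <- synthesize_ftms_spectrum(c("M+0" = 0, "13C6" = 0), config = cfg)
  expect_lt(max(abs(sp$intensity)), 6 * cfg$noise_sd)
  expect_equal(mean(sp$intensity), 0, tolerance = 1e-3)
})

test_that("peak multiplicity at 2.9 mDa split follows the resolving power", {
  amounts <- c("13C1" = 10, "2H1" = 10)
  count_maxima <- function(R) {
    cfg <- ftms_synth_config(resolving_power = R, noise_sd = 0, seed = 1)
    sp <- synthesize_ftms_spectrum(amounts, config = cfg)
    reg <- sp[sp$mz > 182.05 & sp$mz < 182.10, ]
    y <- reg$intensity
    tall <- max(y)
    i <- which(y[-c(1, length(y))] > y[-c(length(y) - 1, length(y))] &
                 y[-c(1, length(y))] > y[-c(1, 2)]) + 1L
    sum(y[i] > 0.1 * tall)
  }
  expect_equal(count_maxima(5e5), 2)
  expect_equal(count_maxima(1e4), 1)
})

test_that("unresolvable spike is rejected", {
  cfg <- ftms_synth_config(resolving_power = 1e4, seed = 1)
  expect_error(
    synthesize_ftms_spectrum(c("13C1" = 10),
                             spike = list(label = "2H1", nmol = 5), cfg),
    "not resolvable")
})

test_that("total synthesized FTMS area is linear in total nmol", {
  base <- c("M+0" = 3, "13C6" = 7)
  areas <- vapply(1:4, function(k) {
    cfg <- ftms_synth_config(noise_sd = 0, seed = 1)
    sp <- synthesize_ftms_spectrum(base * k, config = cfg)
    sum(diff(sp$mz) * (sp$intensity[-1] + sp$intensity[-nrow(sp)]) / 2)
  }, numeric(1))
  fit <- lm(areas ~ I(1:4))
  expect_equal(unname(coef(fit)[1]), 0, tolerance = 1e-6 * areas[1])
  expect_equal(areas / (1:4), rep(areas[1], 4), tolerance = 1e-9)
})

test_that("synthesis is bit-reproducible under a fixed seed", {
  mk <- function() synthesize_ftms_spectrum(
    c("M+0" = 5), config = ftms_synth_config(seed = 99))
  expect_identical(mk(), mk())
  nk <- function() synthesize_nmr_spectrum(
    glucose_mM = 1, config = nmr_synth_config(seed = 99))
  expect_identical(nk(), nk())
  expect_error(ftms_synth_config(), "seed is mandatory")
  expect_error(nmr_synth_config(), "seed is mandatory")
})

test_that("NMR synthesis respects enrichment and the anomer equilibrium", {
  cfg <- nmr_synth_config(noise_sd = 0, seed = 1)
  # F = 0: no satellites anywhere
  s0 <- synthesize_nmr_spectrum(glycogen_mM = 2, glucose_mM = 1,
                                dss_mM = 0.5, config = cfg)
  enr0 <- satellite_enrichment(s0, shift_windows())
  expect_true(all(abs(enr0$F) < 0.005))
  # F = 0.63 on glycogen recovers as satellite share of total area
  s63 <- synthesize_nmr_spectrum(glycogen_mM = 2, F_glycogen = 0.63,
                                 dss_mM = 0.5, config = cfg)
  enr63 <- satellite_enrichment(s63, shift_windows())
  expect_equal(enr63$F[enr63$window == "glycogen_H1a"], 0.63,
               tolerance = 0.01)
  # alpha:beta anomer integrals at the 1:2 equilibrium
  expect_equal(integrate_window(s0, 5.22, 0.02) /
                 integrate_window(s0, 4.64, 0.02), 0.5, tolerance = 0.02)
  expect_error(synthesize_nmr_spectrum(glucose_mM = 1, F_glucose = 1.2,
                                       config = cfg), "F must be in")
})

test_that("spectrum averaging produces the composite mean", {
  cfg1 <- ftms_synth_config(seed = 1); cfg2 <- ftms_synth_config(seed = 2)
  s1 <- synthesize_ftms_spectrum(c("M+0" = 10), config = cfg1)
  s2 <- synthesize_ftms_spectrum(c("M+0" = 10), config = cfg2)
  avg <- average_spectra(list(s1, s2))
  expect_equal(avg$intensity, (s1$intensity + s2$intensity) / 2,
               tolerance = 1e-12)
})
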