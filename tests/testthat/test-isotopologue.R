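# Isotopologue enumeration, exact masses, fine structure, resolvability.

test_that("isotope table constants are internally consistent", {
  expect_true(validate_isotope_table())
})

test_that("species enumeration is a complete sorted cartesian product", {
  expect_equal(nrow(enumerate_species("13C")), 7)           # 6 carbons + 1
  expect_equal(nrow(enumerate_species(c("13C", "2H"))), 56) # (6+1)*(7+1)
  expect_equal(nrow(enumerate_species(character())), 1)
  sp <- enumerate_species(c("13C", "2H"))
  expect_false(any(duplicated(sp[c("n13C", "n2H")])))
  expect_false(is.unsorted(sp$exact_mass, strictly = TRUE))
  # heaviest species is fully labeled
  expect_equal(sp[nrow(sp), c("n13C", "n2H")],
               data.frame(n13C = 6, n2H = 7), ignore_attr = TRUE)
  expect_error(enumerate_species("15N"), "unsupported tracer")
})

test_that("enumeration count matches brute force across formulas", {
  for (met in c("glucose", "hmf", "levulinic_acid")) {
    sp <- enumerate_species(c("13C", "2H"), metabolite = met)
    f <- glycoSIRM:::metabolite_formula(met)
    brute <- nrow(expand.grid(c = 0:f$C, h = 0:f$labelable_H))
    expect_equal(nrow(sp), brute, info = met)
    expect_equal(nrow(sp), (f$C + 1) * (f$labelable_H + 1), info = met)
  }
})

test_that("exact masses match IUPAC monoisotopic sums", {
  expect_equal(exact_mass(0, 0, adduct = "none"), 180.06339, tolerance = 1e-7)
  expect_equal(exact_mass(0, 0, adduct = "M+H"), 181.07066, tolerance = 1e-7)
  # 2H substitution is 2.9219 mDa heavier than 13C substitution
  expect_equal(exact_mass(0, 1) - exact_mass(1, 0), 0.0029219,
               tolerance = 1e-5)
  expect_error(exact_mass(7, 0), "n13C")
  expect_error(exact_mass(0, 8), "non-exchangeable")
})

test_that("exact mass is strictly monotone in the heavy-atom partial order", {
  sp <- enumerate_species(c("13C", "2H"))
  for (i in seq_len(nrow(sp))) {
    heavier <- sp$n13C >= sp$n13C[i] & sp$n2H >= sp$n2H[i] &
      (sp$n13C > sp$n13C[i] | sp$n2H > sp$n2H[i])
    expect_true(all(sp$exact_mass[heavier] > sp$exact_mass[i]))
  }
})

test_that("fine structure reproduces the closed-form all-light probability", {
  fs <- natural_abundance_fine_structure(0, 0)
  p_mono <- 0.9893^6 * 0.999885^12 * 0.99757^6
  expect_equal(fs$probability[1], p_mono, tolerance = 1e-9)
  expect_equal(fs$probability[1], 0.9226, tolerance = 1e-4)
})

test_that("fine-structure probabilities sum to 1 before flooring", {
  for (case in list(c(0, 0), c(6, 0), c(6, 7), c(2, 3))) {
    fs <- natural_abundance_fine_structure(case[1], case[2],
                                           probability_floor = 1e-15)
    expect_lt(abs(sum(fs$probability) + attr(fs, "dropped_mass") - 1), 1e-9)
  }
})

test_that("flooring keeps only the monoisotopic line at floor 0.5", {
  fs <- natural_abundance_fine_structure(0, 0, probability_floor = 0.5)
  expect_equal(nrow(fs), 1)
  expect_equal(fs$k13C + fs$k2H + fs$k17O + fs$k18O, 0)
  expect_error(natural_abundance_fine_structure(0, 0, probability_floor = 1),
               "probability_floor")
})

test_that("fully labeled species varies only in O and exchangeable H", {
  fs <- natural_abundance_fine_structure(6, 7, probability_floor = 1e-15)
  # 12 - 7 = 5 exchangeable hydrogens may still vary; no carbon variation
  expect_true(all(fs$k13C == 0))
  expect_lte(max(fs$k2H), 5)
})

test_that("13C1 vs 2H1 resolvability matches the FWHM criterion", {
  m13 <- exact_mass(1, 0); m2 <- exact_mass(0, 1)
  expect_true(resolvable(m13, m2, 5e5))
  expect_false(resolvable(m13, m2, 1e4))
  expect_false(resolvable(m13, m13, 5e5))
  expect_error(resolvable(-1, 100, 5e5), "positive")
  # FWHM at ~182 and R=500k is ~3.5e-4 Da, far below the 2.9 mDa split
  expect_equal(fwhm_at(182, 5e5), 182 / (5e5 * sqrt(200 / 182)),
               tolerance = 1e-12)
})

test_that("minimum resolving power to split 13C1 from 2H1 is ~6.2e4 by m/dm", {
  m13 <- exact_mass(1, 0); m2 <- exact_mass(0, 1)
  dm <- m2 - m13; mbar <- (m13 + m2) / 2
  expect_equal(mbar / dm, 6.2e4, tolerance = 0.01)
  # brute-force search over an R grid agrees with the closed form under
  # the sqrt(200/m) scaling of the resolving-power model
  closed <- mbar^1.5 / (dm * sqrt(200))
  grid <- seq(1e4, 2e5, by = 10)
  flip <- grid[which(vapply(grid, function(R) resolvable(m13, m2, R),
                            logical(1)))[1]]
  expect_equal(flip, closed, tolerance = 1e-3)
})
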