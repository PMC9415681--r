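# Isotope masses and natural abundances (IUPAC 2021 values, fixed here so
# that exact masses and fine-structure probabilities are reproducible).
# Per element: isotopes in strictly increasing mass order; abundances sum to 1.

ISOTOPE_TABLE <- list(
  C = list(mass = c(12, 13.00335483534),
           abundance = c(0.9893, 0.0107)),
  H = list(mass = c(1.00782503190, 2.01410177784),
           abundance = c(0.999885, 0.000115)),
  O = list(mass = c(15.99491461926, 16.99913175595, 17.99915961214),
           abundance = c(0.99757, 0.00038, 0.00205)),
  N = list(mass = c(14.00307400425, 15.00010889827),
           abundance = c(0.99636, 0.00364)),
  P = list(mass = c(30.97376199768),
           abundance = c(1))
)

PROTON_MASS <- 1.00727646688
# adduct mass shifts for singly charged ions (Na+ = Na - electron)
ADDUCT_MASS <- c("M+H" = PROTON_MASS,
                 "M+Na" = 22.98976928 - 0.000548579909,
                 "M-H" = -PROTON_MASS)

# mass added per tracer substitution
DELTA_13C <- ISOTOPE_TABLE$C$mass[2] - ISOTOPE_TABLE$C$mass[1]  # 1.0033548
DELTA_2H  <- ISOTOPE_TABLE$H$mass[2] - ISOTOPE_TABLE$H$mass[1]  # 1.0062767

# Elemental compositions of the metabolites the pipeline quantifies.
# labelable_H counts only carbon-bound (non-exchangeable) hydrogens: the
# hydroxyl protons of glucose exchange with solvent and can never retain a
# 2H tracer in aqueous workup, which is why the heaviest deuterated glucose
# species is 2H7, not 2H12.
METABOLITE_FORMULAS <- list(
  glucose        = list(C = 6,  H = 12, O = 6,  N = 0, P = 0, labelable_H = 7),
  udp_glucose    = list(C = 15, H = 24, O = 17, N = 2, P = 2, labelable_H = 17),
  hmf            = list(C = 6,  H = 6,  O = 3,  N = 0, P = 0, labelable_H = 4),
  levulinic_acid = list(C = 5,  H = 8,  O = 3,  N = 0, P = 0, labelable_H = 7)
)

#' Validate the embedded isotope table
#'
#' Checks that natural abundances sum to one per element (within 1e-9) and
#' that isotope masses are strictly increasing. Called by the test suite;
#' exported so users can audit the constants behind every exact mass.
#'
#' @return Invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validate_isotope_table <- function() {
  for (el in names(ISOTOPE_TABLE)) {
    tab <- ISOTOPE_TABLE[[el]]
    if (abs(sum(tab$abundance) - 1) > 1e-9)
      stop("abundances for ", el, " do not sum to 1")
    if (is.unsorted(tab$mass, strictly = TRUE))
      stop("masses for ", el, " not strictly increasing")
  }
  invisible(TRUE)
}

#' Monoisotopic mass of a metabolite
#'
#' @param metabolite One of `"glucose"`, `"udp_glucose"`, `"hmf"`,
#'   `"levulinic_acid"`.
#' @return Neutral monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(metabolite = "glucose") {
  f <- metabolite_formula(metabolite)
  f$C * ISOTOPE_TABLE$C$mass[1] + f$H * ISOTOPE_TABLE$H$mass[1] +
    f$O * ISOTOPE_TABLE$O$mass[1] + f$N * ISOTOPE_TABLE$N$mass[1] +
    f$P * ISOTOPE_TABLE$P$mass[1]
}

metabolite_formula <- function(metabolite) {
  f <- METABOLITE_FORMULAS[[metabolite]]
  if (is.null(f))
    stop("unknown metabolite '", metabolite, "'; supported: ",
         paste(names(METABOLITE_FORMULAS), collapse = ", "))
  f
}

#' Exact mass of a tracer-substituted species
#'
#' Monoisotopic neutral mass plus `n13C` x 1.0033548 Da, `n2H` x 1.0062767 Da
#' and the adduct shift. Vectorized over `n13C`/`n2H`.
#'
#' @param n13C,n2H Heavy-atom substitution counts.
#' @param adduct `"M+H"`, `"M+Na"`, `"M-H"`, or `"none"` for the neutral mass.
#' @param metabolite Metabolite name, default glucose.
#' @return Mass in Da.
#' @export
exact_mass <- function(n13C = 0, n2H = 0, adduct = "M+H",
                       metabolite = "glucose") {
  f <- metabolite_formula(metabolite)
  if (any(n13C < 0) || any(n13C > f$C))
    stop("n13C must be in [0, ", f$C, "]")
  if (any(n2H < 0) || any(n2H > f$labelable_H))
    stop("n2H must be in [0, ", f$labelable_H, "] (non-exchangeable H only)")
  shift <- if (identical(adduct, "none")) 0 else {
    if (!adduct %in% names(ADDUCT_MASS))
      stop("unsupported adduct '", adduct, "'")
    ADDUCT_MASS[[adduct]]
  }
  monoisotopic_mass(metabolite) + n13C * DELTA_13C + n2H * DELTA_2H + shift
}

#' Enumerate tracer isotopologue species
#'
#' Complete cartesian enumeration of the isotopologues a tracer set can
#' produce: (nC + 1) x (nH_labelable + 1) species for a dual 13C/2H tracer,
#' where only carbon-bound hydrogens are labelable.
#'
#' @param tracer_elements Character subset of `c("13C", "2H")`; empty gives
#'   the single unlabeled species.
#' @param adduct Adduct for the reported ionic mass (default `"M+H"`, the
#'   positive-mode default).
#' @param metabolite Metabolite name, default glucose.
#' @return A data.frame with columns `label`, `n13C`, `n2H`, `n15N`,
#'   `adduct`, `exact_mass`, sorted by `exact_mass`, no duplicates.
#' @examples
#' nrow(enumerate_species("13C"))              # 7: M+0 ... M+6
#' nrow(enumerate_species(c("13C", "2H")))     # 56
#' @export
enumerate_species <- function(tracer_elements = character(), adduct = "M+H",
                              metabolite = "glucose") {
  bad <- setdiff(tracer_elements, c("13C", "2H"))
  if (length(bad))
    stop("unsupported tracer element(s): ", paste(bad, collapse = ", "),
         " (supported: 13C, 2H)")
  f <- metabolite_formula(metabolite)
  nC <- if ("13C" %in% tracer_elements) f$C else 0
  nH <- if ("2H" %in% tracer_elements) f$labelable_H else 0
  grid <- expand.grid(n13C = 0:nC, n2H = 0:nH)
  grid$n15N <- 0L
  grid$adduct <- adduct
  grid$exact_mass <- exact_mass(grid$n13C, grid$n2H, adduct, metabolite)
  grid$label <- species_label(grid$n13C, grid$n2H)
  grid <- grid[order(grid$exact_mass), c("label", "n13C", "n2H", "n15N",
                                         "adduct", "exact_mass")]
  rownames(grid) <- NULL
  grid
}

species_label <- function(n13C, n2H) {
  lab <- ifelse(n13C == 0 & n2H == 0, "M+0",
                trimws(paste0(ifelse(n13C > 0, paste0("13C", n13C), ""),
                              ifelse(n13C > 0 & n2H > 0, ".", ""),
                              ifelse(n2H > 0, paste0("2H", n2H), ""))))
  lab
}

#' Natural-abundance isotopic fine structure of one species
#'
#' Multinomial expansion of the natural heavy-isotope distribution over the
#' positions not already occupied by tracer atoms: the `C - n13C` remaining
#' carbons, the `H_total - n2H` remaining hydrogens (exchangeable hydroxyl
#' protons still vary naturally) and all oxygens (and N where present).
#' Lines below `probability_floor` are dropped; by default the kept lines are
#' NOT renormalized and the dropped probability mass is reported instead, so
#' downstream correction matrices stay conservative.
#'
#' @param n13C,n2H Tracer substitution counts of the species.
#' @param probability_floor Drop lines below this probability (default 1e-6).
#' @param renormalize If `TRUE`, rescale kept probabilities to sum to 1.
#' @param adduct Adduct for the line masses.
#' @param metabolite Metabolite name.
#' @return data.frame with columns `k13C`, `k2H`, `k17O`, `k18O`, `k15N`,
#'   `mass`, `probability`; attributes `dropped_mass` (probability removed by
#'   the floor) and `renormalized`.
#' @export
natural_abundance_fine_structure <- function(n13C = 0, n2H = 0,
                                             probability_floor = 1e-6,
                                             renormalize = FALSE,
                                             adduct = "M+H",
                                             metabolite = "glucose") {
  if (probability_floor >= 1 || probability_floor <= 0)
    stop("probability_floor must be in (0, 1)")
  f <- metabolite_formula(metabolite)
  freeC <- f$C - n13C
  freeH <- f$H - n2H
  if (freeC < 0 || freeH < 0) stop("tracer counts exceed formula")
  base <- exact_mass(n13C, n2H, adduct, metabolite)

  abC <- ISOTOPE_TABLE$C$abundance; abH <- ISOTOPE_TABLE$H$abundance
  abO <- ISOTOPE_TABLE$O$abundance; abN <- ISOTOPE_TABLE$N$abundance
  d17O <- ISOTOPE_TABLE$O$mass[2] - ISOTOPE_TABLE$O$mass[1]
  d18O <- ISOTOPE_TABLE$O$mass[3] - ISOTOPE_TABLE$O$mass[1]
  d15N <- ISOTOPE_TABLE$N$mass[2] - ISOTOPE_TABLE$N$mass[1]

  oxy <- expand.grid(k17O = 0:f$O, k18O = 0:f$O)
  oxy <- oxy[oxy$k17O + oxy$k18O <= f$O, ]
  oxy$p <- apply(oxy, 1, function(r) {
    stats::dmultinom(c(f$O - r[["k17O"]] - r[["k18O"]], r[["k17O"]],
                       r[["k18O"]]), prob = abO)
  })

  grid <- expand.grid(k13C = 0:freeC, k2H = 0:freeH, io = seq_len(nrow(oxy)),
                      k15N = 0:f$N)
  grid$k17O <- oxy$k17O[grid$io]; grid$k18O <- oxy$k18O[grid$io]
  pO <- oxy$p[grid$io]
  grid$probability <-
    stats::dbinom(grid$k13C, freeC, abC[2]) *
    stats::dbinom(grid$k2H, freeH, abH[2]) * pO *
    stats::dbinom(grid$k15N, f$N, abN[2])
  grid$mass <- base + grid$k13C * DELTA_13C + grid$k2H * DELTA_2H +
    grid$k17O * d17O + grid$k18O * d18O + grid$k15N * d15N

  total <- sum(grid$probability)  # equals 1 up to multinomial truncation
  keep <- grid$probability >= probability_floor
  out <- grid[keep, c("k13C", "k2H", "k17O", "k18O", "k15N", "mass",
                      "probability")]
  out <- out[order(out$mass), ]
  rownames(out) <- NULL
  dropped <- total - sum(out$probability)
  if (renormalize) out$probability <- out$probability / sum(out$probability)
  attr(out, "dropped_mass") <- dropped
  attr(out, "renormalized") <- renormalize
  out
}

#' Peak width (FWHM) at a given m/z for an Orbitrap-like analyzer
#'
#' Resolving power is specified at the reference m/z (200 by convention) and
#' scales as 1/sqrt(m/z), so FWHM(m) = m / (R200 * sqrt(200/m)).
#'
#' @param mz m/z value(s).
#' @param resolving_power FWHM resolving power at `reference_mz`.
#' @param reference_mz Reference m/z for the resolving-power setting.
#' @return FWHM in Da.
#' @export
fwhm_at <- function(mz, resolving_power, reference_mz = 200) {
  if (any(resolving_power <= 0)) stop("resolving_power must be positive")
  if (any(mz <= 0)) stop("m/z must be positive")
  mz / (resolving_power * sqrt(reference_mz / mz))
}

#' Are two masses resolvable at a given resolving power?
#'
#' Two peaks count as resolved when their separation is at least one FWHM at
#' their mean m/z.
#'
#' @param m1,m2 Masses in Da.
#' @param resolving_power FWHM resolving power at `reference_mz`.
#' @param reference_mz Reference m/z for the resolving-power setting.
#' @return Logical.
#' @examples
#' # 13C1 vs 2H1 glucose [M+H]+ differ by 2.92 mDa
#' resolvable(exact_mass(1, 0), exact_mass(0, 1), 500000)  # TRUE
#' resolvable(exact_mass(1, 0), exact_mass(0, 1), 10000)   # FALSE
#' @export
resolvable <- function(m1, m2, resolving_power, reference_mz = 200) {
  if (any(c(m1, m2) <= 0)) stop("masses must be positive")
  abs(m1 - m2) >= fwhm_at((m1 + m2) / 2, resolving_power, reference_mz)
}
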