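---
title: "Methods: microscale glycogen quantification and isotope tracing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microscale glycogen quantification and isotope tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoSIRM)
```

## The measurement model

glycoSIRM quantifies glycogen and its stable-isotope enrichment from three
observables:

1. **Intact glycogen by ¹H-NMR.** The anomeric H1α proton of glucose
   residues in glycogen resonates at 5.41 ppm; free glucose (pooled with
   Glc-6-P, which it shadows) gives the α anomer at 5.22 ppm and the β
   anomer at 4.64 ppm in the 1:2 equilibrium ratio. When the attached
   carbon is ¹³C, the one-bond ¹H–¹³C coupling splits a fraction *F* of
   the resonance into satellite doublets at ±¹J(CH)/2, so
   *F* = I(¹³C) / [I(¹³C) + I(¹²C)] is read directly from integrals.
   Absolute amounts come from the DSS reference (nine equivalent methyl
   protons at 0 ppm): concentration scales as
   (analyte integral / effective protons) / (DSS integral / 9).
2. **Glucose isotopologues by direct-infusion FTMS.** After acid
   hydrolysis, all glucose isotopologues are read in a single MS¹ spectrum.
   Amounts follow by proportionality to a spiked internal standard —
   ¹³C₆-glucose for unlabeled samples, ¹³C₆,²H₇-glucose for labeled ones
   so the spike can never collide with an analyte species (enforced by an
   error).
3. **The glycogen chain.** Net glucose = post − pre hydrolysis; glycogen
   (µg) = net (nmol) / 6.17; divided by the hydrolysis efficiency of a
   glycogen standard; divided by mg protein. The constant 6.17 µmol/mg is
   the glucose-equivalent of a glycogen residue, 1000/(180.06 − 18.01).

Assumptions: glucose pools are well mixed (no positional information is
used from MS — only isotopologue mass); anomers are at equilibrium; the
hydrolysis standard behaves like sample glycogen; exchangeable (hydroxyl)
protons carry no ²H label, which is why ²H₇ is the heaviest deuterated
glucose.

## Isotopologues, fine structure, resolvability

Species are enumerated as the cartesian product of 0–6 ¹³C and 0–7 ²H
substitutions (7, 8 or 56 species depending on the tracer set). Exact
masses use a fixed IUPAC-2021 isotope table embedded in the source; ¹³C
adds 1.0033548 Da, ²H 1.0062767 Da, so ¹³C₁ and ²H₁ differ by 2.9219 mDa.
Natural-abundance isotopic fine structure is the multinomial expansion over
the positions not occupied by tracer atoms; lines below a probability
floor (default 1e-6) are dropped and, by default, *not* renormalized — the
dropped mass is reported, keeping correction matrices conservative.

Resolving power is modeled FWHM-based at m/z 200 with the Orbitrap-type
scaling R(m) = R₂₀₀·√(200/m); two peaks are "resolved" when separated by at
least one FWHM at their mean m/z. The instrument settings 500,000 and
1,000,000 both resolve ¹³C₁ from ²H₁ at m/z ~182 (FWHM ≈ 0.35 mDa); the
minimum is ~6×10⁴. The scaling law is this package's choice — instruments
state only the setting — and is recorded in every synthesis config.

## What the synthetic generator emulates

- **Labeling**: a three-pool mixture — unlabeled, direct (fully labeled
  tracer) and scrambled, the last spread Binomial(positions, *p*) by
  per-position Bernoulli retention. This caricatures pentose-phosphate /
  gluconeogenic scrambling as independent positions; it does not model
  positional isotopomers, real pathway stoichiometry, or ¹³C/²H
  cross-contamination of pools.
- **Hydrolysis**: sequential first-order glycogen → glucose → HMF with
  Arrhenius rate constants. The paper-anchored behavior (recovery > 90% at
  110 °C/10 min, ≥ 71% at 105 °C/10 min, decline by 30 min, unimodal in
  temperature) fixed the calibration: k_hyd = 0.5 min⁻¹ and k_deg =
  0.005 min⁻¹ at the 110 °C reference, activation energies 120 and 140
  kJ/mol. These four numbers are the package's calibration, set once;
  the functional form is a modeling choice, not a fitted mechanism.
- **FTMS spectra**: Gaussian peaks (σ = FWHM/2.3548) at every
  fine-structure line, area ∝ amount × line probability, additive Gaussian
  noise (default 0.5% of the tallest peak), axis sampled at 8 points per
  FWHM over the populated region within m/z 100–1000.
- **NMR spectra**: Lorentzian lines, 1 Hz default width (matching 1 Hz
  exponential line-broadening), 3 Hz for the broad polymeric glycogen
  resonance; anomer doublets at 3.8/8.0 Hz; satellites at ±¹J(CH)/2 with
  ¹J(CH) = 170 Hz (literature convention for anomeric CH — the observed
  coupling is configurable); noise default 1e-4 of the tallest peak
  (cryoprobe-class SNR). Seeds are mandatory in both configs; a missing
  seed is an error, and outputs are bit-reproducible given the seed.

Not emulated: chromatography, ion suppression/matrix effects, phasing or
baseline roll of real FIDs, 2D TOCSY/HSQC. Passing tests therefore
demonstrate correctness of the computation chain under idealized peak
shapes and noise, not robustness to instrument artifacts.

## Quantification: numerical choices

- **Peak picking**: local maxima above `snr × MAD` of the intensity,
  centroided by 3-point parabolic interpolation; Gaussian width estimated
  from the log-intensity parabola.
- **Assignment**: nearest mass within 5 ppm (default; the tolerance is the
  user's to set — 5 ppm at m/z 181 is 0.9 mDa, a third of the ¹³C₁/²H₁
  split). Ties break toward smaller |ppm error|, then the lighter species.
  Species lists whose members fall within tolerance of each other raise an
  ambiguity error up front.
- **Channel areas**: targeted trapezoidal integration in ±3.5σ windows at
  each expected species mass, so species below the picking threshold
  integrate to ≈ 0 instead of dropping out of the fraction vector.
- **Natural-abundance correction**: solve `C·x = observed`, where a
  fine-structure line of species *j* counts toward channel *i* when it
  lies within FWHM/2 of channel *i*'s mass at the working resolving power.
  Tying the matrix to resolving power makes it degrade honestly: at low
  resolution channels merge and the matrix (or the assignment step)
  reports the failure rather than silently misallocating. Condition
  numbers above 1e8 are an error. Negative solutions are clipped to zero
  for transparency (not NNLS); clipped mass above 1% warns.
- **NMR integration**: trapezoid with an endpoint-linear baseline per
  window; each endpoint level is averaged over the outer 5% of the window
  so one noisy sample cannot tilt the baseline. Window half-width defaults
  to 0.02 ppm — wide enough to capture ~99% of a 1 Hz Lorentzian at
  600 MHz, narrow enough that the default window set (parents plus
  satellites) stays disjoint. Satellite-window collisions (e.g. the
  downfield glycogen satellite against the free-glucose parent, which
  appears if windows are widened) raise an error: resolving them needs 2D
  spectra, which are out of scope.
- **Degenerate inputs**: empty spectra, zero DSS integrals, both-zero
  enrichment integrals, non-positive efficiencies and unresolvable spikes
  are all explicit errors; negative net glucose is reported with a warning
  flag, never clipped; pre-hydrolysis values below the limit of
  quantification are treated as zero only under an explicit flag (the
  alternative — borrowing the FTMS pre value — is a config choice, since
  neither reading reproduces published averages exactly).

## Design decisions that were genuinely open

- **Adduct**: positive-mode acquisitions are quantified as [M+H]⁺ by
  default ([M+Na]⁺ is supported); reported masses and assignments flag the
  adduct so a sodiated workflow only changes one argument.
- **Normalization**: per-mg-protein and per-residue-weight are both
  supported and the report labels which was used, because practice mixes
  them.
- **Rounding**: full precision internally; reports print masses and
  percentages at one decimal, headline enrichment comparisons at integer
  precision.
- **cli**: the package functions are the interface; a thin wrapper
  (`inst/scripts/glycosirm.R`) exposes `run_pipeline` to the shell with
  `--config/--seed/--out/--format`.

## Known limitations

- Broad resonances are undercounted by narrow windows: with the 3 Hz
  glycogen default, ±0.02 ppm windows capture ~88% of the Lorentzian area,
  so NMR glycogen (and hence the NMR-visible fraction) is a mild lower
  bound. This mirrors real 1D integration practice; satellite-based *F* is
  unaffected because the truncation cancels in the ratio.
- Scrambled pools deposit some mass on M+0 and the fully labeled species
  (the tails of the binomial), so "unlabeled %" in reports is the observed
  M+0 fraction, not the generative pool fraction.
- Only glucose, UDP-glucose, HMF and levulinic acid formulas are known to
  the mass model; there is no general formula decomposition.
- 2D-derived positional enrichments are not computed; 1D satellite
  analysis covers C1 only.

## Problem sizes

The test suite synthesizes FTMS spectra of ~4×10⁵ points (m/z 180.6–194.6
at 8 points/FWHM, R = 500,000) and NMR spectra of 6.3×10⁴ points
(−0.3–6 ppm at 1e-4 ppm). End-to-end parameter recovery is measured over
100 seeded scenarios (two spectra each); module-level recovery checks use
10-scenario subsets. A full pipeline run takes ~1.5 s on one CPU.
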