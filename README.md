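# glycoSIRM

Microscale quantification of glycogen content and turnover for stable
isotope resolved metabolomics (SIRM), from paired pre-/post-acid-hydrolysis
measurements of glucose by direct-infusion ultra-high-resolution FTMS and
1D ¹H-NMR.

## Who this is for

Metabolomics labs tracing ¹³C₆- or ²H₇-glucose into glycogen in mg amounts
of cells or tissue. Glycogen is first observed intact by solution NMR (the
mobile, solvent-exposed branches give the H1α resonance at 5.41 ppm), then
hydrolyzed to free glucose in hot acid and quantified isotopologue-by-
isotopologue against a spiked ¹³C₆- or ¹³C₆,²H₇-glucose internal standard.
The package implements everything downstream of the spectrometer — and a
synthetic-data layer that emulates the spectrometer, so the whole chain is
testable without instrument data.

## The computation at its core

For each sample:

1. **Net glucose** — `net = post-hydrolysis glucose − pre-hydrolysis glucose`
   (nmol, each from FTMS or NMR quantification).
2. **Glucose equivalents** — a glycogen residue is glucose minus water,
   162.05 g/mol, so `glycogen (µg) = net / 6.17` (6.17 µmol glucose per mg
   glycogen).
3. **Efficiency correction** — divide by the hydrolysis efficiency of a
   glycogen standard digested under the same conditions.
4. **Normalization** — divide by mg protein (or residue weight).

Enrichment observables:

- FTMS: isotopologue fractions after natural-abundance correction
  (solving `C·x = observed`, with `C` built from isotopic fine structure at
  the working resolving power). At resolving power 500,000 the 2.9 mDa
  split between ¹³C₁- and ²H₁-glucose is fully resolved, so ¹³C and ²H
  labeling are read out simultaneously.
- NMR: ¹³C fractional enrichment from satellite intensities,
  `F = I(¹³C) / [I(¹³C) + I(¹²C)]`, and absolute amounts vs the DSS
  reference (9 protons at 0 ppm).
- The **NMR-visible fraction** — intact (pre-hydrolysis NMR) glycogen as a
  percentage of total (post-hydrolysis) glycogen — reports how much of the
  granule is mobile enough for solution NMR.

The synthetic layer also ships a calibrated kinetic model of microwave acid
hydrolysis (sequential first-order glycogen → glucose → HMF with Arrhenius
rates): recovery exceeds 90% at 110 °C/10 min, plateaus over ~105–115 °C,
and declines by 30 min as glucose degrades to hydroxymethylfurfural.

## Worked example

The bundled scenario simulates a BEAS-2B-like ¹³C₆-glucose labeling
experiment (24.2 µg glycogen, 60% direct tracer incorporation, 5%
scrambled, digested 10 min at 110 °C):

```r
library(glycoSIRM)
cfg <- read_run_config(system.file("extdata", "scenario_beas2b.json",
                                   package = "glycoSIRM"))
res <- run_pipeline(cfg)
print(res)
```

```
<glycogen_report>
  Pre-hydrolysis glucose:   29.0 nmol
  Post-hydrolysis glucose:  172.9 nmol
  Net glucose:              143.9 nmol
  Glycogen:                 23.3 ug
  Hydrolysis efficiency:    95.4 %
  Corrected glycogen:       24.4 ug
  Glycogen per mg protein: 40.1 ug/mg
  Split (13C6): unlabeled 35.0%, fully labeled 59.7%, scrambled 5.3%
  Fractional enrichment:    65.0 %
  NMR-visible glycogen:     74 %

QC flags raised: 0 of 5 checks
```

Reading it: 143.9 nmol of glucose was liberated by hydrolysis; at 6.17
nmol/µg that is 23.3 µg of glycogen, and correcting for the 95.4% standard
recovery gives 24.4 µg — within 1% of the simulated 24.2 µg truth. The
isotopologue split recovers the generating scenario (35/60/5), and 74% of
the total glycogen was visible to NMR before hydrolysis. `run_pipeline`
also works on real data (`mode = "analyze"` with CSV or mzML spectra), and
`inst/scripts/glycosirm.R` wraps it for shell use.

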