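# Synthetic direct-infusion FTMS and 1D 1H-NMR spectrum generators. These
# emulate the raw inputs of the pipeline so every downstream stage can be
# exercised (and its parameter recovery measured) without instrument data.

#' FTMS synthesis configuration
#'
#' @param resolving_power FWHM resolving power at m/z 200 (instrument
#'   settings 500000 or 1000000 are typical).
#' @param noise_sd Additive Gaussian noise, as a fraction of the tallest
#'   peak height (default 0.5%).
#' @param mz_range Acquisition window in m/z (default 100-1000).
#' @param grid_oversample Grid points per FWHM (default 8).
#' @param seed Random seed; mandatory, recorded in spectrum metadata. A
#'   missing seed is an error rather than silent nondeterminism.
#' @return Object of class `ftms_synth_config`.
#' @export
ftms_synth_config <- function(resolving_power = 5e5, noise_sd = 0.005,
                              mz_range = c(100, 1000), grid_oversample = 8,
                              seed) {
  if (missing(seed) || is.null(seed))
    stop("seed is mandatory in synthesis configs")
  if (resolving_power <= 0 || noise_sd < 0 || grid_oversample < 2 ||
      diff(mz_range) <= 0)
    stop("invalid ftms_synth_config parameters")
  structure(list(resolving_power = resolving_power, noise_sd = noise_sd,
                 mz_range = mz_range, grid_oversample = grid_oversample,
                 seed = as.integer(seed)),
            class = "ftms_synth_config")
}

#' Synthesize a direct-infusion FTMS profile spectrum
#'
#' Places a Gaussian peak (sigma = FWHM/2.3548 at the line's m/z) at every
#' natural-abundance fine-structure line of every species present, with area
#' proportional to amount x line probability, adds the spiked internal
#' standard, then additive Gaussian noise. The m/z axis covers the populated
#' region (clipped to `mz_range`) at `grid_oversample` points per FWHM.
#'
#' @param amounts Named numeric vector of analyte amounts (nmol); names are
#'   species labels as produced by [enumerate_species()] (e.g. `"M+0"`,
#'   `"13C6"`, `"13C2.2H1"`).
#' @param spike Optional list `list(label = "13C6.2H7", nmol = ...)` for the
#'   internal standard. Must be resolvable from every analyte species at the
#'   configured resolving power, otherwise quantification would be invalid
#'   and an error is raised.
#' @param config An [ftms_synth_config()].
#' @param adduct Adduct for all species.
#' @return data.frame of class `ftms_spectrum` with columns `mz`,
#'   `intensity`; attributes `seed`, `resolving_power`.
#' @export
synthesize_ftms_spectrum <- function(amounts, spike = NULL, config,
                                     adduct = "M+H") {
  stopifnot(inherits(config, "ftms_synth_config"))
  if (any(amounts < 0)) stop("amounts must be non-negative")
  specs <- parse_species_labels(names(amounts))
  amt <- as.numeric(amounts)
  if (!is.null(spike)) {
    sp <- parse_species_labels(spike$label)
    m_spike <- exact_mass(sp$n13C, sp$n2H, adduct)
    m_analyte <- exact_mass(specs$n13C, specs$n2H, adduct)
    clash <- !resolvable(m_analyte, m_spike, config$resolving_power)
    if (any(clash & amt > 0))
      stop("spike species ", spike$label, " is not resolvable from analyte ",
           "species ", paste(names(amounts)[clash & amt > 0], collapse = ", "),
           " at resolving power ", config$resolving_power)
    specs <- rbind(specs, sp)
    amt <- c(amt, spike$nmol)
  }

  # fine-structure lines for every species present
  lines_mass <- numeric(0); lines_area <- numeric(0)
  for (i in seq_len(nrow(specs))) {
    fs <- natural_abundance_fine_structure(specs$n13C[i], specs$n2H[i],
                                           adduct = adduct)
    lines_mass <- c(lines_mass, fs$mass)
    lines_area <- c(lines_area, amt[i] * fs$probability)
  }
  keep <- lines_area > 0
  lines_mass <- lines_mass[keep]; lines_area <- lines_area[keep]

  lo <- max(config$mz_range[1],
            if (length(lines_mass)) min(lines_mass) - 0.5 else
              config$mz_range[1])
  hi <- min(config$mz_range[2],
            if (length(lines_mass)) max(lines_mass) + 0.5 else
              config$mz_range[2])
  dmz <- fwhm_at(lo, config$resolving_power) / config$grid_oversample
  mz <- seq(lo, hi, by = dmz)
  intensity <- numeric(length(mz))
  for (i in seq_along(lines_mass)) {
    sigma <- fwhm_at(lines_mass[i], config$resolving_power) / 2.3548
    win <- which(abs(mz - lines_mass[i]) < 6 * sigma)
    if (length(win))
      intensity[win] <- intensity[win] + lines_area[i] *
        stats::dnorm(mz[win], lines_mass[i], sigma)
  }
  if (config$noise_sd > 0) {
    scale <- if (max(intensity) > 0) max(intensity) else 1
    withr_seed(config$seed, {
      intensity <- intensity +
        stats::rnorm(length(mz), 0, config$noise_sd * scale)
    })
  }
  structure(data.frame(mz = mz, intensity = intensity),
            class = c("ftms_spectrum", "data.frame"),
            seed = config$seed, resolving_power = config$resolving_power)
}

# run expr with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}

# "M+0", "13C6", "2H3", "13C2.2H1" -> data.frame(n13C, n2H)
parse_species_labels <- function(labels) {
  n13C <- integer(length(labels)); n2H <- integer(length(labels))
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (lab != "M+0") {
      m13 <- regmatches(lab, regexec("13C([0-9]+)", lab))[[1]]
      m2 <- regmatches(lab, regexec("2H([0-9]+)", lab))[[1]]
      if (!length(m13) && !length(m2))
        stop("unparseable species label '", lab, "'")
      if (length(m13)) n13C[i] <- as.integer(m13[2])
      if (length(m2)) n2H[i] <- as.integer(m2[2])
    }
  }
  data.frame(n13C = n13C, n2H = n2H)
}

#' 1H-NMR synthesis configuration
#'
#' @param frequency_mhz Spectrometer 1H frequency (600.13 MHz ~ 14.1 T).
#' @param linewidth_hz Lorentzian FWHM for sharp (free glucose, DSS) lines;
#'   the default 1 Hz matches 1 Hz exponential line-broadening processing.
#' @param glycogen_linewidth_hz Broader linewidth for the polymeric glycogen
#'   H1-alpha resonance.
#' @param j_ch_hz One-bond 1H-13C coupling for the anomeric CH; 170 Hz is
#'   the literature convention for anomeric carbons and sets the satellite
#'   spacing (the offset is configurable because observed couplings vary by
#'   a few Hz).
#' @param j_hh_alpha_hz,j_hh_beta_hz Three-bond H1-H2 doublet splittings for
#'   the alpha (3.8 Hz) and beta (8.0 Hz) anomers.
#' @param ppm_range,dppm Axis range and sampling interval in ppm.
#' @param noise_sd Additive Gaussian noise as a fraction of the tallest peak.
#' @param seed Mandatory random seed.
#' @return Object of class `nmr_synth_config`.
#' @export
nmr_synth_config <- function(frequency_mhz = 600.13, linewidth_hz = 1,
                             glycogen_linewidth_hz = 3, j_ch_hz = 170,
                             j_hh_alpha_hz = 3.8, j_hh_beta_hz = 8.0,
                             ppm_range = c(-0.3, 6), dppm = 1e-4,
                             noise_sd = 1e-4, seed) {
  if (missing(seed) || is.null(seed))
    stop("seed is mandatory in synthesis configs")
  if (frequency_mhz <= 0 || linewidth_hz <= 0 || glycogen_linewidth_hz <= 0 ||
      j_ch_hz <= 0 || dppm <= 0 || noise_sd < 0 || diff(ppm_range) <= 0)
    stop("invalid nmr_synth_config parameters")
  structure(list(frequency_mhz = frequency_mhz, linewidth_hz = linewidth_hz,
                 glycogen_linewidth_hz = glycogen_linewidth_hz,
                 j_ch_hz = j_ch_hz, j_hh_alpha_hz = j_hh_alpha_hz,
                 j_hh_beta_hz = j_hh_beta_hz, ppm_range = ppm_range,
                 dppm = dppm, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "nmr_synth_config")
}

#' Synthesize the anomeric region of a 1D 1H-NMR spectrum
#'
#' Lorentzian lines for: the broad glycogen H1-alpha resonance at 5.41 ppm;
#' the free glucose (+ Glc-6-P pool) H1-alpha doublet at 5.22 ppm and
#' H1-beta doublet at 4.64 ppm in the equilibrium alpha:beta area ratio 1:2;
#' and the DSS trimethyl reference singlet at 0 ppm. For each metabolite a
#' fraction `F` of the anomeric-proton area is carried by 13C-satellite
#' doublets at +/- 1J(CH)/2 around the parent resonance (the parent keeps
#' 1 - F), which is exactly the NMR observable behind satellite-based
#' fractional enrichment.
#'
#' Intensity units are arbitrary but linear in concentration: each resonance
#' has area = concentration (mM) x number of contributing protons.
#'
#' @param glycogen_mM NMR-visible glycogen in glucose-residue mM.
#' @param glucose_mM Free glucose (+ Glc-6-P) in mM.
#' @param F_glycogen,F_glucose 13C fractional enrichment at C1, in `[0, 1]`.
#' @param dss_mM DSS concentration (9 equivalent methyl protons).
#' @param config An [nmr_synth_config()].
#' @return data.frame of class `nmr_spectrum` with columns `ppm`,
#'   `intensity` (ppm increasing); attribute `seed`.
#' @export
synthesize_nmr_spectrum <- function(glycogen_mM = 0, glucose_mM = 0,
                                    F_glycogen = 0, F_glucose = 0,
                                    dss_mM = 0.5, config) {
  stopifnot(inherits(config, "nmr_synth_config"))
  if (F_glycogen < 0 || F_glycogen > 1 || F_glucose < 0 || F_glucose > 1)
    stop("fractional enrichment F must be in [0, 1]")
  if (glycogen_mM < 0 || glucose_mM < 0 || dss_mM < 0)
    stop("concentrations must be non-negative")
  hz2ppm <- 1 / config$frequency_mhz
  sat <- config$j_ch_hz / 2 * hz2ppm

  # each row: center ppm, total area, linewidth (Hz), H-H doublet J (Hz)
  peaks <- list()
  add <- function(center, area, lw, j = 0) {
    if (area > 0) peaks[[length(peaks) + 1]] <<- c(center, area, lw, j)
  }
  # DSS reference
  add(0, dss_mM * 9, config$linewidth_hz)
  # glycogen H1-alpha: one anomeric proton per residue, broad
  add(5.41, glycogen_mM * (1 - F_glycogen), config$glycogen_linewidth_hz)
  add(5.41 - sat, glycogen_mM * F_glycogen / 2, config$glycogen_linewidth_hz)
  add(5.41 + sat, glycogen_mM * F_glycogen / 2, config$glycogen_linewidth_hz)
  # free glucose anomers, alpha:beta = 1:2 at equilibrium
  for (an in list(c(5.22, 1 / 3, config$j_hh_alpha_hz),
                  c(4.64, 2 / 3, config$j_hh_beta_hz))) {
    a <- glucose_mM * an[2]
    add(an[1], a * (1 - F_glucose), config$linewidth_hz, an[3])
    add(an[1] - sat, a * F_glucose / 2, config$linewidth_hz, an[3])
    add(an[1] + sat, a * F_glucose / 2, config$linewidth_hz, an[3])
  }

  ppm <- seq(config$ppm_range[1], config$ppm_range[2], by = config$dppm)
  intensity <- numeric(length(ppm))
  for (pk in peaks) {
    w <- pk[3] * hz2ppm   # Lorentzian FWHM in ppm
    jd <- pk[4] * hz2ppm
    centers <- if (jd > 0) pk[1] + c(-jd / 2, jd / 2) else pk[1]
    for (cen in centers) {
      area <- pk[2] / length(centers)
      intensity <- intensity +
        area / pi * (w / 2) / ((ppm - cen)^2 + (w / 2)^2)
    }
  }
  if (config$noise_sd > 0) {
    scale <- if (max(intensity) > 0) max(intensity) else 1
    withr_seed(config$seed, {
      intensity <- intensity +
        stats::rnorm(length(ppm), 0, config$noise_sd * scale)
    })
  }
  structure(data.frame(ppm = ppm, intensity = intensity),
            class = c("nmr_spectrum", "data.frame"), seed = config$seed)
}

#' Average several spectra into a composite
#'
#' Direct-infusion acquisitions are averaged over the whole acquisition time
#' before peak picking; this interpolates each scan onto the first scan's
#' axis and averages intensities.
#'
#' @param spectra List of spectra (data.frames whose first column is the
#'   axis and second the intensity).
#' @return A data.frame with the same columns as the first spectrum.
#' @export
average_spectra <- function(spectra) {
  if (!length(spectra)) stop("no spectra to average")
  ref <- spectra[[1]]
  axis <- ref[[1]]
  acc <- matrix(0, nrow = length(axis), ncol = length(spectra))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    acc[, i] <- stats::approx(s[[1]], s[[2]], xout = axis, rule = 2)$y
  }
  out <- ref
  out[[2]] <- rowMeans(acc)
  out
}
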