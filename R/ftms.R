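# FTMS quantification: from a profile spectrum or centroided peak table to
# natural-abundance-corrected absolute isotopologue amounts via the spiked
# internal standard.

#' Pick peaks from a profile spectrum
#'
#' Local maxima above `snr_threshold` times a robust noise estimate (1.4826
#' x MAD of the intensity about its median), centroided by 3-point parabolic
#' interpolation. A Gaussian width estimate from the log-intensity parabola
#' is returned alongside, giving an apex-height-based area estimate.
#'
#' @param spectrum data.frame with columns `mz`, `intensity`, sorted by m/z.
#' @param snr_threshold Signal-to-noise threshold (default 5).
#' @return data.frame with columns `mz`, `intensity` (apex height), `sigma`
#'   (Gaussian width estimate, NA where the local fit fails) and `area`.
#' @export
pick_peaks <- function(spectrum, snr_threshold = 5) {
  if (!nrow(spectrum)) stop("empty spectrum")
  x <- spectrum$mz; y <- spectrum$intensity
  if (is.unsorted(x)) stop("spectrum must be sorted by m/z")
  noise <- stats::mad(y, center = stats::median(y))
  floorv <- snr_threshold * max(noise, 1e-12 * max(abs(y), 1e-300))
  n <- length(y)
  i <- which(y[-c(1, n)] > y[-c(n - 1, n)] & y[-c(1, n)] > y[-c(1, 2)]) + 1L
  i <- i[y[i] > floorv]
  if (!length(i))
    return(data.frame(mz = numeric(0), intensity = numeric(0),
                      sigma = numeric(0), area = numeric(0)))
  y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
  denom <- y0 - 2 * y1 + y2
  delta <- ifelse(denom < 0, 0.5 * (y0 - y2) / denom, 0)
  dx <- (x[i + 1] - x[i - 1]) / 2
  mz_c <- x[i] + delta * dx
  apex <- y1 - 0.25 * (y0 - y2) * delta
  # Gaussian sigma from the parabola through log intensities
  sigma <- rep(NA_real_, length(i))
  ok <- y0 > 0 & y2 > 0
  a <- rep(NA_real_, length(i))
  a[ok] <- (log(y0[ok]) - 2 * log(y1[ok]) + log(y2[ok])) / dx[ok]^2
  good <- ok & !is.na(a) & a < 0
  sigma[good] <- sqrt(-1 / a[good])
  area <- ifelse(is.na(sigma), NA_real_, apex * sigma * sqrt(2 * pi))
  data.frame(mz = mz_c, intensity = apex, sigma = sigma, area = area)
}

#' Assign picked peaks to isotopologue species
#'
#' Nearest-mass assignment within a ppm tolerance; ties break toward the
#' smaller absolute ppm error and then toward the lighter species.
#' Unassigned peaks are retained with `label = NA`. If two species in the
#' target list lie within the tolerance of each other the assignment is
#' ambiguous by construction and an error lists the clash.
#'
#' @param peaks data.frame from [pick_peaks()] (needs `mz`, `intensity`).
#' @param species data.frame from [enumerate_species()] (plus any spike row).
#' @param tolerance_ppm Mass tolerance in ppm (default 5).
#' @return `peaks` with added columns `label`, `species_mass`, `error_ppm`.
#' @export
assign_peaks <- function(peaks, species, tolerance_ppm = 5) {
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be positive")
  sm <- species$exact_mass
  d <- abs(outer(sm, sm, "-"))
  diag(d) <- Inf
  tol_da <- outer(sm, rep(1, length(sm))) * tolerance_ppm * 1e-6
  if (any(d < tol_da)) {
    ij <- which(d < tol_da, arr.ind = TRUE)[1, ]
    stop("ambiguous species list: ", species$label[ij[1]], " and ",
         species$label[ij[2]], " are within ", tolerance_ppm, " ppm")
  }
  label <- rep(NA_character_, nrow(peaks))
  smass <- rep(NA_real_, nrow(peaks))
  eppm <- rep(NA_real_, nrow(peaks))
  for (k in seq_len(nrow(peaks))) {
    err <- (peaks$mz[k] - sm) / sm * 1e6
    ord <- order(abs(err), sm)
    j <- ord[1]
    if (abs(err[j]) <= tolerance_ppm) {
      label[k] <- species$label[j]
      smass[k] <- sm[j]
      eppm[k] <- err[j]
    }
  }
  cbind(peaks, data.frame(label = label, species_mass = smass,
                          error_ppm = eppm))
}

#' Natural-abundance correction matrix for a species list
#'
#' Column j holds the probability that species j's natural-abundance fine
#' structure contributes signal to the observation channel of species i
#' (rows). A fine-structure line counts toward a channel when it falls
#' within half the peak FWHM of the channel mass at the working resolving
#' power — lines that land between channels are simply lost, so columns sum
#' to at most 1.
#'
#' @param species data.frame from [enumerate_species()] (plus spike rows).
#' @param resolving_power FWHM resolving power at m/z 200.
#' @param probability_floor Fine-structure floor passed through.
#' @return Square matrix with species labels as dimnames.
#' @export
correction_matrix <- function(species, resolving_power = 5e5,
                              probability_floor = 1e-6) {
  n <- nrow(species)
  C <- matrix(0, n, n, dimnames = list(species$label, species$label))
  half_fwhm <- fwhm_at(species$exact_mass, resolving_power) / 2
  for (j in seq_len(n)) {
    fs <- natural_abundance_fine_structure(species$n13C[j], species$n2H[j],
                                           probability_floor = probability_floor,
                                           adduct = species$adduct[j])
    for (l in seq_len(nrow(fs))) {
      dm <- abs(fs$mass[l] - species$exact_mass)
      i <- which.min(dm)
      if (dm[i] <= half_fwhm[i])
        C[i, j] <- C[i, j] + fs$probability[l]
    }
  }
  C
}

#' Correct observed channel intensities for natural isotope abundance
#'
#' Solves `C x = observed` where `C` comes from [correction_matrix()], so
#' that the corrected vector reflects tracer incorporation only. Negative
#' solutions are clipped to zero; if more than 1% of the total mass is
#' clipped a warning reports it.
#'
#' @param observed Named numeric vector of per-channel intensities (names
#'   must match the rows of `C`).
#' @param C Correction matrix from [correction_matrix()].
#' @return Named numeric vector of corrected intensities with attribute
#'   `clipped_mass`.
#' @export
correct_natural_abundance <- function(observed, C) {
  if (is.null(names(observed)) || !all(names(observed) %in% rownames(C)))
    stop("observed intensities must be named by species label")
  obs <- observed[rownames(C)]
  obs[is.na(obs)] <- 0
  if (kappa(C, exact = TRUE) > 1e8)
    stop("correction matrix is ill-conditioned (condition number > 1e8); ",
         "species channels are not separable at this resolving power")
  x <- solve(C, obs)
  clipped <- -sum(x[x < 0])
  x[x < 0] <- 0
  if (sum(x) > 0 && clipped / sum(x) > 0.01)
    warning(sprintf("natural-abundance correction clipped %.2f%% of mass",
                    100 * clipped / sum(x)))
  attr(x, "clipped_mass") <- clipped
  x
}

#' Extract per-species channel areas from a profile spectrum
#'
#' Targeted integration: trapezoidal area in a +/- `halfwidth_sigmas` sigma
#' window around each expected species mass, where sigma follows the
#' resolving-power model. This complements [pick_peaks()] for species whose
#' peaks fall below the picking threshold (their channel then integrates to
#' approximately zero rather than being dropped).
#'
#' @param spectrum data.frame with `mz`, `intensity`.
#' @param masses Numeric vector of expected channel masses.
#' @param resolving_power FWHM resolving power at m/z 200.
#' @param halfwidth_sigmas Window half-width in units of sigma (default 3.5).
#' @return Numeric vector of areas (one per mass).
#' @export
species_channel_areas <- function(spectrum, masses, resolving_power = 5e5,
                                  halfwidth_sigmas = 3.5) {
  x <- spectrum$mz; y <- spectrum$intensity
  vapply(masses, function(m) {
    s <- fwhm_at(m, resolving_power) / 2.3548
    w <- which(x >= m - halfwidth_sigmas * s & x <= m + halfwidth_sigmas * s)
    if (length(w) < 2) return(0)
    sum(diff(x[w]) * (y[w][-1] + y[w][-length(w)]) / 2)
  }, numeric(1))
}

#' Absolute quantification against the spiked standard
#'
#' Amounts follow by proportionality to the spiked internal standard:
#' `amount_j = spike_nmol * intensity_j / intensity_spike`. The spike
#' channel is excluded from analyte totals and fractional distributions.
#' Using a spike that is itself an expected analyte species (e.g. a 13C6
#' spike in a 13C6-tracer experiment) is rejected: such samples require the
#' dual-labeled 13C6,2H7 standard.
#'
#' @param corrected Named numeric vector of natural-abundance-corrected
#'   intensities including the spike channel.
#' @param spike_label Species label of the spiked standard.
#' @param spike_nmol Amount spiked, nmol.
#' @param analyte_labels Labels of the expected analyte species (defaults to
#'   every non-spike channel).
#' @param stage `"pre_hydrolysis"` or `"post_hydrolysis"`.
#' @return Object of class `quant_result`: list with `amount_nmol` (named),
#'   `total_nmol`, `fraction`, `modality = "FTMS"`, `stage`.
#' @export
quantify_with_standard <- function(corrected, spike_label, spike_nmol,
                                   analyte_labels = NULL,
                                   stage = c("post_hydrolysis",
                                             "pre_hydrolysis")) {
  stage <- match.arg(stage)
  if (spike_nmol <= 0) stop("spike_nmol must be positive")
  if (!spike_label %in% names(corrected))
    stop("spike channel '", spike_label, "' not present in corrected vector")
  if (is.null(analyte_labels))
    analyte_labels <- setdiff(names(corrected), spike_label)
  if (spike_label %in% analyte_labels)
    stop("spike species ", spike_label, " coincides with an expected ",
         "analyte isotopologue; use the dual-labeled 13C6.2H7 standard ",
         "for labeled samples")
  i_spike <- corrected[[spike_label]]
  if (i_spike <= 0) stop("spike channel intensity is not positive")
  amounts <- spike_nmol * corrected[analyte_labels] / i_spike
  amounts <- pmax(as.numeric(amounts), 0)
  names(amounts) <- analyte_labels
  total <- sum(amounts)
  fraction <- if (total > 0) amounts / total else amounts * 0
  structure(list(amount_nmol = amounts, total_nmol = total,
                 fraction = fraction, modality = "FTMS", stage = stage,
                 spike_label = spike_label, spike_nmol = spike_nmol),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result> %s, %s: total %.3f nmol\n",
              x$modality, x$stage, x$total_nmol))
  df <- data.frame(amount_nmol = round(x$amount_nmol, 4),
                   fraction = round(x$fraction, 4))
  print(df[df$amount_nmol > 0 | df$fraction > 0, ])
  invisible(x)
}

#' One-call FTMS quantification of a profile spectrum
#'
#' Runs the full chain: pick peaks, assign them to the expected species (for
#' mass-accuracy QC), extract per-channel areas, correct natural abundance,
#' and quantify against the spike.
#'
#' @param spectrum Profile spectrum (`mz`, `intensity`).
#' @param species data.frame of expected analyte species from
#'   [enumerate_species()].
#' @param spike_label,spike_nmol Spiked-standard identity and amount.
#' @param resolving_power FWHM resolving power at m/z 200.
#' @param tolerance_ppm Assignment tolerance.
#' @param snr_threshold Peak-picking threshold.
#' @param stage Stage tag for the result.
#' @return A `quant_result` with extra element `assignments`.
#' @export
ftms_quantify <- function(spectrum, species, spike_label, spike_nmol,
                          resolving_power = 5e5, tolerance_ppm = 5,
                          snr_threshold = 5,
                          stage = c("post_hydrolysis", "pre_hydrolysis")) {
  stage <- match.arg(stage)
  sp <- parse_species_labels(spike_label)
  spike_row <- data.frame(label = spike_label, n13C = sp$n13C, n2H = sp$n2H,
                          n15N = 0L, adduct = species$adduct[1],
                          exact_mass = exact_mass(sp$n13C, sp$n2H,
                                                  species$adduct[1]))
  allsp <- rbind(species, spike_row)
  allsp <- allsp[!duplicated(allsp$label), ]
  peaks <- pick_peaks(spectrum, snr_threshold)
  assigned <- if (nrow(peaks)) assign_peaks(peaks, allsp, tolerance_ppm)
              else peaks
  obs <- species_channel_areas(spectrum, allsp$exact_mass, resolving_power)
  names(obs) <- allsp$label
  C <- correction_matrix(allsp, resolving_power)
  corrected <- correct_natural_abundance(obs, C)
  res <- quantify_with_standard(corrected, spike_label, spike_nmol,
                                analyte_labels = species$label, stage = stage)
  res$assignments <- assigned
  res
}
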