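# File interfaces: two-column CSV peak tables / spectra, mzML via mzR, and
# JSON scenario/report files.

#' Read an m/z,intensity CSV spectrum or peak table
#'
#' @param path CSV file with columns `mz` and `intensity` (header optional;
#'   the first two columns are used).
#' @return data.frame with columns `mz`, `intensity`, sorted by m/z.
#' @export
read_mz_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("mz", "intensity") %in% names(df)))
    names(df)[1:2] <- c("mz", "intensity")
  df <- df[order(df$mz), c("mz", "intensity")]
  rownames(df) <- NULL
  df
}

#' Read a ppm,intensity CSV NMR spectrum
#'
#' @param path CSV file with columns `ppm` and `intensity`.
#' @return data.frame with columns `ppm`, `intensity`, ppm increasing.
#' @export
read_ppm_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("ppm", "intensity") %in% names(df)))
    names(df)[1:2] <- c("ppm", "intensity")
  df <- df[order(df$ppm), c("ppm", "intensity")]
  rownames(df) <- NULL
  df
}

#' Write a spectrum as CSV
#'
#' @param spectrum data.frame (e.g. from [synthesize_ftms_spectrum()] or
#'   [synthesize_nmr_spectrum()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(as.data.frame(spectrum)[, 1:2], path, row.names = FALSE)
  invisible(path)
}

#' Read the first spectrum from an mzML file
#'
#' Requires the mzR package (Bioconductor). Profile or centroid data are
#' returned alike as an m/z,intensity data.frame.
#'
#' @param path mzML file.
#' @param scan Scan number (default 1); `scan = "average"` averages all
#'   scans via [average_spectra()].
#' @return data.frame with columns `mz`, `intensity`.
#' @export
read_mzml <- function(path, scan = 1) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  if (!file.exists(path)) stop("file not found: ", path)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  n <- nrow(mzR::header(fh))
  get1 <- function(i) {
    p <- mzR::peaks(fh, i)
    data.frame(mz = p[, 1], intensity = p[, 2])
  }
  if (identical(scan, "average"))
    average_spectra(lapply(seq_len(n), get1))
  else get1(scan)
}

#' Write a spectrum to mzML
#'
#' Requires the mzR package. Writes a single-scan MS1 mzML file.
#'
#' @param spectrum data.frame with columns `mz`, `intensity`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectrum, path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("writing mzML requires the mzR package")
  hdr <- data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
    peaksCount = nrow(spectrum), totIonCurrent = sum(spectrum$intensity),
    retentionTime = 0, basePeakMZ = spectrum$mz[which.max(spectrum$intensity)],
    basePeakIntensity = max(spectrum$intensity), collisionEnergy = 0,
    ionisationEnergy = 0, lowMZ = min(spectrum$mz), highMZ = max(spectrum$mz),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_, spectrumId = "scan=1",
    centroided = FALSE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_)
  mzR::writeMSData(list(cbind(spectrum$mz, spectrum$intensity)), path,
                   header = hdr)
  invisible(path)
}

#' Read a run-configuration / scenario JSON file
#'
#' @param path JSON file.
#' @return A named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(cfg, class = c("run_config", class(cfg)))
}
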