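## Plain-text serialization: YAML configs, spectra CSV, report JSON/CSV,
## and optional NIfTI volume export.

#' Serialize scanner and tracer configuration to YAML
#'
#' @param model a [ParticleModel-class].
#' @param sequence a [FieldSequence-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeConfigYAML <- function(model, sequence, path) {
  cfg <- list(
    particle = list(
      coreDiameters = model@coreDiameters,
      weights = model@weights,
      saturationMagnetization = model@saturationMagnetization,
      temperature = model@temperature,
      relaxationTime = model@relaxationTime,
      mobility = model@mobility),
    sequence = list(
      driveAmplitudes = sequence@driveAmplitudes,
      dividers = sequence@dividers,
      baseFrequency = sequence@baseFrequency,
      gradients = sequence@gradients,
      samplesPerPeriod = sequence@samplesPerPeriod))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read scanner and tracer configuration from YAML
#'
#' @param path file path written by [writeConfigYAML()].
#' @return list with elements `model` and `sequence`.
#' @export
readConfigYAML <- function(path) {
  cfg <- yaml::read_yaml(path)
  p <- cfg$particle
  s <- cfg$sequence
  list(
    model = particleModel(mobility = p$mobility,
                          coreDiameters = p$coreDiameters,
                          weights = p$weights,
                          saturationMagnetization = p$saturationMagnetization,
                          temperature = p$temperature,
                          relaxationTime = p$relaxationTime),
    sequence = fieldSequence(driveAmplitudes = s$driveAmplitudes,
                             dividers = s$dividers,
                             baseFrequency = s$baseFrequency,
                             gradients = s$gradients,
                             samplesPerPeriod = s$samplesPerPeriod))
}

#' Write / read a harmonic spectrum as CSV
#'
#' Columns: harmonic_index, real, imag, bg_real, bg_imag.
#'
#' @param spec a [HarmonicSpectrum-class].
#' @param path file path.
#' @return `writeSpectrumCSV`: `path` invisibly; `readSpectrumCSV`: a
#'   [HarmonicSpectrum-class].
#' @export
writeSpectrumCSV <- function(spec, path) {
  utils::write.csv(data.frame(
    harmonic_index = seq_along(spec@amplitudes),
    real = Re(spec@amplitudes), imag = Im(spec@amplitudes),
    bg_real = Re(spec@background), bg_imag = Im(spec@background)),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectrumCSV
#' @param fundamental numeric(1), Hz (not stored in the CSV).
#' @export
readSpectrumCSV <- function(path, fundamental = 25e3) {
  d <- utils::read.csv(path)
  d <- d[order(d$harmonic_index), ]
  new("HarmonicSpectrum", fundamental = fundamental,
      amplitudes = complex(real = d$real, imaginary = d$imag),
      background = complex(real = d$bg_real, imaginary = d$bg_imag))
}

#' Export a concentration volume as NIfTI
#'
#' Requires the RNifti package.
#'
#' @param x a [Phantom-class] or [ReconImage-class].
#' @param path file path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
writeVolumeNIfTI <- function(x, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export")
  map <- concentrationMap(x)
  grid <- x@grid
  img <- RNifti::asNifti(map, pixdim = grid@fov / grid@shape)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a study report to disk
#'
#' `per_sample.csv` holds the per-sample table; `report.json` the summary
#' statistics (correlations, stratified deviations, t-test p, seed).
#'
#' @param report an [AgreementReport-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report@table, file.path(dir, "per_sample.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(correlations = as.list(report@correlations),
         deviations = as.list(report@deviations),
         t_test_p = report@tTestP,
         stratum_cut_ug = report@cut,
         seed = report@seed),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
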