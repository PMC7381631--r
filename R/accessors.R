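## Accessor generics and show methods.

#' Total iron mass of a phantom or reconstructed image
#'
#' Integrates the concentration map over the grid: sum of voxel
#' concentrations x voxel volume x molar mass of iron.
#'
#' @param x a [Phantom-class] or [ReconImage-class].
#' @return numeric(1), ug Fe.
#' @export
setGeneric("totalIron", function(x) standardGeneric("totalIron"))

#' @rdname totalIron
#' @export
setMethod("totalIron", "Phantom", function(x)
  ironMassUg(sum(x@map), voxelVolume(x@grid)))

#' @rdname totalIron
#' @export
setMethod("totalIron", "ReconImage", function(x)
  sum(x@values) * x@calibration)

#' Concentration map of a phantom or reconstructed image
#'
#' @param x a [Phantom-class] or [ReconImage-class].
#' @return numeric 3D array, mM Fe.
#' @export
setGeneric("concentrationMap", function(x)
  standardGeneric("concentrationMap"))

#' @rdname concentrationMap
#' @export
setMethod("concentrationMap", "Phantom", function(x) x@map)

#' @rdname concentrationMap
#' @export
setMethod("concentrationMap", "ReconImage", function(x) x@values)

#' Harmonic amplitudes and background of a spectrum
#'
#' @param x a [HarmonicSpectrum-class].
#' @return complex vector indexed by harmonic number.
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))

#' @rdname amplitudes
#' @export
setMethod("amplitudes", "HarmonicSpectrum", function(x) x@amplitudes)

#' @rdname amplitudes
#' @export
setGeneric("background", function(x) standardGeneric("background"))

#' @rdname amplitudes
#' @export
setMethod("background", "HarmonicSpectrum", function(x) x@background)

#' System matrix and per-component metadata
#'
#' @param x a [SystemFunction-class].
#' @return `sfMatrix`: the complex components x voxels matrix.
#'   `componentInfo`: data.frame with frequency (Hz), receive channel,
#'   mixing order and SNR per component.
#' @export
setGeneric("sfMatrix", function(x) standardGeneric("sfMatrix"))

#' @rdname sfMatrix
#' @export
setMethod("sfMatrix", "SystemFunction", function(x) x@matrix)

#' @rdname sfMatrix
#' @export
setGeneric("componentInfo", function(x) standardGeneric("componentInfo"))

#' @rdname sfMatrix
#' @export
setMethod("componentInfo", "SystemFunction", function(x)
  data.frame(frequency = x@componentFreq,
             channel = x@componentChannel,
             mixingOrder = x@componentMixingOrder,
             snr = x@componentSNR))

#' A5/A3 ratio of a reference sample
#'
#' @param x a [ReferenceSample-class].
#' @return numeric(1).
#' @export
setGeneric("a5a3Ratio", function(x) standardGeneric("a5a3Ratio"))

#' @rdname a5a3Ratio
#' @export
setMethod("a5a3Ratio", "ReferenceSample", function(x)
  harmonicRatio(x@spectrum))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ParticleModel", function(object) {
  cat("ParticleModel (", object@mobility, ")\n", sep = "")
  cat("  cores:", paste0(object@coreDiameters, " nm (w=",
                         object@weights, ")", collapse = ", "), "\n")
  cat("  Ms:", object@saturationMagnetization / 1e3, "kA/m  T:",
      object@temperature, "K  tau:", object@relaxationTime * 1e6, "us\n")
})

setMethod("show", "FieldSequence", function(object) {
  f <- object@baseFrequency / object@dividers
  cat("FieldSequence\n")
  cat("  drive:", paste0(object@driveAmplitudes, " mT", collapse = " / "),
      "at", paste0(round(f / 1e3, 2), " kHz", collapse = " / "), "\n")
  cat("  gradients:", paste0(object@gradients, " T/m", collapse = " / "),
      "\n")
  cat("  Lissajous period:", round(lissajousPeriod(object) * 1e3, 2),
      "ms (", object@samplesPerPeriod, "samples )\n")
})

setMethod("show", "VoxelGrid", function(object) {
  cat("VoxelGrid ", paste(object@shape, collapse = " x "), " in ",
      paste(object@fov, collapse = " x "), " mm^3 (voxel ",
      signif(voxelVolume(object), 3), " mm^3)\n", sep = "")
})

setMethod("show", "SystemFunction", function(object) {
  cat("SystemFunction:", nrow(object@matrix), "components x",
      ncol(object@matrix), "voxels\n")
  cat("  sample:", object@sfSample$concentration, "mM in",
      object@sfSample$volume, "ul (", object@sfSample$mobility, ")\n")
  cat("  noise sigma:", object@noiseSigma, "\n")
  if (is.finite(object@componentSNR[1L]))
    cat("  components with SNR >= 7:", sum(object@componentSNR >= 7), "\n")
})

setMethod("show", "Phantom", function(object) {
  cat("Phantom on ", paste(object@grid@shape, collapse = " x "),
      " grid: ", sum(object@map > 0), " active voxels, ",
      signif(totalIron(object), 4), " ug Fe\n", sep = "")
})

setMethod("show", "MPIMeasurement", function(object) {
  cat("MPIMeasurement:", nrow(object@frames), "components x",
      ncol(object@frames), "repetitions (noise sigma",
      object@noiseSigma, ")\n")
})

setMethod("show", "ReconImage", function(object) {
  cat("ReconImage on ", paste(object@grid@shape, collapse = " x "),
      " grid: ", object@selectedComponentCount, " components used, ",
      signif(totalIron(object), 4), " ug Fe integrated\n", sep = "")
})

setMethod("show", "HarmonicSpectrum", function(object) {
  cat("HarmonicSpectrum: fundamental", object@fundamental / 1e3, "kHz,",
      length(object@amplitudes), "harmonics\n")
  a <- Mod(object@amplitudes)
  if (length(a) >= 5L && a[3L] > 0)
    cat("  |A3| =", signif(a[3L], 4), " A5/A3 =",
        signif(a[5L] / a[3L], 4), "\n")
})

setMethod("show", "CalibrationCurve", function(object) {
  cat("CalibrationCurve: slope", signif(object@slope, 4),
      "intercept", signif(object@intercept, 4),
      "R^2", signif(object@rSquared, 6), "\n")
  cat("  LOD", signif(object@lod, 3), "ug/g  LOQ",
      signif(object@loq, 3), "ug/g\n")
})

setMethod("show", "AgreementReport", function(object) {
  n <- table(object@table$group)
  cat("AgreementReport:", paste(names(n), n, collapse = ", "), "\n")
  cat("  Pearson R (MPI vs MPS):",
      signif(object@correlations[["mpi_vs_mps"]], 4), "\n")
  d <- object@deviations
  cat("  |MPI-MPS|/MPS: ", signif(d[["overall"]], 3), "% overall, ",
      signif(d[["above"]], 3), "% above ", object@cut, " ug, ",
      signif(d[["below"]], 3), "% below\n", sep = "")
  cat("  aneurysm vs control t-test p:", signif(object@tTestP, 3), "\n")
})
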