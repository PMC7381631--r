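#' @import methods
NULL

## ---------------------------------------------------------------------------
## Tracer model
## ---------------------------------------------------------------------------

#' Superparamagnetic tracer model
#'
#' Equilibrium Langevin mixture describing a polydisperse iron-oxide tracer
#' such as ferucarbotran (bimodal core population of about 4 nm and 16 nm),
#' with a first-order (Debye) relaxation time that encodes the mobility state
#' of the particles: tissue-bound ("immobilized") tracer responds more slowly
#' than freely suspended ("fluid") tracer, which damps the higher harmonics of
#' its magnetization response.
#'
#' @slot coreDiameters numeric, magnetic core diameters in nm.
#' @slot weights numeric, signal weight fraction of each core population
#'   (sums to 1).
#' @slot saturationMagnetization numeric(1), A/m.
#' @slot temperature numeric(1), sample temperature in K.
#' @slot relaxationTime numeric(1), effective Debye relaxation time in s.
#' @slot mobility character(1), \code{"fluid"} or \code{"immobilized"}.
#'
#' @seealso [particleModel()], [magnetization()]
#' @export
setClass("ParticleModel",
  representation(
    coreDiameters = "numeric",
    weights = "numeric",
    saturationMagnetization = "numeric",
    temperature = "numeric",
    relaxationTime = "numeric",
    mobility = "character"
  )
)

setValidity("ParticleModel", function(object) {
  msg <- character()
  if (length(object@coreDiameters) < 1L || any(object@coreDiameters <= 0))
    msg <- c(msg, "core diameters must be positive")
  if (length(object@weights) != length(object@coreDiameters))
    msg <- c(msg, "one weight per core diameter required")
  if (abs(sum(object@weights) - 1) > 1e-12)
    msg <- c(msg, "weights must sum to 1 (tolerance 1e-12)")
  if (any(object@weights < 0))
    msg <- c(msg, "weights must be nonnegative")
  if (object@saturationMagnetization <= 0)
    msg <- c(msg, "saturation magnetization must be positive")
  if (object@temperature <= 0)
    msg <- c(msg, "temperature must be positive")
  if (object@relaxationTime < 0)
    msg <- c(msg, "relaxation time must be nonnegative")
  if (!object@mobility %in% c("fluid", "immobilized"))
    msg <- c(msg, "mobility must be 'fluid' or 'immobilized'")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Scanner field sequence
## ---------------------------------------------------------------------------

#' Drive-field / selection-field sequence of a field-free-point MPI scanner
#'
#' Three orthogonal sinusoidal drive fields at frequencies
#' \code{baseFrequency / dividers} superimposed on a static selection-field
#' gradient. The field-free point (FFP) then traces a 3D Lissajous trajectory
#' with period \code{lcm(dividers) / baseFrequency}.
#'
#' @slot driveAmplitudes numeric(3), drive amplitudes in mT (x, y, z).
#' @slot dividers integer(3), frequency dividers of the base clock.
#' @slot baseFrequency numeric(1), base clock in Hz.
#' @slot gradients numeric(3), selection-field gradient strengths in T/m.
#' @slot samplesPerPeriod integer(1), receive samples per Lissajous period.
#'
#' @seealso [fieldSequence()], [ffpPosition()], [lissajousPeriod()]
#' @export
setClass("FieldSequence",
  representation(
    driveAmplitudes = "numeric",
    dividers = "integer",
    baseFrequency = "numeric",
    gradients = "numeric",
    samplesPerPeriod = "integer"
  )
)

setValidity("FieldSequence", function(object) {
  msg <- character()
  if (length(object@driveAmplitudes) != 3L || any(object@driveAmplitudes < 0))
    msg <- c(msg, "driveAmplitudes must be 3 nonnegative values (mT)")
  if (length(object@dividers) != 3L || any(object@dividers < 1L))
    msg <- c(msg, "dividers must be 3 positive integers")
  if (length(unique(object@dividers)) == 1L && object@dividers[1L] != 1L)
    msg <- c(msg, "dividers must not all be equal (degenerate Lissajous)")
  if (object@baseFrequency <= 0)
    msg <- c(msg, "baseFrequency must be positive")
  if (length(object@gradients) != 3L || any(object@gradients <= 0))
    msg <- c(msg, "gradients must be 3 positive values (T/m)")
  if (object@samplesPerPeriod < 2L)
    msg <- c(msg, "samplesPerPeriod must be at least 2")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Voxel grid
## ---------------------------------------------------------------------------

#' Voxel grid of the reconstruction / calibration volume
#'
#' Voxel-centered grid, axis order (x, y, z), centered on the scanner
#' isocenter.
#'
#' @slot shape integer(3), voxel counts.
#' @slot fov numeric(3), field of view in mm.
#' @export
setClass("VoxelGrid",
  representation(shape = "integer", fov = "numeric")
)

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be 3 positive integers")
  if (length(object@fov) != 3L || any(object@fov <= 0))
    msg <- c(msg, "fov must be 3 positive lengths (mm)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Harmonic spectrum
## ---------------------------------------------------------------------------

#' Harmonic spectrum of a magnetization response
#'
#' Complex amplitudes at integer multiples of the excitation fundamental,
#' together with the background spectrum of the empty sample holder (zero if
#' no background was acquired). Index 1 is the excitation fundamental.
#'
#' @slot fundamental numeric(1), excitation frequency in Hz.
#' @slot amplitudes complex, amplitude of harmonic k at position k.
#' @slot background complex, same length as \code{amplitudes}.
#' @export
setClass("HarmonicSpectrum",
  representation(
    fundamental = "numeric",
    amplitudes = "complex",
    background = "complex"
  )
)

setValidity("HarmonicSpectrum", function(object) {
  msg <- character()
  if (object@fundamental <= 0)
    msg <- c(msg, "fundamental frequency must be positive")
  if (length(object@amplitudes) < 1L)
    msg <- c(msg, "at least one harmonic required")
  if (length(object@background) != length(object@amplitudes))
    msg <- c(msg, "background must match amplitudes in length")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## System function
## ---------------------------------------------------------------------------

#' MPI system function
#'
#' Complex calibration matrix mapping tracer concentration at each grid voxel
#' to measured frequency components. Rows are (mixing frequency, receive
#' channel) pairs with per-component metadata: frequency, receive channel,
#' mixing order (minimal |kx|+|ky|+|kz| with kx fx + ky fy + kz fz matching
#' the component frequency) and SNR relative to the calibration noise level.
#' The calibration sample (concentration, volume, cuboid dimensions, mobility
#' state) is carried along for unit conversion.
#'
#' @slot matrix complex matrix, components x voxels.
#' @slot componentFreq numeric, Hz per component.
#' @slot componentChannel integer, receive channel (1 = x, 2 = y, 3 = z).
#' @slot componentMixingOrder integer per component.
#' @slot componentSNR numeric per component (Inf for a noiseless simulation).
#' @slot sfSample list with elements \code{concentration} (mM Fe),
#'   \code{volume} (ul), \code{dimensions} (mm, cuboid), \code{mobility}.
#' @slot grid [VoxelGrid-class].
#' @slot sequence [FieldSequence-class] used for the calibration.
#' @slot noiseSigma numeric(1), calibration noise scale (signal units).
#' @export
setClass("SystemFunction",
  representation(
    matrix = "matrix",
    componentFreq = "numeric",
    componentChannel = "integer",
    componentMixingOrder = "integer",
    componentSNR = "numeric",
    sfSample = "list",
    grid = "VoxelGrid",
    sequence = "FieldSequence",
    noiseSigma = "numeric"
  )
)

setValidity("SystemFunction", function(object) {
  msg <- character()
  n <- nrow(object@matrix)
  if (!is.complex(object@matrix))
    msg <- c(msg, "matrix must be complex")
  if (length(object@componentFreq) != n ||
      length(object@componentChannel) != n ||
      length(object@componentMixingOrder) != n ||
      length(object@componentSNR) != n)
    msg <- c(msg, "component metadata must have one entry per matrix row")
  if (ncol(object@matrix) != prod(object@grid@shape))
    msg <- c(msg, "matrix must have one column per grid voxel")
  if (any(object@componentSNR < 0, na.rm = TRUE))
    msg <- c(msg, "component SNR must be nonnegative")
  need <- c("concentration", "volume", "dimensions", "mobility")
  if (!all(need %in% names(object@sfSample)))
    msg <- c(msg, "sfSample must carry concentration, volume, dimensions, mobility")
  else {
    dims <- object@sfSample$dimensions
    if (abs(prod(dims) - object@sfSample$volume) > 1e-9 * object@sfSample$volume)
      msg <- c(msg, "sfSample volume must equal the product of its cuboid dimensions")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Phantom and measurement
## ---------------------------------------------------------------------------

#' Digital tracer phantom
#'
#' 3D iron concentration map (mM Fe) on a voxel grid, standing in for an
#' excised aorta segment with nanoparticle-laden wall. The total iron mass is
#' exact by construction.
#'
#' @slot map numeric 3D array, mM Fe per voxel.
#' @slot grid [VoxelGrid-class].
#' @slot seed integer(1), generator seed.
#' @export
setClass("Phantom",
  representation(map = "array", grid = "VoxelGrid", seed = "integer")
)

setValidity("Phantom", function(object) {
  msg <- character()
  if (!identical(dim(object@map), as.integer(object@grid@shape)))
    msg <- c(msg, "map dimensions must match grid shape")
  if (any(object@map < 0))
    msg <- c(msg, "concentrations must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' MPI measurement frames
#'
#' Repeated acquisitions of the frequency components of one sample, indexed
#' like the rows of the system function they were acquired with.
#'
#' @slot frames complex matrix, components x repetitions.
#' @slot noiseSigma numeric(1), per-frame noise scale.
#' @slot seed integer(1).
#' @export
setClass("MPIMeasurement",
  representation(frames = "matrix", noiseSigma = "numeric", seed = "integer")
)

setValidity("MPIMeasurement", function(object) {
  msg <- character()
  if (!is.complex(object@frames))
    msg <- c(msg, "frames must be complex")
  if (ncol(object@frames) < 1L)
    msg <- c(msg, "at least one repetition required")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Reconstruction
## ---------------------------------------------------------------------------

#' Reconstruction configuration
#'
#' Frequency-component selection and regularized Kaczmarz solver settings.
#' Defaults follow the ex vivo protocol: SNR threshold 7, receive band
#' 90 kHz - 1.25 MHz (which removes the 3rd drive-field harmonic), mixing
#' order at most 25, relative Tikhonov weight 0.1, five sweeps, block average
#' of 20 repetitions, nonnegativity projection on.
#'
#' @slot snrThreshold numeric(1).
#' @slot band numeric(2), Hz.
#' @slot maxMixingOrder integer(1).
#' @slot lambda numeric(1), Tikhonov regularization weight.
#' @slot lambdaMode character(1), \code{"relative"} (lambda scales the mean
#'   squared row magnitude) or \code{"absolute"}.
#' @slot iterations integer(1), full Kaczmarz sweeps.
#' @slot blockAverage integer(1), repetitions averaged before reconstruction.
#' @slot nonneg logical(1), project onto the nonnegative real orthant after
#'   each sweep.
#' @export
setClass("ReconConfig",
  representation(
    snrThreshold = "numeric",
    band = "numeric",
    maxMixingOrder = "integer",
    lambda = "numeric",
    lambdaMode = "character",
    iterations = "integer",
    blockAverage = "integer",
    nonneg = "logical"
  )
)

setValidity("ReconConfig", function(object) {
  msg <- character()
  if (length(object@band) != 2L || object@band[1L] >= object@band[2L])
    msg <- c(msg, "band must be c(low, high) with low < high")
  if (object@iterations < 1L)
    msg <- c(msg, "iterations must be >= 1")
  if (object@lambda < 0)
    msg <- c(msg, "lambda must be nonnegative")
  if (!object@lambdaMode %in% c("relative", "absolute"))
    msg <- c(msg, "lambdaMode must be 'relative' or 'absolute'")
  if (object@blockAverage < 1L)
    msg <- c(msg, "blockAverage must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Reconstructed tracer image
#'
#' Voxel concentrations (mM Fe) reconstructed from an MPI measurement, with
#' the calibration factor needed to convert integrated concentration into
#' iron micrograms, a snapshot of the configuration and the number of
#' frequency components used.
#'
#' @slot values numeric 3D array, mM Fe.
#' @slot grid [VoxelGrid-class].
#' @slot calibration numeric(1), ug Fe per (mM x voxel).
#' @slot config [ReconConfig-class].
#' @slot selectedComponentCount integer(1).
#' @export
setClass("ReconImage",
  representation(
    values = "array",
    grid = "VoxelGrid",
    calibration = "numeric",
    config = "ReconConfig",
    selectedComponentCount = "integer"
  )
)

setValidity("ReconImage", function(object) {
  msg <- character()
  if (!identical(dim(object@values), as.integer(object@grid@shape)))
    msg <- c(msg, "values dimensions must match grid shape")
  if (object@calibration <= 0)
    msg <- c(msg, "calibration factor must be positive")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## MPS quantification
## ---------------------------------------------------------------------------

#' Reference sample for MPS quantification
#'
#' A spectrum of a known iron mass in a known mobility state, used to
#' normalize the 3rd harmonic of an unknown sample.
#'
#' @slot spectrum [HarmonicSpectrum-class].
#' @slot ironMass numeric(1), ug Fe.
#' @slot mobility character(1), \code{"fluid"} or \code{"immobilized"}.
#' @export
setClass("ReferenceSample",
  representation(
    spectrum = "HarmonicSpectrum",
    ironMass = "numeric",
    mobility = "character"
  )
)

setValidity("ReferenceSample", function(object) {
  msg <- character()
  if (object@ironMass <= 0)
    msg <- c(msg, "reference iron mass must be positive")
  if (!object@mobility %in% c("fluid", "immobilized"))
    msg <- c(msg, "mobility must be 'fluid' or 'immobilized'")
  if (length(object@spectrum@amplitudes) < 5L)
    msg <- c(msg, "reference spectrum must reach at least harmonic 5")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Elemental-map calibration
## ---------------------------------------------------------------------------

#' Linear calibration curve for elemental line scans
#'
#' Ordinary least squares fit of mean line intensity against standard
#' concentration, with blank noise, limit of detection (3 sigma criterion)
#' and limit of quantification (10 sigma criterion).
#'
#' @slot slope numeric(1), intensity per (ug/g).
#' @slot intercept numeric(1), intensity.
#' @slot rSquared numeric(1).
#' @slot blankSigma numeric(1), standard deviation of blank line intensities.
#' @slot lod numeric(1), ug/g.
#' @slot loq numeric(1), ug/g.
#' @slot standards data.frame with columns \code{concentration} and
#'   \code{intensity} (per-standard means).
#' @export
setClass("CalibrationCurve",
  representation(
    slope = "numeric",
    intercept = "numeric",
    rSquared = "numeric",
    blankSigma = "numeric",
    lod = "numeric",
    loq = "numeric",
    standards = "data.frame"
  )
)

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (object@rSquared < 0 || object@rSquared > 1 + 1e-12)
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (object@lod > object@loq + 1e-12)
    msg <- c(msg, "lod must not exceed loq")
  if (length(msg)) msg else TRUE
})
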