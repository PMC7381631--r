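## Tracer magnetization physics, FFP trajectory, induced signal, harmonics.

MU0 <- 4e-7 * pi       # vacuum permeability, T m / A
KB <- 1.380649e-23     # Boltzmann constant, J / K

#' Construct a particle model
#'
#' Defaults describe a ferucarbotran-like tracer: bimodal core population of
#' 4 nm and 16 nm with magnetic signal weights 0.3 / 0.7, bulk magnetite
#' saturation magnetization (476 kA/m), body temperature, and a mobility
#' dependent Debye relaxation time (1 us fluid, 3 us immobilized). The
#' immobilized state damps higher harmonics more strongly, as observed for
#' tissue-bound (phagocytosed) tracer versus aqueous suspension.
#'
#' @param mobility "fluid" or "immobilized".
#' @param coreDiameters numeric, core diameters in nm.
#' @param weights numeric, signal weight per core population, summing to 1.
#' @param saturationMagnetization numeric(1), A/m.
#' @param temperature numeric(1), K.
#' @param relaxationTime numeric(1), s; if `NULL` chosen from `mobility`.
#' @return A [ParticleModel-class].
#' @examples
#' particleModel("immobilized")
#' @export
particleModel <- function(mobility = c("immobilized", "fluid"),
                          coreDiameters = c(4, 16),
                          weights = c(0.3, 0.7),
                          saturationMagnetization = 476e3,
                          temperature = 310,
                          relaxationTime = NULL) {
  mobility <- match.arg(mobility)
  if (is.null(relaxationTime))
    relaxationTime <- if (mobility == "immobilized") 3e-6 else 1e-6
  new("ParticleModel",
      coreDiameters = as.numeric(coreDiameters),
      weights = as.numeric(weights),
      saturationMagnetization = saturationMagnetization,
      temperature = temperature,
      relaxationTime = relaxationTime,
      mobility = mobility)
}

#' Construct a field sequence
#'
#' Defaults are the preclinical FFP scanner settings: 12 mT drive fields, a
#' 2.5 MHz base clock divided by 102 / 96 / 99 in x / y / z, and selection
#' field gradients of 1.25 T/m (x, y) and 2.5 T/m (z). One receive sample per
#' base-clock tick over a Lissajous period (`lcm(dividers)` samples) resolves
#' every mixing-frequency bin exactly.
#'
#' @param driveAmplitudes numeric(3), mT.
#' @param dividers integer(3).
#' @param baseFrequency numeric(1), Hz.
#' @param gradients numeric(3), T/m.
#' @param samplesPerPeriod integer(1); if `NULL`, `lcm(dividers)`.
#' @return A [FieldSequence-class].
#' @examples
#' seq <- fieldSequence()
#' lissajousPeriod(seq) # 21.5 ms
#' @export
fieldSequence <- function(driveAmplitudes = c(12, 12, 12),
                          dividers = c(102L, 96L, 99L),
                          baseFrequency = 2.5e6,
                          gradients = c(1.25, 1.25, 2.5),
                          samplesPerPeriod = NULL) {
  dividers <- as.integer(dividers)
  if (is.null(samplesPerPeriod))
    samplesPerPeriod <- as.integer(lcmAll(dividers))
  new("FieldSequence",
      driveAmplitudes = as.numeric(driveAmplitudes),
      dividers = dividers,
      baseFrequency = baseFrequency,
      gradients = as.numeric(gradients),
      samplesPerPeriod = as.integer(samplesPerPeriod))
}

#' Construct a voxel grid
#'
#' @param shape integer(3), voxel counts; default 25 x 25 x 13.
#' @param fov numeric(3), field of view in mm; default 25 x 25 x 13 mm.
#' @return A [VoxelGrid-class].
#' @export
voxelGrid <- function(shape = c(25L, 25L, 13L), fov = c(25, 25, 13)) {
  new("VoxelGrid", shape = as.integer(shape), fov = as.numeric(fov))
}

#' Langevin function
#'
#' L(xi) = coth(xi) - 1/xi, the equilibrium magnetization of an ensemble of
#' non-interacting superparamagnetic moments, as a fraction of saturation.
#' A series expansion (xi/3 - xi^3/45 + 2 xi^5/945) is used for |xi| < 1e-4
#' to avoid catastrophic cancellation.
#'
#' @param xi numeric, dimensionless field-energy ratio m B / (kB T).
#' @return numeric of the same length, in (-1, 1).
#' @examples
#' langevin(1) # 0.31304
#' @export
langevin <- function(xi) {
  if (any(is.na(xi))) stop("langevin: NaN/NA input")
  small <- abs(xi) < 1e-4
  out <- xi
  xs <- xi[small]
  out[small] <- xs / 3 - xs^3 / 45 + 2 * xs^5 / 945
  xl <- xi[!small]
  out[!small] <- 1 / tanh(xl) - 1 / xl
  out
}

## Dimensionless Langevin argument per mT of applied field, one value per
## core population: xi = m_p B / (kB T), m_p = Ms (pi/6) d^3.
langevinBetas <- function(model) {
  d <- model@coreDiameters * 1e-9
  m <- model@saturationMagnetization * pi / 6 * d^3  # A m^2
  m * 1e-3 / (KB * model@temperature)                # per mT (B field)
}

#' Equilibrium magnetization of a tracer model
#'
#' Weight-fraction mixture of Langevin responses over the core populations.
#' Odd in the field and bounded by the saturation magnetization.
#'
#' @param field numeric, applied field in mT (field magnitude with sign).
#' @param model a [ParticleModel-class].
#' @return numeric, magnetization in A/m (same length as `field`).
#' @export
magnetization <- function(field, model) {
  betas <- langevinBetas(model)
  acc <- 0
  for (i in seq_along(betas))
    acc <- acc + model@weights[i] * langevin(betas[i] * field)
  model@saturationMagnetization * acc
}

## Drive-field waveform, n x 3 matrix in mT at times t (s).
driveField <- function(seq, t) {
  f <- seq@baseFrequency / seq@dividers
  cbind(seq@driveAmplitudes[1L] * sin(2 * pi * f[1L] * t),
        seq@driveAmplitudes[2L] * sin(2 * pi * f[2L] * t),
        seq@driveAmplitudes[3L] * sin(2 * pi * f[3L] * t))
}

#' Field-free-point position
#'
#' The FFP sits where the drive field cancels the selection gradient:
#' position_i(t) = (A_i / G_i) sin(2 pi f_i t). Peak-to-peak coverage along
#' axis i is therefore 2 A_i / G_i (19.2 mm for 12 mT against 1.25 T/m,
#' 9.6 mm against 2.5 T/m).
#'
#' @param seq a [FieldSequence-class].
#' @param t numeric, time(s) in seconds.
#' @return matrix `length(t)` x 3, FFP position in mm.
#' @export
ffpPosition <- function(seq, t) {
  stopifnot(all(t >= 0))
  H <- driveField(seq, t)
  sweep(H, 2L, seq@gradients, "/")  # mT / (T/m) = mm
}

#' Lissajous trajectory period
#'
#' `lcm(dividers) / baseFrequency`; the FFP trajectory repeats exactly after
#' this duration (21.54 ms for dividers 102/96/99 at 2.5 MHz, the scanner's
#' stated 21.5 ms temporal resolution).
#'
#' @param seq a [FieldSequence-class].
#' @return numeric(1), seconds.
#' @export
lissajousPeriod <- function(seq) {
  lcmAll(seq@dividers) / seq@baseFrequency
}

## Debye low-pass + time derivative, applied in the frequency domain to a
## real periodic series: multiply bin at frequency f by
## (i 2 pi f) / (1 + i 2 pi f tau).
debyeDerivativeFilter <- function(n, sampleRate, tau) {
  k <- 0:(n - 1L)
  f <- ifelse(k <= n / 2, k, k - n) * sampleRate / n
  w <- 2i * pi * f
  w / (1 + w * tau)
}

#' Induced receive signal of a tracer concentration path
#'
#' Receive-coil signal proportional to dM/dt of the mixture magnetization
#' along each spatial axis, for tracer of time-varying local concentration in
#' the scanner's oscillating total field (drive field plus a static offset).
#' Relaxation enters as a first-order Debye low-pass with the model's
#' relaxation time; the operator is linear in concentration.
#'
#' @param concentration numeric, local tracer concentration seen by the FFP,
#'   sampled uniformly at `seq@baseFrequency` over an integer number of
#'   Lissajous periods (a scalar is recycled over one period).
#' @param model a [ParticleModel-class].
#' @param seq a [FieldSequence-class].
#' @param offsetField numeric(3), static field offset in mT (e.g. the
#'   selection field at the sample position).
#' @return matrix n x 3, signal per receive axis (arbitrary units).
#' @export
inducedSignal <- function(concentration, model, seq,
                          offsetField = c(0, 0, 0)) {
  nper <- seq@samplesPerPeriod
  if (length(concentration) == 1L)
    concentration <- rep(concentration, nper)
  n <- length(concentration)
  if (n %% nper != 0L)
    stop("concentration series must span an integer number of Lissajous ",
         "periods (length a multiple of samplesPerPeriod); got length ", n)
  sampleRate <- nper / lissajousPeriod(seq)
  t <- (0:(n - 1L)) / sampleRate
  H <- driveField(seq, t)
  H <- sweep(H, 2L, offsetField, "+")
  Hm <- sqrt(rowSums(H^2))
  betas <- langevinBetas(model)
  L <- 0
  for (i in seq_along(betas))
    L <- L + model@weights[i] * langevin(betas[i] * Hm)
  scale <- ifelse(Hm > 0, L / Hm, sum(model@weights * betas) / 3)
  M <- H * (scale * model@saturationMagnetization * concentration)
  filt <- debyeDerivativeFilter(n, sampleRate, model@relaxationTime)
  out <- matrix(0, n, 3L)
  for (ax in 1:3)
    out[, ax] <- Re(stats::fft(stats::fft(M[, ax]) * filt, inverse = TRUE)) / n
  out
}

#' Harmonic spectrum of a periodic signal
#'
#' Discrete Fourier decomposition at integer multiples of a fundamental
#' frequency. The signal must span an integer number of fundamental periods
#' so the harmonics fall exactly on DFT bins. Amplitudes are scaled so a pure
#' sine of amplitude a at harmonic k yields |A_k| = a (Parseval-consistent
#' one-sided convention).
#'
#' @param signal numeric, uniformly sampled time series.
#' @param fundamental numeric(1), Hz.
#' @param sampleRate numeric(1), Hz.
#' @param nHarmonics integer(1); default all harmonics up to Nyquist.
#' @return A [HarmonicSpectrum-class] (background zero).
#' @export
harmonicSpectrum <- function(signal, fundamental, sampleRate,
                             nHarmonics = NULL) {
  n <- length(signal)
  cycles <- n * fundamental / sampleRate
  if (abs(cycles - round(cycles)) > 1e-9 || round(cycles) < 1)
    stop("signal must span an integer (>= 1) number of fundamental periods; ",
         "got ", cycles, " periods")
  cycles <- round(cycles)
  X <- stats::fft(signal) * 2 / n
  kmax <- floor((n / 2) / cycles)
  if (is.null(nHarmonics)) nHarmonics <- kmax
  nHarmonics <- min(nHarmonics, kmax)
  idx <- seq_len(nHarmonics) * cycles + 1L
  amps <- X[idx]
  new("HarmonicSpectrum",
      fundamental = fundamental,
      amplitudes = as.complex(amps),
      background = complex(length(amps)))
}

#' Iron mass per particle of each core population
#'
#' Derived from the core volume assuming magnetite (density 5175 kg/m^3,
#' iron mass fraction 3 x 55.845 / 231.53): useful for converting between
#' particle counts and iron mass.
#'
#' @param model a [ParticleModel-class].
#' @return numeric, kg Fe per particle, one entry per core population.
#' @export
ironMassPerParticle <- function(model) {
  d <- model@coreDiameters * 1e-9
  feFraction <- 3 * 55.845 / 231.53
  pi / 6 * d^3 * 5175 * feFraction
}
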