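## Shared reduced-scale scanner for tests: same physics as the full protocol,
## smaller dividers and grid so a system function simulates in seconds.
## Heavy objects are built lazily and cached for the whole test run.

.cache <- new.env(parent = emptyenv())

smallSequence <- function() {
  fieldSequence(dividers = c(17L, 16L, 15L), gradients = c(2, 2, 4))
}

smallGrid <- function() {
  voxelGrid(c(13L, 13L, 7L), c(13, 13, 7))
}

## Reduced band/order settings matched to the small scanner (drive
## fundamentals sit near 150 kHz, so the band keeps everything up to Nyquist).
smallRecon <- function(...) {
  reconConfig(band = c(50e3, 1.25e6), maxMixingOrder = 18L, ...)
}

cached <- function(key, build) {
  if (!exists(key, envir = .cache)) assign(key, build(), envir = .cache)
  get(key, envir = .cache)
}

smallSF <- function() {
  cached("sf_immobilized_noiseless", function()
    simulateSystemFunction(smallGrid(), smallSequence(),
                           particleModel("immobilized"),
                           noiseSigma = 0, maxMixingOrder = 18L,
                           maxComponents = 1800L))
}

smallSFfluid <- function() {
  cached("sf_fluid_noiseless", function()
    simulateSystemFunction(smallGrid(), smallSequence(),
                           particleModel("fluid"),
                           noiseSigma = 0, maxMixingOrder = 18L,
                           maxComponents = 1800L))
}

smallPhantom <- function(mass = 2, seed = 3L) {
  makePhantom(smallGrid(), mass, center = c(0.4, -0.5, 0.3),
              outerSemiAxes = c(2, 2, 3), wallThickness = 1.2, seed = seed)
}
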