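#!/usr/bin/env Rscript
## One-time calibration of the frozen default noise levels in cohortConfig().
##
## Rationale, mirrored in the methods vignette:
##  * The system-function noise is set so that the automatic SNR >= 7
##    selection retains about 487 frequency components inside the receive
##    band at mixing order <= 25 -- the operating regime of the ex vivo
##    protocol this package emulates.
##  * The measurement noise shares the receive chain, scaled so that the
##    MPI-vs-MPS stratified deviations of the default cohort land at or
##    below the protocol's working accuracy.
##  * The MPS noise is set so the 3rd harmonic of a 0.1 ug sample (the
##    bottom of the cohort mass range) keeps a post-averaging SNR of a few
##    hundred, the regime of a 10 s spectrometer acquisition.
##
## Run from the repository root:  Rscript scripts/calibrate_noise.R

suppressMessages(library(MPIron))

grid <- voxelGrid()
seqd <- fieldSequence()
model <- particleModel("immobilized")

message("simulating noiseless system function (takes ~2-3 min) ...")
sf <- simulateSystemFunction(grid, seqd, model, noiseSigma = 0)

info <- componentInfo(sf)
rowRMS <- sqrt(rowMeans(Mod(sfMatrix(sf))^2))
cfg <- reconConfig()
eligible <- info$frequency >= cfg@band[1L] & info$frequency <= cfg@band[2L] &
  info$mixingOrder <= cfg@maxMixingOrder
target <- 487L
sfSigma <- sort(rowRMS[eligible], decreasing = TRUE)[target] / cfg@snrThreshold
message(sprintf("sfNoiseSigma = %.4g  (%d eligible rows; SNR>=7 keeps %d)",
                sfSigma, sum(eligible), target))

## MPS: post-averaging SNR ~300 on A3 at the smallest cohort mass
a3 <- Mod(amplitudes(simulateMPS(0.1, model))[3L])
nAvg <- 1000L
mpsSigma <- a3 / 300 * sqrt(nAvg)
message(sprintf("mpsNoiseSigma = %.4g  (A3 at 0.1 ug = %.4g)", mpsSigma, a3))

## Measurement noise: start at the SF level and report cohort deviations for
## a small ladder of scalings; the frozen default is the largest scale whose
## deviations sit at or below the protocol's printed working accuracy.
for (scale in c(1, 0.5, 0.25)) {
  cc <- cohortConfig(seed = 1L,
                     sfNoiseSigma = sfSigma,
                     measNoiseSigma = sfSigma * scale,
                     mpsNoiseSigma = mpsSigma)
  rep <- runStudy(cc, sf = simulateSystemFunction(
    grid, seqd, model, noiseSigma = sfSigma, seed = cc$seed + 90001L))
  d <- rep@deviations
  message(sprintf(
    "meas scale %.2f: R = %.4f, dev overall %.2f%%, >1ug %.2f%%, <1ug %.2f%%",
    scale, rep@correlations[["mpi_vs_mps"]],
    d[["overall"]], d[["above"]], d[["below"]]))
}
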