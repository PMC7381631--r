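## System-function simulation: one forward model per grid voxel, assembled
## into the complex components x voxels calibration matrix.

## Distinct mixing-frequency bins of a field sequence.
##
## With samplesPerPeriod a multiple of every divider, the drive frequencies
## fall on exact DFT bins f_i = N / divider_i and every intermodulation
## product kx fx + ky fy + kz fz does too. Returns the distinct positive
## bins at or below Nyquist with the minimal mixing order |kx|+|ky|+|kz|
## that reaches each bin.
mixingBins <- function(seq, maxOrder) {
  N <- seq@samplesPerPeriod
  if (any(N %% seq@dividers != 0L))
    stop("samplesPerPeriod must be a multiple of every divider so that ",
         "mixing frequencies fall on exact DFT bins")
  fb <- N / seq@dividers                 # drive-frequency bin indices
  ks <- seq.int(-maxOrder, maxOrder)
  kk <- expand.grid(kx = ks, ky = ks, kz = ks, KEEP.OUT.ATTRS = FALSE)
  ord <- abs(kk$kx) + abs(kk$ky) + abs(kk$kz)
  keep <- ord >= 1L & ord <= maxOrder
  kk <- kk[keep, ]; ord <- ord[keep]
  v <- abs(kk$kx * fb[1L] + kk$ky * fb[2L] + kk$kz * fb[3L])
  keep <- v >= 1 & v <= N / 2
  v <- v[keep]; ord <- ord[keep]
  o <- order(v, ord)
  v <- v[o]; ord <- ord[o]
  first <- !duplicated(v)
  list(bin = as.integer(v[first]), order = as.integer(ord[first]))
}

## Overlap weights (mm^3 per voxel offset) of a cuboid of dimensions
## `dims` (mm) centred on a voxel, on a grid with voxel size `step` (mm).
## Separable product of 1D interval overlaps.
cuboidKernel <- function(dims, step) {
  axisWeights <- function(L, h) {
    kmax <- ceiling((L / 2) / h + 0.5)
    k <- seq.int(-kmax, kmax)
    lo <- pmax((k - 0.5) * h, -L / 2)
    hi <- pmin((k + 0.5) * h, L / 2)
    w <- pmax(hi - lo, 0)
    keep <- w > 1e-12
    list(k = k[keep], w = w[keep])
  }
  wx <- axisWeights(dims[1L], step[1L])
  wy <- axisWeights(dims[2L], step[2L])
  wz <- axisWeights(dims[3L], step[3L])
  g <- expand.grid(ix = seq_along(wx$k), iy = seq_along(wy$k),
                   iz = seq_along(wz$k), KEEP.OUT.ATTRS = FALSE)
  list(offsets = cbind(wx$k[g$ix], wy$k[g$iy], wz$k[g$iz]),
       weights = wx$w[g$ix] * wy$w[g$iy] * wz$w[g$iz])
}

## Raw (unfiltered) DFT rows of the per-axis magnetization time series for a
## block of static field offsets. Returns a complex array of dimension
## (length(bins), 3, nrow(offsets)): bin x channel x voxel.
magnetizationBlockFFT <- function(offsets, seq, model, bins) {
  N <- seq@samplesPerPeriod
  sampleRate <- N / lissajousPeriod(seq)
  t <- (0:(N - 1L)) / sampleRate
  Hd <- driveField(seq, t)
  B <- nrow(offsets)
  betas <- langevinBetas(model)
  M <- matrix(0, N, 3L * B)
  for (b in seq_len(B)) {
    H <- sweep(Hd, 2L, offsets[b, ], "+")
    Hm <- sqrt(rowSums(H^2))
    L <- 0
    for (i in seq_along(betas))
      L <- L + model@weights[i] * langevin(betas[i] * Hm)
    scale <- ifelse(Hm > 0, L / Hm, sum(model@weights * betas) / 3)
    M[, (3L * b - 2L):(3L * b)] <- H * (scale * model@saturationMagnetization)
  }
  FF <- stats::mvfft(M)[bins + 1L, , drop = FALSE]
  dim(FF) <- c(length(bins), 3L, B)
  FF
}

#' Simulate an MPI system function
#'
#' Runs one forward simulation per grid voxel of a calibration sample (a
#' cuboid of tracer at known concentration, default 100 mM in 3 x 3 x 1.5 mm,
#' i.e. 13.5 ul) and collects the mixing-frequency components of the induced
#' signal on all three receive channels into the system matrix. The cuboid
#' extent of the calibration sample is modelled by convolving the voxel point
#' responses with the cuboid's volume-overlap kernel. Complex Gaussian noise
#' of scale \code{noiseSigma} is added per matrix entry, and the per-component
#' SNR (noiseless row RMS over \code{noiseSigma}) is recorded.
#'
#' Only the \code{maxComponents} most energetic (component, channel) rows are
#' retained, found by a deterministic pre-pass over a coarse voxel subsample;
#' rows below any realistic SNR threshold carry no information for
#' reconstruction. Voxel pairs mirrored through the isocenter are related by
#' the odd symmetry of the magnetization response
#' (S(-r, f) = -conj(S(r, f))), which halves the simulation work on
#' symmetric grids.
#'
#' @param grid a [VoxelGrid-class].
#' @param seq a [FieldSequence-class].
#' @param model a [ParticleModel-class]; its mobility state becomes the SF's.
#' @param noiseSigma numeric(1) >= 0, calibration noise per complex entry.
#' @param seed integer(1) or `NULL`, for the calibration noise.
#' @param sfConcentration numeric(1), calibration sample concentration (mM).
#' @param sfDimensions numeric(3), calibration cuboid in mm.
#' @param maxMixingOrder integer(1), highest intermodulation order simulated.
#' @param maxComponents integer(1), rows retained.
#' @param blockSize integer(1), voxels per forward block (memory knob).
#' @return A [SystemFunction-class].
#' @export
simulateSystemFunction <- function(grid, seq, model,
                                   noiseSigma = 0, seed = NULL,
                                   sfConcentration = 100,
                                   sfDimensions = c(3, 3, 1.5),
                                   maxMixingOrder = 25L,
                                   maxComponents = 2500L,
                                   blockSize = 96L) {
  if (noiseSigma < 0) stop("noiseSigma must be nonnegative")
  mb <- mixingBins(seq, maxMixingOrder)
  period <- lissajousPeriod(seq)
  binFreq <- mb$bin / period
  pos <- voxelCenters(grid)
  offsets <- sweep(pos, 2L, seq@gradients, "*")   # mm x T/m = mT
  nvox <- nrow(pos)
  nbin <- length(mb$bin)

  ## ----- pre-pass: rank (bin, channel) rows by filtered energy ------------
  stride <- pmax(1L, floor(grid@shape / 8L))
  sub <- as.matrix(expand.grid(
    x = seq.int(1L, grid@shape[1L], by = stride[1L]),
    y = seq.int(1L, grid@shape[2L], by = stride[2L]),
    z = seq.int(1L, grid@shape[3L], by = stride[3L])))
  subIdx <- sub[, 1L] + grid@shape[1L] * (sub[, 2L] - 1L) +
    prod(grid@shape[1:2]) * (sub[, 3L] - 1L)
  filtMag <- Mod(2i * pi * binFreq / (1 + 2i * pi * binFreq *
                                        model@relaxationTime))
  energy <- matrix(0, nbin, 3L)
  for (start in seq.int(1L, length(subIdx), by = blockSize)) {
    idx <- subIdx[start:min(start + blockSize - 1L, length(subIdx))]
    FF <- magnetizationBlockFFT(offsets[idx, , drop = FALSE], seq, model,
                                mb$bin)
    energy <- energy + apply(Mod(FF)^2, c(1L, 2L), sum)
  }
  energy <- energy * filtMag^2
  nKeep <- min(maxComponents, sum(energy > 0))
  ord <- order(energy, decreasing = TRUE)[seq_len(nKeep)]
  keepBin <- ((ord - 1L) %% nbin) + 1L
  keepChan <- ((ord - 1L) %/% nbin) + 1L
  ## deterministic row order: ascending frequency, then channel
  o <- order(binFreq[keepBin], keepChan)
  keepBin <- keepBin[o]; keepChan <- keepChan[o]
  ## per-channel lookup of which kept rows come from which bin position
  rowsOfChan <- lapply(1:3, function(ch) which(keepChan == ch))
  binPosOfChan <- lapply(1:3, function(ch) keepBin[rowsOfChan[[ch]]])

  ## ----- main pass over voxels (mirror trick on symmetric grids) ----------
  symmetric <- all(grid@shape %% 2L == 1L)
  if (symmetric) {
    ctr <- (prod(grid@shape) + 1L) %/% 2L
    simIdx <- seq_len(ctr)
  } else simIdx <- seq_len(nvox)
  P <- matrix(0i, nKeep, nvox)
  for (start in seq.int(1L, length(simIdx), by = blockSize)) {
    idx <- simIdx[start:min(start + blockSize - 1L, length(simIdx))]
    FF <- magnetizationBlockFFT(offsets[idx, , drop = FALSE], seq, model,
                                mb$bin)
    for (b in seq_along(idx))
      for (ch in 1:3)
        P[rowsOfChan[[ch]], idx[b]] <- FF[binPosOfChan[[ch]], ch, b]
  }
  if (symmetric) {
    mirror <- nvox + 1L - simIdx
    fill <- mirror > max(simIdx)
    P[, mirror[fill]] <- -Conj(P[, simIdx[fill], drop = FALSE])
  }
  ## Debye relaxation + time derivative, per row
  rowFreq <- binFreq[keepBin]
  filt <- 2i * pi * rowFreq / (1 + 2i * pi * rowFreq * model@relaxationTime)
  P <- P * filt

  ## ----- cuboid sample extent: convolve point responses -------------------
  step <- grid@fov / grid@shape
  kern <- cuboidKernel(sfDimensions, step)
  S <- matrix(0i, nKeep, nvox)
  n1 <- grid@shape[1L]; n2 <- grid@shape[2L]; n3 <- grid@shape[3L]
  gx <- rep(seq_len(n1), times = n2 * n3)
  gy <- rep(rep(seq_len(n2), each = n1), times = n3)
  gz <- rep(seq_len(n3), each = n1 * n2)
  for (j in seq_along(kern$weights)) {
    off <- kern$offsets[j, ]
    sx <- gx + off[1L]; sy <- gy + off[2L]; sz <- gz + off[3L]
    ok <- sx >= 1L & sx <= n1 & sy >= 1L & sy <= n2 & sz >= 1L & sz <= n3
    src <- sx[ok] + n1 * (sy[ok] - 1L) + n1 * n2 * (sz[ok] - 1L)
    S[, which(ok)] <- S[, which(ok)] + kern$weights[j] * P[, src]
  }
  S <- S * sfConcentration
  rowRMS <- sqrt(rowMeans(Mod(S)^2))
  if (noiseSigma > 0) {
    S <- S + withSeed(seed, matrix(rcnorm(length(S), noiseSigma),
                                   nrow(S), ncol(S)))
    snr <- rowRMS / noiseSigma
  } else snr <- rep(Inf, nKeep)

  new("SystemFunction",
      matrix = S,
      componentFreq = rowFreq,
      componentChannel = keepChan,
      componentMixingOrder = mb$order[keepBin],
      componentSNR = snr,
      sfSample = list(concentration = sfConcentration,
                      volume = prod(sfDimensions),
                      dimensions = sfDimensions,
                      mobility = model@mobility),
      grid = grid,
      sequence = seq,
      noiseSigma = noiseSigma)
}
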