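## Digital aneurysm phantoms and simulated MPI measurements.

#' Make an aneurysm-like tracer phantom
#'
#' Builds a nonnegative concentration map whose support is a connected
#' ellipsoidal shell (the aneurysm wall, where macrophage-bound tracer
#' accumulates) with an optional mural thrombus blob, scaled so the
#' integrated iron mass equals \code{totalIron} exactly. Default geometry
#' mimics a mouse suprarenal aorta segment of 3 x 3 x 4 mm outer extent
#' (outer semi-axes 1.5 x 1.5 x 2 mm, 1 mm wall), centred near the isocenter
#' with a small seeded jitter.
#'
#' @param grid a [VoxelGrid-class].
#' @param totalIron numeric(1) > 0, total iron mass in ug.
#' @param center numeric(3) or `NULL`; `NULL` draws a jitter of up to
#'   +-1.5 mm (x, y) / +-1 mm (z) around the isocenter from `seed`.
#' @param outerSemiAxes numeric(3), mm.
#' @param wallThickness numeric(1), mm.
#' @param thrombusFraction numeric(1) in [0, 1), fraction of the mass placed
#'   in a blob attached to the wall (0 disables the blob).
#' @param seed integer(1), generator seed.
#' @return A [Phantom-class].
#' @examples
#' ph <- makePhantom(voxelGrid(), totalIron = 2, seed = 1)
#' totalIron(ph)  # exactly 2
#' @export
makePhantom <- function(grid, totalIron,
                        center = NULL,
                        outerSemiAxes = c(1.5, 1.5, 2),
                        wallThickness = 1,
                        thrombusFraction = 0,
                        seed = 1L) {
  if (totalIron <= 0) stop("totalIron must be positive (ug)")
  withSeed(seed, {
    if (is.null(center))
      center <- c(stats::runif(2, -1.5, 1.5), stats::runif(1, -1, 1))
    pos <- voxelCenters(grid)
    rel <- sweep(pos, 2L, center, "-")
    outer <- rowSums(sweep(rel, 2L, outerSemiAxes, "/")^2) <= 1
    innerAxes <- pmax(outerSemiAxes - wallThickness, 0.1)
    inner <- rowSums(sweep(rel, 2L, innerAxes, "/")^2) <= 1
    shell <- outer & !inner
    map <- array(0, grid@shape)
    map[shell] <- 1
    if (thrombusFraction > 0) {
      bc <- center + c(outerSemiAxes[1L] * 0.8, 0, 0)
      blob <- rowSums(sweep(sweep(pos, 2L, bc, "-"), 2L,
                            rep(wallThickness, 3L), "/")^2) <= 1
      bmap <- array(0, grid@shape)
      bmap[blob] <- 1
      if (any(bmap > 0))
        map <- map * (1 - thrombusFraction) / max(sum(map), 1) +
          bmap * thrombusFraction / sum(bmap)
    }
    if (!any(map > 0))
      stop("phantom support is empty on this grid; ",
           "mass not achievable with the requested geometry")
    if (!isConnected(map > 0)) {
      ## keep the dominant region; tiny satellites can appear on coarse grids
      keep <- largestComponent(map > 0)
      map[!keep] <- 0
    }
    ## scale to the requested mass: mass = sum(map) * voxvol * Fe factor
    vol <- voxelVolume(grid)
    map <- map * (totalIron / ironMassUg(sum(map), vol))
    new("Phantom", map = map, grid = grid, seed = as.integer(seed))
  })
}

#' Simulate an MPI measurement of a phantom
#'
#' Projects the phantom concentrations through the system matrix (after
#' scaling by the calibration-sample concentration and volume, so that a
#' reconstruction against the same system function reads out concentration
#' directly) and adds independent complex Gaussian noise per frequency
#' component and repetition.
#'
#' @param phantom a [Phantom-class].
#' @param sf a [SystemFunction-class] on the same grid.
#' @param nRepetitions integer(1), acquired frames (default 20, matching the
#'   block average used in reconstruction).
#' @param noiseSigma numeric(1) >= 0, per-frame per-component noise scale.
#' @param seed integer(1) or `NULL`.
#' @return An [MPIMeasurement-class].
#' @export
simulateMeasurement <- function(phantom, sf, nRepetitions = 20L,
                                noiseSigma = 0, seed = NULL) {
  if (noiseSigma < 0) stop("noiseSigma must be nonnegative")
  if (!identical(phantom@grid@shape, sf@grid@shape) ||
      !isTRUE(all.equal(phantom@grid@fov, sf@grid@fov)))
    stop("phantom and system function grids do not match")
  x <- as.vector(phantom@map) * phantomScale(sf)
  y0 <- as.vector(sf@matrix %*% x)
  nc <- length(y0)
  frames <- matrix(rep(y0, nRepetitions), nc, nRepetitions)
  if (noiseSigma > 0)
    frames <- frames + withSeed(seed, matrix(rcnorm(nc * nRepetitions,
                                                    noiseSigma),
                                             nc, nRepetitions))
  new("MPIMeasurement", frames = frames, noiseSigma = noiseSigma,
      seed = as.integer(if (is.null(seed)) 0L else seed))
}

## Scale factor turning a concentration map (mM) into system-matrix
## coordinates: voxel volume over calibration-sample (concentration x volume).
phantomScale <- function(sf) {
  voxelVolume(sf@grid) /
    (sf@sfSample$concentration * sf@sfSample$volume)
}
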