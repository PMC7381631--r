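## Internal helpers shared across modules.

## Molar mass of iron, g/mol. Used for every mM <-> ug conversion.
FE_MOLAR_MASS <- 55.845

## Evaluate expr with a fixed RNG state, restoring the caller's state after.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

gcd2 <- function(a, b) if (b == 0) a else Recall(b, a %% b)

## Least common multiple of a vector of positive integers.
lcmAll <- function(x) {
  Reduce(function(a, b) a / gcd2(a, b) * b, as.numeric(x))
}

## Circularly symmetric complex Gaussian noise, sd `sigma` per entry
## (real and imaginary parts each N(0, sigma^2 / 2)).
rcnorm <- function(n, sigma) {
  complex(real = stats::rnorm(n, sd = sigma / sqrt(2)),
          imaginary = stats::rnorm(n, sd = sigma / sqrt(2)))
}

## Iron mass (ug) contained in `conc_mM` (mM Fe) filling `volume_mm3` (mm^3).
## 1 mM x 1 mm^3 = 1e-3 mol/l x 1e-6 l x 55.845 g/mol = 0.055845 ug.
ironMassUg <- function(conc_mM, volume_mm3) {
  conc_mM * volume_mm3 * FE_MOLAR_MASS * 1e-3
}

## Voxel-center coordinates (mm) of a grid along one axis.
axisCenters <- function(n, fov) {
  step <- fov / n
  (seq_len(n) - (n + 1) / 2) * step
}

## Voxel-center coordinate matrix (nvox x 3) in grid linear order
## (x fastest, z slowest, matching R array storage).
voxelCenters <- function(grid) {
  cx <- axisCenters(grid@shape[1L], grid@fov[1L])
  cy <- axisCenters(grid@shape[2L], grid@fov[2L])
  cz <- axisCenters(grid@shape[3L], grid@fov[3L])
  as.matrix(expand.grid(x = cx, y = cy, z = cz, KEEP.OUT.ATTRS = FALSE))
}

voxelVolume <- function(grid) prod(grid@fov / grid@shape)

## Largest connected component of a logical 3D mask (6-connectivity),
## via iterative dilation-and-mask flood fill. Used by the optional
## connected-VOI restriction and by phantom construction checks.
largestComponent <- function(mask) {
  if (!any(mask)) return(mask)
  dm <- dim(mask)
  labels <- array(0L, dm)
  cur <- 0L
  remaining <- mask
  while (any(remaining)) {
    cur <- cur + 1L
    seedIdx <- which(remaining)[1L]
    comp <- array(FALSE, dm)
    comp[seedIdx] <- TRUE
    repeat {
      grown <- comp
      grown[-1, , ] <- grown[-1, , ] | comp[-dm[1L], , ]
      grown[-dm[1L], , ] <- grown[-dm[1L], , ] | comp[-1, , ]
      grown[, -1, ] <- grown[, -1, ] | comp[, -dm[2L], ]
      grown[, -dm[2L], ] <- grown[, -dm[2L], ] | comp[, -1, ]
      grown[, , -1] <- grown[, , -1] | comp[, , -dm[3L]]
      grown[, , -dm[3L]] <- grown[, , -dm[3L]] | comp[, , -1]
      grown <- grown & mask
      if (identical(grown, comp)) break
      comp <- grown
    }
    labels[comp] <- cur
    remaining <- remaining & !comp
  }
  sizes <- tabulate(labels[labels > 0L])
  labels == which.max(sizes)
}

isConnected <- function(mask) {
  if (!any(mask)) return(TRUE)
  sum(largestComponent(mask)) == sum(mask)
}
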