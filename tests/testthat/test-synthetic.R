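test_that("system-function simulation is deterministic and symmetric", {
  tiny <- voxelGrid(c(7L, 7L, 5L), c(7, 7, 5))
  a <- simulateSystemFunction(tiny, smallSequence(), particleModel(),
                              noiseSigma = 1e10, seed = 4L,
                              maxMixingOrder = 10L, maxComponents = 200L)
  b <- simulateSystemFunction(tiny, smallSequence(), particleModel(),
                              noiseSigma = 1e10, seed = 4L,
                              maxMixingOrder = 10L, maxComponents = 200L)
  expect_identical(sfMatrix(a), sfMatrix(b))
  ## rows of voxels mirrored through the isocenter have equal magnitudes
  sf <- smallSF()
  S <- sfMatrix(sf)
  nvox <- ncol(S)
  for (v in c(1L, 57L, 400L)) {
    mir <- nvox + 1L - v
    expect_equal(Mod(S[, v]), Mod(S[, mir]), tolerance = 1e-9)
  }
  ## every row carries signal
  expect_true(all(rowSums(Mod(S)^2) > 0))
})

test_that("immobilized tracer yields fewer strong high-order components", {
  rmsI <- sqrt(rowMeans(Mod(sfMatrix(smallSF()))^2))
  rmsF <- sqrt(rowMeans(Mod(sfMatrix(smallSFfluid()))^2))
  infoI <- componentInfo(smallSF())
  infoF <- componentInfo(smallSFfluid())
  ## at a common noise scale, count high-mixing-order components over SNR 7
  sigma0 <- stats::median(rmsF) / 20
  nI <- sum(rmsI / sigma0 >= 7 & infoI$mixingOrder >= 8)
  nF <- sum(rmsF / sigma0 >= 7 & infoF$mixingOrder >= 8)
  expect_lt(nI, nF)
})

test_that("phantoms hit the requested mass exactly and deterministically", {
  g <- smallGrid()
  ph <- makePhantom(g, 2.0, seed = 7)
  expect_equal(totalIron(ph), 2.0, tolerance = 1e-9)
  expect_true(all(concentrationMap(ph) >= 0))
  ## support is one connected region
  expect_true(MPIron:::isConnected(concentrationMap(ph) > 0))
  ## determinism and scaling
  expect_identical(concentrationMap(makePhantom(g, 2.0, seed = 7)),
                   concentrationMap(ph))
  ph4 <- makePhantom(g, 4.0, seed = 7)
  expect_equal(concentrationMap(ph4), 2 * concentrationMap(ph),
               tolerance = 1e-12)
  expect_error(makePhantom(g, 0), "positive")
  expect_error(makePhantom(g, -1), "positive")
})

test_that("measurement frames are the system-matrix projection plus noise", {
  sf <- smallSF()
  ph <- smallPhantom()
  m0 <- simulateMeasurement(ph, sf, nRepetitions = 3L, noiseSigma = 0)
  y <- as.vector(sfMatrix(sf) %*%
                   (as.vector(concentrationMap(ph)) *
                      MPIron:::phantomScale(sf)))
  for (j in 1:3) expect_equal(m0@frames[, j], y, tolerance = 1e-12)
  ## empty phantom, no noise -> zero frames
  empty <- new("Phantom", map = array(0, sf@grid@shape), grid = sf@grid,
               seed = 0L)
  expect_true(all(simulateMeasurement(empty, sf, 2L, 0)@frames == 0))
  ## grid mismatch rejected
  expect_error(simulateMeasurement(makePhantom(voxelGrid(c(5L, 5L, 3L),
                                                         c(5, 5, 3)), 1),
                                   sf), "grid")
  ## block mean of 20 noisy frames concentrates around the projection (CLT)
  sigma <- stats::median(Mod(y))
  mN <- simulateMeasurement(ph, sf, nRepetitions = 20L, noiseSigma = sigma,
                            seed = 5L)
  avg <- rowMeans(mN@frames)
  rmse <- sqrt(mean(Mod(avg - y)^2))
  expect_lt(rmse, 1.3 * sigma / sqrt(20))
  expect_gt(rmse, 0.7 * sigma / sqrt(20))
})

test_that("forward projection is linear in the phantom (superposition)", {
  sf <- smallSF()
  g <- sf@grid
  hot <- function(idx) {
    map <- array(0, g@shape); map[idx] <- 1.5
    new("Phantom", map = map, grid = g, seed = 0L)
  }
  ctr <- which(array(TRUE, g@shape))[c(500L, 501L, 560L)]
  ys <- lapply(ctr, function(i)
    simulateMeasurement(hot(i), sf, 1L, 0)@frames[, 1L])
  both <- array(0, g@shape); both[ctr] <- 1.5
  yAll <- simulateMeasurement(new("Phantom", map = both, grid = g,
                                  seed = 0L), sf, 1L, 0)@frames[, 1L]
  expect_equal(yAll, ys[[1L]] + ys[[2L]] + ys[[3L]], tolerance = 1e-10)
})

test_that("MPS simulation is linear in mass and seeded", {
  model <- particleModel("immobilized")
  z <- simulateMPS(0, model)
  expect_true(all(Mod(amplitudes(z)) == 0))
  s1 <- simulateMPS(1.3, model)
  s2 <- simulateMPS(2.6, model)
  expect_equal(amplitudes(s2), 2 * amplitudes(s1), tolerance = 1e-12)
  n1 <- simulateMPS(1, model, noiseSigma = 1e7, seed = 9L)
  n2 <- simulateMPS(1, model, noiseSigma = 1e7, seed = 9L)
  expect_identical(amplitudes(n1), amplitudes(n2))
  expect_identical(background(n1), background(n2))
  expect_error(simulateMPS(-1, model), "nonnegative")
})

test_that("stain and elemental generators are pure functions of their seed", {
  a <- makeStainImage(0.12, seed = 3L)
  b <- makeStainImage(0.12, seed = 3L)
  expect_identical(a$image, b$image)
  expect_identical(a$ironMask, b$ironMask)
  ## requested area fraction honoured to one pixel quantum
  expect_lte(abs(sum(a$ironMask) / sum(a$tissueMask) - 0.12),
             1 / sum(a$tissueMask))
  s1 <- makeElementalScan(matrix(50, 3, 10), seed = 2L)
  s2 <- makeElementalScan(matrix(50, 3, 10), seed = 2L)
  expect_identical(s1$scans, s2$scans)
  expect_identical(s1$standards, s2$standards)
  ## blank standard at zero noise reads the intercept
  s0 <- makeElementalScan(matrix(50, 3, 10), blankSigma = 0)
  blank <- s0$standards[s0$standards$concentration == 0, "intensity"]
  expect_true(all(blank == s0$meta$intercept))
})
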