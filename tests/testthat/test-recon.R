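## A minimal SystemFunction with hand-set component metadata, for testing
## the selection logic in isolation.
fakeSF <- function(freq, snr, order, channel = rep(1L, length(freq))) {
  g <- voxelGrid(c(2L, 1L, 1L), c(2, 1, 1))
  new("SystemFunction",
      matrix = matrix(1 + 0i, length(freq), 2L),
      componentFreq = freq,
      componentChannel = as.integer(channel),
      componentMixingOrder = as.integer(order),
      componentSNR = snr,
      sfSample = list(concentration = 100, volume = 13.5,
                      dimensions = c(3, 3, 1.5), mobility = "immobilized"),
      grid = g, sequence = fieldSequence(), noiseSigma = 1)
}

test_that("component selection applies SNR, band and mixing-order filters", {
  f3 <- 3 * 2.5e6 / 102  # 3rd drive-field harmonic, ~73.5 kHz
  sf <- fakeSF(freq = c(f3, 1e5, 2e5, 3e5, 4e5),
               snr = c(100, 8, 6.9, 50, 100),
               order = c(3L, 5L, 3L, 26L, 7L))
  cfg <- reconConfig()
  sel <- selectComponents(sf, cfg)
  ## the 3rd harmonic falls below the 90 kHz edge; SNR 6.9 < 7; order 26 > 25
  expect_identical(sel, c(2L, 5L))
  ## sorted ascending by frequency
  sf2 <- fakeSF(freq = c(4e5, 1e5, 2e5), snr = rep(10, 3),
                order = rep(1L, 3))
  expect_identical(selectComponents(sf2, cfg), c(2L, 3L, 1L))
  ## empty selections name the culprit filter
  expect_error(selectComponents(
    fakeSF(1e5, 5, 1L), cfg), "SNR")
  expect_error(selectComponents(
    fakeSF(5e4, 50, 1L), cfg), "band")
  expect_error(selectComponents(
    fakeSF(1e5, 50, 30L), cfg), "order")
})

test_that("block averaging is the component-wise mean of the first n frames", {
  y <- complex(real = 1:4, imaginary = 4:1)
  m <- new("MPIMeasurement", frames = cbind(y, y, y), noiseSigma = 0,
           seed = 0L)
  expect_equal(blockAverage(m, 3L), y)
  m2 <- new("MPIMeasurement", frames = cbind(y, -y), noiseSigma = 0,
            seed = 0L)
  expect_equal(blockAverage(m2, 2L), 0 * y)
  expect_error(blockAverage(m, 5L), "frames")
  ## averaging 20 noisy frames shrinks the error by about sqrt(20)
  set.seed(42)
  errs <- replicate(150, {
    fr <- matrix(MPIron:::rcnorm(8 * 20, 1), 8, 20)
    mm <- new("MPIMeasurement", frames = fr, noiseSigma = 1, seed = 0L)
    c(one = mean(Mod(fr[, 1L])), avg = mean(Mod(blockAverage(mm, 20L))))
  })
  expect_equal(mean(errs["one", ]) / mean(errs["avg", ]), sqrt(20),
               tolerance = 0.1)
})

test_that("Kaczmarz solves identity systems in one sweep", {
  y <- complex(real = c(3, -1, 2), imaginary = c(0, 1, -2))
  A <- diag(3) + 0i
  expect_equal(kaczmarzTikhonov(A, y, lambda = 0, iterations = 1L,
                                nonneg = FALSE), y, tolerance = 1e-12)
})

test_that("Kaczmarz at convergence matches the dense least-squares oracle", {
  set.seed(10)
  A <- matrix(complex(real = rnorm(40 * 12), imaginary = rnorm(40 * 12)),
              40, 12)
  xTrue <- complex(real = runif(12), imaginary = rep(0, 12))
  y <- as.vector(A %*% xTrue)  # consistent system
  xOracle <- qr.solve(A, y)    # dense least-squares solution
  xK <- kaczmarzTikhonov(A, y, lambda = 0, iterations = 50L, nonneg = FALSE)
  expect_equal(xK, xOracle, tolerance = 1e-6)
  ## strong regularization drives the solution toward zero
  xBig <- kaczmarzTikhonov(A, y, lambda = 1e8, iterations = 5L,
                           nonneg = FALSE, lambdaMode = "absolute")
  expect_lt(sqrt(sum(Mod(xBig)^2)), 1e-4 * sqrt(sum(Mod(xOracle)^2)))
  expect_error(kaczmarzTikhonov(A, y[-1]), "mismatch")
})

test_that("the regularized objective is non-increasing over sweeps", {
  set.seed(2)
  A <- matrix(complex(real = rnorm(60 * 25), imaginary = rnorm(60 * 25)),
              60, 25)
  y <- as.vector(A %*% complex(real = runif(25)))
  lambdaEff <- 0.05 * mean(rowSums(Mod(A)^2))
  obj <- vapply(1:8, function(k) {
    x <- kaczmarzTikhonov(A, y, lambda = 0.05, iterations = k,
                          nonneg = FALSE)
    sum(Mod(A %*% x - y)^2) + lambdaEff * sum(Mod(x)^2)
  }, numeric(1))
  expect_true(all(diff(obj) <= 1e-8 * obj[1L]))
})

test_that("zero rows are skipped with a notice", {
  A <- rbind(c(1 + 0i, 0i), c(0i, 0i), c(0i, 1 + 0i))
  y <- c(2 + 0i, 0i, 3 + 0i)
  expect_message(
    x <- kaczmarzTikhonov(A, y, lambda = 0, iterations = 1L, nonneg = FALSE),
    "zero row")
  expect_equal(x, c(2 + 0i, 3 + 0i), tolerance = 1e-12)
})

test_that("reconstruction localizes a one-hot phantom and is deterministic", {
  sf <- smallSF()
  g <- sf@grid
  map <- array(0, g@shape)
  hotIdx <- c(6L, 8L, 4L)  # off-center interior voxel
  map[hotIdx[1L], hotIdx[2L], hotIdx[3L]] <- 2
  ph <- new("Phantom", map = map, grid = g, seed = 0L)
  meas <- simulateMeasurement(ph, sf, 2L, 0)
  cfg <- smallRecon(lambda = 1e-4, iterations = 20L, blockAverage = 2L)
  img <- reconstruct(meas, sf, cfg)
  expect_identical(arrayInd(which.max(concentrationMap(img)), g@shape)[1, ],
                   hotIdx)
  expect_equal(img@selectedComponentCount,
               length(selectComponents(sf, cfg)))
  ## zero measurement -> zero image
  z <- new("MPIMeasurement",
           frames = matrix(0i, nrow(sfMatrix(sf)), 2L),
           noiseSigma = 0, seed = 0L)
  expect_true(all(concentrationMap(reconstruct(z, sf, cfg)) == 0))
  ## bit-identical rerun
  img2 <- reconstruct(meas, sf, cfg)
  expect_identical(concentrationMap(img), concentrationMap(img2))
})
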