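test_that("langevin matches its closed form and limits", {
  expect_identical(langevin(0), 0)
  expect_equal(langevin(1), 1 / tanh(1) - 1, tolerance = 1e-12)
  expect_equal(langevin(1), 0.31304, tolerance = 1e-4)
  expect_equal(langevin(1e6), 1, tolerance = 1e-5)
  ## odd, bounded, continuous across the series switchover
  x <- c(10^seq(-8, 2, by = 0.25))
  expect_equal(langevin(-x), -langevin(x), tolerance = 1e-12)
  expect_true(all(abs(langevin(x)) < 1))
  expect_error(langevin(NaN), "NaN")
})

test_that("magnetization is an odd, saturating Langevin mixture", {
  m <- particleModel("fluid")
  expect_identical(magnetization(0, m), 0)
  expect_equal(magnetization(1e6, m), m@saturationMagnetization,
               tolerance = 1e-3)
  h <- seq(-30, 30, by = 1.5)
  expect_equal(magnetization(-h, m), -magnetization(h, m), tolerance = 1e-12)
  expect_true(all(abs(magnetization(h, m)) <= m@saturationMagnetization))
  ## concavity on the positive axis: doubling the field less than doubles M
  single <- particleModel("fluid", coreDiameters = 16, weights = 1)
  r <- magnetization(12, single) / magnetization(6, single)
  expect_gt(r, 1)
  expect_lt(r, 2)
})

test_that("FFP trajectory covers 2A/G per axis and closes after one period", {
  seqd <- fieldSequence()  # protocol scanner
  f <- seqd@baseFrequency / seqd@dividers
  for (ax in 1:3) {
    ## include each axis's own extrema times so the peak is hit exactly
    t <- c(seq(0, lissajousPeriod(seqd), length.out = 5001),
           1 / (4 * f[ax]), 3 / (4 * f[ax]))
    p <- ffpPosition(seqd, t)[, ax]
    expect_equal(max(p) - min(p),
                 2 * seqd@driveAmplitudes[ax] / seqd@gradients[ax],
                 tolerance = 1e-9)
  }
  ## closure at exactly one period
  T0 <- lissajousPeriod(seqd)
  expect_equal(ffpPosition(seqd, 0.0123), ffpPosition(seqd, 0.0123 + T0),
               tolerance = 1e-9)
  ## zero drive pins the FFP at the isocenter
  still <- fieldSequence(driveAmplitudes = c(0, 0, 0))
  expect_true(all(ffpPosition(still, c(0, 1e-3, 7e-3)) == 0))
})

test_that("Lissajous period is lcm(dividers) / base frequency", {
  expect_equal(lissajousPeriod(fieldSequence()), 53856 / 2.5e6)
  expect_equal(round(lissajousPeriod(fieldSequence()) * 1e3, 1), 21.5)
  expect_equal(lissajousPeriod(fieldSequence(dividers = c(1L, 1L, 1L),
                                             samplesPerPeriod = 16L)),
               0.4e-6)
  ## brute-force lcm oracle on a generic triple
  bf <- function(d) { n <- max(d); while (any(n %% d != 0)) n <- n + 1; n }
  expect_equal(lissajousPeriod(fieldSequence(dividers = c(2L, 3L, 5L),
                                             baseFrequency = 1,
                                             samplesPerPeriod = 30L)),
               bf(c(2, 3, 5)))
})

test_that("induced signal is linear in concentration and needs whole periods", {
  seqd <- fieldSequence(dividers = c(5L, 4L, 3L), baseFrequency = 1e5)
  m <- particleModel("fluid")
  n <- seqd@samplesPerPeriod
  expect_true(all(inducedSignal(0, m, seqd) == 0))
  set.seed(11)
  c1 <- stats::runif(n)  # arbitrary concentration path
  s1 <- inducedSignal(c1, m, seqd)
  s2 <- inducedSignal(2 * c1, m, seqd)
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  expect_error(inducedSignal(c1[-1], m, seqd), "integer number")
})

test_that("harmonic decomposition isolates bins and obeys symmetry", {
  fs <- 1e5; f0 <- 1e3; n <- 1000
  t <- (0:(n - 1)) / fs
  ## pure fundamental
  sp <- harmonicSpectrum(3.7 * sin(2 * pi * f0 * t), f0, fs)
  a <- Mod(amplitudes(sp))
  expect_equal(a[1L], 3.7, tolerance = 1e-10)
  expect_true(all(a[-1L] < 1e-10 * a[1L]))
  ## square wave: odd harmonics fall off as 1/k, even vanish
  ## half-sample phase offset keeps samples away from the zero crossings;
  ## dense sampling keeps aliased high harmonics negligible
  fsq <- 1e6; tq <- (0:9999) / fsq
  sq <- harmonicSpectrum(sign(sin(2 * pi * f0 * (tq + 0.5 / fsq))), f0, fsq,
                         nHarmonics = 9L)
  aq <- Mod(amplitudes(sq))
  for (k in c(3, 5, 7, 9))
    expect_equal(aq[k] / aq[1L], 1 / k, tolerance = 1e-2)
  expect_true(all(aq[c(2, 4, 6, 8)] < 1e-10 * aq[1L]))
  ## Langevin response to a sine: odd M(H) kills even harmonics
  m <- particleModel("fluid")
  resp <- magnetization(25 * sin(2 * pi * f0 * t), m)
  sl <- harmonicSpectrum(resp, f0, fs, nHarmonics = 8L)
  al <- Mod(amplitudes(sl))
  expect_true(all(al[c(2, 4, 6, 8)] < 1e-8 * al[c(1, 3, 5, 7)]))
  expect_error(harmonicSpectrum(sin(2 * pi * f0 * t[1:999]), f0, fs),
               "integer")
})
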