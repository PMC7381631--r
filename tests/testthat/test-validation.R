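test_that("colour-profile segmentation recovers the painted iron fraction", {
  st <- makeStainImage(0.10, seed = 42)
  ## with the ground-truth tissue mask
  seg <- segmentByProfile(st$image, tissueMask = st$tissueMask)
  expect_equal(seg$ratio, 0.10, tolerance = 0.01)
  ## with the Otsu-derived tissue mask (full automatic path)
  seg2 <- segmentByProfile(st$image)
  expect_equal(seg2$ratio, 0.10, tolerance = 0.015)
  ## segmentation agrees with the ground-truth iron mask
  expect_gt(colocalize(seg$ironMask, st$ironMask), 0.95)
})

test_that("segmentation edge cases: no iron, all iron, empty tissue", {
  st0 <- makeStainImage(0, seed = 1)
  expect_equal(segmentByProfile(st0$image, tissueMask = st0$tissueMask)$ratio,
               0)
  st1 <- makeStainImage(1, seed = 1, jitterSD = 2)
  expect_gt(segmentByProfile(st1$image, tissueMask = st1$tissueMask)$ratio,
            0.99)
  expect_error(segmentByProfile(st0$image,
                                tissueMask = matrix(FALSE, 192, 192)),
               "empty")
})

test_that("segmentation is monotone in tolerance and idempotent", {
  st <- makeStainImage(0.15, seed = 5)
  tols <- c(10, 20, 30, 45)
  masks <- lapply(tols, function(tol)
    segmentByProfile(st$image, colorProfile(tolerance = tol),
                     st$tissueMask)$ironMask)
  for (i in seq_len(length(tols) - 1L))
    expect_true(all(masks[[i + 1L]][masks[[i]]]))  # superset at larger tol
  ## idempotent: same inputs, same mask
  again <- segmentByProfile(st$image, colorProfile(tolerance = 20),
                            st$tissueMask)$ironMask
  expect_identical(masks[[2L]], again)
})

test_that("calibration fit recovers exact lines and the printed noise regime", {
  ## exact synthetic standards: R^2 = 1, slope/intercept exact
  conc <- c(0, 1, 5, 25, 100, 250, 1000, 2500, 5000)
  std <- data.frame(concentration = rep(conc, each = 3),
                    intensity = rep(7.5 * conc + 120, each = 3))
  cc <- fitCalibration(std)
  expect_equal(cc@slope, 7.5, tolerance = 1e-12)
  expect_equal(cc@intercept, 120, tolerance = 1e-9)
  expect_equal(cc@rSquared, 1, tolerance = 1e-12)
  ## gelatin-standard regime with modest noise keeps R^2 >= 0.999
  scan <- makeElementalScan(matrix(100, 4, 50), seed = 9)
  cc2 <- fitCalibration(scan$standards)
  expect_gte(cc2@rSquared, 0.999)
  ## degenerate designs are rejected
  expect_error(fitCalibration(data.frame(concentration = c(5, 5, 5),
                                         intensity = 1:3)),
               "distinct")
  expect_error(fitCalibration(data.frame(concentration = c(1, 2, 3),
                                         intensity = 1:3)),
               "blank")
})

test_that("LOD/LOQ follow the 3-sigma and 10-sigma criteria", {
  expect_equal(unname(lodLoq(1, 0.1)), c(30, 100))
  expect_equal(unname(lodLoq(0, 5)), c(0, 0))
  ## the 10/3 ratio is exact for any admissible input
  for (s in c(0.3, 2, 41)) {
    ll <- lodLoq(s, 0.7)
    expect_equal(ll[["loq"]] / ll[["lod"]], 10 / 3, tolerance = 1e-12)
  }
  expect_error(lodLoq(1, 0), "slope")
  ## lod/loq scale linearly with blank noise through the fitted curve
  base <- fitCalibration(makeElementalScan(matrix(10, 2, 20), blankSigma = 5,
                                           seed = 2)$standards)
  expect_equal(base@lod, 3 * base@blankSigma / base@slope)
  expect_equal(base@loq, 10 * base@blankSigma / base@slope)
})

test_that("map quantification inverts the scan generator", {
  set.seed(3)
  truth <- matrix(runif(80, 0, 4000), 4, 20)
  scan <- makeElementalScan(truth, blankSigma = 0)
  cc <- fitCalibration(scan$standards)
  ## zero blank noise: sd of identical blanks is 0 -> lod 0; exact inversion
  qm <- quantifyMap(scan$scans, cc)
  expect_equal(qm$map, truth, tolerance = 1e-9, ignore_attr = TRUE)
  ## intensity at the intercept maps to zero concentration
  qi <- quantifyMap(data.frame(line = 1L, pixel = 1L,
                               intensity = cc@intercept), cc)
  expect_equal(qi$map[1L, 1L], 0)
  ## noisy inversion: RMSE bounded by 2 sigma / slope (Monte Carlo)
  errs <- vapply(1:30, function(s) {
    sc <- makeElementalScan(truth, blankSigma = 12, seed = s)
    q <- quantifyMap(sc$scans, fitCalibration(sc$standards))
    sqrt(mean((q$map - truth)^2))
  }, numeric(1))
  expect_lt(mean(errs), 2 * 12 / 50)
})

test_that("Dice colocalization handles the canonical cases", {
  a <- matrix(FALSE, 6, 6); a[2:4, 2:4] <- TRUE
  expect_equal(colocalize(a, a), 1)
  b <- matrix(FALSE, 6, 6); b[5:6, 5:6] <- TRUE
  expect_equal(colocalize(a, b), 0)
  ## half-overlapping equal-size masks: |A|=|B|=6, intersection 3 -> 1/2...
  ## brute-force check of the formula on random masks
  set.seed(1)
  for (i in 1:5) {
    m1 <- matrix(runif(36) > 0.5, 6, 6)
    m2 <- matrix(runif(36) > 0.5, 6, 6)
    expect_equal(colocalize(m1, m2),
                 2 * sum(m1 & m2) / (sum(m1) + sum(m2)))
  }
  ## equal-size masks overlapping half their union (|A|=|B|=3, 2 shared):
  ## intersection 2, union 4 -> Dice 2*2/6 = 2/3
  m1 <- matrix(FALSE, 4, 4); m1[1:3, 1] <- TRUE
  m2 <- matrix(FALSE, 4, 4); m2[2:4, 1] <- TRUE
  expect_equal(colocalize(m1, m2), 2 / 3)
  expect_equal(colocalize(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 0)
  expect_error(colocalize(m1, matrix(FALSE, 3, 3)), "shape")
})
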