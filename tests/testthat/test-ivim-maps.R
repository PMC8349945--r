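test_that("D' map matches the explicit two-point formula", {
  expect_equal(mapValues(computeDprime(makeStack(1000, 400, 400)))[1], 0)
  m <- computeDprime(makeStack(1000, 900, 300))
  expect_equal(mapValues(m)[1], log(3) / 750)
  expect_equal(mapValues(m)[1] * 1e6, 1464.8, tolerance = 1e-4)

  bad <- computeDprime(makeStack(1000, 900, 0))
  expect_false(any(validMask(bad)))

  noB <- new("DWIStack", bValues = c(0, 800),
             volumes = list(array(1, c(2, 2, 1)), array(1, c(2, 2, 1))))
  expect_error(computeDprime(noB), "missing required b")
})

test_that("f' map recovers perfusion fraction and flags invalid voxels", {
  # pure diffusion voxel: no perfusion excess
  mono <- makeStack(1000, 1000 * exp(-50e-3), 1000 * exp(-800e-3))
  f <- computeFprime(mono)
  expect_equal(mapValues(f)[1], 0, tolerance = 1e-12)

  # oracle voxel through the biexponential forward model
  s <- forwardSignal(1000, 1e-3, 0.2, 50e-3, b = c(0, 50, 800))
  stk <- makeStack(s[1], s[2], s[3])
  dp <- computeDprime(stk)
  fp <- computeFprime(stk, dp)
  expect_equal(mapValues(dp)[1] * 1e6, 1027.1, tolerance = 1e-4)
  expect_equal(mapValues(fp)[1] * 1e3, 182.5, tolerance = 1e-3)

  # fully dephased voxel: f' equals f exactly
  s <- forwardSignal(1000, 1e-3, 0.2, b = c(0, 50, 800),
                     mode = "fully_dephased")
  fp <- computeFprime(makeStack(s[1], s[2], s[3]))
  expect_equal(mapValues(fp)[1], 0.2, tolerance = 1e-12)

  # S(0) <= 0 invalidates; raw negative f' stays valid
  zero <- makeStack(0, 500, 200)
  expect_false(any(validMask(computeFprime(zero))))
  noisy <- makeStack(500, 600, 200)    # S(50) > S(0): f' < 0 under noise
  fneg <- computeFprime(noisy)
  expect_true(all(validMask(fneg)))
  expect_lt(mapValues(fneg)[1], 0)

  wrong <- computeDprime(makeStack(1, 1, 1, dm = c(3, 3, 1)))
  expect_error(computeFprime(makeStack(1, 1, 1, dm = c(2, 2, 1)), wrong),
               "grid mismatch")
})

test_that("ADC map matches the full-range formula", {
  expect_equal(mapValues(computeADC(makeStack(700, 500, 700)))[1], 0)
  m <- computeADC(makeStack(1000, 800, 359.4632))
  expect_equal(mapValues(m)[1] * 1e6, 1279.0, tolerance = 1e-4)
})

test_that("ADC = D' - ln(1 - f')/800 on every valid voxel, even noisy ones", {
  set.seed(10)
  dm <- c(12, 12, 6)
  stk <- makeStack(abs(rnorm(prod(dm), 1000, 200)),
                   abs(rnorm(prod(dm), 800, 200)),
                   abs(rnorm(prod(dm), 400, 200)), dm = dm)
  m <- computeMaps(stk)
  ok <- validMask(m$Dprime) & validMask(m$fprime) & validMask(m$ADC)
  lhs <- mapValues(m$ADC)[ok]
  rhs <- mapValues(m$Dprime)[ok] - log(1 - mapValues(m$fprime)[ok]) / 800
  expect_lt(max(abs(lhs - rhs)), 1e-12)
})

test_that("ADC >= D' on noiseless phantoms, equal only where f' = 0", {
  sc <- buildScene(dim = c(20, 20, 6),
                   lesions = data.frame(class = "FNH", radius = 3),
                   seed = 12)
  m <- computeMaps(simulateDWI(sc, sigma = 0))
  ok <- validMask(m$ADC) & validMask(m$Dprime) & sc@labels != 0L
  expect_true(all(mapValues(m$ADC)[ok] - mapValues(m$Dprime)[ok] > -1e-15))
  mono <- makeStack(1000, 1000 * exp(-50 * 1.3e-3), 1000 * exp(-800 * 1.3e-3))
  mm <- computeMaps(mono)
  expect_equal(mapValues(mm$ADC)[1], mapValues(mm$Dprime)[1],
               tolerance = 1e-12)
})

test_that("fully dephased noiseless phantoms give exact voxel-wise recovery", {
  sc <- buildScene(dim = c(24, 24, 8),
                   lesions = data.frame(class = c("HCC", "haemangioma"),
                                        radius = c(3, 3)),
                   seed = 6)
  stk <- simulateDWI(sc, mode = "fully_dephased", sigma = 0)
  m <- computeMaps(stk)
  inside <- sc@labels != 0L
  expect_equal(mapValues(m$Dprime)[inside], sc@D[inside], tolerance = 1e-12)
  expect_equal(mapValues(m$fprime)[inside], sc@f[inside], tolerance = 1e-12)
})

test_that("finite-Dstar perfusion residue biases D' up and f' down", {
  # incomplete dephasing at b = 50 inflates S(50): D' rises above D while
  # the extrapolated b0 excess shrinks, so f' underestimates f; both
  # converge to exactness as Dstar grows
  sc <- buildScene(dim = c(20, 20, 6),
                   lesions = data.frame(class = "HCC", radius = 3),
                   seed = 13)
  m <- computeMaps(simulateDWI(sc, mode = "biexponential", sigma = 0))
  inside <- sc@labels != 0L
  expect_true(all(mapValues(m$Dprime)[inside] >= sc@D[inside] - 1e-15))
  expect_true(all(mapValues(m$fprime)[inside] <= sc@f[inside] + 1e-15))

  # shrinking bias with increasing Dstar at a fixed voxel
  errD <- errF <- numeric(0)
  for (Ds in c(10e-3, 30e-3, 100e-3, 1)) {
    s <- forwardSignal(1000, 1e-3, 0.15, Ds, b = c(0, 50, 800))
    mm <- computeMaps(makeStack(s[1], s[2], s[3]))
    errD <- c(errD, mapValues(mm$Dprime)[1] - 1e-3)
    errF <- c(errF, 0.15 - mapValues(mm$fprime)[1])
  }
  expect_true(all(errD >= 0) && all(errF >= 0))
  expect_true(all(diff(errD) < 0) && all(diff(errF) < 0))
  expect_lt(errF[4], 1e-6)
})

test_that("D' strictly decreases as S(800) increases with S(50) fixed", {
  s800 <- seq(100, 900, by = 100)
  d <- vapply(s800, function(s)
    mapValues(computeDprime(makeStack(1000, 900, s)))[1], numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("extra b values in the stack are ignored by the estimators", {
  s <- forwardSignal(1000, 1.2e-3, 0.15, 40e-3, b = c(0, 50, 250, 800))
  with250 <- makeStack(s[1], s[2], s[4], extra = list(`250` = s[3]))
  without <- makeStack(s[1], s[2], s[4])
  expect_equal(mapValues(computeDprime(with250)),
               mapValues(computeDprime(without)))
  expect_equal(mapValues(computeFprime(with250)),
               mapValues(computeFprime(without)))
  expect_equal(mapValues(computeADC(with250)),
               mapValues(computeADC(without)))
})
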