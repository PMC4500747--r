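test_that("linear triangle stiffness matches hand assembly", {
  # unit right triangle: K = 1/2 * [[2,-1,-1],[-1,1,0],[-1,0,1]]
  K <- ephapse:::triangle_stiffness(c(0, 1, 0), c(0, 0, 1))
  expect_equal(K, matrix(c(2, -1, -1, -1, 1, 0, -1, 0, 1), 3, 3) / 2,
               tolerance = 1e-12)

  # unit square split into two triangles, unit conductivity: assembled
  # diagonal 1, off-diagonals -1/2 and 0 across the diagonal pairing
  K1 <- ephapse:::triangle_stiffness(c(0, 1, 1), c(0, 0, 1))
  K2 <- ephapse:::triangle_stiffness(c(0, 1, 0), c(0, 1, 1))
  A <- matrix(0, 4, 4)
  A[c(1, 2, 3), c(1, 2, 3)] <- A[c(1, 2, 3), c(1, 2, 3)] + K1
  A[c(1, 3, 4), c(1, 3, 4)] <- A[c(1, 3, 4), c(1, 3, 4)] + K2
  hand <- matrix(c(1, -0.5, 0, -0.5,
                   -0.5, 1, -0.5, 0,
                   0, -0.5, 1, -0.5,
                   -0.5, 0, -0.5, 1), 4, 4)
  expect_equal(A, hand, tolerance = 1e-12)
})

test_that("assembled operators annihilate constant fields (gauge invariance)", {
  cfg <- small_config()
  mesh <- buildTissueSheet(cfg)
  sys <- assembleSystem(mesh, cfg)
  ones <- rep(1, sys$N)
  expect_lt(max(abs(sys$S %*% ones)), 1e-9)    # zero row sums
  expect_lt(max(abs(sys$B %*% ones)), 1e-12)   # V = phi_i - phi_e
  # stiffness block is symmetric positive semi-definite
  expect_true(Matrix::isSymmetric(sys$S, tol = 1e-10))
})

test_that("the resting state is preserved without stimulus", {
  cfg <- small_config(duration = 5)
  cfg@solver$stimAmplitude <- 0
  r <- runProtocol(cfg)
  expect_lt(max(abs(r@traces - r@meta$restingPotential)), 0.05)
})

test_that("passive membrane decays with tau = Cm / gLeak", {
  cfg <- modelConfig(nRows = 1, nCols = 1, duration = 18,
                     ionic = ionicModel(type = "passive", gLeak = 0.25,
                                        Vrest = -80),
                     junctionalFraction = 0, stimAmplitude = 30)
  r <- runProtocol(cfg, stimulusCells = 1)
  v <- r@traces[1, ] - (-80)
  t <- r@time
  post <- t > 2 & v > 0.05 * max(v)
  fit <- lm(log(v[post]) ~ t[post])
  tau <- -1 / coef(fit)[[2]]
  expect_equal(tau, cfg@membrane$Cm / 0.25, tolerance = 0.05)
})

test_that("activation spreads monotonically from the stimulated edge", {
  cfg <- modelConfig(nRows = 3, nCols = 8, ionic = ionicModel(gNa = 40))
  r <- runProtocol(cfg, "longitudinal")
  expect_false(r@blocked)
  ta <- activationTimes(r)
  expect_true(all(!is.na(ta)))
  byCol <- tapply(ta, r@cells$col, mean)
  expect_true(all(diff(byCol) > 0))
  expect_lt(r@meta$maxRelativeResidual, 1e-8)
})

test_that("uncoupled tissue blocks and zero stimulus never activates", {
  cfg <- modelConfig(nRows = 2, nCols = 4, gjBar = 0, duration = 10,
                     junctionalFraction = 0.11,
                     lateralWidth = 1, junctionalWidth = 150)
  r <- runProtocol(cfg, "longitudinal")
  expect_true(r@blocked)
  expect_true(all(is.na(activationTimes(r)[r@cells$col == 4])))

  cfg0 <- modelConfig(nRows = 2, nCols = 3, duration = 5, stimAmplitude = 0)
  r0 <- runProtocol(cfg0, "longitudinal")
  expect_true(all(is.na(activationTimes(r0))))
})

test_that("mirror-symmetric stimulation gives mirror-symmetric activation", {
  cfg <- modelConfig(nRows = 3, nCols = 4, transverseOffset = 0,
                     longitudinalOffset = 0, ionic = ionicModel(gNa = 40))
  r <- runProtocol(cfg, "longitudinal")
  ta <- activationTimes(r)
  top <- ta[r@cells$row == 1][order(r@cells$col[r@cells$row == 1])]
  bot <- ta[r@cells$row == 3][order(r@cells$col[r@cells$row == 3])]
  expect_equal(top, bot, tolerance = 1e-6)
})

test_that("traces round-trip through the tidy CSV writer", {
  cfg <- modelConfig(nRows = 1, nCols = 2, duration = 2)
  r <- runProtocol(cfg)
  f <- tempfile(fileext = ".csv")
  writeTraces(r, f)
  lines <- readLines(f, n = 1)
  expect_match(lines, "^# \\{")
  tab <- read.csv(f, comment.char = "#")
  expect_setequal(names(tab), c("cell", "x", "y", "t", "Vm"))
  expect_equal(nrow(tab), 2 * length(r@time))
})
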