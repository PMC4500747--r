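test_that("generators are bit-deterministic per seed", {
  a <- simulateLocalizationImages(nCx = 4, perinexalPerCx = 1, seed = 3,
                                  imageSize = c(700, 700), noiseSd = 0.02,
                                  blurFWHM = 22)
  b <- simulateLocalizationImages(nCx = 4, perinexalPerCx = 1, seed = 3,
                                  imageSize = c(700, 700), noiseSd = 0.02,
                                  blurFWHM = 22)
  expect_identical(a$cx43@data, b$cx43@data)
  expect_identical(a$truth, b$truth)

  c2 <- simulateLocalizationImages(nCx = 4, perinexalPerCx = 1, seed = 4,
                                   imageSize = c(700, 700))
  expect_false(identical(a$truth$cx, c2$truth$cx))
  # different seeds, identical placement counts by class
  expect_identical(table(a$truth$intendedClass),
                   table(c2$truth$intendedClass))
})

test_that("zero clusters give blank images and an empty truth table", {
  z <- simulateLocalizationImages(nCx = 0, seed = 1)
  expect_equal(sum(z$cx43@data), 0)
  expect_equal(sum(z$nav@data), 0)
  expect_equal(nrow(z$truth), 0)
})

test_that("the pipeline recovers constructed ground truth exactly", {
  img <- simulateLocalizationImages(nCx = 10, perinexalPerCx = 1,
                                    perinexalDistance = 100, seed = 8,
                                    imageSize = c(1100, 1100))
  rep1 <- associateClusters(findClusters(img$cx43), findClusters(img$nav))
  expect_equal(rep1@summary$navPerinexalFraction, 1)
  expect_equal(rep1@summary$navOverlapFraction, 0)
  expect_equal(rep1@summary$nNav, 10)
  expect_equal(rep1@summary$nCx, 10)
})

test_that("placements at the decision boundary are classified by the tie rule", {
  img <- simulateLocalizationImages(nCx = 3, perinexalPerCx = 1,
                                    perinexalDistance = 200,
                                    diameterCV = 0, seed = 12,
                                    imageSize = c(900, 900))
  tr <- img$truth[img$truth$channel == "Nav1.5", ]
  atBoundary <- tr$realizedDistanceNm == 200
  expect_true(all(tr$realizedClass[atBoundary] == "perinexal"))
  navSeg <- findClusters(img$nav)
  rep1 <- associateClusters(findClusters(img$cx43), navSeg)
  mt <- vapply(seq_len(nrow(navSeg@clusters)), function(j)
    which.min((tr$cx - navSeg@clusters$cx[j])^2 +
                (tr$cy - navSeg@clusters$cy[j])^2), 0L)
  expect_equal(rep1@navTable$class, tr$realizedClass[mt])
})

test_that("analytic activation maps encode the requested velocities", {
  m <- simulateActivationMap(vL = 60, vT = 30)
  cv <- computeCV(m$map)
  expect_equal(cv@cvL, m$truth$vL, tolerance = 1e-9)
  expect_equal(cv@cvT, m$truth$vT, tolerance = 1e-9)

  n1 <- simulateActivationMap(vL = 60, vT = 30, noiseSd = 0.5, seed = 2)
  n2 <- simulateActivationMap(vL = 60, vT = 30, noiseSd = 0.5, seed = 2)
  expect_identical(n1$map@times, n2$map@times)
})

test_that("upstroke traces place the inflection at the requested time", {
  up <- simulateUpstroke(tAct = 33, tau = 0.8, dt = 0.05)
  expect_equal(activationTime(up$v, up$time), 33, tolerance = 0.05)
  expect_error(simulateUpstroke(tAct = 500, duration = 100), "tAct")
})
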