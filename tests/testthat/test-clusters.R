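test_that("otsu threshold separates two-level and bimodal images", {
  x <- matrix(c(rep(0, 60), rep(100, 40)), 10, 10)
  t1 <- otsuThreshold(x)
  expect_gt(t1, 0); expect_lt(t1, 100)
  expect_error(otsuThreshold(matrix(5, 4, 4)), "degenerate")

  set.seed(11)
  gm <- c(rnorm(600, 30, 10), rnorm(400, 170, 10))
  gm <- pmin(pmax(round(gm), 0), 255)
  t2 <- otsuThreshold(matrix(gm, 40, 25))
  expect_gt(t2, 30); expect_lt(t2, 170)
})

test_that("otsu equals brute-force search and EBImage on 8-bit images", {
  set.seed(42)
  for (k in 1:10) {
    x <- matrix(sample(0:255, 400, replace = TRUE,
                       prob = runif(256)^2), 20, 20)
    thr <- otsuThreshold(x)
    expect_equal(thr, otsu_bruteforce(x))
    thrEB <- 255 * EBImage::otsu(EBImage::Image(x / 255),
                                 range = c(0, 1), levels = 256)
    expect_lt(abs(thr - thrEB), 2.5)   # bin-convention slack
  }
})

test_that("cluster segmentation matches closed forms and flood fill", {
  empty <- findClusters(matrix(FALSE, 16, 16), pixelSize = 10)
  expect_equal(nrow(empty@clusters), 0)

  mask <- matrix(FALSE, 20, 20)
  mask[6:10, 4:7] <- TRUE                       # 5 x 4 rectangle
  cs <- findClusters(mask, pixelSize = 10)
  expect_equal(nrow(cs@clusters), 1)
  expect_equal(cs@clusters$areaNm2, 2000)
  expect_equal(cs@clusters$cx, 8)
  expect_equal(cs@clusters$cy, 5.5)
  expect_equal(cs@clusters$eqDiameterNm, 2 * sqrt(2000 / pi))

  set.seed(3)
  rnd <- matrix(runif(128 * 128) < 0.2, 128, 128)
  for (conn in c(8, 4)) {
    got <- nrow(findClusters(rnd, connectivity = conn, pixelSize = 10)@clusters)
    expect_equal(got, floodfill_count(rnd, conn))
  }
  # diagonal pixels: one 8-connected cluster, two 4-connected
  dg <- matrix(FALSE, 5, 5); dg[2, 2] <- TRUE; dg[3, 3] <- TRUE
  expect_equal(nrow(findClusters(dg, 8, pixelSize = 1)@clusters), 1)
  expect_equal(nrow(findClusters(dg, 4, pixelSize = 1)@clusters), 2)
})

disc_mask <- function(dim, cx, cy, r) {
  m <- matrix(FALSE, dim[1], dim[2])
  ephapse:::raster_ellipse(m, cx, cy, r, r, 0)
}

test_that("perinexal association follows the edge-to-edge distance rule", {
  dm <- c(80, 200)
  cx43 <- findClusters(disc_mask(dm, 40, 40, 5), pixelSize = 10)

  # identical masks: everything overlaps
  rep0 <- associateClusters(cx43, cx43)
  expect_equal(rep0@summary$navOverlapFraction, 1)
  expect_equal(rep0@summary$cxOverlapFraction, 1)

  near <- findClusters(disc_mask(dm, 40, 40 + 5 + 15 + 5 + 1, 5),
                       pixelSize = 10)    # 15-px gap = 150 nm
  far <- findClusters(disc_mask(dm, 40, 40 + 5 + 25 + 5 + 1, 5),
                      pixelSize = 10)     # 25-px gap = 250 nm
  expect_equal(associateClusters(cx43, near)@navTable$class, "perinexal")
  expect_equal(associateClusters(cx43, far)@navTable$class, "distal")

  # distances agree with the distance-transform oracle
  cxm <- disc_mask(dm, 40, 40, 5)
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(1 - cxm)))
  nm <- disc_mask(dm, 40, 40 + 5 + 15 + 5 + 1, 5)
  expect_equal(associateClusters(cx43, near)@navTable$minEdgeDistanceNm,
               (min(d[nm]) - 1) * 10, tolerance = 1e-9)

  mism <- findClusters(disc_mask(dm, 40, 40, 5), pixelSize = 20)
  expect_error(associateClusters(cx43, mism), "calibration")
})

test_that("per-Cx43 partner counts populate the histograms", {
  dm <- c(120, 120)
  cxm <- disc_mask(dm, 60, 60, 5)
  nm <- disc_mask(dm, 60, 60 + 5 + 10 + 5 + 1, 5) |
    disc_mask(dm, 60, 60 - (5 + 10 + 5 + 1), 5)
  rep1 <- associateClusters(findClusters(cxm, pixelSize = 10),
                            findClusters(nm, pixelSize = 10))
  expect_equal(unname(rep1@summary$cxPerinexalHist), c(0, 0, 1))
  expect_equal(rep1@summary$medianPerinexalPartners, 2)
  expect_equal(rep1@summary$cxPerinexalFraction, 1)
  expect_equal(rep1@summary$navPerinexalFraction, 1)
})

test_that("widening the perinexal band never loses perinexal clusters", {
  img <- simulateLocalizationImages(nCx = 6, perinexalPerCx = 1,
                                    distalPerCx = 1, seed = 9,
                                    imageSize = c(900, 900))
  cx <- findClusters(img$cx43)
  nav <- findClusters(img$nav)
  fr <- vapply(c(50, 100, 200, 300, 500), function(w)
    associateClusters(cx, nav, w)@summary$navPerinexalFraction, 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("channel swap keeps the overlapping pair count symmetric", {
  img <- simulateLocalizationImages(nCx = 5, overlapPerCx = 1,
                                    perinexalPerCx = 1, seed = 21,
                                    imageSize = c(900, 900))
  cx <- findClusters(img$cx43)
  nav <- findClusters(img$nav)
  ab <- associateClusters(cx, nav)
  ba <- associateClusters(nav, cx)
  expect_equal(sum(ab@cxTable$nOverlapping), sum(ba@cxTable$nOverlapping))
  expect_equal(sum(ab@navTable$class == "overlapping") > 0,
               sum(ba@navTable$class == "overlapping") > 0)
})

test_that("summaries are consistent, serializable, and handle empties", {
  img <- simulateLocalizationImages(nCx = 4, perinexalPerCx = 1, seed = 5,
                                    imageSize = c(700, 700))
  cx <- findClusters(img$cx43)
  nav <- findClusters(img$nav)
  rep1 <- associateClusters(cx, nav)

  # fractions recomputed from the per-cluster classes match
  expect_equal(rep1@summary$navPerinexalFraction,
               mean(rep1@navTable$class == "perinexal"))
  tab <- summarizeAssociation(rep1)
  expect_equal(tab$value[tab$statistic == "nav_perinexal_fraction"],
               rep1@summary$navPerinexalFraction)

  f <- tempfile(fileext = ".json")
  writeAssociationReport(rep1, f)
  parsed <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(parsed$summary$navPerinexalFraction,
               rep1@summary$navPerinexalFraction)

  # empty Nav channel: undefined fractions, all Cx43 in histogram bin 0
  emptyNav <- findClusters(matrix(FALSE, cx@dim[1], cx@dim[2]),
                           pixelSize = cx@pixelSize)
  rep0 <- associateClusters(cx, emptyNav)
  expect_true(is.na(rep0@summary$navPerinexalFraction))
  expect_equal(unname(rep0@summary$cxPerinexalHist["0"]),
               nrow(cx@clusters))
})

test_that("calibrated images round-trip through TIFF", {
  img <- calibratedImage(matrix(runif(64), 8, 8), 10, "Cx43")
  f <- tempfile(fileext = ".tif")
  writeCalibratedImage(img, f)
  back <- readCalibratedImage(f, 10, "Cx43")
  expect_equal(dim(back@data), c(8, 8))
  expect_equal(back@data, img@data, tolerance = 0.01)
})
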