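test_that("membrane area bookkeeping is exact for any offset", {
  for (off in list(c(0, 0), c(0.5, 0.2), c(0.3, 0.1))) {
    cfg <- modelConfig(nRows = 2, nCols = 3, transverseOffset = off[1],
                       longitudinalOffset = off[2])
    mesh <- buildTissueSheet(cfg)
    s <- cfg@shape
    P <- 2 * s$length + 2 * s$width + 2 * off[2] * s$length
    expAreaCm2 <- nrow(mesh@cells) *
      (2 * s$length * s$width + P * s$depth) / 1e8
    expect_equal(unname(membraneAreas(mesh)["total"]), expAreaCm2,
                 tolerance = 1e-10)
    if (all(off == 0)) {
      brick <- nrow(mesh@cells) * 2 *
        (s$length * s$width + s$length * s$depth + s$width * s$depth) / 1e8
      expect_equal(unname(membraneAreas(mesh)["total"]), brick,
                   tolerance = 1e-10)
    }
    a <- membraneAreas(mesh)
    expect_lt(a["junctional"] / a["total"], 0.5)
  }
})

test_that("junctional membrane sits only at longitudinal cell ends", {
  mesh <- buildTissueSheet(modelConfig(nRows = 3, nCols = 4))
  j <- mesh@patches[mesh@patches$class == "junctional", ]
  expect_true(all(abs(j$nx) == 1 & j$ny == 0))
  expect_true(all(!is.na(j$neighborCell)))
})

test_that("interior cells interlock with two neighbours per end", {
  mesh <- buildTissueSheet(modelConfig(nRows = 3, nCols = 3))
  # an interior cell of the 3x3 sheet: (row 2, col 2)
  cid <- mesh@cells$id[mesh@cells$row == 2 & mesh@cells$col == 2]
  j <- mesh@junctions
  mine <- j[j$cellA == cid | j$cellB == cid, ]
  partner <- ifelse(mine$cellA == cid, mine$cellB, mine$cellA)
  side <- vapply(seq_len(nrow(mine)), function(k) {
    p <- mesh@patches[if (mine$cellA[k] == cid) mine$patchA[k] else
                        mine$patchB[k], ]
    p$nx
  }, 0)
  expect_equal(sum(side > 0), 2)             # two distinct cells per end
  expect_equal(sum(side < 0), 2)
  expect_equal(length(unique(partner[side > 0])), 2)
  expect_equal(length(unique(partner[side < 0])), 2)
})

test_that("degenerate sheets are handled: 1x1 and 2x1 aligned", {
  m1 <- buildTissueSheet(modelConfig(nRows = 1, nCols = 1))
  expect_equal(nrow(m1@junctions), 0)
  expect_true(all(m1@patches$class == "lateral"))

  cfg <- modelConfig(nRows = 1, nCols = 2, transverseOffset = 0,
                     longitudinalOffset = 0)
  m2 <- buildTissueSheet(cfg)
  expect_equal(nrow(m2@junctions), 1)
  expect_equal(m2@junctions$area,
               cfg@shape$width * cfg@shape$depth / 1e8, tolerance = 1e-10)
})

test_that("the lattice is translation invariant", {
  cfg <- modelConfig(nRows = 2, nCols = 3)
  a <- buildTissueSheet(cfg)
  b <- buildTissueSheet(cfg, origin = c(13.37, -7.7))
  expect_equal(sort(a@patches$area), sort(b@patches$area))
  expect_equal(nrow(a@junctions), nrow(b@junctions))
  expect_equal(sort(a@cleftEdges$G), sort(b@cleftEdges$G))
})

test_that("cleft conductances scale linearly with cleft width", {
  # single cell: every cleft segment is lateral, so doubling the lateral
  # width doubles every conductance exactly
  cfg <- modelConfig(nRows = 1, nCols = 1)
  mesh <- buildTissueSheet(cfg)
  ex2 <- cfg@extracellular
  ex2$lateralWidth <- 2 * ex2$lateralWidth
  mesh2 <- assembleCleftNetwork(mesh, ex2)
  expect_equal(mesh2@cleftEdges$G, 2 * mesh@cleftEdges$G,
               tolerance = 1e-12)

  # mixed network: every conductance touching a lateral segment increases
  cfgM <- modelConfig(nRows = 2, nCols = 3)
  meshM <- buildTissueSheet(cfgM)
  meshM2 <- assembleCleftNetwork(meshM, ex2)
  expect_true(all(meshM2@cleftEdges$G >= meshM@cleftEdges$G - 1e-15))
})

test_that("edema conductivities raise every cleft conductance", {
  cfg <- modelConfig(nRows = 2, nCols = 3)
  ctrl <- buildTissueSheet(cfg)
  aie <- assembleCleftNetwork(ctrl, list(
    junctionalWidth = 15, lateralWidth = 0.1,
    sigmaEffLateral = 203.5, sigmaEffJunctional = 62.8))
  expect_true(all(aie@cleftEdges$G > ctrl@cleftEdges$G))
})

test_that("cleft network reduction matches a dense circuit oracle", {
  cfg <- modelConfig(nRows = 1, nCols = 2, transverseOffset = 0,
                     longitudinalOffset = 0)
  mesh <- buildTissueSheet(cfg)
  cn <- mesh@cleftNodes
  from <- cn$id[cn$type == "lateral"][1]
  to <- cn$id[cn$type == "junctional"][1]
  # implementation-side effective resistance from the reduced network
  n <- nrow(cn)
  ed <- mesh@cleftEdges
  L <- matrix(0, n, n)
  for (k in seq_len(nrow(ed))) {
    a <- ed$a[k]; b <- ed$b[k]; g <- ed$G[k]
    L[a, b] <- L[a, b] - g; L[b, a] <- L[b, a] - g
    L[a, a] <- L[a, a] + g; L[b, b] <- L[b, b] + g
  }
  I <- numeric(n); I[from] <- 1; I[to] <- -1
  keep <- setdiff(seq_len(n), to)
  phi <- numeric(n); phi[keep] <- solve(L[keep, keep], I[keep])
  Rimpl <- phi[from] - phi[to]
  Roracle <- cleft_resistance_oracle(mesh, from, to)
  expect_equal(Rimpl, Roracle, tolerance = 1e-8)
})

test_that("mesh construction rejects invalid configurations", {
  expect_error(modelConfig(cellLength = -1), "positive")
  expect_error(modelConfig(cellLength = 20, cellWidth = 24.1), "exceed")
  expect_error(modelConfig(transverseOffset = 1.2), "offsets")
})

test_that("meshes serialize to JSON and configs round-trip through YAML", {
  cfg <- modelConfig(nRows = 1, nCols = 2, gjBar = 73.5)
  mesh <- buildTissueSheet(cfg)
  fj <- tempfile(fileext = ".json")
  exportMeshJSON(mesh, fj)
  parsed <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(nrow(parsed$patches), nrow(mesh@patches))

  fy <- tempfile(fileext = ".yaml")
  writeModelConfig(cfg, fy)
  cfg2 <- readModelConfig(fy)
  expect_equal(cfg2@gapJunction$gjBar, 73.5)
  expect_equal(cfg2@shape, cfg@shape)
})
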