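# Mesh construction for the microdomain sheet model.
#
# Cells are rectangular prisms (length x width x depth) whose footprints
# interlock in a running bond: the end face of each cell steps at
# transverseOffset * width, and the two halves of the face are staggered by
# longitudinalOffset * length, so with nonzero offsets an interior cell's
# end abuts two longitudinal neighbours. The sheet is isopotential in the
# out-of-plane direction; depth only scales areas.
#
# The extracellular space has two levels: the in-plane cleft network (one
# node per cleft segment between facing membranes) and a bulk interstitial
# compartment surrounding the monolayer. The out-of-plane cap membrane of
# each cell faces the bulk, and every cleft segment drains into the bulk
# through its out-of-plane edges, so the narrow clefts form microdomains
# against a well-perfused interstitium. The bulk node is the potential
# reference (gauge).

UM_PER_CM <- 1e4
round_key <- function(x) round(x, 6)

# footprints: one or two axis-aligned rectangles per cell
build_footprints <- function(shape, layout, origin = c(0, 0)) {
  L <- shape$length; W <- shape$width
  t <- layout$transverseOffset; e <- layout$longitudinalOffset
  nr <- layout$nRows; nc <- layout$nCols
  out <- vector("list", nr * nc)
  i <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    i <- i + 1L
    if (t == 0) {
      x0 <- (c - 1) * L + ((r - 1) %% 2) * e * L + origin[1]
      y0 <- (r - 1) * W + origin[2]
      rects <- matrix(c(x0, x0 + L, y0, y0 + W), 1, 4)
    } else {
      p <- (c - 1) %% 2
      k <- 2 * (r - 1) + p
      m <- (c - 1) %/% 2
      a_k <- (k * (e - 1) * L) %% (2 * L)
      x0 <- a_k + 2 * m * L + origin[1]
      bk <- (k %/% 2) * W + (k %% 2) * t * W + origin[2]
      h_lo <- if (k %% 2 == 0) t * W else (1 - t) * W
      rects <- rbind(
        c(x0, x0 + L, bk, bk + h_lo),
        c(x0 + e * L, x0 + e * L + L, bk + h_lo, bk + W))
    }
    out[[i]] <- cbind(cell = i, rect = seq_len(nrow(rects)), rects)
  }
  fp <- as.data.frame(do.call(rbind, out))
  names(fp) <- c("cell", "rect", "x1", "x2", "y1", "y2")
  fp
}

# intracellular corner nodes: unique rect corners per cell
build_nodes <- function(fp) {
  pts <- rbind(
    data.frame(cell = fp$cell, x = fp$x1, y = fp$y1),
    data.frame(cell = fp$cell, x = fp$x2, y = fp$y1),
    data.frame(cell = fp$cell, x = fp$x2, y = fp$y2),
    data.frame(cell = fp$cell, x = fp$x1, y = fp$y2))
  key <- paste(pts$cell, round_key(pts$x), round_key(pts$y))
  pts <- pts[!duplicated(key), ]
  pts <- pts[order(pts$cell, pts$x, pts$y), ]
  pts$id <- seq_len(nrow(pts))
  rownames(pts) <- NULL
  pts[, c("id", "cell", "x", "y")]
}

node_lookup <- function(nodes) {
  setNames(nodes$id, paste(nodes$cell, round_key(nodes$x), round_key(nodes$y)))
}

# fan triangulation of each (convex) rectangle using the cell's nodes that
# lie on its boundary; degenerate (collinear) fan triangles are skipped
build_triangles <- function(fp, nodes) {
  tris <- list()
  for (i in seq_len(nrow(fp))) {
    r <- fp[i, ]
    cn <- nodes[nodes$cell == r$cell, ]
    on_bnd <- (abs(cn$x - r$x1) < 1e-9 | abs(cn$x - r$x2) < 1e-9 |
               abs(cn$y - r$y1) < 1e-9 | abs(cn$y - r$y2) < 1e-9) &
              cn$x >= r$x1 - 1e-9 & cn$x <= r$x2 + 1e-9 &
              cn$y >= r$y1 - 1e-9 & cn$y <= r$y2 + 1e-9
    b <- cn[on_bnd, ]
    cx <- (r$x1 + r$x2) / 2; cy <- (r$y1 + r$y2) / 2
    ang <- atan2(b$y - cy, b$x - cx)
    b <- b[order(ang), ]
    n <- nrow(b)
    for (j in 2:(n - 1)) {
      p1 <- b[1, ]; p2 <- b[j, ]; p3 <- b[j + 1, ]
      a2 <- (p2$x - p1$x) * (p3$y - p1$y) - (p3$x - p1$x) * (p2$y - p1$y)
      if (abs(a2) > 1e-9)
        tris[[length(tris) + 1]] <- c(r$cell, p1$id, p2$id, p3$id)
    }
  }
  out <- as.data.frame(do.call(rbind, tris))
  names(out) <- c("cell", "n1", "n2", "n3")
  out
}

# directed boundary edges of every rect, with outward normals
rect_edges <- function(fp) {
  e <- rbind(
    data.frame(cell = fp$cell, axis = "h", fixed = fp$y1, lo = fp$x1,
               hi = fp$x2, nrm = -1),
    data.frame(cell = fp$cell, axis = "h", fixed = fp$y2, lo = fp$x1,
               hi = fp$x2, nrm = +1),
    data.frame(cell = fp$cell, axis = "v", fixed = fp$x1, lo = fp$y1,
               hi = fp$y2, nrm = -1),
    data.frame(cell = fp$cell, axis = "v", fixed = fp$x2, lo = fp$y1,
               hi = fp$y2, nrm = +1))
  e$edge <- seq_len(nrow(e))
  e
}

# split each edge into maximal intervals by facing partner (other cell,
# same cell interior, or sheet boundary)
split_edges <- function(edges) {
  out <- list()
  grp <- split(seq_len(nrow(edges)),
               paste(edges$axis, round_key(edges$fixed)))
  for (idx in grp) {
    sub <- edges[idx, ]
    for (i in seq_len(nrow(sub))) {
      E <- sub[i, ]
      opp <- sub[sub$nrm == -E$nrm, , drop = FALSE]
      cuts <- list()
      if (nrow(opp)) {
        lo <- pmax(E$lo, opp$lo); hi <- pmin(E$hi, opp$hi)
        keep <- hi - lo > 1e-9
        if (any(keep))
          cuts <- lapply(which(keep), function(j)
            c(lo = lo[j], hi = hi[j], cell = opp$cell[j], edge = opp$edge[j]))
      }
      segs <- if (length(cuts)) do.call(rbind, cuts) else
        matrix(numeric(0), 0, 4, dimnames = list(NULL, c("lo", "hi", "cell", "edge")))
      segs <- segs[order(segs[, "lo"]), , drop = FALSE]
      pos <- E$lo
      ints <- list()
      addint <- function(lo, hi, pcell, pedge) {
        if (hi - lo > 1e-9)
          ints[[length(ints) + 1]] <<- data.frame(
            cell = E$cell, axis = E$axis, fixed = E$fixed, lo = lo, hi = hi,
            nrm = E$nrm, edge = E$edge, partnerCell = pcell,
            partnerEdge = pedge)
      }
      if (nrow(segs)) for (j in seq_len(nrow(segs))) {
        addint(pos, segs[j, "lo"], NA, NA)
        addint(segs[j, "lo"], segs[j, "hi"], segs[j, "cell"], segs[j, "edge"])
        pos <- segs[j, "hi"]
      }
      addint(pos, E$hi, NA, NA)
      out <- c(out, ints)
    }
  }
  res <- do.call(rbind, out)
  # same-cell contacts are interior (the step line inside a cell): drop
  res[is.na(res$partnerCell) | res$partnerCell != res$cell, ]
}

# integral of the piecewise-linear nodal basis over [a, b] on an edge whose
# nodes sit at positions s (sorted); returns weights summing to 1
edge_weights <- function(s, a, b) {
  w <- numeric(length(s))
  for (j in seq_len(length(s) - 1)) {
    u <- max(a, s[j]); v <- min(b, s[j + 1])
    if (v - u <= 0) next
    h <- s[j + 1] - s[j]
    # mean of hat_j and hat_{j+1} over [u, v], times (v - u)
    phi_j_u <- (s[j + 1] - u) / h; phi_j_v <- (s[j + 1] - v) / h
    w[j] <- w[j] + (phi_j_u + phi_j_v) / 2 * (v - u)
    w[j + 1] <- w[j + 1] + (1 - (phi_j_u + phi_j_v) / 2) * (v - u)
  }
  w / (b - a)
}

#' Build the discretized myocyte sheet
#'
#' Constructs the \code{\link{TissueMesh}} for a configuration: interlocking
#' brick footprints, intracellular corner nodes and triangulation, membrane
#' patches (lateral vs junctional, with the out-of-plane cap membrane
#' apportioned to the lateral patches), gap-junction interfaces at
#' end-to-end contacts, and the extracellular cleft network with
#' conductances from \code{\link{assembleCleftNetwork}}.
#'
#' @param config a \code{\link{ModelConfig}}.
#' @param origin translation applied to the whole lattice (um); mesh
#'   topology, areas and conductances are invariant to it.
#' @return a validated \code{\link{TissueMesh}}.
#' @examples
#' mesh <- buildTissueSheet(modelConfig(nRows = 2, nCols = 2))
#' mesh
#' @export
buildTissueSheet <- function(config, origin = c(0, 0)) {
  methods::validObject(config)
  shape <- config@shape; layout <- config@layout
  D_cm <- shape$depth / UM_PER_CM

  fp <- build_footprints(shape, layout, origin)
  nodes <- build_nodes(fp)
  tri <- build_triangles(fp, nodes)
  look <- node_lookup(nodes)

  ints <- split_edges(rect_edges(fp))

  # cleft segment per unique facing interval (shared ones appear twice)
  ckey <- paste(ints$axis, round_key(ints$fixed), round_key(ints$lo),
                round_key(ints$hi))
  shared <- !is.na(ints$partnerCell)
  useg <- !duplicated(ckey)
  cleft <- data.frame(
    key = ckey[useg], axis = ints$axis[useg], fixed = ints$fixed[useg],
    lo = ints$lo[useg], hi = ints$hi[useg],
    type = ifelse(ints$axis[useg] == "v" & shared[useg],
                  "junctional", "lateral"))
  cleft$id <- seq_len(nrow(cleft))
  cleft$len <- cleft$hi - cleft$lo
  cleft$x <- ifelse(cleft$axis == "v", cleft$fixed, (cleft$lo + cleft$hi) / 2)
  cleft$y <- ifelse(cleft$axis == "v", (cleft$lo + cleft$hi) / 2, cleft$fixed)
  cleft_of <- setNames(cleft$id, cleft$key)
  bathId <- nrow(cleft) + 1L   # bulk interstitial node, appended below

  # membrane patches
  edges <- rect_edges(fp)
  np <- nrow(ints)
  n1 <- n2 <- n3 <- rep(NA_integer_, np)
  w1 <- w2 <- w3 <- rep(NA_real_, np)
  for (i in seq_len(np)) {
    E <- ints[i, ]
    cn <- nodes[nodes$cell == E$cell, ]
    if (E$axis == "v") {
      full <- edges[E$edge, ]
      on <- cn[abs(cn$x - E$fixed) < 1e-9 & cn$y >= full$lo - 1e-9 &
               cn$y <= full$hi + 1e-9, ]
      on <- on[order(on$y), ]
      w <- edge_weights(on$y, E$lo, E$hi)
    } else {
      full <- edges[E$edge, ]
      on <- cn[abs(cn$y - E$fixed) < 1e-9 & cn$x >= full$lo - 1e-9 &
               cn$x <= full$hi + 1e-9, ]
      on <- on[order(on$x), ]
      w <- edge_weights(on$x, E$lo, E$hi)
    }
    keep <- which(w > 1e-12)
    if (length(keep) > 3) {           # keep the 3 largest, renormalize
      keep <- keep[order(w[keep], decreasing = TRUE)][1:3]
    }
    ww <- w[keep] / sum(w[keep])
    n1[i] <- on$id[keep[1]]; w1[i] <- ww[1]
    if (length(keep) > 1) { n2[i] <- on$id[keep[2]]; w2[i] <- ww[2] }
    if (length(keep) > 2) { n3[i] <- on$id[keep[3]]; w3[i] <- ww[3] }
  }

  len_um <- ints$hi - ints$lo
  patches <- data.frame(
    id = seq_len(np), cell = ints$cell,
    class = ifelse(ints$axis == "v" & !is.na(ints$partnerCell),
                   "junctional", "lateral"),
    neighborCell = ints$partnerCell,
    cleft = unname(cleft_of[ckey]),
    n1 = n1, n2 = n2, n3 = n3, w1 = w1, w2 = w2, w3 = w3,
    nx = ifelse(ints$axis == "v", ints$nrm, 0),
    ny = ifelse(ints$axis == "h", ints$nrm, 0),
    midX = ifelse(ints$axis == "v", ints$fixed, (ints$lo + ints$hi) / 2),
    midY = ifelse(ints$axis == "v", (ints$lo + ints$hi) / 2, ints$fixed),
    lenUm = len_um,
    sideArea = len_um / UM_PER_CM * D_cm)
  patches$neighborCell[patches$class != "junctional"] <- NA

  patches$area <- patches$sideArea

  # out-of-plane cap membrane (top + bottom footprint faces): one patch per
  # intracellular triangle (area-lumped on its vertices), facing the bulk
  # interstitial node
  triA <- vapply(seq_len(nrow(tri)), function(k) {
    n <- c(tri$n1[k], tri$n2[k], tri$n3[k])
    x <- nodes$x[n]; y <- nodes$y[n]
    abs(x[1] * (y[2] - y[3]) + x[2] * (y[3] - y[1]) +
          x[3] * (y[1] - y[2])) / 2
  }, 0)
  caps <- data.frame(
    id = NA_integer_, cell = tri$cell, class = "lateral",
    neighborCell = NA, cleft = bathId,
    n1 = tri$n1, n2 = tri$n2, n3 = tri$n3,
    w1 = 1 / 3, w2 = 1 / 3, w3 = 1 / 3,
    nx = 0, ny = 0,
    midX = NA_real_, midY = NA_real_, lenUm = NA_real_,
    sideArea = 0, area = 2 * triA / UM_PER_CM^2)
  patches <- rbind(patches, caps)
  patches$id <- seq_len(nrow(patches))

  # gap-junction interfaces: the two patches of each junctional cleft node
  jp <- patches[patches$class == "junctional", ]
  junctions <- data.frame(id = integer(), cellA = integer(),
                          cellB = integer(), patchA = integer(),
                          patchB = integer(), area = numeric())
  if (nrow(jp)) {
    bycleft <- split(jp, jp$cleft)
    junctions <- do.call(rbind, lapply(bycleft, function(g) {
      stopifnot(nrow(g) == 2)
      data.frame(cellA = g$cell[1], cellB = g$cell[2],
                 patchA = g$id[1], patchB = g$id[2], area = g$sideArea[1])
    }))
    junctions$id <- seq_len(nrow(junctions))
    rownames(junctions) <- NULL
  }

  cells <- do.call(rbind, lapply(split(fp, fp$cell), function(g) {
    a <- (g$x2 - g$x1) * (g$y2 - g$y1)
    data.frame(id = g$cell[1],
               cx = sum((g$x1 + g$x2) / 2 * a) / sum(a),
               cy = sum((g$y1 + g$y2) / 2 * a) / sum(a),
               footprint = sum(a))
  }))
  cells$row <- (cells$id - 1) %/% layout$nCols + 1
  cells$col <- (cells$id - 1) %% layout$nCols + 1
  rownames(cells) <- NULL

  cleftNodes <- cleft[, c("id", "type", "axis", "fixed", "lo",
                          "hi", "len", "x", "y")]
  cleftNodes <- rbind(cleftNodes,
                      data.frame(id = bathId, type = "bath", axis = "",
                                 fixed = NA_real_, lo = NA_real_,
                                 hi = NA_real_, len = NA_real_,
                                 x = NA_real_, y = NA_real_))
  mesh <- new("TissueMesh", cells = cells, nodes = nodes, triangles = tri,
              patches = patches, cleftNodes = cleftNodes,
              cleftEdges = data.frame(a = integer(), b = integer(),
                                      G = numeric()),
              junctions = junctions, shape = shape, layout = layout,
              extracellular = config@extracellular,
              gapJunction = config@gapJunction)
  assembleCleftNetwork(mesh, config@extracellular)
}

#' Assemble (or re-assemble) the extracellular cleft network
#'
#' Computes the inter-node conductances of the cleft network. Each cleft
#' segment carries a half-segment conductance
#' \eqn{G = \sigma_{eff} \, w \, D / (\ell/2)} toward each of its endpoints
#' (junctional segments use the junctional width and conductivity, lateral
#' segments the lateral ones); where several half-segments meet at a point
#' the star is reduced exactly to its equivalent mesh (Kron reduction), so
#' the assembled network has one node per cleft segment. Re-running with new
#' extracellular parameters (e.g. edema) rescales the conductances without
#' rebuilding the mesh.
#'
#' @param mesh a \code{\link{TissueMesh}}.
#' @param extracellular extracellular parameter list; defaults to the one
#'   stored in the mesh.
#' @return the mesh with updated \code{cleftEdges} (and stored parameters).
#' @export
assembleCleftNetwork <- function(mesh, extracellular = NULL) {
  ex <- if (is.null(extracellular)) mesh@extracellular else extracellular
  cnAll <- mesh@cleftNodes
  bath <- cnAll$id[cnAll$type == "bath"]
  cn <- cnAll[cnAll$type != "bath", ]
  D_cm <- mesh@shape$depth / UM_PER_CM
  w_cm <- ifelse(cn$type == "junctional",
                 ex$junctionalWidth * 1e-7,      # nm -> cm
                 ex$lateralWidth / UM_PER_CM)    # um -> cm
  sig <- ifelse(cn$type == "junctional",
                ex$sigmaEffJunctional, ex$sigmaEffLateral)
  half_len_cm <- cn$len / 2 / UM_PER_CM
  Ghalf <- sig * w_cm * D_cm / half_len_cm       # mS

  # endpoints of each segment
  ex1 <- ifelse(cn$axis == "v", cn$fixed, cn$lo)
  ey1 <- ifelse(cn$axis == "v", cn$lo, cn$fixed)
  ex2 <- ifelse(cn$axis == "v", cn$fixed, cn$hi)
  ey2 <- ifelse(cn$axis == "v", cn$hi, cn$fixed)
  pts <- data.frame(node = rep(cn$id, 2), G = rep(Ghalf, 2),
                    key = c(paste(round_key(ex1), round_key(ey1)),
                            paste(round_key(ex2), round_key(ey2))))
  edges <- list()
  for (g in split(pts, pts$key)) {
    if (nrow(g) < 2) next
    Gs <- sum(g$G)
    for (i in 1:(nrow(g) - 1)) for (j in (i + 1):nrow(g)) {
      edges[[length(edges) + 1]] <-
        c(a = g$node[i], b = g$node[j], G = g$G[i] * g$G[j] / Gs)
    }
  }
  # each cleft segment drains into the bulk interstitium through its two
  # out-of-plane edges (path length depth/2, cross-section width x length)
  len_cm <- cn$len / UM_PER_CM
  Gbath <- 4 * sig * w_cm * len_cm / D_cm
  if (length(bath))
    for (i in seq_len(nrow(cn)))
      edges[[length(edges) + 1]] <- c(a = cn$id[i], b = bath, G = Gbath[i])

  ed <- as.data.frame(do.call(rbind, edges))
  # merge parallel edges between the same node pair
  k <- paste(pmin(ed$a, ed$b), pmax(ed$a, ed$b))
  ed <- data.frame(a = pmin(ed$a, ed$b)[!duplicated(k)],
                   b = pmax(ed$a, ed$b)[!duplicated(k)],
                   G = as.numeric(tapply(ed$G, k, sum)[unique(k)]))

  # connectivity check (breadth-first search)
  n <- nrow(cnAll)
  adj <- split(c(ed$b, ed$a), c(ed$a, ed$b))
  seen <- logical(n); queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[as.character(v)]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  if (!all(seen))
    stop("extracellular cleft network is disconnected")

  mesh@cleftEdges <- ed
  mesh@extracellular <- ex
  methods::validObject(mesh)
  mesh
}

#' Membrane area bookkeeping
#'
#' Sums patch areas by class. The total equals the analytic prism surface
#' \eqn{2A + P D} of the footprint; at zero offsets this is exactly the
#' plain-brick value \eqn{2(LW + LD + WD)} per cell.
#'
#' @param mesh a \code{\link{TissueMesh}}.
#' @return named numeric: lateral, junctional, and total membrane area (cm2).
#' @export
membraneAreas <- function(mesh) {
  p <- mesh@patches
  lat <- sum(p$area[p$class == "lateral"])
  jun <- sum(p$area[p$class == "junctional"])
  c(lateral = lat, junctional = jun, total = lat + jun)
}

#' Serialize a mesh to JSON for inspection
#'
#' @param mesh a \code{\link{TissueMesh}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
exportMeshJSON <- function(mesh, path) {
  jsonlite::write_json(
    list(cells = mesh@cells, nodes = mesh@nodes,
         patches = mesh@patches, cleftNodes = mesh@cleftNodes,
         cleftEdges = mesh@cleftEdges, junctions = mesh@junctions,
         shape = mesh@shape, layout = mesh@layout,
         extracellular = mesh@extracellular,
         gapJunction = mesh@gapJunction),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @describeIn buildTissueSheet mesh summary printout
#' @param object a \code{TissueMesh}
#' @export
setMethod("show", "TissueMesh", function(object) {
  a <- membraneAreas(object)
  cat(sprintf("TissueMesh: %d cells (%d x %d), %d intracellular nodes\n",
              nrow(object@cells), object@layout$nRows, object@layout$nCols,
              nrow(object@nodes)))
  cat(sprintf("  %d membrane patches (%d junctional), %d gap-junction interfaces\n",
              nrow(object@patches),
              sum(object@patches$class == "junctional"),
              nrow(object@junctions)))
  cat(sprintf("  %d cleft nodes, %d cleft conductances\n",
              nrow(object@cleftNodes), nrow(object@cleftEdges)))
  cat(sprintf("  membrane area: %.3g cm2 total, junctional fraction %.3f\n",
              a["total"], a["junctional"] / a["total"]))
})
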