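# Coupled intracellular/extracellular solver.
#
# Unknowns are the intracellular corner-node potentials phi_i (per cell,
# linear triangular finite elements for Laplace's equation, scaled by
# sigma_i * depth) and the extracellular cleft-node potentials phi_e
# (cell-centered finite differences on the cleft network). Membrane patches
# tie the two through the capacitive + ionic transmembrane current; gap
# junctions tie the intracellular potentials of end-to-end neighbours.
#
# Time discretization is Crank-Nicolson on the conductive terms with the
# ionic current evaluated at the start-of-step voltage and gating frozen
# within the step (advanced by Rush-Larsen between steps), so the system
# matrix is constant and its sparse Cholesky factorization is reused for
# every step.

triangle_stiffness <- function(x, y) {
  b <- c(y[2] - y[3], y[3] - y[1], y[1] - y[2])
  cc <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1])
  A2 <- abs(x[1] * (y[2] - y[3]) + x[2] * (y[3] - y[1]) +
              x[3] * (y[1] - y[2]))
  (outer(b, b) + outer(cc, cc)) / (2 * A2)
}

patch_weight_list <- function(patches) {
  lapply(seq_len(nrow(patches)), function(i) {
    n <- c(patches$n1[i], patches$n2[i], patches$n3[i])
    w <- c(patches$w1[i], patches$w2[i], patches$w3[i])
    keep <- !is.na(n)
    list(nodes = n[keep], w = w[keep])
  })
}

#' Assemble the discrete operators of the microdomain model
#'
#' Builds the sparse conductance matrix (intracellular stiffness +
#' gap-junction coupling + extracellular cleft Laplacian), the membrane
#' incidence operator mapping node potentials to patch voltages
#' \eqn{V_p = \phi_i(p) - \phi_e(p)}, patch capacitances, and the per-patch
#' sodium conductances, and caches the Crank-Nicolson factorization.
#'
#' @param mesh a \code{\link{TissueMesh}}.
#' @param config a \code{\link{ModelConfig}} (membrane, ionic, distribution
#'   and solver settings are used; extracellular/gap-junction parameters are
#'   taken from the mesh so interventions re-assemble consistently).
#' @param dt time step used for the cached factorization; defaults to the
#'   config's.
#' @return a list of operators (class \code{"ephapseSystem"}).
#' @export
assembleSystem <- function(mesh, config, dt = config@solver$dt) {
  p <- mesh@patches
  nI <- nrow(mesh@nodes)
  nE <- nrow(mesh@cleftNodes)
  N <- nI + nE
  sigD <- config@membrane$sigmaI * mesh@shape$depth / UM_PER_CM

  # intracellular FEM stiffness (block per cell)
  tri <- mesh@triangles
  ii <- jj <- integer(9 * nrow(tri)); vv <- numeric(9 * nrow(tri))
  pos <- 0L
  X <- mesh@nodes$x; Y <- mesh@nodes$y
  for (k in seq_len(nrow(tri))) {
    n <- c(tri$n1[k], tri$n2[k], tri$n3[k])
    Kl <- sigD * triangle_stiffness(X[n], Y[n])
    ii[pos + 1:9] <- rep(n, 3)
    jj[pos + 1:9] <- rep(n, each = 3)
    vv[pos + 1:9] <- as.vector(Kl)
    pos <- pos + 9L
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(N, N))

  # gap-junction coupling: G * (e_a - e_b)(e_a - e_b)^T on patch weights
  wl <- patch_weight_list(p)
  jn <- mesh@junctions
  if (nrow(jn)) {
    gi <- list(); gj <- list(); gv <- list()
    for (k in seq_len(nrow(jn))) {
      pf <- mesh@gapJunction$plaqueFraction
      if (is.null(pf)) pf <- 1
      G <- mesh@gapJunction$gjBar * pf * jn$area[k]
      if (G == 0) next
      a <- wl[[jn$patchA[k]]]; b <- wl[[jn$patchB[k]]]
      nod <- c(a$nodes, b$nodes)
      e <- c(a$w, -b$w)
      gi[[length(gi) + 1]] <- rep(nod, length(nod))
      gj[[length(gj) + 1]] <- rep(nod, each = length(nod))
      gv[[length(gv) + 1]] <- G * as.vector(outer(e, e))
    }
    if (length(gi))
      K <- K + Matrix::sparseMatrix(i = unlist(gi), j = unlist(gj),
                                    x = unlist(gv), dims = c(N, N))
  }

  # extracellular cleft Laplacian
  ed <- mesh@cleftEdges
  a <- ed$a + nI; b <- ed$b + nI
  Le <- Matrix::sparseMatrix(
    i = c(a, b, a, b), j = c(b, a, a, b),
    x = c(-ed$G, -ed$G, ed$G, ed$G), dims = c(N, N))
  S <- K + Le

  # membrane incidence: V_patch = B u
  nP <- nrow(p)
  bi <- list(); bj <- list(); bx <- list()
  for (k in seq_len(nP)) {
    w <- wl[[k]]
    bi[[k]] <- rep(k, length(w$nodes) + 1)
    bj[[k]] <- c(w$nodes, nI + p$cleft[k])
    bx[[k]] <- c(w$w, -1)
  }
  B <- Matrix::sparseMatrix(i = unlist(bi), j = unlist(bj), x = unlist(bx),
                            dims = c(nP, N))
  Cp <- config@membrane$Cm * p$area            # uF per patch
  M <- Matrix::crossprod(B, (Cp / dt) * B)     # B' diag(C/dt) B

  Afull <- Matrix::forceSymmetric(S / 2 + M)
  bath <- mesh@cleftNodes$id[mesh@cleftNodes$type == "bath"]
  ref <- nI + if (length(bath)) bath[1] else 1L   # gauge: bulk interstitium
  free <- setdiff(seq_len(N), ref)
  chol <- Matrix::Cholesky(Afull[free, free], LDL = FALSE, perm = TRUE)

  gNa <- partitionChannels(mesh, config@distribution$junctionalFraction,
                           config@ionic$gNa)

  # cell aggregation of patch voltages (area-weighted)
  agg <- Matrix::sparseMatrix(
    i = p$cell, j = seq_len(nP),
    x = p$area / as.numeric(tapply(p$area, p$cell, sum))[p$cell],
    dims = c(nrow(mesh@cells), nP))

  structure(list(mesh = mesh, config = config, dt = dt, N = N, nI = nI,
                 nE = nE, S = S, B = B, Bt = Matrix::t(B), M = M,
                 R = M - S / 2, Afull = Afull, chol = chol, free = free,
                 ref = ref, Cp = Cp, area = p$area, gNa = gNa, agg = agg),
            class = "ephapseSystem")
}

#' Run a stimulus protocol on the microdomain model
#'
#' Paces the sheet from one edge (the left cell column for longitudinal
#' runs, the bottom cell row for transverse runs) with a transmembrane
#' current pulse and advances the coupled system with Crank-Nicolson steps.
#' The run stops early once every cell has activated (plus a short margin)
#' or at the configured duration.
#'
#' @param config a \code{\link{ModelConfig}}.
#' @param direction \code{"longitudinal"} or \code{"transverse"}; selects
#'   the stimulated edge.
#' @param mesh optional prebuilt \code{\link{TissueMesh}}.
#' @param system optional prebuilt operator set from
#'   \code{\link{assembleSystem}} (reused across runs that share all
#'   parameters, e.g. the two directions of one conduction-velocity
#'   estimate).
#' @param stimulusCells optional explicit cell ids to stimulate (overrides
#'   the edge selection).
#' @param recordEvery record the voltage every this many steps.
#' @return a \code{\link{SimulationResult}}.
#' @export
runProtocol <- function(config, direction = c("longitudinal", "transverse"),
                        mesh = NULL, system = NULL, stimulusCells = NULL,
                        recordEvery = 1L) {
  direction <- match.arg(direction)
  if (is.null(system)) {
    if (is.null(mesh)) mesh <- buildTissueSheet(config)
    system <- assembleSystem(mesh, config)
  }
  mesh <- system$mesh
  cells <- mesh@cells
  if (is.null(stimulusCells)) {
    stimulusCells <- if (direction == "longitudinal")
      cells$id[cells$col == 1] else cells$id[cells$row == 1]
  }
  ionic <- config@ionic
  dt <- system$dt
  sv <- config@solver
  nSteps <- if (is.na(sv$duration)) ceiling(sv$maxDuration / dt)
            else ceiling(sv$duration / dt)
  autoStop <- is.na(sv$duration)

  p <- mesh@patches
  stimPatch <- p$cell %in% stimulusCells
  stimStart <- 0.05
  stimEnd <- stimStart + sv$stimDuration

  Vr <- resting_potential(ionic)
  u <- numeric(system$N)
  u[seq_len(system$nI)] <- Vr
  g0 <- gatingSteadyState(Vr)
  state <- list(m = rep(g0$mInf, nrow(p)), h = rep(g0$hInf, nrow(p)))

  nRec <- nSteps %/% recordEvery + 1L
  traces <- matrix(NA_real_, nrow(cells), nRec)
  tRec <- numeric(nRec)
  Vp <- as.numeric(system$B %*% u)
  traces[, 1] <- as.numeric(system$agg %*% Vp)
  tRec[1] <- 0
  iRec <- 1L

  activatedMargin <- 0L
  maxResidual <- 0
  B <- system$B; Bt <- system$Bt; R <- system$R
  free <- system$free
  lastStep <- nSteps
  for (n in seq_len(nSteps)) {
    t0 <- (n - 1) * dt
    Vp <- as.numeric(B %*% u)
    if (ionic$type == "hh") state <- stepGating(state, Vp, dt)
    Iion <- ionicCurrent(Vp, state, ionic, system$gNa)
    if (t0 >= stimStart && t0 < stimEnd)
      Iion[stimPatch] <- Iion[stimPatch] - sv$stimAmplitude
    Ip <- system$area * Iion
    rhs <- as.numeric(R %*% u) - as.numeric(Bt %*% Ip)
    uNew <- numeric(system$N)
    uNew[free] <- as.numeric(Matrix::solve(system$chol, rhs[free],
                                           system = "A"))
    if (n %% 50 == 0) {
      res <- as.numeric(system$Afull %*% uNew) - rhs
      maxResidual <- max(maxResidual,
                         max(abs(res[free])) / max(1, max(abs(rhs[free]))))
    }
    u <- uNew
    if (n %% recordEvery == 0) {
      iRec <- iRec + 1L
      Vp <- as.numeric(B %*% u)
      traces[, iRec] <- as.numeric(system$agg %*% Vp)
      tRec[iRec] <- n * dt
    }
    if (autoStop && n %% 100 == 0) {
      vmax <- apply(traces[, seq_len(iRec), drop = FALSE], 1, max)
      if (all(vmax > -20)) {
        activatedMargin <- activatedMargin + 1L
        if (activatedMargin >= 2) { lastStep <- n; break }
      }
    }
  }
  traces <- traces[, seq_len(iRec), drop = FALSE]
  tRec <- tRec[seq_len(iRec)]

  distal <- if (direction == "longitudinal")
    cells$id[cells$col == max(cells$col)] else
    cells$id[cells$row == max(cells$row)]
  vmax <- apply(traces, 1, max)
  blocked <- any(vmax[cells$id %in% distal] < -20)

  new("SimulationResult", time = tRec, traces = traces,
      cells = cells, direction = direction, blocked = blocked,
      config = config,
      meta = list(stimulusCells = stimulusCells, steps = lastStep, dt = dt,
                  restingPotential = Vr, maxRelativeResidual = maxResidual))
}

#' Tidy voltage traces
#'
#' @param result a \code{\link{SimulationResult}}.
#' @return data.frame with \code{cell}, \code{x}, \code{y}, \code{t},
#'   \code{Vm}, one row per cell and sample.
#' @export
tracesTable <- function(result) {
  cells <- result@cells
  data.frame(cell = rep(cells$id, length(result@time)),
             x = rep(cells$cx, length(result@time)),
             y = rep(cells$cy, length(result@time)),
             t = rep(result@time, each = nrow(cells)),
             Vm = as.vector(result@traces))
}

#' Write traces as tidy CSV with a JSON metadata header
#'
#' @param result a \code{\link{SimulationResult}}.
#' @param path output file.
#' @param every subsample: keep every this-many-th time point.
#' @return \code{path}, invisibly.
#' @export
writeTraces <- function(result, path, every = 1L) {
  meta <- c(list(direction = result@direction, blocked = result@blocked),
            result@meta[c("steps", "dt", "restingPotential")],
            config_as_list(result@config))
  hdr <- paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  tab <- tracesTable(result)
  keep <- tab$t %in% result@time[seq(1, length(result@time), by = every)]
  con <- file(path, "w")
  writeLines(hdr, con)
  write.csv(tab[keep, ], con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @describeIn runProtocol summary printout of a simulation result
#' @param object a \code{SimulationResult}
#' @export
setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %s pacing, %d cells, %.2f ms simulated%s\n",
              object@direction, nrow(object@cells), max(object@time),
              if (object@blocked) " [conduction block]" else ""))
  cat(sprintf("  dt %g ms, resting potential %.2f mV, max rel. residual %.2g\n",
              object@meta$dt, object@meta$restingPotential,
              object@meta$maxRelativeResidual))
})
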