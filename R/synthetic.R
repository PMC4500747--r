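# Ground-truth generators: gSTED-like two-channel cluster images, analytic
# elliptical activation maps, and sigmoidal upstroke traces. Everything is
# deterministic given the seed, so the analysis pipeline can be validated
# end to end without external data.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(
    rm(".Random.seed", envir = globalenv())) else
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

raster_ellipse <- function(mask, cx, cy, a, b, theta) {
  # pixels whose centre lies inside the rotated ellipse (radii a, b in px)
  r0 <- max(1, floor(cx - max(a, b) - 1)); r1 <- min(nrow(mask), ceiling(cx + max(a, b) + 1))
  c0 <- max(1, floor(cy - max(a, b) - 1)); c1 <- min(ncol(mask), ceiling(cy + max(a, b) + 1))
  if (r0 > r1 || c0 > c1) return(mask)
  rr <- r0:r1; cc <- c0:c1
  X <- outer(rr - cx, rep(1, length(cc)))
  Y <- outer(rep(1, length(rr)), cc - cy)
  u <- X * cos(theta) + Y * sin(theta)
  v <- -X * sin(theta) + Y * cos(theta)
  mask[rr, cc] <- mask[rr, cc] | ((u / a)^2 + (v / b)^2 <= 1)
  mask
}

#' Generate a synthetic two-channel cluster image pair
#'
#' Emulates a gSTED-like field of view: elliptical Cx43 clusters placed on
#' a jittered grid, each with a specified number of Nav1.5 clusters that
#' overlap it, lie at a perinexal edge-to-edge distance from it, or lie
#' distal to it. Clusters are rendered as filled ellipses; optional
#' Gaussian blur (FWHM in nm, sigma = FWHM/2.355) and additive Gaussian
#' noise emulate the imaging chain. The ground-truth table records each
#' placed cluster with its intended class and distance and, for Nav1.5
#' clusters, the post-rasterization realized edge-to-edge distance (on the
#' unblurred masks, in the same empty-pixel-gap convention as
#' \code{\link{associateClusters}}) together with the class this distance
#' implies.
#'
#' @param nCx number of Cx43 clusters.
#' @param cxDiameter mean Cx43 equivalent diameter, nm.
#' @param navDiameter mean Nav1.5 equivalent diameter, nm.
#' @param diameterCV coefficient of variation of cluster diameters.
#' @param overlapPerCx,perinexalPerCx,distalPerCx Nav1.5 clusters of each
#'   class placed per Cx43 cluster.
#' @param perinexalDistance,distalDistance target edge-to-edge distances,
#'   nm.
#' @param imageSize image size in pixels (rows, cols).
#' @param pixelSize pixel size, nm/pixel (10 nm emulates gSTED sampling).
#' @param blurFWHM lateral blur full width at half maximum, nm (22 nm
#'   emulates the gSTED point-spread function; 0 = no blur).
#' @param noiseSd additive Gaussian noise SD as a fraction of the peak
#'   intensity.
#' @param seed random seed; output is bit-identical per seed.
#' @param maxTries placement retries before a generation error.
#' @return list with \code{cx43} and \code{nav}
#'   (\code{\link{CalibratedImage}}s) and \code{truth} (data.frame).
#' @export
simulateLocalizationImages <- function(nCx = 12, cxDiameter = 180,
                                       navDiameter = 100, diameterCV = 0.2,
                                       overlapPerCx = 0, perinexalPerCx = 1,
                                       distalPerCx = 0,
                                       perinexalDistance = 100,
                                       distalDistance = 400,
                                       imageSize = c(512, 512),
                                       pixelSize = 10, blurFWHM = 0,
                                       noiseSd = 0, seed = 1,
                                       maxTries = 200) with_seed(seed, {
  ps <- pixelSize
  nr <- imageSize[1]; nc <- imageSize[2]
  navPerCx <- overlapPerCx + perinexalPerCx + distalPerCx
  # exclusion radius so placements for different Cx43 sites cannot interact
  reach <- (cxDiameter / 2 + distalDistance + navDiameter + 250) / ps
  cellPx <- 2 * reach + 2
  gr <- floor(nr / cellPx); gc <- floor(nc / cellPx)
  if (nCx > 0 && gr * gc < nCx)
    stop("infeasible placement: field too small for ", nCx, " Cx43 sites")
  sites <- with_seed(seed + 1, sample(gr * gc, nCx))

  cxMask <- matrix(FALSE, nr, nc)
  navMask <- matrix(FALSE, nr, nc)
  truth <- list()
  navId <- 0L

  diam <- function(mean) max(3 * ps, rnorm(1, mean, diameterCV * mean))

  for (i in seq_len(nCx)) {
    gi <- (sites[i] - 1) %% gr; gj <- (sites[i] - 1) %/% gr
    cx <- gi * cellPx + cellPx / 2 + runif(1, -2, 2)
    cy <- gj * cellPx + cellPx / 2 + runif(1, -2, 2)
    dC <- diam(cxDiameter)
    ecc <- runif(1, 0.75, 1.33)
    aC <- dC / 2 / ps * sqrt(ecc); bC <- dC / 2 / ps / sqrt(ecc)
    thC <- runif(1, 0, pi)
    cxOne <- raster_ellipse(matrix(FALSE, nr, nc), cx, cy, aC, bC, thC)
    cxMask <- cxMask | cxOne
    cxPix <- which(cxOne)
    truth[[length(truth) + 1]] <- data.frame(
      channel = "Cx43", id = i, parent = NA_integer_, cx = cx, cy = cy,
      diameterNm = dC, intendedClass = NA_character_,
      intendedDistanceNm = NA_real_, realizedDistanceNm = NA_real_,
      realizedClass = NA_character_)

    classes <- rep(c("overlapping", "perinexal", "distal"),
                   times = c(overlapPerCx, perinexalPerCx, distalPerCx))
    for (cls in classes) {
      dN <- diam(navDiameter)
      rN <- dN / 2 / ps
      target <- switch(cls, overlapping = -Inf,
                       perinexal = perinexalDistance,
                       distal = distalDistance)
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        phi <- runif(1, 0, 2 * pi)
        rad <- if (cls == "overlapping") {
          runif(1, 0, 0.4) * min(aC, bC)
        } else {
          # ellipse boundary radius along phi, plus gap, plus nav radius
          ct <- cos(phi - thC); st <- sin(phi - thC)
          rEdge <- 1 / sqrt((ct / aC)^2 + (st / bC)^2)
          rEdge + target / ps + rN + 1
        }
        nx <- cx + rad * cos(phi); ny <- cy + rad * sin(phi)
        if (nx < rN + 2 || nx > nr - rN - 1 || ny < rN + 2 ||
            ny > nc - rN - 1) next
        navOne <- raster_ellipse(matrix(FALSE, nr, nc), nx, ny, rN, rN, 0)
        navPix <- which(navOne)
        if (!length(navPix)) next
        overlapNow <- any(cxMask[navPix])
        realized <- if (overlapNow) 0 else {
          bn <- boundary_pixels(navPix, c(nr, nc))
          bc <- boundary_pixels(cxPix, c(nr, nc))
          (min_pair_dist(bn, bc) - 1) * ps
        }
        realizedClass <- if (overlapNow) "overlapping" else
          if (realized <= 200) "perinexal" else "distal"
        if (cls == "overlapping" && !overlapNow) next
        if (cls != "overlapping" && overlapNow) next
        navMask <- navMask | navOne
        navId <- navId + 1L
        truth[[length(truth) + 1]] <- data.frame(
          channel = "Nav1.5", id = navId, parent = i, cx = nx, cy = ny,
          diameterNm = dN, intendedClass = cls,
          intendedDistanceNm = if (cls == "overlapping") 0 else target,
          realizedDistanceNm = realized, realizedClass = realizedClass)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("infeasible placement: could not place a ", cls,
             " Nav1.5 cluster after ", maxTries, " tries")
    }
  }

  render <- function(mask) {
    img <- matrix(0, nr, nc)
    img[mask] <- 1
    if (blurFWHM > 0) {
      sig <- blurFWHM / 2.355 / ps
      img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                               sigma = sig))
    }
    if (noiseSd > 0) {
      img <- img + rnorm(length(img), 0, noiseSd * max(img, 1e-12))
      img[img < 0] <- 0
    }
    as.matrix(img)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(channel = character(), id = integer(), parent = integer(),
               cx = numeric(), cy = numeric(), diameterNm = numeric(),
               intendedClass = character(), intendedDistanceNm = numeric(),
               realizedDistanceNm = numeric(), realizedClass = character())
  list(cx43 = calibratedImage(render(cxMask), ps, "Cx43"),
       nav = calibratedImage(render(navMask), ps, "Nav1.5"),
       truth = truth)
})

#' Generate an analytic elliptical activation map
#'
#' Activation times \eqn{t(x, y) = \sqrt{(x/v_L)^2 + (y/v_T)^2}} on a
#' regular grid emulating an optical-mapping camera (90 x 60 sites over
#' 16.5 x 12 mm by default), with optional additive Gaussian time noise.
#'
#' @param nL,nT grid size along the longitudinal / transverse axis.
#' @param extentL,extentT field of view, mm.
#' @param vL,vT conduction velocities, cm/s.
#' @param origin pacing origin (row, col); defaults to the grid centre.
#' @param noiseSd additive time noise SD, ms.
#' @param seed random seed (used when \code{noiseSd > 0}).
#' @return list with \code{map} (an \code{\link{ActivationMap}}) and
#'   \code{truth} (list with \code{vL}, \code{vT}, \code{ar}).
#' @export
simulateActivationMap <- function(nL = 90, nT = 60, extentL = 16.5,
                                  extentT = 12, vL = 60, vT = 30,
                                  origin = c(round(nL / 2), round(nT / 2)),
                                  noiseSd = 0, seed = 1) {
  stopifnot(vL > 0, vT > 0)
  spacing <- c(extentL / nL, extentT / nT)           # mm per site
  x <- (seq_len(nL) - origin[1]) * spacing[1]        # mm
  y <- (seq_len(nT) - origin[2]) * spacing[2]
  vLmm <- vL / 100; vTmm <- vT / 100                 # mm/ms
  tt <- sqrt(outer(x / vLmm, rep(1, nT))^2 + outer(rep(1, nL), y / vTmm)^2)
  if (noiseSd > 0)
    tt <- tt + with_seed(seed, matrix(rnorm(nL * nT, 0, noiseSd), nL, nT))
  list(map = activationMap(tt, spacing, origin),
       truth = list(vL = vL, vT = vT, ar = vL / vT))
}

#' Generate a sigmoidal upstroke trace
#'
#' \eqn{V(t) = V_{rest} + A / (1 + e^{-(t - t_{act}) / \tau})}: the maximum
#' first derivative lies exactly at \code{tAct}.
#'
#' @param tAct inflection (true activation) time, ms.
#' @param amplitude upstroke amplitude, mV.
#' @param tau upstroke time constant, ms.
#' @param dt sampling interval, ms.
#' @param duration trace length, ms.
#' @param Vrest resting potential, mV.
#' @param noiseSd additive noise SD, mV.
#' @param seed random seed (used when \code{noiseSd > 0}).
#' @return list with \code{time}, \code{v}, and \code{tAct}.
#' @export
simulateUpstroke <- function(tAct = 50, amplitude = 100, tau = 1, dt = 0.1,
                             duration = 100, Vrest = -80, noiseSd = 0,
                             seed = 1) {
  stopifnot(tAct > 0, tAct < duration)
  time <- seq(0, duration, by = dt)
  v <- Vrest + amplitude / (1 + exp(-(time - tAct) / tau))
  if (noiseSd > 0) v <- v + with_seed(seed, rnorm(length(v), 0, noiseSd))
  list(time = time, v = v, tAct = tAct)
}
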