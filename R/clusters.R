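# Object-based colocalization of Cx43 and Nav1.5 clusters in calibrated
# two-channel micrographs: Otsu thresholding, connected-component labeling,
# and edge-to-edge perinexal association.

#' Construct a calibrated image
#'
#' @param data numeric matrix of non-negative intensities.
#' @param pixelSize pixel size, nm/pixel.
#' @param channel channel label.
#' @return a \code{\link{CalibratedImage}}.
#' @export
calibratedImage <- function(data, pixelSize, channel = "") {
  new("CalibratedImage", data = as.matrix(data), pixelSize = pixelSize,
      channel = channel)
}

#' Read / write a calibrated TIFF image
#'
#' Thin wrappers over \code{EBImage} image IO. \code{EBImage} rescales
#' integer TIFF data to [0, 1]; intensities are used as read (thresholding
#' is scale-invariant).
#'
#' @param path TIFF file.
#' @param pixelSize pixel size, nm/pixel.
#' @param channel channel label; for multi-channel files, the frame index
#'   to extract (1-based) is taken from \code{frame}.
#' @param frame frame index for multi-frame/multi-channel TIFFs.
#' @return a \code{\link{CalibratedImage}}.
#' @export
readCalibratedImage <- function(path, pixelSize, channel = "", frame = 1L) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) > 2) d <- d[, , frame]
  calibratedImage(as.matrix(d), pixelSize, channel)
}

#' @rdname readCalibratedImage
#' @param image a \code{\link{CalibratedImage}}; intensities are rescaled
#'   to [0, 1] for storage when needed.
#' @export
writeCalibratedImage <- function(image, path) {
  d <- image@data
  if (max(d) > 1) d <- d / max(d)
  EBImage::writeImage(EBImage::Image(d), path, type = "tiff")
  invisible(path)
}

#' Otsu intensity threshold
#'
#' Returns the threshold maximizing the between-class variance of the image
#' histogram (the classic cumulative-moment recursion over \code{levels}
#' histogram bins; for integer-valued images with at most \code{levels}
#' distinct values the bins are the integer levels themselves, so the
#' result is exact). Pixels strictly above the threshold are foreground.
#'
#' @param image a \code{\link{CalibratedImage}} or numeric matrix.
#' @param levels number of histogram bins for non-integer data.
#' @return the threshold, on the intensity scale of the image.
#' @export
otsuThreshold <- function(image, levels = 256L) {
  x <- if (methods::is(image, "CalibratedImage")) image@data else image
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0)
    stop("degenerate input: image has a single intensity value")
  isInt <- all(x == round(x)) && (rng[2] - rng[1] + 1) <= levels
  if (isInt) {
    vals <- seq(rng[1], rng[2])
    cnt <- tabulate(x - rng[1] + 1, nbins = length(vals))
  } else {
    br <- seq(rng[1], rng[2], length.out = levels + 1)
    cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE),
                    nbins = levels)
    vals <- (br[-1] + br[-length(br)]) / 2
  }
  w <- cumsum(as.numeric(cnt))
  mu <- cumsum(as.numeric(cnt) * vals)
  muT <- mu[length(mu)]
  n <- w[length(w)]
  sb <- (muT * w / n - mu)^2 / (w / n * (n - w))   # between-class variance
  sb[!is.finite(sb)] <- -Inf
  occ <- which(cnt > 0)
  occ <- occ[-length(occ)]                # top level cannot be a threshold
  best <- occ[which.max(sb[occ])]
  nxt <- min(which(cnt > 0 & seq_along(cnt) > best))
  (vals[best] + vals[nxt]) / 2            # midpoint between the two classes
}

shift_mat <- function(m, di, dj, fill) {
  n <- matrix(fill, nrow(m), ncol(m))
  ri <- seq_len(nrow(m)); rj <- seq_len(ncol(m))
  si <- ri - di; sj <- rj - dj
  ok_i <- si >= 1 & si <= nrow(m); ok_j <- sj >= 1 & sj <= ncol(m)
  n[ri[ok_i], rj[ok_j]] <- m[si[ok_i], sj[ok_j]]
  n
}

label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  lab <- matrix(Inf, nrow(mask), ncol(mask))
  lab[mask] <- which(mask)
  sh <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8)
    sh <- c(sh, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  repeat {
    new <- lab
    for (s in sh) new <- pmin(new, shift_mat(lab, s[1], s[2], Inf))
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  lab[!mask] <- 0
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[mask] <- as.integer(factor(lab[mask]))
  out
}

#' Segment clusters from an image or binary mask
#'
#' Thresholds the image by Otsu's method (unless a logical mask is given)
#' and labels maximal connected components (8-connectivity by default,
#' matching the usual component-labeling convention for punctate
#' immunosignal). Centroids are unweighted pixel-coordinate means; areas
#' and equivalent circular diameters are calibrated.
#'
#' @param image a \code{\link{CalibratedImage}}, or a logical matrix mask
#'   (then \code{pixelSize} must be given).
#' @param connectivity 4 or 8.
#' @param threshold optional fixed threshold; default is Otsu's.
#' @param pixelSize pixel size in nm (required for a bare mask).
#' @return a \code{\link{ClusterSet}}; empty masks give zero clusters.
#' @export
findClusters <- function(image, connectivity = 8, threshold = NULL,
                         pixelSize = NULL) {
  if (methods::is(image, "CalibratedImage")) {
    ps <- image@pixelSize
    if (is.null(threshold)) threshold <- otsuThreshold(image)
    mask <- image@data > threshold
  } else if (is.logical(image)) {
    if (is.null(pixelSize)) stop("pixelSize required for a bare mask")
    ps <- pixelSize
    mask <- image
  } else stop("image must be a CalibratedImage or a logical mask")

  lab <- label_components(mask, connectivity)
  k <- max(lab)
  if (k == 0) {
    clusters <- data.frame(id = integer(), nPixels = integer(),
                           cx = numeric(), cy = numeric(),
                           areaNm2 = numeric(), eqDiameterNm = numeric())
    return(new("ClusterSet", clusters = clusters, pixels = list(),
               dim = dim(mask), pixelSize = ps,
               connectivity = connectivity))
  }
  idx <- which(mask)
  px <- split(idx, lab[idx])
  rows <- (idx - 1) %% nrow(mask) + 1
  cols <- (idx - 1) %/% nrow(mask) + 1
  nPix <- lengths(px)
  clusters <- data.frame(
    id = seq_len(k),
    nPixels = as.integer(nPix),
    cx = as.numeric(tapply(rows, lab[idx], mean)),
    cy = as.numeric(tapply(cols, lab[idx], mean)),
    areaNm2 = nPix * ps^2)
  clusters$eqDiameterNm <- 2 * sqrt(clusters$areaNm2 / pi)
  new("ClusterSet", clusters = clusters, pixels = unname(px),
      dim = dim(mask), pixelSize = ps, connectivity = connectivity)
}

#' @describeIn findClusters printout
#' @param object a \code{ClusterSet}
#' @export
setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet: %d clusters, %d x %d px at %g nm/px (%d-connectivity)\n",
              nrow(object@clusters), object@dim[1], object@dim[2],
              object@pixelSize, as.integer(object@connectivity)))
  if (nrow(object@clusters))
    cat(sprintf("  median equivalent diameter %.0f nm\n",
                median(object@clusters$eqDiameterNm)))
})

# boundary pixels of a cluster (any 4-neighbour outside the cluster)
boundary_pixels <- function(idx, dm) {
  r <- (idx - 1) %% dm[1] + 1
  cc <- (idx - 1) %/% dm[1] + 1
  inset <- matrix(FALSE, dm[1], dm[2]); inset[idx] <- TRUE
  bnd <- r == 1 | r == dm[1] | cc == 1 | cc == dm[2]
  for (s in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    rr <- pmin(pmax(r + s[1], 1), dm[1])
    cj <- pmin(pmax(cc + s[2], 1), dm[2])
    bnd <- bnd | !inset[cbind(rr, cj)]
  }
  cbind(r = r[bnd], c = cc[bnd])
}

# minimum center-to-center pixel distance between two pixel-coordinate sets
min_pair_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

#' Associate Nav1.5 clusters with Cx43 clusters
#'
#' A Nav1.5 cluster overlaps a Cx43 cluster when the two share at least one
#' pixel; it is perinexal to a Cx43 cluster when it does not overlap it and
#' its edge-to-edge distance is at most \code{perinexalWidth} (default
#' 200 nm, the extent of the perinexus from the gap-junction plaque edge).
#' Edge-to-edge distance is measured on the segmented masks as the number
#' of empty pixels separating the clusters (minimum pixel-centre distance
#' minus one pixel), times the pixel size; for classifying each Nav1.5
#' cluster the distance to the whole Cx43 mask is obtained from its
#' Euclidean distance transform, and per-pair distances for the partner
#' counts use boundary-pixel distances. Each Nav1.5 cluster is assigned its
#' best class (overlap > perinexal > distal) over all Cx43 clusters;
#' partners are counted independently for every Cx43 cluster.
#'
#' @param cx43,nav \code{\link{ClusterSet}}s from images of identical
#'   calibration and size.
#' @param perinexalWidth perinexal association distance, nm.
#' @return an \code{\link{AssociationReport}}.
#' @export
associateClusters <- function(cx43, nav, perinexalWidth = 200) {
  if (!isTRUE(all.equal(cx43@pixelSize, nav@pixelSize)) ||
      !identical(cx43@dim, nav@dim))
    stop("calibration mismatch between the two channels")
  ps <- cx43@pixelSize
  dm <- cx43@dim
  nCx <- nrow(cx43@clusters); nNav <- nrow(nav@clusters)

  cxLab <- matrix(0L, dm[1], dm[2])
  for (i in seq_len(nCx)) cxLab[cx43@pixels[[i]]] <- i
  cxMask <- cxLab > 0

  # distance (in px, centre-to-centre) of every pixel to the Cx43 mask
  dmap <- if (any(cxMask))
    EBImage::imageData(EBImage::distmap(EBImage::Image(1 - cxMask))) else
    matrix(Inf, dm[1], dm[2])

  cxBnd <- lapply(cx43@pixels, boundary_pixels, dm = dm)
  navBnd <- lapply(nav@pixels, boundary_pixels, dm = dm)
  cxBox <- lapply(cxBnd, function(b)
    c(min(b[, 1]), max(b[, 1]), min(b[, 2]), max(b[, 2])))

  navClass <- rep("distal", nNav)
  navMinDist <- rep(NA_real_, nNav)
  nOv <- integer(nCx); nPeri <- integer(nCx)
  reachPx <- perinexalWidth / ps + 1   # pair pruning radius in px

  for (j in seq_len(nNav)) {
    pxj <- nav@pixels[[j]]
    ovIds <- setdiff(unique(cxLab[pxj]), 0L)
    d <- min(dmap[pxj])
    navMinDist[j] <- (d - 1) * ps      # empty-pixel gap, calibrated
    if (length(ovIds)) {
      navClass[j] <- "overlapping"
      nOv[ovIds] <- nOv[ovIds] + 1L
      navMinDist[j] <- 0
    } else if (nCx > 0 && (d - 1) * ps <= perinexalWidth) {
      navClass[j] <- "perinexal"
    }
    if (nCx == 0) next
    # per-pair perinexal partners (bounding-box pruned)
    b <- navBnd[[j]]
    lo1 <- min(b[, 1]); hi1 <- max(b[, 1])
    lo2 <- min(b[, 2]); hi2 <- max(b[, 2])
    for (i in seq_len(nCx)) {
      if (i %in% ovIds) next
      bb <- cxBox[[i]]
      gap1 <- max(bb[1] - hi1, lo1 - bb[2], 0)
      gap2 <- max(bb[3] - hi2, lo2 - bb[4], 0)
      if (sqrt(gap1^2 + gap2^2) > reachPx) next
      dij <- min_pair_dist(b, cxBnd[[i]])
      if ((dij - 1) * ps <= perinexalWidth) nPeri[i] <- nPeri[i] + 1L
    }
  }

  hist3 <- function(x) c(`0` = sum(x == 0), `1` = sum(x == 1),
                         `>=2` = sum(x >= 2))
  cxClass <- ifelse(nOv > 0, "overlapping",
                    ifelse(nPeri > 0, "perinexal", "distal"))
  navTable <- data.frame(id = seq_len(nNav), class = navClass,
                         minEdgeDistanceNm = navMinDist)
  cxTable <- data.frame(id = seq_len(nCx), class = cxClass,
                        nOverlapping = nOv, nPerinexal = nPeri,
                        eqDiameterNm = cx43@clusters$eqDiameterNm)
  frac <- function(x) if (nNav == 0) NA_real_ else mean(x)
  cfrac <- function(x) if (nCx == 0) NA_real_ else mean(x)
  summary <- list(
    nNav = nNav, nCx = nCx,
    navOverlapFraction = frac(navClass == "overlapping"),
    navPerinexalFraction = frac(navClass == "perinexal"),
    navDistalFraction = frac(navClass == "distal"),
    cxOverlapFraction = cfrac(cxClass == "overlapping"),
    cxPerinexalFraction = cfrac(cxClass == "perinexal"),
    cxDistalFraction = cfrac(cxClass == "distal"),
    cxWithPerinexalPartner = cfrac(nPeri > 0),
    cxOverlapHist = hist3(nOv),
    cxPerinexalHist = hist3(nPeri),
    medianOverlapPartners = if (nCx) median(nOv) else NA_real_,
    sdOverlapPartners = if (nCx > 1) sd(nOv) else NA_real_,
    medianPerinexalPartners = if (nCx) median(nPeri) else NA_real_,
    sdPerinexalPartners = if (nCx > 1) sd(nPeri) else NA_real_,
    medianCxDiameterNm = if (nCx) median(cx43@clusters$eqDiameterNm)
                         else NA_real_)
  new("AssociationReport", navTable = navTable, cxTable = cxTable,
      summary = summary,
      params = list(perinexalWidth = perinexalWidth, pixelSize = ps))
}

#' Flat summary table of an association report
#'
#' One row per statistic, named after the quantities reported for
#' cluster-association analyses: Nav1.5 class fractions, Cx43 class
#' fractions, partner-count histograms with medians/SD, and the median Cx43
#' cluster size.
#'
#' @param report an \code{\link{AssociationReport}}.
#' @return data.frame with columns \code{statistic} and \code{value}.
#' @export
summarizeAssociation <- function(report) {
  s <- report@summary
  vals <- c(
    n_nav_clusters = s$nNav,
    n_cx43_clusters = s$nCx,
    nav_overlapping_fraction = s$navOverlapFraction,
    nav_perinexal_fraction = s$navPerinexalFraction,
    nav_distal_fraction = s$navDistalFraction,
    cx43_overlapping_fraction = s$cxOverlapFraction,
    cx43_perinexal_fraction = s$cxPerinexalFraction,
    cx43_distal_fraction = s$cxDistalFraction,
    cx43_overlap_partners_0 = unname(s$cxOverlapHist["0"]),
    cx43_overlap_partners_1 = unname(s$cxOverlapHist["1"]),
    cx43_overlap_partners_2plus = unname(s$cxOverlapHist[">=2"]),
    cx43_perinexal_partners_0 = unname(s$cxPerinexalHist["0"]),
    cx43_perinexal_partners_1 = unname(s$cxPerinexalHist["1"]),
    cx43_perinexal_partners_2plus = unname(s$cxPerinexalHist[">=2"]),
    median_overlap_partners = s$medianOverlapPartners,
    sd_overlap_partners = s$sdOverlapPartners,
    median_perinexal_partners = s$medianPerinexalPartners,
    sd_perinexal_partners = s$sdPerinexalPartners,
    median_cx43_diameter_nm = s$medianCxDiameterNm)
  data.frame(statistic = names(vals), value = unname(vals))
}

#' Serialize an association report to JSON / per-cluster CSV
#'
#' @param report an \code{\link{AssociationReport}}.
#' @param path output JSON file.
#' @param clusterCsv optional CSV path for the per-cluster tables.
#' @export
writeAssociationReport <- function(report, path, clusterCsv = NULL) {
  jsonlite::write_json(
    list(summary = report@summary, params = report@params,
         navTable = report@navTable, cxTable = report@cxTable),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(clusterCsv)) {
    nav <- cbind(channel = "Nav1.5", report@navTable)
    write.csv(nav, clusterCsv, row.names = FALSE)
  }
  invisible(path)
}

#' @describeIn associateClusters printout
#' @param object an \code{AssociationReport}
#' @export
setMethod("show", "AssociationReport", function(object) {
  s <- object@summary
  cat(sprintf("AssociationReport: %d Nav1.5 vs %d Cx43 clusters (perinexal width %g nm)\n",
              s$nNav, s$nCx, object@params$perinexalWidth))
  cat(sprintf("  Nav1.5: %.1f%% overlapping, %.1f%% perinexal, %.1f%% distal\n",
              100 * s$navOverlapFraction, 100 * s$navPerinexalFraction,
              100 * s$navDistalFraction))
  cat(sprintf("  Cx43: %.1f%% with overlapping, %.1f%% with perinexal partners\n",
              100 * s$cxOverlapFraction, 100 * s$cxWithPerinexalPartner))
})
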