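#' @import methods
#' @importFrom stats median sd quantile coef lm optimize residuals rnorm runif setNames uniroot
#' @importFrom utils head tail write.csv read.csv write.table
NULL

#' Model configuration for the microdomain conduction model
#'
#' A \code{ModelConfig} bundles every parameter of the microdomain sheet
#' model: cell geometry, sheet layout, extracellular cleft properties,
#' gap-junction coupling, passive membrane constants, the ionic model, the
#' sodium-channel distribution, and solver/stimulus settings. Use
#' \code{\link{modelConfig}} to construct one with nominal defaults.
#'
#' @slot shape list with \code{length}, \code{width}, \code{depth} (um).
#' @slot layout list with \code{nRows}, \code{nCols},
#'   \code{transverseOffset} (fraction of cell width),
#'   \code{longitudinalOffset} (fraction of cell length).
#' @slot extracellular list with \code{junctionalWidth} (nm),
#'   \code{lateralWidth} (um), \code{sigmaEffLateral} and
#'   \code{sigmaEffJunctional} (mS/cm).
#' @slot gapJunction list with \code{gjBar} (mS/cm2 of junctional interface).
#' @slot membrane list with \code{Cm} (uF/cm2) and \code{sigmaI} (mS/cm).
#' @slot ionic list describing the ionic model (see \code{\link{ionicModel}}).
#' @slot distribution list with \code{junctionalFraction}, the fraction of
#'   total cellular sodium conductance placed on junctional membrane.
#' @slot solver list with \code{dt} (ms), \code{duration} (ms),
#'   \code{stimAmplitude} (uA/cm2), \code{stimDuration} (ms).
#' @export
setClass("ModelConfig", representation(
  shape = "list", layout = "list", extracellular = "list",
  gapJunction = "list", membrane = "list", ionic = "list",
  distribution = "list", solver = "list"))

setValidity("ModelConfig", function(object) {
  s <- object@shape; l <- object@layout; e <- object@extracellular
  msg <- character()
  if (!all(vapply(s[c("length", "width", "depth")], function(x)
    is.numeric(x) && x > 0, TRUE)))
    msg <- c(msg, "cell dimensions must be strictly positive")
  if (is.numeric(s$length) && is.numeric(s$width) && s$length <= s$width)
    msg <- c(msg, "cell length must exceed cell width")
  if (l$nRows < 1 || l$nCols < 1)
    msg <- c(msg, "sheet needs at least one row and one column")
  off <- c(l$transverseOffset, l$longitudinalOffset)
  if (any(off < 0 | off >= 1))
    msg <- c(msg, "offsets must lie in [0, 1)")
  if (!all(vapply(e[c("junctionalWidth", "lateralWidth",
                      "sigmaEffLateral", "sigmaEffJunctional")],
                  function(x) is.numeric(x) && x > 0, TRUE)))
    msg <- c(msg, "extracellular widths and conductivities must be positive")
  if (object@gapJunction$gjBar < 0)
    msg <- c(msg, "gap-junction conductance must be non-negative")
  pf <- object@gapJunction$plaqueFraction
  if (!is.null(pf) && (pf <= 0 || pf > 1))
    msg <- c(msg, "plaqueFraction must lie in (0, 1]")
  f <- object@distribution$junctionalFraction
  if (f < 0 || f > 1)
    msg <- c(msg, "junctionalFraction must lie in [0, 1]")
  if (object@solver$dt <= 0) msg <- c(msg, "dt must be positive")
  if (length(msg)) msg else TRUE
})

#' Discretized myocyte sheet
#'
#' A \code{TissueMesh} holds the full discretization of a sheet of brick
#' myocytes: per-cell footprints and intracellular corner nodes with a
#' triangulation, membrane patches classified as lateral or junctional, the
#' extracellular cleft network (one node per cleft segment, conductances on
#' segment adjacencies), and the list of gap-junction interfaces. Built by
#' \code{\link{buildTissueSheet}}.
#'
#' @slot cells data.frame: one row per cell (id, row, col, centre, footprint
#'   area in um2).
#' @slot nodes data.frame: intracellular corner nodes (id, cell, x, y in um).
#'   Nodes are private to each cell; cells communicate only through gap
#'   junctions and the shared extracellular clefts.
#' @slot triangles data.frame: linear triangular elements (cell, n1, n2, n3).
#' @slot patches data.frame: membrane patches with class
#'   (\code{lateral}/\code{junctional}), bound intracellular nodes and
#'   weights, bound cleft node, outward normal, and areas in cm2
#'   (\code{area} includes the patch's share of the out-of-plane cap
#'   membrane; \code{sideArea} is the in-plane face alone).
#' @slot cleftNodes data.frame: extracellular nodes, one per cleft segment,
#'   with segment type, length and endpoints.
#' @slot cleftEdges data.frame: inter-node cleft conductances (mS).
#' @slot junctions data.frame: gap-junction interfaces (cell pair, patch
#'   pair, interface area in cm2).
#' @slot shape,layout,extracellular,gapJunction parameter lists as in
#'   \code{\link{ModelConfig}}.
#' @export
setClass("TissueMesh", representation(
  cells = "data.frame", nodes = "data.frame", triangles = "data.frame",
  patches = "data.frame", cleftNodes = "data.frame",
  cleftEdges = "data.frame", junctions = "data.frame",
  shape = "list", layout = "list", extracellular = "list",
  gapJunction = "list"))

setValidity("TissueMesh", function(object) {
  p <- object@patches
  msg <- character()
  if (nrow(p)) {
    if (!all(p$class %in% c("lateral", "junctional")))
      msg <- c(msg, "patch classes must be 'lateral' or 'junctional'")
    if (any(p$area <= 0)) msg <- c(msg, "patch areas must be positive")
    j <- p[p$class == "junctional", ]
    if (nrow(j) && any(is.na(j$neighborCell)))
      msg <- c(msg, "every junctional patch needs exactly one neighbor cell")
    if (any(is.na(p$cleft)))
      msg <- c(msg, "every membrane patch must bind to one extracellular node")
  }
  if (nrow(object@cleftEdges) && any(object@cleftEdges$G <= 0))
    msg <- c(msg, "cleft conductances must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Simulation result of a conduction protocol
#'
#' Transmembrane voltage traces at each cell centre (patch-area-weighted),
#' produced by \code{\link{runProtocol}}.
#'
#' @slot time numeric vector of sample times (ms).
#' @slot traces matrix, cells x time, of membrane voltage (mV).
#' @slot cells data.frame of cell ids and centre coordinates (um).
#' @slot direction stimulated direction, \code{"longitudinal"} or
#'   \code{"transverse"}.
#' @slot blocked logical: \code{TRUE} when distal cells never activated.
#' @slot config the \code{ModelConfig} used.
#' @slot meta list of run metadata (stimulus, solver diagnostics).
#' @export
setClass("SimulationResult", representation(
  time = "numeric", traces = "matrix", cells = "data.frame",
  direction = "character", blocked = "logical", config = "ModelConfig",
  meta = "list"))

#' Grid of activation times
#'
#' Activation-time map on a regular grid emulating an optical-mapping
#' camera; \code{NA} marks sites that never activated.
#'
#' @slot times matrix of activation times (ms), rows indexed along the
#'   longitudinal (fiber) axis, columns along the transverse axis.
#' @slot spacing site spacing in mm, length 2 (longitudinal, transverse).
#' @slot origin pacing origin as (row, col) grid indices.
#' @export
setClass("ActivationMap", representation(
  times = "matrix", spacing = "numeric", origin = "numeric"))

setValidity("ActivationMap", function(object) {
  msg <- character()
  if (length(object@spacing) != 2 || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be two positive values (mm)")
  o <- object@origin
  if (length(o) != 2 || o[1] < 1 || o[2] < 1 ||
      o[1] > nrow(object@times) || o[2] > ncol(object@times))
    msg <- c(msg, "origin must lie inside the grid")
  if (any(is.infinite(object@times), na.rm = TRUE))
    msg <- c(msg, "activation times must be finite or NA")
  if (length(msg)) msg else TRUE
})

#' Conduction velocity estimate
#'
#' @slot cvL,cvT conduction velocity along and across the fiber axis (cm/s).
#' @slot ar anisotropy ratio, \code{cvL / cvT}.
#' @slot fits list with the per-axis regression details.
#' @export
setClass("CVResult", representation(
  cvL = "numeric", cvT = "numeric", ar = "numeric", fits = "list"))

#' Calibrated single-channel micrograph
#'
#' @slot data numeric matrix of non-negative intensities.
#' @slot pixelSize pixel size in nm/pixel.
#' @slot channel channel label (e.g. \code{"Cx43"}, \code{"Nav1.5"}).
#' @export
setClass("CalibratedImage", representation(
  data = "matrix", pixelSize = "numeric", channel = "character"))

setValidity("CalibratedImage", function(object) {
  msg <- character()
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (any(object@data < 0)) msg <- c(msg, "intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Connected clusters segmented from a binary mask
#'
#' @slot clusters data.frame: id, pixel count, centroid (pixel coordinates),
#'   area in nm2, equivalent circular diameter in nm.
#' @slot pixels list of integer vectors: linear pixel indices per cluster.
#' @slot dim image dimensions.
#' @slot pixelSize nm/pixel.
#' @slot connectivity 4 or 8.
#' @export
setClass("ClusterSet", representation(
  clusters = "data.frame", pixels = "list", dim = "integer",
  pixelSize = "numeric", connectivity = "numeric"))

#' Cluster association report
#'
#' Output of \code{\link{associateClusters}}: per-Nav1.5-cluster class
#' (overlapping / perinexal / distal with respect to the nearest Cx43
#' cluster), per-Cx43 partner counts, and the derived summary statistics.
#'
#' @slot navTable data.frame: one row per Nav1.5 cluster with its class and
#'   the minimum edge-to-edge distance to a Cx43 cluster (nm).
#' @slot cxTable data.frame: one row per Cx43 cluster with counts of
#'   overlapping and perinexal Nav1.5 partners and equivalent diameter (nm).
#' @slot summary named list of the headline statistics (class fractions,
#'   Cx43 fractions with at least one partner, partner-count histograms and
#'   their median/sd, median Cx43 equivalent diameter).
#' @slot params list: perinexal width (nm) and pixel size (nm).
#' @export
setClass("AssociationReport", representation(
  navTable = "data.frame", cxTable = "data.frame",
  summary = "list", params = "list"))

setValidity("AssociationReport", function(object) {
  s <- object@summary
  msg <- character()
  fr <- c(s$navOverlapFraction, s$navPerinexalFraction, s$navDistalFraction)
  if (!any(is.na(fr)) && length(fr) == 3 && abs(sum(fr) - 1) > 1e-8)
    msg <- c(msg, "Nav1.5 class fractions must sum to 1")
  nCx <- nrow(object@cxTable)
  if (!is.null(s$cxOverlapHist) && sum(s$cxOverlapHist) != nCx)
    msg <- c(msg, "overlap histogram must count every Cx43 cluster")
  if (!is.null(s$cxPerinexalHist) && sum(s$cxPerinexalHist) != nCx)
    msg <- c(msg, "perinexal histogram must count every Cx43 cluster")
  if (length(msg)) msg else TRUE
})
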