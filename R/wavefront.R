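# Activation-time and conduction-velocity quantification.

#' Activation time of a voltage trace
#'
#' Activation is the time of the maximum first derivative of the action
#' potential upstroke, computed by central differences with ties broken by
#' the earliest time; an optional quadratic refinement of the derivative
#' peak gives sub-sample resolution. Traces whose depolarization excursion
#' stays below \code{minExcursion} are reported as not activated
#' (\code{NA}).
#'
#' @param v voltage samples, mV.
#' @param time sample times (ms), or a scalar sampling interval.
#' @param minExcursion minimum depolarization above the initial value for
#'   the trace to count as activated, mV.
#' @param refine quadratic sub-sample refinement of the derivative peak.
#' @return activation time in ms, or \code{NA} when there is no upstroke.
#' @export
activationTime <- function(v, time, minExcursion = 10, refine = TRUE) {
  if (length(time) == 1) time <- (seq_along(v) - 1) * time
  stopifnot(length(v) == length(time))
  if (length(v) < 3 || max(v) - v[1] < minExcursion) return(NA_real_)
  dt <- time[2] - time[1]
  dv <- (v[-(1:2)] - v[-((length(v) - 1):length(v))]) / (2 * dt)
  k <- which.max(dv)                      # earliest max by which.max
  tAct <- time[k + 1]
  if (refine && k > 1 && k < length(dv)) {
    y1 <- dv[k - 1]; y2 <- dv[k]; y3 <- dv[k + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) {
      off <- 0.5 * (y1 - y3) / den
      if (abs(off) <= 1) tAct <- tAct + off * dt
    }
  }
  tAct
}

#' Activation times of every cell in a simulation
#'
#' @param result a \code{\link{SimulationResult}}.
#' @param ... passed to \code{\link{activationTime}}.
#' @return numeric vector of activation times (ms), \code{NA} for cells
#'   that never activated.
#' @export
activationTimes <- function(result, ...) {
  apply(result@traces, 1, activationTime, time = result@time, ...)
}

#' Construct an activation map
#'
#' @param times matrix of activation times (ms); rows index the
#'   longitudinal (fiber) axis, columns the transverse axis; \code{NA}
#'   marks sites that never activated.
#' @param spacing site spacing in mm: either a scalar or
#'   (longitudinal, transverse).
#' @param origin pacing origin as (row, col) grid indices.
#' @return an \code{\link{ActivationMap}}.
#' @export
activationMap <- function(times, spacing, origin) {
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  new("ActivationMap", times = times, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Read an activation map stored as a CSV grid
#'
#' @param path CSV file holding the activation-time grid (no header).
#' @param spacing,origin as in \code{\link{activationMap}}.
#' @return an \code{\link{ActivationMap}}.
#' @export
readActivationMap <- function(path, spacing, origin) {
  m <- as.matrix(read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  activationMap(m, spacing, origin)
}

#' @rdname readActivationMap
#' @param map an \code{\link{ActivationMap}}.
#' @export
writeActivationMap <- function(map, path) {
  write.table(map@times, path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

r_squared <- function(fit, y) {
  ssTot <- sum((y - mean(y))^2)
  if (ssTot == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / ssTot
}

fit_ray <- function(d, t, nearField, minSites) {
  keep <- abs(d) > nearField & !is.na(t)
  if (sum(keep) < minSites)
    stop("fewer than ", minSites, " activated sites along the axis")
  fit <- lm(t ~ ad, data = data.frame(t = t[keep], ad = abs(d[keep])))
  slope <- coef(fit)[["ad"]]
  if (slope <= 0) stop("non-positive activation-time slope along the axis")
  list(cv = 100 / slope,                 # ms/mm -> cm/s
       n = sum(keep), slope = slope,
       r2 = r_squared(fit, t[keep]))
}

#' Conduction velocities and anisotropy ratio of an activation map
#'
#' CV along each axis is the inverse slope of the least-squares fit of
#' activation time against distance along the on-axis site rays through the
#' pacing origin (both directions pooled), excluding a near-field ring of
#' two sites around the origin. The anisotropy ratio is
#' \eqn{AR = CV_L / CV_T}.
#'
#' @param map an \code{\link{ActivationMap}}.
#' @param nearFieldSites sites within this many grid steps of the origin
#'   are excluded from the fits.
#' @param minSites minimum number of activated sites required per axis.
#' @return a \code{\link{CVResult}}.
#' @examples
#' m <- simulateActivationMap(vL = 60, vT = 30)
#' computeCV(m$map)
#' @export
computeCV <- function(map, nearFieldSites = 2, minSites = 5) {
  tt <- map@times
  i0 <- map@origin[1]; j0 <- map@origin[2]
  dL <- (seq_len(nrow(tt)) - i0) * map@spacing[1]
  dT <- (seq_len(ncol(tt)) - j0) * map@spacing[2]
  fL <- fit_ray(dL, tt[, j0], nearFieldSites * map@spacing[1], minSites)
  fT <- fit_ray(dT, tt[i0, ], nearFieldSites * map@spacing[2], minSites)
  new("CVResult", cvL = fL$cv, cvT = fT$cv, ar = fL$cv / fT$cv,
      fits = list(longitudinal = fL, transverse = fT))
}

#' Conduction velocity of a simulated propagation run
#'
#' Least-squares fit of cell activation time against the cell-centre
#' coordinate along the propagation axis, over the interior of the sheet
#' (cells within \code{trim} columns/rows of the stimulated and far edges
#' are excluded to avoid stimulus and boundary artifacts).
#'
#' @param result a \code{\link{SimulationResult}}.
#' @param trim columns (rows) dropped at each end of the fit.
#' @param ... passed to \code{\link{activationTimes}}.
#' @return list with \code{cv} (cm/s), \code{n}, \code{r2}, and
#'   \code{blocked}.
#' @export
conductionVelocity <- function(result, trim = 2, ...) {
  cells <- result@cells
  tAct <- activationTimes(result, ...)
  if (result@direction == "longitudinal") {
    keep <- cells$col > trim & cells$col <= max(cells$col) - trim
    coord <- cells$cx
  } else {
    keep <- cells$row > trim & cells$row <= max(cells$row) - trim
    coord <- cells$cy
  }
  keep <- keep & !is.na(tAct)
  if (sum(keep) < 5)
    return(list(cv = NA_real_, n = sum(keep), r2 = NA_real_,
                blocked = TRUE))
  fit <- lm(t ~ x, data = data.frame(t = tAct[keep], x = coord[keep]))
  slope <- coef(fit)[["x"]]               # ms per um
  cv <- if (slope > 0) 0.1 / slope else NA_real_   # -> cm/s
  list(cv = cv, n = sum(keep), r2 = r_squared(fit, tAct[keep]),
       blocked = result@blocked || is.na(cv))
}

#' Longitudinal and transverse conduction velocity of a configuration
#'
#' Runs the two pacing protocols (left-edge and bottom-edge stimulation) on
#' one shared mesh and operator assembly and fits both conduction
#' velocities.
#'
#' @param config a \code{\link{ModelConfig}}.
#' @param mesh,system optional prebuilt mesh / operator set.
#' @param ... passed to \code{\link{conductionVelocity}}.
#' @return a \code{\link{CVResult}}; velocities are \code{NA} under
#'   conduction block.
#' @export
simulateCV <- function(config, mesh = NULL, system = NULL, ...) {
  if (is.null(system)) {
    if (is.null(mesh)) mesh <- buildTissueSheet(config)
    system <- assembleSystem(mesh, config)
  }
  rL <- runProtocol(config, "longitudinal", system = system)
  rT <- runProtocol(config, "transverse", system = system)
  fL <- conductionVelocity(rL, ...)
  fT <- conductionVelocity(rT, ...)
  new("CVResult", cvL = fL$cv, cvT = fT$cv,
      ar = if (is.na(fL$cv) || is.na(fT$cv)) NA_real_ else fL$cv / fT$cv,
      fits = list(longitudinal = fL, transverse = fT))
}

#' Serialize a CV estimate as JSON
#'
#' @param cv a \code{\link{CVResult}}.
#' @param path output file.
#' @export
writeCVResult <- function(cv, path) {
  jsonlite::write_json(list(cvL = cv@cvL, cvT = cv@cvT, ar = cv@ar),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @describeIn computeCV printout
#' @param object a \code{CVResult}
#' @export
setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: CV_L %.2f cm/s, CV_T %.2f cm/s, AR %.3f\n",
              object@cvL, object@cvT, object@ar))
})

#' @describeIn activationMap printout
#' @param object an \code{ActivationMap}
#' @export
setMethod("show", "ActivationMap", function(object) {
  cat(sprintf("ActivationMap: %d x %d sites (%.2f x %.2f mm), origin (%d, %d)\n",
              nrow(object@times), ncol(object@times),
              nrow(object@times) * object@spacing[1],
              ncol(object@times) * object@spacing[2],
              object@origin[1], object@origin[2]))
  cat(sprintf("  %d activated sites, times %.2f-%.2f ms\n",
              sum(!is.na(object@times)), min(object@times, na.rm = TRUE),
              max(object@times, na.rm = TRUE)))
})
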