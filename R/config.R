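#' Ionic membrane model description
#'
#' The conduction model only needs a fast regenerative inward current and a
#' repolarizing outward current, so the default ionic model is a minimal
#' Hodgkin-Huxley-type formulation: a fast sodium current
#' \eqn{I_{Na} = g_{Na} m^3 h (V - E_{Na})} with Ebihara-Johnson style rate
#' constants, plus an instantaneous potassium/leak current
#' \eqn{I_K = g_K (V - E_K)}. \code{gNa} is the peak sodium conductance
#' density averaged over the whole cell membrane; how it is distributed
#' between lateral and junctional membrane is controlled separately by the
#' channel distribution (see \code{\link{partitionChannels}}).
#'
#' A \code{"passive"} model (pure leak \eqn{g_{leak}(V - V_{rest})}) is
#' provided for solver verification: it has the closed-form membrane time
#' constant \eqn{\tau = C_m / g_{leak}}.
#'
#' @param type \code{"hh"} or \code{"passive"}.
#' @param gNa peak sodium conductance density, mS/cm2 of total membrane.
#' @param gK potassium/leak conductance density, mS/cm2.
#' @param ENa,EK reversal potentials, mV.
#' @param gNaScale multiplicative scale on \code{gNa} (sodium-channel
#'   inhibition; flecainide is 0.86).
#' @param gLeak leak conductance for the passive model, mS/cm2.
#' @param Vrest resting potential for the passive model, mV.
#' @return a list describing the ionic model.
#' @export
ionicModel <- function(type = c("hh", "passive"), gNa = 90, gK = 0.45,
                       ENa = 55, EK = -83, gNaScale = 1,
                       gLeak = 0.2, Vrest = -83) {
  type <- match.arg(type)
  stopifnot(gNa >= 0, gK >= 0, gLeak > 0, gNaScale >= 0)
  list(type = type, gNa = gNa, gK = gK, ENa = ENa, EK = EK,
       gNaScale = gNaScale, gLeak = gLeak, Vrest = Vrest)
}

#' Construct a microdomain model configuration
#'
#' Returns a \code{\link{ModelConfig}} populated with the nominal
#' parameterization of the microdomain sheet model: 101 x 24.1 um myocytes
#' offset by 50\% transversely and 20\% longitudinally, 15 nm junctional and
#' 0.1 um lateral clefts with effective conductivities 17.8 and 159.1 mS/cm,
#' and end-to-end gap-junction coupling of 100 mS/cm2 of interface. The
#' out-of-plane cell depth is not separately specified by the nominal
#' parameter set; it defaults to the cell width (the model is isopotential
#' in that direction, so depth only scales areas uniformly).
#'
#' @param nRows,nCols sheet size in cells (transverse x longitudinal).
#' @param cellLength,cellWidth,cellDepth cell dimensions, um.
#' @param transverseOffset fraction of the cell width at which the end face
#'   of each cell steps, interlocking it with two longitudinal neighbours.
#' @param longitudinalOffset fraction of the cell length by which the two
#'   halves of the end face are staggered.
#' @param junctionalWidth junctional cleft width, nm.
#' @param lateralWidth lateral cleft width, um.
#' @param sigmaEffLateral,sigmaEffJunctional effective extracellular
#'   conductivities, mS/cm.
#' @param gjBar gap-junction coupling, mS/cm2 of gap-junction plaque area.
#' @param plaqueFraction fraction of the junctional interface area occupied
#'   by gap-junction plaques (the remainder is perinexal/free disc
#'   membrane), so the conductance of an interface is
#'   \code{gjBar * plaqueFraction * area}.
#' @param Cm membrane capacitance, uF/cm2.
#' @param sigmaI intracellular conductivity, mS/cm.
#' @param ionic ionic model description from \code{\link{ionicModel}}.
#' @param junctionalFraction fraction of total cellular sodium conductance
#'   on junctional membrane: 0.11 reproduces a uniform channel density
#'   (the junctional share of membrane area), 0.90 the polarized model.
#' @param dt solver time step, ms.
#' @param duration simulation duration, ms (\code{NA} = run until all cells
#'   have activated, up to \code{maxDuration}).
#' @param maxDuration cap on the auto-stopped duration, ms.
#' @param stimAmplitude stimulus current density over the stimulated cells'
#'   membrane, uA/cm2.
#' @param stimDuration stimulus pulse width, ms.
#' @return a validated \code{\link{ModelConfig}}.
#' @examples
#' cfg <- modelConfig(nRows = 2, nCols = 3)
#' cfg
#' @export
modelConfig <- function(nRows = 10, nCols = 20,
                        cellLength = 101, cellWidth = 24.1,
                        cellDepth = cellWidth,
                        transverseOffset = 0.5, longitudinalOffset = 0.2,
                        junctionalWidth = 15, lateralWidth = 0.1,
                        sigmaEffLateral = 159.1, sigmaEffJunctional = 17.8,
                        gjBar = 100, plaqueFraction = 0.3,
                        Cm = 1, sigmaI = 6.7,
                        ionic = ionicModel(),
                        junctionalFraction = 0.90,
                        dt = 0.005, duration = NA_real_, maxDuration = 40,
                        stimAmplitude = 150, stimDuration = 1) {
  new("ModelConfig",
      shape = list(length = cellLength, width = cellWidth, depth = cellDepth),
      layout = list(nRows = as.integer(nRows), nCols = as.integer(nCols),
                    transverseOffset = transverseOffset,
                    longitudinalOffset = longitudinalOffset),
      extracellular = list(junctionalWidth = junctionalWidth,
                           lateralWidth = lateralWidth,
                           sigmaEffLateral = sigmaEffLateral,
                           sigmaEffJunctional = sigmaEffJunctional),
      gapJunction = list(gjBar = gjBar, plaqueFraction = plaqueFraction),
      membrane = list(Cm = Cm, sigmaI = sigmaI),
      ionic = ionic,
      distribution = list(junctionalFraction = junctionalFraction),
      solver = list(dt = dt, duration = duration, maxDuration = maxDuration,
                    stimAmplitude = stimAmplitude,
                    stimDuration = stimDuration))
}

#' Junctional sodium fraction of the named channel distributions
#'
#' @param model \code{"uniform"} (11\% of sodium conductance at the
#'   intercalated disc, matching the junctional share of membrane area) or
#'   \code{"polarized"} (90\% at the disc).
#' @return the junctional fraction as a number.
#' @export
channelDistribution <- function(model = c("polarized", "uniform")) {
  model <- match.arg(model)
  c(polarized = 0.90, uniform = 0.11)[[model]]
}

config_as_list <- function(config) {
  list(shape = config@shape, layout = config@layout,
       extracellular = config@extracellular,
       gapJunction = config@gapJunction, membrane = config@membrane,
       ionic = config@ionic, distribution = config@distribution,
       solver = config@solver)
}

list_as_config <- function(x) {
  cfg <- modelConfig()
  for (slot in c("shape", "layout", "extracellular", "gapJunction",
                 "membrane", "ionic", "distribution", "solver")) {
    if (!is.null(x[[slot]])) {
      cur <- methods::slot(cfg, slot)
      cur[names(x[[slot]])] <- x[[slot]]
      methods::slot(cfg, slot) <- cur
    }
  }
  cfg@layout$nRows <- as.integer(cfg@layout$nRows)
  cfg@layout$nCols <- as.integer(cfg@layout$nCols)
  methods::validObject(cfg)
  cfg
}

#' Read or write a model configuration
#'
#' Configurations serialize to YAML (or JSON, by file extension) with keys
#' mirroring the parameter names and units of \code{\link{modelConfig}}.
#'
#' @param path file path; \code{.yaml}/\code{.yml} or \code{.json}.
#' @param config a \code{\link{ModelConfig}}.
#' @return \code{readModelConfig} returns a \code{\link{ModelConfig}};
#'   \code{writeModelConfig} returns \code{path} invisibly.
#' @export
readModelConfig <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  list_as_config(x)
}

#' @rdname readModelConfig
#' @export
writeModelConfig <- function(config, path) {
  x <- config_as_list(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @describeIn modelConfig compact printout of a configuration
#' @param object a \code{ModelConfig}
#' @export
setMethod("show", "ModelConfig", function(object) {
  s <- object@shape; l <- object@layout; e <- object@extracellular
  cat(sprintf("ModelConfig: %d x %d sheet of %.1f x %.1f x %.1f um cells\n",
              l$nRows, l$nCols, s$length, s$width, s$depth))
  cat(sprintf("  offsets: transverse %.0f%% of width, longitudinal %.0f%% of length\n",
              100 * l$transverseOffset, 100 * l$longitudinalOffset))
  cat(sprintf("  clefts: junctional %g nm (sigma_eff %.1f mS/cm), lateral %g um (sigma_eff %.1f mS/cm)\n",
              e$junctionalWidth, e$sigmaEffJunctional,
              e$lateralWidth, e$sigmaEffLateral))
  cat(sprintf("  gj: %.1f mS/cm2 | Cm %.1f uF/cm2, sigma_i %.1f mS/cm\n",
              object@gapJunction$gjBar, object@membrane$Cm,
              object@membrane$sigmaI))
  cat(sprintf("  ionic: %s (gNa %.1f x %.2f, gK %.2f mS/cm2), junctional Na fraction %.2f\n",
              object@ionic$type, object@ionic$gNa, object@ionic$gNaScale,
              object@ionic$gK, object@distribution$junctionalFraction))
  cat(sprintf("  solver: dt %g ms, stimulus %g uA/cm2 for %g ms\n",
              object@solver$dt, object@solver$stimAmplitude,
              object@solver$stimDuration))
})
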