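# Named experimental interventions and the parameter sweeps behind the
# model predictions.

intervention_table <- list(
  AIE = function(cfg) {            # acute interstitial edema
    cfg@extracellular$sigmaEffLateral <- 203.5
    cfg@extracellular$sigmaEffJunctional <- 62.8
    cfg
  },
  GJ_uncoupling = function(cfg) {  # carbenoxolone: 50% of nominal coupling
    cfg@gapJunction$gjBar <- 50
    cfg
  },
  INa_inhibition = function(cfg) { # flecainide: g_Na at 86% of nominal
    cfg@ionic$gNaScale <- 0.86
    cfg
  })

#' Apply named interventions to a configuration
#'
#' The named interventions set the intervention parameter values of the
#' model: \code{AIE} raises the effective extracellular conductivities to
#' 203.5 (lateral) and 62.8 (junctional) mS/cm, \code{GJ_uncoupling} halves
#' the gap-junction coupling to 50 mS/cm2, and \code{INa_inhibition} scales
#' the sodium conductance to 86\% of nominal. Composition is commutative
#' (each intervention assigns absolute values to disjoint parameters) and
#' unflagged parameters are untouched.
#'
#' @param config the base \code{\link{ModelConfig}}.
#' @param interventions character vector among \code{"AIE"},
#'   \code{"GJ_uncoupling"}, \code{"INa_inhibition"} (empty = identity).
#' @return a new \code{\link{ModelConfig}}.
#' @examples
#' cfg <- applyInterventions(modelConfig(), c("AIE", "GJ_uncoupling"))
#' cfg@extracellular$sigmaEffJunctional   # 62.8
#' @export
applyInterventions <- function(config, interventions = character()) {
  unknown <- setdiff(interventions, names(intervention_table))
  if (length(unknown))
    stop("unknown intervention(s): ", paste(unknown, collapse = ", "))
  for (iv in interventions) config <- intervention_table[[iv]](config)
  methods::validObject(config)
  config
}

#' Sweep model predictions over channel distributions and interventions
#'
#' Evaluates conduction velocity and anisotropy over a grid of channel
#' distribution models, extracellular conductivity offsets, gap-junction
#' conductances and sodium-conductance scale factors: one longitudinal plus
#' one transverse simulation per grid point. The mesh is built once;
#' extracellular conductances and operators are re-assembled per grid
#' point. Rows where conduction failed carry \code{NA} velocities and a
#' block flag; the sweep is deterministic given the configuration.
#'
#' Edema is represented as an additive offset on both effective
#' extracellular conductivities, so \code{sigmaOffsets = c(0, 44.4)}
#' spans control and edema; alternatively pass intervention names through
#' \code{conditions}.
#'
#' @param config base \code{\link{ModelConfig}} (its \code{nRows} x
#'   \code{nCols} sets the sweep sheet).
#' @param models channel distributions to run, subset of
#'   \code{c("uniform", "polarized")}.
#' @param sigmaOffsets additive offsets (mS/cm) applied to both effective
#'   extracellular conductivities.
#' @param gjBars gap-junction conductances, mS/cm2.
#' @param gNaScales sodium conductance scale factors.
#' @return data.frame with one row per grid point and direction pair:
#'   model, sigma offsets and resulting conductivities, gjBar, gNaScale,
#'   cvL, cvT, ar, and block flags.
#' @export
runSweep <- function(config, models = c("uniform", "polarized"),
                     sigmaOffsets = 0, gjBars = config@gapJunction$gjBar,
                     gNaScales = 1) {
  stopifnot(length(sigmaOffsets) > 0, length(gjBars) > 0,
            length(gNaScales) > 0)
  grid <- expand.grid(model = models, sigmaOffset = sigmaOffsets,
                      gjBar = gjBars, gNaScale = gNaScales,
                      stringsAsFactors = FALSE)
  mesh0 <- buildTissueSheet(config)
  base <- config
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cfg <- base
    cfg@distribution$junctionalFraction <- channelDistribution(g$model)
    cfg@extracellular$sigmaEffLateral <-
      base@extracellular$sigmaEffLateral + g$sigmaOffset
    cfg@extracellular$sigmaEffJunctional <-
      base@extracellular$sigmaEffJunctional + g$sigmaOffset
    cfg@gapJunction$gjBar <- g$gjBar
    cfg@ionic$gNaScale <- g$gNaScale
    row <- data.frame(model = g$model,
                      sigmaOffset = g$sigmaOffset,
                      sigmaEffLateral = cfg@extracellular$sigmaEffLateral,
                      sigmaEffJunctional = cfg@extracellular$sigmaEffJunctional,
                      gjBar = g$gjBar, gNaScale = g$gNaScale,
                      cvL = NA_real_, cvT = NA_real_, ar = NA_real_,
                      blockedL = NA, blockedT = NA, error = NA_character_)
    res <- tryCatch({
      mesh <- assembleCleftNetwork(mesh0, cfg@extracellular)
      mesh@gapJunction <- cfg@gapJunction
      cv <- simulateCV(cfg, mesh = mesh)
      row$cvL <- cv@cvL; row$cvT <- cv@cvT; row$ar <- cv@ar
      row$blockedL <- cv@fits$longitudinal$blocked
      row$blockedT <- cv@fits$transverse$blocked
      row
    }, error = function(e) { row$error <- conditionMessage(e); row })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
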