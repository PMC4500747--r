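# Ionic membrane model: fast sodium current with m^3*h gating
# (Ebihara-Johnson style rate constants) plus an instantaneous
# potassium/leak current. Gating is integrated with exponential
# (Rush-Larsen) updates, which are unconditionally stable for the stiff
# activation gate at the upstroke.

# rate constants in 1/ms, V in mV
alpha_m <- function(V) {
  x <- V + 47.13
  ifelse(abs(x) < 1e-6, 3.2, 0.32 * x / (1 - exp(-0.1 * x)))
}
beta_m <- function(V) 0.08 * exp(-V / 11)

alpha_h <- function(V) ifelse(V < -40, 0.135 * exp(-(V + 80) / 6.8), 0)
beta_h <- function(V) {
  ifelse(V < -40,
         3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V),
         1 / (0.13 * (1 + exp(-(V + 10.66) / 11.1))))
}

#' Steady state and time constants of the sodium gates
#'
#' @param V membrane potential, mV (vectorized).
#' @return list with \code{mInf}, \code{hInf}, \code{tauM}, \code{tauH}
#'   (time constants in ms).
#' @export
gatingSteadyState <- function(V) {
  am <- alpha_m(V); bm <- beta_m(V)
  ah <- alpha_h(V); bh <- beta_h(V)
  list(mInf = am / (am + bm), hInf = ah / (ah + bh),
       tauM = 1 / (am + bm), tauH = 1 / (ah + bh))
}

#' Advance the gating state by one time step
#'
#' Exponential (Rush-Larsen) update at frozen membrane potential:
#' \eqn{s(t+dt) = s_\infty + (s - s_\infty) e^{-dt/\tau_s}}. This equals the
#' exact solution of each first-order gate ODE for constant voltage and
#' reduces to forward Euler as \eqn{dt \to 0}; gating variables stay in
#' [0, 1] for any dt.
#'
#' @param state list with numeric vectors \code{m} and \code{h}.
#' @param V membrane potential per patch, mV.
#' @param dt time step, ms.
#' @return the updated state list.
#' @export
stepGating <- function(state, V, dt) {
  stopifnot(dt > 0)
  g <- gatingSteadyState(V)
  list(m = g$mInf + (state$m - g$mInf) * exp(-dt / g$tauM),
       h = g$hInf + (state$h - g$hInf) * exp(-dt / g$tauH))
}

#' Ionic current density of a membrane patch
#'
#' For the Hodgkin-Huxley-type model,
#' \eqn{I = g_{Na} m^3 h (V - E_{Na}) + g_K (V - E_K)} with the patch-local
#' sodium conductance density \code{gNa} (see
#' \code{\link{partitionChannels}}); for the passive model,
#' \eqn{I = g_{leak} (V - V_{rest})}. Outward current is positive. Pure
#' function; vectorized over patches.
#'
#' @param V membrane potential, mV.
#' @param state gating state list (\code{m}, \code{h}); ignored by the
#'   passive model.
#' @param ionic ionic model description (\code{\link{ionicModel}}).
#' @param gNa patch-local peak sodium conductance density, mS/cm2.
#' @return current density, uA/cm2.
#' @export
ionicCurrent <- function(V, state, ionic, gNa = ionic$gNa) {
  if (ionic$type == "passive")
    return(ionic$gLeak * (V - ionic$Vrest))
  gNa * ionic$gNaScale * state$m^3 * state$h * (V - ionic$ENa) +
    ionic$gK * (V - ionic$EK)
}

#' Partition sodium conductance between junctional and lateral membrane
#'
#' The cell's total sodium conductance \eqn{G = \bar g_{Na} A_{total}} is
#' conserved for every junctional fraction \eqn{f}: junctional patches carry
#' \eqn{f G} spread uniformly over the junctional area, lateral patches the
#' remainder over the lateral area. \eqn{f = 0.11} reproduces a uniform
#' density (the junctional share of membrane area at nominal geometry);
#' \eqn{f = 0.90} is the polarized, intercalated-disc-enriched model.
#'
#' @param mesh a \code{\link{TissueMesh}}.
#' @param junctionalFraction fraction of total sodium conductance on
#'   junctional membrane, in [0, 1].
#' @param gNaBar peak sodium conductance density averaged over the whole
#'   membrane, mS/cm2.
#' @return numeric vector: sodium conductance density per patch (mS/cm2).
#' @export
partitionChannels <- function(mesh, junctionalFraction, gNaBar) {
  if (junctionalFraction < 0 || junctionalFraction > 1)
    stop("junctionalFraction must lie in [0, 1]")
  p <- mesh@patches
  jun <- p$class == "junctional"
  aJ <- sum(p$area[jun]); aL <- sum(p$area[!jun])
  G <- gNaBar * (aJ + aL)
  g <- numeric(nrow(p))
  if (aJ == 0) {
    if (junctionalFraction > 0)
      message("mesh has no junctional membrane; ",
              "placing all sodium conductance laterally")
    g[!jun] <- G / aL
  } else {
    g[jun] <- junctionalFraction * G / aJ
    g[!jun] <- (1 - junctionalFraction) * G / aL
  }
  g
}

# resting potential: zero of the steady-state ionic current
resting_potential <- function(ionic, gNa = ionic$gNa) {
  if (ionic$type == "passive") return(ionic$Vrest)
  f <- function(V) {
    g <- gatingSteadyState(V)
    ionicCurrent(V, list(m = g$mInf, h = g$hInf), ionic, gNa)
  }
  uniroot(f, c(-105, -50), tol = 1e-10)$root
}
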