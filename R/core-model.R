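#' Worm-like chain force law (Marko-Siggia interpolation)
#'
#' Entropic restoring force of a worm-like chain at end-to-end distance
#' `z`:
#' \deqn{f(z) = \frac{k_BT}{p}\left[\frac{1}{4(1-z/L)^2} - \frac14 +
#'   \frac{z}{L}\right]}
#' This interpolation is accurate to a few percent over the whole force
#' range and is the standard description of PEG spacer elasticity below
#' ~100 pN.
#'
#' @param z extension(s) in nm; must satisfy `0 <= z < L`.
#' @param model a [WLCModel-class].
#' @return Force(s) in pN; strictly increasing in `z`, 0 at `z = 0`,
#'   diverging as `z` approaches the contour length.
#' @examples
#' wlcForce(c(0, 80, 120), WLCModel(p = 0.38, L = 160))
#' @export
wlcForce <- function(z, model) {
  stopifnot(is(model, "WLCModel"))
  if (any(!is.finite(z)) || any(z < 0) || any(z >= model@L))
    stop("extension must satisfy 0 <= z < L")
  x <- z / model@L
  (model@kBT / model@p) * (0.25 / (1 - x)^2 - 0.25 + x)
}

#' Worm-like chain stiffness (analytic derivative of the force law)
#'
#' @inheritParams wlcForce
#' @return df/dz in pN/nm; positive on the whole domain, `(kBT/p) * 3/(2L)`
#'   at zero extension.
#' @examples
#' wlcStiffness(0, WLCModel())
#' @export
wlcStiffness <- function(z, model) {
  stopifnot(is(model, "WLCModel"))
  if (any(!is.finite(z)) || any(z < 0) || any(z >= model@L))
    stop("extension must satisfy 0 <= z < L")
  x <- z / model@L
  (model@kBT / model@p) * (0.5 / (1 - x)^3 + 1) / model@L
}

#' Force balance of the spacer-cantilever series circuit
#'
#' For a base (piezo) displacement `D`, solves the unique equilibrium of a
#' WLC spacer in series with a Hookean cantilever: the spacer extension `z`
#' and force `F` satisfying `wlcForce(z) = F` and `z + F/k_c = D`. The
#' residual `g(z) = z + wlcForce(z)/k_c - D` is strictly increasing, so the
#' root is found by damped Newton iteration safeguarded by bisection, to an
#' absolute tolerance of 1e-9 nm on the residual.
#'
#' @param D base displacement(s), nm, `>= 0`.
#' @param geom a [PullingGeometry-class] (only the cantilever stiffness is
#'   used).
#' @param model a [WLCModel-class] for the spacer.
#' @param tol absolute residual tolerance in nm.
#' @return A list with numeric vectors `force` (pN) and `extension` (nm),
#'   one element per input displacement. `force` is continuous and
#'   nondecreasing in `D`.
#' @examples
#' seriesEquilibrium(125, PullingGeometry(), WLCModel())
#' @export
seriesEquilibrium <- function(D, geom, model, tol = 1e-9) {
  stopifnot(is(geom, "PullingGeometry"), is(model, "WLCModel"))
  if (any(!is.finite(D)) || any(D < 0)) stop("'D' must be nonnegative")
  kc <- geom@cantileverStiffness
  L <- model@L
  zmax <- L * (1 - 1e-12)
  # g(z) = z + wlc(z)/kc - D is monotone; bracket is [0, min(D, zmax)]
  lo <- numeric(length(D))
  hi <- pmin(D, zmax)
  z <- pmin(D, 0.95 * hi + 0.05 * lo)
  for (iter in seq_len(100L)) {
    f <- wlcForce(z, model)
    g <- z + f / kc - D
    if (all(abs(g) < tol)) break
    hi <- ifelse(g > 0, pmin(hi, z), hi)
    lo <- ifelse(g < 0, pmax(lo, z), lo)
    step <- g / (1 + wlcStiffness(z, model) / kc)
    znew <- z - step
    bad <- !is.finite(znew) | znew <= lo | znew >= hi
    znew[bad] <- (lo[bad] + hi[bad]) / 2
    z <- znew
  }
  f <- wlcForce(z, model)
  if (any(abs(z + f / kc - D) >= tol))
    stop(sprintf("series equilibrium did not converge (max residual %.3g nm)",
                 max(abs(z + f / kc - D))))
  list(force = f, extension = z)
}

#' Series stiffness of the spacer-cantilever circuit
#'
#' Slope dF/dD of the force versus base displacement, i.e. the WLC
#' stiffness at the given spacer extension in series with the cantilever:
#' `1 / (1/k_wlc + 1/k_c)`. This is the slope an experimenter measures at
#' the point of rupture, and times the retract speed it gives the loading
#' rate dF/dt.
#'
#' @param z spacer extension(s), nm.
#' @inheritParams seriesEquilibrium
#' @return Stiffness(es) in pN/nm.
#' @export
seriesStiffness <- function(z, geom, model) {
  kw <- wlcStiffness(z, model)
  kc <- geom@cantileverStiffness
  kw * kc / (kw + kc)
}

#' Bell escape rate under force
#'
#' `k(F) = koff * exp(F * deltaX / kBT)`: thermally activated escape over a
#' single barrier tilted by the applied force.
#'
#' @param F force(s), pN, `>= 0`.
#' @param bell a [BellParameters-class].
#' @return Rate(s) in 1/s.
#' @examples
#' bellRate(44, BellParameters(3.2e-4, 1.29))
#' @export
bellRate <- function(F, bell) {
  stopifnot(is(bell, "BellParameters"))
  if (any(!is.finite(F)) || any(F < 0)) stop("'F' must be nonnegative")
  bell@koff * exp(F * bell@deltaX / bell@kBT)
}

#' Most probable rupture force under linear loading (Bell-Evans)
#'
#' For a constant loading rate `r`, the mode of the rupture-force
#' distribution of a Bell bond:
#' \deqn{F^* = \frac{k_BT}{\Delta x}\,
#'   \ln\frac{\dot r\,\Delta x}{k_{off}\,k_BT}}
#' clamped at 0 for sub-threshold loading rates (where the log is
#' negative, the distribution's mode sits at zero force). `F*` is linear
#' in `ln r` with slope `kBT/deltaX`.
#'
#' @param bell a [BellParameters-class]; `deltaX` must be positive.
#' @param loadingRate loading rate(s) `r` in pN/s, `> 0`.
#' @return Most probable rupture force(s), pN.
#' @examples
#' bellEvansMode(BellParameters(3.2e-4, 1.29), 1000)  # ~44 pN
#' @export
bellEvansMode <- function(bell, loadingRate) {
  stopifnot(is(bell, "BellParameters"))
  if (bell@deltaX <= 0) stop("'deltaX' must be positive: mode undefined")
  if (any(!is.finite(loadingRate)) || any(loadingRate <= 0))
    stop("'loadingRate' must be positive")
  pmax(0, (bell@kBT / bell@deltaX) *
            log(loadingRate * bell@deltaX / (bell@koff * bell@kBT)))
}

#' Rupture-force density under linear loading
#'
#' First-passage density of a Bell bond loaded at constant rate `r`:
#' \deqn{p(F) = \frac{k(F)}{\dot r} \exp\!\left[-\frac{k_{off} k_BT}
#'   {\dot r\,\Delta x}\left(e^{F\Delta x / k_BT} - 1\right)\right]}
#' It integrates to 1 on `[0, Inf)` and its argmax coincides with
#' [bellEvansMode()] when the mode is interior. For `deltaX = 0` the
#' escape rate is force-independent and the density degenerates to the
#' exponential law `koff/r * exp(-koff F / r)`.
#'
#' @param bell a [BellParameters-class].
#' @param loadingRate loading rate in pN/s, `> 0` (scalar).
#' @param F nonnegative, increasing force grid (pN).
#' @return Density values (1/pN) on the grid.
#' @seealso [ruptureForceQuantile()], [simulateLinearLoadingEvents()]
#' @export
ruptureForceDensity <- function(bell, loadingRate, F) {
  stopifnot(is(bell, "BellParameters"), length(loadingRate) == 1L)
  if (!is.finite(loadingRate) || loadingRate <= 0)
    stop("'loadingRate' must be positive")
  if (any(F < 0) || is.unsorted(F, strictly = FALSE))
    stop("'F' must be a nonnegative increasing grid")
  if (bell@deltaX == 0)
    return(bell@koff / loadingRate * exp(-bell@koff * F / loadingRate))
  a <- bell@deltaX / bell@kBT
  b <- bell@koff * bell@kBT / (loadingRate * bell@deltaX)
  (bell@koff * exp(a * F) / loadingRate) * exp(-b * expm1(a * F))
}

#' Quantile function of the linear-loading rupture-force law
#'
#' Inverse of the closed-form survival function
#' `S(F) = exp(-b (e^{aF} - 1))` with `a = deltaX/kBT` and
#' `b = koff kBT / (r deltaX)`; used for inverse-transform sampling.
#'
#' @inheritParams ruptureForceDensity
#' @param prob probabilities in (0, 1).
#' @return Forces (pN) with `P(F_rup <= F) = prob`.
#' @export
ruptureForceQuantile <- function(bell, loadingRate, prob) {
  stopifnot(is(bell, "BellParameters"), length(loadingRate) == 1L)
  if (any(prob <= 0) || any(prob >= 1)) stop("'prob' must be in (0, 1)")
  if (bell@deltaX == 0)
    return(-loadingRate / bell@koff * log1p(-prob))
  a <- bell@deltaX / bell@kBT
  b <- bell@koff * bell@kBT / (loadingRate * bell@deltaX)
  log1p(-log1p(-prob) / b) / a
}

#' Upper bound on the thermal off-rate from equilibrium constants
#'
#' `k_off <= K_D * k_on`: with `K_D < 1e-10` M and `k_on` of order
#' `1e5-1e6 1/(M s)` (typical for short dimeric coiled coils), the
#' force-free dissociation rate is bounded by `1e-4 1/s`.
#'
#' @param bound a [KineticBound-class].
#' @return The implied `k_off` upper bound in 1/s.
#' @examples
#' koffUpperBound(KineticBound(1e-10, 1e6))
#' @export
koffUpperBound <- function(bound) {
  stopifnot(is(bound, "KineticBound"))
  bound@koffMax
}
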