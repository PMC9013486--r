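#' Kinetic constants of the C4 photosynthesis model
#'
#' Bundles the enzymatic and anatomical constants of the two-cell C4 model:
#' Michaelis constants of Rubisco for CO2 (`Kc`, ubar) and O2 (`Ko`, mbar),
#' the Michaelis constant of PEP carboxylation (`Kp`, ubar), half the
#' reciprocal of Rubisco specificity (`gamma_star`, dimensionless on a
#' bar/bar basis), bundle-sheath O2 partial pressure (`Os`, mbar),
#' bundle-sheath conductance to CO2 (`gbs`, mol m-2 s-1 bar-1), the
#' partitioning factor of electron transport to the C4 cycle (`x`), the ATP
#' requirement of the C4 cycle (`phi`) and the mesophyll share of dark
#' respiration (`rm_ratio`, so that Rm = rm_ratio * Rd).
#'
#' The defaults are a documented set drawn from the standard C4 modelling
#' literature; every value can be overridden, and all fitting routines record
#' the constant set they used.
#'
#' @param Kc Michaelis constant of Rubisco for CO2 (ubar).
#' @param Ko Michaelis constant of Rubisco for O2 (mbar).
#' @param Kp Michaelis constant of PEP carboxylation for CO2 (ubar).
#' @param gamma_star Half reciprocal of Rubisco specificity (bar/bar).
#' @param Os Bundle-sheath O2 partial pressure (mbar).
#' @param gbs Bundle-sheath conductance to CO2 (mol m-2 s-1 bar-1).
#' @param x Electron-transport partitioning factor to the C4 cycle.
#' @param phi ATP requirement of the C4 cycle.
#' @param rm_ratio Ratio of mesophyll to total mitochondrial respiration.
#' @return An object of class `c4_constants`.
#' @export
#' @examples
#' consts <- c4_constants()
#' consts$Kc
c4_constants <- function(Kc = 1210, Ko = 292, Kp = 82, gamma_star = 0.000193,
                         Os = 210, gbs = 0.003, x = 0.4, phi = 2,
                         rm_ratio = 0.5) {
  vals <- c(Kc = Kc, Ko = Ko, Kp = Kp, gamma_star = gamma_star, Os = Os,
            gbs = gbs, x = x, phi = phi, rm_ratio = rm_ratio)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all C4 constants must be finite and strictly positive")
  if (x >= 1) stop("x must lie in (0, 1)")
  if (rm_ratio > 1) stop("rm_ratio must lie in (0, 1]")
  structure(as.list(vals), class = "c4_constants")
}

#' Leaf-level photosynthetic parameter set
#'
#' The parameters estimated (or assumed) for a single leaf: maximal Rubisco
#' carboxylation rate `Vcmax`, maximal PEP carboxylation rate `Vpmax`,
#' maximal electron transport rate `Jmax` (all umol m-2 s-1), mitochondrial
#' respiration in the light `Rd` (umol m-2 s-1), the empirical curvature
#' factor `theta` of the light response, the fraction of incident light
#' absorbed and useful to PSII `PSabs`, and mesophyll conductance `gm`
#' (mol m-2 s-1 bar-1).
#'
#' @param Vcmax,Vpmax,Jmax Maximal rates (umol m-2 s-1), non-negative.
#' @param Rd Day respiration (umol m-2 s-1), non-negative.
#' @param theta Curvature factor in (0, 1).
#' @param PSabs Absorbed-and-useful light fraction in (0, 1).
#' @param gm Mesophyll conductance (mol m-2 s-1 bar-1), positive.
#' @return An object of class `leaf_params`.
#' @export
leaf_params <- function(Vcmax = 50, Vpmax = 400, Jmax = 400, Rd = 2,
                        theta = 0.3, PSabs = 0.35, gm = 1) {
  if (any(c(Vcmax, Vpmax, Jmax, Rd, gm) < 0))
    stop("Vcmax, Vpmax, Jmax, Rd and gm must be non-negative")
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)")
  if (PSabs <= 0 || PSabs >= 1) stop("PSabs must lie in (0, 1)")
  structure(list(Vcmax = Vcmax, Vpmax = Vpmax, Jmax = Jmax, Rd = Rd,
                 theta = theta, PSabs = PSabs, gm = gm),
            class = "leaf_params")
}

#' Leaf environment for one or more gas-exchange steps
#'
#' Either `Ci` (intercellular CO2 partial pressure, ubar) is given per step,
#' or it is derived as `Ca * ci_over_ca`. CO2 mole fractions in ppm are
#' treated as numerically equal to partial pressures in ubar (1 bar total
#' pressure).
#'
#' @param Ca Ambient CO2 partial pressure (ubar), vectorised.
#' @param I_inc Incident photosynthetically active radiation
#'   (umol photons m-2 s-1), vectorised.
#' @param Ci Optional measured intercellular CO2 (ubar).
#' @param ci_over_ca Fixed Ci/Ca ratio used when `Ci` is absent.
#' @return A data frame with columns `Ca`, `Ci`, `I_inc`.
#' @export
leaf_env <- function(Ca, I_inc, Ci = NULL, ci_over_ca = 0.4) {
  if (any(Ca < 0) || any(I_inc < 0)) stop("Ca and I_inc must be non-negative")
  if (is.null(Ci)) {
    if (ci_over_ca <= 0 || ci_over_ca > 1)
      stop("ci_over_ca must lie in (0, 1]")
    Ci <- Ca * ci_over_ca
  }
  data.frame(Ca = Ca, Ci = Ci, I_inc = I_inc)
}

#' Electron transport rate from the non-rectangular hyperbola
#'
#' Returns the smaller root `Jt` of
#' `theta * Jt^2 - (I2 + Jmax) * Jt + I2 * Jmax = 0`, the non-rectangular
#' hyperbola of whole-chain electron transport against absorbed light `I2`.
#' The root is evaluated in the cancellation-free form
#' `2 * I2 * Jmax / (b + sqrt(b^2 - 4 * theta * I2 * Jmax))` with
#' `b = I2 + Jmax`, which is exact at `I2 = 0` and tends to the rectangular
#' hyperbola as `theta` tends to 0.
#'
#' @param I2 Light absorbed by PSII (umol m-2 s-1), vectorised.
#' @param Jmax Maximal electron transport rate (umol m-2 s-1).
#' @param theta Curvature factor in (0, 1).
#' @return Electron transport rate(s), `0 <= Jt <= min(I2, Jmax)`.
#' @export
#' @examples
#' electron_transport_rate(500, Jmax = 400, theta = 0.3)
electron_transport_rate <- function(I2, Jmax, theta) {
  if (any(I2 < 0)) stop("I2 must be non-negative")
  if (any(Jmax <= 0)) stop("Jmax must be positive")
  if (any(theta <= 0) || any(theta >= 1)) stop("theta must lie in (0, 1)")
  b <- I2 + Jmax
  disc <- b^2 - 4 * theta * I2 * Jmax
  if (any(disc < 0)) stop("negative discriminant in electron transport rate")
  2 * I2 * Jmax / (b + sqrt(disc))
}

# Demand-side rates of the two limiting regimes, as functions of bundle-sheath
# CO2. gamma_star * Os must be in ubar (Os is stored in mbar).
.ac_demand <- function(Cs, params, consts) {
  gOs <- consts$gamma_star * consts$Os * 1000
  (Cs - gOs) * params$Vcmax /
    (Cs + consts$Kc * (1 + consts$Os / consts$Ko)) - params$Rd
}

.aj_demand <- function(Cs, Jt, params, consts) {
  gOs <- consts$gamma_star * consts$Os * 1000
  ((1 - consts$x) * Jt / 3) *
    (1 - gOs / Cs) / (1 + 7 * gOs / (3 * Cs)) - params$Rd
}

# Supply chain shared by both regimes: mesophyll CO2 from eq. Cm = Ci - A/gm,
# bundle-sheath CO2 from Cs = Cm + (pump - A - Rm)/gbs, where pump is the PEP
# carboxylation rate (enzyme regime) or x*Jt/phi (light regime). Cm and Cs are
# floored at tiny positive values for evaluation; the unfloored Cm is used for
# the non-physical flag.
.supply_cs <- function(A, Ci, pump_fun, params, consts) {
  Cm_raw <- Ci - A / params$gm
  Cm <- pmax(Cm_raw, 0)
  Rm <- consts$rm_ratio * params$Rd
  Cs <- Cm + (pump_fun(Cm) - A - Rm) / consts$gbs
  list(Cs = pmax(Cs, 1e-9), Cm_raw = Cm_raw, Cm = Cm)
}

# Vectorised bisection on the self-consistency residual f(A) = A - demand(A).
# f is non-decreasing in A (higher assimilation depletes the supply chain), so
# the sign change is unique; 60 halvings of a bracket ~Vcmax wide resolve A to
# machine precision.
.bisect_A <- function(residual, lo, hi, n_iter = 52) {
  for (i in seq_len(n_iter)) {
    mid <- 0.5 * (lo + hi)
    pos <- residual(mid) >= 0
    hi[pos] <- mid[pos]
    lo[!pos] <- mid[!pos]
  }
  0.5 * (lo + hi)
}

#' Enzyme-limited net CO2 assimilation
#'
#' Solves the coupled supply/demand system of the enzyme-limited regime:
#' mesophyll CO2 `Cm = Ci - A/gm`, PEP carboxylation
#' `Vp = Cm * Vpmax / (Cm + Kp)`, bundle-sheath CO2
#' `Cs = Cm + (Vp - A - Rm)/gbs`, and the Rubisco-limited demand `Ac(Cs)`.
#' The self-consistent `A` is found by bracketed bisection on
#' `f(A) = A - Ac(Cs(A))`, which is monotone, taking the lowest (physical)
#' root. The bracket is `[-Rd - 1, min(Vcmax, Vpmax) + 1]`, widened to
#' `Vcmax + 1` (a guaranteed upper bound since `Ac < Vcmax - Rd`) if the
#' narrow bound does not bracket the root.
#'
#' @param env A data frame from [leaf_env()] (one row per step).
#' @param params A [leaf_params()] object.
#' @param consts A [c4_constants()] object.
#' @param details If `TRUE`, return a data frame with the solution and the
#'   supply-chain state (`Cm`, `Cs`, `Vp`, residual, non-physical flag).
#' @return Net assimilation (umol m-2 s-1) per step, or a data frame when
#'   `details = TRUE`.
#' @export
enzyme_limited_A <- function(env, params, consts = c4_constants(),
                             details = FALSE) {
  Ci <- env$Ci
  pump <- function(Cm) Cm * params$Vpmax / (Cm + consts$Kp)
  residual <- function(A) {
    s <- .supply_cs(A, Ci, pump, params, consts)
    A - .ac_demand(s$Cs, params, consts)
  }
  lo <- rep(-params$Rd - 1, length(Ci))
  hi <- rep(min(params$Vcmax, params$Vpmax) + 1, length(Ci))
  widen <- residual(hi) < 0
  hi[widen] <- params$Vcmax + 1
  A <- .bisect_A(residual, lo, hi)
  if (!details) return(A)
  s <- .supply_cs(A, Ci, pump, params, consts)
  data.frame(A = A, Cm = s$Cm_raw, Cs = s$Cs, Vp = pump(s$Cm),
             residual = residual(A), nonphysical = s$Cm_raw <= 0)
}

#' Electron-transport-limited net CO2 assimilation
#'
#' As [enzyme_limited_A()] but with the PEP pump replaced by the C4-cycle
#' share of electron transport, `x * Jt / phi`, and the demand by the
#' C3-cycle share `(1 - x) * Jt / 3` scaled by the bundle-sheath
#' oxygenation terms. `Jt` comes from [electron_transport_rate()] with
#' `I2 = PSabs * I_inc`. The bisection bracket is `[-Rd - 1, Jt + 1]`; the
#' gross light-limited rate cannot exceed `(1 - x) * Jt / 3 < Jt`.
#'
#' @inheritParams enzyme_limited_A
#' @return Net assimilation (umol m-2 s-1) per step, or a data frame when
#'   `details = TRUE`.
#' @export
light_limited_A <- function(env, params, consts = c4_constants(),
                            details = FALSE) {
  Ci <- env$Ci
  I2 <- params$PSabs * env$I_inc
  Jt <- ifelse(I2 > 0,
               electron_transport_rate(pmax(I2, 1e-12), params$Jmax,
                                       params$theta),
               0)
  pump_of <- function(Jt) consts$x * Jt / consts$phi
  residual <- function(A) {
    s <- .supply_cs(A, Ci, function(Cm) pump_of(Jt), params, consts)
    A - .aj_demand(s$Cs, Jt, params, consts)
  }
  lo <- rep(-params$Rd - 1, length(Ci))
  hi <- Jt + 1
  A <- .bisect_A(residual, lo, hi)
  if (!details) return(A)
  s <- .supply_cs(A, Ci, function(Cm) pump_of(Jt), params, consts)
  data.frame(A = A, Cm = s$Cm_raw, Cs = s$Cs, Jt = Jt,
             residual = residual(A), nonphysical = s$Cm_raw <= 0)
}

#' Net CO2 assimilation as the minimum of the two limited rates
#'
#' `A = min(Ac, Aj)`: the realised assimilation is whichever of the
#' enzyme-limited and electron-transport-limited self-consistent rates is
#' lower at the given environment.
#'
#' @inheritParams enzyme_limited_A
#' @param details If `TRUE`, return a data frame with `A`, both component
#'   rates and the limiting regime (`"enzyme"` or `"light"`).
#' @return Net assimilation per step, or a data frame when `details = TRUE`.
#' @export
net_assimilation <- function(env, params, consts = c4_constants(),
                             details = FALSE) {
  Ac <- enzyme_limited_A(env, params, consts)
  Aj <- light_limited_A(env, params, consts)
  A <- pmin(Ac, Aj)
  if (!details) return(A)
  data.frame(A = A, Ac = Ac, Aj = Aj,
             regime = ifelse(Ac <= Aj, "enzyme", "light"))
}

#' Gas-exchange measurement protocols
#'
#' `aci_protocol()` is the CO2-response protocol: reference CO2 stepped
#' through 200, 100, 50, 250, 400, 650, 800, 1000, 1200 and 1400 ppm at a
#' fixed PAR of 1800 umol m-2 s-1. `ai_protocol()` is the light-response
#' protocol: PAR stepped through 2000, 1500, 1000, 500, 250, 120, 60, 30, 15
#' and 0 umol m-2 s-1 at a fixed reference CO2 of 400 ppm.
#'
#' @param ci_over_ca Ci/Ca ratio used to derive intercellular CO2 when no
#'   measured Ci accompanies the protocol.
#' @return An object of class `curve_protocol` with fields `kind`, `Ca`,
#'   `I_inc`, `ci_over_ca`.
#' @export
aci_protocol <- function(ci_over_ca = 0.4) {
  structure(list(kind = "ACi",
                 Ca = c(200, 100, 50, 250, 400, 650, 800, 1000, 1200, 1400),
                 I_inc = rep(1800, 10), ci_over_ca = ci_over_ca),
            class = "curve_protocol")
}

#' @rdname aci_protocol
#' @export
ai_protocol <- function(ci_over_ca = 0.4) {
  structure(list(kind = "Ai",
                 Ca = rep(400, 10),
                 I_inc = c(2000, 1500, 1000, 500, 250, 120, 60, 30, 15, 0),
                 ci_over_ca = ci_over_ca),
            class = "curve_protocol")
}

#' Predict a response curve with the forward model
#'
#' Evaluates [net_assimilation()] at every step of a measurement protocol,
#' in protocol order.
#'
#' @param protocol A `curve_protocol` from [aci_protocol()] or
#'   [ai_protocol()], optionally carrying a `Ci` vector of measured
#'   intercellular CO2.
#' @param params A [leaf_params()] object.
#' @param consts A [c4_constants()] object.
#' @return A data frame with one row per step: `kind`, `step`, `A`, `Ca`,
#'   `Ci`, `I_inc`.
#' @export
predict_curve <- function(protocol, params, consts = c4_constants()) {
  if (length(protocol$Ca) == 0) stop("empty protocol")
  env <- leaf_env(protocol$Ca, protocol$I_inc, Ci = protocol$Ci,
                  ci_over_ca = protocol$ci_over_ca)
  A <- net_assimilation(env, params, consts)
  data.frame(kind = protocol$kind, step = seq_along(A), A = A,
             Ca = env$Ca, Ci = env$Ci, I_inc = env$I_inc)
}
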