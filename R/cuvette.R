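#' Cuvette chamber configuration
#'
#' Geometry, flow, pressure and boundary-layer conductance of the leaf
#' chamber. The cuvette volume and molar volume describe the air reservoir;
#' at steady state the accumulation terms vanish, so neither enters the
#' solved mole fractions (asserted by test).
#'
#' @param af Air flow through the chamber (mol s-1).
#' @param s Leaf area (m2).
#' @param p_air Air pressure (Pa).
#' @param g_bw Boundary-layer conductance for water vapour (mol m-2 s-1).
#' @param v_cv Cuvette volume (m3).
#' @param v_m Molar volume (m3 mol-1) at 298 K and 100 kPa.
#' @return An object of class \code{chamber_config}.
#' @export
chamber_config <- function(af = 3.5e-4, s = 9e-4, p_air = 103100,
                           g_bw = 2.44, v_cv = 109e-6, v_m = 0.0248) {
  stopifnot(all(af > 0), all(s > 0), all(p_air > 0), all(g_bw > 0),
            v_cv > 0, v_m > 0)
  structure(list(af = af, s = s, p_air = p_air, g_bw = g_bw,
                 v_cv = v_cv, v_m = v_m),
            class = "chamber_config")
}

#' Leaf physiological parameter set
#'
#' Bundles the stomatal/mesophyll conductances for water with the enzyme
#' kinetics and compensation-point model for one plant.
#'
#' @param g_sw Stomatal conductance for H2O (mol m-2 s-1), in [0, 3].
#' @param ca A \code{ca_kinetics} object.
#' @param rub A \code{rubisco_kinetics} object.
#' @param gamma A \code{gamma_cos_spec} object.
#' @param co2c A \code{co2_constants} object.
#' @param g_mw Mesophyll conductance for H2O (mol m-2 s-1); large default so
#'   the intercellular airspace stays near saturation.
#' @return An object of class \code{leaf_parameters}.
#' @export
leaf_parameters <- function(g_sw, ca, rub, gamma = gamma_cos_spec(),
                            co2c = co2_constants(), g_mw = 10) {
  stopifnot(all(g_sw >= 0), all(g_sw <= 3), all(g_mw > 0))
  structure(list(g_sw = g_sw, g_mw = g_mw, ca = ca, rub = rub,
                 gamma = gamma, co2c = co2c),
            class = "leaf_parameters")
}

#' Species conductances from water-vapour conductances
#'
#' Stomatal and boundary-layer conductances for COS and CO2 scaled from the
#' water-vapour values by fixed diffusivity ratios.
#'
#' @param g_sw Stomatal conductance for H2O (mol m-2 s-1).
#' @param g_bw Boundary conductance for H2O (mol m-2 s-1).
#' @return List with \code{g_s_co2}, \code{g_b_co2}, \code{g_s_cos},
#'   \code{g_b_cos} and the water values.
#' @export
species_conductances <- function(g_sw, g_bw = 2.44) {
  list(g_s_h2o = g_sw, g_b_h2o = g_bw,
       g_s_co2 = g_sw / 1.6, g_b_co2 = g_bw / 1.4,
       g_s_cos = g_sw / 1.94, g_b_cos = g_bw / 1.56)
}

#' Wet/dry basis conversion of mole fractions
#'
#' @param x_wet,x_dry Mole fraction on wet/dry-air basis (any per-mol unit).
#' @param h2o Water vapour mole fraction (mmol mol-1), in [0, 1000).
#' @return Converted mole fraction.
#' @export
wet_to_dry <- function(x_wet, h2o) {
  if (any(h2o >= 1000) || any(h2o < 0)) stop("h2o must be in [0, 1000)")
  x_wet / (1 - h2o / 1000)
}

#' @rdname wet_to_dry
#' @export
dry_to_wet <- function(x_dry, h2o) {
  if (any(h2o >= 1000) || any(h2o < 0)) stop("h2o must be in [0, 1000)")
  x_dry * (1 - h2o / 1000)
}

#' Net flux from the chamber mass balance
#'
#' @param cfg A \code{chamber_config}.
#' @param x_in,x_a Inflow and chamber (ambient) mole fractions.
#' @return Flux per leaf area, uptake positive (per-gas units m-2 s-1).
#' @export
net_flux <- function(cfg, x_in, x_a) {
  (cfg$af / cfg$s) * (x_in - x_a)
}

## --- internal vectorized solvers -----------------------------------------
## All take plain numeric vectors (recycled) so the inversion can run the
## whole dataset in one call.

.solve_h2o_core <- function(q, g_bw, g_sw, g_mw, x_in, t_leaf, p_air) {
  x_c <- h2o_saturated_mole_fraction(t_leaf, p_air)
  ## inflow drier than saturation is the physical regime; wetter inflow
  ## reverses the flux sign and the same linear chain still applies
  g_tot <- 1 / (1 / q + 1 / g_bw + 1 / g_sw + 1 / g_mw)
  flux <- g_tot * (x_in - x_c)            # mmol m-2 s-1, uptake-positive
  x_a <- x_in - flux / q
  x_b <- x_a - flux / g_bw
  x_i <- x_b - flux / g_sw
  e <- -flux / 1000                        # mol m-2 s-1, outward-positive
  list(x_a = x_a, x_b = x_b, x_i = x_i, x_c = x_c, flux = flux,
       e_h2o = e, rh_i = 100 * x_i / x_c)
}

.solve_cos_core <- function(q, g_b, g_s, g_m, x_in, gamma, e) {
  g1 <- 1 / (1 / q + 1 / g_b)              # inflow-to-boundary series
  gsp <- g_s + e / 2
  gsm <- g_s - e / 2
  ## eliminate layers: flux F satisfies
  ## F [gsp + g_m*gsm/g1 + g_m] = g_m [gsm*x_in - gamma*gsp]
  flux <- g_m * (gsm * x_in - gamma * gsp) /
    (gsp + g_m * gsm / g1 + g_m)
  x_a <- x_in - flux / q
  x_b <- x_a - flux / g_b
  x_i <- (gsm * x_b - flux) / gsp
  list(x_a = x_a, x_b = x_b, x_i = x_i, x_c = rep(gamma, length.out = length(x_a)),
       flux = flux)
}

.solve_co2_core <- function(q, g_b, g_s, x_in, t_leaf, p_air, e,
                            v_max_rub, dH_a_rub, consts, tol = 1e-12,
                            maxit = 90L) {
  n <- max(length(x_in), length(t_leaf), length(g_s), length(q), length(e),
           length(v_max_rub), length(dH_a_rub))
  rec <- function(v) rep_len(v, n)
  q <- rec(q); g_b <- rec(g_b); g_s <- rec(g_s); x_in <- rec(x_in)
  t_leaf <- rec(t_leaf); p_air <- rec(p_air); e <- rec(e)
  v_max_rub <- rec(v_max_rub); dH_a_rub <- rec(dH_a_rub)

  kc <- q10_scale(consts$kc_298, consts$q10_kc, t_leaf)
  ko <- q10_scale(consts$ko_298, consts$q10_ko, t_leaf)
  gstar <- gamma_star_co2(t_leaf, consts)
  rd <- dark_respiration(t_leaf, consts)
  frub <- exp(((t_leaf + .T0K) - 298) * dH_a_rub /
                (298 * .R_GAS * (t_leaf + .T0K)))
  km <- kc * (1 + consts$p_o2_i / ko)
  inv_g1 <- 1 / q + 1 / g_b
  gsp <- g_s + e / 2
  gsm <- g_s - e / 2

  sink_fun <- function(x_i) {
    p_i <- x_i * p_air * 1e-6
    v_max_rub * frub * (p_i - gstar) / (p_i + km) - rd
  }
  ## residual: intercellular mole fraction implied by the diffusive chain at
  ## the mesophyll sink rate, minus the candidate. Strictly decreasing in x_i.
  resid <- function(x_i) {
    f <- sink_fun(x_i)
    x_b <- x_in - f * inv_g1
    (gsm * x_b - f) / gsp - x_i
  }
  lo <- rep_len(1e-9, n)
  hi <- 2 * x_in
  rlo <- resid(lo)
  rhi <- resid(hi)
  ## respiration behind nearly shut stomata can push the intercellular mole
  ## fraction far above the inflow; widen the bracket geometrically
  for (k in 1:40) {
    grow <- rhi > 0
    if (!any(grow)) break
    hi[grow] <- hi[grow] * 8
    rhi[grow] <- resid(hi)[grow]
  }
  bad <- which(rlo < 0 | rhi > 0)
  if (length(bad)) {
    stop(sprintf(
      "CO2 solver bracket has no sign change at point(s) %s (resid lo %.3g, hi %.3g)",
      paste(utils::head(bad, 5), collapse = ","), rlo[bad[1]], rhi[bad[1]]))
  }
  for (it in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    rm <- resid(mid)
    pos <- rm > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
    if (max(hi - lo) < tol * max(x_in)) break
  }
  x_i <- (lo + hi) / 2
  f <- sink_fun(x_i)
  x_a <- x_in - f / q
  x_b <- x_a - f / g_b
  p_i <- x_i * p_air * 1e-6
  x_c <- NA_real_  # no explicit chloroplast pool: sink given by enzyme model
  list(x_a = x_a, x_b = x_b, x_i = x_i, x_c = x_c, flux = f, p_co2_i = p_i)
}

## --- typed user-facing solvers -------------------------------------------

#' Steady-state water-vapour profile of the chamber-leaf system
#'
#' Solves the linear conductance chain from chamber inflow to the saturated
#' mesophyll surface and reports the layer mole fractions, transpiration and
#' intercellular relative humidity.
#'
#' @param cfg A \code{chamber_config}.
#' @param leaf A \code{leaf_parameters} object.
#' @param x_in Inflow H2O mole fraction (mmol mol-1).
#' @param t_leaf Leaf temperature (degrees C).
#' @return List with layers \code{x_a}, \code{x_b}, \code{x_i}, \code{x_c}
#'   (mmol mol-1), \code{flux} (mmol m-2 s-1, uptake-positive),
#'   \code{e_h2o} (mol m-2 s-1, outward-positive) and \code{rh_i} (percent).
#' @export
solve_h2o <- function(cfg, leaf, x_in, t_leaf) {
  .solve_h2o_core(cfg$af / cfg$s, cfg$g_bw, leaf$g_sw, leaf$g_mw,
                  x_in, t_leaf, cfg$p_air)
}

#' Steady-state COS profile with ternary transpiration correction
#'
#' Solves the three-layer steady state for COS, with the ternary water-vapour
#' term applied at the stomatal interface and the mesophyll sink drawing the
#' chloroplast-level mole fraction to the compensation point.
#'
#' @inheritParams solve_h2o
#' @param x_in_wet Inflow COS mole fraction, wet basis (pmol mol-1).
#' @param e_h2o Transpiration (mol m-2 s-1, outward-positive) from
#'   \code{solve_h2o}.
#' @return List with layer mole fractions (pmol mol-1) and \code{flux}
#'   (pmol m-2 s-1, uptake-positive).
#' @export
solve_cos <- function(cfg, leaf, x_in_wet, t_leaf, e_h2o) {
  sc <- species_conductances(leaf$g_sw, cfg$g_bw)
  .solve_cos_core(cfg$af / cfg$s, sc$g_b_cos, sc$g_s_cos,
                  g_m_cos(t_leaf, leaf$ca), x_in_wet,
                  gamma_cos(t_leaf, leaf$gamma), e_h2o)
}

#' Steady-state CO2 profile with enzyme-limited mesophyll sink
#'
#' As \code{\link{solve_cos}}, but the mesophyll term is the nonlinear
#' enzyme-limited assimilation minus dark respiration; the intercellular mole
#' fraction is found by bracketed root finding (unique root: supply decreases
#' and demand increases with the intercellular mole fraction).
#'
#' @inheritParams solve_cos
#' @param x_in_wet Inflow CO2 mole fraction, wet basis (umol mol-1).
#' @return List with layer mole fractions (umol mol-1), \code{flux}
#'   (umol m-2 s-1) and \code{p_co2_i} (Pa).
#' @export
solve_co2 <- function(cfg, leaf, x_in_wet, t_leaf, e_h2o) {
  sc <- species_conductances(leaf$g_sw, cfg$g_bw)
  .solve_co2_core(cfg$af / cfg$s, sc$g_b_co2, sc$g_s_co2, x_in_wet, t_leaf,
                  cfg$p_air, e_h2o, leaf$rub$v_max_rub, leaf$rub$dH_a_rub,
                  leaf$co2c)
}

#' Deposition velocity and ambient fraction remaining
#'
#' The deposition velocity uses the series conductance from the boundary
#' layer to the stomata; AFR is the relative drawdown of the ambient mole
#' fraction at the intercellular level.
#'
#' @param x_a Ambient mole fraction (> 0).
#' @param x_i Intercellular mole fraction.
#' @param g_b,g_s Boundary and stomatal conductances for the gas
#'   (mol m-2 s-1).
#' @return Deposition velocity (mol m-2 s-1).
#' @export
deposition_velocity <- function(x_a, x_i, g_b, g_s) {
  if (any(x_a <= 0)) stop("x_a must be positive")
  g_bs <- 1 / (1 / g_b + 1 / g_s)
  g_bs * (1 - x_i / x_a)
}

#' @rdname deposition_velocity
#' @export
afr <- function(x_a, x_i) {
  if (any(x_a <= 0)) stop("x_a must be positive")
  1 - x_i / x_a
}

#' Leaf relative uptake ratio
#'
#' COS assimilation normalized by the outflowing COS mole fraction, divided
#' by the equivalently normalized CO2 assimilation.
#'
#' @param a_cos COS assimilation (pmol m-2 s-1).
#' @param cos_out Outflow COS mole fraction (pmol mol-1), > 0.
#' @param a_co2 CO2 assimilation (umol m-2 s-1), nonzero.
#' @param co2_out Outflow CO2 mole fraction (umol mol-1), > 0.
#' @return Dimensionless LRU.
#' @export
lru <- function(a_cos, cos_out, a_co2, co2_out) {
  if (any(cos_out <= 0) || any(co2_out <= 0)) {
    stop("outflow mole fractions must be positive")
  }
  if (any(a_co2 == 0)) stop("a_co2 must be nonzero")
  (a_cos / cos_out) / (a_co2 / co2_out)
}

## Vectorized forward pipeline over plain parameter vectors; the engine
## behind forward_simulate() and the inversion cost.
.forward_core <- function(af, s, p_air, g_bw, g_sw, g_mw,
                          v_max_ca, t_eq_ca, a_t, dH_a_ca, dH_eq_ca,
                          v_max_rub, dH_a_rub, consts, gamma_spec,
                          gamma_param = NULL,
                          cos_in_dry, co2_in_dry, h2o_in, t_leaf,
                          h2o_out_obs = NULL) {
  q <- af / s
  h2o <- .solve_h2o_core(q, g_bw, g_sw, g_mw, h2o_in, t_leaf, p_air)
  e <- h2o$e_h2o
  cos_in_wet <- dry_to_wet(cos_in_dry, h2o_in)
  co2_in_wet <- dry_to_wet(co2_in_dry, h2o_in)

  gm <- v_max_ca * a_t * .f_ca_raw(t_leaf, dH_a_ca, dH_eq_ca, t_eq_ca)
  gam_spec <- gamma_spec
  if (!is.null(gamma_param)) {
    if (gam_spec$variant == "S2") gam_spec$m_cos <- gamma_param
    if (gam_spec$variant %in% c("S3", "S4")) gam_spec$dH_a_gamma <- gamma_param
  }
  gam <- gamma_cos(t_leaf, gam_spec)

  cos <- .solve_cos_core(q, g_bw / 1.56, g_sw / 1.94, gm, cos_in_wet, gam, e)
  co2 <- .solve_co2_core(q, g_bw / 1.4, g_sw / 1.6, co2_in_wet, t_leaf,
                         p_air, e, v_max_rub, dH_a_rub, consts)

  h2o_ref <- if (is.null(h2o_out_obs)) h2o$x_a else h2o_out_obs
  cos_out_dry <- wet_to_dry(cos$x_a, h2o_ref)
  co2_out_dry <- wet_to_dry(co2$x_a, h2o_ref)
  f_cos_dry <- q * (cos_in_dry - cos_out_dry)
  f_co2_dry <- q * (co2_in_dry - co2_out_dry)

  list(h2o = h2o, cos = cos, co2 = co2, q = q, g_m_cos = gm, gamma = gam,
       h2o_out_est = h2o$x_a,
       cos_out_dry = cos_out_dry, co2_out_dry = co2_out_dry,
       f_cos_dry = f_cos_dry, f_co2_dry = f_co2_dry)
}

#' Forward-simulate a cuvette observation
#'
#' Full measurement pipeline for one or more steady-state intervals: convert
#' dry-basis inflows to wet basis, solve the three coupled gas profiles,
#' convert the modeled chamber air back to dry basis (using the modeled
#' outflow humidity, or an observed one if supplied) and emit mass-balance
#' fluxes and diagnostics.
#'
#' @param cfg A \code{chamber_config}.
#' @param leaf A \code{leaf_parameters} object (fields may be vectors,
#'   recycled across points).
#' @param cos_in_dry Inflow COS mole fraction, dry basis (pmol mol-1).
#' @param co2_in_dry Inflow CO2 mole fraction, dry basis (umol mol-1).
#' @param h2o_in Inflow H2O mole fraction (mmol mol-1).
#' @param t_leaf Leaf temperature (degrees C).
#' @param h2o_out_obs Optional observed outflow H2O (mmol mol-1) for the
#'   dry-basis conversion; defaults to the modeled chamber humidity.
#' @return A data.frame, one row per point, with dry-basis outflows, fluxes,
#'   transpiration, layer diagnostics (deposition velocities, AFR, LRU,
#'   intercellular relative humidity).
#' @export
forward_simulate <- function(cfg, leaf, cos_in_dry, co2_in_dry, h2o_in,
                             t_leaf, h2o_out_obs = NULL) {
  stopifnot(inherits(cfg, "chamber_config"), inherits(leaf, "leaf_parameters"))
  gp <- switch(leaf$gamma$variant,
               S2 = leaf$gamma$m_cos,
               S3 = ,
               S4 = leaf$gamma$dH_a_gamma,
               NULL)
  out <- .forward_core(cfg$af, cfg$s, cfg$p_air, cfg$g_bw,
                       leaf$g_sw, leaf$g_mw,
                       leaf$ca$v_max_ca, leaf$ca$t_eq_ca, leaf$ca$a_t,
                       leaf$ca$dH_a_ca, leaf$ca$dH_eq_ca,
                       leaf$rub$v_max_rub, leaf$rub$dH_a_rub,
                       leaf$co2c, leaf$gamma, gp,
                       cos_in_dry, co2_in_dry, h2o_in, t_leaf, h2o_out_obs)
  sc <- species_conductances(leaf$g_sw, cfg$g_bw)
  v_cos <- deposition_velocity(out$cos$x_a, out$cos$x_i, sc$g_b_cos, sc$g_s_cos)
  v_co2 <- deposition_velocity(out$co2$x_a, out$co2$x_i, sc$g_b_co2, sc$g_s_co2)
  data.frame(
    t_leaf_C = rep_len(t_leaf, length(out$cos_out_dry)),
    cos_out_dry = out$cos_out_dry, co2_out_dry = out$co2_out_dry,
    h2o_out_est = out$h2o_out_est,
    f_cos = out$f_cos_dry, f_co2 = out$f_co2_dry,
    e_h2o = out$h2o$e_h2o,
    cos_a = out$cos$x_a, cos_b = out$cos$x_b, cos_i = out$cos$x_i,
    co2_a = out$co2$x_a, co2_b = out$co2$x_b, co2_i = out$co2$x_i,
    h2o_a = out$h2o$x_a, h2o_i = out$h2o$x_i, h2o_c = out$h2o$x_c,
    g_m_cos = rep_len(out$g_m_cos, length(out$cos_out_dry)),
    gamma_cos = rep_len(out$gamma, length(out$cos_out_dry)),
    v_cos = v_cos, v_co2 = v_co2,
    afr_cos = afr(out$cos$x_a, out$cos$x_i),
    afr_co2 = afr(out$co2$x_a, out$co2$x_i),
    lru = lru(out$f_cos_dry, out$cos_out_dry, out$f_co2_dry, out$co2_out_dry),
    rh_i = out$h2o$rh_i
  )
}
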