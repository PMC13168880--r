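#' @keywords internal
"_PACKAGE"

## Universal gas constant, J K-1 mol-1
.R_GAS <- 8.314
.T0K <- 273.15

#' Saturation vapour pressure of water
#'
#' Tetens-type exponential fit used throughout the chamber model.
#'
#' @param t_leaf Leaf temperature (degrees C). Vectorized.
#' @return Saturation vapour pressure (Pa).
#' @examples
#' saturation_vapor_pressure(25)
#' @export
saturation_vapor_pressure <- function(t_leaf) {
  if (any(t_leaf <= -240.97)) {
    stop("t_leaf at or below the -240.97 C singularity of the saturation curve")
  }
  613.5 * exp(17.502 * t_leaf / (t_leaf + 240.97))
}

#' Saturated water-vapour mole fraction
#'
#' Mole fraction of water vapour in air saturated at leaf temperature,
#' used for the mesophyll source layer of the H2O sub-model.
#'
#' @param t_leaf Leaf temperature (degrees C).
#' @param p_air Air pressure (Pa); must exceed the saturation pressure.
#' @return Mole fraction (mmol mol-1).
#' @export
h2o_saturated_mole_fraction <- function(t_leaf, p_air) {
  p_sat <- saturation_vapor_pressure(t_leaf)
  if (any(p_air <= p_sat)) {
    stop("p_air must exceed the saturation vapour pressure")
  }
  1000 * p_sat / p_air
}

#' Q10 temperature scaling
#'
#' @param value_ref Quantity at reference temperature \code{t1}.
#' @param q10 Factor per 10 C warming (> 0).
#' @param t2 Target temperature (degrees C).
#' @param t1 Reference temperature (degrees C), default 25.
#' @return Scaled quantity.
#' @export
q10_scale <- function(value_ref, q10, t2, t1 = 25) {
  stopifnot(all(q10 > 0))
  value_ref * q10^((t2 - t1) / 10)
}

#' RuBisCO kinetics parameters
#'
#' @param v_max_rub Maximum carboxylation capacity (umol m-2 s-1).
#' @param dH_a_rub Activation energy (J mol-1), default 60000.
#' @param t_ref_rub Reference temperature (K), default 298.
#' @return An object of class \code{rubisco_kinetics}.
#' @export
rubisco_kinetics <- function(v_max_rub, dH_a_rub = 60000, t_ref_rub = 298) {
  stopifnot(all(v_max_rub >= 0))
  structure(list(v_max_rub = v_max_rub, dH_a_rub = dH_a_rub,
                 t_ref_rub = t_ref_rub),
            class = "rubisco_kinetics")
}

#' Arrhenius temperature factor for RuBisCO carboxylation
#'
#' Exponential activation-energy response normalized to 1 at the reference
#' temperature (298 K).
#'
#' @param t_leaf Leaf temperature (degrees C).
#' @param kin A \code{rubisco_kinetics} object, or an activation energy in
#'   J mol-1.
#' @return Dimensionless factor.
#' @export
f_rub <- function(t_leaf, kin = rubisco_kinetics(90)) {
  if (inherits(kin, "rubisco_kinetics")) {
    dH <- kin$dH_a_rub; tref <- kin$t_ref_rub
  } else {
    dH <- kin; tref <- 298
  }
  tk <- t_leaf + .T0K
  exp((tk - tref) * dH / (tref * .R_GAS * tk))
}

## Unnormalized CA activity shape: Arrhenius growth damped by a
## activation/inactivation equilibrium above the optimum temperature.
## All temperatures in Kelvin (the equilibrium term uses 1/T_K throughout).
.f_ca_raw <- function(t_leaf, dH_a_ca, dH_eq_ca, t_eq_ca) {
  tk <- t_leaf + .T0K
  tk_eq <- t_eq_ca + .T0K
  num <- tk * exp(-dH_a_ca / (.R_GAS * tk))
  den <- 1 + exp(-(dH_eq_ca / .R_GAS) * (1 / tk - 1 / tk_eq))
  num / den
}

#' Carbonic anhydrase kinetics
#'
#' Builds the CA parameter set and the normalization factor \code{a_t} such
#' that the activity shape equals 1 at the optimum temperature, so the
#' mesophyll COS conductance equals \code{v_max_ca} there.
#'
#' @param v_max_ca Catalytic capacity (mol m-2 s-1).
#' @param t_eq_ca Optimum temperature (degrees C), where activated and
#'   inactivated enzyme pools are equal.
#' @param dH_a_ca Activation energy (J mol-1), default 40000.
#' @param dH_eq_ca Activation-to-inactivation enthalpy (J mol-1), default
#'   100000.
#' @return An object of class \code{ca_kinetics} with field \code{a_t}.
#' @export
ca_kinetics <- function(v_max_ca, t_eq_ca, dH_a_ca = 40000,
                        dH_eq_ca = 100000) {
  stopifnot(all(v_max_ca >= 0), all(t_eq_ca >= 1), all(t_eq_ca <= 60))
  a_t <- 1 / .f_ca_raw(t_eq_ca, dH_a_ca, dH_eq_ca, t_eq_ca)
  structure(list(v_max_ca = v_max_ca, t_eq_ca = t_eq_ca, dH_a_ca = dH_a_ca,
                 dH_eq_ca = dH_eq_ca, a_t = a_t),
            class = "ca_kinetics")
}

#' Mesophyll conductance for COS from CA activity
#'
#' Temperature response of the carbonic-anhydrase-limited mesophyll
#' conductance; equals \code{v_max_ca} exactly at the optimum temperature.
#'
#' @param t_leaf Leaf temperature (degrees C).
#' @param kin A \code{ca_kinetics} object.
#' @return Conductance (mol m-2 s-1).
#' @export
g_m_cos <- function(t_leaf, kin) {
  stopifnot(inherits(kin, "ca_kinetics"))
  kin$v_max_ca * kin$a_t *
    .f_ca_raw(t_leaf, kin$dH_a_ca, kin$dH_eq_ca, kin$t_eq_ca)
}

#' CO2 model constants
#'
#' Michaelis constants, specificity factor, dark respiration and internal O2
#' pressure with their Q10 factors. Defaults follow standard C3 leaf values.
#'
#' @param tau_298 RuBisCO CO2/O2 specificity at 298 K (dimensionless).
#' @param q10_tau Q10 of the specificity factor.
#' @param kc_298 Michaelis constant for carboxylation at 298 K (Pa).
#' @param q10_kc Q10 of \code{kc_298}.
#' @param ko_298 Michaelis constant for oxygenation at 298 K (Pa).
#' @param q10_ko Q10 of \code{ko_298}.
#' @param rd_298 Dark respiration at 298 K (umol m-2 s-1).
#' @param q10_rd Q10 of dark respiration.
#' @param p_o2_i Internal O2 partial pressure (Pa).
#' @return An object of class \code{co2_constants}.
#' @export
co2_constants <- function(tau_298 = 2600, q10_tau = 0.57,
                          kc_298 = 30, q10_kc = 2.1,
                          ko_298 = 30000, q10_ko = 1.2,
                          rd_298 = 3.0, q10_rd = 2.0,
                          p_o2_i = 20900) {
  stopifnot(tau_298 > 0, kc_298 > 0, ko_298 > 0, rd_298 >= 0, p_o2_i > 0)
  structure(list(tau_298 = tau_298, q10_tau = q10_tau, kc_298 = kc_298,
                 q10_kc = q10_kc, ko_298 = ko_298, q10_ko = q10_ko,
                 rd_298 = rd_298, q10_rd = q10_rd, p_o2_i = p_o2_i),
            class = "co2_constants")
}

#' Photorespiratory CO2 compensation point
#'
#' Gamma* from the specificity factor: \code{p_O2 / (2 tau(T))}, with the
#' specificity factor Q10-scaled from 298 K.
#'
#' @param t_leaf Leaf temperature (degrees C).
#' @param consts A \code{co2_constants} object.
#' @return Partial pressure (Pa).
#' @export
gamma_star_co2 <- function(t_leaf, consts = co2_constants()) {
  tau <- q10_scale(consts$tau_298, consts$q10_tau, t_leaf)
  consts$p_o2_i / (2 * tau)
}

#' Dark respiration at leaf temperature
#'
#' @param t_leaf Leaf temperature (degrees C).
#' @param consts A \code{co2_constants} object.
#' @return Respiration flux (umol m-2 s-1).
#' @export
dark_respiration <- function(t_leaf, consts = co2_constants()) {
  q10_scale(consts$rd_298, consts$q10_rd, t_leaf)
}

#' Enzyme-limited gross CO2 assimilation
#'
#' Farquhar-type RuBisCO-limited assimilation as a function of the
#' intercellular CO2 partial pressure (used as a proxy for the chloroplast
#' pressure; no explicit CO2 mesophyll diffusion term).
#'
#' @param p_co2_i Intercellular CO2 partial pressure (Pa), >= 0.
#' @param t_leaf Leaf temperature (degrees C).
#' @param kin A \code{rubisco_kinetics} object.
#' @param consts A \code{co2_constants} object.
#' @return Assimilation flux (umol m-2 s-1); crosses zero at Gamma*.
#' @export
rubisco_assimilation <- function(p_co2_i, t_leaf, kin,
                                 consts = co2_constants()) {
  stopifnot(all(p_co2_i >= 0))
  kc <- q10_scale(consts$kc_298, consts$q10_kc, t_leaf)
  ko <- q10_scale(consts$ko_298, consts$q10_ko, t_leaf)
  gs <- gamma_star_co2(t_leaf, consts)
  vm <- if (inherits(kin, "rubisco_kinetics")) kin$v_max_rub else kin
  vm * f_rub(t_leaf, kin) * (p_co2_i - gs) / (p_co2_i + kc * (1 + consts$p_o2_i / ko))
}

#' COS compensation point temperature function
#'
#' Four variants: \code{S1} (no compensation point, identically zero),
#' \code{S2} (linear in temperature above an intercept temperature),
#' \code{S3}/\code{S4} (Arrhenius forms anchored at 293 K / 298 K). All
#' variants are clamped at zero from below, since the compensation point is a
#' mole fraction.
#'
#' @param variant One of \code{"S1"}, \code{"S2"}, \code{"S3"}, \code{"S4"}.
#' @param m_cos Linear slope (pmol mol-1 K-1), S2 only.
#' @param t_ref_gamma Intercept temperature (degrees C), S2 only.
#' @param gamma_ref Reference compensation point (pmol mol-1), S3/S4;
#'   defaults to 55.0 (S3) or 138.7 (S4).
#' @param t_ref_arrh Arrhenius reference temperature (K); 293 for S3, 298 for
#'   S4. Taken literally (not 292.95/298.15): this is the anchor convention
#'   under which the default activation energy is self-consistent.
#' @param dH_a_gamma Activation energy (J mol-1), S3/S4.
#' @return An object of class \code{gamma_cos_spec}.
#' @export
gamma_cos_spec <- function(variant = c("S2", "S1", "S3", "S4"),
                           m_cos = 16.2, t_ref_gamma = 16.4,
                           gamma_ref = NULL, t_ref_arrh = NULL,
                           dH_a_gamma = 134300) {
  variant <- match.arg(variant)
  if (variant == "S3") {
    if (is.null(gamma_ref)) gamma_ref <- 55.0
    if (is.null(t_ref_arrh)) t_ref_arrh <- 293
  } else if (variant == "S4") {
    if (is.null(gamma_ref)) gamma_ref <- 138.7
    if (is.null(t_ref_arrh)) t_ref_arrh <- 298
  }
  structure(list(variant = variant, m_cos = m_cos, t_ref_gamma = t_ref_gamma,
                 gamma_ref = gamma_ref, t_ref_arrh = t_ref_arrh,
                 dH_a_gamma = dH_a_gamma),
            class = "gamma_cos_spec")
}

#' Evaluate the COS compensation point
#'
#' @param t_leaf Leaf temperature (degrees C).
#' @param spec A \code{gamma_cos_spec} object.
#' @return Compensation point (pmol mol-1), non-negative.
#' @export
gamma_cos <- function(t_leaf, spec = gamma_cos_spec()) {
  stopifnot(inherits(spec, "gamma_cos_spec"))
  g <- switch(spec$variant,
    S1 = rep(0, length(t_leaf)),
    S2 = spec$m_cos * (t_leaf - spec$t_ref_gamma),
    S3 = ,
    S4 = {
      tk <- t_leaf + .T0K
      spec$gamma_ref *
        exp((tk - spec$t_ref_arrh) * spec$dH_a_gamma /
              (spec$t_ref_arrh * .R_GAS * tk))
    },
    stop("unknown gamma_cos variant: ", spec$variant)
  )
  pmax(g, 0)
}

#' Invert a two-point Arrhenius relation for the activation energy
#'
#' Given the compensation point at two temperatures, solves the Arrhenius
#' form for the activation energy. Temperatures are taken exactly as given
#' (supply the printed Kelvin anchors, e.g. 293 and 298, to reproduce
#' tabulated values).
#'
#' @param t1_K,t2_K Temperatures (K), distinct.
#' @param gamma1,gamma2 Compensation points (pmol mol-1), both > 0.
#' @return Activation energy (J mol-1).
#' @export
invert_arrhenius_dH <- function(t1_K, gamma1, t2_K, gamma2) {
  if (any(gamma1 <= 0) || any(gamma2 <= 0)) {
    stop("both compensation points must be positive")
  }
  if (any(t1_K == t2_K)) stop("temperatures must differ")
  log(gamma2 / gamma1) * .R_GAS * t1_K * t2_K / (t2_K - t1_K)
}
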