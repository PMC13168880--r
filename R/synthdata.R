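#' Reference optimized sunflower parameter set
#'
#' Representative optimized physiological parameters for three sunflower
#' plants (per-plant enzyme capacities; shared temperature kinetics,
#' compensation-point slope and stomatal mean), used as defaults for forward
#' simulations and as the generating truth of the synthetic experiments.
#'
#' @return Named list: \code{v_max_ca} and \code{v_max_rub} per plant,
#'   \code{t_eq_ca}, \code{m_cos}, \code{dH_a_rub} (kJ mol-1),
#'   \code{g_sw_mean}.
#' @export
sunflower_reference <- function() {
  list(
    v_max_ca = c("2" = 0.217, "3" = 0.189, "4" = 0.230),   # mol m-2 s-1
    v_max_rub = c("2" = 94.4, "3" = 87.4, "4" = 82.9),     # umol m-2 s-1
    t_eq_ca = 39.7,                                         # deg C
    m_cos = 22.4,                                           # pmol mol-1 K-1
    dH_a_rub = 54.5,                                        # kJ mol-1
    g_sw_mean = 0.64                                        # mol m-2 s-1
  )
}

#' Experiment designs for the synthetic cuvette runs
#'
#' Three designs mirroring the laboratory campaigns: a COS-inflow ramp at two
#' leaf temperatures (compensation-point detection), a stomatal-conductance
#' sweep near 25 C at elevated COS, and a leaf-temperature sweep at fixed
#' stomatal conductance. Each returns an \code{experiment_design} whose
#' \code{points} table lists the controlled variables per 150-s interval.
#'
#' @param plant_id,plant_ids Plant identifier(s).
#' @return An object of class \code{experiment_design}.
#' @export
design_cos_ramp <- function(plant_id = 1) {
  lev_cold <- seq(94, 589, length.out = 4)
  lev_warm <- seq(104, 707, length.out = 4)
  pts <- rbind(
    data.frame(t_leaf_C = 19.8, g_sw = 0.8,
               cos_in_dry = rep(lev_cold, c(2, 2, 2, 1)),
               co2_in_dry = 446.5, h2o_in = 12),
    data.frame(t_leaf_C = 25.0, g_sw = 0.9,
               cos_in_dry = rep(lev_warm, each = 2),
               co2_in_dry = 449.1, h2o_in = 12)
  )
  pts$plant_id <- plant_id
  structure(list(kind = "cos_ramp", points = pts), class = "experiment_design")
}

#' @rdname design_cos_ramp
#' @export
design_gsw_sweep <- function(plant_ids = c(2, 3, 4)) {
  spec <- data.frame(
    plant_id = c(2, 3, 4),
    g_lo = c(0.4, 0.3, 0.3), g_hi = c(1.1, 1.0, 0.6),
    t_leaf_C = c(25.1, 26.4, 24.8),
    cos_in_dry = c(1096.4, 1181.9, 914.4),
    co2_in_dry = c(441.0, 446.2, 447.5))
  spec <- spec[spec$plant_id %in% plant_ids, ]
  pts <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    g <- seq(spec$g_lo[i], spec$g_hi[i], length.out = 8)
    data.frame(t_leaf_C = spec$t_leaf_C[i], g_sw = g,
               cos_in_dry = spec$cos_in_dry[i],
               co2_in_dry = spec$co2_in_dry[i],
               h2o_in = 8 + 10 * (g - 0.3),   # wetter air opens stomata
               plant_id = spec$plant_id[i])
  }))
  structure(list(kind = "gsw_sweep", points = pts),
            class = "experiment_design")
}

#' @rdname design_cos_ramp
#' @export
design_temp_sweep <- function(plant_ids = c(2, 4)) {
  spec <- data.frame(
    plant_id = c(2, 4),
    t_lo = c(19.1, 19.0), t_hi = c(30.9, 29.8),
    cos_in_dry = c(1087.7, 926.8),
    co2_in_dry = c(439.9, 447.3))
  spec <- spec[spec$plant_id %in% plant_ids, ]
  pts <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    data.frame(t_leaf_C = seq(spec$t_lo[i], spec$t_hi[i], length.out = 12),
               g_sw = 0.6,
               cos_in_dry = spec$cos_in_dry[i],
               co2_in_dry = spec$co2_in_dry[i],
               h2o_in = 12, plant_id = spec$plant_id[i])
  }))
  structure(list(kind = "temp_sweep", points = pts),
            class = "experiment_design")
}

#' Observational noise model for synthetic data
#'
#' Gaussian per-gas noise magnitudes matching the 150-second measurement
#' statistics of the cuvette system.
#'
#' @param sigma_cos COS noise SD (pmol mol-1).
#' @param sigma_co2 CO2 noise SD (umol mol-1).
#' @param sigma_h2o H2O noise SD (mmol mol-1).
#' @return An object of class \code{noise_model}.
#' @export
noise_model <- function(sigma_cos = 16.7, sigma_co2 = 0.2, sigma_h2o = 0.3) {
  stopifnot(sigma_cos >= 0, sigma_co2 >= 0, sigma_h2o >= 0)
  structure(list(sigma_cos = sigma_cos, sigma_co2 = sigma_co2,
                 sigma_h2o = sigma_h2o), class = "noise_model")
}

#' Empty-chamber COS emission model
#'
#' Linear temperature dependence of the COS emission from chamber materials.
#' Defaults give an emission of about 4 pmol m-2 s-1 at 25 C, calibrated so
#' that the emission averages roughly 6.7 % of the leaf COS flux over the
#' elevated-COS experiment conditions.
#'
#' @param slope Emission increase per degree (pmol m-2 s-1 K-1).
#' @param intercept Emission at 0 C (pmol m-2 s-1).
#' @param resid_sd Residual SD of the emission fit (pmol m-2 s-1).
#' @return An object of class \code{chamber_emission_model}.
#' @export
chamber_emission_model <- function(slope = 0.12, intercept = 1.05,
                                   resid_sd = 0) {
  stopifnot(resid_sd >= 0)
  structure(list(slope = slope, intercept = intercept, resid_sd = resid_sd),
            class = "chamber_emission_model")
}

#' Temperature-predicted chamber emission
#'
#' @param t_air Air temperature (degrees C).
#' @param emission A \code{chamber_emission_model}.
#' @return Emission flux (pmol m-2 s-1, leaf-area basis).
#' @export
chamber_emission <- function(t_air, emission = chamber_emission_model()) {
  emission$intercept + emission$slope * t_air
}

#' Correct an apparent leaf COS flux for chamber emission
#'
#' Chamber emission raises the outflow COS mole fraction and so masks leaf
#' uptake; adding back the temperature-predicted emission restores the leaf
#' flux. Applied to synthetic data generated with the same emission model and
#' no noise, the round trip is exact.
#'
#' @param f_obs Apparent (uncorrected) leaf flux (pmol m-2 s-1, uptake
#'   positive).
#' @param t_air Air temperature (degrees C).
#' @param emission A \code{chamber_emission_model}.
#' @return Corrected leaf flux (pmol m-2 s-1).
#' @export
correct_chamber_flux <- function(f_obs, t_air,
                                 emission = chamber_emission_model()) {
  f_obs + chamber_emission(t_air, emission)
}

#' Generating truth for synthetic datasets
#'
#' Per-plant enzyme capacities with optional lognormal plant-to-plant
#' jitter (fixed per plant id for reproducibility), shared temperature
#' kinetics and compensation-point model.
#'
#' @param plants Plant ids appearing in the design.
#' @param v_max_ca,v_max_rub Base capacities before jitter.
#' @param t_eq_ca CA optimum temperature (deg C).
#' @param gamma A \code{gamma_cos_spec}.
#' @param dH_a_rub RuBisCO activation energy (J mol-1).
#' @param jitter_cv Lognormal coefficient of variation of the per-plant
#'   capacities (0 disables).
#' @param co2c \code{co2_constants}.
#' @param g_mw Mesophyll conductance for H2O (mol m-2 s-1).
#' @param dH_a_ca,dH_eq_ca Fixed CA enthalpies (J mol-1).
#' @return An object of class \code{synth_truth}.
#' @export
synth_truth <- function(plants, v_max_ca = 0.20, v_max_rub = 90,
                        t_eq_ca = 39.7,
                        gamma = gamma_cos_spec("S2", m_cos = 16.2),
                        dH_a_rub = 60000, jitter_cv = 0.10,
                        co2c = co2_constants(), g_mw = 10,
                        dH_a_ca = 40000, dH_eq_ca = 100000) {
  plants <- sort(unique(plants))
  jit <- function(base, pl, salt) {
    vapply(pl, function(p) {
      if (jitter_cv <= 0) return(base)
      ## deterministic per-plant lognormal jitter
      set.seed(10000L + salt * 100L + as.integer(factor(p, levels = plants)))
      base * stats::rlnorm(1, -jitter_cv^2 / 2, jitter_cv)
    }, numeric(1))
  }
  vca <- jit(v_max_ca, plants, 1L)
  vrb <- jit(v_max_rub, plants, 2L)
  names(vca) <- names(vrb) <- as.character(plants)
  structure(list(plants = plants, v_max_ca = vca, v_max_rub = vrb,
                 t_eq_ca = t_eq_ca, gamma = gamma, dH_a_rub = dH_a_rub,
                 co2c = co2c, g_mw = g_mw, dH_a_ca = dH_a_ca,
                 dH_eq_ca = dH_eq_ca),
            class = "synth_truth")
}

#' Generating truth at the reference optimized sunflower values
#'
#' Convenience constructor: the per-plant capacities and shared kinetics of
#' \code{\link{sunflower_reference}} as a \code{synth_truth} (no extra
#' jitter; the per-plant spread is already in the reference set).
#'
#' @param variant Compensation-point variant for the generating model.
#' @return A \code{synth_truth}.
#' @export
synth_truth_reference <- function(variant = "S2") {
  ref <- sunflower_reference()
  gamma <- switch(variant,
                  S2 = gamma_cos_spec("S2", m_cos = ref$m_cos),
                  gamma_cos_spec(variant))
  tr <- synth_truth(plants = c(2, 3, 4), t_eq_ca = ref$t_eq_ca,
                    gamma = gamma, dH_a_rub = ref$dH_a_rub * 1000,
                    jitter_cv = 0)
  tr$v_max_ca <- ref$v_max_ca
  tr$v_max_rub <- ref$v_max_rub
  tr
}

#' Generate a synthetic cuvette dataset
#'
#' Forward-simulates every design point with the generating truth, adds the
#' chamber COS emission to the chamber budget (raising the outflow mole
#' fraction), then adds independent Gaussian observation noise per gas.
#' Returns both the observation table (observed-point schema, with the
#' generating noise SDs written as the sigma columns) and the noise-free
#' truth record for recovery tests.
#'
#' @param design An \code{experiment_design}.
#' @param truth A \code{synth_truth}.
#' @param cfg A \code{chamber_config}.
#' @param noise A \code{noise_model}; use zeros for noise-free data.
#' @param emission A \code{chamber_emission_model}; the default
#'   \code{chamber_emission_model(0, 0)} adds nothing.
#' @param seed Integer seed for the noise draws.
#' @param exclude_dewpoint Drop points whose chamber air dew point reaches
#'   the leaf temperature (condensation guard); off by default since the
#'   synthetic designs never condense.
#' @return List with \code{points} (observed-point data.frame) and
#'   \code{truth} (the truth object plus the noise-free forward table).
#' @export
generate_dataset <- function(design, truth, cfg = chamber_config(),
                             noise = noise_model(),
                             emission = chamber_emission_model(0, 0),
                             seed = 1, exclude_dewpoint = FALSE) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(truth, "synth_truth"))
  pts <- design$points
  n <- nrow(pts)
  idx <- match(as.character(pts$plant_id), names(truth$v_max_ca))
  if (anyNA(idx)) stop("design contains plants absent from the truth")
  a_t <- 1 / .f_ca_raw(truth$t_eq_ca, truth$dH_a_ca, truth$dH_eq_ca,
                       truth$t_eq_ca)
  gp <- switch(truth$gamma$variant, S2 = truth$gamma$m_cos,
               S3 = , S4 = truth$gamma$dH_a_gamma, NULL)
  fw <- .forward_core(cfg$af, cfg$s, cfg$p_air, cfg$g_bw,
                      pts$g_sw, truth$g_mw,
                      truth$v_max_ca[idx], truth$t_eq_ca, a_t,
                      truth$dH_a_ca, truth$dH_eq_ca,
                      truth$v_max_rub[idx], truth$dH_a_rub,
                      truth$co2c, truth$gamma, gp,
                      pts$cos_in_dry, pts$co2_in_dry, pts$h2o_in,
                      pts$t_leaf_C)
  q <- cfg$af / cfg$s
  set.seed(seed)
  emis <- chamber_emission(pts$t_leaf_C, emission)
  if (emission$resid_sd > 0) {
    emis <- emis + stats::rnorm(n, 0, emission$resid_sd)
  }
  cos_out <- fw$cos_out_dry + emis / q + stats::rnorm(n, 0, noise$sigma_cos)
  co2_out <- fw$co2_out_dry + stats::rnorm(n, 0, noise$sigma_co2)
  h2o_out <- fw$h2o_out_est + stats::rnorm(n, 0, noise$sigma_h2o)

  obs <- data.frame(
    point_id = sprintf("%s_p%02d", design$kind, seq_len(n)),
    plant_id = pts$plant_id,
    t_leaf_C = pts$t_leaf_C, p_air_Pa = cfg$p_air,
    af_mol_s = cfg$af, s_m2 = cfg$s, g_bw = cfg$g_bw,
    g_sw_meas = pts$g_sw,
    cos_in_dry = pts$cos_in_dry, cos_out_dry = cos_out,
    co2_in_dry = pts$co2_in_dry, co2_out_dry = co2_out,
    h2o_in = pts$h2o_in, h2o_out = h2o_out,
    sigma_cos = noise$sigma_cos, sigma_co2 = noise$sigma_co2,
    sigma_h2o = noise$sigma_h2o)
  if (exclude_dewpoint) {
    p_h2o <- obs$h2o_out * obs$p_air_Pa / 1000
    lp <- log(p_h2o / 613.5)
    t_dew <- 240.97 * lp / (17.502 - lp)
    obs <- obs[t_dew < obs$t_leaf_C, , drop = FALSE]
  }
  noise_free <- cbind(pts,
                      data.frame(cos_out_dry = fw$cos_out_dry,
                                 co2_out_dry = fw$co2_out_dry,
                                 h2o_out = fw$h2o_out_est,
                                 f_cos = fw$f_cos_dry, f_co2 = fw$f_co2_dry,
                                 emission = emis))
  list(points = obs, truth = list(params = truth, noise_free = noise_free))
}
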