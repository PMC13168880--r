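# Shared fixtures: small chamber/leaf setups and synthetic datasets built in
# code at test time.

canonical_cfg <- function() chamber_config(af = 3.5e-4, s = 9e-4,
                                           p_air = 103100, g_bw = 2.44)

posterior_leaf <- function(g_sw = 0.64, variant = "S2") {
  ref <- sunflower_reference()
  leaf_parameters(
    g_sw = g_sw,
    ca = ca_kinetics(ref$v_max_ca[["2"]], ref$t_eq_ca),
    rub = rubisco_kinetics(ref$v_max_rub[["2"]], ref$dH_a_rub * 1000),
    gamma = if (variant == "S2") gamma_cos_spec("S2", m_cos = ref$m_cos)
            else gamma_cos_spec(variant))
}

# one-plant dataset (8 stomatal levels), quick to fit
small_dataset <- function(noise = noise_model(0, 0, 0), seed = 1,
                          truth = synth_truth(plants = 2, jitter_cv = 0)) {
  des <- design_gsw_sweep(plant_ids = 2)
  dat <- generate_dataset(des, truth, canonical_cfg(), noise, seed = seed)
  pts <- dat$points
  # nominal measurement sigmas even when no noise was injected
  pts$sigma_cos <- 16.7; pts$sigma_co2 <- 0.2; pts$sigma_h2o <- 0.3
  list(points = pts, truth = dat$truth)
}

# full 48-point two-experiment dataset mirroring the campaign layout
campaign_dataset <- function(truth = synth_truth_reference("S2"),
                             noise = noise_model(), seed = 1) {
  cfg <- canonical_cfg()
  d2 <- generate_dataset(design_gsw_sweep(), truth, cfg, noise, seed = seed)
  d3 <- generate_dataset(design_temp_sweep(), truth, cfg, noise,
                         seed = seed + 5000L)
  pts <- rbind(d2$points, d3$points)
  if (identical(unname(unlist(noise[1:3])), c(0, 0, 0))) {
    pts$sigma_cos <- 16.7; pts$sigma_co2 <- 0.2; pts$sigma_h2o <- 0.3
  }
  list(points = pts,
       noise_free = rbind(d2$truth$noise_free, d3$truth$noise_free),
       truth = truth)
}

# state vector at the generating truth of a dataset
truth_state <- function(prior, truth, points) {
  st <- prior$mean
  pl <- sort(unique(points$plant_id))
  st[paste0("v_max_ca.", pl)] <- truth$v_max_ca[as.character(pl)]
  st[paste0("v_max_rub.", pl)] <- truth$v_max_rub[as.character(pl)]
  st["t_eq_ca"] <- truth$t_eq_ca
  if ("gamma" %in% names(st)) {
    st["gamma"] <- if (truth$gamma$variant == "S2") truth$gamma$m_cos
                   else truth$gamma$dH_a_gamma / 1000
  }
  st["dH_a_rub"] <- truth$dH_a_rub / 1000
  st[paste0("g_sw.", points$point_id)] <- points$g_sw_meas
  st
}
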