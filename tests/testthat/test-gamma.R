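test_that("regression compensation point is exact on a perfect line", {
  r <- regress_gamma(c(200, 400, 600), c(1, 3, 5))
  expect_equal(r$gamma_hat, 100)
  expect_equal(r$slope, 0.01)
  # duplicated points leave the OLS estimate unchanged
  r2 <- regress_gamma(c(200, 400, 600, 200, 400, 600), c(1, 3, 5, 1, 3, 5))
  expect_equal(r2$gamma_hat, r$gamma_hat)
  expect_error(regress_gamma(c(1, 2), c(1, 2)), "3 points")
  expect_error(regress_gamma(c(5, 5, 5), c(1, 2, 3)), "degenerate")
  expect_warning(regress_gamma(c(200, 400, 600), c(5, 3, 1)), "slope")
})

test_that("regression estimator is first-order unbiased under noise", {
  set.seed(11)
  truth <- 120; slope <- 0.012
  x <- seq(200, 700, length.out = 8)
  est <- numeric(1000); hw <- numeric(1000)
  for (r in 1:1000) {
    y <- slope * (x - truth) + rnorm(8, 0, 0.5)
    g <- regress_gamma(x, y)
    est[r] <- g$gamma_hat; hw[r] <- g$ci95_half_width
  }
  expect_lt(abs(mean(est) - truth), mean(hw) / 10)
})

test_that("chamber-residual widening inflates the interval monotonically", {
  set.seed(3)
  x <- seq(150, 650, length.out = 8)
  y <- 0.011 * (x - 110) + rnorm(8, 0, 0.8)
  r <- regress_gamma(x, y)
  expect_equal(widen_ci_with_chamber_residual(r, 0, 0)$ci95_half_width,
               r$ci95_half_width)
  w1 <- widen_ci_with_chamber_residual(r, 1.0, 0)$ci95_half_width
  w2 <- widen_ci_with_chamber_residual(r, 2.73, 0)$ci95_half_width
  w3 <- widen_ci_with_chamber_residual(r, 2.73, 6.9)$ci95_half_width
  expect_true(w1 >= r$ci95_half_width && w2 >= w1 && w3 >= w2)
})

test_that("widening with the chamber residual SDs lands in the expected band", {
  # noise-free ramp data carry the chamber-scale flux scatter instead
  set.seed(21)
  cfg <- canonical_cfg()
  leaf <- posterior_leaf(0.9)
  xin <- seq(100, 700, length.out = 8)
  fw <- forward_simulate(cfg, leaf, xin, 449, 12, 25)
  ratios <- replicate(40, {
    y <- fw$f_cos + rnorm(8, 0, 2.5)
    r <- regress_gamma(fw$cos_out_dry, y)
    widen_ci_with_chamber_residual(r)$ci95_half_width / r$ci95_half_width
  })
  expect_true(all(ratios >= 1))
  expect_gt(mean(ratios), 1)
  expect_lt(mean(ratios), 2.2)
})

test_that("indirect layer inversion returns the prescribed compensation point", {
  # the defining oracle: apply the algebraic inversion to forward-simulated
  # observations generated with the same parameters
  tr <- synth_truth_reference("S2")
  cfg <- canonical_cfg()
  for (des in list(design_gsw_sweep(), design_temp_sweep())) {
    dat <- generate_dataset(des, tr, cfg, noise_model(0, 0, 0), seed = 1)
    pts <- dat$points
    ca <- ca_kinetics(tr$v_max_ca[as.character(pts$plant_id)], tr$t_eq_ca)
    ig <- indirect_gamma(pts, g_sw = pts$g_sw_meas, ca = ca, g_mw = tr$g_mw)
    gam <- gamma_cos(pts$t_leaf_C, tr$gamma)
    expect_lt(max(abs(ig$cos_c - gam) / pmax(gam, 1)), 1e-8)
  }
})

test_that("indirect inversion limits: infinite CA, stagnant chamber", {
  tr <- synth_truth_reference("S2")
  cfg <- canonical_cfg()
  dat <- generate_dataset(design_gsw_sweep(plant_ids = 2), tr, cfg,
                          noise_model(0, 0, 0), seed = 1)
  pts <- dat$points
  ca_inf <- ca_kinetics(1e9, tr$t_eq_ca)
  ig <- indirect_gamma(pts, pts$g_sw_meas, ca_inf, tr$g_mw)
  expect_equal(ig$cos_c, ig$cos_i, tolerance = 1e-6)
  # saturated inflow (no transpiration) and equal in/out: all layers equal
  x_c <- h2o_saturated_mole_fraction(25, cfg$p_air)
  row <- pts[1, ]
  row$t_leaf_C <- 25; row$h2o_in <- x_c; row$h2o_out <- x_c
  row$cos_in_dry <- 500; row$cos_out_dry <- 500
  ig0 <- indirect_gamma(row, 0.6, ca_kinetics(0.2, 39.7), 10)
  wet <- dry_to_wet(500, x_c)
  expect_equal(c(ig0$cos_b, ig0$cos_i, ig0$cos_c), rep(wet, 3),
               tolerance = 1e-9)
  expect_error(indirect_gamma(pts, rep(0, nrow(pts)), ca_inf), "positive")
  expect_error(indirect_gamma(pts[, 1:4], 0.6, ca_inf), "missing columns")
})

test_that("ramp regression recovers the forward model's flux zero-crossing", {
  cfg <- canonical_cfg()
  leaf <- posterior_leaf(0.9)
  xin <- seq(100, 700, length.out = 8)
  fw <- forward_simulate(cfg, leaf, xin, 449, 12, 25)
  r <- regress_gamma(fw$cos_out_dry, fw$f_cos, t_leaf = 25)
  # independent oracle: bisection on the inflow at which the forward flux
  # crosses zero, reported at the corresponding outflow mole fraction
  root <- uniroot(function(x) forward_simulate(cfg, leaf, x, 449, 12, 25)$f_cos,
                  c(10, 700), tol = 1e-10)$root
  out_at_root <- forward_simulate(cfg, leaf, root, 449, 12, 25)$cos_out_dry
  expect_equal(r$gamma_hat, out_at_root, tolerance = 1e-6)
})
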