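test_that("wet/dry conversion matches arithmetic and round-trips", {
  expect_equal(wet_to_dry(950, 20), 950 / 0.98)
  expect_identical(wet_to_dry(123.4, 0), 123.4)
  expect_equal(dry_to_wet(wet_to_dry(871.2, 24.7), 24.7), 871.2)
  expect_error(wet_to_dry(1, 1000), "h2o")
})

test_that("net flux follows the chamber mass balance", {
  cfg <- canonical_cfg()
  expect_equal(net_flux(cfg, 600, 500), (3.5e-4 / 9e-4) * 100)
  expect_identical(net_flux(cfg, 500, 500), 0)
  expect_equal(net_flux(cfg, 500, 600), -net_flux(cfg, 600, 500))
})

test_that("H2O solve matches an independent linear-system oracle", {
  cfg <- canonical_cfg()
  leaf <- posterior_leaf(g_sw = 0.6)
  sol <- solve_h2o(cfg, leaf, 15, 25)
  # oracle: assemble the three balance equations as an explicit 3x3 solve
  q <- cfg$af / cfg$s
  x_c <- 1000 * 613.5 * exp(17.502 * 25 / (25 + 240.97)) / cfg$p_air
  A <- rbind(c(q + cfg$g_bw, -cfg$g_bw, 0),
             c(cfg$g_bw, -(cfg$g_bw + leaf$g_sw), leaf$g_sw),
             c(0, leaf$g_sw, -(leaf$g_sw + leaf$g_mw)))
  b <- c(q * 15, 0, -leaf$g_mw * x_c)
  xs <- solve(A, b)
  expect_equal(c(sol$x_a, sol$x_b, sol$x_i), xs, tolerance = 1e-12)
  expect_equal(sol$x_a, 23.575, tolerance = 1e-4)
  expect_equal(sol$e_h2o, 3.335e-3, tolerance = 1e-3)
  expect_equal(sol$rh_i, 98.92, tolerance = 1e-4)
})

test_that("H2O limits: saturated inflow is stationary, huge g_mw saturates", {
  cfg <- canonical_cfg()
  leaf <- posterior_leaf()
  x_c <- h2o_saturated_mole_fraction(25, cfg$p_air)
  eq <- solve_h2o(cfg, leaf, x_c, 25)
  expect_equal(eq$flux, 0)
  expect_equal(c(eq$x_a, eq$x_b, eq$x_i), rep(x_c, 3))
  leaf_inf <- posterior_leaf(); leaf_inf$g_mw <- 1e9
  expect_equal(solve_h2o(cfg, leaf_inf, 15, 25)$rh_i, 100, tolerance = 1e-8)
})

test_that("COS solve closes all three balance equations to 1e-9", {
  cfg <- canonical_cfg()
  leaf <- posterior_leaf(0.6)
  h <- solve_h2o(cfg, leaf, 15, 25)
  sol <- solve_cos(cfg, leaf, 900, 25, h$e_h2o)
  q <- cfg$af / cfg$s
  sc <- species_conductances(leaf$g_sw, cfg$g_bw)
  gm <- g_m_cos(25, leaf$ca)
  t1 <- q * (900 - sol$x_a)
  t2 <- sc$g_b_cos * (sol$x_a - sol$x_b)
  t3 <- sc$g_s_cos * (sol$x_b - sol$x_i) -
    h$e_h2o * (sol$x_b + sol$x_i) / 2
  t4 <- gm * (sol$x_i - sol$x_c)
  scale <- max(abs(c(t1, t2, t3, t4)))
  expect_lt(max(abs(diff(c(t1, t2, t3, t4)))) / scale, 1e-9)
})

test_that("COS equilibrium and two-resistor limits are exact", {
  cfg <- canonical_cfg()
  leaf <- posterior_leaf(0.6)
  gam25 <- gamma_cos(25, leaf$gamma)
  eq <- solve_cos(cfg, leaf, gam25, 25, 0)
  expect_equal(eq$flux, 0, tolerance = 1e-12)
  expect_equal(c(eq$x_a, eq$x_b, eq$x_i), rep(gam25, 3), tolerance = 1e-12)
  # ternary term breaks the uniform equilibrium when transpiration is on
  eq2 <- solve_cos(cfg, leaf, gam25, 25, 3e-3)
  expect_gt(abs(eq2$flux), 0)
  # gamma = 0 and infinite mesophyll conductance: x_i from the closed-form
  # two-conductance series network
  leaf0 <- posterior_leaf(0.6, variant = "S1")
  leaf0$ca <- ca_kinetics(1e9, 25)
  sol <- solve_cos(cfg, leaf0, 900, 25, 0)
  q <- cfg$af / cfg$s
  sc <- species_conductances(0.6, cfg$g_bw)
  g_ser <- 1 / (1 / q + 1 / sc$g_b_cos + 1 / sc$g_s_cos)
  f_oracle <- g_ser * 900
  expect_equal(sol$flux, f_oracle, tolerance = 1e-6)
  expect_equal(sol$x_i, 0, tolerance = 1e-6 * 900)
})

test_that("COS flux is linear in the inflow mole fraction", {
  cfg <- canonical_cfg()
  leaf <- posterior_leaf(0.6)
  h <- solve_h2o(cfg, leaf, 15, 25)
  xin <- c(200, 600, 1000)
  f <- vapply(xin, function(x) solve_cos(cfg, leaf, x, 25, h$e_h2o)$flux,
              numeric(1))
  # three points collinear
  slope12 <- (f[2] - f[1]) / (xin[2] - xin[1])
  slope23 <- (f[3] - f[2]) / (xin[3] - xin[2])
  expect_equal(slope12, slope23, tolerance = 1e-10)
})

test_that("CO2 solve agrees with a brute-force grid oracle", {
  cfg <- canonical_cfg()
  leaf <- posterior_leaf(0.6)
  h <- solve_h2o(cfg, leaf, 15, 25)
  sol <- solve_co2(cfg, leaf, 400, 25, h$e_h2o)
  q <- cfg$af / cfg$s
  sc <- species_conductances(0.6, cfg$g_bw)
  grid <- seq(1e-3, 400, length.out = 10000)
  supply_demand_gap <- vapply(grid, function(xi) {
    f <- rubisco_assimilation(xi * cfg$p_air * 1e-6, 25, leaf$rub,
                              leaf$co2c) - dark_respiration(25, leaf$co2c)
    x_b <- 400 - f * (1 / q + 1 / sc$g_b_co2)
    xi_implied <- ((sc$g_s_co2 - h$e_h2o / 2) * x_b - f) /
      (sc$g_s_co2 + h$e_h2o / 2)
    abs(xi_implied - xi)
  }, numeric(1))
  expect_equal(sol$x_i, grid[which.min(supply_demand_gap)],
               tolerance = 2 * diff(grid[1:2]) / sol$x_i)
  # residuals close
  f <- sol$flux
  x_b <- 400 - f * (1 / q + 1 / sc$g_b_co2)
  expect_equal(x_b, sol$x_b, tolerance = 1e-9)
})

test_that("CO2 respiration-only and compensation limits behave", {
  cfg <- canonical_cfg()
  leaf <- posterior_leaf(0.6)
  leaf$rub <- rubisco_kinetics(0)
  h <- solve_h2o(cfg, leaf, 15, 25)
  sol <- solve_co2(cfg, leaf, 400, 25, h$e_h2o)
  expect_lt(sol$flux, 0)          # pure source
  expect_gt(sol$x_a, 400)         # outflow exceeds inflow
  # no respiration, inflow at the Gamma*-equivalent mole fraction: zero flux
  leaf2 <- posterior_leaf(0.6)
  leaf2$co2c <- co2_constants(rd_298 = 0)
  x_comp <- gamma_star_co2(25, leaf2$co2c) / cfg$p_air * 1e6
  sol2 <- solve_co2(cfg, leaf2, x_comp, 25, 0)
  expect_equal(sol2$flux, 0, tolerance = 1e-9)
})

test_that("steady state is independent of cuvette and molar volume", {
  leaf <- posterior_leaf(0.6)
  a <- forward_simulate(chamber_config(v_cv = 109e-6, v_m = 0.0248),
                        leaf, 1000, 400, 15, 25)
  b <- forward_simulate(chamber_config(v_cv = 10 * 109e-6, v_m = 0.248),
                        leaf, 1000, 400, 15, 25)
  expect_identical(a, b)
})

test_that("deposition velocity and AFR follow their definitions", {
  expect_equal(afr(100, 0), 1)
  expect_equal(afr(100, 100), 0)
  expect_equal(afr(100, 63), 0.37)
  g_bs <- 1 / (1 / 1.56 + 1 / 0.3)
  expect_equal(deposition_velocity(100, 0, 1.56, 0.3), g_bs)
  expect_equal(deposition_velocity(100, 100, 1.56, 0.3), 0)
  expect_error(afr(0, 1), "positive")
})

test_that("LRU is the ratio of normalized uptakes", {
  expect_equal(lru(30, 1000, 15, 400), 0.8)
  expect_equal(lru(10, 500, 20, 1000), 1)
  expect_equal(lru(0, 1000, 15, 400), 0)
  expect_error(lru(1, 0, 1, 1), "positive")
  expect_error(lru(1, 1, 0, 1), "nonzero")
})

test_that("forward simulation degenerates correctly with dead enzymes", {
  cfg <- canonical_cfg()
  ref <- sunflower_reference()
  dead <- leaf_parameters(0.6, ca_kinetics(0, 30), rubisco_kinetics(0),
                          gamma_cos_spec("S1"))
  out <- forward_simulate(cfg, dead, 1000, 400, 15, 25)
  # zero leaf exchange: chamber equals inflow exactly on the model's wet
  # basis; the dry-basis value differs only by the neglected outlet-flow
  # (transpiration) effect, below 1 %
  expect_equal(out$cos_a, dry_to_wet(1000, 15), tolerance = 1e-9)
  expect_lt(abs(out$cos_out_dry - 1000) / 1000, 0.01)
  expect_gt(out$co2_out_dry, out$cos_out_dry / 1000 * 400)  # respiration source
  dead0 <- dead; dead0$co2c <- co2_constants(rd_298 = 0)
  out0 <- forward_simulate(cfg, dead0, 1000, 400, 15, 25)
  expect_equal(out0$co2_a, dry_to_wet(400, 15), tolerance = 1e-9)
})

test_that("chamber flux equals the mesophyll sink through the linear chain", {
  cfg <- canonical_cfg()
  leaf <- posterior_leaf(0.6)
  h <- solve_h2o(cfg, leaf, 15, 25)
  cos_in_wet <- dry_to_wet(1000, 15)
  sol <- solve_cos(cfg, leaf, cos_in_wet, 25, h$e_h2o)
  sink <- g_m_cos(25, leaf$ca) * (sol$x_i - gamma_cos(25, leaf$gamma))
  expect_equal(sol$flux, sink, tolerance = 1e-9 * abs(sink))
})

test_that("COS deposition velocity responds monotonically to drivers", {
  cfg <- canonical_cfg()
  gs <- seq(0.2, 1.2, by = 0.1)
  v <- vapply(gs, function(g) {
    forward_simulate(cfg, posterior_leaf(g), 1000, 400, 15, 25)$v_cos
  }, numeric(1))
  expect_true(all(diff(v) > 0))
  # larger compensation point, smaller deposition velocity
  ms <- c(5, 15, 25, 35)
  vm <- vapply(ms, function(m) {
    leaf <- posterior_leaf(0.6)
    leaf$gamma <- gamma_cos_spec("S2", m_cos = m)
    forward_simulate(cfg, leaf, 1000, 400, 15, 25)$v_cos
  }, numeric(1))
  expect_true(all(diff(vm) < 0))
})

test_that("LRU increases and saturates along stomatal opening", {
  cfg <- canonical_cfg()
  gs <- seq(0.2, 1.2, by = 0.1)
  l <- vapply(gs, function(g) {
    forward_simulate(cfg, posterior_leaf(g), 1000, 400, 15, 25)$lru
  }, numeric(1))
  expect_true(all(diff(l) >= 0))
  # saturating: increments shrink at high conductance
  expect_lt(diff(l)[length(gs) - 1], diff(l)[1])
})
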