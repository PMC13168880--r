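test_that("error statistics follow their definitions", {
  expect_equal(error_stats(c(1, 2, 3), c(1, 2, 3)), c(rmse = 0, mbe = 0))
  expect_equal(error_stats(c(2, 3, 4), c(1, 2, 3)), c(rmse = 1, mbe = 1))
  expect_equal(error_stats(c(1, 3), c(0, 0)), c(rmse = sqrt(5), mbe = 2))
  expect_error(error_stats(numeric(0), numeric(0)), "non-empty")
  set.seed(2)
  for (i in 1:20) {
    e <- rnorm(10); o <- rnorm(10)
    s <- error_stats(e, o)
    expect_gte(s[["rmse"]], abs(s[["mbe"]]) - 1e-12)
  }
  # equality iff the residual is constant
  s <- error_stats(c(4, 5, 6), c(1, 2, 3))
  expect_equal(s[["rmse"]], abs(s[["mbe"]]))
})

test_that("zero injected noise collapses the ensemble", {
  d <- small_dataset(noise = noise_model(), seed = 9)
  su <- inversion_setup(d$points, "S2")
  pr <- prior_spec(su)
  ens <- suppressWarnings(
    monte_carlo_posterior(su, pr, weight_set(), n_members = 3, seed = 1,
                          noise_scale = 0))
  expect_equal(max(abs(ens$covariance)), 0, tolerance = 1e-20)
  expect_equal(ens$members[1, ], ens$members[3, ])
})

test_that("ensembles are seed-deterministic and summarized consistently", {
  d <- small_dataset(noise = noise_model(), seed = 10)
  su <- inversion_setup(d$points, "S2")
  pr <- prior_spec(su)
  e1 <- suppressWarnings(monte_carlo_posterior(su, pr, n_members = 3, seed = 4))
  e2 <- suppressWarnings(monte_carlo_posterior(su, pr, n_members = 3, seed = 4))
  expect_identical(e1$members, e2$members)
  expect_equal(diag(e1$covariance), apply(e1$members, 2, var),
               tolerance = 1e-12)
  ev <- eigen(e1$covariance, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(abs(ev)))
})

test_that("posterior spread shrinks the prior and correlates COS kinetics", {
  d <- campaign_dataset(seed = 31)
  su <- inversion_setup(d$points, "S2")
  pr <- prior_spec(su)
  ens <- suppressWarnings(
    monte_carlo_posterior(su, pr, weight_set(), n_members = 16, seed = 12))
  # error reduction for the strongly constrained RuBisCO activation energy
  expect_lt(ens$sd[["dH_a_rub"]], 12)
  # the three COS-uptake parameters move together
  cm <- cov2cor(ens$covariance)
  expect_gt(cm["v_max_ca.2", "gamma"], 0.3)
  # covariance estimate stabilizes as members accumulate
  c_half <- cov(ens$members[1:8, c("t_eq_ca", "gamma", "dH_a_rub")])
  c_full <- cov(ens$members[, c("t_eq_ca", "gamma", "dH_a_rub")])
  expect_lt(norm(c_half - c_full, "F"), norm(c_full, "F"))
})

test_that("forward spread collapses with the covariance and trims 3-sigma draws", {
  d <- small_dataset(noise = noise_model(), seed = 13)
  su <- inversion_setup(d$points, "S2")
  pr <- prior_spec(su)
  nx <- length(pr$mean)
  mu <- pr$mean
  fake <- structure(list(mean = mu, sd = setNames(rep(0, nx), names(mu)),
                         covariance = matrix(0, nx, nx,
                                             dimnames = list(names(mu),
                                                             names(mu)))),
                    class = "posterior_ensemble")
  cond <- list(cfg = canonical_cfg(), cos_in_dry = 1000, co2_in_dry = 400,
               h2o_in = 15, t_leaf = 25, variant = "S2", plant = 2,
               point = d$points$point_id[1])
  fs0 <- forward_spread(fake, cond, n_draws = 50, seed = 1)
  expect_equal(unname(fs0$sd), rep(0, 5))
  expect_equal(fs0$discarded_count, 0)
  # a single stochastic component: the per-component 3-sigma trim discards
  # the Gaussian tail mass, about 0.27 % of draws
  fake1 <- fake
  gnm <- "gamma"
  fake1$sd[gnm] <- 2
  fake1$covariance[gnm, gnm] <- 4
  fs1 <- forward_spread(fake1, cond, n_draws = 4000, seed = 2)
  rate <- fs1$discarded_count / 4000
  expect_gt(rate, 0.0002)
  expect_lt(rate, 0.009)
  expect_gt(fs1$sd[["cos_out_dry"]], 0)
})

test_that("posterior spread is narrower than prior spread in forward runs", {
  d <- small_dataset(noise = noise_model(), seed = 14)
  su <- inversion_setup(d$points, "S2")
  pr <- prior_spec(su)
  ens <- suppressWarnings(
    monte_carlo_posterior(su, pr, weight_set(), n_members = 10, seed = 3))
  nx <- length(pr$mean)
  prior_ens <- structure(list(mean = pr$mean, sd = pr$sd,
                              covariance = diag(pr$sd^2) |>
                                `dimnames<-`(list(names(pr$mean),
                                                  names(pr$mean)))),
                         class = "posterior_ensemble")
  cond <- list(cfg = canonical_cfg(), cos_in_dry = 1000, co2_in_dry = 400,
               h2o_in = 15, t_leaf = 25, variant = "S2", plant = 2,
               point = d$points$point_id[1])
  sp_prior <- forward_spread(prior_ens, cond, n_draws = 120, seed = 5)
  sp_post <- forward_spread(ens, cond, n_draws = 120, seed = 5)
  expect_lt(sp_post$sd[["cos_out_dry"]], sp_prior$sd[["cos_out_dry"]])
  expect_lt(sp_post$sd[["co2_out_dry"]], sp_prior$sd[["co2_out_dry"]])
})
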