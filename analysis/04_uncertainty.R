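#!/usr/bin/env Rscript
# Posterior uncertainty for the linear-compensation-point model: a Monte
# Carlo ensemble of re-optimizations (noise in priors and observations),
# the posterior covariance, and correlated-draw forward simulations at the
# canonical chamber condition. Ensemble and draw counts are configurable;
# the defaults keep the run to a few minutes (pass 200 / 500 to reproduce
# the full study setting).
suppressMessages(library(cosleaf))

args <- commandArgs(trailingOnly = TRUE)
n_members <- if (length(args) >= 1) as.integer(args[1]) else 40L
n_draws <- if (length(args) >= 2) as.integer(args[2]) else 500L

pts <- rbind(read_observed_points("results/experiment2_points.csv"),
             read_observed_points("results/experiment3_points.csv"))
emission <- chamber_emission_model()
q <- pts$af_mol_s / pts$s_m2
pts$cos_out_dry <- pts$cos_out_dry - chamber_emission(pts$t_leaf_C, emission) / q

su <- inversion_setup(pts, "S2")
pr <- prior_spec(su)
w <- weight_set()

ens <- suppressWarnings(
  monte_carlo_posterior(su, pr, w, n_members = n_members, seed = 2024))
cat("ensemble members:", ens$member_count, "(failed:", ens$n_failed, ")\n")

shared <- c("v_max_ca.2", "v_max_ca.3", "v_max_ca.4", "t_eq_ca", "gamma",
            "v_max_rub.2", "v_max_rub.3", "v_max_rub.4", "dH_a_rub")
summ <- data.frame(parameter = shared,
                   posterior_mean = ens$mean[shared],
                   posterior_sd = ens$sd[shared],
                   prior_mean = pr$mean[shared], prior_sd = pr$sd[shared])
summ$error_reduction_pct <- 100 * (1 - summ$posterior_sd / summ$prior_sd)
write.csv(summ, "results/posterior_parameters.csv", row.names = FALSE)
print(summ, digits = 3, row.names = FALSE)

write.csv(ens$members, "results/ensemble_members.csv", row.names = FALSE)
write.csv(ens$covariance[shared, shared], "results/posterior_covariance.csv")
cm <- cov2cor(ens$covariance[c("v_max_ca.2", "t_eq_ca", "gamma"),
                             c("v_max_ca.2", "t_eq_ca", "gamma")])
cat("COS-kinetics correlations (v_max_ca.2 / t_eq_ca / gamma):\n")
print(round(cm, 2))

cond <- list(cfg = chamber_config(), cos_in_dry = 1000, co2_in_dry = 400,
             h2o_in = 15, t_leaf = 25, variant = "S2", plant = 2,
             point = pts$point_id[1])
prior_ens <- list(mean = pr$mean, sd = pr$sd,
                  covariance = diag(pr$sd^2) |>
                    `dimnames<-`(list(names(pr$mean), names(pr$mean))))
sp_prior <- forward_spread(prior_ens, cond, n_draws = n_draws, seed = 9)
sp_post <- forward_spread(ens, cond, n_draws = n_draws, seed = 9)
spread <- data.frame(output = names(sp_post$mean),
                     prior_sd = sp_prior$sd, posterior_sd = sp_post$sd,
                     posterior_mean = sp_post$mean)
write.csv(spread, "results/forward_spread.csv", row.names = FALSE)
cat(sprintf(
  "forward spread ([COS]_out): prior sd %.1f -> posterior sd %.1f pmol mol-1 (%d draws, %d discarded)\n",
  sp_prior$sd[["cos_out_dry"]], sp_post$sd[["cos_out_dry"]],
  n_draws, sp_post$discarded_count))
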