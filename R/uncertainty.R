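#' Monte Carlo posterior ensemble
#'
#' Re-optimizes the state for each ensemble member after perturbing both the
#' prior means (within the prior standard deviations, truncated to the
#' bounds) and the observations (within their per-point observational
#' standard deviations, drawn independently per point and member). The
#' member-to-member spread estimates the posterior error; the covariance over
#' members is the posterior covariance.
#'
#' @param setup An \code{inversion_setup}.
#' @param prior A \code{prior_spec}.
#' @param weights A \code{weight_set}.
#' @param n_members Ensemble size (>= 2); 200 reproduces the full study
#'   setting.
#' @param seed Integer seed; the ensemble is bit-reproducible.
#' @param noise_scale Multiplier on both injected noise sources (0 gives
#'   identical members and a zero covariance; 1 is the standard procedure).
#' @param ... Passed to \code{\link{fit_state}}.
#' @return An object of class \code{posterior_ensemble}: \code{members}
#'   (matrix, one row per member), \code{mean}, \code{sd},
#'   \code{covariance}, \code{n_failed}.
#' @export
monte_carlo_posterior <- function(setup, prior, weights = weight_set(),
                                  n_members = 200, seed = 1,
                                  noise_scale = 1, ...) {
  stopifnot(n_members >= 2, noise_scale >= 0)
  set.seed(seed)
  nx <- length(prior$mean)
  d0 <- setup$data
  members <- matrix(NA_real_, n_members, nx,
                    dimnames = list(NULL, names(prior$mean)))
  n_failed <- 0L
  for (m in seq_len(n_members)) {
    pri_m <- prior
    pri_m$mean <- pmin(pmax(prior$mean +
                              stats::rnorm(nx, 0, noise_scale * prior$sd),
                            prior$lower), prior$upper)
    set_m <- setup
    d <- d0
    d$cos_out_dry <- d$cos_out_dry +
      stats::rnorm(nrow(d), 0, noise_scale * d$sigma_cos)
    d$co2_out_dry <- d$co2_out_dry +
      stats::rnorm(nrow(d), 0, noise_scale * d$sigma_co2)
    d$h2o_out <- d$h2o_out +
      stats::rnorm(nrow(d), 0, noise_scale * d$sigma_h2o)
    set_m$data <- d
    f <- tryCatch(fit_state(set_m, pri_m, weights, ...),
                  error = function(e) NULL)
    if (is.null(f)) {
      n_failed <- n_failed + 1L
    } else {
      members[m, ] <- f$par
    }
  }
  ok <- stats::complete.cases(members)
  members <- members[ok, , drop = FALSE]
  structure(list(members = members,
                 mean = colMeans(members),
                 sd = apply(members, 2, stats::sd),
                 covariance = stats::cov(members),
                 member_count = nrow(members), n_failed = n_failed),
            class = "posterior_ensemble")
}

#' Correlated-draw forward spread
#'
#' Samples parameter vectors from the multivariate Gaussian defined by the
#' ensemble mean and covariance (cross-parameter correlations preserved),
#' discards any draw with a component more than three ensemble standard
#' deviations from the mean, runs the forward model at a fixed chamber
#' condition for each retained draw, and summarizes the output spread. A
#' singular covariance is regularized by a jitter of 1e-12 of its trace.
#'
#' @param ensemble A \code{posterior_ensemble} (or a list with \code{mean},
#'   \code{sd}, \code{covariance}).
#' @param condition List with the chamber condition: \code{cfg}
#'   (a \code{chamber_config}), \code{cos_in_dry}, \code{co2_in_dry},
#'   \code{h2o_in}, \code{t_leaf}, and the fixed-model fields
#'   \code{variant}, \code{plant} (which plant's capacities to use),
#'   \code{point} (which point's g_sw entry), plus optionally \code{co2c},
#'   \code{dH_a_ca}, \code{dH_eq_ca}, \code{g_mw}.
#' @param n_draws Number of parameter draws, default 500.
#' @param seed Integer seed.
#' @return An object of class \code{forward_spread}: per-output \code{mean}
#'   and \code{sd} (for the dry-basis outflows and fluxes),
#'   \code{discarded_count}, \code{draw_count}.
#' @export
forward_spread <- function(ensemble, condition, n_draws = 500, seed = 1) {
  set.seed(seed)
  mu <- ensemble$mean
  S <- ensemble$covariance
  sdv <- ensemble$sd
  nx <- length(mu)
  ## regularize and factor; a fully degenerate ensemble draws at the mean
  if (all(S == 0)) {
    ch <- matrix(0, nx, nx)
  } else {
    jit <- 1e-12 * sum(diag(S))
    ch <- tryCatch(chol(S), error = function(e) chol(S + diag(jit, nx)))
  }
  z <- matrix(stats::rnorm(n_draws * nx), n_draws, nx)
  draws <- sweep(z %*% ch, 2, mu, "+")
  colnames(draws) <- names(mu)
  ## per-component 3-sigma trim: drop the whole draw if any parameter strays
  ok_sd <- sdv > 0
  keep <- rep(TRUE, n_draws)
  if (any(ok_sd)) {
    dev <- abs(sweep(draws[, ok_sd, drop = FALSE], 2, mu[ok_sd], "-"))
    dev <- sweep(dev, 2, sdv[ok_sd], "/")
    keep <- apply(dev, 1, max) <= 3
  }
  draws <- draws[keep, , drop = FALSE]

  cfg <- condition$cfg
  co2c <- condition$co2c %||% co2_constants()
  dH_a_ca <- condition$dH_a_ca %||% 40000
  dH_eq_ca <- condition$dH_eq_ca %||% 100000
  g_mw <- condition$g_mw %||% 10
  variant <- condition$variant %||% "S2"
  gspec <- gamma_cos_spec(variant)
  vca_nm <- paste0("v_max_ca.", condition$plant)
  vrb_nm <- paste0("v_max_rub.", condition$plant)
  gsw_nm <- paste0("g_sw.", condition$point)

  outs <- matrix(NA_real_, nrow(draws), 5,
                 dimnames = list(NULL, c("cos_out_dry", "co2_out_dry",
                                         "h2o_out_est", "f_cos", "f_co2")))
  for (k in seq_len(nrow(draws))) {
    x <- draws[k, ]
    gp <- if (variant == "S1") NULL else {
      if (variant == "S2") x[["gamma"]] else x[["gamma"]] * 1000
    }
    t_eq <- min(max(x[["t_eq_ca"]], 1), 60)
    a_t <- 1 / .f_ca_raw(t_eq, dH_a_ca, dH_eq_ca, t_eq)
    fw <- .forward_core(cfg$af, cfg$s, cfg$p_air, cfg$g_bw,
                        max(x[[gsw_nm]], 1e-3), g_mw,
                        max(x[[vca_nm]], 0), t_eq, a_t, dH_a_ca, dH_eq_ca,
                        max(x[[vrb_nm]], 0), x[["dH_a_rub"]] * 1000,
                        co2c, gspec, gp,
                        condition$cos_in_dry, condition$co2_in_dry,
                        condition$h2o_in, condition$t_leaf)
    outs[k, ] <- c(fw$cos_out_dry, fw$co2_out_dry, fw$h2o_out_est,
                   fw$f_cos_dry, fw$f_co2_dry)
  }
  structure(list(mean = colMeans(outs), sd = apply(outs, 2, stats::sd),
                 draw_count = n_draws,
                 discarded_count = n_draws - nrow(draws),
                 draws = outs),
            class = "forward_spread")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Root-mean-square error and mean bias error
#'
#' @param est,obs Equal-length numeric vectors (length >= 1).
#' @return Named vector \code{c(rmse, mbe)}; \code{rmse >= |mbe|} always,
#'   with equality for a constant residual.
#' @export
error_stats <- function(est, obs) {
  if (length(est) == 0 || length(est) != length(obs)) {
    stop("est and obs must be non-empty and of equal length")
  }
  d <- est - obs
  c(rmse = sqrt(mean(d^2)), mbe = mean(d))
}
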