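#' Inversion setup: bind a data-point table to the model structure
#'
#' Groups points by plant (per-plant enzyme capacities, shared temperature
#' kinetics, per-point stomatal conductance) and fixes the non-optimized
#' constants.
#'
#' @param data data.frame with the observed-point schema
#'   (\code{\link{read_observed_points}}).
#' @param variant Compensation-point temperature function: \code{"S1"}
#'   (none), \code{"S2"} (linear), \code{"S3"}/\code{"S4"} (Arrhenius).
#' @param co2c \code{co2_constants}.
#' @param dH_a_ca,dH_eq_ca Fixed CA activation/equilibrium enthalpies
#'   (J mol-1).
#' @param g_mw Mesophyll conductance for H2O (mol m-2 s-1).
#' @return An object of class \code{inversion_setup}.
#' @export
inversion_setup <- function(data, variant = "S2", co2c = co2_constants(),
                            dH_a_ca = 40000, dH_eq_ca = 100000, g_mw = 10) {
  stopifnot(is.data.frame(data), nrow(data) > 0)
  miss <- setdiff(.point_columns, names(data))
  if (length(miss)) stop("data lacks column(s): ", paste(miss, collapse = ", "))
  plants <- sort(unique(data$plant_id))
  structure(list(data = data, variant = variant, co2c = co2c,
                 dH_a_ca = dH_a_ca, dH_eq_ca = dH_eq_ca, g_mw = g_mw,
                 plants = plants,
                 plant_idx = match(data$plant_id, plants),
                 n_points = nrow(data),
                 gamma_spec = gamma_cos_spec(variant)),
            class = "inversion_setup")
}

#' Prior specification for the state vector
#'
#' Builds the prior mean, prior standard deviation and optimizer bounds for
#' every state entry: per-plant CA and RuBisCO capacities, the shared CA
#' optimum temperature, the shared compensation-point parameter (linear slope
#' or activation energy, absent for the no-compensation-point variant), the
#' shared RuBisCO activation energy (kJ mol-1 in the state), and one
#' stomatal conductance per data point. The per-point stomatal prior takes
#' the measured value, with its uncertainty composed in quadrature from the
#' run-to-run variability (0.08 mol m-2 s-1), an instrument term
#' (0.02 mol m-2 s-1) and the relative outflow-humidity error mapped onto
#' the conductance.
#'
#' @param setup An \code{inversion_setup}.
#' @param v_max_ca_prior,v_max_ca_sd Prior mean/SD for the CA capacity
#'   (mol m-2 s-1).
#' @param t_eq_ca_prior,t_eq_ca_sd Prior mean/SD for the CA optimum (deg C).
#' @param gamma_prior,gamma_sd Prior mean/SD for the compensation-point
#'   parameter (pmol mol-1 K-1 for the linear variant; kJ mol-1 for the
#'   Arrhenius variants, defaulting to 134.3 with a 100 % prior error).
#' @param v_max_rub_prior,v_max_rub_sd Prior mean/SD for RuBisCO capacity
#'   (umol m-2 s-1).
#' @param dH_a_rub_prior,dH_a_rub_sd Prior mean/SD for the RuBisCO
#'   activation energy (kJ mol-1).
#' @param g_sw_var_sd,g_sw_instr_sd Components of the stomatal-conductance
#'   prior error (mol m-2 s-1).
#' @return An object of class \code{prior_spec} with named vectors
#'   \code{mean}, \code{sd}, \code{lower}, \code{upper}.
#' @export
prior_spec <- function(setup,
                       v_max_ca_prior = 0.125, v_max_ca_sd = 0.060,
                       t_eq_ca_prior = 30.0, t_eq_ca_sd = 15.0,
                       gamma_prior = NULL, gamma_sd = NULL,
                       v_max_rub_prior = 90.0, v_max_rub_sd = 20.0,
                       dH_a_rub_prior = 60.0, dH_a_rub_sd = 12.0,
                       g_sw_var_sd = 0.08, g_sw_instr_sd = 0.02) {
  stopifnot(inherits(setup, "inversion_setup"))
  pl <- setup$plants
  d <- setup$data
  if (is.null(gamma_prior)) {
    gamma_prior <- if (setup$variant == "S2") 16.2 else 134.3
  }
  if (is.null(gamma_sd)) gamma_sd <- gamma_prior  # 100 % prior error
  g_sw_sd <- sqrt(g_sw_var_sd^2 + g_sw_instr_sd^2 +
                    (d$g_sw_meas * d$sigma_h2o / d$h2o_out)^2)
  nm <- c(paste0("v_max_ca.", pl), paste0("v_max_rub.", pl), "t_eq_ca")
  mean <- c(rep(v_max_ca_prior, length(pl)), rep(v_max_rub_prior, length(pl)),
            t_eq_ca_prior)
  sd <- c(rep(v_max_ca_sd, length(pl)), rep(v_max_rub_sd, length(pl)),
          t_eq_ca_sd)
  lower <- c(rep(0.01, length(pl)), rep(1, length(pl)), 1)
  upper <- c(rep(0.50, length(pl)), rep(200, length(pl)), 60)
  if (setup$variant != "S1") {
    nm <- c(nm, "gamma")
    mean <- c(mean, gamma_prior)
    sd <- c(sd, gamma_sd)
    lower <- c(lower, 1)
    upper <- c(upper, if (setup$variant == "S2") 300 else 500)
  }
  nm <- c(nm, "dH_a_rub", paste0("g_sw.", d$point_id))
  mean <- c(mean, dH_a_rub_prior, d$g_sw_meas)
  sd <- c(sd, dH_a_rub_sd, g_sw_sd)
  lower <- c(lower, 1, rep(0, setup$n_points))
  upper <- c(upper, 100, rep(3, setup$n_points))
  names(mean) <- names(sd) <- names(lower) <- names(upper) <- nm
  structure(list(mean = mean, sd = sd, lower = lower, upper = upper),
            class = "prior_spec")
}

#' Observational weight set
#'
#' Scale factors that sit beside the squared observational errors in the cost
#' denominators: a larger weight shrinks that gas's cost contribution.
#' Defaults are the balanced set corresponding to prior chi-squared targets
#' of 30 (COS), 100 (CO2) and 3 (H2O).
#'
#' @param w_cos,w_co2,w_h2o,w_bg Positive weights.
#' @return An object of class \code{weight_set}.
#' @export
weight_set <- function(w_cos = 0.034, w_co2 = 7.2, w_h2o = 3.24, w_bg = 1.0) {
  stopifnot(w_cos > 0, w_co2 > 0, w_h2o > 0, w_bg > 0)
  structure(list(w_cos = w_cos, w_co2 = w_co2, w_h2o = w_h2o, w_bg = w_bg),
            class = "weight_set")
}

#' Choose weights that hit target prior chi-squared values
#'
#' With the weight dividing the squared misfit, the weighted prior
#' chi-squared equals the unweighted value divided by the weight, so the
#' weight reproducing a target is their ratio.
#'
#' @param unweighted_chi2 Named or ordered numeric: unweighted prior
#'   chi-squared per gas (cos, co2, h2o).
#' @param targets Target prior chi-squared per gas, same order.
#' @return A \code{weight_set}.
#' @export
select_weights <- function(unweighted_chi2, targets) {
  stopifnot(all(unweighted_chi2 > 0), all(targets > 0),
            length(unweighted_chi2) == 3, length(targets) == 3)
  w <- unweighted_chi2 / targets
  weight_set(w_cos = w[[1]], w_co2 = w[[2]], w_h2o = w[[3]])
}

## unpack a packed state vector into model blocks
.unpack_state <- function(x, setup) {
  pl <- setup$plants
  npl <- length(pl)
  v_max_ca <- x[paste0("v_max_ca.", pl)]
  v_max_rub <- x[paste0("v_max_rub.", pl)]
  gamma <- if (setup$variant == "S1") NULL else unname(x["gamma"])
  list(v_max_ca = v_max_ca, v_max_rub = v_max_rub,
       t_eq_ca = unname(x["t_eq_ca"]), gamma = gamma,
       dH_a_rub = unname(x["dH_a_rub"]),
       g_sw = unname(x[paste0("g_sw.", setup$data$point_id)]))
}

## per-point observational cost terms (vectors) for a state; the model/obs
## comparison is on the dry-air measurement basis using the observed outflow
## humidity in the conversion.
.obs_cost_terms <- function(x, setup, weights) {
  st <- .unpack_state(x, setup)
  d <- setup$data
  idx <- setup$plant_idx
  a_t <- 1 / .f_ca_raw(st$t_eq_ca, setup$dH_a_ca, setup$dH_eq_ca, st$t_eq_ca)
  gamma_param <- st$gamma
  if (!is.null(gamma_param) && setup$variant %in% c("S3", "S4")) {
    gamma_param <- gamma_param * 1000  # state in kJ mol-1
  }
  fw <- .forward_core(d$af_mol_s, d$s_m2, d$p_air_Pa, d$g_bw,
                      st$g_sw, setup$g_mw,
                      st$v_max_ca[idx], st$t_eq_ca, a_t,
                      setup$dH_a_ca, setup$dH_eq_ca,
                      st$v_max_rub[idx], st$dH_a_rub * 1000,
                      setup$co2c, setup$gamma_spec, gamma_param,
                      d$cos_in_dry, d$co2_in_dry, d$h2o_in, d$t_leaf_C,
                      h2o_out_obs = d$h2o_out)
  list(
    cos = (fw$cos_out_dry - d$cos_out_dry)^2 / (weights$w_cos * d$sigma_cos^2),
    co2 = (fw$co2_out_dry - d$co2_out_dry)^2 / (weights$w_co2 * d$sigma_co2^2),
    h2o = (fw$h2o_out_est - d$h2o_out)^2 / (weights$w_h2o * d$sigma_h2o^2),
    forward = fw
  )
}

#' Weighted cost function of the state vector
#'
#' Background term penalizing deviation from the prior mean plus per-gas
#' observational misfits, each squared difference divided by its weight times
#' the observational variance. The chi-squared diagnostics divide each part
#' by its count (state entries or data points).
#'
#' @param x Named state vector (as produced by \code{prior_spec}'s mean).
#' @param setup An \code{inversion_setup}.
#' @param prior A \code{prior_spec}.
#' @param weights A \code{weight_set}.
#' @return An object of class \code{cost_breakdown}: \code{j_bg},
#'   \code{j_cos}, \code{j_co2}, \code{j_h2o}, \code{j_tot} and a
#'   \code{chi2} vector.
#' @export
cost <- function(x, setup, prior, weights = weight_set()) {
  terms <- .obs_cost_terms(x, setup, weights)
  j_bg <- sum((x - prior$mean)^2 / (weights$w_bg * prior$sd^2))
  j_cos <- sum(terms$cos)
  j_co2 <- sum(terms$co2)
  j_h2o <- sum(terms$h2o)
  n <- setup$n_points
  structure(list(
    j_bg = j_bg, j_cos = j_cos, j_co2 = j_co2, j_h2o = j_h2o,
    j_tot = j_bg + j_cos + j_co2 + j_h2o,
    chi2 = c(bg = chi2(j_bg, length(x)), cos = chi2(j_cos, n),
             co2 = chi2(j_co2, n), h2o = chi2(j_h2o, n))
  ), class = "cost_breakdown")
}

#' Chi-squared diagnostic: cost per observation
#'
#' @param j_part Cost contribution (>= 0).
#' @param n Number of observations or state entries (> 0).
#' @return \code{j_part / n}.
#' @export
chi2 <- function(j_part, n) {
  if (any(n <= 0)) stop("n must be positive")
  j_part / n
}

## scalar total cost (for the optimizer)
.j_tot <- function(x, setup, prior, weights) {
  terms <- .obs_cost_terms(x, setup, weights)
  sum((x - prior$mean)^2 / (weights$w_bg * prior$sd^2)) +
    sum(terms$cos) + sum(terms$co2) + sum(terms$h2o)
}

## Gradient of the total cost by structured central differences.
## The observational cost separates over data points, a point depends only on
## its own g_sw and its plant's capacities, so whole blocks can be perturbed
## in a single vectorized evaluation: per-point partials come from the
## per-point cost changes, per-plant partials from plant-wise sums.
.j_grad <- function(x, setup, prior, weights) {
  g <- 2 * (x - prior$mean) / (weights$w_bg * prior$sd^2)  # background part
  d <- setup$data
  idx <- setup$plant_idx
  pl <- setup$plants
  point_cost <- function(xx) {
    t <- .obs_cost_terms(xx, setup, weights)
    t$cos + t$co2 + t$h2o
  }
  block_grad <- function(block_names) {
    h <- 1e-6 * pmax(abs(x[block_names]), 1e-2)
    xp <- x; xp[block_names] <- xp[block_names] + h
    xm <- x; xm[block_names] <- xm[block_names] - h
    (point_cost(xp) - point_cost(xm)) / (2 * h)  # one parameter per point
  }
  ## per-point stomatal conductances: one vectorized double evaluation
  gsw_names <- paste0("g_sw.", d$point_id)
  g[gsw_names] <- g[gsw_names] + block_grad(gsw_names)
  ## per-plant capacities: plants are disjoint over points
  for (blk in c("v_max_ca", "v_max_rub")) {
    bn <- paste0(blk, ".", pl)
    h <- 1e-6 * pmax(abs(x[bn]), 1e-2)
    xp <- x; xp[bn] <- xp[bn] + h
    xm <- x; xm[bn] <- xm[bn] - h
    dc <- point_cost(xp) - point_cost(xm)
    per_plant <- vapply(seq_along(pl),
                        function(p) sum(dc[idx == p]), numeric(1))
    g[bn] <- g[bn] + per_plant / (2 * h)
  }
  ## shared scalars: full central differences
  shared <- intersect(c("t_eq_ca", "gamma", "dH_a_rub"), names(x))
  for (nm in shared) {
    h <- 1e-6 * max(abs(x[nm]), 1e-2)
    xp <- x; xp[nm] <- xp[nm] + h
    xm <- x; xm[nm] <- xm[nm] - h
    g[nm] <- g[nm] + (sum(point_cost(xp)) - sum(point_cost(xm))) / (2 * h)
  }
  g
}

#' Fit the state vector by bounded weighted least squares
#'
#' Minimizes the total cost with a bounded quasi-Newton optimizer (L-BFGS-B)
#' starting from the prior mean, honouring the state bounds. The gradient is
#' evaluated by block-structured central differences that exploit the
#' point/plant separability of the observational cost. A small positive floor
#' replaces the zero lower bound on stomatal conductance (the conductance
#' chain is singular at exactly zero).
#'
#' @param setup An \code{inversion_setup}.
#' @param prior A \code{prior_spec}.
#' @param weights A \code{weight_set}.
#' @param start Optional start vector (default: prior mean).
#' @param maxit Iteration cap.
#' @param factr L-BFGS-B convergence factor (relative; multiplied by machine
#'   epsilon internally by \code{optim}).
#' @param g_sw_floor Numerical lower floor for stomatal conductance.
#' @return List with \code{par} (posterior state), \code{cost} (a
#'   \code{cost_breakdown} at the optimum), \code{convergence} flag,
#'   \code{message}, \code{counts} and \code{prior_cost}.
#' @export
fit_state <- function(setup, prior, weights = weight_set(), start = NULL,
                      maxit = 500, factr = 1e6, g_sw_floor = 1e-3) {
  stopifnot(inherits(setup, "inversion_setup"), inherits(prior, "prior_spec"))
  x0 <- if (is.null(start)) prior$mean else start
  lower <- prior$lower
  gsw <- grepl("^g_sw\\.", names(lower))
  lower[gsw] <- pmax(lower[gsw], g_sw_floor)
  x0 <- pmin(pmax(x0, lower), prior$upper)
  opt <- stats::optim(
    x0, fn = .j_tot, gr = .j_grad,
    setup = setup, prior = prior, weights = weights,
    method = "L-BFGS-B", lower = lower, upper = prior$upper,
    ## prior SDs as the natural parameter scales: the state mixes units
    ## spanning four orders of magnitude
    control = list(maxit = maxit, factr = factr, parscale = prior$sd))
  if (opt$convergence != 0) {
    ## a line-search abort at a stationary point (e.g. a zero-residual fixed
    ## point) is convergence in substance; check the scaled gradient
    gsc <- .j_grad(opt$par, setup, prior, weights) * prior$sd
    if (max(abs(gsc)) < 1e-4 * max(1, abs(opt$value))) {
      opt$convergence <- 0L
    } else {
      warning("optimizer did not report convergence: ", opt$message)
    }
  }
  list(par = opt$par,
       cost = cost(opt$par, setup, prior, weights),
       prior_cost = cost(prior$mean, setup, prior, weights),
       convergence = opt$convergence, message = opt$message,
       counts = opt$counts, value = opt$value)
}

#' Candidate-refit weight search
#'
#' Refits the state under each candidate chi-squared target set, computes the
#' cost reduction rates of the COS and CO2 parts, and selects the candidate
#' that optimizes their average subject to every posterior chi-squared
#' (including the background part) exceeding a floor. The literal
#' minimization of the averaged reduction rates is the default; maximization
#' is selectable.
#'
#' @param setup,prior As in \code{\link{fit_state}}.
#' @param targets_grid data.frame with columns \code{cos}, \code{co2},
#'   \code{h2o}: candidate prior chi-squared targets.
#' @param chi2_floor Posterior chi-squared floor guarding against
#'   overfitting.
#' @param maximize Optimize the average reduction rate upward instead.
#' @param ... Passed to \code{fit_state}.
#' @return List with the selected \code{weights}, the winning \code{fit} and
#'   a per-candidate summary table.
#' @export
select_weights_by_refit <- function(setup, prior, targets_grid,
                                    chi2_floor = 0.6, maximize = FALSE, ...) {
  base <- cost(prior$mean, setup, prior, weight_set(1, 1, 1, 1))
  un <- c(base$chi2["cos"], base$chi2["co2"], base$chi2["h2o"])
  rows <- list()
  best <- NULL
  for (k in seq_len(nrow(targets_grid))) {
    tg <- as.numeric(targets_grid[k, c("cos", "co2", "h2o")])
    w <- select_weights(un, tg)
    f <- fit_state(setup, prior, w, ...)
    pc <- f$prior_cost; po <- f$cost
    red <- c(cos = 1 - po$j_cos / pc$j_cos, co2 = 1 - po$j_co2 / pc$j_co2)
    ok <- all(po$chi2 > chi2_floor)
    score <- mean(red)
    rows[[k]] <- data.frame(targets_grid[k, ], avg_reduction = score,
                            admissible = ok)
    if (ok && (is.null(best) ||
               (if (maximize) score > best$score else score < best$score))) {
      best <- list(weights = w, fit = f, score = score)
    }
  }
  list(weights = if (is.null(best)) NULL else best$weights,
       fit = if (is.null(best)) NULL else best$fit,
       table = do.call(rbind, rows))
}
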