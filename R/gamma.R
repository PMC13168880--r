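#' Compensation point by flux-vs-concentration regression
#'
#' Ordinary least squares of the net COS flux on the outflowing COS mole
#' fraction; the compensation point is the mole fraction at which the fitted
#' flux crosses zero (the x-intercept, \code{-b0/b1}). The 95 % confidence
#' interval comes from first-order (delta-method) propagation of the OLS
#' coefficient covariance with a t quantile at n-2 degrees of freedom;
#' Fieller's interval is available as an alternative.
#'
#' @param cos_out Outflow COS mole fractions (pmol mol-1), >= 3 values with
#'   non-degenerate spread.
#' @param f_cos Net COS fluxes (pmol m-2 s-1), uptake positive.
#' @param conf Confidence level, default 0.95.
#' @param method \code{"delta"} (default) or \code{"fieller"}.
#' @param t_leaf Optional leaf temperature label carried into the result.
#' @return An object of class \code{regression_gamma} with fields
#'   \code{gamma_hat}, \code{ci95_half_width} (or the Fieller bounds),
#'   \code{slope}, \code{intercept}, \code{vcov}, \code{sigma2},
#'   \code{n_points}, \code{t_leaf}.
#' @export
regress_gamma <- function(cos_out, f_cos, conf = 0.95,
                          method = c("delta", "fieller"), t_leaf = NA_real_) {
  method <- match.arg(method)
  if (length(cos_out) < 3) stop("need at least 3 points")
  if (length(cos_out) != length(f_cos)) stop("length mismatch")
  if (stats::sd(cos_out) == 0) stop("degenerate abscissa: no spread in cos_out")
  fit <- stats::lm(f_cos ~ cos_out)
  b <- stats::coef(fit)
  b0 <- unname(b[1]); b1 <- unname(b[2])
  if (b1 <= 0) {
    warning("non-positive slope: x-intercept is not a compensation point")
  }
  n <- length(cos_out)
  X <- cbind(1, cos_out)
  xtx_inv <- solve(crossprod(X))
  sigma2 <- sum(stats::residuals(fit)^2) / (n - 2)
  V <- sigma2 * xtx_inv
  gamma_hat <- -b0 / b1
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 2)
  grad <- c(-1 / b1, b0 / b1^2)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  res <- list(gamma_hat = gamma_hat, slope = b1, intercept = b0,
              ci95_half_width = tq * se, se = se, vcov = V,
              xtx_inv = xtx_inv,
              sigma2 = sigma2, n_points = n, t_leaf = t_leaf,
              conf = conf, method = method,
              x = cos_out, y = f_cos)
  if (method == "fieller") {
    ## invert the t test for the ratio -b0/b1
    g <- (tq^2 * V[2, 2]) / b1^2
    if (g < 1) {
      centre <- gamma_hat + g * (gamma_hat + V[1, 2] / V[2, 2]) / (1 - g)
      hw <- tq / (abs(b1) * (1 - g)) *
        sqrt(V[1, 1] + 2 * gamma_hat * V[1, 2] + gamma_hat^2 * V[2, 2] -
               g * (V[1, 1] - V[1, 2]^2 / V[2, 2]))
      res$fieller <- c(lower = centre - hw, upper = centre + hw)
    } else {
      res$fieller <- c(lower = -Inf, upper = Inf)
    }
  }
  class(res) <- "regression_gamma"
  res
}

#' @export
print.regression_gamma <- function(x, ...) {
  cat(sprintf(
    "COS compensation point: %.1f +/- %.1f pmol mol-1 (%.0f %% CI, n = %d)\n",
    x$gamma_hat, x$ci95_half_width, 100 * x$conf, x$n_points))
  cat(sprintf("  slope %.4g pmol m-2 s-1 per pmol mol-1, intercept %.4g\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Widen a compensation-point confidence interval with chamber residuals
#'
#' Residual variability left after the empty-chamber emission correction adds
#' variance to every regression point: a flux residual SD directly, and a
#' concentration residual SD mapped through the regression slope. The OLS
#' coefficient covariance is re-scaled by the inflated per-point variance and
#' the delta-method interval recomputed; the widened interval is never
#' narrower than the original.
#'
#' @param result A \code{regression_gamma} object.
#' @param resid_sd_flux Chamber flux residual SD (pmol m-2 s-1).
#' @param resid_sd_conc Chamber concentration residual SD (pmol mol-1).
#' @return A \code{regression_gamma} with updated \code{ci95_half_width}.
#' @export
widen_ci_with_chamber_residual <- function(result, resid_sd_flux = 2.73,
                                           resid_sd_conc = 6.9) {
  stopifnot(inherits(result, "regression_gamma"),
            resid_sd_flux >= 0, resid_sd_conc >= 0)
  extra <- resid_sd_flux^2 + (result$slope * resid_sd_conc)^2
  V <- result$vcov + extra * result$xtx_inv
  grad <- c(-1 / result$slope, result$intercept / result$slope^2)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  tq <- stats::qt(1 - (1 - result$conf) / 2, df = result$n_points - 2)
  result$vcov <- V
  result$se <- se
  result$ci95_half_width <- max(tq * se, result$ci95_half_width)
  result
}

#' Indirect compensation point from observed layer inversion
#'
#' Algebraically inverts the steady-state layer equations for COS, walking
#' inward from the observed chamber mole fractions: the boundary-layer value
#' from the chamber mass balance, the intercellular value from the stomatal
#' balance with the ternary transpiration term, and the mesophyll-level value
#' from the mesophyll balance with the CA conductance at the fitted kinetics.
#' Transpiration uses the water model's chamber humidity at the fitted
#' stomatal conductance (not the observed outflow humidity), so that the
#' fitted \code{g_sw} is honoured. Applied to noise-free forward-simulated
#' data with the generating parameters, the mesophyll-level value returns the
#' prescribed compensation point exactly.
#'
#' @param data data.frame of observed points (see
#'   \code{\link{read_observed_points}} for the schema); requires columns
#'   \code{cos_in_dry}, \code{cos_out_dry}, \code{h2o_in}, \code{h2o_out},
#'   \code{t_leaf_C}, \code{p_air_Pa}, \code{af_mol_s}, \code{s_m2},
#'   \code{g_bw}.
#' @param g_sw Fitted stomatal conductance per point (mol m-2 s-1).
#' @param ca Fitted \code{ca_kinetics} (fields may be per-point vectors).
#' @param g_mw Mesophyll conductance for H2O (mol m-2 s-1).
#' @return data.frame with columns \code{cos_b}, \code{cos_i}, \code{cos_c}
#'   (pmol mol-1, wet basis) and \code{t_leaf_C} appended to the point ids.
#' @export
indirect_gamma <- function(data, g_sw, ca, g_mw = 10) {
  need <- c("cos_in_dry", "cos_out_dry", "h2o_in", "h2o_out", "t_leaf_C",
            "p_air_Pa", "af_mol_s", "s_m2", "g_bw")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(g_sw <= 0)) stop("non-positive g_sw")
  q <- data$af_mol_s / data$s_m2
  g_b <- data$g_bw / 1.56
  g_s <- g_sw / 1.94
  g_m <- g_m_cos(data$t_leaf_C, ca)

  h2o <- .solve_h2o_core(q, data$g_bw, g_sw, g_mw, data$h2o_in,
                         data$t_leaf_C, data$p_air_Pa)
  f_h2o <- q * (h2o$x_a - data$h2o_in) / 1000   # mol m-2 s-1, outward

  cos_in <- dry_to_wet(data$cos_in_dry, data$h2o_in)
  cos_a <- dry_to_wet(data$cos_out_dry, data$h2o_out)
  cos_b <- cos_a + (q / g_b) * (cos_a - cos_in)
  cos_i <- (-g_b * cos_a + g_b * cos_b + g_s * cos_b - 0.5 * f_h2o * cos_b) /
    (g_s + 0.5 * f_h2o)
  cos_c <- cos_i - (g_s / g_m) * (cos_b - cos_i) +
    (f_h2o / (2 * g_m)) * (cos_b + cos_i)

  out <- data.frame(t_leaf_C = data$t_leaf_C, cos_b = cos_b, cos_i = cos_i,
                    cos_c = cos_c)
  if (!is.null(data$point_id)) out <- cbind(point_id = data$point_id, out)
  out
}
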