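## Canonical column set for one 150-second steady-state data point.
.point_columns <- c("point_id", "plant_id", "t_leaf_C", "p_air_Pa",
                    "af_mol_s", "s_m2", "g_bw", "g_sw_meas",
                    "cos_in_dry", "cos_out_dry", "co2_in_dry", "co2_out_dry",
                    "h2o_in", "h2o_out", "sigma_cos", "sigma_co2", "sigma_h2o")

#' Read / write cuvette data-point tables
#'
#' CSV schema, one row per 150-second steady-state interval: point and plant
#' identifiers, leaf temperature (degrees C), pressure (Pa), air flow
#' (mol s-1), leaf area (m2), boundary and measured stomatal conductance
#' (mol m-2 s-1), dry-basis inflow/outflow COS (pmol mol-1) and CO2
#' (umol mol-1), H2O (mmol mol-1) and per-gas observational standard
#' deviations. Numerics are written with 10 significant digits so the
#' read/write round trip is exact at test tolerance.
#'
#' @param path CSV file path.
#' @return \code{read_observed_points}: a data.frame with the schema above.
#' @export
read_observed_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.point_columns, names(df))
  if (length(miss)) {
    stop("observed-point file lacks column(s): ", paste(miss, collapse = ", "))
  }
  df[, c(.point_columns, setdiff(names(df), .point_columns))]
}

#' @rdname read_observed_points
#' @param data data.frame with the observed-point schema.
#' @export
write_observed_points <- function(data, path) {
  miss <- setdiff(.point_columns, names(data))
  if (length(miss)) {
    stop("data lacks column(s): ", paste(miss, collapse = ", "))
  }
  out <- data
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) signif(v, 10))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
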