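#!/usr/bin/env Rscript
# Compensation-point regressions on the archived laboratory dataset
# (doi:10.5281/zenodo.15489794). This step needs the deposited files, which
# are not bundled here; download them first and pass the path to a CSV with
# the observed-point columns (see ?read_observed_points), e.g.
#
#   Rscript analysis/05_archived_dataset.R data/experiment1.csv
#
# Expected result: compensation points of about 55 pmol mol-1 at 19.8 C and
# about 139 pmol mol-1 at 25.0 C.
suppressMessages(library(cosleaf))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !file.exists(args[1])) {
  stop("archived dataset not available locally; download it from ",
       "https://doi.org/10.5281/zenodo.15489794 and pass the CSV path",
       call. = FALSE)
}
pts <- read_observed_points(args[1])
q <- pts$af_mol_s / pts$s_m2
f_cos <- q * (pts$cos_in_dry - pts$cos_out_dry)
for (d in split(data.frame(out = pts$cos_out_dry, f = f_cos,
                           t = pts$t_leaf_C),
                round(pts$t_leaf_C, 1))) {
  r <- regress_gamma(d$out, d$f, t_leaf = d$t[1])
  cat(sprintf("Gamma_COS at %.1f C: %.1f +/- %.1f pmol mol-1 (n = %d)\n",
              d$t[1], r$gamma_hat, r$ci95_half_width, r$n_points))
}
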