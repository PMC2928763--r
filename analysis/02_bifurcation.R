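#!/usr/bin/env Rscript

# Bifurcation structure: one-parameter sweeps of the DNA-binding rate
# (k3), the maximal synthesis rate (k5) and the Hill coefficient (k6),
# the (k3, k5) region map, and the fold (saddle-node) critical values by
# closed form and numeric scan, plus the basal-rate threshold k0_c.

library(tbpautoreg)

dir.create("results", showWarnings = FALSE)
p <- default_parameters(k0 = 0)

## critical values -----------------------------------------------------
crit <- list(
  k3_closed_form = critical_k3(p)$value,
  k3_numeric     = critical_k3(p, method = "numeric_scan")$value,
  k5_closed_form = critical_k5(p)$value,
  k5_numeric     = critical_k5(p, method = "numeric_scan")$value,
  k0             = critical_k0(default_parameters())$value,
  k0_over_k5     = critical_k0(default_parameters())$ratio_to_k5
)
cat("Fold critical values:\n")
cat(sprintf("  k3_c = %.4g M^-1 s^-1 (closed form) / %.4g (numeric scan)\n",
            crit$k3_closed_form, crit$k3_numeric))
cat(sprintf("  k5_c = %.4g M s^-1 (closed form) / %.4g (numeric scan)\n",
            crit$k5_closed_form, crit$k5_numeric))
cat(sprintf("  k0_c = %.4g M s^-1 (= %.4g * k5)\n", crit$k0, crit$k0_over_k5))
jsonlite::write_json(crit, "results/critical_values.json",
                     auto_unbox = TRUE, digits = NA)

## one-parameter sweeps ------------------------------------------------
sweep_and_save <- function(name, lo, hi, n = 200) {
  vals <- exp(seq(log(lo), log(hi), length.out = n))
  br <- sweep_1d(name, vals, p)
  utils::write.csv(as.data.frame(br),
                   sprintf("results/branch_%s.csv", name),
                   row.names = FALSE)
  cv <- attr(br, "critical_values")
  cat(sprintf("%s sweep [%g, %g]: critical value(s) %s\n", name, lo, hi,
              if (length(cv)) paste(signif(cv, 5), collapse = ", ")
              else "none in range"))
  br
}
invisible(sweep_and_save("k3", 2e4, 2e6))
invisible(sweep_and_save("k5", 5e-14, 5e-12))
invisible(sweep_and_save("k6", 0.3, 4))

## two-parameter region map --------------------------------------------
rm2 <- region_map_2d(exp(seq(log(2e4), log(2e6), length.out = 60)),
                     exp(seq(log(5e-14), log(5e-12), length.out = 60)),
                     p)
utils::write.csv(as.data.frame(rm2), "results/region_map_k3_k5.csv",
                 row.names = FALSE)
cat(sprintf("Region map 60x60: %d bistable / %d monostable-zero cells\n",
            sum(rm2$region == "bistable"),
            sum(rm2$region == "monostable_zero")))
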