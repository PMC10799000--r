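#!/usr/bin/env Rscript
# Gradient statistics: (i) linear regressions of field-moisture Q10 on the
# aridity index per depth and source, (ii) paired t tests between WHC
# moisture treatments, (iii) Pearson correlations of Q10_SOC / Q10_SIC with
# the climate, physical, chemical and substrate factors (Holm-corrected).

library(dryq10)

tabs <- read_tables("results/cohort")
q10 <- readr::read_csv("results/q10.csv", show_col_types = FALSE)

gradient <- aridity_gradient(q10, tabs$sites)
readr::write_csv(gradient, "results/gradient.csv")
cat("aridity slopes (per 0.1 AI):\n")
print(as.data.frame(gradient[, c("depth", "source", "slope_per_0p1_ai",
                                 "r", "p_value")]), digits = 3)

ttests <- moisture_tests(q10)
readr::write_csv(ttests, "results/ttests.csv")
w26 <- ttests[ttests$level_a == "WHC20" & ttests$level_b == "WHC60", ]
cat(sprintf("\nWHC20 vs WHC60: SOC diffs %s, SIC diffs %s (all p < 0.01: %s)\n",
            paste(sprintf("%+.2f", w26$mean_diff[w26$source == "SOC"]),
                  collapse = "/"),
            paste(sprintf("%+.2f", w26$mean_diff[w26$source == "SIC"]),
                  collapse = "/"),
            all(w26$p_value < 0.01)))

correlations <- dplyr::bind_rows(lapply(unique(tabs$samples$depth),
  function(dp) {
    ct <- q10_correlations(q10, tabs$samples, tabs$sites, dp)
    ct$depth <- dp
    ct
  }))
readr::write_csv(correlations, "results/correlations.csv")
top <- correlations[correlations$depth == "topsoil", ]
cat(sprintf("topsoil: r(Q10_SIC, pH) = %+.2f; r(Q10_SOC, OC-MAOM) = %+.2f\n",
            top$r[top$response == "q10_sic" & top$factor == "ph"],
            top$r[top$response == "q10_soc" & top$factor == "oc_maom"]))
cat("wrote results/{gradient,ttests,correlations}.csv\n")
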