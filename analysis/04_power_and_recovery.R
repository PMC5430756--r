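#!/usr/bin/env Rscript
# Monte-Carlo power of the WW-viability test and end-to-end recovery of
# the true heterogametic system from simulated crossing experiments with
# study-like contamination (failed reversals, deaths, Wolbachia-infected
# mothers).

suppressPackageStartupMessages(library(isopodSD))
dir.create("results", showWarnings = FALSE)

# power to reject the 1/3-male (WW inviable) null when the truth is 1/4
grid <- c(30, 60, 100, 200, 500, 1000)
pw <- vapply(grid, function(n)
  viability_power(n, true_male_prop = 0.25, null_male_prop = 1 / 3,
                  alpha = 0.05, n_sim = 20000, seed = n), numeric(1))
pow <- data.frame(pooled_offspring = grid, power = round(pw, 3))
write.table(pow, "results/viability_power.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(pow, row.names = FALSE)
cat("\nAt 30 pooled offspring the viability question is essentially",
    "undecidable (power", sprintf("%.2f", pw[1]),
    "), matching the unresolved 30-offspring species; ~500 offspring",
    "are needed for reliable resolution.\n\n")

# recovery of the true system through simulate -> filter -> classify
recover <- function(system, ww, n_rep = 150) {
  out <- vapply(seq_len(n_rep), function(r) {
    cfg <- experiment_config(system, ww_viable = ww)
    sim <- simulate_experiment(cfg, seed = r * 13 + (system == "XY"))
    if (nrow(sim$broods) == 0) return(NA_character_)
    kept <- suppressWarnings(filter_broods(sim$broods))$kept
    if (nrow(kept) == 0) return(NA_character_)
    classify_species(kept)$system
  }, character(1))
  c(correct = mean(out == system, na.rm = TRUE),
    undetermined = mean(out == "UNDETERMINED", na.rm = TRUE))
}
rec <- rbind(ZW_viable = recover("ZW", TRUE),
             ZW_inviable = recover("ZW", FALSE),
             XY = recover("XY", TRUE))
write.table(data.frame(scenario = rownames(rec), round(rec, 3)),
            "results/system_recovery.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(round(rec, 3))
cat("\nMost failures are honest refusals (UNDETERMINED), driven by",
    "genetic-male-sired broods that slip past the balanced-ratio filter",
    "at rate alpha and then trigger the heterogeneity gate; see the",
    "methods vignette for why this caps recovery near 90% at study-like",
    "contamination.\n")
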