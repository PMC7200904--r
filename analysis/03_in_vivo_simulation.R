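#!/usr/bin/env Rscript
# Step 3 — synthetic in vivo trials and parameter recovery.
#
# The in vivo population values (ingredient DE/ME, ATTD/STTD of P, AID/SID
# of amino acids) cannot be recomputed without animal data, so the package
# treats them as simulation truths: the default scenario mirrors the three
# trial designs (9 pigs/diet, 30% inclusion, TiO2 marker, N-free diet) and
# this script shows that the estimator chain inverts the generator — exactly
# at zero noise, and without material bias at realistic assay noise.

library(swinedigest)

seed <- 20260927L %% 10000L
dir.create("results", showWarnings = FALSE)

## exact inversion at zero assay noise -------------------------------------
sc0 <- default_scenario(seed, noise = list(marker_cv = 0, ge_cv = 0,
                                           conc_cv = 0))
est0 <- ingredient_energy_from_trial(simulate_energy_trial(sc0),
                                     sc0$energy_diets)
message("Noise-free difference-method recovery (truth in brackets):")
for (i in seq_len(nrow(est0$ingredients))) {
  r <- est0$ingredients[i, ]
  message(sprintf("  %-4s DE %7.1f [%d]   ME %7.1f [%d] kcal/kg DM",
                  r$ingredient, r$de, sc0$true_values[[r$ingredient]]$de,
                  r$me, sc0$true_values[[r$ingredient]]$me))
}

## one trial at assay noise (marker 5%, GE 2%, concentrations 5%) ----------
sc <- default_scenario(seed)
energy <- ingredient_energy_from_trial(simulate_energy_trial(sc),
                                       sc$energy_diets)
write.csv(energy$ingredients, "results/simulated_ingredient_energy.csv",
          row.names = FALSE)

p_tab <- p_digestibility_from_trial(simulate_p_trial(sc))
write.csv(p_tab, "results/simulated_p_digestibility.csv", row.names = FALSE)

aa_tab <- aa_digestibility_from_trial(simulate_ileal_trial(sc))
write.csv(aa_tab, "results/simulated_aa_digestibility.csv",
          row.names = FALSE)

message("\nOne noisy trial (n = 9 pigs/diet):")
message("  ingredient energy, kcal/kg DM with 95% margins:")
print(as.data.frame(energy$ingredients), digits = 4, row.names = FALSE)
message("  phosphorus digestibility, %:")
print(as.data.frame(p_tab), digits = 4, row.names = FALSE)
message("  fish-waste lysine: AID ",
        round(aa_tab$aid[aa_tab$diet == "FW" & aa_tab$nutrient == "Lys"], 1),
        "%, SID ",
        round(aa_tab$sid[aa_tab$diet == "FW" & aa_tab$nutrient == "Lys"], 1),
        "% (truths 89.7 / 94.7)")
message("  standardized exceeds apparent everywhere: ",
        all(aa_tab$sid >= aa_tab$aid) && all(p_tab$sttd >= p_tab$attd))
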