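#!/usr/bin/env Rscript
# Step 5 — three-step in vitro digestibility assembly (synthetic bench
# sheet).
#
# No bench measurements ship with the package, so this script runs the in
# vitro calculus on a synthetic flask sheet whose inputs are chosen to be
# typical of 2-g pepsin/pancreatin hydrolyses followed by 200-mg fecal-
# inoculum fermentations: DM disappearance per step, the combined
# total-tract DM digestibility, VFA energy release, and the in vitro
# total-tract DE.

library(swinedigest)

comps <- food_waste_composition()
dir.create("results", showWarnings = FALSE)

# flask-level synthetic inputs (g DM in/out; VFA mmol/L in 30 mL over 200 mg)
bench <- list(
  FW  = list(res = 0.300, ivf = 50, ge_res = 5200,
             vfa = c(acetate = 4, propionate = 1.2, butyrate = 0.4,
                     valerate = 0.05)),
  SMW = list(res = 0.360, ivf = 55, ge_res = 6100,
             vfa = c(acetate = 6, propionate = 2, butyrate = 0.8,
                     valerate = 0.1)),
  FVW = list(res = 1.060, ivf = 35, ge_res = 4050,
             vfa = c(acetate = 6, propionate = 2, butyrate = 0.9,
                     valerate = 0.1)),
  Corn = list(res = 0.500, ivf = 60, ge_res = 4300,
              vfa = c(acetate = 8, propionate = 3, butyrate = 1,
                      valerate = 0.1))
)

tab <- do.call(rbind, lapply(names(bench), function(nm) {
  b <- bench[[nm]]
  moles <- vfa_moles_per_kg(b$vfa, supernatant_l = 0.030, sample_g_dm = 0.200)
  invitro_result(nm, mass_pre_hydrolysis = 2.000,
                 residue_mass_hydrolysis = b$res, ivfdmd = b$ivf,
                 ge_sample = convert_basis(comps[[nm]], "dm")$ge,
                 ge_residue = b$ge_res, vfa_moles = moles)
}))
out <- as.data.frame(tab[, setdiff(names(tab), "gas_curve")])
write.csv(out, "results/invitro_demo.csv", row.names = FALSE)

message("In vitro assembly on a synthetic bench sheet:")
print(out, digits = 4, row.names = FALSE)
message("\nThe hydrolysis step dominates for the protein/fat-rich sources; ",
        "the fibrous FVW leaves most of its mass to fermentation, whose ",
        "VFA credit recovers only part of the residue energy.")
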