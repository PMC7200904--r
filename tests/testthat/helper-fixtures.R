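# shared fixtures: compositions, a noise-free scenario, printed reference
# tables used across test files

table1 <- food_waste_composition()

noise_free <- list(marker_cv = 0, ge_cv = 0, conc_cv = 0)

quiet_scenario <- function(seed = 42L) default_scenario(seed, noise_free)

# published predictions (kcal/kg DM) the equation registry must reproduce;
# fish-waste rows of the chemical-composition family need the NDF=0 override
printed_de <- data.frame(
  equation = as.character(c(1, 2, 3, 8, 9, 10, 11)),
  FW  = c(5234, 4517, 4605, 5566, 4017, 3991, 4104),
  SMW = c(4796, 4831, 4909, 5490, 3502, 5053, 3961),
  FVW = c(2731, 2736, 2786, 2727, -66, 4931, 1019)
)
printed_me <- data.frame(
  equation = as.character(c(4, 12, 13, 14, 15)),
  FW  = c(4090, 5001, 3700, 3624, 3725),
  SMW = c(4759, 4932, 3557, 4644, 3836),
  FVW = c(2749, 2410, 52, 4526, 1395)
)

# published in vivo means and t-interval bounds (kcal/kg DM)
printed_bounds_de <- data.frame(
  ingredient = c("FW", "SMW", "FVW"),
  mean = c(5057, 5071, 2570),
  margin = c(259, 131, 251)
)
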