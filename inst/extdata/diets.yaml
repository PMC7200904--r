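# Diet formulations and analyzed composition for the three digestibility
# trials (all values as-fed basis; inclusion rates in % of diet).
# marker_ti_pct is the analyzed titanium concentration where reported;
# for the ileal trial diets (no analyzed value) it is the nominal Ti from
# 0.40% TiO2 inclusion (0.40 x 47.867/79.866 = 0.24).
energy_balance:
  FW:
    test_ingredient: FW
    ingredients: {Corn: 66.90, FW: 30.00, dicalcium_phosphate: 1.15,
                  limestone: 0.85, salt: 0.40, vtm_premix: 0.30,
                  titanium_dioxide: 0.40}
    marker_ti_pct: 0.25
    analyzed: {dm_pct: 87.73, ge_kcal_kg: 4172, cp_pct: 15.97, ee_pct: 12.65}
  SMW:
    test_ingredient: SMW
    ingredients: {Corn: 66.90, SMW: 30.00, dicalcium_phosphate: 1.15,
                  limestone: 0.85, salt: 0.40, vtm_premix: 0.30,
                  titanium_dioxide: 0.40}
    marker_ti_pct: 0.22
    analyzed: {dm_pct: 86.76, ge_kcal_kg: 4108, cp_pct: 10.12, ee_pct: 11.10}
  FVW:
    test_ingredient: FVW
    ingredients: {Corn: 66.90, FVW: 30.00, dicalcium_phosphate: 1.15,
                  limestone: 0.85, salt: 0.40, vtm_premix: 0.30,
                  titanium_dioxide: 0.40}
    marker_ti_pct: 0.23
    analyzed: {dm_pct: 87.67, ge_kcal_kg: 3786, cp_pct: 7.11, ee_pct: 12.13}
  Control:
    test_ingredient: ~
    ingredients: {Corn: 96.90, dicalcium_phosphate: 1.15, limestone: 0.85,
                  salt: 0.40, vtm_premix: 0.30, titanium_dioxide: 0.40}
    marker_ti_pct: 0.21
    analyzed: {dm_pct: 86.53, ge_kcal_kg: 3821, cp_pct: 5.27, ee_pct: 2.54}
phosphorus:
  FW:
    test_ingredient: FW
    ingredients: {corn_starch: 49.90, FW: 30.00, sucrose: 15.00,
                  soybean_oil: 3.00, limestone: 1.00, salt: 0.40,
                  vtm_premix: 0.30, titanium_dioxide: 0.40}
    marker_ti_pct: 0.22
    analyzed: {dm_pct: 92.78, ca_pct: 1.55, p_pct: 0.57, ash_pct: 5.12,
               ndf_pct: 0.74, adf_pct: 0.68, ge_kcal_kg: 4366}
  SMW:
    test_ingredient: SMW
    ingredients: {corn_starch: 49.90, SMW: 30.00, sucrose: 15.00,
                  soybean_oil: 3.00, limestone: 1.00, salt: 0.40,
                  vtm_premix: 0.30, titanium_dioxide: 0.40}
    marker_ti_pct: 0.23
    analyzed: {dm_pct: 91.58, ca_pct: 0.63, p_pct: 0.13, ash_pct: 2.87,
               ndf_pct: 0.79, adf_pct: 0.55, ge_kcal_kg: 4051}
  FVW:
    test_ingredient: FVW
    ingredients: {corn_starch: 49.90, FVW: 30.00, sucrose: 15.00,
                  soybean_oil: 3.00, limestone: 1.00, salt: 0.40,
                  vtm_premix: 0.30, titanium_dioxide: 0.40}
    marker_ti_pct: 0.20
    analyzed: {dm_pct: 92.66, ca_pct: 0.65, p_pct: 0.08, ash_pct: 3.09,
               ndf_pct: 7.16, adf_pct: 5.47, ge_kcal_kg: 4001}
amino_acids:
  FW:
    test_ingredient: FW
    ingredients: {corn_starch: 43.95, FW: 30.00, sucrose: 20.00,
                  soybean_oil: 3.00, dicalcium_phosphate: 1.10,
                  limestone: 0.85, titanium_dioxide: 0.40, salt: 0.40,
                  vtm_premix: 0.30}
    marker_ti_pct: 0.24
    analyzed: {dm_pct: 92.67, cp_pct: 13.19, ndf_pct: 1.30, adf_pct: 0.19,
               ge_kcal_kg: 3990}
    aa_pct: {Arg: 0.80, His: 0.31, Ile: 0.51, Leu: 0.84, Lys: 0.93,
             Met: 0.33, Phe: 0.48, Thr: 0.52, Trp: 0.12, Val: 0.57,
             Ala: 0.92, Asp: 1.12, Cys: 0.09, Glu: 1.62, Gly: 1.35,
             Pro: 0.83, Ser: 0.47, Tyr: 0.34}
  SMW:
    test_ingredient: SMW
    ingredients: {corn_starch: 43.95, SMW: 30.00, sucrose: 20.00,
                  soybean_oil: 3.00, dicalcium_phosphate: 1.10,
                  limestone: 0.85, titanium_dioxide: 0.40, salt: 0.40,
                  vtm_premix: 0.30}
    marker_ti_pct: 0.24
    analyzed: {dm_pct: 92.38, cp_pct: 6.12, ndf_pct: 0.79, adf_pct: 0.49,
               ge_kcal_kg: 3991}
    aa_pct: {Arg: 0.30, His: 0.17, Ile: 0.27, Leu: 0.44, Lys: 0.40,
             Met: 0.11, Phe: 0.23, Thr: 0.22, Trp: 0.07, Val: 0.29,
             Ala: 0.33, Asp: 0.50, Cys: 0.06, Glu: 0.99, Gly: 0.33,
             Pro: 0.34, Ser: 0.21, Tyr: 0.16}
  FVW:
    test_ingredient: FVW
    ingredients: {corn_starch: 43.95, FVW: 30.00, sucrose: 20.00,
                  soybean_oil: 3.00, dicalcium_phosphate: 1.10,
                  limestone: 0.85, titanium_dioxide: 0.40, salt: 0.40,
                  vtm_premix: 0.30}
    marker_ti_pct: 0.24
    analyzed: {dm_pct: 93.16, cp_pct: 2.84, ndf_pct: 9.03, adf_pct: 5.78,
               ge_kcal_kg: 3569}
    aa_pct: {Arg: 0.09, His: 0.04, Ile: 0.08, Leu: 0.15, Lys: 0.10,
             Met: 0.03, Phe: 0.09, Thr: 0.07, Trp: 0.03, Val: 0.10,
             Ala: 0.12, Asp: 0.24, Cys: 0.03, Glu: 0.33, Gly: 0.10,
             Pro: 0.14, Ser: 0.08, Tyr: 0.04}
  Nfree:
    test_ingredient: ~
    ingredients: {corn_starch: 67.80, sucrose: 20.00, soybean_oil: 4.00,
                  dicalcium_phosphate: 2.15, limestone: 0.45,
                  titanium_dioxide: 0.40, salt: 0.40, vtm_premix: 0.30,
                  potassium_carbonate: 0.40, magnesium_oxide: 0.10,
                  solka_floc: 4.00}
    marker_ti_pct: 0.24
    analyzed: {dm_pct: 93.17, cp_pct: 0.38, ndf_pct: 1.61, adf_pct: 1.35,
               ge_kcal_kg: 3375}
    aa_pct: {Arg: 0.01, His: 0.00, Ile: 0.01, Leu: 0.04, Lys: 0.02,
             Met: 0.01, Phe: 0.02, Thr: 0.01, Trp: 0.02, Val: 0.01,
             Ala: 0.02, Asp: 0.02, Cys: 0.01, Glu: 0.05, Gly: 0.02,
             Pro: 0.03, Ser: 0.01, Tyr: 0.01}
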