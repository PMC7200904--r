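test_that("generation is bitwise-reproducible under a fixed seed", {
  sc <- default_scenario(seed = 123)
  expect_identical(simulate_energy_trial(sc), simulate_energy_trial(sc))
  expect_identical(simulate_ileal_trial(sc), simulate_ileal_trial(sc))
  sc2 <- default_scenario(seed = 124)
  expect_false(identical(simulate_energy_trial(sc),
                         simulate_energy_trial(sc2)))
})

test_that("scenario validation rejects inconsistent truths", {
  tv <- list(Corn = list(de = 3000, me = 3100, dmd = 0.8))
  expect_error(trial_scenario(true_values = tv), "ME exceeds DE")
  expect_error(trial_scenario(true_values = list(A = list(dmd = 1.5))),
               "DMD")
  expect_error(trial_scenario(true_values = list(),
                              noise = list(marker_cv = -0.1, ge_cv = 0,
                                           conc_cv = 0)), "marker_cv")
  expect_error(trial_scenario(true_values = list(),
                              endogenous_aa = c(Lys = -1)), ">= 0")
})

test_that("noise-free energy records return every scenario truth exactly", {
  sc <- quiet_scenario()
  truth <- scenario_diet_truth(sc)
  recs <- simulate_energy_trial(sc)
  diet_ge <- setNames(truth$ge, truth$diet)

  # corn basal diet: DE:GE 0.86 comes back out at CV 0
  corn_truth <- truth[truth$diet == "Control", ]
  expect_equal(corn_truth$de / corn_truth$ge, 0.862, tolerance = 1e-3)
  for (m in c("marker", "total")) {
    pv <- pig_energy_values(recs, diet_ge, method = m)
    for (d in truth$diet) {
      expect_equal(range(pv$de[pv$diet == d]),
                   rep(truth$de[truth$diet == d], 2), tolerance = 1e-9)
      expect_equal(range(pv$me[pv$diet == d]),
                   rep(truth$me[truth$diet == d], 2), tolerance = 1e-9)
    }
  }

  # difference method recovers the ingredient truths to better than 1 kcal
  est <- ingredient_energy_from_trial(recs, sc$energy_diets)
  for (ing in est$ingredients$ingredient) {
    expect_equal(est$ingredients$de[est$ingredients$ingredient == ing],
                 sc$true_values[[ing]]$de, tolerance = 1e-9)
    expect_equal(est$ingredients$me[est$ingredients$ingredient == ing],
                 sc$true_values[[ing]]$me, tolerance = 1e-9)
  }
})

test_that("marker mass balance holds in noise-free records", {
  recs <- simulate_energy_trial(quiet_scenario())
  for (r in recs) {
    intake <- r$feed_intake * r$diet_dm_frac * r$ti_diet
    output <- r$fecal_output * r$ti_feces
    expect_equal(intake, output, tolerance = 1e-12)
  }
})

test_that("noise-free P and ileal trials invert exactly", {
  sc <- quiet_scenario()
  p <- p_digestibility_from_trial(simulate_p_trial(sc))
  for (d in p$diet) {
    expect_equal(p$attd[p$diet == d], sc$true_values[[d]]$attd_p,
                 tolerance = 1e-9)
    expect_gte(p$sttd[p$diet == d], p$attd[p$diet == d])
  }

  recs <- simulate_ileal_trial(sc)
  # N-free records carry the endogenous flows only
  endo_hat <- basal_endogenous_aa(
    recs[vapply(recs, `[[`, character(1), "diet") == "Nfree"])
  expect_equal(endo_hat[names(sc$endogenous_aa)], sc$endogenous_aa,
               tolerance = 1e-9)

  aa <- aa_digestibility_from_trial(recs)
  for (d in c("FW", "SMW", "FVW")) {
    truth <- sc$true_values[[d]]$aid
    sub <- aa[aa$diet == d, ]
    expect_equal(setNames(sub$aid, sub$nutrient)[names(truth)], truth,
                 tolerance = 1e-9)
  }
  # fish waste standardized lysine: the published 94.7 comes back out
  expect_equal(aa$sid[aa$diet == "FW" & aa$nutrient == "Lys"], 94.7,
               tolerance = 1e-6)
})

test_that("true AID of 100% with no endogenous flow empties the digesta", {
  sc <- quiet_scenario()
  sc$true_values$FW$aid <- c(Lys = 100)
  sc$endogenous_aa <- c(Lys = 0)
  sc$ileal_diets <- sc$ileal_diets[c("FW", "Nfree")]
  recs <- simulate_ileal_trial(sc)
  fw <- recs[vapply(recs, `[[`, character(1), "diet") == "FW"]
  expect_true(all(vapply(fw, function(r) r$conc_digesta[["Lys"]],
                         numeric(1)) == 0))
})

test_that("negative-AID truth flows through the pipeline without error", {
  sc <- default_scenario(seed = 5, noise = list(marker_cv = 0.05,
                                                ge_cv = 0.02,
                                                conc_cv = 0.05))
  aa <- aa_digestibility_from_trial(simulate_ileal_trial(sc))
  fvw <- aa[aa$diet == "FVW", ]
  expect_true(any(fvw$aid < 0))
  expect_true(all(fvw$sid >= fvw$aid))
})
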