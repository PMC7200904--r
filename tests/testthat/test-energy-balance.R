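test_that("marker-ratio digestibility follows the marker dilution", {
  # fully digested, no digestion, and a hand-computed intermediate case
  expect_equal(marker_digestibility(4, 0, 0.21, 0.42), 1.0)
  expect_equal(marker_digestibility(4, 4, 0.21, 0.21), 0.0)
  expect_equal(marker_digestibility(4, 2, 0.21, 0.42), 0.75)
  # may go negative when the output is enriched beyond the marker ratio
  expect_lt(marker_digestibility(1, 3, 0.2, 0.4), 0)
  expect_error(marker_digestibility(0, 1, 0.2, 0.4), "undefined")
  expect_error(marker_digestibility(4, 2, 0.2, 0), "undefined")
})

test_that("diet energy recovers DE/ME from a consistent record", {
  # perfect digestion: no fecal or urinary energy, DE = ME = GE
  rec <- collection_record("p1", "d", feed_intake = 1, diet_dm_frac = 0.9,
                           fecal_output = 0.1, fecal_ge = 0,
                           urine_volume = 0, urine_ge = 0,
                           ti_diet = 0.3, ti_feces = 2.7)
  ev <- diet_energy(rec, diet_ge = 4000, method = "total")
  expect_equal(ev$de, 4000)
  expect_equal(ev$me, 4000)

  # record built from true DE:GE 0.80, ME:DE 0.96 by exact mass balance
  ge <- 4400; de <- 0.80 * ge; me <- 0.96 * de
  dmi <- 1.2; fecal_dm <- dmi * 0.2
  rec2 <- collection_record("p2", "d", feed_intake = dmi / 0.88,
                            diet_dm_frac = 0.88, fecal_output = fecal_dm,
                            fecal_ge = dmi * (ge - de) / fecal_dm,
                            urine_volume = 2,
                            urine_ge = dmi * (de - me) / 2,
                            ti_diet = 0.25,
                            ti_feces = 0.25 * dmi / fecal_dm)
  for (m in c("total", "marker")) {
    ev2 <- diet_energy(rec2, ge, method = m)
    expect_equal(ev2$de_ge, 0.80, tolerance = 1e-9)
    expect_equal(ev2$me_de, 0.96, tolerance = 1e-9)
  }

  expect_error(diet_energy(collection_record("p", "d", 0, 0.9, 0.1, 100),
                           4000), "zero DM intake")
})

test_that("corn control record reproduces the observed energy ratios", {
  # build the basal-diet record from the published corn ratios
  # (DE:GE 0.86, ME:DE 0.98) and check they come back out
  ge <- 3821 / 0.8653
  de <- 0.86 * ge; me <- 0.98 * de
  dmi <- 1; fecal_dm <- 0.2
  rec <- collection_record("c1", "Control", feed_intake = dmi / 0.8653,
                           diet_dm_frac = 0.8653, fecal_output = fecal_dm,
                           fecal_ge = (ge - de) / fecal_dm,
                           urine_volume = 2, urine_ge = (de - me) / 2,
                           ti_diet = 0.243, ti_feces = 0.243 / fecal_dm)
  ev <- diet_energy(rec, ge)
  expect_equal(ev$me_de, 0.98, tolerance = 1e-9)
  expect_equal(ev$de_ge, 0.86, tolerance = 1e-9)
})

test_that("difference method isolates the test ingredient's energy", {
  basal <- energy_values(de = 4000, me = 3900)
  # test diet identical to the basal diet: ingredient DE = (1 - w)/f * DE
  same <- ingredient_energy_by_difference(basal, basal)
  expect_equal(same$de, (1 - 0.669 / 0.969) / 0.3 * 4000, tolerance = 1e-12)
  expect_equal(same$de, 1.0319 * 4000, tolerance = 1e-4)

  # a test diet carrying exactly the scaled basal energy: zero-energy filler
  zero <- ingredient_energy_by_difference(
    list(de = 4000 * 0.669 / 0.969, me = 3900 * 0.669 / 0.969), basal)
  expect_equal(zero$de, 0, tolerance = 1e-9)
  expect_equal(zero$me, 0, tolerance = 1e-9)

  expect_error(ingredient_energy_by_difference(basal, basal, test_frac = 0),
               "test_frac")
})

test_that("energy value invariants are enforced", {
  expect_error(energy_values(de = 4000, me = 4100), "ME")
  expect_error(energy_values(de = 4600, me = 4000, ge = 4500), "GE")
  ev <- energy_values(de = 4000, me = 3800, ge = 5000)
  expect_equal(ev$me_de, 3800 / 4000, tolerance = 1e-12)
  expect_lte(ev$de_ge, 1)
})

test_that("feed allowance is three times maintenance on metabolic weight", {
  expect_equal(feed_allowance(1), 591)
  expect_equal(feed_allowance(16.37), 3162.4, tolerance = 1e-4)
  # power law: doubling BW multiplies the allowance by 2^0.6
  expect_equal(feed_allowance(20) / feed_allowance(10), 2^0.6)
  expect_error(feed_allowance(0), "body weight")
})

test_that("implausible marker gradient warns but does not error", {
  expect_warning(
    collection_record("p", "d", 1, 0.9, 0.2, 500, ti_diet = 0.4,
                      ti_feces = 0.2),
    "marker"
  )
})
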