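test_that("basis conversion scales by the DM fraction and round-trips", {
  fw <- table1$FW
  dm <- convert_basis(fw, "dm")
  expect_equal(dm$cp, 62.49, tolerance = 1e-4)       # 57.59 / 0.9216
  expect_equal(dm$ge, 5876 / 0.9216)                 # 6375.9 kcal/kg DM
  expect_equal(dm$aa[["Lys"]], 3.79 / 0.9216)

  # identity when the target equals the current basis; idempotence
  expect_identical(convert_basis(fw, "as_fed"), fw)
  expect_identical(convert_basis(dm, "dm"), dm)

  # round trip within 1e-9 relative on every field
  back <- convert_basis(dm, "as_fed")
  for (f in c("ge", "cp", "ee", "ash", "ndf", "adf", "ca", "p")) {
    expect_equal(back[[f]], fw[[f]], tolerance = 1e-9)
  }
  expect_equal(back$aa, fw$aa, tolerance = 1e-9)
})

test_that("composition validation rejects impossible inputs", {
  expect_error(feed_comp("x", dm_frac = 0, ge = 100), "dm_frac")
  expect_error(feed_comp("x", dm_frac = 1.2, ge = 100), "dm_frac")
  expect_error(feed_comp("x", dm_frac = 0.9, cp = -1), "negative")
  expect_error(feed_comp("x", dm_frac = 0.9, cp = 101), "100")
  # NDF may overlap other fractions: cp+ee+ash+ndf > 100 is legal on DM basis
  expect_s3_class(feed_comp("x", basis = "dm", dm_frac = 1, cp = 60, ee = 20,
                            ash = 15, ndf = 30), "feed_comp")
})

test_that("amino acid codes are normalized case-insensitively", {
  cc <- feed_comp("x", dm_frac = 0.9, aa = c(LYS = 1, met = 0.5, Thr = 0.2))
  expect_named(cc$aa, c("Lys", "Met", "Thr"))
})

test_that("calculated GE matches the proximate-composition equation", {
  # intercept only
  blank <- feed_comp("blank", basis = "dm", dm_frac = 1, cp = 0, ee = 0,
                     ash = 0)
  expect_equal(calculated_ge(blank), 4143)

  # converted analyzed values for the food waste sources
  expect_equal(calculated_ge(table1$FW), 5418, tolerance = 5e-4)
  expect_equal(calculated_ge(table1$SMW), 6363, tolerance = 5e-4)

  # monotone: increasing in EE and CP, decreasing in ash
  base <- feed_comp("b", basis = "dm", dm_frac = 1, cp = 20, ee = 10,
                    ash = 5)
  up_ee <- feed_comp("b", basis = "dm", dm_frac = 1, cp = 20, ee = 11,
                     ash = 5)
  up_ash <- feed_comp("b", basis = "dm", dm_frac = 1, cp = 20, ee = 10,
                      ash = 6)
  expect_gt(calculated_ge(up_ee), calculated_ge(base))
  expect_lt(calculated_ge(up_ash), calculated_ge(base))

  # a field never analyzed fails loudly, it is not silently zero
  expect_error(calculated_ge(feed_comp("x", dm_frac = 0.9, cp = 10)),
               "requires analyzed")
})

test_that("composition CSV round-trips including absent fields and AA", {
  path <- withr::local_tempfile(fileext = ".csv")
  comps <- list(a = feed_comp("a", dm_frac = 0.9, ge = 4000, cp = 10,
                              ee = 5, ash = 3, ndf = NA, adf = 2,
                              aa = c(Lys = 0.5)),
                b = table1$SMW)
  write_composition_csv(comps, path)
  back <- read_composition_csv(path)
  expect_true(is.na(back$a$ndf))
  expect_equal(back$a$aa[["Lys"]], 0.5)
  expect_equal(back$SMW$ge, 5235)
  # writer orders AA columns alphabetically; values round-trip exactly
  expect_equal(back$SMW$aa[names(table1$SMW$aa)], table1$SMW$aa)
})

test_that("packaged fixture carries the four analyzed ingredients as-fed", {
  expect_named(table1, c("FW", "SMW", "FVW", "Corn"))
  expect_true(all(vapply(table1, `[[`, character(1), "basis") == "as_fed"))
  expect_equal(table1$FVW$ndf, 28.20)
  expect_equal(table1$Corn$dm_frac, 0.8594)
  expect_length(table1$FW$aa, 18)
})

test_that("diet specs validate inclusion sums and read from YAML", {
  diets <- trial_diets()
  expect_named(diets, c("energy_balance", "phosphorus", "amino_acids"))
  expect_equal(sum(diets$energy_balance$FW$ingredients), 1, tolerance = 1e-12)
  expect_equal(diets$phosphorus$FW$analyzed$p_pct, 0.57)
  expect_null(diets$amino_acids$Nfree$test_ingredient)
  expect_error(diet_spec("bad", c(corn = 0.5, other = 0.4)), "sum")
  expect_error(diet_spec("bad", c(corn = 1), marker_ti_pct = 0), "marker")
})
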