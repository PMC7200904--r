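test_that("single-equation predictions reproduce spot-checked values", {
  # ash-only regression on fish waste
  expect_equal(round(predict_energy(10, table1$FW)$predicted), 3991)
  # GE-only ME regression degenerates to its intercept at GE = 0
  degen <- feed_comp("degen", basis = "dm", dm_frac = 1, ge = 0)
  out <- predict_energy(12, degen)
  expect_equal(out$predicted, -2331)
  expect_match(out$notes, "negative")
  # low-CP/EE feed can go negative under the proximate regression
  expect_equal(round(predict_energy(9, table1$FVW)$predicted), -66)
})

test_that("family unit conventions are applied (g/kg vs % DM)", {
  cc <- feed_comp("u", basis = "dm", dm_frac = 1, ge = 5000, cp = 10,
                  ee = 5, ash = 2, ndf = 8)
  # chemical family takes g/kg DM
  expect_equal(predict_energy(3, cc)$predicted,
               4168 - 9.1 * 20 + 1.9 * 100 + 3.9 * 50 - 3.6 * 80)
  # regression family takes % DM
  expect_equal(predict_energy(9, cc)$predicted,
               56.1 * 10 + 73.4 * 5 - 12.5 * 2 - 669)
  # in vitro family computes MJ/kg DM then converts
  expect_equal(predict_energy(16, cc, omdv = 800)$predicted,
               mj_to_kcal(0.0189 * 800))
})

test_that("MJ to kcal conversion is the fixed factor", {
  expect_equal(mj_to_kcal(0), 0)
  expect_equal(mj_to_kcal(1), 238.834)
  expect_equal(mj_to_kcal(20.9), 4991.6, tolerance = 1e-4)
})

test_that("every equation is affine: coefficients recoverable numerically", {
  eqs <- energy_equations()
  fields <- c(ge_analyzed = "ge", cp = "cp", ee = "ee", ash = "ash",
              ndf = "ndf", adf = "adf", cf = "cf")
  base_vals <- list(ge = 1000, cp = 10, ee = 10, ash = 5, ndf = 10,
                    adf = 5, cf = 5)
  mk <- function(vals) do.call(feed_comp, c(list("probe", basis = "dm",
                                                 dm_frac = 1), vals))
  for (id in setdiff(names(eqs), c("2", "5", "6", "7"))) {
    eq <- eqs[[id]]
    scale <- if (eq$family == "KERR") 1 else 10
    f0 <- predict_energy(id, mk(base_vals), omdv = 500)$predicted
    for (term in setdiff(names(eq$terms), "intercept")) {
      if (term == "omdv") {
        f1 <- predict_energy(id, mk(base_vals), omdv = 501)$predicted
        slope <- f1 - f0
        expected <- eq$terms[[term]]
      } else {
        vals <- base_vals
        vals[[fields[[term]]]] <- vals[[fields[[term]]]] + 1
        f1 <- predict_energy(id, mk(vals), omdv = 500)$predicted
        slope <- f1 - f0
        # GE enters in kcal/kg DM in every family; proximate inputs are
        # scaled % -> g/kg except in the regression family
        expected <- eq$terms[[term]] *
          (if (term == "ge_analyzed") 1 else scale)
      }
      if (eq$family == "NJP") expected <- mj_to_kcal(expected)
      expect_equal(slope, expected, tolerance = 1e-8,
                   label = paste("eq", id, "term", term))
    }
  }
})

test_that("ME equations 5-7 equal their DE parent minus 0.68 CP by construction", {
  for (comp in table1) {
    cp_gkg <- convert_basis(comp, "dm")$cp * 10
    for (pair in list(c("5", "1"), c("6", "2"), c("7", "3"))) {
      expect_equal(predict_energy(pair[1], comp)$predicted,
                   predict_energy(pair[2], comp)$predicted - 0.68 * cp_gkg,
                   tolerance = 1e-12)
    }
  }
})

test_that("missing inputs fail loudly naming the field", {
  no_ndf <- feed_comp("x", basis = "dm", dm_frac = 1, ge = 4000, cp = 10,
                      ee = 5, ash = 2)
  expect_error(predict_energy(1, no_ndf), "missing input 'ndf'")
  expect_error(predict_energy(16, table1$FW), "omdv")
  expect_error(predict_energy(18, table1$FW, omdv = 500),
               "missing input 'cf'")  # crude fiber never analyzed
  expect_error(predict_energy(99, table1$FW), "unknown equation")
})

test_that("NDF=0 override reproduces the animal-product rows and is flagged", {
  out <- predict_energy(1, table1$FW, ndf_zero = TRUE)
  expect_equal(round(out$predicted), 5234)
  expect_match(out$notes, "NDF term zeroed")
  # default behavior uses analyzed NDF and lands materially lower
  expect_equal(round(predict_energy(1, table1$FW)$predicted), 5065)
})

test_that("batch prediction keeps failed pairs visible", {
  no_ndf <- feed_comp("x", basis = "dm", dm_frac = 1, ge = 4000, cp = 10,
                      ee = 5, ash = 2)
  res <- predict_all(list(table1$SMW, no_ndf), eq_ids = c("1", "10"))
  expect_equal(nrow(res), 4)
  bad <- res[res$ingredient == "x" & res$equation == "1", ]
  expect_true(is.na(bad$predicted))
  expect_match(bad$notes, "ndf")
  expect_false(any(is.na(res$predicted[res$equation == "10"])))
  expect_error(predict_all(list(), eq_ids = "1"), "no compositions")
  expect_error(predict_all(list(table1$FW), eq_ids = "77"), "unknown")
})
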