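#' Synthetic digestibility-trial scenario
#'
#' A fully specified simulation truth for the three trial designs: diet
#' definitions (per kg DM), per-ingredient true energy values and
#' digestibility coefficients, cohort size and body weights, assay noise
#' levels, and a seed. Every estimator in the package applied to noise-free
#' data generated from a scenario returns the scenario truth exactly, which
#' is what makes the in vivo calculus testable without animal data.
#'
#' Diet-level energy truths are derived from ingredient truths by the same
#' contribution algebra the difference method inverts: the basal diet carries
#' `basal_frac_in_basal` of the reference ingredient (corn), a test diet
#' carries `test_frac` of its test ingredient plus `basal_frac_in_test` of
#' corn, and shared minor ingredients are energy-neutral.
#'
#' @param energy_diets,p_diets,ileal_diets Lists of per-diet definitions (see
#'   [default_scenario] for the shape used by the packaged defaults).
#' @param true_values Named list per ingredient with elements among `de`,
#'   `me` (kcal/kg DM), `dmd` (fraction), `attd_p` (%), `aid` (named vector,
#'   %).
#' @param endogenous_aa Named vector of basal endogenous AA flows, g/kg DMI.
#' @param n_pigs_per_diet Replicates per diet.
#' @param bw_mean,bw_sd Initial body weight distribution, kg.
#' @param noise List with `marker_cv`, `ge_cv`, `conc_cv` (assay coefficients
#'   of variation, fractions).
#' @param seed Integer seed; a fixed seed makes the generated records
#'   bitwise-reproducible.
#' @return An object of class `trial_scenario`.
#' @export
trial_scenario <- function(energy_diets = list(), p_diets = list(),
                           ileal_diets = list(), true_values,
                           endogenous_aa = numeric(),
                           n_pigs_per_diet = 9, bw_mean = 16.37, bw_sd = 1.9,
                           noise = list(marker_cv = 0.05, ge_cv = 0.02,
                                        conc_cv = 0.05),
                           seed = 1L) {
  stopifnot(n_pigs_per_diet >= 1, bw_mean > 0, bw_sd >= 0)
  for (nm in c("marker_cv", "ge_cv", "conc_cv")) {
    if (is.null(noise[[nm]]) || noise[[nm]] < 0) {
      stop("noise$", nm, " must be a nonnegative fraction", call. = FALSE)
    }
  }
  for (ing in names(true_values)) {
    tv <- true_values[[ing]]
    if (!is.null(tv$de) && !is.null(tv$me) && tv$me > tv$de) {
      stop("scenario truth for ", ing, ": ME exceeds DE", call. = FALSE)
    }
    if (!is.null(tv$dmd) && (tv$dmd <= 0 || tv$dmd > 1)) {
      stop("scenario truth for ", ing, ": DMD must be in (0, 1]",
           call. = FALSE)
    }
    if (!is.null(tv$attd_p) && (tv$attd_p < -100 || tv$attd_p > 110)) {
      stop("scenario truth for ", ing, ": implausible ATTD of P",
           call. = FALSE)
    }
    if (!is.null(tv$aid) && any(tv$aid > 110)) {
      stop("scenario truth for ", ing, ": AID above 110%", call. = FALSE)
    }
  }
  if (any(endogenous_aa < 0)) {
    stop("endogenous flows must be >= 0", call. = FALSE)
  }
  structure(
    list(energy_diets = energy_diets, p_diets = p_diets,
         ileal_diets = ileal_diets, true_values = true_values,
         endogenous_aa = endogenous_aa, n_pigs_per_diet = n_pigs_per_diet,
         bw_mean = bw_mean, bw_sd = bw_sd, noise = noise,
         seed = as.integer(seed)),
    class = "trial_scenario"
  )
}

# unit-mean lognormal multiplicative noise with a given CV
lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Diet-level energy truths implied by a scenario
#'
#' @param sc A [trial_scenario].
#' @return Tibble with one row per energy diet: true `de`, `me` (kcal/kg DM),
#'   `ge`, `dmd`.
#' @export
scenario_diet_truth <- function(sc) {
  basal <- Filter(function(d) is.null(d$test_ingredient), sc$energy_diets)
  if (length(basal) != 1) stop("scenario needs exactly one basal energy diet",
                               call. = FALSE)
  basal <- basal[[1]]
  ref <- sc$true_values[[basal$ref_ingredient]]
  base_de <- basal$basal_frac * ref$de
  base_me <- basal$basal_frac * ref$me
  base_dmd <- basal$basal_frac * ref$dmd
  rows <- lapply(sc$energy_diets, function(d) {
    if (is.null(d$test_ingredient)) {
      de <- base_de; me <- base_me; dmd <- base_dmd
    } else {
      tv <- sc$true_values[[d$test_ingredient]]
      w <- d$basal_frac_in_test / basal$basal_frac
      de <- d$test_frac * tv$de + w * base_de
      me <- d$test_frac * tv$me + w * base_me
      dmd <- d$test_frac * tv$dmd + w * base_dmd
    }
    if (de > d$ge) stop("diet ", d$name, ": true DE exceeds GE",
                        call. = FALSE)
    tibble::tibble(diet = d$name, ge = d$ge, de = de, me = me, dmd = dmd)
  })
  do.call(rbind, rows)
}

# shared record builder for fecal-collection trials (energy or P diets);
# concentrations are generated by exact mass balance from the truths, then
# perturbed multiplicatively
simulate_collection <- function(sc, diets, truth) {
  n <- sc$n_pigs_per_diet
  recs <- list()
  for (d in diets) {
    tr <- truth[truth$diet == d$name, ]
    bw <- pmax(stats::rnorm(n, sc$bw_mean, sc$bw_sd), 5)
    feed <- feed_allowance(bw) / (tr$me * d$dm_frac)  # kg as-fed/day
    dmi <- feed * d$dm_frac
    fecal_dm <- dmi * (1 - tr$dmd)
    fecal_ge <- dmi * (tr$ge - tr$de) / fecal_dm       # kcal/kg fecal DM
    ti_feces <- d$ti_pct * dmi / fecal_dm              # exact marker balance
    urine_vol <- rep(2, n)                             # L/day
    urine_ge <- dmi * (tr$de - tr$me) / urine_vol
    fecal_ge_obs <- fecal_ge * lnoise(n, sc$noise$ge_cv)
    ti_obs <- ti_feces * lnoise(n, sc$noise$marker_cv)
    urine_ge_obs <- urine_ge * lnoise(n, sc$noise$ge_cv)
    p_feces_obs <- rep(NA_real_, n)
    if (!is.null(d$p_g_per_kg_dm)) {
      attd <- sc$true_values[[d$test_ingredient]]$attd_p
      p_feces <- d$p_g_per_kg_dm * (1 - attd / 100) * dmi / fecal_dm
      p_feces_obs <- p_feces * lnoise(n, sc$noise$conc_cv)
    }
    for (i in seq_len(n)) {
      recs[[length(recs) + 1L]] <- collection_record(
        pig_id = paste0(d$name, "_", i), diet = d$name,
        feed_intake = feed[i], diet_dm_frac = d$dm_frac,
        fecal_output = fecal_dm[i], fecal_ge = fecal_ge_obs[i],
        urine_volume = urine_vol[i], urine_ge = urine_ge_obs[i],
        ti_diet = d$ti_pct, ti_feces = ti_obs[i],
        p_diet = d$p_g_per_kg_dm %||% NA_real_, p_feces = p_feces_obs[i]
      )
    }
  }
  recs
}

#' Simulate an energy-balance trial
#'
#' Generates one [collection_record] per pig and diet: body weights are drawn
#' from the scenario distribution, feed intake follows the three-times-
#' maintenance allowance ([feed_allowance]), and fecal/urine energies and
#' marker concentrations are constructed by exact mass balance from the true
#' diet-level DE/ME ([scenario_diet_truth]) before multiplicative lognormal
#' observation noise is applied. At zero noise every estimator recovers the
#' truth exactly and marker intake equals marker output in every record.
#'
#' @param sc A [trial_scenario].
#' @return List of [collection_record].
#' @export
simulate_energy_trial <- function(sc) {
  stopifnot(inherits(sc, "trial_scenario"))
  truth <- scenario_diet_truth(sc)
  withr::with_seed(sc$seed, simulate_collection(sc, sc$energy_diets, truth))
}

#' Simulate a phosphorus-digestibility trial
#'
#' Same collection machinery as [simulate_energy_trial] over the phosphorus
#' diets (corn-starch based, the test ingredient as sole P source); fecal P
#' is generated from the true apparent total tract digestibility.
#'
#' @param sc A [trial_scenario].
#' @return List of [collection_record] carrying `p_diet`/`p_feces`.
#' @export
simulate_p_trial <- function(sc) {
  stopifnot(inherits(sc, "trial_scenario"))
  truth <- do.call(rbind, lapply(sc$p_diets, function(d) {
    tibble::tibble(diet = d$name, ge = d$ge, de = d$de, me = d$me,
                   dmd = d$dmd)
  }))
  withr::with_seed(sc$seed + 1L,
                   simulate_collection(sc, sc$p_diets, truth))
}

#' Simulate an ileal-digesta trial
#'
#' For each cannulated pig the digesta amino acid concentrations are solved
#' from the true apparent ileal digestibility, the basal endogenous flows and
#' the marker dilution: with digesta DM flow `r` per kg DM intake,
#' `Ti_digesta = Ti_diet / r` and the digesta concentration of an amino acid
#' is its undigested apparent flow divided by `r` (for the N-free diet, the
#' endogenous flow alone). Observation noise is multiplicative lognormal on
#' marker and concentrations. Negative true AID (fruit and vegetable waste)
#' simply yields digesta enriched beyond the dietary supply.
#'
#' @param sc A [trial_scenario].
#' @return List of [digesta_record]; N-free records carry endogenous flows
#'   only.
#' @export
simulate_ileal_trial <- function(sc) {
  stopifnot(inherits(sc, "trial_scenario"))
  if (length(sc$ileal_diets) == 0) stop("scenario has no ileal diets",
                                        call. = FALSE)
  withr::with_seed(sc$seed + 2L, {
    recs <- list()
    n <- sc$n_pigs_per_diet
    for (d in sc$ileal_diets) {
      r <- d$digesta_flow %||% 0.25      # kg digesta DM per kg DMI
      if (is.null(d$test_ingredient)) {
        flow <- sc$endogenous_aa
        conc_diet <- d$aa
      } else {
        aid <- sc$true_values[[d$test_ingredient]]$aid
        conc_diet <- d$aa[names(aid)]
        flow <- conc_diet * (1 - aid / 100)
      }
      for (i in seq_len(n)) {
        ti_dig <- (d$ti_pct / r) * lnoise(1, sc$noise$marker_cv)
        conc_dig <- (flow / r) * lnoise(length(flow), sc$noise$conc_cv)
        recs[[length(recs) + 1L]] <- digesta_record(
          pig_id = paste0(d$name, "_", i), diet = d$name,
          ti_diet = d$ti_pct, ti_digesta = ti_dig,
          conc_diet = conc_diet, conc_digesta = conc_dig
        )
      }
    }
    recs
  })
}

#' Default scenario mirroring the three trial designs
#'
#' Builds a [trial_scenario] from the packaged diet formulations
#' ([trial_diets]) with the in vivo population values of the source trials as
#' the simulation truths: ingredient DE/ME and energy ratios of the
#' energy-balance trial, apparent total tract P digestibility, and apparent
#' ileal AA digestibility with basal endogenous flows derived from the fish
#' waste standardized-minus-apparent gap. Four energy diets (basal 96.9%
#' corn; three 30%-inclusion test diets), three phosphorus diets, three test
#' ileal diets plus the nitrogen-free diet, nine pigs per diet.
#'
#' @param seed Integer seed.
#' @param noise Noise list as in [trial_scenario].
#' @return A [trial_scenario].
#' @export
default_scenario <- function(seed = 1L,
                             noise = list(marker_cv = 0.05, ge_cv = 0.02,
                                          conc_cv = 0.05)) {
  diets <- trial_diets()
  true_values <- list(
    Corn = list(de = 3928, me = 3875, dmd = 0.823),
    FW   = list(de = 5057, me = 4820, dmd = 0.842, attd_p = 56.00,
                aid = c(CP = 83.1, Arg = 92.0, His = 89.5, Ile = 87.1,
                        Leu = 88.2, Lys = 89.7, Met = 92.4, Phe = 87.7,
                        Thr = 83.4, Trp = 91.2, Val = 83.2, Ala = 88.2,
                        Asp = 83.8, Cys = 65.8, Glu = 88.3, Gly = 89.1,
                        Pro = 75.1, Ser = 83.4, Tyr = 86.1)),
    SMW  = list(de = 5071, me = 4922, dmd = 0.901, attd_p = 67.97,
                aid = c(CP = 63.5, Arg = 75.3, His = 76.3, Ile = 78.4,
                        Leu = 80.6, Lys = 77.9, Met = 82.9, Phe = 78.1,
                        Thr = 68.2, Trp = 83.2, Val = 71.2, Ala = 71.6,
                        Asp = 71.1, Cys = 53.6, Glu = 81.7, Gly = 45.3,
                        Pro = -28.9, Ser = 68.4, Tyr = 73.9)),
    FVW  = list(de = 2570, me = 2460, dmd = 0.638, attd_p = 52.95,
                aid = c(CP = -44.5, Arg = -53.1, His = -64.0, Ile = -34.1,
                        Leu = -14.7, Lys = -35.5, Met = -7.4, Phe = -9.8,
                        Thr = -64.2, Trp = 15.0, Val = -49.8, Ala = -44.3,
                        Asp = -5.6, Cys = -87.4, Glu = 5.7, Gly = -226.0,
                        Pro = -413.1, Ser = -39.8, Tyr = -91.1))
  )
  # fish-waste standardized digestibilities; the SID - AID gap times the
  # dietary supply defines the basal endogenous flows used for all diets
  sid_fw <- c(CP = 95.1, Arg = 99.9, His = 95.2, Ile = 94.0, Leu = 94.8,
              Lys = 94.7, Met = 95.0, Phe = 94.4, Thr = 93.3, Trp = 99.2,
              Val = 92.8, Ala = 95.1, Asp = 90.8, Cys = 85.9, Glu = 94.3,
              Gly = 102.9, Pro = 126.7, Ser = 92.8, Tyr = 93.7)

  diet_aa_dm <- function(d) {
    dmf <- d$analyzed$dm_pct / 100
    aa <- c(CP = d$analyzed$cp_pct, d$analyzed$aa_pct)
    aa / dmf * 10   # % as-fed -> g/kg DM
  }
  fw_aa <- diet_aa_dm(diets$amino_acids$FW)
  endo <- (sid_fw - true_values$FW$aid[names(sid_fw)]) / 100 *
    fw_aa[names(sid_fw)]

  energy_diets <- lapply(diets$energy_balance, function(d) {
    dmf <- d$analyzed$dm_pct / 100
    list(name = d$name, dm_frac = dmf,
         ge = d$analyzed$ge_kcal_kg / dmf,
         ti_pct = d$marker_ti_pct / dmf,
         test_ingredient = d$test_ingredient,
         test_frac = if (!is.null(d$test_ingredient))
           unname(d$ingredients[d$test_ingredient]),
         basal_frac_in_test = if (!is.null(d$test_ingredient))
           unname(d$ingredients["Corn"]),
         ref_ingredient = "Corn",
         basal_frac = if (is.null(d$test_ingredient))
           unname(d$ingredients["Corn"]))
  })
  p_diets <- lapply(diets$phosphorus, function(d) {
    dmf <- d$analyzed$dm_pct / 100
    ge <- d$analyzed$ge_kcal_kg / dmf
    # corn-starch/sucrose semi-purified diets: highly digestible, and the
    # concentration-ratio estimators are invariant to the level chosen
    list(name = d$name, dm_frac = dmf, ge = ge, de = 0.88 * ge,
         me = 0.85 * ge, dmd = 0.90,
         ti_pct = d$marker_ti_pct / dmf,
         test_ingredient = d$test_ingredient,
         p_g_per_kg_dm = d$analyzed$p_pct / dmf * 10)
  })
  ileal_diets <- lapply(diets$amino_acids, function(d) {
    dmf <- d$analyzed$dm_pct / 100
    list(name = d$name, dm_frac = dmf,
         ti_pct = d$marker_ti_pct / dmf,
         test_ingredient = d$test_ingredient,
         aa = diet_aa_dm(d), digesta_flow = 0.25)
  })
  trial_scenario(energy_diets = energy_diets, p_diets = p_diets,
                 ileal_diets = ileal_diets, true_values = true_values,
                 endogenous_aa = endo, n_pigs_per_diet = 9,
                 bw_mean = 16.37, bw_sd = 1.9, noise = noise, seed = seed)
}
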