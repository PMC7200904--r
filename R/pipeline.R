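#' Per-pig diet energy values from collection records
#'
#' @param records List of [collection_record].
#' @param diet_ge Named vector: diet gross energy, kcal/kg DM, by diet name.
#' @param method Estimator passed to [diet_energy].
#' @return Tibble: `pig_id`, `diet`, `de`, `me`, `de_ge`, `me_ge`, `me_de`.
#' @export
pig_energy_values <- function(records, diet_ge, method = c("marker", "total")) {
  method <- match.arg(method)
  rows <- lapply(records, function(r) {
    ev <- diet_energy(r, diet_ge[[r$diet]], method = method)
    tibble::tibble(pig_id = r$pig_id, diet = r$diet, de = ev$de, me = ev$me,
                   de_ge = ev$de_ge, me_ge = ev$me_ge, me_de = ev$me_de)
  })
  do.call(rbind, rows)
}

#' Ingredient DE/ME and margins from an energy-balance trial
#'
#' Runs the full difference-method chain: per-pig diet energy values
#' ([pig_energy_values]), the basal-diet mean as the corn credit, per-pig
#' ingredient estimates
#' ([ingredient_energy_by_difference] applied pig by pig against the basal
#' mean), and per-ingredient means with 95% margins of error
#' ([margin_of_error]).
#'
#' @param records List of [collection_record] (one trial).
#' @param diets Energy-diet definitions as in a [trial_scenario] (name,
#'   `ge`, `test_ingredient`, `test_frac`, `basal_frac_in_test`,
#'   `basal_frac`).
#' @param method Estimator passed to [diet_energy].
#' @return List with `diet_values` (per-pig tibble), `ingredients` (tibble:
#'   ingredient, n, de, me, de_sd, me_sd, de_margin, me_margin) and
#'   `per_pig_ingredient` (tibble of per-pig ingredient estimates).
#' @export
ingredient_energy_from_trial <- function(records, diets,
                                         method = c("marker", "total")) {
  method <- match.arg(method)
  diet_ge <- stats::setNames(
    vapply(diets, `[[`, numeric(1), "ge"),
    vapply(diets, `[[`, character(1), "name")
  )
  pv <- pig_energy_values(records, diet_ge, method = method)
  basal <- Filter(function(d) is.null(d$test_ingredient), diets)
  if (length(basal) != 1) stop("need exactly one basal diet", call. = FALSE)
  basal <- basal[[1]]
  basal_pv <- pv[pv$diet == basal$name, ]
  basal_mean <- energy_values(de = mean(basal_pv$de), me = mean(basal_pv$me))
  per_pig <- list()
  for (d in Filter(function(d) !is.null(d$test_ingredient), diets)) {
    dv <- pv[pv$diet == d$name, ]
    for (i in seq_len(nrow(dv))) {
      ing <- ingredient_energy_by_difference(
        test_diet = list(de = dv$de[i], me = dv$me[i]),
        basal_diet = basal_mean,
        basal_frac_in_test = d$basal_frac_in_test,
        basal_frac_in_basal = basal$basal_frac,
        test_frac = d$test_frac
      )
      per_pig[[length(per_pig) + 1L]] <- tibble::tibble(
        ingredient = d$test_ingredient, pig_id = dv$pig_id[i],
        de = ing$de, me = ing$me
      )
    }
  }
  per_pig <- do.call(rbind, per_pig)
  ingredients <- do.call(rbind, lapply(split(per_pig, per_pig$ingredient),
    function(g) {
      tibble::tibble(
        ingredient = g$ingredient[1], n = nrow(g),
        de = mean(g$de), me = mean(g$me),
        de_sd = stats::sd(g$de), me_sd = stats::sd(g$me),
        de_margin = margin_of_error(g$de), me_margin = margin_of_error(g$me)
      )
    }))
  list(diet_values = pv, ingredients = ingredients,
       per_pig_ingredient = per_pig)
}

#' ATTD and STTD of phosphorus from a collection trial
#'
#' Per-pig apparent digestibility ([attd_p]) averaged by diet, with the
#' standardized value from the basal endogenous-loss correction
#' ([sttd_from_attd]).
#'
#' @param records List of [collection_record] carrying P concentrations.
#' @param basal_loss_mg Basal endogenous P loss, mg/kg DM intake.
#' @return Tibble: `diet`, `n`, `attd`, `sttd`, `attd_sd`, `p_g_per_kg_dmi`.
#' @export
p_digestibility_from_trial <- function(records, basal_loss_mg = 190) {
  per_pig <- do.call(rbind, lapply(records, function(r) {
    a <- attd_p(r)
    tibble::tibble(diet = r$diet, attd = a,
                   sttd = sttd_from_attd(a, r$p_diet, basal_loss_mg),
                   p_diet = r$p_diet)
  }))
  do.call(rbind, lapply(split(per_pig, per_pig$diet), function(g) {
    tibble::tibble(diet = g$diet[1], n = nrow(g), attd = mean(g$attd),
                   sttd = mean(g$sttd), attd_sd = stats::sd(g$attd),
                   p_g_per_kg_dmi = g$p_diet[1])
  }))
}

#' AID and SID summary from an ileal trial
#'
#' Estimates basal endogenous flows from the nitrogen-free records
#' ([basal_endogenous_aa]) and applies them to each test diet ([aid_sid]).
#'
#' @param records List of [digesta_record] (test diets plus N-free).
#' @param nfree_diet Name of the nitrogen-free diet in `records`.
#' @return Tibble of [aid_sid] results with a `diet` column.
#' @export
aa_digestibility_from_trial <- function(records, nfree_diet = "Nfree") {
  diets <- vapply(records, `[[`, character(1), "diet")
  nfree <- records[diets == nfree_diet]
  if (length(nfree) == 0) stop("no records for N-free diet '", nfree_diet,
                               "'", call. = FALSE)
  endo <- basal_endogenous_aa(nfree)
  out <- lapply(setdiff(unique(diets), nfree_diet), function(dn) {
    res <- aid_sid(records[diets == dn], endo)
    res$diet <- dn
    res[, c("diet", setdiff(names(res), "diet"))]
  })
  do.call(rbind, out)
}

#' Run the evaluation pipeline
#'
#' Thin orchestration over the package's stages, writing one CSV per stage
#' under `cfg$outdir`, each with a provenance header (package version, seed,
#' config hash). With a fixed seed the reports are byte-identical across
#' runs. Stages:
#' * `simulate` + `energy`: synthetic energy-balance trial and the
#'   difference-method ingredient DE/ME summary.
#' * `phosphorus`: synthetic P trial, ATTD/STTD summary.
#' * `amino_acids`: synthetic ileal trial, AID/SID summary.
#' * `predict`: prediction equations over the packaged composition fixture.
#' * `assess`: accuracy verdicts of the predictions against the simulated
#'   in vivo means (needs `energy` and `predict`).
#'
#' @param cfg List: `seed` (integer), `stages` (character subset of the
#'   above), `outdir`, optional `noise`, `estimator` (`"marker"` or
#'   `"total"`), `ndf_zero` (ingredient names), `basal_loss_mg`.
#' @return Invisibly, a named list of the tibbles written.
#' @export
run_pipeline <- function(cfg) {
  stages <- cfg$stages %||% character()
  if (length(stages) == 0) {
    warning("no stages requested; nothing to do", call. = FALSE)
    return(invisible(list()))
  }
  known <- c("simulate", "energy", "phosphorus", "amino_acids", "predict",
             "assess")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  estimator <- cfg$estimator %||% "marker"
  sc <- default_scenario(seed = seed,
                         noise = cfg$noise %||% list(marker_cv = 0.05,
                                                     ge_cv = 0.02,
                                                     conc_cv = 0.05))
  stamp <- provenance_header(cfg, seed)
  out <- list()
  emit <- function(name, df) {
    path <- file.path(cfg$outdir, paste0(name, ".csv"))
    writeLines(stamp, path)
    suppressWarnings(utils::write.table(
      df, path, sep = ",", row.names = FALSE, append = TRUE, qmethod = "double"
    ))
    out[[name]] <<- df
  }
  energy <- NULL
  if (any(c("simulate", "energy", "assess") %in% stages)) {
    recs <- simulate_energy_trial(sc)
    energy <- ingredient_energy_from_trial(recs, sc$energy_diets,
                                           method = estimator)
    if (any(c("simulate", "energy") %in% stages)) {
      emit("diet_energy", energy$diet_values)
      emit("ingredient_energy", energy$ingredients)
    }
  }
  if ("phosphorus" %in% stages) {
    emit("phosphorus_digestibility",
         p_digestibility_from_trial(simulate_p_trial(sc),
                                    cfg$basal_loss_mg %||% 190))
  }
  if ("amino_acids" %in% stages) {
    emit("aa_digestibility",
         aa_digestibility_from_trial(simulate_ileal_trial(sc)))
  }
  preds <- NULL
  if (any(c("predict", "assess") %in% stages)) {
    comps <- food_waste_composition()
    preds <- predict_all(comps[c("FW", "SMW", "FVW")],
                         eq_ids = as.character(1:15),
                         ndf_zero = cfg$ndf_zero %||% character())
    if ("predict" %in% stages) {
      emit("predictions", preds[, setdiff(names(preds), "inputs")])
    }
  }
  if ("assess" %in% stages) {
    verdicts <- do.call(rbind, lapply(seq_len(nrow(energy$ingredients)),
      function(i) {
        ing <- energy$ingredients[i, ]
        p <- preds[preds$ingredient == ing$ingredient, ]
        rbind(
          assess_predictions(ing$de, ing$de_margin, p[p$output == "DE", ]),
          assess_predictions(ing$me, ing$me_margin, p[p$output == "ME", ])
        )
      }))
    emit("accuracy_verdicts", verdicts)
  }
  invisible(out)
}

provenance_header <- function(cfg, seed) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(cfg[order(names(cfg))]), collapse = ""), f)
  sprintf("# swinedigest %s | seed=%d | config_md5=%s",
          as.character(utils::packageVersion("swinedigest")), seed,
          unname(tools::md5sum(f)))
}
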