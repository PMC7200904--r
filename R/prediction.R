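#' Registry of DE/ME prediction equations
#'
#' All nineteen published prediction equations for digestible (DE) and
#' metabolizable (ME) energy of swine feed ingredients evaluated by the
#' package, kept as transcribed affine coefficient sets. Three families with
#' different input conventions (inferred by reproducing the source tables,
#' since the conventions are stated loosely):
#'
#' * `NP` (chemical composition, eq 1-7): proximate inputs in **g/kg DM**, GE
#'   in kcal/kg DM; output kcal/kg DM. Eq 1 uses analyzed GE, eq 2 the GE
#'   calculated from proximate composition ([calculated_ge]); eq 5-7 are
#'   defined as eq 1-3 output minus 0.68 x CP (g/kg DM) and are evaluated by
#'   composition so that identity holds by construction.
#' * `KERR` (stepwise regressions, eq 8-15): inputs in **% DM**, GE in
#'   kcal/kg DM; output kcal/kg DM.
#' * `NJP` (in vitro OM digestibility + chemistry, eq 16-19): inputs in
#'   **g/kg DM** including OMdv (in vitro digestible OM, g/kg DM); computed
#'   in MJ/kg DM and converted with [mj_to_kcal].
#'
#' @return A named list of equation specs (id, family, output, terms,
#'   and for eq 5-7 the base DE equation id).
#' @export
energy_equations <- function() {
  np <- function(out, terms, base = NULL) {
    list(family = "NP", output = out, terms = terms, base = base)
  }
  kerr <- function(out, terms) list(family = "KERR", output = out, terms = terms)
  njp <- function(terms) list(family = "NJP", output = "DE", terms = terms)
  eqs <- list(
    `1`  = np("DE", c(intercept = 1161, ge_analyzed = 0.749, ash = -4.3,
                      ndf = -4.1)),
    `2`  = np("DE", c(intercept = 1161, ge_calc = 0.749, ash = -4.3,
                      ndf = -4.1)),
    `3`  = np("DE", c(intercept = 4168, ash = -9.1, cp = 1.9, ee = 3.9,
                      ndf = -3.6)),
    `4`  = np("ME", c(intercept = 4194, ash = -9.2, cp = 1.0, ee = 4.1,
                      ndf = -3.5)),
    `5`  = np("ME", c(cp = -0.68), base = "1"),
    `6`  = np("ME", c(cp = -0.68), base = "2"),
    `7`  = np("ME", c(cp = -0.68), base = "3"),
    `8`  = kerr("DE", c(intercept = -2468, ge_analyzed = 1.26)),
    `9`  = kerr("DE", c(intercept = -669, cp = 56.1, ee = 73.4, ash = -12.5)),
    `10` = kerr("DE", c(intercept = 5420, ash = -87.5)),
    `11` = kerr("DE", c(intercept = 665, cp = 46.7, ee = 59.2, ash = -36.5)),
    `12` = kerr("ME", c(intercept = -2331, ge_analyzed = 1.15)),
    `13` = kerr("ME", c(intercept = -443, cp = 48.1, ee = 75.9, ash = -18.0)),
    `14` = kerr("ME", c(intercept = 4996, ash = -84.0)),
    `15` = kerr("ME", c(intercept = 1192, cp = 36.8, ee = 49.7, ash = -43.1)),
    `16` = njp(c(intercept = 0, omdv = 0.0189)),
    `17` = njp(c(intercept = 1.12, omdv = 0.0168, ee = 0.0184)),
    `18` = njp(c(intercept = 5.02, omdv = 0.0127, ee = 0.0172, cf = -0.0124)),
    `19` = njp(c(intercept = 6.05, omdv = 0.0116, ee = 0.0166, adf = -0.0135))
  )
  for (id in names(eqs)) eqs[[id]]$id <- id
  eqs
}

#' Megajoules to kilocalories
#'
#' @param x Energy, MJ.
#' @return Energy, kcal (1 MJ = 238.834 kcal).
#' @export
mj_to_kcal <- function(x) {
  if (any(!is.finite(x))) stop("non-finite energy", call. = FALSE)
  x * 238.834
}

# assemble the input vector an equation family expects from a composition;
# errors loudly on a required field that was never analyzed
equation_inputs <- function(eq, comp, omdv = NULL, ndf_zero = FALSE) {
  d <- convert_basis(comp, "dm")
  scale <- if (eq$family == "KERR") 1 else 10   # % DM -> g/kg DM
  get <- function(field) {
    v <- switch(field,
      ge_analyzed = d$ge,
      ge_calc = calculated_ge(comp),
      omdv = if (is.null(omdv)) NA_real_ else omdv,
      d[[field]]
    )
    if (is.na(v)) {
      stop("equation ", eq$id, " for '", comp$name, "': missing input '",
           field, "'", call. = FALSE)
    }
    if (field %in% c("ge_analyzed", "ge_calc", "omdv")) v
    else if (field == "ndf" && ndf_zero) 0
    else v * scale
  }
  fields <- setdiff(names(eq$terms), "intercept")
  stats::setNames(vapply(fields, get, numeric(1)), fields)
}

#' Predict DE or ME of an ingredient from one equation
#'
#' Applies one equation of the registry ([energy_equations]) to an ingredient
#' composition, handling each family's unit convention and the MJ-to-kcal
#' conversion for the in vitro family.
#'
#' @param eq_id Equation id: `"1"`..`"19"` (or integer).
#' @param comp A [feed_comp] (converted to DM basis internally).
#' @param omdv In vitro OM digestibility, g/kg DM; required by (and only by)
#'   equations 16-19.
#' @param ndf_zero If `TRUE`, the NDF term is evaluated at zero. The source
#'   tables for the animal-product ingredient (fish waste) are reproducible
#'   only under this override; default behavior always uses analyzed NDF.
#' @return A one-row tibble: `equation`, `family`, `output`, `ingredient`,
#'   `predicted` (kcal/kg DM, full precision), `inputs` (list column),
#'   `notes`.
#' @export
#' @examples
#' fw <- food_waste_composition()$FW
#' predict_energy(10, fw)$predicted   # ~3,991 kcal/kg DM
predict_energy <- function(eq_id, comp, omdv = NULL, ndf_zero = FALSE) {
  eqs <- energy_equations()
  eq_id <- as.character(eq_id)
  if (!eq_id %in% names(eqs)) stop("unknown equation id: ", eq_id,
                                   call. = FALSE)
  eq <- eqs[[eq_id]]
  if (eq$family == "NJP" && is.null(omdv)) {
    stop("equation ", eq_id, " for '", comp$name,
         "': missing input 'omdv'", call. = FALSE)
  }
  inputs <- equation_inputs(eq, comp, omdv = omdv, ndf_zero = ndf_zero)
  value <- sum(eq$terms[names(inputs)] * inputs) +
    if ("intercept" %in% names(eq$terms)) eq$terms[["intercept"]] else 0
  if (!is.null(eq$base)) {
    value <- value + predict_energy(eq$base, comp, ndf_zero = ndf_zero)$predicted
  }
  if (eq$family == "NJP") value <- mj_to_kcal(value)
  notes <- character(0)
  if (ndf_zero && "ndf" %in% names(eq$terms)) notes <- c(notes, "NDF term zeroed")
  if (value < 0) notes <- c(notes, "negative prediction (degenerate input)")
  tibble::tibble(
    equation = eq_id, family = eq$family, output = eq$output,
    ingredient = comp$name, predicted = unname(value),
    inputs = list(inputs), notes = paste(notes, collapse = "; ")
  )
}

#' Batch prediction over ingredients and equations
#'
#' One outcome row per (ingredient, equation) pair. Pairs that cannot be
#' evaluated for lack of an analyzed input are reported with `predicted = NA`
#' and the error message in `notes`, never dropped silently.
#'
#' @param comps List of [feed_comp] objects.
#' @param eq_ids Equation ids (default: all of [energy_equations]).
#' @param omdv_map Optional named vector of OMdv (g/kg DM) per ingredient
#'   name, for equations 16-19.
#' @param ndf_zero Character vector of ingredient names for which the NDF
#'   term is zeroed (see [predict_energy]).
#' @return Tibble of prediction outcomes.
#' @export
predict_all <- function(comps, eq_ids = names(energy_equations()),
                        omdv_map = NULL, ndf_zero = character()) {
  if (length(comps) == 0) stop("no compositions supplied", call. = FALSE)
  eq_ids <- as.character(eq_ids)
  unknown <- setdiff(eq_ids, names(energy_equations()))
  if (length(unknown)) stop("unknown equation id: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  rows <- list()
  for (comp in comps) {
    for (id in eq_ids) {
      row <- tryCatch(
        predict_energy(id, comp,
                       omdv = if (!is.null(omdv_map)) omdv_map[[comp$name]],
                       ndf_zero = comp$name %in% ndf_zero),
        error = function(e) {
          eq <- energy_equations()[[id]]
          tibble::tibble(equation = id, family = eq$family,
                         output = eq$output, ingredient = comp$name,
                         predicted = NA_real_, inputs = list(NULL),
                         notes = conditionMessage(e))
        }
      )
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
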