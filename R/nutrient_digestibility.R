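#' Apparent total tract digestibility of phosphorus
#'
#' Marker-ratio digestibility ([marker_digestibility]) applied to the
#' phosphorus concentrations of diet and feces, expressed in percent.
#'
#' @param rec A [collection_record] carrying `p_diet`, `p_feces`, `ti_diet`
#'   and `ti_feces` (diet and fecal concentrations per kg DM).
#' @return ATTD of P, %.
#' @export
attd_p <- function(rec) {
  stopifnot(inherits(rec, "collection_record"))
  if (is.na(rec$p_diet) || is.na(rec$p_feces)) {
    stop("record lacks phosphorus concentrations", call. = FALSE)
  }
  100 * marker_digestibility(rec$p_diet, rec$p_feces,
                             rec$ti_diet, rec$ti_feces)
}

#' Standardized from apparent total tract digestibility
#'
#' Corrects an apparent digestibility for the basal endogenous loss of the
#' nutrient (for phosphorus in growing pigs, 190 mg per kg of DM intake):
#' \deqn{STTD = ATTD + 100 \cdot \frac{loss/1000}{c_{diet}}}
#' where `c_diet` is the dietary nutrient concentration in g per kg DM (so
#' the correction is the endogenous fraction of intake, in percentage
#' points). The correction is additive and nonnegative, so STTD >= ATTD
#' always; it shrinks as the dietary concentration rises.
#'
#' @param attd Apparent digestibility, %.
#' @param nutrient_g_per_kg_dmi Dietary nutrient concentration, g/kg DM
#'   intake (> 0).
#' @param basal_loss_mg_per_kg_dmi Basal endogenous loss, mg/kg DM intake.
#' @return Standardized digestibility, %.
#' @export
#' @examples
#' sttd_from_attd(50, 1.9, 190)  # 60: the loss is 10% of intake
sttd_from_attd <- function(attd, nutrient_g_per_kg_dmi,
                           basal_loss_mg_per_kg_dmi = 190) {
  if (any(nutrient_g_per_kg_dmi <= 0)) {
    stop("dietary nutrient concentration must be > 0", call. = FALSE)
  }
  if (any(basal_loss_mg_per_kg_dmi < 0)) {
    stop("basal endogenous loss must be >= 0", call. = FALSE)
  }
  attd + 100 * (basal_loss_mg_per_kg_dmi / 1000) / nutrient_g_per_kg_dmi
}

#' One pig's ileal digesta record
#'
#' Marker and nutrient concentrations in an assigned diet and in the ileal
#' digesta collected from one cannulated pig, all per kg DM.
#'
#' @param pig_id Pig identifier.
#' @param diet Diet name.
#' @param ti_diet,ti_digesta Titanium, % of DM (> 0).
#' @param conc_diet,conc_digesta Named numeric vectors of nutrient (amino
#'   acid / CP) concentrations, g/kg DM; names are matched between the two.
#' @return An object of class `digesta_record`.
#' @export
digesta_record <- function(pig_id, diet, ti_diet, ti_digesta,
                           conc_diet, conc_digesta) {
  stopifnot(ti_diet > 0, ti_digesta > 0)
  if (any(conc_diet < 0) || any(conc_digesta < 0)) {
    stop("digesta record: concentrations must be >= 0", call. = FALSE)
  }
  names(conc_diet) <- normalize_aa(names(conc_diet))
  names(conc_digesta) <- normalize_aa(names(conc_digesta))
  structure(
    list(pig_id = pig_id, diet = diet, ti_diet = ti_diet,
         ti_digesta = ti_digesta, conc_diet = conc_diet,
         conc_digesta = conc_digesta),
    class = "digesta_record"
  )
}

#' Basal endogenous amino acid losses from a nitrogen-free diet
#'
#' For pigs fed a nitrogen-free diet every amino acid appearing at the distal
#' ileum is of endogenous origin; its flow per kg of DM intake is the digesta
#' concentration deflated by the marker ratio:
#' \deqn{flow = c_{digesta} \cdot \frac{Ti_{diet}}{Ti_{digesta}}}
#' averaged over pigs.
#'
#' @param nfree_records List of [digesta_record] from the N-free diet.
#' @return Named numeric vector: endogenous flow per amino acid, g/kg DMI.
#' @export
basal_endogenous_aa <- function(nfree_records) {
  if (length(nfree_records) == 0) {
    stop("no nitrogen-free records supplied", call. = FALSE)
  }
  flows <- lapply(nfree_records, function(r) {
    stopifnot(inherits(r, "digesta_record"))
    r$conc_digesta * (r$ti_diet / r$ti_digesta)
  })
  nutrients <- sort(unique(unlist(lapply(flows, names))))
  out <- vapply(nutrients, function(nm) {
    mean(vapply(flows, function(f) {
      if (!nm %in% names(f)) stop("record missing nutrient ", nm,
                                  call. = FALSE)
      f[[nm]]
    }, numeric(1)))
  }, numeric(1))
  out
}

#' Apparent and standardized ileal digestibility of amino acids
#'
#' Per pig, AID of each amino acid is the marker-ratio digestibility
#' ([marker_digestibility]) of its diet and digesta concentrations, in
#' percent; SID adds the basal endogenous flow expressed as a share of dietary
#' supply:
#' \deqn{SID = AID + 100 \cdot \frac{e}{c_{diet}}}
#' with `e` the endogenous flow (g/kg DMI) and `c_diet` the dietary
#' concentration (g/kg DM) — the same normalization the marker ratio uses.
#' Digestibilities are computed per pig first and then averaged (the pig is
#' the experimental unit). Negative AID and SID above 100 are legitimate
#' outcomes (high-fiber feeds; proline/glycine) and are flagged in the
#' `flag` column, never clipped.
#'
#' @param test_records List of [digesta_record] from one test diet.
#' @param endogenous Named numeric vector of basal endogenous flows
#'   (g/kg DMI), e.g. from [basal_endogenous_aa]. Every amino acid present in
#'   the records must have an entry; a missing entry is an error, not a
#'   silent zero.
#' @return A tibble with one row per amino acid: `nutrient`, `aid`, `sid`
#'   (%, means over pigs), `aid_sd`, `sid_sd`, `endogenous` (g/kg DMI),
#'   `n`, `flag`.
#' @export
aid_sid <- function(test_records, endogenous) {
  if (length(test_records) == 0) stop("no records supplied", call. = FALSE)
  nutrients <- names(test_records[[1]]$conc_diet)
  missing_e <- setdiff(nutrients, names(endogenous))
  if (length(missing_e)) {
    stop("no endogenous loss entry for: ",
         paste(missing_e, collapse = ", "), call. = FALSE)
  }
  per_pig <- lapply(test_records, function(r) {
    aid <- 100 * marker_digestibility(r$conc_diet[nutrients],
                                      r$conc_digesta[nutrients],
                                      r$ti_diet, r$ti_digesta)
    sid <- aid + 100 * endogenous[nutrients] / r$conc_diet[nutrients]
    list(aid = aid, sid = sid)
  })
  aid_mat <- do.call(rbind, lapply(per_pig, `[[`, "aid"))
  sid_mat <- do.call(rbind, lapply(per_pig, `[[`, "sid"))
  aid <- colMeans(aid_mat)
  sid <- colMeans(sid_mat)
  flag <- ifelse(aid < 0 & sid > 100, "negative AID; SID > 100",
          ifelse(aid < 0, "negative AID",
          ifelse(sid > 100, "SID > 100", "")))
  tibble::tibble(
    nutrient = nutrients,
    aid = unname(aid), sid = unname(sid),
    aid_sd = unname(apply(aid_mat, 2, stats::sd)),
    sid_sd = unname(apply(sid_mat, 2, stats::sd)),
    endogenous = unname(endogenous[nutrients]),
    n = length(test_records),
    flag = unname(flag)
  )
}
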