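#' Ingredient composition with an explicit reporting basis
#'
#' Proximate/amino-acid composition of a feed ingredient, tagged with the basis
#' the concentrations are reported on: `"as_fed"` (per kg of feed as fed,
#' moisture included) or `"dm"` (per kg of dry matter). All concentrations are
#' percent by mass except gross energy, which is kcal/kg. Fields that were not
#' analyzed are carried as `NA` (an explicit absent marker, never zero):
#' downstream consumers that need them fail loudly.
#'
#' Note that on a DM basis the proximate fractions need not sum to 100 —
#' neutral detergent fiber overlaps other fractions — but each individual
#' component must lie in \[0, 100\].
#'
#' @param name Ingredient name.
#' @param basis `"as_fed"` or `"dm"`.
#' @param dm_frac Dry-matter fraction, in (0, 1].
#' @param ge Gross energy, kcal/kg (on `basis`).
#' @param cp,ee,ash,ndf,adf,ca,p,cf Crude protein, ether extract (crude fat),
#'   ash, neutral/acid detergent fiber, calcium, phosphorus and crude fiber,
#'   all % by mass on `basis`. `NA` means not analyzed.
#' @param aa Named numeric vector of amino acid concentrations (% by mass on
#'   `basis`); names are three-letter codes, matched case-insensitively.
#'
#' @return An object of class `feed_comp`.
#' @export
#' @examples
#' fw <- feed_comp("FW", basis = "as_fed", dm_frac = 0.9216, ge = 5876,
#'                 cp = 57.59, ee = 17.38, ash = 15.05, ndf = 3.81)
#' convert_basis(fw, "dm")$cp  # 62.49 % DM
feed_comp <- function(name, basis = c("as_fed", "dm"), dm_frac, ge = NA_real_,
                      cp = NA_real_, ee = NA_real_, ash = NA_real_,
                      ndf = NA_real_, adf = NA_real_, ca = NA_real_,
                      p = NA_real_, cf = NA_real_, aa = NULL) {
  basis <- match.arg(basis)
  if (!is.numeric(dm_frac) || length(dm_frac) != 1L || is.na(dm_frac) ||
      dm_frac <= 0 || dm_frac > 1) {
    stop("invalid composition: 'dm_frac' must be a single value in (0, 1]",
         call. = FALSE)
  }
  conc <- c(ge = ge, cp = cp, ee = ee, ash = ash, ndf = ndf, adf = adf,
            ca = ca, p = p, cf = cf)
  bad <- !is.na(conc) & conc < 0
  if (any(bad)) {
    stop("invalid composition: negative concentration(s): ",
         paste(names(conc)[bad], collapse = ", "), call. = FALSE)
  }
  pct <- conc[setdiff(names(conc), "ge")]
  if (any(!is.na(pct) & pct > 100)) {
    stop("invalid composition: component exceeds 100%", call. = FALSE)
  }
  if (!is.null(aa)) {
    if (is.null(names(aa)) || any(!nzchar(names(aa)))) {
      stop("'aa' must be a named numeric vector", call. = FALSE)
    }
    names(aa) <- normalize_aa(names(aa))
    if (any(!is.na(aa) & aa < 0)) {
      stop("invalid composition: negative amino acid concentration",
           call. = FALSE)
    }
  }
  structure(
    list(name = as.character(name), basis = basis, dm_frac = dm_frac,
         ge = ge, cp = cp, ee = ee, ash = ash, ndf = ndf, adf = adf,
         ca = ca, p = p, cf = cf, aa = aa),
    class = "feed_comp"
  )
}

#' @export
print.feed_comp <- function(x, ...) {
  cat(sprintf("<feed_comp> %s [%s basis, DM %.2f%%]\n",
              x$name, gsub("_", "-", x$basis), 100 * x$dm_frac))
  flds <- c("ge", "cp", "ee", "ash", "ndf", "adf", "ca", "p", "cf")
  v <- vapply(flds, function(f) x[[f]], numeric(1))
  v <- v[!is.na(v)]
  if (length(v)) {
    unit <- ifelse(names(v) == "ge", "kcal/kg", "%")
    cat(paste0("  ", names(v), ": ", formatC(v, digits = 4, format = "fg"),
               " ", unit, collapse = "\n"), "\n")
  }
  if (!is.null(x$aa)) cat("  amino acids:", length(x$aa), "entries\n")
  invisible(x)
}

# canonical three-letter AA codes, case-insensitive on input
normalize_aa <- function(codes) {
  known <- c("Arg", "His", "Ile", "Leu", "Lys", "Met", "Phe", "Thr", "Trp",
             "Val", "Ala", "Asp", "Cys", "Glu", "Gly", "Pro", "Ser", "Tyr")
  idx <- match(tolower(codes), tolower(known))
  out <- ifelse(is.na(idx), codes, known[idx])
  as.character(out)
}

#' Convert a composition between as-fed and dry-matter bases
#'
#' Exact linear rescaling by the dry-matter fraction: as-fed to DM divides
#' every concentration (including gross energy and amino acids) by `dm_frac`,
#' DM to as-fed multiplies. Converting to the current basis is the identity,
#' and a round trip returns the input to within 1e-9 relative.
#'
#' @param comp A [feed_comp].
#' @param target `"as_fed"` or `"dm"`.
#' @return A [feed_comp] on the target basis.
#' @export
convert_basis <- function(comp, target = c("dm", "as_fed")) {
  stopifnot(inherits(comp, "feed_comp"))
  target <- match.arg(target)
  if (comp$basis == target) return(comp)
  if (comp$dm_frac <= 0) stop("invalid composition: dm_frac is zero",
                              call. = FALSE)
  scale <- if (target == "dm") 1 / comp$dm_frac else comp$dm_frac
  out <- comp
  for (f in c("ge", "cp", "ee", "ash", "ndf", "adf", "ca", "p", "cf")) {
    out[[f]] <- comp[[f]] * scale
  }
  if (!is.null(comp$aa)) out$aa <- comp$aa * scale
  out$basis <- target
  out
}

#' Gross energy calculated from proximate composition
#'
#' Estimates gross energy (kcal/kg DM) from ether extract, crude protein and
#' ash, all as % of DM:
#' \deqn{GE = 4143 + 56 \cdot EE + 15 \cdot CP - 44 \cdot ash}
#' Used by the prediction-equation variants that take a calculated rather than
#' analyzed GE. Monotone increasing in EE and CP, decreasing in ash.
#'
#' @param comp A [feed_comp] (converted to DM basis internally).
#' @return Calculated gross energy, kcal/kg DM.
#' @export
calculated_ge <- function(comp) {
  d <- convert_basis(comp, "dm")
  need <- c("ee", "cp", "ash")
  miss <- need[vapply(need, function(f) is.na(d[[f]]), logical(1))]
  if (length(miss)) {
    stop("calculated_ge requires analyzed ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  4143 + 56 * d$ee + 15 * d$cp - 44 * d$ash
}

#' Read/write composition tables
#'
#' One row per ingredient with columns
#' `name,basis,dm_pct,ge_kcal_kg,cp_pct,ee_pct,ash_pct,ndf_pct,adf_pct,ca_pct,p_pct`
#' plus optional `cf_pct` and amino-acid columns `aa_<code>_pct`. Empty cells
#' are read as `NA` (not analyzed). The packaged fixture
#' `system.file("extdata", "table1_composition.csv", package = "swinedigest")`
#' carries the analyzed as-fed composition of the three dried food waste
#' sources (fish waste FW, supermarket waste SMW, fruit and vegetable waste
#' FVW) and corn.
#'
#' @param path CSV file path.
#' @return `read_composition_csv()`: a named list of [feed_comp] objects.
#' @export
read_composition_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("name", "basis", "dm_pct", "ge_kcal_kg", "cp_pct", "ee_pct",
           "ash_pct", "ndf_pct", "adf_pct", "ca_pct", "p_pct")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("composition CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  aa_cols <- grep("^aa_[A-Za-z]{3}_pct$", names(df), value = TRUE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    aa <- NULL
    if (length(aa_cols)) {
      v <- as.numeric(r[aa_cols])
      names(v) <- sub("^aa_([A-Za-z]{3})_pct$", "\\1", aa_cols)
      v <- v[!is.na(v)]
      if (length(v)) aa <- v
    }
    feed_comp(
      name = r$name,
      basis = if (tolower(r$basis) %in% c("dm", "dry_matter")) "dm" else "as_fed",
      dm_frac = r$dm_pct / 100,
      ge = r$ge_kcal_kg, cp = r$cp_pct, ee = r$ee_pct, ash = r$ash_pct,
      ndf = r$ndf_pct, adf = r$adf_pct, ca = r$ca_pct, p = r$p_pct,
      cf = if ("cf_pct" %in% names(df)) r$cf_pct else NA_real_,
      aa = aa
    )
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' @rdname read_composition_csv
#' @param comps Named list of [feed_comp] objects.
#' @export
write_composition_csv <- function(comps, path) {
  aa_codes <- sort(unique(unlist(lapply(comps, function(cc) names(cc$aa)))))
  rows <- lapply(comps, function(cc) {
    base <- data.frame(
      name = cc$name, basis = cc$basis, dm_pct = 100 * cc$dm_frac,
      ge_kcal_kg = cc$ge, cp_pct = cc$cp, ee_pct = cc$ee, ash_pct = cc$ash,
      ndf_pct = cc$ndf, adf_pct = cc$adf, ca_pct = cc$ca, p_pct = cc$p,
      cf_pct = cc$cf, stringsAsFactors = FALSE
    )
    for (code in aa_codes) {
      base[[paste0("aa_", code, "_pct")]] <-
        if (!is.null(cc$aa) && code %in% names(cc$aa)) cc$aa[[code]] else NA_real_
    }
    base
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
}

#' Packaged Table 1 composition fixture
#'
#' Convenience loader for the analyzed as-fed composition of the three dried
#' food waste sources and corn shipped with the package.
#'
#' @return Named list of [feed_comp] objects (`FW`, `SMW`, `FVW`, `Corn`).
#' @export
food_waste_composition <- function() {
  read_composition_csv(system.file("extdata", "table1_composition.csv",
                                   package = "swinedigest", mustWork = TRUE))
}
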