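#' Diet specification
#'
#' A named diet: its ingredient inclusion fractions (which must sum to 1), the
#' analyzed titanium marker concentration (% of diet, as-fed) when marker
#' methods are used, the test ingredient it carries (if any), and optional
#' analyzed composition values.
#'
#' @param name Diet name.
#' @param ingredients Named numeric vector of inclusion fractions (sum to 1
#'   within 1e-9).
#' @param marker_ti_pct Analyzed (or nominal) titanium concentration, % of
#'   diet as-fed; must be > 0 when marker-based digestibility is computed.
#' @param test_ingredient Name of the test ingredient in this diet, or `NULL`
#'   for a basal/N-free diet.
#' @param analyzed Optional named list of analyzed values (e.g. `dm_pct`,
#'   `ge_kcal_kg`, `cp_pct`, `p_pct`, `aa_pct`).
#' @return An object of class `diet_spec`.
#' @export
diet_spec <- function(name, ingredients, marker_ti_pct = NA_real_,
                      test_ingredient = NULL, analyzed = list()) {
  stopifnot(is.numeric(ingredients), !is.null(names(ingredients)))
  if (abs(sum(ingredients) - 1) > 1e-9) {
    stop("diet '", name, "': inclusion fractions sum to ",
         format(sum(ingredients), digits = 12), ", not 1", call. = FALSE)
  }
  if (!is.na(marker_ti_pct) && marker_ti_pct <= 0) {
    stop("diet '", name, "': marker concentration must be > 0", call. = FALSE)
  }
  structure(
    list(name = name, ingredients = ingredients,
         marker_ti_pct = marker_ti_pct,
         test_ingredient = test_ingredient, analyzed = analyzed),
    class = "diet_spec"
  )
}

#' @export
print.diet_spec <- function(x, ...) {
  cat(sprintf("<diet_spec> %s (%d ingredients, Ti %.2f%%)\n",
              x$name, length(x$ingredients), x$marker_ti_pct))
  invisible(x)
}

#' Read diet specifications from YAML
#'
#' Reads a YAML file with one block per experiment (e.g. `energy_balance`,
#' `phosphorus`, `amino_acids`) and one entry per diet, each carrying percent
#' inclusion rates and analyzed composition. The packaged file
#' `system.file("extdata", "diets.yaml", package = "swinedigest")` mirrors the
#' three trial formulations (30% test-ingredient inclusion; 96.9% corn basal
#' diet; N-free diet).
#'
#' @param path YAML file path.
#' @return Nested named list: experiment -> diet name -> [diet_spec].
#' @export
read_diet_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(block) {
    out <- lapply(names(block), function(nm) {
      d <- block[[nm]]
      incl <- unlist(d$ingredients) / 100
      analyzed <- d$analyzed %||% list()
      if (!is.null(d$aa_pct)) analyzed$aa_pct <- unlist(d$aa_pct)
      diet_spec(name = nm, ingredients = incl,
                marker_ti_pct = d$marker_ti_pct %||% NA_real_,
                test_ingredient = d$test_ingredient, analyzed = analyzed)
    })
    names(out) <- names(block)
    out
  })
}

#' Packaged trial diet specifications
#' @return Nested list of [diet_spec] per experiment (see [read_diet_specs]).
#' @export
trial_diets <- function() {
  read_diet_specs(system.file("extdata", "diets.yaml",
                              package = "swinedigest", mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
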