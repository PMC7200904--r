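#' Margin of error of an observed in vivo mean
#'
#' Half-width of the two-sided Student-t confidence interval for the mean of
#' the per-pig estimates:
#' \deqn{m = t_{1-\alpha/2,\,n-1} \cdot s/\sqrt{n}}
#'
#' @param values Per-pig estimates (n >= 2).
#' @param level Confidence level (default 0.95).
#' @return Margin of error, in the units of `values`.
#' @export
#' @examples
#' margin_of_error(rep(5057, 9))  # 0: no variation
margin_of_error <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2) stop("margin of error needs n >= 2", call. = FALSE)
  stopifnot(level > 0, level < 1)
  stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(values) / sqrt(n)
}

#' Accuracy verdicts for energy predictions
#'
#' Classifies each predicted value against the in vivo observed mean: a
#' prediction is accurate ("within") when it falls inside the confidence
#' bounds `mean - margin` and `mean + margin`. The margin is taken as direct
#' input so that either [margin_of_error] output or published bounds can be
#' used verbatim. Rows are returned ranked by absolute signed error;
#' verdicts do not depend on the input order, and narrowing the margin can
#' only turn "within" into "outside".
#'
#' @param observed_mean In vivo observed mean, kcal/kg DM.
#' @param margin Margin of error, kcal/kg DM (>= 0).
#' @param predictions Tibble of prediction outcomes (from [predict_energy] /
#'   [predict_all]) or any data frame with `equation` and `predicted`
#'   columns; `NA` predictions get an `NA` verdict.
#' @return Tibble with one row per prediction: `equation`, `ingredient`,
#'   `observed_mean`, `margin`, `lower`, `upper`, `predicted`, `within`,
#'   `signed_error`, ordered by `abs(signed_error)`.
#' @export
assess_predictions <- function(observed_mean, margin, predictions) {
  if (margin < 0) stop("margin must be >= 0", call. = FALSE)
  stopifnot(all(c("equation", "predicted") %in% names(predictions)))
  lower <- observed_mean - margin
  upper <- observed_mean + margin
  out <- tibble::tibble(
    equation = predictions$equation,
    ingredient = if ("ingredient" %in% names(predictions))
      predictions$ingredient else NA_character_,
    observed_mean = observed_mean,
    margin = margin,
    lower = lower,
    upper = upper,
    predicted = predictions$predicted,
    within = predictions$predicted >= lower & predictions$predicted <= upper,
    signed_error = predictions$predicted - observed_mean
  )
  out[order(abs(out$signed_error)), ]
}
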