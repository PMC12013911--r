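#' Transform a response variable onto its analysis scale
#'
#' Behavioral durations and distances are analyzed on a variance-stabilized
#' scale: `log1p` (natural log of y + 1) for bounded duration data such as
#' post-contact immobility (0-600 s), `sqrt` for distance moved (0-144 cm),
#' or `none` for responses analyzed untransformed.
#'
#' @param values Numeric vector of raw responses. Must be non-negative for
#'   `log1p` and `sqrt`.
#' @param transform One of `"log1p"`, `"sqrt"`, `"none"`.
#' @return Numeric vector of the same length on the analysis scale.
#' @examples
#' transform_response(c(0, 600), "log1p")
#' transform_response(144, "sqrt")
#' @export
transform_response <- function(values, transform = c("log1p", "sqrt", "none")) {
  transform <- match.arg(transform)
  if (transform == "none") {
    return(values)
  }
  bad <- which(values < 0)
  if (length(bad) > 0L) {
    stop("negative response value at index ", bad[1L],
         " cannot be transformed with '", transform, "'")
  }
  switch(transform,
    log1p = log1p(values),
    sqrt  = sqrt(values)
  )
}

#' Invert an analysis-scale transform back to the raw response scale
#'
#' Used by the simulator, which generates on the analysis scale and reports
#' raw responses. Values that would map below zero are clipped to zero.
#'
#' @param values Numeric vector on the analysis scale.
#' @param transform One of `"log1p"`, `"sqrt"`, `"none"`.
#' @return Numeric vector on the raw scale.
#' @export
inverse_transform_response <- function(values, transform = c("log1p", "sqrt", "none")) {
  transform <- match.arg(transform)
  switch(transform,
    none  = values,
    log1p = expm1(pmax(values, 0)),
    sqrt  = pmax(values, 0)^2
  )
}

#' Declare how one outcome is modeled
#'
#' An outcome specification names the response family, the analysis-scale
#' transform (Gaussian families only), the random-effect terms, and the
#' reference treatment level. The treatment contrast reported by all fitting
#' functions is non-reference minus reference on the model scale.
#'
#' @param outcome_id Character label for the outcome.
#' @param family One of `"gaussian"` (transformed continuous response),
#'   `"binary_logit"` (repeated binary choices, logit link), or
#'   `"proportion_logit"` (successes out of trials, logit link).
#' @param transform Analysis-scale transform; only meaningful with
#'   `family = "gaussian"`.
#' @param random_terms Character vector, subset of `"unit_intercept"` and
#'   `"olre"`. An observation-level random effect (`"olre"`) is only valid
#'   with the proportion family, where it absorbs overdispersion.
#' @param treatment_reference Reference treatment level (contrasts are
#'   reported relative to it).
#' @return An object of class `outcome_spec`.
#' @examples
#' outcome_spec("pci_duration", "gaussian", transform = "log1p",
#'              treatment_reference = "control")
#' @export
outcome_spec <- function(outcome_id,
                         family = c("gaussian", "binary_logit", "proportion_logit"),
                         transform = c("none", "log1p", "sqrt"),
                         random_terms = character(),
                         treatment_reference = "control") {
  family <- match.arg(family)
  transform <- match.arg(transform)
  stopifnot(is.character(outcome_id), length(outcome_id) == 1L)
  if (length(random_terms) > 0L) {
    random_terms <- match.arg(random_terms, c("unit_intercept", "olre"),
                              several.ok = TRUE)
  }
  if (family != "gaussian" && transform != "none") {
    stop("transforms apply only to the gaussian family")
  }
  if ("olre" %in% random_terms && family != "proportion_logit") {
    stop("an observation-level random effect requires the proportion_logit family")
  }
  structure(
    list(outcome_id = outcome_id, family = family, transform = transform,
         random_terms = random_terms, treatment_reference = treatment_reference),
    class = "outcome_spec"
  )
}

#' @export
print.outcome_spec <- function(x, ...) {
  cat("Outcome spec '", x$outcome_id, "': family ", x$family, sep = "")
  if (x$transform != "none") cat(", transform ", x$transform, sep = "")
  if (length(x$random_terms)) {
    cat(", random terms: ", paste(x$random_terms, collapse = " + "), sep = "")
  }
  cat(", reference level '", x$treatment_reference, "'\n", sep = "")
  invisible(x)
}
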