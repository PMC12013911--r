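# Classification of replicate experiments against the pooled result.
#
# Three criteria, mirroring the published definitions:
#   P_sig  replicate significance status (p < 0.05) and, when both are
#          significant, sign agree with the overall pooled result (whose
#          significance is judged by its CI95 excluding 0)
#   P_cov  the replicate CI95 covers the pooled point estimate
#   P_acc  both of the above

is_negative_zero <- function(x) {
  is.numeric(x) & x == 0 & (1 / x) == -Inf
}

#' Does a confidence interval exclude zero?
#'
#' A closed-interval check: an interval with a bound exactly at 0 contains
#' 0. The one exception is an IEEE negative-zero bound, which arises when a
#' published bound printed as "-0.00" (negative before rounding) is parsed;
#' such a bound counts as strictly negative.
#'
#' @param ci_low,ci_high Interval bounds.
#' @return Logical.
#' @export
ci_excludes_zero <- function(ci_low, ci_high) {
  (ci_high < 0) | is_negative_zero(ci_high) | (ci_low > 0)
}

as_effect_row <- function(x) {
  if (inherits(x, "replicate_effect")) return(x)
  if (inherits(x, "meta_result")) {
    return(list(lab_id = "overall", outcome_id = x$outcome_id,
                estimate = x$mu, ci_low = x$ci_low, ci_high = x$ci_high,
                p_value = x$p_value))
  }
  as.list(x)
}

#' Classify one replicate against the pooled result
#'
#' @param rep A `replicate_effect` (or list/one-row data.frame with
#'   `lab_id`, `outcome_id`, `estimate`, `ci_low`, `ci_high`, `p_value`).
#' @param overall A `meta_result` (or list with `estimate`/`mu`, `ci_low`,
#'   `ci_high`) for the same outcome.
#' @param sig_level Replicate significance threshold (default 0.05); a
#'   p-value exactly at the threshold counts as non-significant.
#' @return A one-row `data.frame` (class `replicate_assessment`) with
#'   logical columns `sig_congruent`, `covered`, `accurate` plus the
#'   underlying significance flags and signs.
#' @export
classify_replicate <- function(rep, overall, sig_level = 0.05) {
  rep <- as_effect_row(rep)
  overall <- as_effect_row(overall)
  mu <- if (!is.null(overall$mu)) overall$mu else overall$estimate
  needed <- c("estimate", "ci_low", "ci_high", "p_value")
  miss <- needed[vapply(needed, function(f)
    is.null(rep[[f]]) || is.na(rep[[f]]), logical(1))]
  if (length(miss) > 0L) {
    stop("replicate is missing ", paste(miss, collapse = ", "))
  }
  if (!is.null(rep$outcome_id) && !is.null(overall$outcome_id) &&
      !is.na(overall$outcome_id) && rep$outcome_id != overall$outcome_id) {
    stop("outcome_id mismatch: replicate '", rep$outcome_id,
         "' vs overall '", overall$outcome_id, "'")
  }
  rep_sig <- rep$p_value < sig_level
  overall_sig <- ci_excludes_zero(overall$ci_low, overall$ci_high)
  rep_sign <- sign(rep$estimate)
  overall_sign <- sign(mu)
  sig_congruent <- (rep_sig == overall_sig) &&
    (!rep_sig || !overall_sig || rep_sign == overall_sign)
  covered <- rep$ci_low <= mu && mu <= rep$ci_high
  structure(
    data.frame(
      lab_id = rep$lab_id, outcome_id = rep$outcome_id,
      replicate_significant = rep_sig, replicate_sign = rep_sign,
      overall_significant = overall_sig, overall_sign = overall_sign,
      sig_congruent = sig_congruent, covered = covered,
      accurate = sig_congruent && covered,
      stringsAsFactors = FALSE),
    class = c("replicate_assessment", "data.frame")
  )
}

#' Classify every replicate of one outcome
#'
#' @param effects A `replicate_effects` list or `data.frame` of replicate
#'   rows for one outcome.
#' @param overall The pooled `meta_result` (or printed pooled row) for that
#'   outcome.
#' @param sig_level Replicate significance threshold (default 0.05).
#' @return A `data.frame` of assessments, one row per replicate.
#' @export
assess_replicates <- function(effects, overall, sig_level = 0.05) {
  if (inherits(effects, "replicate_effects")) {
    rows <- lapply(effects, classify_replicate, overall = overall,
                   sig_level = sig_level)
  } else {
    rows <- lapply(seq_len(nrow(effects)), function(i) {
      classify_replicate(effects[i, , drop = FALSE], overall,
                         sig_level = sig_level)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

frac <- function(num, den) {
  list(numerator = num, denominator = den,
       proportion = if (den > 0) num / den else NA_real_)
}

#' Aggregate replicate assessments into reproducibility proportions
#'
#' Computes P_sig, P_cov, and P_acc over the requested scope:
#' \describe{
#'   \item{`total`}{all lab-by-outcome replicates.}
#'   \item{`per_outcome`}{one summary per outcome, including the
#'     `cell_fraction` (check-marked cells over labs x 3 criteria).}
#'   \item{`significant_outcomes`}{restricted to outcomes whose overall
#'     pooled effect is significant.}
#' }
#'
#' @param assessments A `data.frame` of rows from [classify_replicate()].
#' @param scope `"total"`, `"per_outcome"`, or `"significant_outcomes"`.
#' @return For `per_outcome`, a `data.frame` with one row per outcome;
#'   otherwise a list of class `reproducibility_summary` with `p_sig`,
#'   `p_cov`, `p_acc` fractions (numerator, denominator, proportion) and
#'   the underlying grid.
#' @export
summarize_reproducibility <- function(assessments,
                                      scope = c("total", "per_outcome",
                                                "significant_outcomes")) {
  scope <- match.arg(scope)
  if (is.null(assessments) || nrow(assessments) == 0L) {
    stop("no assessments to summarize")
  }
  stopifnot(all(assessments$accurate ==
                (assessments$sig_congruent & assessments$covered)))
  if (scope == "significant_outcomes") {
    assessments <- assessments[assessments$overall_significant, , drop = FALSE]
    if (nrow(assessments) == 0L) stop("no significant outcomes in scope")
  }
  if (scope == "per_outcome") {
    out <- do.call(rbind, lapply(split(assessments, assessments$outcome_id),
      function(a) {
        n <- nrow(a)
        data.frame(
          outcome_id = a$outcome_id[1L],
          n_replicates = n,
          p_sig = sum(a$sig_congruent) / n,
          p_cov = sum(a$covered) / n,
          p_acc = sum(a$accurate) / n,
          cell_fraction = sum(a$sig_congruent, a$covered, a$accurate) / (3 * n),
          stringsAsFactors = FALSE
        )
      }))
    rownames(out) <- NULL
    return(out)
  }
  n <- nrow(assessments)
  structure(
    list(scope = scope,
         p_sig = frac(sum(assessments$sig_congruent), n),
         p_cov = frac(sum(assessments$covered), n),
         p_acc = frac(sum(assessments$accurate), n),
         cell_fraction = frac(
           sum(assessments$sig_congruent, assessments$covered,
               assessments$accurate), 3L * n),
         grid = assessments),
    class = "reproducibility_summary"
  )
}

#' @export
print.reproducibility_summary <- function(x, ...) {
  fmt <- function(f) sprintf("%d/%d (%.0f%%)", f$numerator, f$denominator,
                             100 * f$proportion)
  cat("Reproducibility summary (scope: ", x$scope, ")\n", sep = "")
  cat("  P_sig:", fmt(x$p_sig), "  P_cov:", fmt(x$p_cov),
      "  P_acc:", fmt(x$p_acc), "\n")
  invisible(x)
}

#' Render assessments as a check-mark grid
#'
#' One row per lab-by-outcome replicate with check (TRUE) / cross (FALSE)
#' cells per criterion, suitable for delimited-text export.
#'
#' @param assessments A `data.frame` of rows from [classify_replicate()].
#' @return A `data.frame` with columns `outcome_id`, `lab_id`,
#'   `sig_congruent`, `covered`, `accurate`.
#' @export
assessment_grid <- function(assessments) {
  assessments[order(assessments$outcome_id, assessments$lab_id),
              c("outcome_id", "lab_id", "sig_congruent", "covered",
                "accurate")]
}
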