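# Random-effects meta-analysis across laboratories.
#
# Replicate effects enter as (estimate, se) pairs. The variance_interpretation
# flag controls how the SE column becomes the sampling variance v_i:
#   se_squared     v_i = se^2   (statistically correct; default for new work)
#   se_as_variance v_i = se     (reproduces the published pooled rows, which
#                                are only recovered when the printed SE column
#                                enters the pooling as the variances)

effects_to_yv <- function(effects, variance_interpretation) {
  if (inherits(effects, "replicate_effects")) {
    effects <- as.data.frame(effects)
  }
  stopifnot(is.data.frame(effects),
            all(c("estimate", "se") %in% names(effects)))
  if (any(effects$se <= 0)) stop("all standard errors must be > 0")
  v <- switch(variance_interpretation,
    se_squared     = effects$se^2,
    se_as_variance = effects$se,
    stop("variance_interpretation must be 'se_squared' or 'se_as_variance'"))
  list(y = effects$estimate, v = v)
}

#' DerSimonian-Laird estimate of the between-replicate variance
#'
#' Closed-form moment estimator
#' `tau2 = max(0, (Q - (k - 1)) / C)` with fixed-effect weights
#' `w_i = 1 / v_i`, `Q = sum w_i (y_i - ybar_w)^2`, and
#' `C = sum(w) - sum(w^2) / sum(w)`.
#'
#' @param effects A `replicate_effects` list or a `data.frame` with columns
#'   `estimate` and `se` (k >= 2 rows).
#' @param variance_interpretation `"se_squared"` (v = se^2) or
#'   `"se_as_variance"` (v = se); see Details in [pool_random_effects()].
#' @return The non-negative scalar tau-squared.
#' @export
estimate_tau2_dl <- function(effects,
                             variance_interpretation = c("se_squared",
                                                         "se_as_variance")) {
  variance_interpretation <- match.arg(variance_interpretation)
  yv <- effects_to_yv(effects, variance_interpretation)
  k <- length(yv$y)
  if (k < 2L) stop("need at least two replicates")
  w <- 1 / yv$v
  ybar <- sum(w * yv$y) / sum(w)
  q <- sum(w * (yv$y - ybar)^2)
  c_w <- sum(w) - sum(w^2) / sum(w)
  max(0, (q - (k - 1)) / c_w)
}

reml_loglik <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
}

#' REML estimate of the between-replicate variance
#'
#' Maximizes the restricted log-likelihood
#' `-1/2 [ sum log(v_i + tau2) + log sum w_i + sum w_i (y_i - mu_hat)^2 ]`,
#' `w_i = 1 / (v_i + tau2)`, by bounded one-dimensional optimization on
#' `[0, upper]` with `upper = max(100 * max(v), 10 * var(y))`, tolerance
#' 1e-8. A boundary solution collapses to exactly 0.
#'
#' @inheritParams estimate_tau2_dl
#' @return The non-negative scalar tau-squared.
#' @export
estimate_tau2_reml <- function(effects,
                               variance_interpretation = c("se_squared",
                                                           "se_as_variance")) {
  variance_interpretation <- match.arg(variance_interpretation)
  yv <- effects_to_yv(effects, variance_interpretation)
  if (length(yv$y) < 2L) stop("need at least two replicates")
  upper <- max(100 * max(yv$v), 10 * stats::var(yv$y), 1e-3)
  opt <- optimize(reml_loglik, c(0, upper), y = yv$y, v = yv$v,
                  maximum = TRUE, tol = 1e-8)
  tau2 <- opt$maximum
  # optimize() cannot land exactly on the boundary; snap when the boundary
  # is at least as good.
  if (reml_loglik(0, yv$y, yv$v) >= opt$objective) tau2 <- 0
  tau2
}

#' Pool replicate effects with a random-effects meta-analysis
#'
#' Inverse-variance pooling with between-replicate heterogeneity:
#' `mu = sum(w_i y_i) / sum(w_i)` with `w_i = 1 / (v_i + tau2)`,
#' `se_mu = sqrt(1 / sum w_i)`, Wald-z CI95 and p-value, and Cochran's Q
#' from fixed-effect weights. tau2 comes from REML (default) or the
#' DerSimonian-Laird moment estimator.
#'
#' `variance_interpretation` deserves care: the published pooled rows this
#' package reproduces are only recovered when each replicate's printed SE
#' enters directly as its sampling variance (`"se_as_variance"`); the
#' statistically conventional choice for new analyses is `"se_squared"`.
#' Results always record which mode produced them.
#'
#' @param effects A `replicate_effects` list or a `data.frame` with columns
#'   `estimate` and `se` (and optionally `outcome_id`, `lab_id`).
#' @param method `"reml"` or `"dl"`.
#' @param variance_interpretation `"se_squared"` or `"se_as_variance"`.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `meta_result` with elements `mu`, `se_mu`,
#'   `ci_low`, `ci_high`, `p_value`, `tau2`, `q_stat`, `k`, `method`,
#'   `variance_interpretation`, `outcome_id`.
#' @examples
#' eff <- data.frame(estimate = c(0, 2), se = c(1, 1))
#' pool_random_effects(eff, method = "dl")
#' @export
pool_random_effects <- function(effects,
                                method = c("reml", "dl"),
                                variance_interpretation = c("se_squared",
                                                            "se_as_variance"),
                                conf_level = 0.95) {
  method <- match.arg(method)
  variance_interpretation <- match.arg(variance_interpretation)
  if (inherits(effects, "replicate_effects")) effects <- as.data.frame(effects)
  outcome_id <- NA_character_
  if (is.data.frame(effects) && "outcome_id" %in% names(effects)) {
    ids <- unique(effects$outcome_id)
    if (length(ids) > 1L) {
      stop("effects mix outcome_ids: ", paste(ids, collapse = ", "))
    }
    outcome_id <- ids
  }
  yv <- effects_to_yv(effects, variance_interpretation)
  k <- length(yv$y)
  if (k < 2L) stop("need at least two replicates")
  tau2 <- switch(method,
    reml = estimate_tau2_reml(effects, variance_interpretation),
    dl   = estimate_tau2_dl(effects, variance_interpretation))
  w <- 1 / (yv$v + tau2)
  mu <- sum(w * yv$y) / sum(w)
  se_mu <- sqrt(1 / sum(w))
  z <- qnorm(1 - (1 - conf_level) / 2)
  w_fe <- 1 / yv$v
  ybar_fe <- sum(w_fe * yv$y) / sum(w_fe)
  q <- sum(w_fe * (yv$y - ybar_fe)^2)
  structure(
    list(outcome_id = outcome_id, mu = mu, se_mu = se_mu,
         ci_low = mu - z * se_mu, ci_high = mu + z * se_mu,
         p_value = 2 * pnorm(-abs(mu / se_mu)),
         tau2 = tau2, q_stat = q, k = k, method = method,
         variance_interpretation = variance_interpretation),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Random-effects meta-analysis (%s, %s), k = %d\n",
              toupper(x$method), x$variance_interpretation, x$k))
  if (!is.na(x$outcome_id)) cat("  outcome:", x$outcome_id, "\n")
  cat(sprintf("  pooled effect %.4f (SE %.4f), CI95 [%.4f, %.4f], p = %.4g\n",
              x$mu, x$se_mu, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  tau2 = %.4f, Q = %.4f\n", x$tau2, x$q_stat))
  invisible(x)
}
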