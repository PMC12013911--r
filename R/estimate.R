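#' @importFrom stats anova as.formula coef cor lm logLik pchisq pnorm pt
#'   qnorm qt quantile residuals rbinom rnorm runif sd setNames vcov
#'   df.residual optimize wilcox.test cor.test
NULL

new_replicate_effect <- function(lab_id, outcome_id, estimate, se,
                                 ci_low, ci_high, p_value, inference,
                                 n_units, variance_components = numeric(),
                                 degenerate = FALSE, convergence = "converged") {
  structure(
    list(lab_id = lab_id, outcome_id = outcome_id,
         estimate = estimate, se = se, ci_low = ci_low, ci_high = ci_high,
         p_value = p_value, inference = inference, n_units = n_units,
         variance_components = variance_components,
         degenerate = degenerate, convergence = convergence),
    class = "replicate_effect"
  )
}

#' @export
print.replicate_effect <- function(x, ...) {
  cat(sprintf("Replicate effect [%s / %s]: %.4f (SE %.4f), CI95 [%.4f, %.4f], p = %.4g (%s)\n",
              x$lab_id, x$outcome_id, x$estimate, x$se, x$ci_low, x$ci_high,
              x$p_value, x$inference))
  if (x$degenerate) cat("  NOTE: degenerate fit (zero residual variance); CI and p unreliable\n")
  invisible(x)
}

#' Collect replicate effects into a data frame
#'
#' @param x A list of `replicate_effect` objects (class `replicate_effects`)
#'   as returned by [estimate_replicates()].
#' @param ... Unused.
#' @return A `data.frame` with one row per replicate.
#' @export
as.data.frame.replicate_effects <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) {
    data.frame(lab_id = r$lab_id, outcome_id = r$outcome_id,
               estimate = r$estimate, se = r$se,
               ci_low = r$ci_low, ci_high = r$ci_high,
               p_value = r$p_value, inference = r$inference,
               n_units = r$n_units, stringsAsFactors = FALSE)
  }))
}

check_two_levels <- function(table, spec) {
  levs <- unique(table$treatment)
  if (length(levs) != 2L) {
    stop("expected exactly two treatment levels, found: ",
         paste(levs, collapse = ", "))
  }
  if (!spec$treatment_reference %in% levs) {
    stop("reference level '", spec$treatment_reference,
         "' absent from the data (levels: ", paste(levs, collapse = ", "), ")")
  }
  factor(table$treatment,
         levels = c(spec$treatment_reference,
                    setdiff(levs, spec$treatment_reference)))
}

#' Fit a two-group Gaussian model for one replicate
#'
#' Ordinary least squares of the transformed response on a treatment
#' indicator; the reported contrast is non-reference minus reference on the
#' transformed scale, with CI and p-value from the t distribution on the
#' residual degrees of freedom.
#'
#' @param table Observation `data.frame` for a single lab with columns
#'   `lab_id`, `unit_id`, `treatment`, `response`.
#' @param spec An [outcome_spec()] with `family = "gaussian"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A `replicate_effect`.
#' @export
fit_gaussian_model <- function(table, spec, conf_level = 0.95) {
  stopifnot(inherits(spec, "outcome_spec"), spec$family == "gaussian")
  lab <- unique(table$lab_id)
  if (length(lab) != 1L) stop("fit one lab at a time; got labs: ",
                              paste(lab, collapse = ", "))
  trt <- check_two_levels(table, spec)
  if (min(table(trt)) < 2L) stop("need >= 2 units per treatment level")
  y <- transform_response(table$response, spec$transform)
  fit <- lm(y ~ trt)
  est <- unname(coef(fit)[2L])
  # a perfect fit triggers a summary() warning; the degenerate flag covers it
  smry <- suppressWarnings(summary(fit))
  s <- smry$coefficients
  df <- df.residual(fit)
  degenerate <- smry$sigma < sqrt(.Machine$double.eps)
  if (degenerate) {
    se <- 0; ci <- c(est, est); p <- NA_real_
  } else {
    se <- s[2L, 2L]
    tcrit <- qt(1 - (1 - conf_level) / 2, df)
    ci <- est + c(-1, 1) * tcrit * se
    p <- 2 * pt(-abs(est / se), df)
  }
  new_replicate_effect(lab, spec$outcome_id, est, se, ci[1L], ci[2L], p,
                       inference = "t_residual_df",
                       n_units = length(unique(table$unit_id)),
                       degenerate = degenerate)
}

glmer_quietly <- function(expr) {
  msgs <- character()
  fit <- withCallingHandlers(
    expr,
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  list(fit = fit, messages = msgs)
}

wald_effect <- function(fit, lab, outcome_id, n_units, conf_level, messages) {
  fe <- lme4::fixef(fit)
  est <- unname(fe[2L])
  se <- sqrt(vcov(fit)[2L, 2L])
  z <- qnorm(1 - (1 - conf_level) / 2)
  vc <- as.data.frame(lme4::VarCorr(fit))
  new_replicate_effect(
    lab, outcome_id, est, se, est - z * se, est + z * se,
    2 * pnorm(-abs(est / se)), inference = "wald_z", n_units = n_units,
    variance_components = setNames(vc$vcov, vc$grp),
    convergence = if (length(messages)) paste(messages, collapse = "; ")
                  else "converged"
  )
}

#' Fit a logistic mixed model for one replicate
#'
#' Logistic regression of repeated binary choices on treatment with a
#' unit-level (individual) random intercept, fitted by the Laplace
#' approximation (lme4). Only scorable rows with a non-missing response
#' enter the fit. CI and p-value are Wald-z.
#'
#' @param table Observation `data.frame` for a single lab with columns
#'   `unit_id`, `treatment`, `response` (0/1), `scorable`.
#' @param spec An [outcome_spec()] with `family = "binary_logit"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A `replicate_effect`; its `variance_components` carry the
#'   estimated unit-intercept variance.
#' @export
fit_logistic_mixed_model <- function(table, spec, conf_level = 0.95) {
  stopifnot(inherits(spec, "outcome_spec"), spec$family == "binary_logit")
  lab <- unique(table$lab_id)
  if (length(lab) != 1L) stop("fit one lab at a time")
  d <- table[table$scorable & !is.na(table$response), , drop = FALSE]
  if (length(unique(d$unit_id)) < 2L) {
    stop("need at least two units with scorable observations")
  }
  d$trt <- check_two_levels(d, spec)
  means <- tapply(d$response, d$trt, mean)
  if (any(means %in% c(0, 1))) {
    stop("complete separation: a treatment level has all-0 or all-1 ",
         "responses; consider a penalized fit")
  }
  res <- glmer_quietly(
    lme4::glmer(response ~ trt + (1 | unit_id), data = d,
                family = stats::binomial())
  )
  wald_effect(res$fit, lab, spec$outcome_id,
              length(unique(d$unit_id)), conf_level, res$messages)
}

#' Fit a binomial proportion mixed model for one replicate
#'
#' Binomial-logit model of per-dish counts (`successes` out of `trials`)
#' on treatment with a dish random intercept and, when the spec requests
#' it, an observation-level random effect (OLRE, one level per row) that
#' absorbs overdispersion. Fitted by the Laplace approximation (lme4);
#' Wald-z CI and p-value.
#'
#' @param table Observation `data.frame` for a single lab with columns
#'   `unit_id`, `treatment`, `successes`, `trials`.
#' @param spec An [outcome_spec()] with `family = "proportion_logit"`;
#'   include `"olre"` in `random_terms` for the overdispersion term.
#' @param conf_level Confidence level (default 0.95).
#' @return A `replicate_effect`.
#' @export
fit_proportion_mixed_model <- function(table, spec, conf_level = 0.95) {
  stopifnot(inherits(spec, "outcome_spec"),
            spec$family == "proportion_logit")
  lab <- unique(table$lab_id)
  if (length(lab) != 1L) stop("fit one lab at a time")
  d <- table[table$trials > 0L, , drop = FALSE]
  if (nrow(d) == 0L) stop("all rows have zero trials")
  if (any(d$successes > d$trials)) stop("successes exceed trials")
  d$trt <- check_two_levels(d, spec)
  d$.obs <- factor(seq_len(nrow(d)))
  form <- if ("olre" %in% spec$random_terms) {
    cbind(successes, trials - successes) ~ trt + (1 | unit_id) + (1 | .obs)
  } else {
    cbind(successes, trials - successes) ~ trt + (1 | unit_id)
  }
  res <- glmer_quietly(
    lme4::glmer(form, data = d, family = stats::binomial())
  )
  opt <- res$fit@optinfo
  if (!is.null(opt$conv$opt) && opt$conv$opt != 0) {
    stop("mixed-model fit did not converge (optimizer code ", opt$conv$opt, ")")
  }
  wald_effect(res$fit, lab, spec$outcome_id,
              length(unique(d$unit_id)), conf_level, res$messages)
}

#' Estimate the treatment effect in every laboratory
#'
#' Splits an observation table by lab and fits the model named by the
#' outcome spec in each, returning one [new_replicate_effect] per lab.
#'
#' @param table Observation `data.frame` possibly spanning several labs.
#' @param spec An [outcome_spec()].
#' @param conf_level Confidence level (default 0.95).
#' @return A list of `replicate_effect`s (class `replicate_effects`);
#'   convert with [as.data.frame.replicate_effects()].
#' @export
estimate_replicates <- function(table, spec, conf_level = 0.95) {
  fitter <- switch(spec$family,
    gaussian         = fit_gaussian_model,
    binary_logit     = fit_logistic_mixed_model,
    proportion_logit = fit_proportion_mixed_model)
  labs <- sort(unique(table$lab_id))
  out <- lapply(labs, function(l) {
    fitter(table[table$lab_id == l, , drop = FALSE], spec, conf_level)
  })
  structure(out, class = "replicate_effects", names = labs)
}

#' Pearson overdispersion ratio of a binomial fit
#'
#' The ratio of the sum of squared Pearson residuals to the residual
#' degrees of freedom; values near 1 indicate the binomial variance is
#' adequate, values well above 1 indicate overdispersion (motivating an
#' observation-level random effect). The p-value is the chi-square upper
#' tail of the Pearson statistic on the residual df.
#'
#' @param fit A fitted binomial model (`glm` or `glmerMod`).
#' @return A `test_result` with `statistic_name = "dispersion_ratio"`.
#' @export
overdispersion_ratio <- function(fit) {
  r <- residuals(fit, type = "pearson")
  rdf <- df.residual(fit)
  if (rdf <= 0) stop("residual degrees of freedom must be positive")
  stat <- sum(r^2)
  new_test_result("dispersion_ratio", stat / rdf, df = rdf,
                  p_value = pchisq(stat, rdf, lower.tail = FALSE))
}

new_test_result <- function(statistic_name, value, df = NA_real_, p_value,
                            alternative = "two.sided") {
  structure(
    list(statistic_name = statistic_name, value = value, df = df,
         p_value = p_value, alternative = alternative),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s = %.4g", x$statistic_name, x$value))
  if (!is.na(x$df)) cat(sprintf(" (df = %g)", x$df))
  cat(sprintf(", p = %.4g (%s)\n", x$p_value, x$alternative))
  invisible(x)
}

#' Two-sample rank-sum test
#'
#' Mann-Whitney/Wilcoxon rank-sum comparison of two independent samples.
#' The reported W is the number of (a, b) pairs with a > b plus half the
#' number of ties. The two-sided p-value is exact (enumeration) when the
#' combined sample size is at most 20 and the data are tie-free, otherwise
#' a normal approximation with mid-rank tie correction and continuity
#' correction is used.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @return A `test_result` with `statistic_name = "W"`.
#' @export
rank_sum_test <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- (length(group_a) + length(group_b) <= 20L) && !ties
  wt <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = exact, correct = TRUE,
                alternative = "two.sided")
  )
  new_test_result("W", unname(wt$statistic), p_value = wt$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks with a two-sided p-value from the t
#' approximation.
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @return A `test_result` with `statistic_name = "rho"`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) stop("correlation undefined for constant input")
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = FALSE,
             alternative = "two.sided")
  )
  new_test_result("rho", unname(ct$estimate), p_value = ct$p.value)
}

#' Likelihood-ratio test for the treatment-by-laboratory interaction
#'
#' Fits the pooled data (all labs) with laboratory and treatment as fixed
#' effects, with and without their interaction, using the same family
#' machinery as the per-lab fits (ML throughout), and reports
#' `2 * (logLik_full - logLik_reduced)` against the chi-square distribution.
#' A significant interaction means the treatment effect is idiosyncratic to
#' the laboratory — the pipeline's consistency check.
#'
#' @param pooled_table Observation `data.frame` spanning >= 2 labs.
#' @param spec An [outcome_spec()].
#' @return A `test_result` with `statistic_name = "chi2"` and
#'   `df = (n_labs - 1)` for a two-level treatment.
#' @export
interaction_lrt <- function(pooled_table, spec) {
  labs <- unique(pooled_table$lab_id)
  if (length(labs) < 2L) stop("need >= 2 labs for the interaction test")
  for (l in labs) {
    if (length(unique(pooled_table$treatment[pooled_table$lab_id == l])) < 2L) {
      stop("lab ", l, " has a single treatment level; design is singular")
    }
  }
  d <- pooled_table
  d$trt <- check_two_levels(d, spec)
  d$lab <- factor(d$lab_id)
  if (spec$family == "gaussian") {
    d$y <- transform_response(d$response, spec$transform)
    full <- lm(y ~ trt * lab, data = d)
    red  <- lm(y ~ trt + lab, data = d)
    stat <- 2 * (as.numeric(logLik(full)) - as.numeric(logLik(red)))
    df <- length(coef(full)) - length(coef(red))
  } else {
    if (spec$family == "binary_logit") {
      d <- d[d$scorable & !is.na(d$response), , drop = FALSE]
      lhs <- "response"
    } else {
      d <- d[d$trials > 0L, , drop = FALSE]
      d$.obs <- factor(seq_len(nrow(d)))
      lhs <- "cbind(successes, trials - successes)"
    }
    re <- "(1 | unit_id)"
    if ("olre" %in% spec$random_terms) re <- paste(re, "+ (1 | .obs)")
    f_full <- as.formula(paste(lhs, "~ trt * lab +", re))
    f_red  <- as.formula(paste(lhs, "~ trt + lab +", re))
    full <- glmer_quietly(lme4::glmer(f_full, data = d,
                                      family = stats::binomial()))$fit
    red  <- glmer_quietly(lme4::glmer(f_red, data = d,
                                      family = stats::binomial()))$fit
    stat <- 2 * (as.numeric(logLik(full)) - as.numeric(logLik(red)))
    df <- length(lme4::fixef(full)) - length(lme4::fixef(red))
  }
  stat <- max(stat, 0)
  new_test_result("chi2", stat, df = df,
                  p_value = pchisq(stat, df, lower.tail = FALSE))
}
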