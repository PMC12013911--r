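make_gaussian_table <- function(control, treated, lab = "lab_01",
                                outcome = "toy") {
  n1 <- length(control); n2 <- length(treated)
  data.frame(
    lab_id = lab, outcome_id = outcome,
    unit_id = sprintf("%s_u%02d", lab, seq_len(n1 + n2)),
    treatment = rep(c("control", "treated"), c(n1, n2)),
    timepoint = 1L, response = c(control, treated), scorable = TRUE,
    stringsAsFactors = FALSE)
}

toy_spec <- outcome_spec("toy", "gaussian", transform = "none",
                         treatment_reference = "control")

test_that("gaussian fit matches the closed-form two-sample t oracle", {
  # identical groups -> zero contrast
  eff0 <- fit_gaussian_model(make_gaussian_table(c(1, 2, 3), c(1, 2, 3)),
                             toy_spec)
  expect_equal(eff0$estimate, 0)

  oracle <- two_group_t_oracle(c(1, 2, 3), c(2, 3, 4))
  eff <- fit_gaussian_model(make_gaussian_table(c(1, 2, 3), c(2, 3, 4)),
                            toy_spec)
  expect_equal(eff$estimate, 1.0, tolerance = 1e-12)
  expect_equal(eff$se, 0.8165, tolerance = 1e-4)
  expect_equal(eff$se, oracle$se, tolerance = 1e-12)
  expect_equal(eff$p_value, oracle$p, tolerance = 1e-12)
  expect_equal(eff$p_value, 0.287866, tolerance = 1e-5)
  expect_equal(eff$inference, "t_residual_df")
  # CI brackets the estimate
  expect_true(eff$ci_low <= eff$estimate && eff$estimate <= eff$ci_high)
})

test_that("gaussian contrast is shift-invariant and sign-flips with reference", {
  set.seed(14)
  ctl <- rnorm(20, 5); trt <- rnorm(20, 4)
  base <- fit_gaussian_model(make_gaussian_table(ctl, trt), toy_spec)
  shifted <- fit_gaussian_model(make_gaussian_table(ctl + 7, trt + 7),
                                toy_spec)
  expect_equal(base$estimate, shifted$estimate, tolerance = 1e-10)
  expect_equal(base$se, shifted$se, tolerance = 1e-10)

  flipped_spec <- outcome_spec("toy", "gaussian", transform = "none",
                               treatment_reference = "treated")
  flipped <- fit_gaussian_model(make_gaussian_table(ctl, trt), flipped_spec)
  expect_equal(flipped$estimate, -base$estimate, tolerance = 1e-10)
  expect_equal(flipped$ci_low, -base$ci_high, tolerance = 1e-10)
  expect_equal(flipped$ci_high, -base$ci_low, tolerance = 1e-10)
  expect_equal(flipped$p_value, base$p_value, tolerance = 1e-10)
})

test_that("zero residual variance yields the estimate with degenerate inference", {
  eff <- fit_gaussian_model(make_gaussian_table(c(1, 1, 1), c(2, 2, 2)),
                            toy_spec)
  expect_equal(eff$estimate, 1)
  expect_true(eff$degenerate)
  expect_true(is.na(eff$p_value))
})

test_that("logistic mixed fit at the zero-variance boundary equals plain GLM", {
  cfg <- simulation_config("binary_repeated_choice", n_labs = 1,
                           units_per_group_per_lab = 25, alpha = 0.3,
                           beta = 0.6, unit_re_sd = 0, n_timepoints = 12,
                           availability_prob = 1, transform = "none",
                           treatment_levels = c("brown", "green"), seed = 3)
  tab <- simulate_experiment(cfg)
  spec <- outcome_spec("binary_choice", "binary_logit",
                       random_terms = "unit_intercept",
                       treatment_reference = "brown")
  eff <- fit_logistic_mixed_model(tab, spec)
  expect_equal(unname(eff$variance_components["unit_id"]), 0,
               tolerance = 1e-8)
  ref <- glm(response ~ factor(treatment, c("brown", "green")),
             data = tab, family = binomial())
  expect_equal(eff$estimate, unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(eff$se, sqrt(vcov(ref)[2, 2]), tolerance = 1e-5)
})

test_that("complete separation and single-unit inputs are rejected", {
  d <- data.frame(lab_id = "lab_01", outcome_id = "x",
                  unit_id = rep(c("u1", "u2", "u3", "u4"), each = 5),
                  treatment = rep(c("brown", "green"), each = 10),
                  timepoint = rep(1:5, 4),
                  response = rep(c(0L, 1L), each = 10), scorable = TRUE,
                  stringsAsFactors = FALSE)
  spec <- outcome_spec("x", "binary_logit", random_terms = "unit_intercept",
                       treatment_reference = "brown")
  expect_error(fit_logistic_mixed_model(d, spec), "separation")
  d1 <- d[d$unit_id == "u1", ]
  expect_error(fit_logistic_mixed_model(d1, spec), "two units")
})

test_that("proportion mixed fit at the zero-variance boundary equals binomial GLM", {
  cfg <- simulation_config("dish_proportion", n_labs = 1,
                           units_per_group_per_lab = 40, alpha = -0.2,
                           beta = 0.5, unit_re_sd = 0, olre_sd = 0,
                           n_timepoints = 10, availability_prob = 1,
                           transform = "none", group_size = 3,
                           treatment_levels = c("larvae", "adult"), seed = 8)
  tab <- simulate_experiment(cfg)
  spec <- outcome_spec("dish_proportion", "proportion_logit",
                       random_terms = "unit_intercept",
                       treatment_reference = "larvae")
  eff <- fit_proportion_mixed_model(tab, spec)
  expect_equal(unname(eff$variance_components["unit_id"]), 0,
               tolerance = 1e-8)
  ref <- glm(cbind(successes, trials - successes) ~
               factor(treatment, c("larvae", "adult")),
             data = tab, family = binomial())
  expect_equal(eff$estimate, unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(eff$se, sqrt(vcov(ref)[2, 2]), tolerance = 1e-6)
  # all-zero trials is an error
  tab0 <- tab; tab0$trials <- 0L
  expect_error(fit_proportion_mixed_model(tab0, spec), "zero trials")
})

test_that("overdispersion ratio is 0 for a saturated fit and calibrated under the null", {
  d <- data.frame(g = rep(c("a", "b"), each = 2),
                  s = c(2L, 2L, 3L, 3L), n = 4L)
  sat <- glm(cbind(s, n - s) ~ g, data = d, family = binomial())
  expect_equal(overdispersion_ratio(sat)$value, 0, tolerance = 1e-10)

  # correctly specified binomial data -> mean ratio ~ 1
  set.seed(77)
  ratios <- replicate(200, {
    x <- rep(0:1, each = 30)
    s <- rbinom(60, 5, plogis(-0.2 + 0.5 * x))
    overdispersion_ratio(
      glm(cbind(s, 5 - s) ~ x, family = binomial()))$value
  })
  expect_lt(abs(mean(ratios) - 1), 0.1)

  # latent observation-level noise omitted from the fit -> inflated ratio
  set.seed(78)
  ratios_od <- replicate(50, {
    x <- rep(0:1, each = 30)
    s <- rbinom(60, 5, plogis(-0.2 + 0.5 * x + rnorm(60, 0, 1)))
    overdispersion_ratio(
      glm(cbind(s, 5 - s) ~ x, family = binomial()))$value
  })
  expect_gt(mean(ratios_od), 1.2)
})

test_that("rank-sum W follows the pairwise-count convention with exact small-sample p", {
  expect_equal(rank_sum_test(c(3, 4), c(1, 2))$value, 4)
  expect_equal(rank_sum_test(c(1, 2), c(3, 4))$value, 0)

  # interleaved samples: W = 3; exact two-sided p = 0.7 by enumeration of
  # all 20 group assignments (2 * P(W <= 3) = 2 * 7/20)
  en <- rank_sum_enumeration(c(1, 3, 5), c(2, 4, 6))
  r <- rank_sum_test(c(1, 3, 5), c(2, 4, 6))
  expect_equal(r$value, 3)
  expect_equal(en$W, 3)
  expect_equal(r$p_value, 0.7)
  expect_equal(en$p, 0.7)

  # exact route agrees with enumeration on random tie-free data
  set.seed(5)
  for (i in 1:10) {
    a <- sample(100, 6); b <- setdiff(sample(100, 14), a)[1:6]
    en <- rank_sum_enumeration(a, b)
    r <- rank_sum_test(a, b)
    expect_equal(r$value, en$W)
    expect_equal(r$p_value, en$p, tolerance = 1e-12)
  }
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("rank-sum complement identity holds: W(a,b) + W(b,a) = n_a n_b", {
  set.seed(6)
  for (i in 1:20) {
    a <- rnorm(sample(3:40, 1))
    b <- rnorm(sample(3:40, 1))
    expect_equal(rank_sum_test(a, b)$value + rank_sum_test(b, a)$value,
                 length(a) * length(b))
  }
})

test_that("spearman correlation handles monotone and constant inputs", {
  expect_equal(spearman_correlation(1:3, 3:1)$value, -1)
  expect_equal(spearman_correlation(1:3, 1:3)$value, 1)
  set.seed(8)
  x <- rnorm(50); y <- -x + rnorm(50, 0, 0.3)
  r <- spearman_correlation(x, y)
  expect_lt(r$value, -0.8)
  expect_lt(r$p_value, 1e-6)
  # agrees with the mid-rank Pearson definition
  expect_equal(r$value, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
})

test_that("interaction LRT is zero for duplicated labs and matches the RSS oracle", {
  set.seed(33)
  one <- make_gaussian_table(rnorm(15, 5), rnorm(15, 4), lab = "lab_01")
  two <- one
  two$lab_id <- "lab_02"
  two$unit_id <- sub("lab_01", "lab_02", two$unit_id)
  dup <- rbind(one, two)
  lrt0 <- interaction_lrt(dup, toy_spec)
  expect_lt(abs(lrt0$value), 1e-6)

  # balanced two-lab toy vs closed-form RSS likelihood ratio
  set.seed(34)
  labA <- make_gaussian_table(rnorm(12, 5), rnorm(12, 4.2), lab = "lab_01")
  labB <- make_gaussian_table(rnorm(12, 5.5), rnorm(12, 3.1), lab = "lab_02")
  labB$unit_id <- sub("lab_01", "lab_02", labB$unit_id)
  pooled <- rbind(labA, labB)
  lrt <- interaction_lrt(pooled, toy_spec)
  oracle <- balanced_lrt_oracle(pooled$response, pooled$treatment,
                                pooled$lab_id)
  expect_equal(lrt$value, oracle, tolerance = 1e-8)
  expect_equal(lrt$df, 1)

  # a lab with a single treatment level is a singular design
  broken <- pooled[!(pooled$lab_id == "lab_02" &
                       pooled$treatment == "treated"), ]
  expect_error(interaction_lrt(broken, toy_spec), "lab_02")
})
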