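# Independent oracles used by the test suite. Everything here is written
# from first principles and shares no code with the package's fitting
# routines.

# Gauss-Hermite nodes/weights via the Golub-Welsch eigenvalue construction
# (weight function exp(-x^2)).
gauss_hermite_rule <- function(n) {
  J <- matrix(0, n, n)
  i <- seq_len(n - 1L)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1L, ord]^2)
}

# Adaptive Gauss-Hermite marginal log-likelihood for a random-intercept
# logistic model: y_it ~ Bernoulli(plogis(b0 + b1 x_i + u_i)),
# u_i ~ N(0, sigma^2). One quadrature grid per unit, centered at the
# conditional mode with the Laplace scale.
agq_logistic_loglik <- function(par, y, x, unit, rule) {
  b0 <- par[1L]; b1 <- par[2L]; sigma <- exp(par[3L])
  ll <- 0
  for (u in split(seq_along(y), unit)) {
    yi <- y[u]; eta0 <- b0 + b1 * x[u]
    # Newton iterations for the conditional mode of log f(y|u) + log phi(u)
    m <- 0
    for (it in 1:50) {
      p <- plogis(eta0 + m)
      g <- sum(yi - p) - m / sigma^2
      h <- -sum(p * (1 - p)) - 1 / sigma^2
      step <- g / h
      m <- m - step
      if (abs(step) < 1e-12) break
    }
    p <- plogis(eta0 + m)
    h <- -sum(p * (1 - p)) - 1 / sigma^2
    s <- 1 / sqrt(-h)
    z <- m + sqrt(2) * s * rule$nodes
    hz <- vapply(z, function(zz) {
      sum(dbinom(yi, 1L, plogis(eta0 + zz), log = TRUE)) +
        dnorm(zz, 0, sigma, log = TRUE)
    }, numeric(1))
    ll <- ll + log(sum(rule$weights * exp(rule$nodes^2 + hz)) * sqrt(2) * s)
  }
  ll
}

fd_hessian <- function(f, par, h = 1e-4) {
  k <- length(par)
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k); ei[i] <- h; ej[j] <- h
      H[i, j] <- H[j, i] <-
        (f(par + ei + ej) - f(par + ei - ej) -
           f(par - ei + ej) + f(par - ei - ej)) / (4 * h^2)
    }
  }
  H
}

agq_logistic_fit <- function(d, n_nodes = 50L) {
  rule <- gauss_hermite_rule(n_nodes)
  x <- as.numeric(d$trt == levels(factor(d$trt))[2L])
  start_glm <- glm(d$y ~ x, family = binomial())
  start <- c(coef(start_glm), log(0.5))
  nll <- function(p) -agq_logistic_loglik(p, d$y, x, d$unit, rule)
  opt <- optim(start, nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  H <- fd_hessian(nll, opt$par)
  # at a sigma ~ 0 boundary the log-sigma direction is flat; fall back to
  # the fixed-effect block (cross-information with log-sigma vanishes)
  se_beta1 <- tryCatch(sqrt(solve(H)[2L, 2L]),
                       error = function(e) sqrt(solve(H[1:2, 1:2])[2L, 2L]))
  list(beta0 = opt$par[1L], beta1 = opt$par[2L], sigma = exp(opt$par[3L]),
       se_beta1 = se_beta1, loglik = -opt$value,
       convergence = opt$convergence)
}

# Two-stage grid search for the REML tau^2 maximizer (10^4 points per
# stage; second stage refines around the coarse argmax).
reml_loglik_oracle <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
}

reml_grid_tau2 <- function(y, v, upper = NULL) {
  if (is.null(upper)) upper <- max(100 * max(v), 10 * var(y))
  grid <- seq(0, upper, length.out = 10000L)
  ll <- vapply(grid, reml_loglik_oracle, numeric(1), y = y, v = v)
  best <- grid[which.max(ll)]
  step <- grid[2L] - grid[1L]
  grid2 <- seq(max(0, best - step), best + step, length.out = 10000L)
  ll2 <- vapply(grid2, reml_loglik_oracle, numeric(1), y = y, v = v)
  grid2[which.max(ll2)]
}

# Independent re-derivation of the DerSimonian-Laird moment estimator,
# written with explicit loops.
dl_tau2_oracle <- function(y, v) {
  k <- length(y)
  w <- numeric(k)
  for (i in seq_len(k)) w[i] <- 1 / v[i]
  ybar <- 0
  for (i in seq_len(k)) ybar <- ybar + w[i] * y[i]
  ybar <- ybar / sum(w)
  q <- 0
  for (i in seq_len(k)) q <- q + w[i] * (y[i] - ybar)^2
  cw <- sum(w) - sum(w^2) / sum(w)
  max(0, (q - (k - 1)) / cw)
}

# Exact two-sided rank-sum p-value by enumeration of all group assignments
# of the combined sample (tie-free data only).
rank_sum_enumeration <- function(a, b) {
  combined <- c(a, b)
  na <- length(a)
  w_of <- function(av, bv) sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  w_obs <- w_of(a, b)
  idx <- utils::combn(length(combined), na)
  ws <- apply(idx, 2L, function(ii) w_of(combined[ii], combined[-ii]))
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  list(W = w_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Closed-form RSS for a balanced two-way layout: full model = cell means,
# additive model = grand + row + column effects (orthogonal balanced
# design). Gaussian ML likelihood-ratio statistic = n log(RSS_red/RSS_full).
balanced_lrt_oracle <- function(y, trt, lab) {
  n <- length(y)
  cell <- ave(y, trt, lab)
  rss_full <- sum((y - cell)^2)
  add <- ave(y, trt) + ave(y, lab) - mean(y)
  rss_red <- sum((y - add)^2)
  n * log(rss_red / rss_full)
}

# Pooled two-sample t oracle for the gaussian fit examples.
two_group_t_oracle <- function(control, treated) {
  n1 <- length(control); n2 <- length(treated)
  sp2 <- (sum((control - mean(control))^2) + sum((treated - mean(treated))^2)) /
    (n1 + n2 - 2)
  est <- mean(treated) - mean(control)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(estimate = est, se = se, df = df,
       p = 2 * pt(-abs(est / se), df))
}

# Shared fixture: outcome spec matching a simulation archetype.
spec_for_scenario <- function(cfg) {
  fam <- switch(cfg$archetype,
    gaussian_two_group = "gaussian",
    binary_repeated_choice = "binary_logit",
    dish_proportion = "proportion_logit")
  outcome_spec(
    cfg$outcome_id, fam,
    transform = if (fam == "gaussian") cfg$transform else "none",
    random_terms = switch(cfg$archetype,
      gaussian_two_group = character(),
      binary_repeated_choice = "unit_intercept",
      dish_proportion = c("unit_intercept", "olre")),
    treatment_reference = cfg$treatment_levels[1L])
}

effects_fixture_path <- function() {
  system.file("extdata", "insect_multilab_effects.csv",
              package = "labrepro", mustWork = TRUE)
}
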