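# Statistical layer: shifted-gamma and two-state densities, maximum-
# likelihood fitters, nonparametric tests, smoothed densities, kinetics.

test_that("shifted gamma pdf matches closed forms", {
  # alpha = 1, dx = 0 is the exponential density
  p <- gamma_params(1, 0.5, 0)
  expect_equal(dshifted_gamma(0, p), 2)
  expect_equal(dshifted_gamma(1, p), 2 * exp(-2))
  # zero below the shift
  p2 <- gamma_params(5.6, 0.17, 1.57)
  expect_equal(dshifted_gamma(1.5, p2), 0)
  # mode of the wild-type Rh3 basal fit at dx + (alpha-1) beta
  mode_expected <- 1.57 + (5.6 - 1) * 0.17
  opt <- optimize(function(x) dshifted_gamma(x, p2), c(1.57, 5),
                  maximum = TRUE)
  expect_equal(opt$maximum, mode_expected, tolerance = 1e-4)
  expect_equal(mode_expected, 2.352, tolerance = 1e-12)
})

test_that("densities are nonnegative and normalized", {
  params <- list(
    reference_two_state_fits("Rh3", "0wk"),
    reference_two_state_fits("Rh5", "0wk"),   # alpha_on < 1 (J-shaped)
    reference_two_state_fits("Rh6", "2wk"))
  for (p in params) {
    xs <- seq(0, 400, length.out = 4001)
    expect_true(all(dtwo_state(xs, p) >= 0))
    expect_equal(two_state_total_mass(p), 1, tolerance = 1e-6)
  }
  g <- gamma_params(2.2, 0.17, 1.62)
  expect_equal(integrate(function(x) dshifted_gamma(x, g), 1.62, Inf)$value,
               1, tolerance = 1e-6)
})

test_that("two-state density degenerates to its components", {
  base <- reference_two_state_fits("Rh6", "2wk")
  xs <- seq(0, 30, by = 0.01)
  p0 <- two_state_params(base$alpha_off, base$beta_off, base$alpha_on,
                         base$beta_on, 0, base$dx)
  expect_equal(dtwo_state(xs, p0),
               dgamma(xs - base$dx, base$alpha_off, scale = base$beta_off))
  p1 <- two_state_params(base$alpha_off, base$beta_off, base$alpha_on,
                         base$beta_on, 1, base$dx)
  expect_equal(dtwo_state(xs, p1),
               dgamma(xs - base$shift_on, base$alpha_on, scale = base$beta_on))
})

test_that("two-state sampling is reproducible and matches the mixture mean", {
  p <- reference_two_state_fits("Rh5", "0wk")
  a <- sample_two_state_levels(p, 1000, seed = 5)
  b <- sample_two_state_levels(p, 1000, seed = 5)
  expect_identical(a, b)
  # degenerate mixture: p_on = 0 gives only off draws
  p_off <- two_state_params(2, 0.5, 1, 5, 0, 1)
  s <- sample_two_state_levels(p_off, 500, seed = 1)
  expect_true(all(s$states == "off"))
  expect_true(all(s$levels >= 1))
  # closed-form mixture mean as oracle at n = 1e5
  big <- sample_two_state_levels(p, 1e5, seed = 9)
  se <- sd(big$levels) / sqrt(length(big$levels))
  expect_lt(abs(mean(big$levels) - two_state_mean(p)), 3 * se)
  # sampled on-state fraction within a binomial CI of p_on
  p2 <- reference_two_state_fits("Rh5", "2wk")
  big2 <- sample_two_state_levels(p2, 1e5, seed = 10)
  phat <- mean(big2$states == "on")
  ci <- binom.test(sum(big2$states == "on"), 1e5)$conf.int
  expect_true(p2$p_on >= ci[1] && p2$p_on <= ci[2])
})

test_that("shifted-gamma MLE recovers generating parameters", {
  # recovery oracle with the shift given: estimating the shift from the
  # sample minimum carries an O(n^(-1/alpha)) upward bias for steep shapes,
  # so shape/scale recovery is assessed at the true shift
  truth <- reference_wt_gamma_fits("Rh3")
  set.seed(2)
  x <- truth$dx + rgamma(1e5, truth$alpha, scale = truth$beta)
  fit <- fit_shifted_gamma(x, dx = truth$dx)
  expect_lt(abs(fit$alpha - truth$alpha) / truth$alpha, 0.03)
  expect_lt(abs(fit$beta - truth$beta) / truth$beta, 0.03)
  expect_error(fit_shifted_gamma(rep(2, 100)), "degenerate")
})

test_that("shifted-gamma MLE bias at the basal sample size is small", {
  truth <- reference_wt_gamma_fits("Rh3")
  set.seed(31)
  alphas <- replicate(200, {
    x <- truth$dx + rgamma(672, truth$alpha, scale = truth$beta)
    fit_shifted_gamma(x, dx = truth$dx)$alpha
  })
  expect_lt(abs(mean(alphas) - truth$alpha) / truth$alpha, 0.05)
})

test_that("two-state MLE separates off-only data and nests the single gamma", {
  p <- reference_two_state_fits("Rh6", "2wk")
  off_only <- two_state_params(p$alpha_off, p$beta_off, p$alpha_on, p$beta_on,
                               0, p$dx)
  x <- sample_two_state_levels(off_only, 800, seed = 3)$levels
  fit <- fit_two_state(x, seed = 8)
  expect_lt(fit$p_on, 0.05)
  # on genuine mixture data the two-state log-likelihood dominates the
  # nested single-gamma fit
  xm <- sample_two_state_levels(p, 1500, seed = 4)$levels
  f2 <- fit_two_state(xm, seed = 8)
  f1 <- fit_shifted_gamma(xm)
  expect_gte(f2$loglik, attr(f1, "loglik") - 1e-6)
})

test_that("normal mixture EM recovers well-separated components", {
  set.seed(6)
  x <- c(rnorm(1500, 0, 1), rnorm(3500, 10, 2))
  fit <- fit_normal_mixture(x, seed = 6)
  expect_equal(fit$weight_on, 0.7, tolerance = 0.03)
  expect_equal(fit$mu_off, 0, tolerance = 0.15)
  expect_equal(fit$mu_on, 10, tolerance = 0.15)
  expect_lt(fit$mu_off, fit$mu_on)  # ordering contract
  # two point masses: the weight goes to the heavier atom
  xa <- c(rep(0, 500), rep(10, 1500))
  fa <- fit_normal_mixture(xa, seed = 1)
  expect_equal(fa$weight_on, 0.75, tolerance = 0.01)
})

test_that("weight refit against fixed components is a correct 1-D MLE", {
  fixed <- reference_rh6_r8_mixture()
  set.seed(12)
  n <- 2000
  on <- runif(n) < 0.6
  x <- ifelse(on, rnorm(n, fixed$mu_on, fixed$sd_on),
              rnorm(n, fixed$mu_off, fixed$sd_off))
  w <- refit_mixture_weight(x, fixed)
  expect_equal(w, 0.6, tolerance = 0.03)
  # grid-scan oracle agrees with the optimizer
  d_off <- dnorm(x, fixed$mu_off, fixed$sd_off)
  d_on <- dnorm(x, fixed$mu_on, fixed$sd_on)
  grid <- seq(0, 1, by = 1e-4)
  ll <- vapply(grid, function(g) sum(log((1 - g) * d_off + g * d_on)),
               numeric(1))
  expect_equal(w, grid[which.max(ll)], tolerance = 2e-4)
  # all draws from the on component push the weight to 1
  x_on <- rnorm(500, fixed$mu_on, fixed$sd_on)
  expect_gt(refit_mixture_weight(x_on, fixed), 0.97)
})

test_that("KS statistics agree with brute-force oracles on small samples", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    x <- rnorm(n)
    # one-sample oracle: sup over the jump points of the ECDF
    r <- ks_one_sample(x, pnorm)
    s <- sort(x)
    d_oracle <- max(pmax(abs(seq_len(n) / n - pnorm(s)),
                         abs((seq_len(n) - 1) / n - pnorm(s))))
    expect_equal(r$D, d_oracle, tolerance = 1e-12)
    # two-sample one-sided oracle: sup of ECDF_a - ECDF_b over pooled points
    m <- sample(5:20, 1)
    y <- rnorm(m, 0.3)
    r2 <- ks_two_sample_one_sided(x, y)
    pool <- sort(c(x, y))
    dplus <- max(vapply(pool, function(t) {
      mean(x <= t) - mean(y <= t)
    }, numeric(1)))
    expect_equal(r2$D, max(dplus, 0), tolerance = 1e-12)
  }
  # direction convention: stochastically smaller first sample gives D+ ~ 1
  a <- runif(100); b <- runif(100) + 1
  r <- ks_two_sample_one_sided(a, b)
  expect_equal(r$D, 1)
  expect_lt(r$p, 1e-10)
  expect_equal(ks_two_sample_one_sided(a, a)$D, 0)
  # a large shift drives the one-sample D to 1
  expect_gt(ks_one_sample(rnorm(50) + 100, pnorm)$D, 0.999)
})

test_that("Spearman correlation matches the rank formula", {
  x <- c(3.1, 0.2, 5.5, 2.2, 9.9, 1.1, 4.4, 7.7, 6.6, 8.8)
  y <- c(2.0, 1.0, 6.1, 3.3, 9.1, 0.4, 5.2, 8.3, 7.7, 6.4)
  r <- spearman_correlation(x, y)
  d <- rank(x) - rank(y)
  rho_manual <- 1 - 6 * sum(d^2) / (10 * (100 - 1))
  expect_equal(r$rho, rho_manual, tolerance = 1e-12)
  expect_equal(spearman_correlation(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_correlation(1:10, -(1:10))$rho, -1)
  expect_error(spearman_correlation(rep(1, 10), 1:10), "constant")
})

test_that("smoothed density is the direct Gaussian kernel sum", {
  # single observation: the kernel itself
  sd1 <- smoothed_density(0, w = 0.3, grid = seq(-2, 2, by = 0.01))
  expect_equal(sd1$density, dnorm(sd1$grid, 0, 0.3), tolerance = 1e-12)
  # brute-force double loop oracle on 50 points
  set.seed(15)
  x <- rnorm(50, 5, 2)
  sm <- smoothed_density(x, w = 0.5)
  oracle <- vapply(sm$grid, function(g) {
    mean(vapply(x, function(xi) dnorm(g - xi, 0, 0.5), numeric(1)))
  }, numeric(1))
  expect_equal(sm$density, oracle, tolerance = 1e-12)
  # integrates to ~1 (trapezoid over the padded grid)
  dx <- diff(sm$grid[1:2])
  expect_equal(sum(sm$density) * dx, 1, tolerance = 1e-3)
})

test_that("fitters agree with independent reference implementations", {
  # gamma MLE vs fitdistrplus on the same (unshifted) sample
  set.seed(50)
  y <- rgamma(2000, 2.3, scale = 0.6)
  f <- fit_shifted_gamma(y + 1, dx = 1)
  fd <- fitdistrplus::fitdist(y, "gamma")
  expect_equal(f$alpha, unname(fd$estimate["shape"]), tolerance = 1e-3)
  expect_equal(f$beta, 1 / unname(fd$estimate["rate"]), tolerance = 1e-3)

  # two-normal EM vs mclust (unequal-variance model, 2 components);
  # Mclust needs its namespace attached to resolve mclustBIC
  withr::local_package("mclust")
  x <- c(rnorm(700, 2, 0.5), rnorm(1300, 8, 2))
  fm <- fit_normal_mixture(x, seed = 51)
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  ord <- order(mc$parameters$mean)
  expect_equal(fm$weight_on, unname(mc$parameters$pro[ord[2]]),
               tolerance = 0.02)
  expect_equal(fm$mu_off, unname(mc$parameters$mean[ord[1]]),
               tolerance = 0.05)
  expect_equal(fm$mu_on, unname(mc$parameters$mean[ord[2]]),
               tolerance = 0.05)
})

test_that("burst-parameter kinetics and unit conversions are exact", {
  kr <- kinetic_rates_from_gamma(5.6, 0.17, gamma_p = 1, gamma_m = 10)
  expect_equal(kr$lambda_m, 5.6)
  expect_equal(kr$lambda_p, 1.7)
  expect_equal(kr$equilibration_time, 1)
  # round trip rates -> (alpha, beta) -> rates
  alpha <- kr$lambda_m / kr$gamma_p
  beta <- kr$lambda_p / kr$gamma_m
  kr2 <- kinetic_rates_from_gamma(alpha, beta, kr$gamma_p, kr$gamma_m)
  expect_equal(kr2$lambda_m, kr$lambda_m)
  expect_equal(kr2$lambda_p, kr$lambda_p)
  expect_error(kinetic_rates_from_gamma(-1, 1, 1, 1), "positive")

  conv <- intensity_to_molecules(1, mean_on = 1)
  expect_equal(attr(conv, "factor"), 2.5e5)
  expect_equal(as.numeric(intensity_to_molecules(0, mean_on = 11)), 0)

  expect_equal(half_life_to_rate(1), log(2))
  expect_equal(half_life_to_rate(2), 0.3466, tolerance = 1e-4)
  expect_equal(half_life_to_rate(4), half_life_to_rate(2) / 2)
})
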