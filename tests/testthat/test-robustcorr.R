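light <- function(seed = 1) mcmc_settings(n_chains = 2, n_draws = 600,
                                          n_tune = 400, seed = seed)

test_that("log posterior matches a closed-form evaluation at the mode", {
  x <- 0.3; y <- -1.2
  priors <- list(mu_loc = c(0.3, -1.2), mu_scale = c(1, 1),
                 sigma_scale = c(1, 1), nu_rate = 1 / 29)
  nu <- 7; sigma <- c(1.5, 2)
  got <- log_posterior(c(0.3, -1.2), sigma, 0, nu, x, y, priors)
  # single observation at the location, rho = 0: bivariate t density at its
  # mode is gamma((nu+2)/2) / (gamma(nu/2) * nu * pi * s1 * s2)
  ll <- lgamma((nu + 2) / 2) - lgamma(nu / 2) - log(nu * pi) - sum(log(sigma))
  lp <- sum(dnorm(c(0.3, -1.2), priors$mu_loc, priors$mu_scale, log = TRUE)) +
    sum(log(2) + dnorm(sigma, 0, priors$sigma_scale, log = TRUE)) +
    dunif(0, -1, 1, log = TRUE) + dexp(nu - 1, 1 / 29, log = TRUE)
  expect_equal(got, ll + lp, tolerance = 1e-12)
})

test_that("large nu approaches the bivariate normal likelihood", {
  set.seed(2)
  x <- rnorm(40); y <- rnorm(40)
  priors <- robust_corr_priors(x, y)
  mu <- c(0.1, -0.1); sigma <- c(1.1, 0.9); rho <- 0.4; nu <- 1e6
  got_ll <- log_posterior(mu, sigma, rho, nu, x, y, priors) -
    (sum(dnorm(mu, priors$mu_loc, priors$mu_scale, log = TRUE)) +
       sum(log(2) + dnorm(sigma, 0, priors$sigma_scale, log = TRUE)) +
       dunif(rho, -1, 1, log = TRUE) + dexp(nu - 1, 1 / 29, log = TRUE))
  # bivariate normal log likelihood assembled by hand
  z1 <- (x - mu[1]) / sigma[1]; z2 <- (y - mu[2]) / sigma[2]
  q <- (z1^2 - 2 * rho * z1 * z2 + z2^2) / (1 - rho^2)
  normal_ll <- sum(-log(2 * pi) - log(sigma[1]) - log(sigma[2]) -
                     0.5 * log(1 - rho^2) - q / 2)
  expect_lt(abs(got_ll - normal_ll), 1e-3)
})

test_that("invalid parameters yield -Inf, not an exception", {
  priors <- list(mu_loc = c(0, 0), mu_scale = c(1, 1),
                 sigma_scale = c(1, 1), nu_rate = 1 / 29)
  expect_identical(log_posterior(c(0, 0), c(1, 1), 1, 5, 0, 0, priors), -Inf)
  expect_identical(log_posterior(c(0, 0), c(-1, 1), 0.5, 5, 0, 0, priors), -Inf)
  expect_identical(log_posterior(c(0, 0), c(1, 1), 0.5, 0.5, 0, 0, priors), -Inf)
})

test_that("HDI is the shortest interval and beats equal tails on skewed draws", {
  expect_equal(hdi(rep(2.5, 300)), c(2.5, 2.5))
  set.seed(4)
  z <- rnorm(50000)
  h <- hdi(z)
  expect_lt(abs(h[1] + 1.96), 0.1)
  expect_lt(abs(h[2] - 1.96), 0.1)
  s <- rlnorm(20000, sdlog = 1)
  hs <- hdi(s)
  eq <- quantile(s, c(0.025, 0.975))
  expect_lt(diff(hs), unname(diff(eq)))
  expect_error(hdi(rnorm(50)), class = "radecol_domain_error")
})

test_that("split-Rhat separates mixed from unmixed chains", {
  set.seed(6)
  good <- replicate(4, rnorm(2000), simplify = FALSE)
  expect_lt(rhat(good), 1.01)
  bad <- good
  bad[[1]] <- bad[[1]] + 5
  expect_gt(rhat(bad), 1.1)
  # copied chains: no between-chain variance, reported as computed
  expect_lte(rhat(list(good[[1]], good[[1]])), 1 + 1e-6)
  expect_error(rhat(list(rnorm(10))), class = "radecol_domain_error")
})

test_that("ESS calibrates on iid and AR(1) sequences", {
  set.seed(7)
  iid <- replicate(4, rnorm(2000), simplify = FALSE)
  e <- ess(iid)
  expect_lt(abs(e - 8000) / 8000, 0.2)
  ar <- replicate(2, as.vector(arima.sim(list(ar = 0.9), 10000)), simplify = FALSE)
  target <- 20000 * (1 - 0.9) / (1 + 0.9)
  expect_lt(abs(ess(ar) - target) / target, 0.3)
  # constant chains carry no information
  expect_true(is.na(ess(list(rep(1, 100), rep(1, 100)))))
})

test_that("posterior recovers the generating correlation", {
  d <- rbivariate_t(200, rho = 0.8, nu = 5, seed = 41)
  s <- robust_correlation(d[, 1], d[, 2], light(seed = 2))
  expect_lt(abs(s$rho_mean - 0.8), 0.1)
  expect_true(s$hdi_low <= 0.8 && 0.8 <= s$hdi_high)
  d0 <- rbivariate_t(200, rho = 0, nu = 5, seed = 42)
  s0 <- robust_correlation(d0[, 1], d0[, 2], light(seed = 2))
  expect_true(s0$hdi_low <= 0 && 0 <= s0$hdi_high)
})

test_that("negating one variable mirrors the correlation posterior", {
  d <- rbivariate_t(100, rho = 0.6, nu = 6, seed = 43)
  s1 <- robust_correlation(d[, 1], d[, 2], light(seed = 3))
  s2 <- robust_correlation(d[, 1], -d[, 2], light(seed = 3))
  expect_lt(abs(s1$rho_mean + s2$rho_mean), 0.05)
})

test_that("on normal data the posterior mean approaches the Pearson r", {
  d <- rbivariate_t(500, rho = 0.5, nu = 1e6, seed = 44)
  s <- robust_correlation(d[, 1], d[, 2], light(seed = 4))
  expect_lt(abs(s$rho_mean - cor(d[, 1], d[, 2])), 0.05)
})

test_that("degenerate inputs are refused before sampling", {
  expect_error(sample_posterior(rep(1, 10), rnorm(10)),
               class = "radecol_degenerate_error")
  expect_error(sample_posterior(c(1, 2), c(3, 4)),
               class = "radecol_degenerate_error")
})

test_that("the analogue table runs per tissue with listwise complete pairs", {
  co <- generate_cohort(sim_params(n_animals = 6, seed = 55))
  tab <- analogue_correlation_table(co, "Cs137", "Cs",
                                    mcmc_settings(2, 200, 150, seed = 5))
  expect_true(all(tissue_vocabulary() %in% tab$tissue))
  expect_true(all(tab$n == 6))
  expect_true(all(tab$hdi_low <= tab$rho_mean & tab$rho_mean <= tab$hdi_high))
})
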