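# Conjugate Normal-Inverse-Wishart updates and the Student-t predictive.

test_that("scalar conjugate update matches the closed form by hand", {
  prior <- ref_prior1()
  st <- drex:::stats_add(drex:::new_hypothesis_stats(1), 5)
  post <- drex:::niw_posterior(st, prior)
  # kappa1 = 2, mu1 = (0 + 5)/2, nu1 = 3, Lambda1 = 1 + 25 + 0 - 2 * 2.5^2
  expect_equal(post$kappa, 2)
  expect_equal(drop(post$mu), 2.5)
  expect_equal(post$nu, 3)
  expect_equal(drop(post$lambda), 13.5)
})

test_that("an overwhelmingly confident prior pins the posterior mean at mu0", {
  prior <- drex_prior(1, mu0 = 2, kappa0 = 1e12, nu0 = 2, lambda0 = 1)
  st <- drex:::stats_add(drex:::new_hypothesis_stats(1), 7)
  post <- drex:::niw_posterior(st, prior)
  expect_equal(drop(post$mu), 2, tolerance = 1e-9)
})

test_that("incremental statistics equal batch statistics over the window", {
  for (D in 1:3) {
    set.seed(D)
    window <- rnorm(12)
    inc <- drex:::new_hypothesis_stats(D)
    if (length(window) >= D)
      for (p in D:length(window)) inc <- drex:::stats_add(inc, window[(p - D + 1):p])
    bat <- drex:::stats_batch(window, D)
    expect_equal(inc$n, bat$n)
    expect_equal(inc$s, bat$s, tolerance = 1e-10)
    expect_equal(inc$S, bat$S, tolerance = 1e-10)
    # posterior scale matrix from raw sums stays symmetric
    post <- drex:::niw_posterior(inc, drex_prior(D))
    expect_equal(post$lambda, t(post$lambda), tolerance = 1e-12)
  }
})

test_that("scalar prior predictive is the closed-form Student-t", {
  cfg <- drex_config(D = 1, M = Inf, N = 0, prior = ref_prior1())
  st <- drex:::new_hypothesis_stats(1)
  pred <- drex:::predictive_params(drex:::niw_posterior(st, cfg$prior),
                                   numeric(0), cfg)
  expect_equal(pred$location, 0)
  expect_equal(pred$scale, 1)
  expect_equal(pred$dof, 2)
  for (x in c(-3, -0.4, 0, 1.7, 6))
    expect_equal(drex:::t_logdensity(x, pred), dt(x, df = 2, log = TRUE),
                 tolerance = 1e-12)
})

test_that("prior predictive agrees with numerical integration over the prior", {
  # p(x) = int InvGamma(s2; nu0/2, lambda0/2) N(x | mu0, s2 (1 + 1/kappa0)) ds2
  prior <- drex_prior(1, mu0 = 1, kappa0 = 2, nu0 = 4, lambda0 = 6)
  cfg <- drex_config(D = 1, M = Inf, N = 0, prior = prior)
  pred <- drex:::predictive_params(
    drex:::niw_posterior(drex:::new_hypothesis_stats(1), prior), numeric(0), cfg)
  a <- prior$nu0 / 2
  b <- prior$lambda0[1, 1] / 2
  for (x in c(-2, 0.5, 1, 3)) {
    num <- stats::integrate(function(s2) {
      exp(a * log(b) - lgamma(a) - (a + 1) * log(s2) - b / s2) *
        stats::dnorm(x, prior$mu0[1], sqrt(s2 * (1 + 1 / prior$kappa0)))
    }, 0, Inf, rel.tol = 1e-10)$value
    expect_equal(drex:::t_logdensity(x, pred), log(num), tolerance = 1e-7)
  }
})

test_that("conditional predictive is symmetric about its location", {
  set.seed(9)
  cfg <- drex_config(D = 3, M = Inf, N = 0.2)
  st <- drex:::stats_batch(rnorm(10), 3)
  pred <- drex:::predictive_params(drex:::niw_posterior(st, cfg$prior),
                                   c(0.3, -0.8), cfg)
  for (d in c(0.1, 1, 4))
    expect_equal(drex:::t_logdensity(pred$location + d, pred),
                 drex:::t_logdensity(pred$location - d, pred), tolerance = 1e-12)
})

test_that("a large noise floor dominates the predictive scale", {
  cfg <- drex_config(D = 1, M = Inf, N = 50, prior = ref_prior1())
  st <- drex:::stats_batch(c(5, 5, 5, 5), 1)
  pred <- drex:::predictive_params(drex:::niw_posterior(st, cfg$prior),
                                   numeric(0), cfg)
  expect_equal(pred$scale, 50)
  # and keeps surprisal finite even at absurd tones
  fit <- drex(c(rep(0, 10), 1e4), drex_config(D = 1, N = 0.5))
  expect_true(all(is.finite(fit$surprisal)))
  expect_true(all(fit$predictive_scale >= 0.5 - 1e-12))
})
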