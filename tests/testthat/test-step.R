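# The per-tone belief recursion and surprisal.

test_that("beliefs stay normalized and bounded after every step", {
  for (D in c(1L, 2L, 3L)) {
    cfg <- drex_config(D = D, M = 8, hazard = 0.05)
    tones <- rand_tones(40, seed = D)
    state <- drex:::init_state(cfg)
    for (t in seq_along(tones)) {
      state <- drex:::drex_step(state, t, tones, cfg)$state
      w <- exp(state$logw)
      expect_lt(abs(sum(w) - 1), 1e-12)
      expect_true(all(w >= 0))
      expect_lte(max(state$run), min(t, 8))
    }
  }
})

test_that("the empty-history state is the prior with all belief on run 0", {
  for (D in c(1L, 3L)) {
    st <- drex:::init_state(drex_config(D = D))
    expect_identical(st$run, 0L)
    expect_equal(exp(st$logw), 1)
    expect_identical(st$stats[[1]]$n, 0L)
    expect_equal(st$stats[[1]]$s, numeric(D))
  }
})

test_that("hazard splits belief mass exactly as the recursion prescribes", {
  # two hypotheses with identical statistics (hence identical predictive
  # densities) and equal weights: after one step the reset carries the hazard
  # mass and the grown hypotheses keep their prior proportions
  cfg <- drex_config(D = 1, M = Inf, hazard = 0.1, prior = ref_prior1())
  st0 <- drex:::stats_batch(c(1, 2), 1)
  state <- list(run = c(2L, 5L), logw = log(c(0.5, 0.5)),
                stats = list(st0, st0))
  tones <- c(1, 2, 1, 2, 1, 0.5)
  out <- drex:::drex_step(state, 6L, tones, cfg)
  w <- exp(out$state$logw)
  expect_equal(w[out$state$run == 0L], 0.1, tolerance = 1e-12)
  expect_equal(w[out$state$run == 3L], 0.45, tolerance = 1e-12)
  expect_equal(w[out$state$run == 6L], 0.45, tolerance = 1e-12)
})

test_that("first-step surprisal at the prior location is the mode density", {
  cfg <- drex_config(D = 1, M = Inf, N = 0, hazard = 0.01, prior = ref_prior1())
  fit <- drex(0, cfg)
  expect_equal(fit$surprisal[1], -log2(dt(0, df = 2)), tolerance = 1e-12)
  # and the reset mass after one step is exactly the hazard
  state <- drex:::drex_step(drex:::init_state(cfg), 1L, 0, cfg)$state
  expect_equal(exp(state$logw)[state$run == 0L], 0.01, tolerance = 1e-12)
})

test_that("inference is deterministic and rejects non-finite tones", {
  cfg <- drex_config(D = 2)
  tones <- rand_tones(30, seed = 11)
  f1 <- drex(tones, cfg)
  f2 <- drex(tones, cfg)
  expect_identical(f1$surprisal, f2$surprisal)
  expect_identical(f1$beliefs, f2$beliefs)
  expect_error(drex(c(1, NaN, 2), cfg), "finite")
  expect_error(drex(numeric(0), cfg), "empty")
})

test_that("belief rows of a fit sum to one and surprisal is non-negative", {
  cfg <- drex_config(D = 1, M = 10, N = 0.5)
  fit <- drex(rand_tones(50, seed = 3), cfg)
  expect_true(all(abs(rowSums(fit$beliefs) - 1) < 1e-10))
  expect_true(all(is.finite(fit$surprisal)))
  # surprisal can only dip below zero if a density exceeds 1; with N = 0.5
  # the t mode density is bounded by dt(0, df)/0.5, so allow that bound
  expect_true(all(fit$surprisal > -log2(dt(0, df = 60) / 0.5) - 1e-9))
})

test_that("constant input drives surprisal down as evidence accumulates", {
  cfg <- drex_config(D = 1, N = 0.1)
  fit <- drex(rep(3, 50), cfg)
  s <- fit$surprisal
  expect_true(all(diff(s[2:20]) < 0))      # monotone decline while learning
  expect_lt(s[50], s[2])
})
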