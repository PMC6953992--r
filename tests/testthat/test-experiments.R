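# Statistical summaries and the replication harness (scaled-down runs; the
# full-size paradigm analyses live in the acceptance tests).

test_that("t and F summaries match hand computation and each other", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  tt <- drex:::drex_ttest(x, y)
  expect_equal(tt$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$df, 4)
  # identical samples: t = 0, p = 1
  t0 <- drex:::drex_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # one-way ANOVA with two groups squares the t statistic
  an <- drex:::drex_anova1(c(x, y), rep(c("a", "b"), each = 3))
  expect_equal(an$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(an$p_value, tt$p_value, tolerance = 1e-12)
  # degenerate zero-variance cells are an explicit error, never NaN
  expect_error(drex:::drex_ttest(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(drex:::drex_anova1(c(1, 1, 2, 3), rep(c("a", "b"), each = 2)),
               "degenerate")
})

test_that("two-way main-effects ANOVA reports both factors with Type II SS", {
  set.seed(1)
  f1 <- rep(c("lo", "mid", "hi"), times = c(30, 20, 10))
  f2 <- rep(c("x", "y"), 30)
  y <- ifelse(f1 == "hi", 3, ifelse(f1 == "mid", 1.5, 0)) +
    (f2 == "y") * 1 + rnorm(60, 0, 0.5)
  an <- drex:::drex_anova2(y, f1, f2)
  expect_equal(an$df_error, 60 - 4)
  expect_lt(an$f1$p_value, 1e-6)
  expect_lt(an$f2$p_value, 1e-6)
})

test_that("run_trials produces fresh, reproducible, annotated trials", {
  par <- list(standard = 0, deviant_offsets = 6, n_deviants = 2)
  tr <- run_trials("oddball", par, n_trials = 3, base_seed = 10)
  expect_length(tr, 3)
  expect_true(all(vapply(tr, function(z) all(z$probe_surprisals >= 0) &&
                           all(is.finite(z$probe_surprisals)), logical(1))))
  tr2 <- run_trials("oddball", par, n_trials = 3, base_seed = 10)
  expect_identical(tr, tr2)
  # a stochastic paradigm yields distinct stimuli across trial seeds
  trg <- run_trials("gaussian_context", list(sd = 3, n_tones = 40), n_trials = 2,
                    base_seed = 10)
  expect_false(identical(trg[[1]]$probe_surprisals, trg[[2]]$probe_surprisals))
  expect_error(run_trials("oddball", par, n_trials = 1), "at least 2")
})

test_that("deviant surprisal grows with frequency distance", {
  rep <- replicate_oddball_distance(n_trials = 4, base_seed = 3)
  expect_true(all(diff(rep$descriptives$mean) > 0))
  expect_identical(rep$direction, "increasing with offset")
  expect_lt(rep$p_value, 1e-4)
})

test_that("covering the block pattern removes the deviant's surprisal", {
  rep <- replicate_predictability(n_pairs = 6, base_seed = 2)
  expect_lt(rep$extra$diff_d6_high, rep$extra$diff_d1_high / 2)
  expect_gt(rep$extra$diff_d1_high, 1)
})

test_that("swapping pattern labels flips the pattern-oddball effect", {
  r1 <- replicate_pattern_oddball(n_probes = 12, n_patterns = 160,
                                  base_seed = 5, control_d1 = FALSE)
  r2 <- replicate_pattern_oddball(n_probes = 12, n_patterns = 160,
                                  base_seed = 5, control_d1 = FALSE,
                                  config = drex_config(D = 3))
  # same run twice is reproducible
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  s <- gen_pattern_oddball(standard_pattern = c("B", "B", "A", "A"),
                           deviant_pattern = c("A", "A", "B", "B"),
                           n_patterns = 160, p_deviant = 0.1, seed = 5)
  # with roles swapped the now-deviant AABB pattern carries the high surprisal
  fit <- drex(s, drex:::center_prior(drex_config(D = 3), s$tones),
              keep_beliefs = FALSE)
  isd <- s$metadata$is_deviant
  first <- function(idx) (idx - 1) * 4 + 1
  dev <- which(isd & seq_along(isd) > 12)
  std <- which(!isd & seq_along(isd) > 12)
  expect_gt(mean(fit$surprisal[first(dev)]), mean(fit$surprisal[first(std)]))
})

test_that("matched contexts produce no spurious context effect", {
  # null control: identical narrow and broad sd; the context comparison
  # should be non-significant at alpha = 0.01 in nearly every seed
  n_sig <- 0L
  for (seed in 1:25) {
    g <- replicate_gaussian_context(sd_narrow = 3, sd_broad = 3,
                                    n_tones = 150, base_seed = 1000 + seed)
    if (g$context$p_value < 0.01) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 2L)
})

test_that("reports serialize and print cleanly", {
  rep <- replicate_oddball_distance(n_trials = 3, base_seed = 8)
  expect_output(print(rep), "oddball_distance")
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path, seed = 8)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$report$p_value, rep$p_value, tolerance = 1e-12)
  expect_equal(j$report$config$D, 1)
})
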