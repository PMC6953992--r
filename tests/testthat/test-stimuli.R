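# Paradigm generators: construction-time annotations, determinism, and the
# statistical properties each paradigm is defined by.

expect_valid_seq <- function(s) {
  expect_s3_class(s, "tone_seq")
  expect_true(all(is.finite(s$tones)))
  dp <- s$deviant_positions
  expect_true(all(dp >= 1 & dp <= length(s$tones)))
  expect_false(is.unsorted(dp))
  if (!is.na(s$transition_index))
    expect_true(s$transition_index >= 1 && s$transition_index <= length(s$tones))
}

test_that("every generator is a pure function of parameters and seed", {
  gens <- list(
    function(sd) gen_oddball(0, c(2, 6), n_deviants = 3, seed = sd),
    function(sd) gen_roving_oddball(c(2, 6, 12), n_trains = 6, seed = sd),
    function(sd) gen_pattern_oddball(n_patterns = 20, p_deviant = 0.2, seed = sd),
    function(sd) gen_predictability_oddball("low", n_blocks = 8, seed = sd),
    function(sd) gen_biased_context(n_deviants = 15, seed = sd),
    function(sd) gen_gaussian_context(sd = 3, n_tones = 60, seed = sd),
    function(sd) gen_reg_rand(pattern_length = 4, n_tones = 40, seed = sd))
  for (g in gens) {
    a <- g(7); b <- g(7); c <- g(8)
    expect_valid_seq(a)
    expect_identical(a$tones, b$tones)
    expect_identical(a$deviant_positions, b$deviant_positions)
    expect_false(identical(a$tones, c$tones))
  }
})

test_that("oddball length arithmetic and annotations are exact", {
  s <- gen_oddball(0, 6, n_standards_between = 9, n_deviants = 2, seed = 1)
  expect_length(s$tones, 20)
  expect_identical(s$deviant_positions, c(10L, 20L))
  expect_true(all(s$tones[s$deviant_positions] == 6))
  expect_true(all(s$tones[-s$deviant_positions] == 0))
  s4 <- gen_oddball(0, c(2, 6, 12, 24), n_deviants = 3, seed = 2)
  expect_equal(as.vector(table(s4$metadata$offsets)), rep(3, 4))
  expect_equal(s4$tones[s4$deviant_positions], s4$metadata$offsets)
  expect_error(gen_oddball(0, c(0, 6)), "nonzero")
})

test_that("roving trains have the advertised structure", {
  s <- gen_roving_oddball(2, n_trains = 3, seed = 4)
  expect_length(s$tones, 6)
  expect_length(s$deviant_positions, 2)     # internal boundaries only
  s2 <- gen_roving_oddball(c(2, 6, 12), n_trains = 12, step_range = c(2, 6), seed = 9)
  expect_equal(as.vector(table(s2$metadata$train_conditions)), rep(4, 3))
  starts <- s2$metadata$train_starts
  tr_tones <- s2$tones[starts]
  expect_true(all(abs(diff(tr_tones)) >= 2 - 1e-12))   # minimum step respected
  expect_true(all(abs(diff(tr_tones)) <= 6 + 1e-12))
  # within-train constancy
  ks <- s2$metadata$train_conditions
  for (i in seq_along(starts))
    expect_equal(length(unique(s2$tones[starts[i]:(starts[i] + ks[i] - 1)])), 1L)
  expect_error(gen_roving_oddball(integer(0)), "empty")
  expect_error(gen_roving_oddball(c(1, 2)), "at least 2")
})

test_that("pattern streams honor the deviance probability", {
  s0 <- gen_pattern_oddball(n_patterns = 3, p_deviant = 0, seed = 1)
  expect_equal(s0$tones, rep(c(0, 0, 6, 6), 3))
  expect_length(s0$deviant_positions, 0)
  s1 <- gen_pattern_oddball(n_patterns = 3, p_deviant = 1, seed = 1)
  expect_equal(s1$tones, rep(c(6, 6, 0, 0), 3))
  expect_identical(s1$deviant_positions, c(1L, 5L, 9L))
  # deviant count inside the binomial 99% interval at n = 1000
  sb <- gen_pattern_oddball(n_patterns = 1000, p_deviant = 0.1, seed = 42)
  ci <- qbinom(c(0.005, 0.995), 1000, 0.1)
  expect_gte(sum(sb$metadata$is_deviant), ci[1])
  expect_lte(sum(sb$metadata$is_deviant), ci[2])
  expect_error(gen_pattern_oddball(standard_pattern = c("A", "B"),
                                   deviant_pattern = c("B", "A", "A")), "equal length")
})

test_that("predictability blocks match their condition", {
  hi <- gen_predictability_oddball("high", n_blocks = 3, seed = 1)
  expect_equal(hi$tones, rep(c(0, 0, 0, 0, 6), 3))
  expect_identical(hi$deviant_positions, c(5L, 10L, 15L))
  lo <- gen_predictability_oddball("low", n_blocks = 4000, seed = 1)
  expect_true(all(lo$metadata$block_lengths %in% 2:6))
  expect_equal(mean(lo$metadata$block_lengths), 4, tolerance = 0.1)
  expect_length(lo$deviant_positions, 4000)   # one B per block in both
  expect_error(gen_predictability_oddball("medium"), "arg")
})

test_that("biased contexts draw offsets with the advertised probabilities", {
  s <- gen_biased_context(deviant_offsets = c(2, 6, 12), context = "small_biased",
                          bias_probs = c(1, 0, 0), n_deviants = 10, seed = 1)
  expect_true(all(s$metadata$offsets == 2))      # degenerate bias = plain oddball
  big <- gen_biased_context(context = "large_biased", bias_probs = c(0.7, 0.2, 0.1),
                            n_deviants = 3000, seed = 5)
  freq <- table(factor(big$metadata$offsets, levels = c(2, 6, 12))) / 3000
  expect_equal(as.vector(freq), c(0.1, 0.2, 0.7), tolerance = 0.03)
  expect_error(gen_biased_context(bias_probs = c(0.5, 0.2, 0.1)), "summing to 1")
})

test_that("gaussian contexts have the requested moments and deviants", {
  s <- gen_gaussian_context(mean = 0, sd = 5, n_tones = 3000, deviant_every = 10,
                            seed = 3)
  expect_true(all(s$tones[s$deviant_positions] == 24))  # two octaves up
  nondev <- s$tones[-s$deviant_positions]
  expect_equal(stats::sd(nondev), 5, tolerance = 0.2)
  expect_equal(mean(nondev), 0, tolerance = 0.3)
  expect_error(gen_gaussian_context(sd = 0), "positive")
})

test_that("regular halves repeat exactly and random halves carry more entropy", {
  s <- gen_reg_rand(pattern_length = 4, direction = "REG_RAND", n_tones = 48,
                    seed = 6)
  reg <- s$tones[1:(s$transition_index - 1)]
  expect_equal(reg, rep_len(reg[1:4], length(reg)))     # exact period 4
  expect_length(unique(reg[1:4]), 4L)                   # distinct pattern tones
  s2 <- gen_reg_rand(pattern_length = 4, direction = "RAND_REG", n_tones = 48,
                     seed = 6)
  expect_identical(s2$tones[s2$transition_index:48][1:20],
                   s$tones[1:20])                       # direction swaps halves
  # plug-in entropy: uniform draws from a 20-tone pool beat a 4-cycle
  plug_in <- function(x) { p <- table(x) / length(x); -sum(p * log(p)) }
  big <- gen_reg_rand(pattern_length = 4, direction = "RAND_REG", n_tones = 400,
                      seed = 8)
  rand_half <- big$tones[1:(big$transition_index - 1)]
  reg_half <- big$tones[big$transition_index:400]
  expect_gt(plug_in(rand_half), plug_in(reg_half))
  expect_error(gen_reg_rand(pool = 1:3, pattern_length = 4), "pool")
})
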