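# Replication harness: run the model over trial ensembles per paradigm, probe
# surprisal at annotated positions, and summarize with the standard tests
# (t-tests, one-way and main-effects two-way ANOVA). Probes within the first
# 5 tones of a sequence are excluded (burn-in: the prior dominates there).

.BURN_IN <- 5L

# The default prior locates its mean in a stimulus-centred tone space. The
# harness therefore re-centres the prior mean on each stream's mean tone
# (empirical-Bayes initialization); the model is exactly translation-
# equivariant, so this equals shifting the tones to a centred space. Other
# prior hyperparameters are kept as configured.
center_prior <- function(config, tones) {
  p <- config$prior
  drex_config(D = config$D, M = config$M, N = config$N, hazard = config$hazard,
              prior = drex_prior(config$D, mu0 = mean(tones), kappa0 = p$kappa0,
                                 nu0 = p$nu0, lambda0 = p$lambda0),
              log_base = config$log_base)
}

# --- report container --------------------------------------------------------

new_report <- function(experiment, statistic_name, statistic, df, p_value,
                       direction = NA_character_, descriptives = NULL,
                       config = NULL, base_seed = NA_integer_, extra = list()) {
  structure(list(experiment = experiment, statistic_name = statistic_name,
                 statistic = statistic, df = df, p_value = p_value,
                 direction = direction, descriptives = descriptives,
                 config = config, base_seed = base_seed, extra = extra),
            class = "drex_report")
}

#' @export
print.drex_report <- function(x, ...) {
  dfs <- paste(x$df, collapse = ",")
  cat("Experiment: ", x$experiment, "\n  ", x$statistic_name, "(", dfs, ") = ",
      signif(x$statistic, 4), ", p = ", format(x$p_value, digits = 3),
      if (!is.na(x$direction)) paste0("  [", x$direction, "]"), "\n", sep = "")
  if (!is.null(x$descriptives)) {
    cat("  descriptives (surprisal, bits):\n")
    print(x$descriptives, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

# --- statistical summaries ---------------------------------------------------

.check_var <- function(split_values) {
  v <- vapply(split_values, function(g) stats::var(g), numeric(1))
  if (any(!is.finite(v) | v == 0))
    stop("degenerate (zero-variance or singleton) cell in statistical test")
}

# two-sample (pooled-variance) or paired t-test, reported with df
drex_ttest <- function(x, y, paired = FALSE) {
  .check_var(list(x, y))
  tt <- stats::t.test(x, y, paired = paired, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = unname(if (paired) tt$estimate
                                                else diff(rev(tt$estimate))))
}

# one-way ANOVA via aov()
drex_anova1 <- function(values, group) {
  group <- factor(group)
  .check_var(split(values, group))
  sm <- summary(stats::aov(values ~ group))[[1]]
  list(statistic = sm[1, "F value"], df = c(sm[1, "Df"], sm[2, "Df"]),
       p_value = sm[1, "Pr(>F)"])
}

# two-way main-effects ANOVA; Type II sums of squares so that the (possibly
# unbalanced) factors are each tested adjusted for the other
drex_anova2 <- function(values, f1, f2, interaction = FALSE) {
  f1 <- factor(f1); f2 <- factor(f2)
  .check_var(split(values, interaction(f1, f2), drop = TRUE))
  form <- if (interaction) values ~ f1 * f2 else values ~ f1 + f2
  fit <- stats::lm(form)
  an <- car::Anova(fit, type = 2)
  dfe <- an["Residuals", "Df"]
  eff <- function(row) list(statistic = an[row, "F value"],
                            df = c(an[row, "Df"], dfe),
                            p_value = an[row, "Pr(>F)"])
  list(f1 = eff("f1"), f2 = eff("f2"), df_error = dfe)
}

# --- generic trial runner ----------------------------------------------------

#' Run the model over an ensemble of freshly generated trials
#'
#' For each trial a new stimulus is generated (seed = \code{base_seed} +
#' trial index - 1) and the model is run from a fresh state; surprisal is
#' probed at the annotated deviant positions (excluding the first 5 tones).
#'
#' @param paradigm paradigm name understood by the stimulus generators:
#'   one of \code{"oddball"}, \code{"roving"}, \code{"pattern"},
#'   \code{"predictability"}, \code{"biased_context"},
#'   \code{"gaussian_context"}, \code{"reg_rand"}.
#' @param parameters list of generator arguments (see the \code{gen_*}
#'   functions).
#' @param config a [drex_config()].
#' @param n_trials number of trials (at least 2).
#' @param base_seed integer; trial i uses seed \code{base_seed + i - 1}.
#' @return a list of trial results, each with elements \code{condition},
#'   \code{probe_surprisals}, \code{probe_positions}, \code{trial_seed}.
#' @examples
#' tr <- run_trials("oddball", list(standard = 0, deviant_offsets = 6,
#'                  n_deviants = 2), n_trials = 2, base_seed = 1)
#' length(tr)
#' @export
run_trials <- function(paradigm, parameters = list(), config = drex_config(),
                       n_trials = 10, base_seed = 1) {
  if (n_trials < 2) stop("n_trials must be at least 2")
  lapply(seq_len(n_trials), function(i) {
    seed <- base_seed + i - 1L
    seq <- generate_stimulus(paradigm, parameters, seed = seed)
    fit <- drex(seq, config, keep_beliefs = FALSE)
    probes <- seq$deviant_positions[seq$deviant_positions > .BURN_IN]
    list(condition = seq$condition, probe_surprisals = fit$surprisal[probes],
         probe_positions = probes, trial_seed = seed)
  })
}

# --- paradigm replications ---------------------------------------------------

#' Oddball: deviant surprisal versus frequency distance
#'
#' Interleaved oddball streams with deviants at several frequency offsets;
#' marginal statistics (\code{D = 1}) suffice for deviant surprisal to grow
#' with the frequency distance between deviant and standard.
#'
#' @param config a [drex_config()] (default \code{D = 1}).
#' @param offsets deviant offsets, semitones.
#' @param n_deviants deviants per offset per trial.
#' @param n_trials number of trials.
#' @param base_seed integer seed.
#' @return a \code{drex_report}: one-way ANOVA of per-trial mean deviant
#'   surprisal across offsets, with per-offset descriptives in increasing
#'   offset order.
#' @export
replicate_oddball_distance <- function(config = drex_config(D = 1),
                                       offsets = c(2, 6, 12, 24), n_deviants = 6,
                                       n_trials = 10, base_seed = 1) {
  rows <- list()
  for (i in seq_len(n_trials)) {
    seq <- gen_oddball(0, offsets, n_standards_between = 9,
                       n_deviants = n_deviants, seed = base_seed + i - 1L)
    fit <- drex(seq, center_prior(config, seq$tones), keep_beliefs = FALSE)
    keep <- seq$deviant_positions > .BURN_IN
    s <- fit$surprisal[seq$deviant_positions[keep]]
    off <- seq$metadata$offsets[keep]
    rows[[i]] <- aggregate(surprisal ~ offset, data.frame(offset = off, surprisal = s), mean)
    rows[[i]]$trial <- i
  }
  df <- do.call(rbind, rows)
  an <- drex_anova1(df$surprisal, df$offset)
  desc <- aggregate(surprisal ~ offset, df, function(z) c(mean = mean(z), sd = stats::sd(z)))
  desc <- data.frame(offset = desc$offset, mean = desc$surprisal[, "mean"],
                     sd = desc$surprisal[, "sd"])
  desc <- desc[order(desc$offset), ]
  new_report("oddball_distance", "F", an$statistic, an$df, an$p_value,
             direction = if (all(diff(desc$mean) > 0)) "increasing with offset" else "non-monotone",
             descriptives = desc, config = config, base_seed = base_seed,
             extra = list(data = df, monotone = all(diff(desc$mean) > 0)))
}

#' Roving oddball: standard and deviant surprisal versus train length
#'
#' Each trial is one roving stream whose trains draw their length (standards
#' per train) balanced from \code{conditions}, as in the roving paradigm where
#' train length varies unpredictably within the stream. Per trial and
#' condition, surprisal at the final standard of each train and at each
#' deviant (train onset) is averaged over trains after a two-train burn-in,
#' giving one observation per trial per condition; each measure is summarized
#' by a one-way ANOVA across conditions.
#'
#' @param config a [drex_config()] (default \code{D = 1}).
#' @param conditions standards-per-train conditions.
#' @param n_trials number of streams (50 for error df 147 over 3 conditions).
#' @param n_trains trains per stream (a multiple of
#'   \code{length(conditions)}).
#' @param base_seed integer seed.
#' @return list with elements \code{standards} and \code{deviants}, each a
#'   \code{drex_report}.
#' @export
replicate_roving <- function(config = drex_config(D = 1), conditions = c(2, 6, 12),
                             n_trials = 50, n_trains = 18, base_seed = 1) {
  rows <- list()
  for (i in seq_len(n_trials)) {
    seq <- gen_roving_oddball(conditions, n_trains = n_trains,
                              seed = base_seed + i - 1L)
    fit <- drex(seq, center_prior(config, seq$tones), keep_beliefs = FALSE)
    starts <- seq$metadata$train_starts
    ks <- seq$metadata$train_conditions
    use <- 3:n_trains                       # two-train burn-in
    d <- data.frame(condition = ks[use],
                    deviant = fit$surprisal[starts[use]],
                    final_standard = fit$surprisal[starts[use] + ks[use] - 1L])
    agg <- merge(aggregate(deviant ~ condition, d, mean),
                 aggregate(final_standard ~ condition, d, mean))
    agg$trial <- i
    rows[[i]] <- agg
  }
  df <- do.call(rbind, rows)
  mk <- function(col, label) {
    an <- drex_anova1(df[[col]], df$condition)
    desc <- aggregate(df[[col]], list(condition = df$condition),
                      function(z) c(mean = mean(z), sd = stats::sd(z)))
    desc <- data.frame(condition = desc$condition, mean = desc$x[, "mean"],
                       sd = desc$x[, "sd"])
    dirn <- if (all(diff(desc$mean) < 0)) "decreasing with standards" else
      if (all(diff(desc$mean) > 0)) "increasing with standards" else "no monotone trend"
    new_report(paste0("roving_", label), "F", an$statistic, an$df, an$p_value,
               direction = dirn, descriptives = desc, config = config,
               base_seed = base_seed, extra = list(data = df[, c("condition", "trial", col)]))
  }
  list(standards = mk("final_standard", "standards"),
       deviants = mk("deviant", "deviants"))
}

#' Pattern oddball: first-tone deviance requires joint statistics
#'
#' A stream of AABB patterns with rare BBAA deviants. With \code{D = 3} the
#' model conditions on the two preceding tones, so the first tone of a BBAA
#' pattern (a third consecutive B) is surprising; with \code{D = 1} the
#' stream's marginal tone statistics are identical for the two pattern types
#' and no first-tone difference is expected.
#'
#' @param config a [drex_config()] (default \code{D = 3}).
#' @param n_probes probes per group (38 for df 74).
#' @param n_patterns pattern slots in the stream (enlarged automatically if
#'   too few deviants occur).
#' @param p_deviant per-pattern deviance probability.
#' @param base_seed integer seed.
#' @param control_d1 also run the \code{D = 1} negative control on the same
#'   stream (reported in \code{extra$control_d1}).
#' @return a \code{drex_report}: pooled two-sample t-test of first-tone
#'   surprisal, deviant minus standard patterns.
#' @export
replicate_pattern_oddball <- function(config = drex_config(D = 3), n_probes = 38,
                                      n_patterns = 520, p_deviant = 0.1,
                                      base_seed = 1, control_d1 = TRUE) {
  burn_patterns <- 12L
  np <- n_patterns
  seed <- base_seed
  for (attempt in 1:6) {
    seq <- gen_pattern_oddball(n_patterns = np, p_deviant = p_deviant, seed = seed)
    L <- seq$metadata$pattern_length
    is_dev <- seq$metadata$is_deviant
    dev_idx <- which(is_dev & seq_along(is_dev) > burn_patterns)
    std_idx <- which(!is_dev & seq_along(is_dev) > burn_patterns)
    if (length(dev_idx) >= n_probes && length(std_idx) >= n_probes) break
    np <- ceiling(np * 1.5)
    seed <- seed + 17L
    if (attempt == 6) stop("could not realize enough deviant patterns")
  }
  dev_idx <- dev_idx[seq_len(n_probes)]
  # standards: evenly spread over the stream (deterministic)
  std_idx <- std_idx[round(seq(1, length(std_idx), length.out = n_probes))]
  first_tone <- function(p) (p - 1L) * L + 1L

  run_one <- function(cfg) {
    fit <- drex(seq, center_prior(cfg, seq$tones), keep_beliefs = FALSE)
    list(dev = fit$surprisal[first_tone(dev_idx)],
         std = fit$surprisal[first_tone(std_idx)])
  }
  s <- run_one(config)
  tt <- drex_ttest(s$dev, s$std)
  desc <- data.frame(group = c("deviant (BBAA)", "standard (AABB)"),
                     mean = c(mean(s$dev), mean(s$std)),
                     sd = c(stats::sd(s$dev), stats::sd(s$std)))
  extra <- list(surprisals = s)
  if (control_d1) {
    cfg1 <- drex_config(D = 1, M = config$M, N = config$N, hazard = config$hazard,
                        log_base = config$log_base)
    s1 <- run_one(cfg1)
    tt1 <- drex_ttest(s1$dev, s1$std)
    extra$control_d1 <- new_report("pattern_oddball_D1", "t", tt1$statistic,
                                   tt1$df, tt1$p_value,
                                   direction = sprintf("mean diff %.3f", tt1$mean_diff),
                                   config = cfg1, base_seed = base_seed)
  }
  new_report("pattern_oddball", "t", tt$statistic, tt$df, tt$p_value,
             direction = if (tt$mean_diff > 0) "deviant > standard" else "deviant < standard",
             descriptives = desc, config = config, base_seed = base_seed,
             extra = extra)
}

#' Predictability oddball: differential surprisal under marginal statistics
#'
#' High-predictability blocks (AAAAB) versus low-predictability blocks (2-6
#' standards then B). With \code{D = 1} the two conditions share marginal tone
#' statistics, so the differential surprisal (deviant minus immediately
#' preceding standard) should not differ between conditions (paired t-test
#' across blocks). With a dimensionality covering the whole block pattern
#' (\code{D = 6}), the model learns the AAAAB cycle and the deviant B loses
#' most of its surprisal (reported as mean differential surprisal).
#'
#' @param config a [drex_config()] with \code{D = 1}.
#' @param config_high_d a [drex_config()] whose D spans the AAAAB pattern.
#' @param n_pairs independent high/low stream pairs (24 for df 23); the paired
#'   observation is each stream's mean differential surprisal over its probed
#'   blocks, so stream-level variability enters the error term.
#' @param n_blocks blocks per stream; the last \code{n_probe} are probed.
#' @param n_probe probed blocks per stream.
#' @param jitter probability that a high-predictability block departs from 4
#'   standards ("usually 4": default 1/3, so two thirds of blocks are strict
#'   AAAAB).
#' @param base_seed integer seed.
#' @return a \code{drex_report} for the paired t-test; \code{extra} holds the
#'   per-stream mean differentials and the high-D comparison
#'   (\code{diff_d1_high}, \code{diff_d6_high}: mean differential surprisal in
#'   the high condition at \code{D = 1} and at the high dimensionality).
#' @export
replicate_predictability <- function(config = drex_config(D = 1),
                                     config_high_d = drex_config(D = 6),
                                     n_pairs = 24, n_blocks = 14, n_probe = 10,
                                     jitter = 1 / 3, base_seed = 1) {
  mean_diff <- function(seq, cfg) {
    fit <- drex(seq, center_prior(cfg, seq$tones), keep_beliefs = FALSE)
    pos <- seq$deviant_positions
    pos <- pos[(length(pos) - n_probe + 1L):length(pos)]
    mean(fit$surprisal[pos] - fit$surprisal[pos - 1L])
  }
  d_hi <- d_lo <- d_hi6 <- numeric(n_pairs)
  for (j in seq_len(n_pairs)) {
    hi <- gen_predictability_oddball("high", n_blocks = n_blocks, jitter = jitter,
                                     seed = base_seed + j - 1L)
    lo <- gen_predictability_oddball("low", n_blocks = n_blocks,
                                     seed = base_seed + 500L + j - 1L)
    d_hi[j] <- mean_diff(hi, config)
    d_lo[j] <- mean_diff(lo, config)
    d_hi6[j] <- mean_diff(hi, config_high_d)
  }
  tt <- drex_ttest(d_hi, d_lo, paired = TRUE)
  desc <- data.frame(condition = c("high", "low"),
                     mean = c(mean(d_hi), mean(d_lo)),
                     sd = c(stats::sd(d_hi), stats::sd(d_lo)))
  new_report("predictability", "t", tt$statistic, tt$df, tt$p_value,
             direction = sprintf("mean paired diff %.3f", tt$mean_diff),
             descriptives = desc, config = config, base_seed = base_seed,
             extra = list(diff_high = d_hi, diff_low = d_lo,
                          diff_d1_high = mean(d_hi), diff_d6_high = mean(d_hi6),
                          config_high_d = config_high_d))
}

#' Statistical oddball: spectral change and statistical context effects
#'
#' Two oddball streams share three deviant offsets but differ in the offset
#' probabilities (biased toward small changes in one context, large changes
#' in the other). Deviant surprisal is analyzed with a main-effects two-way
#' ANOVA on spectral change (3 levels) and context (2 levels).
#'
#' @param config a [drex_config()] (default \code{D = 1}).
#' @param offsets three deviant offsets, semitones.
#' @param bias_probs probability triple (small-biased order).
#' @param n_probes named/unnamed length-2 vector: probed deviants per context
#'   (small-, then large-biased); defaults give error df 477.
#' @param base_seed integer seed.
#' @return list with \code{drex_report}s \code{spectral} and \code{context}
#'   plus the probe-level \code{data}.
#' @export
replicate_biased_context <- function(config = drex_config(D = 1),
                                     offsets = c(2, 6, 12),
                                     bias_probs = c(0.7, 0.2, 0.1),
                                     n_probes = c(240, 241), base_seed = 1) {
  burn_dev <- 5L
  run_ctx <- function(ctx, n_probe, seed) {
    seq <- gen_biased_context(standard = 0, deviant_offsets = offsets,
                              context = ctx, bias_probs = bias_probs,
                              n_deviants = n_probe + burn_dev, seed = seed)
    fit <- drex(seq, center_prior(config, seq$tones), keep_beliefs = FALSE)
    use <- (burn_dev + 1L):(n_probe + burn_dev)
    data.frame(context = ctx,
               offset = seq$metadata$offsets[use],
               surprisal = fit$surprisal[seq$deviant_positions[use]])
  }
  df <- rbind(run_ctx("small_biased", n_probes[1], base_seed),
              run_ctx("large_biased", n_probes[2], base_seed + 500L))
  an <- drex_anova2(df$surprisal, df$offset, df$context)
  desc <- aggregate(surprisal ~ offset + context, df,
                    function(z) c(mean = mean(z), n = length(z)))
  desc <- data.frame(offset = desc$offset, context = desc$context,
                     mean = desc$surprisal[, "mean"], n = desc$surprisal[, "n"])
  off_means <- aggregate(surprisal ~ offset, df, mean)
  # context direction from per-offset (adjusted) means: the raw marginal
  # means are confounded by the deliberately unbalanced offset mix
  cell <- aggregate(surprisal ~ offset + context, df, mean)
  adj <- aggregate(surprisal ~ context, cell, mean)
  spectral <- new_report("biased_context_spectral", "F", an$f1$statistic,
                         an$f1$df, an$f1$p_value,
                         direction = if (all(diff(off_means$surprisal[order(off_means$offset)]) > 0))
                           "increasing with offset" else "non-monotone",
                         descriptives = desc, config = config, base_seed = base_seed)
  small_elev <- adj$surprisal[adj$context == "small_biased"] >
    adj$surprisal[adj$context == "large_biased"]
  context <- new_report("biased_context_context", "F", an$f2$statistic,
                        an$f2$df, an$f2$p_value,
                        direction = if (small_elev) "small-biased context elevates surprisal"
                        else "large-biased context elevates surprisal",
                        descriptives = desc, config = config, base_seed = base_seed)
  list(spectral = spectral, context = context, data = df)
}

#' Gaussian contexts: deviant surprisal in narrow versus broad variance
#'
#' Deviants two octaves above the mean embedded in i.i.d. Gaussian streams of
#' narrow or broad standard deviation. Deviant surprisal is compared between
#' contexts (two-sample t-test; expected direction narrow > broad), and an
#' adaptation analysis within the broad context bins deviant probes by the
#' number N_a of the preceding \code{k} tones falling outside the frequency
#' band mean +/- \code{delta_f}; the per-bin mean surprisal and the sign of
#' its trend are reported (the trend direction is a reported diagnostic, not
#' an asserted effect).
#'
#' @param config a [drex_config()] (default \code{D = 1}).
#' @param sd_narrow,sd_broad context standard deviations, semitones.
#' @param n_tones tones per stream.
#' @param deviant_every deviant period.
#' @param k preceding tones considered in the adaptation analysis.
#' @param delta_f half-width of the adaptation frequency band, semitones.
#' @param base_seed integer seed.
#' @return list with the t-test \code{drex_report}, the \code{adaptation}
#'   table, and \code{trend} (sign of the fitted slope of surprisal on N_a).
#' @export
replicate_gaussian_context <- function(config = drex_config(D = 1),
                                       sd_narrow = 1, sd_broad = 5,
                                       n_tones = 400, deviant_every = 10,
                                       k = 5, delta_f = 5, base_seed = 1) {
  burn_dev <- 2L
  run_ctx <- function(sd, seed) {
    seq <- gen_gaussian_context(mean = 0, sd = sd, n_tones = n_tones,
                                deviant_every = deviant_every, seed = seed)
    fit <- drex(seq, center_prior(config, seq$tones), keep_beliefs = FALSE)
    pos <- seq$deviant_positions
    pos <- pos[-seq_len(burn_dev)]
    list(seq = seq, pos = pos, s = fit$surprisal[pos])
  }
  nar <- run_ctx(sd_narrow, base_seed)
  bro <- run_ctx(sd_broad, base_seed + 500L)
  tt <- drex_ttest(nar$s, bro$s)
  desc <- data.frame(context = c("narrow", "broad"),
                     mean = c(mean(nar$s), mean(bro$s)),
                     sd = c(stats::sd(nar$s), stats::sd(bro$s)))
  # adaptation: count preceding tones outside the band, excluding deviants
  na_count <- vapply(bro$pos, function(p) {
    prev <- bro$seq$tones[max(1L, p - k):(p - 1L)]
    sum(abs(prev - 0) > delta_f)
  }, numeric(1))
  adapt <- aggregate(list(mean_surprisal = bro$s), list(N_a = na_count), mean)
  adapt$n <- as.integer(table(na_count)[as.character(adapt$N_a)])
  trend <- if (nrow(adapt) > 1 && stats::var(na_count) > 0)
    sign(unname(stats::coef(stats::lm(bro$s ~ na_count))[2])) else NA_real_
  report <- new_report("gaussian_context", "t", tt$statistic, tt$df, tt$p_value,
                       direction = if (tt$mean_diff > 0) "narrow > broad" else "broad >= narrow",
                       descriptives = desc, config = config, base_seed = base_seed)
  list(context = report, adaptation = adapt, trend = trend)
}

#' Regular/random transitions: detection asymmetry and pattern-length effect
#'
#' Trial-averaged surprisal time-courses around transitions between a
#' cyclically repeating pattern (REG) and random draws from a tone pool
#' (RAND), with a dimensionality exceeding the longest pattern. Metrics: the
#' REG-to-RAND detection lag (tones until the averaged surprisal first
#' exceeds the pre-transition mean + 3 sd; structure loss is abrupt), the
#' RAND-to-REG detection lag (tones until it first falls below the
#' pre-transition mean - 1 sd; structure gain is gradual, at least one full
#' cycle), and the steady-state REG surprisal, which grows with pattern
#' length (higher entropy patterns are harder to consolidate).
#'
#' @param pattern_lengths pattern lengths to test.
#' @param config a [drex_config()]; default uses
#'   \code{D = max(pattern_lengths) + 1}.
#' @param n_trials trials averaged per condition.
#' @param half_len tones per regime half.
#' @param base_seed integer seed.
#' @return list with per-length metrics table (\code{lag_reg_rand},
#'   \code{lag_rand_reg}, \code{steady_reg}) and the averaged time-courses.
#' @export
replicate_reg_rand <- function(pattern_lengths = c(4, 8, 12), config = NULL,
                               n_trials = 10, half_len = 100, base_seed = 1) {
  if (is.null(config)) config <- drex_config(D = max(pattern_lengths) + 1, M = 50)
  if (config$D <= max(pattern_lengths))
    stop("config$D must exceed the longest pattern length")
  n_tones <- 2L * half_len
  trans <- half_len + 1L
  curves <- list()
  metrics <- data.frame()
  for (L in pattern_lengths) {
    for (dir in c("REG_RAND", "RAND_REG")) {
      mat <- vapply(seq_len(n_trials), function(i) {
        seq <- gen_reg_rand(pattern_length = L, direction = dir,
                            n_tones = n_tones,
                            seed = base_seed + 100L * L + i - 1L)
        drex(seq, center_prior(config, seq$tones), keep_beliefs = FALSE)$surprisal
      }, numeric(n_tones))
      curves[[paste(dir, L, sep = "_")]] <- rowMeans(mat)
    }
    avg_rr <- curves[[paste("REG_RAND", L, sep = "_")]]
    avg_rg <- curves[[paste("RAND_REG", L, sep = "_")]]
    pre <- function(curve) curve[(trans - 30L):(trans - 1L)]
    post <- function(curve) curve[trans:(trans + 39L)]
    # detection lag = first tone from which the averaged curve stays beyond
    # the threshold for the rest of the analysis window (detection with
    # retention); an isolated excursion of the averaged curve is noise, not a
    # detected regime change
    retained <- function(beyond) {
      ok <- which(rev(cumprod(rev(beyond))) == 1)
      if (length(ok)) ok[1] else NA_integer_
    }
    up_thr <- mean(pre(avg_rr)) + 3 * stats::sd(pre(avg_rr))
    dn_thr <- mean(pre(avg_rg)) - 1 * stats::sd(pre(avg_rg))
    lag_up <- retained(post(avg_rr) > up_thr)
    lag_dn <- retained(post(avg_rg) < dn_thr)
    steady <- mean(avg_rg[(n_tones - 39L):n_tones])   # REG tail of RAND->REG
    metrics <- rbind(metrics, data.frame(
      pattern_length = L,
      lag_reg_rand = if (is.na(lag_up)) Inf else lag_up,
      lag_rand_reg = if (is.na(lag_dn)) Inf else lag_dn,
      steady_reg = steady))
  }
  list(metrics = metrics, curves = curves, transition = trans,
       config = config, base_seed = base_seed)
}
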