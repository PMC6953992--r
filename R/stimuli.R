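# Seeded generators for the deviance / regularity paradigms used in the
# auditory statistical-learning literature. Every generator is a pure
# function of its parameters and seed; annotations (deviant positions,
# transition index) are recorded at construction time. Tones are emitted
# directly in semitones (log-frequency re 440 Hz); positions are 1-based.

#' Annotated tone sequence
#'
#' Container for a single-source tone sequence together with its construction
#' annotations: positions of deviant tones, an optional regime-transition
#' index, a condition label, and generator metadata.
#'
#' @param tones numeric vector of tones in semitones; must be finite.
#' @param deviant_positions sorted integer positions (1-based) of deviants.
#' @param condition optional condition label.
#' @param transition_index optional 1-based index of the first tone of the
#'   second regime (regular/random transitions).
#' @param metadata list of generator parameters.
#' @return an object of class \code{tone_seq}.
#' @examples
#' tone_seq(c(0, 0, 0, 12), deviant_positions = 4L)
#' @export
tone_seq <- function(tones, deviant_positions = integer(0),
                     condition = NA_character_, transition_index = NA_integer_,
                     metadata = list()) {
  tones <- as.numeric(tones)
  if (length(tones) == 0L) stop("empty tone sequence")
  if (any(!is.finite(tones))) stop("tones must be finite")
  dp <- as.integer(deviant_positions)
  if (any(dp < 1L | dp > length(tones))) stop("deviant_positions out of range")
  if (is.unsorted(dp)) dp <- sort(dp)
  ti <- as.integer(transition_index)
  if (!is.na(ti) && (ti < 1L || ti > length(tones))) stop("transition_index out of range")
  structure(list(tones = tones, deviant_positions = dp, condition = condition,
                 transition_index = ti, metadata = metadata),
            class = "tone_seq")
}

#' @export
length.tone_seq <- function(x) length(x$tones)

#' @export
print.tone_seq <- function(x, ...) {
  cat("tone_seq: ", length(x$tones), " tones",
      if (!is.na(x$condition)) paste0(" [", x$condition, "]"), "\n", sep = "")
  cat("  range: ", signif(min(x$tones), 4), " to ", signif(max(x$tones), 4),
      " semitones; ", length(x$deviant_positions), " annotated deviants\n", sep = "")
  if (!is.na(x$transition_index))
    cat("  regime transition at tone ", x$transition_index, "\n", sep = "")
  invisible(x)
}

#' @export
plot.tone_seq <- function(x, ...) {
  plot(x$tones, type = "o", pch = 20, cex = 0.6, xlab = "tone index",
       ylab = "semitones", ...)
  if (length(x$deviant_positions))
    points(x$deviant_positions, x$tones[x$deviant_positions], col = 2, pch = 1, cex = 1.3)
  if (!is.na(x$transition_index)) abline(v = x$transition_index - 0.5, lty = 2, col = 4)
  invisible(x)
}

#' Oddball sequence: standards with rare frequency deviants
#'
#' Repeats a standard tone and interleaves deviants offset from it in
#' frequency. Each requested offset occurs \code{n_deviants} times; the order
#' of deviant instances is randomized by \code{seed}.
#'
#' @param standard standard tone, semitones.
#' @param deviant_offsets nonzero offsets of deviants from the standard,
#'   semitones.
#' @param n_standards_between number of standards preceding each deviant
#'   (at least 2).
#' @param n_deviants number of deviant instances per offset.
#' @param seed integer RNG seed.
#' @return a [tone_seq()]; \code{metadata$offsets} records the offset of each
#'   deviant in sequence order.
#' @examples
#' gen_oddball(0, c(2, 6, 12, 24), n_standards_between = 9, n_deviants = 2, seed = 1)
#' @export
gen_oddball <- function(standard, deviant_offsets, n_standards_between = 9,
                        n_deviants = 6, seed = 1) {
  if (any(deviant_offsets == 0)) stop("deviant offsets must be nonzero")
  if (n_standards_between < 2) stop("n_standards_between must be at least 2")
  if (n_deviants < 1) stop("n_deviants must be at least 1")
  slots <- rep(deviant_offsets, each = n_deviants)
  slots <- with_seed(seed, sample(slots))
  block <- n_standards_between + 1L
  tones <- rep(standard, block * length(slots))
  pos <- block * seq_along(slots)
  tones[pos] <- standard + slots
  tone_seq(tones, deviant_positions = pos, condition = "oddball",
           metadata = list(paradigm = "oddball", standard = standard,
                           offsets = slots, n_standards_between = n_standards_between,
                           seed = seed))
}

#' Roving oddball: trains of a repeating standard that changes over time
#'
#' Emits consecutive trains; each train repeats one tone k times, where k is
#' drawn (balanced) from \code{n_standards_conditions}, then jumps to a new
#' frequency, so each deviant becomes the new standard. Train onsets after the
#' first are the deviants.
#'
#' @param n_standards_conditions integer vector of per-train repetition counts
#'   (each at least 2); assignment to trains is balanced, order randomized.
#' @param step_range length-2 vector: minimum and maximum frequency jump
#'   magnitude between consecutive trains, semitones.
#' @param n_trains number of trains.
#' @param freq_range length-2 vector bounding tone frequencies, semitones.
#' @param seed integer RNG seed.
#' @return a [tone_seq()]; \code{metadata$train_starts} and
#'   \code{metadata$train_conditions} record per-train structure.
#' @examples
#' gen_roving_oddball(c(2, 6, 12), n_trains = 6, seed = 1)
#' @export
gen_roving_oddball <- function(n_standards_conditions, step_range = c(2, 6),
                               n_trains = 12, freq_range = c(-12, 12), seed = 1) {
  if (length(n_standards_conditions) == 0L) stop("empty conditions list")
  if (any(n_standards_conditions < 2)) stop("each condition count must be at least 2")
  if (step_range[1] <= 0 || step_range[2] < step_range[1]) stop("invalid step_range")
  if (diff(freq_range) < 2 * step_range[1]) stop("freq_range too narrow for step_range")
  with_seed(seed, {
    ks <- sample(rep_len(n_standards_conditions, n_trains))
    tone <- runif(1, freq_range[1], freq_range[2])
    train_tones <- numeric(n_trains)
    for (i in seq_len(n_trains)) {
      train_tones[i] <- tone
      repeat {
        cand <- runif(1, freq_range[1], freq_range[2])
        d <- abs(cand - tone)
        if (d >= step_range[1] && d <= step_range[2]) break
      }
      tone <- cand
    }
    tones <- rep(train_tones, times = ks)
    starts <- cumsum(c(1L, ks[-n_trains]))
    tone_seq(tones, deviant_positions = starts[-1L], condition = "roving",
             metadata = list(paradigm = "roving", train_starts = starts,
                             train_conditions = ks, step_range = step_range,
                             seed = seed))
  })
}

#' Pattern oddball: streams of a standard tone pattern with deviant patterns
#'
#' Concatenates \code{n_patterns} copies of the standard pattern; each copy is
#' independently replaced by the deviant pattern with probability
#' \code{p_deviant}. The annotated deviant position is the first tone of each
#' deviant pattern.
#'
#' @param standard_pattern,deviant_pattern character vectors of equal length
#'   of tone labels.
#' @param tone_map named numeric vector mapping labels to semitones.
#' @param n_patterns number of pattern slots.
#' @param p_deviant per-pattern deviance probability.
#' @param seed integer RNG seed.
#' @return a [tone_seq()]; \code{metadata$is_deviant} flags each pattern slot.
#' @examples
#' gen_pattern_oddball(n_patterns = 10, p_deviant = 0.2, seed = 1)
#' @export
gen_pattern_oddball <- function(standard_pattern = c("A", "A", "B", "B"),
                                deviant_pattern = c("B", "B", "A", "A"),
                                tone_map = c(A = 0, B = 6),
                                n_patterns = 100, p_deviant = 0.1, seed = 1) {
  if (length(standard_pattern) != length(deviant_pattern))
    stop("standard and deviant patterns must have equal length")
  labs <- unique(c(standard_pattern, deviant_pattern))
  if (!all(labs %in% names(tone_map))) stop("tone_map must cover all pattern labels")
  if (p_deviant < 0 || p_deviant > 1) stop("p_deviant must be a probability")
  L <- length(standard_pattern)
  is_dev <- with_seed(seed, stats::runif(n_patterns) < p_deviant)
  std <- unname(tone_map[standard_pattern])
  dev <- unname(tone_map[deviant_pattern])
  tones <- unlist(lapply(is_dev, function(d) if (d) dev else std), use.names = FALSE)
  pos <- (which(is_dev) - 1L) * L + 1L
  tone_seq(tones, deviant_positions = pos, condition = "pattern_oddball",
           metadata = list(paradigm = "pattern", pattern_length = L,
                           is_deviant = is_dev, tone_map = tone_map,
                           p_deviant = p_deviant, seed = seed))
}

#' High- or low-predictability oddball blocks
#'
#' Blocks of standards (label A) terminated by a deviant (label B). In the
#' \code{"high"} condition each block has 4 standards (optionally jittered to
#' 3 or 5 with probability \code{jitter}); in the \code{"low"} condition the
#' per-block standard count is uniform on 2..6, matching the deviant rate of
#' the high condition in expectation.
#'
#' @param condition \code{"high"} or \code{"low"}.
#' @param n_blocks number of blocks (at least 1).
#' @param tone_map named numeric vector with entries \code{A} and \code{B}.
#' @param jitter probability that a high-predictability block deviates from 4
#'   standards (default 0: strict AAAAB).
#' @param seed integer RNG seed.
#' @return a [tone_seq()] with deviant (B) positions annotated;
#'   \code{metadata$block_lengths} gives per-block standard counts.
#' @examples
#' gen_predictability_oddball("high", n_blocks = 3)
#' gen_predictability_oddball("low", n_blocks = 3, seed = 7)
#' @export
gen_predictability_oddball <- function(condition = c("high", "low"), n_blocks = 24,
                                       tone_map = c(A = 0, B = 6), jitter = 0,
                                       seed = 1) {
  condition <- match.arg(condition)
  if (n_blocks < 1) stop("n_blocks must be at least 1")
  ks <- with_seed(seed, {
    if (condition == "high") {
      k <- rep(4L, n_blocks)
      j <- stats::runif(n_blocks) < jitter
      k[j] <- sample(c(3L, 5L), sum(j), replace = TRUE)
      k
    } else sample(2:6, n_blocks, replace = TRUE)
  })
  tones <- unlist(lapply(ks, function(k) c(rep(tone_map[["A"]], k), tone_map[["B"]])),
                  use.names = FALSE)
  pos <- cumsum(ks + 1L)
  tone_seq(tones, deviant_positions = pos, condition = condition,
           metadata = list(paradigm = "predictability", block_lengths = ks,
                           tone_map = tone_map, jitter = jitter, seed = seed))
}

#' Statistical oddball with context-biased deviant probabilities
#'
#' Oddball stream whose deviants take one of three offsets with probabilities
#' biased toward small changes (\code{"small_biased"}: \code{bias_probs}
#' aligned with offsets sorted by magnitude) or toward large changes
#' (\code{"large_biased"}: the reversed probabilities).
#'
#' @param standard standard tone, semitones.
#' @param deviant_offsets three offsets, semitones (sorted by magnitude).
#' @param context \code{"small_biased"} or \code{"large_biased"}.
#' @param bias_probs probability triple summing to 1, aligned with
#'   \code{deviant_offsets} in the small-biased context.
#' @param n_deviants number of deviants; each is preceded by
#'   \code{n_standards_between} standards.
#' @param n_standards_between standards before each deviant.
#' @param seed integer RNG seed.
#' @return a [tone_seq()]; \code{metadata$offsets} records each deviant's
#'   offset in sequence order.
#' @examples
#' gen_biased_context(context = "small_biased", n_deviants = 20, seed = 3)
#' @export
gen_biased_context <- function(standard = 0, deviant_offsets = c(2, 6, 12),
                               context = c("small_biased", "large_biased"),
                               bias_probs = c(0.7, 0.2, 0.1),
                               n_deviants = 50, n_standards_between = 9, seed = 1) {
  context <- match.arg(context)
  if (length(deviant_offsets) != 3L) stop("exactly three deviant offsets are required")
  if (length(bias_probs) != 3L || abs(sum(bias_probs) - 1) > 1e-8)
    stop("bias_probs must be three probabilities summing to 1")
  if (any(bias_probs < 0)) stop("bias_probs must be non-negative")
  ord <- order(abs(deviant_offsets))
  offs <- deviant_offsets[ord]
  probs <- if (context == "small_biased") bias_probs else rev(bias_probs)
  drawn <- with_seed(seed, sample(offs, n_deviants, replace = TRUE, prob = probs))
  block <- n_standards_between + 1L
  tones <- rep(standard, block * n_deviants)
  pos <- block * seq_len(n_deviants)
  tones[pos] <- standard + drawn
  tone_seq(tones, deviant_positions = pos, condition = context,
           metadata = list(paradigm = "biased_context", standard = standard,
                           offsets = drawn, bias_probs = probs, seed = seed))
}

#' Gaussian tone sequence with periodic out-of-distribution deviants
#'
#' Tones are i.i.d. Gaussian in semitones (a narrow or broad statistical
#' context, depending on \code{sd}); every \code{deviant_every}-th tone is
#' replaced by a deviant \code{deviant_offset} semitones above the mean
#' (default +24: two octaves).
#'
#' @param mean context mean, semitones.
#' @param sd context standard deviation, semitones (positive).
#' @param n_tones sequence length.
#' @param deviant_every deviant period in tones.
#' @param deviant_offset deviant offset above the mean, semitones.
#' @param seed integer RNG seed.
#' @return a [tone_seq()].
#' @examples
#' gen_gaussian_context(sd = 5, n_tones = 50, deviant_every = 10, seed = 2)
#' @export
gen_gaussian_context <- function(mean = 0, sd = 1, n_tones = 400,
                                 deviant_every = 10, deviant_offset = 24, seed = 1) {
  if (sd <= 0) stop("sd must be positive")
  if (deviant_every < 2) stop("deviant_every must be at least 2")
  tones <- with_seed(seed, stats::rnorm(n_tones, mean, sd))
  pos <- seq(deviant_every, n_tones, by = deviant_every)
  tones[pos] <- mean + deviant_offset
  tone_seq(tones, deviant_positions = pos,
           condition = if (sd <= 2) "narrow" else "broad",
           metadata = list(paradigm = "gaussian_context", mean = mean, sd = sd,
                           deviant_offset = deviant_offset, seed = seed))
}

#' Regular-to-random (and reverse) tone sequences
#'
#' One half of the sequence is random draws (with replacement) from a tone
#' pool; the other half cyclically repeats a pattern of
#' \code{pattern_length} distinct pool tones. \code{direction} selects which
#' half comes first; the transition index marks the first tone of the second
#' regime.
#'
#' @param pool candidate tones, semitones.
#' @param pattern_length number of distinct tones in the repeating pattern
#'   (at most the pool size).
#' @param direction \code{"RAND_REG"} (random first) or \code{"REG_RAND"}.
#' @param n_tones total length (greater than twice the pattern length).
#' @param transition 1-based index of the first tone of the second regime;
#'   defaults to the midpoint.
#' @param seed integer RNG seed.
#' @return a [tone_seq()] with \code{transition_index} set.
#' @examples
#' gen_reg_rand(pattern_length = 4, direction = "REG_RAND", n_tones = 40, seed = 5)
#' @export
gen_reg_rand <- function(pool = seq(-12, 12, length.out = 20), pattern_length = 4,
                         direction = c("RAND_REG", "REG_RAND"), n_tones = 160,
                         transition = NULL, seed = 1) {
  direction <- match.arg(direction)
  if (pattern_length > length(pool)) stop("pattern_length exceeds pool size")
  if (n_tones <= 2 * pattern_length) stop("n_tones must exceed twice the pattern length")
  if (is.null(transition)) transition <- floor(n_tones / 2) + 1L
  if (transition < 2L || transition > n_tones) stop("transition out of range")
  with_seed(seed, {
    pattern <- sample(pool, pattern_length)
    n1 <- transition - 1L
    n2 <- n_tones - n1
    reg <- function(n) rep_len(pattern, n)
    rnd <- function(n) sample(pool, n, replace = TRUE)
    tones <- if (direction == "RAND_REG") c(rnd(n1), reg(n2)) else c(reg(n1), rnd(n2))
    tone_seq(tones, condition = direction, transition_index = as.integer(transition),
             metadata = list(paradigm = "reg_rand", pattern = pattern,
                             pattern_length = pattern_length, pool = pool,
                             seed = seed))
  })
}

# dispatch used by run_trials() and the command-line `simulate` entry point
generate_stimulus <- function(paradigm, parameters = list(), seed = 1) {
  gen <- switch(paradigm,
                oddball = gen_oddball,
                roving = gen_roving_oddball,
                pattern = gen_pattern_oddball,
                predictability = gen_predictability_oddball,
                biased_context = gen_biased_context,
                gaussian_context = gen_gaussian_context,
                reg_rand = gen_reg_rand,
                stop("unknown paradigm: ", paradigm))
  do.call(gen, c(parameters, list(seed = seed)))
}
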