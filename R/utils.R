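# Small internal numerics helpers.

# log(sum(exp(x))) without overflow; returns -Inf for empty/all -Inf input
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Convert frequency in Hz to semitones re 440 Hz
#'
#' Tones are modelled on a logarithmic frequency scale; 12 semitones span one
#' octave, with 440 Hz mapping to 0 semitones.
#'
#' @param hz numeric vector of frequencies in Hz (must be positive).
#' @return numeric vector of semitones relative to 440 Hz.
#' @examples
#' hz_to_semitones(c(440, 880, 220))
#' @export
hz_to_semitones <- function(hz) {
  if (any(!is.finite(hz)) || any(hz <= 0)) stop("frequencies must be positive and finite")
  12 * log2(hz / 440)
}

#' @rdname hz_to_semitones
#' @param semitones numeric vector of semitones re 440 Hz.
#' @export
semitones_to_hz <- function(semitones) 440 * 2^(semitones / 12)

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All stimulus randomness goes through this.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
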