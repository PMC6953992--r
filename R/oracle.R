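#' Exact changepoint-enumeration predictive (test oracle)
#'
#' Computes the context-integrated one-step-ahead predictive density of every
#' tone by brute force: for tone t it enumerates all 2^(t-1) placements of
#' changepoints in the t-1 gaps between preceding tones, scores each placement
#' by its hazard prior times the sequential marginal likelihood of the
#' observed prefix under that segmentation, and mixes the per-placement
#' predictive densities. This is an independent, exponential-cost route to the
#' same quantity that the run-length recursion in [drex()] computes in linear
#' time; the two must agree to high precision.
#'
#' @param x numeric vector of tones (semitones) or a [tone_seq()];
#'   length at most 12 (combinatorial cost).
#' @param config a [drex_config()] with unbounded memory (\code{M = Inf}).
#' @return numeric vector of per-tone mixture log-predictive densities
#'   (natural log), comparable to \code{drex(x, config)$log_predictive}.
#' @examples
#' cfg <- drex_config(D = 1, M = Inf, hazard = 0.05)
#' x <- c(0, 0.5, 6)
#' all.equal(enumerate_predictive(x, cfg), drex(x, cfg)$log_predictive)
#' @export
enumerate_predictive <- function(x, config) {
  seq <- if (inherits(x, "tone_seq")) x else tone_seq(x)
  tones <- seq$tones
  T <- length(tones)
  if (T > 12L) stop("enumeration refuses sequences longer than 12 tones (2^(T-1) placements)")
  if (is.finite(config$M)) stop("enumeration requires unbounded memory (M = Inf)")
  lh <- log(config$hazard)
  l1h <- log1p(-config$hazard)
  out <- numeric(T)

  for (t in seq_len(T)) {
    ng <- t - 1L
    n_pl <- 2L^ng
    lw <- lik <- pred <- numeric(n_pl)
    for (p in seq_len(n_pl)) {
      # bits of p-1 give the changepoint indicator for each gap; gap j sits
      # between tones j and j+1, a 1 starting a new segment at tone j+1
      z <- if (ng > 0L) as.integer(intToBits(p - 1L))[seq_len(ng)] else integer(0)
      lw[p] <- sum(z) * lh + (ng - sum(z)) * l1h
      seg_start <- 1L
      st <- new_hypothesis_stats(config$D)
      ll <- 0
      for (u in seq_len(t)) {
        if (u > 1L && z[u - 1L] == 1L) {     # changepoint in gap u-1
          seg_start <- u
          st <- new_hypothesis_stats(config$D)
        }
        m <- min(config$D - 1L, u - seg_start)
        tail <- if (m > 0L) tones[(u - m):(u - 1L)] else numeric(0)
        ld <- t_logdensity(tones[u], predictive_params(niw_posterior(st, config$prior),
                                                       tail, config))
        if (u < t) ll <- ll + ld else pred[p] <- ld
        if (u - seg_start + 1L >= config$D)
          st <- stats_add(st, tones[(u - config$D + 1L):u])
      }
      lik[p] <- ll
    }
    out[t] <- logsumexp(lw + lik + pred) - logsumexp(lw + lik)
  }
  out
}
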