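# S3 methods for fitted drex objects.

#' @export
print.drex <- function(x, ...) {
  cfg <- x$config
  cat("Dynamic regularity extraction fit\n")
  cat("  ", length(x$tones), " tones; D = ", cfg$D, ", M = ",
      if (is.finite(cfg$M)) cfg$M else "unbounded", ", N = ", cfg$N,
      ", hazard = ", cfg$hazard, "\n", sep = "")
  units <- if (abs(cfg$log_base - 2) < 1e-12) "bits" else "nats"
  cat("  mean surprisal: ", signif(mean(x$surprisal), 4), " ", units,
      "; max ", signif(max(x$surprisal), 4), " at tone ",
      which.max(x$surprisal), "\n", sep = "")
  invisible(x)
}

#' Summarize a fitted drex model
#'
#' @param object a [drex()] fit.
#' @param n_top number of highest-surprisal tones to list.
#' @param ... unused.
#' @return a \code{summary.drex} object: surprisal quantiles, the most
#'   surprising tones, deviant/standard means when annotations are present,
#'   and the configuration.
#' @export
summary.drex <- function(object, n_top = 5, ...) {
  s <- object$surprisal
  top <- order(s, decreasing = TRUE)[seq_len(min(n_top, length(s)))]
  dev <- object$seq$deviant_positions
  out <- list(n = length(s),
              quantiles = stats::quantile(s, c(0, .25, .5, .75, 1)),
              top = data.frame(t = top, tone = object$tones[top], surprisal = s[top]),
              deviant_mean = if (length(dev)) mean(s[dev]) else NA_real_,
              standard_mean = if (length(dev)) mean(s[-dev]) else NA_real_,
              config = object$config)
  class(out) <- "summary.drex"
  out
}

#' @export
print.summary.drex <- function(x, ...) {
  cat("drex fit over", x$n, "tones\n")
  cat("surprisal quantiles:\n"); print(signif(x$quantiles, 4))
  if (!is.na(x$deviant_mean))
    cat("mean surprisal at annotated deviants: ", signif(x$deviant_mean, 4),
        "; elsewhere: ", signif(x$standard_mean, 4), "\n", sep = "")
  cat("most surprising tones:\n"); print(x$top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.drex <- function(object, ...) {
  T <- length(object$tones)
  c(predictive_location = object$predictive_location[T],
    predictive_scale = object$predictive_scale[T],
    predictive_dof = object$predictive_dof[T],
    map_run_length = object$map_run_length[T])
}

#' @export
fitted.drex <- function(object, ...) object$predictive_location

#' One-step-ahead innovations standardized by the predictive scale
#' @param object a [drex()] fit.
#' @param ... unused.
#' @export
residuals.drex <- function(object, ...) {
  (object$tones - object$predictive_location) / object$predictive_scale
}

#' @export
logLik.drex <- function(object, ...) {
  structure(sum(object$log_predictive), df = NA_integer_,
            nobs = length(object$tones), class = "logLik")
}

# predictive mixture components for the tone after the end of the sequence
next_tone_mixture <- function(object) {
  cfg <- object$config
  state <- object$state
  tones <- object$tones
  t <- length(tones) + 1L
  comp <- lapply(seq_along(state$run), function(i) {
    m <- min(cfg$D - 1L, state$run[i])
    tail <- if (m > 0L) tones[(t - m):(t - 1L)] else numeric(0)
    predictive_params(niw_posterior(state$stats[[i]], cfg$prior), tail, cfg)
  })
  data.frame(run_length = state$run, weight = exp(state$logw),
             location = vapply(comp, `[[`, numeric(1), "location"),
             scale = vapply(comp, `[[`, numeric(1), "scale"),
             dof = vapply(comp, `[[`, numeric(1), "dof"))
}

#' Predictive distribution of the next tone
#'
#' Without \code{newdata}, returns the mixture components (one per context
#' hypothesis) of the one-step-ahead predictive distribution after the last
#' observed tone. With \code{newdata}, evaluates the mixture at candidate
#' next tones and returns their log-density and surprisal.
#'
#' @param object a [drex()] fit.
#' @param newdata optional numeric vector of candidate next tones, semitones.
#' @param ... unused.
#' @return a data frame of mixture components, or (given \code{newdata}) a
#'   data frame with \code{tone}, \code{log_density}, \code{surprisal}.
#' @export
predict.drex <- function(object, newdata = NULL, ...) {
  mix <- next_tone_mixture(object)
  if (is.null(newdata)) return(mix)
  ld <- vapply(as.numeric(newdata), function(x) {
    logsumexp(log(mix$weight) +
                mapply(function(l, s, d) t_logdensity(x, list(location = l, scale = s, dof = d)),
                       mix$location, mix$scale, mix$dof))
  }, numeric(1))
  data.frame(tone = as.numeric(newdata), log_density = ld,
             surprisal = -ld / log(object$config$log_base))
}

#' Simulate future tones from the fitted predictive model
#'
#' Continues the sequence by sampling each next tone from the current
#' context-integrated predictive mixture, then updating the model state with
#' the sampled tone, for \code{n_ahead} steps.
#'
#' @param object a [drex()] fit.
#' @param nsim number of simulated continuations.
#' @param seed optional RNG seed.
#' @param n_ahead tones to simulate per continuation.
#' @param ... unused.
#' @return an \code{n_ahead} x \code{nsim} matrix of tones (semitones).
#' @export
simulate.drex <- function(object, nsim = 1, seed = NULL, n_ahead = 20, ...) {
  cfg <- object$config
  sim_one <- function() {
    state <- object$state
    tones <- object$tones
    out <- numeric(n_ahead)
    for (j in seq_len(n_ahead)) {
      mix <- next_tone_mixture(structure(list(config = cfg, state = state,
                                              tones = tones), class = "drex"))
      i <- sample.int(nrow(mix), 1L, prob = mix$weight)
      x <- mix$location[i] + mix$scale[i] * stats::rt(1, mix$dof[i])
      tones <- c(tones, x)
      out[j] <- x
      state <- drex_step(state, length(tones), tones, cfg)$state
    }
    out
  }
  body <- function() vapply(seq_len(nsim), function(k) sim_one(), numeric(n_ahead))
  if (is.null(seed)) body() else with_seed(seed, body())
}

#' Plot a fitted drex model
#'
#' Two stacked panels: the tone sequence (deviants highlighted, transition
#' marked) and the per-tone surprisal trace.
#'
#' @param x a [drex()] fit.
#' @param ... further arguments passed to the surprisal panel's plot call.
#' @export
plot.drex <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(2.5, 4, 1, 1))
  on.exit(par(op))
  plot(x$seq)
  units <- if (abs(x$config$log_base - 2) < 1e-12) "bits" else "nats"
  plot(x$surprisal, type = "l", xlab = "tone index",
       ylab = paste0("surprisal (", units, ")"), ...)
  dev <- x$seq$deviant_positions
  if (length(dev)) points(dev, x$surprisal[dev], col = 2, pch = 20)
  if (!is.na(x$seq$transition_index))
    abline(v = x$seq$transition_index - 0.5, lty = 2, col = 4)
  invisible(x)
}
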