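#' Prior hyperparameters for the Gaussian observation model
#'
#' The model assumes tones (in semitones, log-frequency) within one statistical
#' context are draws from a D-variate Gaussian over lagged tone vectors with
#' unknown mean and covariance. A conjugate Normal-Inverse-Wishart (NIW) prior
#' is placed on those parameters so that sufficient statistics can be updated
#' exactly, one tone at a time, and the posterior predictive is multivariate
#' Student-t in closed form.
#'
#' @param D dimensionality of the lag embedding (positive integer).
#' @param mu0 prior mean, semitones; scalar (recycled) or length-D vector.
#'   Default 0: the stimulus space is assumed centred.
#' @param kappa0 prior pseudo-count on the mean (positive). Default 1: the
#'   prior mean is worth one observation.
#' @param nu0 prior degrees of freedom; must exceed \code{D - 1}. Default
#'   \code{D + 2}, the smallest integer value giving a finite prior mean for
#'   the covariance.
#' @param lambda0 prior scale matrix, semitones^2; a scalar \code{s} is
#'   expanded to \code{s * diag(D)}. Default 25 (sd of 5 semitones per
#'   coordinate under the prior expectation): weak and wide.
#' @return an object of class \code{drex_prior}.
#' @seealso [drex_config()]
#' @examples
#' drex_prior(D = 3)
#' @export
drex_prior <- function(D, mu0 = 0, kappa0 = 1, nu0 = D + 2, lambda0 = 25) {
  D <- as.integer(D)
  if (length(D) != 1L || is.na(D) || D < 1L) stop("D must be a positive integer")
  if (length(mu0) == 1L) mu0 <- rep(as.numeric(mu0), D)
  if (length(mu0) != D || any(!is.finite(mu0))) stop("mu0 must be finite, scalar or length D")
  if (length(kappa0) != 1L || !is.finite(kappa0) || kappa0 <= 0) stop("kappa0 must be a positive real")
  if (length(nu0) != 1L || !is.finite(nu0) || nu0 <= D - 1) stop("nu0 must exceed D - 1")
  if (length(lambda0) == 1L && !is.matrix(lambda0)) {
    if (!is.finite(lambda0) || lambda0 <= 0) stop("scalar lambda0 must be positive")
    lambda0 <- diag(as.numeric(lambda0), D)
  }
  lambda0 <- as.matrix(lambda0)
  if (!all(dim(lambda0) == c(D, D))) stop("lambda0 must be a D x D matrix")
  if (max(abs(lambda0 - t(lambda0))) > 1e-8) stop("lambda0 must be symmetric")
  ev <- tryCatch(chol(lambda0), error = function(e) NULL)
  if (is.null(ev)) stop("lambda0 must be symmetric positive definite")
  structure(list(D = D, mu0 = mu0, kappa0 = as.numeric(kappa0),
                 nu0 = as.numeric(nu0), lambda0 = (lambda0 + t(lambda0)) / 2),
            class = "drex_prior")
}

#' Model configuration for dynamic regularity extraction
#'
#' Bundles the parameters governing sequential inference over a tone sequence:
#' the dimensionality of the collected statistics, the perceptual constraints
#' (working memory and observation noise), the changepoint hazard, the prior,
#' and the log base used to report surprisal.
#'
#' @param D positive integer; the span of temporal covariance collected.
#'   \code{D = 1} tracks marginal mean and variance of single tones;
#'   \code{D = k} additionally tracks covariances across k consecutive tones
#'   via overlapping lag vectors.
#' @param M working-memory capacity in observations: the maximum number of
#'   past tones that may inform a prediction, and hence the largest context
#'   (run length) that can be maintained. \code{Inf} disables the limit.
#'   When finite, \code{M >= D} is required. Default 25.
#' @param N observation noise, semitones: a lower bound imposed on the
#'   predictive standard deviation, preventing over-confident predictions.
#'   Default 0.5.
#' @param hazard per-tone prior probability that the statistical context
#'   changes; strictly inside (0, 1). Default 0.01.
#' @param prior a [drex_prior()]; defaults to \code{drex_prior(D)}.
#' @param log_base base for reporting surprisal: 2 (bits, the default) or
#'   \code{exp(1)} (nats).
#' @return an object of class \code{drex_config}.
#' @examples
#' drex_config(D = 1)
#' drex_config(D = 3, M = 40, N = 0.25, hazard = 0.05)
#' @export
drex_config <- function(D = 1, M = 25, N = 0.5, hazard = 0.01,
                        prior = NULL, log_base = 2) {
  D <- as.integer(D)
  if (length(D) != 1L || is.na(D) || D < 1L) stop("D must be a positive integer")
  if (length(M) != 1L || is.na(M) || M < 1) stop("M must be a positive integer or Inf")
  if (is.finite(M)) {
    M <- as.integer(M)
    if (M < D) stop("bounded memory M must satisfy M >= D")
  }
  if (length(N) != 1L || !is.finite(N) || N < 0) stop("N must be a non-negative real")
  if (length(hazard) != 1L || !is.finite(hazard) || hazard <= 0 || hazard >= 1)
    stop("hazard must lie strictly inside (0, 1)")
  if (is.null(prior)) prior <- drex_prior(D)
  if (!inherits(prior, "drex_prior")) stop("prior must be a drex_prior object")
  if (prior$D != D) stop("prior dimensionality (", prior$D, ") does not match D (", D, ")")
  if (length(log_base) != 1L || !is.finite(log_base) || log_base <= 1)
    stop("log_base must be a real > 1 (2 for bits, exp(1) for nats)")
  structure(list(D = D, M = M, N = as.numeric(N), hazard = as.numeric(hazard),
                 prior = prior, log_base = as.numeric(log_base)),
            class = "drex_config")
}

#' @export
print.drex_prior <- function(x, ...) {
  cat("Normal-Inverse-Wishart prior (D = ", x$D, ")\n", sep = "")
  cat("  mu0:     ", paste(signif(x$mu0, 4), collapse = " "), " semitones\n", sep = "")
  cat("  kappa0:  ", x$kappa0, "\n  nu0:     ", x$nu0, "\n", sep = "")
  cat("  lambda0: ", if (x$D == 1L) paste0(signif(x$lambda0[1, 1], 4), " semitones^2")
      else paste0(x$D, " x ", x$D, " matrix, diag ",
                  paste(signif(diag(x$lambda0), 4), collapse = " ")), "\n", sep = "")
  invisible(x)
}

#' @export
print.drex_config <- function(x, ...) {
  cat("drex model configuration\n")
  cat("  D (statistics dimensionality): ", x$D, "\n", sep = "")
  cat("  M (memory, observations):      ", if (is.finite(x$M)) x$M else "unbounded", "\n", sep = "")
  cat("  N (noise floor, semitones):    ", x$N, "\n", sep = "")
  cat("  hazard (changepoint prob.):    ", x$hazard, "\n", sep = "")
  cat("  surprisal units:               ", if (abs(x$log_base - 2) < 1e-12) "bits" else
      if (abs(x$log_base - exp(1)) < 1e-12) "nats" else paste0("log base ", x$log_base), "\n", sep = "")
  print(x$prior)
  invisible(x)
}

# serialize a config to a plain list (for JSON echo in output artifacts)
config_to_list <- function(config) {
  list(D = config$D, M = if (is.finite(config$M)) config$M else "unbounded",
       N = config$N, hazard = config$hazard, log_base = config$log_base,
       prior = list(mu0 = config$prior$mu0, kappa0 = config$prior$kappa0,
                    nu0 = config$prior$nu0, Lambda0 = config$prior$lambda0))
}

#' Read a model configuration from a JSON file
#'
#' Expects keys \code{D, M, N, hazard, log_base} and optionally
#' \code{prior: {mu0, kappa0, nu0, Lambda0}}. Missing keys fall back to the
#' [drex_config()] defaults; \code{M} may be the string \code{"unbounded"}.
#'
#' @param path path to a JSON file.
#' @return a [drex_config()] object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  D <- if (!is.null(j$D)) j$D else 1
  M <- if (!is.null(j$M)) { if (identical(j$M, "unbounded")) Inf else j$M } else 25
  prior <- if (!is.null(j$prior)) {
    p <- j$prior
    drex_prior(D,
               mu0 = if (!is.null(p$mu0)) p$mu0 else 0,
               kappa0 = if (!is.null(p$kappa0)) p$kappa0 else 1,
               nu0 = if (!is.null(p$nu0)) p$nu0 else D + 2,
               lambda0 = if (!is.null(p$Lambda0)) as.matrix(p$Lambda0) else 25)
  } else NULL
  drex_config(D = D, M = M,
              N = if (!is.null(j$N)) j$N else 0.5,
              hazard = if (!is.null(j$hazard)) j$hazard else 0.01,
              prior = prior,
              log_base = if (!is.null(j$log_base)) j$log_base else 2)
}
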