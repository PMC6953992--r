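# Core sequential inference: run-length hypotheses over contexts delimited by
# latent changepoints, conjugate NIW statistics per hypothesis, Student-t
# predictive conditioned on the recent lag tail, and the hazard-driven belief
# recursion. All mixture arithmetic is in log space.

# --- sufficient statistics ---------------------------------------------------

# A hypothesis with run length c attributes the last c tones to the current
# context. Its statistics are sums over the n = max(0, c - D + 1) overlapping
# lag-embedded D-vectors that fit fully inside that window.
new_hypothesis_stats <- function(D) {
  list(n = 0L, s = numeric(D), S = matrix(0, D, D))
}

# add one embedded D-vector to the raw sums
stats_add <- function(st, v) {
  if (length(v) != length(st$s)) stop("dimension mismatch in statistics update")
  list(n = st$n + 1L, s = st$s + v, S = st$S + tcrossprod(v))
}

# remove one embedded D-vector (sliding window at the memory cap)
stats_remove <- function(st, v) {
  list(n = st$n - 1L, s = st$s - v, S = st$S - tcrossprod(v))
}

# batch statistics over a window of tones: sums over all embedded vectors
# fully inside the window (used at the memory cap and as a test oracle)
stats_batch <- function(window, D) {
  st <- new_hypothesis_stats(D)
  L <- length(window)
  if (L >= D) for (p in D:L) st <- stats_add(st, window[(p - D + 1L):p])
  st
}

# Posterior NIW parameters given raw-sum statistics:
#   kappa_n = kappa0 + n
#   mu_n    = (kappa0 mu0 + sum v) / kappa_n
#   nu_n    = nu0 + n
#   Lambda_n = Lambda0 + sum v v' + kappa0 mu0 mu0' - kappa_n mu_n mu_n'
niw_posterior <- function(st, prior) {
  kn <- prior$kappa0 + st$n
  mun <- (prior$kappa0 * prior$mu0 + st$s) / kn
  Ln <- prior$lambda0 + st$S + prior$kappa0 * tcrossprod(prior$mu0) -
    kn * tcrossprod(mun)
  list(kappa = kn, mu = mun, nu = prior$nu0 + st$n, lambda = (Ln + t(Ln)) / 2)
}

# --- predictive distribution -------------------------------------------------

# Joint posterior predictive for a new embedded D-vector is multivariate
# Student-t: dof nu_n - D + 1, location mu_n, scale Lambda_n (kappa_n + 1) /
# (kappa_n (nu_n - D + 1)). The next tone occupies the last coordinate; the
# first D-1 coordinates are conditioned on the observed context tail (or on
# however many tail tones exist near the sequence start, marginalizing the
# rest). The resulting univariate Student-t has its scale floored at N.
predictive_params <- function(post, tail, config) {
  D <- config$D
  dof <- post$nu - D + 1
  Sigma <- post$lambda * (post$kappa + 1) / (post$kappa * dof)
  m <- length(tail)
  if (m == 0L) {
    loc <- post$mu[D]
    s2 <- Sigma[D, D]
    dfc <- dof
  } else {
    idx <- (D - m):(D - 1L)             # tail tones, oldest first
    S11 <- Sigma[idx, idx, drop = FALSE]
    S12 <- Sigma[idx, D]
    dv <- tail - post$mu[idx]
    sol <- tryCatch(solve(S11, cbind(dv, S12)), error = function(e)
      stop("non-positive-definite conditional scale: ", conditionMessage(e)))
    loc <- post$mu[D] + sum(S12 * sol[, 1L])
    s2r <- Sigma[D, D] - sum(S12 * sol[, 2L])
    d1 <- sum(dv * sol[, 1L])           # Mahalanobis term of the tail
    dfc <- dof + m
    s2 <- s2r * (dof + d1) / dfc
  }
  if (!is.finite(s2) || s2 < -1e-8)
    stop("non-positive-definite conditional scale (variance ", s2, ")")
  scale <- max(sqrt(max(s2, 0)), config$N)
  if (scale <= 0)
    stop("degenerate predictive scale with N = 0; set a positive noise floor N")
  list(location = loc, scale = scale, dof = dfc)
}

# log density of a location-scale Student-t
t_logdensity <- function(x, pred) {
  stats::dt((x - pred$location) / pred$scale, df = pred$dof, log = TRUE) -
    log(pred$scale)
}

# --- state -------------------------------------------------------------------

# State: parallel vectors/lists over hypotheses, ordered by run length.
#   run   integer run lengths
#   logw  normalized log belief weights
#   stats list of raw-sum statistics
init_state <- function(config) {
  list(run = 0L, logw = 0, stats = list(new_hypothesis_stats(config$D)))
}

# weights below this are clamped to zero (hypothesis dropped), then the
# remainder renormalized
.W_FLOOR <- log(1e-300)

# One inference step at time t (tones[t] is the incoming tone). Returns the
# updated state plus the pre-update mixture log-predictive (natural log),
# surprisal in config units, and a moment-matched predictive summary.
drex_step <- function(state, t, tones, config) {
  x <- tones[t]
  if (!is.finite(x)) stop("non-finite tone value at position ", t)
  H <- length(state$run)
  logd <- numeric(H)
  locs <- scales <- dofs <- numeric(H)
  for (i in seq_len(H)) {
    m <- min(config$D - 1L, state$run[i])
    tail <- if (m > 0L) tones[(t - m):(t - 1L)] else numeric(0)
    post <- niw_posterior(state$stats[[i]], config$prior)
    pred <- predictive_params(post, tail, config)
    logd[i] <- t_logdensity(x, pred)
    locs[i] <- pred$location; scales[i] <- pred$scale; dofs[i] <- pred$dof
  }

  # mixture predictive BEFORE updating with x (this is the surprisal)
  log_mix <- logsumexp(state$logw + logd)
  surprisal <- -log_mix / log(config$log_base)

  # moment-matched one-step-ahead summary (diagnostic)
  w <- exp(state$logw)
  mloc <- sum(w * locs)
  cvar <- ifelse(dofs > 2, scales^2 * dofs / (dofs - 2), scales^2)
  mvar <- sum(w * (cvar + locs^2)) - mloc^2
  imap <- which.max(state$logw)

  # belief recursion: grow with (1 - hazard), reset mass with hazard
  run <- state$run + 1L
  logw <- state$logw + logd + log1p(-config$hazard)
  stats <- state$stats
  for (i in seq_len(H)) {
    if (run[i] >= config$D)
      stats[[i]] <- stats_add(stats[[i]], tones[(t - config$D + 1L):t])
    if (is.finite(config$M) && run[i] > config$M) {
      # memory cap: slide the window to the last M tones
      stats[[i]] <- stats_remove(stats[[i]],
                                 tones[(t - config$M):(t - config$M + config$D - 1L)])
      run[i] <- config$M
    }
  }
  # merge duplicate hypotheses at the cap (their windows, hence statistics,
  # coincide; probability mass is conserved)
  if (is.finite(config$M)) {
    dup <- which(run == config$M)
    if (length(dup) > 1L) {
      keep <- dup[1L]
      logw[keep] <- logsumexp(logw[dup])
      drop <- dup[-1L]
      run <- run[-drop]; logw <- logw[-drop]; stats <- stats[-drop]
    }
  }
  # prepend the reset (changepoint) hypothesis: prior statistics, run 0
  run <- c(0L, run)
  logw <- c(log_mix + log(config$hazard), logw)
  stats <- c(list(new_hypothesis_stats(config$D)), stats)

  logw <- logw - logsumexp(logw)
  keep <- logw > .W_FLOOR
  if (!all(keep)) {
    run <- run[keep]; logw <- logw[keep]; stats <- stats[keep]
    logw <- logw - logsumexp(logw)
  }

  list(state = list(run = run, logw = logw, stats = stats),
       surprisal = surprisal, log_predictive = log_mix,
       pred_location = mloc, pred_scale = sqrt(max(mvar, 0)),
       pred_dof = dofs[imap])
}

# --- fitting -----------------------------------------------------------------

#' Fit the dynamic regularity extraction model to a tone sequence
#'
#' Runs sequential Bayesian inference over a sequence of tones (semitones,
#' log-frequency scale). The generating distribution within a statistical
#' context is a D-variate Gaussian over lagged tone vectors with unknown
#' parameters, which are assumed to change at latent changepoint times with
#' per-tone probability \code{hazard}. The model maintains one hypothesis per
#' possible context length (run length), updates each hypothesis's conjugate
#' Normal-Inverse-Wishart statistics incrementally, and predicts the next tone
#' by integrating the per-context Student-t predictives over the belief
#' distribution across contexts. The surprisal of tone t is the negative log
#' of that mixture predictive evaluated at the observed tone, using beliefs
#' formed from tones 1..t-1 only.
#'
#' Working memory \code{M} caps the run length: the longest-context hypothesis
#' keeps sliding-window statistics over the last M tones. Observation noise
#' \code{N} floors the predictive standard deviation.
#'
#' @param x a numeric vector of tones in semitones, or a [tone_seq()] object.
#' @param config a [drex_config()].
#' @param keep_beliefs logical; retain the full per-tone run-length posterior
#'   matrix (default TRUE).
#' @return an object of class \code{drex} with components
#'   \item{surprisal}{per-tone surprisal (bits by default)}
#'   \item{log_predictive}{per-tone mixture log-predictive density, natural log}
#'   \item{beliefs}{T x (max run length + 1) matrix; row t is the run-length
#'     posterior after observing tone t (columns are run lengths 0, 1, ...)}
#'   \item{map_run_length}{per-tone maximum a posteriori run length}
#'   \item{predictive_location, predictive_scale, predictive_dof}{moment-matched
#'     one-step-ahead predictive summaries formed before observing each tone}
#'   \item{state}{final hypothesis set (used by [predict.drex()] and
#'     [simulate.drex()])}
#' @examples
#' seq <- gen_oddball(0, 12, n_standards_between = 9, n_deviants = 2, seed = 1)
#' fit <- drex(seq, drex_config(D = 1))
#' fit
#' plot(fit)
#' @seealso [drex_config()], [enumerate_predictive()]
#' @export
drex <- function(x, config = drex_config(), keep_beliefs = TRUE) {
  seq <- if (inherits(x, "tone_seq")) x else tone_seq(x)
  tones <- seq$tones
  T <- length(tones)
  if (T < 1L) stop("empty sequence")
  if (!inherits(config, "drex_config")) stop("config must be a drex_config object")

  state <- init_state(config)
  ncol_b <- (if (is.finite(config$M)) min(T, config$M) else T) + 1L
  beliefs <- if (keep_beliefs) matrix(0, T, ncol_b,
                                      dimnames = list(NULL, paste0("r", 0:(ncol_b - 1L)))) else NULL
  surprisal <- logpred <- ploc <- pscale <- pdof <- numeric(T)
  maprl <- integer(T)

  for (t in seq_len(T)) {
    st <- drex_step(state, t, tones, config)
    surprisal[t] <- st$surprisal
    logpred[t] <- st$log_predictive
    ploc[t] <- st$pred_location; pscale[t] <- st$pred_scale; pdof[t] <- st$pred_dof
    state <- st$state
    maprl[t] <- state$run[which.max(state$logw)]
    if (keep_beliefs) beliefs[t, state$run + 1L] <- exp(state$logw)
  }

  structure(list(tones = tones, seq = seq, config = config,
                 surprisal = surprisal, log_predictive = logpred,
                 beliefs = beliefs, map_run_length = maprl,
                 predictive_location = ploc, predictive_scale = pscale,
                 predictive_dof = pdof, state = state,
                 call = match.call()),
            class = "drex")
}
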