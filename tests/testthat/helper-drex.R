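# shared fixtures: tiny configs and a reference prior used across test files

cfg1 <- function(...) drex_config(D = 1, M = Inf, ...)

# the reference scalar prior with a standard-t(2) prior predictive:
# scale^2 = lambda0 (kappa0 + 1) / (kappa0 nu0) = 1, dof = nu0 = 2
ref_prior1 <- function() drex_prior(1, mu0 = 0, kappa0 = 1, nu0 = 2, lambda0 = 1)

rand_tones <- function(n, seed) {
  set.seed(seed)
  stats::rnorm(n, 0, 4)
}

# D = 1 single-context sequential log-predictive (no changepoints): an
# independent implementation of the conjugate chain used as a limit oracle
single_context_logpred <- function(x, prior, N = 0) {
  out <- numeric(length(x))
  n <- 0; s <- 0; S <- 0
  for (t in seq_along(x)) {
    kn <- prior$kappa0 + n
    mun <- (prior$kappa0 * prior$mu0[1] + s) / kn
    nun <- prior$nu0 + n
    Ln <- prior$lambda0[1, 1] + S + prior$kappa0 * prior$mu0[1]^2 - kn * mun^2
    sc <- max(sqrt(Ln * (kn + 1) / (kn * nun)), N)
    out[t] <- stats::dt((x[t] - mun) / sc, df = nun, log = TRUE) - log(sc)
    n <- n + 1; s <- s + x[t]; S <- S + x[t]^2
  }
  out
}
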