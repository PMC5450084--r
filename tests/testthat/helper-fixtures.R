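# Shared fixtures, all built in code at test time.

# A deterministic profile with every noise source switched off: event times,
# deviation counts and periodicities are then exactly recoverable.
noiseless_profile <- function(...) {
  gait_profile(stride_time_mean = 1.0, gait_speed = 1.27,
               stride_jitter_sd = 0, accel_noise_sd = 0,
               force_noise_sd = 0, cop_noise_sd = 0,
               n_posterior_deviations = 0L, n_ml_deviations = 0L, ...)
}

# Independent trapezoid integrator (oracle for the impulse features).
trapz_oracle <- function(t, y) {
  n <- length(t)
  sum((y[-1] + y[-n]) / 2 * diff(t))
}

# Small labelled feature table with planted structure: `informative`
# separates the classes, `duplicate` copies it, the rest is noise.
planted_table <- function(n_faller = 20, n_nonfaller = 30, n_noise = 4,
                          sep = 2, noise_sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    n <- n_faller + n_nonfaller
    y <- rep(c("faller", "non_faller"), c(n_faller, n_nonfaller))
    inf <- ifelse(y == "faller", sep, 0) + rnorm(n, 0, noise_sd)
    X <- data.frame(informative = inf)
    for (j in seq_len(n_noise)) X[[sprintf("noise%02d", j)]] <- rnorm(n)
    X$duplicate <- inf
    feature_table(X, y)
  })
}

# Independent SU implementation for oracles (entropies from contingency
# tables, no shared code with the package internals).
su_oracle <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  h <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hx <- h(rowSums(p)); hy <- h(colSums(p)); hxy <- h(as.vector(p))
  if (hx + hy == 0) return(0)
  2 * (hx + hy - hxy) / (hx + hy)
}
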