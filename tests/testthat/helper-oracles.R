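# Independent oracles used across the suite.  Each is deliberately coded
# by a different route than the implementation it checks.

# AIF sampler that tolerates unsorted time vectors (quadrature routines
# do not guarantee monotone abscissae)
aifAt <- function(model, s) {
  o <- order(s)
  out <- numeric(length(s))
  out[o] <- sampleAIF(model, s[o])
  out
}

# Frame average of the one-tissue water model by direct trapezoid
# convolution at dense time points (no FFT, no shared grid machinery)
oracleH2oFrame <- function(cbf, lambda, aif, fs, fd, dt = 0.01) {
  f <- cbf / (100 * 60)
  k2 <- f / lambda
  tt <- seq(fs, fs + fd, length.out = 21)
  vals <- vapply(tt, function(t) {
    if (t <= 0) return(0)
    s <- seq(0, t, by = dt)
    f * pracma::trapz(s, aifAt(aif, s) * exp(-k2 * (t - s)))
  }, numeric(1))
  pracma::trapz(tt, vals) / fd
}

# Brute-force staging rule table: enumerates the three abnormality flags
# and looks the stage up in an explicit 8-row table
oracleStage <- function(cbf, cbv, oef,
                        cbfLower = 31.1, cbvUpper = 3.9,
                        oefUpper = 55.7) {
  tab <- data.frame(
    lowF = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
    highV = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    highE = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stage = c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 2L))
  key <- paste(cbf < cbfLower, cbv > cbvUpper, oef > oefUpper)
  tab$stage[match(key, paste(tab$lowF, tab$highV, tab$highE))]
}

# Exact two-sided permutation p value of the Mann-Whitney U statistic
# (enumerates every assignment; no ties assumed)
oraclePermU <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  pooled <- c(x, y)
  uOf <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u0 <- uOf(seq_len(n1))
  mid <- n1 * (n - n1) / 2
  sets <- utils::combn(n, n1)
  us <- apply(sets, 2, uOf)
  mean(abs(us - mid) >= abs(u0 - mid) - 1e-12)
}

# small noiseless configuration used by several tests
noiselessConfig <- function(n, seed, prevalence = c(9, 13, 2) / 24) {
  cohortConfig(nPatients = n, seed = seed, stagePrevalence = prevalence,
               reactivityNoiseSd = 0, tacNoiseModel = "none",
               tacNoiseScale = 0)
}
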