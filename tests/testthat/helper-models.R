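# Shared helpers: small models and an independent brute-force oracle.
# The oracle loops explicitly over every microstate with scalar
# arithmetic; it shares no code path with enumerate_equilibrium().

R_KCAL <- 1.98720425864083e-3

hh <- function(pH, pka, h = 1) 1 / (1 + 10^(h * (pH - pka)))

# brute-force semi-grand statistics by explicit microstate loop
brute_stats <- function(pka, W, pH, temperature = 298.15) {
  n <- length(pka)
  kT <- R_KCAL * temperature
  nstates <- 2^n
  Z <- 0
  m1 <- numeric(n)
  m2 <- matrix(0, n, n)
  for (code in 0:(nstates - 1)) {
    s <- as.integer(intToBits(code)[1:n])
    E <- 0
    for (i in 1:n) {
      E <- E + log(10) * kT * (pH - pka[i]) * s[i]
      if (i < n) for (j in (i + 1):n) E <- E + W[i, j] * s[i] * s[j]
    }
    w <- exp(-E / kT)
    Z <- Z + w
    m1 <- m1 + w * s
    m2 <- m2 + w * outer(s, s)
  }
  m1 <- m1 / Z
  m2 <- m2 / Z
  list(logZ = log(Z), free_energy = -kT * log(Z), mean = m1,
       cov = m2 - outer(m1, m1))
}

coupled_pair_model <- function(pka = c(4.0, 5.0), w = 2.0,
                               temperature = 298.15) {
  W <- matrix(0, 2, 2)
  W[1, 2] <- W[2, 1] <- w
  site_model(pka, W, temperature = temperature)
}

# six sites, mixed couplings, both compartments; used where the spec of a
# test needs "a small system with structure"
mixed_six_model <- function() {
  W <- matrix(0, 6, 6)
  W[1, 2] <- W[2, 1] <- 2.0
  W[3, 4] <- W[4, 3] <- -1.5
  W[2, 5] <- W[5, 2] <- 1.0
  site_model(c(4.2, 4.8, 5.1, 4.5, 5.4, 4.0), W,
             labels = sprintf("r%d", 1:6),
             compartment = rep(c("lumenal", "stromal"), each = 3))
}

# exact per-site curve injected as a titration_curve (zero-width CI)
exact_curve <- function(pH, mean, subject = "exact",
                        scale = "per-site") {
  phlinkage:::new_titration_curve(pH, mean, mean, mean, 1L,
                                  subject = subject, scale = scale)
}

# replicate-based standard error of the per-site mean at one pH
replicate_se <- function(ensemble, pH, site_id) {
  arr <- replicate_site_means(ensemble)
  v <- arr[phlinkage:::.ph_key(pH), , site_id]
  sd(v) / sqrt(length(v))
}
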