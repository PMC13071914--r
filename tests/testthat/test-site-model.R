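# Site model construction, exact enumeration, dimer building and the
# Metropolis sampler.

test_that("site_model validates its invariants", {
  expect_s3_class(site_model(4.25), "site_model")
  W <- matrix(c(0, 1, 2, 0), 2)
  expect_error(site_model(c(4, 5), W), "symmetric")
  W <- matrix(c(1, 2, 2, 0), 2)
  expect_error(site_model(c(4, 5), W), "zero diagonal")
  expect_error(site_model(c(4, 5), compartment = "cytosol"), "lumenal")
  expect_error(site_model(4.25, temperature = -1), "temperature")
  expect_error(site_model(c(4, 5), labels = "one"), "one entry per site")
})

test_that("single-site enumeration reproduces Henderson-Hasselbalch", {
  m <- site_model(4.25)
  expect_equal(unname(enumerate_equilibrium(m, 4.25)$mean), 0.5)
  for (pH in c(3, 5.5, 7.2)) {
    expect_equal(unname(enumerate_equilibrium(m, pH)$mean),
                 hh(pH, 4.25), tolerance = 1e-12)
  }
  # saturation limits
  expect_lt(enumerate_equilibrium(m, 15)$mean, 1e-10)
  expect_equal(unname(enumerate_equilibrium(m, -6)$mean), 1,
               tolerance = 1e-10)
})

test_that("enumeration matches the brute-force oracle with couplings", {
  cases <- list(
    list(pka = c(4.0, 5.0), w = 2.0, pH = 4.5),
    list(pka = c(4.0, 5.0), w = -2.0, pH = 4.5),
    list(pka = c(5.5, 5.5), w = 3.0, pH = 6.0)
  )
  for (cs in cases) {
    m <- coupled_pair_model(cs$pka, cs$w)
    eq <- enumerate_equilibrium(m, cs$pH)
    ref <- brute_stats(cs$pka, m$coupling, cs$pH)
    expect_equal(unname(eq$mean), ref$mean, tolerance = 1e-12)
    expect_equal(unname(eq$cov), ref$cov, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(eq$free_energy, ref$free_energy, tolerance = 1e-12)
  }
  # a model with several components against the same oracle
  m6 <- mixed_six_model()
  eq <- enumerate_equilibrium(m6, 4.8)
  ref <- brute_stats(m6$pka_int, m6$coupling, 4.8)
  expect_equal(unname(eq$mean), ref$mean, tolerance = 1e-12)
  expect_equal(unname(eq$cov), ref$cov, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(eq$free_energy, ref$free_energy, tolerance = 1e-10)
})

test_that("means lie in [0,1] and covariance is symmetric PSD", {
  m <- mixed_six_model()
  for (pH in c(3, 5, 8)) {
    eq <- enumerate_equilibrium(m, pH)
    expect_true(all(eq$mean >= 0 & eq$mean <= 1))
    expect_equal(eq$cov, t(eq$cov))
    expect_gte(min(eigen(eq$cov, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-12)
  }
})

test_that("dG/dpH equals ln(10) kT <n> (thermodynamic consistency)", {
  set.seed(4)
  h <- 1e-4
  for (rep in 1:4) {
    n <- sample(2:5, 1)
    W <- matrix(0, n, n)
    pairs <- which(upper.tri(W), arr.ind = TRUE)
    k <- sample(nrow(pairs), min(2, nrow(pairs)))
    for (p in k) {
      W[pairs[p, 1], pairs[p, 2]] <- W[pairs[p, 2], pairs[p, 1]] <-
        runif(1, -3, 3)
    }
    m <- site_model(runif(n, 3.5, 6.5), W)
    pH <- runif(1, 3, 8)
    g <- function(p) enumerate_equilibrium(m, p)$free_energy
    lhs <- (g(pH + h) - g(pH - h)) / (2 * h)
    rhs <- log(10) * kT_kcal() * sum(enumerate_equilibrium(m, pH)$mean)
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
})

test_that("enumeration refuses oversized coupled components", {
  n <- 21
  W <- matrix(1, n, n)
  diag(W) <- 0
  m <- site_model(rep(4.5, n), W)
  expect_error(enumerate_equilibrium(m, 5), "enumeration bound")
})

test_that("build_dimer_model duplicates, shifts and couples correctly", {
  mono <- mixed_six_model()
  # zero shift, no interchain coupling: independent copies
  d0 <- build_dimer_model(mono)
  expect_equal(d0$n_sites, 12L)
  expect_equal(d0$chain, rep(c("A", "B"), each = 6))
  grid <- seq(3, 8, 0.5)
  exm <- exact_titration(mono, grid)
  exd <- exact_titration(d0, grid)
  expect_equal(exd$mean[, 1:6], exm$mean, ignore_attr = TRUE)
  expect_equal(exd$mean[, 7:12], exm$mean, ignore_attr = TRUE)
  # additive shift
  d1 <- build_dimer_model(site_model(4.25), interface_pka_shift = -1)
  expect_equal(d1$pka_int, c(3.25, 3.25))
  # interchain coupling appears in the cross-chain covariance, and only
  # for the listed pair
  d2 <- build_dimer_model(site_model(c(4.5, 4.6, 4.7)),
                          interchain_coupling = data.frame(
                            i = 2, j = 2, energy = 1.5))
  eq <- enumerate_equilibrium(d2, 4.6)
  cross <- eq$cov[1:3, 4:6]
  expect_gt(abs(cross[2, 2]), 1e-3)
  expect_equal(cross[-2, ], matrix(0, 2, 3), ignore_attr = TRUE)
  expect_equal(cross[2, -2], c(0, 0), ignore_attr = TRUE)
  expect_error(build_dimer_model(mono, interchain_coupling = data.frame(
    i = 7, j = 1, energy = 1)), "out of range")
  expect_error(build_dimer_model(mono, interface_pka_shift = c(1, 2)),
               "length")
})

test_that("exact relative dimerization energy anchors and cancels", {
  mono <- mixed_six_model()
  grid <- seq(3, 8, 0.25)
  # independent copies: identically zero at all pH
  prof0 <- exact_relative_dimerization_energy(
    mono, build_dimer_model(mono), grid, 3)
  expect_lt(max(abs(prof0$value)), 1e-10)
  # anchoring at ref pH
  d <- build_dimer_model(mono, interface_pka_shift = -0.7)
  prof <- exact_relative_dimerization_energy(mono, d, grid, 3)
  expect_identical(prof$value[1], 0)
  expect_error(exact_relative_dimerization_energy(mono, d, grid, 3.1),
               "grid")
  # closed form for the 1-site case
  m1 <- site_model(4.25)
  d1 <- build_dimer_model(m1, -1)
  p1 <- exact_relative_dimerization_energy(m1, d1, grid, 3)
  kT <- kT_kcal()
  closed <- -2 * kT * log((1 + 10^(3.25 - grid)) / (1 + 10^(3.25 - 3))) +
    2 * kT * log((1 + 10^(4.25 - grid)) / (1 + 10^(4.25 - 3)))
  expect_equal(p1$value, closed, tolerance = 1e-12)
})

test_that("sampler is seed-deterministic and handles degenerate length", {
  m <- coupled_pair_model()
  e1 <- sample_ensemble(m, c(4, 5), 3, 200, seed = 9)
  e2 <- sample_ensemble(m, c(4, 5), 3, 200, seed = 9)
  expect_identical(e1$trajectories, e2$trajectories)
  e3 <- sample_ensemble(m, c(4, 5), 3, 200, seed = 10)
  expect_false(identical(e1$trajectories, e3$trajectories))
  e4 <- sample_ensemble(m, 4.5, 1, 1, seed = 1)
  expect_equal(nrow(e4$trajectories[[1]][[1]]), 1L)
  expect_error(sample_ensemble(m, numeric(0), 2, 10, 1), "empty")
  expect_error(sample_ensemble(m, 4, 2, 10, 1, flip_attempt_prob = 0),
               "flip_attempt_prob")
})

test_that("sampled means converge to the enumeration oracle", {
  # single site at its pKa: midpoint within 3 SE
  m1 <- site_model(4.25)
  e <- sample_ensemble(m1, 4.25, n_replicates = 5, n_frames = 1e4,
                       seed = 21)
  se <- replicate_se(e, 4.25, "site01_A")
  est <- mean(replicate_site_means(e)[1, , 1])
  expect_lt(abs(est - 0.5), 3 * se + 1e-12)
  # six-site mixed-coupling model at pH 5 against enumeration
  m6 <- mixed_six_model()
  e6 <- sample_ensemble(m6, 5, n_replicates = 5, n_frames = 2e4,
                        seed = 22)
  truth <- enumerate_equilibrium(m6, 5)$mean
  arr <- replicate_site_means(e6)
  for (id in site_ids(m6)) {
    se <- replicate_se(e6, 5, id)
    expect_lt(abs(mean(arr[1, , id]) - truth[id]), 3 * se + 5e-4)
  }
})

test_that("sampler respects Boltzmann microstate frequencies", {
  # empirical joint-state frequencies of a coupled pair match the exact
  # distribution (a stationary-distribution / detailed-balance check)
  m <- coupled_pair_model(c(4.5, 4.7), 2.0)
  pH <- 4.6
  e <- sample_ensemble(m, pH, n_replicates = 4, n_frames = 3e4,
                       seed = 31)
  S <- do.call(rbind, e$trajectories[[1]])
  code <- S[, 1] + 2 * S[, 2]
  emp <- tabulate(code + 1L, 4) / length(code)
  states <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  kT <- kT_kcal()
  w <- exp(-state_energy(m, states, pH) / kT)
  expect_equal(emp, w / sum(w), tolerance = 0.02)
})
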