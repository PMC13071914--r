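# Correlation maps, threshold networks and protonation correlation times.

test_that("pairwise correlation matches the enumerated value and sign", {
  # strong positive coupling penalizes double protonation: negative
  # correlation at pH between the pKa's
  m <- coupled_pair_model(c(4.3, 4.7), 3)
  pH <- 4.5
  eq <- enumerate_equilibrium(m, pH)
  truth <- eq$cov[1, 2] / sqrt(eq$cov[1, 1] * eq$cov[2, 2])
  expect_lt(truth, 0)
  e <- sample_ensemble(m, pH, n_replicates = 5, n_frames = 2e4,
                       seed = 51)
  cm <- pairwise_correlation(e, pH)
  expect_equal(cm$cor, t(cm$cor))
  expect_lt(abs(cm$cor[1, 2] - truth), 0.05)
  # flipping the coupling sign flips the correlation sign
  m2 <- coupled_pair_model(c(4.3, 4.7), -3)
  e2 <- sample_ensemble(m2, pH, n_replicates = 5, n_frames = 2e4,
                        seed = 51)
  expect_gt(pairwise_correlation(e2, pH)$cor[1, 2], 0)
})

test_that("independent sites decorrelate and zero variance masks", {
  m <- site_model(c(4.5, 5.0), labels = c("a", "b"))
  e <- sample_ensemble(m, 4.7, n_replicates = 5, n_frames = 2e4,
                       seed = 52)
  cm <- pairwise_correlation(e, 4.7)
  expect_lt(abs(cm$cor["a_A", "b_A"]), 0.03)
  # site protonated in every frame: masked undefined, not zero
  tr <- lapply(1:3, function(r) {
    mm <- cbind(rbinom(100, 1, 0.5), 1L)
    colnames(mm) <- c("a_A", "b_A")
    mm
  })
  ens <- protonation_ensemble(
    "monomer",
    data.frame(site_id = c("a_A", "b_A"), label = c("a", "b"),
               chain = "A", compartment = "lumenal"),
    list(`4` = tr), pH_grid = 4)
  cmm <- pairwise_correlation(ens, 4)
  expect_true(is.na(cmm$cor["b_A", "b_A"]))
  expect_true(is.na(cmm$cor["a_A", "b_A"]))
  expect_equal(cmm$cor["a_A", "a_A"], 1)
})

test_that("per-replicate pooling averages within-replicate maps", {
  m <- coupled_pair_model(c(4.4, 4.6), -2.5)
  e <- sample_ensemble(m, 4.5, n_replicates = 4, n_frames = 5e3,
                       seed = 53)
  cm <- pairwise_correlation(e, 4.5, pooling = "per-replicate")
  per_rep <- sapply(e$trajectories[[1]], function(S) cor(S)[1, 2])
  expect_equal(cm$cor[1, 2], mean(per_rep), tolerance = 1e-12)
})

test_that("networks threshold, flag compartments, and skip masked pairs", {
  sites <- data.frame(site_id = c("a_A", "b_A", "c_A"),
                      label = c("a", "b", "c"), chain = "A",
                      compartment = c("lumenal", "stromal", "lumenal"))
  cm <- structure(list(
    pH = 5,
    cor = matrix(c(1, 0.45, NA, 0.45, 1, NA, NA, NA, NA), 3, 3,
                 dimnames = list(sites$site_id, sites$site_id)),
    n_effective = 100L, pooling = "pooled", sites = sites),
    class = "correlation_map")
  net <- build_network(cm, threshold = 0.3)
  expect_equal(nrow(net), 1L)
  expect_true(net$cross_compartment)
  expect_equal(net$sign, "positive")
  # sub-threshold map gives an empty network; masked pairs never edge
  cm$cor[1, 2] <- cm$cor[2, 1] <- 0.2
  expect_equal(nrow(build_network(cm, threshold = 0.3)), 0L)
  expect_error(build_network(cm, threshold = 1.2), "threshold")
})

test_that("planted couplings surface as edges at the right pH", {
  # cooperative pair: correlated through its transition, silent once
  # both sites saturate at either pH extreme
  m <- coupled_pair_model(c(4.4, 4.6), -3)
  e <- sample_ensemble(m, c(2, 5.5, 9), n_replicates = 4,
                       n_frames = 1e4, seed = 54)
  maps <- lapply(c(2, 5.5, 9), function(p) pairwise_correlation(e, p))
  net <- build_network(maps, threshold = 0.3)
  expect_true(5.5 %in% net$pH)      # edge near the effective pKa's
  expect_false(2 %in% net$pH)       # saturated protonated: no edge
  expect_false(9 %in% net$pH)       # saturated deprotonated: no edge
  # anticooperative pairs instead stay anticorrelated at acidic pH,
  # where the pair is locked into single-proton microstates
  m2 <- coupled_pair_model(c(4.4, 4.6), 3)
  e2 <- sample_ensemble(m2, 3, n_replicates = 4, n_frames = 1e4,
                        seed = 55)
  net2 <- build_network(pairwise_correlation(e2, 3), threshold = 0.3)
  expect_equal(net2$sign, "negative")
})

test_that("correlation time is 0.5 for white noise and matches the
           two-state Markov closed form", {
  set.seed(61)
  x <- matrix(rbinom(2e4, 1, 0.5), ncol = 1,
              dimnames = list(NULL, "s"))
  ct <- correlation_time(x, "s")
  expect_lt(abs(ct$tau - 0.5), 0.1)
  # symmetric two-state chain via the sampler at pH = pKa: flip
  # probability per sweep = attempt probability, lambda = 1 - 2p
  p <- 0.05
  m <- site_model(4.25)
  e <- sample_ensemble(m, 4.25, n_replicates = 1, n_frames = 2e5,
                       seed = 62, flip_attempt_prob = p)
  ct2 <- correlation_time(e, "site01", 4.25)
  lam <- 1 - 2 * p
  closed <- 0.5 + lam / (1 - lam)
  expect_lt(abs(ct2$tau - closed) / closed, 0.15)
  # zero-variance series: undefined with a reason
  x1 <- matrix(1L, 100, 1, dimnames = list(NULL, "s"))
  ct3 <- correlation_time(x1, "s")
  expect_false(ct3$defined)
  expect_match(ct3$reason, "variance")
  expect_error(correlation_time(x[1:5, , drop = FALSE], "s"),
               "10 frames")
})

test_that("slow attempt rates lengthen correlation times accordingly", {
  m <- site_model(4.25)
  taus <- sapply(c(1, 0.01), function(a) {
    e <- sample_ensemble(m, 4.25, n_replicates = 2, n_frames = 1e5,
                         seed = 63, flip_attempt_prob = a)
    correlation_time(e, "site01", 4.25)$tau
  })
  expect_gt(taus[2] / taus[1], 10)
})

test_that("strongly correlated sites exchange protons more slowly", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 3
  m <- site_model(c(4.5, 4.5, 4.5), W)
  e <- sample_ensemble(m, 4.0, n_replicates = 5, n_frames = 3e4,
                       seed = 64, flip_attempt_prob = 0.5)
  taus <- sapply(site_ids(m), function(s)
    correlation_time(e, s, 4.0)$tau)
  expect_gt(taus[1], taus[3])
  expect_gt(taus[2], taus[3])
})
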