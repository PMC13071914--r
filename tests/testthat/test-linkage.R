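# The linkage relation: delta protonation, trapezoidal integration,
# per-residue decomposition, screening, and bootstrap bands.

test_that("delta protonation follows the closed form and partitions", {
  mono <- site_model(4.25)
  d <- build_dimer_model(mono, -1)
  grid <- seq(3, 8, 0.25)
  dq <- delta_protonation(mono, d, grid)
  closed <- 2 * hh(grid, 3.25) - 2 * hh(grid, 4.25)
  expect_equal(dq$total, closed, tolerance = 1e-12)
  expect_true(all(dq$total < 0))
  # identical curves give identically zero
  dq0 <- delta_protonation(mono, build_dimer_model(mono), grid)
  expect_equal(dq0$total, rep(0, length(grid)), tolerance = 1e-14)
  # subset partition: lumenal + stromal = all
  m6 <- mixed_six_model()
  d6 <- build_dimer_model(m6, interface_pka_shift = runif(6, -1, 0))
  all_q <- delta_protonation(m6, d6, grid)$total
  lum <- delta_protonation(m6, d6, grid, compartment = "lumenal")$total
  str <- delta_protonation(m6, d6, grid, compartment = "stromal")$total
  expect_equal(all_q, lum + str, tolerance = 1e-12)
  expect_error(delta_protonation(m6, d6, grid, sites = "nope"), "empty")
})

test_that("linkage integration matches exact free energies and analytics", {
  mono <- site_model(4.25)
  d <- build_dimer_model(mono, -1)
  grid <- seq(3, 8, 0.05)
  prof <- integrate_linkage(delta_protonation(mono, d, grid), ref_pH = 3)
  ex <- exact_relative_dimerization_energy(mono, d, grid, 3)
  expect_lt(max(abs(prof$value - ex$value)), 1e-3)
  # quadrature error shrinks ~quadratically with the step
  coarse <- seq(3, 8, 0.2)
  pc <- integrate_linkage(delta_protonation(mono, d, coarse), ref_pH = 3)
  exc <- exact_relative_dimerization_energy(mono, d, coarse, 3)
  err_c <- max(abs(pc$value - exc$value))
  expect_gt(err_c / max(abs(prof$value - ex$value)), 8)
  # constant dq = -1 across 3..8: ddG(8) = -5 ln(10) kT
  g58 <- seq(3, 8, 0.25)
  pconst <- integrate_linkage(rep(-1, length(g58)), g58, ref_pH = 3)
  expect_equal(pconst$value[length(g58)], -5 * log(10) * kT_kcal(298.15),
               tolerance = 1e-12)
  # zero dq gives the pH-independent profile
  p0 <- integrate_linkage(rep(0, length(g58)), g58, ref_pH = 3)
  expect_equal(p0$value, rep(0, length(g58)))
  expect_error(integrate_linkage(rep(1, 3), c(3, 4, 5), ref_pH = 4.5),
               "grid")
})

test_that("changing the reference pH rigidly shifts the profile", {
  mono <- mixed_six_model()
  d <- build_dimer_model(mono, interface_pka_shift = -0.6)
  grid <- seq(3, 8, 0.25)
  pA <- integrate_linkage(delta_protonation(mono, d, grid), ref_pH = 3)
  pB <- anchor_profile(pA, 7)
  direct <- integrate_linkage(delta_protonation(mono, d, grid),
                              ref_pH = 7)
  expect_equal(pB$value, direct$value, tolerance = 1e-12)
  expect_equal(pA$value - pA$value[match(7, grid)], pB$value,
               tolerance = 1e-12)
})

test_that("residue decomposition sums exactly and flags key residues", {
  m6 <- mixed_six_model()
  shift <- c(-1.2, 0, 0, 0, 0, 0)   # plant one strong lumenal shift
  d6 <- build_dimer_model(m6, shift)
  grid <- seq(3, 8, 0.25)
  dec <- residue_decomposition(m6, d6, grid, ref_pH = 3)
  tot <- Reduce(`+`, lapply(dec$residues, function(p) p$value))
  expect_lt(max(abs(tot - dec$total$value)), 1e-10)
  # the shifted residue dominates; untouched-but-uncoupled residues flat
  expect_gt(max(abs(dec$residues$r1$value)), 1)
  expect_lt(max(abs(dec$residues$r6$value)), 1e-10)
  scr <- screen_key_residues(dec, 1)
  expect_true("r1" %in% scr$label)
  # residues coupled to nothing shifted contribute nothing
  dec0 <- residue_decomposition(m6, build_dimer_model(m6), grid,
                                ref_pH = 3)
  expect_equal(nrow(screen_key_residues(dec0, 1)), 0L)
  expect_equal(nrow(screen_key_residues(dec0, 1e-6)), 0L)
  # a near-zero threshold returns every residue with any pH
  # sensitivity: the shifted residue and the ones coupled to it (r2
  # directly, r5 through r2); the exact-zero residues stay out
  scr_all <- screen_key_residues(dec, 1e-12)
  expect_setequal(scr_all$label, c("r1", "r2", "r5"))
  expect_true(!is.unsorted(rev(scr_all$max_abs_contribution)))
})

test_that("bootstrap profile bands are deterministic and contain the
           point estimate", {
  mono <- coupled_pair_model(c(4.5, 5.2), 1)
  d <- build_dimer_model(mono, c(-0.8, 0))
  grid <- seq(3, 8, 0.5)
  em <- sample_ensemble(mono, grid, 5, 2000, seed = 71,
                        system = "monomer")
  ed <- sample_ensemble(d, grid, 5, 2000, seed = 72, system = "dimer")
  b1 <- bootstrap_profile(em, ed, ref_pH = 3, n_boot = 300, seed = 5)
  b2 <- bootstrap_profile(em, ed, ref_pH = 3, n_boot = 300, seed = 5)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  expect_true(all(b1$ci_lo <= b1$value & b1$value <= b1$ci_hi))
  # per-residue bands sum-check at the point-estimate level
  dec <- bootstrap_profile(em, ed, ref_pH = 3, n_boot = 300, seed = 5,
                           per_residue = TRUE)
  tot <- Reduce(`+`, lapply(dec$residues, function(p) p$value))
  expect_equal(tot, dec$total$value, tolerance = 1e-10)
})

test_that("noise-free identical replicates give zero-width bands", {
  mono <- site_model(4.25)
  d <- build_dimer_model(mono, -1)
  grid <- seq(3, 8, 0.5)
  exm <- exact_titration(mono, grid)$mean
  make_ens <- function(model, means, system) {
    tr <- lapply(seq_along(grid), function(i) {
      lapply(1:5, function(r) {
        mm <- matrix(rep(round(means[i, ]), each = 10), nrow = 10)
        colnames(mm) <- site_ids(model)
        mm
      })
    })
    names(tr) <- phlinkage:::.ph_key(grid)
    protonation_ensemble(system, site_metadata(model), tr, grid)
  }
  # binary states cannot encode a fractional mean, so use saturated
  # deterministic data (all-protonated monomer and dimer): dq = 0
  ones <- matrix(1, length(grid), 1)
  em <- make_ens(mono, ones, "monomer")
  ed <- make_ens(d, cbind(ones, ones), "dimer")
  b <- bootstrap_profile(em, ed, ref_pH = 3, n_boot = 200, seed = 1)
  expect_equal(b$ci_hi - b$ci_lo, rep(0, length(grid)))
  expect_equal(b$value, rep(0, length(grid)))
})

test_that("direction: interface-stabilized deprotonation lowers ddG
           with pH", {
  # dimer titrates lower than 2x monomer (negative interface shifts):
  # dq < 0 through the transition, so the profile decreases
  mono <- mixed_six_model()
  d <- build_dimer_model(mono, interface_pka_shift = -0.8)
  grid <- seq(3, 8, 0.25)
  prof <- exact_relative_dimerization_energy(mono, d, grid, 3)
  expect_lt(prof$value[length(grid)], -0.5)
  expect_true(all(diff(prof$value) <= 1e-12))
})

test_that("unmatched monomer/dimer sites are reported by name", {
  mono <- site_model(c(4.5, 5), labels = c("a", "b"))
  other <- build_dimer_model(site_model(c(4.5), labels = "a"))
  expect_error(delta_protonation(mono, other, seq(3, 8, 1)),
               "no dimer match.*b")
})
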