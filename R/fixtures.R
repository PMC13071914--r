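# A small membrane-sensor-like benchmark system with planted ground truth:
# 10 lumen-facing and 6 stroma-facing titratable sites, a handful of
# strong pairwise couplings (including one lumen-stroma pair), three
# dimer-interface pKa shifts on otherwise uncoupled lumenal sites, two
# interchain couplings on stromal sites, and two kinetically slow sites.
# Every planted feature is recoverable exactly from the enumeration
# oracle, which is what makes the system useful as a benchmark.

#' Toy monomer model with planted couplings
#'
#' 16 titratable sites (10 lumenal, labelled `L01`-`L10`, with pKa values
#' shifted above the aqueous glutamate reference of 4.25, and 6 stromal,
#' `S01`-`S06`). Three strong pairwise couplings are planted:
#' `L03`-`L04` at +3 kcal/mol (anticooperative), `S04`-`S05` at
#' -2 kcal/mol (cooperative) and the cross-compartment pair `L07`-`S02`
#' at -2.5 kcal/mol.
#'
#' @param temperature kelvin.
#' @return a [site_model()].
#' @export
toy_monomer_model <- function(temperature = 298.15) {
  labels <- c(sprintf("L%02d", 1:10), sprintf("S%02d", 1:6))
  pka <- c(4.8, 5.2, 4.5, 4.6, 5.0, 5.4, 4.9, 5.1, 4.7, 5.3,
           4.2, 4.8, 4.0, 4.4, 4.5, 4.3)
  compartment <- rep(c("lumenal", "stromal"), c(10L, 6L))
  W <- matrix(0, 16, 16, dimnames = list(labels, labels))
  W["L03", "L04"] <- W["L04", "L03"] <- 3.0
  W["S04", "S05"] <- W["S05", "S04"] <- -2.0
  W["L07", "S02"] <- W["S02", "L07"] <- -2.5
  site_model(pka, W, labels = labels, compartment = compartment,
             temperature = temperature)
}

#' Toy dimer model with planted interface shifts
#'
#' Two copies of [toy_monomer_model()] with interface pKa shifts of -1.0
#' planted on the lumenal sites `L01`, `L05` and `L09` (the interface
#' stabilizes their deprotonated, charged forms) and two interchain
#' couplings on stromal sites: `S01(A)`-`S01(B)` at +2.5 kcal/mol and
#' `S03(A)`-`S03(B)` at -2.0 kcal/mol.
#'
#' @param temperature kelvin.
#' @return a two-chain [site_model()] with 32 sites.
#' @export
toy_dimer_model <- function(temperature = 298.15) {
  mono <- toy_monomer_model(temperature)
  shift <- numeric(16)
  shift[match(c("L01", "L05", "L09"), mono$labels)] <- -1.0
  ic <- data.frame(i = match(c("S01", "S03"), mono$labels),
                   j = match(c("S01", "S03"), mono$labels),
                   energy = c(2.5, -2.0))
  build_dimer_model(mono, interface_pka_shift = shift,
                    interchain_coupling = ic)
}

#' Ground truth planted in the toy system
#'
#' @return list: `shifted_residues` (lumenal residues with interface pKa
#'   shifts, the expected hits of [screen_key_residues()] on the
#'   lumenal-only decomposition), `coupled_pairs` (data.frame of planted
#'   couplings with chain scope), `cross_compartment_pair`, `slow_sites`
#'   (with their default attempt probabilities).
#' @export
toy_planted_truth <- function() {
  list(
    shifted_residues = c("L01", "L05", "L09"),
    coupled_pairs = data.frame(
      site_i = c("L03", "S04", "L07", "S01", "S03"),
      site_j = c("L04", "S05", "S02", "S01", "S03"),
      energy = c(3.0, -2.0, -2.5, 2.5, -2.0),
      scope = c("intra", "intra", "intra", "inter", "inter"),
      stringsAsFactors = FALSE),
    cross_compartment_pair = c("L07", "S02"),
    slow_sites = c(L10 = 0.1, S06 = 0.05)
  )
}

#' Per-site flip-attempt probabilities for a toy model
#'
#' All sites attempt flips every sweep except the two planted slow
#' exchangers (`L10` at 0.1, `S06` at 0.05), emulating residues with slow
#' proton exchange dynamics.
#'
#' @param model a toy monomer or dimer model.
#' @return numeric vector, one probability per site.
#' @export
toy_flip_probs <- function(model) {
  slow <- toy_planted_truth()$slow_sites
  p <- rep(1, model$n_sites)
  p[model$labels %in% names(slow)] <-
    slow[model$labels[model$labels %in% names(slow)]]
  p
}
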