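#' Define a model of interacting titratable sites
#'
#' An Ising-like semi-grand-canonical model of `n` titratable sites. A
#' microstate is a binary vector `s` (1 = protonated, proton bound). Its
#' energy at a given pH is
#' \deqn{E(s; pH) = \sum_i \ln(10)\,kT\,(pH - pKa_i)\, s_i +
#'       \sum_{i<j} W_{ij}\, s_i s_j}
#' in kcal/mol, where `pKa_i` are the intrinsic pKa values and `W` couples
#' pairs of *protonated* sites. Positive `W` penalizes double protonation
#' (anticooperative proton binding, Hill h < 1, negative state correlation);
#' negative `W` is cooperative. With zero coupling each site titrates as an
#' exact Henderson-Hasselbalch sigmoid centred at its intrinsic pKa.
#'
#' @param pka_int numeric vector of intrinsic pKa values (pH units), one per
#'   site.
#' @param coupling symmetric numeric matrix of pairwise interaction energies
#'   between protonated states (kcal/mol), zero diagonal. `NULL` means no
#'   coupling.
#' @param labels per-site residue identifiers (unique within a chain).
#' @param chain per-site chain tag (recycled if scalar).
#' @param compartment per-site tag, each `"lumenal"` or `"stromal"`
#'   (recycled if scalar).
#' @param temperature temperature in kelvin (default 298.15).
#' @return An object of class `site_model`.
#' @seealso [enumerate_equilibrium()], [sample_ensemble()],
#'   [build_dimer_model()]
#' @export
site_model <- function(pka_int, coupling = NULL, labels = NULL,
                       chain = "A", compartment = "lumenal",
                       temperature = 298.15) {
  pka_int <- as.numeric(pka_int)
  n <- length(pka_int)
  if (n < 1L || any(!is.finite(pka_int))) {
    stop("pka_int must be a non-empty vector of finite values", call. = FALSE)
  }
  if (is.null(coupling)) coupling <- matrix(0, n, n)
  coupling <- as.matrix(coupling)
  if (!all(dim(coupling) == c(n, n)) || any(!is.finite(coupling))) {
    stop("coupling must be a finite ", n, "x", n, " matrix", call. = FALSE)
  }
  if (!isTRUE(all.equal(coupling, t(coupling), tolerance = 0)) ||
      any(diag(coupling) != 0)) {
    stop("coupling matrix must be symmetric with exactly zero diagonal",
         call. = FALSE)
  }
  if (is.null(labels)) labels <- sprintf("site%02d", seq_len(n))
  labels <- as.character(labels)
  chain <- rep_len(as.character(chain), n)
  compartment <- rep_len(as.character(compartment), n)
  if (length(labels) != n) {
    stop("labels must have one entry per site", call. = FALSE)
  }
  if (!all(compartment %in% c("lumenal", "stromal"))) {
    stop("compartment tags must be 'lumenal' or 'stromal'", call. = FALSE)
  }
  if (anyDuplicated(paste(labels, chain))) {
    stop("site (label, chain) pairs must be unique", call. = FALSE)
  }
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      temperature <= 0) {
    stop("temperature must be a single positive number (kelvin)",
         call. = FALSE)
  }
  structure(
    list(n_sites = n, pka_int = pka_int, coupling = coupling,
         labels = labels, chain = chain, compartment = compartment,
         temperature = temperature),
    class = "site_model"
  )
}

#' @export
print.site_model <- function(x, ...) {
  n_coup <- sum(x$coupling[upper.tri(x$coupling)] != 0)
  cat("site_model:", x$n_sites, "titratable sites,",
      n_coup, "nonzero couplings,",
      length(unique(x$chain)), "chain(s),",
      sprintf("T = %.2f K\n", x$temperature))
  cat("  pKa range:", sprintf("%.2f - %.2f", min(x$pka_int),
                              max(x$pka_int)), "\n")
  invisible(x)
}

#' Per-site identifiers of a model (label_chain)
#' @param model a [site_model()].
#' @return character vector of unique site ids.
#' @export
site_ids <- function(model) paste(model$labels, model$chain, sep = "_")

#' Site metadata table of a model
#'
#' @param model a [site_model()].
#' @return data.frame with columns `site_id`, `label`, `chain`,
#'   `compartment`, `pka_int` and, for dimer models built with
#'   [build_dimer_model()], `monomer_site_match`.
#' @export
site_metadata <- function(model) {
  md <- data.frame(
    site_id = site_ids(model),
    label = model$labels,
    chain = model$chain,
    compartment = model$compartment,
    pka_int = model$pka_int,
    stringsAsFactors = FALSE
  )
  if (!is.null(model$monomer_site_match)) {
    md$monomer_site_match <- model$monomer_site_match
  }
  md
}

#' Microstate energies at a given pH
#'
#' @param model a [site_model()].
#' @param states integer/numeric matrix (rows = microstates, columns =
#'   sites) with entries in {0,1}.
#' @param pH scalar pH.
#' @return numeric vector of energies in kcal/mol.
#' @export
state_energy <- function(model, states, pH) {
  states <- matrix(as.numeric(states), ncol = model$n_sites)
  mu <- log(10) * kT_kcal(model$temperature) * (pH - model$pka_int)
  drop(states %*% mu) + 0.5 * rowSums((states %*% model$coupling) * states)
}

#' Duplicate a monomer model into a two-chain dimer model
#'
#' Sites are duplicated with chain tags `A` and `B`; each copy's intrinsic
#' pKa is shifted by `interface_pka_shift` (the synthetic analogue of
#' dimer-interface electrostatics that stabilize or destabilize the charged
#' forms); intra-chain couplings are copied into both chains, and any listed
#' inter-chain couplings are added symmetrically.
#'
#' @param monomer a single-chain [site_model()].
#' @param interface_pka_shift numeric vector, length `monomer$n_sites`;
#'   added to the intrinsic pKa of both copies of each site.
#' @param interchain_coupling `NULL`, or a data.frame/list with elements
#'   `i` (site index in chain A), `j` (site index in chain B) and `energy`
#'   (kcal/mol).
#' @return A `site_model` with `2 * n_sites` sites, chains `A`/`B`, and a
#'   `monomer_site_match` field mapping each dimer site to its monomer
#'   label.
#' @export
build_dimer_model <- function(monomer, interface_pka_shift = 0,
                              interchain_coupling = NULL) {
  stopifnot(inherits(monomer, "site_model"))
  n <- monomer$n_sites
  shift <- rep_len(as.numeric(interface_pka_shift), n)
  if (!(length(interface_pka_shift) %in% c(1L, n))) {
    stop("interface_pka_shift must have length 1 or n_sites", call. = FALSE)
  }
  W <- matrix(0, 2 * n, 2 * n)
  W[seq_len(n), seq_len(n)] <- monomer$coupling
  W[n + seq_len(n), n + seq_len(n)] <- monomer$coupling
  if (!is.null(interchain_coupling)) {
    ic <- as.data.frame(interchain_coupling)
    if (!all(c("i", "j", "energy") %in% names(ic))) {
      stop("interchain_coupling needs columns i, j, energy", call. = FALSE)
    }
    if (any(ic$i < 1 | ic$i > n | ic$j < 1 | ic$j > n)) {
      stop("interchain_coupling indices out of range 1..", n, call. = FALSE)
    }
    for (k in seq_len(nrow(ic))) {
      a <- ic$i[k]
      b <- n + ic$j[k]
      W[a, b] <- W[a, b] + ic$energy[k]
      W[b, a] <- W[a, b]
    }
  }
  dimer <- site_model(
    pka_int = c(monomer$pka_int + shift, monomer$pka_int + shift),
    coupling = W,
    labels = rep(monomer$labels, 2L),
    chain = rep(c("A", "B"), each = n),
    compartment = rep(monomer$compartment, 2L),
    temperature = monomer$temperature
  )
  dimer$monomer_site_match <- rep(monomer$labels, 2L)
  dimer
}
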