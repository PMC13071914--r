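# Exact statistical mechanics by enumeration. The coupling graph is split
# into connected components; the pH field is single-site, so the partition
# function factorizes over components and only each component's microstates
# need enumerating. The per-component size bound keeps 2^k enumeration
# feasible even for dimers whose total site count is large.

.ENUM_MAX_COMPONENT <- 20L

# connected components of the nonzero-coupling graph (indices list)
.coupling_components <- function(coupling) {
  n <- nrow(coupling)
  adj <- abs(coupling) > 0
  seen <- logical(n)
  comps <- list()
  for (start in seq_len(n)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      members <- c(members, v)
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

# all 2^k binary states as a k-column matrix
.all_states <- function(k) {
  m <- as.matrix(expand.grid(rep(list(0:1), k), KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- NULL
  m
}

#' Exact semi-grand-canonical statistics by enumeration
#'
#' Enumerates protonation microstates exactly and returns the semi-grand
#' free energy \eqn{G(pH) = -kT \ln \sum_s e^{-E(s;pH)/kT}}, per-site mean
#' protonations and the site-site covariance matrix. The sum factorizes
#' over connected components of the coupling graph, so only each
#' component's `2^k` states are enumerated; any component larger than 20
#' sites is refused.
#'
#' @param model a [site_model()].
#' @param pH scalar pH.
#' @return list with elements `pH`, `free_energy` (kcal/mol), `logZ`,
#'   `mean` (named per-site vector in \[0,1\]) and `cov` (covariance matrix
#'   of the binary states).
#' @export
enumerate_equilibrium <- function(model, pH) {
  stopifnot(inherits(model, "site_model"), is.numeric(pH), length(pH) == 1L)
  n <- model$n_sites
  kT <- kT_kcal(model$temperature)
  comps <- .coupling_components(model$coupling)
  big <- lengths(comps) > .ENUM_MAX_COMPONENT
  if (any(big)) {
    stop("exact enumeration refused: coupling component with ",
         max(lengths(comps)), " sites exceeds the enumeration bound of ",
         .ENUM_MAX_COMPONENT, " sites", call. = FALSE)
  }
  mu <- log(10) * kT * (pH - model$pka_int)
  means <- numeric(n)
  covm <- matrix(0, n, n)
  logZ <- 0
  for (comp in comps) {
    k <- length(comp)
    S <- .all_states(k)
    E <- drop(S %*% mu[comp]) +
      0.5 * rowSums((S %*% model$coupling[comp, comp, drop = FALSE]) * S)
    w <- -E / kT
    wmax <- max(w)
    p <- exp(w - wmax)
    Zc <- sum(p)
    p <- p / Zc
    logZ <- logZ + wmax + log(Zc)
    m <- drop(crossprod(S, p))
    second <- crossprod(S, S * p)        # E[s_i s_j] within component
    means[comp] <- m
    covm[comp, comp] <- second - tcrossprod(m)
  }
  names(means) <- site_ids(model)
  dimnames(covm) <- list(names(means), names(means))
  list(pH = pH, free_energy = -kT * logZ, logZ = logZ,
       mean = means, cov = covm)
}

#' Exact titration curves and free energies over a pH grid
#'
#' @param model a [site_model()].
#' @param pH_grid numeric vector of pH values.
#' @return list with `pH` (the grid), `mean` (matrix, pH x site, per-site
#'   mean protonation), `free_energy` (vector, kcal/mol) and `total`
#'   (vector, total mean protonation per pH).
#' @export
exact_titration <- function(model, pH_grid) {
  pH_grid <- as.numeric(pH_grid)
  stopifnot(length(pH_grid) >= 1L)
  res <- lapply(pH_grid, function(p) enumerate_equilibrium(model, p))
  means <- do.call(rbind, lapply(res, `[[`, "mean"))
  rownames(means) <- NULL
  list(pH = pH_grid, mean = means,
       free_energy = vapply(res, `[[`, numeric(1), "free_energy"),
       total = rowSums(means))
}

#' Exact relative dimerization free-energy profile
#'
#' Computes \eqn{\Delta\Delta G(pH) = [G_D(pH) - 2 G_M(pH)] -
#' [G_D(pH_{ref}) - 2 G_M(pH_{ref})]} from exact semi-grand free energies.
#' pH-independent offsets cancel by construction; only the pH dependence of
#' the dimerization free energy is defined (linkage gives no absolute
#' \eqn{\Delta G}).
#'
#' @param monomer,dimer [site_model()] objects; both must be enumerable.
#' @param pH_grid numeric grid containing `ref_pH`.
#' @param ref_pH reference pH at which the profile is anchored to zero.
#' @return A `free_energy_profile` (see [integrate_linkage()]).
#' @export
exact_relative_dimerization_energy <- function(monomer, dimer, pH_grid,
                                               ref_pH) {
  pH_grid <- as.numeric(pH_grid)
  iref <- match(ref_pH, pH_grid)
  if (is.na(iref)) {
    stop("ref_pH = ", ref_pH, " is not a point of the pH grid ",
         "(no silent interpolation)", call. = FALSE)
  }
  gM <- exact_titration(monomer, pH_grid)$free_energy
  gD <- exact_titration(dimer, pH_grid)$free_energy
  raw <- gD - 2 * gM
  new_free_energy_profile(pH_grid, raw - raw[iref], ref_pH = ref_pH,
                          subject = "all", subset = "all",
                          temperature = monomer$temperature,
                          method = "exact enumeration")
}
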