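# 2M <-> D mass action at fixed total chain concentration: converting a
# relative dimerization free-energy profile into the pH-driven shift of
# the monomer fraction. Only *relative* free energies are available from
# linkage, so everything is parameterized by the monomer fraction at the
# reference pH instead of an absolute dimerization constant.

#' Monomer fraction under 2M <-> D mass action
#'
#' For the dimensionless `kappa` = (dimerization constant) x (total chain
#' concentration), the fraction of chains in monomeric form is the unique
#' root in (0, 1\] of \eqn{2\kappa f^2 + f - 1 = 0}, evaluated in the
#' cancellation-free form \eqn{f = 2 / (1 + \sqrt{1 + 8\kappa})} (exact at
#' `kappa = 0`, where `f = 1`).
#'
#' @param kappa nonnegative numeric (vectorized).
#' @return monomer fraction(s) in (0, 1\].
#' @export
solve_mass_action <- function(kappa) {
  kappa <- as.numeric(kappa)
  if (any(!is.finite(kappa)) || any(kappa < 0)) {
    stop("kappa must be finite and nonnegative", call. = FALSE)
  }
  2 / (1 + sqrt(1 + 8 * kappa))
}

#' pH-induced shift of the monomer fraction
#'
#' Propagates a relative dimerization free-energy profile through the
#' 2M <-> D equilibrium. For each reference monomer fraction `f_ref`
#' (the fraction of *chains* monomeric at the reference pH), the implied
#' \eqn{\kappa_{ref} = (1 - f_{ref}) / (2 f_{ref}^2)} is scaled as
#' \eqn{\kappa(pH) = \kappa_{ref}\, e^{-\Delta\Delta G(pH)/kT}} (dimer
#' destabilization, \eqn{\Delta\Delta G > 0}, lowers \eqn{\kappa} and
#' raises the monomer fraction) and resolved through
#' [solve_mass_action()]. Because the absolute dimerization constant and
#' concentration are unknown, results are always reported against
#' `f_ref`, never an assumed concentration.
#'
#' @param profile a `free_energy_profile` (typically the lumenal-only
#'   profile); re-anchored at `ref_pH` if needed.
#' @param ref_pH reference pH (default: the profile's own reference).
#' @param f_ref_grid reference monomer fractions, each strictly inside
#'   (0, 1); endpoints are excluded with a message (kappa degenerate).
#' @param with_ci propagate the profile's CI band (monotone map, so band
#'   edges map to band edges).
#' @return data.frame of class `monomer_fraction_curve`: `f_ref`, `pH`,
#'   `f`, `shift` (= `f - f_ref`), and `ci_lo`/`ci_hi` when propagated;
#'   attributes `ref_pH`, `subset`, `temperature`.
#' @export
fraction_shift <- function(profile, ref_pH = attr(profile, "ref_pH"),
                           f_ref_grid = c(0.1, 0.25, 0.5, 0.75, 0.9),
                           with_ci = !is.null(profile$ci_lo)) {
  stopifnot(inherits(profile, "free_energy_profile"))
  if (ref_pH != attr(profile, "ref_pH")) {
    profile <- anchor_profile(profile, ref_pH)
  }
  f_ref_grid <- as.numeric(f_ref_grid)
  drop_end <- f_ref_grid <= 0 | f_ref_grid >= 1
  if (any(drop_end)) {
    message("excluding f_ref value(s) at 0 or 1 (kappa degenerate): ",
            paste(f_ref_grid[drop_end], collapse = ", "))
    f_ref_grid <- f_ref_grid[!drop_end]
  }
  if (!length(f_ref_grid)) stop("no valid f_ref values", call. = FALSE)
  kT <- kT_kcal(attr(profile, "temperature"))
  with_ci <- with_ci && !is.null(profile$ci_lo)
  rows <- lapply(f_ref_grid, function(fr) {
    kap_ref <- (1 - fr) / (2 * fr^2)
    f <- solve_mass_action(kap_ref * exp(-profile$value / kT))
    out <- data.frame(f_ref = fr, pH = profile$pH, f = f,
                      shift = f - fr)
    if (with_ci) {
      # f is increasing in ddG (larger ddG -> smaller kappa -> more
      # monomer), so the band endpoints map directly
      out$ci_lo <- solve_mass_action(kap_ref * exp(-profile$ci_lo / kT))
      out$ci_hi <- solve_mass_action(kap_ref * exp(-profile$ci_hi / kT))
    }
    out
  })
  structure(do.call(rbind, rows),
            ref_pH = ref_pH, subset = attr(profile, "subset"),
            temperature = attr(profile, "temperature"),
            fraction_of = "chains",
            class = c("monomer_fraction_curve", "data.frame"))
}

#' Monomer-fraction curve with propagated uncertainty bands
#'
#' Convenience wrapper around [fraction_shift()] that requires the input
#' profile to carry a CI band and always propagates it.
#'
#' @inheritParams fraction_shift
#' @return a `monomer_fraction_curve` with `ci_lo`/`ci_hi`.
#' @export
fraction_uncertainty <- function(profile,
                                 ref_pH = attr(profile, "ref_pH"),
                                 f_ref_grid = c(0.1, 0.25, 0.5, 0.75,
                                                0.9)) {
  if (is.null(profile$ci_lo)) {
    stop("profile carries no CI band; use bootstrap_profile() first",
         call. = FALSE)
  }
  fraction_shift(profile, ref_pH, f_ref_grid, with_ci = TRUE)
}

#' @export
print.monomer_fraction_curve <- function(x, ...) {
  cat(sprintf(
    "monomer_fraction_curve: fraction of chains monomeric vs pH, ref pH %g (subset %s)\n",
    attr(x, "ref_pH"), attr(x, "subset")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
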