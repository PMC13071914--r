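# Wyman linkage: the pH derivative of the dimerization free energy equals
# ln(10) kT times the difference between product and reactant protonation
# curves. Integrating the measured difference gives the relative
# dimerization free energy, with an exact per-residue additive
# decomposition.

new_free_energy_profile <- function(pH, value, ref_pH, subject, subset,
                                    temperature, method,
                                    ci_lo = NULL, ci_hi = NULL) {
  out <- data.frame(pH = pH, value = value)
  if (!is.null(ci_lo)) {
    out$ci_lo <- ci_lo
    out$ci_hi <- ci_hi
  }
  structure(out, ref_pH = ref_pH, subject = subject, subset = subset,
            temperature = temperature, method = method,
            class = c("free_energy_profile", "data.frame"))
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf(
    "free_energy_profile [%s, subset %s]: ddG vs pH, ref pH %g, T = %.2f K (%s)\n",
    attr(x, "subject"), attr(x, "subset"), attr(x, "ref_pH"),
    attr(x, "temperature"), attr(x, "method")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

# per-site mean-protonation curves: matrix pH x site_id
.site_mean_curves <- function(x, pH_grid = NULL) {
  if (inherits(x, "site_model")) {
    if (is.null(pH_grid)) stop("pH_grid required for exact curves",
                               call. = FALSE)
    ex <- exact_titration(x, pH_grid)
    list(pH = ex$pH, mean = ex$mean, sites = site_metadata(x),
         temperature = x$temperature)
  } else if (inherits(x, "protonation_ensemble")) {
    arr <- replicate_site_means(x)
    list(pH = x$pH_grid, mean = apply(arr, c(1L, 3L), mean, na.rm = TRUE),
         sites = x$sites, temperature = x$temperature)
  } else {
    stop("expected a site_model or protonation_ensemble", call. = FALSE)
  }
}

# match dimer sites (chains A,B) to monomer labels for a subset filter
.match_sites <- function(mono_sites, dim_sites, sites = NULL,
                         compartment = NULL) {
  match_lab <- dim_sites$monomer_site_match %||% dim_sites$label
  keep <- rep(TRUE, nrow(mono_sites))
  if (!is.null(sites)) keep <- keep & mono_sites$label %in% sites
  if (!is.null(compartment)) {
    keep <- keep & mono_sites$compartment %in% compartment
  }
  labels <- mono_sites$label[keep]
  if (!length(labels)) stop("site subset is empty", call. = FALSE)
  unmatched <- setdiff(labels, match_lab)
  if (length(unmatched)) {
    stop("monomer sites with no dimer match: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  bad <- names(which(table(match_lab[match_lab %in% labels]) != 2L))
  if (length(bad)) {
    stop("each monomer site must map to exactly two dimer sites ",
         "(chains A and B); violated for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(labels = labels,
       mono_id = mono_sites$site_id[keep],
       dim_id = lapply(labels, function(l)
         dim_sites$site_id[match_lab == l]))
}

#' Protonation difference between dimer and two monomers
#'
#' Computes the per-residue proton-binding difference
#' \eqn{\Delta q_i(pH) = \langle x_i\rangle_{D,A} +
#' \langle x_i\rangle_{D,B} - 2\langle x_i\rangle_M} and the subset total
#' \eqn{\Delta Q = \sum_i \Delta q_i} (units: protons). This is the
#' integrand of the linkage relation. Dimer chains enter as a sum of both
#' chain curves so the 2M<->D stoichiometry is exact.
#'
#' @param monomer,dimer matched [protonation_ensemble()] objects, or
#'   [site_model()] objects for exact enumeration curves.
#' @param pH_grid required when models are given; ensembles use their own
#'   (shared) grid.
#' @param sites,compartment optional subset filters on monomer residues.
#' @return object of class `delta_protonation`: `pH`, `per_site` (matrix
#'   pH x residue label), `total`, `subset`, `temperature`.
#' @export
delta_protonation <- function(monomer, dimer, pH_grid = NULL,
                              sites = NULL, compartment = NULL) {
  cm <- .site_mean_curves(monomer, pH_grid)
  cd <- .site_mean_curves(dimer, pH_grid)
  if (length(cm$pH) != length(cd$pH) || any(cm$pH != cd$pH)) {
    stop("monomer and dimer pH grids differ", call. = FALSE)
  }
  mm <- .match_sites(cm$sites, cd$sites, sites, compartment)
  per_site <- vapply(seq_along(mm$labels), function(k) {
    cd$mean[, mm$dim_id[[k]][1L]] + cd$mean[, mm$dim_id[[k]][2L]] -
      2 * cm$mean[, mm$mono_id[k]]
  }, numeric(length(cm$pH)))
  per_site <- matrix(per_site, nrow = length(cm$pH),
                     dimnames = list(NULL, mm$labels))
  subset <- if (!is.null(sites)) "custom"
            else if (!is.null(compartment))
              paste(compartment, collapse = "+")
            else "all"
  structure(list(pH = cm$pH, per_site = per_site,
                 total = rowSums(per_site), subset = subset,
                 temperature = cm$temperature),
            class = "delta_protonation")
}

#' Integrate the linkage relation into a free-energy profile
#'
#' \deqn{\Delta\Delta G(pH) = \ln(10)\, kT \int_{pH_{ref}}^{pH}
#' \Delta Q(u)\, du} by the trapezoidal rule on the measured grid (no
#' interpolation: the grid is the resolution). The profile is exactly zero
#' at the reference pH. With protonation as proton *binding*,
#' \eqn{\Delta Q < 0} over an interval means the dimer binds fewer protons
#' there, and the profile decreases across it (dimer stabilized at higher
#' pH).
#'
#' @param delta_q a `delta_protonation` object, or a numeric vector of
#'   per-pH \eqn{\Delta Q} values.
#' @param pH_grid grid matching `delta_q` (taken from the object if one is
#'   given); strictly increasing.
#' @param ref_pH reference pH; must be a grid point.
#' @param temperature kelvin (taken from the object if available).
#' @param subject descriptor stored on the profile.
#' @return a `free_energy_profile` data.frame (`pH`, `value` in kcal/mol).
#' @export
integrate_linkage <- function(delta_q, pH_grid = NULL, ref_pH,
                              temperature = NULL, subject = "total") {
  subset <- "all"
  if (inherits(delta_q, "delta_protonation")) {
    pH_grid <- delta_q$pH
    temperature <- temperature %||% delta_q$temperature
    subset <- delta_q$subset
    delta_q <- delta_q$total
  }
  temperature <- temperature %||% 298.15
  pH_grid <- as.numeric(pH_grid)
  stopifnot(length(delta_q) == length(pH_grid))
  if (any(diff(pH_grid) <= 0)) {
    stop("pH grid must be strictly increasing", call. = FALSE)
  }
  iref <- match(ref_pH, pH_grid)
  if (is.na(iref)) {
    stop("ref_pH = ", ref_pH, " is not a grid point ",
         "(no silent interpolation)", call. = FALSE)
  }
  ct <- drop(pracma::cumtrapz(pH_grid, delta_q))
  val <- log(10) * kT_kcal(temperature) * (ct - ct[iref])
  new_free_energy_profile(pH_grid, val, ref_pH = ref_pH,
                          subject = subject, subset = subset,
                          temperature = temperature,
                          method = "trapezoidal linkage integration")
}

#' Re-anchor a free-energy profile at a different reference pH
#'
#' Uses reference invariance: changing the reference rigidly shifts the
#' profile.
#'
#' @param profile a `free_energy_profile`.
#' @param ref_pH new reference (a grid point).
#' @return the shifted profile.
#' @export
anchor_profile <- function(profile, ref_pH) {
  iref <- match(ref_pH, profile$pH)
  if (is.na(iref)) stop("ref_pH not on the profile grid", call. = FALSE)
  shift <- profile$value[iref]
  profile$value <- profile$value - shift
  if (!is.null(profile$ci_lo)) {
    profile$ci_lo <- profile$ci_lo - shift
    profile$ci_hi <- profile$ci_hi - shift
  }
  attr(profile, "ref_pH") <- ref_pH
  profile
}

#' Per-residue decomposition of the relative dimerization free energy
#'
#' Each residue's profile is the linkage integral of its own
#' \eqn{\Delta q_i}; the residue profiles sum exactly to the total. A
#' residue may contribute strongly to the absolute dimerization free
#' energy yet show a flat relative profile - flatness means no *pH
#' sensitivity*, not no contribution.
#'
#' @inheritParams delta_protonation
#' @param ref_pH reference pH (grid point).
#' @return list of class `linkage_decomposition`: `total` (profile),
#'   `residues` (named list of profiles), `delta` (the
#'   `delta_protonation` input).
#' @export
residue_decomposition <- function(monomer, dimer, pH_grid = NULL, ref_pH,
                                  sites = NULL, compartment = NULL) {
  dq <- delta_protonation(monomer, dimer, pH_grid, sites, compartment)
  total <- integrate_linkage(dq, ref_pH = ref_pH)
  residues <- lapply(colnames(dq$per_site), function(lab) {
    p <- integrate_linkage(dq$per_site[, lab], dq$pH, ref_pH = ref_pH,
                           temperature = dq$temperature, subject = lab)
    attr(p, "subset") <- dq$subset
    p
  })
  names(residues) <- colnames(dq$per_site)
  structure(list(total = total, residues = residues, delta = dq),
            class = "linkage_decomposition")
}

#' Screen residues by their pH-sensitivity contribution
#'
#' Ranks residues by the maximum absolute value of their relative
#' free-energy contribution over the grid and keeps those reaching the
#' threshold (default 1 kcal/mol). Ties break by residue label order.
#'
#' @param decomposition a `linkage_decomposition` from
#'   [residue_decomposition()].
#' @param threshold_kcal positive threshold in kcal/mol.
#' @return data.frame `label`, `max_abs_contribution`, ranked.
#' @export
screen_key_residues <- function(decomposition, threshold_kcal = 1) {
  stopifnot(inherits(decomposition, "linkage_decomposition"),
            threshold_kcal > 0)
  mx <- vapply(decomposition$residues,
               function(p) max(abs(p$value)), numeric(1))
  ord <- order(-mx, names(mx))
  out <- data.frame(label = names(mx)[ord],
                    max_abs_contribution = unname(mx[ord]),
                    stringsAsFactors = FALSE)
  out[out$max_abs_contribution >= threshold_kcal, , drop = FALSE]
}

#' Bootstrap confidence band on a linkage free-energy profile
#'
#' Resamples monomer and dimer replicates independently, recomputes the
#' full chain (curves -> delta Q -> trapezoidal integration) for every
#' resample, and returns the 16th-84th percentile band (68%).
#'
#' @param monomer,dimer matched [protonation_ensemble()] objects.
#' @param ref_pH reference pH (grid point).
#' @param sites,compartment optional subset filters.
#' @param n_boot bootstrap resamples (>= 100).
#' @param seed integer seed; same seed gives identical bands.
#' @param per_residue also compute bands for each residue profile.
#' @return a `free_energy_profile` with `ci_lo`/`ci_hi` (attribute
#'   `boot_se` holds the per-pH bootstrap standard error); when
#'   `per_residue = TRUE` a `linkage_decomposition` whose profiles all
#'   carry bands.
#' @export
bootstrap_profile <- function(monomer, dimer, ref_pH, sites = NULL,
                              compartment = NULL, n_boot = 1000L,
                              seed = 1L, per_residue = FALSE) {
  stopifnot(inherits(monomer, "protonation_ensemble"),
            inherits(dimer, "protonation_ensemble"),
            n_boot >= 100L)
  arrM <- replicate_site_means(monomer)
  arrD <- replicate_site_means(dimer)
  mm <- .match_sites(monomer$sites, dimer$sites, sites, compartment)
  pH <- monomer$pH_grid
  if (length(pH) != length(dimer$pH_grid) || any(pH != dimer$pH_grid)) {
    stop("monomer and dimer pH grids differ", call. = FALSE)
  }
  iref <- match(ref_pH, pH)
  if (is.na(iref)) stop("ref_pH not on the grid", call. = FALSE)
  kfac <- log(10) * kT_kcal(monomer$temperature)
  dimA <- vapply(mm$dim_id, `[`, character(1), 1L)
  dimB <- vapply(mm$dim_id, `[`, character(1), 2L)

  per_site_dq <- function(im, id) {
    mono <- apply(arrM[, im, mm$mono_id, drop = FALSE], c(1L, 3L), mean)
    dA <- apply(arrD[, id, dimA, drop = FALSE], c(1L, 3L), mean)
    dB <- apply(arrD[, id, dimB, drop = FALSE], c(1L, 3L), mean)
    dA + dB - 2 * mono
  }
  integ <- function(dq) {
    ct <- pracma::cumtrapz(pH, dq)
    kfac * sweep(ct, 2L, ct[iref, ])
  }
  nM <- dim(arrM)[2L]
  nD <- dim(arrD)[2L]
  point_dq <- per_site_dq(seq_len(nM), seq_len(nD))
  point_prof <- integ(point_dq)

  if (nM == 1L || nD == 1L) {
    warning("single replicate: bootstrap band has zero width",
            call. = FALSE)
  }
  restore <- .save_rng_state()
  on.exit(restore())
  set.seed(as.integer(seed))
  n_res <- length(mm$labels)
  n_ph <- length(pH)
  boot_tot <- matrix(NA_real_, n_boot, n_ph)
  boot_res <- if (per_residue) {
    array(NA_real_, c(n_boot, n_ph, n_res))
  }
  for (b in seq_len(n_boot)) {
    prof <- integ(per_site_dq(sample.int(nM, nM, replace = TRUE),
                              sample.int(nD, nD, replace = TRUE)))
    boot_tot[b, ] <- rowSums(prof)
    if (per_residue) boot_res[b, , ] <- prof
  }
  band <- function(bm) {
    qs <- apply(bm, 2L, quantile, probs = c(0.16, 0.84), names = FALSE)
    list(lo = qs[1L, ], hi = qs[2L, ], se = apply(bm, 2L, sd))
  }
  subset <- if (!is.null(sites)) "custom"
            else if (!is.null(compartment))
              paste(compartment, collapse = "+") else "all"
  btot <- band(boot_tot)
  total <- new_free_energy_profile(
    pH, rowSums(point_prof), ref_pH = ref_pH, subject = "total",
    subset = subset, temperature = monomer$temperature,
    method = "linkage integration, replicate bootstrap",
    ci_lo = pmin(btot$lo, rowSums(point_prof)),
    ci_hi = pmax(btot$hi, rowSums(point_prof)))
  attr(total, "boot_se") <- btot$se
  attr(total, "n_boot") <- n_boot
  if (!per_residue) return(total)
  residues <- lapply(seq_len(n_res), function(k) {
    bk <- band(boot_res[, , k, drop = TRUE])
    p <- new_free_energy_profile(
      pH, point_prof[, k], ref_pH = ref_pH, subject = mm$labels[k],
      subset = subset, temperature = monomer$temperature,
      method = "linkage integration, replicate bootstrap",
      ci_lo = pmin(bk$lo, point_prof[, k]),
      ci_hi = pmax(bk$hi, point_prof[, k]))
    attr(p, "boot_se") <- bk$se
    p
  })
  names(residues) <- mm$labels
  structure(list(total = total, residues = residues, delta = NULL),
            class = "linkage_decomposition")
}
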