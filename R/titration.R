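# Titration curves with replicate-bootstrap confidence bands, and the
# Hill-equation fit for pKa and cooperativity.

new_titration_curve <- function(pH, mean, ci_lo, ci_hi, n_replicates,
                                subject, scale = c("per-site", "global")) {
  scale <- match.arg(scale)
  out <- data.frame(pH = pH, mean = mean, ci_lo = ci_lo, ci_hi = ci_hi,
                    n_replicates = n_replicates)
  structure(out, subject = subject, scale = scale,
            class = c("titration_curve", "data.frame"))
}

#' @export
print.titration_curve <- function(x, ...) {
  cat("titration_curve:", attr(x, "subject"),
      sprintf("(%s scale, %d pH points)\n", attr(x, "scale"), nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Percentile bootstrap confidence interval over replicates
#'
#' Resamples whole replicates with replacement (frames within a replicate
#' are autocorrelated, so the replicate is the only plausibly independent
#' unit), averages each resample, and returns the 16th-84th percentile
#' interval (68% coverage). Deterministic given `seed`. A single replicate
#' yields a zero-width interval with a warning flag.
#'
#' @param stat numeric vector (one value per replicate) or matrix
#'   (replicates x points) of per-replicate statistics.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed integer seed.
#' @param level coverage level (default 0.68).
#' @return list with `lower`, `upper` (per point), `level`, and
#'   `degenerate` (TRUE when only one replicate was available).
#' @export
bootstrap_ci <- function(stat, n_boot = 1000L, seed = 1L, level = 0.68) {
  if (is.null(dim(stat))) stat <- matrix(stat, ncol = 1L)
  n_rep <- nrow(stat)
  stopifnot(n_rep >= 1L, n_boot >= 100L)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  if (n_rep == 1L) {
    warning("single replicate: bootstrap interval has zero width",
            call. = FALSE)
    return(list(lower = drop(stat[1L, ]), upper = drop(stat[1L, ]),
                level = level, degenerate = TRUE))
  }
  restore <- .save_rng_state()
  on.exit(restore())
  set.seed(as.integer(seed))
  idx <- matrix(sample.int(n_rep, n_boot * n_rep, replace = TRUE),
                nrow = n_boot)
  boots <- matrix(NA_real_, n_boot, ncol(stat))
  for (b in seq_len(n_boot)) {
    boots[b, ] <- colMeans(stat[idx[b, ], , drop = FALSE])
  }
  qs <- apply(boots, 2L, quantile, probs = probs, names = FALSE)
  list(lower = qs[1L, ], upper = qs[2L, ], level = level,
       degenerate = FALSE)
}

# resolve site_ids from label / compartment filters
.select_sites <- function(ensemble, sites = NULL, compartment = NULL) {
  md <- ensemble$sites
  keep <- rep(TRUE, nrow(md))
  if (!is.null(sites)) keep <- keep & (md$site_id %in% sites |
                                         md$label %in% sites)
  if (!is.null(compartment)) keep <- keep & md$compartment %in% compartment
  md$site_id[keep]
}

#' Titration curve of one residue
#'
#' Mean protonation of a site versus pH, averaged over frames and
#' replicates, with a 68% replicate-bootstrap band. For dimers the
#' `"average-chains"` policy returns the arithmetic mean of the two chain
#' curves (fits are typically done on this average, per-chain curves being
#' diagnostics).
#'
#' @param ensemble a [protonation_ensemble()].
#' @param site residue label (e.g. `"L03"`), or a full `site_id`
#'   (`"L03_A"`) under the single-chain policy.
#' @param chain_policy `"single-chain"` or `"average-chains"`.
#' @param chain chain tag required when `chain_policy = "single-chain"`
#'   and the label occurs in more than one chain.
#' @param n_boot,seed bootstrap settings (see [bootstrap_ci()]).
#' @return a `titration_curve` data.frame (`pH`, `mean`, `ci_lo`, `ci_hi`,
#'   `n_replicates`).
#' @export
residue_curve <- function(ensemble, site,
                          chain_policy = c("single-chain",
                                           "average-chains"),
                          chain = NULL, n_boot = 1000L, seed = 1L) {
  chain_policy <- match.arg(chain_policy)
  md <- ensemble$sites
  hit <- md$label == site | md$site_id == site
  if (!any(hit)) stop("site '", site, "' not found", call. = FALSE)
  if (chain_policy == "average-chains") {
    chains <- unique(md$chain[hit])
    if (length(chains) != 2L) {
      stop("average-chains requires the site in exactly two chains; '",
           site, "' is present in ", length(chains), call. = FALSE)
    }
    cols <- md$site_id[hit]
  } else {
    if (!is.null(chain)) hit <- hit & md$chain == chain
    if (sum(hit) != 1L) {
      stop("site '", site, "' is ambiguous across chains; give `chain`",
           call. = FALSE)
    }
    cols <- md$site_id[hit]
  }
  arr <- replicate_site_means(ensemble)
  # replicate-level statistic: mean over the selected chain copies
  stat <- apply(arr[, , cols, drop = FALSE], c(1L, 2L), mean)
  .curve_from_stat(t(stat), ensemble, subject = paste0(
    site, if (chain_policy == "average-chains") " (chain average)"
    else if (!is.null(chain)) paste0("_", chain) else ""),
    scale = "per-site", n_boot = n_boot, seed = seed)
}

# stat: replicates x pH matrix (NA for missing replicates)
.curve_from_stat <- function(stat, ensemble, subject, scale,
                             n_boot, seed, factor = 1) {
  n_rep <- colSums(!is.na(stat))
  est <- colMeans(stat, na.rm = TRUE) * factor
  if (nrow(stat) == 1L) {
    ci <- list(lower = est, upper = est)
  } else {
    ci <- bootstrap_ci(stat * factor, n_boot = n_boot, seed = seed)
  }
  new_titration_curve(ensemble$pH_grid, est, ci$lower, ci$upper, n_rep,
                      subject = subject, scale = scale)
}

#' Global titration curve over a site subset
#'
#' Sum of the per-site mean protonations over a subset of sites, scaled by
#' a stoichiometry factor (e.g. 2 for the monomer so that "2x monomer"
#' matches dimer stoichiometry). Exactly additive: the global curve equals
#' `stoichiometry_factor` times the sum of its per-site curves.
#'
#' @param ensemble a [protonation_ensemble()].
#' @param sites optional character vector of labels or site_ids.
#' @param compartment optional filter, `"lumenal"` and/or `"stromal"`.
#' @param stoichiometry_factor positive scalar multiplier.
#' @param n_boot,seed bootstrap settings.
#' @return a `titration_curve` on the global scale (values in
#'   \[0, n_sites x factor\]).
#' @export
global_curve <- function(ensemble, sites = NULL, compartment = NULL,
                         stoichiometry_factor = 1, n_boot = 1000L,
                         seed = 1L) {
  stopifnot(stoichiometry_factor > 0)
  ids <- .select_sites(ensemble, sites, compartment)
  if (!length(ids)) stop("site subset is empty", call. = FALSE)
  arr <- replicate_site_means(ensemble)
  stat <- apply(arr[, , ids, drop = FALSE], c(1L, 2L), sum)
  subject <- sprintf("global[%s]%s",
                     if (!is.null(compartment))
                       paste(compartment, collapse = "+") else "all",
                     if (stoichiometry_factor != 1)
                       sprintf(" x%g", stoichiometry_factor) else "")
  .curve_from_stat(t(stat), ensemble, subject = subject, scale = "global",
                   n_boot = n_boot, seed = seed,
                   factor = stoichiometry_factor)
}

#' Fit the Hill equation to a titration curve
#'
#' Weighted nonlinear least squares of
#' \deqn{\langle x\rangle(pH) = \frac{1}{1 + 10^{\,h\,(pH - pKa)}}}
#' so that the fitted curve equals 0.5 exactly at `pH = pKa`. Hill
#' coefficient `h < 1` indicates anticooperative proton binding, `h > 1`
#' cooperative. Weights are inverse squared CI half-widths (uniform when
#' the band is degenerate); initial values are `pKa` = grid pH whose mean
#' is closest to 0.5 and `h = 1`. The fit is flagged `low_confidence` when
#' the curve never crosses 0.5 inside the grid or the fitted pKa falls
#' outside it (such fits are merely indicative).
#'
#' @param curve a per-site `titration_curve` (values in \[0,1\], >= 3 pH
#'   points).
#' @return object of class `hill_fit`: `pka`, `hill_h`, standard errors,
#'   `converged`, `low_confidence`, `reason`.
#' @export
fit_hill <- function(curve) {
  stopifnot(inherits(curve, "titration_curve"))
  if (nrow(curve) < 3L) stop("need >= 3 pH points", call. = FALSE)
  if (attr(curve, "scale") != "per-site" ||
      any(curve$mean < -1e-9 | curve$mean > 1 + 1e-9)) {
    stop("Hill fit requires a per-site curve with values in [0, 1]",
         call. = FALSE)
  }
  half <- (curve$ci_hi - curve$ci_lo) / 2
  w <- if (any(half <= .Machine$double.eps^0.5)) {
    rep(1, nrow(curve))
  } else {
    1 / half^2
  }
  pka0 <- curve$pH[which.min(abs(curve$mean - 0.5))]
  df <- data.frame(pH = curve$pH, y = curve$mean)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 / (1 + 10^(h * (pH - pka))),
                      data = df, weights = w,
                      start = list(pka = pka0, h = 1),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(list(pka = NA_real_, hill_h = NA_real_,
                          se_pka = NA_real_, se_h = NA_real_,
                          converged = FALSE, low_confidence = TRUE,
                          reason = conditionMessage(fit),
                          subject = attr(curve, "subject")),
                     class = "hill_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    c(pka = NA_real_, h = NA_real_))
  crosses <- min(curve$mean) <= 0.5 && max(curve$mean) >= 0.5
  in_grid <- cf[["pka"]] >= min(curve$pH) && cf[["pka"]] <= max(curve$pH)
  reason <- if (!crosses) {
    "curve does not cross 0.5 within the pH grid"
  } else if (!in_grid) {
    "fitted pKa lies outside the pH grid"
  } else {
    NA_character_
  }
  structure(list(pka = unname(cf[["pka"]]), hill_h = unname(cf[["h"]]),
                 se_pka = unname(se[[1L]]), se_h = unname(se[[2L]]),
                 converged = cf[["h"]] > 0,
                 low_confidence = !crosses || !in_grid, reason = reason,
                 subject = attr(curve, "subject")),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("hill_fit [%s]: pKa = %.3f (+/- %.3f), h = %.3f (+/- %.3f)%s\n",
              x$subject %||% "?", x$pka, x$se_pka, x$hill_h, x$se_h,
              if (isTRUE(x$low_confidence))
                paste0("  [low confidence: ", x$reason, "]") else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
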