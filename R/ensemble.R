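# Container for per-pH, per-replicate binary protonation trajectories of
# one system (monomer or dimer).

.ph_key <- function(pH) sprintf("%.6g", as.numeric(pH))

#' Construct a protonation ensemble
#'
#' @param system `"monomer"` or `"dimer"`.
#' @param sites site-metadata data.frame with columns `site_id`, `label`,
#'   `chain`, `compartment` (and `monomer_site_match` for dimers).
#' @param trajectories list over pH (named by pH) of lists of replicate
#'   state matrices (frames x sites, entries in {0,1}, columns ordered as
#'   `sites$site_id`).
#' @param pH_grid numeric, strictly increasing; defaults to the trajectory
#'   names.
#' @param frame_spacing time per frame in arbitrary units (default 1).
#' @param temperature kelvin, recorded for downstream energetics.
#' @return object of class `protonation_ensemble`.
#' @export
protonation_ensemble <- function(system, sites, trajectories,
                                 pH_grid = NULL, frame_spacing = 1,
                                 temperature = 298.15) {
  system <- match.arg(system, c("monomer", "dimer"))
  if (is.null(pH_grid)) pH_grid <- as.numeric(names(trajectories))
  pH_grid <- as.numeric(pH_grid)
  if (any(diff(pH_grid) <= 0)) {
    stop("pH grid must be strictly increasing", call. = FALSE)
  }
  names(trajectories) <- .ph_key(pH_grid)
  n_sites <- nrow(sites)
  for (k in names(trajectories)) {
    reps <- trajectories[[k]]
    if (!length(reps)) stop("no replicates at pH ", k, call. = FALSE)
    for (r in seq_along(reps)) {
      m <- reps[[r]]
      if (ncol(m) != n_sites) {
        stop("trajectory at pH ", k, " replicate ", r,
             " has wrong site count", call. = FALSE)
      }
      if (!all(m %in% c(0L, 1L))) {
        stop("non-binary protonation state at pH ", k, " replicate ", r,
             call. = FALSE)
      }
    }
  }
  structure(
    list(system = system, sites = sites, pH_grid = pH_grid,
         trajectories = trajectories, frame_spacing = frame_spacing,
         temperature = temperature),
    class = "protonation_ensemble"
  )
}

#' @export
print.protonation_ensemble <- function(x, ...) {
  nr <- lengths(x$trajectories)
  nf <- vapply(x$trajectories, function(r) nrow(r[[1L]]), integer(1))
  cat("protonation_ensemble (", x$system, "): ", nrow(x$sites),
      " sites, pH ", min(x$pH_grid), "-", max(x$pH_grid), " (",
      length(x$pH_grid), " points), ", min(nr), "-", max(nr),
      " replicates x ", min(nf), "-", max(nf), " frames\n", sep = "")
  invisible(x)
}

#' Number of replicates at each pH
#' @param ensemble a [protonation_ensemble()].
#' @return integer vector named by pH.
#' @export
n_replicates <- function(ensemble) lengths(ensemble$trajectories)

# replicate trajectory matrices at one pH
.traj_at <- function(ensemble, pH) {
  k <- .ph_key(pH)
  out <- ensemble$trajectories[[k]]
  if (is.null(out)) {
    stop("pH ", pH, " is not present in the ensemble grid", call. = FALSE)
  }
  out
}

#' Per-replicate, per-site time-average protonation
#'
#' The sufficient statistic for titration curves, linkage and bootstrap
#' resampling: the time average of each site's binary state in each
#' replicate at each pH.
#'
#' @param ensemble a [protonation_ensemble()].
#' @return 3-d array `[pH, replicate, site]` with dimnames.
#' @export
replicate_site_means <- function(ensemble) {
  n_ph <- length(ensemble$pH_grid)
  n_rep <- max(n_replicates(ensemble))
  ids <- ensemble$sites$site_id
  out <- array(NA_real_, dim = c(n_ph, n_rep, length(ids)),
               dimnames = list(.ph_key(ensemble$pH_grid), NULL, ids))
  for (i in seq_len(n_ph)) {
    reps <- ensemble$trajectories[[i]]
    for (r in seq_along(reps)) out[i, r, ] <- colMeans(reps[[r]])
  }
  out
}

#' Sample a synthetic protonation ensemble by Metropolis Monte Carlo
#'
#' Semi-grand-canonical single-site Metropolis sampling of a
#' [site_model()] across a pH grid. One frame is one full sweep over
#' sites; a site is attempted with its `flip_attempt_prob` (values < 1
#' emulate kinetically slow proton exchangers) and flips are accepted with
#' probability `min(1, exp(-dE/kT))`. The initial state of each replicate
#' is drawn from the independent-site Henderson-Hasselbalch probabilities
#' and a short burn-in is discarded. Identical `(model, seed, settings)`
#' give bit-identical trajectories; per-site time averages converge to the
#' [enumerate_equilibrium()] means as `n_frames` grows.
#'
#' @param model a [site_model()].
#' @param pH_grid numeric vector of pH values (non-empty).
#' @param n_replicates independent replicate chains per pH.
#' @param n_frames recorded sweeps per replicate (>= 1).
#' @param seed integer seed; all randomness flows from it.
#' @param flip_attempt_prob scalar or per-site vector in (0, 1].
#' @param system tag stored on the ensemble (`"monomer"` or `"dimer"`).
#' @param n_burnin discarded equilibration sweeps (default 100).
#' @param frame_spacing time units per frame (default 1, i.e. sweeps).
#' @return a [protonation_ensemble()].
#' @export
sample_ensemble <- function(model, pH_grid, n_replicates = 5L,
                            n_frames = 10000L, seed = 1L,
                            flip_attempt_prob = 1,
                            system = c("monomer", "dimer"),
                            n_burnin = 100L, frame_spacing = 1) {
  stopifnot(inherits(model, "site_model"))
  system <- match.arg(system)
  pH_grid <- sort(as.numeric(pH_grid))
  if (!length(pH_grid)) stop("pH grid is empty", call. = FALSE)
  if (any(!is.finite(c(model$pka_int, model$coupling)))) {
    stop("non-finite model parameters", call. = FALSE)
  }
  n <- model$n_sites
  ap <- rep_len(as.numeric(flip_attempt_prob), n)
  if (any(ap <= 0 | ap > 1)) {
    stop("flip_attempt_prob entries must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(n_frames >= 1L, n_replicates >= 1L, n_burnin >= 0L)
  kT <- kT_kcal(model$temperature)
  ids <- site_ids(model)
  old <- .save_rng_state()
  on.exit(old())
  set.seed(as.integer(seed))
  trajs <- vector("list", length(pH_grid))
  for (i in seq_along(pH_grid)) {
    pH <- pH_grid[i]
    mu <- log(10) * kT * (pH - model$pka_int)
    p_init <- 1 / (1 + 10^(pH - model$pka_int))
    reps <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      init <- rbinom(n, 1L, p_init)
      m <- .cpp_metropolis(mu, model$coupling, ap, kT, init,
                           as.integer(n_frames), as.integer(n_burnin))
      colnames(m) <- ids
      reps[[r]] <- m
    }
    trajs[[i]] <- reps
  }
  names(trajs) <- .ph_key(pH_grid)
  protonation_ensemble(system = system, sites = site_metadata(model),
                       trajectories = trajs, pH_grid = pH_grid,
                       frame_spacing = frame_spacing,
                       temperature = model$temperature)
}

# preserve caller's RNG state across seeded internals
.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() invisible(NULL)
  }
}
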