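# Pairwise protonation correlations, threshold networks, and protonation
# correlation times.

.VAR_MASK <- 1e-6  # sites with sample variance below this are undefined

#' Pairwise protonation correlation map at one pH
#'
#' Pearson correlation (the phi coefficient, since states are binary)
#' between the protonation series of every site pair. Pairs involving a
#' site whose sample variance is below `1e-6` (e.g. always protonated at
#' that pH) are masked `NA` - undefined, never zero. Pooling
#' concatenates frames across replicates (default; replicates trapped in
#' distinct protonation configurations then show up as correlation);
#' `"per-replicate"` instead averages the within-replicate correlation
#' maps, which is insensitive to between-replicate trapping.
#'
#' @param ensemble a [protonation_ensemble()].
#' @param pH a pH present in the ensemble grid.
#' @param pooling `"pooled"` or `"per-replicate"`.
#' @return object of class `correlation_map`: `pH`, `cor` (symmetric
#'   matrix, unit diagonal where defined), `n_effective` (total frames),
#'   `pooling`, `sites` (metadata).
#' @export
pairwise_correlation <- function(ensemble, pH,
                                 pooling = c("pooled", "per-replicate")) {
  pooling <- match.arg(pooling)
  reps <- .traj_at(ensemble, pH)
  ids <- ensemble$sites$site_id
  if (pooling == "pooled") {
    S <- do.call(rbind, reps)
    cm <- .masked_cor(S)
  } else {
    maps <- lapply(reps, .masked_cor)
    cm <- Reduce(`+`, lapply(maps, function(m) ifelse(is.na(m), 0, m)))
    cnt <- Reduce(`+`, lapply(maps, function(m) !is.na(m)))
    cm <- cm / cnt          # NaN where defined in no replicate
    cm[cnt == 0L] <- NA_real_
  }
  dimnames(cm) <- list(ids, ids)
  structure(list(pH = pH, cor = cm,
                 n_effective = sum(vapply(reps, nrow, integer(1))),
                 pooling = pooling, sites = ensemble$sites),
            class = "correlation_map")
}

.masked_cor <- function(S) {
  v <- apply(S, 2L, var)
  ok <- v >= .VAR_MASK
  n <- ncol(S)
  cm <- matrix(NA_real_, n, n)
  if (any(ok)) {
    cm[ok, ok] <- suppressWarnings(cor(S[, ok, drop = FALSE]))
    diag(cm)[ok] <- 1
  }
  cm
}

#' @export
print.correlation_map <- function(x, ...) {
  def <- x$cor[upper.tri(x$cor)]
  def <- def[!is.na(def)]
  cat(sprintf(
    "correlation_map at pH %g (%s, n = %d frames): %d defined pairs, max |c| = %s\n",
    x$pH, x$pooling, x$n_effective, length(def),
    if (length(def)) sprintf("%.3f", max(abs(def))) else "-"))
  invisible(x)
}

#' Threshold correlation network
#'
#' Edges are site pairs whose defined correlation magnitude reaches the
#' threshold; edges between sites in different membrane compartments
#' (lumenal vs stromal) are flagged `cross_compartment` - the signature
#' of stroma-lumen electrostatic communication. Masked (undefined) pairs
#' never contribute an edge.
#'
#' @param maps a `correlation_map` or list of them (one per pH).
#' @param threshold correlation-magnitude threshold in (0, 1); default
#'   0.3 ("substantial" correlation - tunable, sweep it for sensitivity).
#' @return data.frame of class `correlation_network`: `site_i`, `site_j`,
#'   `pH`, `correlation`, `sign`, `cross_compartment`.
#' @export
build_network <- function(maps, threshold = 0.3) {
  stopifnot(threshold > 0, threshold < 1)
  if (inherits(maps, "correlation_map")) maps <- list(maps)
  rows <- lapply(maps, function(m) {
    cm <- m$cor
    ut <- which(upper.tri(cm) & !is.na(cm) & abs(cm) >= threshold,
                arr.ind = TRUE)
    if (!nrow(ut)) return(NULL)
    comp <- setNames(m$sites$compartment, m$sites$site_id)
    i_id <- rownames(cm)[ut[, 1L]]
    j_id <- colnames(cm)[ut[, 2L]]
    data.frame(site_i = i_id, site_j = j_id, pH = m$pH,
               correlation = cm[ut],
               sign = ifelse(cm[ut] > 0, "positive", "negative"),
               cross_compartment = comp[i_id] != comp[j_id],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(site_i = character(), site_j = character(),
                      pH = numeric(), correlation = numeric(),
                      sign = character(), cross_compartment = logical())
  }
  structure(out, threshold = threshold,
            class = c("correlation_network", "data.frame"))
}

# biased fluctuation autocovariance via FFT; returns C(t)/C(0), t = 0..n-1
.acf_norm <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  m <- stats::nextn(2L * n)
  f <- fft(c(xc, rep(0, m - n)))
  ac <- Re(fft(Mod(f)^2, inverse = TRUE))[seq_len(n)] / m
  if (ac[1L] <= 0) return(NULL)
  ac / ac[1L]
}

#' Protonation correlation time of a site
#'
#' Integrated autocorrelation time of the binary protonation series,
#' \deqn{\tau = \Delta t \left(\tfrac12 + \sum_{t\ge 1} C(t)\right)}
#' where `C(t)` is the normalized fluctuation autocorrelation averaged
#' over replicates and the sum is truncated at the first nonpositive lag
#' (initial-positive-sequence truncation, the standard bias/variance
#' compromise for short noisy binary series). White noise gives
#' `tau = 0.5` frame units; kinetically trapped sites give large values.
#'
#' @param ensemble a [protonation_ensemble()] (or a single frames x sites
#'   state matrix).
#' @param site site label or site_id.
#' @param pH pH at which to analyse (ignored for a raw matrix).
#' @return object of class `correlation_time`: `site`, `pH`, `tau`
#'   (frame units), `tau_time` (`tau * frame_spacing`), `cutoff_lag`,
#'   `defined`, `reason`.
#' @export
correlation_time <- function(ensemble, site, pH = NULL) {
  if (is.matrix(ensemble)) {
    series <- list(ensemble[, site])
    spacing <- 1
  } else {
    stopifnot(inherits(ensemble, "protonation_ensemble"))
    ids <- .select_sites(ensemble, sites = site)
    if (length(ids) != 1L) {
      stop("site '", site, "' does not resolve to exactly one site",
           call. = FALSE)
    }
    reps <- .traj_at(ensemble, pH)
    series <- lapply(reps, function(m) m[, ids])
    spacing <- ensemble$frame_spacing
  }
  if (any(lengths(series) < 10L)) {
    stop("need at least 10 frames per replicate", call. = FALSE)
  }
  acfs <- Filter(Negate(is.null), lapply(series, .acf_norm))
  if (!length(acfs)) {
    return(structure(list(site = site, pH = pH, tau = NA_real_,
                          tau_time = NA_real_, cutoff_lag = NA_integer_,
                          defined = FALSE,
                          reason = "site has zero variance"),
                     class = "correlation_time"))
  }
  nmin <- min(lengths(acfs))
  C <- rowMeans(vapply(acfs, function(a) a[seq_len(nmin)],
                       numeric(nmin)))
  lagC <- C[-1L]
  cutoff <- which(lagC <= 0)[1L]
  if (is.na(cutoff)) cutoff <- length(lagC) + 1L
  tau <- 0.5 + sum(lagC[seq_len(cutoff - 1L)])
  structure(list(site = site, pH = pH, tau = tau,
                 tau_time = tau * spacing, cutoff_lag = cutoff,
                 defined = TRUE, reason = NA_character_),
            class = "correlation_time")
}

#' @export
print.correlation_time <- function(x, ...) {
  if (x$defined) {
    cat(sprintf(
      "correlation_time [%s, pH %s]: tau = %.2f frames (cutoff lag %d)\n",
      x$site, format(x$pH), x$tau, x$cutoff_lag))
  } else {
    cat(sprintf("correlation_time [%s]: undefined (%s)\n", x$site,
                x$reason))
  }
  invisible(x)
}
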