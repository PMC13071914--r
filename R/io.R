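# File formats: long-format occupancy TSV (+ site-metadata TSV), a
# whitespace "matrix" dialect with the pH encoded in the filename, YAML
# run configuration, and TSV/JSON writers for analysis artifacts.

#' Write a protonation ensemble as a long-format occupancy TSV
#'
#' Columns: `system`, `pH`, `replicate`, `frame`, then one 0/1 column per
#' site (named by `site_id`). A companion site-metadata TSV (`site_id`,
#' `label`, `chain`, `compartment`, `monomer_site_match`) is written next
#' to it unless `metadata_path = NULL`.
#'
#' @param ensemble a [protonation_ensemble()].
#' @param path output TSV path.
#' @param metadata_path companion metadata TSV (default:
#'   `<path>.sites.tsv`).
#' @return `path`, invisibly.
#' @export
write_occupancy <- function(ensemble, path,
                            metadata_path = paste0(path, ".sites.tsv")) {
  blocks <- list()
  for (i in seq_along(ensemble$pH_grid)) {
    pH <- ensemble$pH_grid[i]
    reps <- ensemble$trajectories[[i]]
    for (r in seq_along(reps)) {
      m <- reps[[r]]
      blocks[[length(blocks) + 1L]] <- data.frame(
        system = ensemble$system, pH = pH, replicate = r,
        frame = seq_len(nrow(m)), m, check.names = FALSE)
    }
  }
  out <- do.call(rbind, blocks)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    md <- ensemble$sites
    if (is.null(md$monomer_site_match)) md$monomer_site_match <- NA
    write.table(md, metadata_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read a site-metadata table
#' @param path TSV with columns `site_id`, `label`, `chain`,
#'   `compartment` (and optionally `monomer_site_match`, `pka_int`).
#' @return data.frame.
#' @export
read_site_metadata <- function(path) {
  md <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("site_id", "label", "chain", "compartment")
  miss <- setdiff(need, names(md))
  if (length(miss)) {
    stop("site metadata ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  md
}

#' Read a long-format occupancy TSV into a protonation ensemble
#'
#' Validates states strictly (any non-0/1 value is fatal with its line
#' number), rejects duplicate `(system, pH, replicate, frame)` keys, and
#' requires a constant `system` column per file. Round-trips losslessly
#' with [write_occupancy()].
#'
#' @param path occupancy TSV.
#' @param metadata_path companion site-metadata TSV (default:
#'   `<path>.sites.tsv`).
#' @param frame_spacing,temperature stored on the ensemble.
#' @return a [protonation_ensemble()].
#' @export
read_occupancy <- function(path, metadata_path = paste0(path,
                                                        ".sites.tsv"),
                           frame_spacing = 1, temperature = 298.15) {
  md <- read_site_metadata(metadata_path)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  key_cols <- c("system", "pH", "replicate", "frame")
  miss <- setdiff(key_cols, names(tab))
  if (length(miss)) {
    stop("occupancy file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  site_cols <- setdiff(names(tab), key_cols)
  miss <- setdiff(md$site_id, site_cols)
  if (length(miss)) {
    stop("occupancy file lacks site column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  states <- as.matrix(tab[, md$site_id, drop = FALSE])
  bad <- which(!(states %in% c(0L, 1L)))
  if (length(bad)) {
    row <- ((bad[1L] - 1L) %% nrow(states)) + 1L
    col <- md$site_id[((bad[1L] - 1L) %/% nrow(states)) + 1L]
    stop("non-binary state value ", states[bad[1L]], " at line ",
         row + 1L, " (site ", col, ") of ", path, call. = FALSE)
  }
  if (length(unique(tab$system)) != 1L) {
    stop("occupancy file mixes systems; write one file per system",
         call. = FALSE)
  }
  key <- paste(tab$system, tab$pH, tab$replicate, tab$frame)
  dup <- anyDuplicated(key)
  if (dup) {
    stop("duplicate (system, pH, replicate, frame) key at line ",
         dup + 1L, " of ", path, call. = FALSE)
  }
  pH_grid <- sort(unique(tab$pH))
  trajs <- lapply(pH_grid, function(p) {
    sel <- tab$pH == p
    reps <- sort(unique(tab$replicate[sel]))
    lapply(reps, function(r) {
      rows <- which(sel & tab$replicate == r)
      rows <- rows[order(tab$frame[rows])]
      m <- states[rows, , drop = FALSE]
      storage.mode(m) <- "integer"
      colnames(m) <- md$site_id
      m
    })
  })
  names(trajs) <- .ph_key(pH_grid)
  protonation_ensemble(system = tab$system[1L], sites = md,
                       trajectories = trajs, pH_grid = pH_grid,
                       frame_spacing = frame_spacing,
                       temperature = temperature)
}

#' Read whitespace-matrix occupancy files (pH encoded in the filename)
#'
#' Dialect used by some constant-pH MD post-processing layouts: each file
#' is a whitespace-separated frames x sites 0/1 matrix without header or
#' pH column; the pH is carried by a filename token `pH<value>` and the
#' replicate by an optional token `rep<id>` (e.g.
#' `occ_pH5.0_rep2.dat`). Files sharing a pH become replicates in
#' reading order of their `rep` ids.
#'
#' @param paths character vector of matrix files.
#' @param metadata_path site-metadata TSV defining site order.
#' @param system `"monomer"` or `"dimer"`.
#' @param frame_spacing,temperature stored on the ensemble.
#' @return a [protonation_ensemble()].
#' @export
read_occupancy_matrix <- function(paths, metadata_path,
                                  system = c("monomer", "dimer"),
                                  frame_spacing = 1,
                                  temperature = 298.15) {
  system <- match.arg(system)
  md <- read_site_metadata(metadata_path)
  tok <- regmatches(basename(paths),
                    regexpr("pH[0-9]+(\\.[0-9]+)?", basename(paths)))
  if (length(tok) != length(paths)) {
    stop("every filename must carry a pH token like 'pH5.0'; missing in: ",
         paste(basename(paths)[!grepl("pH[0-9]", basename(paths))],
               collapse = ", "), call. = FALSE)
  }
  pHs <- as.numeric(sub("^pH", "", tok))
  rep_tok <- regmatches(basename(paths),
                        regexpr("rep[0-9]+", basename(paths)))
  rep_id <- rep(1L, length(paths))
  has_rep <- grepl("rep[0-9]+", basename(paths))
  rep_id[has_rep] <- as.integer(sub("^rep", "", rep_tok))
  pH_grid <- sort(unique(pHs))
  trajs <- lapply(pH_grid, function(p) {
    idx <- which(pHs == p)
    idx <- idx[order(rep_id[idx])]
    lapply(idx, function(i) {
      m <- as.matrix(read.table(paths[i], header = FALSE))
      if (ncol(m) != nrow(md)) {
        stop(basename(paths[i]), ": ", ncol(m),
             " columns but metadata defines ", nrow(md), " sites",
             call. = FALSE)
      }
      storage.mode(m) <- "integer"
      dimnames(m) <- list(NULL, md$site_id)
      m
    })
  })
  names(trajs) <- .ph_key(pH_grid)
  protonation_ensemble(system = system, sites = md,
                       trajectories = trajs, pH_grid = pH_grid,
                       frame_spacing = frame_spacing,
                       temperature = temperature)
}

#' Write a titration curve (or several) as TSV
#' @param curves a `titration_curve` or list of them.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "titration_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cu) {
    data.frame(subject = attr(cu, "subject"), pH = cu$pH,
               mean = cu$mean, ci_lo = cu$ci_lo, ci_hi = cu$ci_hi,
               n_replicates = cu$n_replicates)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write free-energy profiles as TSV
#' @param profiles a `free_energy_profile`, a `linkage_decomposition`,
#'   or a list of profiles.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "free_energy_profile")) {
    profiles <- list(profiles)
  } else if (inherits(profiles, "linkage_decomposition")) {
    profiles <- c(list(total = profiles$total), profiles$residues)
  }
  rows <- lapply(profiles, function(p) {
    data.frame(subject = attr(p, "subject"), subset = attr(p, "subset"),
               ref_pH = attr(p, "ref_pH"), pH = p$pH,
               ddG_kcal_mol = p$value,
               ci_lo = p$ci_lo %||% NA_real_,
               ci_hi = p$ci_hi %||% NA_real_)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Sections: `sites` (label, chain, compartment, pka_int), `couplings`
#' (i, j, energy; labels or indices), `dimer` (interface_pka_shift as a
#' site->shift map, interchain as i, j, energy), `sampling` (pH grid or
#' from/to/by, replicates, frames, seed, flip_attempt_prob, burnin),
#' `analysis` (ref_pH_linkage, ref_pH_fraction, temperature,
#' correlation_threshold, n_boot, f_ref_grid, compartment subset,
#' screen_threshold_kcal).
#'
#' @param path YAML file.
#' @return list of class `run_config` with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    sampling = list(replicates = 5L, frames = 10000L, seed = 1L,
                    burnin = 100L),
    analysis = list(ref_pH_linkage = 3, ref_pH_fraction = 7.5,
                    temperature = 298.15, correlation_threshold = 0.3,
                    n_boot = 1000L,
                    f_ref_grid = c(0.1, 0.25, 0.5, 0.75, 0.9),
                    compartment = "lumenal",
                    screen_threshold_kcal = 1)
  )
  cfg$sampling <- modifyList(defaults$sampling, cfg$sampling %||% list())
  cfg$analysis <- modifyList(defaults$analysis, cfg$analysis %||% list())
  s <- cfg$sampling
  if (is.null(s$pH_grid) && !is.null(s$pH)) {
    cfg$sampling$pH_grid <- seq(s$pH$from, s$pH$to, by = s$pH$by)
  }
  grid <- cfg$sampling$pH_grid
  if (!is.null(grid)) {
    for (rp in c("ref_pH_linkage", "ref_pH_fraction")) {
      if (!any(abs(grid - cfg$analysis[[rp]]) < 1e-9)) {
        stop(rp, " = ", cfg$analysis[[rp]],
             " is not a point of the pH grid", call. = FALSE)
      }
    }
  }
  cfg$source_path <- path
  structure(cfg, class = "run_config")
}

#' Build a monomer (and optionally dimer) model from a run configuration
#'
#' @param config a `run_config` from [read_run_config()].
#' @return list with `monomer` and (when the config has a `dimer`
#'   section) `dimer` [site_model()]s.
#' @export
config_models <- function(config) {
  st <- config$sites
  if (is.null(st)) stop("config has no `sites` section", call. = FALSE)
  labels <- vapply(st, function(x) as.character(x$label), character(1))
  pka <- vapply(st, function(x) as.numeric(x$pka_int), numeric(1))
  comp <- vapply(st, function(x)
    as.character(x$compartment %||% "lumenal"), character(1))
  n <- length(labels)
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  for (cp in config$couplings %||% list()) {
    i <- if (is.character(cp$i)) match(cp$i, labels) else as.integer(cp$i)
    j <- if (is.character(cp$j)) match(cp$j, labels) else as.integer(cp$j)
    if (is.na(i) || is.na(j)) {
      stop("coupling references unknown site", call. = FALSE)
    }
    W[i, j] <- W[j, i] <- as.numeric(cp$energy)
  }
  mono <- site_model(pka, W, labels = labels, compartment = comp,
                     temperature = config$analysis$temperature)
  out <- list(monomer = mono)
  if (!is.null(config$dimer)) {
    shift <- numeric(n)
    for (sh in config$dimer$interface_pka_shift %||% list()) {
      i <- match(as.character(sh$site), labels)
      if (is.na(i)) stop("interface shift on unknown site ", sh$site,
                         call. = FALSE)
      shift[i] <- as.numeric(sh$shift)
    }
    ic <- NULL
    if (length(config$dimer$interchain %||% list())) {
      ic <- do.call(rbind, lapply(config$dimer$interchain, function(cp) {
        data.frame(
          i = if (is.character(cp$i)) match(cp$i, labels)
              else as.integer(cp$i),
          j = if (is.character(cp$j)) match(cp$j, labels)
              else as.integer(cp$j),
          energy = as.numeric(cp$energy))
      }))
    }
    out$dimer <- build_dimer_model(mono, shift, ic)
  }
  out
}
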