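# End-to-end orchestration: simulate (or load) monomer and dimer
# ensembles, then titration curves -> correlations -> linkage free
# energies -> monomer fractions, writing TSV/JSON artifacts with
# provenance. All randomness flows from the config seed; a rerun with the
# same config and inputs is bit-identical.

#' Run the full pH-linkage analysis pipeline
#'
#' Stages: `simulate` (synthetic ensembles from the configured site
#' model; skipped when occupancy inputs are given), `titrate` (per-site
#' and global titration curves + Hill fits), `correlate` (per-pH
#' correlation maps, threshold network, correlation times), `linkage`
#' (bootstrap free-energy profiles, per-residue decomposition,
#' key-residue screen), `fraction` (monomer-fraction shift), `report`
#' (provenance and summary JSON).
#'
#' @param config a `run_config` (see [read_run_config()]) or the path to
#'   a YAML configuration.
#' @param out_dir output directory (created if missing).
#' @param stages character subset of the stage names above.
#' @param ensembles optional named list with `monomer` and/or `dimer`
#'   [protonation_ensemble()] objects, bypassing simulation.
#' @return invisibly, a list with the computed objects (`ensembles`,
#'   `curves`, `hill`, `maps`, `network`, `profiles`, `screen`,
#'   `fractions`) and the paths written.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         stages = c("simulate", "titrate", "correlate",
                                    "linkage", "fraction", "report"),
                         ensembles = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  out_dir <- out_dir %||% config$output$dir %||% "phlinkage_out"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  an <- config$analysis
  sa <- config$sampling
  res <- list(paths = character())
  keep <- function(p) res$paths <<- c(res$paths, p)

  # --- inputs: simulate, load, or take injected ensembles -------------
  if (is.null(ensembles)) {
    ensembles <- list()
    if (!is.null(config$input)) {
      for (sys in intersect(names(config$input), c("monomer", "dimer"))) {
        ensembles[[sys]] <- read_occupancy(
          config$input[[sys]],
          config$input[[paste0(sys, "_sites")]] %||%
            paste0(config$input[[sys]], ".sites.tsv"),
          temperature = an$temperature)
      }
    } else if ("simulate" %in% stages) {
      models <- config_models(config)
      fp <- sa$flip_attempt_prob %||% 1
      for (sys in names(models)) {
        fps <- if (length(fp) == 1L) fp else rep_len(fp,
                                                    models[[sys]]$n_sites)
        ensembles[[sys]] <- sample_ensemble(
          models[[sys]], sa$pH_grid, n_replicates = sa$replicates,
          n_frames = sa$frames, seed = sa$seed + match(sys, names(models)),
          flip_attempt_prob = fps, system = sys, n_burnin = sa$burnin)
        p <- file.path(out_dir, paste0("occupancy_", sys, ".tsv"))
        write_occupancy(ensembles[[sys]], p)
        keep(p)
      }
    } else {
      stop("no ensembles: give `input` paths in the config, include the ",
           "simulate stage, or pass `ensembles`", call. = FALSE)
    }
  }
  if (!length(ensembles)) stop("no ensembles available", call. = FALSE)
  if (length(ensembles) == 2L &&
      !identical(ensembles$monomer$pH_grid, ensembles$dimer$pH_grid)) {
    stop("monomer and dimer pH grids differ; refusing to analyse",
         call. = FALSE)
  }
  res$ensembles <- ensembles

  # --- titration ------------------------------------------------------
  if ("titrate" %in% stages) {
    curves <- list()
    fits <- list()
    for (sys in names(ensembles)) {
      ens <- ensembles[[sys]]
      pol <- if (sys == "dimer") "average-chains" else "single-chain"
      for (lab in unique(ens$sites$label)) {
        cu <- residue_curve(ens, lab, chain_policy = pol,
                            n_boot = an$n_boot, seed = sa$seed)
        attr(cu, "subject") <- paste0(sys, ":", attr(cu, "subject"))
        curves[[length(curves) + 1L]] <- cu
        fits[[attr(cu, "subject")]] <- unclass(fit_hill(cu))
      }
      gfac <- if (sys == "monomer") 2 else 1
      curves[[length(curves) + 1L]] <- local({
        g <- global_curve(ens, stoichiometry_factor = gfac,
                          n_boot = an$n_boot, seed = sa$seed)
        attr(g, "subject") <- paste0(sys, ":", attr(g, "subject"))
        g
      })
    }
    keep(write_curves(curves, file.path(out_dir, "titration_curves.tsv")))
    jsonlite::write_json(fits, file.path(out_dir, "hill_fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    keep(file.path(out_dir, "hill_fits.json"))
    res$curves <- curves
    res$hill <- fits
  }

  # --- correlations ---------------------------------------------------
  if ("correlate" %in% stages) {
    res$maps <- list()
    nets <- list()
    tau_rows <- list()
    for (sys in names(ensembles)) {
      ens <- ensembles[[sys]]
      maps <- lapply(ens$pH_grid, function(p)
        pairwise_correlation(ens, p))
      res$maps[[sys]] <- maps
      for (m in maps) {
        p <- file.path(out_dir, sprintf("cormap_%s_pH%s.tsv", sys,
                                        .ph_key(m$pH)))
        write.table(round(m$cor, 6), p, sep = "\t", quote = FALSE,
                    col.names = NA)
        keep(p)
      }
      net <- build_network(maps, threshold = an$correlation_threshold)
      net$system <- rep(sys, nrow(net))
      nets[[sys]] <- net
      for (p in ens$pH_grid) {
        for (id in ens$sites$site_id) {
          ct <- correlation_time(ens, id, p)
          tau_rows[[length(tau_rows) + 1L]] <- data.frame(
            system = sys, site = id, pH = p, tau_frames = ct$tau,
            defined = ct$defined)
        }
      }
    }
    net_all <- do.call(rbind, nets)
    p <- file.path(out_dir, "correlation_network.tsv")
    write.table(net_all, p, sep = "\t", quote = FALSE, row.names = FALSE)
    keep(p)
    p <- file.path(out_dir, "correlation_times.tsv")
    write.table(do.call(rbind, tau_rows), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    keep(p)
    res$network <- net_all
  }

  # --- linkage --------------------------------------------------------
  if ("linkage" %in% stages) {
    if (is.null(ensembles$monomer) || is.null(ensembles$dimer)) {
      stop("linkage stage needs both monomer and dimer ensembles",
           call. = FALSE)
    }
    prof_all <- bootstrap_profile(ensembles$monomer, ensembles$dimer,
                                  ref_pH = an$ref_pH_linkage,
                                  n_boot = an$n_boot, seed = sa$seed)
    prof_sub <- bootstrap_profile(ensembles$monomer, ensembles$dimer,
                                  ref_pH = an$ref_pH_linkage,
                                  compartment = an$compartment,
                                  n_boot = an$n_boot, seed = sa$seed,
                                  per_residue = TRUE)
    screen <- screen_key_residues(prof_sub,
                                  threshold_kcal = an$screen_threshold_kcal)
    keep(write_profiles(prof_all, file.path(out_dir, "ddG_all.tsv")))
    keep(write_profiles(prof_sub, file.path(out_dir,
                                            "ddG_by_residue.tsv")))
    jsonlite::write_json(
      list(threshold_kcal = an$screen_threshold_kcal,
           ref_pH = an$ref_pH_linkage, subset = an$compartment,
           residues = screen),
      file.path(out_dir, "key_residues.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    keep(file.path(out_dir, "key_residues.json"))
    res$profiles <- list(all = prof_all, subset = prof_sub)
    res$screen <- screen
  }

  # --- monomer fraction ----------------------------------------------
  if ("fraction" %in% stages) {
    if (is.null(res$profiles)) {
      stop("fraction stage needs the linkage stage (or its profiles)",
           call. = FALSE)
    }
    prof <- anchor_profile(res$profiles$subset$total, an$ref_pH_fraction)
    frac <- fraction_uncertainty(prof, f_ref_grid = an$f_ref_grid)
    p <- file.path(out_dir, "monomer_fraction.tsv")
    write.table(as.data.frame(frac), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    keep(p)
    res$fractions <- frac
  }

  # --- provenance -----------------------------------------------------
  if ("report" %in% stages) {
    prov <- list(
      package = "phlinkage",
      version = as.character(utils::packageVersion("phlinkage")),
      r_version = R.version.string,
      seed = sa$seed,
      temperature = an$temperature,
      ref_pH_linkage = an$ref_pH_linkage,
      ref_pH_fraction = an$ref_pH_fraction,
      correlation_threshold = an$correlation_threshold,
      n_boot = an$n_boot,
      config_md5 = if (!is.null(config$source_path))
        unname(tools::md5sum(config$source_path)) else NA,
      artifacts = basename(res$paths))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    keep(file.path(out_dir, "provenance.json"))
  }
  invisible(res)
}
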