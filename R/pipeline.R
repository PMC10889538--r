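#' Default analysis configuration
#'
#' All tunable parameters of the pipeline with their standard defaults:
#' 100 ps analysis stride, H-bond criteria 3.6 A / 90 deg with a 0.6
#' occurrence threshold, 4 A hydrophobic contacts, RMSD-cluster cutoff
#' 4 A with a 2.4-7.0 A / 0.2 A sweep, secondary-structure pruning sweep
#' 0.05-1.0 / 0.05, temperature 310 K, pocket isovalue 0.5 at 0.5 A grid
#' spacing with a 1.4 A probe, and a 2 A porcupine display threshold.
#'
#' @return nested named list; amend fields and pass to [run_dynasome()] /
#'   [run_pocketome()], or serialise with `yaml::write_yaml()` (the
#'   config round-trips through YAML unchanged).
#' @export
default_config <- function() {
  list(
    seed = 1,
    stride_ps = 100,
    fit_region = NULL,              # e.g. "TM1"; NULL = all atoms
    analysis_region = NULL,         # e.g. "L-loop"; NULL = all residues
    hbond = list(dist_cutoff = 3.6, angle_cutoff = 90, min_frequency = 0.6),
    hydrophobic = list(cutoff = 4, min_separation = 2),
    cluster = list(cutoff = 4, r_min = 2.4, r_max = 7.0, step = 0.2),
    ss = list(prune_min = 0.05, prune_max = 1.0, prune_step = 0.05),
    pca = list(n_modes = 3, atom_names = "CA", amplitude_threshold = 2),
    fel = list(T = 310, k = NULL, grid_size = 100, min_barrier = 0.5),
    pocket = list(spacing = 0.5, probe = 1.4, isovalue = 0.5,
                  m_rays = 14, n_hits = 9, lining_cutoff = 4),
    density_bin = 0.1
  )
}

## merge user config over defaults, recursively
merge_config <- function(config) {
  base <- default_config()
  rec <- function(b, u) {
    for (nm in names(u)) {
      if (is.null(u[[nm]])) next           # NULL-valued defaults stay NULL
      b[[nm]] <- if (is.list(b[[nm]]) && is.list(u[[nm]]))
        rec(b[[nm]], u[[nm]]) else u[[nm]]
    }
    b
  }
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  rec(base, config)
}

.write_csv <- function(df, dir, name, manifest, module, params = NULL) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  manifest[[length(manifest) + 1]] <- list(file = name, module = module,
                                           parameters = params)
  manifest
}

#' Run the full dynamics characterisation pipeline
#'
#' Orchestrates, in order: stride sampling, superposition onto the first
#' frame, per-frame RMSD / per-residue RMSF / radius-of-gyration series
#' and their probability densities, hydrogen-bond occurrence, secondary
#' structure with helical content and folding-pattern clustering,
#' reference-based RMSD clustering with the cutoff sweep, PCA with
#' projections and the C-alpha cross-correlation map, and the free-energy
#' landscape with well decomposition.  Every CSV artefact is listed in a
#' JSON manifest together with the module and parameters that produced it.
#' Reruns with the same config and seed are byte-identical.
#'
#' @param ens an [Ensemble] (possibly multi-source, from [concatenate()]).
#' @param config configuration list (see [default_config()]) or a YAML path.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with the main in-memory results.
#' @export
run_dynasome <- function(ens, config = NULL, out_dir = tempfile("dynasome")) {
  cfg <- merge_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  top <- ens$topology
  stage <- "stride"
  res <- tryCatch({
    if (cfg$stride_ps > ens$stride) ens <- stride_sample(ens, cfg$stride_ps)
    stage <- "fit"
    fit_sel <- if (is.null(cfg$fit_region)) NULL
               else select_atoms(top, region = cfg$fit_region)
    ens <- fit_ensemble(ens, selection = fit_sel)
    ana_sel <- if (is.null(cfg$analysis_region)) seq_len(n_atoms(top))
               else select_atoms(top, region = cfg$analysis_region)
    ca_sel <- intersect(ana_sel, select_atoms(top, atom_names = cfg$pca$atom_names))
    stage <- "descriptors"
    ref <- get_frame(ens, 1)
    rmsd_v <- rmsd_series(ens, ref, selection = ca_sel, fit = FALSE)
    rmsf_v <- rmsf(ens, selection = ca_sel, fit = FALSE)
    rg_v <- rg_series(ens, selection = intersect(
      ana_sel, select_atoms(top, heavy = TRUE)))
    manifest <- .write_csv(
      data.frame(frame = seq_along(rmsd_v), time = ens$time,
                 source = ens$source, rmsd = rmsd_v, rg = rg_v),
      out_dir, "per_frame.csv", manifest, "geometry",
      list(stride_ps = cfg$stride_ps))
    manifest <- .write_csv(
      data.frame(resid = top$atoms$resid[ca_sel], rmsf = rmsf_v),
      out_dir, "rmsf.csv", manifest, "geometry", NULL)
    dens <- function(v) density_profile(v, bin = cfg$density_bin)
    manifest <- .write_csv(dens(rmsd_v), out_dir, "rmsd_density.csv",
                           manifest, "geometry", list(bin = cfg$density_bin))
    manifest <- .write_csv(dens(rg_v), out_dir, "rg_density.csv",
                           manifest, "geometry", list(bin = cfg$density_bin))
    stage <- "contacts"
    hb <- hbond_occurrence(ens, min_frequency = cfg$hbond$min_frequency,
                           dist_cutoff = cfg$hbond$dist_cutoff,
                           angle_cutoff = cfg$hbond$angle_cutoff)
    manifest <- .write_csv(hb, out_dir, "hbond_occurrence.csv", manifest,
                           "interactions", cfg$hbond)
    stage <- "secondary_structure"
    ss_full <- lapply(seq_len(n_frames(ens)), function(f)
      assign_secondary_structure(ens$xyz[f, ], top))
    writeLines(vapply(ss_full, paste0, "", collapse = ""),
               file.path(out_dir, "ss_strings.txt"))
    manifest[[length(manifest) + 1]] <- list(file = "ss_strings.txt",
                                             module = "secondary_structure",
                                             parameters = NULL)
    region <- if (is.null(cfg$analysis_region)) NULL
              else top$regions[[cfg$analysis_region]]
    hel <- vapply(ss_full, function(a) helical_content(a, region), numeric(1))
    manifest <- .write_csv(data.frame(frame = seq_along(hel), helical = hel),
                           out_dir, "helical_content.csv", manifest,
                           "secondary_structure", NULL)
    ss_cl <- cluster_by_ss(ss_full,
                           prune_distances = seq(cfg$ss$prune_min,
                                                 cfg$ss$prune_max,
                                                 by = cfg$ss$prune_step))
    manifest <- .write_csv(data.frame(frame = seq_along(ss_cl$labels),
                                      ss_cluster = ss_cl$labels),
                           out_dir, "ss_clusters.csv", manifest,
                           "secondary_structure", cfg$ss)
    stage <- "rmsd_clustering"
    cl <- reference_cluster(ens, selection = ca_sel,
                            cutoff_r = cfg$cluster$cutoff, seed = cfg$seed)
    manifest <- .write_csv(data.frame(frame = seq_along(cl$labels),
                                      cluster = cl$labels),
                           out_dir, "rmsd_clusters.csv", manifest,
                           "conformational_clustering", cfg$cluster)
    sweep_tab <- cutoff_sweep(ens, selection = ca_sel,
                              r_min = cfg$cluster$r_min,
                              r_max = cfg$cluster$r_max,
                              step = cfg$cluster$step, seed = cfg$seed)
    manifest <- .write_csv(sweep_tab, out_dir, "cutoff_sweep.csv", manifest,
                           "conformational_clustering", cfg$cluster)
    stage <- "pca"
    pc <- pca_ensemble(ens, selection = ca_sel, fit = FALSE)
    proj <- project_ensemble(ens, pc, n_modes = cfg$pca$n_modes, fit = FALSE)
    manifest <- .write_csv(proj, out_dir, "projections.csv", manifest,
                           "collective_motion", cfg$pca)
    manifest <- .write_csv(
      data.frame(mode = seq_along(pc$explained_variance),
                 eigenvalue = pc$eigenvalues,
                 explained = pc$explained_variance,
                 cumulative = pc$cumulative_variance),
      out_dir, "pca_spectrum.csv", manifest, "collective_motion", NULL)
    arrows <- mode_displacements(pc, 1, cfg$pca$amplitude_threshold)
    manifest <- .write_csv(arrows[arrows$displayed, , drop = FALSE], out_dir,
                           "mode1_arrows.csv", manifest, "collective_motion",
                           list(threshold = cfg$pca$amplitude_threshold))
    cc <- cross_correlation(ens, selection = ca_sel, fit = FALSE)
    manifest <- .write_csv(as.data.frame(unclass(cc)), out_dir,
                           "cross_correlation.csv", manifest,
                           "collective_motion", NULL)
    stage <- "free_energy"
    fes <- free_energy_landscape(proj, T = cfg$fel$T, k = cfg$fel$k,
                                 grid_size = cfg$fel$grid_size)
    wells <- detect_wells(fes, min_barrier = cfg$fel$min_barrier)
    comp <- well_composition(wells, fes$source)
    surf_df <- data.frame(R1 = rep(fes$R1, times = length(fes$R2)),
                          R2 = rep(fes$R2, each = length(fes$R1)),
                          P = as.vector(fes$P), dG = as.vector(fes$dG))
    manifest <- .write_csv(surf_df, out_dir, "fel_surface.csv", manifest,
                           "free_energy", cfg$fel)
    manifest <- .write_csv(comp, out_dir, "well_composition.csv", manifest,
                           "free_energy", cfg$fel)
    list(rmsd = rmsd_v, rmsf = rmsf_v, rg = rg_v, hbonds = hb,
         ss_clusters = ss_cl, clusters = cl, sweep = sweep_tab, pca = pc,
         projections = proj, correlation = cc, surface = fes,
         wells = wells, composition = comp)
  }, error = function(e) {
    stop("dynasome pipeline failed at stage '", stage, "' (frames 1-",
         n_frames(ens), "): ", conditionMessage(e), call. = FALSE)
  })
  jsonlite::write_json(list(pipeline = "dynasome", seed = cfg$seed,
                            artefacts = manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Run the pocket characterisation pipeline
#'
#' Builds the ensemble pocket-frequency map at the configured isovalue,
#' extracts labelled pockets, per-frame volume series, lining residues,
#' arginine orientations and hydrophobicity scores, and writes CSV
#' artefacts plus a JSON manifest.
#'
#' @inheritParams run_dynasome
#' @return (invisibly) list with `map`, per-pocket `volumes` and `lining`.
#' @export
run_pocketome <- function(ens, config = NULL, out_dir = tempfile("pocketome")) {
  cfg <- merge_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  stage <- "frequency_map"
  res <- tryCatch({
    map <- pocket_frequency_map(ens, isovalue = cfg$pocket$isovalue,
                                spacing = cfg$pocket$spacing,
                                probe = cfg$pocket$probe,
                                m_rays = cfg$pocket$m_rays,
                                n_hits = cfg$pocket$n_hits)
    manifest <- .write_csv(map$pockets, out_dir, "pockets.csv", manifest,
                           "pockets", cfg$pocket)
    stage <- "series"
    volumes <- list(); lining <- list()
    for (p in map$pockets$label) {
      v <- pocket_volume_series(map, p)
      volumes[[p]] <- v
      manifest <- .write_csv(
        data.frame(frame = seq_along(v), time = ens$time, volume = v),
        out_dir, paste0("volume_", p, ".csv"), manifest, "pockets", NULL)
      f_open <- which.max(v)
      nodes <- map$per_frame[[f_open]]$nodes_xyz
      lr <- lining_residues(ens$xyz[f_open, ], ens$topology, nodes,
                            cutoff = cfg$pocket$lining_cutoff)
      if (nrow(lr$residues)) {
        lr$residues$hydrophobicity <- as.numeric(
          hydrophobicity_score(lr$residues$resname))
        manifest <- .write_csv(lr$residues, out_dir,
                               paste0("lining_", p, ".csv"), manifest,
                               "pockets", list(frame = f_open))
      }
      lining[[p]] <- lr
    }
    list(map = map, volumes = volumes, lining = lining)
  }, error = function(e) {
    stop("pocketome pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  jsonlite::write_json(list(pipeline = "pocketome", seed = cfg$seed,
                            artefacts = manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
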