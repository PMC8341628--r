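# End-to-end orchestration: images (or polygons, or cached descriptors)
# -> outlines -> normalized descriptors -> three shape PCAs -> trait table
# -> correlations -> feature-set comparison, all reproducible from one
# root seed. Per-stage streams are derived from the root so adding CV
# replicates never perturbs the simulated data: the generator uses the
# root seed itself and cross-validation uses root + 10000.

#' Default pipeline configuration
#'
#' Settings mirror the standard analysis: 20 harmonics, erosion-dilation
#' cleaning, eigenvalue-above-mean effective-component rule, 70/30 split,
#' 1000 cross-validation replicates, alpha 0.05.
#'
#' @param mode Input mode: "synthetic", "images", "polygons" or "nefds".
#' @param seed Root seed.
#' @param output_dir Artifact directory (NULL = no files written).
#' @return Named list of settings; override fields as needed and pass to
#'   [run_pipeline()].
#' @export
pipeline_config <- function(mode = "synthetic", seed = 1L, output_dir = NULL) {
  list(
    mode = mode,
    seed = as.integer(seed),
    output_dir = output_dir,
    n_harmonics = 20L,
    clean_mode = "erosion_dilation",
    clean_radius = 1L,
    min_area_px = 20L,
    appendix_hint = "left",
    effective_criterion = "gt_mean",
    feature_labels = c("S", "A", "G", "LW", "Q", "QLW", "GLW", "SALW"),
    train_frac = 0.7,
    n_reps = 1000L,
    alpha = 0.05,
    # synthetic mode
    n_species = 10L,
    n_specimens = 3L,
    spores_per_specimen = c(10L, 37L),
    spores_per_image = c(1L, 4L),
    scale_um_per_px = 0.1,
    use_rasters = FALSE,
    ranges = NULL,
    # images mode
    manifest = NULL,        # data.frame or CSV path: image_id, path, specimen_id, species_id
    # polygons mode
    polygons = NULL, meta = NULL,
    # nefds mode
    nefd_file = NULL, nefd_meta = NULL
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields present in the file override [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full morphometric pipeline
#'
#' Executes every stage for the configured input and returns (and
#' optionally writes) the complete artifact set: normalized descriptors,
#' the three shape PCAs, the spore- and image-level trait tables, the
#' trait correlation matrix, and the cross-validated feature-set
#' comparison. Re-running with an identical configuration reproduces all
#' numbers exactly.
#'
#' @param config List from [pipeline_config()] /
#'   [read_pipeline_config()].
#' @return Object of class `pipeline_run` with elements `nefds`, `pcas`,
#'   `records`, `traits`, `correlations`, `comparison`, `config`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t0 <- Sys.time()
  log_lines <- character(0L)
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  say("pipeline start: mode=%s seed=%d", config$mode, config$seed)
  inp <- stage("input", pipeline_input(config, say))
  polygons <- inp$polygons
  meta <- inp$meta

  nefds <- inp$nefds
  if (is.null(nefds)) {
    say("elliptic Fourier analysis: %d outlines, %d harmonics",
        length(polygons), config$n_harmonics)
    # raster-derived outlines carry pixel noise: smooth before the
    # appendix-side (180-degree flip) detection
    flip_smooth <- if (isTRUE(config$use_rasters) || config$mode == "images")
      2L else 0L
    nefds <- stage("efa", lapply(polygons, function(p)
      normalize_efd(compute_efd(p, config$n_harmonics), poly = p,
                    flip_smooth = flip_smooth)))
  }

  say("fitting shape PCAs (symmetric, asymmetric, global)")
  pcas <- stage("pca", {
    out <- lapply(c(symmetric = "symmetric", asymmetric = "asymmetric",
                    global = "global"),
                  function(v) fit_shape_pca(nefd_matrix(nefds, v), v))
    for (v in names(out))
      out[[v]]$effective_idx <-
        effective_components(out[[v]], config$effective_criterion)
    out
  })

  say("building trait tables")
  required_pcs <- list(symmetric = 1L, asymmetric = 1:3, global = 1:2)
  records <- stage("traits", {
    scores <- lapply(pcas, function(p) p$scores)
    eff <- lapply(names(pcas), function(v) {
      avail <- seq_len(ncol(pcas[[v]]$scores))
      sort(union(intersect(required_pcs[[v]], avail),
                 intersect(pcas[[v]]$effective_idx, avail)))
    })
    names(eff) <- names(pcas)
    if (!is.null(inp$records_base)) {
      # descriptor-only input: size traits come with the metadata
      tab <- inp$records_base
      for (v in names(scores)) {
        sc <- scores[[v]][match(tab$spore_id, rownames(scores[[v]])),
                          eff[[v]], drop = FALSE]
        colnames(sc) <- sprintf("%s_PC%d", v, eff[[v]])
        tab <- cbind(tab, sc)
      }
      tab
    } else {
      spore_records(meta, polygons, scores, eff)
    }
  })
  traits <- stage("aggregate", aggregate_per_image(records))
  say("%d spores in %d images aggregated", nrow(records), nrow(traits))

  say("trait correlations (Spearman, alpha=%.2f)", config$alpha)
  cor_traits <- intersect(
    c("symmetric_PC1", "asymmetric_PC1", "asymmetric_PC2", "asymmetric_PC3",
      "global_PC1", "global_PC2", "length_um", "width_um", "q_ratio"),
    names(traits))
  correlations <- stage("correlate",
    spearman_matrix(traits, cor_traits, alpha = config$alpha))

  say("feature-set comparison: %s; %d replicates",
      paste(config$feature_labels, collapse = ","), config$n_reps)
  comparison <- stage("compare",
    compare_feature_sets(traits, feature_sets(config$feature_labels),
                         n_reps = config$n_reps,
                         train_frac = config$train_frac,
                         seed = config$seed + 10000L))

  run <- structure(list(
    nefds = nefds, pcas = pcas, records = records, traits = traits,
    correlations = correlations, comparison = comparison,
    config = config, truth = inp$truth,
    log = log_lines
  ), class = "pipeline_run")

  if (!is.null(config$output_dir)) {
    say("writing artifacts to %s", config$output_dir)
    stage("write", write_pipeline_artifacts(run, config$output_dir,
                                            image_ids = meta$image_id[
                                              match(names(nefds), meta$spore_id)]))
  }
  say("pipeline done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  run$log <- log_lines
  run
}

# Resolve the configured input into polygons + per-spore metadata (or
# cached descriptors).
pipeline_input <- function(config, say) {
  mode <- match.arg(config$mode, c("synthetic", "images", "polygons", "nefds"))
  if (mode == "synthetic") {
    say("simulating panel: %d species x %d specimens", config$n_species,
        config$n_specimens)
    ranges <- if (is.null(config$ranges)) default_panel_ranges() else config$ranges
    panel <- sample_species_panel(config$n_species, config$n_specimens,
                                  ranges, seed = config$seed)
    ds <- generate_dataset(panel,
                           spores_per_specimen = config$spores_per_specimen,
                           scale_um_per_px = config$scale_um_per_px,
                           seed = config$seed,
                           spores_per_image = config$spores_per_image,
                           rasterize = isTRUE(config$use_rasters))
    if (isTRUE(config$use_rasters)) {
      say("extracting outlines from %d rasters", length(ds$images))
      ext <- extract_from_images(ds$images, ds$manifest, config)
      return(c(ext, list(truth = ds$truth)))
    }
    meta <- ds$truth[c("spore_id", "image_id", "specimen_id", "species_id")]
    polys <- lapply(ds$polygons, standardize_orientation,
                    appendix_hint = config$appendix_hint)
    return(list(polygons = polys, meta = meta, truth = ds$truth, nefds = NULL))
  }
  if (mode == "images") {
    man <- config$manifest
    if (is.character(man)) man <- utils::read.csv(man, stringsAsFactors = FALSE)
    if (is.null(man) || !all(c("image_id", "path", "specimen_id", "species_id")
                             %in% names(man)))
      stop("images mode needs a manifest with image_id, path, specimen_id, species_id")
    images <- list()
    for (i in seq_len(nrow(man))) {
      if (!file.exists(man$path[i]))
        stop("manifest references a missing image: ", man$image_id[i])
      images[[man$image_id[i]]] <-
        read_binary_image(man$path[i], config$scale_um_per_px)
    }
    ext <- extract_from_images(images, man, config)
    return(c(ext, list(truth = NULL)))
  }
  if (mode == "polygons") {
    if (is.null(config$polygons) || is.null(config$meta))
      stop("polygons mode needs config$polygons and config$meta")
    meta <- config$meta
    polys <- lapply(config$polygons, standardize_orientation,
                    appendix_hint = config$appendix_hint)
    return(list(polygons = polys, meta = meta, truth = NULL, nefds = NULL))
  }
  # cached descriptors: size traits must travel with the metadata
  nf <- read_nefd_file(config$nefd_file)
  meta <- config$nefd_meta
  if (is.character(meta)) meta <- utils::read.csv(meta, stringsAsFactors = FALSE)
  need <- c("spore_id", "image_id", "specimen_id", "species_id",
            "length_um", "width_um")
  if (is.null(meta) || !all(need %in% names(meta)))
    stop("nefds mode needs nefd_meta with ", paste(need, collapse = ", "))
  base <- meta[need]
  base$q_ratio <- base$length_um / base$width_um
  base$size_int <- sqrt(base$length_um * base$width_um)
  list(polygons = NULL, meta = meta, truth = NULL,
       nefds = nf$nefds[meta$spore_id], records_base = base)
}

# Trace every image, match outlines to manifest rows (left-to-right within
# an image), and standardize orientation.
extract_from_images <- function(images, manifest, config) {
  polygons <- list(); meta_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    image_id <- manifest$image_id[i]
    img <- images[[image_id]]
    if (is.null(img)) stop("manifest references a missing image: ", image_id)
    img <- morphological_clean(img, config$clean_mode, config$clean_radius)
    chains <- trace_boundary(img, min_area = config$min_area_px)
    if (length(chains) == 0L) next
    polys <- lapply(chains, chain_to_polygon)
    ord <- order(vapply(polys, function(p) min(p[, 1L]), 0))
    polys <- polys[ord]
    for (k in seq_along(polys)) {
      spore_id <- sprintf("%s_spr%02d", image_id, k)
      polygons[[spore_id]] <-
        standardize_orientation(polys[[k]], config$appendix_hint)
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        spore_id = spore_id, image_id = image_id,
        specimen_id = manifest$specimen_id[i],
        species_id = manifest$species_id[i], stringsAsFactors = FALSE)
    }
  }
  if (length(polygons) == 0L) stop("no outlines extracted from any image")
  list(polygons = polygons, meta = do.call(rbind, meta_rows), nefds = NULL)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline run (mode=%s, seed=%d): %d spores, %d images\n",
              x$config$mode, x$config$seed, nrow(x$records), nrow(x$traits)))
  print(x$comparison)
  invisible(x)
}

#' Write the artifact set of a pipeline run
#'
#' CSV tables (eigenvalues, scores, traits, correlations, comparison and
#' per-replicate accuracies), the descriptor text file, shape-range
#' figures for each effective component, the log, and a run manifest with
#' the seed and a configuration fingerprint.
#'
#' @param run A `pipeline_run`.
#' @param dir Output directory (created if needed).
#' @param image_ids Optional image ids for the descriptor file.
#' @return Invisibly, `dir`.
#' @export
write_pipeline_artifacts <- function(run, dir, image_ids = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  write_nefd_file(run$nefds, file.path(dir, "nefds.txt"), image_ids = image_ids)
  for (v in names(run$pcas)) {
    p <- run$pcas[[v]]
    wcsv(summary(p), sprintf("pca_%s_eigenvalues.csv", v))
    wcsv(data.frame(spore_id = rownames(p$scores), p$scores),
         sprintf("pca_%s_scores.csv", v))
    mean_shape <- mean_nefd(run$nefds)
    for (pc in p$effective_idx) {
      rng <- pc_shape_range(p, mean_shape, pc = pc, k_sd = 2)
      grDevices::png(file.path(dir, sprintf("shape_range_%s_PC%d.png", v, pc)),
                     width = 900, height = 300)
      graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
      for (w in c("minus", "mean", "plus")) {
        poly <- rng[[w]]
        graphics::plot(rbind(poly, poly[1L, ]), type = "l", asp = 1,
                       axes = FALSE, xlab = "", ylab = "",
                       main = sprintf("%s PC%d %s", v, pc, w))
      }
      grDevices::dev.off()
    }
  }
  wcsv(run$records, "spore_records.csv")
  wcsv(run$traits, "trait_table.csv")
  if (!is.null(run$truth)) wcsv(run$truth, "truth.csv")
  utils::write.csv(run$correlations$rho, file.path(dir, "spearman_rho.csv"))
  utils::write.csv(run$correlations$p, file.path(dir, "spearman_p.csv"))
  wcsv(run$comparison$summary, "cv_comparison.csv")
  wcsv(data.frame(replicate = seq_len(nrow(run$comparison$accuracies)),
                  run$comparison$accuracies), "cv_replicates.csv")
  cfg <- run$config
  cfg$polygons <- cfg$meta <- cfg$manifest <- NULL
  manifest <- c(
    sprintf("package_version: %s",
            as.character(utils::packageVersion("sporemorph"))),
    sprintf("r_version: %s", R.version.string),
    sprintf("seed: %d", cfg$seed),
    sprintf("config_fingerprint: %s", config_fingerprint(cfg)),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  )
  writeLines(manifest, file.path(dir, "run_manifest.txt"))
  writeLines(run$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

# order-stable fingerprint of the configuration (FNV-1a over the deparsed
# settings; enough to detect config drift between runs)
config_fingerprint <- function(cfg) {
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(h, b) * 16777619) %% 4294967296
  sprintf("%08x", h)
}
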