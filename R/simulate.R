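# Generative model of spore silhouettes: a bent capsule with an apical
# bump. The four shape axes (relative width, single bow of the long axis,
# S-curvature differentiating the two ends, end taper) are the silhouette
# features that outline PCAs of real spore panels load on, so parameter
# recovery is directly testable downstream.

.spore_param_names <- c("length_um", "width_um", "bow_kappa1", "end_kappa2",
                        "taper_p", "apiculus_h", "apiculus_sigma")
.spore_log_params <- c("length_um", "width_um")

#' Spore silhouette parameters
#'
#' Construct and validate the parameter set of the bent-capsule spore
#' generator.
#'
#' @param length_um,width_um Spore length and width in micrometres
#'   (width < length).
#' @param bow_kappa1 Amplitude of the single bow of the long axis, as a
#'   fraction of length (|value| <= 0.2).
#' @param end_kappa2 Amplitude of the S-curvature that differentiates the
#'   proximal and distal ends, as a fraction of length (|value| <= 0.2).
#' @param taper_p End-taper exponent in (0, 2]: small values give blunt,
#'   cylindric ends, large values give drawn-out, fusiform ends.
#' @param apiculus_h Height of the hilar-appendix bump in micrometres
#'   (0 disables it).
#' @param apiculus_sigma Width of the bump as a fraction of length.
#' @return A named list of class `spore_params`.
#' @export
spore_params <- function(length_um, width_um, bow_kappa1 = 0, end_kappa2 = 0,
                         taper_p = 0.75, apiculus_h = 0, apiculus_sigma = 0.04) {
  p <- list(length_um = length_um, width_um = width_um,
            bow_kappa1 = bow_kappa1, end_kappa2 = end_kappa2,
            taper_p = taper_p, apiculus_h = apiculus_h,
            apiculus_sigma = apiculus_sigma)
  validate_spore_params(p)
  structure(p, class = "spore_params")
}

validate_spore_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in .spore_param_names)
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite scalar")
  if (p$length_um <= 0 || p$width_um <= 0)
    stop("length_um and width_um must be positive")
  if (p$width_um >= p$length_um)
    stop("width_um must be smaller than length_um")
  if (p$taper_p <= 0 || p$taper_p > 2)
    stop("taper_p must lie in (0, 2]")
  if (abs(p$bow_kappa1) > 0.2 || abs(p$end_kappa2) > 0.2)
    stop("|bow_kappa1| and |end_kappa2| must not exceed 0.2")
  if (p$apiculus_h < 0) stop("apiculus_h must be nonnegative")
  if (p$apiculus_sigma <= 0) stop("apiculus_sigma must be positive")
  invisible(p)
}

#' Default parameter ranges of the synthetic species panel
#'
#' Ranges over which species mean parameters are drawn, and the default
#' between-specimen and within-specimen (spore) standard deviations.
#' Dimensions emulate needle-shaped to short-cylindric basidiospores of a
#' few to ~20 micrometres; length and width vary on the log scale.
#'
#' @return A list with components `mean_range` (named list of c(lo, hi)),
#'   `specimen_sd` and `spore_sd` (named numeric vectors; log-scale entries
#'   for `length_um` and `width_um`).
#' @export
default_panel_ranges <- function() {
  list(
    mean_range = list(
      length_um      = c(8, 18),
      width_um       = c(2, 4.5),
      bow_kappa1     = c(0.0, 0.12),
      end_kappa2     = c(-0.04, 0.04),
      taper_p        = c(0.4, 1.0),
      apiculus_h     = c(0.15, 0.4),
      apiculus_sigma = c(0.03, 0.06)
    ),
    specimen_sd = c(length_um = 0.04, width_um = 0.04, bow_kappa1 = 0.015,
                    end_kappa2 = 0.008, taper_p = 0.05, apiculus_h = 0.03,
                    apiculus_sigma = 0.004),
    spore_sd = c(length_um = 0.05, width_um = 0.06, bow_kappa1 = 0.02,
                 end_kappa2 = 0.01, taper_p = 0.06, apiculus_h = 0.04,
                 apiculus_sigma = 0.005)
  )
}

#' Sample a panel of synthetic species
#'
#' Draws species mean parameters uniformly from the configured ranges and,
#' per species, the between-specimen random effects (log-scale for length
#' and width, additive otherwise). The panel mirrors a balanced
#' species-by-specimen collection design.
#'
#' @param n_species Number of species (>= 2).
#' @param n_specimens Specimens per species (>= 1).
#' @param ranges Ranges/SDs as returned by [default_panel_ranges()]; SDs of
#'   zero give deterministic species (useful for ground-truth tests).
#' @param seed Integer seed; the panel is reproducible from it.
#' @return List of `species_shape_model` objects, one per species, each
#'   holding the species id, mean [spore_params()], the SD vectors, and an
#'   `n_specimens x n_params` matrix of specimen effects.
#' @export
sample_species_panel <- function(n_species, n_specimens,
                                 ranges = default_panel_ranges(), seed = 1L) {
  if (n_species < 2L) stop("n_species must be at least 2")
  if (n_specimens < 1L) stop("n_specimens must be at least 1")
  check_ranges(ranges)
  set.seed(as.integer(seed))
  lapply(seq_len(n_species), function(s) {
    mean_par <- lapply(ranges$mean_range, function(r) stats::runif(1L, r[1L], r[2L]))
    # keep the capsule well-posed even for extreme draws
    if (mean_par$width_um >= mean_par$length_um)
      mean_par$width_um <- 0.6 * mean_par$length_um
    eff <- vapply(.spore_param_names, function(nm)
      stats::rnorm(n_specimens, 0, ranges$specimen_sd[[nm]]), numeric(n_specimens))
    eff <- matrix(eff, nrow = n_specimens,
                  dimnames = list(NULL, .spore_param_names))
    structure(list(
      species_id = sprintf("sp%02d", s),
      mean = do.call(spore_params, mean_par),
      specimen_sd = ranges$specimen_sd,
      spore_sd = ranges$spore_sd,
      specimen_effects = eff
    ), class = "species_shape_model")
  })
}

check_ranges <- function(ranges) {
  if (!all(c("mean_range", "specimen_sd", "spore_sd") %in% names(ranges)))
    stop("ranges must list mean_range, specimen_sd and spore_sd")
  if (!setequal(names(ranges$mean_range), .spore_param_names))
    stop("mean_range must cover exactly the spore parameters")
  for (nm in .spore_param_names) {
    r <- ranges$mean_range[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1L] > r[2L])
      stop("invalid range for '", nm, "'")
    if (ranges$specimen_sd[[nm]] < 0 || ranges$spore_sd[[nm]] < 0)
      stop("standard deviations must be nonnegative")
  }
  rl <- ranges$mean_range
  if (rl$length_um[1L] <= 0 || rl$width_um[1L] <= 0)
    stop("length_um and width_um ranges must be positive")
  if (rl$taper_p[1L] <= 0 || rl$taper_p[2L] > 2)
    stop("taper_p range must lie in (0, 2]")
  if (max(abs(rl$bow_kappa1)) > 0.2 || max(abs(rl$end_kappa2)) > 0.2)
    stop("curvature ranges must lie within [-0.2, 0.2]")
  invisible(ranges)
}

#' Draw one spore from a species model
#'
#' Combines the species mean, the stored specimen effect and fresh spore
#' noise: length and width multiplicatively (log-normal), the curvature,
#' taper and apiculus terms additively (normal). The result is clipped to
#' the [spore_params()] invariants. Draws come from the current RNG stream;
#' seed at the caller.
#'
#' @param model A `species_shape_model`.
#' @param specimen_idx Specimen index within the model's design.
#' @return A [spore_params()] object.
#' @export
sample_spore <- function(model, specimen_idx) {
  stopifnot(inherits(model, "species_shape_model"))
  if (specimen_idx < 1L || specimen_idx > nrow(model$specimen_effects))
    stop("specimen_idx outside the model's design")
  eff <- model$specimen_effects[specimen_idx, ]
  noise <- stats::rnorm(length(.spore_param_names), 0, model$spore_sd[.spore_param_names])
  names(noise) <- .spore_param_names
  p <- model$mean
  out <- list()
  for (nm in .spore_param_names) {
    if (nm %in% .spore_log_params)
      out[[nm]] <- exp(log(p[[nm]]) + eff[[nm]] + noise[[nm]])
    else
      out[[nm]] <- p[[nm]] + eff[[nm]] + noise[[nm]]
  }
  # clip to invariants rather than reject: draws stay reproducible
  out$bow_kappa1 <- max(-0.2, min(0.2, out$bow_kappa1))
  out$end_kappa2 <- max(-0.2, min(0.2, out$end_kappa2))
  out$taper_p <- max(1e-3, min(2, out$taper_p))
  out$apiculus_h <- max(0, out$apiculus_h)
  out$apiculus_sigma <- max(1e-3, out$apiculus_sigma)
  if (out$width_um >= out$length_um) out$width_um <- 0.95 * out$length_um
  do.call(spore_params, out)
}

#' Render a spore silhouette as a closed polygon
#'
#' The silhouette is built on a centerline running from x = 0 to
#' x = length, vertically offset by
#' `y_c(t) = bow_kappa1 * L * sin(pi t) + end_kappa2 * L * sin(2 pi t)`,
#' with half-width `w(t) = (W/2) * (4 t (1 - t))^taper_p` and a Gaussian
#' apiculus bump of height `apiculus_h` and width `apiculus_sigma * L`
#' added to the adaxial (upper) profile at the proximal end (t = 0, left).
#'
#' @param params A [spore_params()] object.
#' @param n_points Approximate number of polygon vertices (>= 50).
#' @return Counterclockwise two-column polygon matrix in micrometres.
#' @export
render_polygon <- function(params, n_points = 200L) {
  validate_spore_params(params)
  if (n_points < 50L) stop("n_points must be at least 50")
  L <- params$length_um; W <- params$width_um
  if (W / 2 <= 0) stop("degenerate parameters: nonpositive half-width everywhere")
  m <- ceiling(n_points / 2)
  t <- seq(0, 1, length.out = m + 1L)
  yc <- params$bow_kappa1 * L * sin(pi * t) + params$end_kappa2 * L * sin(2 * pi * t)
  w <- (W / 2) * (4 * t * (1 - t))^params$taper_p
  bump <- params$apiculus_h * exp(-0.5 * (t / params$apiculus_sigma)^2)
  lower <- cbind(L * t, yc - w)
  upper <- cbind(L * rev(t), rev(yc + w + bump))
  poly <- rbind(lower, upper)
  # drop duplicate junction vertices (w = 0 at the ends when no bump)
  keep <- c(TRUE, rowSums(abs(diff(poly))) > 1e-12)
  poly <- poly[keep, , drop = FALSE]
  if (sum(abs(poly[1L, ] - poly[nrow(poly), ])) < 1e-12)
    poly <- poly[-nrow(poly), , drop = FALSE]
  ensure_ccw(poly)
}

#' Rasterize polygons into a binary image
#'
#' Emulates micrograph capture of silhouettes: foreground (spore) pixels
#' are 1 (white), background 0 (black). Pixel centers falling inside a
#' polygon become foreground (point-in-polygon via [mgcv::in.out()]).
#'
#' @param polys A polygon matrix or a list of them (micrometre coordinates).
#' @param scale_um_per_px Micrometres per pixel (> 0).
#' @param pad_px Background margin around the silhouettes, in pixels.
#' @param canvas_px Optional fixed c(rows, cols); silhouettes that do not
#'   fit with the requested margin raise an error.
#' @return A `binary_image`: list with `pixels` (0/1 matrix, row 1 = top),
#'   `scale_um_per_px`, and `origin_um` (x, y of the bottom-left canvas
#'   corner).
#' @export
rasterize_polygon <- function(polys, scale_um_per_px, pad_px = 4L, canvas_px = NULL) {
  if (is.matrix(polys) || is.data.frame(polys)) polys <- list(polys)
  if (length(polys) == 0L) stop("no polygons to rasterize")
  polys <- lapply(polys, as_polygon_matrix)
  if (scale_um_per_px <= 0) stop("scale_um_per_px must be positive")
  all_xy <- do.call(rbind, polys)
  s <- scale_um_per_px
  x0 <- min(all_xy[, 1L]) - pad_px * s
  y0 <- min(all_xy[, 2L]) - pad_px * s
  nc <- ceiling((max(all_xy[, 1L]) - x0) / s) + pad_px
  nr <- ceiling((max(all_xy[, 2L]) - y0) / s) + pad_px
  if (!is.null(canvas_px)) {
    if (nr > canvas_px[1L] || nc > canvas_px[2L])
      stop("silhouette larger than the requested canvas")
    nr <- canvas_px[1L]; nc <- canvas_px[2L]
  }
  cx <- x0 + (seq_len(nc) - 0.5) * s
  cy <- y0 + (seq_len(nr) - 0.5) * s          # bottom-up
  centers <- cbind(rep(cx, each = nr), rep(cy, times = nc))
  inside <- rep(FALSE, nrow(centers))
  for (p in polys) {
    bnd <- rbind(p, p[1L, , drop = FALSE])
    inside <- inside | mgcv::in.out(bnd, centers)
  }
  # matrix filled bottom-up per column; flip rows so row 1 is the top
  img <- matrix(as.integer(inside), nrow = nr, ncol = nc)
  img <- img[rev(seq_len(nr)), , drop = FALSE]
  binary_image(img, s, origin_um = c(x0, y0))
}

#' Construct a binary image object
#'
#' @param pixels Integer 0/1 matrix, row 1 at the top (image convention).
#' @param scale_um_per_px Micrometres per pixel.
#' @param origin_um Coordinates (x, y) of the bottom-left canvas corner.
#' @return A `binary_image` object.
#' @export
binary_image <- function(pixels, scale_um_per_px, origin_um = c(0, 0)) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (!all(pixels %in% c(0L, 1L))) stop("pixels must be 0/1")
  if (scale_um_per_px <= 0) stop("scale_um_per_px must be positive")
  structure(list(pixels = pixels, scale_um_per_px = scale_um_per_px,
                 origin_um = as.numeric(origin_um)),
            class = "binary_image")
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("binary image: %d x %d px, %.4g um/px, %d foreground px\n",
              nrow(x$pixels), ncol(x$pixels), x$scale_um_per_px,
              sum(x$pixels)))
  invisible(x)
}

#' Generate a synthetic spore dataset
#'
#' Draws spores for every specimen of a panel, groups them into images
#' (one to several spores per image), and returns polygons, optional
#' binary rasters, the image manifest and the ground-truth parameter table.
#' Everything is reproducible from the seed.
#'
#' @param panel Output of [sample_species_panel()].
#' @param spores_per_specimen Single count, or c(lo, hi) range from which
#'   per-specimen counts are drawn uniformly (emulating uneven herbarium
#'   yields).
#' @param scale_um_per_px Raster scale (micrometres per pixel).
#' @param seed Integer seed.
#' @param spores_per_image Single count or c(lo, hi) range; spores of one
#'   specimen are packed into images of this size.
#' @param n_points Vertices per rendered polygon.
#' @param rasterize If `FALSE`, skip raster generation (polygon-only
#'   dataset; much faster for large panels).
#' @param pad_px Margin passed to [rasterize_polygon()].
#' @return A `synthetic_dataset`: list with `polygons` (named list),
#'   `images` (named list of `binary_image` or NULL), `manifest`
#'   (data.frame: image_id, specimen_id, species_id, n_spores), and
#'   `truth` (data.frame: spore_id, image_id, specimen_id, species_id and
#'   one column per generator parameter).
#' @export
generate_dataset <- function(panel, spores_per_specimen = c(10L, 37L),
                             scale_um_per_px = 0.1, seed = 1L,
                             spores_per_image = c(1L, 1L),
                             n_points = 200L, rasterize = TRUE, pad_px = 4L) {
  stopifnot(length(panel) >= 1L, inherits(panel[[1L]], "species_shape_model"))
  rng_spec <- range(as.integer(spores_per_specimen))
  rng_img <- range(as.integer(spores_per_image))
  if (rng_spec[1L] < 1L || rng_img[1L] < 1L)
    stop("spore counts must be positive")
  set.seed(as.integer(seed))
  truth <- list(); manifest <- list()
  polygons <- list(); images <- list()
  img_counter <- 0L
  for (model in panel) {
    n_specimens <- nrow(model$specimen_effects)
    for (sp_i in seq_len(n_specimens)) {
      specimen_id <- sprintf("%s_spec%02d", model$species_id, sp_i)
      n_sp <- if (rng_spec[1L] == rng_spec[2L]) rng_spec[1L] else
        sample(seq(rng_spec[1L], rng_spec[2L]), 1L)
      drawn <- 0L
      while (drawn < n_sp) {
        take <- if (rng_img[1L] == rng_img[2L]) rng_img[1L] else
          sample(seq(rng_img[1L], rng_img[2L]), 1L)
        take <- min(take, n_sp - drawn)
        img_counter <- img_counter + 1L
        image_id <- sprintf("img%04d", img_counter)
        group_polys <- list()
        for (k in seq_len(take)) {
          drawn <- drawn + 1L
          pars <- sample_spore(model, sp_i)
          spore_id <- sprintf("%s_spr%03d", specimen_id, drawn)
          poly <- render_polygon(pars, n_points)
          polygons[[spore_id]] <- poly
          group_polys[[k]] <- poly
          truth[[length(truth) + 1L]] <- data.frame(
            spore_id = spore_id, image_id = image_id,
            specimen_id = specimen_id, species_id = model$species_id,
            as.data.frame(unclass(pars)), stringsAsFactors = FALSE)
        }
        manifest[[length(manifest) + 1L]] <- data.frame(
          image_id = image_id, specimen_id = specimen_id,
          species_id = model$species_id, n_spores = take,
          stringsAsFactors = FALSE)
        if (rasterize) {
          # lay spores side by side with a clear gap so components stay disjoint
          gap <- 2 * max(vapply(group_polys, function(p) diff(range(p[, 2L])), 0))
          placed <- list(); xoff <- 0
          for (k in seq_along(group_polys)) {
            p <- group_polys[[k]]
            p[, 1L] <- p[, 1L] - min(p[, 1L]) + xoff
            placed[[k]] <- p
            xoff <- max(p[, 1L]) + gap
          }
          images[[image_id]] <- rasterize_polygon(placed, scale_um_per_px,
                                                  pad_px = pad_px)
        }
      }
    }
  }
  structure(list(
    polygons = polygons,
    images = if (rasterize) images else NULL,
    manifest = do.call(rbind, manifest),
    truth = do.call(rbind, truth),
    scale_um_per_px = scale_um_per_px,
    seed = as.integer(seed)
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic spore dataset: %d spores, %d images, %d specimens, %d species\n",
              nrow(x$truth), nrow(x$manifest),
              length(unique(x$manifest$specimen_id)),
              length(unique(x$manifest$species_id))))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes PNG images (if present), and the manifest and ground-truth
#' tables as CSV.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  if (!is.null(dataset$images)) {
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (id in names(dataset$images))
      write_binary_image(dataset$images[[id]],
                         file.path(img_dir, paste0(id, ".png")))
  }
  invisible(dir)
}
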