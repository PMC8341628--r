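# From micrograph to outline: binarization, morphological cleaning,
# Freeman chain-code boundary tracing, and a fixed orientation standard
# (hilar appendix upper-left), mirroring a manual chain-coding workflow as
# an automated filter chain.
#
# Pixel conventions: matrices are row x col with row 1 at the top; chain
# codes use Freeman directions 0-7 with 0 = east and values increasing
# counterclockwise in y-up coordinates (2 = up, 4 = west, 6 = down).

# Freeman direction -> (drow, dcol) in matrix coordinates
.freeman_drow <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
.freeman_dcol <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)

#' Binarize a grayscale image
#'
#' Foreground (spore) pixels are the bright ones, matching the convention
#' of white spores on black background. The threshold is chosen
#' automatically by Otsu's method or fixed manually.
#'
#' @param gray Numeric matrix; values in \[0, 1\] or \[0, 255\] (rescaled
#'   automatically).
#' @param method "otsu" (automatic) or "fixed".
#' @param threshold Threshold in \[0, 1\] for `method = "fixed"`; pixels
#'   with intensity >= threshold become foreground.
#' @param scale_um_per_px Spatial scale attached to the result.
#' @return A [binary_image()].
#' @export
binarize <- function(gray, method = c("otsu", "fixed"), threshold = NULL,
                     scale_um_per_px = 1) {
  method <- match.arg(method)
  if (!is.matrix(gray) || !is.numeric(gray))
    stop("gray must be a numeric matrix (single-channel image)")
  if (max(gray) > 1) gray <- gray / 255
  rng <- range(gray)
  if (diff(rng) < .Machine$double.eps)
    stop("blank image: all pixels share one intensity, cannot binarize")
  if (method == "otsu") {
    threshold <- EBImage::otsu(EBImage::Image(gray), range = c(0, 1))
  } else {
    if (is.null(threshold)) stop("method = 'fixed' needs a threshold")
    if (threshold <= rng[1L] || threshold > rng[2L])
      stop("fixed threshold separates no pixels")
  }
  binary_image(matrix(as.integer(gray >= threshold), nrow(gray), ncol(gray)),
               scale_um_per_px)
}

#' Morphological cleaning of a binary image
#'
#' An erosion-dilation filter (morphological opening) removes noisy
#' protruding pixels from outlines; a dilation-erosion filter (closing)
#' fills artifact cavities. `"both"` applies opening then closing.
#'
#' @param img A [binary_image()].
#' @param mode One of "erosion_dilation", "dilation_erosion", "both",
#'   "none".
#' @param radius Structuring-element radius in pixels (disc of diameter
#'   2 * radius + 1).
#' @return A cleaned [binary_image()]. If cleaning erases an object
#'   entirely a warning reports how many were lost.
#' @export
morphological_clean <- function(img, mode = c("erosion_dilation",
                                              "dilation_erosion",
                                              "both", "none"),
                                radius = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(img, "binary_image"))
  if (mode == "none") return(img)
  if (radius < 1L) stop("radius must be at least 1")
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  px <- img$pixels
  n_before <- max(label_components(px))
  out <- px
  if (mode %in% c("erosion_dilation", "both"))
    out <- EBImage::opening(out, brush)
  if (mode %in% c("dilation_erosion", "both"))
    out <- EBImage::closing(out, brush)
  out <- matrix(as.integer(out > 0), nrow(px), ncol(px))
  n_after <- max(label_components(out))
  if (n_after < n_before)
    warning(sprintf("morphological cleaning erased %d object(s)",
                    n_before - n_after))
  binary_image(out, img$scale_um_per_px, img$origin_um)
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so
# labels that touch diagonally are merged afterwards with a small
# union-find over the label ids.
label_components <- function(px) {
  lab <- EBImage::bwlabel(px)
  lab <- matrix(as.integer(lab), nrow(px), ncol(px))
  k <- max(lab)
  if (k < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])),  # SE diag
    cbind(as.vector(lab[-1L, -nc]), as.vector(lab[-nr, -1L]))   # NE diag
  )
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                 pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    ri <- find(pairs[r, 1L]); rj <- find(pairs[r, 2L])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_len(k), find, 0L)
  dense <- match(root, sort(unique(root)))
  lab[lab > 0L] <- dense[lab[lab > 0L]]
  lab
}

#' Trace spore boundaries as Freeman chain codes
#'
#' Finds 8-connected foreground components and traces each boundary with
#' Moore neighbor tracing, starting from the topmost-then-leftmost
#' boundary pixel and proceeding counterclockwise in y-up coordinates.
#' Objects touching the image border and objects below `min_area` pixels
#' are skipped with a warning (stand-in for the manual selection of
#' intact, well-placed spores).
#'
#' @param img A [binary_image()].
#' @param min_area Minimum component size in pixels.
#' @return A list of `chain_code` objects: `start` (row, col; 1-based),
#'   `directions` (integers 0-7), `dims`, `scale_um_per_px`.
#' @export
trace_boundary <- function(img, min_area = 5L) {
  stopifnot(inherits(img, "binary_image"))
  px <- img$pixels
  if (sum(px) == 0L) stop("no foreground object in image")
  lab <- label_components(px)
  nr <- nrow(px); nc <- ncol(px)
  chains <- list()
  n_skipped_border <- 0L; n_skipped_small <- 0L
  for (id in seq_len(max(lab))) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < min_area) { n_skipped_small <- n_skipped_small + 1L; next }
    if (any(idx[, 1L] == 1L | idx[, 1L] == nr |
            idx[, 2L] == 1L | idx[, 2L] == nc)) {
      n_skipped_border <- n_skipped_border + 1L; next
    }
    ch <- moore_trace(lab == id, nr, nc)
    if (length(ch$directions) < 4L) { n_skipped_small <- n_skipped_small + 1L; next }
    ch$scale_um_per_px <- img$scale_um_per_px
    chains[[length(chains) + 1L]] <- ch
  }
  if (n_skipped_border > 0L)
    warning(sprintf("%d object(s) touching the image border skipped",
                    n_skipped_border))
  if (n_skipped_small > 0L)
    warning(sprintf("%d object(s) below min_area skipped", n_skipped_small))
  if (length(chains) == 0L && n_skipped_border + n_skipped_small == 0L)
    stop("no traceable object found")
  chains
}

# Moore boundary tracing of one component (logical mask). The neighborhood
# is scanned in increasing Freeman direction (counterclockwise in y-up)
# starting two positions past the backtrack direction, which walks the
# boundary with the object kept to the left in y-up coordinates. Stops on
# Jacob's criterion (start pixel re-entered from the initial direction).
moore_trace <- function(mask, nr, nc) {
  fg <- which(mask, arr.ind = TRUE)
  ord <- order(fg[, 1L], fg[, 2L])
  start <- fg[ord[1L], ]                       # topmost, then leftmost
  dirs <- integer(0L)
  cur <- start
  came <- 6L                                   # pretend we arrived moving down
  first_move <- NA_integer_
  max_iter <- 4L * nrow(fg) + 8L
  for (iter in seq_len(max_iter)) {
    found <- FALSE
    k0 <- (came + 6L) %% 8L
    for (s in 0L:7L) {
      k <- (k0 + s) %% 8L
      r2 <- cur[1L] + .freeman_drow[k + 1L]
      c2 <- cur[2L] + .freeman_dcol[k + 1L]
      if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc && mask[r2, c2]) {
        if (is.na(first_move)) first_move <- k
        else if (cur[1L] == start[1L] && cur[2L] == start[2L] && k == first_move)
          return(new_chain_code(start, dirs, c(nr, nc)))
        dirs <- c(dirs, k)
        cur <- c(r2, c2)
        came <- k
        found <- TRUE
        break
      }
    }
    if (!found) break                          # isolated pixel
  }
  new_chain_code(start, dirs, c(nr, nc))
}

new_chain_code <- function(start, directions, dims) {
  structure(list(start = as.integer(start), directions = as.integer(directions),
                 dims = as.integer(dims), scale_um_per_px = NA_real_),
            class = "chain_code")
}

#' @export
print.chain_code <- function(x, ...) {
  cat(sprintf("Freeman chain code: start (%d, %d), %d moves\n",
              x$start[1L], x$start[2L], length(x$directions)))
  invisible(x)
}

#' Verify that a chain code closes on its start pixel
#'
#' @param chain A `chain_code`.
#' @return `TRUE` or `FALSE`.
#' @export
chain_is_closed <- function(chain) {
  stopifnot(inherits(chain, "chain_code"))
  sum(.freeman_drow[chain$directions + 1L]) == 0L &&
    sum(.freeman_dcol[chain$directions + 1L]) == 0L
}

#' Convert a chain code to a polygon in micrometres
#'
#' Boundary pixel centers are converted to physical coordinates with the
#' image row axis flipped so y increases upward; counterclockwise
#' orientation is enforced.
#'
#' @param chain A `chain_code` (must be closed).
#' @param scale_um_per_px Scale; defaults to the scale recorded in the
#'   chain.
#' @return Two-column polygon matrix.
#' @export
chain_to_polygon <- function(chain, scale_um_per_px = NULL) {
  stopifnot(inherits(chain, "chain_code"))
  if (!chain_is_closed(chain)) stop("open chain code: displacements do not cancel")
  s <- if (is.null(scale_um_per_px)) chain$scale_um_per_px else scale_um_per_px
  if (is.na(s) || s <= 0) stop("no valid scale for chain_to_polygon")
  rows <- cumsum(c(chain$start[1L], .freeman_drow[chain$directions + 1L]))
  cols <- cumsum(c(chain$start[2L], .freeman_dcol[chain$directions + 1L]))
  n <- length(rows)
  rows <- rows[-n]; cols <- cols[-n]           # last point repeats the start
  nr <- chain$dims[1L]
  poly <- cbind(x = (cols - 0.5) * s, y = (nr - rows + 0.5) * s)
  ensure_ccw(poly)
}

#' Standardize outline orientation
#'
#' Rotates a polygon by 0 or 180 degrees about its centroid so the
#' proximal (hilar appendix) end lies in the upper-left quadrant relative
#' to the centroid. In `auto` mode the appendix end is the sharper end:
#' the end of the major axis carrying the higher boundary-curvature
#' extremum (the appendix is a narrow protrusion, hence a curvature
#' spike). `"left"`/`"right"` name the appendix end directly and skip
#' detection.
#'
#' @param poly Two-column polygon matrix.
#' @param appendix_hint "auto", "left" or "right".
#' @param tie_tol Relative difference between the two end-curvature peaks
#'   below which the ends are considered indistinguishable (warning, no
#'   rotation).
#' @return The polygon, possibly rotated by 180 degrees.
#' @export
standardize_orientation <- function(poly, appendix_hint = c("auto", "left", "right"),
                                    tie_tol = 0.15) {
  appendix_hint <- match.arg(appendix_hint)
  poly <- as_polygon_matrix(poly)
  ctr <- polygon_centroid(poly)
  rel <- sweep(poly, 2L, ctr)
  # major axis from the vertex covariance
  ev <- eigen(stats::cov(rel), symmetric = TRUE)$vectors[, 1L]
  if (appendix_hint == "auto") {
    side <- sharper_end(rel, ev, tie_tol)
    if (is.na(side)) {
      warning("appendix end indistinguishable (symmetric outline); no rotation")
      return(poly)
    }
    t_ax <- rel %*% ev
    app_idx <- if (side > 0) which.max(t_ax) else which.min(t_ax)
  } else {
    app_idx <- if (appendix_hint == "left") which.min(rel[, 1L]) else which.max(rel[, 1L])
  }
  app <- rel[app_idx, ]
  rotate <- if (abs(app[1L]) > 1e-9) app[1L] > 0 else app[2L] < 0
  if (rotate) poly <- sweep(-rel, 2L, -ctr)    # 180 deg about the centroid
  poly
}

# Which end of the major axis (unit vector ev) is sharper? Resamples the
# outline uniformly by arc length, optionally smooths coordinates
# (suppresses pixel quantization; unnecessary for noise-free outlines),
# measures discrete turning, and compares the integrated absolute turning
# over the outer 15 percent of the axial extent at each end. Returns +1
# (positive-ev end), -1, or NA on a tie.
sharper_end <- function(rel, ev, tie_tol, m = 256L, window = 2L) {
  rs <- resample_closed(rel, m)
  if (window > 0L) {
    idx <- function(k) ((seq_len(m) - 1L + k) %% m) + 1L
    sm <- rs * 0
    for (k in seq(-window, window)) sm <- sm + rs[idx(k), , drop = FALSE]
    sm <- sm / (2L * window + 1L)
  } else {
    sm <- rs
  }
  nxt <- rbind(sm[-1L, ], sm[1L, ])
  e <- nxt - sm
  ang <- atan2(e[, 2L], e[, 1L])
  turn <- diff(c(ang, ang[1L]))
  turn <- (turn + pi) %% (2 * pi) - pi
  ds <- sqrt(rowSums(e^2))
  kappa <- abs(turn) / pmax(ds, .Machine$double.eps)
  t_ax <- sm %*% ev
  rng <- range(t_ax)
  cut <- 0.15 * diff(rng)
  hi <- t_ax >= rng[2L] - cut
  lo <- t_ax <= rng[1L] + cut
  if (!any(hi) || !any(lo)) return(NA_real_)
  # integrated absolute turning: a protruding appendix adds extra back-and-
  # forth turning beyond the half-turn every end cap carries, and the
  # integral is far more raster-robust than the pointwise curvature peak
  peak_hi <- sum(abs(turn[hi])); peak_lo <- sum(abs(turn[lo]))
  denom <- max(peak_hi, peak_lo)
  if (denom <= 0 || abs(peak_hi - peak_lo) / denom < tie_tol) return(NA_real_)
  if (peak_hi > peak_lo) 1 else -1
}

# Resample a closed polygon to m points equally spaced in arc length.
resample_closed <- function(poly, m) {
  closed <- rbind(poly, poly[1L, , drop = FALSE])
  d <- sqrt(rowSums(diff(closed)^2))
  keep <- d > 0
  closed <- closed[c(TRUE, keep), , drop = FALSE]
  d <- d[keep]
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  tt <- seq(0, total, length.out = m + 1L)[-(m + 1L)]
  cbind(stats::approx(s, closed[, 1L], xout = tt)$y,
        stats::approx(s, closed[, 2L], xout = tt)$y)
}

#' Extract standardized outlines from a binary image
#'
#' Convenience chain: morphological cleaning, boundary tracing,
#' chain-to-polygon conversion and orientation standardization.
#'
#' @param img A [binary_image()].
#' @param clean_mode,radius Passed to [morphological_clean()].
#' @param min_area Passed to [trace_boundary()].
#' @param appendix_hint Passed to [standardize_orientation()].
#' @return List of polygons (possibly empty if all objects were skipped).
#' @export
extract_outlines <- function(img, clean_mode = "erosion_dilation", radius = 1L,
                             min_area = 20L, appendix_hint = "auto") {
  img <- morphological_clean(img, clean_mode, radius)
  chains <- trace_boundary(img, min_area = min_area)
  lapply(chains, function(ch)
    standardize_orientation(chain_to_polygon(ch), appendix_hint))
}
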