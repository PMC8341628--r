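# Linear measurements and trait bookkeeping. The observation unit of all
# comparative statistics is the image: spore-level traits are averaged per
# image before correlations or discriminant analysis, because shape and
# size records extracted by different tools can only be aligned at the
# image level.

#' Measure spore length and width from an outline
#'
#' Length is the maximum Feret diameter (largest pairwise distance between
#' outline points, the mycological "longest dimension"); width is the
#' maximal caliper extent measured perpendicular to the length axis (the
#' "broadest dimension" across the long axis).
#'
#' @param poly Two-column polygon matrix (micrometres).
#' @return Named numeric vector `c(length_um, width_um)`.
#' @export
measure_length_width <- function(poly) {
  poly <- as_polygon_matrix(poly)
  hull_idx <- grDevices::chull(poly)
  h <- poly[hull_idx, , drop = FALSE]
  if (nrow(h) < 2L) stop("degenerate polygon: no extent")
  d2 <- outer(h[, 1L], h[, 1L], "-")^2 + outer(h[, 2L], h[, 2L], "-")^2
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1L, ]
  len <- sqrt(d2[ij[1L], ij[2L]])
  if (len <= 0) stop("degenerate polygon: all points coincide")
  axis <- (h[ij[2L], ] - h[ij[1L], ]) / len
  perp <- c(-axis[2L], axis[1L])
  proj <- poly %*% perp
  wid <- max(proj) - min(proj)
  # length is the longer dimension by definition
  if (wid > len) { tmp <- len; len <- wid; wid <- tmp }
  c(length_um = len, width_um = wid)
}

#' Derived size traits
#'
#' The classical length-to-width ratio Q (the traditional scalar shape
#' proxy) and the integrated size sqrt(length * width), a size measure
#' less entangled with shape than either linear measurement.
#'
#' @param length_um,width_um Positive reals with length >= width.
#' @return Named vector `c(q_ratio, size_int)`.
#' @export
derived_size_traits <- function(length_um, width_um) {
  if (any(length_um <= 0) || any(width_um <= 0))
    stop("length and width must be positive")
  if (any(length_um < width_um))
    stop("length must be at least the width")
  c(q_ratio = unname(length_um / width_um),
    size_int = unname(sqrt(length_um * width_um)))
}

#' Build the spore-level trait table
#'
#' Combines metadata, linear measurements from polygons, derived size
#' traits, and PC scores from the three shape spaces into one row per
#' spore.
#'
#' @param meta Data frame with columns `spore_id`, `image_id`,
#'   `specimen_id`, `species_id` (one row per spore).
#' @param polygons Named list of polygons (names = spore_id).
#' @param pca_scores Named list of score matrices keyed by variant (e.g.
#'   `list(symmetric = ..., asymmetric = ..., global = ...)`), rows named
#'   by spore_id; each contributes its effective components as
#'   `<variant>_PC<k>` columns. May be NULL.
#' @param effective Named list of effective component indices per variant;
#'   defaults to all columns present in each score matrix.
#' @return Data frame, one row per spore.
#' @export
spore_records <- function(meta, polygons, pca_scores = NULL, effective = NULL) {
  need <- c("spore_id", "image_id", "specimen_id", "species_id")
  if (!all(need %in% names(meta))) stop("meta lacks id columns")
  lw <- t(vapply(meta$spore_id, function(id) {
    if (is.null(polygons[[id]])) stop("no polygon for spore ", id)
    measure_length_width(polygons[[id]])
  }, numeric(2L)))
  out <- data.frame(meta[need], lw, row.names = NULL)
  out$q_ratio <- out$length_um / out$width_um
  out$size_int <- sqrt(out$length_um * out$width_um)
  for (variant in names(pca_scores)) {
    sc <- pca_scores[[variant]]
    keep <- if (is.null(effective[[variant]])) seq_len(ncol(sc)) else effective[[variant]]
    sc <- sc[match(out$spore_id, rownames(sc)), keep, drop = FALSE]
    colnames(sc) <- sprintf("%s_PC%d", variant, keep)
    out <- cbind(out, sc)
  }
  rownames(out) <- NULL
  out
}

#' Aggregate spore records to average-per-image trait values
#'
#' Arithmetic mean of every numeric trait over the spores of each image.
#' Specimen and species labels must be constant within an image.
#'
#' @param records Data frame from [spore_records()].
#' @return Data frame with one row per image (`image_id`, `specimen_id`,
#'   `species_id`, `n_spores`, mean trait columns).
#' @export
aggregate_per_image <- function(records) {
  need <- c("spore_id", "image_id", "specimen_id", "species_id")
  if (!all(need %in% names(records))) stop("records lack id columns")
  traits <- setdiff(names(records), need)
  if (!all(vapply(records[traits], is.numeric, TRUE)))
    stop("non-numeric trait column present")
  if (anyNA(records[traits])) stop("missing trait values")
  by_img <- split(records, records$image_id)
  rows <- lapply(by_img, function(g) {
    if (length(unique(g$specimen_id)) != 1L || length(unique(g$species_id)) != 1L)
      stop("conflicting specimen/species labels within image ", g$image_id[1L])
    cbind(data.frame(image_id = g$image_id[1L], specimen_id = g$specimen_id[1L],
                     species_id = g$species_id[1L], n_spores = nrow(g),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(colMeans(g[traits]))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$image_id), , drop = FALSE]
}

#' Spearman correlation matrix of morphometric traits
#'
#' Pairwise Spearman rank correlations (average ranks on ties) over the
#' average-per-image observations, with two-sided p-values from the
#' t-approximation and a significance mask at `alpha`. P-values are
#' unadjusted by default; `adjust = "holm"` applies a Holm correction
#' across the strictly-lower-triangle tests.
#'
#' @param table Data frame of observations (e.g. from
#'   [aggregate_per_image()]).
#' @param traits Character vector of trait column names (default: all
#'   numeric columns except `n_spores`).
#' @param alpha Significance level (default 0.05).
#' @param adjust "none" or "holm".
#' @return List with matrices `rho`, `p`, `significant`, and `alpha`;
#'   class `trait_correlations`. Constant traits give NA entries with a
#'   warning.
#' @export
spearman_matrix <- function(table, traits = NULL, alpha = 0.05,
                            adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (is.null(traits))
    traits <- setdiff(names(table)[vapply(table, is.numeric, TRUE)], "n_spores")
  if (!all(traits %in% names(table))) stop("unknown trait column requested")
  x <- as.matrix(table[traits])
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 observations")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  const <- apply(x, 2L, function(col) stats::sd(col) == 0)
  if (any(const))
    warning("constant trait column(s): ", paste(traits[const], collapse = ", "),
            "; correlations reported as NA")
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  rho[const, ] <- NA_real_; rho[, const] <- NA_real_
  diag(rho)[!const] <- 1
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p)[!const] <- 0
  if (adjust == "holm") {
    lower <- lower.tri(p)
    p[lower] <- stats::p.adjust(p[lower], method = "holm")
    p[upper.tri(p)] <- t(p)[upper.tri(p)]
  }
  structure(list(rho = rho, p = p, significant = !is.na(p) & p < alpha,
                 alpha = alpha, n = n, adjust = adjust),
            class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, digits = 2, ...) {
  cat(sprintf("Spearman correlations over %d observations (alpha = %g, %s)\n",
              x$n, x$alpha, x$adjust))
  print(round(x$rho, digits))
  invisible(x)
}

#' @export
plot.trait_correlations <- function(x, ...) {
  k <- ncol(x$rho)
  rho <- x$rho
  rho[!x$significant] <- NA                  # only significant cells colored
  graphics::image(seq_len(k), seq_len(k), t(rho[k:1, , drop = FALSE]),
                  zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(21, "Blue-Red 3", rev = TRUE), ...)
  graphics::axis(1, seq_len(k), colnames(rho), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(k), rev(rownames(rho)), las = 2, cex.axis = 0.7)
  graphics::box()
  invisible(x)
}
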