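# Principal-component shape spaces over normalized elliptic Fourier
# coefficient vectors. Covariance PCA (no standardization): after
# first-harmonic normalization the coefficients share one dimensionless
# scale, and standardizing would inflate the high-harmonic noise terms.

#' Fit a principal-component shape space
#'
#' Covariance-matrix PCA of spore-level coefficient vectors of one variant
#' (symmetric, asymmetric or global block of the normalized descriptors).
#' Eigenvector signs are fixed so each component's largest-magnitude
#' loading is positive, making scores reproducible across platforms.
#'
#' @param vectors Numeric matrix, spores x coefficients (from
#'   [nefd_matrix()]), or a named list of `spore_nefd` objects.
#' @param variant "symmetric", "asymmetric" or "global"; used to build the
#'   matrix when `vectors` is a list, and recorded in the result.
#' @return Object of class `shape_pca`: `variant`, `center` (mean vector),
#'   `eigenvalues` (descending), `loadings` (coefficients x components),
#'   `scores` (spores x components), `proportion` of variance,
#'   `effective_idx` (see [effective_components()], default criterion).
#' @export
fit_shape_pca <- function(vectors, variant = c("global", "symmetric", "asymmetric")) {
  variant <- match.arg(variant)
  if (is.list(vectors) && !is.data.frame(vectors) && !is.matrix(vectors))
    vectors <- nefd_matrix(vectors, variant)
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2L) stop("need at least 2 spores for a PCA")
  if (ncol(vectors) < 1L) stop("need at least 1 coefficient column")
  pc <- stats::prcomp(vectors, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  load <- pc$rotation
  scores <- pc$x
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(load))) {
    s <- sign(load[which.max(abs(load[, j])), j])
    if (s < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  colnames(load) <- colnames(scores) <- paste0("PC", seq_len(ncol(load)))
  res <- structure(list(
    variant = variant,
    center = pc$center,
    eigenvalues = ev,
    loadings = load,
    scores = scores,
    proportion = ev / sum(ev),
    n_spores = nrow(vectors)
  ), class = "shape_pca")
  res$effective_idx <- effective_components(res)
  res
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("shape PCA (%s variant): %d spores, %d coefficients\n",
              x$variant, x$n_spores, nrow(x$loadings)))
  k <- min(5L, length(x$eigenvalues))
  cat("  variance proportions:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$proportion[seq_len(k)]),
            collapse = ", "), "\n")
  cat("  effective components:", paste(x$effective_idx, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.shape_pca <- function(object, ...) {
  data.frame(component = seq_along(object$eigenvalues),
             eigenvalue = object$eigenvalues,
             proportion = object$proportion,
             cumulative = cumsum(object$proportion),
             effective = seq_along(object$eigenvalues) %in% object$effective_idx)
}

#' Select the effective principal components
#'
#' A component is "effective" when its eigenvalue exceeds an
#' eigenvalue-magnitude threshold. The default `gt_mean` retains
#' eigenvalues strictly greater than the mean eigenvalue — the
#' covariance-PCA analogue of the Kaiser rule, since raw covariance
#' eigenvalues of normalized Fourier coefficients are far below 1.
#' `kaiser_scaled` is the literal rule applied to eigenvalues divided by
#' their mean (identical selection to `gt_mean`; kept as the explicitly
#' scaled reading). `proportion` retains components explaining at least
#' `p` of total variance. At least PC1 is always returned.
#'
#' @param res A `shape_pca`.
#' @param criterion "gt_mean", "kaiser_scaled", or "proportion".
#' @param p Variance-share threshold for `criterion = "proportion"`.
#' @return Integer vector of component indices.
#' @export
effective_components <- function(res, criterion = c("gt_mean", "kaiser_scaled",
                                                    "proportion"), p = 0.05) {
  criterion <- match.arg(criterion)
  ev <- res$eigenvalues
  idx <- switch(criterion,
    gt_mean = which(ev > mean(ev)),
    kaiser_scaled = which(ev / mean(ev) > 1),
    proportion = which(res$proportion >= p))
  if (length(idx) == 0L) idx <- 1L
  sort(idx)
}

#' Project new coefficient vectors into a fitted shape space
#'
#' @param object A `shape_pca`.
#' @param newdata Matrix of coefficient vectors (same columns as the fit).
#' @param ... Unused.
#' @return Score matrix.
#' @export
predict.shape_pca <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$center))
    stop("newdata has the wrong number of coefficient columns")
  sweep(newdata, 2L, object$center) %*% object$loadings
}

#' Shape range along a principal component
#'
#' Reconstructs the mean outline and the outlines at the mean plus and
#' minus `k_sd` standard deviations along one component, the standard
#' visualization of what a shape PC encodes.
#'
#' @param res A `shape_pca`.
#' @param mean_nefd A `spore_nefd` whose coefficients carry the
#'   out-of-variant entries (typically the element-wise mean descriptor
#'   set, see [mean_nefd()]).
#' @param pc Component index.
#' @param k_sd Number of SDs (default 2).
#' @param n_points Points per reconstructed outline.
#' @return List with polygons `minus`, `mean`, `plus` and the inputs
#'   recorded; class `pc_shape_range`.
#' @export
pc_shape_range <- function(res, mean_nefd, pc = 1L, k_sd = 2, n_points = 200L) {
  stopifnot(inherits(res, "shape_pca"))
  if (pc < 1L || pc > ncol(res$loadings)) stop("pc out of range")
  base <- res$center
  dev <- k_sd * sqrt(res$eigenvalues[pc]) * res$loadings[, pc]
  names(dev) <- rownames(res$loadings)
  mk <- function(v) {
    names(v) <- rownames(res$loadings)
    reconstruct_outline(vector_to_nefd(v, mean_nefd), n_points = n_points)
  }
  structure(list(minus = mk(base - dev), mean = mk(base), plus = mk(base + dev),
                 variant = res$variant, pc = pc, k_sd = k_sd),
            class = "pc_shape_range")
}

#' @export
plot.pc_shape_range <- function(x, ...) {
  all_pts <- rbind(x$minus, x$mean, x$plus)
  graphics::plot(NA, xlim = range(all_pts[, 1L]), ylim = range(all_pts[, 2L]),
                 asp = 1, xlab = "", ylab = "",
                 main = sprintf("%s PC%d: mean ± %g SD", x$variant, x$pc, x$k_sd), ...)
  closed <- function(p) rbind(p, p[1L, , drop = FALSE])
  graphics::lines(closed(x$minus), col = "steelblue", lty = 2)
  graphics::lines(closed(x$mean), col = "black", lwd = 2)
  graphics::lines(closed(x$plus), col = "firebrick", lty = 2)
  invisible(x)
}

#' Element-wise mean of normalized descriptor sets
#'
#' @param nefds List of `spore_nefd` objects with equal harmonic counts.
#' @return A `spore_nefd` holding the coefficient-wise mean (constants are
#'   exact by construction) and the mean size scalar.
#' @export
mean_nefd <- function(nefds) {
  stopifnot(length(nefds) >= 1L)
  H <- unique(vapply(nefds, function(n) n$n_harmonics, 0L))
  if (length(H) != 1L) stop("descriptor sets have differing harmonic counts")
  cf <- Reduce(`+`, lapply(nefds, function(n) n$coeffs)) / length(nefds)
  out <- nefds[[1L]]
  out$coeffs <- cf
  out$size_scalar <- mean(vapply(nefds, function(n) n$size_scalar, 0))
  out
}
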