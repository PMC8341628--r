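# Elliptic Fourier analysis of closed outlines.
#
# An outline (x(t), y(t)), parameterized by arc length t over one period T,
# is expanded as a truncated Fourier series per coordinate; each harmonic n
# contributes a quadruple (a_n, b_n, c_n, d_n). For a polygon the
# coordinate functions are piecewise linear in t, so the Fourier integrals
# have closed forms (chord-length formulas) — no quadrature is involved.

#' Elliptic Fourier descriptors of a closed polygon
#'
#' Computes the closed-form elliptic Fourier coefficients of the polygonal
#' outline under arc-length parameterization. Harmonic n is the quadruple
#' \eqn{(a_n, b_n, c_n, d_n)} with
#' \deqn{x(t) = A_0 + \sum_n a_n \cos(2\pi n t/T) + b_n \sin(2\pi n t/T)}
#' and likewise \eqn{y(t)} with \eqn{c_n, d_n}.
#'
#' @param poly Two-column matrix of outline vertices (micrometres; closure
#'   implied, counterclockwise preferred).
#' @param n_harmonics Number of harmonics to keep (default 20).
#' @return An object of class `spore_efd`: list with `n_harmonics`,
#'   centroid terms `A0`, `C0`, and `coeffs`, an `n_harmonics x 4` matrix
#'   with columns `a`, `b`, `c`, `d`.
#' @export
compute_efd <- function(poly, n_harmonics = 20L) {
  poly <- as_polygon_matrix(poly)
  if (n_harmonics < 1L) stop("n_harmonics must be at least 1")
  closed <- rbind(poly, poly[1L, , drop = FALSE])
  d <- diff(closed)
  dt <- sqrt(rowSums(d^2))
  keep <- dt > 0                      # repeated vertices contribute nothing
  d <- d[keep, , drop = FALSE]; dt <- dt[keep]
  if (length(dt) < 3L || sum(dt) <= 0) stop("zero-perimeter polygon")
  pts <- closed[c(keep, FALSE), , drop = FALSE]   # segment start points
  t1 <- cumsum(dt)                     # segment end times
  t0 <- c(0, t1[-length(t1)])          # segment start times
  T <- t1[length(t1)]
  n <- seq_len(n_harmonics)
  w <- 2 * pi / T
  ang1 <- outer(t1, n) * w             # segments x harmonics
  ang0 <- outer(t0, n) * w
  dcos <- cos(ang1) - cos(ang0)
  dsin <- sin(ang1) - sin(ang0)
  fac <- T / (2 * pi^2 * n^2)
  vx <- d[, 1L] / dt; vy <- d[, 2L] / dt
  coeffs <- cbind(
    a = fac * colSums(vx * dcos),
    b = fac * colSums(vx * dsin),
    c = fac * colSums(vy * dcos),
    d = fac * colSums(vy * dsin)
  )
  # DC terms: exact integral of the piecewise-linear coordinates
  A0 <- sum(pts[, 1L] * dt + d[, 1L] * dt / 2) / T
  C0 <- sum(pts[, 2L] * dt + d[, 2L] * dt / 2) / T
  structure(list(n_harmonics = as.integer(n_harmonics),
                 A0 = A0, C0 = C0, coeffs = coeffs),
            class = "spore_efd")
}

#' @export
print.spore_efd <- function(x, ...) {
  cat(sprintf("elliptic Fourier descriptors: %d harmonics, centroid (%.3g, %.3g)\n",
              x$n_harmonics, x$A0, x$C0))
  invisible(x)
}

# Rotate the start point by phase theta: harmonic n picks up rotation n*theta
# acting on the (cos, sin) columns.
rotate_start_point <- function(coeffs, theta) {
  n <- seq_len(nrow(coeffs))
  cn <- cos(n * theta); sn <- sin(n * theta)
  cbind(a = coeffs[, "a"] * cn + coeffs[, "b"] * sn,
        b = -coeffs[, "a"] * sn + coeffs[, "b"] * cn,
        c = coeffs[, "c"] * cn + coeffs[, "d"] * sn,
        d = -coeffs[, "c"] * sn + coeffs[, "d"] * cn)
}

# Rotate the plane by -psi (align direction psi with +x): premultiply each
# harmonic's 2x2 coefficient block by R(psi).
rotate_plane <- function(coeffs, psi) {
  cp <- cos(psi); sp <- sin(psi)
  cbind(a = cp * coeffs[, "a"] + sp * coeffs[, "c"],
        b = cp * coeffs[, "b"] + sp * coeffs[, "d"],
        c = -sp * coeffs[, "a"] + cp * coeffs[, "c"],
        d = -sp * coeffs[, "b"] + cp * coeffs[, "d"])
}

# 180-degree shape rotation that preserves a1 = 1: rotate the plane by pi
# and shift the start point by half a period; harmonic n is multiplied by
# (-1)^(n+1), so odd harmonics (including the first) are untouched.
flip_180 <- function(coeffs) {
  n <- seq_len(nrow(coeffs))
  coeffs * (-1)^(n + 1)
}

#' Normalize elliptic Fourier descriptors
#'
#' Removes translation (drops the centroid terms), the arbitrary start
#' point of outline recording, rotation, and size, using the ellipse of the
#' first harmonic: the start point is rotated onto the semi-major axis, the
#' plane is rotated so that axis lies along +x, and all coefficients are
#' divided by the semi-major axis length. The result satisfies
#' \eqn{a_1 = 1, b_1 = 0, c_1 = 0}; the removed size is retained as
#' `size_scalar`. The residual 180-degree ambiguity is resolved so that
#' the proximal (hilar-appendix) end of the outline, identified via the
#' upstream orientation standard (upper-left of the centroid), maps to
#' negative x; a mirror-symmetric outline with no distinguishable ends is
#' left as the rotations produce it.
#'
#' @param efd A `spore_efd` from [compute_efd()].
#' @param poly The source polygon (optional). When supplied, the
#'   appendix (sharper) end is detected on the full-resolution outline,
#'   which is far more sensitive than detection on the truncated Fourier
#'   reconstruction; the detection is intrinsic to the shape, so the
#'   result stays pose-invariant.
#' @param flip_smooth Smoothing half-window (in resampled outline points)
#'   applied before measuring boundary turning for the flip decision: 0
#'   for outlines rendered or traced without pixel noise, 2 or more for
#'   raster-derived outlines.
#' @return An object of class `spore_nefd`: list with `n_harmonics`,
#'   normalized `coeffs` (first row (1, 0, 0, d1)), `size_scalar`
#'   (semi-major axis, micrometres), and the applied `theta`, `psi`,
#'   `flipped`.
#' @export
normalize_efd <- function(efd, poly = NULL, flip_smooth = 0L) {
  stopifnot(inherits(efd, "spore_efd"))
  cf <- efd$coeffs
  a1 <- cf[1L, "a"]; b1 <- cf[1L, "b"]; c1 <- cf[1L, "c"]; d1 <- cf[1L, "d"]
  if (sum(abs(c(a1, b1, c1, d1))) < .Machine$double.eps^0.5)
    stop("degenerate first harmonic: cannot normalize")
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 + c1^2 - b1^2 - d1^2)
  cf1 <- rotate_start_point(cf, theta)
  maj <- unname(sqrt(cf1[1L, "a"]^2 + cf1[1L, "c"]^2))
  min_ <- unname(sqrt(cf1[1L, "b"]^2 + cf1[1L, "d"]^2))
  if (min_ > maj) {                   # theta aligned with the minor axis
    theta <- theta + pi / 2
    cf1 <- rotate_start_point(cf, theta)
    tmp <- maj; maj <- min_; min_ <- tmp
  }
  if (maj <= 0) stop("degenerate first harmonic: zero semi-major axis")
  if (min_ / maj > 0.999 && efd$n_harmonics >= 2L) {
    # near-circular first harmonic: its axis direction is numerically
    # meaningless, take the spatial rotation from the second harmonic
    psi <- atan2(cf1[2L, "c"], cf1[2L, "a"])
    warning("near-circular first harmonic; rotation taken from harmonic 2")
  } else {
    psi <- atan2(cf1[1L, "c"], cf1[1L, "a"])
  }
  cf2 <- rotate_plane(cf1, psi) / maj
  nefd <- structure(list(n_harmonics = efd$n_harmonics, coeffs = cf2,
                         size_scalar = maj, theta = theta, psi = psi,
                         flipped = FALSE),
                    class = "spore_nefd")
  # resolve the residual 180-degree ambiguity so the proximal (appendix)
  # end sits at negative x; the rule is intrinsic to the shape, keeping
  # the descriptors invariant to the input pose
  if (proximal_end_at_positive_x(nefd, efd, poly, flip_smooth)) {
    nefd$coeffs <- flip_180(nefd$coeffs)
    nefd$flipped <- TRUE
  }
  nefd
}

# The proximal end is the sharper end: the appendix is a protrusion, so
# its end carries extra integrated boundary turning. Detection runs on
# the full-resolution source polygon when available (mapped into the
# normalized frame through the spatial rotation psi), else on the
# truncated reconstruction. On a sharpness tie the flip is fixed by the
# sign convention d2 >= 0 (a 180-degree flip negates exactly the even
# harmonics; genuinely end-symmetric outlines have vanishing even
# harmonics and the choice is immaterial).
proximal_end_at_positive_x <- function(nefd, efd, poly = NULL,
                                       flip_smooth = 0L) {
  if (!is.null(poly)) {
    poly <- as_polygon_matrix(poly)
    rel <- cbind(poly[, 1L] - efd$A0, poly[, 2L] - efd$C0)
    u <- c(cos(nefd$psi), sin(nefd$psi))   # maps to +x after rotation
    side <- sharper_end(rel, u, tie_tol = 0.05, m = 512L,
                        window = flip_smooth)
  } else {
    rec <- reconstruct_outline(nefd, n_points = 256L)
    side <- sharper_end(rec, c(1, 0), tie_tol = 0.05, m = 512L,
                        window = flip_smooth)
  }
  if (!is.na(side)) return(side > 0)
  d2 <- if (nefd$n_harmonics >= 2L) nefd$coeffs[2L, "d"] else 0
  if (abs(d2) > 1e-9) return(d2 < 0)
  FALSE
}

#' @export
print.spore_nefd <- function(x, ...) {
  cat(sprintf(
    "normalized EFDs: %d harmonics (%d coefficients, %d free), size %.4g um\n",
    x$n_harmonics, 4L * x$n_harmonics, 4L * x$n_harmonics - 3L,
    x$size_scalar))
  invisible(x)
}

#' Reconstruct an outline from (normalized) elliptic Fourier descriptors
#'
#' Evaluates the truncated Fourier series at equally spaced parameter
#' values. For normalized descriptors the outline is dimensionless (unit
#' semi-major axis) unless `rescale = TRUE`, which multiplies by the
#' retained `size_scalar`.
#'
#' @param d A `spore_efd` or `spore_nefd`.
#' @param n_points Number of points to evaluate (>= 16).
#' @param n_harmonics Optionally truncate to fewer harmonics.
#' @param rescale For `spore_nefd`, restore the removed size.
#' @return Two-column polygon matrix.
#' @export
reconstruct_outline <- function(d, n_points = 200L, n_harmonics = NULL,
                                rescale = FALSE) {
  stopifnot(inherits(d, "spore_efd") || inherits(d, "spore_nefd"))
  if (n_points < 16L) stop("n_points must be at least 16")
  H <- if (is.null(n_harmonics)) d$n_harmonics else min(n_harmonics, d$n_harmonics)
  cf <- d$coeffs[seq_len(H), , drop = FALSE]
  tt <- seq(0, 1, length.out = n_points + 1L)[-(n_points + 1L)]
  ang <- outer(2 * pi * tt, seq_len(H))
  ct <- cos(ang); st <- sin(ang)
  x <- ct %*% cf[, "a"] + st %*% cf[, "b"]
  y <- ct %*% cf[, "c"] + st %*% cf[, "d"]
  if (inherits(d, "spore_efd")) {
    x <- x + d$A0; y <- y + d$C0
  } else if (rescale) {
    x <- x * d$size_scalar; y <- y * d$size_scalar
  }
  cbind(x = as.numeric(x), y = as.numeric(y))
}

assert_normalized <- function(nefd, tol = 1e-9) {
  if (!inherits(nefd, "spore_nefd"))
    stop("input must be a normalized descriptor set (spore_nefd)")
  cf <- nefd$coeffs
  if (abs(cf[1L, "a"] - 1) > tol || abs(cf[1L, "b"]) > tol ||
      abs(cf[1L, "c"]) > tol)
    stop("descriptors are not normalized: (a1, b1, c1) != (1, 0, 0)")
  invisible(nefd)
}

#' Flatten normalized descriptors to a feature vector
#'
#' Coefficients are laid out per harmonic in the quadruple order
#' (a_n, b_n, c_n, d_n), harmonics ascending, with the three constants
#' fixed by normalization (a1 = 1, b1 = 0, c1 = 0) dropped. With 20
#' harmonics the global vector has 77 entries; the symmetric block
#' \{a_n, d_n\} has 39 and the asymmetric block \{b_n, c_n\} has 38.
#' Shapes mirror-symmetric about the normalized major axis carry no
#' asymmetric signal (b_n = c_n = 0).
#'
#' @param nefd A `spore_nefd`.
#' @param variant One of "global", "symmetric", "asymmetric".
#' @return Named numeric vector (names like `"a2"`, `"d1"`), in a fixed
#'   package-wide order.
#' @export
nefd_to_vector <- function(nefd, variant = c("global", "symmetric", "asymmetric")) {
  variant <- match.arg(variant)
  assert_normalized(nefd)
  cf <- nefd$coeffs
  H <- nefd$n_harmonics
  out <- numeric(0L)
  for (n in seq_len(H)) {
    quad <- cf[n, c("a", "b", "c", "d")]
    keep <- switch(variant,
      global = if (n == 1L) "d" else c("a", "b", "c", "d"),
      symmetric = if (n == 1L) "d" else c("a", "d"),
      asymmetric = if (n == 1L) character(0L) else c("b", "c"))
    if (length(keep)) {
      v <- quad[keep]
      names(v) <- paste0(keep, n)
      out <- c(out, v)
    }
  }
  out
}

#' Split normalized descriptors into symmetric and asymmetric blocks
#'
#' @param nefd A `spore_nefd`.
#' @return List with `symmetric` and `asymmetric` named vectors (see
#'   [nefd_to_vector()]).
#' @export
split_sym_asym <- function(nefd) {
  list(symmetric = nefd_to_vector(nefd, "symmetric"),
       asymmetric = nefd_to_vector(nefd, "asymmetric"))
}

#' Feature matrix from a list of normalized descriptor sets
#'
#' @param nefds Named list of `spore_nefd` objects (names become row names).
#' @param variant Passed to [nefd_to_vector()].
#' @return Numeric matrix, one row per spore.
#' @export
nefd_matrix <- function(nefds, variant = "global") {
  stopifnot(length(nefds) >= 1L)
  rows <- lapply(nefds, nefd_to_vector, variant = variant)
  lens <- vapply(rows, length, 0L)
  if (length(unique(lens)) != 1L)
    stop("descriptor sets have differing harmonic counts")
  out <- do.call(rbind, rows)
  rownames(out) <- names(nefds)
  out
}

# Re-embed a (possibly perturbed) feature vector into a full NEFD, taking
# unlisted coefficients from `template` and restoring the normalization
# constants. Used for mean +/- k SD shape reconstruction.
vector_to_nefd <- function(vec, template) {
  stopifnot(inherits(template, "spore_nefd"))
  cf <- template$coeffs
  for (nm in names(vec)) {
    col <- substr(nm, 1L, 1L)
    n <- as.integer(substring(nm, 2L))
    if (!col %in% c("a", "b", "c", "d") || is.na(n) || n < 1L || n > nrow(cf))
      stop("unrecognized coefficient name: ", nm)
    cf[n, col] <- vec[[nm]]
  }
  cf[1L, "a"] <- 1; cf[1L, "b"] <- 0; cf[1L, "c"] <- 0
  out <- template
  out$coeffs <- cf
  out
}
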