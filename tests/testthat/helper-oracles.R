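# Independent oracles and fixture builders shared across the suite.

# Brute-force elliptic Fourier coefficients by composite Simpson
# integration of the Fourier integrals over the polygon's piecewise-linear
# arc-length parameterization. Independent of the closed-form route used
# by compute_efd().
brute_force_efd <- function(poly, n_harmonics, n_sub = 64L) {
  closed <- rbind(poly, poly[1L, , drop = FALSE])
  d <- diff(closed)
  dt <- sqrt(rowSums(d^2))
  keep <- dt > 0
  d <- d[keep, , drop = FALSE]
  dt <- dt[keep]
  pts <- closed[c(keep, FALSE), , drop = FALSE]
  t0 <- c(0, cumsum(dt)[-length(dt)])
  T <- sum(dt)
  coeffs <- matrix(0, n_harmonics, 4L, dimnames = list(NULL, c("a", "b", "c", "d")))
  A0 <- 0; C0 <- 0
  for (i in seq_along(dt)) {
    # Simpson nodes on segment i (x, y linear in t)
    u <- seq(0, 1, length.out = 2L * n_sub + 1L)
    tt <- t0[i] + u * dt[i]
    x <- pts[i, 1L] + u * d[i, 1L]
    y <- pts[i, 2L] + u * d[i, 2L]
    wts <- c(1, rep(c(4, 2), n_sub - 1L), 4, 1) * (dt[i] / (2L * n_sub)) / 3
    A0 <- A0 + sum(wts * x)
    C0 <- C0 + sum(wts * y)
    for (n in seq_len(n_harmonics)) {
      cn <- cos(2 * pi * n * tt / T); sn <- sin(2 * pi * n * tt / T)
      coeffs[n, "a"] <- coeffs[n, "a"] + sum(wts * x * cn)
      coeffs[n, "b"] <- coeffs[n, "b"] + sum(wts * x * sn)
      coeffs[n, "c"] <- coeffs[n, "c"] + sum(wts * y * cn)
      coeffs[n, "d"] <- coeffs[n, "d"] + sum(wts * y * sn)
    }
  }
  list(A0 = A0 / T, C0 = C0 / T, coeffs = coeffs * 2 / T)
}

# Random smooth star-shaped polygon around the origin (always simple).
random_star_polygon <- function(n_vertices = 60L, n_modes = 5L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- rep(1, n_vertices)
  for (k in seq_len(n_modes))
    r <- r + stats::runif(1, 0, 0.25 / k) * cos(k * th + stats::runif(1, 0, 2 * pi))
  scale <- stats::runif(1, 0.5, 10)
  cbind(scale * r * cos(th), scale * 0.6 * r * sin(th))
}

rot2 <- function(theta)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)

# A spore trait table with a clean hierarchical signal, for the
# discriminant-analysis tests that do not need the image pipeline.
gaussian_trait_table <- function(n_species = 10L, n_per_species = 20L,
                                 p = 4L, effect = 0, seed = 1L) {
  set.seed(seed)
  species <- rep(sprintf("sp%02d", seq_len(n_species)), each = n_per_species)
  centers <- matrix(stats::rnorm(n_species * p, 0, effect), n_species, p)
  x <- centers[rep(seq_len(n_species), each = n_per_species), , drop = FALSE] +
    matrix(stats::rnorm(length(species) * p), ncol = p)
  colnames(x) <- paste0("t", seq_len(p))
  data.frame(species_id = species, x, stringsAsFactors = FALSE)
}

# Small synthetic panel -> spore-level NEFDs + truth, bypassing rasters.
panel_nefds <- function(ranges, n_species = 8L, n_specimens = 2L,
                        spores = 10L, seed = 1L, n_harmonics = 20L) {
  panel <- sample_species_panel(n_species, n_specimens, ranges, seed = seed)
  ds <- generate_dataset(panel, spores_per_specimen = spores, seed = seed,
                         rasterize = FALSE)
  nefds <- lapply(ds$polygons, function(p)
    normalize_efd(compute_efd(p, n_harmonics), poly = p))
  list(nefds = nefds, truth = ds$truth, dataset = ds)
}

# Ranges where every parameter is pinned except those listed in `vary`
# (given as list(name = c(lo, hi))); SDs zero except spore-level noise on
# the varying parameters.
pinned_ranges <- function(vary, spore_noise = NULL) {
  r <- default_panel_ranges()
  pin <- list(length_um = 12, width_um = 3, bow_kappa1 = 0, end_kappa2 = 0,
              taper_p = 0.7, apiculus_h = 0.3, apiculus_sigma = 0.04)
  for (nm in names(pin)) r$mean_range[[nm]] <- rep(pin[[nm]], 2L)
  for (nm in names(vary)) r$mean_range[[nm]] <- vary[[nm]]
  r$specimen_sd[] <- 0
  r$spore_sd[] <- 0
  for (nm in names(spore_noise)) r$spore_sd[[nm]] <- spore_noise[[nm]]
  r
}
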