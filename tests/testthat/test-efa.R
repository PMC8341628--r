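test_that("first harmonic of a circle is the circle", {
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  circ <- cbind(3 * cos(th), 3 * sin(th))
  e <- compute_efd(circ, 3)
  expect_equal(unname(e$coeffs[1, ]), c(3, 0, 0, 3), tolerance = 1e-3)
  expect_equal(e$A0, 0, tolerance = 1e-6)
  expect_equal(e$C0, 0, tolerance = 1e-6)
  expect_error(compute_efd(cbind(c(1, 1, 1), c(2, 2, 2)), 3), "zero-perimeter")
})

test_that("translation shifts only the centroid terms", {
  poly <- render_polygon(spore_params(10, 4, bow_kappa1 = 0.05, taper_p = 0.6), 200)
  e1 <- compute_efd(poly, 10)
  shifted <- sweep(poly, 2, c(-10, 7), "-")
  e2 <- compute_efd(shifted, 10)
  expect_equal(e2$coeffs, e1$coeffs, tolerance = 1e-12)
  expect_equal(e2$A0 - e1$A0, 10, tolerance = 1e-9)
  expect_equal(e2$C0 - e1$C0, -7, tolerance = 1e-9)
})

test_that("closed-form coefficients match brute-force Fourier integration", {
  set.seed(101)
  for (i in 1:5) {
    poly <- random_star_polygon(50)
    e <- compute_efd(poly, 8)
    o <- brute_force_efd(poly, 8)
    scale <- max(abs(o$coeffs))
    expect_lt(max(abs(e$coeffs - o$coeffs)) / scale, 1e-8)
    expect_lt(abs(e$A0 - o$A0) / scale, 1e-8)
    expect_lt(abs(e$C0 - o$C0) / scale, 1e-8)
  }
})

test_that("normalization of an exact ellipse gives the analytic result", {
  # construct the EFD of the ellipse with semi-axes (5, 2) directly
  e <- structure(list(n_harmonics = 2L, A0 = 0, C0 = 0,
                      coeffs = rbind(c(a = 5, b = 0, c = 0, d = 2),
                                     c(a = 0, b = 0, c = 0, d = 0))),
                 class = "spore_efd")
  n <- normalize_efd(e)
  expect_equal(unname(n$coeffs[1, ]), c(1, 0, 0, 0.4), tolerance = 1e-12)
  expect_equal(n$size_scalar, 5)
})

test_that("normalized descriptors are invariant to pose, scale, start point and sampling", {
  poly <- render_polygon(spore_params(12, 3, bow_kappa1 = 0.08,
                                      end_kappa2 = 0.03, taper_p = 0.6,
                                      apiculus_h = 0.3), 240)
  ref <- normalize_efd(compute_efd(poly, 20), poly = poly)
  transformed <- 2.5 * poly %*% t(rot2(37 * pi / 180))
  transformed <- transformed[c(81:nrow(transformed), 1:80), ]
  transformed <- sweep(transformed, 2, c(10, -7), "-")
  alt <- normalize_efd(compute_efd(transformed, 20), poly = transformed)
  expect_lt(max(abs(alt$coeffs - ref$coeffs)), 1e-6)
  expect_equal(alt$size_scalar / ref$size_scalar, 2.5, tolerance = 1e-9)
  # denser sampling of the same silhouette converges to the same NEFD
  dense_poly <- render_polygon(spore_params(12, 3, bow_kappa1 = 0.08,
                                            end_kappa2 = 0.03, taper_p = 0.6,
                                            apiculus_h = 0.3), 480)
  dense <- normalize_efd(compute_efd(dense_poly, 20), poly = dense_poly)
  expect_lt(max(abs(dense$coeffs - ref$coeffs)), 5e-3)
})

test_that("coefficient bookkeeping: 80 stored, 3 constants, 77 free at 20 harmonics", {
  poly <- render_polygon(spore_params(11, 3.2, bow_kappa1 = 0.05, taper_p = 0.7), 200)
  n <- normalize_efd(compute_efd(poly, 20))
  expect_equal(length(n$coeffs), 80)
  expect_equal(n$coeffs[1, "a"], c(a = 1), tolerance = 1e-9)
  expect_lt(abs(n$coeffs[1, "b"]), 1e-9)
  expect_lt(abs(n$coeffs[1, "c"]), 1e-9)
  expect_length(nefd_to_vector(n, "global"), 77)
  expect_length(nefd_to_vector(n, "symmetric"), 39)
  expect_length(nefd_to_vector(n, "asymmetric"), 38)
  # one harmonic leaves a single free coefficient (d1)
  n1 <- normalize_efd(compute_efd(poly, 1))
  expect_identical(names(nefd_to_vector(n1, "global")), "d1")
})

test_that("reconstruction converges monotonically to the outline", {
  poly <- render_polygon(spore_params(12, 3, bow_kappa1 = 0.08, taper_p = 0.6,
                                      apiculus_h = 0.3), 300)
  e <- compute_efd(poly, 20)
  errs <- vapply(1:20, function(H)
    mean_outline_distance(poly, reconstruct_outline(e, 400, n_harmonics = H)),
    0)
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[20], 0.01 * 12)               # < 1% of spore length
  # a 1-harmonic shape is reconstructed exactly
  ell <- structure(list(n_harmonics = 1L, A0 = 2, C0 = -1,
                        coeffs = rbind(c(a = 5, b = 0, c = 0, d = 2))),
                   class = "spore_efd")
  rec <- reconstruct_outline(ell, 64)
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  expect_equal(rec, cbind(x = 2 + 5 * cos(th), y = -1 + 2 * sin(th)),
               tolerance = 1e-12)
  expect_error(reconstruct_outline(ell, 8), "n_points")
})

test_that("mirror-symmetric outlines carry no asymmetric signal", {
  sym <- render_polygon(spore_params(12, 3, taper_p = 0.6), 300)
  n <- normalize_efd(compute_efd(sym, 20))
  blocks <- split_sym_asym(n)
  expect_lt(sqrt(sum(blocks$asymmetric^2)),
            1e-3 * sqrt(sum(blocks$symmetric^2)))
  # bowing the capsule creates asymmetric signal
  bowed <- render_polygon(spore_params(12, 3, bow_kappa1 = 0.1, taper_p = 0.6), 300)
  nb <- normalize_efd(compute_efd(bowed, 20))
  expect_gt(sqrt(sum(split_sym_asym(nb)$asymmetric^2)),
            sqrt(sum(blocks$asymmetric^2)))
})

test_that("reflection negates the asymmetric block and keeps the symmetric one", {
  poly <- render_polygon(spore_params(12, 3, bow_kappa1 = 0.07,
                                      end_kappa2 = -0.03, taper_p = 0.6,
                                      apiculus_h = 0.25), 240)
  n1 <- normalize_efd(compute_efd(poly, 20), poly = poly)
  mirrored <- ensure_ccw(cbind(poly[, 1], -poly[, 2]))
  n2 <- normalize_efd(compute_efd(mirrored, 20), poly = mirrored)
  b1 <- split_sym_asym(n1); b2 <- split_sym_asym(n2)
  expect_equal(b2$symmetric, b1$symmetric, tolerance = 1e-6)
  expect_equal(b2$asymmetric, -b1$asymmetric, tolerance = 1e-6)
})

test_that("split and vector layouts are consistent and guarded", {
  poly <- render_polygon(spore_params(10, 3, bow_kappa1 = 0.05, taper_p = 0.7), 200)
  e <- compute_efd(poly, 20)
  expect_error(nefd_to_vector(e), "spore_nefd")
  n <- normalize_efd(e)
  g <- nefd_to_vector(n, "global")
  s <- split_sym_asym(n)
  expect_setequal(names(g), c(names(s$symmetric), names(s$asymmetric)))
  expect_equal(g[names(s$symmetric)], s$symmetric)
  # re-embedding a vector reproduces the source descriptors
  back <- sporemorph:::vector_to_nefd(g, n)
  expect_equal(back$coeffs, n$coeffs, tolerance = 1e-12)
})

test_that("descriptor files round-trip exactly", {
  polys <- list(a = render_polygon(spore_params(10, 3, taper_p = 0.7), 200),
                b = render_polygon(spore_params(14, 3.5, bow_kappa1 = 0.09), 200))
  nefds <- lapply(polys, function(p) normalize_efd(compute_efd(p, 20)))
  path <- withr::local_tempfile(fileext = ".txt")
  write_nefd_file(nefds, path, image_ids = c("img1", "img1"))
  back <- read_nefd_file(path)
  expect_identical(names(back$nefds), c("a", "b"))
  expect_equal(back$nefds$a$coeffs, nefds$a$coeffs, tolerance = 1e-15)
  expect_equal(back$nefds$b$size_scalar, nefds$b$size_scalar, tolerance = 1e-15)
  expect_identical(unname(back$image_ids), c("img1", "img1"))
})
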