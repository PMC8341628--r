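test_that("species panels are reproducible and seed-sensitive", {
  p1 <- sample_species_panel(10, 3, seed = 1)
  p2 <- sample_species_panel(10, 3, seed = 1)
  p3 <- sample_species_panel(3, 2, seed = 2)
  expect_length(p1, 10)
  expect_equal(nrow(p1[[1]]$specimen_effects), 3)
  expect_identical(p1, p2)
  p4 <- sample_species_panel(3, 2, seed = 1)
  expect_false(identical(p4[[1]]$mean, p3[[1]]$mean))
  # species means mutually distinct in at least one parameter
  lens <- vapply(p1, function(m) m$mean$length_um, 0)
  expect_equal(length(unique(lens)), 10)
  expect_error(sample_species_panel(1, 3), "n_species")
  bad <- default_panel_ranges(); bad$mean_range$taper_p <- c(0, 3)
  expect_error(sample_species_panel(3, 2, bad), "taper_p")
})

test_that("spore draws respect the hierarchical structure", {
  r <- pinned_ranges(vary = list())          # all SDs zero
  panel <- sample_species_panel(2, 1, r, seed = 7)
  set.seed(1)
  s1 <- sample_spore(panel[[1]], 1)
  s2 <- sample_spore(panel[[1]], 1)
  expect_equal(unclass(s1), unclass(s2))     # zero variance: identical spores
  expect_equal(s1$length_um, panel[[1]]$mean$length_um)
  # noise on length only leaves width untouched
  r2 <- pinned_ranges(vary = list(), spore_noise = list(length_um = 0.05))
  panel2 <- sample_species_panel(2, 1, r2, seed = 7)
  set.seed(2)
  draws <- replicate(20, sample_spore(panel2[[1]], 1)$width_um)
  expect_equal(length(unique(draws)), 1L)
  expect_error(sample_spore(panel2[[1]], 5), "specimen_idx")
})

test_that("log-scale length noise gives the expected coefficient of variation", {
  r <- pinned_ranges(vary = list(), spore_noise = list(length_um = 0.05))
  panel <- sample_species_panel(2, 1, r, seed = 3)
  set.seed(42)
  lens <- replicate(1000, sample_spore(panel[[1]], 1)$length_um)
  cv <- sd(lens) / mean(lens)
  # lognormal with sdlog 0.05 has CV = sqrt(exp(0.05^2) - 1) ~ 0.05
  expect_gt(cv, 0.04)
  expect_lt(cv, 0.06)
})

test_that("rendered capsules have the stated geometry", {
  straight <- render_polygon(spore_params(10, 4, taper_p = 0.5), 300)
  expect_gt(polygon_area(straight), 0)
  expect_equal(diff(range(straight[, 1])), 10, tolerance = 1e-9)
  # mirror symmetry about the long axis when all asymmetry terms vanish
  reflected <- cbind(straight[, 1], -straight[, 2])
  expect_lt(mean_outline_distance(reflected, straight), 1e-3 * 4)
  # single bow breaks the symmetry and lengthens the outline
  bowed <- render_polygon(spore_params(10, 4, bow_kappa1 = 0.1, taper_p = 0.5), 300)
  expect_gt(polygon_perimeter(bowed), polygon_perimeter(straight))
  expect_gt(mean_outline_distance(cbind(bowed[, 1], -bowed[, 2]), bowed), 0.01)
  expect_identical(sign(polygon_area(bowed)), 1)
  # refinement convergence
  coarse <- render_polygon(spore_params(10, 4, taper_p = 0.5), 50)
  fine <- render_polygon(spore_params(10, 4, taper_p = 0.5), 400)
  expect_lt(hausdorff_distance(coarse, fine), 0.05 * 4)
  expect_error(render_polygon(spore_params(10, 4), 20), "n_points")
  expect_error(spore_params(10, 12), "width_um")
  expect_error(spore_params(10, 4, taper_p = 3), "taper_p")
})

test_that("rasterization conserves area and follows the scaling law", {
  poly <- render_polygon(spore_params(10, 4, taper_p = 0.5), 300)
  img <- rasterize_polygon(poly, 0.1)
  expect_s3_class(img, "binary_image")
  area_px <- sum(img$pixels) * 0.1^2
  expect_lt(abs(area_px - polygon_area(poly)) / polygon_area(poly), 0.05)
  img2 <- rasterize_polygon(poly, 0.05)
  expect_gt(sum(img2$pixels) / sum(img$pixels), 3.6)
  expect_lt(sum(img2$pixels) / sum(img$pixels), 4.4)
  expect_error(rasterize_polygon(list(), 0.1), "no polygons")
  expect_error(rasterize_polygon(poly, 0.1, canvas_px = c(10, 10)), "canvas")
})

test_that("generated datasets have consistent bookkeeping", {
  panel <- sample_species_panel(4, 3, seed = 5)
  ds <- generate_dataset(panel, spores_per_specimen = 5, seed = 5,
                         rasterize = FALSE)
  expect_equal(nrow(ds$truth), 4 * 3 * 5)
  expect_length(ds$polygons, nrow(ds$truth))
  expect_true(all(ds$manifest$image_id %in% ds$truth$image_id))
  ds2 <- generate_dataset(panel, spores_per_specimen = 5, seed = 5,
                          rasterize = FALSE)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$truth, ds2$truth)
  # ranged design: counts within bounds, multi-spore images within bounds
  ds3 <- generate_dataset(panel, spores_per_specimen = c(10, 37), seed = 1,
                          spores_per_image = c(1, 4), rasterize = FALSE)
  per_spec <- table(ds3$truth$specimen_id)
  expect_true(all(per_spec >= 10 & per_spec <= 37))
  expect_true(all(ds3$manifest$n_spores >= 1 & ds3$manifest$n_spores <= 4))
  expect_equal(sum(ds3$manifest$n_spores), nrow(ds3$truth))
})

test_that("ground truth is recoverable from noise-free rasters", {
  r <- pinned_ranges(vary = list(apiculus_h = c(0, 0)))
  panel <- sample_species_panel(2, 1, r, seed = 1)
  ds <- generate_dataset(panel, spores_per_specimen = 1, seed = 1,
                         scale_um_per_px = 0.1, rasterize = TRUE)
  img <- ds$images[[1]]
  poly <- chain_to_polygon(trace_boundary(img, min_area = 20)[[1]])
  lw <- measure_length_width(poly)
  truth <- ds$truth[1, ]
  expect_lt(abs(lw["length_um"] - truth$length_um), 2 * 0.1)
  expect_lt(abs(lw["width_um"] - truth$width_um), 2 * 0.1)
})

test_that("datasets round-trip to disk as text and images", {
  panel <- sample_species_panel(2, 1, seed = 9)
  ds <- generate_dataset(panel, spores_per_specimen = 2, seed = 9,
                         rasterize = TRUE)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  expect_equal(man$image_id, ds$manifest$image_id)
  img_files <- list.files(file.path(dir, "images"), full.names = TRUE)
  expect_length(img_files, length(ds$images))
  back <- read_binary_image(img_files[1], ds$scale_um_per_px)
  id1 <- sub("[.]png$", "", basename(img_files[1]))
  expect_identical(back$pixels, ds$images[[id1]]$pixels)
})
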