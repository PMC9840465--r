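# Synthetic scene generation, the defocus render model, and tiling.

test_that("scene with no domes has a flat surface and zero dome area", {
  p <- scene_pars(field_size_um = 64, n_planes = 4, n_nuclei = 5,
                  n_domes = 0, seed = 2)
  sc <- generate_scene(p)
  expect_true(all(sc$surface$height_um == sc$surface$base_height_um))
  expect_equal(sc$truth$true_total_dome_area_um2, 0)
  expect_false(any(dome_mask(sc$surface)))
})

test_that("requested object counts are honoured exactly", {
  p <- scene_pars(field_size_um = 512, n_planes = 4, n_nuclei = 100,
                  n_domes = 0, n_autophagosomes = 12,
                  autophagosome_area_um2 = c(2, 6), seed = 3)
  sc <- generate_scene(p)
  expect_equal(nrow(sc$truth$nuclei), 100)
  expect_equal(nrow(sc$truth$autophagosomes), 12)
  pm <- mito_field_pars(seed = 4, density = 2)
  scm <- generate_scene(pm)
  expect_equal(nrow(scm$truth$mito), round(2 * 48^2 / 100))
})

test_that("generation and rendering are bit-identical for a fixed seed", {
  p <- tiny_dome_scene(seed = 9, field = 96, n_planes = 8, radius = 30,
                       apex = 25)
  s1 <- generate_scene(p); s2 <- generate_scene(p)
  expect_identical(s1, s2)
  z1 <- render_zstack(s1$ideal$brightfield, s1$surface, p)
  z2 <- render_zstack(s2$ideal$brightfield, s2$surface, p)
  expect_identical(z1$data, z2$data)
})

test_that("rasterized dome mask area matches pi r^2 within a perimeter band", {
  for (seed in 1:3) {
    p <- scene_pars(field_size_um = 256, n_planes = 12, n_nuclei = 0,
                    n_domes = 2, dome_radius_um = c(25, 40),
                    dome_apex_um = 20, seed = seed)
    sc <- generate_scene(p)
    analytic <- sc$truth$true_total_dome_area_um2
    raster <- sum(dome_mask(sc$surface)) * p$pixel_size_um^2
    band <- sum(2 * pi * sc$truth$domes$radius_um) * p$pixel_size_um
    expect_lt(abs(raster - analytic), band)
  }
})

test_that("surface follows the spherical-cap profile", {
  p <- tiny_dome_scene(seed = 1, field = 128, radius = 40, apex = 30)
  sc <- generate_scene(p)
  h <- sc$surface$height_um
  centre <- h[64, 64]
  expect_equal(centre, 30, tolerance = 0.01)
  # height is base outside the footprint and decreases radially inside
  expect_equal(h[5, 5], 0)
  ring1 <- h[64, 64 + 20]; ring2 <- h[64, 64 + 35]
  expect_true(centre > ring1 && ring1 > ring2 && ring2 >= 0)
})

test_that("invalid scene parameters are rejected", {
  expect_error(scene_pars(regular_area_um2 = c(0.5, 3),
                          enlarged_area_um2 = c(2, 6)),
               "strictly above")
  expect_error(scene_pars(field_size_um = 64,
                          dome_specs = list(list(center = c(60, 60),
                                                 radius_um = 20,
                                                 apex_height_um = 10))),
               "fit inside")
  expect_error(scene_pars(dome_specs = list(list(center = c(256, 256),
                                                 radius_um = 20,
                                                 apex_height_um = 30))),
               "overhang")
  # over-crowded field errors and names the object class
  expect_error(generate_scene(
    scene_pars(field_size_um = 64, n_planes = 2, n_nuclei = 500,
               n_domes = 0, seed = 1)),
    "nuclei")
})

test_that("defocus blur follows sigma = rate * |z - height|", {
  p <- scene_pars(field_size_um = 64, n_planes = 3, z_step_um = 5,
                  n_nuclei = 0, n_domes = 0, blur_rate_px_per_um = 0.3,
                  seed = 6)
  sc <- generate_scene(p)
  flat <- sc$surface  # height 0 everywhere
  zs <- render_zstack(sc$ideal$brightfield, flat, p, noise = FALSE)
  # plane at the surface height: sigma 0, equals the ideal image exactly
  expect_identical(zs$data[, , 1], sc$ideal$brightfield)
  # plane at |z - h| = 10 um with rate 0.3: sigma 3.0 px
  expect_equal(zs$data[, , 3],
               domescope:::.gblur(sc$ideal$brightfield, 3.0),
               tolerance = 1e-12)
})

test_that("the true plane maximizes local contrast, exhaustively on plateaus", {
  # piecewise-flat surface: left half at plane 1, right half at plane 3
  p <- scene_pars(field_size_um = 96, n_planes = 5, n_nuclei = 0,
                  n_domes = 0, seed = 10)
  sc <- generate_scene(p)
  surf <- sc$surface
  surf$height_um[, 1:48] <- 5
  surf$height_um[, 49:96] <- 15
  zs <- render_zstack(sc$ideal$brightfield, surf, p, noise = FALSE)
  true_q <- round(surf$height_um / 5)
  tex <- textured_pixels(sc$ideal$brightfield)
  v <- vapply(seq_len(p$n_planes),
              function(k) focus_measure(zs$data[, , k]),
              matrix(0, 96, 96))
  am <- apply(v, c(1, 2), which.max) - 1L
  # away from the height step every textured pixel is exactly right
  interior <- col(true_q) %in% c(5:43, 54:92)
  expect_true(all((am == true_q)[tex & interior]))
})

test_that("argmax height tracks a dome surface at representative geometry", {
  p <- scene_pars(field_size_um = 256, n_planes = 10, n_nuclei = 0,
                  dome_specs = list(list(center = c(128, 128),
                                         radius_um = 50,
                                         apex_height_um = 40)),
                  seed = 10)
  sc <- generate_scene(p)
  zs <- render_zstack(sc$ideal$brightfield, sc$surface, p, noise = FALSE)
  true_q <- true_height_planes(sc)
  tex <- textured_pixels(sc$ideal$brightfield)
  # exact-match is only well-posed where (a) the surface is locally flat
  # within the focus window -- a window straddling a slope sees several
  # heights -- and (b) the height is away from the half-step quantization
  # boundary, where the two neighbouring planes are equally sharp
  h <- sc$surface$height_um
  hmax <- EBImage::imageData(EBImage::dilate(h, EBImage::makeBrush(7, "box")))
  hmin <- -EBImage::imageData(EBImage::dilate(-h, EBImage::makeBrush(7, "box")))
  well_posed <- (hmax - hmin) < 2.5 & abs(h - round(h / 5) * 5) < 1.5
  v <- vapply(seq_len(p$n_planes),
              function(k) focus_measure(zs$data[, , k]),
              matrix(0, 256, 256))
  am <- apply(v, c(1, 2), which.max) - 1L
  expect_gte(mean((am == true_q)[tex & well_posed]), 0.99)
  expect_gte(mean((abs(am - true_q) <= 1)[tex]), 0.99)
})

test_that("insufficient z coverage is an error", {
  p <- tiny_dome_scene(seed = 1, field = 96, n_planes = 3, radius = 30,
                       apex = 25)  # 3 planes cover only 10 um
  sc0 <- generate_scene(tiny_dome_scene(seed = 1, field = 96, n_planes = 8,
                                        radius = 30, apex = 25))
  expect_error(render_zstack(sc0$ideal$brightfield, sc0$surface, p),
               "does not cover")
})

test_that("tile grid arithmetic and exact reassembly", {
  # 5x5 grid, tile 512 px, overlap 0.125 -> stride 448, side 2304
  img <- matrix(0, 2304, 2304)
  ts <- tile_mosaic(img, grid = c(5, 5), overlap_fraction = 0.125)
  expect_equal(ts$tile_px, c(512L, 512L))
  expect_equal(ts$stride_px, c(448L, 448L))
  # zero overlap partitions the image; reassembly is exact
  set.seed(1)
  img <- matrix(runif(120 * 120), 120)
  ts0 <- tile_mosaic(img, c(3, 3), 0)
  expect_equal(ts0$tile_px, c(40L, 40L))
  expect_identical(paste_tiles(ts0), img)
  # overlapping tiling also reassembles bit-exactly
  img2 <- matrix(runif(153 * 153), 153)  # tile 85 px, stride 68 px
  ts1 <- tile_mosaic(img2, c(2, 2), 0.2)
  expect_identical(paste_tiles(ts1), img2)
  # 3D stacks tile the same way
  arr <- array(runif(60 * 60 * 3), c(60, 60, 3))
  ts3 <- tile_mosaic(arr, c(2, 2), 0)
  expect_identical(paste_tiles(ts3), arr)
})

test_that("non-integral tile geometry errors with a suggested size", {
  err <- tryCatch(tile_mosaic(matrix(0, 512, 512), c(2, 2), 0.125),
                  error = function(e) conditionMessage(e))
  expect_match(err, "nearest valid side")
  expect_match(err, "510")  # tile 272 px, stride 238... = 272 * 0.875 integer
})

test_that("scene tiles round-trip through TIFF with metadata", {
  p <- tiny_dome_scene(seed = 12, field = 96, n_planes = 6, radius = 30,
                       apex = 25)
  sc <- generate_scene(p)
  zs <- render_zstack(sc$ideal$brightfield, sc$surface, p)
  dir <- withr::local_tempdir()
  write_scene_tiles(sc, list(brightfield = zs), grid = c(2, 2),
                    overlap_fraction = 0, dir = dir)
  ts <- read_scene_tiles(dir, "brightfield")
  expect_equal(ts$grid, c(2, 2))
  # float-32 TIFF round trip: equal to single precision
  expect_equal(paste_tiles(ts), zs$data, tolerance = 1e-6)
  gt <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(sum(gt$class == "dome"), 1)
  # 16-bit integer height-map round trip is exact
  hm <- matrix(sample(0:19, 64 * 64, replace = TRUE), 64)
  f <- file.path(dir, "hm.tif")
  write_image_tiff(hm, f, integer = TRUE)
  expect_identical(read_image_tiff(f, integer = TRUE), hm)
})
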