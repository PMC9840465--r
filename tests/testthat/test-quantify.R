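# Structure quantification: nuclei, domes, features, the pixel classifier,
# mitochondria and puncta.

test_that("nuclei counting: blank, well-separated, watershed splitting", {
  expect_equal(count_nuclei(matrix(0, 64, 64), 1)$count, 0)
  p <- scene_pars(field_size_um = 512, n_planes = 4, n_nuclei = 100,
                  nucleus_sep_diameters = 2, n_domes = 0, seed = 3)
  sc <- generate_scene(p)
  expect_equal(count_nuclei(sc$ideal$nuclear, 1)$count, 100)
  # two nuclei overlapping by < 30% of radius are split by the watershed
  grids <- domescope:::.coord_grids(64, 1)
  r <- 8
  img <- matrix(0.02, 64, 64)
  img <- domescope:::.draw_disc(img, grids, 24, 32, r, 0.9, 0.8)
  img <- domescope:::.draw_disc(img, grids, 24 + 1.7 * r, 32, r, 0.9, 0.8)
  res <- count_nuclei(pmin(img, 1), 1)
  expect_equal(res$count, 2)
})

test_that("dome segmentation from height-maps", {
  flat <- matrix(5, 100, 100)
  d0 <- segment_domes(flat, 1, min_height_um = 2.5)
  expect_equal(d0$total_dome_area_um2, 0)
  expect_equal(d0$dome_count, 0)
  # one raised disc of radius 50 px on a 1 um grid
  grids <- domescope:::.coord_grids(128, 1)
  hm <- matrix(0, 128, 128)
  hm[domescope:::.disc_mask(grids, 64, 64, 50)] <- 10
  d1 <- segment_domes(hm, 1, min_height_um = 2.5, min_area_um2 = 100)
  expect_equal(d1$dome_count, 1)
  expect_equal(d1$total_dome_area_um2, pi * 50^2, tolerance = 0.05)
  expect_equal(d1$base_height_um, 0)
  # apex below the height threshold: excluded entirely
  hm2 <- hm; hm2[hm2 > 0] <- 2
  d2 <- segment_domes(hm2, 1, min_height_um = 2.5, min_area_um2 = 100)
  expect_equal(d2$total_dome_area_um2, 0)
  # a height-map that is mostly unique values has no modal plateau
  expect_error(segment_domes(matrix(runif(64^2), 64), 1, 2.5), "smooth")
})

test_that("dome area is monotone in both thresholds", {
  p <- tiny_dome_scene(seed = 13, field = 128, n_planes = 8, radius = 40,
                       apex = 30)
  sc <- generate_scene(p)
  hm <- sc$surface$height_um
  hm_q <- round(hm / 5) * 5  # quantized like an EDF height-map
  areas_h <- vapply(c(2.5, 7.5, 12.5, 17.5), function(mh)
    segment_domes(hm_q, 1, mh, 100)$total_dome_area_um2, numeric(1))
  expect_true(all(diff(areas_h) <= 0))
  areas_a <- vapply(c(0, 500, 2000, 6000), function(ma)
    segment_domes(hm_q, 1, 2.5, ma)$total_dome_area_um2, numeric(1))
  expect_true(all(diff(areas_a) <= 0))
})

test_that("feature stacks: count, degeneracy, equivariance", {
  set.seed(5)
  img <- matrix(runif(64 * 64), 64)
  fs <- extract_features(img, scales = c(1, 2))
  expect_equal(dim(fs)[3], 5 * 2)
  # constant image: every derivative-based feature is (numerically) zero
  fc <- extract_features(matrix(0.3, 64, 64), scales = c(1, 2))
  deriv <- grep("gradmag|laplacian|steig|localvar", dimnames(fc)[[3]])
  expect_lt(max(abs(fc[, , deriv])), 1e-8)
  # shifting the image shifts the features (interior pixels):
  # sh row i = img row i + 4, so F(sh)[20:45, ] must equal F(img)[24:49, ]
  sh <- img[c(5:64, 1:4), ]
  f1 <- extract_features(img, 2)[24:49, 20:45, ]
  f2 <- extract_features(sh, 2)[20:45, 20:45, ]
  expect_equal(f2, f1, tolerance = 1e-6)
})

test_that("pixel classifier separates a bright/dark toy and is deterministic", {
  p <- mito_field_pars(seed = 6, density = 2)
  sc <- generate_scene(p)
  img <- sc$ideal$mito
  fs <- extract_features(img, scales = c(1, 2))
  labels <- matrix(0L, nrow(img), ncol(img))
  labels[img < 0.1] <- 1L   # background
  labels[img > 0.8] <- 2L   # organelle
  # keep the problem sparse, as manual annotation would be (per class, as
  # an annotator scribbles on both object and background)
  set.seed(7)
  keep <- c(sample(which(labels == 1L), 1500), sample(which(labels == 2L), 500))
  sparse <- matrix(0L, nrow(img), ncol(img)); sparse[keep] <- labels[keep]
  model <- train_pixel_classifier(fs, sparse, seed = 11)
  expect_gte(model$holdout_accuracy, 0.99)
  pr1 <- predict_pixels(model, img)
  model2 <- train_pixel_classifier(fs, sparse, seed = 11)
  pr2 <- predict_pixels(model2, img)
  expect_identical(pr1$class_map, pr2$class_map)
  # per-pixel class probabilities sum to one
  expect_equal(apply(pr1$prob, c(1, 2), sum),
               matrix(1, nrow(img), ncol(img)), tolerance = 1e-9)
  # single-class labels are rejected, small classes are named
  one <- sparse; one[one == 2L] <- 0L
  expect_error(train_pixel_classifier(fs, one, seed = 1), ">= 2")
  few <- sparse; few[which(few == 2L)[-(1:10)]] <- 0L
  expect_error(train_pixel_classifier(fs, few, seed = 1), "2")
})

test_that("mitochondrial footprint and area conservation", {
  blank <- segment_mitochondria(matrix(0, 64, 64), 0.1)
  expect_equal(blank$mito_footprint, 0)
  expect_equal(nrow(blank$objects), 0)
  p <- mito_field_pars(seed = 8, density = 5)
  sc <- generate_scene(p)
  seg <- segment_mitochondria(sc$ideal$mito, 0.1)
  true_fp <- sum(sc$truth$mito$area_um2) / 48^2
  expect_equal(seg$mito_footprint, true_fp, tolerance = 0.01 / true_fp)
  # object areas sum exactly to footprint x field area
  expect_equal(sum(seg$objects$area_um2),
               seg$mito_footprint * length(sc$ideal$mito) * 0.1^2)
})

test_that("enlarged-mitochondrion classification by area threshold", {
  tab <- data.frame(object_id = 1:9, area_um2 = c(1:9) / 2)
  # threshold above the maximum: none enlarged
  expect_equal(classify_enlarged(tab, 10)$enlarged_count, 0)
  # strict inequality at the median of an odd-sized set: (n-1)/2 enlarged
  med <- median(tab$area_um2)
  r <- classify_enlarged(tab, med)
  expect_equal(r$enlarged_count, 4)
  expect_equal(r$fraction, 4 / 9)
  expect_error(classify_enlarged(tab, -1), "non-negative")
  expect_equal(classify_enlarged(tab[0, ], 1)$fraction, 0)
})

test_that("generator enlarged fraction is recovered through segmentation", {
  p <- mito_field_pars(seed = 9, density = 3, enlarged_fraction = 0.2)
  sc <- generate_scene(p)
  seg <- segment_mitochondria(sc$ideal$mito, 0.1)
  # threshold between the generator's regular and enlarged ranges
  r <- classify_enlarged(seg$objects, 2.0)
  expect_equal(r$fraction, 0.2, tolerance = 0.25)  # +-0.05 absolute
  expect_lt(abs(r$fraction - mean(sc$truth$mito$class == "enlarged")), 0.05)
})

test_that("large-puncta counting: threshold, ground truth, monotonicity", {
  expect_equal(count_large_puncta(matrix(0, 64, 64), 1, 1)$count, 0)
  # 7 puncta above the area cutoff, 5 below
  grids <- domescope:::.coord_grids(256, 0.5)
  img <- matrix(0.02, 256, 256)
  big_r <- sqrt(20 / pi); small_r <- sqrt(2 / pi)
  centres <- expand.grid(x = seq(15, 115, by = 25), y = seq(15, 115, by = 25))
  for (i in 1:7)
    img <- domescope:::.draw_disc(img, grids, centres$x[i], centres$y[i],
                                  big_r, 0.9, 0.25)
  for (i in 8:12)
    img <- domescope:::.draw_disc(img, grids, centres$x[i], centres$y[i],
                                  small_r, 0.9, 0.25)
  img <- pmin(img, 1)
  expect_equal(count_large_puncta(img, 0.5, min_area_um2 = 10,
                                  intensity_quantile = 0.99)$count, 7)
  # doubling the minimum area can never increase the count
  counts <- vapply(c(1, 2, 4, 8, 16, 32),
                   function(a) count_large_puncta(img, 0.5, a, 0.99)$count,
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(count_large_puncta(img, 0.5, 1, intensity_quantile = 1.2),
               "quantile")
})

test_that("enlarged threshold default is the control-area percentile", {
  areas <- c(rep(1, 39), 5)
  expect_equal(enlarged_threshold(areas),
               as.numeric(quantile(areas, 0.975)))
  expect_error(enlarged_threshold(numeric(0)))
})
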