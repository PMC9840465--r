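# Segmentation and measurement of biological structures: nuclei, fluid
# domes (from height-maps), mitochondria and autophagosome puncta.

# Label-map helper: relabel components consecutively (1..n), background 0.
.relabel <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (length(u)) out[] <- match(lab, u, nomatch = 0L)
  out
}

# Per-label pixel counts and centroids (um, pixel-centre convention).
.object_table <- function(lab, pixel_size_um, aux = NULL, aux_name = NULL) {
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids))
    return(data.frame(object_id = integer(0), area_um2 = numeric(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0)))
  f <- factor(lab[lab > 0], levels = ids)
  npix <- as.integer(table(f))
  rowi <- row(lab)[lab > 0]; coli <- col(lab)[lab > 0]
  cy <- tapply((rowi - 0.5) * pixel_size_um, f, mean)
  cx <- tapply((coli - 0.5) * pixel_size_um, f, mean)
  out <- data.frame(object_id = seq_along(ids),
                    area_um2 = npix * pixel_size_um^2,
                    centroid_x_um = as.numeric(cx),
                    centroid_y_um = as.numeric(cy))
  if (!is.null(aux)) out[[aux_name]] <- as.numeric(tapply(aux[lab > 0], f, mean))
  out
}

#' Count nuclei in a nuclear-stain composite
#'
#' Gaussian smoothing, Otsu threshold, hole filling, distance-transform
#' watershed to split touching nuclei, and a minimum-area filter.
#'
#' @param image calibrated 2D nuclear-channel image.
#' @param pixel_size_um um per pixel.
#' @param min_area_um2 discard components smaller than this (default 20).
#' @param sigma_px Gaussian pre-smoothing sigma (default 1).
#' @return list(count, centroids (matrix, um), label_map).
#' @export
count_nuclei <- function(image, pixel_size_um, min_area_um2 = 20,
                         sigma_px = 1) {
  stopifnot(is.matrix(image), pixel_size_um > 0)
  if (max(image) - min(image) < 1e-8)
    return(list(count = 0L,
                centroids = matrix(numeric(0), 0, 2,
                                   dimnames = list(NULL, c("x", "y"))),
                label_map = matrix(0L, nrow(image), ncol(image))))
  sm <- .gblur(image, sigma_px)
  rng <- range(sm)
  smn <- (sm - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(smn), range = c(0, 1))
  mask <- smn > thr
  mask <- EBImage::fillHull(EBImage::Image(mask)) > 0
  dm <- EBImage::distmap(EBImage::Image(mask))
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1))
  min_px <- max(1L, round(min_area_um2 / pixel_size_um^2))
  cnt <- table(lab[lab > 0])
  keep <- as.integer(names(cnt)[cnt >= min_px])
  lab[!(lab %in% keep)] <- 0L
  lab <- .relabel(matrix(as.integer(lab), nrow(image), ncol(image)))
  tab <- .object_table(lab, pixel_size_um)
  list(count = nrow(tab),
       centroids = cbind(x = tab$centroid_x_um, y = tab$centroid_y_um),
       label_map = lab)
}

#' Segment fluid domes from a topography height-map
#'
#' The base (plate-attached) plane is the mode of the height values; the
#' dome mask is where height exceeds the base by at least
#' \code{min_height_um}; connected components smaller than
#' \code{min_area_um2} are discarded. Detection uses the height-map only:
#' dome cells sit on a higher plane than plate-attached cells, which is the
#' cue the topography encodes.
#'
#' @param height_map_um height-map in um (plane index times z-step; see
#'   \code{\link{height_to_um}}).
#' @param pixel_size_um um per pixel.
#' @param min_height_um minimum elevation above the base plane. A value
#'   between 0.5 and 1.5 z-steps is sensible: half a z-step is the height
#'   quantization floor (smallest detectable lift) and captures the dome rim
#'   where the cap tapers toward the base; larger values are more
#'   conservative against unsmoothed argmax noise.
#' @param min_area_um2 minimum dome area (default 500).
#' @return list(label_map, total_dome_area_um2, dome_count, objects
#'   (per-dome area, centroid, mean height), base_height_um).
#' @export
segment_domes <- function(height_map_um, pixel_size_um, min_height_um,
                          min_area_um2 = 500) {
  stopifnot(is.matrix(height_map_um), pixel_size_um > 0, min_height_um > 0,
            min_area_um2 >= 0)
  vals <- as.vector(height_map_um)
  if (length(unique(vals)) > 0.5 * length(vals))
    stop("height-map has no modal plateau (> 50% unique values); ",
         "smooth the height-map (e.g. median filter) before segmentation")
  tb <- table(vals)
  base <- as.numeric(names(tb)[which.max(tb)])
  mask <- (height_map_um - base) >= min_height_um
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  min_px <- round(min_area_um2 / pixel_size_um^2)
  cnt <- table(lab[lab > 0])
  keep <- as.integer(names(cnt)[cnt >= min_px])
  lab[!(lab %in% keep)] <- 0L
  lab <- .relabel(matrix(as.integer(lab), nrow(mask), ncol(mask)))
  tab <- .object_table(lab, pixel_size_um, aux = height_map_um,
                       aux_name = "mean_height_um")
  list(label_map = lab, total_dome_area_um2 = sum(tab$area_um2),
       dome_count = nrow(tab), objects = tab, base_height_um = base)
}

#' Per-pixel feature stack for pixel classification
#'
#' At each scale s: Gaussian-smoothed intensity, gradient magnitude,
#' Laplacian, largest structure-tensor eigenvalue, and local variance
#' (window 2*ceiling(2s)+1). Five features per scale, deterministic.
#'
#' @param image 2D matrix.
#' @param scales numeric vector of Gaussian scales in px (> 0, non-empty).
#' @return array rows x cols x (5 * length(scales)) with named slices.
#' @export
extract_features <- function(image, scales = c(1, 2, 4)) {
  stopifnot(is.matrix(image), length(scales) >= 1, all(scales > 0))
  feats <- list()
  for (s in scales) {
    g <- .gblur(image, s)
    gx <- .conv3(g, .sobel_x) / 8
    gy <- .conv3(g, t(.sobel_x)) / 8
    lap <- .conv3(g, matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3))
    jxx <- .gblur(gx^2, s); jyy <- .gblur(gy^2, s); jxy <- .gblur(gx * gy, s)
    eig <- (jxx + jyy) / 2 + sqrt(pmax(((jxx - jyy) / 2)^2 + jxy^2, 0))
    w <- 2L * as.integer(ceiling(2 * s)) + 1L
    m <- .box_mean(image, w); v <- pmax(.box_mean(image^2, w) - m^2, 0)
    feats[[paste0("gauss_s", s)]] <- g
    feats[[paste0("gradmag_s", s)]] <- sqrt(gx^2 + gy^2)
    feats[[paste0("laplacian_s", s)]] <- lap
    feats[[paste0("steig_s", s)]] <- eig
    feats[[paste0("localvar_s", s)]] <- v
  }
  arr <- array(unlist(feats, use.names = FALSE),
               dim = c(nrow(image), ncol(image), length(feats)))
  dimnames(arr) <- list(NULL, NULL, names(feats))
  attr(arr, "scales") <- scales
  arr
}

#' Train a pixel classifier from sparse labels
#'
#' Fits a decision-tree ensemble (random forest) on the labelled pixels of
#' one or more feature stacks and reports held-out accuracy on a stratified
#' 20\% split. Deterministic for a fixed seed.
#'
#' @param feature_stacks a feature array from \code{\link{extract_features}}
#'   or a list of them.
#' @param label_masks integer matrix (or list matching
#'   \code{feature_stacks}): 0 = unlabelled, 1..K = class labels.
#' @param seed integer training seed.
#' @param num_trees forest size (default 100).
#' @param min_labels minimum labelled pixels per class (default 50).
#' @return list of class \code{"pixel_classifier"}: the fitted forest,
#'   feature names, scales, classes, seed, holdout_accuracy.
#' @export
train_pixel_classifier <- function(feature_stacks, label_masks, seed = 1L,
                                   num_trees = 100L, min_labels = 50L) {
  if (!is.list(feature_stacks)) feature_stacks <- list(feature_stacks)
  if (!is.list(label_masks)) label_masks <- list(label_masks)
  stopifnot(length(feature_stacks) == length(label_masks))
  X <- NULL; y <- integer(0)
  for (i in seq_along(feature_stacks)) {
    fs <- feature_stacks[[i]]; lm <- label_masks[[i]]
    stopifnot(all(dim(fs)[1:2] == dim(lm)))
    sel <- which(lm > 0)
    nf <- dim(fs)[3]
    Xi <- matrix(fs, ncol = nf)[sel, , drop = FALSE]
    X <- rbind(X, Xi); y <- c(y, lm[sel])
  }
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need >= 2 labelled classes, got ",
                                length(classes))
  nper <- table(factor(y, levels = classes))
  short <- names(nper)[nper < min_labels]
  if (length(short))
    stop("class(es) with fewer than ", min_labels, " labelled pixels: ",
         paste(short, collapse = ", "))
  colnames(X) <- dimnames(feature_stacks[[1]])[[3]]
  set.seed(seed)
  test_idx <- unlist(lapply(classes, function(cl) {
    idx <- which(y == cl)
    sample(idx, max(1, round(0.2 * length(idx))))
  }))
  train_idx <- setdiff(seq_along(y), test_idx)
  df <- data.frame(X, .class = factor(y, levels = classes))
  fit <- ranger::ranger(.class ~ ., data = df[train_idx, ],
                        num.trees = num_trees, probability = TRUE,
                        seed = seed, num.threads = 1)
  pr <- stats::predict(fit, df[test_idx, ], num.threads = 1, seed = seed)
  pred <- classes[max.col(pr$predictions, ties.method = "first")]
  acc <- mean(pred == y[test_idx])
  structure(list(forest = fit, feature_names = colnames(X),
                 scales = attr(feature_stacks[[1]], "scales"),
                 classes = classes, seed = seed, holdout_accuracy = acc),
            class = "pixel_classifier")
}

#' Apply a pixel classifier to an image
#'
#' @param model a \code{\link{train_pixel_classifier}} model.
#' @param image 2D matrix (features are recomputed at the model's scales).
#' @return list(class_map (integer matrix of class labels), prob (array of
#'   per-class probabilities, summing to 1 per pixel)).
#' @export
predict_pixels <- function(model, image) {
  stopifnot(inherits(model, "pixel_classifier"))
  fs <- extract_features(image, model$scales)
  X <- matrix(fs, ncol = dim(fs)[3])
  colnames(X) <- model$feature_names
  pr <- stats::predict(model$forest, data.frame(X), num.threads = 1,
                       seed = model$seed)
  p <- pr$predictions
  cm <- matrix(model$classes[max.col(p, ties.method = "first")],
               nrow(image), ncol(image))
  list(class_map = cm,
       prob = array(p, dim = c(nrow(image), ncol(image), ncol(p))))
}

#' Segment mitochondria and measure the mitochondrial footprint
#'
#' Foreground is obtained either from a trained pixel classifier or a
#' deterministic threshold; connected components become objects with areas
#' and centroids. The footprint is the fraction of field pixels occupied by
#' mitochondria (so object areas always sum to footprint times field area).
#'
#' @param image calibrated mitochondrial-channel image.
#' @param pixel_size_um um per pixel.
#' @param model optional \code{\link{train_pixel_classifier}} model;
#'   \code{foreground_class} selects its mitochondrion class.
#' @param threshold deterministic alternative: \code{list(method = "otsu")}
#'   or \code{list(method = "fixed", value = v)}.
#' @param foreground_class class label treated as mitochondrion when a model
#'   is used (default 2, i.e. the second class).
#' @param min_area_um2 discard components below this area (default 0).
#' @return list(label_map, objects, mito_footprint).
#' @export
segment_mitochondria <- function(image, pixel_size_um, model = NULL,
                                 threshold = list(method = "otsu"),
                                 foreground_class = 2L, min_area_um2 = 0) {
  stopifnot(is.matrix(image), pixel_size_um > 0)
  if (!is.null(model)) {
    mask <- predict_pixels(model, image)$class_map == foreground_class
  } else if (max(image) - min(image) < 1e-8) {
    mask <- matrix(FALSE, nrow(image), ncol(image))
  } else if (threshold$method == "otsu") {
    rng <- range(image)
    xn <- (image - rng[1]) / diff(rng)
    mask <- xn > EBImage::otsu(EBImage::Image(xn), range = c(0, 1))
  } else {
    mask <- image > threshold$value
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  if (min_area_um2 > 0) {
    min_px <- round(min_area_um2 / pixel_size_um^2)
    cnt <- table(lab[lab > 0])
    keep <- as.integer(names(cnt)[cnt >= min_px])
    lab[!(lab %in% keep)] <- 0L
  }
  lab <- .relabel(matrix(as.integer(lab), nrow(image), ncol(image)))
  tab <- .object_table(lab, pixel_size_um)
  list(label_map = lab, objects = tab,
       mito_footprint = sum(lab > 0) / length(lab))
}

#' Classify mitochondria as regular or enlarged by area threshold
#'
#' @param objects an object table with column \code{area_um2}.
#' @param area_threshold_um2 objects strictly above this area are classed
#'   \code{"enlarged"} (>= 0).
#' @return list(enlarged_count, fraction (0 when the table is empty),
#'   objects with a \code{class} column).
#' @export
classify_enlarged <- function(objects, area_threshold_um2) {
  stopifnot(is.data.frame(objects), "area_um2" %in% names(objects))
  if (area_threshold_um2 < 0) stop("area threshold must be non-negative")
  cls <- ifelse(objects$area_um2 > area_threshold_um2, "enlarged", "regular")
  objects$class <- cls
  n <- nrow(objects)
  list(enlarged_count = sum(cls == "enlarged"),
       fraction = if (n > 0) sum(cls == "enlarged") / n else 0,
       objects = objects)
}

#' Default enlarged-mitochondrion area threshold from control fields
#'
#' The area cutoff separating regular from enlarged mitochondria is not a
#' universal constant; by default it is taken as the 97.5th percentile of
#' object areas observed in untreated control fields, recomputed per
#' experiment.
#'
#' @param control_areas_um2 vector of object areas from control fields.
#' @param prob percentile (default 0.975).
#' @return area threshold in um^2.
#' @export
enlarged_threshold <- function(control_areas_um2, prob = 0.975) {
  stopifnot(length(control_areas_um2) > 0, prob > 0, prob < 1)
  as.numeric(stats::quantile(control_areas_um2, prob))
}

#' Count large puncta (e.g. autophagosomes)
#'
#' Thresholds the image at an intensity quantile and counts connected
#' components with area at least \code{min_area_um2}.
#'
#' @param image calibrated channel image.
#' @param pixel_size_um um per pixel.
#' @param min_area_um2 minimum punctum area.
#' @param intensity_quantile threshold quantile in (0, 1) (default 0.99).
#' @return list(count, objects, label_map).
#' @export
count_large_puncta <- function(image, pixel_size_um, min_area_um2,
                               intensity_quantile = 0.99) {
  stopifnot(is.matrix(image), pixel_size_um > 0, min_area_um2 >= 0)
  if (intensity_quantile <= 0 || intensity_quantile >= 1)
    stop("intensity_quantile must lie strictly inside (0, 1)")
  thr <- stats::quantile(image, intensity_quantile)
  mask <- image > thr
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  min_px <- max(1L, round(min_area_um2 / pixel_size_um^2))
  cnt <- table(lab[lab > 0])
  keep <- as.integer(names(cnt)[cnt >= min_px])
  lab[!(lab %in% keep)] <- 0L
  lab <- .relabel(matrix(as.integer(lab), nrow(image), ncol(image)))
  tab <- .object_table(lab, pixel_size_um)
  list(count = nrow(tab), objects = tab, label_map = lab)
}

#' Summarize a monolayer field into standard metrics
#'
#' @param nuclei result of \code{\link{count_nuclei}} (or NULL).
#' @param domes result of \code{\link{segment_domes}} (or NULL).
#' @param mito result of \code{\link{segment_mitochondria}} (or NULL).
#' @param enlarged result of \code{\link{classify_enlarged}} (or NULL).
#' @param puncta result of \code{\link{count_large_puncta}} (or NULL).
#' @return one-row data.frame of monolayer metrics (NA where a component
#'   was not measured).
#' @export
monolayer_metrics <- function(nuclei = NULL, domes = NULL, mito = NULL,
                              enlarged = NULL, puncta = NULL) {
  data.frame(
    nuclei_count = if (is.null(nuclei)) NA_integer_ else nuclei$count,
    total_dome_area_um2 =
      if (is.null(domes)) NA_real_ else domes$total_dome_area_um2,
    dome_count = if (is.null(domes)) NA_integer_ else domes$dome_count,
    mito_footprint = if (is.null(mito)) NA_real_ else mito$mito_footprint,
    enlarged_mito_count =
      if (is.null(enlarged)) NA_integer_ else enlarged$enlarged_count,
    enlarged_mito_fraction =
      if (is.null(enlarged)) NA_real_ else enlarged$fraction,
    autophagosome_count = if (is.null(puncta)) NA_integer_ else puncta$count)
}
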