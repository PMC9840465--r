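# Synthetic monolayer scenes with known ground truth.
#
# Geometry conventions used throughout the package:
#  - images are R matrices indexed [row, col]; pixel (i, j) covers the
#    half-open physical square [(j-1)*px, j*px) x [(i-1)*px, i*px) um,
#    origin at the top-left corner; centroids are reported at pixel centers;
#  - z plane k (k = 0 .. n_planes-1) sits at height k * z_step_um, plane 0
#    being the culture-plate surface (lowest plane).

#' Synthetic scene parameters
#'
#' Bundles and validates every knob of the synthetic monolayer generator.
#' Defaults emulate a single stitched field of a differentiated renal
#' proximal-tubule monolayer imaged in 5 um z-steps: a 512 um field at
#' 1 um/px with nuclei and a few fluid domes tens of micrometers tall.
#' Fine-pixel presets (small \code{field_size_um}, small
#' \code{pixel_size_um}) are appropriate for mitochondria and autophagosome
#' fields.
#'
#' @param field_size_um length of the square field side, um.
#' @param pixel_size_um um per pixel (> 0).
#' @param z_step_um z-stack step, um (default 5).
#' @param n_planes number of z planes (default 20).
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_radius_um range c(lo, hi) of nucleus radii, um.
#' @param nucleus_sep_diameters minimum centre separation between nuclei, in
#'   units of the maximum nucleus diameter (default 1).
#' @param dome_specs optional list of domes, each
#'   \code{list(center = c(x_um, y_um), radius_um, apex_height_um)}; when
#'   NULL, \code{n_domes} domes with radii in \code{dome_radius_um} and apex
#'   \code{dome_apex_um} are placed at random without overlap.
#' @param n_domes,dome_radius_um,dome_apex_um random-dome parameters used
#'   when \code{dome_specs} is NULL. The default apex of 40 um (8 z-steps)
#'   reflects that fluid domes lift the monolayer by tens of micrometers --
#'   the reason 20-50 plane stacks are acquired at all -- and keeps the dome
#'   rim, where the cap tapers toward the base, resolvable above the
#'   half-z-step height-quantization floor.
#' @param mito_density mitochondria per 100 um^2 of field area.
#' @param enlarged_fraction fraction of mitochondria drawn from the enlarged
#'   size range, in [0, 1].
#' @param regular_area_um2,enlarged_area_um2 area ranges c(lo, hi) for
#'   regular and enlarged mitochondria; the ranges must not overlap and the
#'   enlarged range must lie strictly above the regular one.
#' @param n_autophagosomes number of autophagosome puncta.
#' @param autophagosome_area_um2 area range for puncta, um^2.
#' @param blur_rate_px_per_um defocus blur coefficient: Gaussian blur sigma
#'   in px per um of distance between a z plane and the local surface.
#' @param noise c(gaussian_sd, poisson_scale): read-noise standard deviation
#'   (intensity units, image scale [0, 1]) and shot-noise photon count at
#'   unit intensity (0 disables the Poisson component).
#' @param seed integer seed for the scene's pseudo-random stream.
#' @return validated list of class \code{"scene_pars"}.
#' @export
scene_pars <- function(field_size_um = 512, pixel_size_um = 1,
                       z_step_um = 5, n_planes = 20,
                       n_nuclei = 150, nucleus_radius_um = c(5, 7),
                       nucleus_sep_diameters = 1,
                       dome_specs = NULL, n_domes = 3,
                       dome_radius_um = c(45, 60), dome_apex_um = 40,
                       mito_density = 0, enlarged_fraction = 0.2,
                       regular_area_um2 = c(0.4, 1.5),
                       enlarged_area_um2 = c(2.5, 6),
                       n_autophagosomes = 0,
                       autophagosome_area_um2 = c(0.5, 3),
                       blur_rate_px_per_um = 0.5,
                       noise = c(gaussian_sd = 0.01, poisson_scale = 200),
                       seed = 1L) {
  stopifnot(pixel_size_um > 0, z_step_um > 0, field_size_um > 0,
            n_planes >= 1, n_nuclei >= 0, n_autophagosomes >= 0,
            mito_density >= 0, enlarged_fraction >= 0, enlarged_fraction <= 1,
            blur_rate_px_per_um >= 0, length(noise) == 2, all(noise >= 0),
            nucleus_sep_diameters >= 0,
            length(nucleus_radius_um) == 2,
            diff(nucleus_radius_um) >= 0, nucleus_radius_um[1] > 0)
  if (!(enlarged_area_um2[1] > regular_area_um2[2]))
    stop("enlarged mitochondrion area range must lie strictly above ",
         "the regular range")
  pars <- list(
    field_size_um = field_size_um, pixel_size_um = pixel_size_um,
    z_step_um = z_step_um, n_planes = as.integer(n_planes),
    n_nuclei = as.integer(n_nuclei), nucleus_radius_um = nucleus_radius_um,
    nucleus_sep_diameters = nucleus_sep_diameters,
    dome_specs = dome_specs, n_domes = as.integer(n_domes),
    dome_radius_um = dome_radius_um, dome_apex_um = dome_apex_um,
    mito_density = mito_density, enlarged_fraction = enlarged_fraction,
    regular_area_um2 = regular_area_um2, enlarged_area_um2 = enlarged_area_um2,
    n_autophagosomes = as.integer(n_autophagosomes),
    autophagosome_area_um2 = autophagosome_area_um2,
    blur_rate_px_per_um = blur_rate_px_per_um,
    noise = c(gaussian_sd = unname(noise[1]),
              poisson_scale = unname(noise[2])),
    seed = as.integer(seed))
  if (!is.null(dome_specs)) .check_dome_specs(dome_specs, pars)
  class(pars) <- "scene_pars"
  pars
}

.check_dome_specs <- function(specs, pars) {
  for (d in specs) {
    stopifnot(length(d$center) == 2, d$radius_um > 0, d$apex_height_um > 0)
    if (d$apex_height_um > d$radius_um)
      stop("dome apex height must not exceed its radius ",
           "(spherical cap would overhang)")
    if (any(d$center - d$radius_um < 0) ||
        any(d$center + d$radius_um > pars$field_size_um))
      stop("dome does not fit inside the field")
  }
  invisible(TRUE)
}

# Rejection-sample n centre points in [margin, field-margin]^2 with pairwise
# minimum separation; errors with the object class name when the field is
# too crowded to place them all.
.place_points <- function(n, field_um, min_sep_um, margin_um, what,
                          max_tries = 5000L) {
  if (n == 0) return(matrix(numeric(0), ncol = 2,
                            dimnames = list(NULL, c("x", "y"))))
  lo <- margin_um; hi <- field_um - margin_um
  if (hi <= lo) stop("field too small to place ", what)
  pts <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      p <- stats::runif(2, lo, hi)
      if (i == 1 ||
          min((pts[seq_len(i - 1), 1] - p[1])^2 +
              (pts[seq_len(i - 1), 2] - p[2])^2) >= min_sep_um^2) {
        pts[i, ] <- p; ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place ", what,
                  ": field too crowded (placed ", i - 1, " of ", n, ")")
  }
  pts
}

# Pixel-centre coordinate grids in um for a npx x npx field.
.coord_grids <- function(npx, px) {
  cc <- (seq_len(npx) - 0.5) * px
  list(x = matrix(cc, npx, npx, byrow = TRUE),
       y = matrix(cc, npx, npx, byrow = FALSE))
}

# Add a soft-edged disc (logistic profile) to an image, in place.
.draw_disc <- function(img, grids, cx, cy, r_um, value, edge_um) {
  d <- sqrt((grids$x - cx)^2 + (grids$y - cy)^2)
  img + value / (1 + exp((d - r_um) / edge_um))
}

# Hard-rasterized disc mask (pixel centre within radius).
.disc_mask <- function(grids, cx, cy, r_um) {
  (grids$x - cx)^2 + (grids$y - cy)^2 <= r_um^2
}

# Spherical-cap height profile: cap of base radius R and apex height h
# (h <= R), evaluated at radial distance d from the centre.
.cap_height <- function(d, R, h) {
  Rs <- (R^2 + h^2) / (2 * h)
  z <- sqrt(pmax(Rs^2 - d^2, 0)) - (Rs - h)
  ifelse(d <= R, pmax(z, 0), 0)
}

#' Generate a ground-truth synthetic monolayer scene
#'
#' Places nuclei, domes, mitochondria and autophagosome puncta; builds the
#' monolayer surface height map (flat base plus spherical-cap domes) and
#' sharp, noise-free "ideal" images for each channel. Rendering through the
#' defocus optics is a separate step (\code{\link{render_zstack}}).
#'
#' All randomness derives from a single stream seeded with \code{pars$seed};
#' per-channel render substream seeds are derived deterministically and
#' stored in the result, so identical parameters give bit-identical scenes.
#'
#' @param pars a \code{\link{scene_pars}} object.
#' @return list of class \code{"scene"} with elements
#'   \describe{
#'     \item{truth}{ground truth: \code{nuclei} (centroid matrix, um),
#'       \code{domes} (data.frame center_x/center_y/radius_um/apex_height_um),
#'       \code{mito} (data.frame centroid, rasterized area_um2, class),
#'       \code{autophagosomes}, and \code{true_total_dome_area_um2}
#'       (analytic sum of pi r^2).}
#'     \item{surface}{list(height_um matrix, base_height_um).}
#'     \item{ideal}{named list of sharp channel images in [0, 1]:
#'       brightfield, nuclear, mito, autophagosome.}
#'     \item{pars, channel_seeds}{inputs and derived render seeds.}
#'   }
#' @export
generate_scene <- function(pars) {
  stopifnot(inherits(pars, "scene_pars"))
  set.seed(pars$seed)
  channels <- c("brightfield", "nuclear", "mito", "autophagosome")
  channel_seeds <- stats::setNames(
    sample.int(.Machine$integer.max - 1L, length(channels)), channels)
  px <- pars$pixel_size_um
  npx <- round(pars$field_size_um / px)
  grids <- .coord_grids(npx, px)

  ## domes
  domes <- pars$dome_specs
  if (is.null(domes) && pars$n_domes > 0) {
    rads <- stats::runif(pars$n_domes, pars$dome_radius_um[1],
                         pars$dome_radius_um[2])
    margin <- max(rads) + px
    ctr <- .place_points(pars$n_domes, pars$field_size_um,
                         min_sep_um = 2 * max(rads) + 2 * px,
                         margin_um = margin, what = "domes")
    domes <- lapply(seq_len(pars$n_domes), function(i)
      list(center = ctr[i, ], radius_um = rads[i],
           apex_height_um = min(pars$dome_apex_um, rads[i])))
  }
  if (is.null(domes)) domes <- list()
  .check_dome_specs(domes, pars)

  height <- matrix(0, npx, npx)
  for (d in domes) {
    dist <- sqrt((grids$x - d$center[1])^2 + (grids$y - d$center[2])^2)
    height <- pmax(height, .cap_height(dist, d$radius_um, d$apex_height_um))
  }
  surface <- list(height_um = height, base_height_um = 0)
  dome_df <- if (length(domes)) data.frame(
    center_x_um = vapply(domes, function(d) d$center[1], 0),
    center_y_um = vapply(domes, function(d) d$center[2], 0),
    radius_um = vapply(domes, function(d) d$radius_um, 0),
    apex_height_um = vapply(domes, function(d) d$apex_height_um, 0)
  ) else data.frame(center_x_um = numeric(0), center_y_um = numeric(0),
                    radius_um = numeric(0), apex_height_um = numeric(0))

  ## nuclei
  r_nuc <- if (pars$n_nuclei > 0)
    stats::runif(pars$n_nuclei, pars$nucleus_radius_um[1],
                 pars$nucleus_radius_um[2]) else numeric(0)
  sep <- pars$nucleus_sep_diameters * 2 * max(pars$nucleus_radius_um)
  nuc <- .place_points(pars$n_nuclei, pars$field_size_um, min_sep_um = sep,
                       margin_um = max(pars$nucleus_radius_um) + px,
                       what = "nuclei")

  ## mitochondria
  n_mito <- round(pars$mito_density * pars$field_size_um^2 / 100)
  mito <- .place_objects_with_area(
    n = n_mito, enlarged_fraction = pars$enlarged_fraction,
    regular = pars$regular_area_um2, enlarged = pars$enlarged_area_um2,
    field_um = pars$field_size_um, px = px, what = "mitochondria")

  ## autophagosomes
  auto <- .place_objects_with_area(
    n = pars$n_autophagosomes, enlarged_fraction = 0,
    regular = pars$autophagosome_area_um2, enlarged = c(Inf, Inf),
    field_um = pars$field_size_um, px = px, what = "autophagosomes")

  ## ideal channel images
  set.seed(channel_seeds[["brightfield"]])
  tex <- matrix(stats::rnorm(npx * npx), npx, npx)
  tex <- as.matrix(EBImage::gblur(tex, sigma = 1))
  tex <- (tex - mean(tex)) / stats::sd(tex)
  brightfield <- pmin(pmax(0.5 + 0.17 * tex, 0.02), 0.98)

  nuclear <- matrix(0.02, npx, npx)
  if (pars$n_nuclei > 0)
    for (i in seq_len(pars$n_nuclei))
      nuclear <- .draw_disc(nuclear, grids, nuc[i, 1], nuc[i, 2],
                            r_nuc[i], 0.9, edge_um = 0.8 * px)
  nuclear <- pmin(nuclear, 1)

  draw_objects <- function(tab) {
    img <- matrix(0.02, npx, npx)
    areas <- numeric(nrow(tab))
    if (nrow(tab)) for (i in seq_len(nrow(tab))) {
      r <- sqrt(tab$area_um2[i] / pi)
      img <- .draw_disc(img, grids, tab$x[i], tab$y[i], r, 0.9,
                        edge_um = 0.5 * px)
      areas[i] <- sum(.disc_mask(grids, tab$x[i], tab$y[i], r)) * px^2
    }
    list(img = pmin(img, 1), raster_area = areas)
  }
  md <- draw_objects(mito)
  ad <- draw_objects(auto)
  mito$area_um2 <- md$raster_area    # rasterized area: what a perfect
  auto$area_um2 <- ad$raster_area    # segmenter of the pixel grid recovers

  truth <- list(
    nuclei = nuc,
    domes = dome_df,
    mito = mito[, c("x", "y", "area_um2", "class")],
    autophagosomes = auto[, c("x", "y", "area_um2")],
    true_total_dome_area_um2 = sum(pi * dome_df$radius_um^2))

  structure(list(
    truth = truth, surface = surface,
    ideal = list(brightfield = brightfield, nuclear = nuclear,
                 mito = md$img, autophagosome = ad$img),
    pars = pars, channel_seeds = channel_seeds),
    class = "scene")
}

# Place n objects with target areas drawn from the regular/enlarged ranges;
# returns data.frame(x, y, area_um2 (target), class). Separation keeps
# rendered discs from touching.
.place_objects_with_area <- function(n, enlarged_fraction, regular, enlarged,
                                     field_um, px, what) {
  if (n == 0)
    return(data.frame(x = numeric(0), y = numeric(0), area_um2 = numeric(0),
                      class = character(0), stringsAsFactors = FALSE))
  n_enl <- round(enlarged_fraction * n)
  cls <- c(rep("enlarged", n_enl), rep("regular", n - n_enl))
  area <- ifelse(cls == "enlarged",
                 stats::runif(n, enlarged[1], enlarged[2]),
                 stats::runif(n, regular[1], regular[2]))
  rmax <- sqrt(max(area) / pi)
  pts <- .place_points(n, field_um, min_sep_um = 2 * rmax + 3 * px,
                       margin_um = rmax + 2 * px, what = what)
  data.frame(x = pts[, 1], y = pts[, 2], area_um2 = area, class = cls,
             stringsAsFactors = FALSE)
}

#' Rasterized dome mask of a scene surface
#'
#' @param surface a scene \code{surface} list (height_um, base_height_um).
#' @return logical matrix: TRUE where the surface is above its base.
#' @export
dome_mask <- function(surface) {
  surface$height_um > surface$base_height_um
}
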