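# File layouts: multi-page TIFF per tile and channel (plane order = z
# ascending), float-32 composites, 16-bit integer height-maps, CSV tables,
# JSON metadata sidecars.

#' Write a z-stack as a multi-page TIFF
#'
#' Planes are written in ascending z order as 32-bit float pages.
#'
#' @param stack a \code{\link{zstack}}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_zstack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "zstack"))
  pages <- lapply(seq_len(dim(stack$data)[3]),
                  function(k) stack$data[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a multi-page TIFF as a z-stack
#'
#' @param path TIFF file.
#' @param z_step_um,pixel_size_um,channel calibration and label to attach.
#' @return a \code{\link{zstack}}.
#' @export
read_zstack_tiff <- function(path, z_step_um, pixel_size_um,
                             channel = "brightfield") {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  zstack(arr, z_step_um, pixel_size_um, channel)
}

#' Write a 2D image as TIFF
#'
#' Intensity images are written as 32-bit float; integer height-maps
#' (\code{integer = TRUE}) as 16-bit unsigned plane indices.
#'
#' @param image matrix; for \code{integer = TRUE}, non-negative integers
#'   < 65536.
#' @param path output path.
#' @param integer write as 16-bit integer map (default FALSE).
#' @return the path, invisibly.
#' @export
write_image_tiff <- function(image, path, integer = FALSE) {
  if (integer) {
    stopifnot(all(image >= 0), all(image < 65536))
    tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L)
  } else {
    tiff::writeTIFF(pmin(pmax(image, 0), 1), path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read a 2D TIFF image
#'
#' @param path TIFF file.
#' @param integer read back a 16-bit integer map (default FALSE).
#' @return matrix.
#' @export
read_image_tiff <- function(path, integer = FALSE) {
  if (integer) {
    m <- tiff::readTIFF(path, as.is = TRUE)
    matrix(as.integer(m), nrow(m), ncol(m))
  } else {
    tiff::readTIFF(path)
  }
}

#' Write a scene's tiles, ground truth and metadata to disk
#'
#' Layout under \code{dir}: \code{<channel>_r<i>_c<j>.tif} multi-page tile
#' stacks, \code{ground_truth.csv} (object class, centroid, size, height)
#' and \code{metadata.json} (calibration, grid, overlap, seed).
#'
#' @param scene a \code{\link{generate_scene}} result.
#' @param stacks named list of \code{\link{zstack}}s (one per channel).
#' @param grid,overlap_fraction tiling parameters.
#' @param dir output directory (created if needed).
#' @return list(tile_files, truth_file, metadata_file), invisibly.
#' @export
write_scene_tiles <- function(scene, stacks, grid, overlap_fraction, dir) {
  stopifnot(inherits(scene, "scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (ch in names(stacks)) {
    ts <- tile_mosaic(stacks[[ch]]$data, grid, overlap_fraction)
    for (tl in ts$tiles) {
      f <- file.path(dir, sprintf("%s_r%d_c%d.tif", ch, tl$row, tl$col))
      write_zstack_tiff(zstack(tl$data, stacks[[ch]]$z_step_um,
                               stacks[[ch]]$pixel_size_um, ch), f)
      files <- c(files, f)
    }
  }
  tr <- scene$truth
  gt <- rbind(
    if (nrow(tr$nuclei)) data.frame(class = "nucleus",
      x_um = tr$nuclei[, 1], y_um = tr$nuclei[, 2],
      size_um = NA_real_, height_um = NA_real_),
    if (nrow(tr$domes)) data.frame(class = "dome",
      x_um = tr$domes$center_x_um, y_um = tr$domes$center_y_um,
      size_um = tr$domes$radius_um, height_um = tr$domes$apex_height_um),
    if (nrow(tr$mito)) data.frame(class = paste0("mito_", tr$mito$class),
      x_um = tr$mito$x, y_um = tr$mito$y,
      size_um = tr$mito$area_um2, height_um = NA_real_),
    if (nrow(tr$autophagosomes)) data.frame(class = "autophagosome",
      x_um = tr$autophagosomes$x, y_um = tr$autophagosomes$y,
      size_um = tr$autophagosomes$area_um2, height_um = NA_real_))
  truth_file <- file.path(dir, "ground_truth.csv")
  utils::write.csv(gt, truth_file, row.names = FALSE)
  meta <- list(pixel_size_um = scene$pars$pixel_size_um,
               z_step_um = scene$pars$z_step_um,
               n_planes = scene$pars$n_planes,
               field_size_um = scene$pars$field_size_um,
               grid = as.integer(grid), overlap_fraction = overlap_fraction,
               seed = scene$pars$seed,
               channels = names(stacks),
               true_total_dome_area_um2 = tr$true_total_dome_area_um2)
  metadata_file <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, metadata_file, auto_unbox = TRUE, digits = NA)
  invisible(list(tile_files = files, truth_file = truth_file,
                 metadata_file = metadata_file))
}

#' Read tiles written by \code{\link{write_scene_tiles}} as a tile set
#'
#' @param dir tile directory containing \code{metadata.json}.
#' @param channel channel to load.
#' @return a tile set (as \code{\link{tile_mosaic}} produces) of z-stack
#'   arrays, plus attached metadata.
#' @export
read_scene_tiles <- function(dir, channel = "brightfield") {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  g <- meta$grid
  field_px <- round(meta$field_size_um / meta$pixel_size_um)
  geom <- lapply(1:2, function(d)
    .tile_geometry(field_px, g[d], meta$overlap_fraction))
  tiles <- list()
  for (i in seq_len(g[1])) for (j in seq_len(g[2])) {
    f <- file.path(dir, sprintf("%s_r%d_c%d.tif", channel, i, j))
    zs <- read_zstack_tiff(f, meta$z_step_um, meta$pixel_size_um, channel)
    tiles[[length(tiles) + 1L]] <- list(
      data = zs$data, row = i, col = j,
      offset_px = c(dy = geom[[1]]$stride * (i - 1),
                    dx = geom[[2]]$stride * (j - 1)))
  }
  structure(list(tiles = tiles, grid = g,
                 overlap_fraction = meta$overlap_fraction,
                 tile_px = c(geom[[1]]$tile, geom[[2]]$tile),
                 stride_px = c(geom[[1]]$stride, geom[[2]]$stride),
                 full_dim = c(field_px, field_px), metadata = meta),
            class = "tile_set")
}
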