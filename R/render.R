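# Optical render model: a z-stack of an ideal (sharp) image seen through a
# microscope focused at successive planes. Defocus is modelled as an
# isotropic Gaussian PSF whose sigma grows linearly with the distance
# between the focal plane and the local specimen surface.

# Gaussian blur returning a plain matrix; sigma 0 is the identity.
.gblur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  rmax <- min(dim(m)) - 1L
  if (rmax %% 2L == 0L) rmax <- rmax - 1L
  EBImage::imageData(EBImage::gblur(m, sigma = sigma, radius = min(r, rmax)))
}

#' Construct a z-stack container
#'
#' @param data numeric array rows x cols x planes (plane 1 = lowest z).
#' @param z_step_um,pixel_size_um calibration.
#' @param channel channel label.
#' @return list of class \code{"zstack"}.
#' @export
zstack <- function(data, z_step_um, pixel_size_um, channel = "brightfield") {
  stopifnot(length(dim(data)) == 3, all(data >= 0),
            z_step_um > 0, pixel_size_um > 0)
  structure(list(data = data, z_step_um = z_step_um,
                 pixel_size_um = pixel_size_um, channel = channel),
            class = "zstack")
}

#' Render an ideal image into a defocus z-stack
#'
#' For each plane k at height \code{k * z_step_um} the per-pixel blur sigma
#' is \code{blur_rate_px_per_um * |z_plane - surface_height|}; the plane at
#' the local surface height is therefore the sharpest. Gaussian read noise
#' and Poisson shot noise are applied after blurring, and intensities are
#' clipped to [0, 1] (detector range). For tractability, per-pixel sigmas
#' are quantized to \code{sigma_quantum} px bins; the image is blurred once
#' per distinct bin and pixels are assembled from the matching bin.
#'
#' @param ideal sharp 2D image (matrix, values in [0, 1]).
#' @param surface scene surface list (height_um, base_height_um) with the
#'   same geometry as \code{ideal}.
#' @param pars a \code{\link{scene_pars}} (z_step_um, n_planes,
#'   blur_rate_px_per_um, noise, pixel_size_um are used).
#' @param channel channel label; also selects the deterministic noise
#'   substream (a scene's \code{channel_seeds}).
#' @param noise_seed explicit noise seed; overrides the derived substream.
#' @param noise apply noise? Set FALSE for noise-free renders.
#' @param sigma_quantum blur-sigma quantization step in px (default 0.5).
#' @return a \code{\link{zstack}}.
#' @export
render_zstack <- function(ideal, surface, pars, channel = "brightfield",
                          noise_seed = NULL, noise = TRUE,
                          sigma_quantum = 0.5) {
  stopifnot(inherits(pars, "scene_pars"), is.matrix(ideal),
            all(dim(ideal) == dim(surface$height_um)))
  h <- surface$height_um
  zmax <- (pars$n_planes - 1) * pars$z_step_um
  if (max(h) > zmax)
    stop("z range (", pars$n_planes, " planes x ", pars$z_step_um,
         " um) does not cover the maximum surface height (", max(h), " um)")
  if (is.null(noise_seed))
    noise_seed <- (pars$seed * 7919L +
                     utf8ToInt(substr(channel, 1, 1)) * 104729L) %%
      (.Machine$integer.max - 1L) + 1L

  rate <- pars$blur_rate_px_per_um
  planes <- array(0, dim = c(nrow(ideal), ncol(ideal), pars$n_planes))
  # blur bank shared across planes: one blurred copy per quantized sigma
  bank <- new.env(parent = emptyenv())
  get_blur <- function(s) {
    key <- format(s)
    if (is.null(bank[[key]])) bank[[key]] <- .gblur(ideal, s)
    bank[[key]]
  }
  for (k in seq_len(pars$n_planes)) {
    z <- (k - 1) * pars$z_step_um
    sig <- rate * abs(z - h)
    bin <- round(sig / sigma_quantum) * sigma_quantum
    plane <- ideal
    for (s in sort(unique(as.vector(bin)))) {
      if (s == 0) next
      idx <- bin == s
      plane[idx] <- get_blur(s)[idx]
    }
    planes[, , k] <- plane
  }
  if (noise) {
    set.seed(noise_seed)
    g_sd <- pars$noise[["gaussian_sd"]]
    p_sc <- pars$noise[["poisson_scale"]]
    n <- length(planes)
    if (p_sc > 0)
      planes[] <- stats::rpois(n, lambda = pmax(planes, 0) * p_sc) / p_sc
    if (g_sd > 0)
      planes[] <- planes + stats::rnorm(n, sd = g_sd)
    planes[] <- pmin(pmax(planes, 0), 1)
  }
  zstack(planes, pars$z_step_um, pars$pixel_size_um, channel)
}

#' Cut an image or z-stack into an overlapping tile grid
#'
#' Tiles are laid out on a regular grid; adjacent tiles share
#' \code{overlap_fraction} of their width/height. The tile side t must
#' satisfy \code{(g - 1) * t * (1 - f) + t = image side} with both t and the
#' stride \code{t * (1 - f)} integer; otherwise an error suggests the
#' nearest valid image side. Pasting tiles back at their nominal offsets
#' reproduces the input exactly.
#'
#' @param x 2D matrix, 3D array (rows x cols x planes) or \code{\link{zstack}}.
#' @param grid c(rows, cols) of the tile grid.
#' @param overlap_fraction fraction of tile side shared by neighbours,
#'   in [0, 0.5).
#' @return list of class \code{"tile_set"}: \code{tiles} (each with
#'   \code{data}, grid position \code{row}/\code{col}, and 0-based nominal
#'   \code{offset_px} c(dy, dx)), plus \code{grid}, \code{overlap_fraction},
#'   \code{tile_px}, \code{stride_px}, \code{full_dim}.
#' @export
tile_mosaic <- function(x, grid = c(2, 2), overlap_fraction = 0.125) {
  stopifnot(length(grid) == 2, all(grid >= 1),
            overlap_fraction >= 0, overlap_fraction < 0.5)
  zs <- inherits(x, "zstack")
  data <- if (zs) x$data else x
  dims <- dim(data)
  stopifnot(length(dims) %in% c(2, 3))
  geom <- lapply(1:2, function(d)
    .tile_geometry(dims[d], grid[d], overlap_fraction))
  tiles <- list()
  for (i in seq_len(grid[1])) for (j in seq_len(grid[2])) {
    oy <- geom[[1]]$stride * (i - 1)
    ox <- geom[[2]]$stride * (j - 1)
    rows <- (oy + 1):(oy + geom[[1]]$tile)
    cols <- (ox + 1):(ox + geom[[2]]$tile)
    td <- if (length(dims) == 2) data[rows, cols, drop = FALSE]
          else data[rows, cols, , drop = FALSE]
    tiles[[length(tiles) + 1L]] <-
      list(data = td, row = i, col = j, offset_px = c(dy = oy, dx = ox))
  }
  structure(list(tiles = tiles, grid = grid,
                 overlap_fraction = overlap_fraction,
                 tile_px = c(geom[[1]]$tile, geom[[2]]$tile),
                 stride_px = c(geom[[1]]$stride, geom[[2]]$stride),
                 full_dim = dims[1:2]),
            class = "tile_set")
}

.tile_geometry <- function(side, g, f) {
  if (g == 1) return(list(tile = side, stride = side))
  denom <- (g - 1) * (1 - f) + 1
  tile <- side / denom
  stride <- tile * (1 - f)
  if (abs(tile - round(tile)) > 1e-9 || abs(stride - round(stride)) > 1e-9) {
    # nearest valid side: scan tile sizes with integer stride
    cand <- unique(round(tile) + -8:8)
    cand <- cand[cand > 0]
    ok <- cand[abs(cand * (1 - f) - round(cand * (1 - f))) < 1e-9]
    sug <- if (length(ok)) ok[which.min(abs(ok * denom - side))] else round(tile)
    stop("tile geometry is not integral for side ", side, ", grid ", g,
         ", overlap ", f, "; nearest valid side is ", round(sug * denom),
         " px (tile ", sug, " px)")
  }
  list(tile = as.integer(round(tile)), stride = as.integer(round(stride)))
}

#' Paste tiles back at given offsets (last-write-wins)
#'
#' Utility used for exact reassembly checks; for blended mosaics see
#' \code{\link{stitch}}.
#'
#' @param tile_set a \code{\link{tile_mosaic}} result.
#' @return array/matrix of the reassembled full image.
#' @export
paste_tiles <- function(tile_set) {
  stopifnot(inherits(tile_set, "tile_set"))
  t1 <- tile_set$tiles[[1]]$data
  dims <- dim(t1)
  full <- if (length(dims) == 2)
    matrix(0, tile_set$full_dim[1], tile_set$full_dim[2])
  else array(0, c(tile_set$full_dim, dims[3]))
  for (tl in tile_set$tiles) {
    rows <- (tl$offset_px[1] + 1):(tl$offset_px[1] + dim(tl$data)[1])
    cols <- (tl$offset_px[2] + 1):(tl$offset_px[2] + dim(tl$data)[2])
    if (length(dims) == 2) full[rows, cols] <- tl$data
    else full[rows, cols, ] <- tl$data
  }
  full
}
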