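# Extended-depth-of-field reconstruction: fuse a z-stack into an
# all-in-focus composite plus a topography height-map (the per-pixel index
# of the most in-focus plane), then stitch tiled fields into a mosaic.

# Reflection-pad a matrix by k pixels on every side (edge not duplicated).
.pad_reflect <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(k < nr, k < nc)
  ri <- c((k + 1):2, 1:nr, (nr - 1):(nr - k))
  ci <- c((k + 1):2, 1:nc, (nc - 1):(nc - k))
  m[ri, ci]
}

# Box-window mean via integral image on a reflection-padded input; exact
# and fast, window w odd.
.box_mean <- function(m, w) {
  k <- (w - 1L) %/% 2L
  p <- .pad_reflect(m, k)
  s <- apply(apply(p, 2, cumsum), 1, cumsum)  # s = t(cumsum rows of colcumsum)
  s <- t(s)
  s <- rbind(0, cbind(0, s))
  nr <- nrow(m); nc <- ncol(m)
  i1 <- 1:nr; j1 <- 1:nc
  (s[i1 + w, j1 + w, drop = FALSE] - s[i1, j1 + w, drop = FALSE] -
      s[i1 + w, j1, drop = FALSE] + s[i1, j1, drop = FALSE]) / (w * w)
}

.sobel_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)

# 3x3 convolution with reflection padding (kernels here are small).
.conv3 <- function(m, k) {
  p <- .pad_reflect(m, 1L)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1)
    out <- out + k[di + 2, dj + 2] *
      p[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj), drop = FALSE]
  out
}

#' Per-pixel focus score of an image
#'
#' \code{"variance"} is the local intensity variance in a square window;
#' \code{"tenengrad"} is the window mean of the squared Sobel gradient
#' magnitude. Both are non-negative, zero on constant images, and
#' translation-equivariant away from borders (borders use reflection
#' padding).
#'
#' @param image 2D numeric matrix.
#' @param method \code{"variance"} (default) or \code{"tenengrad"}.
#' @param window_px odd window side >= 3 and not larger than the image.
#' @return matrix of focus scores, same shape as \code{image}.
#' @export
focus_measure <- function(image, method = c("variance", "tenengrad"),
                          window_px = 7L) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), window_px >= 3, window_px %% 2 == 1)
  if (window_px > min(dim(image)))
    stop("focus window (", window_px, " px) larger than the image")
  switch(method,
    variance = {
      m <- .box_mean(image, window_px)
      m2 <- .box_mean(image^2, window_px)
      pmax(m2 - m^2, 0)
    },
    tenengrad = {
      gx <- .conv3(image, .sobel_x)
      gy <- .conv3(image, t(.sobel_x))
      .box_mean(gx^2 + gy^2, window_px)
    })
}

#' Extended-depth-of-field composition of a z-stack
#'
#' Scores every plane with \code{\link{focus_measure}}, takes the per-pixel
#' argmax over z (ties resolved to the lowest plane index), median-smooths
#' the resulting index map, and samples the composite from the smoothed
#' indices.
#'
#' @param stack a \code{\link{zstack}} (or rows x cols x planes array).
#' @param method,window_px passed to \code{\link{focus_measure}}.
#' @param smooth_radius_px radius of the median filter applied to the raw
#'   argmax index map (0 disables smoothing).
#' @return list of class \code{"composite_result"}: \code{composite} (2D),
#'   \code{height_map} (integer plane indices, 0-based), \code{focus_quality}
#'   (max focus score), \code{z_step_um}, \code{pixel_size_um}.
#' @export
edf_compose <- function(stack, method = "variance", window_px = 7L,
                        smooth_radius_px = 2L) {
  if (inherits(stack, "zstack")) {
    data <- stack$data; z_step <- stack$z_step_um; px <- stack$pixel_size_um
  } else {
    data <- stack; z_step <- 1; px <- 1
  }
  stopifnot(length(dim(data)) == 3)
  n <- dim(data)[3]
  if (n < 2) {
    warning("single-plane stack: passthrough composite, constant height-map")
    return(structure(list(composite = data[, , 1],
                          height_map = matrix(0L, dim(data)[1], dim(data)[2]),
                          focus_quality = focus_measure(data[, , 1],
                                                        window_px = window_px),
                          z_step_um = z_step, pixel_size_um = px),
                     class = "composite_result"))
  }
  best_score <- focus_measure(data[, , 1], method, window_px)
  hm <- matrix(0L, dim(data)[1], dim(data)[2])
  for (k in 2:n) {
    sc <- focus_measure(data[, , k], method, window_px)
    upd <- sc > best_score            # strict: ties keep the lowest plane
    hm[upd] <- k - 1L
    best_score[upd] <- sc[upd]
  }
  if (smooth_radius_px > 0 && n > 1) {
    sm <- EBImage::medianFilter(hm / (n - 1), size = as.integer(smooth_radius_px))
    hm <- matrix(as.integer(round(EBImage::imageData(sm) * (n - 1))),
                 nrow(hm), ncol(hm))
  }
  comp <- matrix(0, nrow(hm), ncol(hm))
  flat <- seq_along(hm)
  comp[flat] <- data[flat + as.numeric(hm) * length(hm)]
  structure(list(composite = comp, height_map = hm,
                 focus_quality = best_score,
                 z_step_um = z_step, pixel_size_um = px),
            class = "composite_result")
}

#' Convert a height-map of plane indices to micrometers
#' @param height_map integer plane-index matrix (0-based).
#' @param z_step_um z-step calibration.
#' @return matrix of heights in um.
#' @export
height_to_um <- function(height_map, z_step_um) height_map * z_step_um

# Normalized phase correlation between two same-size matrices.
# Returns list(shift = c(dy, dx), peak): shifting `b` by `shift` (positive =
# down/right) best aligns it with `a`.
.phase_correlate <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(shift = c(0L, 0L), peak = 0))
  fa <- stats::fft(a - mean(a))
  fb <- stats::fft(b - mean(b))
  cp <- fa * Conj(fb)
  cp <- cp / pmax(Mod(cp), 1e-12)
  r <- Re(stats::fft(cp, inverse = TRUE)) / length(cp)
  pk <- which.max(r)
  peak <- r[pk]
  ij <- arrayInd(pk, dim(r)) - 1L
  wrap <- function(s, nlen) if (s > nlen / 2) s - nlen else s
  shift <- c(wrap(ij[1], nrow(r)), wrap(ij[2], ncol(r)))
  list(shift = shift, peak = peak)
}

#' Register tiled composites by phase correlation on overlap strips
#'
#' For each pair of grid neighbours, the nominal overlap strips are cross-
#' registered by normalized phase correlation; per-tile residual offsets are
#' reconciled over the grid in raster order by averaging the estimates
#' propagated from the left and top neighbours, rounding to integer pixels
#' and clipping to \code{search_radius_px}. Pairs whose correlation peak
#' falls below \code{min_peak} (featureless overlap) contribute the nominal
#' offset and flag the tile.
#'
#' @param tile_set a \code{\link{tile_mosaic}}-style tile set whose tiles
#'   hold 2D composites (use \code{\link{edf_compose}} per tile first).
#' @param search_radius_px maximum residual shift considered, px.
#' @param min_peak minimum acceptable phase-correlation peak.
#' @return data.frame (tile, row, col, nominal_dy, nominal_dx, dy, dx,
#'   flagged): dy/dx are residuals relative to the nominal grid offsets.
#' @export
register_tiles <- function(tile_set, search_radius_px = 5L, min_peak = 0.03) {
  stopifnot(inherits(tile_set, "tile_set"))
  tiles <- tile_set$tiles
  g <- tile_set$grid
  ov <- round(tile_set$tile_px - tile_set$stride_px)
  if ((g[1] > 1 && ov[1] < 16) || (g[2] > 1 && ov[2] < 16))
    stop("overlap must be >= 16 px in the registration dimension (got ",
         paste(ov, collapse = "x"), ")")
  idx <- function(i, j) (i - 1) * g[2] + j
  n <- length(tiles)
  res <- matrix(0, n, 2)
  flagged <- logical(n)
  measured <- function(ta, tb, dir) {
    # overlap strips at nominal positions; dir: "h" (b right of a) or "v"
    if (dir == "h") {
      sa <- ta$data[, (ncol(ta$data) - ov[2] + 1):ncol(ta$data), drop = FALSE]
      sb <- tb$data[, 1:ov[2], drop = FALSE]
    } else {
      sa <- ta$data[(nrow(ta$data) - ov[1] + 1):nrow(ta$data), , drop = FALSE]
      sb <- tb$data[1:ov[1], , drop = FALSE]
    }
    .phase_correlate(sa, sb)
  }
  for (i in seq_len(g[1])) for (j in seq_len(g[2])) {
    k <- idx(i, j)
    if (i == 1 && j == 1) next
    est <- list(); ok <- logical(0)
    if (j > 1) {
      pc <- measured(tiles[[idx(i, j - 1)]], tiles[[k]], "h")
      est <- c(est, list(res[idx(i, j - 1), ] + pc$shift))
      ok <- c(ok, pc$peak >= min_peak)
    }
    if (i > 1) {
      pc <- measured(tiles[[idx(i - 1, j)]], tiles[[k]], "v")
      est <- c(est, list(res[idx(i - 1, j), ] + pc$shift))
      ok <- c(ok, pc$peak >= min_peak)
    }
    if (!any(ok)) {
      res[k, ] <- c(0, 0)
      flagged[k] <- TRUE
    } else {
      e <- do.call(rbind, est[ok])
      r <- round(colMeans(e))
      res[k, ] <- pmin(pmax(r, -search_radius_px), search_radius_px)
    }
  }
  data.frame(
    tile = seq_len(n),
    row = vapply(tiles, `[[`, 0L, "row"),
    col = vapply(tiles, `[[`, 0L, "col"),
    nominal_dy = vapply(tiles, function(t) t$offset_px[1], 0),
    nominal_dx = vapply(tiles, function(t) t$offset_px[2], 0),
    dy = res[, 1], dx = res[, 2], flagged = flagged)
}

#' Stitch registered tiles into a mosaic
#'
#' Places each 2D tile at nominal + residual offset. \code{"feather"}
#' blends overlaps with linear distance-to-edge weights (for intensity
#' composites); \code{"nearest"} assigns every mosaic pixel from the tile
#' whose centre is closest, which is mandatory for height-maps because plane
#' indices are categorical and must never be averaged.
#'
#' @param tile_set tile set whose tiles hold 2D images.
#' @param offsets a \code{\link{register_tiles}} result (or NULL for nominal
#'   offsets only).
#' @param blend \code{"feather"} or \code{"nearest"}.
#' @return list of class \code{"mosaic"}: \code{image}, \code{provenance}
#'   (source-tile index per pixel, NA where feather-blended across tiles is
#'   attributed to the dominant-weight tile).
#' @export
stitch <- function(tile_set, offsets = NULL, blend = c("feather", "nearest")) {
  blend <- match.arg(blend)
  stopifnot(inherits(tile_set, "tile_set"))
  tiles <- tile_set$tiles
  n <- length(tiles)
  off <- t(vapply(seq_len(n), function(k) {
    nom <- tiles[[k]]$offset_px
    if (is.null(offsets)) as.numeric(nom)
    else as.numeric(nom) + c(offsets$dy[k], offsets$dx[k])
  }, numeric(2)))
  th <- vapply(tiles, function(t) nrow(t$data), 0L)
  tw <- vapply(tiles, function(t) ncol(t$data), 0L)
  o_min <- apply(off, 2, min)
  H <- as.integer(max(off[, 1] + th) - o_min[1])
  W <- as.integer(max(off[, 2] + tw) - o_min[2])
  acc <- matrix(0, H, W); wsum <- matrix(0, H, W)
  bestw <- matrix(-Inf, H, W); prov <- matrix(NA_integer_, H, W)
  nearest_img <- matrix(0, H, W)
  for (k in seq_len(n)) {
    rows <- (off[k, 1] - o_min[1] + 1):(off[k, 1] - o_min[1] + th[k])
    cols <- (off[k, 2] - o_min[2] + 1):(off[k, 2] - o_min[2] + tw[k])
    d <- tiles[[k]]$data
    wy <- pmin(seq_len(th[k]), th[k]:1)
    wx <- pmin(seq_len(tw[k]), tw[k]:1)
    w <- outer(wy, wx, pmin)         # distance-to-edge ramp
    acc[rows, cols] <- acc[rows, cols] + d * w
    wsum[rows, cols] <- wsum[rows, cols] + w
    upd <- w > bestw[rows, cols]
    pr <- prov[rows, cols]; pr[upd] <- k; prov[rows, cols] <- pr
    ni <- nearest_img[rows, cols]; ni[upd] <- d[upd]
    nearest_img[rows, cols] <- ni
    bw <- bestw[rows, cols]; bw[upd] <- w[upd]; bestw[rows, cols] <- bw
  }
  gaps <- which(wsum == 0)
  if (length(gaps))
    stop("offsets leave ", length(gaps), " mosaic pixel(s) uncovered, e.g. ",
         paste(utils::head(gaps, 5), collapse = ", "))
  img <- if (blend == "feather") acc / wsum else nearest_img
  if (blend == "nearest" &&
      all(vapply(tiles, function(t) is.integer(t$data), logical(1))))
    storage.mode(img) <- "integer"   # height-maps stay integer plane indices
  structure(list(image = img, provenance = prov, blend = blend),
            class = "mosaic")
}
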