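# Small scene builders shared across tests.

# A compact dome scene: one centred spherical-cap dome on a textured field.
tiny_dome_scene <- function(seed = 1, field = 128, n_planes = 8,
                            radius = 40, apex = 30) {
  scene_pars(field_size_um = field, pixel_size_um = 1, z_step_um = 5,
             n_planes = n_planes, n_nuclei = 0,
             dome_specs = list(list(center = c(field / 2, field / 2),
                                    radius_um = radius,
                                    apex_height_um = apex)),
             seed = seed)
}

# Fine-pixel mitochondria field (48 x 48 um at 0.1 um/px).
mito_field_pars <- function(seed = 1, density = 3, enlarged_fraction = 0.2) {
  scene_pars(field_size_um = 48, pixel_size_um = 0.1, n_planes = 2,
             n_nuclei = 0, n_domes = 0, mito_density = density,
             enlarged_fraction = enlarged_fraction, seed = seed)
}

# Cut a 2D image into a tile set at nominal offsets plus integer jitter
# (per-tile c(dy, dx)); mimics stage drift during acquisition. Tile
# geometry is computed on a field x field grid; `full` may be larger so
# that positive jitter stays inside the canvas.
jittered_tiles <- function(full, grid, overlap_fraction, jitter,
                           field = min(dim(full)), margin = 3L) {
  stopifnot(all(dim(full) >= field + 2 * margin), all(abs(jitter) <= margin))
  ts <- tile_mosaic(full[1:field, 1:field], grid, overlap_fraction)
  for (k in seq_along(ts$tiles)) {
    off <- ts$tiles[[k]]$offset_px + jitter[k, ] + margin
    rows <- (off[1] + 1):(off[1] + ts$tile_px[1])
    cols <- (off[2] + 1):(off[2] + ts$tile_px[2])
    ts$tiles[[k]]$data <- full[rows, cols]
  }
  ts
}

# Quantized ground-truth height-map (nearest plane index) of a scene.
true_height_planes <- function(scene) {
  round(scene$surface$height_um / scene$pars$z_step_um)
}

# Pixels with enough local texture for focus estimation: local variance of
# the ideal image above a fixed floor.
textured_pixels <- function(ideal, floor = 1e-4, window = 7) {
  m <- domescope:::.box_mean(ideal, window)
  v <- domescope:::.box_mean(ideal^2, window) - m^2
  v >= floor
}

# Gaussian elution profile helper for MS tests.
gaussian_profile <- function(rt, A, mu, sigma) A * exp(-(rt - mu)^2 / (2 * sigma^2))
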