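# Simulation of weakly fluorescent point objects imaged through the
# effective confocal PSF, with Poisson photon-counting noise and the
# 8-bit photon-count encoding.

#' Simulation configuration
#'
#' Defaults reproduce the reference simulation: an 8 x 8 array of
#' point sources at 20-pixel XY spacing, centered laterally and axially
#' in a 200 x 200 x 40 voxel grid of 80 x 80 x 250 nm voxels, with the
#' average detected image normalized so its brightest voxel expects 1
#' photon, optional uniform background of 0.01 photons per voxel, and
#' 8-bit encoding in which code 255 corresponds to 4 photons.
#'
#' @param grid_dims Integer length-3 `c(nx, ny, nz)` voxel counts.
#' @param voxel_pitch Numeric length-3 `c(dx, dy, dz)` in nm.
#' @param xy_spacing Lateral spacing between neighboring objects, voxels.
#' @param array_shape Integer length-2: objects along x and y.
#' @param peak_photons Expected photons at the brightest voxel of the
#'   average detected image after normalization.
#' @param background Uniform background added to every voxel of the
#'   average detected image, photons/voxel (0 = noise-free variant).
#' @param seed Master seed; expanded into per-stage seeds.
#' @param photons_full_scale Photons corresponding to 8-bit code 255.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(grid_dims = c(200L, 200L, 40L),
                       voxel_pitch = c(80, 80, 250),
                       xy_spacing = 20L,
                       array_shape = c(8L, 8L),
                       peak_photons = 1,
                       background = 0,
                       seed = 1L,
                       photons_full_scale = 4) {
  stopifnot(length(grid_dims) == 3L, length(array_shape) == 2L,
            length(voxel_pitch) == 3L)
  stop_if_not_positive(grid_dims, "grid_dims")
  stop_if_not_positive(voxel_pitch, "voxel_pitch")
  stop_if_not_positive(xy_spacing, "xy_spacing")
  stop_if_not_positive(array_shape, "array_shape")
  stop_if_not_positive(peak_photons, "peak_photons")
  stop_if_not_positive(photons_full_scale, "photons_full_scale")
  if (background < 0) stop("background must be >= 0", call. = FALSE)
  cfg <- structure(
    list(grid_dims = as.integer(grid_dims),
         voxel_pitch = as.numeric(voxel_pitch),
         xy_spacing = as.integer(xy_spacing),
         array_shape = as.integer(array_shape),
         peak_photons = as.numeric(peak_photons),
         background = as.numeric(background),
         seed = as.integer(seed),
         photons_full_scale = as.numeric(photons_full_scale)),
    class = "sim_config"
  )
  extent <- (cfg$array_shape - 1L) * cfg$xy_spacing
  margin <- (cfg$grid_dims[1:2] - extent) / 2
  if (any(margin < cfg$xy_spacing / 2)) {
    stop("object array footprint does not fit in the grid with margin >= spacing/2",
         call. = FALSE)
  }
  cfg
}

#' Lay out the ground-truth point-source array
#'
#' Places `array_shape[1] * array_shape[2]` single-voxel objects on a
#' square lattice of pitch `xy_spacing`, laterally centered in the grid
#' (first center at index `(nx - (n1 - 1) * spacing) / 2`, rounded to a
#' voxel) and all at the central z-slice `floor(nz / 2)` (0-based).
#'
#' @param config A [sim_config()].
#' @return An `object_layout`: a list with `centers` (n x 3 integer
#'   matrix of 1-based voxel indices), `brightness`, and `grid_dims`.
#' @export
make_object_layout <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  d <- config$grid_dims
  sh <- config$array_shape
  sp <- config$xy_spacing
  # 0-based first-center offset so the array is laterally centered:
  # for nx = 200, 8 objects, spacing 20 this is 30 (centers 30..170).
  first <- floor((d[1:2] - (sh - 1L) * sp) / 2)
  cx <- first[1] + sp * (seq_len(sh[1]) - 1L)
  cy <- first[2] + sp * (seq_len(sh[2]) - 1L)
  cz <- floor(d[3] / 2)
  centers <- as.matrix(expand.grid(x = cx, y = cy))
  centers <- cbind(centers, z = cz)
  # to 1-based indices
  centers <- centers + 1L
  storage.mode(centers) <- "integer"
  structure(
    list(centers = centers, brightness = 1, grid_dims = d),
    class = "object_layout"
  )
}

#' @export
print.object_layout <- function(x, ...) {
  cat(sprintf("Object layout: %d point sources in a %d x %d x %d grid\n",
              nrow(x$centers), x$grid_dims[1], x$grid_dims[2], x$grid_dims[3]))
  invisible(x)
}

#' Render point objects into an expected-photon field
#'
#' @param layout An `object_layout`.
#' @param brightness Expected photons placed at each impulse voxel.
#' @return A numeric 3-D array, zero except single-voxel impulses.
#' @export
render_objects <- function(layout, brightness = 1) {
  stopifnot(inherits(layout, "object_layout"))
  stop_if_not_positive(brightness, "brightness")
  field <- array(0, dim = layout$grid_dims)
  if (nrow(layout$centers) > 0) {
    field[layout$centers] <- brightness
  }
  field
}

#' Convolve a photon field with a PSF
#'
#' Linear (zero-padded, not circular) 3-D convolution by FFT, with the
#' PSF's center voxel as the kernel origin, cropped back to the input
#' grid.  Tiny negative values from FFT round-off (>= -1e-12 relative to
#' the peak) are clipped to zero.
#'
#' @param field Numeric 3-D array of expected photons.
#' @param psf A `psf_volume` (for simulation, `peak_one` normalized).
#' @param voxel_pitch Optional pitch of `field` for a consistency check
#'   against the PSF's pitch.
#' @return Numeric 3-D array, same dims as `field`.
#' @export
convolve_psf <- function(field, psf, voxel_pitch = NULL) {
  stopifnot(inherits(psf, "psf_volume"))
  if (!is.null(voxel_pitch) &&
      !isTRUE(all.equal(as.numeric(voxel_pitch), psf$voxel_pitch))) {
    stop("field and PSF voxel pitch differ", call. = FALSE)
  }
  out <- conv3(field, psf$values, psf$center)
  floor_tol <- -1e-12 * max(abs(out), 1)
  if (any(out < floor_tol)) {
    warning("convolution produced negatives beyond the numerical floor")
  }
  out[out < 0] <- 0
  out
}

#' Normalize a photon field to a target peak
#'
#' Rescales so the maximum voxel equals `peak_photons` exactly (the
#' simulation's "average of 1 detected photon at the brightest voxel").
#'
#' @param field Numeric 3-D array with a positive maximum.
#' @param peak_photons Target peak in photons.
#' @return Rescaled array.
#' @export
normalize_to_photons <- function(field, peak_photons = 1) {
  m <- max(field)
  if (!is.finite(m) || m <= 0) stop("field maximum must be positive", call. = FALSE)
  field * (peak_photons / m)
}

#' Add a uniform background
#'
#' @param field Numeric array.
#' @param b Background in photons/voxel, added to every voxel.
#' @return `field + b`.
#' @export
add_background <- function(field, b) {
  if (length(b) != 1 || !is.finite(b) || b < 0) {
    stop("background must be a single non-negative number", call. = FALSE)
  }
  field + b
}

#' Draw the Poisson photon-count realization
#'
#' Each voxel of the count stack is an independent Poisson draw whose
#' mean is the corresponding voxel of the average detected image.
#' Reproducible: a fixed seed and the fixed column-major traversal give
#' bit-identical output.
#'
#' @param field Numeric 3-D array of non-negative means (photons/voxel).
#' @param seed Integer seed.
#' @return A `count_stack`: list with integer `values` and the `seed`.
#' @export
sample_poisson <- function(field, seed) {
  if (any(field < 0)) stop("Poisson means must be non-negative", call. = FALSE)
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  counts <- array(stats::rpois(length(field), as.vector(field)), dim = dim3(field))
  structure(list(values = counts, seed = as.integer(seed)), class = "count_stack")
}

#' @export
print.count_stack <- function(x, ...) {
  d <- dim3(x$values)
  cat(sprintf("Photon count stack %d x %d x %d (seed %d): %g photons total, max %d\n",
              d[1], d[2], d[3], x$seed, sum(x$values), max(x$values)))
  invisible(x)
}

#' Encode photon values as an 8-bit stack
#'
#' `code = round(value * 255 / photons_full_scale)`, rounding half away
#' from zero, clipped to \[0, 255\] (values above full scale saturate).
#' With the default full scale of 4 photons, 4 photons map to code 255
#' and 1 photon to code 64.
#'
#' @param x A `count_stack` or a numeric array of photon values.
#' @param photons_full_scale Photons corresponding to code 255.
#' @return An 8-bit `encoded_stack` with
#'   `photons_per_code = photons_full_scale / 255`.
#' @export
encode_8bit <- function(x, photons_full_scale = 4) {
  stop_if_not_positive(photons_full_scale, "photons_full_scale")
  v <- if (inherits(x, "count_stack")) x$values else x
  v <- as.array(v)
  if (length(dim(v)) < 3L) dim(v) <- c(dim(v), rep(1L, 3L - length(dim(v))))
  codes <- round_half_away(v * 255 / photons_full_scale)
  codes[codes > 255] <- 255
  codes[codes < 0] <- 0
  encoded_stack(codes, photons_full_scale / 255, 8L)
}

#' Run the full simulation to an encoded stack
#'
#' Convenience wrapper chaining [make_object_layout()],
#' [render_objects()], [convolve_psf()], [normalize_to_photons()],
#' [add_background()], [sample_poisson()] and [encode_8bit()].  The
#' master seed in `config` is expanded into per-stage seeds (only the
#' Poisson stage consumes one) recorded in the result.
#'
#' @param config A [sim_config()].
#' @param psf Effective confocal `psf_volume` on the simulation grid.
#' @return A list with elements `layout`, `average_image` (expected
#'   photons/voxel, background included), `counts` (`count_stack`),
#'   `encoded` (8-bit `encoded_stack`), and `seeds`.
#' @export
simulate_stack <- function(config, psf) {
  stopifnot(inherits(config, "sim_config"), inherits(psf, "psf_volume"))
  seeds <- expand_seed(config$seed, c("poisson"))
  layout <- make_object_layout(config)
  field <- render_objects(layout, brightness = 1)
  blurred <- convolve_psf(field, psf, config$voxel_pitch)
  avg <- normalize_to_photons(blurred, config$peak_photons)
  avg <- add_background(avg, config$background)
  counts <- sample_poisson(avg, seeds[["poisson"]])
  enc <- encode_8bit(counts, config$photons_full_scale)
  list(layout = layout, average_image = avg, counts = counts,
       encoded = enc, seeds = seeds, config = config)
}
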