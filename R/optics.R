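#' Optical parameters for point-spread-function generation
#'
#' Bundles the microscope and sampling parameters needed to evaluate a
#' scalar Born & Wolf widefield PSF on a voxel grid.
#'
#' @param numerical_aperture Objective numerical aperture (dimensionless).
#'   Must not exceed `refractive_index`, otherwise the defocus term of the
#'   scalar model is unphysical.
#' @param refractive_index Immersion/sample refractive index assumed by the
#'   Born & Wolf model (a single uniform medium).
#' @param wavelength Wavelength in nanometres (excitation or emission,
#'   depending on which PSF is being generated).
#' @param voxel_pitch Numeric length-3 vector `c(dx, dy, dz)` in nanometres.
#' @param grid_dims Integer length-3 vector `c(nx, ny, nz)` of voxel counts.
#' @return An object of class `optical_params`.
#' @examples
#' optical_params(1.4, 1.5, 488, c(80, 80, 250), c(32, 32, 8))
#' @export
optical_params <- function(numerical_aperture, refractive_index, wavelength,
                           voxel_pitch, grid_dims) {
  stop_if_not_positive(numerical_aperture, "numerical_aperture")
  stop_if_not_positive(refractive_index, "refractive_index")
  stop_if_not_positive(wavelength, "wavelength")
  stopifnot(length(voxel_pitch) == 3L, length(grid_dims) == 3L)
  stop_if_not_positive(voxel_pitch, "voxel_pitch")
  stop_if_not_positive(grid_dims, "grid_dims")
  if (numerical_aperture > refractive_index) {
    stop("numerical_aperture must not exceed refractive_index", call. = FALSE)
  }
  structure(
    list(
      numerical_aperture = as.numeric(numerical_aperture),
      refractive_index = as.numeric(refractive_index),
      wavelength = as.numeric(wavelength),
      voxel_pitch = as.numeric(voxel_pitch),
      grid_dims = as.integer(grid_dims)
    ),
    class = "optical_params"
  )
}

#' @export
print.optical_params <- function(x, ...) {
  cat(sprintf(
    "Optical parameters: NA %.2f, n %.2f, lambda %g nm\n  voxel pitch %g x %g x %g nm, grid %d x %d x %d\n",
    x$numerical_aperture, x$refractive_index, x$wavelength,
    x$voxel_pitch[1], x$voxel_pitch[2], x$voxel_pitch[3],
    x$grid_dims[1], x$grid_dims[2], x$grid_dims[3]
  ))
  invisible(x)
}

# Construct a psf_volume container.  `center` is the 1-based voxel index of
# the focal point; for a grid of size n it sits at floor(n/2) + 1, which
# keeps FFT convolution alignment unambiguous.
new_psf_volume <- function(values, voxel_pitch, center, normalization) {
  structure(
    list(
      values = values,
      voxel_pitch = as.numeric(voxel_pitch),
      center = as.integer(center),
      normalization = normalization
    ),
    class = "psf_volume"
  )
}

psf_center_index <- function(grid_dims) as.integer(floor(grid_dims / 2) + 1L)

#' @export
print.psf_volume <- function(x, ...) {
  d <- dim3(x$values)
  cat(sprintf(
    "PSF volume %d x %d x %d (pitch %g x %g x %g nm), %s normalized\n  center voxel (%d, %d, %d), total %.6g\n",
    d[1], d[2], d[3], x$voxel_pitch[1], x$voxel_pitch[2], x$voxel_pitch[3],
    x$normalization, x$center[1], x$center[2], x$center[3], sum(x$values)
  ))
  invisible(x)
}

# Evaluate the Born & Wolf pupil integral
#   I(r, z) = integral_0^1 J0(k NA r rho) exp(-i k z rho^2 NA^2 / (2 n)) rho drho
# at given radial/axial offsets (nm) by fixed-order Gauss-Legendre
# quadrature.  Returns |I|^2, unnormalized.  `r` may be a vector; `z` is
# scalar.  Vectorized through a Bessel matrix times a complex weight
# vector.
bw_intensity <- function(r, z, k, na, n, nodes, weights) {
  besmat <- matrix(
    besselJ(as.vector(outer(r, nodes, function(rr, rho) k * na * rr * rho)), 0),
    nrow = length(r)
  )
  phase <- -k * z * nodes^2 * na^2 / (2 * n)
  wre <- weights * nodes * cos(phase)
  wim <- weights * nodes * sin(phase)
  re <- drop(besmat %*% wre)
  im <- drop(besmat %*% wim)
  re^2 + im^2
}

#' Widefield Born & Wolf point spread function
#'
#' Evaluates the scalar Born & Wolf intensity PSF
#' \deqn{h(r, z) = \left| \int_0^1 J_0(k\,\mathrm{NA}\, r \rho)\,
#'   e^{-i k z \rho^2 \mathrm{NA}^2 / (2n)}\, \rho\, d\rho \right|^2,
#'   \quad k = 2\pi/\lambda,}
#' at voxel centers relative to the grid center voxel, and normalizes the
#' volume so its peak equals 1.  The defining 1-D pupil integral is
#' computed by fixed-order Gauss--Legendre quadrature; the order is grown
#' until doubling it changes no voxel by more than 1e-8 relative, so the
#' sampled values are quadrature-converged.
#'
#' @param params An [optical_params()] object.
#' @return A `psf_volume` with `peak_one` normalization, centered at
#'   `floor(grid_dims / 2) + 1` in each axis.
#' @examples
#' p <- optical_params(1.4, 1.5, 510, c(80, 80, 250), c(33, 33, 9))
#' psf <- born_wolf_psf(p)
#' max(psf$values) == 1
#' @export
born_wolf_psf <- function(params) {
  stopifnot(inherits(params, "optical_params"))
  d <- params$grid_dims
  if (any(d < 3L)) stop("grid_dims too small: center voxel must be interior", call. = FALSE)
  ctr <- psf_center_index(d)
  pitch <- params$voxel_pitch
  k <- 2 * pi / params$wavelength
  na <- params$numerical_aperture
  n <- params$refractive_index

  ix <- (seq_len(d[1]) - ctr[1]) * pitch[1]
  iy <- (seq_len(d[2]) - ctr[2]) * pitch[2]
  r2 <- outer(ix^2, iy^2, "+")
  r2u <- sort(unique(as.vector(r2)))
  ridx <- match(as.vector(r2), r2u)
  ru <- sqrt(r2u)
  zoff <- (seq_len(d[3]) - ctr[3]) * pitch[3]
  zu <- sort(unique(abs(zoff)))

  eval_all <- function(order) {
    gl <- pracma::gaussLegendre(order, 0, 1)
    vals <- vapply(
      zu,
      function(z) bw_intensity(ru, z, k, na, n, gl$x, gl$w),
      numeric(length(ru))
    )
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(ru))
    vals # length(ru) x length(zu)
  }

  order <- 64L
  prev <- eval_all(order)
  repeat {
    order <- order * 2L
    cur <- eval_all(order)
    floor_val <- 1e-12 * max(cur)
    rel <- abs(cur - prev) / pmax(abs(cur), floor_val)
    if (max(rel) <= 1e-8 || order >= 2048L) break
    prev <- cur
  }

  vol <- array(0, dim = d)
  zmap <- match(abs(zoff), zu)
  for (iz in seq_len(d[3])) {
    vol[, , iz] <- matrix(cur[ridx, zmap[iz]], d[1], d[2])
  }
  vol <- vol / vol[ctr[1], ctr[2], ctr[3]]
  new_psf_volume(vol, pitch, ctr, "peak_one")
}

#' Effective confocal PSF from excitation and emission PSFs
#'
#' The closed-pinhole confocal approximation: the effective PSF is the
#' voxelwise product of the excitation-wavelength and emission-wavelength
#' widefield PSFs, renormalized to peak 1.
#'
#' @param ex,em `psf_volume` objects on identical grids (same dims, pitch,
#'   center).
#' @return A `peak_one` `psf_volume`.
#' @export
effective_confocal_psf <- function(ex, em) {
  stopifnot(inherits(ex, "psf_volume"), inherits(em, "psf_volume"))
  if (!identical(dim3(ex$values), dim3(em$values)) ||
      !isTRUE(all.equal(ex$voxel_pitch, em$voxel_pitch)) ||
      !identical(ex$center, em$center)) {
    stop("excitation and emission PSFs must share grid dims, pitch and center",
         call. = FALSE)
  }
  prod_vals <- ex$values * em$values
  out <- new_psf_volume(prod_vals, ex$voxel_pitch, ex$center, "peak_one")
  renormalize_psf(out, "peak_one")
}

#' Renormalize a PSF volume
#'
#' @param psf A `psf_volume`.
#' @param mode `"peak_one"` (maximum voxel exactly 1) or `"sum_one"`
#'   (voxel total 1; required by the deconvolver's forward model so that
#'   convolution conserves photon flux).
#' @return The rescaled `psf_volume`.
#' @export
renormalize_psf <- function(psf, mode = c("peak_one", "sum_one")) {
  stopifnot(inherits(psf, "psf_volume"))
  mode <- match.arg(mode)
  total <- sum(psf$values)
  if (!is.finite(total) || total <= 0) stop("cannot normalize an all-zero PSF", call. = FALSE)
  scale <- if (mode == "peak_one") max(psf$values) else total
  out <- psf
  out$values <- psf$values / scale
  out$normalization <- mode
  out
}

# Full width at half maximum of the central lateral profile (along x at
# the center y/z), by linear interpolation.  Used by tests; exported for
# completeness of the PSF toolkit.

#' Lateral FWHM of a PSF volume
#'
#' Measures the full width at half maximum along the central x row of the
#' focal slice, by linear interpolation between voxel samples, in the
#' units of the lateral voxel pitch (nm).
#'
#' @param psf A `psf_volume`.
#' @return FWHM in nanometres.
#' @export
psf_lateral_fwhm <- function(psf) {
  stopifnot(inherits(psf, "psf_volume"))
  ctr <- psf$center
  prof <- psf$values[, ctr[2], ctr[3]]
  prof <- prof / max(prof)
  half_cross <- function(idx) {
    # idx runs from the peak outward; find first crossing below 0.5
    below <- which(prof[idx] < 0.5)
    if (!length(below)) return(NA_real_)
    j <- below[1]
    i1 <- idx[j - 1L]; i2 <- idx[j]
    frac <- (prof[i1] - 0.5) / (prof[i1] - prof[i2])
    abs(i2 - i1) * frac + abs(i1 - ctr[1])
  }
  right <- half_cross(ctr[1]:length(prof))
  left <- half_cross(ctr[1]:1)
  (right + left) * psf$voxel_pitch[1]
}

#' Write / read a PSF volume as 32-bit multi-page TIFF
#'
#' One page per z-slice, z ascending, 32 bits per sample.  Values must
#' lie in \[0, 1\] (true for both supported normalizations); they are
#' stored as 32-bit samples with absolute precision 2^-32, below every
#' tolerance used in this package.  Reading accepts both this dialect
#' and 32-bit float TIFFs from other tools.  Pitch, center and
#' normalization are stored in a plain-text sidecar `<path>.meta`.
#'
#' @param psf A `psf_volume`.
#' @param path Output TIFF path.
#' @return `write_psf_tiff` returns `path` invisibly; `read_psf_tiff`
#'   returns the `psf_volume`.
#' @export
write_psf_tiff <- function(psf, path) {
  stopifnot(inherits(psf, "psf_volume"))
  d <- dim3(psf$values)
  pages <- lapply(seq_len(d[3]), function(iz) t(psf$values[, , iz]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  write_sidecar(path, list(
    kind = "psf_volume",
    voxel_pitch = paste(psf$voxel_pitch, collapse = ","),
    center = paste(psf$center, collapse = ","),
    normalization = psf$normalization
  ))
  invisible(path)
}

#' @rdname write_psf_tiff
#' @export
read_psf_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  vol <- array(0, dim = d)
  for (iz in seq_along(pages)) vol[, , iz] <- t(pages[[iz]])
  meta <- read_sidecar(path)
  pitch <- as.numeric(strsplit(meta$voxel_pitch, ",")[[1]])
  ctr <- as.integer(strsplit(meta$center, ",")[[1]])
  new_psf_volume(vol, pitch, ctr, meta$normalization)
}
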