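# Internal FFT-based linear (zero-padded) 3-D convolution.
#
# All convolutions in the package go through conv3(): the simulator's
# PSF convolution and both applications (forward and adjoint) inside the
# Richardson-Lucy iteration.  Zero padding to at least n + k - 1 along
# each axis makes the convolution linear, not circular, so stack borders
# see no wrap-around; dims are rounded up to 2/3/5-smooth sizes for FFT
# speed.  fftwtools (FFTW) does the transforms.

fft3 <- function(x, inverse = FALSE) {
  fftwtools::fftw_c2c_3d(x, inverse = if (inverse) 1L else 0L)
}

pad_dims <- function(nd, kd) {
  full <- nd + kd - 1L
  vapply(full, function(n) as.integer(stats::nextn(n, c(2L, 3L, 5L))), integer(1))
}

embed3 <- function(x, pd) {
  d <- dim3(x)
  out <- array(0, dim = pd)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
  out
}

# Precompute the transformed kernel (and its spatial reverse) once so a
# deconvolution run pays 2 kernel FFTs total, then 4 per iteration.
conv3_plan <- function(kernel, center, data_dims) {
  kd <- dim3(kernel)
  ctr <- as.integer(center)
  stopifnot(all(ctr >= 1L), all(ctr <= kd))
  pd <- pad_dims(as.integer(data_dims), kd)
  kf <- fft3(embed3(kernel, pd) + 0i)
  krev <- kernel[kd[1]:1, kd[2]:1, kd[3]:1, drop = FALSE]
  dim(krev) <- kd
  kf_rev <- fft3(embed3(krev, pd) + 0i)
  list(
    data_dims = as.integer(data_dims), kernel_dims = kd, pad = pd,
    center = ctr, center_rev = kd + 1L - ctr,
    kf = kf, kf_rev = kf_rev
  )
}

# Apply the planned convolution.  adjoint = TRUE convolves with the
# spatially reversed kernel (the transpose of the forward operator),
# which is what the RL update's back-projection needs.
conv3_apply <- function(plan, x, adjoint = FALSE) {
  d <- plan$data_dims
  stopifnot(identical(dim3(x), d))
  xf <- fft3(embed3(x, plan$pad) + 0i)
  kf <- if (adjoint) plan$kf_rev else plan$kf
  full <- Re(fft3(xf * kf, inverse = TRUE)) / prod(plan$pad)
  ctr <- if (adjoint) plan$center_rev else plan$center
  out <- full[
    ctr[1]:(ctr[1] + d[1] - 1L),
    ctr[2]:(ctr[2] + d[2] - 1L),
    ctr[3]:(ctr[3] + d[3] - 1L),
    drop = FALSE
  ]
  dim(out) <- d
  out
}

# One-shot convenience used by the simulator.
conv3 <- function(x, kernel, center) {
  conv3_apply(conv3_plan(kernel, center, dim3(x)), x)
}

# Smallest centered box (full z range, symmetric lateral half-width)
# holding at least `keep` of the kernel total.  Used to crop the
# effective confocal PSF before repeated RL convolutions; the confocal
# product PSF decays so fast laterally that a tiny lateral crop retains
# all but a ~1e-6 fraction of the flux.
crop_kernel_support <- function(psf, keep = 1 - 1e-6) {
  stopifnot(inherits(psf, "psf_volume"))
  v <- psf$values
  d <- dim3(v)
  ctr <- psf$center
  total <- sum(v)
  hmax <- max(ctr[1] - 1L, d[1] - ctr[1], ctr[2] - 1L, d[2] - ctr[2])
  for (h in 0:hmax) {
    xr <- max(1L, ctr[1] - h):min(d[1], ctr[1] + h)
    yr <- max(1L, ctr[2] - h):min(d[2], ctr[2] + h)
    if (sum(v[xr, yr, , drop = FALSE]) >= keep * total) break
  }
  xr <- max(1L, ctr[1] - h):min(d[1], ctr[1] + h)
  yr <- max(1L, ctr[2] - h):min(d[2], ctr[2] + h)
  vals <- v[xr, yr, , drop = FALSE]
  new_psf_volume(
    vals, psf$voxel_pitch,
    c(ctr[1] - xr[1] + 1L, ctr[2] - yr[1] + 1L, ctr[3]),
    psf$normalization
  )
}
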