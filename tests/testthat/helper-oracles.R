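# Independent oracles used across the suite.  These deliberately avoid
# the package's own computational paths: the PSF oracle uses adaptive
# quadrature (stats::integrate), the convolution oracle is a direct
# spatial-domain sum, and the RL oracle iterates with the brute-force
# convolution.

# Born & Wolf intensity at radial offset r (nm) and defocus z (nm),
# normalized so the focal peak is 1, by adaptive quadrature on the real
# and imaginary parts of the pupil integral.
bw_oracle <- function(r, z, lambda, na = 1.4, n = 1.5) {
  k <- 2 * pi / lambda
  fre <- function(rho) besselJ(k * na * r * rho, 0) * cos(-k * z * rho^2 * na^2 / (2 * n)) * rho
  fim <- function(rho) besselJ(k * na * r * rho, 0) * sin(-k * z * rho^2 * na^2 / (2 * n)) * rho
  re <- stats::integrate(fre, 0, 1, rel.tol = 1e-12, abs.tol = 1e-14, subdivisions = 500L)$value
  im <- stats::integrate(fim, 0, 1, rel.tol = 1e-12, abs.tol = 1e-14, subdivisions = 500L)$value
  (re^2 + im^2) / 0.25   # peak: |integral of rho d rho|^2 = 1/4
}

# Direct spatial-domain linear convolution: out[i] = sum_j x[j] k[i - j + c]
# with 1-based kernel center c, zero outside the kernel.  O(n * k) loops;
# only for small grids.
conv_brute <- function(x, kern, center) {
  dx <- dim(x); dk <- dim(kern)
  out <- array(0, dx)
  for (ox in seq_len(dx[1])) for (oy in seq_len(dx[2])) for (oz in seq_len(dx[3])) {
    acc <- 0
    for (kx in seq_len(dk[1])) for (ky in seq_len(dk[2])) for (kz in seq_len(dk[3])) {
      jx <- ox - (kx - center[1]); jy <- oy - (ky - center[2]); jz <- oz - (kz - center[3])
      if (jx >= 1 && jx <= dx[1] && jy >= 1 && jy <= dx[2] && jz >= 1 && jz <= dx[3]) {
        acc <- acc + x[jx, jy, jz] * kern[kx, ky, kz]
      }
    }
    out[ox, oy, oz] <- acc
  }
  out
}

# Adjoint (correlation) counterpart of conv_brute.
corr_brute <- function(x, kern, center) {
  kd <- dim(kern)
  krev <- kern[kd[1]:1, kd[2]:1, kd[3]:1, drop = FALSE]
  dim(krev) <- kd
  conv_brute(x, krev, kd + 1L - center)
}

# Independent Richardson-Lucy iteration (additive background, flat
# initialization), using the brute-force convolutions only.
rl_oracle <- function(d, kern, center, iterations, b = 0) {
  kern <- kern / sum(kern)
  x <- array(mean(pmax(d - b, 0)), dim(d))
  for (i in seq_len(iterations)) {
    denom <- conv_brute(x, kern, center) + b
    ratio <- ifelse(denom > 0, d / denom, 0)
    x <- x * corr_brute(ratio, kern, center)
  }
  x
}

# Small effective confocal PSF shared by tests (33 x 33 x 9 grid keeps
# the Born & Wolf evaluation fast while retaining realistic structure).
small_psf_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dims <- c(33L, 33L, 9L)
      ex <- born_wolf_psf(optical_params(1.4, 1.5, 488, c(80, 80, 250), dims))
      em <- born_wolf_psf(optical_params(1.4, 1.5, 510, c(80, 80, 250), dims))
      cache <<- list(ex = ex, em = em, eff = effective_confocal_psf(ex, em))
    }
    cache
  }
})

# Small simulation configuration compatible with the small PSF grid:
# a 3 x 3 array at 8-px spacing in a 33 x 33 x 9 grid.
small_sim_config <- function(seed = 1L, background = 0) {
  sim_config(grid_dims = c(33L, 33L, 9L), voxel_pitch = c(80, 80, 250),
             xy_spacing = 8L, array_shape = c(3L, 3L), peak_photons = 1,
             background = background, seed = seed)
}

# Linear interpolation FWHM of a sampled profile with peak at index p.
fwhm_brute <- function(prof, p) {
  prof <- prof / prof[p]
  cross <- function(idx) {
    below <- which(prof[idx] < 0.5)
    j <- below[1]
    i1 <- idx[j - 1L]; i2 <- idx[j]
    abs(i2 - i1) * (prof[i1] - 0.5) / (prof[i1] - prof[i2]) + abs(i1 - p)
  }
  cross(p:length(prof)) + cross(p:1)
}
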