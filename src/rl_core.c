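/* Richardson-Lucy inner loop with FFTW-backed linear convolution.
 *
 * The multiplicative EM update for Poisson counts with an additive
 * background, x <- x * Ht(d / (H x + b)), needs four large FFTs per
 * iteration (forward + inverse for each of H and Ht).  Doing these at
 * the R level allocates several working copies per transform; here one
 * real and one half-complex buffer are reused for every transform and
 * the kernel spectra are computed once.
 *
 * Layout: R arrays are column-major with x fastest; FFTW is row-major,
 * so transforms are planned with dims reversed (n0 = nz, n1 = ny,
 * n2 = nx) and the half-complex dimension is along x.
 *
 * Zero padding to pad >= data + kernel - 1 along each axis keeps the
 * convolution linear (no wrap-around); the caller chooses smooth padded
 * sizes.  Cropping offsets follow the kernel center: the forward
 * convolution reads the full result at offset (center - 1), the
 * adjoint (spatially reversed kernel) at (kdim - center).
 */

#include <R.h>
#include <Rinternals.h>
#include <string.h>
#include <math.h>
#include <fftw3.h>

typedef struct {
  int nx, ny, nz;    /* data dims */
  int px, py, pz;    /* padded dims */
  int hx;            /* px/2 + 1, half-complex extent along x */
  double *real_buf;
  fftw_complex *cplx_buf;
  fftw_plan fwd, inv;
} conv_ws;

static void ws_embed(conv_ws *w, const double *src, int sx, int sy, int sz)
{
  memset(w->real_buf, 0, sizeof(double) * (size_t) w->px * w->py * w->pz);
  for (int z = 0; z < sz; z++)
    for (int y = 0; y < sy; y++)
      memcpy(w->real_buf + ((size_t) z * w->py + y) * w->px,
             src + ((size_t) z * sy + y) * sx,
             sizeof(double) * (size_t) sx);
}

static void ws_crop(conv_ws *w, double *dst, int ox, int oy, int oz)
{
  for (int z = 0; z < w->nz; z++)
    for (int y = 0; y < w->ny; y++)
      memcpy(dst + ((size_t) z * w->ny + y) * w->nx,
             w->real_buf + ((size_t) (z + oz) * w->py + (y + oy)) * w->px + ox,
             sizeof(double) * (size_t) w->nx);
}

/* real_buf -> spectrum * kf (scaled) -> real_buf */
static void ws_convolve(conv_ws *w, const fftw_complex *kf)
{
  fftw_execute(w->fwd);
  size_t nc = (size_t) w->hx * w->py * w->pz;
  double scale = 1.0 / ((double) w->px * w->py * w->pz);
  for (size_t i = 0; i < nc; i++) {
    double re = w->cplx_buf[i][0] * kf[i][0] - w->cplx_buf[i][1] * kf[i][1];
    double im = w->cplx_buf[i][0] * kf[i][1] + w->cplx_buf[i][1] * kf[i][0];
    w->cplx_buf[i][0] = re * scale;
    w->cplx_buf[i][1] = im * scale;
  }
  fftw_execute(w->inv);
}

SEXP C_rl_core(SEXP d_, SEXP ddim_, SEXP k_, SEXP kdim_, SEXP kcenter_,
               SEXP pad_, SEXP iter_, SEXP bg_, SEXP x0_, SEXP want_trace_)
{
  const double *d = REAL(d_);
  const double *kern = REAL(k_);
  const int *dd = INTEGER(ddim_);
  const int *kd = INTEGER(kdim_);
  const int *kc = INTEGER(kcenter_);   /* 1-based */
  const int *pp = INTEGER(pad_);
  const int iterations = asInteger(iter_);
  const double b = asReal(bg_);
  const double x0 = asReal(x0_);
  const int want_trace = asLogical(want_trace_);

  conv_ws w;
  w.nx = dd[0]; w.ny = dd[1]; w.nz = dd[2];
  w.px = pp[0]; w.py = pp[1]; w.pz = pp[2];
  w.hx = w.px / 2 + 1;
  const size_t n = (size_t) w.nx * w.ny * w.nz;
  const size_t np = (size_t) w.px * w.py * w.pz;
  const size_t nc = (size_t) w.hx * w.py * w.pz;

  w.real_buf = fftw_alloc_real(np);
  w.cplx_buf = fftw_alloc_complex(nc);
  fftw_complex *kf = fftw_alloc_complex(nc);
  fftw_complex *kf_rev = fftw_alloc_complex(nc);
  if (!w.real_buf || !w.cplx_buf || !kf || !kf_rev)
    error("allocation failure in RL core");

  w.fwd = fftw_plan_dft_r2c_3d(w.pz, w.py, w.px, w.real_buf, w.cplx_buf,
                               FFTW_ESTIMATE);
  w.inv = fftw_plan_dft_c2r_3d(w.pz, w.py, w.px, w.cplx_buf, w.real_buf,
                               FFTW_ESTIMATE);

  /* kernel spectrum */
  ws_embed(&w, kern, kd[0], kd[1], kd[2]);
  fftw_execute(w.fwd);
  memcpy(kf, w.cplx_buf, sizeof(fftw_complex) * nc);

  /* spatially reversed kernel spectrum */
  {
    size_t kn = (size_t) kd[0] * kd[1] * kd[2];
    double *krev = (double *) R_alloc(kn, sizeof(double));
    for (int z = 0; z < kd[2]; z++)
      for (int y = 0; y < kd[1]; y++)
        for (int x = 0; x < kd[0]; x++)
          krev[((size_t) z * kd[1] + y) * kd[0] + x] =
            kern[((size_t) (kd[2] - 1 - z) * kd[1] + (kd[1] - 1 - y)) * kd[0] +
                 (kd[0] - 1 - x)];
    ws_embed(&w, krev, kd[0], kd[1], kd[2]);
    fftw_execute(w.fwd);
    memcpy(kf_rev, w.cplx_buf, sizeof(fftw_complex) * nc);
  }

  SEXP est_ = PROTECT(allocVector(REALSXP, (R_xlen_t) n));
  SEXP trace_ = PROTECT(allocVector(REALSXP, want_trace ? iterations : 0));
  double *x = REAL(est_);
  double *trace = REAL(trace_);
  double *work = (double *) R_alloc(n, sizeof(double));

  for (size_t i = 0; i < n; i++) x[i] = x0;

  const int ofx = kc[0] - 1, ofy = kc[1] - 1, ofz = kc[2] - 1;
  const int orx = kd[0] - kc[0], ory = kd[1] - kc[1], orz = kd[2] - kc[2];

  for (int it = 0; it < iterations; it++) {
    /* forward model mu = H x + b, stored in work */
    ws_embed(&w, x, w.nx, w.ny, w.nz);
    ws_convolve(&w, kf);
    ws_crop(&w, work, ofx, ofy, ofz);

    double ll = 0.0;
    int impossible = 0;
    for (size_t i = 0; i < n; i++) {
      double mu = work[i] + b;
      if (mu < 0) mu = 0;        /* FFT round-off floor */
      if (mu > 0) {
        if (want_trace) ll += d[i] * log(mu) - mu;
        work[i] = d[i] / mu;     /* ratio */
      } else {
        if (d[i] > 0) impossible = 1;
        work[i] = 0.0;
      }
    }
    if (want_trace) trace[it] = impossible ? R_NegInf : ll;

    /* multiplicative update x *= Ht ratio */
    ws_embed(&w, work, w.nx, w.ny, w.nz);
    ws_convolve(&w, kf_rev);
    ws_crop(&w, work, orx, ory, orz);
    for (size_t i = 0; i < n; i++) {
      x[i] *= work[i];
      if (x[i] < 0) x[i] = 0;
    }
    R_CheckUserInterrupt();
  }

  fftw_destroy_plan(w.fwd);
  fftw_destroy_plan(w.inv);
  fftw_free(w.real_buf);
  fftw_free(w.cplx_buf);
  fftw_free(kf);
  fftw_free(kf_rev);

  SEXP out = PROTECT(allocVector(VECSXP, 2));
  SET_VECTOR_ELT(out, 0, est_);
  SET_VECTOR_ELT(out, 1, trace_);
  SEXP nms = PROTECT(allocVector(STRSXP, 2));
  SET_STRING_ELT(nms, 0, mkChar("estimate"));
  SET_STRING_ELT(nms, 1, mkChar("trace"));
  setAttrib(out, R_NamesSymbol, nms);
  UNPROTECT(4);
  return out;
}

static const R_CallMethodDef call_entries[] = {
  {"C_rl_core", (DL_FUNC) &C_rl_core, 10},
  {NULL, NULL, 0}
};

void R_init_photondecon(DllInfo *dll)
{
  R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
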