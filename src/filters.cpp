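#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// One zero-phase pass pair over all columns of the extended buffer X
// (ext x nc, column-major). The direct-form II transposed recursion is
// serial in time but independent across columns, so the column loop is
// innermost and vectorizes.
static void pass_all(const std::vector<double>& b,
                     const std::vector<double>& a,
                     std::vector<double>& X, int ext, int nc,
                     const std::vector<double>& zi, bool forward) {
  const int m = (int)zi.size();
  // extended-precision state keeps the cascade linear to ~1e-13 relative
  std::vector<long double> Z(std::max(m, 1) * nc, 0.0L);
  const int i0 = forward ? 0 : ext - 1;
  const int di = forward ? 1 : -1;
  // initialize state from the first processed sample of each column
  for (int c = 0; c < nc; ++c) {
    long double x0 = X[(size_t)c * ext + i0];
    for (int j = 0; j < m; ++j)
      Z[(size_t)j * nc + c] = (long double)zi[j] * x0;
  }
  for (int i = i0, step = 0; step < ext; ++step, i += di) {
    double* xrow = &X[i];  // element (i, c) at i + c*ext
    for (int c = 0; c < nc; ++c) {
      long double xi = xrow[(size_t)c * ext];
      long double yi = b[0] * xi + (m > 0 ? Z[c] : 0.0L);
      for (int j = 0; j < m - 1; ++j)
        Z[(size_t)j * nc + c] =
            b[j + 1] * xi + Z[(size_t)(j + 1) * nc + c] - a[j + 1] * yi;
      if (m > 0)
        Z[(size_t)(m - 1) * nc + c] = b[m] * xi - a[m] * yi;
      xrow[(size_t)c * ext] = (double)yi;
    }
  }
}

// Zero-phase (forward-backward) filtering of every column of x.
// Columns are extended at both ends by 'npad' samples of odd reflection;
// the filter state starts at zi (the steady-state unit-step state, computed
// in R) scaled by the first processed sample, which suppresses start-up
// transients.
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt(NumericMatrix x, NumericVector b_, NumericVector a_,
                           NumericVector zi_, int npad) {
  const int n = x.nrow(), nc = x.ncol();
  const int nord = std::max(b_.size(), a_.size());
  std::vector<double> b(nord, 0.0), a(nord, 0.0);
  for (int i = 0; i < b_.size(); ++i) b[i] = b_[i];
  for (int i = 0; i < a_.size(); ++i) a[i] = a_[i];
  std::vector<double> zi(zi_.begin(), zi_.end());
  if (n <= npad)
    stop("trace shorter than reflection pad");

  const int ext = n + 2 * npad;
  std::vector<double> X((size_t)ext * nc);
  for (int c = 0; c < nc; ++c) {
    const double* xc = &x(0, c);
    double* xe = &X[(size_t)c * ext];
    for (int i = 0; i < npad; ++i) xe[i] = 2.0 * xc[0] - xc[npad - i];
    std::copy(xc, xc + n, xe + npad);
    for (int i = 0; i < npad; ++i)
      xe[npad + n + i] = 2.0 * xc[n - 1] - xc[n - 2 - i];
  }
  pass_all(b, a, X, ext, nc, zi, true);
  pass_all(b, a, X, ext, nc, zi, false);

  NumericMatrix out(n, nc);
  for (int c = 0; c < nc; ++c)
    std::copy(&X[(size_t)c * ext + npad], &X[(size_t)c * ext + npad + n],
              &out(0, c));
  return out;
}

// Band phase walks for a block of oscillators: instantaneous frequency is
// fc plus a clipped AR(1) deviation driven by the supplied innovations;
// phase is its cumulative sum (times 2*pi/fs) plus the initial phase.
// eps: n x nc innovations; d0, phi0: per-oscillator initial deviation and
// phase. Returns both the phase and the instantaneous frequency (Hz).
// [[Rcpp::export]]
List cpp_phase_walk(NumericMatrix eps, NumericVector d0,
                    NumericVector phi0, double rho, double clip,
                    double fc, double fs) {
  const int n = eps.nrow(), nc = eps.ncol();
  NumericMatrix out(n, nc), freq(n, nc);
  const double twopi_fs = 2.0 * M_PI / fs;
  for (int c = 0; c < nc; ++c) {
    double d = d0[c], acc = 0.0;
    const double* e = &eps(0, c);
    double* o = &out(0, c);
    double* f = &freq(0, c);
    for (int i = 0; i < n; ++i) {
      d = rho * d + e[i];
      double dc = d < -clip ? -clip : (d > clip ? clip : d);
      acc += fc + dc;
      o[i] = phi0[c] + twopi_fs * acc;
      f[i] = fc + dc;
    }
  }
  return List::create(Named("phase") = out, Named("freq") = freq);
}

// Kuramoto-style phase coupling for the planted regions of one band.
// Each region integrates a blended instantaneous frequency
//   (1 - B) * f_own + sum_e share_e * f_shared_e
// plus a sinusoidal pull sum_e share_e * gain * sin(psi_e + lag_e - phi),
// where share_e = weight_e(t) / degree and B = sum_e share_e. At full
// weight the region tracks its shared process (zero detuning, so the pull
// drives the phase error to zero); at zero weight it follows its own walk.
// freq_own: n x Rp (planted regions only); psi/freq_sh: n x E; edges:
// E x 2 1-based indices into the planted-region columns (0 = not
// incident); weight: n x E.
// [[Rcpp::export]]
NumericMatrix cpp_phase_couple(NumericMatrix freq_own, NumericVector phi0,
                               NumericMatrix psi, NumericMatrix freq_sh,
                               IntegerMatrix edges, NumericVector lags,
                               NumericMatrix weight, NumericVector degree,
                               double gain, double fs) {
  const int n = freq_own.nrow(), Rp = freq_own.ncol(), E = psi.ncol();
  NumericMatrix out(n, Rp);
  // incident edge lists per region: (edge index, lagged flag)
  std::vector<std::vector<std::pair<int, bool> > > inc(Rp);
  for (int e = 0; e < E; ++e) {
    inc[edges(e, 0) - 1].push_back(std::make_pair(e, false));
    inc[edges(e, 1) - 1].push_back(std::make_pair(e, true));
  }
  const double twopi_fs = 2.0 * M_PI / fs;
  std::vector<double> phi(phi0.begin(), phi0.end());
  for (int t = 0; t < n; ++t) {
    for (int r = 0; r < Rp; ++r) {
      double B = 0.0, fb = 0.0, pull = 0.0;
      for (size_t k = 0; k < inc[r].size(); ++k) {
        const int e = inc[r][k].first;
        const double share = weight(t, e) / degree[r];
        const double target = psi(t, e) + (inc[r][k].second ? lags[e] : 0.0);
        B += share;
        fb += share * freq_sh(t, e);
        pull += share * gain * std::sin(target - phi[r]);
      }
      double f = (1.0 - B) * freq_own(t, r) + fb + pull;
      phi[r] += twopi_fs * f;
      out(t, r) = phi[r];
    }
  }
  return out;
}

// Time-resolved wPLI from the analytic signal.
// z: complex array [trials x regions x samples] (R dim order).
// For each sample t and pair (i, j), with X_k = z_{ik} * conj(z_{jk}) over
// trials k: wPLI = |sum Im(X_k)| / sum |Im(X_k)|, 0 when the denominator
// vanishes. Returns a [samples x regions x regions] array, symmetric with a
// zero diagonal.
// [[Rcpp::export]]
NumericVector cpp_wpli(ComplexVector z, IntegerVector dims) {
  const int K = dims[0], R = dims[1], T = dims[2];
  NumericVector out(Dimension(T, R, R));
  const Rcomplex* zp = z.begin();
  const R_xlen_t KR = (R_xlen_t)K * R;

  for (int t = 0; t < T; ++t) {
    const Rcomplex* zt = zp + (R_xlen_t)t * KR;
    for (int i = 0; i < R; ++i) {
      const Rcomplex* zi = zt + (R_xlen_t)i * K;
      for (int j = i + 1; j < R; ++j) {
        const Rcomplex* zj = zt + (R_xlen_t)j * K;
        double num = 0.0, den = 0.0;
        for (int k = 0; k < K; ++k) {
          // Im(z_i * conj(z_j))
          double im = zi[k].i * zj[k].r - zi[k].r * zj[k].i;
          num += im;
          den += std::abs(im);
        }
        double w = (den > 0.0) ? std::abs(num) / den : 0.0;
        out[t + (R_xlen_t)T * (i + (R_xlen_t)R * j)] = w;
        out[t + (R_xlen_t)T * (j + (R_xlen_t)R * i)] = w;
      }
    }
  }
  return out;
}
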