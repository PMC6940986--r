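// Debye-formula forward scattering and the hot loops built on it:
// exact O(N^2) sum, distance-histogram accelerated sum, the Metropolis
// annealer for dummy-residue reconstruction, and the (phi, t) rigid-body
// grid scan. All randomness comes from R's RNG so set.seed() governs
// reproducibility.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sinc(double x) {
  return (std::fabs(x) < 1e-12) ? 1.0 : std::sin(x) / x;
}

// [[Rcpp::export]]
NumericVector debye_exact_cpp(NumericMatrix X, NumericVector f, NumericVector q) {
  const int n = X.nrow(), nq = q.size();
  NumericVector I(nq);
  double self = 0.0;
  for (int i = 0; i < n; ++i) self += f[i] * f[i];
  for (int k = 0; k < nq; ++k) I[k] = self;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = X(i, 0) - X(j, 0);
      const double dy = X(i, 1) - X(j, 1);
      const double dz = X(i, 2) - X(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double w = 2.0 * f[i] * f[j];
      for (int k = 0; k < nq; ++k) I[k] += w * sinc(q[k] * d);
    }
  }
  return I;
}

// Weighted pair-distance histogram: bin b holds sum of 2*f_i*f_j for pairs
// whose distance falls in [b*bin, (b+1)*bin); evaluated at bin centers.
// [[Rcpp::export]]
NumericVector debye_hist_cpp(NumericMatrix X, NumericVector f, NumericVector q,
                             double bin) {
  const int n = X.nrow(), nq = q.size();
  // max distance first
  double dmax = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = X(i, 0) - X(j, 0);
      const double dy = X(i, 1) - X(j, 1);
      const double dz = X(i, 2) - X(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > dmax) dmax = d2;
    }
  }
  dmax = std::sqrt(dmax);
  const int nb = std::max(1, (int)std::floor(dmax / bin) + 1);
  std::vector<double> w(nb, 0.0), wd(nb, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = X(i, 0) - X(j, 0);
      const double dy = X(i, 1) - X(j, 1);
      const double dz = X(i, 2) - X(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      int b = (int)std::floor(d / bin);
      if (b >= nb) b = nb - 1;
      const double ww = 2.0 * f[i] * f[j];
      w[b] += ww;
      wd[b] += ww * d;   // evaluate at the weighted mean distance per bin
    }
  }
  double self = 0.0;
  for (int i = 0; i < n; ++i) self += f[i] * f[i];
  NumericVector I(nq);
  for (int k = 0; k < nq; ++k) {
    double s = self;
    for (int b = 0; b < nb; ++b) {
      if (w[b] == 0.0) continue;
      s += w[b] * sinc(q[k] * wd[b] / w[b]);
    }
    I[k] = s;
  }
  return I;
}

// [[Rcpp::export]]
double max_pair_dist_cpp(NumericMatrix X) {
  const int n = X.nrow();
  double m = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = X(i, 0) - X(j, 0);
      const double dy = X(i, 1) - X(j, 1);
      const double dz = X(i, 2) - X(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > m) m = d2;
    }
  }
  return std::sqrt(m);
}

// Number of cross pairs between A and B closer than cut.
// [[Rcpp::export]]
int count_close_cross_cpp(NumericMatrix A, NumericMatrix B, double cut) {
  const int na = A.nrow(), nb = B.nrow();
  const double c2 = cut * cut;
  int cnt = 0;
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      const double dx = A(i, 0) - B(j, 0);
      const double dy = A(i, 1) - B(j, 1);
      const double dz = A(i, 2) - B(j, 2);
      if (dx * dx + dy * dy + dz * dz < c2) ++cnt;
    }
  }
  return cnt;
}

// Reduced chi^2 after optimal scaling of Im onto (Id, sd).
static double chi2_scaled(const std::vector<double> &Im, const NumericVector &Id,
                          const NumericVector &isd2, int nq, double *c_out) {
  double s_md = 0.0, s_mm = 0.0;
  for (int k = 0; k < nq; ++k) {
    s_md += Im[k] * Id[k] * isd2[k];
    s_mm += Im[k] * Im[k] * isd2[k];
  }
  const double c = (s_mm > 0) ? s_md / s_mm : 1.0;
  double s = 0.0;
  for (int k = 0; k < nq; ++k) {
    const double r = c * Im[k] - Id[k];
    s += r * r * isd2[k];
  }
  if (c_out) *c_out = c;
  return s / (nq - 1);
}

// Simulated-annealing dummy-residue reconstruction.
// Energy = chi2(scaled Debye curve vs data) + wbond * sum (d_adj - bond0)^2
//        + wclash * (# non-adjacent pairs closer than clashd).
// Single-bead Gaussian moves (sd = stepsd), hard wall at radius rmax.
// [[Rcpp::export]]
List anneal_cpp(NumericMatrix X0, NumericVector q, NumericVector Id,
                NumericVector sd, double wbond, double wclash, double bond0,
                double clashd, double rmax, double stepsd, double t0fac,
                double cooling, int steps_per_stage, int max_stages,
                int patience) {
  const int n = X0.nrow(), nq = q.size();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = X0(i, 0); y[i] = X0(i, 1); z[i] = X0(i, 2); }
  NumericVector isd2(nq);
  for (int k = 0; k < nq; ++k) isd2[k] = 1.0 / (sd[k] * sd[k]);

  // initial model intensity
  std::vector<double> Im(nq, 0.0);
  for (int k = 0; k < nq; ++k) Im[k] = n; // self terms, f = 1
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int k = 0; k < nq; ++k) Im[k] += 2.0 * sinc(q[k] * d);
    }
  }
  // linear-interpolation sinc table over the reachable q*d range
  const double xmax = q[nq - 1] * 2.0 * rmax * 1.05 + 1.0;
  const double dx = 0.002;
  const int ntab = (int)std::ceil(xmax / dx) + 2;
  std::vector<double> tab(ntab);
  for (int k = 0; k < ntab; ++k) tab[k] = sinc(k * dx);
  auto sinc_t = [&](double xx) {
    const double u = xx / dx;
    const int k = (int)u;
    if (k + 1 >= ntab) return sinc(xx);
    const double f = u - k;
    return tab[k] * (1.0 - f) + tab[k + 1] * f;
  };
  auto dist = [&](int i, int j) {
    const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  };
  double ebond = 0.0;
  for (int i = 0; i + 1 < n; ++i) {
    const double d = dist(i, i + 1) - bond0;
    ebond += d * d;
  }
  int nclash = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 2; j < n; ++j)
      if (dist(i, j) < clashd) ++nclash;

  double chi2 = chi2_scaled(Im, Id, isd2, nq, nullptr);
  double E = chi2 + wbond * ebond + wclash * nclash;

  std::vector<double> dIm(nq), dold(n), dnew(n);
  const double r2max = rmax * rmax;

  // Initial temperature from the per-move energy scale: the mean |dE| of
  // probe moves (none applied). Using the total energy instead would leave
  // the final temperature far above the move scale and nothing would
  // freeze within the stage budget.
  double dEsum = 0.0; int nprobe = 0;
  for (int s = 0; s < 50; ++s) {
    const int i = (int)std::floor(R::runif(0.0, 1.0) * n);
    const double nx = x[i] + R::norm_rand() * stepsd;
    const double ny = y[i] + R::norm_rand() * stepsd;
    const double nz = z[i] + R::norm_rand() * stepsd;
    if (nx * nx + ny * ny + nz * nz > r2max) continue;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double ox = x[i] - x[j], oy = y[i] - y[j], oz = z[i] - z[j];
      dold[j] = std::sqrt(ox * ox + oy * oy + oz * oz);
      const double ax = nx - x[j], ay = ny - y[j], az = nz - z[j];
      dnew[j] = std::sqrt(ax * ax + ay * ay + az * az);
    }
    for (int k = 0; k < nq; ++k) dIm[k] = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      for (int k = 0; k < nq; ++k)
        dIm[k] += 2.0 * (sinc(q[k] * dnew[j]) - sinc(q[k] * dold[j]));
    }
    double debond = 0.0;
    if (i > 0) {
      const double a = dnew[i - 1] - bond0, b = dold[i - 1] - bond0;
      debond += a * a - b * b;
    }
    if (i + 1 < n) {
      const double a = dnew[i + 1] - bond0, b = dold[i + 1] - bond0;
      debond += a * a - b * b;
    }
    std::vector<double> Imp(nq);
    for (int k = 0; k < nq; ++k) Imp[k] = Im[k] + dIm[k];
    const double chi2p = chi2_scaled(Imp, Id, isd2, nq, nullptr);
    dEsum += std::fabs(chi2p - chi2 + wbond * debond);
    ++nprobe;
  }
  const double dE0 = (nprobe > 0) ? dEsum / nprobe : 1.0;
  double T = t0fac * std::max(dE0, 1e-8);
  double bestE = E, bestChi2 = chi2;
  NumericMatrix bestX(n, 3);
  for (int i = 0; i < n; ++i) { bestX(i, 0) = x[i]; bestX(i, 1) = y[i]; bestX(i, 2) = z[i]; }

  std::vector<double> Imnew(nq);
  int stale = 0;
  int stages_run = 0;
  for (int st = 0; st < max_stages; ++st) {
    ++stages_run;
    bool improved = false;
    for (int s = 0; s < steps_per_stage; ++s) {
      const int i = (int)std::floor(R::runif(0.0, 1.0) * n);
      const double nx = x[i] + R::norm_rand() * stepsd;
      const double ny = y[i] + R::norm_rand() * stepsd;
      const double nz = z[i] + R::norm_rand() * stepsd;
      if (nx * nx + ny * ny + nz * nz > r2max) continue;
      // distance changes
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const double ox = x[i] - x[j], oy = y[i] - y[j], oz = z[i] - z[j];
        dold[j] = std::sqrt(ox * ox + oy * oy + oz * oz);
        const double ax = nx - x[j], ay = ny - y[j], az = nz - z[j];
        dnew[j] = std::sqrt(ax * ax + ay * ay + az * az);
      }
      for (int k = 0; k < nq; ++k) dIm[k] = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const double dn_ = dnew[j], do_ = dold[j];
        for (int k = 0; k < nq; ++k)
          dIm[k] += 2.0 * (sinc_t(q[k] * dn_) - sinc_t(q[k] * do_));
      }
      double debond = 0.0;
      if (i > 0) {
        const double a = dnew[i - 1] - bond0, b = dold[i - 1] - bond0;
        debond += a * a - b * b;
      }
      if (i + 1 < n) {
        const double a = dnew[i + 1] - bond0, b = dold[i + 1] - bond0;
        debond += a * a - b * b;
      }
      int dclash = 0;
      for (int j = 0; j < n; ++j) {
        if (std::abs(j - i) <= 1) continue;
        if (dnew[j] < clashd) ++dclash;
        if (dold[j] < clashd) --dclash;
      }
      for (int k = 0; k < nq; ++k) Imnew[k] = Im[k] + dIm[k];
      const double chi2new = chi2_scaled(Imnew, Id, isd2, nq, nullptr);
      const double Enew = chi2new + wbond * (ebond + debond) + wclash * (nclash + dclash);
      const double dE = Enew - E;
      if (dE <= 0.0 || R::runif(0.0, 1.0) < std::exp(-dE / T)) {
        x[i] = nx; y[i] = ny; z[i] = nz;
        Im.swap(Imnew);
        ebond += debond;
        nclash += dclash;
        chi2 = chi2new;
        E = Enew;
        if (E < bestE) {
          bestE = E;
          bestChi2 = chi2;
          for (int m = 0; m < n; ++m) { bestX(m, 0) = x[m]; bestX(m, 1) = y[m]; bestX(m, 2) = z[m]; }
          improved = true;
        }
      }
    }
    T *= cooling;
    stale = improved ? 0 : stale + 1;
    if (stale >= patience) break;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["X"] = bestX, _["energy"] = bestE, _["chi2"] = bestChi2,
                      _["stages"] = stages_run);
}

// Grid scan over rotation phi (about z) of body B and axial separation t:
// body A stays put (centroid at +t/2 handled by caller passing A centered at
// origin top; here A is fixed as given and B is rotated then shifted down by
// t). Returns chi2 (NA when clashed) and clash counts per (phi, t) pair.
// [[Rcpp::export]]
List scan_phi_t_cpp(NumericMatrix A, NumericMatrix B, NumericVector q,
                    NumericVector Id, NumericVector sd, NumericVector phis,
                    NumericVector ts, double clashd) {
  const int na = A.nrow(), nb = B.nrow(), nq = q.size();
  const int np = phis.size(), nt = ts.size();
  NumericVector isd2(nq);
  for (int k = 0; k < nq; ++k) isd2[k] = 1.0 / (sd[k] * sd[k]);

  // intra-body terms are invariant under the scan
  std::vector<double> Iintra(nq, 0.0);
  for (int k = 0; k < nq; ++k) Iintra[k] = na + nb; // f = 1 self terms
  for (int i = 0; i < na; ++i)
    for (int j = i + 1; j < na; ++j) {
      const double dx = A(i, 0) - A(j, 0), dy = A(i, 1) - A(j, 1), dz = A(i, 2) - A(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int k = 0; k < nq; ++k) Iintra[k] += 2.0 * sinc(q[k] * d);
    }
  for (int i = 0; i < nb; ++i)
    for (int j = i + 1; j < nb; ++j) {
      const double dx = B(i, 0) - B(j, 0), dy = B(i, 1) - B(j, 1), dz = B(i, 2) - B(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int k = 0; k < nq; ++k) Iintra[k] += 2.0 * sinc(q[k] * d);
    }

  NumericMatrix chi2(np, nt), scale(np, nt);
  IntegerMatrix clash(np, nt);
  const double c2 = clashd * clashd;
  std::vector<double> bx(nb), by(nb);
  std::vector<double> Im(nq);
  for (int p = 0; p < np; ++p) {
    const double a = phis[p] * M_PI / 180.0;
    const double ca = std::cos(a), sa = std::sin(a);
    for (int j = 0; j < nb; ++j) {
      bx[j] = ca * B(j, 0) - sa * B(j, 1);
      by[j] = sa * B(j, 0) + ca * B(j, 1);
    }
    for (int t = 0; t < nt; ++t) {
      const double tz = ts[t];
      int cnt = 0;
      for (int k = 0; k < nq; ++k) Im[k] = Iintra[k];
      for (int i = 0; i < na; ++i) {
        for (int j = 0; j < nb; ++j) {
          const double dx = A(i, 0) - bx[j];
          const double dy = A(i, 1) - by[j];
          const double dz = A(i, 2) - (B(j, 2) - tz);
          const double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < c2) ++cnt;
          const double d = std::sqrt(d2);
          for (int k = 0; k < nq; ++k) Im[k] += 2.0 * sinc(q[k] * d);
        }
      }
      clash(p, t) = cnt;
      if (cnt > 0) {
        chi2(p, t) = NA_REAL;
        scale(p, t) = NA_REAL;
      } else {
        double c;
        chi2(p, t) = chi2_scaled(Im, Id, isd2, nq, &c);
        scale(p, t) = c;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["chi2"] = chi2, _["clash"] = clash, _["scale"] = scale);
}
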