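#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Cell-list accelerated geometric hydrogen-bond detection.
// donors/hydro are parallel 1-based index vectors (one entry per D-H bond),
// acc the acceptor candidates. Criterion: d(D,A) <= distCut (nm) and the
// H-D-A angle at the donor <= angCut (degrees); pairs closer than covCut
// are treated as covalent and skipped; D == A never reported.
// [[Rcpp::export]]
IntegerMatrix detect_hbonds_cpp(NumericMatrix xyz, IntegerVector donors,
                                IntegerVector hydro, IntegerVector acc,
                                double distCut, double angCut, double covCut) {
  const int nd = donors.size(), na = acc.size();
  const double cut2 = distCut * distCut, cov2 = covCut * covCut;
  const double cosCut = std::cos(angCut * M_PI / 180.0);
  const double cell = distCut;

  // hash acceptor atoms into cubic cells of edge = cutoff
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(na * 2);
  auto key = [cell](double x, double y, double z) -> long long {
    long long ix = (long long)std::floor(x / cell) + 524288;
    long long iy = (long long)std::floor(y / cell) + 524288;
    long long iz = (long long)std::floor(z / cell) + 524288;
    return (ix << 40) | (iy << 20) | iz;
  };
  for (int j = 0; j < na; ++j) {
    int a = acc[j] - 1;
    grid[key(xyz(a, 0), xyz(a, 1), xyz(a, 2))].push_back(a);
  }

  std::vector<int> outD, outH, outA;
  for (int i = 0; i < nd; ++i) {
    int d = donors[i] - 1, h = hydro[i] - 1;
    double dx = xyz(d, 0), dy = xyz(d, 1), dz = xyz(d, 2);
    double hx = xyz(h, 0) - dx, hy = xyz(h, 1) - dy, hz = xyz(h, 2) - dz;
    double hn = std::sqrt(hx * hx + hy * hy + hz * hz);
    if (hn <= 0) stop("zero-length donor-hydrogen bond vector");
    long long cx = (long long)std::floor(dx / cell);
    long long cy = (long long)std::floor(dy / cell);
    long long cz = (long long)std::floor(dz / cell);
    for (long long ox = -1; ox <= 1; ++ox)
      for (long long oy = -1; oy <= 1; ++oy)
        for (long long oz = -1; oz <= 1; ++oz) {
          long long k = ((cx + ox + 524288) << 40) |
                        ((cy + oy + 524288) << 20) | (cz + oz + 524288);
          auto it = grid.find(k);
          if (it == grid.end()) continue;
          for (int a : it->second) {
            if (a == d) continue;
            double ax = xyz(a, 0) - dx, ay = xyz(a, 1) - dy, az = xyz(a, 2) - dz;
            double d2 = ax * ax + ay * ay + az * az;
            if (d2 > cut2 || d2 <= cov2) continue;
            double an = std::sqrt(d2);
            double cosang = (hx * ax + hy * ay + hz * az) / (hn * an);
            if (cosang >= cosCut) {
              outD.push_back(d + 1); outH.push_back(h + 1); outA.push_back(a + 1);
            }
          }
        }
  }
  IntegerMatrix out(outD.size(), 3);
  for (size_t r = 0; r < outD.size(); ++r) {
    out(r, 0) = outD[r]; out(r, 1) = outH[r]; out(r, 2) = outA[r];
  }
  colnames(out) = CharacterVector::create("donor", "hydrogen", "acceptor");
  return out;
}

// Shrake-Rupley solvent-accessible surface area for one frame.
// points: precomputed quasi-uniform unit sphere points (n x 3, Fibonacci
// lattice). radii in nm include only the vdW part; probe added here.
// Returns per-atom accessible area in nm^2.
// [[Rcpp::export]]
NumericVector sasa_frame_cpp(NumericMatrix xyz, NumericVector radii,
                             double probe, NumericMatrix points) {
  const int n = xyz.nrow(), np = points.nrow();
  NumericVector area(n);
  std::vector<double> X(n), Y(n), Z(n), R(n);
  for (int i = 0; i < n; ++i) {
    X[i] = xyz(i, 0); Y[i] = xyz(i, 1); Z[i] = xyz(i, 2);
    R[i] = radii[i] + probe;
  }
  std::vector<double> PX(np), PY(np), PZ(np);
  for (int p = 0; p < np; ++p) {
    PX[p] = points(p, 0); PY[p] = points(p, 1); PZ[p] = points(p, 2);
  }
  // neighbor lists under the maximal contact distance, closest first so a
  // buried test point is rejected early
  std::vector<std::vector<std::pair<double, int> > > nb(n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = X[i] - X[j], dy = Y[i] - Y[j], dz = Z[i] - Z[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      double lim = R[i] + R[j];
      if (d2 < lim * lim) {
        nb[i].push_back(std::make_pair(d2, j));
        nb[j].push_back(std::make_pair(d2, i));
      }
    }
  }
  std::vector<double> NX, NY, NZ, NR2;
  for (int i = 0; i < n; ++i) {
    std::sort(nb[i].begin(), nb[i].end());
    const int nn = (int)nb[i].size();
    NX.resize(nn); NY.resize(nn); NZ.resize(nn); NR2.resize(nn);
    for (int q = 0; q < nn; ++q) {
      int j = nb[i][q].second;
      NX[q] = X[j] - X[i]; NY[q] = Y[j] - Y[i]; NZ[q] = Z[j] - Z[i];
      NR2[q] = R[j] * R[j];
    }
    const double ri = R[i];
    int accessible = 0;
    int last = 0;
    for (int p = 0; p < np; ++p) {
      const double px = ri * PX[p], py = ri * PY[p], pz = ri * PZ[p];
      bool buried = false;
      for (int k = 0; k < nn; ++k) {
        // start at the neighbor that blocked the previous point
        int q = k + last; if (q >= nn) q -= nn;
        double dx = px - NX[q], dy = py - NY[q], dz = pz - NZ[q];
        if (dx * dx + dy * dy + dz * dz < NR2[q]) {
          buried = true;
          last = q;
          break;
        }
      }
      if (!buried) ++accessible;
    }
    area[i] = 4.0 * M_PI * ri * ri * (double)accessible / (double)np;
  }
  return area;
}
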