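#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Linear indexing is column-major (x fastest), matching R arrays.
static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// reflect an out-of-range index back into [0, n) (mirror without repeat)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n - 2;
  i = i % period;
  if (i < 0) i += period;
  if (i >= n) i = period - i;
  return i;
}

static void conv_axis(const std::vector<double>& in, std::vector<double>& out,
                      int nx, int ny, int nz, const NumericVector& kern, int axis) {
  int kl = kern.size();
  int kr = (kl - 1) / 2; // kernel is odd-length, centred
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        for (int t = -kr; t <= kr; ++t) {
          int ii = i, jj = j, kk = k;
          if (axis == 0) ii = reflect_idx(i + t, nx);
          else if (axis == 1) jj = reflect_idx(j + t, ny);
          else kk = reflect_idx(k + t, nz);
          acc += kern[t + kr] * in[lin(ii, jj, kk, nx, ny)];
        }
        out[lin(i, j, k, nx, ny)] = acc;
      }
    }
  }
}

// Separable 3D convolution with reflective boundaries. Kernels must have odd
// length; pass a length-1 kernel c(1) to skip an axis (used for 2D slice ops).
// [[Rcpp::export]]
NumericVector conv_sep3_cpp(NumericVector arr, IntegerVector dims,
                            NumericVector kx, NumericVector ky, NumericVector kz) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> a(arr.begin(), arr.end()), b(a.size());
  conv_axis(a, b, nx, ny, nz, kx, 0);
  conv_axis(b, a, nx, ny, nz, ky, 1);
  conv_axis(a, b, nx, ny, nz, kz, 2);
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = dims;
  return out;
}

// 26-connected component labelling of a binary volume (BFS flood fill).
// Returns an integer array; background = 0, components numbered from 1 in
// order of their smallest linear index (deterministic).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
            int w = lin(ii, jj, kk, nx, ny);
            if (mask[w] && lab[w] == 0) { lab[w] = next; stack.push_back(w); }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Trilinear resampling of a source volume onto an output grid under an
// affine map: source position = Ainv %*% out_position + tinv (physical um).
// Voxel (0-based) centre of index i is origin + (i + 0.5) * spacing.
// [[Rcpp::export]]
NumericVector affine_resample_cpp(NumericVector vals, IntegerVector sdims,
                                  NumericVector sspac, NumericVector sorig,
                                  IntegerVector odims, NumericVector ospac,
                                  NumericVector oorig, NumericMatrix Ainv,
                                  NumericVector tinv, double fill) {
  int snx = sdims[0], sny = sdims[1], snz = sdims[2];
  int nx = odims[0], ny = odims[1], nz = odims[2];
  NumericVector out(nx * ny * nz, fill);
  for (int k = 0; k < nz; ++k) {
    double pz = oorig[2] + (k + 0.5) * ospac[2];
    for (int j = 0; j < ny; ++j) {
      double py = oorig[1] + (j + 0.5) * ospac[1];
      for (int i = 0; i < nx; ++i) {
        double px = oorig[0] + (i + 0.5) * ospac[0];
        double qx = Ainv(0,0)*px + Ainv(0,1)*py + Ainv(0,2)*pz + tinv[0];
        double qy = Ainv(1,0)*px + Ainv(1,1)*py + Ainv(1,2)*pz + tinv[1];
        double qz = Ainv(2,0)*px + Ainv(2,1)*py + Ainv(2,2)*pz + tinv[2];
        // continuous 0-based voxel coordinate of the sample point
        double cx = (qx - sorig[0]) / sspac[0] - 0.5;
        double cy = (qy - sorig[1]) / sspac[1] - 0.5;
        double cz = (qz - sorig[2]) / sspac[2] - 0.5;
        int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy), z0 = (int)std::floor(cz);
        double fx = cx - x0, fy = cy - y0, fz = cz - z0;
        if (x0 < -1 || x0 >= snx || y0 < -1 || y0 >= sny || z0 < -1 || z0 >= snz)
          continue;
        double acc = 0.0;
        for (int dz = 0; dz <= 1; ++dz)
          for (int dy = 0; dy <= 1; ++dy)
            for (int dx = 0; dx <= 1; ++dx) {
              int xi = x0 + dx, yi = y0 + dy, zi = z0 + dz;
              double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
              double v = fill;
              if (xi >= 0 && xi < snx && yi >= 0 && yi < sny && zi >= 0 && zi < snz)
                v = vals[lin(xi, yi, zi, snx, sny)];
              acc += w * v;
            }
        out[lin(i, j, k, nx, ny)] = acc;
      }
    }
  }
  out.attr("dim") = odims;
  return out;
}

// Fused resample + joint histogram + mutual information for registration:
// samples the moving volume at each reference voxel centre mapped through
// src = Ainv * p + tinv, bins both images with fixed equal-width bins
// (ref_bin precomputed; moving binned over [mlo, mhi]), and returns MI in
// nats. Avoids allocating the resampled volume on every objective call.
// [[Rcpp::export]]
double mi_affine_cpp(NumericVector vals, IntegerVector sdims,
                     NumericVector sspac, NumericVector sorig,
                     IntegerVector odims, NumericVector ospac,
                     NumericVector oorig, NumericMatrix Ainv,
                     NumericVector tinv, double fill,
                     IntegerVector ref_bin, double mlo, double mhi, int bins,
                     int stride) {
  int snx = sdims[0], sny = sdims[1], snz = sdims[2];
  int nx = odims[0], ny = odims[1], nz = odims[2];
  std::vector<double> joint(bins * bins, 0.0);
  double scale = (mhi > mlo) ? bins / (mhi - mlo) : 0.0;
  long n = 0;
  for (int k = 0; k < nz; k += stride) {
    double pz = oorig[2] + (k + 0.5) * ospac[2];
    for (int j = 0; j < ny; j += stride) {
      double py = oorig[1] + (j + 0.5) * ospac[1];
      for (int i = 0; i < nx; i += stride) {
        long idx = lin(i, j, k, nx, ny);
        ++n;
        double px = oorig[0] + (i + 0.5) * ospac[0];
        double qx = Ainv(0,0)*px + Ainv(0,1)*py + Ainv(0,2)*pz + tinv[0];
        double qy = Ainv(1,0)*px + Ainv(1,1)*py + Ainv(1,2)*pz + tinv[1];
        double qz = Ainv(2,0)*px + Ainv(2,1)*py + Ainv(2,2)*pz + tinv[2];
        double cx = (qx - sorig[0]) / sspac[0] - 0.5;
        double cy = (qy - sorig[1]) / sspac[1] - 0.5;
        double cz = (qz - sorig[2]) / sspac[2] - 0.5;
        int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy), z0 = (int)std::floor(cz);
        double fx = cx - x0, fy = cy - y0, fz = cz - z0;
        double v = fill;
        if (x0 >= -1 && x0 < snx && y0 >= -1 && y0 < sny && z0 >= -1 && z0 < snz) {
          double acc = 0.0;
          for (int dz = 0; dz <= 1; ++dz)
            for (int dy = 0; dy <= 1; ++dy)
              for (int dx = 0; dx <= 1; ++dx) {
                int xi = x0 + dx, yi = y0 + dy, zi = z0 + dz;
                double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
                double vv = fill;
                if (xi >= 0 && xi < snx && yi >= 0 && yi < sny && zi >= 0 && zi < snz)
                  vv = vals[lin(xi, yi, zi, snx, sny)];
                acc += w * vv;
              }
          v = acc;
        }
        int bm = (int)((v - mlo) * scale);
        if (bm < 0) bm = 0;
        if (bm >= bins) bm = bins - 1;
        joint[(ref_bin[idx] - 1) + bins * bm] += 1.0;
      }
    }
  }
  if (n == 0) return 0.0;
  std::vector<double> pr(bins, 0.0), pm(bins, 0.0);
  for (int b = 0; b < bins; ++b)
    for (int m = 0; m < bins; ++m) {
      double p = joint[b + bins * m] / n;
      pr[b] += p; pm[m] += p;
    }
  double mi = 0.0;
  for (int b = 0; b < bins; ++b)
    for (int m = 0; m < bins; ++m) {
      double p = joint[b + bins * m] / n;
      if (p > 0) mi += p * std::log(p / (pr[b] * pm[m]));
    }
  return mi;
}

// 26-neighbourhood local maxima with plateau handling: a voxel is marked if no
// neighbour is strictly greater; connected equal-valued groups of marked
// voxels collapse to one seed (smallest linear index) and are rejected if the
// plateau continues into an unmarked voxel of equal value (shoulder).
// Returns 1-based linear indices of seeds.
// [[Rcpp::export]]
IntegerVector local_maxima_cpp(NumericVector dens, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<char> ismax(n, 0);
  for (int v = 0; v < n; ++v) {
    if (dens[v] <= 0) continue;
    int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
    bool ok = true;
    for (int dk = -1; dk <= 1 && ok; ++dk)
      for (int dj = -1; dj <= 1 && ok; ++dj)
        for (int di = -1; di <= 1 && ok; ++di) {
          if (!di && !dj && !dk) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
          if (dens[lin(ii, jj, kk, nx, ny)] > dens[v]) ok = false;
        }
    ismax[v] = ok ? 1 : 0;
  }
  std::vector<char> seen(n, 0);
  std::vector<int> seeds;
  std::vector<int> stack, comp;
  for (int s = 0; s < n; ++s) {
    if (!ismax[s] || seen[s]) continue;
    comp.clear(); stack.clear();
    stack.push_back(s); seen[s] = 1;
    bool shoulder = false;
    double val = dens[s];
    int rep = s;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      comp.push_back(v);
      if (v < rep) rep = v;
      int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
            int w = lin(ii, jj, kk, nx, ny);
            if (dens[w] == val) {
              if (!ismax[w]) shoulder = true;
              else if (!seen[w]) { seen[w] = 1; stack.push_back(w); }
            }
          }
    }
    if (!shoulder) seeds.push_back(rep + 1);
  }
  std::sort(seeds.begin(), seeds.end());
  return wrap(seeds);
}

// Synchronized multi-source region growing for patch segmentation.
// Seeds carry peak densities; one 26-connected voxel shell is claimed per
// round. A voxel is eligible for patch p iff dens >= thresholds[p]; competing
// claims resolve by higher peak density, then lower patch id.
// [[Rcpp::export]]
IntegerVector grow_patches_cpp(NumericVector dens, IntegerVector dims,
                               IntegerVector seed_idx, NumericVector peak_dens,
                               NumericVector thresholds) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz, np = seed_idx.size();
  IntegerVector lab(n, 0);
  std::vector<int> frontier, nextf;
  for (int p = 0; p < np; ++p) {
    int s = seed_idx[p] - 1;
    lab[s] = p + 1;
    frontier.push_back(s);
  }
  std::vector<int> claim(n, 0); // patch id claiming a voxel this round
  while (!frontier.empty()) {
    std::vector<int> touched;
    for (size_t f = 0; f < frontier.size(); ++f) {
      int v = frontier[f];
      int p = lab[v]; // 1-based patch id
      int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
            int w = lin(ii, jj, kk, nx, ny);
            if (lab[w] != 0) continue;
            if (dens[w] < thresholds[p - 1]) continue;
            if (claim[w] == 0) { claim[w] = p; touched.push_back(w); }
            else {
              int q = claim[w];
              if (peak_dens[p - 1] > peak_dens[q - 1] ||
                  (peak_dens[p - 1] == peak_dens[q - 1] && p < q)) claim[w] = p;
            }
          }
    }
    nextf.clear();
    for (size_t t = 0; t < touched.size(); ++t) {
      int w = touched[t];
      lab[w] = claim[w];
      claim[w] = 0;
      nextf.push_back(w);
    }
    frontier.swap(nextf);
  }
  lab.attr("dim") = dims;
  return lab;
}

// Budgeted multi-source BFS used to carve a toy atlas into contiguous regions:
// round-robin over regions, each claiming one 6-connected voxel per cycle
// until its voxel budget is exhausted or it is walled in. Deterministic.
// [[Rcpp::export]]
IntegerVector grow_regions_budgeted_cpp(IntegerVector dims, IntegerVector seed_idx,
                                        IntegerVector budgets) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz, nr = seed_idx.size();
  IntegerVector lab(n, 0);
  std::vector< std::queue<int> > qs(nr);
  std::vector<int> left(budgets.begin(), budgets.end());
  const int dx[6] = {1,-1,0,0,0,0}, dy[6] = {0,0,1,-1,0,0}, dz[6] = {0,0,0,0,1,-1};
  for (int r = 0; r < nr; ++r) {
    int s = seed_idx[r] - 1;
    if (left[r] > 0 && lab[s] == 0) {
      lab[s] = r + 1; --left[r];
      qs[r].push(s);
    }
  }
  bool any = true;
  while (any) {
    any = false;
    for (int r = 0; r < nr; ++r) {
      if (left[r] <= 0) continue;
      bool claimed = false;
      while (!qs[r].empty() && !claimed) {
        int v = qs[r].front();
        int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
        bool exhausted = true;
        for (int d = 0; d < 6; ++d) {
          int ii = i + dx[d], jj = j + dy[d], kk = k + dz[d];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
          int w = lin(ii, jj, kk, nx, ny);
          if (lab[w] == 0) {
            if (!claimed) {
              lab[w] = r + 1; --left[r];
              qs[r].push(w);
              claimed = true; any = true;
            }
            exhausted = false;
            if (claimed) break;
          }
        }
        if (exhausted) qs[r].pop();
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
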