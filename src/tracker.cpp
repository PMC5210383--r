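// Deterministic streamline propagation and tract-density voxel traversal.
//
// Conventions (shared with the R side):
//  - grids are axis-aligned; world mm of 0-based voxel index i is
//    origin + i * voxel_size
//  - continuous index coordinate of world point p is (p - origin)/voxel_size;
//    the physical volume is ci in [-0.5, n - 0.5] per axis
//  - tensors are stored as (x,y,z,6) column-major with component order
//    Dxx, Dyy, Dzz, Dxy, Dxz, Dyz

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Grid {
  int n[3];
  double vox[3];
  double org[3];
};

inline bool inside(const Grid& g, const double* p) {
  for (int a = 0; a < 3; ++a) {
    double ci = (p[a] - g.org[a]) / g.vox[a];
    if (ci < -0.5 || ci > g.n[a] - 0.5) return false;
  }
  return true;
}

inline void to_index(const Grid& g, const double* p, double* ci) {
  for (int a = 0; a < 3; ++a) ci[a] = (p[a] - g.org[a]) / g.vox[a];
}

inline int nearest_voxel(const Grid& g, const double* p) {
  int idx[3];
  for (int a = 0; a < 3; ++a) {
    double ci = (p[a] - g.org[a]) / g.vox[a];
    int i = (int)std::lround(ci);
    if (i < 0) i = 0;
    if (i >= g.n[a]) i = g.n[a] - 1;
    idx[a] = i;
  }
  return idx[0] + g.n[0] * (idx[1] + g.n[1] * idx[2]);
}

// trilinear interpolation of `ncomp` 3D volumes stacked in `arr`
// (length n0*n1*n2*ncomp), clamped at the edges
inline void trilerp(const Grid& g, const double* arr, int ncomp,
                    const double* p, double* out) {
  double ci[3];
  to_index(g, p, ci);
  int i0[3];
  double f[3];
  for (int a = 0; a < 3; ++a) {
    double c = ci[a];
    if (c < 0) c = 0;
    if (c > g.n[a] - 1) c = g.n[a] - 1;
    int lo = (int)std::floor(c);
    if (lo > g.n[a] - 2) lo = g.n[a] - 2;
    if (lo < 0) lo = 0;
    i0[a] = lo;
    f[a] = (g.n[a] == 1) ? 0.0 : c - lo;
  }
  const long nxy = (long)g.n[0] * g.n[1];
  const long nvox = nxy * g.n[2];
  double w[8];
  long off[8];
  int m = 0;
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx) {
        int ii = i0[0] + dx; if (ii >= g.n[0]) ii = g.n[0] - 1;
        int jj = i0[1] + dy; if (jj >= g.n[1]) jj = g.n[1] - 1;
        int kk = i0[2] + dz; if (kk >= g.n[2]) kk = g.n[2] - 1;
        w[m] = (dx ? f[0] : 1 - f[0]) * (dy ? f[1] : 1 - f[1]) *
               (dz ? f[2] : 1 - f[2]);
        off[m] = ii + (long)g.n[0] * jj + nxy * kk;
        ++m;
      }
  for (int c = 0; c < ncomp; ++c) {
    const double* v = arr + (long)c * nvox;
    double s = 0;
    for (int k = 0; k < 8; ++k) s += w[k] * v[off[k]];
    out[c] = s;
  }
}

// principal eigenvector of symmetric 3x3 (6 unique comps) by shifted power
// iteration; `v` holds the start direction on entry, the eigenvector on exit
inline void principal_evec(const double* D, double* v, int iters) {
  const double dxx = D[0], dyy = D[1], dzz = D[2];
  const double dxy = D[3], dxz = D[4], dyz = D[5];
  // Gershgorin shift to make the matrix positive definite without flattening
  // the spectrum
  double lb = dxx - std::fabs(dxy) - std::fabs(dxz);
  double lb2 = dyy - std::fabs(dxy) - std::fabs(dyz);
  double lb3 = dzz - std::fabs(dxz) - std::fabs(dyz);
  if (lb2 < lb) lb = lb2;
  if (lb3 < lb) lb = lb3;
  double s = (lb < 0) ? -lb : 0.0;
  s += 1e-12;
  double x = v[0], y = v[1], z = v[2];
  for (int it = 0; it < iters; ++it) {
    double nx = (dxx + s) * x + dxy * y + dxz * z;
    double ny = dxy * x + (dyy + s) * y + dyz * z;
    double nz = dxz * x + dyz * y + (dzz + s) * z;
    double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
    if (nn < 1e-300) { nx = 1; ny = 0; nz = 0; nn = 1; }
    x = nx / nn; y = ny / nn; z = nz / nn;
  }
  v[0] = x; v[1] = y; v[2] = z;
}

enum Term {
  TERM_NONE = 0, TERM_FA = 1, TERM_ANGLE = 2, TERM_TD = 3,
  TERM_MASK = 4, TERM_VOLUME = 5, TERM_MAXLEN = 6
};

struct HalfTrack {
  std::vector<double> pts;  // x,y,z triples, excluding the seed
  int term;
};

struct Params {
  double step, cos_max, fa_lo, fa_hi, min_len, max_len;
  double td_thresh;
  bool use_td, use_mask;
};

}  // namespace

static void propagate(const Grid& g, const double* tens, const double* fa,
                      const double* td, const int* mask, const Params& pp,
                      const double* seed, const double* dir0,
                      int max_steps, HalfTrack& out) {
  double p[3] = {seed[0], seed[1], seed[2]};
  double d[3] = {dir0[0], dir0[1], dir0[2]};
  out.pts.clear();
  out.term = TERM_NONE;
  double D[6];
  for (int step = 0; step < max_steps; ++step) {
    double pn[3] = {p[0] + pp.step * d[0], p[1] + pp.step * d[1],
                    p[2] + pp.step * d[2]};
    if (!inside(g, pn)) { out.term = TERM_VOLUME; return; }
    double fav;
    trilerp(g, fa, 1, pn, &fav);
    if (fav < pp.fa_lo || fav > pp.fa_hi) { out.term = TERM_FA; return; }
    trilerp(g, tens, 6, pn, D);
    double v[3] = {d[0], d[1], d[2]};
    principal_evec(D, v, 24);
    double dot = v[0] * d[0] + v[1] * d[1] + v[2] * d[2];
    if (dot < 0) { v[0] = -v[0]; v[1] = -v[1]; v[2] = -v[2]; dot = -dot; }
    if (dot < pp.cos_max) { out.term = TERM_ANGLE; return; }
    if (pp.use_td && td[nearest_voxel(g, pn)] > pp.td_thresh) {
      out.term = TERM_TD; return;
    }
    if (pp.use_mask && !mask[nearest_voxel(g, pn)]) {
      out.term = TERM_MASK; return;
    }
    out.pts.push_back(pn[0]); out.pts.push_back(pn[1]); out.pts.push_back(pn[2]);
    p[0] = pn[0]; p[1] = pn[1]; p[2] = pn[2];
    d[0] = v[0]; d[1] = v[1]; d[2] = v[2];
  }
  out.term = TERM_MAXLEN;
}

// [[Rcpp::export(name = ".cpp_track")]]
List cpp_track(IntegerVector dim, NumericVector voxel_size,
               NumericVector origin, NumericVector tensors, NumericVector fa,
               NumericMatrix seeds, double step, double max_angle_deg,
               double fa_lo, double fa_hi, double min_len, double max_len,
               SEXP td_map, double td_thresh, SEXP mask_vec) {
  Grid g;
  for (int a = 0; a < 3; ++a) {
    g.n[a] = dim[a];
    g.vox[a] = voxel_size[a];
    g.org[a] = origin[a];
  }
  Params pp;
  pp.step = step;
  pp.cos_max = std::cos(max_angle_deg * M_PI / 180.0);
  pp.fa_lo = fa_lo; pp.fa_hi = fa_hi;
  pp.min_len = min_len; pp.max_len = max_len;
  pp.use_td = td_map != R_NilValue;
  pp.td_thresh = td_thresh;
  pp.use_mask = mask_vec != R_NilValue;
  const double* td = pp.use_td ? REAL(td_map) : nullptr;
  const int* mask = pp.use_mask ? INTEGER(mask_vec) : nullptr;
  const double* tens = REAL(tensors);
  const double* fav = REAL(fa);
  const int nseed = seeds.nrow();
  const int max_steps_total = (int)std::floor(max_len / step + 1e-9);

  std::vector<double> all_pts;
  std::vector<int> npts, term_a, term_b, keep_seed;
  std::vector<double> lengths;
  int n_seed_invalid = 0, n_short = 0;
  HalfTrack back, fwd;
  double D[6];

  for (int si = 0; si < nseed; ++si) {
    double seed[3] = {seeds(si, 0), seeds(si, 1), seeds(si, 2)};
    if (!inside(g, seed)) { ++n_seed_invalid; continue; }
    double fas;
    trilerp(g, fav, 1, seed, &fas);
    if (fas < pp.fa_lo || fas > pp.fa_hi) { ++n_seed_invalid; continue; }
    if (pp.use_td && td[nearest_voxel(g, seed)] > pp.td_thresh) {
      ++n_seed_invalid; continue;
    }
    if (pp.use_mask && !mask[nearest_voxel(g, seed)]) {
      ++n_seed_invalid; continue;
    }
    trilerp(g, tens, 6, seed, D);
    double v0[3] = {1.0, 0.5, 0.25};  // deterministic, genericity-breaking start
    principal_evec(D, v0, 96);
    double neg[3] = {-v0[0], -v0[1], -v0[2]};
    propagate(g, tens, fav, td, mask, pp, seed, neg, max_steps_total, back);
    int used = (int)back.pts.size() / 3;
    propagate(g, tens, fav, td, mask, pp, seed, v0, max_steps_total - used, fwd);
    int nf = (int)fwd.pts.size() / 3;
    int ntot = used + 1 + nf;
    double len = (ntot - 1) * pp.step;
    if (len < pp.min_len) { ++n_short; continue; }
    // assemble: reversed backward half, seed, forward half
    for (int i = used - 1; i >= 0; --i) {
      all_pts.push_back(back.pts[3 * i]);
      all_pts.push_back(back.pts[3 * i + 1]);
      all_pts.push_back(back.pts[3 * i + 2]);
    }
    all_pts.push_back(seed[0]); all_pts.push_back(seed[1]); all_pts.push_back(seed[2]);
    for (size_t i = 0; i < fwd.pts.size(); ++i) all_pts.push_back(fwd.pts[i]);
    npts.push_back(ntot);
    lengths.push_back(len);
    term_a.push_back(back.term == TERM_NONE ? TERM_MAXLEN : back.term);
    term_b.push_back(fwd.term == TERM_NONE ? TERM_MAXLEN : fwd.term);
    keep_seed.push_back(si + 1);
  }

  const int ns = (int)npts.size();
  NumericMatrix pts((int)(all_pts.size() / 3), 3);
  for (size_t i = 0; i < all_pts.size() / 3; ++i) {
    pts(i, 0) = all_pts[3 * i];
    pts(i, 1) = all_pts[3 * i + 1];
    pts(i, 2) = all_pts[3 * i + 2];
  }
  return List::create(
      _["points"] = pts, _["n_points"] = IntegerVector(npts.begin(), npts.end()),
      _["length"] = NumericVector(lengths.begin(), lengths.end()),
      _["term_first"] = IntegerVector(term_a.begin(), term_a.end()),
      _["term_last"] = IntegerVector(term_b.begin(), term_b.end()),
      _["seed_index"] = IntegerVector(keep_seed.begin(), keep_seed.end()),
      _["n_seed_invalid"] = n_seed_invalid, _["n_short"] = n_short,
      _["n_streamlines"] = ns);
}

// Amanatides & Woo traversal of one segment; stamps visited voxels
static void walk_segment(const Grid& g, const double* p0, const double* p1,
                         int stream_id, std::vector<int>& stamp,
                         std::vector<double>& counts) {
  double c0[3], c1[3];
  to_index(g, p0, c0);
  to_index(g, p1, c1);
  int idx[3], end_idx[3], stepdir[3];
  double tmax[3], tdelta[3];
  for (int a = 0; a < 3; ++a) {
    int i = (int)std::lround(c0[a]);
    if (i < 0) i = 0;
    if (i >= g.n[a]) i = g.n[a] - 1;
    idx[a] = i;
    int e = (int)std::lround(c1[a]);
    if (e < 0) e = 0;
    if (e >= g.n[a]) e = g.n[a] - 1;
    end_idx[a] = e;
    double d = c1[a] - c0[a];
    if (d > 1e-12) {
      stepdir[a] = 1;
      tmax[a] = ((idx[a] + 0.5) - c0[a]) / d;
      tdelta[a] = 1.0 / d;
    } else if (d < -1e-12) {
      stepdir[a] = -1;
      tmax[a] = ((idx[a] - 0.5) - c0[a]) / d;
      tdelta[a] = -1.0 / d;
    } else {
      stepdir[a] = 0;
      tmax[a] = R_PosInf;
      tdelta[a] = R_PosInf;
    }
  }
  const long nxy = (long)g.n[0] * g.n[1];
  for (int guard = 0; guard < 4 * (g.n[0] + g.n[1] + g.n[2]); ++guard) {
    long lin = idx[0] + (long)g.n[0] * idx[1] + nxy * idx[2];
    if (stamp[lin] != stream_id) {
      stamp[lin] = stream_id;
      counts[lin] += 1.0;
    }
    if (idx[0] == end_idx[0] && idx[1] == end_idx[1] && idx[2] == end_idx[2])
      return;
    int a = 0;
    if (tmax[1] < tmax[a]) a = 1;
    if (tmax[2] < tmax[a]) a = 2;
    idx[a] += stepdir[a];
    if (idx[a] < 0 || idx[a] >= g.n[a]) return;
    tmax[a] += tdelta[a];
  }
}

// [[Rcpp::export(name = ".cpp_td_counts")]]
NumericVector cpp_td_counts(IntegerVector dim, NumericVector voxel_size,
                            NumericVector origin, NumericMatrix points,
                            IntegerVector n_points) {
  Grid g;
  for (int a = 0; a < 3; ++a) {
    g.n[a] = dim[a];
    g.vox[a] = voxel_size[a];
    g.org[a] = origin[a];
  }
  const long nvox = (long)g.n[0] * g.n[1] * g.n[2];
  std::vector<double> counts(nvox, 0.0);
  std::vector<int> stamp(nvox, -1);
  long pos = 0;
  for (int s = 0; s < n_points.size(); ++s) {
    int np = n_points[s];
    for (int i = 0; i + 1 < np; ++i) {
      double p0[3] = {points(pos + i, 0), points(pos + i, 1), points(pos + i, 2)};
      double p1[3] = {points(pos + i + 1, 0), points(pos + i + 1, 1),
                      points(pos + i + 1, 2)};
      walk_segment(g, p0, p1, s, stamp, counts);
    }
    if (np == 1) {  // a degenerate single-point streamline still visits its voxel
      double p0[3] = {points(pos, 0), points(pos, 1), points(pos, 2)};
      walk_segment(g, p0, p0, s, stamp, counts);
    }
    pos += np;
  }
  NumericVector out(counts.begin(), counts.end());
  out.attr("dim") = dim;
  return out;
}
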