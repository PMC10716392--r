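#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Scattering amplitude A_k(q) = sum_j w_jk exp(i q . r_j) for K weight
// columns sharing one set of positions (e.g. SAXS/SANS_H2O/SANS_D2O in one
// pass).  pos: N x 3 (nm), W: N x K, Q: M x 3 (nm^-1).  Returns M x K.
// [[Rcpp::export]]
ComplexMatrix amplitude_kernel(NumericMatrix pos, NumericMatrix W,
                               NumericMatrix Q) {
  const int n = pos.nrow(), k = W.ncol(), m = Q.nrow();
  if (W.nrow() != n) stop("weight rows must match atom count");
  ComplexMatrix out(m, k);
  std::vector<double> re(k), im(k);
  for (int iq = 0; iq < m; ++iq) {
    const double qx = Q(iq, 0), qy = Q(iq, 1), qz = Q(iq, 2);
    std::fill(re.begin(), re.end(), 0.0);
    std::fill(im.begin(), im.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      const double ph = qx * pos(j, 0) + qy * pos(j, 1) + qz * pos(j, 2);
      const double c = std::cos(ph), s = std::sin(ph);
      for (int l = 0; l < k; ++l) {
        const double w = W(j, l);
        re[l] += w * c;
        im[l] += w * s;
      }
    }
    for (int l = 0; l < k; ++l) {
      out(iq, l).r = re[l];
      out(iq, l).i = im[l];
    }
  }
  return out;
}

// Minimum Euclidean distance from each point to a reference set.
// [[Rcpp::export]]
NumericVector min_dist_kernel(NumericMatrix pts, NumericMatrix ref) {
  const int n = pts.nrow(), r = ref.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < r; ++j) {
      const double dx = x - ref(j, 0), dy = y - ref(j, 1), dz = z - ref(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Debye double sum I(q) = sum_jk f_j f_k sinc(q r_jk) for constant per-atom
// weights; the brute-force orientational average used as an oracle.
// [[Rcpp::export]]
NumericVector debye_kernel(NumericMatrix pos, NumericVector w,
                           NumericVector q) {
  const int n = pos.nrow(), m = q.size();
  NumericVector out(m);
  for (int iq = 0; iq < m; ++iq) {
    const double qq = q[iq];
    double acc = 0.0;
    for (int j = 0; j < n; ++j) {
      acc += w[j] * w[j];
      for (int k = j + 1; k < n; ++k) {
        const double dx = pos(j, 0) - pos(k, 0), dy = pos(j, 1) - pos(k, 1),
                     dz = pos(j, 2) - pos(k, 2);
        const double rr = std::sqrt(dx * dx + dy * dy + dz * dz);
        const double x = qq * rr;
        const double sinc = (x < 1e-12) ? 1.0 : std::sin(x) / x;
        acc += 2.0 * w[j] * w[k] * sinc;
      }
    }
    out[iq] = acc;
  }
  return out;
}

namespace {

struct SphereGrid {
  // direction -> candidate icosphere faces, via a theta/phi bucket grid
  int nth, nph;
  std::vector<std::vector<int> > faces_in_cell;

  int cell_of(double x, double y, double z) const {
    const double r = std::sqrt(x * x + y * y + z * z);
    const double ct = (r > 0) ? z / r : 1.0;
    int it = (int)std::floor((ct + 1.0) * 0.5 * nth);
    if (it < 0) it = 0;
    if (it >= nth) it = nth - 1;
    double ph = std::atan2(y, x);
    if (ph < 0) ph += 2.0 * M_PI;
    int ip = (int)std::floor(ph / (2.0 * M_PI) * nph);
    if (ip < 0) ip = 0;
    if (ip >= nph) ip = nph - 1;
    return it * nph + ip;
  }
};

inline double det3(const double *a, const double *b, const double *c) {
  return a[0] * (b[1] * c[2] - b[2] * c[1]) -
         a[1] * (b[0] * c[2] - b[2] * c[0]) +
         a[2] * (b[0] * c[1] - b[1] * c[0]);
}

} // namespace

// Radius of the star-shaped surface along each query direction: the radial
// field is the spherical-barycentric linear interpolation of the vertex
// radii over the icosphere triangle containing the direction (monotone in
// the radii, so nested radii give nested surfaces).  dirs: V x 3 unit
// vertex directions, faces: F x 3 (1-based), radii: V, query: M x 3
// (directions, need not be unit, relative to center).  Returns M radii.
// [[Rcpp::export]]
NumericVector surface_radius_kernel(NumericMatrix dirs, IntegerMatrix faces,
                                    NumericVector radii, NumericMatrix query) {
  const int V = dirs.nrow(), F = faces.nrow(), M = query.nrow();
  if ((int)radii.size() != V) stop("radii length must match vertex count");

  // bucket faces by the cells their vertex directions fall in, padded by
  // registering each face in the cells of its vertices and its centroid;
  // query falls back to a full scan if no bucketed candidate contains it.
  SphereGrid grid;
  grid.nth = std::max(4, (int)std::floor(std::sqrt((double)F / 8.0)));
  grid.nph = 2 * grid.nth;
  grid.faces_in_cell.assign(grid.nth * grid.nph, std::vector<int>());
  for (int f = 0; f < F; ++f) {
    double cx = 0, cy = 0, cz = 0;
    int cells[4];
    for (int v = 0; v < 3; ++v) {
      const int idx = faces(f, v) - 1;
      cells[v] = grid.cell_of(dirs(idx, 0), dirs(idx, 1), dirs(idx, 2));
      cx += dirs(idx, 0);
      cy += dirs(idx, 1);
      cz += dirs(idx, 2);
    }
    cells[3] = grid.cell_of(cx, cy, cz);
    for (int v = 0; v < 4; ++v) {
      bool seen = false;
      for (int u = 0; u < v; ++u)
        if (cells[u] == cells[v]) seen = true;
      if (!seen) grid.faces_in_cell[cells[v]].push_back(f);
    }
  }

  const double eps = -1e-10;
  NumericVector out(M);
  for (int i = 0; i < M; ++i) {
    double d[3] = {query(i, 0), query(i, 1), query(i, 2)};
    const double dn = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (dn < 1e-14) { // center: report max radius, point is trivially inside
      double mx = 0;
      for (int v = 0; v < V; ++v)
        if (radii[v] > mx) mx = radii[v];
      out[i] = mx;
      continue;
    }
    d[0] /= dn; d[1] /= dn; d[2] /= dn;

    double found = -1.0;
    const std::vector<int> &cand = grid.faces_in_cell[grid.cell_of(d[0], d[1], d[2])];
    for (int pass = 0; pass < 2 && found < 0; ++pass) {
      const int ncand = (pass == 0) ? (int)cand.size() : F;
      double best_minbc = -1e30;
      int best_f = -1;
      for (int c = 0; c < ncand; ++c) {
        const int f = (pass == 0) ? cand[c] : c;
        const int a = faces(f, 0) - 1, b = faces(f, 1) - 1, cc = faces(f, 2) - 1;
        double va[3] = {dirs(a, 0), dirs(a, 1), dirs(a, 2)};
        double vb[3] = {dirs(b, 0), dirs(b, 1), dirs(b, 2)};
        double vc[3] = {dirs(cc, 0), dirs(cc, 1), dirs(cc, 2)};
        const double s1 = det3(va, vb, d), s2 = det3(vb, vc, d), s3 = det3(vc, va, d);
        const double mn = std::min(s1, std::min(s2, s3));
        if (mn > best_minbc) { best_minbc = mn; best_f = f; }
        if (s1 >= eps && s2 >= eps && s3 >= eps) {
          // barycentric radial interpolation; s2, s3, s1 are the weights of
          // vertices a, b, c respectively
          const double tot = s1 + s2 + s3;
          if (tot > 1e-300) {
            found = (s2 * radii[a] + s3 * radii[b] + s1 * radii[cc]) / tot;
            break;
          }
        }
      }
      // numerical sliver on the full scan: take the face that came closest
      if (pass == 1 && found < 0 && best_f >= 0) {
        const int a = faces(best_f, 0) - 1;
        found = radii[a];
      }
    }
    out[i] = found;
  }
  return out;
}

// Fast path for a uniform |q| ladder sharing one direction set:
// Q(s, d) = (q0 + s*dq) * dir_d.  Per atom and direction the phase factors
// advance by a fixed complex rotation, replacing nq sincos calls by nq
// complex multiplies.  Returns (nq*ndir) x K with |q| as the slow index,
// matching an outer product of q over directions.
// [[Rcpp::export]]
ComplexMatrix amplitude_ladder_kernel(NumericMatrix pos, NumericMatrix W,
                                      NumericMatrix dirs, double q0,
                                      double dq, int nq) {
  const int n = pos.nrow(), k = W.ncol(), nd = dirs.nrow();
  if (W.nrow() != n) stop("weight rows must match atom count");
  const int m = nq * nd;
  std::vector<double> re((size_t)m * k, 0.0), im((size_t)m * k, 0.0);
  for (int d = 0; d < nd; ++d) {
    const double dx = dirs(d, 0), dy = dirs(d, 1), dz = dirs(d, 2);
    for (int j = 0; j < n; ++j) {
      const double t = dx * pos(j, 0) + dy * pos(j, 1) + dz * pos(j, 2);
      double cr = std::cos(q0 * t), ci = std::sin(q0 * t);
      const double rr = std::cos(dq * t), ri = std::sin(dq * t);
      for (int s = 0; s < nq; ++s) {
        const size_t base = ((size_t)s * nd + d) * k;
        for (int l = 0; l < k; ++l) {
          const double w = W(j, l);
          re[base + l] += w * cr;
          im[base + l] += w * ci;
        }
        const double nc = cr * rr - ci * ri;
        ci = cr * ri + ci * rr;
        cr = nc;
      }
    }
  }
  ComplexMatrix out(m, k);
  for (int i = 0; i < m; ++i)
    for (int l = 0; l < k; ++l) {
      out(i, l).r = re[(size_t)i * k + l];
      out(i, l).i = im[(size_t)i * k + l];
    }
  return out;
}
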