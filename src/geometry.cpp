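// Geometry kernels: kd-tree nearest neighbour, point-to-plane ICP,
// ray-triangle intersection. All distances in mm; indices returned 1-based.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// ---- kd-tree over a fixed 3D point set --------------------------------

struct KDNode {
  int axis;          // split axis, -1 for leaf
  double split;
  int left, right;   // node indices, -1 if none
  int begin, end;    // range into idx for leaves
};

struct KDTree {
  const arma::mat &pts;     // n x 3
  std::vector<int> idx;     // permutation of 0..n-1
  std::vector<KDNode> nodes;
  static const int LEAF = 12;

  explicit KDTree(const arma::mat &p) : pts(p) {
    idx.resize(p.n_rows);
    for (size_t i = 0; i < p.n_rows; ++i) idx[i] = (int)i;
    if (!idx.empty()) build(0, (int)idx.size());
  }

  int build(int begin, int end) {
    KDNode nd;
    if (end - begin <= LEAF) {
      nd.axis = -1; nd.split = 0; nd.left = nd.right = -1;
      nd.begin = begin; nd.end = end;
      nodes.push_back(nd);
      return (int)nodes.size() - 1;
    }
    // widest-spread axis
    arma::vec lo(3, arma::fill::value(arma::datum::inf));
    arma::vec hi(3, arma::fill::value(-arma::datum::inf));
    for (int i = begin; i < end; ++i)
      for (int d = 0; d < 3; ++d) {
        double v = pts(idx[i], d);
        if (v < lo[d]) lo[d] = v;
        if (v > hi[d]) hi[d] = v;
      }
    int ax = (int)(hi - lo).index_max();
    int mid = (begin + end) / 2;
    std::nth_element(idx.begin() + begin, idx.begin() + mid, idx.begin() + end,
                     [&](int a, int b) {
                       double va = pts(a, ax), vb = pts(b, ax);
                       if (va != vb) return va < vb;
                       return a < b;  // deterministic
                     });
    nd.axis = ax; nd.split = pts(idx[mid], ax);
    nd.begin = nd.end = -1;
    int me = (int)nodes.size();
    nodes.push_back(nd);
    int l = build(begin, mid);
    int r = build(mid, end);
    nodes[me].left = l; nodes[me].right = r;
    return me;
  }

  // nearest neighbour with lowest-index tie-break
  void query(const double *q, int node, int &best, double &bestd2) const {
    const KDNode &nd = nodes[node];
    if (nd.axis < 0) {
      for (int i = nd.begin; i < nd.end; ++i) {
        int j = idx[i];
        double dx = pts(j, 0) - q[0], dy = pts(j, 1) - q[1], dz = pts(j, 2) - q[2];
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < bestd2 || (d2 == bestd2 && j < best)) { bestd2 = d2; best = j; }
      }
      return;
    }
    double diff = q[nd.axis] - nd.split;
    int near = diff <= 0 ? nd.left : nd.right;
    int far  = diff <= 0 ? nd.right : nd.left;
    query(q, near, best, bestd2);
    if (diff * diff <= bestd2) query(q, far, best, bestd2);
  }

  void nn(const double *q, int &best, double &d2) const {
    best = -1; d2 = arma::datum::inf;
    query(q, 0, best, d2);
  }
};

arma::mat33 expso3(const arma::vec3 &w) {
  double th = arma::norm(w);
  arma::mat33 I(arma::fill::eye);
  if (th < 1e-12) return I;
  arma::vec3 a = w / th;
  arma::mat33 K = {{0, -a[2], a[1]}, {a[2], 0, -a[0]}, {-a[1], a[0], 0}};
  return I + std::sin(th) * K + (1.0 - std::cos(th)) * (K * K);
}

arma::mat33 reorthonormalize(const arma::mat33 &R) {
  arma::mat U, V; arma::vec s;
  arma::svd(U, s, V, arma::mat(R));
  arma::mat33 Q = U * V.t();
  if (arma::det(Q) < 0) { U.col(2) *= -1.0; Q = U * V.t(); }
  return Q;
}

}  // namespace

// For each query row, index (1-based) of and distance to the nearest
// reference row; deterministic lowest-index tie-break.
// [[Rcpp::export]]
List cpp_nearest(const arma::mat &query, const arma::mat &ref) {
  KDTree tree(ref);
  int n = (int)query.n_rows;
  IntegerVector out_idx(n);
  NumericVector out_dist(n);
  for (int i = 0; i < n; ++i) {
    double q[3] = {query(i, 0), query(i, 1), query(i, 2)};
    int best; double d2;
    tree.nn(q, best, d2);
    out_idx[i] = best + 1;
    out_dist[i] = std::sqrt(d2);
  }
  return List::create(_["index"] = out_idx, _["distance"] = out_dist);
}

// Point-to-plane ICP of `moving` onto (`fixed`, `fixed_normals`), starting at
// (R0, t0), with staged correspondence-rejection thresholds. An iteration is
// accepted only if the correspondence RMS does not increase; convergence when
// the relative RMS change drops below `tol`.
// [[Rcpp::export]]
List cpp_icp_point_to_plane(const arma::mat &moving, const arma::mat &fixed,
                            const arma::mat &fixed_normals,
                            const arma::mat &R0, const arma::vec &t0,
                            const arma::vec &thresholds, double tol,
                            int max_iter) {
  KDTree tree(fixed);
  arma::mat33 R = R0; arma::vec3 t = t0;
  int n = (int)moving.n_rows;
  int iterations = 0, n_corr = 0;
  bool converged = false, failed = false;
  double rms = NA_REAL;
  std::vector<double> trace;

  auto correspond = [&](const arma::mat33 &Rc, const arma::vec3 &tc, double thr,
                        std::vector<int> &mi, std::vector<int> &fi,
                        double &rms_out) {
    mi.clear(); fi.clear();
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      arma::vec3 p = Rc * moving.row(i).t() + tc;
      double q[3] = {p[0], p[1], p[2]};
      int best; double d2;
      tree.nn(q, best, d2);
      if (std::sqrt(d2) <= thr) {
        arma::vec3 d = p - fixed.row(best).t();
        double r = arma::dot(d, fixed_normals.row(best).t());
        ss += r * r;
        mi.push_back(i); fi.push_back(best);
      }
    }
    rms_out = mi.empty() ? NA_REAL : std::sqrt(ss / mi.size());
  };

  for (size_t s = 0; s < thresholds.n_elem && !failed; ++s) {
    double thr = thresholds[s];
    double prev_rms = arma::datum::inf;
    arma::mat33 R_prev = R; arma::vec3 t_prev = t;
    for (;;) {
      std::vector<int> mi, fi;
      double rms_now;
      correspond(R, t, thr, mi, fi, rms_now);
      if ((int)mi.size() < 3) { failed = true; break; }
      if (rms_now > prev_rms + 1e-12) {  // overshoot: revert, end stage
        R = R_prev; t = t_prev; rms = prev_rms; break;
      }
      rms = rms_now; n_corr = (int)mi.size();
      trace.push_back(rms_now);
      if (rms_now < 1e-12 ||  // at numerical floor: a fixed point
          prev_rms - rms_now <= tol * std::max(rms_now, 1e-12)) {
        converged = true; break;
      }
      if (iterations >= max_iter) break;
      // 6x6 normal equations for (omega, dt)
      arma::mat A(6, 6, arma::fill::zeros);
      arma::vec b(6, arma::fill::zeros);
      for (size_t k = 0; k < mi.size(); ++k) {
        arma::vec3 p = R * moving.row(mi[k]).t() + t;
        arma::vec3 nrm = fixed_normals.row(fi[k]).t();
        arma::vec3 q = fixed.row(fi[k]).t();
        double r = arma::dot(p - q, nrm);
        arma::vec J(6);
        arma::vec3 cxn = arma::cross(p, nrm);
        J[0] = cxn[0]; J[1] = cxn[1]; J[2] = cxn[2];
        J[3] = nrm[0]; J[4] = nrm[1]; J[5] = nrm[2];
        A += J * J.t();
        b -= r * J;
      }
      arma::vec x;
      if (!arma::solve(x, A, b, arma::solve_opts::likely_sympd)) { failed = true; break; }
      arma::mat33 Rd = expso3(x.subvec(0, 2));
      R_prev = R; t_prev = t; prev_rms = rms_now;
      R = reorthonormalize(Rd * R);
      t = Rd * t + x.subvec(3, 5);
      ++iterations;
    }
  }
  return List::create(
      _["rotation"] = R, _["translation"] = t, _["rms_residual"] = rms,
      _["n_correspondences"] = n_corr, _["iterations"] = iterations,
      _["converged"] = converged && !failed, _["failed"] = failed,
      _["rms_trace"] = trace);
}

// Intersections of the line origin + s*dir with a triangle mesh
// (Moller-Trumbore). mode 0: smallest s in [smin, smax]; mode 1: smallest |s|
// with s in [smin, smax]. Returns NA when no intersection lies in range.
// [[Rcpp::export]]
double cpp_ray_mesh(const arma::vec &origin, const arma::vec &dir,
                    const arma::mat &vertices, const arma::imat &faces,
                    double smin, double smax, int mode) {
  const double EPS = 1e-12;
  double best = NA_REAL;
  bool have = false;
  for (size_t f = 0; f < faces.n_rows; ++f) {
    arma::vec3 v0 = vertices.row(faces(f, 0)).t();
    arma::vec3 e1 = vertices.row(faces(f, 1)).t() - v0;
    arma::vec3 e2 = vertices.row(faces(f, 2)).t() - v0;
    arma::vec3 pv = arma::cross(dir, e2);
    double det = arma::dot(e1, pv);
    if (std::fabs(det) < EPS) continue;
    double inv = 1.0 / det;
    arma::vec3 tv = origin - v0;
    double u = arma::dot(tv, pv) * inv;
    if (u < -1e-9 || u > 1.0 + 1e-9) continue;
    arma::vec3 qv = arma::cross(tv, e1);
    double v = arma::dot(dir, qv) * inv;
    if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
    double s = arma::dot(e2, qv) * inv;
    if (s < smin || s > smax) continue;
    bool better = !have || (mode == 0 ? s < best : std::fabs(s) < std::fabs(best));
    if (better) { best = s; have = true; }
  }
  return have ? best : NA_REAL;
}

// Batched cpp_ray_mesh over rows of `origins`/`dirs`.
// [[Rcpp::export]]
NumericVector cpp_ray_mesh_batch(const arma::mat &origins, const arma::mat &dirs,
                                 const arma::mat &vertices, const arma::imat &faces,
                                 double smin, double smax, int mode) {
  int n = (int)origins.n_rows;
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = cpp_ray_mesh(origins.row(i).t(), dirs.row(i).t(), vertices, faces,
                          smin, smax, mode);
  return out;
}
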