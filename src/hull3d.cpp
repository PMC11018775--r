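#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Incremental 3D convex hull, returning the faces of the LOWER hull
// (outward normal with negative z component) as 1-based vertex indices.
// Used to construct the convex envelope of a free-energy surface sampled on
// the composition simplex: points are (phi1, phi2, f).

namespace {

struct Face {
  int a, b, c;        // vertex indices (0-based)
  double nx, ny, nz;  // outward normal
  double d;           // plane offset: dot(n, x) = d on the plane
  bool alive;
};

inline void face_plane(Face& f, const std::vector<double>& X,
                       const std::vector<double>& Y, const std::vector<double>& Z) {
  double ux = X[f.b] - X[f.a], uy = Y[f.b] - Y[f.a], uz = Z[f.b] - Z[f.a];
  double vx = X[f.c] - X[f.a], vy = Y[f.c] - Y[f.a], vz = Z[f.c] - Z[f.a];
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  f.d = f.nx * X[f.a] + f.ny * Y[f.a] + f.nz * Z[f.a];
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_lower_hull3(const NumericMatrix& pts, double eps_rel = 1e-9) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points for a 3D hull");
  std::vector<double> X(n), Y(n), Z(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    X[i] = pts(i, 0); Y[i] = pts(i, 1); Z[i] = pts(i, 2);
    scale = std::max(scale, std::fabs(X[i]));
    scale = std::max(scale, std::fabs(Y[i]));
    scale = std::max(scale, std::fabs(Z[i]));
  }
  const double eps = eps_rel * std::max(1.0, scale * scale * scale);

  // initial tetrahedron: four points in general position
  int i0 = 0;
  for (int i = 1; i < n; ++i)
    if (X[i] < X[i0] || (X[i] == X[i0] && (Y[i] < Y[i0] || (Y[i] == Y[i0] && Z[i] < Z[i0]))))
      i0 = i;
  int i1 = -1; double best = -1.0;
  for (int i = 0; i < n; ++i) {
    double dx = X[i] - X[i0], dy = Y[i] - Y[i0], dz = Z[i] - Z[i0];
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 > best) { best = d2; i1 = i; }
  }
  int i2 = -1; best = eps;
  for (int i = 0; i < n; ++i) {
    double ux = X[i1] - X[i0], uy = Y[i1] - Y[i0], uz = Z[i1] - Z[i0];
    double vx = X[i] - X[i0], vy = Y[i] - Y[i0], vz = Z[i] - Z[i0];
    double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
    double a2 = cx * cx + cy * cy + cz * cz;
    if (a2 > best) { best = a2; i2 = i; }
  }
  if (i2 < 0) stop("points are collinear; no 3D hull");
  int i3 = -1; best = eps;
  {
    Face f0; f0.a = i0; f0.b = i1; f0.c = i2;
    face_plane(f0, X, Y, Z);
    for (int i = 0; i < n; ++i) {
      double v = std::fabs(f0.nx * X[i] + f0.ny * Y[i] + f0.nz * Z[i] - f0.d);
      if (v > best) { best = v; i3 = i; }
    }
  }
  if (i3 < 0) stop("points are coplanar; no 3D hull");

  double cx = (X[i0] + X[i1] + X[i2] + X[i3]) / 4.0;
  double cy = (Y[i0] + Y[i1] + Y[i2] + Y[i3]) / 4.0;
  double cz = (Z[i0] + Z[i1] + Z[i2] + Z[i3]) / 4.0;

  std::vector<Face> faces;
  faces.reserve(8 * (size_t)std::sqrt((double)n) + 64);
  int tet[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
  for (int t = 0; t < 4; ++t) {
    Face f; f.a = tet[t][0]; f.b = tet[t][1]; f.c = tet[t][2]; f.alive = true;
    face_plane(f, X, Y, Z);
    if (f.nx * cx + f.ny * cy + f.nz * cz - f.d > 0) { // orient outward
      std::swap(f.b, f.c);
      face_plane(f, X, Y, Z);
    }
    faces.push_back(f);
  }

  std::vector<bool> used(n, false);
  used[i0] = used[i1] = used[i2] = used[i3] = true;

  for (int p = 0; p < n; ++p) {
    if (used[p]) continue;
    used[p] = true;
    // visible faces
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      double v = faces[f].nx * X[p] + faces[f].ny * Y[p] + faces[f].nz * Z[p] - faces[f].d;
      if (v > eps) vis.push_back((int)f);
    }
    if (vis.empty()) continue; // inside hull
    // horizon edges: edges of visible faces occurring exactly once
    std::map<std::pair<int,int>, std::pair<int,int> > edges; // undirected -> (count, oriented-first)
    for (size_t k = 0; k < vis.size(); ++k) {
      Face& f = faces[vis[k]];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int t = 0; t < 3; ++t) {
        int u = e[t][0], v = e[t][1];
        std::pair<int,int> key = u < v ? std::make_pair(u, v) : std::make_pair(v, u);
        std::map<std::pair<int,int>, std::pair<int,int> >::iterator it = edges.find(key);
        if (it == edges.end()) edges[key] = std::make_pair(1, u);
        else it->second.first += 1;
      }
      f.alive = false;
    }
    for (std::map<std::pair<int,int>, std::pair<int,int> >::iterator it = edges.begin();
         it != edges.end(); ++it) {
      if (it->second.first != 1) continue;
      // keep the orientation the dead face used so the new face is outward
      int u = it->second.second;
      int v = (it->first.first == u) ? it->first.second : it->first.first;
      Face f; f.a = u; f.b = v; f.c = p; f.alive = true;
      face_plane(f, X, Y, Z);
      if (f.nx * cx + f.ny * cy + f.nz * cz - f.d > eps) {
        std::swap(f.b, f.c);
        face_plane(f, X, Y, Z);
      }
      faces.push_back(f);
    }
    // compact occasionally to keep the scan cheap
    if (faces.size() > 64 && faces.size() % 4096 == 0) {
      std::vector<Face> keep;
      keep.reserve(faces.size());
      for (size_t f = 0; f < faces.size(); ++f)
        if (faces[f].alive) keep.push_back(faces[f]);
      faces.swap(keep);
    }
  }

  // collect lower-hull faces (outward normal pointing downward in z)
  std::vector<int> keepi;
  for (size_t f = 0; f < faces.size(); ++f)
    if (faces[f].alive && faces[f].nz < -eps) keepi.push_back((int)f);
  IntegerMatrix out((int)keepi.size(), 3);
  for (size_t k = 0; k < keepi.size(); ++k) {
    out(k, 0) = faces[keepi[k]].a + 1;
    out(k, 1) = faces[keepi[k]].b + 1;
    out(k, 2) = faces[keepi[k]].c + 1;
  }
  return out;
}
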