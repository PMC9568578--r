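#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 3D topology-preserving curve thinning with (26, 6) connectivity.
// A voxel is deletable when it is "simple" (removal preserves both the
// foreground 26-topology and the background 6-topology of its 3x3x3
// neighbourhood) and not a curve endpoint. Deletion proceeds in six
// directional sub-iterations (U/D/N/S/E/W border voxels), sequentially with
// re-checking, until stable. The result is a <= 1 voxel wide curve skeleton.

namespace {

struct Off { int dx, dy, dz; };

// all 26 neighbourhood offsets (max-norm 1, not the centre)
static std::vector<Off> off26() {
  std::vector<Off> v;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        if (dx || dy || dz) v.push_back({dx, dy, dz});
  return v;
}

static const std::vector<Off>& O26() { static std::vector<Off> v = off26(); return v; }

// index of offset within the 3x3x3 cube (0..26), centre = 13
inline int cube_idx(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

// number of 26-connected components of the foreground within N26*
static int n_fg_components(const bool nb[27]) {
  int comp = 0;
  bool seen[27] = {false};
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++comp;
    std::queue<int> q; q.push(i); seen[i] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int nx = cx + dx, ny = cy + dy, nz = cz + dz;
            if (nx < 0 || nx > 2 || ny < 0 || ny > 2 || nz < 0 || nz > 2) continue;
            int j = nx + 3 * ny + 9 * nz;
            if (j == 13 || j == c || seen[j] || !nb[j]) continue;
            seen[j] = true; q.push(j);
          }
    }
  }
  return comp;
}

// number of 6-connected components of the background within N18 that are
// 6-adjacent to the centre (i.e. contain a face neighbour)
static int n_bg_components(const bool nb[27]) {
  // N18: offsets with max-norm 1 and at most two non-zero coordinates
  auto in18 = [](int i) {
    if (i == 13) return false;
    int dx = i % 3 - 1, dy = (i / 3) % 3 - 1, dz = i / 9 - 1;
    return std::abs(dx) + std::abs(dy) + std::abs(dz) <= 2;
  };
  auto is_face = [](int i) {
    int dx = i % 3 - 1, dy = (i / 3) % 3 - 1, dz = i / 9 - 1;
    return std::abs(dx) + std::abs(dy) + std::abs(dz) == 1;
  };
  bool seen[27] = {false};
  int comp = 0;
  for (int i = 0; i < 27; ++i) {
    if (!in18(i) || nb[i] || seen[i] || !is_face(i)) continue;
    // BFS over background cells of N18 with 6-adjacency, seeded at a face cell
    ++comp;
    std::queue<int> q; q.push(i); seen[i] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      const int steps[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (auto& s : steps) {
        int nx = cx + s[0], ny = cy + s[1], nz = cz + s[2];
        if (nx < 0 || nx > 2 || ny < 0 || ny > 2 || nz < 0 || nz > 2) continue;
        int j = nx + 3 * ny + 9 * nz;
        if (j == 13 || seen[j] || !in18(j) || nb[j]) continue;
        seen[j] = true; q.push(j);
      }
    }
  }
  return comp;
}

class Grid {
public:
  Grid(const LogicalVector& mask, const IntegerVector& dims)
    : d1(dims[0]), d2(dims[1]), d3(dims[2]), fg(mask.size()) {
    for (R_xlen_t i = 0; i < mask.size(); ++i) fg[i] = mask[i] == TRUE;
  }
  int d1, d2, d3;
  std::vector<char> fg;
  inline bool at(int x, int y, int z) const {
    if (x < 0 || x >= d1 || y < 0 || y >= d2 || z < 0 || z >= d3) return false;
    return fg[(size_t)x + (size_t)d1 * ((size_t)y + (size_t)d2 * z)] != 0;
  }
  inline size_t lin(int x, int y, int z) const {
    return (size_t)x + (size_t)d1 * ((size_t)y + (size_t)d2 * z);
  }
  void neighbourhood(int x, int y, int z, bool nb[27]) const {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          nb[cube_idx(dx, dy, dz)] = (dx || dy || dz) ? at(x + dx, y + dy, z + dz) : false;
  }
  int n26(int x, int y, int z) const {
    int n = 0;
    for (const auto& o : O26()) if (at(x + o.dx, y + o.dy, z + o.dz)) ++n;
    return n;
  }
  bool simple(int x, int y, int z) const {
    bool nb[27];
    neighbourhood(x, y, z, nb);
    return n_fg_components(nb) == 1 && n_bg_components(nb) == 1;
  }
};

} // namespace

// [[Rcpp::export(name = ".thin3d_cpp")]]
LogicalVector thin3d_cpp(LogicalVector mask, IntegerVector dims) {
  if (dims.size() != 3) stop("dims must have length 3");
  Grid g(mask, dims);
  const int dirs[6][3] = {{0,0,1},{0,0,-1},{0,1,0},{0,-1,0},{1,0,0},{-1,0,0}};
  bool changed = true;
  std::vector<size_t> cand;
  std::vector<int> cx, cy, cz;
  while (changed) {
    changed = false;
    for (auto& dir : dirs) {
      cand.clear(); cx.clear(); cy.clear(); cz.clear();
      for (int z = 0; z < g.d3; ++z)
        for (int y = 0; y < g.d2; ++y)
          for (int x = 0; x < g.d1; ++x) {
            if (!g.at(x, y, z)) continue;
            if (g.at(x + dir[0], y + dir[1], z + dir[2])) continue; // not a border in this direction
            int n = g.n26(x, y, z);
            if (n <= 1) continue;                 // endpoint or isolated: keep
            if (!g.simple(x, y, z)) continue;
            cand.push_back(g.lin(x, y, z));
            cx.push_back(x); cy.push_back(y); cz.push_back(z);
          }
      // sequential deletion with re-check preserves topology
      for (size_t i = 0; i < cand.size(); ++i) {
        int x = cx[i], y = cy[i], z = cz[i];
        if (!g.fg[cand[i]]) continue;
        if (g.n26(x, y, z) <= 1) continue;
        if (!g.simple(x, y, z)) continue;
        g.fg[cand[i]] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] = g.fg[i] != 0;
  return out;
}

// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  IntegerVector lab(mask.size(), 0);
  std::vector<Off> offs;
  if (connectivity == 26) offs = off26();
  else offs = { {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1} };
  auto lin = [&](int x, int y, int z) {
    return (size_t)x + (size_t)d1 * ((size_t)y + (size_t)d2 * z);
  };
  int next = 0;
  std::queue<std::array<int,3>> q;
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d1; ++x) {
        size_t i = lin(x, y, z);
        if (mask[i] != TRUE || lab[i] != 0) continue;
        ++next;
        lab[i] = next;
        q.push({x, y, z});
        while (!q.empty()) {
          auto c = q.front(); q.pop();
          for (const auto& o : offs) {
            int nx = c[0] + o.dx, ny = c[1] + o.dy, nz = c[2] + o.dz;
            if (nx < 0 || nx >= d1 || ny < 0 || ny >= d2 || nz < 0 || nz >= d3) continue;
            size_t j = lin(nx, ny, nz);
            if (mask[j] == TRUE && lab[j] == 0) {
              lab[j] = next;
              q.push({nx, ny, nz});
            }
          }
        }
      }
  lab.attr("dim") = dims;
  return lab;
}
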