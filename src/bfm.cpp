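// Bond-fluctuation Monte Carlo kernel.
//
// Lattice state is passed in as flat R structures: wrapped integer node
// coordinates (N x 3, values in [0,L)), unwrapped real coordinates for
// displacement tracking, an occupancy index over the L^3 sites (1-based node
// id or 0), per-node residue type indices, and a precomputed pair-energy
// lookup table over (type a, type b, squared separation r2 = 1..8).
// Chains are laid out contiguously: node n (0-based) sits at position
// n % chain_len of chain n / chain_len.
//
// All randomness comes from R's generator (RNGScope), so runs are
// reproducible from set.seed() alone.

#include <Rcpp.h>
using namespace Rcpp;

static const int RC2 = 8;  // squared interaction cutoff, r_c = sqrt(8)

// Interaction shell: all integer vectors with 0 < |v|^2 <= 8, fixed order.
struct Shell {
  std::vector<int> dx, dy, dz, r2;
  Shell() {
    for (int z = -2; z <= 2; ++z)
      for (int y = -2; y <= 2; ++y)
        for (int x = -2; x <= 2; ++x) {
          int s = x * x + y * y + z * z;
          if (s > 0 && s <= RC2) {
            dx.push_back(x); dy.push_back(y); dz.push_back(z); r2.push_back(s);
          }
        }
  }
  int size() const { return (int)dx.size(); }
};
static const Shell shell;

static inline int wrap(int a, int L) {
  if (a < 0) return a + L;
  if (a >= L) return a - L;
  return a;
}

static inline int mimg(int d, int L) {
  if (2 * d > L) return d - L;
  if (2 * d < -L) return d + L;
  return d;
}

static inline int site_of(int x, int y, int z, int L) {
  return x + L * (y + L * z);
}

// [[Rcpp::export]]
IntegerMatrix cpp_interaction_offsets() {
  IntegerMatrix out(shell.size(), 3);
  for (int k = 0; k < shell.size(); ++k) {
    out(k, 0) = shell.dx[k]; out(k, 1) = shell.dy[k]; out(k, 2) = shell.dz[k];
  }
  return out;
}

static inline double pair_e(const double* et, int a, int b, int r2) {
  // et is 20 x 20 x 8, 0-based [a + 20*b + 400*(r2-1)]
  return et[a + 20 * b + 400 * (r2 - 1)];
}

// Energy felt at site (x,y,z) by a probe node `self` of type `ta`, summed
// over occupied sites within the interaction range.  `self` itself is
// skipped; optionally its bonded neighbours are too.  `flat` holds the
// precomputed flat site offsets of the interaction shell, valid away from
// the boundary.
static double site_energy(int x, int y, int z, int self, int ta,
                          const int* occ, const int* typ, const int* flat,
                          int L, const double* et, bool periodic,
                          bool exclude_bonded, int chain_len) {
  double e = 0.0;
  const int chain_self = self / chain_len;
  const int nsh = shell.size();
  if (x >= 2 && x < L - 2 && y >= 2 && y < L - 2 && z >= 2 && z < L - 2) {
    const int s0 = site_of(x, y, z, L);
    for (int k = 0; k < nsh; ++k) {
      int id = occ[s0 + flat[k]];
      if (id == 0) continue;
      int other = id - 1;
      if (other == self) continue;
      if (exclude_bonded && other / chain_len == chain_self &&
          std::abs(other - self) == 1) continue;
      e += pair_e(et, ta - 1, typ[other] - 1, shell.r2[k]);
    }
    return e;
  }
  for (int k = 0; k < nsh; ++k) {
    int nx = x + shell.dx[k], ny = y + shell.dy[k], nz = z + shell.dz[k];
    if (periodic) {
      nx = wrap(nx, L); ny = wrap(ny, L); nz = wrap(nz, L);
    } else if (nx < 0 || nx >= L || ny < 0 || ny >= L || nz < 0 || nz >= L) {
      continue;
    }
    int id = occ[site_of(nx, ny, nz, L)];
    if (id == 0) continue;
    int other = id - 1;
    if (other == self) continue;
    if (exclude_bonded && other / chain_len == chain_self &&
        std::abs(other - self) == 1) continue;
    e += pair_e(et, ta - 1, typ[other] - 1, shell.r2[k]);
  }
  return e;
}

static std::vector<int> flat_offsets(int L) {
  std::vector<int> flat(shell.size());
  for (int k = 0; k < shell.size(); ++k)
    flat[k] = shell.dx[k] + L * (shell.dy[k] + L * shell.dz[k]);
  return flat;
}

// [[Rcpp::export]]
List cpp_run_sweeps(IntegerMatrix coords_, NumericMatrix unwrapped_,
                    IntegerVector occ_, IntegerVector typ, int chain_len,
                    int L, NumericVector etable, LogicalVector bond_ok,
                    double Tred, int n_sweeps, IntegerVector hops_,
                    double energy, bool periodic, int n_move_dirs,
                    bool exclude_bonded, bool cube,
                    IntegerVector occ_cube_) {
  IntegerMatrix coords = clone(coords_);
  NumericMatrix unwrapped = clone(unwrapped_);
  IntegerVector occ = clone(occ_);
  IntegerVector occ_cube = clone(occ_cube_);
  IntegerVector hops = clone(hops_);
  const double* et = etable.begin();
  const int N = coords.nrow();
  const int n_chains = N / chain_len;

  // move directions: 6 unit vectors, or the full 26-neighbour stencil
  std::vector<int> mx, my, mz;
  if (n_move_dirs == 6) {
    int ux[6] = {1, -1, 0, 0, 0, 0};
    int uy[6] = {0, 0, 1, -1, 0, 0};
    int uz[6] = {0, 0, 0, 0, 1, -1};
    mx.assign(ux, ux + 6); my.assign(uy, uy + 6); mz.assign(uz, uz + 6);
  } else {
    for (int z = -1; z <= 1; ++z)
      for (int y = -1; y <= 1; ++y)
        for (int x = -1; x <= 1; ++x)
          if (x || y || z) { mx.push_back(x); my.push_back(y); mz.push_back(z); }
  }
  const int ndir = (int)mx.size();

  int* cx = &coords(0, 0);
  int* cy = &coords(0, 1);
  int* cz = &coords(0, 2);
  const int* p_occ = occ.begin();
  const int* p_typ = typ.begin();
  const std::vector<int> flat = flat_offsets(L);
  const int* p_flat = flat.data();

  RNGScope scope;
  long long accepted = 0;
  long long attempts = (long long)n_sweeps * N;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int a = 0; a < N; ++a) {
      // random chain, then random residue of that chain, then random step
      int ch = (int)(unif_rand() * n_chains); if (ch == n_chains) --ch;
      int pos = (int)(unif_rand() * chain_len); if (pos == chain_len) --pos;
      int n = ch * chain_len + pos;
      int d = (int)(unif_rand() * ndir); if (d == ndir) --d;

      int ox = cx[n], oy = cy[n], oz = cz[n];
      int nx = ox + mx[d], ny = oy + my[d], nz = oz + mz[d];
      if (periodic) {
        nx = wrap(nx, L); ny = wrap(ny, L); nz = wrap(nz, L);
      } else if (nx < 0 || nx >= L || ny < 0 || ny >= L || nz < 0 || nz >= L) {
        continue;
      }
      int tgt = site_of(nx, ny, nz, L);
      if (cube) {
        // Carmesin-Kremer occupancy: the 8 corner sites of the target cube
        // must be free or owned by the moving node itself
        if (!periodic && (nx >= L - 1 || ny >= L - 1 || nz >= L - 1)) continue;
        bool blocked = false;
        for (int c = 0; c < 8 && !blocked; ++c) {
          int px = nx + (c & 1), py = ny + ((c >> 1) & 1), pz = nz + ((c >> 2) & 1);
          if (periodic) { px = wrap(px, L); py = wrap(py, L); pz = wrap(pz, L); }
          int id = occ_cube[site_of(px, py, pz, L)];
          if (id != 0 && id != n + 1) blocked = true;
        }
        if (blocked) continue;
      } else if (occ[tgt] != 0) {
        continue;                               // excluded volume
      }

      // bond-length constraints with chain neighbours
      bool ok = true;
      for (int nb = -1; nb <= 1 && ok; nb += 2) {
        int p2 = pos + nb;
        if (p2 < 0 || p2 >= chain_len) continue;
        int m = ch * chain_len + p2;
        int bx = cx[m] - nx, by = cy[m] - ny, bz = cz[m] - nz;
        if (periodic) { bx = mimg(bx, L); by = mimg(by, L); bz = mimg(bz, L); }
        if (bx < -3 || bx > 3 || by < -3 || by > 3 || bz < -3 || bz > 3) {
          ok = false;
        } else {
          ok = bond_ok[(bx + 3) + 7 * ((by + 3) + 7 * (bz + 3))];
        }
      }
      if (!ok) continue;

      int ta = typ[n];
      double e_old = site_energy(ox, oy, oz, n, ta, p_occ, p_typ, p_flat, L,
                                 et, periodic, exclude_bonded, chain_len);
      double e_new = site_energy(nx, ny, nz, n, ta, p_occ, p_typ, p_flat, L,
                                 et, periodic, exclude_bonded, chain_len);
      double dE = e_new - e_old;
      if (dE > 0.0 && unif_rand() >= std::exp(-dE / Tred)) continue;

      // accept
      occ[site_of(ox, oy, oz, L)] = 0;
      occ[tgt] = n + 1;
      if (cube) {
        for (int c = 0; c < 8; ++c) {
          int qx = ox + (c & 1), qy = oy + ((c >> 1) & 1), qz = oz + ((c >> 2) & 1);
          if (periodic) { qx = wrap(qx, L); qy = wrap(qy, L); qz = wrap(qz, L); }
          occ_cube[site_of(qx, qy, qz, L)] = 0;
        }
        for (int c = 0; c < 8; ++c) {
          int qx = nx + (c & 1), qy = ny + ((c >> 1) & 1), qz = nz + ((c >> 2) & 1);
          if (periodic) { qx = wrap(qx, L); qy = wrap(qy, L); qz = wrap(qz, L); }
          occ_cube[site_of(qx, qy, qz, L)] = n + 1;
        }
      }
      cx[n] = nx; cy[n] = ny; cz[n] = nz;
      unwrapped(n, 0) += mx[d]; unwrapped(n, 1) += my[d]; unwrapped(n, 2) += mz[d];
      energy += dE;   // each affected pair appears once in the site-energy sums
      hops[n] += 1;
      ++accepted;
    }
  }

  return List::create(_["coords"] = coords, _["unwrapped"] = unwrapped,
                      _["occ"] = occ, _["occ_cube"] = occ_cube,
                      _["hops"] = hops,
                      _["energy"] = energy,
                      _["accepted"] = (double)accepted,
                      _["attempts"] = (double)attempts);
}

// Per-node interaction energies (each pair contributes to both members).
// [[Rcpp::export]]
NumericVector cpp_node_energies(IntegerMatrix coords, IntegerVector occ,
                                IntegerVector typ, int chain_len, int L,
                                NumericVector etable, bool periodic,
                                bool exclude_bonded) {
  const int N = coords.nrow();
  NumericVector out(N);
  const double* et = etable.begin();
  const std::vector<int> flat = flat_offsets(L);
  const int* cx = &coords(0, 0);
  const int* cy = &coords(0, 1);
  const int* cz = &coords(0, 2);
  for (int n = 0; n < N; ++n) {
    out[n] = site_energy(cx[n], cy[n], cz[n], n, typ[n], occ.begin(),
                         typ.begin(), flat.data(), L, et, periodic,
                         exclude_bonded, chain_len);
  }
  return out;
}
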