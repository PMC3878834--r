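#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Random sequential update for the lattice exclusion process.
//
// One time step of duration tau is: a motility sweep of N(t) uniform draws
// (with replacement) from the agent list, then a proliferation sweep of
// another N(t) draws. A selected agent moves with probability
// pm * (1 - q)^a, where a is its number of occupied von Neumann neighbours
// at the moment of selection; the target is one of the four neighbours with
// probability 1/4 and the move aborts silently if the target is occupied or
// off-lattice. Proliferation deposits a daughter with probability pp under
// the same target rule; daughters join the sampling pool immediately but the
// number of draws in the sweep stays fixed at N(t) from the sweep's start.
// Off-lattice sites behave as permanently occupied unless periodic = true.

static inline int occupied_at(const std::vector<unsigned char>& occ, int dim,
                              int x, int y, bool periodic) {
  if (periodic) {
    x = (x + dim) % dim;
    y = (y + dim) % dim;
  } else if (x < 0 || x >= dim || y < 0 || y >= dim) {
    return 1; // boundary acts as occupied
  }
  return occ[(size_t)y * dim + x];
}

// [[Rcpp::export]]
List simulate_core(int dim, IntegerMatrix agents0, double pm, double q,
                   double pp, int n_steps, IntegerVector record_steps,
                   bool periodic) {
  const int n0 = agents0.nrow();
  std::vector<int> ax(n0), ay(n0);
  std::vector<unsigned char> occ((size_t)dim * dim, 0);

  for (int i = 0; i < n0; ++i) {
    int x = agents0(i, 0), y = agents0(i, 1);
    if (x < 0 || x >= dim || y < 0 || y >= dim)
      stop("agent coordinates outside the lattice");
    size_t k = (size_t)y * dim + x;
    if (occ[k]) stop("two agents occupy the same lattice site");
    occ[k] = 1;
    ax[i] = x;
    ay[i] = y;
  }

  double padh[5];
  for (int a = 0; a <= 4; ++a) padh[a] = pm * std::pow(1.0 - q, a);

  const int dx[4] = {1, -1, 0, 0};
  const int dy[4] = {0, 0, 1, -1};

  List snapshots(record_steps.size());
  int next_rec = 0;
  auto take_snapshot = [&](int slot) {
    const int n = (int)ax.size();
    IntegerMatrix m(n, 2);
    for (int i = 0; i < n; ++i) {
      m(i, 0) = ax[i];
      m(i, 1) = ay[i];
    }
    snapshots[slot] = m;
  };
  while (next_rec < record_steps.size() && record_steps[next_rec] == 0) {
    take_snapshot(next_rec);
    ++next_rec;
  }

  for (int s = 1; s <= n_steps; ++s) {
    const int N = (int)ax.size();

    // motility sweep
    for (int k = 0; k < N; ++k) {
      int i = (int)(unif_rand() * N);
      if (i == N) i = N - 1;
      const int x = ax[i], y = ay[i];
      int a = occupied_at(occ, dim, x + 1, y, periodic) +
              occupied_at(occ, dim, x - 1, y, periodic) +
              occupied_at(occ, dim, x, y + 1, periodic) +
              occupied_at(occ, dim, x, y - 1, periodic);
      const double p = padh[a];
      if (p <= 0.0 || unif_rand() >= p) continue;
      const int d = std::min(3, (int)(unif_rand() * 4));
      int tx = x + dx[d], ty = y + dy[d];
      if (periodic) {
        tx = (tx + dim) % dim;
        ty = (ty + dim) % dim;
      } else if (tx < 0 || tx >= dim || ty < 0 || ty >= dim) {
        continue;
      }
      const size_t kt = (size_t)ty * dim + tx;
      if (occ[kt]) continue;
      occ[(size_t)y * dim + x] = 0;
      occ[kt] = 1;
      ax[i] = tx;
      ay[i] = ty;
    }

    // proliferation sweep: N draws, pool grows as daughters are added
    if (pp > 0.0) {
      for (int k = 0; k < N; ++k) {
        const int cur = (int)ax.size();
        int i = (int)(unif_rand() * cur);
        if (i == cur) i = cur - 1;
        if (unif_rand() >= pp) continue;
        const int x = ax[i], y = ay[i];
        const int d = std::min(3, (int)(unif_rand() * 4));
        int tx = x + dx[d], ty = y + dy[d];
        if (periodic) {
          tx = (tx + dim) % dim;
          ty = (ty + dim) % dim;
        } else if (tx < 0 || tx >= dim || ty < 0 || ty >= dim) {
          continue;
        }
        const size_t kt = (size_t)ty * dim + tx;
        if (occ[kt]) continue;
        occ[kt] = 1;
        ax.push_back(tx);
        ay.push_back(ty);
      }
    }

    while (next_rec < record_steps.size() && record_steps[next_rec] == s) {
      take_snapshot(next_rec);
      ++next_rec;
    }
  }

  if (next_rec < record_steps.size())
    stop("record step beyond the simulated horizon");
  return snapshots;
}

// Isolation flags via a cell-list neighbourhood search: a point is isolated
// iff no other point lies at Euclidean distance <= r (boundary inclusive, so
// lattice nearest neighbours at exactly one spacing count as contacts).

// [[Rcpp::export]]
LogicalVector isolated_flags_core(NumericVector x, NumericVector y,
                                  double r) {
  const int n = x.size();
  LogicalVector out(n, true);
  if (n == 0 || r <= 0) return out;
  const double inv = 1.0 / r;
  std::unordered_map<long long, std::vector<int>> bins;
  bins.reserve((size_t)n * 2);
  auto key = [&](double px, double py) {
    long long ix = (long long)std::floor(px * inv);
    long long iy = (long long)std::floor(py * inv);
    return (ix << 32) ^ (iy & 0xffffffffLL);
  };
  for (int i = 0; i < n; ++i) bins[key(x[i], y[i])].push_back(i);
  const double r2 = r * r;
  for (int i = 0; i < n; ++i) {
    const long long ix = (long long)std::floor(x[i] * inv);
    const long long iy = (long long)std::floor(y[i] * inv);
    bool iso = true;
    for (long long bx = ix - 1; bx <= ix + 1 && iso; ++bx) {
      for (long long by = iy - 1; by <= iy + 1 && iso; ++by) {
        auto it = bins.find((bx << 32) ^ (by & 0xffffffffLL));
        if (it == bins.end()) continue;
        for (int j : it->second) {
          if (j == i) continue;
          const double ddx = x[i] - x[j], ddy = y[i] - y[j];
          if (ddx * ddx + ddy * ddy <= r2) {
            iso = false;
            break;
          }
        }
      }
    }
    out[i] = iso;
  }
  return out;
}
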