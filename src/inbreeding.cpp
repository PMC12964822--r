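// Compiled kernels for pedigree inbreeding coefficients.
//
// All functions receive a pedigree already renumbered and sorted by
// ascending LAP (longest ancestral path): parents strictly precede
// progeny, metafounders occupy the leading positions, sire/dam are
// 1-based indices with 0 meaning "none" (metafounder parent slots).
//
// The L referred to throughout is the unit lower-triangular factor of
// A = L D L', whose row s holds the expected gene fractions animal s
// inherits from each ancestor; D is the diagonal of Mendelian-sampling
// variances, d_i = 0.5 - 0.25 (F_si + F_di) for real animals and
// d_m = gamma_m for metafounders.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <deque>
#include <unordered_map>
#include <algorithm>
#ifdef _OPENMP
#include <omp.h>
#endif

using namespace Rcpp;

static inline double parent_F(int p, const std::vector<double>& f) {
  // p is a 0-based index; callers guarantee p >= 0
  return f[p];
}

// ---------------------------------------------------------------------------
// LAP numbers by Kahn's algorithm (explicit queue: no recursion depth limit),
// with cycle detection.  Input indices are positions in the *raw* (unsorted)
// record vector.
// [[Rcpp::export]]
IntegerVector cpp_lap(IntegerVector sire, IntegerVector dam, LogicalVector is_meta) {
  const int n = sire.size();
  std::vector<std::vector<int>> children(n);
  std::vector<int> indeg(n, 0), lap(n, -1);
  for (int i = 0; i < n; ++i) {
    if (is_meta[i]) continue;
    int s = sire[i] - 1, d = dam[i] - 1;
    if (s < 0 || d < 0)
      stop("real animal at position %d lacks a parent; assign metafounders first", i + 1);
    if (s >= n || d >= n)
      stop("parent index out of range for animal at position %d", i + 1);
    children[s].push_back(i);
    indeg[i] = (s == d) ? 1 : 2;
    if (d != s) children[d].push_back(i);
  }
  std::deque<int> q;
  for (int i = 0; i < n; ++i)
    if (indeg[i] == 0) { lap[i] = 0; q.push_back(i); }
  int done = 0;
  while (!q.empty()) {
    int i = q.front(); q.pop_front();
    ++done;
    for (int c : children[i]) {
      int cand = lap[i] + 1;
      if (cand > lap[c]) lap[c] = cand;
      if (--indeg[c] == 0) q.push_back(c);
    }
  }
  if (done < n) {
    for (int i = 0; i < n; ++i)
      if (is_meta[i] ? false : (lap[i] < 0 && indeg[i] > 0))
        stop("pedigree cycle detected involving record %d", i + 1);
    stop("pedigree cycle detected");
  }
  // a metafounder never has parents, so lap[meta] = 0 by construction
  return wrap(lap);
}

// ---------------------------------------------------------------------------
// Tabular method: dense A, row-by-row.  Oracle; caller enforces the size cap.
// [[Rcpp::export]]
NumericMatrix cpp_tabular_A(IntegerVector sire, IntegerVector dam,
                            LogicalVector is_meta, NumericVector gamma) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    if (is_meta[i]) {
      A(i, i) = gamma[i];            // off-diagonals between metafounders stay 0
      continue;
    }
    const int s = sire[i] - 1, d = dam[i] - 1;
    for (int j = 0; j < i; ++j) {
      double v = 0.5 * (A(s, j) + A(d, j));
      A(i, j) = v;
      A(j, i) = v;
    }
    A(i, i) = 1.0 + 0.5 * A(s, d);
  }
  return A;
}

// ---------------------------------------------------------------------------
// Memoized recursive kinship (REC oracle).  Pairs stored in a hash map keyed
// by (max, min) index so each A_{i,j} is computed once.
namespace {
struct RecKin {
  const int *sire, *dam;
  const int *is_meta;
  const double *gamma;
  long long n;
  std::unordered_map<long long, double> memo;

  double a(int i, int j) {
    if (i < j) std::swap(i, j);
    // metafounders precede real animals, so i meta => j meta
    if (is_meta[i]) return (i == j) ? gamma[i] : 0.0;
    long long key = (long long)i * n + j;
    auto it = memo.find(key);
    if (it != memo.end()) return it->second;
    const int s = sire[i] - 1, d = dam[i] - 1;
    double v;
    if (i == j) v = 1.0 + 0.5 * a(s, d);
    else        v = 0.5 * (a(s, j) + a(d, j));
    memo.emplace(key, v);
    return v;
  }
};
} // namespace

// [[Rcpp::export]]
List cpp_kinship_pairs(IntegerVector sire, IntegerVector dam,
                       LogicalVector is_meta, NumericVector gamma,
                       IntegerVector I, IntegerVector J) {
  RecKin rk{INTEGER(sire), INTEGER(dam), LOGICAL(is_meta), REAL(gamma),
            (long long)sire.size(), {}};
  const int m = I.size();
  NumericVector out(m);
  for (int k = 0; k < m; ++k) out[k] = rk.a(I[k] - 1, J[k] - 1);
  return List::create(_["a"] = out,
                      _["pairs_stored"] = (double)rk.memo.size());
}

// [[Rcpp::export]]
List cpp_rec_F(IntegerVector sire, IntegerVector dam,
               LogicalVector is_meta, NumericVector gamma) {
  const int n = sire.size();
  RecKin rk{INTEGER(sire), INTEGER(dam), LOGICAL(is_meta), REAL(gamma),
            (long long)n, {}};
  NumericVector f(n);
  for (int i = 0; i < n; ++i)
    f[i] = is_meta[i] ? gamma[i] - 1.0 : rk.a(i, i) - 1.0;
  return List::create(_["f"] = f, _["pairs_stored"] = (double)rk.memo.size());
}

// ---------------------------------------------------------------------------
// Sparse L-row computation, descending-LAP bucket scheme (the SI traversal):
// start with coefficient 1 at the owner, repeatedly pop the highest-LAP
// pending animal (ascending index within a bucket for determinism), emit its
// coefficient and push half of it onto each parent.
namespace {
struct LRowWork {
  int n = 0;
  const int *sire = nullptr, *dam = nullptr, *lap = nullptr;
  const int *is_meta = nullptr;
  std::vector<double> coef;
  std::vector<char> pending;
  std::vector<std::vector<int>> bucket;

  void bind(int n_, const int* s, const int* d, const int* l, const int* m,
            int max_lap) {
    n = n_; sire = s; dam = d; lap = l; is_meta = m;
    coef.assign(n, 0.0);
    pending.assign(n, 0);
    bucket.assign(max_lap + 1, {});
  }

  // emit(k, c) is called once per ancestor (including s itself) in strictly
  // descending LAP order; buffers are self-cleaning.
  template <typename Emit>
  void row(int s, Emit&& emit) {
    coef[s] = 1.0;
    pending[s] = 1;
    bucket[lap[s]].push_back(s);
    for (int l = lap[s]; l >= 0; --l) {
      std::vector<int>& b = bucket[l];
      if (b.empty()) continue;
      std::sort(b.begin(), b.end());
      for (int k : b) {
        const double c = coef[k];
        emit(k, c);
        if (!is_meta[k]) {
          const int p1 = sire[k] - 1, p2 = dam[k] - 1;
          coef[p1] += 0.5 * c;
          if (!pending[p1]) { pending[p1] = 1; bucket[lap[p1]].push_back(p1); }
          coef[p2] += 0.5 * c;
          if (!pending[p2]) { pending[p2] = 1; bucket[lap[p2]].push_back(p2); }
        }
      }
      for (int k : b) { coef[k] = 0.0; pending[k] = 0; }
      b.clear();
    }
  }
};
} // namespace

// [[Rcpp::export]]
List cpp_L_row(IntegerVector sire, IntegerVector dam, IntegerVector lap,
               LogicalVector is_meta, int s) {
  const int n = sire.size();
  int max_lap = 0;
  for (int i = 0; i < n; ++i) if (lap[i] > max_lap) max_lap = lap[i];
  LRowWork w;
  w.bind(n, INTEGER(sire), INTEGER(dam), INTEGER(lap), LOGICAL(is_meta), max_lap);
  std::vector<int> idx;
  std::vector<double> val;
  w.row(s - 1, [&](int k, double c) { idx.push_back(k + 1); val.push_back(c); });
  return List::create(_["index"] = wrap(idx), _["coef"] = wrap(val));
}

// ---------------------------------------------------------------------------
// Meuwissen & Luo: per-animal ancestor traversal in descending identification
// order (max-heap), accumulating F_i = sum L^2 d - 1 with d built on the fly.
// [[Rcpp::export]]
List cpp_inbreeding_ML(IntegerVector sire, IntegerVector dam,
                       LogicalVector is_meta, NumericVector gamma) {
  const int n = sire.size();
  const int *sp = INTEGER(sire), *dp = INTEGER(dam);
  const int *mp = LOGICAL(is_meta);
  const double *gp = REAL(gamma);
  std::vector<double> f(n), d(n);
  std::vector<double> coef(n, 0.0);
  std::vector<char> inq(n, 0);
  std::vector<int> emitted;
  long long entries = 0;
  std::priority_queue<int> pq;
  for (int i = 0; i < n; ++i) {
    if (mp[i]) { f[i] = gp[i] - 1.0; d[i] = gp[i]; continue; }
    const int s = sp[i] - 1, dd = dp[i] - 1;
    d[i] = 0.5 - 0.25 * (f[s] + f[dd]);
    double a = 0.0;
    emitted.clear();
    coef[i] = 1.0; inq[i] = 1; pq.push(i);
    while (!pq.empty()) {
      const int k = pq.top(); pq.pop();
      const double c = coef[k];
      a += c * c * d[k];
      ++entries;
      emitted.push_back(k);
      if (!mp[k]) {
        const int p1 = sp[k] - 1, p2 = dp[k] - 1;
        coef[p1] += 0.5 * c;
        if (!inq[p1]) { inq[p1] = 1; pq.push(p1); }
        coef[p2] += 0.5 * c;
        if (!inq[p2]) { inq[p2] = 1; pq.push(p2); }
      }
    }
    for (int k : emitted) { coef[k] = 0.0; inq[k] = 0; }
    f[i] = a - 1.0;
  }
  return List::create(_["f"] = wrap(f), _["d"] = wrap(d),
                      _["l_row_entries"] = (double)entries);
}

// ---------------------------------------------------------------------------
// Sargolzaei & Iwaisaki: as ML but the traversal pops ancestors in descending
// LAP order via the bucket scheme.
// [[Rcpp::export]]
List cpp_inbreeding_SI(IntegerVector sire, IntegerVector dam, IntegerVector lap,
                       LogicalVector is_meta, NumericVector gamma) {
  const int n = sire.size();
  const int *sp = INTEGER(sire), *dp = INTEGER(dam), *lp = INTEGER(lap);
  const int *mp = LOGICAL(is_meta);
  const double *gp = REAL(gamma);
  int max_lap = 0;
  for (int i = 0; i < n; ++i) if (lp[i] > max_lap) max_lap = lp[i];
  LRowWork w;
  w.bind(n, sp, dp, lp, mp, max_lap);
  std::vector<double> f(n), d(n);
  long long entries = 0;
  for (int i = 0; i < n; ++i) {
    if (mp[i]) { f[i] = gp[i] - 1.0; d[i] = gp[i]; continue; }
    const int s = sp[i] - 1, dd = dp[i] - 1;
    d[i] = 0.5 - 0.25 * (f[s] + f[dd]);
    double a = 0.0;
    w.row(i, [&](int k, double c) { a += c * c * d[k]; ++entries; });
    f[i] = a - 1.0;
  }
  return List::create(_["f"] = wrap(f), _["d"] = wrap(d),
                      _["l_row_entries"] = (double)entries);
}

// ---------------------------------------------------------------------------
// Shared sire-group layout: real animals grouped by (LAP block, sire index).
// Every real animal belongs to exactly one group.
namespace {
struct Groups {
  std::vector<int> animal;        // real-animal indices, ordered by (lap, sire, id)
  std::vector<int> group_start;   // offsets into `animal`, one per group (+ sentinel)
  std::vector<int> group_sire;    // sire (0-based) of each group
  std::vector<int> block_start;   // offsets into groups, one per LAP block (+ sentinel)
};

static Groups build_groups(int n, const int* sire, const int* lap, const int* is_meta) {
  Groups g;
  g.animal.reserve(n);
  for (int i = 0; i < n; ++i) if (!is_meta[i]) g.animal.push_back(i);
  std::stable_sort(g.animal.begin(), g.animal.end(), [&](int a, int b) {
    if (lap[a] != lap[b]) return lap[a] < lap[b];
    if (sire[a] != sire[b]) return sire[a] < sire[b];
    return a < b;
  });
  const int m = (int)g.animal.size();
  int prev_lap = -1, prev_sire = -1;
  for (int k = 0; k < m; ++k) {
    const int i = g.animal[k];
    if (lap[i] != prev_lap || sire[i] != prev_sire) {
      if (lap[i] != prev_lap) g.block_start.push_back((int)g.group_start.size());
      g.group_start.push_back(k);
      g.group_sire.push_back(sire[i] - 1);
      prev_lap = lap[i]; prev_sire = sire[i];
    }
  }
  g.group_start.push_back(m);
  g.block_start.push_back((int)g.group_sire.size());
  return g;
}
} // namespace

// ---------------------------------------------------------------------------
// Original indirect method (I): one reduced pedigree over all sires (kept set
// = every animal with progeny, which is closed under parentage), per-group
// backward substitution from the sire's reduced position to the start, full
// forward substitution up to mip_s, then F_j = y_{d_j} / 2.
// [[Rcpp::export]]
List cpp_inbreeding_I(IntegerVector sire, IntegerVector dam, IntegerVector lap,
                      LogicalVector is_meta, NumericVector gamma) {
  const int n = sire.size();
  const int *sp = INTEGER(sire), *dp = INTEGER(dam), *lp = INTEGER(lap);
  const int *mp = LOGICAL(is_meta);
  const double *gp = REAL(gamma);

  // reduced pedigree: animals with at least one progeny (ancestor-closed)
  std::vector<char> kept(n, 0);
  for (int i = 0; i < n; ++i) {
    if (mp[i]) continue;
    kept[sp[i] - 1] = 1;
    kept[dp[i] - 1] = 1;
  }
  std::vector<int> rpos(n, -1), rorig;
  for (int i = 0; i < n; ++i)
    if (kept[i]) { rpos[i] = (int)rorig.size(); rorig.push_back(i); }
  const int rn = (int)rorig.size();

  Groups g = build_groups(n, sp, lp, mp);

  std::vector<double> f(n), d(n);
  for (int i = 0; i < n; ++i)
    if (mp[i]) { f[i] = gp[i] - 1.0; d[i] = gp[i]; }

  std::vector<double> z(rn, 0.0), y(rn, 0.0);
  long long fwd = 0, bwd = 0;
  const int ngroups = (int)g.group_sire.size();

  for (int gi = 0; gi < ngroups; ++gi) {
    const int s = g.group_sire[gi];
    const int rs = rpos[s];
    // backward substitution: z = L'_{s,:} on reduced indices
    z[rs] = 1.0;
    for (int k = rs; k >= 0; --k) {
      const double zk = z[k];
      ++bwd;
      if (zk != 0.0) {
        const int o = rorig[k];
        if (!mp[o]) {
          z[rpos[sp[o] - 1]] += 0.5 * zk;
          z[rpos[dp[o] - 1]] += 0.5 * zk;
        }
      }
    }
    // mip_s: mate with the largest reduced identification number
    int mip = -1;
    for (int k = g.group_start[gi]; k < g.group_start[gi + 1]; ++k) {
      const int rdj = rpos[dp[g.animal[k]] - 1];
      if (rdj > mip) mip = rdj;
    }
    // forward substitution over the reduced pedigree, positions 1..mip_s
    for (int k = 0; k <= mip; ++k) {
      const int o = rorig[k];
      if (mp[o]) y[k] = gp[o] * z[k];
      else y[k] = 0.5 * (y[rpos[sp[o] - 1]] + y[rpos[dp[o] - 1]]) + d[o] * z[k];
      ++fwd;
    }
    // progeny F (and their Mendelian variances for later groups)
    for (int k = g.group_start[gi]; k < g.group_start[gi + 1]; ++k) {
      const int j = g.animal[k];
      f[j] = 0.5 * y[rpos[dp[j] - 1]];
      d[j] = 0.5 - 0.25 * (f[sp[j] - 1] + f[dp[j] - 1]);
    }
    const int hi = std::max(rs, mip);
    for (int k = 0; k <= hi; ++k) { z[k] = 0.0; y[k] = 0.0; }
  }

  return List::create(_["f"] = wrap(f), _["d"] = wrap(d),
                      _["elements_computed_forward"] = (double)fwd,
                      _["elements_computed_backward"] = (double)bwd,
                      _["sire_groups"] = (double)ngroups,
                      _["reduced_n"] = (double)rn);
}

// ---------------------------------------------------------------------------
// Modified indirect method (MI).
//
// Per sire group: compute the sparse L-row of the sire (descending-LAP
// buckets), seed y[k] = d_k L_{s,k} over the sire's ancestors (metafounders
// flagged at seed time, their y is final), then for each mate run a flagged
// recursive forward substitution y_i = (y_si + y_di)/2 + seed_i realized with
// an explicit stack, and take F_j = y_{d_j} / 2.  Workspaces are reset
// sparsely through the touched list.  LAP blocks run sequentially; the sire
// groups inside one block are independent and are partitioned across workers
// in contiguous chunks (results do not depend on the worker count: each
// group only reads state finalized in earlier blocks and writes the F of its
// own progeny).
namespace {
struct MIWorkspace {
  LRowWork lrow;
  std::vector<double> y;
  std::vector<char> flag;
  std::vector<int> touched;
  std::vector<int> stack;
  long long fwd = 0, lent = 0;
  bool bound = false;
};
} // namespace

// [[Rcpp::export]]
List cpp_inbreeding_MI(IntegerVector sire, IntegerVector dam, IntegerVector lap,
                       LogicalVector is_meta, NumericVector gamma,
                       int workers, bool capture) {
  const int n = sire.size();
  if (workers < 1) stop("workers must be >= 1");
  // copies: no R API access inside parallel regions
  std::vector<int> sv(INTEGER(sire), INTEGER(sire) + n);
  std::vector<int> dv(INTEGER(dam), INTEGER(dam) + n);
  std::vector<int> lv(INTEGER(lap), INTEGER(lap) + n);
  std::vector<int> mv(LOGICAL(is_meta), LOGICAL(is_meta) + n);
  std::vector<double> gv(REAL(gamma), REAL(gamma) + n);
  const int *sp = sv.data(), *dp = dv.data(), *lp = lv.data(), *mp = mv.data();

  int max_lap = 0;
  for (int i = 0; i < n; ++i) if (lv[i] > max_lap) max_lap = lv[i];

  Groups g = build_groups(n, sp, lp, mp);
  const int nblocks = (int)g.block_start.size() - 1;

  std::vector<double> f(n), d(n);
  for (int i = 0; i < n; ++i)
    if (mp[i]) { f[i] = gv[i] - 1.0; d[i] = gv[i]; }

  if (capture) workers = 1;  // capture is a single-threaded debug mode
  std::vector<MIWorkspace> ws(workers);
  std::vector<int> cap_s, cap_i;
  std::vector<double> cap_y;

  for (int b = 0; b < nblocks; ++b) {
    const int g0 = g.block_start[b], g1 = g.block_start[b + 1];
#ifdef _OPENMP
#pragma omp parallel num_threads(workers) if (workers > 1)
#endif
    {
#ifdef _OPENMP
      const int tid = omp_get_thread_num();
#else
      const int tid = 0;
#endif
      MIWorkspace& w = ws[tid];
      if (!w.bound) {
        w.lrow.bind(n, sp, dp, lp, mp, max_lap);
        w.y.assign(n, 0.0);
        w.flag.assign(n, 0);
        w.bound = true;
      }
#ifdef _OPENMP
#pragma omp for schedule(static)
#endif
      for (int gi = g0; gi < g1; ++gi) {
        const int s = g.group_sire[gi];
        // (1) L-row of the sire; (2) seed y with d * L over ANC_s
        w.lrow.row(s, [&](int k, double c) {
          ++w.lent;
          w.y[k] = d[k] * c;
          w.touched.push_back(k);
          if (mp[k]) {           // metafounder seeds are final: y = gamma * L
            w.flag[k] = 1;
            ++w.fwd;
            if (capture) { cap_s.push_back(s + 1); cap_i.push_back(k + 1); cap_y.push_back(w.y[k]); }
          }
        });
        // (3) flagged recursive forward substitution per mate; F_j = y_dj / 2
        for (int k = g.group_start[gi]; k < g.group_start[gi + 1]; ++k) {
          const int j = g.animal[k];
          const int dj = dp[j] - 1;
          if (!w.flag[dj]) {
            std::vector<int>& st = w.stack;
            st.push_back(dj);
            while (!st.empty()) {
              const int i = st.back();
              if (w.flag[i]) { st.pop_back(); continue; }
              if (mp[i]) {       // unseeded metafounder: y stays 0
                w.flag[i] = 1;
                w.touched.push_back(i);
                ++w.fwd;
                if (capture) { cap_s.push_back(s + 1); cap_i.push_back(i + 1); cap_y.push_back(w.y[i]); }
                st.pop_back();
                continue;
              }
              const int p1 = sp[i] - 1, p2 = dp[i] - 1;
              const bool f1 = w.flag[p1], f2 = w.flag[p2];
              if (f1 && f2) {
                w.y[i] += 0.5 * (w.y[p1] + w.y[p2]);  // += keeps the d*L seed as the z-term
                w.flag[i] = 1;
                w.touched.push_back(i);
                ++w.fwd;
                if (capture) { cap_s.push_back(s + 1); cap_i.push_back(i + 1); cap_y.push_back(w.y[i]); }
                st.pop_back();
              } else {
                if (!f1) st.push_back(p1);
                if (!f2 && p2 != p1) st.push_back(p2);
              }
            }
          }
          f[j] = 0.5 * w.y[dj];
          d[j] = 0.5 - 0.25 * (f[sp[j] - 1] + f[dp[j] - 1]);
        }
        // (4) sparse reset of the workspace
        for (int t : w.touched) { w.y[t] = 0.0; w.flag[t] = 0; }
        w.touched.clear();
      }
    } // end parallel region; block published before the next one starts
  }

  long long fwd = 0, lent = 0;
  for (const MIWorkspace& w : ws) { fwd += w.fwd; lent += w.lent; }

  List out = List::create(_["f"] = wrap(f), _["d"] = wrap(d),
                          _["elements_computed_forward"] = (double)fwd,
                          _["l_row_entries"] = (double)lent,
                          _["sire_groups"] = (double)g.group_sire.size(),
                          _["workers"] = workers);
  if (capture)
    out["capture"] = DataFrame::create(_["sire"] = wrap(cap_s),
                                       _["animal"] = wrap(cap_i),
                                       _["y"] = wrap(cap_y));
  return out;
}

// [[Rcpp::export]]
bool cpp_has_openmp() {
#ifdef _OPENMP
  return true;
#else
  return false;
#endif
}
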