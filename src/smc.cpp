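// Sequential Markov coalescent (SMC) with piecewise-constant demography and
// an optional two-population clean-split model.
//
// Time is measured in units of 2*N0 generations, N0 being the most recent
// epoch size.  With theta_pb = 2*N0*mu per bp, expected pairwise diversity at
// constant size is 2*theta_pb*E[T2] = 4*N0*mu.  Recombination breakpoints
// along the sequence arise at rate rho_pb * B per bp, rho_pb = 2*N0*r and B
// the total branch length of the current marginal tree.  At a breakpoint the
// branch above a uniformly chosen point is erased up to the root and the
// detached lineage re-coalesces into the remaining tree (McVean & Cardin).
//
// All randomness goes through R's RNG so results are reproducible from
// set.seed() alone.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

namespace {

struct Demography {
  std::vector<double> start;  // epoch start times, start[0] == 0
  std::vector<double> size;   // relative sizes (N_epoch / N0), > 0

  int epoch_at(double t) const {
    int e = static_cast<int>(start.size()) - 1;
    while (e > 0 && t < start[e]) --e;
    return e;
  }
};

// Waiting time from t for an inhomogeneous exponential with hazard
// base / size(t).  base is constant over the wait (no other events).
double sample_wait(const Demography& d, double t, double base) {
  if (base <= 0.0) return R_PosInf;
  double target = R::exp_rand();
  int e = d.epoch_at(t);
  double cur = t;
  for (;;) {
    double rate = base / d.size[e];
    double nxt = (e + 1 < static_cast<int>(d.start.size()))
                     ? d.start[e + 1]
                     : R_PosInf;
    double need = target / rate;
    if (!R_finite(nxt) || cur + need <= nxt) return cur + need - t;
    target -= rate * (nxt - cur);
    cur = nxt;
    ++e;
  }
}

struct Tree {
  int n;  // leaves
  std::vector<int> parent, ch1, ch2, pop;
  std::vector<double> time;
  int root;

  double ptime(int v) const {
    return parent[v] < 0 ? R_PosInf : time[parent[v]];
  }
};

double total_branch(const Tree& tr) {
  double b = 0.0;
  int nn = 2 * tr.n - 1;
  for (int v = 0; v < nn; ++v) {
    if (v == tr.root || tr.parent[v] < 0) continue;
    b += tr.time[tr.parent[v]] - tr.time[v];
  }
  return b;
}

// leaves under node v (iterative DFS)
void leaves_under(const Tree& tr, int v, std::vector<int>& out) {
  out.clear();
  std::vector<int> stack;
  stack.push_back(v);
  while (!stack.empty()) {
    int u = stack.back();
    stack.pop_back();
    if (u < tr.n) {
      out.push_back(u);
    } else {
      stack.push_back(tr.ch1[u]);
      stack.push_back(tr.ch2[u]);
    }
  }
}

void build_initial_tree(Tree& tr, const Demography& dem,
                        const IntegerVector& pop_of_leaf, double split_time) {
  int n = tr.n;
  std::vector<int> active;
  active.reserve(n);
  for (int i = 0; i < n; ++i) {
    tr.time[i] = 0.0;
    tr.parent[i] = -1;
    tr.ch1[i] = tr.ch2[i] = -1;
    tr.pop[i] = pop_of_leaf[i];
    active.push_back(i);
  }
  int next_id = n;
  double t = 0.0;
  while (static_cast<int>(active.size()) > 1) {
    bool split_phase = (t < split_time);
    double k0 = 0, k1 = 0;
    if (split_phase) {
      for (int id : active) (tr.pop[id] == 1 ? k1 : k0) += 1.0;
    } else {
      k0 = static_cast<double>(active.size());
    }
    double base = split_phase
                      ? 0.5 * (k0 * (k0 - 1.0) + k1 * (k1 - 1.0))
                      : 0.5 * k0 * (k0 - 1.0);
    if (base <= 0.0) {
      if (!R_finite(split_time) || !split_phase)
        stop("coalescent stalled: no joinable lineage pairs");
      t = split_time;
      continue;
    }
    double w = sample_wait(dem, t, base);
    if (split_phase && t + w >= split_time) {
      t = split_time;  // populations merge; restart clock there
      continue;
    }
    t += w;
    // choose a within-population pair
    int want_pop = -1;
    if (split_phase) {
      double p0 = 0.5 * k0 * (k0 - 1.0) / base;
      want_pop = (unif_rand() < p0) ? 0 : 1;
    }
    std::vector<int> cand;
    if (split_phase) {
      for (int id : active)
        if (tr.pop[id] == want_pop) cand.push_back(id);
    } else {
      cand = active;
    }
    int i = static_cast<int>(unif_rand() * cand.size());
    int j = static_cast<int>(unif_rand() * (cand.size() - 1));
    if (j >= i) ++j;
    int a = cand[i], b = cand[j];
    int u = next_id++;
    tr.time[u] = t;
    tr.ch1[u] = a;
    tr.ch2[u] = b;
    tr.parent[u] = -1;
    tr.pop[u] = (t < split_time) ? tr.pop[a] : -1;
    tr.parent[a] = u;
    tr.parent[b] = u;
    active.erase(std::remove(active.begin(), active.end(), a), active.end());
    active.erase(std::remove(active.begin(), active.end(), b), active.end());
    active.push_back(u);
  }
  tr.root = active[0];
}

// One SMC recombination event.  in_float is scratch of length 2n-1.
void smc_event(Tree& tr, const Demography& dem, double split_time,
               std::vector<char>& in_float) {
  int nn = 2 * tr.n - 1;
  // 1. sample recombination point: edge v -> parent, height u
  double B = total_branch(tr);
  double pick = unif_rand() * B, acc = 0.0;
  int v = -1;
  for (int w = 0; w < nn; ++w) {
    if (w == tr.root || tr.parent[w] < 0) continue;
    acc += tr.time[tr.parent[w]] - tr.time[w];
    if (acc >= pick) { v = w; break; }
  }
  if (v < 0) {  // numeric slack: take last valid edge
    for (int w = nn - 1; w >= 0; --w)
      if (w != tr.root && tr.parent[w] >= 0) { v = w; break; }
  }
  double u_h = tr.time[v] + unif_rand() * (tr.time[tr.parent[v]] - tr.time[v]);

  // 2. prune: detach v, splice out its parent q
  int q = tr.parent[v];
  int sib = (tr.ch1[q] == v) ? tr.ch2[q] : tr.ch1[q];
  int gp = tr.parent[q];
  tr.parent[v] = -1;
  tr.parent[sib] = gp;
  if (gp >= 0) {
    if (tr.ch1[gp] == q) tr.ch1[gp] = sib; else tr.ch2[gp] = sib;
  } else {
    tr.root = sib;
  }

  // mark floating subtree
  std::fill(in_float.begin(), in_float.end(), 0);
  {
    std::vector<int> stack(1, v);
    while (!stack.empty()) {
      int w = stack.back();
      stack.pop_back();
      in_float[w] = 1;
      if (w >= tr.n) { stack.push_back(tr.ch1[w]); stack.push_back(tr.ch2[w]); }
    }
  }
  in_float[q] = 1;  // q is out of the tree until reused

  int fpop = tr.pop[v];  // -1 when the detached top is above the split

  // 3. re-coalesce from u_h upward.
  // Lineage counts in the remaining tree: every internal node (root included,
  // whose upward lineage extends to infinity) reduces the spanning-edge count
  // by one as time passes it.
  std::vector<std::pair<double, int> > events;  // (time, pop) of internal nodes
  double k_all = 0.0, k_same = 0.0;
  for (int w = 0; w < nn; ++w) {
    if (in_float[w]) continue;
    double pt = (w == tr.root) ? R_PosInf : tr.time[tr.parent[w]];
    if (tr.time[w] <= u_h && u_h < pt) {
      k_all += 1.0;
      if (fpop < 0 || tr.pop[w] < 0 || tr.pop[w] == fpop) k_same += 1.0;
    }
    if (w >= tr.n && tr.time[w] > u_h)
      events.push_back(std::make_pair(tr.time[w], tr.pop[w]));
  }
  std::sort(events.begin(), events.end());

  double t = u_h;
  double t_coal = R_PosInf;
  size_t ei = 0;
  for (;;) {
    double seg_end = (ei < events.size()) ? events[ei].first : R_PosInf;
    bool below_split = (t < split_time);
    if (below_split && split_time < seg_end) seg_end = split_time;
    double k = (t < split_time && fpop >= 0) ? k_same : k_all;
    double w = sample_wait(dem, t, k);
    if (t + w < seg_end) { t_coal = t + w; break; }
    if (!R_finite(seg_end))
      stop("SMC re-coalescence failed to terminate");
    t = seg_end;
    if (ei < events.size() && events[ei].first == seg_end) {
      k_all -= 1.0;
      int ep = events[ei].second;
      if (fpop < 0 || ep < 0 || ep == fpop) k_same -= 1.0;
      ++ei;
    }
    // crossing split_time just switches the k used above
  }

  // choose the target edge uniformly among those spanning t_coal
  bool restrict_pop = (t_coal < split_time && fpop >= 0);
  std::vector<int> targets;
  for (int w = 0; w < nn; ++w) {
    if (in_float[w]) continue;
    double pt = (w == tr.root) ? R_PosInf : tr.time[tr.parent[w]];
    if (tr.time[w] <= t_coal && t_coal < pt) {
      if (!restrict_pop || tr.pop[w] < 0 || tr.pop[w] == fpop)
        targets.push_back(w);
    }
  }
  if (targets.empty()) stop("SMC re-coalescence found no target lineage");
  int tgt = targets[static_cast<int>(unif_rand() * targets.size())];

  // 4. re-attach: reuse node id q
  int tp = tr.parent[tgt];
  tr.time[q] = t_coal;
  tr.ch1[q] = v;
  tr.ch2[q] = tgt;
  tr.pop[q] = (t_coal < split_time) ? fpop : -1;
  tr.parent[q] = tp;
  tr.parent[v] = q;
  tr.parent[tgt] = q;
  if (tp >= 0) {
    if (tr.ch1[tp] == tgt) tr.ch1[tp] = q; else tr.ch2[tp] = q;
  } else {
    tr.root = q;
  }
  std::fill(in_float.begin(), in_float.end(), 0);
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
List smc_chromosome_cpp(int n_seq, double chrom_length, double theta_pb,
                        double rho_pb, NumericVector epoch_start,
                        NumericVector epoch_size, IntegerVector pop_of_leaf,
                        double split_time) {
  if (n_seq < 2) stop("need at least two sequences");
  if (epoch_start.size() != epoch_size.size() || epoch_start.size() < 1)
    stop("epoch_start and epoch_size must have equal positive length");
  if (epoch_start[0] != 0.0) stop("first epoch must start at time 0");
  for (int i = 0; i < epoch_size.size(); ++i)
    if (epoch_size[i] <= 0.0) stop("epoch sizes must be positive");

  Demography dem;
  dem.start = as<std::vector<double> >(epoch_start);
  dem.size = as<std::vector<double> >(epoch_size);

  Tree tr;
  tr.n = n_seq;
  int nn = 2 * n_seq - 1;
  tr.parent.assign(nn + 1, -1);
  tr.ch1.assign(nn + 1, -1);
  tr.ch2.assign(nn + 1, -1);
  tr.pop.assign(nn + 1, -1);
  tr.time.assign(nn + 1, 0.0);
  build_initial_tree(tr, dem, pop_of_leaf, split_time);

  std::vector<char> in_float(nn + 1, 0);
  std::vector<double> positions;
  std::vector<unsigned char> haps;  // stacked n_seq-byte columns
  std::vector<int> leaf_buf;
  std::vector<std::pair<double, int> > muts;  // (pos, node) within a segment

  double x = 0.0;
  while (x < chrom_length) {
    double B = total_branch(tr);
    double d = (rho_pb > 0.0 && B > 0.0) ? R::exp_rand() / (rho_pb * B)
                                         : R_PosInf;
    double xnext = std::min(chrom_length, x + d);
    double seg = xnext - x;
    if (theta_pb > 0.0 && seg > 0.0 && B > 0.0) {
      int nmut = static_cast<int>(R::rpois(theta_pb * B * seg));
      if (nmut > 0) {
        muts.clear();
        for (int m = 0; m < nmut; ++m) {
          double pick = unif_rand() * B, acc = 0.0;
          int node = -1;
          for (int w = 0; w < nn; ++w) {
            if (w == tr.root || tr.parent[w] < 0) continue;
            acc += tr.time[tr.parent[w]] - tr.time[w];
            if (acc >= pick) { node = w; break; }
          }
          if (node < 0) continue;
          muts.push_back(std::make_pair(x + unif_rand() * seg, node));
        }
        std::sort(muts.begin(), muts.end());
        for (size_t m = 0; m < muts.size(); ++m) {
          positions.push_back(muts[m].first);
          size_t off = haps.size();
          haps.resize(off + n_seq, 0);
          leaves_under(tr, muts[m].second, leaf_buf);
          for (size_t l = 0; l < leaf_buf.size(); ++l)
            haps[off + leaf_buf[l]] = 1;
        }
      }
    }
    x = xnext;
    if (x < chrom_length) smc_event(tr, dem, split_time, in_float);
    if (positions.size() % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  int S = static_cast<int>(positions.size());
  RawMatrix H(n_seq, S);
  if (S > 0) std::memcpy(RAW(H), haps.data(), haps.size());
  return List::create(_["positions"] = wrap(positions), _["haplotypes"] = H);
}

//' @noRd
// [[Rcpp::export]]
IntegerVector hap_col_counts_cpp(RawMatrix h, IntegerVector rows) {
  int S = h.ncol();
  int k = rows.size();
  IntegerVector out(S);
  const Rbyte* p = RAW(h);
  int n = h.nrow();
  for (int j = 0; j < S; ++j) {
    const Rbyte* col = p + static_cast<size_t>(j) * n;
    int c = 0;
    for (int i = 0; i < k; ++i) c += col[rows[i] - 1];
    out[j] = c;
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
IntegerMatrix hap_extract_cpp(RawMatrix h, IntegerVector rows,
                              IntegerVector cols) {
  int nr = rows.size(), nc = cols.size(), n = h.nrow();
  IntegerMatrix out(nr, nc);
  const Rbyte* p = RAW(h);
  for (int j = 0; j < nc; ++j) {
    const Rbyte* col = p + static_cast<size_t>(cols[j] - 1) * n;
    for (int i = 0; i < nr; ++i) out(i, j) = col[rows[i] - 1];
  }
  return out;
}

// Additive (numerator) relationship matrix by the tabular method.
// sire/dam are 0 for unknown, otherwise 1-based indices of earlier rows.
//' @noRd
// [[Rcpp::export]]
NumericMatrix a_tabular_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    if (s >= i || d >= i) stop("pedigree must be sorted parents-first");
    double f = (s >= 0 && d >= 0) ? 0.5 * A(s, d) : 0.0;
    A(i, i) = 1.0 + f;
    for (int j = 0; j < i; ++j) {
      double a = 0.0;
      if (s >= 0) a += 0.5 * A(j, s);
      if (d >= 0) a += 0.5 * A(j, d);
      A(i, j) = a;
      A(j, i) = a;
    }
  }
  return A;
}
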