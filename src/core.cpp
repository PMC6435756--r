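#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Graphs arrive as CSR adjacency over proper (non-loop) edges:
//   indptr: length n+1, 0-based offsets; nbr / wt: flat neighbour ids (0-based)
//   and positive edge weights, each undirected edge stored in both directions.
// Self-loops are kept out of the adjacency on purpose: they travel with the
// node under any move, so they cancel in every move/merge delta.
//
// All deltas below use the unified "score" form
//   score(v -> c) = w(v, c\v) - gam * mass_v * (A_c - [v in c] * mass_v)
// where mass = node size and gam = gamma for CPM, mass = strength and
// gam = gamma / (2m) for modularity; the true quality delta of a move is
// (score(target) - score(current)) times a positive constant, so argmax
// decisions and sign tests are identical for both objectives.

static inline int rand_below(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// Greedy local moving. fast = false: Louvain-style full sweeps in fresh random
// order until a sweep makes no move. fast = true: queue of all nodes in random
// order; after a move, neighbours outside the new community re-enter the queue;
// when the queue drains, a verification sweep re-checks every node and reseeds
// the queue, so the returned partition is node optimal unconditionally.
// [[Rcpp::export]]
IntegerVector cpp_move_nodes(IntegerVector indptr, IntegerVector nbr,
                             NumericVector wt, NumericVector mass,
                             IntegerVector memb0, double gam, double tol,
                             bool fast) {
  const int n = mass.size();
  IntegerVector memb(n);
  for (int i = 0; i < n; ++i) memb[i] = memb0[i];

  std::vector<double> A(n, 0.0);
  std::vector<int> csize(n, 0);
  for (int v = 0; v < n; ++v) { A[memb[v]] += mass[v]; csize[memb[v]]++; }
  std::vector<int> freelab;
  for (int c = n - 1; c >= 0; --c) if (csize[c] == 0) freelab.push_back(c);

  std::vector<double> wbuf(n, 0.0);
  std::vector<int> touched; touched.reserve(64);

  // ring queue of capacity n; the in-queue flag keeps entries unique
  std::vector<int> q(n);
  std::vector<char> inq(n, 0);
  int head = 0, count = 0;

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  auto shuffle = [&]() {
    for (int i = n - 1; i > 0; --i) { int j = rand_below(i + 1); std::swap(ord[i], ord[j]); }
  };

  auto push = [&](int v) {
    if (!inq[v]) { q[(head + count) % n] = v; ++count; inq[v] = 1; }
  };
  auto pop = [&]() {
    int v = q[head]; head = (head + 1) % n; --count; inq[v] = 0; return v;
  };

  // try to move v greedily; ties keep the current community, otherwise the
  // lowest community label wins (a fresh community counts as the largest label)
  auto consider = [&](int v) -> bool {
    const int cv = memb[v];
    touched.clear();
    for (int e = indptr[v]; e < indptr[v + 1]; ++e) {
      int c = memb[nbr[e]];
      if (wbuf[c] == 0.0) touched.push_back(c);  // weights are strictly positive
      wbuf[c] += wt[e];
    }
    const double mv = mass[v];
    const double cur = wbuf[cv] - gam * mv * (A[cv] - mv);
    double best = 0.0;   // fresh empty community scores exactly 0
    int bestc = -1;      // -1 encodes the fresh community
    for (size_t t = 0; t < touched.size(); ++t) {
      int c = touched[t];
      if (c == cv) continue;
      double s = wbuf[c] - gam * mv * A[c];
      if (s > best + tol) { best = s; bestc = c; }
      else if (s >= best - tol && (bestc == -1 || c < bestc)) { bestc = c; }
    }
    for (size_t t = 0; t < touched.size(); ++t) wbuf[touched[t]] = 0.0;
    if (cur >= best - tol) return false;           // staying is (tied-)best
    int ct;
    if (bestc == -1) {
      if (csize[cv] == 1) return false;            // fresh move of a singleton is a relabel
      ct = freelab.back(); freelab.pop_back();
    } else ct = bestc;
    A[cv] -= mv; csize[cv]--;
    if (csize[cv] == 0) freelab.push_back(cv);
    A[ct] += mv; csize[ct]++;
    memb[v] = ct;
    return true;
  };

  auto requeue_neighbours = [&](int v) {
    int cv = memb[v];
    for (int e = indptr[v]; e < indptr[v + 1]; ++e)
      if (memb[nbr[e]] != cv) push(nbr[e]);
  };

  if (fast) {
    shuffle();
    for (int i = 0; i < n; ++i) push(ord[i]);
    for (;;) {
      while (count > 0) {
        int v = pop();
        if (consider(v)) requeue_neighbours(v);
      }
      bool clean = true;
      shuffle();
      for (int i = 0; i < n; ++i) {
        int v = ord[i];
        if (consider(v)) { clean = false; requeue_neighbours(v); }
      }
      if (clean) break;
    }
  } else {
    bool moved = true;
    while (moved) {
      moved = false;
      shuffle();
      for (int i = 0; i < n; ++i) if (consider(ord[i])) moved = true;
    }
  }
  return memb;
}

// Randomized refinement: within each community S of pmemb, nodes of rmemb0
// that are still singletons and well connected to S may merge into a refined
// community C within S that is itself well connected to S; the target is drawn
// with probability proportional to exp(delta / theta) among candidates with
// delta >= 0 (staying put, delta = 0, always included).
// Well-connectedness uses the CPM-style cut bound E(X, S\X) >= gam * A_X * (A_S - A_X)
// with the same mass/gam rescaling as above.
// only_comm >= 0 restricts processing to that single community (0-based).
// [[Rcpp::export]]
IntegerVector cpp_refine(IntegerVector indptr, IntegerVector nbr, NumericVector wt,
                         NumericVector mass, IntegerVector pmemb, IntegerVector rmemb0,
                         double gam, double theta, double tol, int only_comm) {
  const int n = mass.size();
  IntegerVector rmemb(n);
  for (int i = 0; i < n; ++i) rmemb[i] = rmemb0[i];

  int C = 0;
  for (int v = 0; v < n; ++v) if (pmemb[v] >= C) C = pmemb[v] + 1;
  std::vector<int> cnt(C, 0), start(C + 1, 0);
  for (int v = 0; v < n; ++v) cnt[pmemb[v]]++;
  for (int c = 0; c < C; ++c) start[c + 1] = start[c] + cnt[c];
  std::vector<int> members(n), pos(start.begin(), start.end() - 1);
  for (int v = 0; v < n; ++v) members[pos[pmemb[v]]++] = v;

  std::vector<double> totS(n, 0.0), rA(n, 0.0), rcut(n, 0.0), wbuf(n, 0.0);
  std::vector<int> rn(n, 0);
  std::vector<int> touched; touched.reserve(64);
  std::vector<int> cand; cand.reserve(64);
  std::vector<double> cdelta; cdelta.reserve(64);

  for (int c = 0; c < C; ++c) {
    if (only_comm >= 0 && c != only_comm) continue;
    const int s0 = start[c], s1 = start[c + 1], sz = s1 - s0;
    if (sz < 2) continue;

    double AS = 0.0;
    for (int i = s0; i < s1; ++i) {
      int v = members[i];
      AS += mass[v];
      double t = 0.0;
      for (int e = indptr[v]; e < indptr[v + 1]; ++e)
        if (pmemb[nbr[e]] == c) t += wt[e];
      totS[v] = t;
    }
    // refined-community aggregates (labels are node-indexed, < n)
    for (int i = s0; i < s1; ++i) {
      int v = members[i], l = rmemb[v];
      rA[l] += mass[v]; rn[l]++; rcut[l] += totS[v];
      for (int e = indptr[v]; e < indptr[v + 1]; ++e) {
        int u = nbr[e];
        if (pmemb[u] == c && rmemb[u] == l) rcut[l] -= wt[e];
      }
    }

    std::vector<int> ordS(members.begin() + s0, members.begin() + s1);
    for (int i = sz - 1; i > 0; --i) { int j = rand_below(i + 1); std::swap(ordS[i], ordS[j]); }

    for (int i = 0; i < sz; ++i) {
      int v = ordS[i], lv = rmemb[v];
      if (rn[lv] != 1) continue;                       // only still-singleton nodes merge
      const double mv = mass[v];
      if (totS[v] < gam * mv * (AS - mv) - tol) continue;  // v not well connected to S

      touched.clear();
      for (int e = indptr[v]; e < indptr[v + 1]; ++e) {
        int u = nbr[e];
        if (pmemb[u] != c) continue;
        int l = rmemb[u];
        if (l == lv) continue;
        if (wbuf[l] == 0.0) touched.push_back(l);
        wbuf[l] += wt[e];
      }
      cand.clear(); cdelta.clear();
      cand.push_back(lv); cdelta.push_back(0.0);       // staying put
      double dmax = 0.0;
      for (size_t t = 0; t < touched.size(); ++t) {
        int l = touched[t];
        if (rcut[l] < gam * rA[l] * (AS - rA[l]) - tol) continue;  // target not well connected
        double d = wbuf[l] - gam * mv * rA[l];
        if (d < -tol) continue;                        // quality-decreasing mergers excluded
        cand.push_back(l); cdelta.push_back(d);
        if (d > dmax) dmax = d;
      }
      int chosen = lv;
      if (cand.size() > 1) {
        double tot = 0.0;
        for (size_t t = 0; t < cand.size(); ++t) {
          cdelta[t] = std::exp((cdelta[t] - dmax) / theta);
          tot += cdelta[t];
        }
        double u = unif_rand() * tot, acc = 0.0;
        chosen = cand[cand.size() - 1];
        for (size_t t = 0; t < cand.size(); ++t) {
          acc += cdelta[t];
          if (u <= acc) { chosen = cand[t]; break; }
        }
      }
      if (chosen != lv) {
        double wvc = wbuf[chosen];
        rA[chosen] += mv; rn[chosen]++;
        rcut[chosen] += totS[v] - 2.0 * wvc;
        rn[lv] = 0; rA[lv] = 0.0; rcut[lv] = 0.0;
        rmemb[v] = chosen;
      }
      for (size_t t = 0; t < touched.size(); ++t) wbuf[touched[t]] = 0.0;
    }

    for (int i = s0; i < s1; ++i) {    // reset scratch for the next community
      int v = members[i], l = rmemb[v];
      totS[v] = 0.0; rA[l] = 0.0; rn[l] = 0; rcut[l] = 0.0;
    }
  }
  return rmemb;
}
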