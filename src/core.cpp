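#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Breakpoint-graph machinery.  All graphs here are multigraphs on gene
// extremities in which every vertex has at most one edge of each of the two
// genome classes, so components are alternating even cycles and paths.
// Vertices are 1-based on the R side; 0 means "no partner".

// ---------------------------------------------------------------------------
// Decompose a concrete breakpoint graph given the two partner arrays.
// Returns cycle lengths (edge counts) and path lengths with endpoints.
// [[Rcpp::export]]
List bg_decompose_core(IntegerVector next1, IntegerVector next2) {
  int m = next1.size();
  if (next2.size() != m) stop("partner arrays differ in length");
  std::vector<char> vis(m, 0);
  std::vector<int> cyc, plen, pend1, pend2;

  // paths (and isolated vertices) first: start from endpoints
  for (int v = 0; v < m; ++v) {
    if (vis[v]) continue;
    bool h1 = next1[v] > 0, h2 = next2[v] > 0;
    if (h1 && h2) continue;               // interior or cycle vertex
    vis[v] = 1;
    if (!h1 && !h2) {                     // isolated vertex: 0-path
      plen.push_back(0); pend1.push_back(v + 1); pend2.push_back(v + 1);
      continue;
    }
    int cls = h1 ? 0 : 1;                 // class of the first edge
    int u = v, len = 0;
    while (true) {
      int w = (cls == 0) ? next1[u] : next2[u];
      if (w == 0) break;
      ++len;
      u = w - 1;
      vis[u] = 1;
      cls ^= 1;
    }
    plen.push_back(len); pend1.push_back(v + 1); pend2.push_back(u + 1);
  }

  // remaining unvisited vertices lie on cycles
  for (int v = 0; v < m; ++v) {
    if (vis[v]) continue;
    int u = v, cls = 0, len = 0;
    do {
      int w = (cls == 0) ? next1[u] : next2[u];
      if (w == 0) stop("internal: broken alternating cycle");
      ++len;
      u = w - 1;
      vis[u] = 1;
      cls ^= 1;
    } while (!(u == v && cls == 0));
    cyc.push_back(len);
  }

  return List::create(_["cycle_len"] = wrap(cyc),
                      _["path_len"] = wrap(plen),
                      _["path_end1"] = wrap(pend1),
                      _["path_end2"] = wrap(pend2));
}

// ---------------------------------------------------------------------------
// Shared helpers for the ambiguous breakpoint graph (ABG).
//
// Squares are rows of `sq` with columns (ga, gb, ba, bb): the two pairs of
// paralogous vertices of the underlying adjacency.  The four candidate
// S-edges occupy fixed slots:
//   slot 0: ga-ba   slot 1: gb-bb   (parallel pair, choice 0)
//   slot 2: ga-bb   slot 3: gb-ba   (crossed pair,  choice 1)

static inline void slot_ends(const IntegerMatrix &sq, int i, int s,
                             int &x, int &y) {
  switch (s) {
  case 0: x = sq(i, 0); y = sq(i, 2); break;
  case 1: x = sq(i, 1); y = sq(i, 3); break;
  case 2: x = sq(i, 0); y = sq(i, 3); break;
  default: x = sq(i, 1); y = sq(i, 2); break;
  }
}

static inline bool slots_compatible(int sq1, int sl1, int sq2, int sl2) {
  if (sq1 != sq2) return true;
  // same square: must be in the same (paralogous) pair
  return (sl1 < 2) == (sl2 < 2);
}

struct SInc {              // per-vertex candidate S-edge incidence
  int cnt = 0;
  int to[2];               // partner vertex (0-based)
  int square[2];
  int slot[2];
};

static std::vector<SInc> build_sinc(int m, const IntegerMatrix &sq,
                                    const LogicalMatrix &present) {
  std::vector<SInc> inc(m);
  int a = sq.nrow();
  for (int i = 0; i < a; ++i) {
    for (int s = 0; s < 4; ++s) {
      if (!present(i, s)) continue;
      int x, y;
      slot_ends(sq, i, s, x, y);
      --x; --y;
      if (inc[x].cnt >= 2 || inc[y].cnt >= 2)
        stop("internal: more than two candidate S-edges at a vertex");
      inc[x].to[inc[x].cnt] = y; inc[x].square[inc[x].cnt] = i;
      inc[x].slot[inc[x].cnt] = s; ++inc[x].cnt;
      inc[y].to[inc[y].cnt] = x; inc[y].square[inc[y].cnt] = i;
      inc[y].slot[inc[y].cnt] = s; ++inc[y].cnt;
    }
  }
  return inc;
}

// ---------------------------------------------------------------------------
// Exhaustive sweep over all resolutions of the free squares; used by the
// brute-force oracle (full graph) and for scoring fully fixed components.
//
// Scores are returned in half units (2 * sigma_k) so they stay integral.
// Path validity: a component endpoint lacking an S-edge only terminates a
// countable path when the vertex is a true S-telomere (s_ok), and one
// lacking a D-edge only when it is a true D-telomere (d_ok); fragments cut
// off by masked edges are thereby never scored.
// [[Rcpp::export]]
List abg_sweep_core(int m, IntegerVector dnext, IntegerMatrix sq,
                    IntegerVector fixed, LogicalMatrix present,
                    LogicalVector s_ok, LogicalVector d_ok) {
  int a = sq.nrow();
  std::vector<int> freesq;
  for (int i = 0; i < a; ++i) if (fixed[i] < 0) freesq.push_back(i);
  int nf = freesq.size();
  if (nf > 25) stop("too many free squares for an exhaustive sweep");
  uint64_t nmask = (uint64_t)1 << nf;

  std::vector<int> snext(m, -1), sstamp(m, -1), vstamp(m, -1);
  std::vector<int> choice(a);
  for (int i = 0; i < a; ++i) choice[i] = fixed[i] < 0 ? 0 : fixed[i];

  const int NK = 4;                     // k = 2, 4, 6, inf
  long best2[NK] = {-1, -1, -1, -1};
  std::vector<IntegerVector> bestch(NK);
  for (int k = 0; k < NK; ++k) bestch[k] = IntegerVector(a);

  for (uint64_t mask = 0; mask < nmask; ++mask) {
    // first free square = most significant bit -> ascending mask enumerates
    // choice tuples in lexicographic order with "parallel" (0) first
    for (int j = 0; j < nf; ++j)
      choice[freesq[j]] = (mask >> (nf - 1 - j)) & 1;

    int stamp = (int)mask + 1;
    for (int i = 0; i < a; ++i) {
      int base = choice[i] == 0 ? 0 : 2;
      for (int s = base; s < base + 2; ++s) {
        if (!present(i, s)) continue;
        int x, y;
        slot_ends(sq, i, s, x, y);
        --x; --y;
        snext[x] = y; sstamp[x] = stamp;
        snext[y] = x; sstamp[y] = stamp;
      }
    }

    long c2 = 0, c4 = 0, c6 = 0, ct = 0, p0 = 0, p2 = 0, p4 = 0, pe = 0;
    for (int v = 0; v < m; ++v) {
      if (vstamp[v] == stamp) continue;
      bool hs = sstamp[v] == stamp, hd = dnext[v] > 0;
      if (hs && hd) continue;
      vstamp[v] = stamp;
      bool ok = !hs ? (bool)s_ok[v] : (bool)d_ok[v];
      if (!hs && !hd) {
        if (ok && d_ok[v]) { ++p0; ++pe; }
        continue;
      }
      int cls = hs ? 0 : 1, u = v, len = 0;
      while (true) {
        int w;
        if (cls == 0) w = (sstamp[u] == stamp) ? snext[u] + 1 : 0;
        else w = dnext[u];
        if (w == 0) break;
        ++len;
        u = w - 1;
        vstamp[u] = stamp;
        cls ^= 1;
      }
      bool ok2 = (cls == 0) ? (bool)s_ok[u] : (bool)d_ok[u];
      if ((len % 2) == 0 && ok && ok2) {
        ++pe;
        if (len == 0) ++p0; else if (len == 2) ++p2; else if (len == 4) ++p4;
      }
    }
    for (int v = 0; v < m; ++v) {
      if (vstamp[v] == stamp) continue;
      int u = v, cls = 0, len = 0;
      do {
        int w;
        if (cls == 0) {
          if (sstamp[u] != stamp) stop("internal: cycle walk left the graph");
          w = snext[u] + 1;
        } else w = dnext[u];
        ++len;
        u = w - 1;
        vstamp[u] = stamp;
        cls ^= 1;
      } while (!(u == v && cls == 0));
      ++ct;
      if (len == 2) ++c2; else if (len == 4) ++c4; else if (len == 6) ++c6;
    }

    long s2 = 2 * c2 + p0;
    long s4 = s2 + 2 * c4 + p2;
    long s6 = s4 + 2 * c6 + p4;
    long sinf = 2 * ct + pe;
    long sc[NK] = {s2, s4, s6, sinf};
    for (int k = 0; k < NK; ++k) {
      if (sc[k] > best2[k]) {           // strict: keep first (lex smallest)
        best2[k] = sc[k];
        for (int i = 0; i < a; ++i) bestch[k][i] = choice[i];
      }
    }
  }

  return List::create(
    _["best2"] = IntegerVector::create(best2[0], best2[1], best2[2], best2[3]),
    _["choice2"] = bestch[0], _["choice4"] = bestch[1],
    _["choice6"] = bestch[2], _["choiceInf"] = bestch[3],
    _["n_masks"] = (double)nmask);
}

// ---------------------------------------------------------------------------
// Enumerate all players: valid cycles of length <= kmax and valid even paths
// of length <= kmax - 2 (excluding 0-paths, which are isolated vertices),
// over the currently present candidate S-edges and (masked) D-edges.
// s_telo / d_telo are the *original* telomere statuses, used for path-end
// validity.  Each player is reported once.
// [[Rcpp::export]]
List enumerate_players_core(int m, IntegerVector dnext, IntegerMatrix sq,
                            LogicalMatrix present, LogicalVector s_telo,
                            LogicalVector d_telo, int kmax) {
  std::vector<SInc> inc = build_sinc(m, sq, present);
  std::vector<int> ptype, plen;
  std::vector<std::vector<int>> pverts, psq, pslot;

  auto emit = [&](int type, std::initializer_list<int> verts,
                  std::initializer_list<int> sqs,
                  std::initializer_list<int> slots) {
    ptype.push_back(type);
    plen.push_back((int)verts.size() - (type == 1 ? 1 : 0));
    pverts.emplace_back(verts);
    psq.emplace_back(sqs);
    pslot.emplace_back(slots);
  };

  // --- cycles, anchored at their lexicographically smallest D-edge ---
  for (int u = 0; u < m; ++u) {
    int v = dnext[u] - 1;
    if (v <= u) continue;                       // each D-edge once, u < v
    // 2-cycles
    for (int e = 0; e < inc[u].cnt; ++e) {
      if (inc[u].to[e] == v)
        emit(0, {u, v}, {inc[u].square[e]}, {inc[u].slot[e]});
    }
    // 4-cycles: u -D- v -S- w -D- x -S- u
    for (int e = 0; e < inc[v].cnt; ++e) {
      int w = inc[v].to[e];
      if (w == u) continue;
      int x = dnext[w] - 1;
      if (x < 0) continue;
      int mn = w < x ? w : x;
      if (mn < u) continue;                     // anchored elsewhere
      for (int f = 0; f < inc[x].cnt; ++f) {
        if (inc[x].to[f] != u) continue;
        if (!slots_compatible(inc[v].square[e], inc[v].slot[e],
                              inc[x].square[f], inc[x].slot[f])) continue;
        emit(0, {u, v, w, x},
             {inc[v].square[e], inc[x].square[f]},
             {inc[v].slot[e], inc[x].slot[f]});
      }
    }
    if (kmax >= 6) {
      // 6-cycles: u -D- v -S- w -D- x -S- y -D- z -S- u
      for (int e = 0; e < inc[v].cnt; ++e) {
        int w = inc[v].to[e];
        if (w == u) continue;
        int x = dnext[w] - 1;
        if (x < 0 || x == u || x == v) continue;
        int mn1 = w < x ? w : x;
        if (mn1 < u) continue;
        for (int f = 0; f < inc[x].cnt; ++f) {
          int y = inc[x].to[f];
          if (y == u || y == v || y == w) continue;
          if (!slots_compatible(inc[v].square[e], inc[v].slot[e],
                                inc[x].square[f], inc[x].slot[f])) continue;
          int z = dnext[y] - 1;
          if (z < 0 || z == v || z == w || z == x) continue;
          int mn2 = y < z ? y : z;
          if (mn2 < u) continue;
          for (int g = 0; g < inc[z].cnt; ++g) {
            if (inc[z].to[g] != u) continue;
            if (!slots_compatible(inc[v].square[e], inc[v].slot[e],
                                  inc[z].square[g], inc[z].slot[g])) continue;
            if (!slots_compatible(inc[x].square[f], inc[x].slot[f],
                                  inc[z].square[g], inc[z].slot[g])) continue;
            emit(0, {u, v, w, x, y, z},
                 {inc[v].square[e], inc[x].square[f], inc[z].square[g]},
                 {inc[v].slot[e], inc[x].slot[f], inc[z].slot[g]});
          }
        }
      }
    }
  }

  // --- even paths, anchored at their unique true D-telomere end ---
  for (int u = 0; u < m; ++u) {
    if (!d_telo[u]) continue;
    for (int e = 0; e < inc[u].cnt; ++e) {
      int v = inc[u].to[e];
      int w = dnext[v] - 1;
      if (w < 0) continue;
      if (s_telo[w]) {                          // valid 2-path u-v-w
        emit(1, {u, v, w}, {inc[u].square[e]}, {inc[u].slot[e]});
      }
      if (kmax >= 6) {
        // valid 4-path u -S- v -D- w -S- x -D- y
        for (int f = 0; f < inc[w].cnt; ++f) {
          int x = inc[w].to[f];
          if (x == u || x == v) continue;
          if (!slots_compatible(inc[u].square[e], inc[u].slot[e],
                                inc[w].square[f], inc[w].slot[f])) continue;
          int y = dnext[x] - 1;
          if (y < 0 || y == u || y == v || y == w) continue;
          if (!s_telo[y]) continue;
          emit(1, {u, v, w, x, y},
               {inc[u].square[e], inc[w].square[f]},
               {inc[u].slot[e], inc[w].slot[f]});
        }
      }
    }
  }

  int np = ptype.size();
  List players(np);
  for (int i = 0; i < np; ++i) {
    IntegerVector vv(pverts[i].begin(), pverts[i].end());
    IntegerVector ss(psq[i].begin(), psq[i].end());
    IntegerVector ll(pslot[i].begin(), pslot[i].end());
    players[i] = List::create(_["type"] = ptype[i] == 0 ? "cycle" : "path",
                              _["len"] = ptype[i] == 0 ? (int)pverts[i].size()
                                                       : (int)pverts[i].size() - 1,
                              _["vertices"] = vv + 1,
                              _["squares"] = ss + 1,
                              _["slots"] = ll + 1);
  }
  return players;
}
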