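// Seed-and-extend alignment kernel for long noisy reads:
//   exact k-mer seeding -> co-linear chaining -> banded affine-gap (Gotoh)
//   alignment with free end gaps on the target.
// Coordinates are 0-based on input and output; R wrappers convert.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static inline int b2i(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

// Exact k-mer hits between query and target, chained co-linearly.
// Returns the best chain: total anchored query bases plus its extent and
// the diagonal range it spans (tpos - qpos), which the banded aligner uses
// to size its band. score = 0 means no acceptable chain.
// [[Rcpp::export(name = ".cpp_chain")]]
List cpp_chain(std::string query, std::string target, int k = 15,
               int max_occ = 50, int max_indel = 20000, int max_hits = 2000) {
  int m = (int)query.size(), n = (int)target.size();
  List fail = List::create(_["score"] = 0);
  if (m < k || n < k) return fail;
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  std::unordered_map<uint64_t, std::vector<int>> idx;
  idx.reserve((size_t)n * 2);
  {
    uint64_t h = 0; int run = 0;
    for (int j = 0; j < n; ++j) {
      int b = b2i(target[j]);
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask; ++run;
      if (run >= k) {
        std::vector<int> &v = idx[h];
        if ((int)v.size() <= max_occ) v.push_back(j - k + 1);
      }
    }
  }

  // Collect hits; if too many, re-collect with a coarser query stride so the
  // O(h^2) chaining stays cheap. Hits emerge sorted by (qpos, tpos).
  std::vector<int> qv, tv;
  int stride = 1;
  for (;;) {
    qv.clear(); tv.clear();
    uint64_t h = 0; int run = 0;
    bool over = false;
    for (int i = 0; i < m && !over; ++i) {
      int b = b2i(query[i]);
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask; ++run;
      if (run >= k) {
        int qpos = i - k + 1;
        if (qpos % stride) continue;
        std::unordered_map<uint64_t, std::vector<int>>::iterator it = idx.find(h);
        if (it == idx.end()) continue;
        if ((int)it->second.size() > max_occ) continue;
        for (size_t z = 0; z < it->second.size(); ++z) {
          qv.push_back(qpos); tv.push_back(it->second[z]);
          if ((int)qv.size() > 4 * max_hits) { over = true; break; }
        }
      }
    }
    if (!over && (int)qv.size() <= max_hits) break;
    if (stride >= 256) break;
    stride *= 2;
  }
  int h = (int)qv.size();
  if (h == 0) return fail;
  if (h > 4 * max_hits) { qv.resize(4 * max_hits); tv.resize(4 * max_hits); h = 4 * max_hits; }

  std::vector<int> f(h), pre(h, -1);
  int besti = 0;
  for (int i = 0; i < h; ++i) {
    f[i] = k;
    for (int j = i - 1; j >= 0; --j) {
      if (qv[j] >= qv[i] || tv[j] >= tv[i]) continue;
      int dq = qv[i] - qv[j], dt = tv[i] - tv[j];
      int dd = dt - dq; if (dd < 0) dd = -dd;
      if (dd > max_indel) continue;
      int gain = std::min(k, std::min(dq, dt));
      if (f[j] + gain > f[i]) { f[i] = f[j] + gain; pre[i] = j; }
    }
    if (f[i] > f[besti]) besti = i;
  }

  int qlo = qv[besti], qhi = qv[besti] + k, tlo = tv[besti], thi = tv[besti] + k;
  int dmin = tv[besti] - qv[besti], dmax = dmin;
  for (int i = besti; i != -1; i = pre[i]) {
    qlo = qv[i]; tlo = tv[i];
    int d = tv[i] - qv[i];
    if (d < dmin) dmin = d;
    if (d > dmax) dmax = d;
  }
  return List::create(
    _["score"] = f[besti], _["qlo"] = qlo, _["qhi"] = qhi,
    _["tlo"] = tlo, _["thi"] = thi, _["dmin"] = dmin, _["dmax"] = dmax,
    _["nhits"] = h, _["stride"] = stride);
}

// Banded global-in-query alignment of query against target[wlo, whi), with
// free target gaps at both ends. Band: for query prefix i, target column j is
// allowed iff i + dlo <= j <= i + dhi (window coordinates), where
// dlo/dhi derive from the chain's diagonal range plus pad.
// Affine gaps: a gap of length g costs gap_open + g * gap_ext.
// [[Rcpp::export(name = ".cpp_banded_align")]]
List cpp_banded_align(std::string query, std::string target,
                      int wlo, int whi, int dmin, int dmax, int pad = 200,
                      int match = 2, int mismatch = -4,
                      int gap_open = 4, int gap_ext = 2) {
  const int NEG = -(1 << 29);
  int m = (int)query.size();
  int W = whi - wlo;
  if (m <= 0 || W <= 0) stop("empty query or target window");
  int dlo = dmin - wlo - pad;
  int dhi = dmax - wlo + pad;
  if (dlo < -m) dlo = -m;
  if (dhi > W) dhi = W;
  int bw = dhi - dlo + 1;
  if (bw < 1) stop("degenerate band");
  if ((double)(m + 1) * bw > 6e8) stop("band too large");

  int go = gap_open + gap_ext, ge = gap_ext;

  std::vector<int> Mp(bw, NEG), Ip(bw, NEG), Dp(bw, NEG);
  std::vector<int> Mc(bw, NEG), Ic(bw, NEG), Dc(bw, NEG);
  // traceback: bits 0-1 = M predecessor (0=M,1=I,2=D), bit 2 = I from extend,
  // bit 3 = D from extend
  std::vector<uint8_t> tb((size_t)(m + 1) * bw, 0);

  // row 0: alignment may start at any target offset j (free leading gap)
  for (int c = 0; c < bw; ++c) {
    int j = 0 + dlo + c;
    if (j >= 0 && j <= W) { Mp[c] = 0; }
  }

  for (int i = 1; i <= m; ++i) {
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Ic.begin(), Ic.end(), NEG);
    std::fill(Dc.begin(), Dc.end(), NEG);
    char qc = query[i - 1];
    size_t rowoff = (size_t)i * bw;
    for (int c = 0; c < bw; ++c) {
      int j = i + dlo + c;
      if (j < 0 || j > W) continue;
      uint8_t t = 0;
      // M: consume query i and target j (needs j >= 1); diagonal predecessor
      // sits at the same band column of the previous row.
      if (j >= 1) {
        int best = Mp[c]; int st = 0;
        if (Ip[c] > best) { best = Ip[c]; st = 1; }
        if (Dp[c] > best) { best = Dp[c]; st = 2; }
        if (best > NEG) {
          int s = (b2i(qc) >= 0 && b2i(qc) == b2i(target[wlo + j - 1])) ? match : mismatch;
          Mc[c] = best + s;
          t |= (uint8_t)st;
        }
      }
      // I: consume query base only; predecessor (i-1, j) = band column c+1.
      if (c + 1 < bw) {
        int op = (Mp[c + 1] > NEG) ? Mp[c + 1] - go : NEG;
        int ex = (Ip[c + 1] > NEG) ? Ip[c + 1] - ge : NEG;
        if (op >= ex) { Ic[c] = op; }
        else { Ic[c] = ex; t |= 4; }
      }
      // D: consume target base only; predecessor (i, j-1) = band column c-1.
      if (c - 1 >= 0 && j >= 1) {
        int op = (Mc[c - 1] > NEG) ? Mc[c - 1] - go : NEG;
        int ex = (Dc[c - 1] > NEG) ? Dc[c - 1] - ge : NEG;
        if (op >= ex) { Dc[c] = op; }
        else if (ex > NEG) { Dc[c] = ex; t |= 8; }
      }
      tb[rowoff + c] = t;
    }
    std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Dp, Dc);
  }

  // free trailing target gap: best over last row of M and I states
  int bestc = -1, bests = NEG, bestst = 0;
  for (int c = 0; c < bw; ++c) {
    int j = m + dlo + c;
    if (j < 0 || j > W) continue;
    if (Mp[c] > bests) { bests = Mp[c]; bestc = c; bestst = 0; }
    if (Ip[c] > bests) { bests = Ip[c]; bestc = c; bestst = 1; }
  }
  if (bestc < 0 || bests <= NEG / 2)
    return List::create(_["aligned"] = false);

  // traceback
  std::string ops;
  ops.reserve(m + 64);
  int i = m, c = bestc, st = bestst;
  int jend = m + dlo + c;
  while (i > 0) {
    uint8_t t = tb[(size_t)i * bw + c];
    if (st == 0) {
      int j = i + dlo + c;
      char qc = query[i - 1], tc = target[wlo + j - 1];
      ops.push_back((b2i(qc) >= 0 && b2i(qc) == b2i(tc)) ? 'M' : 'X');
      st = t & 3;
      i -= 1; // c unchanged: diagonal predecessor same column previous row
    } else if (st == 1) {
      ops.push_back('I');
      st = (t & 4) ? 1 : 0;
      i -= 1; c += 1;
    } else {
      ops.push_back('D');
      st = (t & 8) ? 2 : 0;
      c -= 1;
    }
  }
  int jstart = i + dlo + c; // i == 0
  std::reverse(ops.begin(), ops.end());

  // run-length encode; gather stats
  std::vector<std::string> rops; std::vector<int> rlens;
  int nmatch = 0, nmis = 0, nins = 0, ndel = 0;
  for (size_t z = 0; z < ops.size();) {
    size_t w = z;
    while (w < ops.size() && ops[w] == ops[z]) ++w;
    rops.push_back(std::string(1, ops[z]));
    rlens.push_back((int)(w - z));
    int len = (int)(w - z);
    switch (ops[z]) {
      case 'M': nmatch += len; break;
      case 'X': nmis += len; break;
      case 'I': nins += len; break;
      case 'D': ndel += len; break;
    }
    z = w;
  }

  return List::create(
    _["aligned"] = true,
    _["score"] = bests,
    _["tstart"] = wlo + jstart,   // 0-based inclusive start in full target
    _["tend"] = wlo + jend,       // 0-based exclusive end
    _["ops"] = rops, _["lens"] = rlens,
    _["nmatch"] = nmatch, _["nmismatch"] = nmis,
    _["nins"] = nins, _["ndel"] = ndel);
}
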