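#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 2-bit encoding; -1 for non-ACGT
static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// [[Rcpp::export(name = ".anchors_cpp")]]
DataFrame anchors_cpp(std::string target, std::string query, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  // kmer -> position if unique, -2 if multiple
  auto scan = [&](const std::string& s,
                  std::unordered_map<uint64_t, int64_t>& m) {
    uint64_t h = 0; int valid = 0;
    const int64_t n = (int64_t)s.size();
    m.reserve((size_t)(n > 0 ? n : 1));
    for (int64_t i = 0; i < n; ++i) {
      int b = base2bit(s[(size_t)i]);
      if (b < 0) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        int64_t pos = i - k + 1;
        auto it = m.find(h);
        if (it == m.end()) m.emplace(h, pos); else it->second = -2;
      }
    }
  };
  std::unordered_map<uint64_t, int64_t> tmap, qmap;
  scan(target, tmap);
  scan(query, qmap);

  // co-matches in target order (tmap iteration order is unordered: rescan target)
  std::vector<int64_t> tpos, qpos;
  {
    uint64_t h = 0; int valid = 0;
    const int64_t n = (int64_t)target.size();
    for (int64_t i = 0; i < n; ++i) {
      int b = base2bit(target[(size_t)i]);
      if (b < 0) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        int64_t pos = i - k + 1;
        auto it = tmap.find(h);
        if (it == tmap.end() || it->second != pos) continue; // not unique in target
        auto iq = qmap.find(h);
        if (iq == qmap.end() || iq->second < 0) continue;    // absent/multi in query
        tpos.push_back(pos); qpos.push_back(iq->second);
      }
    }
  }
  // merge maximal runs of consecutive co-matches (t+1, q+1)
  std::vector<int> at, aq, alen;
  size_t i = 0, n = tpos.size();
  while (i < n) {
    size_t j = i;
    while (j + 1 < n && tpos[j + 1] == tpos[j] + 1 && qpos[j + 1] == qpos[j] + 1) ++j;
    at.push_back((int)tpos[i]);
    aq.push_back((int)qpos[i]);
    alen.push_back((int)(tpos[j] - tpos[i]) + k);
    i = j + 1;
  }
  return DataFrame::create(_["t_start"] = at, _["q_start"] = aq,
                           _["length"] = alen);
}

// Co-linear chaining DP with bounded predecessor lookback.
// Score = anchored bases - affine cost on |dt - dq| between consecutive anchors.
// Returns chain membership (1-based chain id per anchor, 0 = unchained) and
// per-chain scores; anchors must be supplied sorted by (t_start, q_start).
// [[Rcpp::export(name = ".chain_cpp")]]
List chain_cpp(IntegerVector t_start, IntegerVector q_start, IntegerVector len,
               double gap_open, double gap_extend, int lookback,
               double min_score) {
  const int n = t_start.size();
  std::vector<double> dp(n);
  std::vector<int> parent(n, -1);
  for (int i = 0; i < n; ++i) {
    dp[i] = (double)len[i];
    int lo = std::max(0, i - lookback);
    for (int j = i - 1; j >= lo; --j) {
      int dt = t_start[i] - (t_start[j] + len[j]);
      int dq = q_start[i] - (q_start[j] + len[j]);
      if (dt < 0 || dq < 0) continue;
      int g = std::abs(dt - dq);
      double cost = (g == 0) ? 0.0 : gap_open + gap_extend * (double)g;
      double s = dp[j] + (double)len[i] - cost;
      if (s > dp[i]) { dp[i] = s; parent[i] = j; }
    }
  }
  // greedy extraction: best unused endpoint first, backtrack until used anchor
  std::vector<int> chain_id(n, 0);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return dp[a] > dp[b]; });
  std::vector<double> scores;
  int next_id = 0;
  for (int oi = 0; oi < n; ++oi) {
    int i = order[oi];
    if (chain_id[i] != 0 || dp[i] < min_score) continue;
    ++next_id;
    double sc = dp[i];
    int j = i;
    while (j >= 0 && chain_id[j] == 0) {
      chain_id[j] = next_id;
      int p = parent[j];
      if (p >= 0 && chain_id[p] != 0) { sc -= dp[p]; break; }
      j = p;
    }
    scores.push_back(sc);
  }
  return List::create(_["chain_id"] = IntegerVector(chain_id.begin(), chain_id.end()),
                      _["score"] = NumericVector(scores.begin(), scores.end()));
}

// column op codes
enum { OP_MATCH = 1, OP_MISMATCH = 2, OP_TGAP = 3, OP_QGAP = 4 };

struct OpSink {
  std::vector<int> ops, lens;
  void push(int op, int l) {
    if (l <= 0) return;
    if (!ops.empty() && ops.back() == op) lens.back() += l;
    else { ops.push_back(op); lens.push_back(l); }
  }
};

// Banded affine (Gotoh) global alignment of t_seg vs q_seg, emitting column ops.
// Gap of length L costs gap_open + gap_extend * L.
// V = best, E = gap-in-target (consumes query), F = gap-in-query (consumes target).
// Traceback byte per cell:
//   bits 0-1: V origin (0 diag, 1 E, 2 F)
//   bit 2: E extends E (else opened from V at (i, j-1))
//   bit 3: F extends F (else opened from V at (i-1, j))
//   bit 6: diagonal move is a mismatch
static void nw_affine_band(const char* T, int nt, const char* Q, int nq,
                           int match, int mismatch, int gap_open, int gap_extend,
                           int band_margin, OpSink& sink) {
  if (nt == 0 && nq == 0) return;
  if (nt == 0) { sink.push(OP_TGAP, nq); return; }
  if (nq == 0) { sink.push(OP_QGAP, nt); return; }
  const int NEG = -1000000000;
  const int go = gap_open, ge = gap_extend;
  const int half = std::abs(nq - nt) + band_margin;
  // band for row i: j in [i - half, i + half + (nq - nt) if positive] — use a
  // symmetric corridor wide enough to contain (0,0) and (nt,nq)
  auto jlo = [&](int i) {
    int c = i + std::min(0, nq - nt) - half;
    return std::max(0, c);
  };
  auto jhi = [&](int i) {
    int c = i + std::max(0, nq - nt) + half;
    return std::min(nq, c);
  };
  const int bw = 2 * half + std::abs(nq - nt) + 3;
  if ((size_t)(nt + 1) * (size_t)bw > (size_t)512 * 1024 * 1024) {
    // degenerate huge gap: fall back to a naive diagonal + tail-gap fill
    int d = std::min(nt, nq);
    for (int u = 0; u < d; ++u)
      sink.push(T[u] == Q[u] ? OP_MATCH : OP_MISMATCH, 1);
    if (nq > d) sink.push(OP_TGAP, nq - d);
    if (nt > d) sink.push(OP_QGAP, nt - d);
    return;
  }
  std::vector<int> Vc(bw, NEG), Ec(bw, NEG), Fc(bw, NEG),
                   Vp(bw, NEG), Ep(bw, NEG), Fp(bw, NEG);
  std::vector<uint8_t> tb((size_t)(nt + 1) * bw, 0);

  // row 0: only gaps in target
  for (int j = jlo(0); j <= jhi(0); ++j) {
    int idx = j - jlo(0);
    if (j == 0) { Vp[idx] = 0; Ep[idx] = NEG; }
    else {
      Ep[idx] = -(go + ge * j);
      Vp[idx] = Ep[idx];
      uint8_t c = 0x01;                 // V from E
      if (j > 1) c |= 0x04;             // E extends E
      tb[idx] = c;
    }
    Fp[idx] = NEG;
  }
  for (int i = 1; i <= nt; ++i) {
    int lo = jlo(i), hi = jhi(i), plo = jlo(i - 1), phi = jhi(i - 1);
    std::fill(Vc.begin(), Vc.end(), NEG);
    std::fill(Ec.begin(), Ec.end(), NEG);
    std::fill(Fc.begin(), Fc.end(), NEG);
    for (int j = lo; j <= hi; ++j) {
      int idx = j - lo;
      uint8_t code = 0;
      // F from row above, same j
      int f = NEG;
      if (j >= plo && j <= phi) {
        int p = j - plo;
        int fo = (Vp[p] > NEG) ? Vp[p] - (go + ge) : NEG;
        int fe = (Fp[p] > NEG) ? Fp[p] - ge : NEG;
        f = std::max(fo, fe);
        if (fe > fo) code |= 0x08;
      }
      // E from same row, j-1
      int e = NEG;
      if (j - 1 >= lo) {
        int p = j - 1 - lo;
        int eo = (Vc[p] > NEG) ? Vc[p] - (go + ge) : NEG;
        int ee = (Ec[p] > NEG) ? Ec[p] - ge : NEG;
        e = std::max(eo, ee);
        if (ee > eo) code |= 0x04;
      }
      // diagonal
      int m = NEG;
      bool mm = false;
      if (j >= 1 && j - 1 >= plo && j - 1 <= phi) {
        int p = j - 1 - plo;
        if (Vp[p] > NEG) {
          mm = !(T[i - 1] == Q[j - 1]);
          m = Vp[p] + (mm ? mismatch : match);
        }
      }
      int best = std::max(m, std::max(e, f));
      if (best <= NEG) continue;
      Vc[idx] = best; Ec[idx] = e; Fc[idx] = f;
      if (best == m) code |= 0x00;
      else if (best == e) code |= 0x01;
      else code |= 0x02;
      if (mm) code |= 0x40;
      tb[(size_t)i * bw + idx] = code;
    }
    std::swap(Vc, Vp); std::swap(Ec, Ep); std::swap(Fc, Fp);
  }
  // traceback from (nt, nq)
  std::vector<int> rev_ops;
  int i = nt, j = nq;
  int state = tb[(size_t)i * bw + (j - jlo(i))] & 0x03; // V origin
  while (i > 0 || j > 0) {
    if (j == 0) state = 2;
    else if (i == 0) state = 1;
    uint8_t c = tb[(size_t)i * bw + (j - jlo(i))];
    if (state == 1) {                   // gap in target, consume query base
      rev_ops.push_back(OP_TGAP);
      bool ext = (c & 0x04) != 0;
      --j;
      if (!ext && (i > 0 || j > 0))
        state = tb[(size_t)i * bw + (j - jlo(i))] & 0x03;
    } else if (state == 2) {            // gap in query, consume target base
      rev_ops.push_back(OP_QGAP);
      bool ext = (c & 0x08) != 0;
      --i;
      if (!ext && (i > 0 || j > 0))
        state = tb[(size_t)i * bw + (j - jlo(i))] & 0x03;
    } else {                            // diagonal
      rev_ops.push_back((c & 0x40) ? OP_MISMATCH : OP_MATCH);
      --i; --j;
      if (i > 0 || j > 0)
        state = tb[(size_t)i * bw + (j - jlo(i))] & 0x03;
    }
  }
  for (auto it = rev_ops.rbegin(); it != rev_ops.rend(); ++it) sink.push(*it, 1);
}

// Fill gaps between consecutive chain anchors with banded affine NW.
// Anchors: 0-based (t_start, q_start, length), strictly increasing, plus the
// head (sequence starts) and tail (sequence ends) regions.
// [[Rcpp::export(name = ".fill_chain_cpp")]]
List fill_chain_cpp(std::string target, std::string query,
                    IntegerVector t_start, IntegerVector q_start,
                    IntegerVector len, int max_gap,
                    int match, int mismatch, int gap_open, int gap_extend,
                    int band_margin, bool align_ends) {
  const int n = t_start.size();
  if (n == 0) stop("chain has no anchors");
  OpSink sink;
  std::vector<int> un_ts, un_te, un_qs, un_qe;
  int chain_t0 = t_start[0], chain_q0 = q_start[0];

  auto fill_gap = [&](int t0, int t1, int q0, int q1) {
    int nt = t1 - t0, nq = q1 - q0;
    if (nt == 0 && nq == 0) return;
    if (std::max(nt, nq) > max_gap) {
      un_ts.push_back(t0); un_te.push_back(t1);
      un_qs.push_back(q0); un_qe.push_back(q1);
      return;
    }
    nw_affine_band(target.data() + t0, nt, query.data() + q0, nq,
                   match, mismatch, gap_open, gap_extend, band_margin, sink);
  };

  if (align_ends && (t_start[0] > 0 || q_start[0] > 0)) {
    int nt = t_start[0], nq = q_start[0];
    if (std::max(nt, nq) <= max_gap) {
      chain_t0 = 0; chain_q0 = 0;
      nw_affine_band(target.data(), nt, query.data(), nq,
                     match, mismatch, gap_open, gap_extend, band_margin, sink);
    }
  }
  for (int a = 0; a < n; ++a) {
    if (a > 0) fill_gap(t_start[a - 1] + len[a - 1], t_start[a],
                        q_start[a - 1] + len[a - 1], q_start[a]);
    sink.push(OP_MATCH, len[a]);
  }
  int t_end = t_start[n - 1] + len[n - 1];
  int q_end = q_start[n - 1] + len[n - 1];
  if (align_ends && ((int)target.size() > t_end || (int)query.size() > q_end)) {
    int nt = (int)target.size() - t_end, nq = (int)query.size() - q_end;
    if (std::max(nt, nq) <= max_gap) {
      nw_affine_band(target.data() + t_end, nt, query.data() + q_end, nq,
                     match, mismatch, gap_open, gap_extend, band_margin, sink);
      t_end = (int)target.size(); q_end = (int)query.size();
    }
  }
  return List::create(
      _["ops"] = IntegerVector(sink.ops.begin(), sink.ops.end()),
      _["lens"] = IntegerVector(sink.lens.begin(), sink.lens.end()),
      _["t_start"] = chain_t0, _["q_start"] = chain_q0,
      _["t_end"] = t_end, _["q_end"] = q_end,
      _["unaligned"] = DataFrame::create(
          _["t_start"] = IntegerVector(un_ts.begin(), un_ts.end()),
          _["t_end"] = IntegerVector(un_te.begin(), un_te.end()),
          _["q_start"] = IntegerVector(un_qs.begin(), un_qs.end()),
          _["q_end"] = IntegerVector(un_qe.begin(), un_qe.end())));
}

// Per-target-base column class counts from a filled chain.
// match/mismatch/q_gap columns consume one target base; t_gap columns are
// assigned to the target position of their left flank (clipped to >= 0).
// [[Rcpp::export(name = ".per_base_counts_cpp")]]
List per_base_counts_cpp(IntegerVector ops, IntegerVector lens, int t0,
                         int chrom_len) {
  IntegerVector cm(chrom_len), cx(chrom_len), ct(chrom_len), cq(chrom_len);
  int64_t t = t0;
  for (int r = 0; r < ops.size(); ++r) {
    int op = ops[r], l = lens[r];
    switch (op) {
    case OP_MATCH:
      for (int i = 0; i < l; ++i) if (t + i >= 0 && t + i < chrom_len) cm[t + i]++;
      t += l; break;
    case OP_MISMATCH:
      for (int i = 0; i < l; ++i) if (t + i >= 0 && t + i < chrom_len) cx[t + i]++;
      t += l; break;
    case OP_QGAP:
      for (int i = 0; i < l; ++i) if (t + i >= 0 && t + i < chrom_len) cq[t + i]++;
      t += l; break;
    case OP_TGAP: {
      int64_t p = t - 1; if (p < 0) p = 0;
      if (p < chrom_len) ct[p] += l;
      break;
    }
    default: stop("unknown op code");
    }
  }
  return List::create(_["match"] = cm, _["mismatch"] = cx,
                      _["t_gap"] = ct, _["q_gap"] = cq);
}

// Count indel events (maximal gap runs) per target position (left flank).
// [[Rcpp::export(name = ".indel_events_cpp")]]
IntegerVector indel_events_cpp(IntegerVector ops, IntegerVector lens, int t0,
                               int chrom_len) {
  IntegerVector ev(chrom_len);
  int64_t t = t0;
  for (int r = 0; r < ops.size(); ++r) {
    int op = ops[r], l = lens[r];
    if (op == OP_MATCH || op == OP_MISMATCH) { t += l; continue; }
    int64_t p = (op == OP_TGAP) ? std::max((int64_t)0, t - 1) : t;
    if (p < chrom_len) ev[p]++;
    if (op == OP_QGAP) t += l;
  }
  return ev;
}
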