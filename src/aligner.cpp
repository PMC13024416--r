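// Local DNA alignment kernels: a full Smith-Waterman (Gotoh affine) used as
// the reference aligner, and a word-seeded banded gapped aligner used for
// genome-scale homology search. Scores follow the BLASTN convention: a gap of
// length k costs gap_open + k * gap_extend; IUPAC ambiguity codes score as
// mismatches and never seed words.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static const int NEG_INF = -(1 << 29);

static std::vector<uint8_t> encode_seq(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': case 'a': v[i] = 0; break;
      case 'C': case 'c': v[i] = 1; break;
      case 'G': case 'g': v[i] = 2; break;
      case 'T': case 't': v[i] = 3; break;
      default: v[i] = 4;  // ambiguity: mismatch-only, never seeds
    }
  }
  return v;
}

struct Aln {
  int score, q_start, q_end, s_start, s_end, matches, aln_length;
  std::string cigar;
};

static inline std::string build_cigar(const std::vector<char>& ops) {
  std::string out;
  size_t i = 0;
  while (i < ops.size()) {
    size_t j = i;
    while (j < ops.size() && ops[j] == ops[i]) ++j;
    out += std::to_string(j - i);
    out += ops[i];
    i = j;
  }
  return out;
}

// Traceback codes packed into one byte per cell:
//   bits 0-1: H source (0 = local stop, 1 = diagonal, 2 = E gap, 3 = F gap)
//   bit 2: E opened here (came from H), bit 3: F opened here
// E consumes a subject base against a gap in the query (CIGAR 'D');
// F consumes a query base against a gap in the subject (CIGAR 'I').

// Full Smith-Waterman with affine gaps and traceback. Row i consumes query
// base i-1, column j consumes subject base j-1.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string subject,
                  int match, int mismatch, int gap_open, int gap_extend) {
  std::vector<uint8_t> q = encode_seq(query), s = encode_seq(subject);
  const int m = (int)q.size(), n = (int)s.size();
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Ecur(n + 1, NEG_INF);
  std::vector<int> F(n + 1, NEG_INF);
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0; Ecur[0] = NEG_INF;
    for (int j = 1; j <= n; ++j) {
      uint8_t flags = 0;
      int e_open = Hcur[j - 1] - gap_open - gap_extend;
      int e_ext = Ecur[j - 1] - gap_extend;
      int e = e_open >= e_ext ? e_open : e_ext;
      if (e_open >= e_ext) flags |= 4;
      int f_open = Hprev[j] - gap_open - gap_extend;
      int f_ext = F[j] - gap_extend;
      int f = f_open >= f_ext ? f_open : f_ext;
      if (f_open >= f_ext) flags |= 8;
      int sc = (q[i - 1] < 4 && q[i - 1] == s[j - 1]) ? match : mismatch;
      int diag = Hprev[j - 1] + sc;
      int h = 0; uint8_t src = 0;
      if (diag > h) { h = diag; src = 1; }
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      Hcur[j] = h; Ecur[j] = e; F[j] = f;
      tb[(size_t)i * (n + 1) + j] = (uint8_t)(flags | src);
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }
  if (best <= 0) {
    return List::create(_["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0, _["matches"] = 0,
                        _["aln_length"] = 0, _["cigar"] = "");
  }
  std::vector<char> ops;
  int i = bi, j = bj, matches = 0;
  int state = 0;  // 0 = H, 2 = E, 3 = F
  while (i > 0 && j > 0) {
    uint8_t t = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      uint8_t src = t & 3;
      if (src == 0) break;
      if (src == 1) {
        ops.push_back('M');
        if (q[i - 1] < 4 && q[i - 1] == s[j - 1]) ++matches;
        --i; --j;
      } else if (src == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      ops.push_back('D');
      if (t & 4) state = 0;
      --j;
    } else {
      ops.push_back('I');
      if (t & 8) state = 0;
      --i;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best, _["q_start"] = i, _["q_end"] = bi,
                      _["s_start"] = j, _["s_end"] = bj,
                      _["matches"] = matches, _["aln_length"] = (int)ops.size(),
                      _["cigar"] = build_cigar(ops));
}

struct Cluster {
  int dmin, dmax, smin, smax, qmin, qmax;
};

// Word-seeded, banded, gapped local alignment. Seeds are exact word_size
// matches; seeds close in diagonal and subject position form a cluster; an
// ungapped X-drop extension widens the window along the query, then a banded
// affine DP around the cluster's diagonal range reports the best local
// alignment in the band.
// [[Rcpp::export(name = ".seed_extend_cpp")]]
DataFrame seed_extend_cpp(std::string query, std::string subject,
                          int match, int mismatch, int gap_open, int gap_extend,
                          int word_size, int x_drop, int band,
                          int min_raw_score, int pad, int cluster_gap) {
  std::vector<uint8_t> q = encode_seq(query), s = encode_seq(subject);
  const int m = (int)q.size(), n = (int)s.size();
  std::vector<Aln> out;
  if (m >= word_size && n >= word_size) {
    // hash query words (2 bits/base)
    std::unordered_map<uint64_t, std::vector<int>> index;
    uint64_t w = 0;
    uint64_t mask = (word_size >= 32) ? ~0ULL : ((1ULL << (2 * word_size)) - 1);
    int run = 0;
    for (int i = 0; i < m; ++i) {
      if (q[i] > 3) { run = 0; w = 0; continue; }
      w = ((w << 2) | q[i]) & mask;
      if (++run >= word_size) index[w].push_back(i - word_size + 1);
    }
    std::vector<std::pair<int, int>> seeds;  // (diag, s_pos); q_pos = s_pos - diag
    w = 0; run = 0;
    for (int j = 0; j < n; ++j) {
      if (s[j] > 3) { run = 0; w = 0; continue; }
      w = ((w << 2) | s[j]) & mask;
      if (++run >= word_size) {
        auto it = index.find(w);
        if (it != index.end()) {
          int sp = j - word_size + 1;
          for (int qp : it->second) seeds.push_back(std::make_pair(sp - qp, sp));
        }
      }
    }
    std::sort(seeds.begin(), seeds.end());
    std::vector<Cluster> clusters;
    for (auto& sd : seeds) {
      int d = sd.first, sp = sd.second, qp = sp - d;
      bool joined = false;
      if (!clusters.empty()) {
        Cluster& c = clusters.back();
        if (d - c.dmax <= band && d - c.dmin <= 2 * band &&
            sp >= c.smin - cluster_gap && sp <= c.smax + cluster_gap) {
          if (d > c.dmax) c.dmax = d;
          if (sp < c.smin) c.smin = sp;
          if (sp > c.smax) c.smax = sp;
          if (qp < c.qmin) c.qmin = qp;
          if (qp > c.qmax) c.qmax = qp;
          joined = true;
        }
      }
      if (!joined) clusters.push_back(Cluster{d, d, sp, sp, qp, qp});
    }
    for (auto& c : clusters) {
      // ungapped X-drop extension along the central diagonal to widen the
      // query window beyond the outermost seeds
      int d0 = (c.dmin + c.dmax) / 2;
      int qa = c.qmin, qb = std::min(m, c.qmax + word_size);
      {
        int i = c.qmin, j = c.qmin + d0;
        int sc = 0, bestu = 0, bi = qb;
        for (int k = 0; i + k < m && j + k < n && j + k >= 0; ++k) {
          sc += (q[i + k] < 4 && q[i + k] == s[j + k]) ? match : mismatch;
          if (sc > bestu) { bestu = sc; bi = i + k + 1; }
          if (bestu - sc > x_drop) break;
        }
        if (bi > qb) qb = bi;
        sc = 0; bestu = 0;
        int li = qa;
        for (int k = 1; i - k >= 0 && j - k >= 0; ++k) {
          sc += (q[i - k] < 4 && q[i - k] == s[j - k]) ? match : mismatch;
          if (sc > bestu) { bestu = sc; li = i - k; }
          if (bestu - sc > x_drop) break;
        }
        if (li < qa) qa = li;
      }
      int i0 = std::max(0, qa - pad);
      int i1 = std::min(m, qb + pad);
      int dlo = c.dmin - band, dhi = c.dmax + band;
      int W = dhi - dlo + 1;
      int nrow = i1 - i0;
      if (nrow <= 0 || W <= 0) continue;
      // banded DP: cell (r, k) has consumed I = i0 + r + 1 query bases and
      // J = I + dlo + k subject bases, i.e. it scores query base i0+r against
      // subject base js = i0 + r + dlo + k
      std::vector<int> Hp(W, 0), Hc(W, 0), Ep(W, NEG_INF), Ec(W, NEG_INF);
      std::vector<int> Fp(W, NEG_INF), Fc(W, NEG_INF);
      std::vector<uint8_t> tb((size_t)nrow * W, 0);
      int best = 0, br = -1, bk = -1;
      for (int r = 0; r < nrow; ++r) {
        int qi = i0 + r;
        for (int k = 0; k < W; ++k) {
          int js = qi + dlo + k;
          if (js < 0 || js >= n) {
            Hc[k] = 0; Ec[k] = NEG_INF; Fc[k] = NEG_INF;
            tb[(size_t)r * W + k] = 0;
            continue;
          }
          uint8_t flags = 0;
          int e = NEG_INF;
          if (k >= 1) {
            int e_open = Hc[k - 1] - gap_open - gap_extend;
            int e_ext = Ec[k - 1] - gap_extend;
            e = e_open >= e_ext ? e_open : e_ext;
            if (e_open >= e_ext) flags |= 4;
          }
          int f = NEG_INF;
          if (k + 1 < W) {
            int hup = (r > 0) ? Hp[k + 1] : 0;
            int fup = (r > 0) ? Fp[k + 1] : NEG_INF;
            int f_open = hup - gap_open - gap_extend;
            int f_ext = fup - gap_extend;
            f = f_open >= f_ext ? f_open : f_ext;
            if (f_open >= f_ext) flags |= 8;
          }
          int hd = (r > 0) ? Hp[k] : 0;  // diagonal predecessor (r-1, k)
          int sc = (q[qi] < 4 && q[qi] == s[js]) ? match : mismatch;
          int diag = hd + sc;
          int h = 0; uint8_t src = 0;
          if (diag > h) { h = diag; src = 1; }
          if (e > h) { h = e; src = 2; }
          if (f > h) { h = f; src = 3; }
          Hc[k] = h; Ec[k] = e; Fc[k] = f;
          tb[(size_t)r * W + k] = (uint8_t)(flags | src);
          if (h > best) { best = h; br = r; bk = k; }
        }
        std::swap(Hp, Hc); std::swap(Ep, Ec); std::swap(Fp, Fc);
      }
      if (best < min_raw_score || br < 0) continue;
      // traceback
      std::vector<char> ops;
      int ci = i0 + br + 1;                 // query bases consumed
      int cj = i0 + br + dlo + bk + 1;      // subject bases consumed
      int r = br, k = bk, state = 0, matches = 0;
      while (r >= 0) {
        uint8_t t = tb[(size_t)r * W + k];
        if (state == 0) {
          uint8_t src = t & 3;
          if (src == 0) break;
          if (src == 1) {
            ops.push_back('M');
            if (q[ci - 1] < 4 && q[ci - 1] == s[cj - 1]) ++matches;
            --ci; --cj; --r;  // k unchanged on diagonal move
          } else if (src == 2) state = 2;
          else state = 3;
        } else if (state == 2) {
          ops.push_back('D');
          if (t & 4) state = 0;
          --cj; --k;
          if (k < 0) break;
        } else {
          ops.push_back('I');
          if (t & 8) state = 0;
          --ci; --r; ++k;
          if (k >= W) break;
        }
      }
      std::reverse(ops.begin(), ops.end());
      Aln a;
      a.score = best;
      a.q_start = ci; a.q_end = i0 + br + 1;
      a.s_start = cj; a.s_end = i0 + br + dlo + bk + 1;
      a.matches = matches; a.aln_length = (int)ops.size();
      a.cigar = build_cigar(ops);
      out.push_back(a);
    }
  }
  // drop exact duplicates (overlapping clusters can converge on one alignment)
  std::vector<Aln> uniq;
  for (auto& a : out) {
    bool dup = false;
    for (auto& u : uniq) {
      if (u.q_start == a.q_start && u.q_end == a.q_end &&
          u.s_start == a.s_start && u.s_end == a.s_end) { dup = true; break; }
    }
    if (!dup) uniq.push_back(a);
  }
  int N = (int)uniq.size();
  IntegerVector score(N), qs(N), qe(N), ss(N), se(N), mt(N), al(N);
  CharacterVector cg(N);
  for (int i = 0; i < N; ++i) {
    score[i] = uniq[i].score; qs[i] = uniq[i].q_start; qe[i] = uniq[i].q_end;
    ss[i] = uniq[i].s_start; se[i] = uniq[i].s_end; mt[i] = uniq[i].matches;
    al[i] = uniq[i].aln_length; cg[i] = uniq[i].cigar;
  }
  return DataFrame::create(_["raw_score"] = score, _["q_start"] = qs,
                           _["q_end"] = qe, _["s_start"] = ss, _["s_end"] = se,
                           _["matches"] = mt, _["aligned_length"] = al,
                           _["cigar"] = cg, _["stringsAsFactors"] = false);
}
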