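// Core sequence kernels: affine-gap local alignment (band-indexed DP with
// traceback) and k-mer seed machinery used for anchoring and homology search.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <limits>
using namespace Rcpp;

static inline int b2i(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char rcbase(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = rcbase(s[i]);
  return r;
}

typedef std::unordered_map<uint64_t, std::vector<int>> KmerMap;

// index k-mer start positions (1-based) of t; lists longer than max_occ + 1
// are flagged by overflow and skipped at query time
static void build_index(const std::string& t, int k, int max_occ, KmerMap& idx) {
  idx.clear();
  if ((int)t.size() < k) return;
  uint64_t key = 0;
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (size_t i = 0; i < t.size(); ++i) {
    int v = b2i(t[i]);
    if (v < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)v) & mask;
    if (++run >= k) {
      std::vector<int>& vec = idx[key];
      if ((int)vec.size() <= max_occ) vec.push_back((int)i - k + 2);
    }
  }
}

// shared k-mers between q and t as (qpos, tpos) pairs, 1-based starts.
// [[Rcpp::export]]
IntegerMatrix cpp_seed_hits(std::string q, std::string t, int k = 14,
                            int max_occ = 50, int max_hits = 500000) {
  KmerMap idx;
  build_index(t, k, max_occ, idx);
  std::vector<int> qp, tp;
  if ((int)q.size() >= k) {
    uint64_t key = 0;
    uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int run = 0;
    for (size_t i = 0; i < q.size(); ++i) {
      int v = b2i(q[i]);
      if (v < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)v) & mask;
      if (++run >= k) {
        KmerMap::const_iterator it = idx.find(key);
        if (it != idx.end() && (int)it->second.size() <= max_occ) {
          for (size_t h = 0; h < it->second.size(); ++h) {
            if ((int)qp.size() >= max_hits) goto done;
            qp.push_back((int)i - k + 2);
            tp.push_back(it->second[h]);
          }
        }
      }
    }
  }
done:
  IntegerMatrix out(qp.size(), 2);
  for (size_t i = 0; i < qp.size(); ++i) { out(i, 0) = qp[i]; out(i, 1) = tp[i]; }
  colnames(out) = CharacterVector::create("qpos", "tpos");
  return out;
}

// Seed-vote anchoring of many query fragments against one target sequence.
// For each fragment and strand, k-mer hits vote on 'bin'-sized diagonal bins;
// the densest bin (plus neighbours) defines a candidate target interval.
// Returns one row per fragment: strand (1 fwd / -1 rev / 0 none), votes on the
// best strand, votes on the other, target lo/hi and query lo/hi of the voting
// seeds.
// [[Rcpp::export]]
IntegerMatrix cpp_anchor_candidates(CharacterVector frags, std::string target,
                                    int k = 14, int max_occ = 50, int bin = 1000) {
  KmerMap idx;
  build_index(target, k, max_occ, idx);
  int n = frags.size();
  IntegerMatrix out(n, 7);
  colnames(out) = CharacterVector::create("strand", "votes", "votes_other",
                                          "tlo", "thi", "qlo", "qhi");
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int f = 0; f < n; ++f) {
    std::string fw = as<std::string>(frags[f]);
    int best_strand = 0, best_votes = 0, other_votes = 0;
    int btlo = 0, bthi = 0, bqlo = 0, bqhi = 0;
    for (int s = 0; s < 2; ++s) {
      std::string q = (s == 0) ? fw : revcomp(fw);
      std::vector<int> qp, tp;
      if ((int)q.size() >= k) {
        uint64_t key = 0; int run = 0;
        for (size_t i = 0; i < q.size(); ++i) {
          int v = b2i(q[i]);
          if (v < 0) { run = 0; key = 0; continue; }
          key = ((key << 2) | (uint64_t)v) & mask;
          if (++run >= k) {
            KmerMap::const_iterator it = idx.find(key);
            if (it != idx.end() && (int)it->second.size() <= max_occ) {
              for (size_t h = 0; h < it->second.size(); ++h) {
                qp.push_back((int)i - k + 2);
                tp.push_back(it->second[h]);
              }
            }
          }
        }
      }
      if (qp.empty()) continue;
      std::unordered_map<int, int> binvotes;
      for (size_t i = 0; i < qp.size(); ++i) {
        int d = tp[i] - qp[i];
        int b = (int)std::floor((double)d / bin);
        binvotes[b]++;
      }
      int bb = 0, bv = -1;
      for (std::unordered_map<int, int>::iterator it = binvotes.begin();
           it != binvotes.end(); ++it) {
        int v = it->second;
        std::unordered_map<int, int>::iterator n1 = binvotes.find(it->first - 1);
        std::unordered_map<int, int>::iterator n2 = binvotes.find(it->first + 1);
        if (n1 != binvotes.end()) v += n1->second;
        if (n2 != binvotes.end()) v += n2->second;
        if (v > bv) { bv = v; bb = it->first; }
      }
      int tlo = std::numeric_limits<int>::max(), thi = 0;
      int qlo = std::numeric_limits<int>::max(), qhi = 0;
      for (size_t i = 0; i < qp.size(); ++i) {
        int b = (int)std::floor((double)(tp[i] - qp[i]) / bin);
        if (b >= bb - 1 && b <= bb + 1) {
          if (tp[i] < tlo) tlo = tp[i];
          if (tp[i] > thi) thi = tp[i];
          if (qp[i] < qlo) qlo = qp[i];
          if (qp[i] > qhi) qhi = qp[i];
        }
      }
      if (bv > best_votes) {
        other_votes = best_votes;
        best_votes = bv; best_strand = (s == 0) ? 1 : -1;
        btlo = tlo; bthi = thi; bqlo = qlo; bqhi = qhi;
      } else if (bv > other_votes) {
        other_votes = bv;
      }
    }
    out(f, 0) = best_strand; out(f, 1) = best_votes; out(f, 2) = other_votes;
    out(f, 3) = btlo; out(f, 4) = bthi; out(f, 5) = bqlo; out(f, 6) = bqhi;
  }
  return out;
}

// Affine-gap local alignment (Smith-Waterman) restricted to diagonals
// dlo <= j - i <= dhi (pass dlo = -(nchar(a)), dhi = nchar(b) for the full
// matrix). A gap of length L costs gap_open + gap_ext * L. Characters outside
// {A,C,G,T} (case-insensitive) score as mismatch against everything,
// including themselves. Returns the optimal in-band score, 1-based inclusive
// coordinates of the aligned subsequences and the two gapped rows.
// [[Rcpp::export]]
List cpp_sw_affine(std::string a, std::string b, double match = 5.0,
                   double mismatch = -4.0, double gap_open = 30.0,
                   double gap_ext = 0.1, int dlo = NA_INTEGER,
                   int dhi = NA_INTEGER) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = -1,
                        _["b_start"] = 0, _["b_end"] = -1,
                        _["a_row"] = "", _["b_row"] = "");
  if (dlo == NA_INTEGER) dlo = -n;
  if (dhi == NA_INTEGER) dhi = m;
  if (dlo > dhi) stop("dlo > dhi");
  if (dlo < -n) dlo = -n;
  if (dhi > m) dhi = m;
  const int W = dhi - dlo + 1;
  const double NEG = -std::numeric_limits<double>::infinity();

  // rolling rows for H, E, F; full byte traceback
  std::vector<double> Hprev(W, 0.0), Hcur(W, 0.0);
  std::vector<double> Eprev(W, NEG), Ecur(W, NEG);
  std::vector<double> Fprev(W, NEG), Fcur(W, NEG);
  std::vector<uint8_t> tb((size_t)(n + 1) * W, 0);

  double best = 0.0; int bi = 0, bw = 0;
  for (int i = 1; i <= n; ++i) {
    for (int w = 0; w < W; ++w) { Hcur[w] = 0.0; Ecur[w] = NEG; Fcur[w] = NEG; }
    int va = b2i(a[i - 1]);
    for (int w = 0; w < W; ++w) {
      int j = i + dlo + w;
      if (j < 1 || j > m) continue;
      // E: gap in a (move left, consume b)
      double e = NEG; uint8_t eb = 0;
      if (w - 1 >= 0 && (i + dlo + w - 1) >= 1) {
        double open_e = Hcur[w - 1] - gap_open - gap_ext;
        double ext_e = (Ecur[w - 1] == NEG) ? NEG : Ecur[w - 1] - gap_ext;
        if (ext_e > open_e) { e = ext_e; eb = 4; } else { e = open_e; }
      }
      // F: gap in b (move up, consume a)
      double fv = NEG; uint8_t fb = 0;
      if (w + 1 < W && (i - 1 + dlo + w + 1) <= m) {
        double open_f = Hprev[w + 1] - gap_open - gap_ext;
        double ext_f = (Fprev[w + 1] == NEG) ? NEG : Fprev[w + 1] - gap_ext;
        if (ext_f > open_f) { fv = ext_f; fb = 8; } else { fv = open_f; }
      }
      int vb = b2i(b[j - 1]);
      double s = (va >= 0 && va == vb) ? match : mismatch;
      double diag = ((j - 1 >= 1 || j == 1) ? Hprev[w] : 0.0) + s;
      if (i == 1 || j == 1) diag = s;  // Hprev holds row i-1; boundary H = 0
      double h = 0.0; uint8_t hb = 0;
      if (diag > h) { h = diag; hb = 1; }
      if (e > h) { h = e; hb = 2; }
      if (fv > h) { h = fv; hb = 3; }
      Hcur[w] = h; Ecur[w] = e; Fcur[w] = fv;
      tb[(size_t)i * W + w] = (uint8_t)(hb | eb | fb);
      if (h > best) { best = h; bi = i; bw = w; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }

  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = -1,
                        _["b_start"] = 0, _["b_end"] = -1,
                        _["a_row"] = "", _["b_row"] = "");

  // traceback
  std::string ra, rb;
  int i = bi, w = bw;
  int a_end = bi, b_end = bi + dlo + bw;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0) {
    uint8_t code = tb[(size_t)i * W + w];
    int j = i + dlo + w;
    if (state == 0) {
      uint8_t hb = code & 3;
      if (hb == 0) break;
      if (hb == 1) { ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); i -= 1; }
      else if (hb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      bool ext = (code & 4) != 0;
      w -= 1;
      if (!ext) state = 0;
    } else {
      ra.push_back(a[i - 1]); rb.push_back('-');
      bool ext = (code & 8) != 0;
      i -= 1; w += 1;
      if (!ext) state = 0;
    }
  }
  int a_start = i + 1, b_start = i + dlo + w + 1;
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = best, _["a_start"] = a_start,
                      _["a_end"] = a_end, _["b_start"] = b_start,
                      _["b_end"] = b_end, _["a_row"] = ra, _["b_row"] = rb);
}
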