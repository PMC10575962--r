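#include <Rcpp.h>
#include <vector>
#include <map>
#include <string>
using namespace Rcpp;

static const int NEG = -1000000000;

// Banded glocal affine-gap alignment: global in the query (with terminal
// soft-clips allowed only at reference ends), local in the reference.
// Gap of length k costs gap_open + k * gap_extend. States: M diag, X gap in
// query (consumes reference, i.e. deletion), Y gap in reference (insertion).
// The band restricts cells to |j - i - d0| <= band (reference column j,
// query row i, expected start offset d0). band >= n disables banding.
struct AlnRes {
  int score = NA_INTEGER;
  int start = 0;
  std::string cigar;
  bool hit_edge = false;
  bool aligned = false;
};

static AlnRes align_one(const std::string &query, const std::string &ref,
                        int d0, int band, int match, int mismatch,
                        int gap_open, int gap_extend) {
  AlnRes out;
  int m = query.size(), n = ref.size();
  if (m == 0) stop("empty query");
  bool banded = band < n;
  size_t sz = (size_t)(m + 1) * (n + 1);
  std::vector<int> M(sz, NEG), X(sz, NEG), Y(sz, NEG);
  std::vector<signed char> tM(sz, -1), tX(sz, -1), tY(sz, -1);
  auto ix = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  for (int j = 0; j <= n; ++j) M[ix(0, j)] = 0;   // free leading reference
  for (int i = 0; i <= m; ++i) M[ix(i, 0)] = 0;   // prefix clip at ref start

  for (int i = 1; i <= m; ++i) {
    int lo = 1, hi = n;
    if (banded) {
      lo = std::max(1, i + d0 - band);
      hi = std::min(n, i + d0 + band);
      if (lo > hi) continue;
    }
    for (int j = lo; j <= hi; ++j) {
      size_t c = ix(i, j), d = ix(i - 1, j - 1), u = ix(i - 1, j),
             l = ix(i, j - 1);
      int s = (query[i - 1] == ref[j - 1]) ? match : mismatch;
      // M
      int best = M[d]; signed char tb = 0;
      if (X[d] > best) { best = X[d]; tb = 1; }
      if (Y[d] > best) { best = Y[d]; tb = 2; }
      if (best > NEG / 2) { M[c] = best + s; tM[c] = tb; }
      // X: gap in query (delete ref base j)
      int xo = (M[l] > NEG / 2) ? M[l] + gap_open + gap_extend : NEG;
      int xe = (X[l] > NEG / 2) ? X[l] + gap_extend : NEG;
      if (xo >= xe) { if (xo > NEG / 2) { X[c] = xo; tX[c] = 0; } }
      else { X[c] = xe; tX[c] = 1; }
      // Y: gap in ref (insert query base i)
      int yo = (M[u] > NEG / 2) ? M[u] + gap_open + gap_extend : NEG;
      int ye = (Y[u] > NEG / 2) ? Y[u] + gap_extend : NEG;
      if (yo >= ye) { if (yo > NEG / 2) { Y[c] = yo; tY[c] = 0; } }
      else { Y[c] = ye; tY[c] = 1; }
    }
  }

  // terminal: free trailing reference (row m) or suffix clip at ref end
  int best = NEG, bi = m, bj = 0;
  for (int j = 0; j <= n; ++j)
    if (M[ix(m, j)] > best) { best = M[ix(m, j)]; bi = m; bj = j; }
  for (int i = 0; i <= m; ++i)
    if (M[ix(i, n)] > best) { best = M[ix(i, n)]; bi = i; bj = n; }
  if (best <= NEG / 2) return out;

  // traceback
  std::vector<char> ops;              // reversed column ops
  bool hit_edge = false;
  int i = bi, j = bj, state = 0;
  if (bi < m) for (int k = 0; k < m - bi; ++k) ops.push_back('S');
  while (true) {
    if (banded && i >= 1 && (j == i + d0 - band || j == i + d0 + band))
      hit_edge = true;
    if (state == 0) {
      if (i == 0) break;                       // started at ref offset j
      if (j == 0) {                            // prefix clip of i bases
        for (int k = 0; k < i; ++k) ops.push_back('S');
        i = 0; break;
      }
      signed char tb = tM[ix(i, j)];
      ops.push_back(query[i - 1] == ref[j - 1] ? '=' : 'X');
      --i; --j; state = tb;
    } else if (state == 1) {
      ops.push_back('D');
      signed char tb = tX[ix(i, j)];
      --j; state = (tb == 0) ? 0 : 1;
    } else {
      ops.push_back('I');
      signed char tb = tY[ix(i, j)];
      --i; state = (tb == 0) ? 0 : 2;
    }
  }
  int start = j;                               // 0-based ref offset
  std::reverse(ops.begin(), ops.end());

  // left-align indel runs: bubble each I/D run leftward past a diagonal
  // column while the exchanged bases are identical (score-preserving).
  bool changed = true;
  while (changed) {
    changed = false;
    // recompute query/ref positions per column
    int nc = ops.size();
    std::vector<int> qp(nc), rp(nc);
    int q = 0, r = start;
    for (int k = 0; k < nc; ++k) {
      qp[k] = q; rp[k] = r;
      if (ops[k] == '=' || ops[k] == 'X') { ++q; ++r; }
      else if (ops[k] == 'I' || ops[k] == 'S') { ++q; }
      else if (ops[k] == 'D') { ++r; }
    }
    for (int k = 1; k < nc; ++k) {
      if ((ops[k] == 'I' || ops[k] == 'D') &&
          (ops[k - 1] == '=' || ops[k - 1] == 'X')) {
        // find run end
        int e = k; while (e < nc && ops[e] == ops[k]) ++e;
        bool ok;
        if (ops[k] == 'D') ok = (ref[rp[e - 1]] == ref[rp[k - 1]]);
        else ok = (query[qp[e - 1]] == query[qp[k - 1]]);
        if (ok) {
          char diag = ops[k - 1];
          for (int t = k; t < e; ++t) ops[t - 1] = ops[t];
          ops[e - 1] = diag;
          changed = true;
          break;  // recompute positions
        }
      }
    }
  }

  // run-length encode
  std::string cigar;
  int nc = ops.size();
  for (int k = 0; k < nc;) {
    int e = k; while (e < nc && ops[e] == ops[k]) ++e;
    cigar += std::to_string(e - k); cigar += ops[k];
    k = e;
  }
  out.score = best; out.start = start; out.cigar = cigar;
  out.hit_edge = hit_edge; out.aligned = true;
  return out;
}

// [[Rcpp::export]]
List cpp_align(std::string query, std::string ref, int d0, int band,
               int match, int mismatch, int gap_open, int gap_extend) {
  AlnRes r = align_one(query, ref, d0, band, match, mismatch, gap_open,
                       gap_extend);
  if (!r.aligned)
    return List::create(_["score"] = NA_INTEGER, _["aligned"] = false);
  return List::create(_["score"] = r.score, _["start"] = r.start,
                      _["cigar"] = r.cigar, _["hit_edge"] = r.hit_edge,
                      _["aligned"] = true);
}

// Batch aligner with a gapless fast path: when the query differs from the
// reference window at its expected offset by at most fast_max_mm
// substitutions, that overlay is already optimal under this scoring (one
// substitution costs match - mismatch = 5, the cheapest gap pairing more),
// so the DP is skipped. Otherwise the banded DP runs, doubling the band
// while the optimal path touches its edge.
// [[Rcpp::export]]
List cpp_align_batch(CharacterVector queries, std::string ref,
                     IntegerVector d0s, int band, int match, int mismatch,
                     int gap_open, int gap_extend, int fast_max_mm) {
  int nq = queries.size(), n = ref.size();
  IntegerVector score(nq), start(nq);
  CharacterVector cigar(nq);
  for (int r = 0; r < nq; ++r) {
    std::string q = as<std::string>(queries[r]);
    int m = q.size(), d0 = d0s[r];
    bool done = false;
    if (d0 >= 0 && d0 + m <= n) {
      std::vector<int> mm;
      for (int t = 0; t < m && (int)mm.size() <= fast_max_mm; ++t)
        if (q[t] != ref[d0 + t]) mm.push_back(t);
      if ((int)mm.size() <= fast_max_mm) {
        std::string cg;
        int prev = 0;
        for (int t = 0; t <= (int)mm.size(); ++t) {
          int upto = (t < (int)mm.size()) ? mm[t] : m;
          if (upto > prev) { cg += std::to_string(upto - prev); cg += '='; }
          if (t < (int)mm.size()) { cg += "1X"; prev = upto + 1; }
          else prev = upto;
        }
        score[r] = (m - mm.size()) * match + mm.size() * mismatch;
        start[r] = d0;
        cigar[r] = cg;
        done = true;
      }
    }
    if (!done) {
      int b = band;
      AlnRes a;
      while (true) {
        a = align_one(q, ref, d0, b, match, mismatch, gap_open, gap_extend);
        if (!a.hit_edge || b >= n) break;
        b = std::min(2 * b, n);
      }
      score[r] = a.aligned ? a.score : NA_INTEGER;
      start[r] = a.aligned ? a.start : NA_INTEGER;
      cigar[r] = a.cigar;
    }
  }
  return List::create(_["score"] = score, _["start"] = start,
                      _["cigar"] = cigar);
}

// Sliding-window quality trimmer. Truncates at the first window whose mean
// Phred falls below min_mean_q, then extends over immediately following
// bases that individually pass. Returns kept length per read.
// [[Rcpp::export]]
IntegerVector cpp_window_trim(CharacterVector quals, int window,
                              double min_mean_q, int phred_offset) {
  int nr = quals.size();
  IntegerVector keep(nr);
  for (int r = 0; r < nr; ++r) {
    std::string q = as<std::string>(quals[r]);
    int L = q.size(), k = L;
    if (L >= window) {
      double sum = 0;
      for (int t = 0; t < window; ++t) sum += q[t] - phred_offset;
      for (int s = 0; s + window <= L; ++s) {
        if (s > 0) sum += (q[s + window - 1] - phred_offset) -
                          (q[s - 1] - phred_offset);
        if (sum / window < min_mean_q) {
          k = s;
          while (k < L && (q[k] - phred_offset) >= min_mean_q) ++k;
          break;
        }
      }
    }
    keep[r] = k;
  }
  return keep;
}

// For each query, Hamming-compare the substring starting at `offset`
// (0-based) against every candidate (over the candidate's length); report
// best candidate, its distance, and the runner-up distance.
// [[Rcpp::export]]
List cpp_best_hamming(CharacterVector queries, CharacterVector candidates,
                      int offset) {
  int nq = queries.size(), nc = candidates.size();
  std::vector<std::string> cand(nc);
  for (int c = 0; c < nc; ++c) cand[c] = as<std::string>(candidates[c]);
  IntegerVector best_idx(nq), best_d(nq), second_d(nq);
  for (int r = 0; r < nq; ++r) {
    std::string q = as<std::string>(queries[r]);
    int b1 = 1000000, b2 = 1000000, bi = NA_INTEGER;
    for (int c = 0; c < nc; ++c) {
      int lc = cand[c].size(), d;
      if (offset + lc > (int)q.size()) d = 1000000;
      else {
        d = 0;
        for (int t = 0; t < lc; ++t) if (q[offset + t] != cand[c][t]) ++d;
      }
      if (d < b1) { b2 = b1; b1 = d; bi = c + 1; }
      else if (d < b2) b2 = d;
    }
    best_idx[r] = bi; best_d[r] = b1; second_d[r] = b2;
  }
  return List::create(_["best"] = best_idx, _["best_dist"] = best_d,
                      _["second_dist"] = second_d);
}

// Pileup accumulator. Bases count only when Phred strictly exceeds
// min_phred; deletions always count (no base quality exists for them);
// insertions count when every inserted base passes. Returns a 5 x L count
// matrix (A,C,G,T,del) plus insertion and deletion event tables keyed by
// 0-based reference offset (insertions sit before that offset).
// [[Rcpp::export]]
List cpp_pileup(IntegerVector starts, CharacterVector cigars,
                CharacterVector seqs, CharacterVector quals,
                int reflen, int min_phred, int phred_offset) {
  IntegerMatrix counts(5, reflen);
  std::map<std::pair<int, std::string>, int> ins;
  std::map<std::pair<int, int>, int> del;
  int nr = starts.size();
  for (int r = 0; r < nr; ++r) {
    if (starts[r] == NA_INTEGER) continue;
    std::string cig = as<std::string>(cigars[r]);
    std::string sq = as<std::string>(seqs[r]);
    std::string ql = as<std::string>(quals[r]);
    int qpos = 0, rpos = starts[r];
    size_t p = 0;
    while (p < cig.size()) {
      int len = 0;
      while (p < cig.size() && isdigit(cig[p])) len = len * 10 + (cig[p++] - '0');
      char op = cig[p++];
      if (op == '=' || op == 'X' || op == 'M') {
        for (int t = 0; t < len; ++t) {
          if (rpos >= 0 && rpos < reflen &&
              (ql[qpos] - phred_offset) > min_phred) {
            switch (sq[qpos]) {
              case 'A': counts(0, rpos)++; break;
              case 'C': counts(1, rpos)++; break;
              case 'G': counts(2, rpos)++; break;
              case 'T': counts(3, rpos)++; break;
              default: break;                 // N and friends: ignored
            }
          }
          ++qpos; ++rpos;
        }
      } else if (op == 'I') {
        bool pass = true;
        for (int t = 0; t < len; ++t)
          if ((ql[qpos + t] - phred_offset) <= min_phred) pass = false;
        if (pass && rpos > 0 && rpos <= reflen)
          ins[std::make_pair(rpos, sq.substr(qpos, len))]++;
        qpos += len;
      } else if (op == 'D') {
        if (rpos >= 0 && rpos + len <= reflen) {
          del[std::make_pair(rpos, len)]++;
          for (int t = 0; t < len; ++t) counts(4, rpos + t)++;
        }
        rpos += len;
      } else if (op == 'S') {
        qpos += len;
      } else stop("bad cigar op");
    }
  }
  int ni = ins.size(), nd = del.size(), k;
  IntegerVector ipos(ni), icnt(ni); CharacterVector iseq(ni);
  k = 0;
  for (auto &e : ins) { ipos[k] = e.first.first; iseq[k] = e.first.second;
                        icnt[k] = e.second; ++k; }
  IntegerVector dpos(nd), dlen(nd), dcnt(nd);
  k = 0;
  for (auto &e : del) { dpos[k] = e.first.first; dlen[k] = e.first.second;
                        dcnt[k] = e.second; ++k; }
  return List::create(
    _["counts"] = counts,
    _["insertions"] = DataFrame::create(_["pos"] = ipos, _["seq"] = iseq,
                                        _["count"] = icnt,
                                        _["stringsAsFactors"] = false),
    _["deletions"] = DataFrame::create(_["pos"] = dpos, _["len"] = dlen,
                                       _["count"] = dcnt));
}
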