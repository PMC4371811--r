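// Alignment and read-merging primitives.
//
// All scoring schemes are fixed and documented at the R level:
//  - global (end-to-end) alignment: match +1, mismatch -2, gap -2 per
//    column (linear), terminal gaps penalized; identity = matches /
//    alignment columns, columns = len(a) + len(b) - aligned_pairs.
//  - local alignment: match +1, mismatch -2, gap open -2 (first gapped
//    column), gap extend -1 (subsequent columns).
// Ties among equal-scoring global alignments resolve to the path with
// more matches, then more aligned pairs; local-alignment traceback ties
// resolve diagonal > up > left. Every statistic is deterministic.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

static const int NW_MATCH = 1;
static const int NW_MISMATCH = -2;
static const int NW_GAP = -2;
static const int NEG_INF = -1000000000;

struct NwStat {
  int score;
  int matches;
  int pairs; // aligned base pairs (match + mismatch columns)
};

static inline char upc(char c) {
  return (c >= 'a' && c <= 'z') ? c - 32 : c;
}

static std::string upper(const std::string& s) {
  std::string r(s);
  for (size_t i = 0; i < r.size(); ++i) r[i] = upc(r[i]);
  return r;
}

// Global alignment, linear gaps, tracking matches/pairs along one optimal
// path. The DP cell packs (biased score, matches, pairs) into one int64
// (score in the high bits), so a single max() both maximizes the score
// and, among equal-score paths, prefers more matches then more aligned
// pairs -- a deterministic tie-break. Two rolling rows, O(n*m) time.
static const long long NW_BIAS = 1LL << 22;
static const long long PK_SCORE = 1LL << 40;
static const long long PK_MATCH = 1LL << 20;
static std::vector<long long> nwPrev, nwCur; // reused across calls

static NwStat nw_stats(const std::string& a, const std::string& b) {
  const int n = (int)a.size(), m = (int)b.size();
  if ((int)nwPrev.size() < m + 1) {
    nwPrev.resize(m + 1);
    nwCur.resize(m + 1);
  }
  const long long GAP = (long long)NW_GAP * PK_SCORE;
  const long long DIAG_EQ = (long long)NW_MATCH * PK_SCORE + PK_MATCH + 1;
  const long long DIAG_NE = (long long)NW_MISMATCH * PK_SCORE + 1;
  nwPrev[0] = NW_BIAS * PK_SCORE;
  for (int j = 1; j <= m; ++j) nwPrev[j] = nwPrev[j - 1] + GAP;
  for (int i = 1; i <= n; ++i) {
    nwCur[0] = nwPrev[0] + GAP;
    const char ai = a[i - 1];
    long long diag = nwPrev[0];
    for (int j = 1; j <= m; ++j) {
      long long v = diag + ((ai == b[j - 1]) ? DIAG_EQ : DIAG_NE);
      const long long up = nwPrev[j] + GAP;
      const long long left = nwCur[j - 1] + GAP;
      if (up > v) v = up;
      if (left > v) v = left;
      diag = nwPrev[j];
      nwCur[j] = v;
    }
    std::swap(nwPrev, nwCur);
  }
  const long long v = nwPrev[m];
  NwStat st;
  st.score = (int)((v >> 40) - NW_BIAS);
  st.matches = (int)((v >> 20) & 0xFFFFF);
  st.pairs = (int)(v & 0xFFFFF);
  return st;
}

static inline double nw_identity_of(const NwStat& st, int la, int lb) {
  const int columns = la + lb - st.pairs;
  if (columns <= 0) return 1.0;
  return (double)st.matches / (double)columns;
}

// [[Rcpp::export]]
List cpp_nw_stats(std::string a, std::string b) {
  a = upper(a);
  b = upper(b);
  NwStat st = nw_stats(a, b);
  const int columns = (int)a.size() + (int)b.size() - st.pairs;
  return List::create(_["score"] = st.score, _["matches"] = st.matches,
                      _["pairs"] = st.pairs, _["columns"] = columns,
                      _["identity"] = nw_identity_of(st, a.size(), b.size()));
}

// All-pairs p-distance (1 - global identity, gaps counted as differences).
// [[Rcpp::export]]
NumericMatrix cpp_pdist(CharacterVector seqs) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = upper(as<std::string>(seqs[i]));
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      NwStat st = nw_stats(s[i], s[j]);
      const double p = 1.0 - nw_identity_of(st, s[i].size(), s[j].size());
      d(i, j) = p;
      d(j, i) = p;
    }
  }
  return d;
}

// ---------------------------------------------------------------------------
// k-mer machinery (k <= 15, 2 bits per base; k-mers containing non-ACGT are
// skipped). Used only as a conservative pre-filter / candidate selector.

static inline int base2code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

static void collect_kmers(const std::string& s, int k,
                          std::vector<uint32_t>& out) {
  out.clear();
  const int n = (int)s.size();
  if (n < k) return;
  const uint32_t mask = (k >= 16) ? 0xffffffffu : ((1u << (2 * k)) - 1u);
  uint32_t code = 0;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    const int b = base2code(s[i]);
    if (b < 0) {
      run = 0;
      code = 0;
      continue;
    }
    code = ((code << 2) | (uint32_t)b) & mask;
    if (++run >= k) out.push_back(code);
  }
}

// 8-mer presence bitset (65536 bits) for fast containment tests.
struct KmerSet8 {
  std::vector<uint64_t> bits;
  KmerSet8() : bits(1024, 0) {}
  void add(uint32_t km) { bits[km >> 6] |= (uint64_t)1 << (km & 63); }
  bool has(uint32_t km) const {
    return (bits[km >> 6] >> (km & 63)) & 1;
  }
};

// Count of query 8-mer positions present in the set.
static int kmer_hits(const std::vector<uint32_t>& qk, const KmerSet8& ks) {
  int c = 0;
  for (size_t i = 0; i < qk.size(); ++i)
    if (ks.has(qk[i])) ++c;
  return c;
}

// Conservative lower bound on shared query 8-mers if identity >= thr:
// each of the <= (1-thr)*(la+lb) edits can destroy at most k kmers.
static int kmer_bound(int nqk, int la, int lb, double thr, int k) {
  const double emax = (1.0 - thr) * (double)(la + lb);
  int b = nqk - (int)(k * emax) - 1;
  return b < 0 ? 0 : b;
}

// Greedy abundance-ordered centroid clustering: sequence i joins the first
// centroid with global identity >= threshold, else founds a new centroid.
// Input must already be sorted (abundance desc, ties lexicographic).
// Returns 1-based centroid ordinal per sequence.
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double threshold) {
  const int n = seqs.size();
  const int K = 8;
  IntegerVector assign(n);
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = upper(as<std::string>(seqs[i]));
  std::vector<int> centroidIdx;
  std::vector<KmerSet8> centroidKmers;
  std::vector<uint32_t> qk;
  for (int i = 0; i < n; ++i) {
    collect_kmers(s[i], K, qk);
    const int la = (int)s[i].size();
    int hit = 0;
    for (size_t c = 0; c < centroidIdx.size(); ++c) {
      const std::string& cen = s[centroidIdx[c]];
      const int lb = (int)cen.size();
      const int lo = std::min(la, lb), hi = std::max(la, lb);
      if ((double)lo / (double)hi < threshold) continue;
      if (kmer_hits(qk, centroidKmers[c]) <
          kmer_bound((int)qk.size(), la, lb, threshold, K))
        continue;
      NwStat st = nw_stats(s[i], cen);
      if (nw_identity_of(st, la, lb) >= threshold) {
        hit = (int)c + 1;
        break;
      }
    }
    if (hit == 0) {
      centroidIdx.push_back(i);
      KmerSet8 ks;
      for (size_t j = 0; j < qk.size(); ++j) ks.add(qk[j]);
      centroidKmers.push_back(ks);
      hit = (int)centroidIdx.size();
    }
    assign[i] = hit;
  }
  return assign;
}

// Map sequences onto fixed centroids: best global identity >= threshold,
// ties broken toward the lowest centroid index (most abundant first).
// [[Rcpp::export]]
List cpp_assign_centroids(CharacterVector seqs, CharacterVector centroids,
                          double threshold) {
  const int n = seqs.size(), nc = centroids.size();
  const int K = 8;
  std::vector<std::string> cen(nc);
  std::vector<KmerSet8> cks(nc);
  std::vector<uint32_t> tmp;
  for (int c = 0; c < nc; ++c) {
    cen[c] = upper(as<std::string>(centroids[c]));
    collect_kmers(cen[c], K, tmp);
    for (size_t j = 0; j < tmp.size(); ++j) cks[c].add(tmp[j]);
  }
  IntegerVector idx(n);
  NumericVector ident(n);
  std::vector<uint32_t> qk;
  for (int i = 0; i < n; ++i) {
    std::string q = upper(as<std::string>(seqs[i]));
    collect_kmers(q, K, qk);
    const int la = (int)q.size();
    int best = 0;
    double bestId = -1.0;
    for (int c = 0; c < nc; ++c) {
      const int lb = (int)cen[c].size();
      const int lo = std::min(la, lb), hi = std::max(la, lb);
      if ((double)lo / (double)hi < threshold) continue;
      if (kmer_hits(qk, cks[c]) <
          kmer_bound((int)qk.size(), la, lb, threshold, K))
        continue;
      NwStat st = nw_stats(q, cen[c]);
      const double id = nw_identity_of(st, la, lb);
      if (id >= threshold && id > bestId + 1e-12) {
        bestId = id;
        best = c + 1;
      }
    }
    idx[i] = best;
    ident[i] = best ? bestId : NA_REAL;
  }
  return List::create(_["index"] = idx, _["identity"] = ident);
}

// ---------------------------------------------------------------------------
// Paired-read merging: overlap scan maximizing matches (ties -> longer
// overlap), mismatch fraction capped, disagreeing bases take the
// higher-quality call (tie -> mate 1), overlap quality = max of the two.
// read2 must already be reverse-complemented (and its qualities reversed).
// status: 1 merged, 0 no admissible overlap, 2 merged product too short.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector s1, List q1, CharacterVector s2rc,
                     List q2rc, int minOverlap, double maxMismatchDensity,
                     int minMergedLen) {
  const int n = s1.size();
  IntegerVector status(n);
  CharacterVector outSeq(n);
  List outQual(n);
  IntegerVector outOverlap(n);
  for (int i = 0; i < n; ++i) {
    std::string a = upper(as<std::string>(s1[i]));
    std::string b = upper(as<std::string>(s2rc[i]));
    IntegerVector qa = q1[i], qb = q2rc[i];
    const int la = (int)a.size(), lb = (int)b.size();
    const int maxO = std::min(la, lb);
    int bestO = -1, bestMatches = -1;
    for (int o = minOverlap; o <= maxO; ++o) {
      int matches = 0;
      const int off = la - o;
      for (int j = 0; j < o; ++j)
        if (a[off + j] == b[j]) ++matches;
      const int mism = o - matches;
      if ((double)mism / (double)o > maxMismatchDensity) continue;
      if (matches >= bestMatches) { // >= : ties prefer the longer overlap
        bestMatches = matches;
        bestO = o;
      }
    }
    if (bestO < 0) {
      status[i] = 0;
      outSeq[i] = NA_STRING;
      outQual[i] = R_NilValue;
      outOverlap[i] = NA_INTEGER;
      continue;
    }
    const int o = bestO;
    const int mlen = la + lb - o;
    if (mlen < minMergedLen) {
      status[i] = 2;
      outSeq[i] = NA_STRING;
      outQual[i] = R_NilValue;
      outOverlap[i] = o;
      continue;
    }
    std::string m(mlen, 'N');
    IntegerVector qm(mlen);
    const int off = la - o;
    for (int j = 0; j < off; ++j) {
      m[j] = a[j];
      qm[j] = qa[j];
    }
    for (int j = 0; j < o; ++j) {
      const char c1 = a[off + j], c2 = b[j];
      const int v1 = qa[off + j], v2 = qb[j];
      if (c1 == c2) m[off + j] = c1;
      else m[off + j] = (v2 > v1) ? c2 : c1;
      qm[off + j] = std::max(v1, v2);
    }
    for (int j = o; j < lb; ++j) {
      m[off + j] = b[j];
      qm[off + j] = qb[j];
    }
    status[i] = 1;
    outSeq[i] = m;
    outQual[i] = qm;
    outOverlap[i] = o;
  }
  return List::create(_["status"] = status, _["sequence"] = outSeq,
                      _["quality"] = outQual, _["overlap"] = outOverlap);
}

// ---------------------------------------------------------------------------
// Local (Smith-Waterman) alignment with affine gaps, with traceback so the
// hit's identity and spans are available. Traceback tie-break diag > up >
// left; the reported cell is the first maximal cell in row-major order.

struct SwHit {
  int score;
  int matches;
  int columns;
  int qstart, qend; // 0-based half-open on query
  int rstart, rend;
};

static std::vector<int> swH, swE, swF; // reused across calls

static SwHit sw_align(const std::string& q, const std::string& r, int match,
                      int mismatch, int gapOpen, int gapExt) {
  const int n = (int)q.size(), m = (int)r.size();
  const size_t sz = (size_t)(n + 1) * (m + 1);
  if (swH.size() < sz) {
    swH.resize(sz);
    swE.resize(sz);
    swF.resize(sz);
  }
  const int W = m + 1;
#define IDX(i, j) ((size_t)(i) * W + (j))
  for (int j = 0; j <= m; ++j) {
    swH[IDX(0, j)] = 0;
    swE[IDX(0, j)] = NEG_INF;
    swF[IDX(0, j)] = NEG_INF;
  }
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    swH[IDX(i, 0)] = 0;
    swE[IDX(i, 0)] = NEG_INF;
    swF[IDX(i, 0)] = NEG_INF;
    const char qi = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int e = std::max(swH[IDX(i, j - 1)] + gapOpen,
                             swE[IDX(i, j - 1)] + gapExt);
      const int f = std::max(swH[IDX(i - 1, j)] + gapOpen,
                             swF[IDX(i - 1, j)] + gapExt);
      swE[IDX(i, j)] = e;
      swF[IDX(i, j)] = f;
      int h = swH[IDX(i - 1, j - 1)] +
              ((qi == r[j - 1]) ? match : mismatch);
      if (f > h) h = f;
      if (e > h) h = e;
      if (h < 0) h = 0;
      swH[IDX(i, j)] = h;
      if (h > best) {
        best = h;
        bi = i;
        bj = j;
      }
    }
  }
  SwHit hit;
  hit.score = best;
  hit.matches = 0;
  hit.columns = 0;
  hit.qend = bi;
  hit.rend = bj;
  // traceback
  int i = bi, j = bj;
  int state = 0; // 0 = H, 1 = E (gap in query axis), 2 = F
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (swH[IDX(i, j)] == 0) break;
      const int d = swH[IDX(i - 1, j - 1)] +
                    ((q[i - 1] == r[j - 1]) ? match : mismatch);
      if (swH[IDX(i, j)] == d) {
        if (q[i - 1] == r[j - 1]) ++hit.matches;
        ++hit.columns;
        --i;
        --j;
      } else if (swH[IDX(i, j)] == swF[IDX(i, j)]) {
        state = 2;
      } else {
        state = 1;
      }
    } else if (state == 1) { // gap consuming reference (E)
      ++hit.columns;
      if (swE[IDX(i, j)] == swH[IDX(i, j - 1)] + gapOpen) state = 0;
      --j;
    } else { // gap consuming query (F)
      ++hit.columns;
      if (swF[IDX(i, j)] == swH[IDX(i - 1, j)] + gapOpen) state = 0;
      --i;
    }
  }
#undef IDX
  hit.qstart = i;
  hit.rstart = j;
  return hit;
}

// [[Rcpp::export]]
List cpp_sw(std::string q, std::string r, int match, int mismatch,
            int gapOpen, int gapExt) {
  q = upper(q);
  r = upper(r);
  SwHit h = sw_align(q, r, match, mismatch, gapOpen, gapExt);
  return List::create(
      _["score"] = h.score, _["matches"] = h.matches,
      _["columns"] = h.columns,
      _["identity"] = h.columns > 0 ? (double)h.matches / h.columns : 0.0,
      _["qstart"] = h.qstart, _["qend"] = h.qend, _["rstart"] = h.rstart,
      _["rend"] = h.rend);
}

// Nearest-neighbor search: 12-mer index pre-screen, local alignment on
// candidates, all hits tied at the maximal score kept (after the
// coverage/identity reporting floor). Returns, per query, the 1-based
// indices of the best references plus the best hit's identity and score.
// [[Rcpp::export]]
List cpp_classify(CharacterVector queries, CharacterVector refs, int k,
                  int maxCandidates, double minCoverage, double minIdentity,
                  int match, int mismatch, int gapOpen, int gapExt) {
  const int nq = queries.size(), nr = refs.size();
  std::vector<std::string> R(nr);
  std::unordered_map<uint32_t, std::vector<int> > index;
  std::vector<uint32_t> tmp;
  for (int j = 0; j < nr; ++j) {
    R[j] = upper(as<std::string>(refs[j]));
    collect_kmers(R[j], k, tmp);
    std::sort(tmp.begin(), tmp.end());
    tmp.erase(std::unique(tmp.begin(), tmp.end()), tmp.end());
    for (size_t t = 0; t < tmp.size(); ++t) index[tmp[t]].push_back(j);
  }
  List hitList(nq);
  NumericVector bestIdent(nq);
  IntegerVector bestScore(nq);
  std::vector<int> count(nr, 0);
  std::vector<int> touched;
  for (int i = 0; i < nq; ++i) {
    std::string q = upper(as<std::string>(queries[i]));
    collect_kmers(q, k, tmp);
    std::sort(tmp.begin(), tmp.end());
    tmp.erase(std::unique(tmp.begin(), tmp.end()), tmp.end());
    touched.clear();
    for (size_t t = 0; t < tmp.size(); ++t) {
      std::unordered_map<uint32_t, std::vector<int> >::const_iterator it =
          index.find(tmp[t]);
      if (it == index.end()) continue;
      for (size_t u = 0; u < it->second.size(); ++u) {
        const int rj = it->second[u];
        if (count[rj] == 0) touched.push_back(rj);
        ++count[rj];
      }
    }
    // candidates: refs sharing k-mers, by shared count desc (ties by index)
    std::vector<std::pair<int, int> > cand;
    for (size_t t = 0; t < touched.size(); ++t)
      cand.push_back(std::make_pair(-count[touched[t]], touched[t]));
    for (size_t t = 0; t < touched.size(); ++t) count[touched[t]] = 0;
    std::sort(cand.begin(), cand.end());
    if ((int)cand.size() > maxCandidates) cand.resize(maxCandidates);
    int topScore = -1;
    double topId = 0.0;
    std::vector<int> ties;
    for (size_t t = 0; t < cand.size(); ++t) {
      const int rj = cand[t].second;
      SwHit h = sw_align(q, R[rj], match, mismatch, gapOpen, gapExt);
      if (h.columns == 0) continue;
      const double cov = (double)(h.qend - h.qstart) / (double)q.size();
      const double id = (double)h.matches / (double)h.columns;
      if (cov < minCoverage || id < minIdentity) continue;
      if (h.score > topScore) {
        topScore = h.score;
        topId = id;
        ties.clear();
        ties.push_back(rj + 1);
      } else if (h.score == topScore) {
        ties.push_back(rj + 1);
      }
    }
    std::sort(ties.begin(), ties.end());
    hitList[i] = IntegerVector(ties.begin(), ties.end());
    bestIdent[i] = topScore >= 0 ? topId : NA_REAL;
    bestScore[i] = topScore >= 0 ? topScore : NA_INTEGER;
  }
  return List::create(_["hits"] = hitList, _["identity"] = bestIdent,
                      _["score"] = bestScore);
}

// Per-position match profile of `center` against `ref` under the global
// scheme: out[i] is TRUE when centroid base i aligns to an identical
// reference base on the tracked optimal path. Used by the two-parent
// chimera model.
// [[Rcpp::export]]
LogicalVector cpp_match_profile(std::string center, std::string ref) {
  center = upper(center);
  ref = upper(ref);
  const int n = (int)center.size(), m = (int)ref.size();
  // full DP with pointers (sequences are amplicon-sized)
  std::vector<std::vector<int> > S(n + 1, std::vector<int>(m + 1));
  std::vector<std::vector<uint8_t> > P(n + 1,
                                       std::vector<uint8_t>(m + 1, 0));
  for (int j = 0; j <= m; ++j) {
    S[0][j] = NW_GAP * j;
    P[0][j] = 2; // left
  }
  for (int i = 1; i <= n; ++i) {
    S[i][0] = NW_GAP * i;
    P[i][0] = 1; // up
    for (int j = 1; j <= m; ++j) {
      const bool eq = (center[i - 1] == ref[j - 1]);
      const int sd = S[i - 1][j - 1] + (eq ? NW_MATCH : NW_MISMATCH);
      const int su = S[i - 1][j] + NW_GAP;
      const int sl = S[i][j - 1] + NW_GAP;
      if (sd >= su && sd >= sl) {
        S[i][j] = sd;
        P[i][j] = 0;
      } else if (su >= sl) {
        S[i][j] = su;
        P[i][j] = 1;
      } else {
        S[i][j] = sl;
        P[i][j] = 2;
      }
    }
  }
  LogicalVector out(n);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const uint8_t p = P[i][j];
    if (p == 0) {
      out[i - 1] = (center[i - 1] == ref[j - 1]);
      --i;
      --j;
    } else if (p == 1) {
      out[i - 1] = false;
      --i;
    } else {
      --j;
    }
  }
  return out;
}

// Top-N reference candidates per query by shared 12-mer count (used to
// shortlist chimera parents). Returns an IntegerMatrix (topn x nq) of
// 1-based reference indices, 0-padded.
// [[Rcpp::export]]
IntegerMatrix cpp_kmer_topn(CharacterVector queries, CharacterVector refs,
                            int k, int topn) {
  const int nq = queries.size(), nr = refs.size();
  std::unordered_map<uint32_t, std::vector<int> > index;
  std::vector<uint32_t> tmp;
  for (int j = 0; j < nr; ++j) {
    std::string r = upper(as<std::string>(refs[j]));
    collect_kmers(r, k, tmp);
    std::sort(tmp.begin(), tmp.end());
    tmp.erase(std::unique(tmp.begin(), tmp.end()), tmp.end());
    for (size_t t = 0; t < tmp.size(); ++t) index[tmp[t]].push_back(j);
  }
  IntegerMatrix out(topn, nq);
  std::vector<int> count(nr, 0);
  std::vector<int> touched;
  for (int i = 0; i < nq; ++i) {
    std::string q = upper(as<std::string>(queries[i]));
    collect_kmers(q, k, tmp);
    std::sort(tmp.begin(), tmp.end());
    tmp.erase(std::unique(tmp.begin(), tmp.end()), tmp.end());
    touched.clear();
    for (size_t t = 0; t < tmp.size(); ++t) {
      std::unordered_map<uint32_t, std::vector<int> >::const_iterator it =
          index.find(tmp[t]);
      if (it == index.end()) continue;
      for (size_t u = 0; u < it->second.size(); ++u) {
        const int rj = it->second[u];
        if (count[rj] == 0) touched.push_back(rj);
        ++count[rj];
      }
    }
    std::vector<std::pair<int, int> > cand;
    for (size_t t = 0; t < touched.size(); ++t)
      cand.push_back(std::make_pair(-count[touched[t]], touched[t]));
    for (size_t t = 0; t < touched.size(); ++t) count[touched[t]] = 0;
    std::sort(cand.begin(), cand.end());
    for (int t = 0; t < topn; ++t)
      out(t, i) = (t < (int)cand.size()) ? cand[t].second + 1 : 0;
  }
  return out;
}
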