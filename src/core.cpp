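#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>
using namespace Rcpp;

// base encoding: A=0 C=1 G=2 T=3, anything else -1
static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}
static inline char cmpl(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp1(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = cmpl(r[i]);
  return r;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = revcomp1(std::string(x[i]));
  return out;
}

// Merge read pairs over their best-scoring overlap.
// Offset d = start of revcomp(mate2) relative to mate1 start. Offsets are
// visited in order of decreasing overlap length (ties: smaller d first), so
// the first strictly best score automatically realises the tie-break rule
// "longest overlap, then smallest offset"; the search stops as soon as no
// remaining overlap length can strictly beat the current best score.
// Score = matches - mismatches over the overlap; input N bases are skipped
// for scoring. The maximal-scoring offset is accepted only if its mismatch
// fraction is <= max_mismatch_frac.
// Consensus: agreeing bases keep max quality; disagreements (or input N)
// become N with quality 0; bases covered by one mate only are retained and
// lie outside the reported overlap span.
// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2, CharacterVector qual2,
                     int min_overlap, double max_mismatch_frac) {
  R_xlen_t n = seq1.size();
  LogicalVector merged(n);
  CharacterVector mseq(n), mqual(n);
  IntegerVector offset(n, NA_INTEGER), ol_start(n, NA_INTEGER),
      ol_end(n, NA_INTEGER), n_masked(n, NA_INTEGER);
  std::string s2r, q2r, cons, consq;
  // offset visit order, cached for the previous (L1, L2) combination
  std::vector<std::pair<int, int> > order;  // (overlap_len, d), ol desc
  int cacheL1 = -1, cacheL2 = -1;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s1 = CHAR(STRING_ELT(seq1, i));
    const char* q1 = CHAR(STRING_ELT(qual1, i));
    const char* s2 = CHAR(STRING_ELT(seq2, i));
    const char* q2 = CHAR(STRING_ELT(qual2, i));
    const int L1 = (int)strlen(s1), L2 = (int)strlen(s2);
    s2r.resize(L2); q2r.resize(L2);
    for (int j = 0; j < L2; ++j) {
      s2r[j] = cmpl(s2[L2 - 1 - j]);
      q2r[j] = q2[L2 - 1 - j];
    }
    if (L1 != cacheL1 || L2 != cacheL2) {
      // d >= 0 only: mate 1 starts at or before reverse-complemented
      // mate 2 (proper fragment orientation; adapter read-through pairs
      // are out of scope, like gapped overlaps)
      order.clear();
      for (int d = 0; d <= L1 - min_overlap; ++d) {
        int ol = std::min(L1, d + L2) - std::max(0, d);
        if (ol >= min_overlap)
          order.push_back(std::make_pair(-ol, d));
      }
      std::sort(order.begin(), order.end());  // ol desc, then d asc
      cacheL1 = L1; cacheL2 = L2;
    }
    int best_score = INT_MIN, best_d = 0, best_ol = 0, best_mm = 0;
    bool found = false;
    for (size_t oi = 0; oi < order.size(); ++oi) {
      const int olen = -order[oi].first;
      const int d = order[oi].second;
      if (found && best_score >= olen) break;  // cannot strictly improve
      int a = std::max(0, d), b = std::min(L1, d + L2);
      int mm = 0, mt = 0;
      bool aborted = false;
      for (int p = a; p < b; ++p) {
        char c1 = s1[p], c2 = s2r[p - d];
        if (enc(c1) < 0 || enc(c2) < 0) continue;
        if (c1 == c2) ++mt; else ++mm;
        if (found && olen - 2 * mm < best_score) { aborted = true; break; }
      }
      if (aborted) continue;
      int score = mt - mm;
      if (!found || score > best_score) {
        found = true; best_score = score; best_d = d;
        best_ol = olen; best_mm = mm;
      }
    }
    if (!found || (double)best_mm > max_mismatch_frac * (double)best_ol) {
      merged[i] = false;
      continue;
    }
    merged[i] = true;
    offset[i] = best_d;
    const int d = best_d;
    const int lo = std::min(0, d), hi = std::max(L1, d + L2);
    const int mlen = hi - lo;
    cons.assign(mlen, 'N'); consq.assign(mlen, '!');
    int masked = 0;
    for (int p = lo; p < hi; ++p) {
      bool in1 = (p >= 0 && p < L1);
      bool in2 = (p >= d && p < d + L2);
      int o = p - lo;
      if (in1 && in2) {
        char c1 = s1[p], c2 = s2r[p - d];
        if (c1 == c2 && enc(c1) >= 0) {
          cons[o] = c1;
          consq[o] = std::max(q1[p], q2r[p - d]);
        } else {
          cons[o] = 'N'; consq[o] = '!';
          ++masked;
        }
      } else if (in1) {
        cons[o] = s1[p]; consq[o] = q1[p];
      } else {
        cons[o] = s2r[p - d]; consq[o] = q2r[p - d];
      }
    }
    mseq[i] = cons; mqual[i] = consq;
    ol_start[i] = std::max(0, d) - lo;
    ol_end[i] = std::min(L1, d + L2) - lo;
    n_masked[i] = masked;
  }
  return List::create(_["merged"] = merged, _["seq"] = mseq,
                      _["qual"] = mqual, _["offset"] = offset,
                      _["ol_start"] = ol_start, _["ol_end"] = ol_end,
                      _["n_masked"] = n_masked);
}

// Exhaustive gapless aligner: scans every placement on both strands and
// returns the unique placement with fewest mismatches if that minimum is
// <= max_mismatch and strictly better than the runner-up. N bases in the
// read are ignored (neither match nor mismatch); non-ACGT genome characters
// (contig separators) always mismatch.
// [[Rcpp::export]]
List align_scan_cpp(CharacterVector reads, std::string genome,
                    int max_mismatch) {
  const int G = (int)genome.size();
  R_xlen_t n = reads.size();
  IntegerVector start(n, NA_INTEGER), strand(n, NA_INTEGER),
      nmis(n, NA_INTEGER);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string rd = std::string(reads[i]);
    std::string rc = revcomp1(rd);
    const int L = (int)rd.size();
    if (L > G) continue;
    int best = INT_MAX, best2 = INT_MAX, bpos = -1, bstr = -1;
    for (int str = 0; str < 2; ++str) {
      const std::string& q = (str == 0) ? rd : rc;
      for (int p = 0; p + L <= G; ++p) {
        // a placement only matters if its mismatch count can still reach
        // the final minimum, which is bounded by min(best, max_mismatch)
        const int lim = std::min(best, max_mismatch);
        int mm = 0;
        for (int j = 0; j < L; ++j) {
          char cq = q[j];
          if (enc(cq) < 0) continue;        // masked read base
          if (cq != genome[p + j]) {
            if (++mm > lim) break;
          }
        }
        if (mm > lim) continue;
        if (mm < best) {
          best2 = best; best = mm; bpos = p; bstr = str;
        } else if (mm <= best2) {
          best2 = mm;   // includes mm == best: equally good second site
        }
      }
    }
    if (bpos >= 0 && best <= max_mismatch && best < best2) {
      start[i] = bpos; strand[i] = bstr; nmis[i] = best;
    }
  }
  return List::create(_["start"] = start, _["strand"] = strand,
                      _["nmis"] = nmis);
}

// k-mer index over the forward genome: sorted keys with positions.
// k <= 16 so the 2-bit code fits exactly in a double.
// [[Rcpp::export]]
List kmer_index_cpp(std::string genome, int k) {
  const int G = (int)genome.size();
  std::vector<std::pair<uint64_t, int> > kv;
  kv.reserve(G > k ? G - k + 1 : 0);
  uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int p = 0; p < G; ++p) {
    int c = enc(genome[p]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) kv.push_back(std::make_pair(key, p - k + 1));
  }
  std::sort(kv.begin(), kv.end());
  NumericVector keys(kv.size());
  IntegerVector pos(kv.size());
  for (size_t i = 0; i < kv.size(); ++i) {
    keys[i] = (double)kv[i].first;
    pos[i] = kv[i].second;
  }
  return List::create(_["keys"] = keys, _["pos"] = pos, _["k"] = k);
}

static void seed_candidates(const std::string& q, int k,
                            const std::vector<int>& offs,
                            const std::vector<uint64_t>& keys,
                            const IntegerVector& pos,
                            std::vector<int>& out) {
  const int L = (int)q.size();
  if (L < k) return;
  for (size_t oi = 0; oi < offs.size(); ++oi) {
    int o = offs[oi];
    if (o + k > L) continue;
    uint64_t key = 0; bool ok = true;
    for (int j = 0; j < k; ++j) {
      int c = enc(q[o + j]);
      if (c < 0) { ok = false; break; }
      key = (key << 2) | (uint64_t)c;
    }
    if (!ok) continue;
    std::vector<uint64_t>::const_iterator it =
        std::lower_bound(keys.begin(), keys.end(), key);
    for (; it != keys.end() && *it == key; ++it) {
      int diag = pos[(int)(it - keys.begin())] - o;
      out.push_back(diag);
    }
  }
}

// Seeded version of the exhaustive aligner for large references: candidate
// placements come from exact k-mer seed hits (read and reverse-complement);
// each candidate is verified by full mismatch counting and the unique-best
// rule is applied over the candidate set.
// [[Rcpp::export]]
List align_index_cpp(CharacterVector reads, std::string genome,
                     NumericVector keys_d, IntegerVector pos, int k,
                     int max_mismatch, int stride) {
  const int G = (int)genome.size();
  std::vector<uint64_t> keys(keys_d.size());
  for (R_xlen_t i = 0; i < keys_d.size(); ++i)
    keys[i] = (uint64_t)keys_d[i];
  R_xlen_t n = reads.size();
  IntegerVector start(n, NA_INTEGER), strand(n, NA_INTEGER),
      nmis(n, NA_INTEGER);
  std::vector<int> candF, candR;
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string rd = std::string(reads[i]);
    std::string rc = revcomp1(rd);
    const int L = (int)rd.size();
    candF.clear(); candR.clear();
    // cheap pass first: seeds at both read ends and the middle; escalate
    // to a full strided pass only when nothing hits (masked/error bases)
    std::vector<int> offs;
    offs.push_back(0);
    if (L >= 2 * k) offs.push_back((L - k) / 2);
    if (L > k) offs.push_back(L - k);
    seed_candidates(rd, k, offs, keys, pos, candF);
    seed_candidates(rc, k, offs, keys, pos, candR);
    if (candF.empty() && candR.empty()) {
      offs.clear();
      for (int o = 0; o + k <= L; o += stride) offs.push_back(o);
      seed_candidates(rd, k, offs, keys, pos, candF);
      seed_candidates(rc, k, offs, keys, pos, candR);
    }
    std::sort(candF.begin(), candF.end());
    candF.erase(std::unique(candF.begin(), candF.end()), candF.end());
    std::sort(candR.begin(), candR.end());
    candR.erase(std::unique(candR.begin(), candR.end()), candR.end());
    int best = INT_MAX, best2 = INT_MAX, bpos = -1, bstr = -1;
    for (int str = 0; str < 2; ++str) {
      const std::string& q = (str == 0) ? rd : rc;
      const std::vector<int>& cand = (str == 0) ? candF : candR;
      for (size_t ci = 0; ci < cand.size(); ++ci) {
        int p = cand[ci];
        if (p < 0 || p + L > G) continue;
        const int lim = std::min(best, max_mismatch);
        int mm = 0;
        for (int j = 0; j < L; ++j) {
          char cq = q[j];
          if (enc(cq) < 0) continue;
          if (cq != genome[p + j]) {
            if (++mm > lim) break;
          }
        }
        if (mm > lim) continue;
        if (mm < best) {
          best2 = best; best = mm; bpos = p; bstr = str;
        } else if (mm <= best2) {
          best2 = mm;
        }
      }
    }
    if (bpos >= 0 && best <= max_mismatch && best < best2) {
      start[i] = bpos; strand[i] = bstr; nmis[i] = best;
    }
  }
  return List::create(_["start"] = start, _["strand"] = strand,
                      _["nmis"] = nmis);
}

// Accumulate filtered base calls into an L x 8 count matrix
// (columns: A,C,G,T for read1-forward then A,C,G,T for read1-reverse).
// Inputs are reference-oriented sequences/qualities with 0-based starts;
// only positions inside [ol_start, ol_end) (reference-oriented overlap
// span), with base != N and quality >= qmin, are counted. CIGAR strings
// ("" means gapless full-length match) follow SAM semantics; insertions
// are skipped, deletions give no call, soft clips are excluded. Reads
// running over the contig end are truncated.
// [[Rcpp::export]]
void pileup_cpp(IntegerVector counts, int L, IntegerVector start,
                IntegerVector orient, CharacterVector seq,
                CharacterVector qual, IntegerVector ol_start,
                IntegerVector ol_end, CharacterVector cigar, int qmin) {
  R_xlen_t n = seq.size();
  const char qthr = (char)(qmin + 33);
  int* cnt = INTEGER(counts);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (start[i] == NA_INTEGER) continue;
    const char* s = CHAR(STRING_ELT(seq, i));
    const char* q = CHAR(STRING_ELT(qual, i));
    const int o8 = (orient[i] == 0) ? 0 : 4;
    const int a = ol_start[i], b = ol_end[i];
    std::string cg = std::string(cigar[i]);
    int rpos = start[i];  // reference position
    int qpos = 0;         // query position
    if (cg.empty()) cg = std::to_string((int)strlen(s)) + "M";
    size_t ci = 0;
    while (ci < cg.size()) {
      int len = 0;
      while (ci < cg.size() && cg[ci] >= '0' && cg[ci] <= '9')
        len = len * 10 + (cg[ci++] - '0');
      char op = cg[ci++];
      switch (op) {
      case 'M': case '=': case 'X':
        for (int j = 0; j < len; ++j, ++rpos, ++qpos) {
          if (rpos < 0 || rpos >= L) continue;
          if (qpos < a || qpos >= b) continue;
          int c = enc(s[qpos]);
          if (c < 0 || q[qpos] < qthr) continue;
          ++cnt[rpos + (R_xlen_t)L * (o8 + c)];
        }
        break;
      case 'I': case 'S': qpos += len; break;
      case 'D': case 'N': rpos += len; break;
      case 'H': case 'P': break;
      default: stop("unsupported CIGAR op '%c'", op);
      }
    }
  }
}

// Inject context-free miscalls: each base b is replaced by base a with
// probability rates(b, a). Uses R's RNG so results are governed by
// set.seed. Candidate error positions are drawn by geometric
// skip-sampling at the maximum per-base rate and thinned to the true
// base-specific rate, so the cost is proportional to the number of
// errors, not the number of bases.
// [[Rcpp::export]]
CharacterVector apply_errors_cpp(CharacterVector seqs, NumericMatrix rates) {
  double tot[4];
  double pmax = 0.0;
  for (int b = 0; b < 4; ++b) {
    tot[b] = 0.0;
    for (int a = 0; a < 4; ++a)
      if (a != b) tot[b] += rates(b, a);
    if (tot[b] > pmax) pmax = tot[b];
  }
  static const char BASECH[4] = {'A', 'C', 'G', 'T'};
  R_xlen_t n = seqs.size();
  if (pmax <= 0.0) return seqs;
  const double lq = std::log1p(-pmax);
  CharacterVector out(n);
  std::string s;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* src = CHAR(STRING_ELT(seqs, i));
    const R_xlen_t L = (R_xlen_t)strlen(src);
    bool copied = false;
    // geometric skips between candidate positions
    double p = std::floor(std::log(unif_rand()) / lq);
    while (p < (double)L) {
      int b = enc(copied ? s[(size_t)p] : src[(size_t)p]);
      if (b >= 0 && tot[b] > 0.0) {
        double u = unif_rand() * pmax;
        if (u < tot[b]) {
          if (!copied) { s.assign(src, (size_t)L); copied = true; }
          for (int a = 0; a < 4; ++a) {
            if (a == b) continue;
            if (u < rates(b, a)) { s[(size_t)p] = BASECH[a]; break; }
            u -= rates(b, a);
          }
        }
      }
      p += 1.0 + std::floor(std::log(unif_rand()) / lq);
    }
    if (copied) out[i] = s;
    else out[i] = STRING_ELT(seqs, i);
  }
  return out;
}

// Per-position trinucleotide code: left*16 + centre*4 + right (0..63), or
// -1 where the centre base is N or a neighbour is missing/N.
// [[Rcpp::export]]
IntegerVector triplet_codes_cpp(std::string seq) {
  const int L = (int)seq.size();
  IntegerVector code(L, -1);
  for (int p = 1; p + 1 < L; ++p) {
    int l = enc(seq[p - 1]), c = enc(seq[p]), r = enc(seq[p + 1]);
    if (l < 0 || c < 0 || r < 0) continue;
    code[p] = l * 16 + c * 4 + r;
  }
  return code;
}

// Pairwise comparison of equal-length strings: mismatches over positions
// where both characters are ACGT (N and separator characters are skipped).
// [[Rcpp::export]]
List mismatch_count_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  IntegerVector mm(n), ncmp(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string x = std::string(a[i]), y = std::string(b[i]);
    size_t L = std::min(x.size(), y.size());
    int m = 0, c = 0;
    for (size_t j = 0; j < L; ++j) {
      if (enc(x[j]) < 0 || enc(y[j]) < 0) continue;
      ++c;
      if (x[j] != y[j]) ++m;
    }
    mm[i] = m; ncmp[i] = c;
  }
  return List::create(_["mismatch"] = mm, _["compared"] = ncmp);
}

// [[Rcpp::export]]
NumericVector mean_qual_cpp(CharacterVector qual) {
  R_xlen_t n = qual.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string q = std::string(qual[i]);
    double s = 0.0;
    for (size_t j = 0; j < q.size(); ++j) s += (double)(q[j] - 33);
    out[i] = q.empty() ? NA_REAL : s / (double)q.size();
  }
  return out;
}
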