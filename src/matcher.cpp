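// Seed-and-extend short-read matcher over a two-part reference: genomic
// chromosomes plus spliced transcript sequences (splice-aware by construction).
// Presence/absence semantics with a best-hit location for downstream counting.
#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int baseCode(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': case 'U': case 'u': return 3;
  default: return -1;
  }
}

static inline char upBase(char c) {
  if (c >= 'a' && c <= 'z') return c - 32;
  return c;
}

struct SeedIndexCpp {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::vector<int> isTranscript;          // 1 = spliced transcript reference
  std::vector<uint64_t> keys;             // canonical k-mers, sorted
  std::vector<int32_t> refId;             // parallel to keys
  std::vector<int32_t> pos;               // 0-based position of forward k-mer
  std::vector<uint8_t> fwdIsCanon;        // forward k-mer equals canonical form
};

static inline uint64_t revcompKmer(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (x & 3ULL));
    x >>= 2;
  }
  return r;
}

// Enumerate valid k-mers of s; cb(startPos, fwdCode).
template <typename F>
static void eachKmer(const std::string &s, int k, F cb) {
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t cur = 0;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = baseCode(s[i]);
    if (c < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t)c) & mask;
    if (++run >= k) cb(i - k + 1, cur);
  }
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names,
                     IntegerVector isTranscript, int k) {
  if (k < 2 || k > 31) stop("k must be between 2 and 31");
  SeedIndexCpp *idx = new SeedIndexCpp();
  idx->k = k;
  const int nref = seqs.size();
  size_t total = 0;
  for (int r = 0; r < nref; ++r) {
    std::string s = as<std::string>(seqs[r]);
    idx->names.push_back(as<std::string>(names[r]));
    idx->isTranscript.push_back(isTranscript[r]);
    if ((int)s.size() >= k) total += s.size() - k + 1;
    idx->seqs.push_back(std::move(s));
  }
  idx->keys.reserve(total);
  idx->refId.reserve(total);
  idx->pos.reserve(total);
  idx->fwdIsCanon.reserve(total);
  for (int r = 0; r < nref; ++r) {
    eachKmer(idx->seqs[r], k, [&](int p, uint64_t fwd) {
      uint64_t rc = revcompKmer(fwd, k);
      uint64_t canon = fwd <= rc ? fwd : rc;
      idx->keys.push_back(canon);
      idx->refId.push_back(r);
      idx->pos.push_back(p);
      idx->fwdIsCanon.push_back(fwd <= rc ? 1 : 0);
    });
  }
  // sort parallel arrays by (key, refId, pos) for deterministic queries
  std::vector<size_t> ord(idx->keys.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (idx->keys[a] != idx->keys[b]) return idx->keys[a] < idx->keys[b];
    if (idx->refId[a] != idx->refId[b]) return idx->refId[a] < idx->refId[b];
    return idx->pos[a] < idx->pos[b];
  });
  SeedIndexCpp *out = new SeedIndexCpp();
  out->k = k;
  out->names = idx->names;
  out->seqs = idx->seqs;
  out->isTranscript = idx->isTranscript;
  out->keys.reserve(ord.size());
  out->refId.reserve(ord.size());
  out->pos.reserve(ord.size());
  out->fwdIsCanon.reserve(ord.size());
  for (size_t i : ord) {
    out->keys.push_back(idx->keys[i]);
    out->refId.push_back(idx->refId[i]);
    out->pos.push_back(idx->pos[i]);
    out->fwdIsCanon.push_back(idx->fwdIsCanon[i]);
  }
  delete idx;
  XPtr<SeedIndexCpp> ptr(out, true);
  return ptr;
}

// [[Rcpp::export]]
int cpp_index_size(SEXP xp) {
  XPtr<SeedIndexCpp> idx(xp);
  return (int)idx->keys.size();
}

// [[Rcpp::export]]
DataFrame cpp_query_index(SEXP xp, std::string kmer) {
  XPtr<SeedIndexCpp> idx(xp);
  const int k = idx->k;
  if ((int)kmer.size() != k) stop("query length must equal index k");
  uint64_t fwd = 0;
  for (int i = 0; i < k; ++i) {
    int c = baseCode(kmer[i]);
    if (c < 0) stop("query contains a non-ACGT base");
    fwd = (fwd << 2) | (uint64_t)c;
  }
  uint64_t rc = revcompKmer(fwd, k);
  uint64_t canon = fwd <= rc ? fwd : rc;
  auto lo = std::lower_bound(idx->keys.begin(), idx->keys.end(), canon);
  auto hi = std::upper_bound(idx->keys.begin(), idx->keys.end(), canon);
  std::vector<std::string> name;
  std::vector<int> p;
  std::vector<std::string> strand;
  for (auto it = lo; it != hi; ++it) {
    size_t i = it - idx->keys.begin();
    name.push_back(idx->names[idx->refId[i]]);
    p.push_back(idx->pos[i] + 1);
    // strand of the query relative to the reference forward strand
    bool sameAsFwd = (fwd <= rc) == (idx->fwdIsCanon[i] == 1);
    strand.push_back(sameAsFwd ? "+" : "-");
  }
  return DataFrame::create(_["ref"] = name, _["pos"] = p, _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

static inline std::string revcompStr(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (upBase(c)) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': case 'U': c = 'A'; break;
    default: c = 'N';
    }
  }
  return r;
}

struct Cand { int32_t ref; int8_t strand; int32_t diag; };

// [[Rcpp::export]]
List cpp_match_reads(SEXP xp, CharacterVector reads, int minSeedHits,
                     double maxMismatchRate) {
  XPtr<SeedIndexCpp> idx(xp);
  const int k = idx->k;
  const int n = reads.size();
  LogicalVector matched(n);
  CharacterVector refName(n);
  IntegerVector refIdOut(n);
  IntegerVector posOut(n);
  CharacterVector strandOut(n);
  IntegerVector mism(n);
  IntegerVector nRefs(n);
  LogicalVector refIsTx(n);

  std::vector<Cand> cands;
  for (int i = 0; i < n; ++i) {
    std::string read = as<std::string>(reads[i]);
    const int L = (int)read.size();
    matched[i] = false;
    refName[i] = NA_STRING;
    refIdOut[i] = NA_INTEGER;
    posOut[i] = NA_INTEGER;
    strandOut[i] = NA_STRING;
    mism[i] = NA_INTEGER;
    nRefs[i] = 0;
    refIsTx[i] = NA_LOGICAL;
    if (L < k) continue;
    const int maxMism = (int)std::floor(maxMismatchRate * L);
    cands.clear();
    // sparse seeding: ~11 seeds spread over the read (plus both ends);
    // co-linear voting still requires minSeedHits agreeing diagonals
    const int step = std::max(1, (L - k) / 10);
    eachKmer(read, k, [&](int p, uint64_t fwd) {
      if (p % step != 0 && p != L - k) return;
      uint64_t rc = revcompKmer(fwd, k);
      uint64_t canon = fwd <= rc ? fwd : rc;
      bool readFwdIsCanon = fwd <= rc;
      auto lo = std::lower_bound(idx->keys.begin(), idx->keys.end(), canon);
      auto hi = std::upper_bound(idx->keys.begin(), idx->keys.end(), canon);
      for (auto it = lo; it != hi; ++it) {
        size_t j = it - idx->keys.begin();
        bool plus = readFwdIsCanon == (idx->fwdIsCanon[j] == 1);
        int32_t d;
        if (plus) d = idx->pos[j] - p;
        else d = idx->pos[j] - (L - k - p);
        cands.push_back({idx->refId[j], (int8_t)(plus ? 1 : 0), d});
      }
    });
    if (cands.empty()) continue;
    std::sort(cands.begin(), cands.end(), [](const Cand &a, const Cand &b) {
      if (a.ref != b.ref) return a.ref < b.ref;
      if (a.strand != b.strand) return a.strand > b.strand; // '+' first
      return a.diag < b.diag;
    });
    std::string rcRead;
    bool haveRc = false;
    int bestMism = -1, bestRef = -1, bestPos = -1;
    char bestStrand = '+';
    std::vector<int> refsHit;
    size_t a = 0;
    while (a < cands.size()) {
      size_t b = a + 1;
      while (b < cands.size() && cands[b].ref == cands[a].ref &&
             cands[b].strand == cands[a].strand && cands[b].diag == cands[a].diag)
        ++b;
      if ((int)(b - a) >= minSeedHits) {
        const Cand &c = cands[a];
        const std::string &ref = idx->seqs[c.ref];
        if (c.diag >= 0 && c.diag + L <= (int)ref.size()) {
          const std::string *q;
          if (c.strand == 1) q = &read;
          else {
            if (!haveRc) { rcRead = revcompStr(read); haveRc = true; }
            q = &rcRead;
          }
          int mm = 0;
          for (int t = 0; t < L && mm <= maxMism; ++t) {
            char rb = upBase(ref[c.diag + t]);
            char qb = upBase((*q)[t]);
            if (rb != qb || rb == 'N' || qb == 'N') ++mm;
          }
          if (mm <= maxMism) {
            if (refsHit.empty() || refsHit.back() != c.ref) refsHit.push_back(c.ref);
            // prefer fewer mismatches; on ties prefer a spliced-transcript
            // reference over a chromosome (splice-aware interpretation)
            bool better = bestMism < 0 || mm < bestMism ||
              (mm == bestMism && idx->isTranscript[c.ref] == 1 &&
               idx->isTranscript[bestRef] == 0);
            if (better) {
              bestMism = mm; bestRef = c.ref; bestPos = c.diag;
              bestStrand = c.strand == 1 ? '+' : '-';
            }
          }
        }
      }
      a = b;
    }
    if (bestMism >= 0) {
      matched[i] = true;
      refName[i] = idx->names[bestRef];
      refIdOut[i] = bestRef + 1;
      posOut[i] = bestPos + 1;
      strandOut[i] = bestStrand == '+' ? "+" : "-";
      mism[i] = bestMism;
      nRefs[i] = (int)refsHit.size();
      refIsTx[i] = idx->isTranscript[bestRef] == 1;
    }
  }
  return List::create(_["matched"] = matched, _["ref"] = refName,
                      _["pos"] = posOut, _["strand"] = strandOut,
                      _["mismatches"] = mism, _["n_refs"] = nRefs,
                      _["ref_is_transcript"] = refIsTx);
}
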