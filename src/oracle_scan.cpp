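// Exhaustive ungapped read placement with at most max_mm mismatches.
// Completeness by pigeonhole seeding: a read is split into max_mm + 1
// non-overlapping segments; any placement with <= max_mm mismatches has at
// least one error-free segment, so looking up an exact k-mer prefix of every
// segment in a genome k-mer index enumerates every valid placement. Each
// candidate diagonal is then verified base by base with early exit.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

static bool packKmer(const char* s, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return true;
}

struct Hit {
  int read;    // 0-based read index
  int contig;  // 0-based contig index
  int pos;     // 0-based start within contig
  char strand;
  int mm;
};

// [[Rcpp::export]]
DataFrame cpp_scan_reads(CharacterVector genome, CharacterVector reads,
                         int max_mm) {
  const int ncontig = genome.size();
  std::vector<std::string> contigs(ncontig);
  std::vector<long long> offset(ncontig + 1, 0);
  for (int i = 0; i < ncontig; ++i) {
    contigs[i] = as<std::string>(genome[i]);
    offset[i + 1] = offset[i] + (long long)contigs[i].size();
  }
  std::string cat;
  cat.reserve((size_t)offset[ncontig]);
  for (int i = 0; i < ncontig; ++i) cat += contigs[i];
  const long long G = (long long)cat.size();

  const int k = 16;
  std::unordered_map<uint64_t, std::vector<int>> index;
  index.reserve((size_t)(G > 0 ? G : 1));
  if (G >= k) {
    uint64_t key = 0;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int valid = 0;
    for (long long i = 0; i < G; ++i) {
      int b = base2bit(cat[(size_t)i]);
      if (b < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++valid >= k) index[key].push_back((int)(i - k + 1));
    }
  }

  std::vector<Hit> hits;
  const int nseg = max_mm + 1;

  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const int L = (int)fwd.size();
    std::string rev(fwd.rbegin(), fwd.rend());
    for (auto& c : rev) c = comp(c);

    const char* seqs[2] = { fwd.c_str(), rev.c_str() };
    const char strands[2] = { '+', '-' };

    for (int si = 0; si < 2; ++si) {
      const char* q = seqs[si];
      std::unordered_set<long long> seen;

      auto verify = [&](long long startg) {
        if (startg < 0 || startg + L > G) return;
        if (!seen.insert(startg).second) return;
        // reject placements spanning a contig boundary
        int ci = 0;
        while (ci < ncontig && offset[ci + 1] <= startg) ++ci;
        if (ci >= ncontig || startg + L > offset[ci + 1]) return;
        int mm = 0;
        const char* g = cat.c_str() + startg;
        for (int i = 0; i < L; ++i) {
          char gb = g[i], qb = q[i];
          if (gb >= 'a') gb -= 32;
          if (qb >= 'a') qb -= 32;
          if (gb != qb || gb == 'N') {
            if (++mm > max_mm) return;
          }
        }
        Hit h;
        h.read = r; h.contig = ci; h.pos = (int)(startg - offset[ci]);
        h.strand = strands[si]; h.mm = mm;
        hits.push_back(h);
      };

      if (L >= nseg * k && G >= k) {
        for (int s = 0; s < nseg; ++s) {
          int segStart = (int)(((long long)s * L) / nseg);
          if (segStart + k > L) segStart = L - k;
          uint64_t key;
          if (!packKmer(q + segStart, k, key)) continue;
          auto it = index.find(key);
          if (it == index.end()) continue;
          for (int p : it->second) verify((long long)p - segStart);
        }
      } else {
        // read too short for seeding: exhaustive sliding scan
        for (long long p = 0; p + L <= G; ++p) verify(p);
      }
    }
  }

  const size_t n = hits.size();
  IntegerVector read(n), contig(n), pos(n), mm(n);
  CharacterVector strand(n);
  for (size_t i = 0; i < n; ++i) {
    read[i] = hits[i].read + 1;
    contig[i] = hits[i].contig + 1;
    pos[i] = hits[i].pos;
    strand[i] = std::string(1, hits[i].strand);
    mm[i] = hits[i].mm;
  }
  return DataFrame::create(_["read"] = read, _["contig"] = contig,
                           _["pos"] = pos, _["strand"] = strand,
                           _["mm"] = mm);
}
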