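// Compiled core: circular k-mer seed index, error-tolerant read mapping,
// paired-end classification, guided greedy-overlap assembly, allele pileup.
// All coordinates are 0-based half-open; positions on the circular consensus
// are taken modulo its length M.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <array>
#include <algorithm>
#include <cctype>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char base_comp(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = base_comp(s[i]);
  return out;
}

static std::string upper_str(const std::string& s) {
  std::string out(s);
  for (auto& c : out) c = std::toupper(static_cast<unsigned char>(c));
  return out;
}

// encode s[o .. o+k) as 2-bit packed integer; false if any non-ACGT base
static bool encode_kmer(const std::string& s, int o, int k, uint64_t& key) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[o + i]);
    if (c < 0) return false;
    v = (v << 2) | static_cast<uint64_t>(c);
  }
  key = v;
  return true;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp_str(as<std::string>(x[i]));
  return out;
}

// ---------------------------------------------------------------------------
// Seed index over all M circular k-mers of the consensus (forward strand;
// reverse-strand placements are found by mapping the reverse complement of
// the read).
// ---------------------------------------------------------------------------

struct SeedIndex {
  std::string cons;  // uppercase consensus
  int M;
  int k;
  std::unordered_map<uint64_t, std::vector<int>> tab;
};

// [[Rcpp::export]]
SEXP cpp_index_build(std::string consensus, int seed_len) {
  SeedIndex* idx = new SeedIndex();
  idx->cons = upper_str(consensus);
  idx->M = static_cast<int>(idx->cons.size());
  idx->k = seed_len;
  std::string ext = idx->cons + idx->cons.substr(0, std::min(idx->M, seed_len - 1));
  for (int p = 0; p < idx->M; ++p) {
    uint64_t key;
    if (encode_kmer(ext, p, seed_len, key)) idx->tab[key].push_back(p);
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
IntegerVector cpp_index_lookup(SEXP xp, std::string seed) {
  XPtr<SeedIndex> idx(xp);
  std::string s = upper_str(seed);
  if (static_cast<int>(s.size()) != idx->k)
    stop("seed must have length %d", idx->k);
  uint64_t key;
  if (!encode_kmer(s, 0, idx->k, key)) return IntegerVector(0);
  auto it = idx->tab.find(key);
  if (it == idx->tab.end()) return IntegerVector(0);
  return wrap(it->second);
}

// [[Rcpp::export]]
int cpp_index_size(SEXP xp) {
  XPtr<SeedIndex> idx(xp);
  size_t n = 0;
  for (auto& kv : idx->tab) n += kv.second.size();
  return static_cast<int>(n);
}

// circular Hamming distance of s placed at pos; early exit above cap
static int mm_at(const SeedIndex& idx, const std::string& s, int pos, int cap) {
  const int L = static_cast<int>(s.size()), M = idx.M;
  int mm = 0, q = pos % M;
  for (int i = 0; i < L; ++i) {
    if (idx.cons[q] != s[i] && ++mm > cap) return mm;
    if (++q == M) q = 0;
  }
  return mm;
}

struct Placement {
  int pos;
  int strand;  // 0 forward, 1 reverse
  int mm;
};

static void collect_candidates(const SeedIndex& idx, const std::string& s,
                               int stride, std::vector<int>& cands) {
  const int L = static_cast<int>(s.size()), k = idx.k, M = idx.M;
  if (L < k) return;
  const int last = L - k;
  for (int o = 0;; o += stride) {
    bool is_last = false;
    if (o >= last) { o = last; is_last = true; }
    uint64_t key;
    if (encode_kmer(s, o, k, key)) {
      auto it = idx.tab.find(key);
      if (it != idx.tab.end())
        for (int p : it->second) {
          int c = (p - o) % M;
          if (c < 0) c += M;
          cands.push_back(c);
        }
    }
    if (is_last) break;
  }
  std::sort(cands.begin(), cands.end());
  cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
}

static void map_oriented(const SeedIndex& idx, const std::string& s, int strand,
                         int max_mm, int stride, std::vector<Placement>& out) {
  std::vector<int> cands;
  collect_candidates(idx, s, stride, cands);
  for (int c : cands) {
    int mm = mm_at(idx, s, c, max_mm);
    if (mm <= max_mm) out.push_back({c, strand, mm});
  }
}

static std::vector<Placement> map_both(const SeedIndex& idx, const std::string& read,
                                       int max_mm, int stride) {
  std::vector<Placement> out;
  std::string fwd = upper_str(read);
  map_oriented(idx, fwd, 0, max_mm, stride, out);
  std::string rev = revcomp_str(fwd);
  map_oriented(idx, rev, 1, max_mm, stride, out);
  std::stable_sort(out.begin(), out.end(), [](const Placement& a, const Placement& b) {
    if (a.mm != b.mm) return a.mm < b.mm;
    if (a.pos != b.pos) return a.pos < b.pos;
    return a.strand < b.strand;
  });
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_map_read(SEXP xp, std::string read, int max_mm, int stride) {
  XPtr<SeedIndex> idx(xp);
  std::vector<Placement> pl = map_both(*idx, read, max_mm, stride);
  IntegerVector pos(pl.size()), mm(pl.size()), strand(pl.size());
  for (size_t i = 0; i < pl.size(); ++i) {
    pos[i] = pl[i].pos;
    strand[i] = pl[i].strand;
    mm[i] = pl[i].mm;
  }
  return DataFrame::create(_["position"] = pos, _["strand"] = strand,
                           _["mismatches"] = mm);
}

// Circular insert distance between a forward placement (pa, La) and a
// reverse placement (pb, Lb). On a circle the two mates bound two candidate
// fragments: the arc from the forward mate's start to the reverse mate's end
// (d1), and the complementary traversal from the reverse mate's start to the
// forward mate's end (d2) - which is the physical fragment when the pair
// spans the origin "the other way". The insert is whichever arc falls inside
// the accepted window (the shorter one if both do); -1 if neither does.
static int circ_insert(int pa, int La, int pb, int Lb, int M, int d_min, int d_max) {
  int d1 = (pb + Lb - pa) % M;
  if (d1 < 0) d1 += M;
  if (d1 == 0) d1 = M;
  int d2 = (pa + La - pb) % M;
  if (d2 < 0) d2 += M;
  if (d2 == 0) d2 = M;
  const bool ok1 = d1 >= d_min && d1 <= d_max;
  const bool ok2 = d2 >= d_min && d2 <= d_max;
  if (ok1 && ok2) return std::min(d1, d2);
  if (ok1) return d1;
  if (ok2) return d2;
  return -1;
}

// [[Rcpp::export]]
List cpp_classify_pairs(SEXP xp, CharacterVector r1, CharacterVector r2,
                        double max_mm_rate, int stride, int d_min, int d_max) {
  XPtr<SeedIndex> idx(xp);
  const int n = r1.size();
  if (r2.size() != n) stop("r1 and r2 must have equal length");
  LogicalVector is_mito(n);
  IntegerVector ins(n, NA_INTEGER);
  IntegerVector pos1(n, NA_INTEGER), str1(n, NA_INTEGER), mm1(n, NA_INTEGER);
  IntegerVector pos2(n, NA_INTEGER), str2(n, NA_INTEGER), mm2(n, NA_INTEGER);
  const int M = idx->M;

  for (int i = 0; i < n; ++i) {
    std::string s1 = as<std::string>(r1[i]), s2 = as<std::string>(r2[i]);
    const int L1 = static_cast<int>(s1.size()), L2 = static_cast<int>(s2.size());
    int cap1 = static_cast<int>(max_mm_rate * L1);
    int cap2 = static_cast<int>(max_mm_rate * L2);
    std::vector<Placement> p1 = map_both(*idx, s1, cap1, stride);
    if (p1.empty()) continue;
    std::vector<Placement> p2 = map_both(*idx, s2, cap2, stride);
    if (p2.empty()) continue;
    int best = -1, best_ins = NA_INTEGER;
    size_t bi = 0, bj = 0;
    for (size_t a = 0; a < p1.size(); ++a) {
      for (size_t b = 0; b < p2.size(); ++b) {
        if (p1[a].strand == p2[b].strand) continue;
        int d = (p1[a].strand == 0)
                    ? circ_insert(p1[a].pos, L1, p2[b].pos, L2, M, d_min, d_max)
                    : circ_insert(p2[b].pos, L2, p1[a].pos, L1, M, d_min, d_max);
        if (d < 0) continue;
        int tot = p1[a].mm + p2[b].mm;
        if (best < 0 || tot < best) {
          best = tot; best_ins = d; bi = a; bj = b;
        }
      }
    }
    if (best >= 0) {
      is_mito[i] = true;
      ins[i] = best_ins;
      pos1[i] = p1[bi].pos; str1[i] = p1[bi].strand; mm1[i] = p1[bi].mm;
      pos2[i] = p2[bj].pos; str2[i] = p2[bj].strand; mm2[i] = p2[bj].mm;
    }
  }
  return List::create(_["is_mito"] = is_mito, _["insert_size"] = ins,
                      _["pos1"] = pos1, _["strand1"] = str1, _["mm1"] = mm1,
                      _["pos2"] = pos2, _["strand2"] = str2, _["mm2"] = mm2);
}

// ---------------------------------------------------------------------------
// Anchor selection: map every read (both orientations) against the reference
// seed index and keep the best-matching read whose placement start lies
// inside the start window (begin_pos < 0), or whose placement end lies
// within `window` bases upstream of `begin_pos` on the circle (closing the
// traversal; begin_pos >= 0). "Best" = fewest mismatches, ties broken by
// earliest read in input order, forward orientation first, then by the
// placement closest to the window anchor.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_select_anchor(SEXP xp, CharacterVector reads, double tol_rate,
                       int stride, int window, int begin_pos) {
  XPtr<SeedIndex> idx(xp);
  const int M = idx->M;
  const bool at_end = begin_pos >= 0;
  int best_read = -1, best_mm = 0, best_orient = 0, best_pos = -1, best_d = 0;
  for (int i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    const int L = static_cast<int>(s.size());
    if (L < idx->k) continue;
    const int cap = static_cast<int>(tol_rate * L);
    std::vector<Placement> pl = map_both(*idx, s, cap, stride);
    for (const Placement& p : pl) {
      int d;
      if (!at_end) {
        if (p.pos >= window) continue;
        d = p.pos;
      } else {
        const int e = (p.pos + L) % M;
        d = (begin_pos - e) % M;
        if (d < 0) d += M;
        if (d >= window) continue;
      }
      bool better = false;
      if (best_read < 0 || p.mm < best_mm) {
        better = true;
      } else if (p.mm == best_mm && best_read == i) {
        if (p.strand < best_orient ||
            (p.strand == best_orient && d < best_d)) better = true;
      }
      if (better) {
        best_read = i; best_mm = p.mm; best_orient = p.strand;
        best_pos = p.pos; best_d = d;
      }
    }
  }
  return List::create(_["index"] = best_read + 1, _["orientation"] = best_orient,
                      _["position"] = best_pos, _["mismatches"] = best_mm);
}

// ---------------------------------------------------------------------------
// Guided greedy-overlap assembly.
//
// The read pool is reads plus their reverse complements; pool entry 2*i is
// reads[i] forward, 2*i + 1 its reverse complement, so "input order" ties
// resolve by read index first, forward orientation before reverse. Starting
// from the beginning anchor the contig is extended rightward; at each step
// the candidate with the longest overlap wins (ties: fewest overlap
// mismatches, then pool order). Candidates are generated by exact match of a
// read's first prefix_seed bases against the contig tail; the full overlap is
// then verified at <= max_mm_rate mismatches. The ending anchor is detected
// by direct error-tolerant alignment flush with the contig tail once the
// contig length enters [target_len - len_tol, target_len + len_tol]; the
// circle closes there. Assembly then continues for `overhang` extra bases so
// that reads spanning the origin contribute wrapped majority votes to the
// start of the consensus.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_assemble(CharacterVector reads, int begin_pool, int end_pool,
                  int min_overlap, double max_mm_rate, int max_length,
                  int target_len, int len_tol, int overhang) {
  const int n = reads.size();
  std::vector<std::string> pool(2 * static_cast<size_t>(n));
  int max_read_len = 0;
  for (int i = 0; i < n; ++i) {
    pool[2 * i] = upper_str(as<std::string>(reads[i]));
    pool[2 * i + 1] = revcomp_str(pool[2 * i]);
    max_read_len = std::max(max_read_len, static_cast<int>(pool[2 * i].size()));
  }
  const int prefix_seed = std::min(31, min_overlap);

  // index pool reads by their leading prefix_seed bases
  std::unordered_map<uint64_t, std::vector<int>> pref;
  for (size_t j = 0; j < pool.size(); ++j) {
    if (static_cast<int>(pool[j].size()) < min_overlap + 1) continue;  // cannot extend
    uint64_t key;
    if (encode_kmer(pool[j], 0, prefix_seed, key))
      pref[key].push_back(static_cast<int>(j));
  }

  std::string contig = pool[begin_pool];
  (void)end_pool;  // the ending anchor fixes target_len; closure is verified
                   // by head-tail self-alignment below
  std::vector<std::array<int, 4>> votes;
  votes.reserve(target_len + overhang + max_read_len);
  // After each incorporation the working contig is re-called from the
  // accumulated majority votes (ties alphabetical), so isolated sequencing
  // errors in individual reads wash out as vote depth builds and the exact
  // prefix-seed candidate lookup keeps finding extension reads.
  auto add_votes = [&](const std::string& s, int at) {
    if (static_cast<int>(votes.size()) < at + static_cast<int>(s.size()))
      votes.resize(at + s.size(), {0, 0, 0, 0});
    for (size_t i = 0; i < s.size(); ++i) {
      int c = base_code(s[i]);
      if (c >= 0) votes[at + i][c] += 1;
    }
    for (size_t i = 0; i < s.size(); ++i) {
      const std::array<int, 4>& v = votes[at + i];
      int bestc = 0;
      for (int c = 1; c < 4; ++c)
        if (v[c] > v[bestc]) bestc = c;
      if (v[bestc] > 0) contig[at + i] = "ACGT"[bestc];
    }
  };
  add_votes(contig, 0);
  int n_used = 1;

  // The circle is closed by self-alignment: once the contig is long enough
  // that a circle length near target_len would leave at least min_overlap
  // bases of tail, the tail is compared against the contig head; agreement
  // within the overlap mismatch tolerance fixes the circle length exactly.
  // Longer candidate circles are tried first; a chance agreement at
  // >= min_overlap bases is vanishingly unlikely on non-repetitive mtDNA.
  int circle_len = -1;
  auto check_close = [&]() {
    if (circle_len >= 0) return;
    const int clen = static_cast<int>(contig.size());
    const int mc_hi = std::min(clen - min_overlap, target_len + len_tol);
    const int mc_lo = std::max(min_overlap, target_len - len_tol);
    for (int mc = mc_hi; mc >= mc_lo; --mc) {
      const int ov = clen - mc;
      const int cap = static_cast<int>(max_mm_rate * ov);
      int mm = 0;
      bool ok = true;
      for (int j = 0; j < ov; ++j)
        if (contig[mc + j] != contig[j] && ++mm > cap) { ok = false; break; }
      if (ok) { circle_len = mc; return; }
    }
  };
  check_close();

  while (true) {
    const int clen = static_cast<int>(contig.size());
    if (circle_len >= 0 && clen >= circle_len + overhang) break;
    if (clen > max_length) {
      if (circle_len >= 0) break;  // junction closed; stop growing the overhang
      return List::create(_["status"] = "runaway", _["length"] = clen);
    }

    // scan anchor positions left to right = overlaps longest first
    int best_j = -1, best_mm = 0, best_p = -1;
    const int p_lo = std::max(0, clen - max_read_len + 1);
    const int p_hi = clen - min_overlap;
    for (int p = p_lo; p <= p_hi; ++p) {
      uint64_t key;
      if (!encode_kmer(contig, p, prefix_seed, key)) continue;
      auto it = pref.find(key);
      if (it == pref.end()) continue;
      const int o = clen - p;
      for (int j : it->second) {
        const std::string& s = pool[j];
        if (static_cast<int>(s.size()) <= o) continue;  // contained, no extension
        const int cap = static_cast<int>(max_mm_rate * o);
        int mm = 0;
        bool ok = true;
        for (int t = prefix_seed; t < o; ++t)
          if (s[t] != contig[p + t] && ++mm > cap) { ok = false; break; }
        if (!ok) continue;
        if (best_j < 0 || mm < best_mm || (mm == best_mm && j < best_j)) {
          best_j = j; best_mm = mm; best_p = p;
        }
      }
      if (best_j >= 0) break;  // longest valid overlap found
    }

    if (best_j < 0) {
      if (circle_len >= 0) break;  // stall past the junction is benign
      return List::create(_["status"] = "gap", _["stall"] = clen);
    }
    const std::string& s = pool[best_j];
    const int o = clen - best_p;
    contig.append(s, o, s.size() - o);
    add_votes(s, best_p);
    ++n_used;
    check_close();
  }

  if (circle_len < 0)
    return List::create(_["status"] = "gap", _["stall"] = static_cast<int>(contig.size()));

  // fold overhang votes back onto the circle and call the majority base
  const int M = circle_len;
  std::string seq(M, 'N');
  IntegerVector support(M);
  const int vlen = static_cast<int>(votes.size());
  for (int i = 0; i < M; ++i) {
    std::array<int, 4> v = votes[i];
    for (int q = i + M; q < vlen; q += M)
      for (int c = 0; c < 4; ++c) v[c] += votes[q][c];
    int tot = v[0] + v[1] + v[2] + v[3];
    int bestc = 0;
    for (int c = 1; c < 4; ++c)
      if (v[c] > v[bestc]) bestc = c;
    support[i] = tot;
    seq[i] = "ACGT"[bestc];
    if (tot == 0) seq[i] = 'N';
  }
  return List::create(_["status"] = "ok", _["sequence"] = seq,
                      _["support"] = support, _["length"] = M,
                      _["reads_used"] = n_used);
}

// ---------------------------------------------------------------------------
// Allele pileup over placed reads (forward-strand base counts).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_pileup(int M, CharacterVector reads, IntegerVector pos,
                         IntegerVector strand) {
  const int n = reads.size();
  if (pos.size() != n || strand.size() != n)
    stop("reads, pos and strand must have equal length");
  IntegerMatrix counts(4, M);
  for (int i = 0; i < n; ++i) {
    if (pos[i] == NA_INTEGER) continue;
    std::string s = upper_str(as<std::string>(reads[i]));
    if (strand[i] == 1) s = revcomp_str(s);
    int q = pos[i] % M;
    for (size_t j = 0; j < s.size(); ++j) {
      int c = base_code(s[j]);
      if (c >= 0) counts(c, q) += 1;
      if (++q == M) q = 0;
    }
  }
  rownames(counts) = CharacterVector::create("A", "C", "G", "T");
  return counts;
}
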