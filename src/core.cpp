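// Hot loops for the fixture-scale pipeline: k-mer seed index + ungapped
// seed-and-extend read mapping, maximal-exact-match anchor discovery, and the
// paired-end read simulator. Substitution-only alignment model throughout:
// junction logic, not basecaller realism, is the target.
#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <string>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline int base2code(char c) {
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
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

struct SeqIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  // k-mer code -> packed (target << 32 | pos)
  std::unordered_map<uint64_t, std::vector<uint64_t>> table;
};

// returns false if the window contains a non-ACGT character
static inline bool kmer_code(const std::string& s, size_t off, int k, uint64_t& code) {
  uint64_t c = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2code(s[off + i]);
    if (b < 0) return false;
    c = (c << 2) | (uint64_t)b;
  }
  code = c;
  return true;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs, int k) {
  if (k < 11 || k > 31) stop("k must be in [11, 31]");
  if (names.size() == 0) stop("empty sequence set");
  SeqIndex* idx = new SeqIndex();
  idx->k = k;
  for (R_xlen_t t = 0; t < names.size(); ++t) {
    idx->names.push_back(as<std::string>(names[t]));
    idx->seqs.push_back(as<std::string>(seqs[t]));
  }
  for (size_t t = 0; t < idx->seqs.size(); ++t) {
    const std::string& s = idx->seqs[t];
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + k <= s.size(); ++p) {
      uint64_t code;
      if (!kmer_code(s, p, k, code)) continue;
      idx->table[code].push_back(((uint64_t)t << 32) | (uint64_t)p);
    }
  }
  XPtr<SeqIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
int cpp_index_k(SEXP xp) { return XPtr<SeqIndex>(xp)->k; }

// [[Rcpp::export]]
CharacterVector cpp_index_names(SEXP xp) {
  XPtr<SeqIndex> idx(xp);
  return wrap(idx->names);
}

// [[Rcpp::export]]
IntegerVector cpp_index_lengths(SEXP xp) {
  XPtr<SeqIndex> idx(xp);
  IntegerVector out(idx->seqs.size());
  for (size_t i = 0; i < idx->seqs.size(); ++i) out[i] = (int)idx->seqs[i].size();
  return out;
}

// number of distinct indexed (target, position) entries
// [[Rcpp::export]]
double cpp_index_n_positions(SEXP xp) {
  XPtr<SeqIndex> idx(xp);
  double n = 0;
  for (auto& kv : idx->table) n += kv.second.size();
  return n;
}

// occurrence list of one k-mer (1-based target id and position), for tests
// [[Rcpp::export]]
DataFrame cpp_index_query(SEXP xp, std::string kmer) {
  XPtr<SeqIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("query length must equal k");
  uint64_t code;
  std::vector<int> tid, pos;
  if (kmer_code(kmer, 0, idx->k, code)) {
    auto it = idx->table.find(code);
    if (it != idx->table.end()) {
      for (uint64_t v : it->second) {
        tid.push_back((int)(v >> 32) + 1);
        pos.push_back((int)(v & 0xffffffffULL) + 1);
      }
    }
  }
  return DataFrame::create(_["target"] = tid, _["pos"] = pos);
}

struct Cand { int strand; int tid; long diag; int votes; };
struct Aln { int score = -1; int a = 0; int b = 0; int strand = 0; int tid = -1; long diag = 0; };

// best-scoring contiguous ungapped segment (match +1 / mismatch -3) of read s
// against target t along a fixed diagonal; 1-D local alignment
static Aln extend_on_diag(const std::string& s, const std::string& t, long diag) {
  Aln best;
  long imin = std::max<long>(0, -diag);
  long imax = std::min<long>((long)s.size(), (long)t.size() - diag);
  int cur = 0; long cura = imin;
  for (long i = imin; i < imax; ++i) {
    int sc = (s[i] == t[diag + i]) ? 1 : -3;
    if (cur <= 0) { cur = sc; cura = i; }
    else cur += sc;
    if (cur > best.score) { best.score = cur; best.a = (int)cura; best.b = (int)i + 1; }
  }
  // trim trailing mismatches (a max segment never ends on one, but be safe)
  return best;
}

// Map reads with seed-vote then ungapped extension. Returns one row per read:
// status 0 = unique, 1 = ambiguous, 2 = unmapped; pos/qstart/qend 0-based,
// qstart/qend delimit the aligned read interval in reference-forward
// orientation (soft clips are qstart and len - qend).
// [[Rcpp::export]]
DataFrame cpp_map_reads(SEXP xp, CharacterVector reads, int seed_step, int min_score) {
  XPtr<SeqIndex> idx(xp);
  const int k = idx->k;
  R_xlen_t n = reads.size();
  IntegerVector status(n), tid(n), pos(n), qstart(n), qend(n), score(n), score2(n);
  CharacterVector strand(n);

  std::unordered_map<uint64_t, int> votes;
  for (R_xlen_t r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int len = (int)fwd.size();
    status[r] = 2; tid[r] = NA_INTEGER; pos[r] = NA_INTEGER;
    qstart[r] = NA_INTEGER; qend[r] = NA_INTEGER; strand[r] = NA_STRING;
    score[r] = 0; score2[r] = 0;
    if (len < k) continue;
    std::string rev = revcomp(fwd);
    votes.clear();
    for (int st = 0; st < 2; ++st) {
      const std::string& s = (st == 0) ? fwd : rev;
      for (int off = 0;; off += seed_step) {
        if (off > len - k) { off = len - k; }
        uint64_t code;
        if (kmer_code(s, off, k, code)) {
          auto it = idx->table.find(code);
          if (it != idx->table.end() && it->second.size() <= 64) {
            for (uint64_t v : it->second) {
              int t = (int)(v >> 32);
              long p = (long)(v & 0xffffffffULL);
              long diag = p - off;
              // pack: strand(1) | tid(15) | diag+len (signed shift, 32)
              uint64_t key = ((uint64_t)st << 48) | ((uint64_t)t << 33) |
                             (uint64_t)(diag + (long)len);
              votes[key]++;
            }
          }
        }
        if (off == len - k) break;
      }
    }
    if (votes.empty()) continue;
    std::vector<std::pair<int, uint64_t>> cand;
    cand.reserve(votes.size());
    for (auto& kv : votes) cand.push_back({kv.second, kv.first});
    std::sort(cand.begin(), cand.end(),
              [](const std::pair<int, uint64_t>& a, const std::pair<int, uint64_t>& b) {
                return a.first > b.first || (a.first == b.first && a.second < b.second);
              });
    size_t ncand = std::min<size_t>(cand.size(), 8);
    Aln best, second;
    for (size_t c = 0; c < ncand; ++c) {
      uint64_t key = cand[c].second;
      int st = (int)(key >> 48);
      int t = (int)((key >> 33) & 0x7fff);
      long diag = (long)(key & 0xffffffffULL) - (long)len;
      const std::string& s = (st == 0) ? fwd : rev;
      Aln a = extend_on_diag(s, idx->seqs[t], diag);
      a.strand = st; a.tid = t; a.diag = diag;
      if (a.score > best.score) { second = best; best = a; }
      else if (a.score > second.score) { second = a; }
    }
    if (best.score < min_score) continue;
    score[r] = best.score;
    score2[r] = std::max(second.score, 0);
    bool tie = (second.score == best.score) &&
               (second.tid != best.tid || second.diag != best.diag || second.strand != best.strand);
    tid[r] = best.tid + 1;
    pos[r] = (int)(best.diag + best.a);
    qstart[r] = best.a;
    qend[r] = best.b;
    strand[r] = (best.strand == 0) ? "+" : "-";
    status[r] = tie ? 1 : 0;
  }
  return DataFrame::create(_["status"] = status, _["tid"] = tid, _["pos"] = pos,
                           _["strand"] = strand, _["qstart"] = qstart, _["qend"] = qend,
                           _["score"] = score, _["score2"] = score2,
                           _["stringsAsFactors"] = false);
}

// Maximal exact matches >= min_len between contig and target, one strand.
static void mems_one_strand(const std::string& q, const std::string& t, int min_len,
                            std::vector<int>& cs, std::vector<int>& ce,
                            std::vector<int>& ts, std::vector<int>& te) {
  int k0 = std::min(min_len, 31);
  if (k0 < 11) k0 = std::min(min_len, 11);
  if ((int)q.size() < k0 || (int)t.size() < k0) return;
  std::unordered_map<uint64_t, std::vector<int>> th;
  for (size_t p = 0; p + k0 <= t.size(); ++p) {
    uint64_t code;
    if (kmer_code(t, p, k0, code)) th[code].push_back((int)p);
  }
  // diag -> sorted contig seed positions
  std::unordered_map<long, std::vector<int>> diags;
  for (size_t p = 0; p + k0 <= q.size(); ++p) {
    uint64_t code;
    if (!kmer_code(q, p, k0, code)) continue;
    auto it = th.find(code);
    if (it == th.end()) continue;
    for (int tp : it->second) diags[(long)tp - (long)p].push_back((int)p);
  }
  for (auto& kv : diags) {
    long d = kv.first;
    std::vector<int>& ps = kv.second;
    std::sort(ps.begin(), ps.end());
    size_t i = 0;
    while (i < ps.size()) {
      int runs = ps[i], rune = ps[i] + k0;
      size_t j = i + 1;
      while (j < ps.size() && ps[j] <= rune) { rune = ps[j] + k0; ++j; }
      // extend maximally
      int a = runs, b = rune;
      while (a > 0 && d + a > 0 && q[a - 1] == t[d + a - 1]) --a;
      while (b < (int)q.size() && d + b < (long)t.size() && q[b] == t[d + b]) ++b;
      // skip any later runs swallowed by the extension
      while (j < ps.size() && ps[j] < b) ++j;
      if (b - a >= min_len) {
        cs.push_back(a); ce.push_back(b);
        ts.push_back((int)(d + a)); te.push_back((int)(d + b));
      }
      i = j;
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_find_mems(std::string contig, std::string target, int min_len) {
  std::vector<int> cs, ce, ts, te;
  std::vector<std::string> strand;
  mems_one_strand(contig, target, min_len, cs, ce, ts, te);
  size_t nf = cs.size();
  for (size_t i = 0; i < nf; ++i) strand.push_back("+");
  std::string rc = revcomp(contig);
  std::vector<int> rcs, rce, rts, rte;
  mems_one_strand(rc, target, min_len, rcs, rce, rts, rte);
  int L = (int)contig.size();
  for (size_t i = 0; i < rcs.size(); ++i) {
    cs.push_back(L - rce[i]); ce.push_back(L - rcs[i]);
    ts.push_back(rts[i]); te.push_back(rte[i]);
    strand.push_back("-");
  }
  IntegerVector len(cs.size());
  for (size_t i = 0; i < cs.size(); ++i) len[i] = ce[i] - cs[i];
  return DataFrame::create(_["cstart"] = wrap(cs), _["cend"] = wrap(ce),
                           _["tstart"] = wrap(ts), _["tend"] = wrap(te),
                           _["len"] = len, _["strand"] = wrap(strand),
                           _["stringsAsFactors"] = false);
}

// Paired-end simulator: fragment starts uniform over the genome, truncated
// normal insert (min = read length), inward mate orientation, independent
// per-base substitution errors. Deterministic for a fixed seed.
// [[Rcpp::export]]
List cpp_simulate_reads(CharacterVector seqs, int read_len, double insert_mean,
                        double insert_sd, double n_pairs, double err, double seed) {
  size_t nt = seqs.size();
  std::vector<std::string> ss(nt);
  std::vector<double> cum(nt + 1, 0.0);
  for (size_t t = 0; t < nt; ++t) {
    ss[t] = as<std::string>(seqs[t]);
    cum[t + 1] = cum[t] + (double)ss[t].size();
  }
  double total = cum[nt];
  long np = (long)n_pairs;
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::normal_distribution<double> norm(insert_mean, insert_sd);
  CharacterVector r1(np), r2(np);
  IntegerVector t_id(np), f_start(np), f_len(np);
  const char bases[4] = {'A', 'C', 'G', 'T'};
  for (long i = 0; i < np; ++i) {
    int tries = 0;
    for (;;) {
      if (++tries > 1000) stop("cannot place fragment: targets shorter than insert?");
      double u = unif(rng) * total;
      size_t t = (size_t)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin()) - 1;
      if (t >= nt) t = nt - 1;
      long start = (long)(u - cum[t]);
      long ins = (long)std::llround(norm(rng));
      if (ins < read_len) ins = read_len;
      if (start + ins > (long)ss[t].size()) continue;
      std::string frag = ss[t].substr(start, ins);
      std::string a = frag.substr(0, read_len);
      std::string b = revcomp(frag.substr(ins - read_len, read_len));
      if (err > 0) {
        for (auto* rd : {&a, &b}) {
          for (auto& c : *rd) {
            if (unif(rng) < err) {
              char nb = bases[(int)(unif(rng) * 4) & 3];
              while (nb == c) nb = bases[(int)(unif(rng) * 4) & 3];
              c = nb;
            }
          }
        }
      }
      r1[i] = a; r2[i] = b;
      t_id[i] = (int)t + 1; f_start[i] = (int)start; f_len[i] = (int)ins;
      break;
    }
  }
  return List::create(_["r1"] = r1, _["r2"] = r2, _["t_id"] = t_id,
                      _["f_start"] = f_start, _["f_len"] = f_len);
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }

// random nucleotide string with given GC fraction, deterministic per seed
// [[Rcpp::export]]
std::string cpp_random_seq(double len, double gc, double seed) {
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::string s((size_t)len, 'A');
  for (auto& c : s) {
    if (unif(rng) < gc) c = (unif(rng) < 0.5) ? 'G' : 'C';
    else c = (unif(rng) < 0.5) ? 'A' : 'T';
  }
  return s;
}
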