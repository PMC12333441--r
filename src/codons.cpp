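#include <Rcpp.h>
using namespace Rcpp;

// DNA utilities shared by the codon generator and the decoder. Sequences are
// plain std::string over {A,C,G,T}; all predicates assume validated input
// (the R wrappers check the alphabet).

static inline char complement_base(char b) {
  switch (b) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
  }
  return 'N';
}

static inline int hamming_impl(const std::string& a, const std::string& b) {
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) if (a[i] != b[i]) ++d;
  return d;
}

// [[Rcpp::export]]
IntegerVector cpp_hamming_pairs(CharacterVector a, CharacterVector b) {
  if (a.size() != b.size()) stop("a and b must have the same length");
  IntegerVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    std::string sa = as<std::string>(a[i]), sb = as<std::string>(b[i]);
    if (sa.size() != sb.size()) stop("sequence length mismatch at element %d", (int)(i + 1));
    out[i] = hamming_impl(sa, sb);
  }
  return out;
}

// Hamming distance of every string in x to the single reference string.
// [[Rcpp::export]]
IntegerVector cpp_hamming_to_ref(CharacterVector x, std::string ref) {
  IntegerVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    if (s.size() != ref.size()) stop("sequence length mismatch at element %d", (int)(i + 1));
    out[i] = hamming_impl(s, ref);
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_hamming_matrix(CharacterVector x, CharacterVector y) {
  std::vector<std::string> xs(x.size()), ys(y.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) xs[i] = as<std::string>(x[i]);
  for (R_xlen_t j = 0; j < y.size(); ++j) ys[j] = as<std::string>(y[j]);
  IntegerMatrix out(x.size(), y.size());
  for (size_t i = 0; i < xs.size(); ++i)
    for (size_t j = 0; j < ys.size(); ++j) {
      if (xs[i].size() != ys[j].size()) stop("sequence length mismatch");
      out(i, j) = hamming_impl(xs[i], ys[j]);
    }
  return out;
}

// [[Rcpp::export]]
int cpp_min_pairwise_distance(CharacterVector x) {
  if (x.size() < 2) stop("need at least two sequences");
  std::vector<std::string> xs(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) xs[i] = as<std::string>(x[i]);
  int best = (int)xs[0].size() + 1;
  for (size_t i = 0; i + 1 < xs.size(); ++i)
    for (size_t j = i + 1; j < xs.size(); ++j) {
      int d = hamming_impl(xs[i], xs[j]);
      if (d < best) best = d;
    }
  return best;
}

// Intramolecular hairpin: stem s1 = seq[i, i+k), s2 = seq[j, j+k) with
// k >= min_stem, j >= i + k + min_loop and s2 == revcomp(s1). Checking only
// k == min_stem suffices: any longer stem contains a min_stem one.
static bool hairpin_impl(const std::string& s, int min_stem, int min_loop) {
  int n = (int)s.size(), k = min_stem;
  if (n < 2 * k + min_loop) return false;
  for (int i = 0; i + k <= n; ++i) {
    for (int j = i + k + min_loop; j + k <= n; ++j) {
      bool ok = true;
      for (int t = 0; t < k; ++t) {
        if (s[j + t] != complement_base(s[i + k - 1 - t])) { ok = false; break; }
      }
      if (ok) return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
LogicalVector cpp_has_hairpin(CharacterVector seqs, int min_stem, int min_loop) {
  LogicalVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = hairpin_impl(as<std::string>(seqs[i]), min_stem, min_loop);
  return out;
}

static bool palindrome_impl(const std::string& s) {
  int n = (int)s.size();
  if (n % 2 != 0) return false;
  for (int i = 0; i < n; ++i)
    if (s[n - 1 - i] != complement_base(s[i])) return false;
  return true;
}

static inline std::string index_to_seq(long long idx, int L) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string s(L, 'A');
  long long rem = idx;
  for (int p = L - 1; p >= 0; --p) {
    s[p] = bases[rem & 3];
    rem >>= 2;
  }
  return s;
}

static bool passes_filters(const std::string& s, double gc_min, double gc_max,
                           int max_homopolymer, int min_stem, int min_loop) {
  int L = (int)s.size();
  int gc = 0, run = 1, maxrun = 1;
  for (int i = 0; i < L; ++i) {
    if (s[i] == 'G' || s[i] == 'C') ++gc;
    if (i > 0) {
      run = (s[i] == s[i - 1]) ? run + 1 : 1;
      if (run > maxrun) maxrun = run;
    }
  }
  double frac = (double)gc / L;
  if (frac < gc_min - 1e-9 || frac > gc_max + 1e-9) return false;
  if (maxrun > max_homopolymer) return false;
  if (palindrome_impl(s)) return false;
  if (hairpin_impl(s, min_stem, min_loop)) return false;
  return true;
}

// Greedy lexicode accretion. `order` is an optional 1-based permutation of
// candidate indices (seeded shuffle); when NULL candidates are scanned in
// lexicographic order 0 .. 4^L - 1. `seed_codons` are codons from other
// cycles: candidates must keep distance >= seed_min_distance from them
// (1 = merely distinct, min_distance = full cross-cycle separation) but the
// seeds are not returned.
// [[Rcpp::export]]
CharacterVector cpp_generate_codons(int L, int min_distance, double gc_min, double gc_max,
                                    int max_homopolymer, int min_stem, int min_loop,
                                    int n_required, Nullable<NumericVector> order,
                                    CharacterVector seed_codons, int seed_min_distance) {
  long long total = 1LL << (2 * L);
  std::vector<std::string> seeds(seed_codons.size());
  for (R_xlen_t i = 0; i < seed_codons.size(); ++i) seeds[i] = as<std::string>(seed_codons[i]);
  std::vector<std::string> accepted;
  accepted.reserve(n_required);

  NumericVector ord;
  bool shuffled = order.isNotNull();
  if (shuffled) ord = order.get();
  long long n_candidates = shuffled ? (long long)ord.size() : total;

  for (long long c = 0; c < n_candidates; ++c) {
    if (c % 1048576 == 0) Rcpp::checkUserInterrupt();
    long long idx = shuffled ? (long long)ord[(R_xlen_t)c] - 1 : c;
    std::string s = index_to_seq(idx, L);
    if (!passes_filters(s, gc_min, gc_max, max_homopolymer, min_stem, min_loop)) continue;
    bool ok = true;
    for (size_t a = 0; a < accepted.size(); ++a)
      if (hamming_impl(s, accepted[a]) < min_distance) { ok = false; break; }
    if (ok)
      for (size_t a = 0; a < seeds.size(); ++a)
        if (hamming_impl(s, seeds[a]) < seed_min_distance) { ok = false; break; }
    if (!ok) continue;
    accepted.push_back(s);
    if ((int)accepted.size() == n_required) break;
  }
  return wrap(accepted);
}
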