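// Dynamic-programming alignment kernels: global and free-end-gap pairwise
// alignment under unit edit costs, and approximate motif (tag/primer) search
// with optional IUPAC-degenerate matching of motif letters.
//
// All coordinates returned to R are 0-based, half-open.

#include <Rcpp.h>
#include <string>
#include <vector>
#include <climits>

using namespace Rcpp;

// IUPAC nucleotide bitmask: A=1, C=2, G=4, T/U=8.
static inline int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;
    case 'T': case 'U': return 8;
    case 'R': return 1 | 4;      case 'Y': return 2 | 8;
    case 'S': return 2 | 4;      case 'W': return 1 | 8;
    case 'K': return 4 | 8;      case 'M': return 1 | 2;
    case 'B': return 2 | 4 | 8;  case 'D': return 1 | 4 | 8;
    case 'H': return 1 | 2 | 8;  case 'V': return 1 | 2 | 4;
    case 'N': return 15;
    default:  return 0;
  }
}

// Per-cell state; propagated so no traceback pass is needed.
struct Cell {
  int cost;     // edits (substitutions + indels) inside the aligned region
  int matches;  // match columns inside the aligned region
  int cols;     // alignment columns inside the aligned region
  int si, sj;   // 0-based start of the aligned region in a and b
};

// Candidate comparison. Evaluation order diag > up (gap in b, consumes a)
// > left (gap in a, consumes b) supplies the traceback tie preference:
// a later candidate replaces the incumbent only when strictly better.
static inline bool better_global(const Cell& cand, const Cell& cur) {
  if (cand.cost != cur.cost) return cand.cost < cur.cost;
  return cand.matches > cur.matches;
}
static inline bool better_free(const Cell& cand, const Cell& cur) {
  int sc = cand.matches - cand.cost, su = cur.matches - cur.cost;
  if (sc != su) return sc > su;
  return cand.cost < cur.cost;
}

// Pairwise alignment of a (rows) vs b (columns).
static Cell align_pair(const std::string& a, const std::string& b,
                       bool free_ends, int* end_i = nullptr,
                       int* end_j = nullptr) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<Cell> dp((size_t)(n + 1) * (m + 1));
  auto at = [&](int i, int j) -> Cell& { return dp[(size_t)i * (m + 1) + j]; };

  for (int j = 0; j <= m; ++j)
    at(0, j) = free_ends ? Cell{0, 0, 0, 0, j} : Cell{j, 0, j, 0, 0};
  for (int i = 1; i <= n; ++i)
    at(i, 0) = free_ends ? Cell{0, 0, 0, i, 0} : Cell{i, 0, i, 0, 0};

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      bool hit = (a[(size_t)i - 1] == b[(size_t)j - 1]);
      const Cell& d = at(i - 1, j - 1);
      Cell best{d.cost + (hit ? 0 : 1), d.matches + (hit ? 1 : 0),
                d.cols + 1, d.si, d.sj};
      const Cell& u = at(i - 1, j);
      Cell cu{u.cost + 1, u.matches, u.cols + 1, u.si, u.sj};
      if (free_ends ? better_free(cu, best) : better_global(cu, best))
        best = cu;
      const Cell& l = at(i, j - 1);
      Cell cl{l.cost + 1, l.matches, l.cols + 1, l.si, l.sj};
      if (free_ends ? better_free(cl, best) : better_global(cl, best))
        best = cl;
      at(i, j) = best;
    }
  }

  int bi = n, bj = m;
  if (free_ends) {
    // End anywhere on the last row or last column (trailing gaps free).
    // Tie preference: larger i+j, then larger i — favours the longer overlap.
    Cell best = at(n, 0); bi = n; bj = 0;
    auto consider = [&](int i, int j) {
      const Cell& c = at(i, j);
      if (better_free(c, best) ||
          (!better_free(best, c) &&
           (i + j > bi + bj || (i + j == bi + bj && i > bi)))) {
        best = c; bi = i; bj = j;
      }
    };
    for (int j = 0; j <= m; ++j) consider(n, j);
    for (int i = 0; i <= n; ++i) consider(i, m);
  }
  if (end_i) *end_i = bi;
  if (end_j) *end_j = bj;
  return at(bi, bj);
}

// [[Rcpp::export]]
List cpp_align(std::string a, std::string b, bool free_end_gaps) {
  int ei, ej;
  Cell c = align_pair(a, b, free_end_gaps, &ei, &ej);
  return List::create(
      _["edits"] = c.cost, _["matches"] = c.matches, _["columns"] = c.cols,
      _["span_a"] = IntegerVector::create(c.si, ei),
      _["span_b"] = IntegerVector::create(c.sj, ej));
}

// Identity / coverage for one (already canonically ordered) pair:
// a is the longer sequence, b the shorter.
static void sim_pair(const std::string& a, const std::string& b,
                     double* identity, double* coverage) {
  int ei, ej;
  Cell c = align_pair(a, b, true, &ei, &ej);
  *identity = (c.cols > 0) ? (double)c.matches / c.cols : 0.0;
  *coverage = (b.size() > 0) ? (double)(ej - c.sj) / b.size() : 0.0;
}

// [[Rcpp::export]]
List cpp_similarity(std::string a, std::string b) {
  double id, cov;
  sim_pair(a, b, &id, &cov);
  return List::create(_["identity"] = id, _["coverage"] = cov);
}

// All-pairs identity/coverage. Pair order is canonicalised (longer first,
// ties broken lexicographically) inside, so the matrices are exactly
// symmetric regardless of input order.
// [[Rcpp::export]]
List cpp_similarity_matrix(CharacterVector seqs) {
  const int n = seqs.size();
  NumericMatrix identity(n, n), coverage(n, n);
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    identity(i, i) = 1.0;
    coverage(i, i) = 1.0;
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const std::string *x = &s[i], *y = &s[j];
      if (y->size() > x->size() ||
          (y->size() == x->size() && *y < *x))
        std::swap(x, y);
      double id, cov;
      sim_pair(*x, *y, &id, &cov);
      identity(i, j) = identity(j, i) = id;
      coverage(i, j) = coverage(j, i) = cov;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["identity"] = identity, _["coverage"] = coverage);
}

// Approximate motif search: the pattern must be fully aligned inside the
// text; text ends are free (unanchored) or the start is pinned to text
// position 0 (anchored). Returns the best hit as (edits, start, end);
// the caller applies the max_edits cut-off. Tie rule: fewest edits, then
// smallest start, then smallest end.
// [[Rcpp::export]]
List cpp_find_motif(std::string text, std::string pattern, bool anchored,
                    bool degenerate) {
  const int n = (int)text.size(), m = (int)pattern.size();
  const int INF = n + m + 10;
  // rows = pattern prefix length, cols = text position
  std::vector<int> cost((size_t)(m + 1) * (n + 1));
  std::vector<int> start((size_t)(m + 1) * (n + 1));
  auto C = [&](int i, int j) -> int& { return cost[(size_t)i * (n + 1) + j]; };
  auto S = [&](int i, int j) -> int& { return start[(size_t)i * (n + 1) + j]; };

  std::vector<int> tmask(n), pmask(m);
  for (int j = 0; j < n; ++j) tmask[j] = iupac_mask(text[(size_t)j]);
  for (int i = 0; i < m; ++i) pmask[i] = iupac_mask(pattern[(size_t)i]);

  for (int j = 0; j <= n; ++j) {
    C(0, j) = (anchored && j > 0) ? INF : 0;
    S(0, j) = j;
  }
  for (int i = 1; i <= m; ++i) { C(i, 0) = i; S(i, 0) = 0; }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      bool hit = degenerate ? ((tmask[(size_t)j - 1] & pmask[(size_t)i - 1]) != 0)
                            : (text[(size_t)j - 1] == pattern[(size_t)i - 1]);
      int c = C(i - 1, j - 1) + (hit ? 0 : 1);  // diag
      int st = S(i - 1, j - 1);
      int cu = C(i - 1, j) + 1;                  // consume pattern (gap in text)
      if (cu < c || (cu == c && S(i - 1, j) < st)) { c = cu; st = S(i - 1, j); }
      int cl = C(i, j - 1) + 1;                  // consume text (gap in pattern)
      if (cl < c || (cl == c && S(i, j - 1) < st)) { c = cl; st = S(i, j - 1); }
      C(i, j) = c; S(i, j) = st;
    }
  }

  int be = -1, bc = INF, bs = 0;
  for (int j = 0; j <= n; ++j) {
    int c = C(m, j), st = S(m, j);
    if (c < bc || (c == bc && (st < bs || (st == bs && j < be)))) {
      bc = c; bs = st; be = j;
    }
  }
  if (bc >= INF)
    return List::create(_["edits"] = NA_INTEGER, _["start"] = NA_INTEGER,
                        _["end"] = NA_INTEGER);
  return List::create(_["edits"] = bc, _["start"] = bs, _["end"] = be);
}
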