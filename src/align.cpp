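#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap alignment kernels for short nucleotide sequences.
// Convention: a gap of length L costs gap_open + L * gap_extend (both
// negative), i.e. opening the first gapped position already pays both
// penalties. 'N' matches nothing: scoring any column involving N uses the
// mismatch score.

static const double NEG_INF = -1e30;

static inline double subst(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

// Forward, linear-memory local DP: returns best score and its end cell
// (1-based positions in s1/s2). Ties resolved toward the smallest (i, j)
// so results are deterministic.
static void sw_forward(const std::string& s1, const std::string& s2,
                       double match, double mismatch,
                       double gap_open, double gap_extend,
                       double& best, int& bi, int& bj) {
  const int m = s1.size(), n = s2.size();
  std::vector<double> H(n + 1, 0.0), E(n + 1, NEG_INF);
  best = 0.0; bi = 0; bj = 0;
  for (int i = 1; i <= m; ++i) {
    double diag = 0.0;      // H[i-1][j-1]
    double F = NEG_INF;     // gap in s2 (vertical) for current row
    H[0] = 0.0;
    for (int j = 1; j <= n; ++j) {
      E[j] = std::max(E[j] + gap_extend, H[j] + gap_open + gap_extend);
      F    = std::max(F    + gap_extend, H[j - 1] + gap_open + gap_extend);
      double h = diag + subst(s1[i - 1], s2[j - 1], match, mismatch);
      h = std::max(h, std::max(E[j], F));
      h = std::max(h, 0.0);
      diag = H[j];
      H[j] = h;
      if (h > best + 1e-12) { best = h; bi = i; bj = j; }
    }
  }
}

// Full-matrix local DP with traceback over a (small) rectangle.
// Returns score, 1-based alignment interval within the rectangle, and
// column statistics. Rectangle corners are passed by the caller.
struct AlnStats {
  double score;
  int q_start, q_end, s_start, s_end;  // 1-based, inclusive, in full seqs
  int length, n_ident, n_gap;
};

static AlnStats sw_traceback(const std::string& s1, const std::string& s2,
                             int i0, int i1, int j0, int j1,
                             double match, double mismatch,
                             double gap_open, double gap_extend) {
  // operate on s1[i0-1 .. i1-1], s2[j0-1 .. j1-1]
  const int m = i1 - i0 + 1, n = j1 - j0 + 1;
  std::vector<double> H((m + 1) * (n + 1), 0.0),
      E((m + 1) * (n + 1), NEG_INF), F((m + 1) * (n + 1), NEG_INF);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double e = std::max(E[at(i, j - 1)] + gap_extend,
                          H[at(i, j - 1)] + gap_open + gap_extend);
      double f = std::max(F[at(i - 1, j)] + gap_extend,
                          H[at(i - 1, j)] + gap_open + gap_extend);
      double d = H[at(i - 1, j - 1)] +
        subst(s1[i0 - 1 + i - 1], s2[j0 - 1 + j - 1], match, mismatch);
      double h = std::max(0.0, std::max(d, std::max(e, f)));
      E[at(i, j)] = e; F[at(i, j)] = f; H[at(i, j)] = h;
      if (h > best + 1e-12) { best = h; bi = i; bj = j; }
    }
  }
  AlnStats st; st.score = best;
  st.length = 0; st.n_ident = 0; st.n_gap = 0;
  if (best <= 0.0) {
    st.q_start = st.q_end = st.s_start = st.s_end = 0;
    return st;
  }
  // traceback from (bi, bj) in state H until H == 0
  int i = bi, j = bj; char state = 'H';
  int qe = i0 + bi - 1, se = j0 + bj - 1;
  int qs = qe, ss = se;
  while (i > 0 && j > 0) {
    if (state == 'H') {
      double h = H[at(i, j)];
      if (h <= 0.0) break;
      double d = H[at(i - 1, j - 1)] +
        subst(s1[i0 - 1 + i - 1], s2[j0 - 1 + j - 1], match, mismatch);
      if (std::abs(h - d) < 1e-9) {
        st.length++;
        if (s1[i0 - 1 + i - 1] == s2[j0 - 1 + j - 1] &&
            s1[i0 - 1 + i - 1] != 'N') st.n_ident++;
        qs = i0 + i - 2 + 1; ss = j0 + j - 2 + 1;
        --i; --j;
      } else if (std::abs(h - E[at(i, j)]) < 1e-9) {
        state = 'E';
      } else {
        state = 'F';
      }
    } else if (state == 'E') {  // gap in s1, consumes s2[j]
      st.length++; st.n_gap++;
      ss = j0 + j - 2 + 1;
      double e = E[at(i, j)];
      bool open = std::abs(e - (H[at(i, j - 1)] + gap_open + gap_extend)) < 1e-9;
      --j;
      state = open ? 'H' : 'E';
    } else {  // 'F': gap in s2, consumes s1[i]
      st.length++; st.n_gap++;
      qs = i0 + i - 2 + 1;
      double f = F[at(i, j)];
      bool open = std::abs(f - (H[at(i - 1, j)] + gap_open + gap_extend)) < 1e-9;
      --i;
      state = open ? 'H' : 'F';
    }
  }
  st.q_start = qs; st.q_end = qe; st.s_start = ss; st.s_end = se;
  return st;
}

// [[Rcpp::export(name = ".sw_align")]]
List sw_align_cpp(std::string s1, std::string s2,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  if (s1.empty() || s2.empty()) {
    return List::create(_["score"] = 0.0, _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0, _["length"] = 0,
                        _["n_ident"] = 0, _["n_gap"] = 0);
  }
  double best; int bi, bj;
  sw_forward(s1, s2, match, mismatch, gap_open, gap_extend, best, bi, bj);
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0, _["length"] = 0,
                        _["n_ident"] = 0, _["n_gap"] = 0);
  }
  // locate the start by running the same DP on the reversed prefixes ending
  // at (bi, bj); then trace back inside the (small) bounded rectangle.
  std::string r1(s1.rbegin() + (s1.size() - bi), s1.rend());
  std::string r2(s2.rbegin() + (s2.size() - bj), s2.rend());
  double rbest; int ri, rj;
  sw_forward(r1, r2, match, mismatch, gap_open, gap_extend, rbest, ri, rj);
  int i0 = bi - ri + 1, j0 = bj - rj + 1;
  AlnStats st = sw_traceback(s1, s2, i0, bi, j0, bj,
                             match, mismatch, gap_open, gap_extend);
  return List::create(_["score"] = st.score,
                      _["q_start"] = st.q_start, _["q_end"] = st.q_end,
                      _["s_start"] = st.s_start, _["s_end"] = st.s_end,
                      _["length"] = st.length, _["n_ident"] = st.n_ident,
                      _["n_gap"] = st.n_gap);
}

// Score-only local alignment (used for E-value calibration).
// [[Rcpp::export(name = ".sw_score")]]
double sw_score_cpp(std::string s1, std::string s2,
                    double match, double mismatch,
                    double gap_open, double gap_extend) {
  if (s1.empty() || s2.empty()) return 0.0;
  double best; int bi, bj;
  sw_forward(s1, s2, match, mismatch, gap_open, gap_extend, best, bi, bj);
  return best;
}

// Global (Needleman-Wunsch) alignment with affine gaps; end gaps are
// penalized. Returns score plus per-column statistics needed for the
// uncorrected distance: columns where both sequences have a residue,
// and how many of those mismatch.
// [[Rcpp::export(name = ".nw_align")]]
List nw_align_cpp(std::string s1, std::string s2,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int m = s1.size(), n = s2.size();
  std::vector<double> H((m + 1) * (n + 1), NEG_INF),
      E((m + 1) * (n + 1), NEG_INF), F((m + 1) * (n + 1), NEG_INF);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  H[at(0, 0)] = 0.0;
  for (int j = 1; j <= n; ++j) {
    E[at(0, j)] = gap_open + gap_extend * j;
    H[at(0, j)] = E[at(0, j)];
  }
  for (int i = 1; i <= m; ++i) {
    F[at(i, 0)] = gap_open + gap_extend * i;
    H[at(i, 0)] = F[at(i, 0)];
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double e = std::max(E[at(i, j - 1)] + gap_extend,
                          H[at(i, j - 1)] + gap_open + gap_extend);
      double f = std::max(F[at(i - 1, j)] + gap_extend,
                          H[at(i - 1, j)] + gap_open + gap_extend);
      double d = H[at(i - 1, j - 1)] +
        subst(s1[i - 1], s2[j - 1], match, mismatch);
      E[at(i, j)] = e; F[at(i, j)] = f;
      H[at(i, j)] = std::max(d, std::max(e, f));
    }
  }
  // traceback
  int i = m, j = n; char state = 'H';
  int aligned = 0, mismatches = 0, length = 0;
  while (i > 0 || j > 0) {
    if (i == 0) { --j; ++length; continue; }
    if (j == 0) { --i; ++length; continue; }
    if (state == 'H') {
      double h = H[at(i, j)];
      double d = H[at(i - 1, j - 1)] + subst(s1[i - 1], s2[j - 1], match, mismatch);
      if (std::abs(h - d) < 1e-9) {
        ++length; ++aligned;
        // N columns count as mismatches: N matches nothing
        if (s1[i - 1] != s2[j - 1] || s1[i - 1] == 'N' || s2[j - 1] == 'N')
          ++mismatches;
        --i; --j;
      } else if (std::abs(h - E[at(i, j)]) < 1e-9) {
        state = 'E';
      } else {
        state = 'F';
      }
    } else if (state == 'E') {
      ++length;
      double e = E[at(i, j)];
      bool open = std::abs(e - (H[at(i, j - 1)] + gap_open + gap_extend)) < 1e-9;
      --j;
      state = open ? 'H' : 'E';
    } else {
      ++length;
      double f = F[at(i, j)];
      bool open = std::abs(f - (H[at(i - 1, j)] + gap_open + gap_extend)) < 1e-9;
      --i;
      state = open ? 'H' : 'F';
    }
  }
  return List::create(_["score"] = H[at(m, n)], _["length"] = length,
                      _["aligned"] = aligned, _["mismatches"] = mismatches);
}
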