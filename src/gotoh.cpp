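// Three-state affine-gap pairwise alignment (Gotoh) with deterministic
// traceback. States: M = residue pair, X = gap in s2 (consumes s1),
// Y = gap in s1 (consumes s2). A gap of length L costs gop + (L-1)*gep.
// Tie-break preference everywhere: M > X > Y (and, in local mode,
// continuing an alignment over restarting), applied from the end of the
// traceback, so results are bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".gotoh_align_cpp")]]
List gotoh_align_cpp(IntegerVector s1, IntegerVector s2,
                     NumericMatrix score, double gop, double gep,
                     bool local, bool free_end_gaps) {
  const int n = s1.size(), m = s2.size();
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // predecessor state codes: 0 = M, 1 = X, 2 = Y, 3 = fresh start (local)
  std::vector<unsigned char> pM((n + 1) * W, 0), pX((n + 1) * W, 0),
      pY((n + 1) * W, 0);

#define AT(A, i, j) A[(size_t)(i) * W + (j)]

  AT(M, 0, 0) = 0.0;
  // local alignments start through the explicit fresh-start option, so the
  // boundaries stay at -Inf in local mode
  if (!local) {
    for (int i = 1; i <= n; ++i) {
      AT(X, i, 0) = free_end_gaps ? 0.0 : -(gop + (i - 1) * gep);
      AT(pX, i, 0) = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= m; ++j) {
      AT(Y, 0, j) = free_end_gaps ? 0.0 : -(gop + (j - 1) * gep);
      AT(pY, 0, j) = (j == 1) ? 0 : 2;
    }
  }

  double best = 0.0;
  int best_i = 0, best_j = 0, best_st = 0;
  bool have_best = false;

  for (int i = 1; i <= n; ++i) {
    const int a = s1[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      const int b = s2[j - 1] - 1;
      const double s = score(a, b);

      // M state
      {
        double val = AT(M, i - 1, j - 1);
        unsigned char st = 0;
        if (AT(X, i - 1, j - 1) > val) { val = AT(X, i - 1, j - 1); st = 1; }
        if (AT(Y, i - 1, j - 1) > val) { val = AT(Y, i - 1, j - 1); st = 2; }
        if (local && 0.0 > val) { val = 0.0; st = 3; }
        AT(M, i, j) = (val == NEG_INF) ? NEG_INF : s + val;
        AT(pM, i, j) = st;
      }
      // X state: gap in s2, consumes s1[i]
      {
        double val = (AT(M, i - 1, j) == NEG_INF) ? NEG_INF
                                                  : AT(M, i - 1, j) - gop;
        unsigned char st = 0;
        if (AT(X, i - 1, j) != NEG_INF && AT(X, i - 1, j) - gep > val) {
          val = AT(X, i - 1, j) - gep; st = 1;
        }
        if (AT(Y, i - 1, j) != NEG_INF && AT(Y, i - 1, j) - gop > val) {
          val = AT(Y, i - 1, j) - gop; st = 2;
        }
        AT(X, i, j) = val;
        AT(pX, i, j) = st;
      }
      // Y state: gap in s1, consumes s2[j]
      {
        double val = (AT(M, i, j - 1) == NEG_INF) ? NEG_INF
                                                  : AT(M, i, j - 1) - gop;
        unsigned char st = 0;   // codes are absolute states: 0=M, 1=X, 2=Y
        if (AT(X, i, j - 1) != NEG_INF && AT(X, i, j - 1) - gop > val) {
          val = AT(X, i, j - 1) - gop; st = 1;
        }
        if (AT(Y, i, j - 1) != NEG_INF && AT(Y, i, j - 1) - gep > val) {
          val = AT(Y, i, j - 1) - gep; st = 2;
        }
        AT(Y, i, j) = val;
        AT(pY, i, j) = st;
      }

      if (local && AT(M, i, j) > best) {
        best = AT(M, i, j);
        best_i = i; best_j = j; best_st = 0;
        have_best = true;
      }
    }
  }

  if (!local) {
    auto consider = [&](int i, int j) {
      const double vals[3] = { AT(M, i, j), AT(X, i, j), AT(Y, i, j) };
      for (int st = 0; st < 3; ++st) {
        if (!have_best || vals[st] > best) {
          best = vals[st]; best_i = i; best_j = j; best_st = st;
          have_best = true;
        }
      }
    };
    consider(n, m);
    if (free_end_gaps) {
      for (int j = m; j >= 0; --j) consider(n, j);
      for (int i = n; i >= 0; --i) consider(i, m);
    }
  }

  std::vector<int> ri, rj;
  if (!local || have_best) {
    int i = best_i, j = best_j, st = best_st;
    while (i > 0 || j > 0) {
      if (st == 0) {
        if (i == 0 && j == 0) break;
        ri.push_back(i); rj.push_back(j);
        const unsigned char prev = AT(pM, i, j);
        --i; --j;
        if (prev == 3) break;     // local fresh start
        st = prev;
      } else if (st == 1) {
        const unsigned char prev = AT(pX, i, j);
        --i;
        st = prev;
      } else {
        const unsigned char prev = AT(pY, i, j);
        --j;
        st = prev;
      }
    }
  }
  std::reverse(ri.begin(), ri.end());
  std::reverse(rj.begin(), rj.end());

  double out_score = best;
  if (local && !have_best) out_score = 0.0;

#undef AT
  return List::create(_["score"] = out_score,
                      _["i"] = wrap(ri), _["j"] = wrap(rj));
}
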