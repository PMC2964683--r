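#include <Rcpp.h>
using namespace Rcpp;

// Sequences are integer-encoded A=1, C=2, G=3, T=4; Watson-Crick
// complementarity is p + q == 5.

// Antiparallel ungapped dimer screen.  Both inputs read 5'->3'; every
// alignment offset pairs p[i] with q[j] where i + j is constant, so j
// decreases as i increases (antiparallel).  A dimer is flagged when a run
// of complementary pairs reaches stem_min anywhere, or end_min when the
// run includes either primer's 3'-terminal base (i == n-1 or j == m-1).
// [[Rcpp::export]]
bool dimer_hit_cpp(IntegerVector p, IntegerVector q,
                   int stem_min, int end_min) {
  const int n = p.size(), m = q.size();
  for (int k = 0; k <= n + m - 2; ++k) {
    const int ilo = std::max(0, k - m + 1);
    const int ihi = std::min(n - 1, k);
    int run = 0;
    bool run3p = false;
    for (int i = ilo; i <= ihi; ++i) {
      const int j = k - i;
      if (p[i] + q[j] == 5) {
        ++run;
        if (i == n - 1 || j == m - 1) run3p = true;
        if (run >= stem_min) return true;
        if (run3p && run >= end_min) return true;
      } else {
        run = 0;
        run3p = false;
      }
    }
  }
  return false;
}

// Hairpin screen: a stem of exactly stem_min bases pairing antiparallel
// with a downstream window separated by a loop of at least loop_min
// bases.  Checking stems of exactly stem_min is sufficient: any longer
// stem contains a stem_min-long sub-stem adjacent to the same loop.
// [[Rcpp::export]]
bool hairpin_hit_cpp(IntegerVector p, int stem_min, int loop_min) {
  const int n = p.size();
  for (int i = 0; i + stem_min <= n; ++i) {
    for (int j = i + stem_min + loop_min; j + stem_min <= n; ++j) {
      bool ok = true;
      for (int t = 0; t < stem_min; ++t) {
        if (p[i + t] + p[j + stem_min - 1 - t] != 5) { ok = false; break; }
      }
      if (ok) return true;
    }
  }
  return false;
}
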