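#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive terminal-inverted-repeat arm-pair scan.
//
// seq4: window encoded A=0, C=1, G=2, T=3 (any other/ambiguous base = -1,
// which never matches). Complement of base x is 3 - x under this coding.
// Left arm starts are restricted to [lsMin, lsMax], right arm ends to
// [reMin, reMax] (all 0-based here; the R wrapper converts).
//
// A candidate of arm length L with m mismatches scores L - m. Ties are broken
// by fewer mismatches, then smaller enclosed span (right end - left start),
// then leftmost left arm, then leftmost right arm. Returns the 1-based
// c(leftStart, rightEnd, armLength, mismatches) of the best candidate, or an
// empty vector when none satisfies the constraints.
// [[Rcpp::export]]
IntegerVector tir_scan_cpp(IntegerVector seq4,
                           int lsMin, int lsMax, int reMin, int reMax,
                           int minArm, int maxArm, int maxMismatch) {
    const int n = seq4.size();
    int bestScore = -1, bestM = 0, bestSpan = 0, bestI = -1, bestE = -1,
        bestL = 0;
    if (lsMin < 0) lsMin = 0;
    if (reMax > n - 1) reMax = n - 1;
    for (int i = lsMin; i <= lsMax && i < n; ++i) {
        int eLow = i + 2 * minArm - 1;  // need non-overlapping arms of minArm
        if (eLow < reMin) eLow = reMin;
        for (int e = eLow; e <= reMax; ++e) {
            int m = 0;
            int tmax = maxArm;
            for (int t = 0; t < tmax; ++t) {
                int pl = i + t, pr = e - t;
                if (pl >= pr) break;  // arms would touch/overlap
                int a = seq4[pl], b = seq4[pr];
                bool match = (a >= 0 && b >= 0 && a == 3 - b);
                if (!match) {
                    ++m;
                    if (m > maxMismatch) break;
                }
                int L = t + 1;
                if (L < minArm) continue;
                // non-overlap at this length: left end < right start
                if (i + L - 1 >= e - L + 1) break;
                int score = L - m;
                int span = e - i + 1;
                bool better = false;
                if (score > bestScore) better = true;
                else if (score == bestScore) {
                    if (m < bestM) better = true;
                    else if (m == bestM) {
                        if (span < bestSpan) better = true;
                        else if (span == bestSpan) {
                            if (i < bestI) better = true;
                            else if (i == bestI && e < bestE) better = true;
                        }
                    }
                }
                if (better) {
                    bestScore = score; bestM = m; bestSpan = span;
                    bestI = i; bestE = e; bestL = L;
                }
            }
        }
    }
    if (bestScore < 0) return IntegerVector(0);
    return IntegerVector::create(bestI + 1, bestE + 1, bestL, bestM);
}
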