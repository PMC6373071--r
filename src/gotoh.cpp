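#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Affine-gap global alignment (Gotoh three-state recurrence).
//
// Gap run of length L costs gap_open + (L-1) * gap_extend (both negative,
// added to the score).  The DP is filled over suffixes and the traceback
// walks forward from the start of both sequences, so score ties resolve
// with the preference diagonal > up > left applied left-to-right; this
// makes aligned strings bit-reproducible.
//
// States: M = diagonal column (a[i] vs b[j]);
//         X = "up" column, consumes a[i], gap in b;
//         Y = "left" column, consumes b[j], gap in a.
//
// B<state>[i][j] = best score of aligning a[i..m) with b[j..n) given the
// column immediately to the LEFT had the given state (gap continuation
// pricing only; the M-context table is also the overall answer at 0,0).

// [[Rcpp::export]]
List gotoh_align_cpp(IntegerVector ai, IntegerVector bi, NumericMatrix sub,
                     double gap_open, double gap_extend) {
    const int m = ai.size(), n = bi.size();
    const double NEG = -1e30;
    const int W = n + 1;
    std::vector<double> BM((m + 1) * W), BX((m + 1) * W), BY((m + 1) * W);
    auto at = [W](int i, int j) { return i * W + j; };

    for (int i = m; i >= 0; --i) {
        for (int j = n; j >= 0; --j) {
            if (i == m && j == n) {
                BM[at(i, j)] = BX[at(i, j)] = BY[at(i, j)] = 0.0;
                continue;
            }
            double tM = (i < m && j < n)
                ? sub(ai[i], bi[j]) + BM[at(i + 1, j + 1)] : NEG;
            double x = (i < m) ? BX[at(i + 1, j)] : NEG;
            double y = (j < n) ? BY[at(i, j + 1)] : NEG;
            BM[at(i, j)] = std::max(tM, std::max(x + gap_open, y + gap_open));
            BX[at(i, j)] = std::max(tM, std::max(x + gap_extend, y + gap_open));
            BY[at(i, j)] = std::max(tM, std::max(x + gap_open, y + gap_extend));
        }
    }

    // forward traceback; candidate values repeat the fill arithmetic exactly,
    // so equality comparison against the stored optimum is safe
    std::vector<int> outa, outb;  // 1-based index into a/b, 0 = gap
    outa.reserve(m + n);
    outb.reserve(m + n);
    int i = 0, j = 0;
    char state = 'M';
    while (i < m || j < n) {
        double cur = (state == 'M') ? BM[at(i, j)]
                   : (state == 'X') ? BX[at(i, j)] : BY[at(i, j)];
        double tM = (i < m && j < n)
            ? sub(ai[i], bi[j]) + BM[at(i + 1, j + 1)] : NEG;
        double tX = (i < m)
            ? ((state == 'X') ? gap_extend : gap_open) + BX[at(i + 1, j)] : NEG;
        double tY = (j < n)
            ? ((state == 'Y') ? gap_extend : gap_open) + BY[at(i, j + 1)] : NEG;
        if (tM == cur) {
            outa.push_back(i + 1); outb.push_back(j + 1);
            ++i; ++j; state = 'M';
        } else if (tX == cur) {
            outa.push_back(i + 1); outb.push_back(0);
            ++i; state = 'X';
        } else {
            outa.push_back(0); outb.push_back(j + 1);
            ++j; state = 'Y';
        }
    }

    return List::create(_["score"] = BM[at(0, 0)],
                        _["a_idx"] = wrap(outa),
                        _["b_idx"] = wrap(outb));
}
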