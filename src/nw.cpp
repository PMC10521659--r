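#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with an arbitrary substitution matrix
// and a linear gap penalty. a and b are 1-based codes indexing rows/columns
// of S. Ties resolve diagonal > up (gap in b) > left (gap in a), so the
// traceback is deterministic. Returns the optimal score and the aligned
// index vectors (0 marks a gap).
// [[Rcpp::export]]
List nw_align(IntegerVector a, IntegerVector b, NumericMatrix S, double gap) {
    const int n = a.size(), m = b.size();
    NumericMatrix F(n + 1, m + 1);
    for (int i = 1; i <= n; ++i) F(i, 0) = i * gap;
    for (int j = 1; j <= m; ++j) F(0, j) = j * gap;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double diag = F(i - 1, j - 1) + S(a[i - 1] - 1, b[j - 1] - 1);
            double up = F(i - 1, j) + gap;
            double left = F(i, j - 1) + gap;
            double best = diag;
            if (up > best) best = up;
            if (left > best) best = left;
            F(i, j) = best;
        }
    }
    std::vector<int> ai, bi;
    int i = n, j = m;
    const double eps = 1e-9;
    while (i > 0 || j > 0) {
        if (i > 0 && j > 0 &&
            std::abs(F(i, j) - (F(i - 1, j - 1) +
                                S(a[i - 1] - 1, b[j - 1] - 1))) < eps) {
            ai.push_back(i); bi.push_back(j); --i; --j;
        } else if (i > 0 && std::abs(F(i, j) - (F(i - 1, j) + gap)) < eps) {
            ai.push_back(i); bi.push_back(0); --i;
        } else {
            ai.push_back(0); bi.push_back(j); --j;
        }
    }
    std::reverse(ai.begin(), ai.end());
    std::reverse(bi.begin(), bi.end());
    return List::create(_["score"] = F(n, m),
                        _["ai"] = wrap(ai), _["bi"] = wrap(bi));
}
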