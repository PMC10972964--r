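#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Match-maximizing global alignment with free gaps and no mismatch penalty:
// the optimum equals the longest common subsequence. Exact O(nm) DP; inputs
// are gene-sized (<= a few kb), so no banding is needed.

static std::vector<int> lcs_table(const std::string& a, const std::string& b) {
    const int n = a.size(), m = b.size();
    std::vector<int> dp((n + 1) * (m + 1), 0);
    for (int i = 1; i <= n; ++i) {
        const int row = i * (m + 1), prev = (i - 1) * (m + 1);
        for (int j = 1; j <= m; ++j) {
            if (a[i - 1] == b[j - 1])
                dp[row + j] = dp[prev + j - 1] + 1;
            else
                dp[row + j] = std::max(dp[prev + j], dp[row + j - 1]);
        }
    }
    return dp;
}

// [[Rcpp::export(name = ".lcs_length_cpp")]]
int lcs_length_cpp(const std::string& a, const std::string& b) {
    if (a.empty() || b.empty()) stop("sequences must be non-empty");
    std::vector<int> dp = lcs_table(a, b);
    return dp[a.size() * (b.size() + 1) + b.size()];
}

// One optimal alignment with a deterministic traceback: prefer a match,
// otherwise consume from `a` (gap in `b`) when scores tie.
// [[Rcpp::export(name = ".lcs_align_cpp")]]
CharacterVector lcs_align_cpp(const std::string& a, const std::string& b) {
    if (a.empty() || b.empty()) stop("sequences must be non-empty");
    const int n = a.size(), m = b.size();
    std::vector<int> dp = lcs_table(a, b);
    std::string ga, gb;
    int i = n, j = m;
    while (i > 0 && j > 0) {
        if (a[i - 1] == b[j - 1] &&
            dp[i * (m + 1) + j] == dp[(i - 1) * (m + 1) + j - 1] + 1) {
            ga += a[i - 1]; gb += b[j - 1]; --i; --j;
        } else if (dp[(i - 1) * (m + 1) + j] >= dp[i * (m + 1) + j - 1]) {
            ga += a[i - 1]; gb += '-'; --i;
        } else {
            ga += '-'; gb += b[j - 1]; --j;
        }
    }
    while (i > 0) { ga += a[i - 1]; gb += '-'; --i; }
    while (j > 0) { ga += '-'; gb += b[j - 1]; --j; }
    std::reverse(ga.begin(), ga.end());
    std::reverse(gb.begin(), gb.end());
    return CharacterVector::create(ga, gb);
}
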