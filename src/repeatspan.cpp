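#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Small Levenshtein DP between two short strings, with an early cap:
// values above `cap` are only needed to know they exceed it, so we
// return cap+1 whenever the true distance is larger.
static int edit_small(const std::string &a, const std::string &b, int cap) {
    const int n = (int)a.size(), m = (int)b.size();
    if (std::abs(n - m) > cap) return cap + 1;
    std::vector<int> prev(m + 1), cur(m + 1);
    for (int j = 0; j <= m; ++j) prev[j] = j;
    for (int i = 1; i <= n; ++i) {
        cur[0] = i;
        int rowmin = cur[0];
        for (int j = 1; j <= m; ++j) {
            int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
            int del = prev[j] + 1;
            int ins = cur[j - 1] + 1;
            cur[j] = std::min(sub, std::min(del, ins));
            rowmin = std::min(rowmin, cur[j]);
        }
        if (rowmin > cap) return cap + 1;
        std::swap(prev, cur);
    }
    return prev[m];
}

// Semi-global (infix) alignment: the whole of `anchor` against any
// substring of `read`, unit costs. Returns the optimal edit distance and
// the 0-based half-open read interval of the best hit. Ties are broken by
// minimum distance, then leftmost read start, then leftmost read end.
// [[Rcpp::export(name = ".cppInfixAlign")]]
IntegerVector cpp_infix_align(std::string read, std::string anchor) {
    const int L = (int)read.size(), K = (int)anchor.size();
    // D over anchor rows; origin = leftmost read start among optimal paths
    std::vector<int> D(L + 1), Dn(L + 1), O(L + 1), On(L + 1);
    for (int j = 0; j <= L; ++j) { D[j] = 0; O[j] = j; }
    for (int i = 1; i <= K; ++i) {
        Dn[0] = i; On[0] = 0;
        for (int j = 1; j <= L; ++j) {
            int sub = D[j - 1] + (anchor[i - 1] == read[j - 1] ? 0 : 1);
            int del = D[j] + 1;      // consume anchor base (gap in read)
            int ins = Dn[j - 1] + 1; // consume read base (gap in anchor)
            int best = std::min(sub, std::min(del, ins));
            int org = INT_MAX;
            if (sub == best) org = std::min(org, O[j - 1]);
            if (del == best) org = std::min(org, O[j]);
            if (ins == best) org = std::min(org, On[j - 1]);
            Dn[j] = best; On[j] = org;
        }
        std::swap(D, Dn); std::swap(O, On);
    }
    int bestd = INT_MAX, bests = -1, beste = -1;
    for (int j = 0; j <= L; ++j) {
        if (D[j] < bestd ||
            (D[j] == bestd && (O[j] < bests || (O[j] == bests && j < beste)))) {
            bestd = D[j]; bests = O[j]; beste = j;
        }
    }
    return IntegerVector::create(_["distance"] = bestd,
                                 _["start"] = bests, _["end"] = beste);
}

// Minimum-cost tiling of `tract` with catalog motifs. From each position a
// step either consumes u in [unit_min, unit_max] bases at the edit cost of
// the best motif (capped at max_unit_cost, inadmissible above it) or falls
// back to a single base labelled "other" at cost 1. Backward DP gives the
// optimal suffix costs; the forward walk re-derives each step, preferring
// at equal total cost: any catalog step over the fallback, the core label,
// then the longer unit, then the lexicographically smaller label.
// motifs[0] must be the core motif.
// [[Rcpp::export(name = ".cppTokenize")]]
List cpp_tokenize(std::string tract, CharacterVector motifs,
                  int unit_min, int unit_max, int max_unit_cost) {
    const int n = (int)tract.size(), M = motifs.size();
    std::vector<std::string> mot(M);
    for (int k = 0; k < M; ++k) mot[k] = as<std::string>(motifs[k]);

    std::vector<int> best(n + 1, INT_MAX / 2);
    best[n] = 0;
    // cost[i][u-index][motif] recomputed on the fly in the walk; DP keeps cost only
    for (int i = n - 1; i >= 0; --i) {
        best[i] = 1 + best[i + 1]; // fallback
        for (int u = unit_min; u <= unit_max; ++u) {
            if (i + u > n) break;
            const std::string seg = tract.substr(i, u);
            for (int k = 0; k < M; ++k) {
                int c = edit_small(seg, mot[k], max_unit_cost);
                if (c <= max_unit_cost && c + best[i + u] < best[i])
                    best[i] = c + best[i + u];
            }
        }
    }

    std::vector<std::string> lab;
    std::vector<int> st, en, co;
    int i = 0;
    while (i < n) {
        // candidates achieving best[i]
        int pick_u = -1, pick_k = -1, pick_c = -1;
        for (int u = unit_min; u <= unit_max; ++u) {
            if (i + u > n) break;
            const std::string seg = tract.substr(i, u);
            for (int k = 0; k < M; ++k) {
                int c = edit_small(seg, mot[k], max_unit_cost);
                if (c > max_unit_cost || c + best[i + u] != best[i]) continue;
                bool take = false;
                if (pick_u < 0) take = true;
                else {
                    bool cand_core = (k == 0), cur_core = (pick_k == 0);
                    if (cand_core != cur_core) take = cand_core;
                    else if (u != pick_u) take = u > pick_u;
                    else take = mot[k] < mot[pick_k];
                }
                if (take) { pick_u = u; pick_k = k; pick_c = c; }
            }
        }
        if (pick_u > 0) {
            lab.push_back(mot[pick_k]); st.push_back(i);
            en.push_back(i + pick_u); co.push_back(pick_c);
            i += pick_u;
        } else { // fallback single base
            lab.push_back("other"); st.push_back(i);
            en.push_back(i + 1); co.push_back(1);
            i += 1;
        }
    }
    return List::create(_["label"] = wrap(lab), _["start"] = wrap(st),
                        _["end"] = wrap(en), _["cost"] = wrap(co),
                        _["total_cost"] = best[0]);
}
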