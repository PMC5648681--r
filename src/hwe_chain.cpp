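#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Markov-chain exact test of Hardy-Weinberg proportions.
//
// The conditional distribution of a genotype table given its allele counts
// (Levene's distribution) is exactly the distribution induced by pairing the
// 2n observed allele copies uniformly at random into n genotypes.  The chain
// therefore walks on allele pairings: each step proposes switching one
// allele between two randomly chosen genotypes (the classic genotype-switch
// proposal).  That proposal is symmetric on pairings and the uniform pairing
// distribution is the target, so every proposal is accepted; no
// case-by-case acceptance ratios are needed and detailed balance holds by
// construction.
//
// The p-value is the proportion of post-dememorization states whose
// conditional probability is <= that of the observed table (ties count as
// extreme, with a small numerical tolerance).

static inline double cell_lgamma(const std::vector<int> &tab, int k, int i, int j) {
    int lo = i < j ? i : j, hi = i < j ? j : i;
    return lgamma((double) tab[hi * k + lo] + 1.0);
}

// [[Rcpp::export]]
List hwe_chain_cpp(IntegerMatrix counts, int steps, int demem, int batches,
                   int thin = 0) {
    int k = counts.nrow();
    // expand table into allele pairs (a[i], b[i]) per individual
    std::vector<int> A, B;
    std::vector<int> tab(k * k, 0); // lower triangle storage: tab[hi*k+lo]
    for (int i = 0; i < k; ++i) {
        for (int j = 0; j <= i; ++j) {
            int c = counts(i, j);
            if (i != j) c += counts(j, i); // tolerate upper-triangle input
            for (int r = 0; r < c; ++r) { A.push_back(i); B.push_back(j); }
            tab[i * k + j] = c;
        }
    }
    int n = (int) A.size();
    if (n < 2) return List::create(_["p"] = 1.0, _["se"] = 0.0,
                                   _["degenerate"] = true);

    // log "score" of a table: H*log2 - sum lgamma(n_ij + 1); differs from the
    // log conditional probability by a constant, which cancels in comparisons
    int H = 0;
    double sumlg = 0.0;
    for (int i = 0; i < k; ++i)
        for (int j = 0; j <= i; ++j) {
            sumlg += lgamma((double) tab[i * k + j] + 1.0);
            if (i != j) H += tab[i * k + j];
        }
    const double LOG2 = std::log(2.0);
    double score = H * LOG2 - sumlg;
    const double score_obs = score;
    int curH = H;
    const double tol = 1e-9;

    RNGScope scope;
    long long hits = 0, total = 0;
    int nb = batches > 0 ? batches : 1;
    std::vector<double> bh(nb, 0.0), bt(nb, 0.0);
    long long post = steps;
    long long per_batch = post / nb > 0 ? post / nb : 1;
    // optional thinned histogram of the heterozygote count, for external
    // checks of the chain's long-run table frequencies
    std::vector<double> het_hist(thin > 0 ? n + 1 : 0, 0.0);

    for (long long s = 0; s < (long long) steps + demem; ++s) {
        int u = (int) (unif_rand() * n); if (u >= n) u = n - 1;
        int v = (int) (unif_rand() * (n - 1)); if (v >= n - 1) v = n - 2;
        if (v >= u) ++v;
        bool su = unif_rand() < 0.5, sv = unif_rand() < 0.5;
        int x = su ? A[u] : B[u];
        int y = sv ? A[v] : B[v];
        if (x != y) {
            int au = A[u], bu = B[u], av = A[v], bv = B[v];
            // remove the two old genotypes
            score += cell_lgamma(tab, k, au, bu);
            { int lo = au < bu ? au : bu, hi = au < bu ? bu : au; tab[hi * k + lo]--; }
            score -= cell_lgamma(tab, k, au, bu);
            if (au != bu) { score -= LOG2; --curH; }
            score += cell_lgamma(tab, k, av, bv);
            { int lo = av < bv ? av : bv, hi = av < bv ? bv : av; tab[hi * k + lo]--; }
            score -= cell_lgamma(tab, k, av, bv);
            if (av != bv) { score -= LOG2; --curH; }
            // swap the chosen allele copies
            if (su) A[u] = y; else B[u] = y;
            if (sv) A[v] = x; else B[v] = x;
            int nu1 = A[u], nu2 = B[u], nv1 = A[v], nv2 = B[v];
            score += cell_lgamma(tab, k, nu1, nu2);
            { int lo = nu1 < nu2 ? nu1 : nu2, hi = nu1 < nu2 ? nu2 : nu1; tab[hi * k + lo]++; }
            score -= cell_lgamma(tab, k, nu1, nu2);
            if (nu1 != nu2) { score += LOG2; ++curH; }
            score += cell_lgamma(tab, k, nv1, nv2);
            { int lo = nv1 < nv2 ? nv1 : nv2, hi = nv1 < nv2 ? nv2 : nv1; tab[hi * k + lo]++; }
            score -= cell_lgamma(tab, k, nv1, nv2);
            if (nv1 != nv2) { score += LOG2; ++curH; }
        }
        if (s >= demem) {
            long long t = s - demem;
            bool hit = score <= score_obs + tol;
            if (hit) ++hits;
            ++total;
            int b = (int) (t / per_batch); if (b >= nb) b = nb - 1;
            bt[b] += 1.0; if (hit) bh[b] += 1.0;
            if (thin > 0 && t % thin == 0) het_hist[curH] += 1.0;
        }
        // guard against floating drift in the incremental score
        if ((s & 0xFFFFF) == 0xFFFFF) {
            double sl = 0.0; int hh = 0;
            for (int i = 0; i < k; ++i)
                for (int j = 0; j <= i; ++j) {
                    sl += lgamma((double) tab[i * k + j] + 1.0);
                    if (i != j) hh += tab[i * k + j];
                }
            score = hh * LOG2 - sl;
        }
    }

    double p = total > 0 ? (double) hits / (double) total : 1.0;
    // batch-means Monte-Carlo standard error
    double mb = 0.0; int used = 0;
    for (int b = 0; b < nb; ++b) if (bt[b] > 0) { mb += bh[b] / bt[b]; ++used; }
    double se = 0.0;
    if (used > 1) {
        mb /= used;
        double ss = 0.0;
        for (int b = 0; b < nb; ++b)
            if (bt[b] > 0) { double d = bh[b] / bt[b] - mb; ss += d * d; }
        se = std::sqrt(ss / (used - 1.0) / used);
    }
    List out = List::create(_["p"] = p, _["se"] = se, _["degenerate"] = false);
    if (thin > 0) out["het_hist"] = wrap(het_hist);
    return out;
}
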