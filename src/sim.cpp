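// Simulation cores: multiscale complexity profile, disruption-model
// (Moran origin-fixation) evolution, and differential-mobility/attractor
// evolution. All randomness comes from R's RNG so runs are reproducible
// with set.seed().
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// rolling means at window lam for a circular 0/1 sequence, via prefix sums
static void rollmean(const std::vector<double> &cs, int n, int lam,
                     std::vector<double> &out) {
    for (int k = 0; k < n; ++k)
        out[k] = (cs[k + lam] - cs[k]) / lam;
}

// [[Rcpp::export]]
NumericVector msc_profile_cpp(NumericVector x) {
    int n = x.size();
    int nl = n / 2;
    std::vector<double> cs(2 * n + 1, 0.0);
    for (int i = 0; i < 2 * n; ++i)
        cs[i + 1] = cs[i] + x[i % n];
    NumericVector out(nl);
    std::vector<double> y1(n), y2(n);
    for (int lam = 1; lam <= nl; ++lam) {
        rollmean(cs, n, lam, y1);
        rollmean(cs, n, 2 * lam, y2);
        double acc = 0.0;
        for (int k = 0; k < n; ++k)
            acc += std::fabs(y1[k] - y2[k]);
        out[lam - 1] = acc / n;
    }
    return out;
}

// fraction of the N circular k-windows containing >= 1 essential gene
static double lethal_frac(const std::vector<int> &e, int k) {
    int n = e.size();
    int wsum = 0;
    for (int i = 0; i < k; ++i) wsum += e[i];
    int lethal = (wsum > 0);
    for (int st = 1; st < n; ++st) {
        wsum -= e[st - 1];
        wsum += e[(st + k - 1) % n];
        if (wsum > 0) ++lethal;
    }
    return (double)lethal / n;
}

static int block_count(const std::vector<int> &e) {
    int n = e.size(), m = 0, blocks = 0;
    for (int i = 0; i < n; ++i) m += e[i];
    if (m == 0) return 0;
    if (m == n) return 1;
    for (int i = 0; i < n; ++i)
        if (e[i] == 1 && e[(i + n - 1) % n] == 0) ++blocks;
    return blocks;
}

static double moran_p(double s, double Ne) {
    if (std::fabs(Ne * s) < 1e-8) return 1.0 / Ne;
    if (Ne * s < -700.0) {
        double num = -expm1(-s);
        if (num < 0) num = 0;
        return exp((Ne - 1.0) * s) * num;
    }
    return (-expm1(-s)) / (-expm1(-Ne * s));
}

// [[Rcpp::export]]
List evolve_disruption_cpp(IntegerVector ess, int k, double r, double Ne,
                           double steps, double record_every) {
    int n = ess.size();
    std::vector<int> g(ess.begin(), ess.end()), prop(n);
    long long nsteps = (long long)steps;
    long long rec = (long long)record_every;
    if (rec < 1) rec = 1;
    long long nsnap = nsteps / rec + 1;
    IntegerMatrix snapshots(nsnap, n);
    NumericVector snapStep(nsnap);
    IntegerVector blocks(nsnap);
    RNGScope scope;
    double f0 = lethal_frac(g, k);
    long long accepted = 0, isnap = 0;
    for (int j = 0; j < n; ++j) snapshots(0, j) = g[j];
    snapStep[0] = 0; blocks[0] = block_count(g);
    ++isnap;
    for (long long t = 1; t <= nsteps; ++t) {
        int gi = (int)(unif_rand() * n); if (gi >= n) gi = n - 1;
        int dest = (int)(unif_rand() * n); if (dest >= n) dest = n - 1;
        // remove gene gi, insert so it lands at position dest of the result
        int v = g[gi];
        int idx = 0;
        for (int j = 0; j < n; ++j) {
            if (j == dest) { prop[j] = v; continue; }
            if (idx == gi) ++idx;
            prop[j] = g[idx++];
        }
        double f1 = lethal_frac(prop, k);
        double s = expm1(r * (f0 - f1));
        double P = moran_p(s, Ne);
        if (unif_rand() < P) {
            g = prop;
            f0 = f1;
            ++accepted;
        }
        if (t % rec == 0 && isnap < nsnap) {
            for (int j = 0; j < n; ++j) snapshots(isnap, j) = g[j];
            snapStep[isnap] = (double)t;
            blocks[isnap] = block_count(g);
            ++isnap;
        }
    }
    IntegerVector fin(g.begin(), g.end());
    return List::create(_["step"] = snapStep, _["block_count"] = blocks,
                        _["snapshots"] = snapshots,
                        _["accepted"] = (double)accepted, _["final"] = fin);
}

// distance (in genes, shorter circular arc) from each IR to the nearest
// attractor gene; IR i lies between gene i and gene i+1 (0-based). The two
// IRs flanking an attractor have distance 0.
static void ir_distance(const std::vector<int> &att, std::vector<double> &d) {
    int n = att.size();
    const double INF = 1e18;
    // forward: genes strictly between IR i and the next attractor clockwise
    double run = INF;
    for (int pass = 0; pass < 2; ++pass) {
        for (int i = n - 1; i >= 0; --i) {
            // gene i+1 (mod n) sits just after IR i
            if (att[(i + 1) % n]) run = 0;
            else if (run < INF) ++run;
            if (pass == 1) d[i] = run;
        }
    }
    // backward: genes strictly between IR i and the previous attractor
    run = INF;
    for (int pass = 0; pass < 2; ++pass) {
        for (int i = 0; i < n; ++i) {
            if (att[i]) run = 0;            // gene i sits just before IR i
            else if (run < INF) ++run;
            if (pass == 1 && run < d[i]) d[i] = run;
        }
    }
}

// [[Rcpp::export]]
List simulate_mobility_cpp(IntegerVector high0, IntegerVector att0,
                           double beta, double alpha, double gamma,
                           int epoch_steps, int n_epochs) {
    int n = high0.size();
    std::vector<int> high(high0.begin(), high0.end());
    std::vector<int> att(att0.begin(), att0.end());
    IntegerMatrix snapshots(n_epochs, n);
    std::vector<double> d(n), w(n), cum(n);
    RNGScope scope;
    for (int ep = 0; ep < n_epochs; ++ep) {
        for (int st = 0; st < epoch_steps; ++st) {
            // select gene by mobility weight 1 or 1+beta
            int nh = 0;
            for (int i = 0; i < n; ++i) nh += high[i];
            double tot = (n - nh) + (1.0 + beta) * nh;
            double u = unif_rand() * tot;
            int gi = n - 1;
            double acc = 0.0;
            for (int i = 0; i < n; ++i) {
                acc += high[i] ? (1.0 + beta) : 1.0;
                if (u < acc) { gi = i; break; }
            }
            int hv = high[gi], av = att[gi];
            // intermediate of n-1 genes
            high.erase(high.begin() + gi);
            att.erase(att.begin() + gi);
            int m = n - 1;
            int natt = 0;
            for (int i = 0; i < m; ++i) natt += att[i];
            int ir;
            if (natt == 0) {
                ir = (int)(unif_rand() * m); if (ir >= m) ir = m - 1;
            } else {
                d.assign(m, 0.0);
                ir_distance(att, d);
                double wt = 0.0;
                for (int i = 0; i < m; ++i) {
                    wt += 1.0 + alpha * std::exp(-d[i] / gamma);
                    cum[i] = wt;
                }
                double uu = unif_rand() * wt;
                ir = m - 1;
                for (int i = 0; i < m; ++i)
                    if (uu < cum[i]) { ir = i; break; }
            }
            // IR ir lies after gene ir (0-based) -> insert at index ir + 1
            int pos = (ir + 1) % m;
            high.insert(high.begin() + pos, hv);
            att.insert(att.begin() + pos, av);
        }
        for (int j = 0; j < n; ++j) snapshots(ep, j) = high[j];
    }
    IntegerVector hf(high.begin(), high.end());
    IntegerVector af(att.begin(), att.end());
    return List::create(_["snapshots"] = snapshots, _["high"] = hf,
                        _["attractor"] = af);
}
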