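// Generalized Louvain optimization of multilayer modularity on a dense
// supra-modularity matrix B (node-layer elements, layer-major order:
// element e = l*K + i for node i in layer l).
//
// Iterated multilevel scheme: randomized-order local moves at the element
// level (strict gain > EPS only, guaranteeing termination under floating
// point), aggregation, classic multilevel on the aggregate, then back to
// element-level moves, repeated until neither phase improves.  Returning
// to the finest level after aggregation avoids the lock-in of plain
// single-pass Louvain, which matters on small instances checked against
// the brute-force oracle.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <numeric>
#include <algorithm>

using namespace Rcpp;

static const double EPS = 1e-12;

// randomized-order local moves on dense symmetric M; comm holds current
// community ids (arbitrary ints < n); returns true if anything moved
static bool move_phase_dense(const std::vector<double>& M, int n,
                             std::vector<int>& comm, std::mt19937& rng,
                             int max_passes)
{
    std::vector<double> cw(n, 0.0);
    std::vector<int> touched; touched.reserve(n);
    std::vector<int> order(n);
    std::iota(order.begin(), order.end(), 0);
    // community sizes + free labels so elements can detach into a fresh
    // singleton when negatively attached to every existing community
    std::vector<int> csize(n, 0);
    for (int i = 0; i < n; ++i) ++csize[comm[i]];
    std::vector<int> freelist;
    for (int c = 0; c < n; ++c) if (csize[c] == 0) freelist.push_back(c);

    bool any = false;
    for (int pass = 0; pass < max_passes; ++pass) {
        std::shuffle(order.begin(), order.end(), rng);
        int moves = 0;
        for (int oi = 0; oi < n; ++oi) {
            int i = order[oi];
            int a = comm[i];
            touched.clear();
            const double* col = &M[(size_t)i * n];   // symmetric
            for (int j = 0; j < n; ++j) {
                if (j == i) continue;
                double w = col[j];
                if (w != 0.0) {
                    int c = comm[j];
                    if (cw[c] == 0.0) touched.push_back(c);
                    cw[c] += w;
                }
            }
            if (cw[a] == 0.0) touched.push_back(a);
            double base = cw[a];                     // w(i, a \ {i})
            // strict improvement only; ties keep the first candidate
            // encountered (order already randomized by the shuffle)
            int best = a; double best_gain = EPS;
            for (size_t t = 0; t < touched.size(); ++t) {
                int c = touched[t];
                if (c == a) continue;
                double g = cw[c] - base;
                if (g > best_gain) { best = c; best_gain = g; }
            }
            bool detach = false;
            if (csize[a] > 1 && !freelist.empty() && -base > best_gain) {
                best = freelist.back();              // fresh singleton
                best_gain = -base;
                detach = true;
            }
            for (size_t t = 0; t < touched.size(); ++t) cw[touched[t]] = 0.0;
            if (best != a) {
                if (detach) freelist.pop_back();
                if (--csize[a] == 0) freelist.push_back(a);
                ++csize[best];
                comm[i] = best;
                ++moves;
            }
        }
        if (moves == 0) break;
        any = true;
    }
    return any;
}

// relabel communities consecutively, return their count
static int relabel(std::vector<int>& comm)
{
    int mx = 0;
    for (size_t i = 0; i < comm.size(); ++i) mx = std::max(mx, comm[i]);
    std::vector<int> remap((size_t)mx + 1, -1);
    int nc = 0;
    for (size_t i = 0; i < comm.size(); ++i)
        if (remap[comm[i]] < 0) remap[comm[i]] = nc++;
    for (size_t i = 0; i < comm.size(); ++i) comm[i] = remap[comm[i]];
    return nc;
}

static std::vector<double> aggregate_dense(const std::vector<double>& M,
                                           int n,
                                           const std::vector<int>& comm,
                                           int nc)
{
    std::vector<double> M2((size_t)nc * nc, 0.0);
    for (int j = 0; j < n; ++j) {
        int cj = comm[j];
        const double* col = &M[(size_t)j * n];
        for (int i = 0; i < n; ++i) {
            double w = col[i];
            if (w != 0.0) M2[(size_t)comm[i] + (size_t)cj * nc] += w;
        }
    }
    return M2;
}

// classic multilevel Louvain on a dense matrix (used on aggregates)
static std::vector<int> louvain_dense(const std::vector<double>& B0, int n0,
                                      std::mt19937& rng, int max_passes)
{
    std::vector<double> M(B0);
    int n = n0;
    std::vector<int> global(n0);
    std::iota(global.begin(), global.end(), 0);
    while (true) {
        std::vector<int> comm(n);
        std::iota(comm.begin(), comm.end(), 0);
        bool moved = move_phase_dense(M, n, comm, rng, max_passes);
        int nc = relabel(comm);
        for (int e = 0; e < n0; ++e) global[e] = comm[global[e]];
        if (!moved || nc == n) break;
        M = aggregate_dense(M, n, comm, nc);
        n = nc;
    }
    return global;
}

// Kernighan-Lin-style bipartition attempt on one community's internal
// block Bs (m x m): starting from everything on one side, repeatedly move
// the element with the best (possibly negative) within-weight change to
// the other side, lock it, and keep the best prefix of the move sequence.
// A kept prefix with positive cumulative gain corresponds to a cut with
// negative weight, i.e. a split that strictly increases Q.  Deterministic
// (ties keep the lowest index).
static bool kl_split(const std::vector<double>& Bs, int m,
                     std::vector<int>& side)
{
    side.assign(m, 0);
    std::vector<double> w0(m, 0.0), w1(m, 0.0);   // weight to each side
    for (int i = 0; i < m; ++i)
        for (int j = 0; j < m; ++j)
            if (j != i) w0[i] += Bs[i + (size_t)j * m];

    bool improved_any = false;
    for (int pass = 0; pass < 10; ++pass) {
        std::vector<char> locked(m, 0);
        std::vector<int> side_work = side;
        std::vector<double> a0 = w0, a1 = w1;
        std::vector<int> seq(m);
        std::vector<double> cum(m);
        double c = 0.0;
        for (int step = 0; step < m; ++step) {
            int best = -1; double bg = 0.0;
            for (int i = 0; i < m; ++i) {
                if (locked[i]) continue;
                double own = side_work[i] == 0 ? a0[i] : a1[i];
                double oth = side_work[i] == 0 ? a1[i] : a0[i];
                double d = 2.0 * (oth - own);
                if (best < 0 || d > bg) { bg = d; best = i; }
            }
            int s = side_work[best];
            side_work[best] = 1 - s;
            locked[best] = 1;
            for (int i = 0; i < m; ++i) {
                if (i == best) continue;
                double w = Bs[i + (size_t)best * m];
                if (w != 0.0) {
                    if (s == 0) { a0[i] -= w; a1[i] += w; }
                    else        { a1[i] -= w; a0[i] += w; }
                }
            }
            c += bg;
            seq[step] = best;
            cum[step] = c;
        }
        int bp = -1; double bpv = EPS;
        for (int k = 0; k < m - 1; ++k)        // flipping all = no split
            if (cum[k] > bpv) { bpv = cum[k]; bp = k; }
        if (bp < 0) break;
        for (int k = 0; k <= bp; ++k) side[seq[k]] = 1 - side[seq[k]];
        for (int i = 0; i < m; ++i) { w0[i] = 0.0; w1[i] = 0.0; }
        for (int i = 0; i < m; ++i)
            for (int j = 0; j < m; ++j)
                if (j != i) {
                    double w = Bs[i + (size_t)j * m];
                    if (side[j] == 0) w0[i] += w; else w1[i] += w;
                }
        improved_any = true;
    }
    if (!improved_any) return false;
    bool has0 = false, has1 = false;
    for (int i = 0; i < m; ++i) (side[i] ? has1 : has0) = true;
    return has0 && has1;
}

// Try splitting each community via a KL bipartition of its internal block;
// repeated applications across outer iterations give k-way splits.
static bool split_phase_dense(const std::vector<double>& B, int n,
                              std::vector<int>& comm)
{
    int nc = relabel(comm);
    bool any = false;
    int next_label = nc;
    std::vector<int> side;
    for (int c = 0; c < nc; ++c) {
        std::vector<int> members;
        for (int e = 0; e < n; ++e) if (comm[e] == c) members.push_back(e);
        int m = (int)members.size();
        if (m < 2) continue;
        std::vector<double> Bs((size_t)m * m);
        for (int j = 0; j < m; ++j)
            for (int i = 0; i < m; ++i)
                Bs[i + (size_t)j * m] = B[members[i] + (size_t)members[j] * n];
        if (kl_split(Bs, m, side)) {
            for (int i = 0; i < m; ++i)
                if (side[i]) comm[members[i]] = next_label;
            ++next_label;
            any = true;
        }
    }
    if (any) relabel(comm);
    return any;
}

// iterated refinement wrapper for a dense element-level matrix:
// element moves, aggregate merges and community splits alternate until a
// full cycle leaves the partition unchanged
static std::vector<int> louvain_iterated_dense(const std::vector<double>& B,
                                               int n, std::mt19937& rng,
                                               int max_passes)
{
    std::vector<int> comm(n);
    std::iota(comm.begin(), comm.end(), 0);
    while (true) {
        bool moved = move_phase_dense(B, n, comm, rng, max_passes);
        int nc = relabel(comm);
        bool merged = false;
        if (nc < n && nc > 1) {
            std::vector<double> M = aggregate_dense(B, n, comm, nc);
            std::vector<int> up = louvain_dense(M, nc, rng, max_passes);
            int nup = relabel(up);
            if (nup < nc) merged = true;
            for (int e = 0; e < n; ++e) comm[e] = up[comm[e]];
        }
        if (moved || merged) continue;
        // only at local convergence of moves and merges, attempt splits
        // as an escape from single-move local optima
        if (!split_phase_dense(B, n, comm)) break;
    }
    return comm;
}

// Sum of B over same-community ordered pairs, diagonal included.
static double q_raw_of(const std::vector<double>& B, int n,
                       const std::vector<int>& lab)
{
    double q = 0.0;
    for (int j = 0; j < n; ++j) {
        int lj = lab[j];
        const double* col = &B[(size_t)j * n];
        for (int i = 0; i < n; ++i)
            if (lab[i] == lj) q += col[i];
    }
    return q;
}

static std::mt19937 seeded_rng(int seed, int stream)
{
    std::seed_seq ss{seed, stream, 1640531527};
    return std::mt19937(ss);
}

// ---- structured fast path -------------------------------------------------
// The supra-modularity matrix of an ordinally coupled multilayer network is
// block sparse: dense K x K intralayer blocks plus omega on the two
// node-identity couplings to adjacent layers.  Element-level moves scan
// K + 2 neighbours per element instead of K*L.
//
// BL: K x K x L array of per-layer modularity blocks (A_l - gamma*null),
// column-major within each layer slice (blocks are symmetric).

static bool move_phase_layers(const double* BL, int K, int L, double omega,
                              std::vector<int>& comm, std::mt19937& rng,
                              int max_passes)
{
    int n = K * L;
    std::vector<double> cw(n, 0.0);
    std::vector<int> touched; touched.reserve(K + 2);
    std::vector<int> order(n);
    std::iota(order.begin(), order.end(), 0);
    std::vector<int> csize(n, 0);
    for (int e = 0; e < n; ++e) ++csize[comm[e]];
    std::vector<int> freelist;
    for (int c = 0; c < n; ++c) if (csize[c] == 0) freelist.push_back(c);

    bool any = false;
    for (int pass = 0; pass < max_passes; ++pass) {
        std::shuffle(order.begin(), order.end(), rng);
        int moves = 0;
        for (int oi = 0; oi < n; ++oi) {
            int e = order[oi];
            int l = e / K, i = e % K;
            int a = comm[e];
            touched.clear();
            const double* col = BL + (size_t)l * K * K + (size_t)i * K;
            int base_e = l * K;
            for (int j = 0; j < K; ++j) {
                if (j == i) continue;
                double w = col[j];
                if (w != 0.0) {
                    int c = comm[base_e + j];
                    if (cw[c] == 0.0) touched.push_back(c);
                    cw[c] += w;
                }
            }
            if (omega != 0.0) {
                if (l > 0) {
                    int c = comm[e - K];
                    if (cw[c] == 0.0) touched.push_back(c);
                    cw[c] += omega;
                }
                if (l < L - 1) {
                    int c = comm[e + K];
                    if (cw[c] == 0.0) touched.push_back(c);
                    cw[c] += omega;
                }
            }
            if (cw[a] == 0.0) touched.push_back(a);
            double base = cw[a];
            int best = a; double best_gain = EPS;
            for (size_t t = 0; t < touched.size(); ++t) {
                int c = touched[t];
                if (c == a) continue;
                double g = cw[c] - base;
                if (g > best_gain) { best = c; best_gain = g; }
            }
            bool detach = false;
            if (csize[a] > 1 && !freelist.empty() && -base > best_gain) {
                best = freelist.back();
                best_gain = -base;
                detach = true;
            }
            for (size_t t = 0; t < touched.size(); ++t) cw[touched[t]] = 0.0;
            if (best != a) {
                if (detach) freelist.pop_back();
                if (--csize[a] == 0) freelist.push_back(a);
                ++csize[best];
                comm[e] = best;
                ++moves;
            }
        }
        if (moves == 0) break;
        any = true;
    }
    return any;
}

static std::vector<double> aggregate_layers(const double* BL, int K, int L,
                                            double omega,
                                            const std::vector<int>& comm,
                                            int nc)
{
    std::vector<double> M((size_t)nc * nc, 0.0);
    for (int l = 0; l < L; ++l) {
        const double* blk = BL + (size_t)l * K * K;
        for (int j = 0; j < K; ++j) {
            int cj = comm[l * K + j];
            for (int i = 0; i < K; ++i) {
                double w = blk[i + (size_t)j * K];
                if (w != 0.0) M[(size_t)comm[l * K + i] + (size_t)cj * nc] += w;
            }
        }
    }
    if (omega != 0.0)
        for (int l = 0; l + 1 < L; ++l)
            for (int i = 0; i < K; ++i) {
                int c1 = comm[l * K + i], c2 = comm[(l + 1) * K + i];
                M[(size_t)c1 + (size_t)c2 * nc] += omega;
                M[(size_t)c2 + (size_t)c1 * nc] += omega;
            }
    return M;
}

static bool split_phase_layers(const double* BL, int K, int L, double omega,
                               std::vector<int>& comm)
{
    int n = K * L;
    int nc = relabel(comm);
    bool any = false;
    int next_label = nc;
    std::vector<int> side;
    for (int c = 0; c < nc; ++c) {
        std::vector<int> members;
        for (int e = 0; e < n; ++e) if (comm[e] == c) members.push_back(e);
        int m = (int)members.size();
        if (m < 2) continue;
        std::vector<int> ml(m), mi(m);
        for (int i = 0; i < m; ++i) { ml[i] = members[i] / K;
                                      mi[i] = members[i] % K; }
        std::vector<double> Bs((size_t)m * m, 0.0);
        for (int j = 0; j < m; ++j) {
            const double* blk = BL + (size_t)ml[j] * K * K
                                   + (size_t)mi[j] * K;
            for (int i = 0; i < m; ++i) {
                if (i == j) continue;
                double w = 0.0;
                if (ml[i] == ml[j]) {
                    if (mi[i] != mi[j]) w = blk[mi[i]];
                } else if (mi[i] == mi[j] &&
                           (ml[i] - ml[j] == 1 || ml[j] - ml[i] == 1)) {
                    w = omega;
                }
                Bs[i + (size_t)j * m] = w;
            }
        }
        if (kl_split(Bs, m, side)) {
            for (int i = 0; i < m; ++i)
                if (side[i]) comm[members[i]] = next_label;
            ++next_label;
            any = true;
        }
    }
    if (any) relabel(comm);
    return any;
}

static std::vector<int> louvain_layers(const double* BL, int K, int L,
                                       double omega, std::mt19937& rng,
                                       int max_passes)
{
    int n = K * L;
    std::vector<int> comm(n);
    std::iota(comm.begin(), comm.end(), 0);
    while (true) {
        bool moved = move_phase_layers(BL, K, L, omega, comm, rng,
                                       max_passes);
        int nc = relabel(comm);
        bool merged = false;
        if (nc < n && nc > 1) {
            std::vector<double> M = aggregate_layers(BL, K, L, omega, comm,
                                                     nc);
            std::vector<int> up = louvain_dense(M, nc, rng, max_passes);
            int nup = relabel(up);
            if (nup < nc) merged = true;
            for (int e = 0; e < n; ++e) comm[e] = up[comm[e]];
        }
        if (moved || merged) continue;
        if (!split_phase_layers(BL, K, L, omega, comm)) break;
    }
    return comm;
}

static double q_raw_layers(const double* BL, int K, int L, double omega,
                           const std::vector<int>& lab)
{
    double q = 0.0;
    for (int l = 0; l < L; ++l) {
        const double* blk = BL + (size_t)l * K * K;
        const int* gl = lab.data() + l * K;
        for (int j = 0; j < K; ++j)
            for (int i = 0; i < K; ++i)
                if (gl[i] == gl[j]) q += blk[i + (size_t)j * K];
    }
    if (omega != 0.0)
        for (int l = 0; l + 1 < L; ++l)
            for (int i = 0; i < K; ++i)
                if (lab[l * K + i] == lab[(l + 1) * K + i]) q += 2.0 * omega;
    return q;
}

// ---- exported entry points ------------------------------------------------

// [[Rcpp::export]]
List genlouvain_core(NumericMatrix B, int n_nodes, int n_layers,
                     int seed, int max_passes)
{
    int n = B.nrow();
    std::vector<double> Bv(B.begin(), B.end());
    std::mt19937 rng = seeded_rng(seed, 0);
    std::vector<int> lab = louvain_iterated_dense(Bv, n, rng, max_passes);
    double qr = q_raw_of(Bv, n, lab);
    IntegerMatrix labels(n_layers, n_nodes);
    for (int l = 0; l < n_layers; ++l)
        for (int i = 0; i < n_nodes; ++i)
            labels(l, i) = lab[l * n_nodes + i] + 1;
    return List::create(_["labels"] = labels, _["q_raw"] = qr);
}

// [[Rcpp::export]]
List genlouvain_layers_core(NumericVector BL, int n_nodes, int n_layers,
                            double omega, int seed, int max_passes)
{
    std::mt19937 rng = seeded_rng(seed, 0);
    std::vector<int> lab = louvain_layers(BL.begin(), n_nodes, n_layers,
                                          omega, rng, max_passes);
    double qr = q_raw_layers(BL.begin(), n_nodes, n_layers, omega, lab);
    IntegerMatrix labels(n_layers, n_nodes);
    for (int l = 0; l < n_layers; ++l)
        for (int i = 0; i < n_nodes; ++i)
            labels(l, i) = lab[l * n_nodes + i] + 1;
    return List::create(_["labels"] = labels, _["q_raw"] = qr);
}

// Repeated runs with per-run sub-streams; returns the mean co-assignment
// (allegiance) matrix over layers and runs, plus per-run raw Q values.
// [[Rcpp::export]]
List consensus_layers_core(NumericVector BL, int n_nodes, int n_layers,
                           double omega, int n_runs, int seed,
                           int max_passes)
{
    NumericMatrix P(n_nodes, n_nodes);
    NumericVector qs(n_runs);
    IntegerMatrix labels1(n_layers, n_nodes);
    for (int r = 0; r < n_runs; ++r) {
        std::mt19937 rng = seeded_rng(seed, r + 1);
        std::vector<int> lab = louvain_layers(BL.begin(), n_nodes, n_layers,
                                              omega, rng, max_passes);
        qs[r] = q_raw_layers(BL.begin(), n_nodes, n_layers, omega, lab);
        if (r == 0)
            for (int l = 0; l < n_layers; ++l)
                for (int i = 0; i < n_nodes; ++i)
                    labels1(l, i) = lab[l * n_nodes + i] + 1;
        for (int i = 0; i < n_nodes; ++i)
            for (int j = i + 1; j < n_nodes; ++j) {
                int cnt = 0;
                for (int l = 0; l < n_layers; ++l)
                    if (lab[l * n_nodes + i] == lab[l * n_nodes + j]) ++cnt;
                P(i, j) += (double)cnt / n_layers;
            }
    }
    double inv = 1.0 / n_runs;
    for (int i = 0; i < n_nodes; ++i) {
        P(i, i) = 1.0;
        for (int j = i + 1; j < n_nodes; ++j) {
            double v = P(i, j) * inv;
            P(i, j) = v;
            P(j, i) = v;
        }
    }
    return List::create(_["P"] = P, _["q_raw"] = qs,
                        _["labels_first"] = labels1);
}
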