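#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Neighbour offsets for a 3D connectivity scheme: 6 = faces, 18 = faces+edges,
// 26 = faces+edges+corners.
static std::vector<std::array<int, 3>> conn_offsets(int conn) {
    std::vector<std::array<int, 3>> off;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (m == 0) continue;
                if (conn == 6 && m > 1) continue;
                if (conn == 18 && m > 2) continue;
                off.push_back({dx, dy, dz});
            }
    return off;
}

// Scratch buffers reused across maps in a batch.
struct TfceScratch {
    std::vector<int> parent, csize, order, roots;
    std::vector<double> accum, w;
    std::vector<char> added;
    TfceScratch(int N)
        : parent(N), csize(N), accum(N), w(N), added(N, 0) {
        order.reserve(N);
        roots.reserve(256);
    }
};

// Weighted union-find: find the root of v while accumulating the offset
// chain into w[v] (full path compression).
static inline int find_root_w(std::vector<int> &parent, std::vector<double> &w,
                              int v) {
    if (parent[v] == v) return v;
    // collect the path
    int stack[64];
    int sp = 0;
    int u = v;
    while (parent[u] != u) {
        stack[sp++] = u;
        u = parent[u];
        if (sp == 64) {  // extremely deep path: compress what we have
            double acc = 0;
            for (int i = sp - 1; i >= 0; --i) {
                acc += w[stack[i]];
                parent[stack[i]] = u;
                w[stack[i]] = acc;
            }
            sp = 0;
        }
    }
    double acc = 0;
    for (int i = sp - 1; i >= 0; --i) {
        acc += w[stack[i]];
        parent[stack[i]] = u;
        w[stack[i]] = acc;
    }
    return u;
}

// TFCE of one dense column-major 3D map. score(v) = sum over thresholds
// h = dh, 2dh, ... of e(v,h)^E * h^H * dh with e(v,h) the size of the
// 26/18/6-connected component of {x >= h} containing v. Voxels are admitted
// in decreasing order into a union-find forest; per threshold each live
// component root receives the increment once (weighted union-find offsets
// give every member its own admission-time-correct total).
static void tfce_one(const double *x, double *score, int nx, int ny, int nz,
                     double H, double E, int n_steps, double dh_in,
                     const std::vector<std::array<int, 3>> &offs,
                     const std::vector<int> &lin_offs, TfceScratch &S) {
    const int N = nx * ny * nz;
    std::fill(score, score + N, 0.0);
    double maxval = 0.0;
    for (int i = 0; i < N; ++i)
        if (x[i] > maxval) maxval = x[i];
    if (maxval <= 0.0) return;

    double dh = dh_in;
    int K;
    if (dh <= 0.0) {
        dh = maxval / n_steps;
        K = n_steps;
    } else {
        K = (int)std::floor(maxval / dh + 1e-9);
        if (K < 1) return;
    }
    // Admission uses x >= h - slack: the top threshold K*dh equals the map
    // maximum only up to rounding, and without slack a 1-ulp wobble in the
    // input would gain or lose a whole integration step at the peak.
    const double slack = 1e-9 * dh;

    S.order.clear();
    for (int i = 0; i < N; ++i)
        if (x[i] > 0.0) S.order.push_back(i);
    std::sort(S.order.begin(), S.order.end(),
              [&](int a, int b) { return x[a] > x[b]; });
    S.roots.clear();

    auto &parent = S.parent;
    auto &csize = S.csize;
    auto &accum = S.accum;
    auto &w = S.w;

    size_t ptr = 0;
    for (int k = K; k >= 1; --k) {
        const double h = k * dh;
        while (ptr < S.order.size() && x[S.order[ptr]] >= h - slack) {
            const int v = S.order[ptr++];
            parent[v] = v;
            csize[v] = 1;
            accum[v] = 0.0;
            w[v] = 0.0;
            S.added[v] = 1;
            S.roots.push_back(v);
            const int vz = v / (nx * ny);
            const int vy = (v / nx) % ny;
            const int vx = v % nx;
            const bool interior = vx > 0 && vx < nx - 1 && vy > 0 &&
                                  vy < ny - 1 && vz > 0 && vz < nz - 1;
            const size_t no = offs.size();
            for (size_t o = 0; o < no; ++o) {
                int u;
                if (interior) {
                    u = v + lin_offs[o];
                } else {
                    const int ux = vx + offs[o][0];
                    const int uy = vy + offs[o][1];
                    const int uz = vz + offs[o][2];
                    if (ux < 0 || ux >= nx || uy < 0 || uy >= ny ||
                        uz < 0 || uz >= nz)
                        continue;
                    u = ux + nx * (uy + ny * uz);
                }
                if (!S.added[u]) continue;
                const int ru = find_root_w(parent, w, u);
                const int rv = find_root_w(parent, w, v);
                if (ru == rv) continue;
                // merge smaller component into larger; the absorbed root
                // keeps its past accumulation as an offset
                int win = ru, lose = rv;
                if (csize[win] < csize[lose]) std::swap(win, lose);
                w[lose] = accum[lose] - accum[win];
                parent[lose] = win;
                csize[win] += csize[lose];
            }
        }
        // one increment per live component at this threshold
        const double hH = std::pow(h, H) * dh;
        size_t nroots = 0;
        for (size_t i = 0; i < S.roots.size(); ++i) {
            const int r = S.roots[i];
            if (parent[r] != r) continue;      // absorbed: drop lazily
            accum[r] += std::pow((double)csize[r], E) * hH;
            S.roots[nroots++] = r;
        }
        S.roots.resize(nroots);
    }
    for (size_t i = 0; i < ptr; ++i) {
        const int v = S.order[i];
        const int r = find_root_w(parent, w, v);
        score[v] = accum[r] + w[v];
        // w[v] is the compressed offset of v to its root (0 for the root)
        S.added[v] = 0;  // leave the scratch clean for the next map
    }
}

// [[Rcpp::export]]
NumericVector tfce_dense_cpp(NumericVector x, IntegerVector dims,
                             double H, double E, int n_steps, int conn,
                             double dh) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const int N = nx * ny * nz;
    if (x.size() != N) stop("map length does not match dims");
    for (int i = 0; i < N; ++i)
        if (!R_finite(x[i])) stop("non-finite value in TFCE input");
    const auto offs = conn_offsets(conn);
    std::vector<int> lin_offs(offs.size());
    for (size_t o = 0; o < offs.size(); ++o)
        lin_offs[o] = offs[o][0] + nx * (offs[o][1] + ny * offs[o][2]);
    TfceScratch S(N);
    NumericVector score(N);
    tfce_one(REAL(x), REAL(score), nx, ny, nz, H, E, n_steps, dh, offs,
             lin_offs, S);
    return score;
}

// Max TFCE score per permutation, both directions, for a block of statistic
// maps given as rows of T over the masked voxels `lin` (1-based linear
// indices into the dense grid). Returns a B x 2 matrix (positive, negative).
// [[Rcpp::export]]
NumericMatrix tfce_max_batch_cpp(NumericMatrix T, IntegerVector lin,
                                 IntegerVector dims, double H, double E,
                                 int n_steps, int conn, double dh) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const int N = nx * ny * nz;
    const int B = T.nrow();
    const int V = T.ncol();
    if (lin.size() != V) stop("lin length does not match T columns");
    const auto offs = conn_offsets(conn);
    std::vector<int> lin_offs(offs.size());
    for (size_t o = 0; o < offs.size(); ++o)
        lin_offs[o] = offs[o][0] + nx * (offs[o][1] + ny * offs[o][2]);
    TfceScratch S(N);
    std::vector<double> dense(N, 0.0), score(N);
    NumericMatrix out(B, 2);
    for (int b = 0; b < B; ++b) {
        for (int v = 0; v < V; ++v) {
            const double t = T(b, v);
            if (!R_finite(t)) stop("non-finite statistic in permutation");
            dense[lin[v] - 1] = t;
        }
        double mx = 0.0;
        tfce_one(dense.data(), score.data(), nx, ny, nz, H, E, n_steps, dh,
                 offs, lin_offs, S);
        for (int v = 0; v < V; ++v)
            if (score[lin[v] - 1] > mx) mx = score[lin[v] - 1];
        out(b, 0) = mx;
        for (int v = 0; v < V; ++v) dense[lin[v] - 1] = -dense[lin[v] - 1];
        mx = 0.0;
        tfce_one(dense.data(), score.data(), nx, ny, nz, H, E, n_steps, dh,
                 offs, lin_offs, S);
        for (int v = 0; v < V; ++v)
            if (score[lin[v] - 1] > mx) mx = score[lin[v] - 1];
        out(b, 1) = mx;
        for (int v = 0; v < V; ++v) dense[lin[v] - 1] = 0.0;
    }
    return out;
}

// Connected-component labelling of a dense logical 3D mask. Labels are
// 1..n_components in order of first encounter along the linear (column-major)
// scan; background is 0.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int conn) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t N = (R_xlen_t)nx * ny * nz;
    if (mask.size() != N) stop("mask length does not match dims");
    IntegerVector labels(N, 0);
    const auto offs = conn_offsets(conn);
    std::vector<int> queue;
    int next = 0;
    for (int s = 0; s < N; ++s) {
        if (!mask[s] || labels[s] != 0) continue;
        ++next;
        labels[s] = next;
        queue.clear();
        queue.push_back(s);
        while (!queue.empty()) {
            const int v = queue.back();
            queue.pop_back();
            const int vz = v / (nx * ny);
            const int vy = (v / nx) % ny;
            const int vx = v % nx;
            for (const auto &o : offs) {
                const int ux = vx + o[0], uy = vy + o[1], uz = vz + o[2];
                if (ux < 0 || ux >= nx || uy < 0 || uy >= ny ||
                    uz < 0 || uz >= nz)
                    continue;
                const int u = ux + nx * (uy + ny * uz);
                if (mask[u] && labels[u] == 0) {
                    labels[u] = next;
                    queue.push_back(u);
                }
            }
        }
    }
    return labels;
}
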