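#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exhaustive best-subset enumeration over a bounded pool, on top of the
// symmetric sweep operator applied to the centred cross-product matrix of
// [forced covariates, pool covariates, outcome].  Centring absorbs the
// intercept, so after sweeping a set of variable rows the bottom-right
// element is the residual sum of squares of the model containing those
// variables plus an intercept.
//
// Enumeration walks a removal tree: the root has every pool variable swept
// in; each child removes one variable and may recursively remove any later
// variable in the current removable list, so every subset of the pool is
// visited exactly once.  Because RSS can only grow as variables are
// removed, a subtree whose entry RSS is already no better than the
// incumbent best at every model size the subtree can still reach cannot
// improve the per-size table and is pruned.
//
// The engine assumes the full design [forced, pool] has full column rank;
// if any sweep pivot underflows the tolerance at the root, it reports
// failure and the R wrapper falls back to a direct per-subset fit.

struct SearchState {
    std::vector<double> A;      // d x d symmetric work matrix
    std::vector<double> diag0;  // original diagonal, for pivot tolerance
    int d;                      // f + m + 1
    int f;                      // forced variables (always swept)
    int m;                      // pool size
    int max_free;
    double tol;
    std::vector<int> inset;     // pool membership of current subset
    int s_cur;
    long long nodes;
    std::vector<double> best_rss;            // indexed by size 0..max_free
    std::vector<std::vector<int> > best_set; // pool positions, sorted
};

static inline double rss_now(const SearchState& st) {
    return st.A[(size_t)(st.d - 1) * st.d + (st.d - 1)];
}

// Goodnight-style sweep of row/column k; applying it twice restores the
// matrix up to a harmless sign flip of row/column k, which never touches
// the diagonal nor any future pivot or RSS readout.
static void sweep_sym(std::vector<double>& A, int d, int k) {
    double* a = A.data();
    const double piv = a[(size_t)k * d + k];
    const double inv = 1.0 / piv;
    for (int i = 0; i < d; ++i) {
        if (i == k) continue;
        const double aik = a[(size_t)i * d + k];
        if (aik == 0.0) continue;
        const double fct = aik * inv;
        double* rowi = a + (size_t)i * d;
        const double* rowk = a + (size_t)k * d;
        for (int j = 0; j < d; ++j) rowi[j] -= fct * rowk[j];
        rowi[k] = fct;  // undo the k-column update inside the row loop
    }
    double* rowk = a + (size_t)k * d;
    for (int j = 0; j < d; ++j) rowk[j] *= inv;
    for (int i = 0; i < d; ++i) a[(size_t)i * d + k] = rowk[i];
    rowk[k] = -inv;
}

static void record(SearchState& st) {
    const int s = st.s_cur;
    if (s > st.max_free) return;
    const double rss = rss_now(st);
    if (rss < st.best_rss[s]) {
        st.best_rss[s] = rss;
        std::vector<int>& dst = st.best_set[s];
        dst.clear();
        for (int v = 0; v < st.m; ++v) if (st.inset[v]) dst.push_back(v);
    } else if (rss == st.best_rss[s]) {
        // exact tie: keep the lexicographically smaller index set
        std::vector<int> cur;
        for (int v = 0; v < st.m; ++v) if (st.inset[v]) cur.push_back(v);
        if (std::lexicographical_compare(cur.begin(), cur.end(),
                                         st.best_set[s].begin(),
                                         st.best_set[s].end()))
            st.best_set[s] = cur;
    }
}

static void enumerate(SearchState& st, const std::vector<int>& removable,
                      size_t from) {
    ++st.nodes;
    record(st);
    const size_t nr = removable.size();
    for (size_t t = from; t < nr; ++t) {
        const int v = removable[t];
        const int col = st.f + v;
        sweep_sym(st.A, st.d, col);  // remove v from the model
        st.inset[v] = 0;
        --st.s_cur;

        // sizes still reachable inside this subtree
        int lo = st.s_cur - (int)(nr - t - 1);
        if (lo < 0) lo = 0;
        int hi = std::min(st.s_cur, st.max_free);
        bool open = false;
        const double rss = rss_now(st);
        for (int s2 = lo; s2 <= hi; ++s2)
            if (rss < st.best_rss[s2]) { open = true; break; }
        if (open) enumerate(st, removable, t + 1);

        sweep_sym(st.A, st.d, col);  // put v back
        st.inset[v] = 1;
        ++st.s_cur;
    }
}

// M: centred cross-product matrix of [forced, pool, y] (d = f + m + 1)
// remove_order: 0-based pool positions, most important first
// [[Rcpp::export(name = ".subset_search_engine")]]
List subset_search_engine(NumericMatrix M, int f, int m, int max_free,
                          IntegerVector remove_order, double tol_rel) {
    const int d = f + m + 1;
    if (M.nrow() != d || M.ncol() != d) stop("cross-product matrix has wrong size");
    SearchState st;
    st.d = d; st.f = f; st.m = m;
    st.max_free = std::min(max_free, m);
    st.A.assign(M.begin(), M.end());
    st.diag0.resize(d);
    for (int i = 0; i < d; ++i) st.diag0[i] = st.A[(size_t)i * d + i];
    st.tol = tol_rel;
    st.inset.assign(m, 1);
    st.s_cur = m;
    st.nodes = 0;
    st.best_rss.assign(st.max_free + 1, R_PosInf);
    st.best_set.assign(st.max_free + 1, std::vector<int>());

    // sweep everything in; a tiny pivot means rank deficiency -> bail out
    for (int k = 0; k < f + m; ++k) {
        const double piv = st.A[(size_t)k * d + k];
        const double ref = st.diag0[k] > 0 ? st.diag0[k] : 1.0;
        if (!(piv > tol_rel * ref)) {
            return List::create(Named("ok") = false,
                                Named("aliased_column") = k + 1);
        }
        sweep_sym(st.A, d, k);
    }

    std::vector<int> removable(remove_order.begin(), remove_order.end());
    if ((int)removable.size() != m) stop("remove_order must cover the pool");
    enumerate(st, removable, 0);

    List sets(st.max_free + 1);
    NumericVector rss(st.max_free + 1);
    for (int s = 0; s <= st.max_free; ++s) {
        rss[s] = st.best_rss[s];
        IntegerVector iv(st.best_set[s].size());
        for (size_t i = 0; i < st.best_set[s].size(); ++i)
            iv[i] = st.best_set[s][i] + 1;  // 1-based pool positions
        sets[s] = iv;
    }
    return List::create(Named("ok") = true,
                        Named("rss") = rss,
                        Named("sets") = sets,
                        Named("nodes") = (double)st.nodes);
}
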