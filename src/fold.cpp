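#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

// Minimum-free-energy folding under a simplified nearest-neighbour model.
// Energy terms (kcal/mol): base-pair energies GC -3, AU -2, GU -1; a -1
// bonus for every stacked pair (i,j)/(i+1,j-1); hairpin-loop closing
// penalty 3.0 + 0.1 per unpaired nucleotide beyond the 3-nt minimum loop.
// Lonely pairs are allowed; interior/bulge/multibranch loops carry no
// explicit penalty, so the total energy of a structure is a function of its
// pair set alone (which keeps the model exhaustively enumerable).

static const double E_GC = -3.0;
static const double E_AU = -2.0;
static const double E_GU = -1.0;
static const double E_STACK = -1.0;
static const double HAIRPIN_BASE = 3.0;
static const double HAIRPIN_PER_NT = 0.1;
static const int MIN_LOOP = 3;
static const double INF = 1e9;
static const double EPS = 1e-9;

static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    default: return -1;
    }
}

static inline double pair_energy(int a, int b) {
    if ((a == 2 && b == 1) || (a == 1 && b == 2)) return E_GC;
    if ((a == 0 && b == 3) || (a == 3 && b == 0)) return E_AU;
    if ((a == 2 && b == 3) || (a == 3 && b == 2)) return E_GU;
    return INF;
}

static inline double hairpin_pen(int loop_len) {
    return HAIRPIN_BASE + HAIRPIN_PER_NT * (loop_len - MIN_LOOP);
}

struct FoldState {
    int n;
    std::vector<int> code;
    // flattened n x n matrices, index i*n + j (0-based, i < j)
    std::vector<double> V;    // min energy with (i,j) paired
    std::vector<double> Wne;  // min energy over non-empty structures on [i,j]
    std::vector<int> pair;    // traceback result: partner or -1

    double atV(int i, int j) const { return (i >= 0 && j < n && j - i > MIN_LOOP) ? V[i * n + j] : INF; }
    double atW(int i, int j) const {  // min over all structures incl. empty
        if (i > j || j - i < MIN_LOOP + 1) return 0.0;
        double w = Wne[i * n + j];
        return w < 0.0 ? w : 0.0;
    }
    double atWne(int i, int j) const { return (i <= j && j - i > MIN_LOOP) ? Wne[i * n + j] : INF; }
};

static void fill_dp(FoldState &st) {
    int n = st.n;
    st.V.assign((size_t)n * n, INF);
    st.Wne.assign((size_t)n * n, INF);
    for (int span = MIN_LOOP + 1; span < n; ++span) {
        for (int i = 0; i + span < n; ++i) {
            int j = i + span;
            double bp = pair_energy(st.code[i], st.code[j]);
            if (bp < INF / 2) {
                double best = hairpin_pen(j - i - 1);
                double vin = st.atV(i + 1, j - 1);
                if (vin < INF / 2 && vin + E_STACK < best) best = vin + E_STACK;
                double wn = st.atWne(i + 1, j - 1);
                if (wn < INF / 2 && wn < best) best = wn;
                st.V[i * n + j] = bp + best;
            }
            double w = st.atWne(i + 1, j);
            for (int k = i + MIN_LOOP + 1; k <= j; ++k) {
                double v = st.atV(i, k);
                if (v < INF / 2) {
                    double cand = v + st.atW(k + 1, j);
                    if (cand < w) w = cand;
                }
            }
            st.Wne[i * n + j] = w;
        }
    }
}

static void trace_V(FoldState &st, int i, int j);

static void trace_Wne(FoldState &st, int i, int j) {
    if (i > j || j - i <= MIN_LOOP) return;
    double target = st.atWne(i, j);
    if (target > INF / 2) return;
    if (std::fabs(st.atWne(i + 1, j) - target) < EPS) {
        trace_Wne(st, i + 1, j);
        return;
    }
    for (int k = i + MIN_LOOP + 1; k <= j; ++k) {
        double v = st.atV(i, k);
        if (v < INF / 2 && std::fabs(v + st.atW(k + 1, j) - target) < EPS) {
            trace_V(st, i, k);
            if (st.atW(k + 1, j) < -EPS) trace_Wne(st, k + 1, j);
            return;
        }
    }
}

static void trace_V(FoldState &st, int i, int j) {
    st.pair[i] = j;
    st.pair[j] = i;
    double bp = pair_energy(st.code[i], st.code[j]);
    double rem = st.V[i * st.n + j] - bp;
    if (std::fabs(rem - hairpin_pen(j - i - 1)) < EPS) return;
    double vin = st.atV(i + 1, j - 1);
    if (vin < INF / 2 && std::fabs(vin + E_STACK - rem) < EPS) {
        trace_V(st, i + 1, j - 1);
        return;
    }
    trace_Wne(st, i + 1, j - 1);
}

// [[Rcpp::export(name = ".rna_fold_internal")]]
List rna_fold_internal(std::string seq) {
    int n = (int)seq.size();
    FoldState st;
    st.n = n;
    st.code.resize(n);
    for (int i = 0; i < n; ++i) {
        int c = base_code(seq[i]);
        if (c < 0) stop("non-nucleotide character in sequence: '%c'", seq[i]);
        st.code[i] = c;
    }
    st.pair.assign(n, -1);
    double mfe = 0.0;
    if (n > MIN_LOOP + 1) {
        fill_dp(st);
        double w = st.atW(0, n - 1);
        if (w < -EPS) {
            mfe = w;
            trace_Wne(st, 0, n - 1);
        }
    }
    std::string db(n, '.');
    IntegerVector pt(n);
    for (int i = 0; i < n; ++i) {
        if (st.pair[i] >= 0) {
            db[i] = (st.pair[i] > i) ? '(' : ')';
            pt[i] = st.pair[i] + 1;
        } else {
            pt[i] = 0;
        }
    }
    return List::create(_["mfe"] = mfe, _["dotbracket"] = db, _["pair_table"] = pt);
}

// Energy of a given pair set under the same model; used for serialization
// checks and by tests that re-score traceback output.
// [[Rcpp::export(name = ".rna_energy_of_pairs")]]
double rna_energy_of_pairs(std::string seq, IntegerVector pt) {
    int n = (int)seq.size();
    if (pt.size() != n) stop("pair table length must equal sequence length");
    double e = 0.0;
    for (int i = 0; i < n; ++i) {
        int j = pt[i] - 1;
        if (j > i) {
            double bp = pair_energy(base_code(seq[i]), base_code(seq[j]));
            if (bp > INF / 2) stop("non-complementary pair in pair table");
            e += bp;
            if (i + 1 < n && pt[i + 1] - 1 == j - 1 && j - 1 > i + 1) e += E_STACK;
            bool inner = false;
            for (int k = i + 1; k < j && !inner; ++k) inner = pt[k] > 0;
            if (!inner) e += hairpin_pen(j - i - 1);
        }
    }
    return e;
}
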