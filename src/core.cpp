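#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Rotation matrix from a unit quaternion (a0, a1, a2, a3), row-major.
// Diagonal: a0^2+a1^2-a2^2-a3^2 etc.; off-diagonals in the standard
// (Horn) convention so that det = +1.
static void quat_to_rot(const double *q, double R[9]) {
    double a0 = q[0], a1 = q[1], a2 = q[2], a3 = q[3];
    R[0] = a0 * a0 + a1 * a1 - a2 * a2 - a3 * a3;
    R[1] = 2.0 * (a1 * a2 - a0 * a3);
    R[2] = 2.0 * (a1 * a3 + a0 * a2);
    R[3] = 2.0 * (a1 * a2 + a0 * a3);
    R[4] = a0 * a0 + a2 * a2 - a1 * a1 - a3 * a3;
    R[5] = 2.0 * (a2 * a3 - a0 * a1);
    R[6] = 2.0 * (a1 * a3 - a0 * a2);
    R[7] = 2.0 * (a2 * a3 + a0 * a1);
    R[8] = a0 * a0 + a3 * a3 - a1 * a1 - a2 * a2;
}

// Shortest-augmenting-path solver for the rectangular (asymmetric)
// assignment problem: every row assigned to exactly one column, every
// column to at most one row, n <= m. Forbidden edges carry cost = +Inf.
// Returns total cost, or -1 feasibility flag via `feasible`.
// Follows the dual-update formulation used by modern LSAP codes
// (Crouse 2016); deterministic: ties resolved by lowest column index,
// preferring unassigned columns at equal path cost.
static bool solve_rect_assignment(const std::vector<double> &cost, int n, int m,
                                  std::vector<int> &col4row, double &total) {
    std::vector<double> u(n, 0.0), v(m, 0.0);
    std::vector<int> row4col(m, -1);
    col4row.assign(n, -1);
    std::vector<double> shortest(m);
    std::vector<int> path(m);
    std::vector<char> done(m);

    for (int cur = 0; cur < n; ++cur) {
        std::fill(shortest.begin(), shortest.end(), INF);
        std::fill(path.begin(), path.end(), -1);
        std::fill(done.begin(), done.end(), 0);
        std::vector<int> SR, SC;
        double minVal = 0.0;
        int i = cur, sink = -1;
        while (sink == -1) {
            SR.push_back(i);
            double lowest = INF;
            int j_low = -1;
            bool j_low_free = false;
            for (int j = 0; j < m; ++j) {
                if (done[j]) continue;
                double c = cost[(size_t)i * m + j];
                double r = (c == INF) ? INF : minVal + c - u[i] - v[j];
                if (r < shortest[j]) { shortest[j] = r; path[j] = i; }
                bool free_col = (row4col[j] == -1);
                if (shortest[j] < lowest ||
                    (shortest[j] == lowest && free_col && !j_low_free)) {
                    lowest = shortest[j];
                    j_low = j;
                    j_low_free = free_col;
                }
            }
            if (!std::isfinite(lowest)) return false;  // no augmenting path
            minVal = lowest;
            done[j_low] = 1;
            SC.push_back(j_low);
            if (row4col[j_low] == -1) sink = j_low;
            else i = row4col[j_low];
        }
        u[cur] += minVal;
        for (size_t k = 0; k < SR.size(); ++k) {
            int r = SR[k];
            if (r != cur) u[r] += minVal - shortest[col4row[r]];
        }
        for (size_t k = 0; k < SC.size(); ++k) {
            int j = SC[k];
            v[j] -= minVal - shortest[j];
        }
        int j = sink;
        while (true) {
            int r = path[j];
            row4col[j] = r;
            int tmp = col4row[r];
            col4row[r] = j;
            if (r == cur) break;
            j = tmp;
        }
    }
    total = 0.0;
    for (int r = 0; r < n; ++r) total += cost[(size_t)r * m + col4row[r]];
    return true;
}

// [[Rcpp::export(name = ".cpp_solve_aap")]]
List cpp_solve_aap(NumericMatrix cost) {
    int n = cost.nrow(), m = cost.ncol();
    if (n > m) stop("assignment requires nrow(cost) <= ncol(cost)");
    std::vector<double> c((size_t)n * m);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < m; ++j) {
            double x = cost(i, j);
            c[(size_t)i * m + j] = ISNA(x) ? INF : x;
        }
    std::vector<int> col4row;
    double total = 0.0;
    bool ok = solve_rect_assignment(c, n, m, col4row, total);
    IntegerVector assign(n);
    if (ok)
        for (int i = 0; i < n; ++i) assign[i] = col4row[i] + 1;
    else
        std::fill(assign.begin(), assign.end(), NA_INTEGER);
    return List::create(_["assignment"] = assign, _["total_cost"] = total,
                        _["feasible"] = ok);
}

// Nearest target index for each row of Pa (coordinates n x 3, Q m x 3).
// Optional label compatibility: lab vectors are integer codes; 0 in labP
// means "no restriction" is NOT implied -- filtering only if same_prop.
// Ties broken by lowest target index.
// [[Rcpp::export(name = ".cpp_closest_map")]]
IntegerVector cpp_closest_map(NumericMatrix Pa, NumericMatrix Q,
                              IntegerVector labP, IntegerVector labQ,
                              bool same_prop) {
    int n = Pa.nrow(), m = Q.nrow();
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        double best = INF;
        int jbest = -1;
        for (int j = 0; j < m; ++j) {
            if (same_prop && labP[i] != labQ[j]) continue;
            double dx = Pa(i, 0) - Q(j, 0);
            double dy = Pa(i, 1) - Q(j, 1);
            double dz = Pa(i, 2) - Q(j, 2);
            double d = dx * dx + dy * dy + dz * dz;
            if (d < best) { best = d; jbest = j; }
        }
        out[i] = (jbest >= 0) ? jbest + 1 : NA_INTEGER;
    }
    return out;
}

// Objective g(a) evaluated in one shot: transform P by (quaternion,
// translation) packed in a7, build squared-distance costs, and either
// take the closest-point mean (kind = 0) or solve the assignment
// problem (kind = 1).  mode: 0 = all pairs, 1 = same property
// (incompatible edges removed; label code 0 = NONE matches nothing and
// the atom is excluded from the mean), 2 = relaxed (incompatible edges
// kept at `penalty`).  Returns the mean squared residual in A^2, or
// +Inf when the graph is infeasible.
// [[Rcpp::export(name = ".cpp_objective")]]
double cpp_objective(NumericMatrix P, NumericMatrix Q, NumericVector a7,
                     IntegerVector labP, IntegerVector labQ, int kind,
                     int mode, double penalty) {
    int n = P.nrow(), m = Q.nrow();
    double q[4] = {a7[0], a7[1], a7[2], a7[3]};
    double nq = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
    if (nq <= 0) stop("zero quaternion");
    for (int k = 0; k < 4; ++k) q[k] /= nq;
    double R[9];
    quat_to_rot(q, R);
    double tx = a7[4], ty = a7[5], tz = a7[6];

    // rows of P entering the graph
    std::vector<int> rows;
    rows.reserve(n);
    for (int i = 0; i < n; ++i) {
        if (mode == 1 && labP[i] == 0) continue;  // NONE: excluded
        rows.push_back(i);
    }
    int nr = (int)rows.size();
    if (nr == 0) return INF;

    std::vector<double> Pt((size_t)nr * 3);
    for (int k = 0; k < nr; ++k) {
        int i = rows[k];
        double x = P(i, 0), y = P(i, 1), z = P(i, 2);
        Pt[k * 3 + 0] = R[0] * x + R[1] * y + R[2] * z + tx;
        Pt[k * 3 + 1] = R[3] * x + R[4] * y + R[5] * z + ty;
        Pt[k * 3 + 2] = R[6] * x + R[7] * y + R[8] * z + tz;
    }

    if (kind == 0) {
        // closest-point mapping (restricted to compatible labels in
        // same-property mode)
        double sum = 0.0;
        for (int k = 0; k < nr; ++k) {
            int i = rows[k];
            double best = INF;
            for (int j = 0; j < m; ++j) {
                if (mode == 1 && labP[i] != labQ[j]) continue;
                double dx = Pt[k * 3] - Q(j, 0);
                double dy = Pt[k * 3 + 1] - Q(j, 1);
                double dz = Pt[k * 3 + 2] - Q(j, 2);
                double d = dx * dx + dy * dy + dz * dz;
                if (d < best) best = d;
            }
            if (!std::isfinite(best)) return INF;
            sum += best;
        }
        return sum / nr;
    }

    if (nr > m) return INF;  // cannot assign injectively
    std::vector<double> cost((size_t)nr * m);
    for (int k = 0; k < nr; ++k) {
        int i = rows[k];
        for (int j = 0; j < m; ++j) {
            double dx = Pt[k * 3] - Q(j, 0);
            double dy = Pt[k * 3 + 1] - Q(j, 1);
            double dz = Pt[k * 3 + 2] - Q(j, 2);
            double d = dx * dx + dy * dy + dz * dz;
            if (mode == 1 && labP[i] != labQ[j]) d = INF;
            else if (mode == 2 && labP[i] != labQ[j]) d = penalty;
            cost[(size_t)k * m + j] = d;
        }
    }
    std::vector<int> col4row;
    double total = 0.0;
    bool ok = solve_rect_assignment(cost, nr, m, col4row, total);
    if (!ok) return INF;
    return total / nr;
}
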