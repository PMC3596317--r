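#include <Rcpp.h>
#include <cmath>
#include <set>
#include <utility>
#include <vector>
using namespace Rcpp;

// Quasi-uniform unit-sphere dots (golden-spiral), deterministic.
static std::vector<double> sphere_dots(int n) {
    std::vector<double> pts(3 * n);
    const double ga = M_PI * (3.0 - std::sqrt(5.0));
    for (int i = 0; i < n; ++i) {
        double z = 1.0 - (2.0 * i + 1.0) / n;
        double r = std::sqrt(std::max(0.0, 1.0 - z * z));
        double th = ga * i;
        pts[3 * i]     = r * std::cos(th);
        pts[3 * i + 1] = r * std::sin(th);
        pts[3 * i + 2] = z;
    }
    return pts;
}

// Shrake-Rupley solvent-accessible surface area, one value per atom.
// xyz: n x 3 matrix, radii: per-atom vdW radii (Angstrom).
// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radii,
                       double probe, int n_points) {
    int n = xyz.nrow();
    NumericVector area(n);
    if (n == 0) return area;
    std::vector<double> dots = sphere_dots(n_points);
    std::vector<double> R(n);
    double rmax = 0.0;
    for (int i = 0; i < n; ++i) {
        R[i] = radii[i] + probe;
        if (R[i] > rmax) rmax = R[i];
    }
    std::vector<int> nb;
    nb.reserve(64);
    for (int i = 0; i < n; ++i) {
        double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
        double Ri = R[i];
        nb.clear();
        double reach = Ri + rmax;
        for (int j = 0; j < n; ++j) {
            if (j == i) continue;
            double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi, dz = xyz(j, 2) - zi;
            double d2 = dx * dx + dy * dy + dz * dz;
            double cut = Ri + R[j];
            if (d2 < cut * cut && d2 < reach * reach) nb.push_back(j);
        }
        int exposed = 0;
        for (int k = 0; k < n_points; ++k) {
            double px = xi + Ri * dots[3 * k];
            double py = yi + Ri * dots[3 * k + 1];
            double pz = zi + Ri * dots[3 * k + 2];
            bool free_pt = true;
            for (size_t m = 0; m < nb.size(); ++m) {
                int j = nb[m];
                double dx = px - xyz(j, 0), dy = py - xyz(j, 1), dz = pz - xyz(j, 2);
                if (dx * dx + dy * dy + dz * dz < R[j] * R[j]) { free_pt = false; break; }
            }
            if (free_pt) ++exposed;
        }
        area[i] = 4.0 * M_PI * Ri * Ri * exposed / n_points;
    }
    return area;
}

// Intermolecular 12-6 Lennard-Jones + Coulomb, truncated and shifted at `cutoff`.
// sigma/eps are per-atom; Lorentz-Berthelot combination. Charges in e,
// energies kcal/mol with relative dielectric `eps_r`.
// [[Rcpp::export(name = ".pair_energies_cpp")]]
NumericVector pair_energies_cpp(NumericMatrix a_xyz, NumericVector a_sig,
                                NumericVector a_eps, NumericVector a_q,
                                NumericMatrix b_xyz, NumericVector b_sig,
                                NumericVector b_eps, NumericVector b_q,
                                double cutoff, double eps_r) {
    const double COUL = 332.0636;
    int na = a_xyz.nrow(), nb_ = b_xyz.nrow();
    double c2 = cutoff * cutoff;
    double evdw = 0.0, eelec = 0.0;
    for (int i = 0; i < na; ++i) {
        double xi = a_xyz(i, 0), yi = a_xyz(i, 1), zi = a_xyz(i, 2);
        for (int j = 0; j < nb_; ++j) {
            double dx = b_xyz(j, 0) - xi, dy = b_xyz(j, 1) - yi, dz = b_xyz(j, 2) - zi;
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 >= c2 || d2 <= 1e-12) continue;
            double d = std::sqrt(d2);
            double sig = 0.5 * (a_sig[i] + b_sig[j]);
            double eps = std::sqrt(a_eps[i] * b_eps[j]);
            double sr2 = sig * sig / d2;
            double sr6 = sr2 * sr2 * sr2;
            double src2 = sig * sig / c2;
            double src6 = src2 * src2 * src2;
            evdw += 4.0 * eps * (sr6 * sr6 - sr6) - 4.0 * eps * (src6 * src6 - src6);
            double qq = a_q[i] * b_q[j];
            if (qq != 0.0)
                eelec += COUL * qq / eps_r * (1.0 / d - 1.0 / cutoff);
        }
    }
    return NumericVector::create(evdw, eelec);
}

// AIR effective-distance energy. groups: list of 0-based atom-index vectors,
// one per active residue on the receptor; passive_xyz: all restrained partner
// atoms. d_eff(i) = (sum over pairs d^-6)^(-1/6); E = k * sum max(0, d_eff - ub)^2.
// [[Rcpp::export(name = ".air_energy_cpp")]]
double air_energy_cpp(NumericMatrix rec_xyz, List groups, NumericMatrix passive_xyz,
                      double upper_bound, double k) {
    int np = passive_xyz.nrow();
    double e = 0.0;
    for (int g = 0; g < groups.size(); ++g) {
        IntegerVector idx = groups[g];
        double s = 0.0;
        for (int ii = 0; ii < idx.size(); ++ii) {
            int i = idx[ii];
            double xi = rec_xyz(i, 0), yi = rec_xyz(i, 1), zi = rec_xyz(i, 2);
            for (int j = 0; j < np; ++j) {
                double dx = passive_xyz(j, 0) - xi, dy = passive_xyz(j, 1) - yi,
                       dz = passive_xyz(j, 2) - zi;
                double d2 = dx * dx + dy * dy + dz * dz;
                if (d2 < 1e-12) d2 = 1e-12;
                double d6 = d2 * d2 * d2;
                s += 1.0 / d6;
            }
        }
        if (s <= 0.0) continue;
        double deff = std::pow(s, -1.0 / 6.0);
        double viol = deff - upper_bound;
        if (viol > 0.0) e += k * viol * viol;
    }
    return e;
}

// Residue-residue heavy-atom contact pairs within cutoff.
// Returns a 2-column matrix of 1-based (group_a, group_b) indices.
// [[Rcpp::export(name = ".contact_pairs_cpp")]]
IntegerMatrix contact_pairs_cpp(NumericMatrix a_xyz, IntegerVector a_grp,
                                NumericMatrix b_xyz, IntegerVector b_grp,
                                double cutoff) {
    int na = a_xyz.nrow(), nb_ = b_xyz.nrow();
    double c2 = cutoff * cutoff;
    std::set<std::pair<int, int> > hits;
    for (int i = 0; i < na; ++i) {
        double xi = a_xyz(i, 0), yi = a_xyz(i, 1), zi = a_xyz(i, 2);
        for (int j = 0; j < nb_; ++j) {
            double dx = b_xyz(j, 0) - xi, dy = b_xyz(j, 1) - yi, dz = b_xyz(j, 2) - zi;
            if (dx * dx + dy * dy + dz * dz < c2)
                hits.insert(std::make_pair(a_grp[i], b_grp[j]));
        }
    }
    IntegerMatrix out(hits.size(), 2);
    int r = 0;
    for (std::set<std::pair<int, int> >::iterator it = hits.begin();
         it != hits.end(); ++it, ++r) {
        out(r, 0) = it->first;
        out(r, 1) = it->second;
    }
    return out;
}

// Complex SASA with receptor short-circuit: receptor atoms with no peptide
// sphere overlap keep their precomputed free-receptor area (receptor-receptor
// occlusion is pose-independent); only near-interface receptor atoms and all
// peptide atoms are recomputed. Returns per-atom areas, receptor then peptide.
// [[Rcpp::export(name = ".sasa_complex_cpp")]]
NumericVector sasa_complex_cpp(NumericMatrix rec_xyz, NumericVector rec_radii,
                               NumericVector rec_free,
                               NumericMatrix pep_xyz, NumericVector pep_radii,
                               double probe, int n_points) {
    int nr = rec_xyz.nrow(), np = pep_xyz.nrow();
    NumericVector area(nr + np);
    std::vector<double> dots = sphere_dots(n_points);
    std::vector<double> Rr(nr), Rp(np);
    double rmax = 0.0;
    for (int i = 0; i < nr; ++i) { Rr[i] = rec_radii[i] + probe; rmax = std::max(rmax, Rr[i]); }
    for (int j = 0; j < np; ++j) { Rp[j] = pep_radii[j] + probe; rmax = std::max(rmax, Rp[j]); }

    std::vector<int> nb; nb.reserve(128);
    // which receptor atoms need recomputation
    std::vector<char> touch(nr, 0);
    for (int i = 0; i < nr; ++i) {
        double xi = rec_xyz(i, 0), yi = rec_xyz(i, 1), zi = rec_xyz(i, 2);
        for (int j = 0; j < np; ++j) {
            double dx = pep_xyz(j, 0) - xi, dy = pep_xyz(j, 1) - yi, dz = pep_xyz(j, 2) - zi;
            double cut = Rr[i] + Rp[j];
            if (dx * dx + dy * dy + dz * dz < cut * cut) { touch[i] = 1; break; }
        }
    }
    for (int i = 0; i < nr; ++i) {
        if (!touch[i]) { area[i] = rec_free[i]; continue; }
        double xi = rec_xyz(i, 0), yi = rec_xyz(i, 1), zi = rec_xyz(i, 2);
        double Ri = Rr[i];
        nb.clear();
        for (int j = 0; j < nr; ++j) {
            if (j == i) continue;
            double dx = rec_xyz(j, 0) - xi, dy = rec_xyz(j, 1) - yi, dz = rec_xyz(j, 2) - zi;
            double cut = Ri + Rr[j];
            if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(j);
        }
        int nrec_nb = nb.size();
        for (int j = 0; j < np; ++j) {
            double dx = pep_xyz(j, 0) - xi, dy = pep_xyz(j, 1) - yi, dz = pep_xyz(j, 2) - zi;
            double cut = Ri + Rp[j];
            if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(nr + j);
        }
        int exposed = 0;
        for (int k = 0; k < n_points; ++k) {
            double px = xi + Ri * dots[3 * k];
            double py = yi + Ri * dots[3 * k + 1];
            double pz = zi + Ri * dots[3 * k + 2];
            bool free_pt = true;
            for (size_t m = 0; m < nb.size(); ++m) {
                int j = nb[m];
                double ax, ay, az, Rj;
                if ((int)m < nrec_nb) { ax = rec_xyz(j, 0); ay = rec_xyz(j, 1); az = rec_xyz(j, 2); Rj = Rr[j]; }
                else { ax = pep_xyz(j - nr, 0); ay = pep_xyz(j - nr, 1); az = pep_xyz(j - nr, 2); Rj = Rp[j - nr]; }
                double dx = px - ax, dy = py - ay, dz = pz - az;
                if (dx * dx + dy * dy + dz * dz < Rj * Rj) { free_pt = false; break; }
            }
            if (free_pt) ++exposed;
        }
        area[i] = 4.0 * M_PI * Ri * Ri * exposed / n_points;
    }
    for (int j = 0; j < np; ++j) {
        double xj = pep_xyz(j, 0), yj = pep_xyz(j, 1), zj = pep_xyz(j, 2);
        double Rj = Rp[j];
        nb.clear();
        int nrec_nb = 0;
        for (int i = 0; i < nr; ++i) {
            double dx = rec_xyz(i, 0) - xj, dy = rec_xyz(i, 1) - yj, dz = rec_xyz(i, 2) - zj;
            double cut = Rj + Rr[i];
            if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(i);
        }
        nrec_nb = nb.size();
        for (int i = 0; i < np; ++i) {
            if (i == j) continue;
            double dx = pep_xyz(i, 0) - xj, dy = pep_xyz(i, 1) - yj, dz = pep_xyz(i, 2) - zj;
            double cut = Rj + Rp[i];
            if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(i);
        }
        int exposed = 0;
        for (int k = 0; k < n_points; ++k) {
            double px = xj + Rj * dots[3 * k];
            double py = yj + Rj * dots[3 * k + 1];
            double pz = zj + Rj * dots[3 * k + 2];
            bool free_pt = true;
            for (size_t m = 0; m < nb.size(); ++m) {
                int i = nb[m];
                double ax, ay, az, Ri;
                if ((int)m < nrec_nb) { ax = rec_xyz(i, 0); ay = rec_xyz(i, 1); az = rec_xyz(i, 2); Ri = Rr[i]; }
                else { ax = pep_xyz(i, 0); ay = pep_xyz(i, 1); az = pep_xyz(i, 2); Ri = Rp[i]; }
                double dx = px - ax, dy = py - ay, dz = pz - az;
                if (dx * dx + dy * dy + dz * dz < Ri * Ri) { free_pt = false; break; }
            }
            if (free_pt) ++exposed;
        }
        area[nr + j] = 4.0 * M_PI * Rj * Rj * exposed / n_points;
    }
    return area;
}
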