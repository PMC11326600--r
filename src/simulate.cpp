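// Fixed-step kinetic Monte Carlo core for the half-sarcomere model.
//
// Chemistry: per step, each myosin head (visited in a fresh random
// permutation) makes at most one transition, drawn with probabilities
// p = 1 - exp(-k * dt) for the transitions available to its current state;
// competing transitions are resolved by a single uniform draw over
// {stay, option1, option2}. Mechanics: after any accepted transition the
// linear force balance of the spring network is re-solved (direct dense
// solve), so chemistry always sees elastically equilibrated positions.
// Titin bears force only in extension (slack under compression).

#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct Model {
  // node layout
  int n_nodes, n_actin, n_myosin;
  int zline, mline;                 // 0-based node indices
  std::vector<int> actin, myosin;   // 0-based node indices
  double x_anchor, gamma0;
  std::vector<double> x0;           // rest positions (initial & fixed values)
  // springs
  double k_a, k_m, k_t, k_f, k_xb;
  double a0, m0, b0, d_ps, x_f0;
  // kinetics (energies in pN nm)
  double kbt, dG_bind, dG_stroke, dG_hyd, dG_dpi;
  double k_bind, k23_cap, k_atp0;
  double ln_atp, ln_adppi;
};

struct RateSet {
  double k12(const Model& M, double s) {
    return M.k_bind * std::exp(-0.25 * M.k_xb * s * s / M.kbt);
  }
  double k21(const Model& M, double s) {
    // k12 / K12
    return M.k_bind *
      std::exp((0.25 * M.k_xb * s * s + M.dG_bind) / M.kbt);
  }
  double k32(const Model& M, double s) {
    double g = M.dG_stroke - M.dG_dpi +
      0.5 * M.k_xb * (2.0 * s * M.d_ps + M.d_ps * M.d_ps) +
      M.kbt * M.ln_adppi;
    return M.k23_cap * std::exp(g / M.kbt);
  }
  double k31(const Model& M, double s) {
    double g = -M.dG_bind - M.dG_stroke - M.dG_hyd + M.dG_dpi -
      0.5 * M.k_xb * (s + M.d_ps) * (s + M.d_ps) -
      M.kbt * M.ln_atp;
    return M.k_atp0 * std::exp(-g / M.kbt);
  }
};

// Solve equilibrium positions for the current cross-bridge configuration.
// states/partner are per-myosin (partner is a 0-based actin-array index, -1
// if unbound). Returns positions for all nodes (fixed Z-line kept at x0).
void solve_mechanics(const Model& M,
                     const std::vector<int>& states,
                     const std::vector<int>& partner,
                     std::vector<double>& pos,
                     bool& titin_engaged) {
  const int nf = M.n_nodes - 1; // all nodes free except the Z-line
  // free-coordinate index of node i (zline is node 0 by construction)
  auto fidx = [&](int node) { return node - 1; };

  arma::mat K(nf, nf);
  arma::vec V(nf);

  auto assemble = [&](bool with_titin) {
    K.zeros();
    V.zeros();
    // oriented spring (i Z-ward, j M-ward), j == -2 encodes the fixed anchor
    auto add_spring = [&](int i, int j, double k, double r) {
      double xj_fixed = (j == -2) ? M.x_anchor : 0.0;
      int ci = (i == M.zline) ? -1 : fidx(i);
      int cj = (j < 0 || j == M.zline) ? -1 : fidx(j);
      if (ci >= 0) {
        K(ci, ci) += k;
        if (cj >= 0) K(ci, cj) -= k; else V(ci) += k * ((j == -2) ? xj_fixed : M.x0[M.zline]);
        V(ci) -= k * r;
      }
      if (cj >= 0) {
        K(cj, cj) += k;
        if (ci >= 0) K(cj, ci) -= k; else V(cj) += k * M.x0[i];
        V(cj) += k * r;
      }
    };
    // thin filament: zline - a1 - ... - aN
    add_spring(M.zline, M.actin[0], M.k_a, M.a0);
    for (int i = 0; i + 1 < M.n_actin; ++i)
      add_spring(M.actin[i], M.actin[i + 1], M.k_a, M.a0);
    // thick filament: m1 - ... - mN - Mline
    for (int j = 0; j + 1 < M.n_myosin; ++j)
      add_spring(M.myosin[j], M.myosin[j + 1], M.k_m, M.m0);
    add_spring(M.myosin[M.n_myosin - 1], M.mline, M.k_m, M.m0);
    // titin: Z-line to the myosin node most distal from the M-line
    if (with_titin) add_spring(M.zline, M.myosin[0], M.k_t, M.gamma0);
    // external substrate spring: M-line to fixed anchor
    add_spring(M.mline, -2, M.k_f, M.x_f0);
    // bound cross-bridges
    for (int m = 0; m < M.n_myosin; ++m) {
      if (states[m] != 1) {
        double rest = (states[m] == 3) ? (M.b0 - M.d_ps) : M.b0;
        add_spring(M.actin[partner[m]], M.myosin[m], M.k_xb, rest);
      }
    }
  };

  auto run_solve = [&](bool with_titin, arma::vec& out) -> bool {
    assemble(with_titin);
    return arma::solve(out, K, V, arma::solve_opts::no_approx);
  };

  arma::vec p(nf);
  if (!run_solve(true, p)) stop("stiffness matrix is singular");
  titin_engaged = true;
  if (p(fidx(M.myosin[0])) < M.gamma0) {
    // titin compressed -> slack; drop it unless the titin-free solution
    // stretches it again (then keep the engaged branch)
    arma::vec p2(nf);
    if (!run_solve(false, p2)) stop("stiffness matrix is singular");
    if (p2(fidx(M.myosin[0])) < M.gamma0) {
      p = p2;
      titin_engaged = false;
    }
  }
  for (int i = 0; i < M.n_nodes; ++i)
    pos[i] = (i == M.zline) ? M.x0[i] : p(fidx(i));
}

double elastic_energy(const Model& M,
                      const std::vector<int>& states,
                      const std::vector<int>& partner,
                      const std::vector<double>& pos,
                      double& e_external) {
  double e_int = 0.0;
  auto eseg = [&](double xi, double xj, double k, double r) {
    double ext = xj - xi - r;
    return 0.5 * k * ext * ext;
  };
  e_int += eseg(pos[M.zline], pos[M.actin[0]], M.k_a, M.a0);
  for (int i = 0; i + 1 < M.n_actin; ++i)
    e_int += eseg(pos[M.actin[i]], pos[M.actin[i + 1]], M.k_a, M.a0);
  for (int j = 0; j + 1 < M.n_myosin; ++j)
    e_int += eseg(pos[M.myosin[j]], pos[M.myosin[j + 1]], M.k_m, M.m0);
  e_int += eseg(pos[M.myosin[M.n_myosin - 1]], pos[M.mline], M.k_m, M.m0);
  double titin_ext = pos[M.myosin[0]] - pos[M.zline] - M.gamma0;
  if (titin_ext > 0) e_int += 0.5 * M.k_t * titin_ext * titin_ext;
  for (int m = 0; m < M.n_myosin; ++m) {
    if (states[m] != 1) {
      double rest = (states[m] == 3) ? (M.b0 - M.d_ps) : M.b0;
      e_int += eseg(pos[M.actin[partner[m]]], pos[M.myosin[m]], M.k_xb, rest);
    }
  }
  e_external = eseg(pos[M.mline], M.x_anchor, M.k_f, M.x_f0);
  return e_int;
}

} // namespace

// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
List simulate_core(List lattice_spec, List kinetic_spec, List control) {
  Model M;
  M.n_nodes = as<int>(lattice_spec["n_nodes"]);
  M.n_actin = as<int>(lattice_spec["n_actin"]);
  M.n_myosin = as<int>(lattice_spec["n_myosin"]);
  M.zline = as<int>(lattice_spec["zline"]);
  M.mline = as<int>(lattice_spec["mline"]);
  M.actin = as<std::vector<int>>(lattice_spec["actin"]);
  M.myosin = as<std::vector<int>>(lattice_spec["myosin"]);
  M.x_anchor = as<double>(lattice_spec["x_anchor"]);
  M.gamma0 = as<double>(lattice_spec["gamma0"]);
  M.x0 = as<std::vector<double>>(lattice_spec["x0"]);
  M.k_a = as<double>(kinetic_spec["k_a"]);
  M.k_m = as<double>(kinetic_spec["k_m"]);
  M.k_t = as<double>(kinetic_spec["k_t"]);
  M.k_f = as<double>(kinetic_spec["k_f"]);
  M.k_xb = as<double>(kinetic_spec["k_xb"]);
  M.a0 = as<double>(kinetic_spec["a0"]);
  M.m0 = as<double>(kinetic_spec["m0"]);
  M.b0 = as<double>(kinetic_spec["b0"]);
  M.d_ps = as<double>(kinetic_spec["d_ps"]);
  M.x_f0 = as<double>(kinetic_spec["x_f0"]);
  M.kbt = as<double>(kinetic_spec["kbt"]);
  M.dG_bind = as<double>(kinetic_spec["dG_bind"]);
  M.dG_stroke = as<double>(kinetic_spec["dG_stroke"]);
  M.dG_hyd = as<double>(kinetic_spec["dG_hyd"]);
  M.dG_dpi = as<double>(kinetic_spec["dG_dpi"]);
  M.k_bind = as<double>(kinetic_spec["k_bind"]);
  M.k23_cap = as<double>(kinetic_spec["k23_cap"]);
  M.k_atp0 = as<double>(kinetic_spec["k_atp0"]);
  M.ln_atp = as<double>(kinetic_spec["ln_atp"]);
  M.ln_adppi = as<double>(kinetic_spec["ln_adppi"]);

  const double dt = as<double>(control["dt"]);
  const long n_steps = (long)as<double>(control["n_steps"]);
  const int stride = as<int>(control["record_stride"]);
  const double p_cap = as<double>(control["p_cap"]);
  const double cutoff = as<double>(control["strain_cutoff"]);
  const bool rate_override = as<bool>(control["rate_override"]);
  // optional constant-rate override used by tests (all six rates fixed)
  double o12 = 0, o21 = 0, o23 = 0, o32 = 0, o31 = 0, o13 = 0;
  if (rate_override) {
    NumericVector ov = control["override_rates"];
    o12 = ov[0]; o21 = ov[1]; o23 = ov[2]; o32 = ov[3]; o31 = ov[4]; o13 = ov[5];
  }

  RateSet R;
  const int nm = M.n_myosin, na = M.n_actin;
  std::vector<int> states(nm, 1), partner(nm, -1);
  std::vector<bool> occupied(na, false);
  std::vector<double> pos = M.x0;
  bool titin_engaged = true;

  // recording
  const long n_rec = n_steps / stride + 1;
  NumericVector rec_time(n_rec), rec_force(n_rec), rec_eint(n_rec), rec_eext(n_rec);
  IntegerMatrix rec_state(n_rec, nm), rec_partner(n_rec, nm);
  NumericMatrix rec_strain(n_rec, nm);
  NumericMatrix rec_pos(n_rec, M.n_nodes);
  std::vector<double> ev31_t, ev13_t;
  std::vector<int> ev31_m, ev13_m;
  NumericMatrix state_time(nm, 3);
  IntegerMatrix trans_count(3, 3);
  double esd_sum = 0.0;
  long esd_n = 0, cap_events = 0, rejected_claims = 0;
  long rec_i = 0;

  auto strain_of = [&](int m) {
    return pos[M.myosin[m]] - pos[M.actin[partner[m]]] - M.b0;
  };

  auto record = [&](double t) {
    rec_time[rec_i] = t;
    double e_ext = 0.0;
    double e_int = elastic_energy(M, states, partner, pos, e_ext);
    rec_eint[rec_i] = e_int;
    rec_eext[rec_i] = e_ext;
    rec_force[rec_i] = M.k_f * ((M.x_anchor - pos[M.mline]) - M.x_f0);
    for (int m = 0; m < nm; ++m) {
      rec_state(rec_i, m) = states[m];
      rec_partner(rec_i, m) = (partner[m] < 0) ? NA_INTEGER : partner[m] + 1;
      rec_strain(rec_i, m) = (partner[m] < 0) ? NA_REAL : strain_of(m);
    }
    for (int i = 0; i < M.n_nodes; ++i) rec_pos(rec_i, i) = pos[i];
    ++rec_i;
  };

  // eligible actin node for a detached myosin: unoccupied node minimising
  // |x_m - x_a - b0|; ties break toward the Z-line; none beyond the cutoff
  auto eligible = [&](int m, double& s_out) -> int {
    double xm = pos[M.myosin[m]];
    int best = -1;
    double best_abs = cutoff;
    for (int i = 0; i < na; ++i) {
      if (occupied[i]) continue;
      double s = xm - pos[M.actin[i]] - M.b0;
      double a = std::fabs(s);
      if (a < best_abs - 1e-12 || (best < 0 && a <= cutoff)) {
        if (a <= cutoff) { best = i; best_abs = a; s_out = s; }
      }
      // exact tie: keep the earlier (more Z-ward) node, i.e. do nothing
    }
    return best;
  };

  std::vector<int> perm(nm);
  record(0.0);

  for (long step = 1; step <= n_steps; ++step) {
    // fresh random permutation of myosin visit order (Fisher-Yates)
    for (int i = 0; i < nm; ++i) perm[i] = i;
    for (int i = nm - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }

    bool any_transition = false;
    for (int pi = 0; pi < nm; ++pi) {
      int m = perm[pi];
      int st = states[m];
      // up to two candidate transitions: (target state, partner, rate)
      int tgt[2] = {0, 0}, tgt_partner[2] = {-1, -1};
      double rate[2] = {0.0, 0.0};
      int nopt = 0;
      if (st == 1) {
        double s = 0.0;
        int node = eligible(m, s);
        if (node >= 0) {
          tgt[nopt] = 2; tgt_partner[nopt] = node;
          rate[nopt++] = rate_override ? o12 : R.k12(M, s);
          tgt[nopt] = 3; tgt_partner[nopt] = node;
          rate[nopt++] = rate_override ? o13 : M.k_atp0;
        } else if (na > 0) {
          ++rejected_claims; // contention or cutoff: no claim this step
        }
      } else {
        double s = strain_of(m);
        if (st == 2) {
          tgt[nopt] = 1; rate[nopt++] = rate_override ? o21 : R.k21(M, s);
          tgt[nopt] = 3; tgt_partner[1] = partner[m];
          rate[nopt++] = rate_override ? o23 : M.k23_cap;
          tgt_partner[0] = -1;
        } else { // state 3
          tgt[nopt] = 2; tgt_partner[0] = partner[m];
          rate[nopt++] = rate_override ? o32 : R.k32(M, s);
          tgt[nopt] = 1; tgt_partner[1] = -1;
          rate[nopt++] = rate_override ? o31 : R.k31(M, s);
        }
      }
      if (nopt == 0) continue;
      double p0 = 1.0 - std::exp(-rate[0] * dt);
      double p1 = (nopt > 1) ? 1.0 - std::exp(-rate[1] * dt) : 0.0;
      double ptot = p0 + p1;
      if (ptot > p_cap) {
        double sc = p_cap / ptot;
        p0 *= sc; p1 *= sc;
        ++cap_events;
      }
      double u = unif_rand();
      int chosen = -1;
      if (u < p0) chosen = 0;
      else if (u < p0 + p1) chosen = 1;
      if (chosen < 0) continue;

      int to = tgt[chosen];
      // bookkeeping of occupancy and events
      if (st == 1) {
        partner[m] = tgt_partner[chosen];
        occupied[partner[m]] = true;
        if (to == 3) { ev13_t.push_back(step * dt); ev13_m.push_back(m + 1); }
      } else if (to == 1) {
        occupied[partner[m]] = false;
        partner[m] = -1;
        if (st == 3) { ev31_t.push_back(step * dt); ev31_m.push_back(m + 1); }
      }
      trans_count(st - 1, to - 1) += 1;
      states[m] = to;
      any_transition = true;
    }

    if (any_transition) solve_mechanics(M, states, partner, pos, titin_engaged);

    for (int m = 0; m < nm; ++m) {
      state_time(m, states[m] - 1) += dt;
      if (states[m] == 3) {
        esd_sum += -strain_of(m);
        ++esd_n;
      }
    }
    if (step % stride == 0) record(step * dt);
  }

  return List::create(
    _["time"] = rec_time,
    _["force"] = rec_force,
    _["energy_internal"] = rec_eint,
    _["energy_external"] = rec_eext,
    _["state"] = rec_state,
    _["partner"] = rec_partner,
    _["strain"] = rec_strain,
    _["positions"] = rec_pos,
    _["hydrolysis_times"] = wrap(ev31_t),
    _["hydrolysis_myosin"] = wrap(ev31_m),
    _["reverse_times"] = wrap(ev13_t),
    _["reverse_myosin"] = wrap(ev13_m),
    _["state_time"] = state_time,
    _["transition_counts"] = trans_count,
    _["esd_sum"] = esd_sum,
    _["esd_n"] = (double)esd_n,
    _["cap_events"] = (double)cap_events,
    _["rejected_claims"] = (double)rejected_claims
  );
}

// Mechanics-only entry point: equilibrium for a fixed cross-bridge
// configuration, used to cross-check the compiled assembly against the plain
// R implementation.
// [[Rcpp::export]]
List mechanics_core(List lattice_spec, List kinetic_spec,
                    IntegerVector states_in, IntegerVector partner_in) {
  Model M;
  M.n_nodes = as<int>(lattice_spec["n_nodes"]);
  M.n_actin = as<int>(lattice_spec["n_actin"]);
  M.n_myosin = as<int>(lattice_spec["n_myosin"]);
  M.zline = as<int>(lattice_spec["zline"]);
  M.mline = as<int>(lattice_spec["mline"]);
  M.actin = as<std::vector<int>>(lattice_spec["actin"]);
  M.myosin = as<std::vector<int>>(lattice_spec["myosin"]);
  M.x_anchor = as<double>(lattice_spec["x_anchor"]);
  M.gamma0 = as<double>(lattice_spec["gamma0"]);
  M.x0 = as<std::vector<double>>(lattice_spec["x0"]);
  M.k_a = as<double>(kinetic_spec["k_a"]);
  M.k_m = as<double>(kinetic_spec["k_m"]);
  M.k_t = as<double>(kinetic_spec["k_t"]);
  M.k_f = as<double>(kinetic_spec["k_f"]);
  M.k_xb = as<double>(kinetic_spec["k_xb"]);
  M.a0 = as<double>(kinetic_spec["a0"]);
  M.m0 = as<double>(kinetic_spec["m0"]);
  M.b0 = as<double>(kinetic_spec["b0"]);
  M.d_ps = as<double>(kinetic_spec["d_ps"]);
  M.x_f0 = as<double>(kinetic_spec["x_f0"]);

  std::vector<int> states = as<std::vector<int>>(states_in);
  std::vector<int> partner(M.n_myosin, -1);
  for (int m = 0; m < M.n_myosin; ++m)
    partner[m] = (partner_in[m] == NA_INTEGER) ? -1 : partner_in[m] - 1;

  std::vector<double> pos = M.x0;
  bool titin_engaged = true;
  solve_mechanics(M, states, partner, pos, titin_engaged);
  double e_ext = 0.0;
  double e_int = elastic_energy(M, states, partner, pos, e_ext);
  return List::create(
    _["positions"] = wrap(pos),
    _["external_force"] = M.k_f * ((M.x_anchor - pos[M.mline]) - M.x_f0),
    _["energy_internal"] = e_int,
    _["energy_external"] = e_ext,
    _["titin_engaged"] = titin_engaged
  );
}
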