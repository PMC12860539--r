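#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// 4x4 Hermite bending element, DOFs (w_i, th_i, w_j, th_j)
static mat element_k(double EI, double L) {
  mat k(4, 4);
  double L2 = L * L;
  k = {{ 12.0,    6.0 * L, -12.0,    6.0 * L},
       {6.0 * L,  4.0 * L2, -6.0 * L, 2.0 * L2},
       {-12.0,   -6.0 * L,  12.0,   -6.0 * L},
       {6.0 * L,  2.0 * L2, -6.0 * L, 4.0 * L2}};
  return (EI / (L * L2)) * k;
}

// Solve (K + springs) u = F with prescribed-zero DOFs eliminated in place.
// Kbase is the unconstrained beam stiffness; springs act on w DOFs.
static vec solve_state(const mat& Kbase,
                       const std::vector<int>& spr_node,   // 0-based node
                       const std::vector<double>& spr_k,
                       const std::vector<double>& spr_z0,
                       const std::vector<int>& fixed,      // 0-based DOF
                       const vec& F_ext, bool& ok) {
  const uword nd = Kbase.n_rows;
  mat K = Kbase;
  vec F = F_ext;
  for (size_t s = 0; s < spr_node.size(); ++s) {
    uword wd = 2 * (uword)spr_node[s];
    K(wd, wd) += spr_k[s];
    F(wd) += spr_k[s] * spr_z0[s];
  }
  for (int d : fixed) {
    K.row((uword)d).zeros();
    K.col((uword)d).zeros();
    K((uword)d, (uword)d) = 1.0;
    F((uword)d) = 0.0;
  }
  vec u;
  ok = solve(u, K, F, solve_opts::no_approx);
  if (!ok) u = vec(nd, fill::zeros);
  return u;
}

// Quasi-static bevel-tip insertion: 1-mm steps, preloaded tissue springs,
// spring shift toward the base after each element length of advance.
// [[Rcpp::export]]
Rcpp::List cpp_simulate_insertion(int n_nodes, double needle_length,
                                  double EI, double d_outer, double alpha_deg,
                                  double bevel_dir, arma::vec modulus,
                                  int target_depth, double t_ref,
                                  bool fixed_point, double fp_tol,
                                  int fp_maxit, bool record_springs) {
  const int n_elements = n_nodes - 1;
  const double Le = needle_length / n_elements;
  const double alpha = alpha_deg * M_PI / 180.0;
  const double fc_geom = d_outer * d_outer / (4.0 * std::tan(alpha / 2.0));
  const int nd = 2 * n_nodes;
  const int tip = n_nodes - 1;          // 0-based tip node
  const int behind = n_nodes - 2;       // node immediately proximal to tip

  mat Kbase(nd, nd, fill::zeros);
  mat ke = element_k(EI, Le);
  for (int e = 0; e < n_elements; ++e)
    Kbase.submat(2 * e, 2 * e, 2 * e + 3, 2 * e + 3) += ke;

  std::vector<int> spr_node;
  std::vector<double> spr_k, spr_z0;

  mat W(target_depth, n_nodes, fill::zeros);
  mat TH(target_depth, n_nodes, fill::zeros);
  vec theta_tip_v(target_depth, fill::zeros), beta_v(target_depth),
      Fc_v(target_depth), Fcz_v(target_depth);

  std::vector<double> ledger;           // depth, slot, node(1-based), k, z0
  vec u(nd, fill::zeros);
  double theta_tip = 0.0;               // from the previous converged state
  double advance = 0.0;                 // advance since the last spring shift

  for (int depth = 1; depth <= target_depth; ++depth) {
    double C = modulus(depth - 1);      // modulus over interval (depth-1, depth]

    // Step 1: new spring behind the tip, at rest at the node's current shape
    spr_node.push_back(behind);
    spr_k.push_back(C * t_ref);
    spr_z0.push_back(u(2 * behind));

    // guided region: w pinned where the needle is outside the tissue,
    // rotation pinned at the base only
    std::vector<int> fixed;
    fixed.push_back(1);                 // theta at base node
    for (int i = 0; i < n_nodes; ++i)
      if (i * Le <= needle_length - depth + 1e-9)
        fixed.push_back(2 * i);

    // Steps 2-3: tip load from the bevel cutting force, then static solve
    double Fc = C * fc_geom;
    double th_used = theta_tip;
    double th_force = theta_tip;  // slope entering the applied cutting force
    double Fcz = 0.0;
    bool ok = true;
    int iters = fixed_point ? fp_maxit : 1;
    for (int it = 0; it < iters; ++it) {
      th_force = th_used;
      Fcz = bevel_dir * Fc * std::cos(alpha + bevel_dir * th_used);
      vec F(nd, fill::zeros);
      F(2 * tip) = Fcz;
      u = solve_state(Kbase, spr_node, spr_k, spr_z0, fixed, F, ok);
      if (!ok) break;
      double th_new = u(2 * tip + 1);
      if (!fixed_point || std::abs(th_new - th_used) < fp_tol) {
        th_used = th_new;
        break;
      }
      th_used = th_new;
    }
    if (!ok)
      Rcpp::stop("singular beam system at insertion step %d", depth);

    for (int i = 0; i < n_nodes; ++i) {
      W(depth - 1, i) = u(2 * i);
      TH(depth - 1, i) = u(2 * i + 1);
    }
    theta_tip_v(depth - 1) = u(2 * tip + 1);
    beta_v(depth - 1) = alpha + bevel_dir * th_force;
    Fc_v(depth - 1) = Fc;
    Fcz_v(depth - 1) = Fcz;

    if (record_springs)
      for (size_t s = 0; s < spr_node.size(); ++s) {
        ledger.push_back(depth);
        ledger.push_back((double)(s + 1));
        ledger.push_back((double)(spr_node[s] + 1));
        ledger.push_back(spr_k[s]);
        ledger.push_back(spr_z0[s]);
      }

    // Step 4: after one element length of advance, shift springs one node
    // toward the base, keeping every spring's force unchanged
    advance += 1.0;
    if (advance >= Le) {
      advance -= Le;
      for (size_t s = 0; s < spr_node.size(); ++s) {
        int old_node = spr_node[s];
        int new_node = old_node - 1;
        if (new_node < 0) new_node = 0;   // never reached for depth <= 125
        spr_z0[s] = u(2 * new_node) + (spr_z0[s] - u(2 * old_node));
        spr_node[s] = new_node;
      }
    }

    theta_tip = u(2 * tip + 1);  // used by the next step's cutting force
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("W") = W,
      Rcpp::Named("Theta") = TH,
      Rcpp::Named("theta_tip") = theta_tip_v,
      Rcpp::Named("beta") = beta_v,
      Rcpp::Named("Fc") = Fc_v,
      Rcpp::Named("Fcz") = Fcz_v);
  if (record_springs) {
    mat L(ledger.size() / 5, 5);
    for (uword r = 0; r < L.n_rows; ++r)
      for (uword c = 0; c < 5; ++c) L(r, c) = ledger[5 * r + c];
    out["springs"] = L;
  }
  return out;
}
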