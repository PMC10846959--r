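// Reversible-jump MCMC for variable-rates Brownian motion on a fixed
// binary tree.  Each branch either evolves at the background rate sigma2
// or carries a multiplicative scalar drawn from a log-uniform prior; the
// likelihood is the restricted (independent contrasts) likelihood via
// Felsenstein pruning.  A power parameter on the likelihood supports
// stepping-stone marginal-likelihood estimation.  All randomness comes
// from R's RNG so runs are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tree {
  int ntip, nnode, nedge;
  IntegerVector parent, child;     // edge arrays (1-based node ids)
  NumericVector len;
  IntegerVector po_node;           // internal nodes, children first
  IntegerVector po_e1, po_e2;      // the two child edges of each node
};

// contrasts log-likelihood given per-edge scalars; z is the working trait
double pruning_loglik(const Tree& tr, const std::vector<double>& z,
                      const std::vector<double>& scalar, double sigma2) {
  int nn = tr.ntip + tr.nnode;
  std::vector<double> val(nn), extra(nn, 0.0);
  for (int i = 0; i < tr.ntip; ++i) val[i] = z[i];
  double ll = 0.0;
  const double LOG2PI = 1.8378770664093453;
  for (int k = 0; k < tr.po_node.size(); ++k) {
    int e1 = tr.po_e1[k], e2 = tr.po_e2[k];
    int c1 = tr.child[e1] - 1, c2 = tr.child[e2] - 1;
    double v1 = tr.len[e1] * scalar[e1] + extra[c1];
    double v2 = tr.len[e2] * scalar[e2] + extra[c2];
    double vc = v1 + v2;
    double con = val[c1] - val[c2];
    ll += -0.5 * (LOG2PI + std::log(sigma2 * vc) +
                  con * con / (sigma2 * vc));
    int v = tr.po_node[k] - 1;
    val[v] = (val[c1] * v2 + val[c2] * v1) / vc;
    extra[v] = v1 * v2 / vc;
  }
  return ll;
}

Tree build_tree(List pre) {
  Tree tr;
  tr.ntip = as<int>(pre["ntip"]);
  tr.nnode = as<int>(pre["nnode"]);
  tr.parent = pre["parent"];
  tr.child = pre["child"];
  tr.len = pre["len"];
  tr.nedge = tr.parent.size();
  tr.po_node = pre["po_node"];
  tr.po_e1 = pre["po_e1"];
  tr.po_e2 = pre["po_e2"];
  return tr;
}

} // namespace

// [[Rcpp::export]]
List vr_mcmc_cpp(List pre, NumericVector y, NumericVector x,
                 double power, int iterations, int thin,
                 double pi_active, double log_r_bound,
                 double log_s2_lo, double log_s2_hi,
                 double sd_logr, double sd_logs2, double sd_slope,
                 bool allow_scalars, bool regression,
                 double init_log_s2) {
  Tree tr = build_tree(pre);
  int E = tr.nedge;
  bool has_x = regression;

  std::vector<double> scalar(E, 1.0);
  std::vector<bool> active(E, false);
  std::vector<double> logr(E, 0.0);
  double log_s2 = init_log_s2;
  double slope = 0.0;

  std::vector<double> z(tr.ntip);
  auto update_z = [&](double b) {
    for (int i = 0; i < tr.ntip; ++i)
      z[i] = has_x ? y[i] - b * x[i] : y[i];
  };
  update_z(slope);

  double ll = pruning_loglik(tr, z, scalar, std::exp(log_s2));

  int n_keep = iterations / thin;
  NumericVector out_s2(n_keep), out_ll(n_keep), out_slope(n_keep);
  NumericMatrix out_scalar(n_keep, E);
  int kept = 0;

  double log_pi = std::log(pi_active), log_1mpi = std::log(1.0 - pi_active);

  for (int it = 1; it <= iterations; ++it) {
    double u_move = unif_rand();
    // move mix: sigma2 walk, slope walk (regression only), and - when
    // scalars are allowed - RJ toggles plus scalar perturbations
    double p_s2 = allow_scalars ? 0.25 : (has_x ? 0.60 : 1.00);
    double p_slope_hi = allow_scalars ? 0.40 : 1.00;
    if (u_move < p_s2) {
      double prop = log_s2 + norm_rand() * sd_logs2;
      if (prop >= log_s2_lo && prop <= log_s2_hi) {
        double ll_new = pruning_loglik(tr, z, scalar, std::exp(prop));
        if (std::log(unif_rand()) < power * (ll_new - ll)) {
          log_s2 = prop; ll = ll_new;
        }
      }
    } else if (has_x && u_move < p_slope_hi) {
      double prop = slope + norm_rand() * sd_slope;
      update_z(prop);
      double ll_new = pruning_loglik(tr, z, scalar, std::exp(log_s2));
      if (std::log(unif_rand()) < power * (ll_new - ll)) {
        slope = prop; ll = ll_new;
      } else {
        update_z(slope);
      }
    } else if (allow_scalars) {
      int e = (int)std::floor(unif_rand() * E);
      if (e >= E) e = E - 1;
      if (unif_rand() < 0.5) {
        // RJ toggle: birth proposes the scalar from its prior, so the
        // scalar prior density cancels against the proposal density
        if (!active[e]) {
          double lr = (unif_rand() * 2.0 - 1.0) * log_r_bound;
          double old = scalar[e];
          scalar[e] = std::exp(lr);
          double ll_new = pruning_loglik(tr, z, scalar, std::exp(log_s2));
          double log_acc = power * (ll_new - ll) + (log_pi - log_1mpi);
          if (std::log(unif_rand()) < log_acc) {
            active[e] = true; logr[e] = lr; ll = ll_new;
          } else scalar[e] = old;
        } else {
          double old = scalar[e];
          scalar[e] = 1.0;
          double ll_new = pruning_loglik(tr, z, scalar, std::exp(log_s2));
          double log_acc = power * (ll_new - ll) + (log_1mpi - log_pi);
          if (std::log(unif_rand()) < log_acc) {
            active[e] = false; logr[e] = 0.0; ll = ll_new;
          } else scalar[e] = old;
        }
      } else if (active[e]) {
        double lr = logr[e] + norm_rand() * sd_logr;
        if (lr >= -log_r_bound && lr <= log_r_bound) {
          double old = scalar[e];
          scalar[e] = std::exp(lr);
          double ll_new = pruning_loglik(tr, z, scalar, std::exp(log_s2));
          if (std::log(unif_rand()) < power * (ll_new - ll)) {
            logr[e] = lr; ll = ll_new;
          } else scalar[e] = old;
        }
      }
    }
    if (it % thin == 0 && kept < n_keep) {
      out_s2[kept] = std::exp(log_s2);
      out_ll[kept] = ll;
      out_slope[kept] = slope;
      for (int e = 0; e < E; ++e) out_scalar(kept, e) = scalar[e];
      ++kept;
    }
  }
  return List::create(_["sigma2"] = out_s2, _["loglik"] = out_ll,
                      _["slope"] = out_slope, _["scalars"] = out_scalar);
}

// [[Rcpp::export]]
double contrasts_loglik_cpp(List pre, NumericVector y,
                            NumericVector scalars, double sigma2) {
  Tree tr = build_tree(pre);
  std::vector<double> z(y.begin(), y.end());
  std::vector<double> sc(scalars.begin(), scalars.end());
  return pruning_loglik(tr, z, sc, sigma2);
}
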