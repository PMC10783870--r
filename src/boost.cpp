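// Core numeric loops: coordinate-descent boosting with validation-based
// early stopping, and connected-component labelling for cluster-based
// permutation tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double err_norm(const arma::vec& r, int norm) {
  return norm == 1 ? arma::accu(arma::abs(r)) : arma::dot(r, r);
}

// Boosting for all channels of one run.
//
// Z: n x J lagged (optionally basis-smeared) design matrix, normalized units
// Y: n x C response matrix, normalized units
// train_idx, val_idx: 0-based row indices
// comp_of_col: 0-based predictor-component index per column (for selective
//   stopping, which freezes whole predictors)
//
// Returns per channel the coefficient vector with the smallest validation
// error over the run's history, plus a compact numeric history.
// [[Rcpp::export]]
List boost_run_cpp(const arma::mat& Z, const arma::mat& Y,
                   const arma::uvec& train_idx, const arma::uvec& val_idx,
                   double delta0, double mindelta, int error_norm_i,
                   int selective_stopping, const arma::ivec& comp_of_col,
                   int max_iter) {
  const arma::uword J = Z.n_cols;
  const arma::uword C = Y.n_cols;
  const int n_comp = comp_of_col.max() + 1;

  arma::mat Ztr = Z.rows(train_idx);
  arma::mat Zval = Z.rows(val_idx);
  arma::mat G;           // Gram matrix for the fast l2 path
  arma::vec bdiag(J);
  const bool l2 = (error_norm_i == 2);
  if (l2) {
    G = Ztr.t() * Ztr;
    bdiag = G.diag();
  } else {
    for (arma::uword j = 0; j < J; ++j) bdiag(j) = arma::dot(Ztr.col(j), Ztr.col(j));
  }

  arma::mat coefs(J, C, arma::fill::zeros);
  List histories(C);

  for (arma::uword ch = 0; ch < C; ++ch) {
    arma::vec yc = Y.col(ch);
    arma::vec r_tr = yc.elem(train_idx);
    arma::vec r_val = yc.elem(val_idx);

    arma::vec a;                    // l2: Ztr' r_tr, updated incrementally
    if (l2) a = Ztr.t() * r_tr;

    double E_tr = err_norm(r_tr, error_norm_i);
    double E_val = err_norm(r_val, error_norm_i);

    arma::vec coef(J, arma::fill::zeros);
    arma::vec best_coef(J, arma::fill::zeros);
    double best_val = E_val;

    double delta = delta0;
    int counter = 0;
    std::vector<int> comp_counter(n_comp, 0);
    std::vector<bool> frozen(n_comp, false);
    const bool selective = selective_stopping > 0;

    std::vector<double> h_step, h_col, h_dir, h_tr, h_val;

    int iter = 0;
    while (iter < max_iter) {
      // all predictors frozen -> done
      if (selective) {
        bool all_frozen = true;
        for (int p = 0; p < n_comp; ++p) if (!frozen[p]) { all_frozen = false; break; }
        if (all_frozen) break;
      }

      // find the candidate step with the lowest training error
      long best_j = -1;
      double best_s = 0.0;
      double best_err = E_tr; // must strictly reduce
      if (l2) {
        for (arma::uword j = 0; j < J; ++j) {
          if (frozen[comp_of_col(j)]) continue;
          double aj = a(j);
          double s = (aj >= 0) ? delta : -delta;
          double gain = 2.0 * delta * std::fabs(aj) - delta * delta * bdiag(j);
          double e = E_tr - gain;
          if (e < best_err - 1e-15 * (1.0 + std::fabs(E_tr))) {
            best_err = e; best_j = (long)j; best_s = s;
          }
        }
      } else {
        for (arma::uword j = 0; j < J; ++j) {
          if (frozen[comp_of_col(j)]) continue;
          const double* z = Ztr.colptr(j);
          double e_add = 0.0, e_sub = 0.0;
          const double* r = r_tr.memptr();
          const arma::uword n_tr = r_tr.n_elem;
          for (arma::uword t = 0; t < n_tr; ++t) {
            double zt = delta * z[t];
            e_add += std::fabs(r[t] - zt);
            e_sub += std::fabs(r[t] + zt);
          }
          if (e_add < best_err - 1e-15 * (1.0 + E_tr)) {
            best_err = e_add; best_j = (long)j; best_s = delta;
          }
          if (e_sub < best_err - 1e-15 * (1.0 + E_tr)) {
            best_err = e_sub; best_j = (long)j; best_s = -delta;
          }
        }
      }

      if (best_j < 0) {
        // no step reduces the training error: shrink delta or stop
        delta *= 0.5;
        if (delta < mindelta) break;
        continue;
      }

      // accept the step
      coef(best_j) += best_s;
      E_tr = best_err;
      if (E_tr < 0) E_tr = 0;
      if (l2) {
        a -= best_s * G.col(best_j);
      } else {
        r_tr -= best_s * Ztr.col(best_j);
      }
      r_val -= best_s * Zval.col(best_j);
      double new_val = err_norm(r_val, error_norm_i);

      ++iter;
      h_step.push_back((double)iter);
      h_col.push_back((double)(best_j + 1));
      h_dir.push_back(best_s > 0 ? 1.0 : -1.0);
      h_tr.push_back(E_tr);
      h_val.push_back(new_val);

      if (new_val < best_val) {
        best_val = new_val;
        best_coef = coef;
      }

      if (selective) {
        int p = comp_of_col(best_j);
        if (new_val > E_val) {
          if (++comp_counter[p] >= selective_stopping) frozen[p] = true;
        } else {
          comp_counter[p] = 0;
        }
      } else {
        if (new_val > E_val) {
          if (++counter >= 2) { E_val = new_val; break; }
        } else {
          counter = 0;
        }
      }
      E_val = new_val;
    }

    coefs.col(ch) = best_coef;
    arma::uword m = h_step.size();
    arma::mat H(m, 5);
    for (arma::uword i = 0; i < m; ++i) {
      H(i, 0) = h_step[i]; H(i, 1) = h_col[i]; H(i, 2) = h_dir[i];
      H(i, 3) = h_tr[i];   H(i, 4) = h_val[i];
    }
    histories[ch] = H;
  }

  return List::create(_["coefs"] = coefs, _["histories"] = histories);
}

// Connected-component labelling of suprathreshold elements.
//
// t_map: statistic per element; adjacency: list of 1-based neighbor index
// vectors per element. Positive (t > thr) and negative (t < -thr) clusters
// are formed separately. Returns labels (0 = no cluster) and per-cluster
// signed masses (sum of t within the cluster).
// [[Rcpp::export]]
List cluster_components_cpp(const arma::vec& t_map, const List& adjacency,
                            double threshold) {
  const int n = t_map.n_elem;
  std::vector<int> labels(n, 0);
  std::vector<double> masses;
  int next_label = 0;
  std::vector<int> stack;

  for (int sign = 1; sign >= -1; sign -= 2) {
    for (int i = 0; i < n; ++i) {
      if (labels[i] != 0) continue;
      if (sign * t_map(i) <= threshold) continue;
      // BFS from i over same-sign suprathreshold neighbors
      ++next_label;
      double mass = 0.0;
      stack.clear();
      stack.push_back(i);
      labels[i] = next_label;
      while (!stack.empty()) {
        int u = stack.back(); stack.pop_back();
        mass += t_map(u);
        IntegerVector nb = adjacency[u];
        for (int k = 0; k < nb.size(); ++k) {
          int v = nb[k] - 1;
          if (labels[v] == 0 && sign * t_map(v) > threshold) {
            labels[v] = next_label;
            stack.push_back(v);
          }
        }
      }
      masses.push_back(mass);
    }
  }
  return List::create(_["labels"] = IntegerVector(labels.begin(), labels.end()),
                      _["masses"] = NumericVector(masses.begin(), masses.end()));
}

// Maximum absolute cluster mass for each row of a permutation x element
// statistic matrix (the permutation null distribution).
// [[Rcpp::export]]
NumericVector max_cluster_mass_cpp(const arma::mat& t_maps, const List& adjacency,
                                   double threshold) {
  const int n_perm = t_maps.n_rows;
  const int n = t_maps.n_cols;
  NumericVector out(n_perm);
  std::vector<int> labels(n);
  std::vector<int> stack;

  for (int p = 0; p < n_perm; ++p) {
    std::fill(labels.begin(), labels.end(), 0);
    double max_mass = 0.0;
    int next_label = 0;
    for (int sign = 1; sign >= -1; sign -= 2) {
      for (int i = 0; i < n; ++i) {
        if (labels[i] != 0) continue;
        if (sign * t_maps(p, i) <= threshold) continue;
        ++next_label;
        double mass = 0.0;
        stack.clear();
        stack.push_back(i);
        labels[i] = next_label;
        while (!stack.empty()) {
          int u = stack.back(); stack.pop_back();
          mass += t_maps(p, u);
          IntegerVector nb = adjacency[u];
          for (int k = 0; k < nb.size(); ++k) {
            int v = nb[k] - 1;
            if (labels[v] == 0 && sign * t_maps(p, v) > threshold) {
              labels[v] = next_label;
              stack.push_back(v);
            }
          }
        }
        if (std::fabs(mass) > max_mass) max_mass = std::fabs(mass);
      }
    }
    out[p] = max_mass;
  }
  return out;
}
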