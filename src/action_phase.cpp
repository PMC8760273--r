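// Action-phase inner loop of the maze agent.
//
// One iteration covers a decision period: sample a decision from the
// output-layer rates (one categorical draw over the one-hot block), execute
// its action sequence with wall rejection, score the delayed risk from the
// rightward displacement, read the observation window at the new position,
// and update the middle-layer steady-state activity.  Sufficient statistics
// for the session-end plasticity update are accumulated online.
//
// All random draws go through R's RNG so that set.seed() in R governs the
// whole trajectory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::vec sigmoid(const arma::vec& u) {
  return 1.0 / (1.0 + arma::exp(-u));
}

// [[Rcpp::export(name = ".action_phase_cpp")]]
List action_phase_cpp(const IntegerMatrix grid,
                      int start_r, int start_c,          // 1-based
                      const arma::mat& dW, const arma::mat& dK,
                      const arma::mat& dV,
                      const arma::vec& hd, const arma::vec& md,
                      const arma::vec& x0,
                      int T, int window, int period_len, int d_star,
                      double g_success, double g_partial, double g_fail,
                      bool immediate_mod, bool log_activity) {
  const int H = grid.nrow(), W = grid.ncol();
  const int half = window / 2;
  const int n_o = window * window;
  const int n_x = dW.n_rows;
  const int n_y = dV.n_rows;
  const int max_periods = (T + period_len - 1) / period_len;

  int r = start_r - 1, c = start_c - 1;     // 0-based position

  arma::mat S_xo(n_x, n_o, arma::fill::zeros);
  arma::mat S_xxp(n_x, n_x, arma::fill::zeros);
  arma::mat S_dxm(n_y, n_x, arma::fill::zeros);
  arma::mat S_dx(n_y, n_x, arma::fill::zeros);
  arma::vec S_d(n_y, arma::fill::zeros);
  arma::vec S_o(n_o, arma::fill::zeros);
  arma::vec S_x(n_x, arma::fill::zeros);
  arma::vec S_xp(n_x, arma::fill::zeros);
  arma::vec S_xp_w(n_x, arma::fill::zeros);
  arma::vec S_y(n_y, arma::fill::zeros);
  double S_w = 0.0;

  std::vector<int> decisions, col_trace;
  std::vector<double> gammas;
  arma::mat X_log, Y_log;
  IntegerMatrix pos_log;
  if (log_activity) {
    X_log.set_size(n_x, max_periods);
    Y_log.set_size(n_y, max_periods);
    pos_log = IntegerMatrix(T, 2);
  }

  arma::vec x_prev = x0;
  arma::vec o(n_o), x(n_x), y(n_y);
  bool success = (c == W - 1);
  int steps = 0, p = 0;
  double gamma_prev = 0.5;                  // neutral before first evaluation

  while (!success && steps < T) {
    // decision from output layer (fed by the delayed middle-layer rates)
    y = sigmoid(dV * x_prev + md);
    double tot = arma::accu(y);
    double u = R::runif(0.0, tot);
    int k = 0;
    double cum = y[0];
    while (cum < u && k < n_y - 1) cum += y[++k];

    // execute the four-step action sequence with wall rejection
    int prev_col = c;
    int code = k;
    int digits[16];
    for (int i = period_len - 1; i >= 0; --i) {
      digits[i] = code % 4;                 // 0 up, 1 down, 2 left, 3 right
      code /= 4;
    }
    for (int i = 0; i < period_len && steps < T; ++i) {
      int nr = r, nc = c;
      switch (digits[i]) {
        case 0: nr = r - 1; break;
        case 1: nr = r + 1; break;
        case 2: nc = c - 1; break;
        case 3: nc = c + 1; break;
      }
      if (nr >= 0 && nr < H && nc >= 0 && nc < W && grid(nr, nc) == 1) {
        r = nr; c = nc;
      }
      ++steps;
      if (log_activity) {
        pos_log(steps - 1, 0) = r + 1;
        pos_log(steps - 1, 1) = c + 1;
      }
      if (c == W - 1) { success = true; break; }
    }
    if (success) { col_trace.push_back(c + 1); break; }

    // delayed risk from the rightward displacement over the period
    int dx = c - prev_col;
    double gamma = (dx >= d_star) ? g_success
                   : (dx > 0 ? g_partial : g_fail);

    // observation window at the new position (outside the grid reads wall)
    int idx = 0;
    for (int dr = -half; dr <= half; ++dr) {
      for (int dc = -half; dc <= half; ++dc) {
        int rr = r + dr, cc = c + dc;
        o[idx++] = (rr >= 0 && rr < H && cc >= 0 && cc < W &&
                    grid(rr, cc) == 1) ? 1.0 : 0.0;
      }
    }

    // middle-layer steady state
    x = sigmoid(dW * o + dK * x_prev + hd);

    // plasticity sufficient statistics
    double w_eff = immediate_mod ? (1.0 - 2.0 * gamma_prev)
                                 : (1.0 - 2.0 * gamma);
    for (int j = 0; j < n_o; ++j) {
      if (o[j] > 0.5) S_xo.col(j) += x;
    }
    S_o += o;
    S_x += x;
    S_xxp += x * x_prev.t();
    S_dxm.row(k) += w_eff * x_prev.t();
    S_dx.row(k) += x_prev.t();
    S_d[k] += 1.0;
    S_xp += x_prev;
    S_xp_w += w_eff * x_prev;
    S_w += w_eff;
    S_y += y;

    decisions.push_back(k);
    gammas.push_back(gamma);
    col_trace.push_back(c + 1);
    if (log_activity) {
      X_log.col(p) = x;
      Y_log.col(p) = y;
    }
    gamma_prev = gamma;
    x_prev = x;
    ++p;
  }

  List out = List::create(
    Named("success") = success,
    Named("duration") = steps,
    Named("n_periods") = p,
    Named("decisions") = IntegerVector(decisions.begin(), decisions.end()),
    Named("gamma") = NumericVector(gammas.begin(), gammas.end()),
    Named("col_trace") = IntegerVector(col_trace.begin(), col_trace.end()),
    Named("final_pos") = IntegerVector::create(r + 1, c + 1),
    Named("x_final") = x_prev,
    Named("stats") = List::create(
      Named("S_xo") = S_xo, Named("S_xxp") = S_xxp,
      Named("S_dxm") = S_dxm, Named("S_dx") = S_dx,
      Named("S_d") = S_d,
      Named("S_o") = S_o, Named("S_x") = S_x,
      Named("S_xp") = S_xp, Named("S_xp_w") = S_xp_w,
      Named("S_y") = S_y, Named("S_w") = S_w,
      Named("n_periods") = p));
  if (log_activity) {
    out["X"] = (p > 0) ? wrap(X_log.cols(0, p - 1))
                       : wrap(arma::mat(n_x, 0));
    out["Y"] = (p > 0) ? wrap(Y_log.cols(0, p - 1))
                       : wrap(arma::mat(n_y, 0));
    out["positions"] = (steps > 0)
      ? pos_log(Range(0, steps - 1), Range(0, 1))
      : IntegerMatrix(0, 2);
  }
  return out;
}
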