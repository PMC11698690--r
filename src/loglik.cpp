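#include <Rcpp.h>
using namespace Rcpp;

// Session log-likelihood of the dual-system model.
//
// Encodings: stake 1=low 2=high; state, action, planet, keyidx all 1-based;
// reward is the learning signal already selected by the caller (base or
// delivered points). par_low / par_high each hold
// (alpha, beta, lam, w, pi, rho) for the trial's stake condition; the
// seven-parameter hybrid model is the special case where everything but w
// is tied. tprob is P(planet | state, action) flattened with planet
// fastest: tprob[(s-1)*4 + (a-1)*2 + (p-1)].
//
// Only the first-stage choice enters the likelihood (the planet offers a
// single forced action). The choice-perseveration indicator rep(a) marks
// the action leading to the planet chosen on the previous trial; the
// response-stickiness indicator resp(a) marks the action whose key matches
// the previous response key.
// [[Rcpp::export]]
double hybrid_loglik_cpp(IntegerVector stake, IntegerVector state,
                         IntegerVector action, IntegerVector planet,
                         IntegerVector keyidx, NumericVector reward,
                         NumericVector par_low, NumericVector par_high,
                         NumericVector tprob) {
  const int n = stake.size();
  double q1[2][2] = {{0, 0}, {0, 0}};  // first-stage Q_MF
  double q2[2] = {0, 0};               // planet Q_MF (single action)
  double e1[2][2];                     // eligibility traces
  double e2[2];

  // modal planet per (state, action), for rep(a)
  int det_planet[2][2];
  for (int s = 0; s < 2; ++s)
    for (int a = 0; a < 2; ++a)
      det_planet[s][a] = (tprob[s * 4 + a * 2] >= tprob[s * 4 + a * 2 + 1])
                             ? 0 : 1;

  int prev_planet = -1, prev_key = -1;
  double ll = 0.0;

  for (int t = 0; t < n; ++t) {
    const double *par = (stake[t] == 2) ? &par_high[0] : &par_low[0];
    const double alpha = par[0], beta = par[1], lam = par[2], w = par[3],
                 pi = par[4], rho = par[5];
    const int s = state[t] - 1, a = action[t] - 1, p = planet[t] - 1;
    const int key = keyidx[t] - 1;

    // choice probability of the observed first-stage action
    double x[2];
    for (int ai = 0; ai < 2; ++ai) {
      double qmb = tprob[s * 4 + ai * 2] * q2[0] +
                   tprob[s * 4 + ai * 2 + 1] * q2[1];
      double qnet = w * qmb + (1.0 - w) * q1[s][ai];
      double rep = (prev_planet >= 0 && det_planet[s][ai] == prev_planet)
                       ? 1.0 : 0.0;
      int key_ai = (ai == a) ? key : 1 - key;
      double resp = (prev_key >= 0 && key_ai == prev_key) ? 1.0 : 0.0;
      x[ai] = beta * (qnet + pi * rep + rho * resp);
    }
    double m = (x[0] > x[1]) ? x[0] : x[1];
    double lse = m + std::log(std::exp(x[0] - m) + std::exp(x[1] - m));
    ll += x[a] - lse;

    // SARSA(lambda): traces reset each trial, two update passes
    for (int i = 0; i < 2; ++i) {
      e2[i] = 0.0;
      for (int j = 0; j < 2; ++j) e1[i][j] = 0.0;
    }
    // stage 1
    e1[s][a] += 1.0;
    double d1 = q2[p] - q1[s][a];
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j) q1[i][j] += alpha * d1 * e1[i][j];
    for (int i = 0; i < 2; ++i) q2[i] += alpha * d1 * e2[i];
    for (int i = 0; i < 2; ++i) {
      e2[i] *= lam;
      for (int j = 0; j < 2; ++j) e1[i][j] *= lam;
    }
    // stage 2
    e2[p] += 1.0;
    double d2 = reward[t] - q2[p];
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j) q1[i][j] += alpha * d2 * e1[i][j];
    for (int i = 0; i < 2; ++i) q2[i] += alpha * d2 * e2[i];
    for (int i = 0; i < 2; ++i) {
      e2[i] *= lam;
      for (int j = 0; j < 2; ++j) e1[i][j] *= lam;
    }

    prev_planet = p;
    prev_key = key;
  }
  return ll;
}

// Session log-likelihood of the risk-sensitive utility model.
//
// U(s,a) = R(s,a) - mu * sign(R(s,a)) * sqrt(h(s,a)) over the two
// first-stage actions; softmax with inverse temperature beta_u. Learning
// runs over every trial in order; the log-likelihood sums only trials
// passing the stake filter (0 = all, 1 = low, 2 = high). TD errors are
// clipped to [-dlim, dlim] before use; the risk table h is updated with
// the squared clipped first-stage TD error.
// [[Rcpp::export]]
double utility_loglik_cpp(IntegerVector stake, IntegerVector state,
                          IntegerVector action, IntegerVector planet,
                          NumericVector reward, double mu, double beta_u,
                          double eta, double gam, double dlim, int filter) {
  const int n = stake.size();
  double r1[2][2] = {{0, 0}, {0, 0}};  // expected return, first stage
  double r2[2] = {0, 0};               // expected return, planets
  double h[2][2] = {{0, 0}, {0, 0}};   // risk (return variance)
  double ll = 0.0;

  for (int t = 0; t < n; ++t) {
    const int s = state[t] - 1, a = action[t] - 1, p = planet[t] - 1;

    if (filter == 0 || stake[t] == filter) {
      double x[2];
      for (int ai = 0; ai < 2; ++ai) {
        double rv = r1[s][ai];
        double sgn = (rv > 0) - (rv < 0);
        x[ai] = beta_u * (rv - mu * sgn * std::sqrt(h[s][ai]));
      }
      double m = (x[0] > x[1]) ? x[0] : x[1];
      double lse = m + std::log(std::exp(x[0] - m) + std::exp(x[1] - m));
      ll += x[a] - lse;
    }

    double d1 = gam * r2[p] - r1[s][a];
    if (d1 > dlim) d1 = dlim;
    if (d1 < -dlim) d1 = -dlim;
    double d2 = reward[t] - r2[p];
    if (d2 > dlim) d2 = dlim;
    if (d2 < -dlim) d2 = -dlim;
    r1[s][a] += eta * d1;
    r2[p] += eta * d2;
    h[s][a] += eta * (d1 * d1 - h[s][a]);
  }
  return ll;
}
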