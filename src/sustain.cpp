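// SUSTAIN trial-loop engine.
//
// The network state is tiny (a handful of clusters on [0,1]^2, two
// association weights per cluster, two attention weights), but training
// runs are long (15 sessions x 80 trials) and model fitting averages
// hundreds of runs per objective evaluation, so the sequential trial loop
// lives here. All randomness goes through R's RNG so that set.seed() in R
// governs every draw.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Net {
  std::vector<double> px, py;  // cluster positions on [0,1]^2
  std::vector<double> wa, wb;  // association weights to category units A, B
  double lam0, lam1;           // attention weights (lambda)
};

struct Par {
  double r, beta, d, eta, eta_lambda, tau;
  bool shuffle;
  bool recruit_on_choice;  // gate recruitment on the sampled choice
                           // instead of the winner's predicted category
};

// attention-weighted cluster activations; ties broken toward lowest index
void activations(const Net& net, double x0, double x1, double r,
                 std::vector<double>& H, int& winner) {
  double a0 = std::pow(net.lam0, r);
  double a1 = std::pow(net.lam1, r);
  double denom = a0 + a1;
  if (!(denom > 0.0)) { a0 = a1 = 0.5; denom = 1.0; }
  const int n = (int)net.px.size();
  H.resize(n);
  winner = 0;
  for (int j = 0; j < n; ++j) {
    const double mu0 = std::fabs(x0 - net.px[j]);
    const double mu1 = std::fabs(x1 - net.py[j]);
    H[j] = (a0 * std::exp(-net.lam0 * mu0) + a1 * std::exp(-net.lam1 * mu1)) / denom;
    if (H[j] > H[winner]) winner = j;
  }
}

// winner-take-all lateral inhibition: out = H_win^beta / sum_k H_k^beta * H_win
double compete_out(const std::vector<double>& H, int winner, double beta) {
  double s = 0.0;
  for (double h : H) s += std::pow(h, beta);
  if (!(s > 0.0)) return H[winner];
  return std::pow(H[winner], beta) / s * H[winner];
}

struct StepOut {
  int winner;       // decision-time winner (0-based)
  int choice;       // 0 = A, 1 = B
  bool correct;
  bool recruited;
  double p_correct; // probability assigned to the fed-back category
  double lam0_used, lam1_used;
};

// one supervised trial: (shuffle ->) activate -> compete -> decide ->
// recruit-on-surprise -> update winner position/associations and lambda
StepOut step(Net& net, double x0, double x1, int cat, const Par& p, bool learn) {
  StepOut out;

  if (net.px.empty()) {  // first trial seeds a cluster on the stimulus
    net.px.push_back(x0); net.py.push_back(x1);
    net.wa.push_back(0.0); net.wb.push_back(0.0);
  }

  if (p.shuffle && net.lam0 != net.lam1) {
    // uniform permutation of the two attention weights; a symmetric pair
    // is left untouched (the permutation is the identity)
    if (unif_rand() < 0.5) std::swap(net.lam0, net.lam1);
  }
  out.lam0_used = net.lam0;
  out.lam1_used = net.lam1;

  std::vector<double> H;
  int win;
  activations(net, x0, x1, p.r, H, win);
  out.winner = win;

  double hout = compete_out(H, win, p.beta);
  double CA = net.wa[win] * hout;
  double CB = net.wb[win] * hout;
  double pA = 1.0 / (1.0 + std::exp(-p.d * (CA - CB)));
  out.choice = (unif_rand() < pA) ? 0 : 1;
  out.correct = (out.choice == cat);
  out.p_correct = (cat == 0) ? pA : 1.0 - pA;

  // surprise-gated recruitment: a confident misclassification spawns a
  // cluster on the stimulus, which becomes the winner for this trial's
  // update. The default reads "classification" as the winner's predicted
  // category (argmax of its association weights, ties to A); optionally
  // the sampled choice is used instead.
  out.recruited = false;
  int uwin = win;
  const int predicted = (net.wa[win] >= net.wb[win]) ? 0 : 1;
  const bool misclassified =
      p.recruit_on_choice ? !out.correct : (predicted != cat);
  if (learn && misclassified && H[win] > p.tau) {
    net.px.push_back(x0); net.py.push_back(x1);
    net.wa.push_back(0.0); net.wb.push_back(0.0);
    uwin = (int)net.px.size() - 1;
    out.recruited = true;
    double s = 0.0;
    for (double h : H) s += std::pow(h, p.beta);
    s += 1.0;  // new cluster activates at exactly 1
    hout = 1.0 / s;
    CA = 0.0; CB = 0.0;
  }

  if (learn) {
    const double mu0 = std::fabs(x0 - net.px[uwin]);
    const double mu1 = std::fabs(x1 - net.py[uwin]);
    // receptive-field tuning toward dimensions the winner matches tightly
    net.lam0 += p.eta_lambda * std::exp(-net.lam0 * mu0) * (1.0 - net.lam0 * mu0);
    net.lam1 += p.eta_lambda * std::exp(-net.lam1 * mu1) * (1.0 - net.lam1 * mu1);
    if (net.lam0 < 0.0) net.lam0 = 0.0;
    if (net.lam1 < 0.0) net.lam1 = 0.0;
    // winner drifts toward the stimulus
    net.px[uwin] += p.eta * (x0 - net.px[uwin]);
    net.py[uwin] += p.eta * (x1 - net.py[uwin]);
    // humble-teacher delta rule on the winner's association weights
    const double errA = (cat == 0) ? ((CA < 1.0) ? 1.0 - CA : 0.0)
                                   : ((CA > 0.0) ? -CA : 0.0);
    const double errB = (cat == 1) ? ((CB < 1.0) ? 1.0 - CB : 0.0)
                                   : ((CB > 0.0) ? -CB : 0.0);
    net.wa[uwin] += p.eta * errA * hout;
    net.wb[uwin] += p.eta * errB * hout;
  }

  return out;
}

Par make_par(double r, double beta, double d_dec, double eta,
             double eta_lambda, double tau, bool shuffle,
             bool recruit_on_choice) {
  Par p;
  p.r = r; p.beta = beta; p.d = d_dec; p.eta = eta;
  p.eta_lambda = eta_lambda; p.tau = tau; p.shuffle = shuffle;
  p.recruit_on_choice = recruit_on_choice;
  return p;
}

void init_net(Net& net, Nullable<NumericMatrix> init_pos,
              Nullable<NumericMatrix> init_assoc, Nullable<NumericVector> init_lam) {
  net.lam0 = 1.0; net.lam1 = 1.0;
  if (init_lam.isNotNull()) {
    NumericVector l(init_lam);
    net.lam0 = l[0]; net.lam1 = l[1];
  }
  if (init_pos.isNotNull()) {
    NumericMatrix pos(init_pos);
    NumericMatrix w(init_assoc);
    for (int j = 0; j < pos.nrow(); ++j) {
      net.px.push_back(pos(j, 0)); net.py.push_back(pos(j, 1));
      net.wa.push_back(w(j, 0));   net.wb.push_back(w(j, 1));
    }
  }
}

}  // namespace

// Run one agent over a fixed stimulus sequence, returning the per-trial
// trace, correction-loop replays (decision-only, state frozen), and the
// final network state. `cat` uses 0 = A, 1 = B.
// [[Rcpp::export]]
List sustain_run_cpp(NumericMatrix X, IntegerVector cat,
                     double r, double beta, double d_dec, double eta,
                     double eta_lambda, double tau,
                     bool shuffle, bool learn,
                     bool emit_corrections, int correction_cap,
                     bool recruit_on_choice = false,
                     Nullable<NumericMatrix> init_pos = R_NilValue,
                     Nullable<NumericMatrix> init_assoc = R_NilValue,
                     Nullable<NumericVector> init_lam = R_NilValue) {
  const int n = X.nrow();
  Par p = make_par(r, beta, d_dec, eta, eta_lambda, tau, shuffle,
                   recruit_on_choice);
  Net net;
  init_net(net, init_pos, init_assoc, init_lam);

  IntegerVector winner(n), choice(n), n_clusters(n);
  LogicalVector correct(n), recruited(n);
  NumericVector p_correct(n), lam_x(n), lam_y(n);
  std::vector<int> ctrial, cattempt, cchoice;
  std::vector<int> ccorrect, capped_flag;

  for (int t = 0; t < n; ++t) {
    StepOut o = step(net, X(t, 0), X(t, 1), cat[t], p, learn);
    winner[t] = o.winner + 1;
    choice[t] = o.choice;
    correct[t] = o.correct;
    recruited[t] = o.recruited;
    p_correct[t] = o.p_correct;
    lam_x[t] = o.lam0_used;
    lam_y[t] = o.lam1_used;
    n_clusters[t] = (int)net.px.size();

    if (emit_corrections && !o.correct) {
      // replay the same stimulus (no reinforcement, no update) until the
      // agent re-decides correctly, capped
      bool done = false;
      for (int a = 1; a <= correction_cap && !done; ++a) {
        std::vector<double> H;
        int win;
        activations(net, X(t, 0), X(t, 1), p.r, H, win);
        double hout = compete_out(H, win, p.beta);
        double dC = (net.wa[win] - net.wb[win]) * hout;
        double pA = 1.0 / (1.0 + std::exp(-p.d * dC));
        int ch = (unif_rand() < pA) ? 0 : 1;
        bool ok = (ch == cat[t]);
        ctrial.push_back(t + 1);
        cattempt.push_back(a);
        cchoice.push_back(ch);
        ccorrect.push_back(ok ? 1 : 0);
        capped_flag.push_back(0);
        done = ok;
      }
      if (!done) capped_flag.back() = 1;
    }
  }

  const int nc = (int)net.px.size();
  NumericMatrix pos(nc, 2), assoc(nc, 2);
  for (int j = 0; j < nc; ++j) {
    pos(j, 0) = net.px[j]; pos(j, 1) = net.py[j];
    assoc(j, 0) = net.wa[j]; assoc(j, 1) = net.wb[j];
  }

  return List::create(
    _["winner"] = winner, _["choice"] = choice, _["correct"] = correct,
    _["recruited"] = recruited, _["p_correct"] = p_correct,
    _["lam_x"] = lam_x, _["lam_y"] = lam_y, _["n_clusters"] = n_clusters,
    _["corr_trial"] = wrap(ctrial), _["corr_attempt"] = wrap(cattempt),
    _["corr_choice"] = wrap(cchoice), _["corr_correct"] = wrap(ccorrect),
    _["corr_capped"] = wrap(capped_flag),
    _["pos"] = pos, _["assoc"] = assoc,
    _["lam"] = NumericVector::create(net.lam0, net.lam1));
}

// Batch of independent training runs over pre-generated stimulus
// sequences; returns per-run, per-session first-attempt accuracy.
// Used by the model-fitting objective (common random numbers: the caller
// seeds R's RNG before each call).
// [[Rcpp::export]]
NumericMatrix sustain_curve_batch_cpp(List X_list, List cat_list,
                                      double r, double beta, double d_dec,
                                      double eta, double eta_lambda, double tau,
                                      bool shuffle, int trials_per_session,
                                      bool recruit_on_choice = false) {
  const int n_runs = X_list.size();
  Par p = make_par(r, beta, d_dec, eta, eta_lambda, tau, shuffle,
                   recruit_on_choice);
  int n_sessions = 0;
  NumericMatrix out;
  for (int s = 0; s < n_runs; ++s) {
    NumericMatrix X = X_list[s];
    IntegerVector cat = cat_list[s];
    if (s == 0) {
      n_sessions = X.nrow() / trials_per_session;
      out = NumericMatrix(n_runs, n_sessions);
    }
    Net net;
    net.lam0 = 1.0; net.lam1 = 1.0;
    for (int sess = 0; sess < n_sessions; ++sess) {
      int n_ok = 0;
      for (int t = 0; t < trials_per_session; ++t) {
        const int row = sess * trials_per_session + t;
        StepOut o = step(net, X(row, 0), X(row, 1), cat[row], p, true);
        if (o.correct) ++n_ok;
      }
      out(s, sess) = (double)n_ok / trials_per_session;
    }
  }
  return out;
}

// Final cluster counts (and per-category counts by dominant association
// weight) for a batch of training runs; used for recruitment diagnostics.
// [[Rcpp::export]]
List sustain_cluster_batch_cpp(List X_list, List cat_list,
                               double r, double beta, double d_dec,
                               double eta, double eta_lambda, double tau,
                               bool shuffle,
                               bool recruit_on_choice = false) {
  const int n_runs = X_list.size();
  Par p = make_par(r, beta, d_dec, eta, eta_lambda, tau, shuffle,
                   recruit_on_choice);
  IntegerVector total(n_runs), n_a(n_runs), n_b(n_runs);
  for (int s = 0; s < n_runs; ++s) {
    NumericMatrix X = X_list[s];
    IntegerVector cat = cat_list[s];
    Net net;
    net.lam0 = 1.0; net.lam1 = 1.0;
    for (int t = 0; t < X.nrow(); ++t)
      step(net, X(t, 0), X(t, 1), cat[t], p, true);
    total[s] = (int)net.px.size();
    int a = 0, b = 0;
    for (size_t j = 0; j < net.px.size(); ++j) {
      if (net.wa[j] >= net.wb[j]) ++a; else ++b;
    }
    n_a[s] = a; n_b[s] = b;
  }
  return List::create(_["total"] = total, _["n_a"] = n_a, _["n_b"] = n_b);
}
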