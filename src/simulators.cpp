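// Event-driven simulators for the competitive birth-death-immigration model
// of T cell repertoire formation.  R's RNG is used throughout so that
// set.seed() in R governs reproducibility.

#include <Rcpp.h>
using namespace Rcpp;

// Deterministic mean total repertoire size N(t), with the d -> 0 limit.
static inline double nbar(double t, double influx, double d) {
  if (d == 0.0) return influx * t;
  return influx * (-expm1(-d * t)) / d;
}

// Exact Gillespie simulation of the coupled dynamics.  A per-cell list of
// clone indices gives O(1) selection of the proliferating/dying cell, since
// both birth and death pick a cell with probability proportional to clone
// size.  Total rates: recruitment theta, proliferation b0 (if N > 0; the
// per-cell rate is b0/N so the clone-summed rate is b0), death d*N.
// Snapshots are the piecewise-constant state at the last event <= record
// time.  init_sizes/init_trec seed pre-existing clones (may be empty).
// [[Rcpp::export]]
List simulate_exact_cpp(double b0, double d, double theta, int C0,
                        NumericVector record_times,
                        IntegerVector init_sizes, NumericVector init_trec) {
  std::vector<int> size;
  std::vector<double> trec;
  std::vector<int> cellclone;  // one entry per living cell
  for (int i = 0; i < init_sizes.size(); ++i) {
    size.push_back(init_sizes[i]);
    trec.push_back(init_trec[i]);
    for (int c = 0; c < init_sizes[i]; ++c) cellclone.push_back(i);
  }

  int K = record_times.size();
  List snap_id(K), snap_size(K), snap_trec(K);
  double t_end = record_times[K - 1];

  double t = 0.0;
  int k = 0;  // next record index
  long long n_events = 0, n_extinct = 0;

  auto record_upto = [&](double tnow) {
    while (k < K && record_times[k] < tnow) {
      std::vector<int> ids, sz;
      std::vector<double> tr;
      for (size_t i = 0; i < size.size(); ++i) {
        if (size[i] > 0) {
          ids.push_back((int)i + 1);
          sz.push_back(size[i]);
          tr.push_back(trec[i]);
        }
      }
      snap_id[k] = wrap(ids);
      snap_size[k] = wrap(sz);
      snap_trec[k] = wrap(tr);
      ++k;
    }
  };

  while (true) {
    double N = (double)cellclone.size();
    double lambda = theta + (N > 0 ? b0 : 0.0) + d * N;
    if (lambda <= 0.0) { t = t_end; break; }
    t += R::exp_rand() / lambda;
    if (t > t_end) break;
    record_upto(t);
    ++n_events;
    double u = unif_rand() * lambda;
    if (u < theta) {
      size.push_back(C0);
      trec.push_back(t);
      int id = (int)size.size() - 1;
      for (int c = 0; c < C0; ++c) cellclone.push_back(id);
    } else if (u < theta + (N > 0 ? b0 : 0.0)) {
      int idx = (int)(unif_rand() * cellclone.size());
      int cl = cellclone[idx];
      size[cl] += 1;
      cellclone.push_back(cl);
    } else {
      int idx = (int)(unif_rand() * cellclone.size());
      int cl = cellclone[idx];
      size[cl] -= 1;
      cellclone[idx] = cellclone.back();
      cellclone.pop_back();
      if (size[cl] == 0) ++n_extinct;
    }
  }
  record_upto(t_end + 1.0);  // flush remaining record times

  return List::create(_["id"] = snap_id, _["size"] = snap_size,
                      _["t_recruit"] = snap_trec,
                      _["n_events"] = (double)n_events,
                      _["n_extinct"] = (double)n_extinct);
}

// One clone under the mean-field approximation: birth-death process with
// per-cell birth rate beta(t) = b0 / Nbar(t) (monotonically decreasing) and
// per-cell death rate d, started at C0 cells at time ti.  Event times are
// drawn by thinning an inhomogeneous Poisson process with the piecewise
// majorant lambda*(t) = C * (beta(t_prev) + d), refreshed after every
// accepted or rejected event (valid because beta only decreases).  Returns
// the clone size at each record time (0 before recruitment or after
// extinction).
static void meanfield_clone(double ti, int C0, double b0, double d,
                            double influx, NumericVector record_times,
                            int* out, int stride) {
  int K = record_times.size();
  double t_endv = record_times[K - 1];
  double t = ti;
  int C = C0;
  int k = 0;
  while (k < K && record_times[k] < ti) { out[k * stride] = 0; ++k; }
  while (C > 0) {
    double beta_prev = b0 / nbar(t, influx, d);
    double lam_star = C * (beta_prev + d);
    double tnext = t + R::exp_rand() / lam_star;
    if (tnext > t_endv) break;
    while (k < K && record_times[k] < tnext) { out[k * stride] = C; ++k; }
    t = tnext;
    double beta_now = b0 / nbar(t, influx, d);
    double lam_now = C * (beta_now + d);
    if (unif_rand() * lam_star < lam_now) {  // accept event
      if (unif_rand() * (beta_now + d) < beta_now) C += 1; else C -= 1;
    }
  }
  while (k < K) { out[k * stride] = C; ++k; }
}

// Mean-field simulation of the whole repertoire: recruitment times are a
// homogeneous Poisson process of rate theta on (0, t_end]; each clone is then
// simulated independently.  Returns a clones x record_times size matrix plus
// recruitment times.
// [[Rcpp::export]]
List simulate_meanfield_cpp(double b0, double d, double theta, int C0,
                            NumericVector record_times) {
  int K = record_times.size();
  double t_end = record_times[K - 1];
  double influx = b0 + theta * (double)C0;
  int M = (int)R::rpois(theta * t_end);
  NumericVector ti(M);
  for (int i = 0; i < M; ++i) ti[i] = unif_rand() * t_end;
  std::sort(ti.begin(), ti.end());
  IntegerMatrix sizes(M, K);
  for (int i = 0; i < M; ++i) {
    if (ti[i] <= 0.0) ti[i] = std::nextafter(0.0, 1.0);  // a.s. unreachable
    meanfield_clone(ti[i], C0, b0, d, influx, record_times, &sizes(i, 0), M);
  }
  return List::create(_["t_recruit"] = ti, _["sizes"] = sizes);
}

// Replicated single-clone mean-field trajectories (oracle helper): n_reps
// independent clones all recruited at ti; returns n_reps x record_times.
// [[Rcpp::export]]
IntegerMatrix meanfield_clone_cpp(double ti, int C0, double b0, double d,
                                  double theta, NumericVector record_times,
                                  int n_reps) {
  if (ti <= 0.0) stop("t_recruit must be strictly positive");
  double influx = b0 + theta * (double)C0;
  IntegerMatrix sizes(n_reps, record_times.size());
  for (int i = 0; i < n_reps; ++i)
    meanfield_clone(ti, C0, b0, d, influx, record_times, &sizes(i, 0), n_reps);
  return sizes;
}
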