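#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Count-based continuous-time chain for the two-layer voter model on the
// complete graph with self-links. State: a = n_Rb, b = n_Br, r = n_Rr,
// q = N - a - b - r = n_Bb. Six state-changing channels (copy channels that
// share a target with externalization are merged by summing rates):
//   0: Rb -> Bb   c*a*(b+q)/N + e*a
//   1: Br -> Rr   c*b*(a+r)/N + e*b
//   2: Rr -> Br   c*r*(b+q)/N
//   3: Bb -> Rb   c*q*(a+r)/N
//   4: Rb -> Rr   i*a
//   5: Br -> Bb   i*b
// Null events (copying one's own colour, externalizing/internalizing a frank
// agent) carry no rate here; the agent-based reference includes them, and the
// two agree in distribution on everything but per-event traces.

// status codes: 1 red consensus, 2 blue consensus, 0 truncated at t_max,
// 3 frozen (total rate 0 away from consensus; only possible when i = 0)

// [[Rcpp::export]]
List cpp_cvm_gillespie(int a, int b, int r, int N,
                       double c, double e, double i,
                       double t_max, NumericVector grid,
                       int record_events) {
  double t = 0.0;
  const int G = grid.size();
  IntegerMatrix grid_states(G, 3);
  int g = 0;  // next grid index awaiting a state

  std::vector<double> ev_t;
  std::vector<int> ev_a, ev_b, ev_r;
  bool rec = record_events > 0;
  if (rec) {
    ev_t.reserve(1024); ev_a.reserve(1024); ev_b.reserve(1024); ev_r.reserve(1024);
    ev_t.push_back(0.0); ev_a.push_back(a); ev_b.push_back(b); ev_r.push_back(r);
  }

  int status = 0;
  long long n_events = 0;
  double rate[6];

  for (;;) {
    bool consensus = (a == 0 && b == 0 && (r == 0 || r == N));
    int q = N - a - b - r;
    double R = a + r, B = b + q;
    rate[0] = c * a * B / N + e * a;
    rate[1] = c * b * R / N + e * b;
    rate[2] = c * r * B / N;
    rate[3] = c * q * R / N;
    rate[4] = i * a;
    rate[5] = i * b;
    double total = rate[0] + rate[1] + rate[2] + rate[3] + rate[4] + rate[5];

    if (consensus || total <= 0.0) {
      status = consensus ? (r == N ? 1 : 2) : 3;
      // state persists forever; fill any remaining grid points
      while (g < G) {
        grid_states(g, 0) = a; grid_states(g, 1) = b; grid_states(g, 2) = r; ++g;
      }
      break;
    }

    double dt = exp_rand() / total;
    double t_next = t + dt;

    // grid points passed before the next event see the current state
    while (g < G && grid[g] < t_next) {
      if (grid[g] > t_max) break;
      grid_states(g, 0) = a; grid_states(g, 1) = b; grid_states(g, 2) = r; ++g;
    }

    if (t_next > t_max) {
      status = 0;
      t = t_max;
      while (g < G) {  // grid is validated to lie within [0, t_max] in R
        grid_states(g, 0) = a; grid_states(g, 1) = b; grid_states(g, 2) = r; ++g;
      }
      break;
    }

    double u = unif_rand() * total;
    int k = 0;
    double acc = rate[0];
    while (u > acc && k < 5) { ++k; acc += rate[k]; }
    switch (k) {
      case 0: --a; break;           // Rb -> Bb
      case 1: --b; ++r; break;      // Br -> Rr
      case 2: --r; ++b; break;      // Rr -> Br
      case 3: ++a; break;           // Bb -> Rb
      case 4: --a; ++r; break;      // Rb -> Rr
      case 5: --b; break;           // Br -> Bb
    }
    t = t_next;
    ++n_events;
    if (rec && (long long)ev_t.size() < (long long)record_events) {
      ev_t.push_back(t); ev_a.push_back(a); ev_b.push_back(b); ev_r.push_back(r);
    }
    if (n_events % 1048576 == 0) checkUserInterrupt();
  }

  List out = List::create(
    _["status"] = status,
    _["t_end"] = t,
    _["n_events"] = (double)n_events,
    _["a"] = a, _["b"] = b, _["r"] = r,
    _["grid_states"] = grid_states);
  if (rec) {
    out["times"] = NumericVector(ev_t.begin(), ev_t.end());
    out["ev_a"] = IntegerVector(ev_a.begin(), ev_a.end());
    out["ev_b"] = IntegerVector(ev_b.begin(), ev_b.end());
    out["ev_r"] = IntegerVector(ev_r.begin(), ev_r.end());
  }
  return out;
}

// Literal per-agent Monte Carlo algorithm for the two-layer model: pick a
// focal agent uniformly, draw u ~ U(0, c+e+i) to select copy / externalize /
// internalize, apply the (possibly null) update, then advance time by an
// Exponential(mean 1/((c+e+i)N)) increment and test for consensus.
// Retained as the reference implementation for equivalence tests.

// [[Rcpp::export]]
List cpp_cvm_agent(IntegerVector ext0, IntegerVector int0,
                   double c, double e, double i, double t_max) {
  const int N = ext0.size();
  std::vector<int> ext(ext0.begin(), ext0.end());   // 1 = red, 0 = blue
  std::vector<int> itn(int0.begin(), int0.end());
  int nR_ext = 0, nR_int = 0;
  for (int k = 0; k < N; ++k) { nR_ext += ext[k]; nR_int += itn[k]; }
  const double cei = c + e + i;
  double t = 0.0;
  int status = 0;
  long long n_steps = 0;

  for (;;) {
    if ((nR_ext == N && nR_int == N) || (nR_ext == 0 && nR_int == 0)) {
      status = (nR_ext == N) ? 1 : 2;
      break;
    }
    int f = (int)(unif_rand() * N); if (f == N) f = N - 1;
    double u = unif_rand() * cei;
    if (u < c) {                       // copy a random neighbour (self allowed)
      int n = (int)(unif_rand() * N); if (n == N) n = N - 1;
      if (ext[f] != ext[n]) { nR_ext += ext[n] - ext[f]; ext[f] = ext[n]; }
    } else if (u < c + e) {            // externalize: private overwrites public
      if (ext[f] != itn[f]) { nR_ext += itn[f] - ext[f]; ext[f] = itn[f]; }
    } else {                           // internalize: public overwrites private
      if (itn[f] != ext[f]) { nR_int += ext[f] - itn[f]; itn[f] = ext[f]; }
    }
    t += exp_rand() / (cei * N);
    if (t > t_max) { status = 0; t = t_max; break; }
    if (++n_steps % 1048576 == 0) checkUserInterrupt();
  }
  return List::create(_["status"] = status, _["t_end"] = t,
                      _["n_events"] = (double)n_steps,
                      _["nR_ext"] = nR_ext, _["nR_int"] = nR_int);
}

// Single-layer voter model, count-based: R -> B and B -> R each at rate
// c*R*(N-R)/N (neutral drift).

// [[Rcpp::export]]
List cpp_bvm_gillespie(int R, int N, double c, double t_max,
                       int record_events) {
  double t = 0.0;
  std::vector<double> ev_t; std::vector<int> ev_R;
  bool rec = record_events > 0;
  if (rec) { ev_t.push_back(0.0); ev_R.push_back(R); }
  int status = 0;
  long long n_events = 0;
  for (;;) {
    if (R == 0 || R == N) { status = (R == N) ? 1 : 2; break; }
    double one_way = c * (double)R * (double)(N - R) / N;
    double dt = exp_rand() / (2.0 * one_way);
    if (t + dt > t_max) { status = 0; t = t_max; break; }
    t += dt;
    R += (unif_rand() < 0.5) ? 1 : -1;
    ++n_events;
    if (rec && (long long)ev_t.size() < (long long)record_events) {
      ev_t.push_back(t); ev_R.push_back(R);
    }
    if (n_events % 1048576 == 0) checkUserInterrupt();
  }
  List out = List::create(_["status"] = status, _["t_end"] = t,
                          _["n_events"] = (double)n_events, _["R"] = R);
  if (rec) {
    out["times"] = NumericVector(ev_t.begin(), ev_t.end());
    out["ev_R"] = IntegerVector(ev_R.begin(), ev_R.end());
  }
  return out;
}

// Literal per-agent single-layer algorithm: focal copies a uniformly random
// neighbour (self allowed); time advances by Exponential(mean 1/(cN)).

// [[Rcpp::export]]
List cpp_bvm_agent(IntegerVector col0, double c, double t_max) {
  const int N = col0.size();
  std::vector<int> col(col0.begin(), col0.end());
  int nR = 0;
  for (int k = 0; k < N; ++k) nR += col[k];
  double t = 0.0;
  int status = 0;
  long long n_steps = 0;
  for (;;) {
    if (nR == 0 || nR == N) { status = (nR == N) ? 1 : 2; break; }
    int f = (int)(unif_rand() * N); if (f == N) f = N - 1;
    int n = (int)(unif_rand() * N); if (n == N) n = N - 1;
    if (col[f] != col[n]) { nR += col[n] - col[f]; col[f] = col[n]; }
    t += exp_rand() / (c * N);
    if (t > t_max) { status = 0; t = t_max; break; }
    if (++n_steps % 1048576 == 0) checkUserInterrupt();
  }
  return List::create(_["status"] = status, _["t_end"] = t,
                      _["n_events"] = (double)n_steps, _["nR"] = nR);
}
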