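#include <Rcpp.h>
using namespace Rcpp;

// Euler simulation of the Ornstein-Uhlenbeck accumulator for one evidence
// level. State starts at 0 and integrates
//   EA <- EA + leak*EA*dt + k*evidence*dt + N(0, sigma) [+ bias if evidence==0]
// until |EA| > boundary. sigma is a per-step SD tied to dt (not scaled by
// sqrt(dt)); leak is in 1/s. Traces that fail to cross within max_t are
// redrawn against a shared redraw budget; once the budget is spent the call
// aborts (aborted = true) so that pathological parameter points cost little
// inside optimization loops. Uses R's RNG, so set.seed() governs output.
// Marsaglia polar normal generator over R's uniform stream: much faster than
// inversion in this hot loop while still fully governed by set.seed().
struct PolarNormal {
  bool has_spare = false;
  double spare = 0.0;
  double draw() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif_rand() - 1.0;
      v = 2.0 * unif_rand() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    const double m = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * m;
    has_spare = true;
    return u * m;
  }
};

// [[Rcpp::export]]
List ou_simulate_level(double leak, double k, double sigma, double bias,
                       double ndt, double boundary, double evidence,
                       int n_traces, double dt, double max_t,
                       int redraw_budget) {
  PolarNormal rng;
  IntegerVector choice(n_traces);
  NumericVector rt(n_traces);
  const int max_steps = (int)std::floor(max_t / dt);
  const double drift = k * evidence * dt;
  const double step_bias = (evidence == 0.0) ? bias : 0.0;
  const double leak_dt = leak * dt;
  int redraws = 0;
  bool aborted = false;
  int done = 0;
  for (int i = 0; i < n_traces && !aborted; ++i) {
    int ch = 0;
    double t_dec = 0.0;
    for (;;) {
      double ea = 0.0;
      int step = 0;
      while (step < max_steps) {
        ++step;
        ea += leak_dt * ea + drift + rng.draw() * sigma + step_bias;
        if (ea > boundary || ea < -boundary) break;
      }
      if (ea > boundary) { ch = 1; t_dec = step * dt; break; }
      if (ea < -boundary) { ch = -1; t_dec = step * dt; break; }
      if (++redraws > redraw_budget) { aborted = true; break; }
    }
    if (aborted) break;
    choice[i] = ch;
    rt[i] = t_dec + ndt;
    ++done;
  }
  return List::create(_["choice"] = choice, _["rt"] = rt,
                      _["n_redrawn"] = redraws, _["aborted"] = aborted,
                      _["n_done"] = done);
}
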