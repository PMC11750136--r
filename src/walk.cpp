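#include <Rcpp.h>
using namespace Rcpp;

// Core loop of the biased random-walk trajectory generator.
// State 0 = free diffusion; state j (1-based) = drift toward chamber j with
// magnitude gain[j-1] * step_sd per frame.  Boundaries reflect.
// Uses R's RNG so set.seed() in the caller makes output reproducible.
// [[Rcpp::export(name = ".walk_cpp")]]
List walk_cpp(int n_frames, double x0, double y0, double w, double h,
              double step_sd, NumericVector cx, NumericVector cy,
              NumericVector gain, double persistence) {
  int k = cx.size();
  NumericVector x(n_frames), y(n_frames);
  IntegerVector state(n_frames);
  // switching weights: free state weight 1, chamber j weight gain[j]
  double wsum = 1.0;
  for (int j = 0; j < k; ++j) wsum += gain[j];
  int s = 0;
  double px = x0, py = y0;
  for (int i = 0; i < n_frames; ++i) {
    if (i > 0 && unif_rand() >= persistence) {
      double u = unif_rand() * wsum;
      s = 0;
      if (u >= 1.0) {
        u -= 1.0;
        for (int j = 0; j < k; ++j) {
          if (u < gain[j]) { s = j + 1; break; }
          u -= gain[j];
        }
      }
    }
    double dx = norm_rand() * step_sd, dy = norm_rand() * step_sd;
    if (s > 0) {
      double vx = cx[s - 1] - px, vy = cy[s - 1] - py;
      double d = std::sqrt(vx * vx + vy * vy);
      if (d > 1e-9) {
        double g = gain[s - 1] * step_sd / d;
        dx += vx * g;
        dy += vy * g;
      }
    }
    px += dx; py += dy;
    // reflecting boundaries
    while (px < 0.0 || px > w) px = (px < 0.0) ? -px : 2.0 * w - px;
    while (py < 0.0 || py > h) py = (py < 0.0) ? -py : 2.0 * h - py;
    x[i] = px; y[i] = py; state[i] = s;
  }
  return List::create(_["x"] = x, _["y"] = y, _["state"] = state);
}
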