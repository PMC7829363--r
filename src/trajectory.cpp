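// Momentum-smoothed random-walk (Ornstein-Uhlenbeck speed + diffusing
// heading) trajectory with specular reflection at arena walls and hole
// boundaries. Randomness is supplied from R so that set.seed() reproduces
// trajectories bitwise.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

// holes: matrix with rows (type, a, b, c, d);
// type 0 = rectangle (xmin, ymin, xmax, ymax), type 1 = disc (cx, cy, r, 0)
bool in_hole(double x, double y, const NumericMatrix& holes, int* which_hole) {
  for (int h = 0; h < holes.nrow(); ++h) {
    if (holes(h, 0) == 0.0) {
      if (x > holes(h, 1) && x < holes(h, 3) && y > holes(h, 2) && y < holes(h, 4)) {
        *which_hole = h;
        return true;
      }
    } else {
      double dx = x - holes(h, 1), dy = y - holes(h, 2);
      if (dx * dx + dy * dy < holes(h, 3) * holes(h, 3)) {
        *which_hole = h;
        return true;
      }
    }
  }
  return false;
}

bool accessible(double x, double y, double W, double H, const NumericMatrix& holes) {
  int dummy;
  return x >= 0 && x <= W && y >= 0 && y <= H && !in_hole(x, y, holes, &dummy);
}

} // namespace

// [[Rcpp::export]]
NumericMatrix ou_trajectory_cpp(double x0, double y0, double phi0, double s0,
                                int n_steps, double dt,
                                double speed_mean, double speed_sd, double relax,
                                double turn_sd,
                                NumericVector eps_speed, NumericVector eps_turn,
                                double width, double height, NumericMatrix holes) {
  NumericMatrix out(n_steps + 1, 2);
  out(0, 0) = x0;
  out(0, 1) = y0;
  double x = x0, y = y0, phi = phi0, s = s0;
  const double sq = std::sqrt(dt);
  for (int k = 0; k < n_steps; ++k) {
    s += relax * (speed_mean - s) * dt +
         speed_sd * std::sqrt(2.0 * relax) * sq * eps_speed[k];
    if (s < 0) s = -s; // reflect speed at zero
    phi += turn_sd * sq * eps_turn[k];
    double nx = x + s * std::cos(phi) * dt;
    double ny = y + s * std::sin(phi) * dt;
    // specular reflection at arena walls
    if (nx < 0)      { nx = -nx;              phi = M_PI - phi; }
    if (nx > width)  { nx = 2 * width - nx;   phi = M_PI - phi; }
    if (ny < 0)      { ny = -ny;              phi = -phi; }
    if (ny > height) { ny = 2 * height - ny;  phi = -phi; }
    int h = -1;
    if (in_hole(nx, ny, holes, &h)) {
      if (holes(h, 0) == 0.0) {
        // rectangle: reflect across the edge whose slab the previous
        // position was outside of
        bool prev_in_x = (x > holes(h, 1) && x < holes(h, 3));
        if (!prev_in_x) {
          if (x <= holes(h, 1)) nx = 2 * holes(h, 1) - nx;
          else                  nx = 2 * holes(h, 3) - nx;
          phi = M_PI - phi;
        } else {
          if (y <= holes(h, 2)) ny = 2 * holes(h, 2) - ny;
          else                  ny = 2 * holes(h, 4) - ny;
          phi = -phi;
        }
      } else {
        // disc: push the point radially to the mirror radius and reflect
        // the heading about the boundary normal
        double cx = holes(h, 1), cy = holes(h, 2), r = holes(h, 3);
        double dx = nx - cx, dy = ny - cy;
        double rr = std::sqrt(dx * dx + dy * dy);
        if (rr < 1e-12) { rr = 1e-12; dx = 1e-12; }
        double rmir = 2 * r - rr;
        nx = cx + dx / rr * rmir;
        ny = cy + dy / rr * rmir;
        double psi = std::atan2(dy, dx); // boundary normal direction
        phi = 2 * psi + M_PI - phi;      // specular reflection about normal
      }
    }
    if (!accessible(nx, ny, width, height, holes)) {
      // rare corner case (e.g., double reflection): stay put, turn around
      nx = x;
      ny = y;
      phi = phi + M_PI;
    }
    x = nx;
    y = ny;
    out(k + 1, 0) = x;
    out(k + 1, 1) = y;
  }
  return out;
}
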