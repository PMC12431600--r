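#include <Rcpp.h>
using namespace Rcpp;

// Render an anti-aliased ellipse (with an optional central marker disc)
// translated per frame by (shift_x[f], shift_y[f]).  Anti-aliasing is by
// regular subpixel supersampling (ss x ss samples per pixel).  Pixels are
// indexed with their centres at integer coordinates, x rightward (columns),
// y downward (rows), origin at pixel (0, 0).  Returns an h x w x n array.
// [[Rcpp::export(name = ".render_frames_cpp")]]
NumericVector render_frames_cpp(NumericVector shift_x, NumericVector shift_y,
                                int width, int height,
                                double cx, double cy,
                                double ax, double ay,
                                double marker_radius,
                                double background, double foreground,
                                double marker_intensity,
                                int ss) {
  const int n = shift_x.size();
  NumericVector out(static_cast<R_xlen_t>(width) * height * n, background);
  const double mr2 = marker_radius * marker_radius;
  const double inv_ss2 = 1.0 / (ss * ss);

  for (int f = 0; f < n; ++f) {
    const double ex = cx + shift_x[f];  // ellipse centre this frame
    const double ey = cy + shift_y[f];
    int c0 = std::max(0, (int)std::floor(ex - ax - 1.0));
    int c1 = std::min(width - 1, (int)std::ceil(ex + ax + 1.0));
    int r0 = std::max(0, (int)std::floor(ey - ay - 1.0));
    int r1 = std::min(height - 1, (int)std::ceil(ey + ay + 1.0));
    R_xlen_t base = static_cast<R_xlen_t>(f) * width * height;
    for (int c = c0; c <= c1; ++c) {
      for (int r = r0; r <= r1; ++r) {
        double acc = 0.0;
        for (int i = 0; i < ss; ++i) {
          double px = c - 0.5 + (i + 0.5) / ss;
          double u = (px - ex) / ax;
          double dx2 = (px - ex) * (px - ex);
          for (int jdx = 0; jdx < ss; ++jdx) {
            double py = r - 0.5 + (jdx + 0.5) / ss;
            double v = (py - ey) / ay;
            if (u * u + v * v <= 1.0) {
              double dy2 = (py - ey) * (py - ey);
              acc += (dx2 + dy2 <= mr2) ? marker_intensity : foreground;
            } else {
              acc += background;
            }
          }
        }
        out[base + static_cast<R_xlen_t>(c) * height + r] = acc * inv_ss2;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(height, width, n);
  return out;
}
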