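#include <Rcpp.h>
using namespace Rcpp;

// Sequential sinus-rhythm IBI recurrence: each interval depends on the time of
// the preceding pulse through the respiratory-sinus-arrhythmia phase, so the
// beat train cannot be vectorised. Uses R's RNG (rnorm) so results are
// reproducible under set.seed().
//
// Returns a two-column matrix (t_s, ibi_ms); beats are the interval endpoints,
// t in (0, duration_s].
// [[Rcpp::export(name = ".sinus_ibi_cpp")]]
NumericMatrix sinus_ibi_cpp(double duration_s, double mean_rr_ms,
                            double rsa_amp_ms, double rsa_freq_hz,
                            double jitter_sd_ms) {
  const double two_pi = 2.0 * M_PI;
  const double tol = 1e-9;
  std::vector<double> t_out, ibi_out;
  t_out.reserve((size_t)(duration_s * 1000.0 / mean_rr_ms) + 16);
  ibi_out.reserve(t_out.capacity());

  double t = 0.0;
  while (true) {
    double ibi = mean_rr_ms + rsa_amp_ms * std::sin(two_pi * rsa_freq_hz * t);
    if (jitter_sd_ms > 0.0) ibi += R::rnorm(0.0, jitter_sd_ms);
    if (ibi < 200.0) ibi = 200.0;  // physiological floor, keeps t increasing
    double t_next = t + ibi / 1000.0;
    if (t_next > duration_s + tol) break;
    t_out.push_back(t_next);
    ibi_out.push_back(ibi);
    t = t_next;
  }

  NumericMatrix out(t_out.size(), 2);
  for (size_t i = 0; i < t_out.size(); ++i) {
    out(i, 0) = t_out[i];
    out(i, 1) = ibi_out[i];
  }
  colnames(out) = CharacterVector::create("t_s", "ibi_ms");
  return out;
}
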