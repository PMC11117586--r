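#include <Rcpp.h>
using namespace Rcpp;

// Sequential dispersion clustering of one time-ordered gaze stream.
// A valid sample joins the open cluster iff its distance to the cluster's
// running centroid (or first member, when first_point_rule) is <= tolerance
// and the time since the last member is <= max_gap. Otherwise the cluster is
// closed and a new one starts at the sample. On close, an optional secondary
// tolerance drops members farther than t2 from the final centroid and the
// centroid is recomputed once. Clusters whose duration (last - first member
// time) reaches min_duration are emitted as fixations.
// [[Rcpp::export(name = ".detect_fixations_cpp")]]
DataFrame detect_fixations_cpp(NumericVector t, NumericVector x,
                               NumericVector y, LogicalVector valid,
                               double tolerance, double min_duration,
                               double max_gap, double secondary_tolerance,
                               bool first_point_rule) {
  int n = t.size();
  std::vector<double> onset, offset, cx, cy;
  std::vector<int> nsamp;
  std::vector<int> members;
  double sx = 0.0, sy = 0.0;

  bool use_t2 = R_finite(secondary_tolerance) && secondary_tolerance > 0;

  auto close_cluster = [&]() {
    int m = members.size();
    if (m == 0) return;
    double mx = sx / m, my = sy / m;
    double first_t = t[members.front()], last_t = t[members.back()];
    int kept = m;
    if (use_t2) {
      double kx = 0.0, ky = 0.0;
      kept = 0;
      first_t = R_PosInf;
      last_t = R_NegInf;
      for (int idx : members) {
        double d = std::sqrt((x[idx] - mx) * (x[idx] - mx) +
                             (y[idx] - my) * (y[idx] - my));
        if (d <= secondary_tolerance) {
          kx += x[idx];
          ky += y[idx];
          if (t[idx] < first_t) first_t = t[idx];
          if (t[idx] > last_t) last_t = t[idx];
          ++kept;
        }
      }
      if (kept > 0) {
        mx = kx / kept;
        my = ky / kept;
      }
    }
    if (kept > 0 && last_t - first_t >= min_duration) {
      onset.push_back(first_t);
      offset.push_back(last_t);
      cx.push_back(mx);
      cy.push_back(my);
      nsamp.push_back(kept);
    }
    members.clear();
    sx = sy = 0.0;
  };

  for (int i = 0; i < n; ++i) {
    if (!valid[i]) continue;
    if (!members.empty()) {
      double gap = t[i] - t[members.back()];
      double refx, refy;
      if (first_point_rule) {
        refx = x[members.front()];
        refy = y[members.front()];
      } else {
        refx = sx / members.size();
        refy = sy / members.size();
      }
      double d = std::sqrt((x[i] - refx) * (x[i] - refx) +
                           (y[i] - refy) * (y[i] - refy));
      if (gap > max_gap || d > tolerance) close_cluster();
    }
    members.push_back(i);
    sx += x[i];
    sy += y[i];
  }
  close_cluster();

  return DataFrame::create(
      _["onset_ms"] = wrap(onset), _["offset_ms"] = wrap(offset),
      _["duration_ms"] = [&] {
        NumericVector d(onset.size());
        for (size_t i = 0; i < onset.size(); ++i) d[i] = offset[i] - onset[i];
        return d;
      }(),
      _["centroid_x_px"] = wrap(cx), _["centroid_y_px"] = wrap(cy),
      _["n_samples"] = wrap(nsamp));
}
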