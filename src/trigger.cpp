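#include <Rcpp.h>
using namespace Rcpp;

// Trigger/quiescence state machine over a triaxial sample matrix (units g).
//
// States: quiescent -> armed when any-axis |sample - reference| > arm_g;
// armed -> active (retroactively from the arming sample) when a deviation
// > confirm_g occurs within `window` samples of arming, else back to
// quiescent (the armed samples stay quiescent). Active ends after `quiet`
// samples without an arm-level deviation; samples after the last deviation
// are left quiescent so that a motionless block starts its quiescent run
// immediately. The reference is updated with the coincident sample whenever
// either limit is exceeded. All comparisons are strict (> not >=).
//
// [[Rcpp::export]]
LogicalVector trigger_machine_cpp(NumericMatrix a, double arm_g, double confirm_g,
                                  int window, int quiet) {
  int n = a.nrow();
  LogicalVector active(n);
  if (n == 0) return active;
  double ref[3] = {a(0, 0), a(0, 1), a(0, 2)};
  int state = 0;  // 0 quiescent, 1 armed, 2 active
  int arm_i = -1, last_ex = -1;
  for (int i = 0; i < n; ++i) {
    double dev = 0.0;
    for (int k = 0; k < 3; ++k) {
      double d = std::abs(a(i, k) - ref[k]);
      if (d > dev) dev = d;
    }
    if (state == 1 && i - arm_i > window) state = 0;  // arming window expired
    if (state == 0) {
      if (dev > arm_g) {
        state = 1;
        arm_i = i;
        for (int k = 0; k < 3; ++k) ref[k] = a(i, k);
      }
    } else if (state == 1) {
      if (dev > confirm_g) {
        state = 2;
        last_ex = i;
        for (int j = arm_i; j <= i; ++j) active[j] = true;
        for (int k = 0; k < 3; ++k) ref[k] = a(i, k);
      } else if (dev > arm_g) {
        for (int k = 0; k < 3; ++k) ref[k] = a(i, k);
      }
    } else {  // active
      if (dev > arm_g) {
        for (int j = last_ex + 1; j <= i; ++j) active[j] = true;
        last_ex = i;
        for (int k = 0; k < 3; ++k) ref[k] = a(i, k);
      } else if (i - last_ex > quiet) {
        state = 0;
      }
    }
  }
  return active;
}
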