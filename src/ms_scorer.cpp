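#include <Rcpp.h>
using namespace Rcpp;

// Time-stepped Go/no-go trial scorer. Walks a millisecond clock, tracks the
// continuous beam-break run length, grants at most `max_ext` window
// extensions for sub-criterion pokes that started inside the initial
// window, and reports the first instant a run reaches the criterion. Kept
// deliberately naive (per-step state updates, no event arithmetic) so it is
// an independent check on the event-driven R scorer.

static bool poking_at(const NumericVector& onset, const NumericVector& dur,
                      double t) {
  for (int i = 0; i < onset.size(); ++i) {
    if (t >= onset[i] && t < onset[i] + dur[i]) return true;
  }
  return false;
}

// [[Rcpp::export]]
List ms_score_trial(NumericVector onset, NumericVector dur,
                    double criterion, double window, double extension,
                    int max_ext, double dt) {
  double w = window;
  int ext_left = max_ext;
  double run = 0.0, run_start = NA_REAL;
  bool prev = false;
  double alert = NA_REAL;
  const double eps = dt * 1e-6;
  double horizon = window + extension + criterion + 1.0;
  long nstep = (long)std::ceil(horizon / dt) + 2;

  for (long i = 0; i < nstep; ++i) {
    double t = i * dt;
    bool pk = poking_at(onset, dur, t);

    if (t >= w - eps) {
      // Window closing. A sub-criterion poke that started inside the
      // initial window and is ongoing (or ended at this very instant)
      // still earns the extension.
      if (prev && run < criterion - eps && ext_left > 0 &&
          run_start < window - eps) {
        w = window + extension;
        --ext_left;
      } else if (!(pk && prev && run >= criterion - eps)) {
        break; // trial over, no alert
      }
    }

    if (pk) {
      if (!prev) {
        run_start = t;
        run = 0.0;
      }
      run += dt;
      if (ISNA(alert) && run >= criterion - eps) {
        alert = run_start + criterion;
        break;
      }
    } else {
      if (prev && run < criterion - eps && ext_left > 0 &&
          run_start < window - eps) {
        // sub-criterion poke just ended inside the active window
        if (run_start < w - eps) {
          w = window + extension;
          --ext_left;
        }
      }
      run = 0.0;
      run_start = NA_REAL;
    }
    prev = pk;
  }

  bool responded = !ISNA(alert);
  // An alert computed past the active window close does not count.
  if (responded && alert > w + eps) responded = false;
  return List::create(_["responded"] = responded,
                      _["latency_s"] = responded ? alert : NA_REAL);
}
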