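#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie direct method) of a mass-action
// reaction network with optional piecewise-constant scaling of flagged
// reactions (the c_p(t) schedule). Propensities are
//   rate_j * sched_j(t) * prod_i falling_factorial(x_i, order_ij).
// Because flagged rates are piecewise constant in time, exactness is
// preserved by capping each waiting time at the next schedule breakpoint
// and re-drawing (the exponential clock is memoryless).
//
// The event path is sampled onto the output grid by
// last-value-carried-forward. Uses R's RNG, so runs are reproducible via
// set.seed().
// [[Rcpp::export(name = ".ssaCore")]]
IntegerMatrix ssaCore(IntegerMatrix stoich,      // species x reactions
                      IntegerMatrix orders,      // species x reactions
                      NumericVector rates,
                      LogicalVector timeDependent,
                      NumericVector schedTimes,  // breakpoints (first <= t0)
                      NumericVector schedValues,
                      IntegerVector init,
                      NumericVector outTimes,
                      double maxEvents) {
  const int nS = stoich.nrow();
  const int nR = stoich.ncol();
  const int nT = outTimes.size();

  // sparse reactant lists per reaction
  std::vector<std::vector<int>> reacSp(nR);
  std::vector<std::vector<int>> reacOrd(nR);
  // sparse change lists per reaction
  std::vector<std::vector<int>> chSp(nR), chVal(nR);
  for (int j = 0; j < nR; ++j) {
    for (int i = 0; i < nS; ++i) {
      if (orders(i, j) > 0) {
        reacSp[j].push_back(i);
        reacOrd[j].push_back(orders(i, j));
      }
      if (stoich(i, j) != 0) {
        chSp[j].push_back(i);
        chVal[j].push_back(stoich(i, j));
      }
    }
  }

  std::vector<double> x(nS);
  for (int i = 0; i < nS; ++i) x[i] = init[i];

  IntegerMatrix out(nT, nS);
  double t = outTimes[0];
  int outIdx = 0;

  // current schedule segment
  int seg = 0;
  const int nSeg = schedTimes.size();
  while (seg + 1 < nSeg && schedTimes[seg + 1] <= t) ++seg;
  bool anyTD = false;
  for (int j = 0; j < nR; ++j) if (timeDependent[j]) anyTD = true;

  std::vector<double> a(nR);
  double nEvents = 0.0;
  const double tEnd = outTimes[nT - 1];

  auto record_until = [&](double tNow) {
    while (outIdx < nT && outTimes[outIdx] <= tNow) {
      for (int i = 0; i < nS; ++i) out(outIdx, i) = (int)x[i];
      ++outIdx;
    }
  };

  // state at the first grid point
  record_until(t);

  while (t < tEnd) {
    // propensities
    double a0 = 0.0;
    double sv = schedValues[seg];
    for (int j = 0; j < nR; ++j) {
      double aj = rates[j];
      if (timeDependent[j]) aj *= sv;
      if (aj > 0.0) {
        const std::vector<int>& sp = reacSp[j];
        const std::vector<int>& od = reacOrd[j];
        for (size_t k = 0; k < sp.size(); ++k) {
          double xv = x[sp[k]];
          for (int o = 0; o < od[k]; ++o) { aj *= xv; xv -= 1.0; }
        }
        if (aj < 0.0) aj = 0.0;
      }
      a[j] = aj;
      a0 += aj;
    }
    if (!R_finite(a0)) stop("propensity overflow/NaN at t = %f", t);

    double nextBreak = (anyTD && seg + 1 < nSeg) ? schedTimes[seg + 1]
                                                 : R_PosInf;
    if (a0 <= 0.0) {
      // nothing can fire until the schedule changes
      double tJump = std::min(nextBreak, tEnd);
      record_until(std::min(tJump, tEnd) == tEnd ? tEnd : tJump - 1e-12);
      t = tJump;
      if (t >= tEnd) break;
      ++seg;
      continue;
    }
    double u1 = unif_rand();
    if (u1 <= 0.0) u1 = 1e-300;
    double tau = -std::log(u1) / a0;
    if (t + tau >= nextBreak) {
      // cross the breakpoint without firing; redraw in the new segment
      record_until(nextBreak - 1e-12);
      t = nextBreak;
      ++seg;
      continue;
    }
    double tNew = t + tau;
    if (tNew >= tEnd) {
      t = tEnd;
      break;
    }
    // choose reaction
    double u2 = unif_rand() * a0;
    int j = 0;
    double cum = a[0];
    while (cum < u2 && j < nR - 1) { ++j; cum += a[j]; }
    // record grid points passed before the state changes
    record_until(tNew - 1e-12);
    for (size_t k = 0; k < chSp[j].size(); ++k) {
      x[chSp[j][k]] += chVal[j][k];
      if (x[chSp[j][k]] < 0)
        stop("species %d driven negative at t = %f (reaction %d)",
             chSp[j][k] + 1, tNew, j + 1);
    }
    t = tNew;
    if (++nEvents > maxEvents)
      stop("event budget exceeded (%.0f events); raise maxEvents", maxEvents);
  }
  // remaining grid points carry the final state
  record_until(tEnd);
  return out;
}
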