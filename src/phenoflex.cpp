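#include <Rcpp.h>
using namespace Rcpp;

// Hourly kinetic bloom engine.
//
// Chill: two-step dynamic model. An intermediate precursor x builds towards a
// temperature-dependent steady state xs(T) at rate k1(T) (both Arrhenius in
// Kelvin; E0/E1 are activation energies divided by the gas constant). Whenever
// x completes (x >= 1) a sigmoidal fraction sigma(T) of it is converted to an
// irreversible chill portion.
//
// Heat: growing degree hours (GDH), a cosine response between base Tb,
// optimum Tu and critical Tc, weighted by a capped-exponential transition
// w = min(1, exp(s1 * (y - yc))) so forcing only counts once the chill
// requirement yc is (nearly) met. Bloom is the first hour with z >= zc.
//
// Parameter vector order (shared with the R side):
// yc, zc, s1, Tu, E0, E1, A0, A1, Tf, Tc, Tb, slope

static inline double gdh_one(double T, double Tu, double Tb, double Tc) {
  if (T <= Tb || T >= Tc) return 0.0;
  if (T <= Tu)
    return (Tu - Tb) / 2.0 * (1.0 + std::cos(M_PI + M_PI * (T - Tb) / (Tu - Tb)));
  return (Tu - Tb) * (1.0 + std::cos(M_PI / 2.0 + M_PI / 2.0 * (T - Tu) / (Tc - Tu)));
}

// [[Rcpp::export]]
NumericVector gdh_value_cpp(NumericVector temp, double Tu, double Tb, double Tc) {
  int n = temp.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = gdh_one(temp[i], Tu, Tb, Tc);
  return out;
}

// Full engine run over an hourly temperature vector. Stops at bloom unless a
// trajectory is requested. bloom_hour is 1-based; -1 is the no-bloom sentinel.
// [[Rcpp::export]]
List pf_run_cpp(NumericVector temp, NumericVector par, bool keep_traj = false) {
  double yc = par[0], zc = par[1], s1 = par[2], Tu = par[3], E0 = par[4],
         E1 = par[5], A0 = par[6], A1 = par[7], Tf = par[8], Tc = par[9],
         Tb = par[10], slope = par[11];
  int n = temp.size();
  NumericVector ytr, ztr;
  if (keep_traj) {
    ytr = NumericVector(n);
    ztr = NumericVector(n);
  }
  double x = 0.0, y = 0.0, z = 0.0;
  int bloom = -1;
  int last = n;
  double bloom_frac = -1.0;
  for (int i = 0; i < n; i++) {
    double T = temp[i], TK = T + 273.15;
    double xs = (A0 / A1) * std::exp(-(E0 - E1) / TK);
    double ek1 = std::exp(-A1 * std::exp(-E1 / TK));
    double xst = xs - (xs - x) * ek1;
    if (xst >= 1.0) {
      double sig = 1.0 / (1.0 + std::exp(-slope * (T - Tf)));
      double d = xst * sig;
      x = xst - d;
      y += d;
    } else {
      x = xst;
    }
    double w = std::exp(s1 * (y - yc));
    if (w > 1.0) w = 1.0;
    double zprev = z;
    z += gdh_one(T, Tu, Tb, Tc) * w;
    if (keep_traj) {
      ytr[i] = y;
      ztr[i] = z;
    }
    if (bloom < 0 && z >= zc) {
      bloom = i + 1;
      // sub-hour interpolation of the threshold crossing
      bloom_frac = i + (z > zprev ? (zc - zprev) / (z - zprev) : 1.0);
      if (!keep_traj) {
        last = i + 1;
        break;
      }
    }
  }
  List out = List::create(_["bloom_hour"] = bloom, _["x"] = x, _["y"] = y,
                          _["z"] = z, _["hours_run"] = last,
                          _["bloom_hour_frac"] = bloom_frac);
  if (keep_traj) {
    out["y_traj"] = ytr;
    out["z_traj"] = ztr;
  }
  return out;
}

// Cumulative chill portions after each hour. Depends only on the chill
// kinetics (E0, E1, A0, A1, Tf, slope), so it can be cached across objective
// evaluations when those parameters are held fixed during fitting.
// [[Rcpp::export]]
NumericVector pf_chill_traj_cpp(NumericVector temp, double E0, double E1,
                                double A0, double A1, double Tf, double slope) {
  int n = temp.size();
  NumericVector y(n);
  double x = 0.0, acc = 0.0;
  for (int i = 0; i < n; i++) {
    double T = temp[i], TK = T + 273.15;
    double xs = (A0 / A1) * std::exp(-(E0 - E1) / TK);
    double ek1 = std::exp(-A1 * std::exp(-E1 / TK));
    double xst = xs - (xs - x) * ek1;
    if (xst >= 1.0) {
      double sig = 1.0 / (1.0 + std::exp(-slope * (T - Tf)));
      double d = xst * sig;
      x = xst - d;
      acc += d;
    } else {
      x = xst;
    }
    y[i] = acc;
  }
  return y;
}

// Fractional bloom hour (threshold crossing interpolated within the hour)
// given a precomputed chill trajectory: the fast path for fitting. The
// sub-hour resolution keeps the calibration objective smooth in the
// parameters instead of piecewise-constant at day resolution.
// [[Rcpp::export]]
double pf_bloom_from_traj_cpp(NumericVector temp, NumericVector ytraj,
                              double yc, double zc, double s1, double Tu,
                              double Tc, double Tb) {
  int n = temp.size();
  double z = 0.0;
  for (int i = 0; i < n; i++) {
    double w = std::exp(s1 * (ytraj[i] - yc));
    if (w > 1.0) w = 1.0;
    double zprev = z;
    z += gdh_one(temp[i], Tu, Tb, Tc) * w;
    if (z >= zc) return i + (z > zprev ? (zc - zprev) / (z - zprev) : 1.0);
  }
  return -1.0;
}
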