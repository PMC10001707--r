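#include <Rcpp.h>
using namespace Rcpp;

// Explicit-Euler integration loop of the well-mixed lake box model.
// Replicates R/kinetics.R::lake_derivatives() term by term; keep in step.
//
// State order:  pc, dc, iss, nh4, no3, ip
// par order:    mypc, deac, tetg, kn, kp, kmdm, chl_to_c, n_to_c, p_to_c,
//               i_k, v_settle_iss, v_settle_dc, nh4_pref, tet_miner
// opt order:    a_w, a_phi, a_iss, a_dc, b_w, b_phi, b_iss, b_dc, mu0
// inflow:       n x 5 matrix (nh4, no3, ip, iss, dc_in), concentrations mg/L
// dep_gday:     n x 3 matrix (nh4, no3, ip) dry deposition, g/day
// Forcing vectors are sampled at the left endpoint of each step.

// [[Rcpp::export]]
List sim_core(NumericVector y0,
              double dt_days,
              NumericVector t_water,
              NumericVector i_surf,
              NumericMatrix inflow,
              NumericVector q_in_m3d,
              NumericVector q_runoff_m3d,
              NumericVector runoff_conc,
              NumericMatrix dep_gday,
              NumericVector par,
              NumericVector opt,
              double volume,
              double depth,
              double rel_change_max = 0.5) {
  const int n = t_water.size();
  if (i_surf.size() != n || inflow.nrow() != n || q_in_m3d.size() != n ||
      q_runoff_m3d.size() != n || dep_gday.nrow() != n) {
    stop("forcing arrays must all have one row per step");
  }

  const double mypc = par[0], deac = par[1], tetg = par[2], kn = par[3],
               kp = par[4], kmdm = par[5], chl_to_c = par[6], n_to_c = par[7],
               p_to_c = par[8], ik = par[9], v_iss = par[10], v_dc = par[11],
               pref = par[12], tet_m = par[13];
  const double a_w = opt[0], a_phi = opt[1], a_iss = opt[2], a_dc = opt[3],
               b_w = opt[4], b_phi = opt[5], b_iss = opt[6], b_dc = opt[7],
               mu0 = opt[8];
  const double kirk = 0.425 * mu0 - 0.19;

  NumericMatrix out(n + 1, 6);
  double pc = y0[0], dc = y0[1], iss = y0[2], nh4 = y0[3], no3 = y0[4],
         ip = y0[5];
  long clipped = 0;

  for (int i = 0; i < n; ++i) {
    out(i, 0) = pc; out(i, 1) = dc; out(i, 2) = iss;
    out(i, 3) = nh4; out(i, 4) = no3; out(i, 5) = ip;

    const double chl = chl_to_c * pc;
    const double a = a_w + a_phi * chl + a_iss * iss + a_dc * dc;
    const double b = b_w + b_phi * chl + b_iss * iss + b_dc * dc;
    const double kd = a * std::sqrt(1.0 + kirk * b / a) / mu0;

    const double fT = std::pow(tetg, t_water[i] - 20.0);
    const double kdH = kd * depth;
    const double I = i_surf[i];
    double fI;
    if (I <= 0.0) {
      fI = 0.0;
    } else if (kdH > 1e-12) {
      fI = std::log((ik + I) / (ik + I * std::exp(-kdH))) / kdH;
    } else {
      fI = I / (ik + I);
    }

    const double din = nh4 + no3;
    const double fN = din > 0.0 ? din / (kn + din) : 0.0;
    const double fP = ip > 0.0 ? ip / (kp + ip) : 0.0;
    const double fnut = fN < fP ? fN : fP;

    const double growth = mypc * fT * fI * fnut * pc;
    const double death = deac * pc;
    const double miner = kmdm * std::pow(tet_m, t_water[i] - 20.0) * dc;

    const double Din = q_in_m3d[i] / volume;
    const double Dr = q_runoff_m3d[i] / volume;
    const double Dout = Din + Dr;
    const double fpref = din > 0.0 ? nh4 / (nh4 + pref) : 0.0;

    const double d0 = growth - death - Dout * pc;
    const double d1 = death - miner + Din * inflow(i, 4) - Dout * dc -
                      (v_dc / depth) * dc;
    const double d2 = Din * inflow(i, 3) - Dout * iss - (v_iss / depth) * iss;
    const double d3 = -growth * n_to_c * fpref + miner * n_to_c +
                      Din * inflow(i, 0) + Dr * runoff_conc[0] - Dout * nh4 +
                      dep_gday(i, 0) / volume;
    const double d4 = -growth * n_to_c * (1.0 - fpref) + Din * inflow(i, 1) +
                      Dr * runoff_conc[1] - Dout * no3 + dep_gday(i, 1) / volume;
    const double d5 = -growth * p_to_c + miner * p_to_c + Din * inflow(i, 2) +
                      Dr * runoff_conc[2] - Dout * ip + dep_gday(i, 2) / volume;

    const double y[6] = {pc, dc, iss, nh4, no3, ip};
    const double d[6] = {d0, d1, d2, d3, d4, d5};
    double ynew[6];
    for (int k = 0; k < 6; ++k) {
      const double step = d[k] * dt_days;
      if (y[k] > 1.0 && std::fabs(step) > rel_change_max * y[k]) {
        stop("unstable step at step %d: constituent %d changed by more than "
             "%.0f%% in one step; reduce dt", i + 1, k + 1,
             100.0 * rel_change_max);
      }
      ynew[k] = y[k] + step;
      if (ynew[k] < 0.0) { ynew[k] = 0.0; ++clipped; }
    }
    pc = ynew[0]; dc = ynew[1]; iss = ynew[2];
    nh4 = ynew[3]; no3 = ynew[4]; ip = ynew[5];
  }
  out(n, 0) = pc; out(n, 1) = dc; out(n, 2) = iss;
  out(n, 3) = nh4; out(n, 4) = no3; out(n, 5) = ip;

  return List::create(_["states"] = out, _["clipped"] = (double)clipped);
}
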