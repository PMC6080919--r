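// Core stochastic engine for the two-step congression simulation.
//
// All randomness comes from R's RNG (RNGScope), with a fixed draw order so
// a given seed reproduces a run bit-identically:
//   per step: (1) microtubules in index order -- one uniform per growing
//   filament (catastrophe), two uniforms per shrinking filament that hits
//   length 0 (renucleation direction); (2) free chromosomes in id order --
//   three standard normals each (Brownian displacement); (3) capture
//   attempts in chromosome id order, candidate microtubules in index order
//   -- one uniform per candidate.
//
// Units: lengths in um, time in seconds internally; rate parameters arrive
// in the per-minute units used throughout the package and are converted
// once.

#include <Rcpp.h>
using namespace Rcpp;

static inline double unit_dir(double u1, double u2, double *d) {
  double z = 2.0 * u1 - 1.0;
  double phi = 2.0 * M_PI * u2;
  double s = sqrt(std::max(0.0, 1.0 - z * z));
  d[0] = s * cos(phi);
  d[1] = s * sin(phi);
  d[2] = z;
  return z;
}

// piecewise-constant, right-continuous gate lookup
static inline double gate_at(double t_min, const NumericVector &gt,
                             const NumericVector &gf) {
  double g = 0.0;
  for (int i = 0; i < gt.size(); ++i) {
    if (t_min >= gt[i]) g = gf[i]; else break;
  }
  return g;
}

// [[Rcpp::export]]
List run_engine_cpp(NumericVector center, double nucleus_radius,
                    NumericMatrix centrosomes, NumericVector p_ap,
                    NumericMatrix chrom0, List par,
                    NumericVector gate_time, NumericVector gate_frac) {
  RNGScope scope;

  const double dt = as<double>(par["dt"]);             // s
  const double t_end = as<double>(par["t_end"]);       // min
  const double t_x = as<double>(par["t_x"]);           // min
  const double t_m = as<double>(par["t_m"]);           // min
  const double v_g = as<double>(par["mt_growth_speed"]) / 60.0;  // um/s
  const double v_s = as<double>(par["mt_shrink_speed"]) / 60.0;  // um/s
  const double k0 = as<double>(par["catastrophe_base"]) / 60.0;  // 1/s
  const double k1 = as<double>(par["catastrophe_slope"]) / 60.0; // 1/(s um)
  const int n_per = as<int>(par["n_mt_per_aster"]);
  const double rho_c = as<double>(par["capture_radius"]);
  const double k_on = as<double>(par["base_binding_rate"]);      // 1/s
  const double v_dyn = as<double>(par["transport_speed"]) / 60.0; // um/s
  const double arrival_radius = as<double>(par["arrival_radius"]);
  const double chrom_radius = as<double>(par["chromosome_radius"]);
  const int variant = as<int>(par["model_variant"]);
  const double D = as<double>(par["diffusion"]);       // um^2/s
  const int report_every = as<int>(par["report_every"]); // steps
  const bool stabilize = as<bool>(par["stabilize_on_capture"]);

  const int n_steps = (int)std::lround(t_end * 60.0 / dt);
  const int n_mt = 2 * n_per;
  const int n_chrom = chrom0.nrow();
  const double reach = rho_c + chrom_radius;
  const double sd_axis = sqrt(2.0 * D * dt);
  const double refl_radius = nucleus_radius - chrom_radius;

  // microtubule state
  std::vector<int> aster(n_mt);
  std::vector<double> dirx(n_mt), diry(n_mt), dirz(n_mt), len(n_mt, 0.0);
  std::vector<int> mstate(n_mt, 1); // 1 grow, -1 shrink, 0 paused
  std::vector<int> mt_attached(n_mt, -1);
  for (int i = 0; i < n_mt; ++i) {
    aster[i] = i < n_per ? 0 : 1;
    double d[3];
    unit_dir(unif_rand(), unif_rand(), d);
    dirx[i] = d[0]; diry[i] = d[1]; dirz[i] = d[2];
  }

  // chromosome state
  std::vector<double> cx(n_chrom), cy(n_chrom), cz(n_chrom);
  std::vector<int> cstate(n_chrom, 0); // 0 free, 1 captured, 2 arrived
  std::vector<double> cap_time(n_chrom, NA_REAL);
  std::vector<double> arr_time(n_chrom, NA_REAL);
  std::vector<int> att_mt(n_chrom, -1);
  std::vector<double> att_dist(n_chrom, 0.0);
  for (int c = 0; c < n_chrom; ++c) {
    cx[c] = chrom0(c, 0); cy[c] = chrom0(c, 1); cz[c] = chrom0(c, 2);
  }

  const int n_frames = n_steps / report_every + 1;
  NumericVector traj(n_frames * n_chrom * 3);
  IntegerMatrix states(n_frames, n_chrom);
  NumericVector frame_t(n_frames);
  int frame = 0;
  // frame 0
  for (int c = 0; c < n_chrom; ++c) {
    traj[frame + n_frames * (c + n_chrom * 0)] = cx[c];
    traj[frame + n_frames * (c + n_chrom * 1)] = cy[c];
    traj[frame + n_frames * (c + n_chrom * 2)] = cz[c];
    states(frame, c) = 0;
  }
  frame_t[0] = 0.0;
  frame = 1;

  for (int step = 1; step <= n_steps; ++step) {
    const double t0 = (step - 1) * dt;        // s, step entry
    const double t0_min = t0 / 60.0;
    const double t_min = step * dt / 60.0;    // min, step end

    // --- (1) microtubules ---
    for (int i = 0; i < n_mt; ++i) {
      if (mstate[i] == 1) {
        double u = unif_rand();
        double L = len[i] + v_g * dt;
        // boundary intersection along the direction
        double ox = centrosomes(aster[i], 0) - center[0];
        double oy = centrosomes(aster[i], 1) - center[1];
        double oz = centrosomes(aster[i], 2) - center[2];
        double b = ox * dirx[i] + oy * diry[i] + oz * dirz[i];
        double c0 = ox * ox + oy * oy + oz * oz -
                    nucleus_radius * nucleus_radius;
        double disc = b * b - c0;
        double lmax = -b + sqrt(disc > 0 ? disc : 0);
        bool hit = L >= lmax;
        if (hit) L = lmax;
        double p_cat = 1.0 - exp(-(k0 + k1 * L) * dt);
        len[i] = L;
        if (hit || u < p_cat) mstate[i] = -1;
      } else if (mstate[i] == -1) {
        double L = len[i] - v_s * dt;
        if (L <= 0) {
          if (mt_attached[i] >= 0) { // full depolymerization: release
            int c = mt_attached[i];
            cstate[c] = 0;
            att_mt[c] = -1;
            mt_attached[i] = -1;
          }
          double d[3];
          unit_dir(unif_rand(), unif_rand(), d);
          dirx[i] = d[0]; diry[i] = d[1]; dirz[i] = d[2];
          len[i] = 0.0;
          mstate[i] = 1;
        } else {
          len[i] = L;
          if (mt_attached[i] >= 0) { // tip slides the lateral attachment
            int c = mt_attached[i];
            if (att_dist[c] > L) att_dist[c] = L;
          }
        }
      }
      // paused (stabilized) filaments: frozen
    }

    // --- (2) free chromosomes: advection + Brownian, reflecting sphere ---
    for (int c = 0; c < n_chrom; ++c) {
      if (cstate[c] != 0) continue;
      double x = cx[c], y = cy[c], z = cz[c];
      if (variant >= 2 && t0_min <= t_m) {
        double f = dt / 60.0 / (t_x - t0_min);
        x += (p_ap[0] - x) * f;
        y += (p_ap[1] - y) * f;
        z += (p_ap[2] - z) * f;
      }
      x += sd_axis * norm_rand();
      y += sd_axis * norm_rand();
      z += sd_axis * norm_rand();
      double rx = x - center[0], ry = y - center[1], rz = z - center[2];
      double r = sqrt(rx * rx + ry * ry + rz * rz);
      if (r > refl_radius) {
        double s = (2.0 * refl_radius - r) / r;
        if (s < 0) s = 0;
        x = center[0] + rx * s;
        y = center[1] + ry * s;
        z = center[2] + rz * s;
      }
      cx[c] = x; cy[c] = y; cz[c] = z;
    }

    // --- (3) capture attempts ---
    double gate = (variant == 3) ? gate_at(t0_min, gate_time, gate_frac)
                                 : 1.0;
    if (gate > 0) {
      const double p_bind = 1.0 - exp(-k_on * gate * dt);
      for (int c = 0; c < n_chrom; ++c) {
        if (cstate[c] != 0) continue;
        bool captured = false;
        for (int a = 0; a < 2 && !captured; ++a) {
          double relx = cx[c] - centrosomes(a, 0);
          double rely = cy[c] - centrosomes(a, 1);
          double relz = cz[c] - centrosomes(a, 2);
          double R2 = relx * relx + rely * rely + relz * relz;
          double Rd = sqrt(R2);
          int lo = a * n_per, hi = lo + n_per;
          for (int i = lo; i < hi; ++i) {
            if (len[i] + reach < Rd) continue;    // tip cannot reach
            double tproj = relx * dirx[i] + rely * diry[i] + relz * dirz[i];
            double tc = tproj < 0 ? 0 : (tproj > len[i] ? len[i] : tproj);
            double ddx = relx - tc * dirx[i];
            double ddy = rely - tc * diry[i];
            double ddz = relz - tc * dirz[i];
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 > reach * reach) continue;
            double u = unif_rand();
            if (u < p_bind) {
              cstate[c] = 1;
              cap_time[c] = t_min;
              att_mt[c] = i;
              att_dist[c] = tc;
              cx[c] = centrosomes(a, 0) + tc * dirx[i];
              cy[c] = centrosomes(a, 1) + tc * diry[i];
              cz[c] = centrosomes(a, 2) + tc * dirz[i];
              if (stabilize) mstate[i] = 0;
              mt_attached[i] = c;
              captured = true;
              break;
            }
          }
        }
      }
    }

    // --- (4) poleward transport of captured chromosomes ---
    for (int c = 0; c < n_chrom; ++c) {
      if (cstate[c] != 1) continue;
      int i = att_mt[c];
      att_dist[c] -= v_dyn * dt;
      if (att_dist[c] < 0) att_dist[c] = 0;
      int a = aster[i];
      cx[c] = centrosomes(a, 0) + att_dist[c] * dirx[i];
      cy[c] = centrosomes(a, 1) + att_dist[c] * diry[i];
      cz[c] = centrosomes(a, 2) + att_dist[c] * dirz[i];
      if (att_dist[c] <= arrival_radius) {
        cstate[c] = 2;
        arr_time[c] = t_min;
        mt_attached[i] = -1;
        att_mt[c] = -1;
        if (stabilize) mstate[i] = -1; // released filament depolymerizes
      }
    }

    if (step % report_every == 0) {
      for (int c = 0; c < n_chrom; ++c) {
        traj[frame + n_frames * (c + n_chrom * 0)] = cx[c];
        traj[frame + n_frames * (c + n_chrom * 1)] = cy[c];
        traj[frame + n_frames * (c + n_chrom * 2)] = cz[c];
        states(frame, c) = cstate[c];
      }
      frame_t[frame] = step * dt;
      ++frame;
    }
  }

  traj.attr("dim") = IntegerVector::create(n_frames, n_chrom, 3);
  return List::create(
    _["traj"] = traj,
    _["frame_t"] = frame_t,
    _["states"] = states,
    _["capture_time"] = NumericVector(cap_time.begin(), cap_time.end()),
    _["arrival_time"] = NumericVector(arr_time.begin(), arr_time.end()),
    _["final_state"] = IntegerVector(cstate.begin(), cstate.end()),
    _["mt_length"] = NumericVector(len.begin(), len.end()),
    _["mt_state"] = IntegerVector(mstate.begin(), mstate.end()));
}
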