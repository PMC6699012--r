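#include <Rcpp.h>
using namespace Rcpp;

// Monthly-cycle cohort propagation.
//
// States: post-surgery within the complication-risk window (ps[1..W], a
// month-in-state tunnel; the long-term postoperative complication is an
// intra-state event overlay: one-time cost, event-month utility and event
// mortality, without interrupting the tunnel clock), post-surgery beyond
// the window (ps_rest, background risks only), post-NOM appendix in situ
// (pn), the single-cycle recurrence event tunnel (rec_ev), appendiceal
// cancer by month in state (ad[1..TUN], ca[1..TUN]) with chronic
// continuation (ad_chr, ca_chr) and remission (rem_ad, rem_ca) states that
// both retain the final-year excess mortality hazard for life - the
// remission series governs quality of life, not risk exit - and absorbing
// dead. In nonoperative-management arms the cancer-presentation hazard
// applies arm-wide (pn, ps, ps_rest): the tumor missed at index
// presentation is not eliminated by a later appendectomy for recurrence.
//
// Background mortality applies first in every transition; event mortality
// at event entry. One-time event costs are charged in full at the event
// cycle; state payoffs (background cost, utility, life-time) accumulate in
// trapezoid (half-cycle-corrected) form.

// [[Rcpp::export]]
List cohort_engine_cpp(int T, NumericVector q_bg, NumericVector bg_cost,
                       NumericVector u_base, NumericVector disc,
                       NumericVector h_rec, NumericVector h_can, List pars,
                       double entry_ps, double entry_pn, double entry_dead,
                       bool nom_arm, bool trace) {
  const double h_ltc = pars["h_ltc"], p_death_ltc = pars["p_death_ltc"];
  const double c_ltc = pars["c_ltc"], u_ltc = pars["u_ltc"];
  const int W = pars["ltc_window"];  // complication-risk window, months
  const double c_rec = pars["c_rec"], d_rec = pars["d_rec"],
               u_rec = pars["u_rec"];
  const double frac_carc = pars["frac_carc"];
  const double c_adeno = pars["c_adeno"], c_carc = pars["c_carc"];
  const NumericVector h_ad = pars["h_adeno"], h_ca = pars["h_carc"];
  const NumericVector rf_ad = pars["remfrac_adeno"],
      rf_ca = pars["remfrac_carc"];
  const double h_ad_chr = pars["h_adeno_chr"], h_ca_chr = pars["h_carc_chr"];
  const double r5_ad = pars["r5_adeno"], r5_ca = pars["r5_carc"];
  const double u_cancer = pars["u_cancer"];
  const int TUN = h_ad.size();

  double pn = entry_pn, dead = entry_dead;
  double ps_rest = 0.0, rec_ev = 0.0;
  double ad_chr = 0.0, ca_chr = 0.0, rem_ad = 0.0, rem_ca = 0.0;
  std::vector<double> ps(W + 1, 0.0), ad(TUN + 1, 0.0), ca(TUN + 1, 0.0);
  ps[1] = entry_ps;  // months 1..W since surgery; entry surgery at month 0

  NumericMatrix occ(trace ? T + 1 : 1, 8);
  NumericVector cyc_cost(trace ? T + 1 : 1), cyc_qalm(trace ? T + 1 : 1),
      cyc_ly(trace ? T + 1 : 1);

  double acc_cost = 0, acc_qalm = 0, acc_ly = 0;
  double acc_cost_u = 0, acc_qalm_u = 0, acc_ly_u = 0;

  double prev_cost, prev_qalm, prev_ly;
  {
    const double alive = entry_ps + pn;
    prev_cost = alive * bg_cost[0];
    prev_qalm = alive * u_base[0];
    prev_ly = alive;
    if (trace) {
      occ(0, 0) = entry_ps; occ(0, 1) = pn; occ(0, 7) = dead;
    }
  }

  for (int t = 1; t <= T; ++t) {
    const double q = q_bg[t], s1 = 1.0 - q;
    const double hc = nom_arm ? h_can[t] : 0.0;
    double dead_new = dead;
    double ev_cost = 0.0, ltc_surv = 0.0, can_in = 0.0;

    // post-surgery tunnel: background death, then (NOM arms) cancer
    // presentation, then the complication event overlay; survivors advance
    {
      double x = ps[W];
      dead_new += x * q;
      double a = x * s1;
      can_in += a * hc;
      a *= (1.0 - hc);
      const double fl = a * h_ltc;
      dead_new += fl * p_death_ltc;
      ev_cost += fl * c_ltc;
      ltc_surv += fl * (1.0 - p_death_ltc);
      const double ps_rest_in = a - fl * p_death_ltc;
      for (int m = W - 1; m >= 1; --m) {
        x = ps[m];
        dead_new += x * q;
        a = x * s1;
        can_in += a * hc;
        a *= (1.0 - hc);
        const double f = a * h_ltc;
        dead_new += f * p_death_ltc;
        ev_cost += f * c_ltc;
        ltc_surv += f * (1.0 - p_death_ltc);
        ps[m + 1] = a - f * p_death_ltc;
      }
      // beyond the window: background (and, NOM arms, cancer) risks only
      dead_new += ps_rest * q;
      double ar = ps_rest * s1;
      can_in += ar * hc;
      ps_rest = ar * (1.0 - hc) + ps_rest_in;
    }

    // recurrence-event tunnel empties into the start of the surgery tunnel
    dead_new += rec_ev * q;
    ps[1] = rec_ev * s1;

    // post-NOM: background death, cancer presentation, late recurrence
    {
      dead_new += pn * q;
      const double a = pn * s1;
      can_in += a * hc;
      const double rf = a * (1.0 - hc) * h_rec[t];
      pn = a * (1.0 - hc) - rf;
      ev_cost += rf * c_rec;
      dead_new += rf * d_rec;
      rec_ev = rf * (1.0 - d_rec);
    }

    const double ad_in = can_in * (1.0 - frac_carc);
    const double ca_in = can_in * frac_carc;
    ev_cost += ad_in * c_adeno + ca_in * c_carc;

    // cancer tunnels; year-5 survivors split into remission (baseline
    // quality of life) and chronic disease, both keeping the final hazard
    {
      double sv = ad[TUN] * s1 * (1.0 - h_ad[TUN - 1]);
      dead_new += ad[TUN] - sv;
      double rem_in = sv * r5_ad, chr_in = sv * (1.0 - r5_ad);
      for (int m = TUN - 1; m >= 1; --m) {
        sv = ad[m] * s1 * (1.0 - h_ad[m - 1]);
        dead_new += ad[m] - sv;
        ad[m + 1] = sv;
      }
      ad[1] = ad_in;
      sv = ad_chr * s1 * (1.0 - h_ad_chr);
      dead_new += ad_chr - sv;
      ad_chr = sv + chr_in;
      sv = rem_ad * s1 * (1.0 - h_ad_chr);
      dead_new += rem_ad - sv;
      rem_ad = sv + rem_in;
    }
    {
      double sv = ca[TUN] * s1 * (1.0 - h_ca[TUN - 1]);
      dead_new += ca[TUN] - sv;
      double rem_in = sv * r5_ca, chr_in = sv * (1.0 - r5_ca);
      for (int m = TUN - 1; m >= 1; --m) {
        sv = ca[m] * s1 * (1.0 - h_ca[m - 1]);
        dead_new += ca[m] - sv;
        ca[m + 1] = sv;
      }
      ca[1] = ca_in;
      sv = ca_chr * s1 * (1.0 - h_ca_chr);
      dead_new += ca_chr - sv;
      ca_chr = sv + chr_in;
      sv = rem_ca * s1 * (1.0 - h_ca_chr);
      dead_new += rem_ca - sv;
      rem_ca = sv + rem_in;
    }
    dead = dead_new;

    double ps_tot = ps_rest;
    for (int m = 1; m <= W; ++m) ps_tot += ps[m];
    double ad_tot = ad_chr, ca_tot = ca_chr;
    double ad_act_q = ad_chr, ca_act_q = ca_chr;  // mass at cancer utility
    for (int m = 1; m <= TUN; ++m) {
      ad_tot += ad[m]; ca_tot += ca[m];
      ad_act_q += ad[m] * (1.0 - rf_ad[m - 1]);
      ca_act_q += ca[m] * (1.0 - rf_ca[m - 1]);
    }
    const double cancer_tot = ad_tot + ca_tot + rem_ad + rem_ca;
    const double active_q = ad_act_q + ca_act_q;
    const double alive = ps_tot + pn + rec_ev + cancer_tot;

    if (std::abs(alive + dead - 1.0) > 1e-9) {
      stop("probability mass not conserved at cycle %d (total %.12f)", t,
           alive + dead);
    }

    const double pay_cost = alive * bg_cost[t];
    const double pay_qalm =
        (ps_tot - ltc_surv + pn + rem_ad + rem_ca) * u_base[t] +
        ltc_surv * u_ltc + rec_ev * u_rec + active_q * u_cancer +
        (ad_tot + ca_tot - active_q) * u_base[t];
    const double pay_ly = alive;

    const double cc = 0.5 * (prev_cost + pay_cost) + ev_cost;
    const double cq = 0.5 * (prev_qalm + pay_qalm);
    const double cl = 0.5 * (prev_ly + pay_ly);
    acc_cost += cc * disc[t]; acc_qalm += cq * disc[t]; acc_ly += cl * disc[t];
    acc_cost_u += cc; acc_qalm_u += cq; acc_ly_u += cl;

    if (trace) {
      occ(t, 0) = ps_tot; occ(t, 1) = pn; occ(t, 2) = rec_ev;
      occ(t, 3) = ltc_surv; occ(t, 4) = ad_tot; occ(t, 5) = ca_tot;
      occ(t, 6) = rem_ad + rem_ca; occ(t, 7) = dead;
      cyc_cost[t] = cc * disc[t]; cyc_qalm[t] = cq * disc[t];
      cyc_ly[t] = cl * disc[t];
    }

    prev_cost = pay_cost; prev_qalm = pay_qalm; prev_ly = pay_ly;
    if (dead > 1.0 - 1e-14) break;
  }

  List out = List::create(
      _["cost_disc"] = acc_cost, _["qalm_disc"] = acc_qalm,
      _["ly_disc"] = acc_ly, _["cost_undisc"] = acc_cost_u,
      _["qalm_undisc"] = acc_qalm_u, _["ly_undisc"] = acc_ly_u,
      _["final_dead"] = dead);
  if (trace) {
    out["occupancy"] = occ;
    out["cycle_cost"] = cyc_cost;
    out["cycle_qalm"] = cyc_qalm;
    out["cycle_ly"] = cyc_ly;
  }
  return out;
}

// Individual-level Monte Carlo simulation of the identical event structure
// and accounting conventions; its mean discounted cost / QALM / LY
// estimators are unbiased for the cohort engine's expectations, making it
// an independent validation oracle. Uses R's RNG so set.seed() governs
// reproducibility.

enum MsState { PS = 0, PN = 1, REC = 2, CAN = 4, CHR = 5, REMI = 6,
               GONE = 7 };

// [[Rcpp::export]]
List microsim_cpp(int n, int T, NumericVector q_bg, NumericVector bg_cost,
                  NumericVector u_base, NumericVector disc, NumericVector h_rec,
                  NumericVector h_can, List pars, NumericVector leaf_prob,
                  NumericVector leaf_cost, NumericVector leaf_util,
                  IntegerVector leaf_state, LogicalVector leaf_failure,
                  bool nom_arm, bool keep_patients) {
  const double h_ltc = pars["h_ltc"], p_death_ltc = pars["p_death_ltc"];
  const double c_ltc = pars["c_ltc"], u_ltc = pars["u_ltc"];
  const int W = pars["ltc_window"];
  const double frac_carc = pars["frac_carc"];
  const double c_adeno = pars["c_adeno"], c_carc = pars["c_carc"];
  const NumericVector h_ad = pars["h_adeno"], h_ca = pars["h_carc"];
  const NumericVector rf_ad = pars["remfrac_adeno"],
      rf_ca = pars["remfrac_carc"];
  const double h_ad_chr = pars["h_adeno_chr"], h_ca_chr = pars["h_carc_chr"];
  const double r5_ad = pars["r5_adeno"], r5_ca = pars["r5_carc"];
  const double u_cancer = pars["u_cancer"];
  const double p_c_rec = pars["p_c_rec"], p_stc = pars["p_stc"],
               p_pm = pars["p_pm"], p_mca = pars["p_mca"];
  const double c_er = pars["c_er"], c_appy = pars["c_appy"],
               c_drain = pars["c_drain"], c_stc = pars["c_stc"];
  const double u_interval = pars["u_interval"], u_recur = pars["u_recur"],
               u_comp = pars["u_comp"];
  const int TUN = h_ad.size();
  const int n_leaf = leaf_prob.size();

  std::vector<double> leaf_cum(n_leaf);
  double accp = 0.0;
  for (int i = 0; i < n_leaf; ++i) { accp += leaf_prob[i]; leaf_cum[i] = accp; }

  double sum_c = 0, sum_q = 0, sum_l = 0, ss_c = 0, ss_q = 0, ss_l = 0;
  long n_fail = 0;
  NumericMatrix patients(keep_patients ? n : 1, 4);

  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    const double u = unif_rand() * accp;
    int leaf = 0;
    while (leaf < n_leaf - 1 && u > leaf_cum[leaf]) ++leaf;
    double cost = leaf_cost[leaf], qalm = 0.0, ly = 0.0;
    int state = leaf_state[leaf];  // 0 = post-surgery, 1 = post-NOM, 7 dead
    if (leaf_failure[leaf]) ++n_fail;
    double prev_c = 0, prev_q = 0, prev_l = 0;
    if (state != GONE) {
      qalm = leaf_util[leaf];
      ly = 1.0;
      prev_c = bg_cost[0]; prev_q = u_base[0]; prev_l = 1.0;
    }
    int m_ps = (state == PS) ? 0 : -1;  // months since surgery
    int m_in = 0, ctype = 0;            // cancer tunnel month and type
    bool had_event = false;             // event utility this month
    double ev_util = 0.0;
    int death_month = -1;

    for (int t = 1; t <= T && state != GONE; ++t) {
      const double q = q_bg[t];
      const double hc = nom_arm ? h_can[t] : 0.0;
      double ev_cost = 0.0;
      had_event = false;

      switch (state) {
        case PS:
          if (unif_rand() < q) { state = GONE; break; }
          ++m_ps;
          if (hc > 0 && unif_rand() < hc) {
            if (unif_rand() < frac_carc) { ctype = 2; ev_cost += c_carc; }
            else { ctype = 1; ev_cost += c_adeno; }
            state = CAN; m_in = 1;
            break;
          }
          if (m_ps <= W && unif_rand() < h_ltc) {
            ev_cost += c_ltc;
            if (unif_rand() < p_death_ltc) state = GONE;
            else { had_event = true; ev_util = u_ltc; }
          }
          break;
        case REC:
          if (unif_rand() < q) state = GONE;
          else { state = PS; m_ps = 0; }
          break;
        case PN:
          if (unif_rand() < q) { state = GONE; break; }
          if (hc > 0 && unif_rand() < hc) {
            if (unif_rand() < frac_carc) { ctype = 2; ev_cost += c_carc; }
            else { ctype = 1; ev_cost += c_adeno; }
            state = CAN; m_in = 1;
            break;
          }
          if (unif_rand() < h_rec[t]) {
            if (unif_rand() < p_c_rec) {
              ev_cost += c_er + c_drain + c_appy;
              if (unif_rand() < p_mca) state = GONE;
              else { state = REC; ev_util = u_interval; }
            } else {
              ev_cost += c_er + c_appy;
              double uu = u_recur;
              if (unif_rand() < p_stc) { ev_cost += c_stc; uu = u_comp; }
              if (unif_rand() < p_pm) state = GONE;
              else { state = REC; ev_util = uu; }
            }
          }
          break;
        case CAN: {
          const double hz = (ctype == 1) ? h_ad[m_in - 1] : h_ca[m_in - 1];
          if (unif_rand() < q) state = GONE;
          else if (unif_rand() < hz) state = GONE;
          else if (m_in == TUN) {
            const double r5 = (ctype == 1) ? r5_ad : r5_ca;
            state = (unif_rand() < r5) ? REMI : CHR;
          } else ++m_in;
          break;
        }
        case CHR: case REMI: {
          const double hz = (ctype == 1) ? h_ad_chr : h_ca_chr;
          if (unif_rand() < q) state = GONE;
          else if (unif_rand() < hz) state = GONE;
          break;
        }
      }

      double pay_c = 0, pay_q = 0, pay_l = 0;
      if (state != GONE) {
        pay_c = bg_cost[t];
        pay_l = 1.0;
        switch (state) {
          case PS: pay_q = had_event ? u_ltc : u_base[t]; break;
          case PN: case REMI: pay_q = u_base[t]; break;
          case REC: pay_q = ev_util; break;
          case CAN: {
            const double rf = (ctype == 1) ? rf_ad[m_in - 1]
                                           : rf_ca[m_in - 1];
            pay_q = (unif_rand() < rf) ? u_base[t] : u_cancer;
            break;
          }
          case CHR: pay_q = u_cancer; break;
        }
      } else if (death_month < 0) {
        death_month = t;
      }
      cost += (0.5 * (prev_c + pay_c) + ev_cost) * disc[t];
      qalm += 0.5 * (prev_q + pay_q) * disc[t];
      ly += 0.5 * (prev_l + pay_l) * disc[t];
      prev_c = pay_c; prev_q = pay_q; prev_l = pay_l;
    }

    sum_c += cost; sum_q += qalm; sum_l += ly;
    ss_c += cost * cost; ss_q += qalm * qalm; ss_l += ly * ly;
    if (keep_patients) {
      patients(i, 0) = cost; patients(i, 1) = qalm / 12.0;
      patients(i, 2) = ly / 12.0; patients(i, 3) = death_month;
    }
  }

  const double nn = static_cast<double>(n);
  auto se = [nn](double s, double ss) {
    if (nn < 2) return NA_REAL;
    const double var = (ss - s * s / nn) / (nn - 1.0);
    return std::sqrt(std::max(var, 0.0) / nn);
  };
  List out = List::create(
      _["n"] = n, _["mean_cost"] = sum_c / nn,
      _["mean_qaly"] = sum_q / nn / 12.0, _["mean_ly"] = sum_l / nn / 12.0,
      _["se_cost"] = se(sum_c, ss_c), _["se_qaly"] = se(sum_q, ss_q) / 12.0,
      _["se_ly"] = se(sum_l, ss_l) / 12.0,
      _["acute_failure_fraction"] = static_cast<double>(n_fail) / nn);
  if (keep_patients) out["patients"] = patients;
  return out;
}
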