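// Millisecond-resolution simulation loop for the three-layer spiking network.
//
// Populations: 0 = source (Poisson generators, no dynamics), 1 = reservoir E,
// 2 = reservoir I, 3 = sink E (readout), 4 = sink I.  Eight projections, each
// a dense (pre x post) weight matrix plus a fixed boolean connectivity mask.
// Excitatory classes follow the anti-symmetric additive STDP rule, inhibitory
// classes the symmetric rule; both use nearest-neighbour pairing against each
// neuron's stored last spike time, applied in both directions every step.
// Spikes are delivered with a one-step synaptic delay.  All randomness comes
// from R's RNG so set.seed() at the R level makes runs bit-reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Proj {
  NumericMatrix W;   // pre x post, 0 off-mask
  IntegerMatrix M;   // 0/1 mask
  bool exc;          // excitatory class (E->E / E->I)
  bool all_to_all;   // E-STDP pairing scheme for this projection
  double Am;         // depression amplitude for this projection
  double gmax;
  int pre, post;     // population ids
};

inline double clip01(double w, double gmax) {
  if (w < 0.0) return 0.0;
  if (w > gmax) return gmax;
  return w;
}

} // namespace

// [[Rcpp::export]]
List engine_run(List Wl, List Ml, List state, List delays, NumericMatrix pat,
                IntegerVector segPat, IntegerVector segLen, List par,
                bool estdp_on, bool istdp_on, int diag_every, int record) {
  RNGScope scope;

  const double dt       = as<double>(par["dt"]);
  const double tau_m    = as<double>(par["tau_m"]);
  const double V_T      = as<double>(par["V_T"]);
  const double V_rest   = as<double>(par["V_rest"]);
  const double V_reset  = as<double>(par["V_reset"]);
  const double E_ex     = as<double>(par["E_ex"]);
  const double E_inh    = as<double>(par["E_inh"]);
  const double tau_AMPA = as<double>(par["tau_AMPA"]);
  const double tau_GABA = as<double>(par["tau_GABA"]);
  const double g_leak   = as<double>(par["g_leak"]);
  const double g_leak_g = as<double>(par["g_leak_gaba"]);
  const int    ref_steps= as<int>(par["ref_steps"]);
  const int    ref_steps_inh = as<int>(par["ref_steps_inh"]);
  const double bg_p     = as<double>(par["bg_p"]);      // sink-layer background
  const double bg_w     = as<double>(par["bg_w"]);
  const IntegerVector ata = as<IntegerVector>(par["estdp_all_to_all"]); // per projection
  const double A_plus   = as<double>(par["A_plus"]);
  const double A_minus  = as<double>(par["A_minus"]);
  const double A_minus_ro = as<double>(par["A_minus_readout"]);
  const double tau_plus = as<double>(par["tau_plus"]);
  const double tau_minus= as<double>(par["tau_minus"]);
  const double B_plus   = as<double>(par["B_plus"]);
  const double B_minus  = as<double>(par["B_minus"]);
  const double tau_i    = as<double>(par["tau_i"]);
  const double gE_max   = as<double>(par["gE_max"]);
  const double gI_max   = as<double>(par["gI_max"]);
  const double p_black  = as<double>(par["p_black"]);   // f_black * dt / 1000
  const double p_noise  = as<double>(par["p_noise"]);
  const double noise_fr = as<double>(par["noise_fraction"]);
  const bool exact_decay= as<bool>(par["exact_decay"]);

  if (p_black > 1.0 || p_noise > 1.0)
    stop("per-step spike probability f*dt exceeds 1; reduce rate or dt");

  const double decE = exact_decay ? std::exp(-dt / tau_AMPA) : (1.0 - dt / tau_AMPA);
  const double decI = exact_decay ? std::exp(-dt / tau_GABA) : (1.0 - dt / tau_GABA);

  // clone weights so the caller's network is untouched (R value semantics)
  const char *pn[8] = {"w12","w22ee","w22ei","w22ie","w22ii","w23","w33ei","w33ie"};
  //                    pre,post,exc
  const int ppre [8] = {0,1,1,2,2,1,3,4};
  const int ppost[8] = {1,1,2,1,2,3,4,3};
  const bool pexc[8] = {true,true,true,false,false,true,true,false};
  std::vector<Proj> proj;
  for (int k = 0; k < 8; ++k) {
    Proj p;
    p.W = clone(as<NumericMatrix>(Wl[pn[k]]));
    p.M = as<IntegerMatrix>(Ml[pn[k]]);
    p.exc = pexc[k]; p.gmax = pexc[k] ? gE_max : gI_max;
    p.pre = ppre[k]; p.post = ppost[k];
    p.all_to_all = ata[k] != 0;
    p.Am = (k == 2 || k == 5 || k == 6) ? A_minus_ro : A_minus;  // E->I and readout classes: potentiation-biased
    proj.push_back(p);
  }

  const int K   = pat.nrow();
  const int nE  = as<NumericVector>(state["V1"]).size();
  const int nI  = as<NumericVector>(state["V2"]).size();
  const int nME = as<NumericVector>(state["V3"]).size();
  const int nMI = as<NumericVector>(state["V4"]).size();
  const int nPop[5] = {K, nE, nI, nME, nMI};

  std::vector<std::vector<double> > V(5), gex(5), ginh(5), last(5);
  std::vector<std::vector<int> > refr(5);
  for (int pp = 1; pp <= 4; ++pp) refr[pp].assign(
    as<NumericVector>(state[std::string("V") + std::to_string(pp)]).size(), 0);
  for (int pp = 1; pp <= 4; ++pp) {
    char b[8];
    std::snprintf(b, 8, "V%d", pp);    V[pp]    = as<std::vector<double> >(state[b]);
    std::snprintf(b, 8, "gex%d", pp);  gex[pp]  = as<std::vector<double> >(state[b]);
    std::snprintf(b, 8, "ginh%d", pp); ginh[pp] = as<std::vector<double> >(state[b]);
  }
  for (int pp = 0; pp <= 4; ++pp) {
    char b[8];
    std::snprintf(b, 8, "last%d", pp);
    last[pp] = as<std::vector<double> >(state[b]);
  }
  double t = as<double>(state["t"]);   // ms, absolute

  // spike traces for all-to-all E-STDP pairing: x decays with tau_plus
  // (potentiation side, any neuron as presynaptic), y with tau_minus
  // (depression side, any neuron as postsynaptic)
  const double dec_xp = std::exp(-dt / tau_plus);
  const double dec_ym = std::exp(-dt / tau_minus);
  std::vector<std::vector<double> > trx(5), try_(5);
  for (int pp = 0; pp <= 4; ++pp) {
    trx[pp].assign(nPop[pp], 0.0);
    try_[pp].assign(nPop[pp], 0.0);
  }

  std::vector<std::vector<int> > cur(5), prev(5);

  // per-neuron axonal delays: spikes emitted at t are delivered at t + d_i
  std::vector<std::vector<int> > del(5);
  int D = 1;
  for (int pp = 0; pp <= 4; ++pp) {
    del[pp] = as<std::vector<int> >(delays[pp]);
    if ((int)del[pp].size() != nPop[pp]) stop("delay vector length mismatch");
    for (size_t i = 0; i < del[pp].size(); ++i) {
      if (del[pp][i] < 1) stop("delays must be >= 1 step");
      if (del[pp][i] + 1 > D) D = del[pp][i] + 1;
    }
  }
  std::vector<std::vector<std::vector<int> > > arr(5);   // arrival ring buffers
  for (int pp = 0; pp <= 4; ++pp) arr[pp].assign(D, std::vector<int>());
  int ring = 0;

  const int nseg = segPat.size();
  IntegerMatrix sink_counts(nME, nseg);
  IntegerVector resE_counts(nseg), resI_counts(nseg), seg_ms(nseg);

  // diagnostics accumulators (reservoir E population means)
  std::vector<double> dg_t, dg_iex, dg_iinh, dg_inet, dg_rate;
  double acc_iex = 0, acc_iinh = 0, acc_spk = 0;
  long   acc_n = 0;

  // optional spike record
  std::vector<int> rec_layer, rec_id;  std::vector<double> rec_t;

  std::vector<double> inc_ex[5], inc_in[5];
  for (int pp = 1; pp <= 4; ++pp) {
    inc_ex[pp].assign(nPop[pp], 0.0);
    inc_in[pp].assign(nPop[pp], 0.0);
  }

  std::vector<double> psrc(K, 0.0);    // per-step spike probability per source neuron

  for (int s = 0; s < nseg; ++s) {
    const int pidx = segPat[s] - 1;    // 1-based from R; 0 => blank stimulus
    const int len = segLen[s];
    seg_ms[s] = len;

    // source firing probabilities for this presentation; the 10%-of-white
    // noise subset is redrawn at every presentation
    for (int k = 0; k < K; ++k) {
      if (pidx >= 0 && pat(k, pidx) > 0.5) psrc[k] = p_black;
      else psrc[k] = (unif_rand() < noise_fr) ? p_noise : 0.0;
    }

    for (int step = 0; step < len; ++step) {
      t += dt;

      // 1. source spikes for this step (scheduled into the arrival buffers)
      cur[0].clear();
      for (int k = 0; k < K; ++k)
        if (psrc[k] > 0.0 && unif_rand() < psrc[k]) cur[0].push_back(k);

      // 2. synaptic delivery of last step's spikes (one-step delay)
      for (int pp = 1; pp <= 4; ++pp) {
        std::fill(inc_ex[pp].begin(), inc_ex[pp].end(), 0.0);
        std::fill(inc_in[pp].begin(), inc_in[pp].end(), 0.0);
      }
      for (size_t q = 0; q < proj.size(); ++q) {
        Proj &P = proj[q];
        const std::vector<int> &sp = arr[P.pre][ring];
        if (sp.empty()) continue;
        const int npost = P.W.ncol();
        std::vector<double> &tgt = P.exc ? inc_ex[P.post] : inc_in[P.post];
        const double *w = REAL(P.W);
        const int npre = P.W.nrow();
        for (size_t a = 0; a < sp.size(); ++a) {
          const int i = sp[a];
          for (int j = 0; j < npost; ++j) tgt[j] += w[i + (size_t)j * npre];
        }
      }

      // independent background afferents keep the network fluctuation-driven
      if (bg_p > 0.0) {
        for (int pp = 1; pp <= 4; ++pp)
          for (int i = 0; i < nPop[pp]; ++i)
            if (unif_rand() < bg_p) inc_ex[pp][i] += bg_w;
      }

      // 3. conductance decay + inputs, membrane Euler step, threshold/reset
      for (int pp = 1; pp <= 4; ++pp) {
        cur[pp].clear();
        const int n = nPop[pp];
        for (int i = 0; i < n; ++i) {
          double ge = gex[pp][i] * decE + inc_ex[pp][i];
          double gi = ginh[pp][i] * decI + inc_in[pp][i];
          double v = V[pp][i];
          const double geL = ge / g_leak, giL = gi / g_leak_g;
          if (pp == 1 && diag_every > 0) {
            acc_iex  += (E_ex  - v) * geL;
            acc_iinh += (E_inh - v) * giL;
            ++acc_n;
          }
          if (refr[pp][i] > 0) {
            --refr[pp][i];                 // absolute refractory: hold at reset
            v = V_reset;
          } else {
            const double v_old = v;
            v += dt / tau_m * ((V_rest - v) + (E_ex - v) * geL + (E_inh - v) * giL);
            if (!std::isfinite(v))
              stop("non-finite membrane potential at t=%f (population %d)", t, pp);
            if (v >= V_T || v_old >= V_T) {
              v = V_reset; cur[pp].push_back(i);
              refr[pp][i] = (pp == 2) ? ref_steps_inh : ref_steps;
            }
          }
          V[pp][i] = v; gex[pp][i] = ge; ginh[pp][i] = gi;
        }
      }

      resE_counts[s] += (int)cur[1].size();
      resI_counts[s] += (int)cur[2].size();
      for (size_t a = 0; a < cur[3].size(); ++a) ++sink_counts(cur[3][a], s);
      if (diag_every > 0) acc_spk += cur[1].size();

      // 4. STDP (nearest-neighbour pairing against stored last spike times,
      //    which still exclude this step's spikes)
      if (estdp_on || istdp_on) {
        for (size_t q = 0; q < proj.size(); ++q) {
          Proj &P = proj[q];
          if (P.exc ? !estdp_on : !istdp_on) continue;
          double *w = REAL(P.W);
          const int *m = INTEGER(P.M);
          const int npre = P.W.nrow(), npost = P.W.ncol();
          const std::vector<double> &lpre = last[P.pre];
          const std::vector<double> &lpost = last[P.post];
          const std::vector<double> &xpre = trx[P.pre];
          const std::vector<double> &ypost = try_[P.post];
          // postsynaptic spike: potentiation side
          for (size_t a = 0; a < cur[P.post].size(); ++a) {
            const int j = cur[P.post][a];
            const size_t off = (size_t)j * npre;
            for (int i = 0; i < npre; ++i) {
              if (!m[i + off]) continue;
              double dlt;
              if (P.exc) {
                dlt = P.all_to_all ? A_plus * xpre[i]
                                 : A_plus * std::exp((lpre[i] - t) / tau_plus);
              } else {
                const double dtp = lpre[i] - t;
                dlt = (-dtp <= tau_i) ? B_plus * std::exp(dtp / tau_i)
                                      : -B_minus * std::exp(dtp / tau_i);
              }
              w[i + off] = clip01(w[i + off] + dlt, P.gmax);
            }
          }
          // presynaptic spike: depression side
          for (size_t a = 0; a < cur[P.pre].size(); ++a) {
            const int i = cur[P.pre][a];
            for (int j = 0; j < npost; ++j) {
              const size_t off = (size_t)j * npre;
              if (!m[i + off]) continue;
              double dlt;
              if (P.exc) {
                dlt = P.all_to_all ? -P.Am * ypost[j]
                                 : -P.Am * std::exp(-(t - lpost[j]) / tau_minus);
              } else {
                const double dtp = t - lpost[j];
                dlt = (dtp <= tau_i) ? B_plus * std::exp(-dtp / tau_i)
                                     : -B_minus * std::exp(-dtp / tau_i);
              }
              w[i + off] = clip01(w[i + off] + dlt, P.gmax);
            }
          }
        }
      }

      // 5. commit this step's spikes (traces updated after STDP so that
      //    simultaneous pre/post spikes do not pair with each other)
      for (int pp = 0; pp <= 4; ++pp) {
        double *x = trx[pp].data(), *y = try_[pp].data();
        for (int i = 0; i < nPop[pp]; ++i) { x[i] *= dec_xp; y[i] *= dec_ym; }
        for (size_t a = 0; a < cur[pp].size(); ++a) {
          x[cur[pp][a]] += 1.0; y[cur[pp][a]] += 1.0;
        }
      }
      for (int pp = 0; pp <= 4; ++pp) {
        for (size_t a = 0; a < cur[pp].size(); ++a) last[pp][cur[pp][a]] = t;
        if (record == 2 || (record == 1 && pp >= 1)) {
          for (size_t a = 0; a < cur[pp].size(); ++a) {
            rec_layer.push_back(pp); rec_id.push_back(cur[pp][a] + 1);
            rec_t.push_back(t);
          }
        }
        for (size_t a = 0; a < cur[pp].size(); ++a) {
          const int i = cur[pp][a];
          arr[pp][(ring + del[pp][i]) % D].push_back(i);
        }
        prev[pp].swap(cur[pp]);
      }
      for (int pp = 0; pp <= 4; ++pp) arr[pp][ring].clear();
      ring = (ring + 1) % D;

      // 6. periodic diagnostics row
      if (diag_every > 0 && acc_n >= (long)diag_every * nE) {
        dg_t.push_back(t);
        dg_iex.push_back(acc_iex / acc_n);
        dg_iinh.push_back(acc_iinh / acc_n);
        dg_inet.push_back((acc_iex + acc_iinh) / acc_n);
        dg_rate.push_back(acc_spk / nE / (acc_n / (double)nE) * (1000.0 / dt));
        acc_iex = acc_iinh = acc_spk = 0; acc_n = 0;
      }
    }
  }

  List Wout;
  for (int k = 0; k < 8; ++k) Wout[pn[k]] = proj[k].W;

  List st;
  for (int pp = 1; pp <= 4; ++pp) {
    char b[8];
    std::snprintf(b, 8, "V%d", pp);    st[b] = wrap(V[pp]);
    std::snprintf(b, 8, "gex%d", pp);  st[b] = wrap(gex[pp]);
    std::snprintf(b, 8, "ginh%d", pp); st[b] = wrap(ginh[pp]);
  }
  for (int pp = 0; pp <= 4; ++pp) {
    char b[8];
    std::snprintf(b, 8, "last%d", pp); st[b] = wrap(last[pp]);
  }
  st["t"] = t;

  List diag = List::create(_["time_ms"] = wrap(dg_t), _["mean_Iex"] = wrap(dg_iex),
                           _["mean_Iinh"] = wrap(dg_iinh), _["mean_Inet"] = wrap(dg_inet),
                           _["mean_rate_hz"] = wrap(dg_rate));
  List spikes = List::create(_["layer"] = wrap(rec_layer), _["neuron_id"] = wrap(rec_id),
                             _["time_ms"] = wrap(rec_t));

  return List::create(_["W"] = Wout, _["state"] = st, _["sink_counts"] = sink_counts,
                      _["resE_counts"] = resE_counts, _["resI_counts"] = resI_counts,
                      _["seg_ms"] = seg_ms, _["diag"] = diag, _["spikes"] = spikes);
}
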