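#include <Rcpp.h>
using namespace Rcpp;

// Exact-event (Gillespie) SIR on an explicit network with two edge classes:
// household edges (rate beta_h) and community edges (rate beta_c); recovery
// at rate gamma.  Rates are piecewise-constant in time: `wstart`/`wend`
// delimit intervention windows during which the household and community
// rates are multiplied by `wmh`/`wmc`.  Waiting times that cross a window
// boundary are discarded at the boundary and redrawn (valid for
// piecewise-constant intensities by the memoryless property).
//
// Randomness comes from R's RNG stream (unif_rand), so set.seed() in R makes
// runs reproducible; draws are consumed in documented order: (1) waiting
// time, (2) event class, (3) source infective, (4) target neighbour.
//
// adj: concatenated adjacency; for node v, neighbours are
// adj[ptr[v]..ptr[v+1]-1] with edge class in cls (0 = household,
// 1 = community).  status: 0 = S, 1 = I, 2 = R.

// [[Rcpp::export]]
List gillespie_sir_cpp(IntegerVector ptr, IntegerVector adj, IntegerVector cls,
                       IntegerVector init_infected, double beta_h,
                       double beta_c, double gamma,
                       NumericVector wstart, NumericVector wend,
                       NumericVector wmh, NumericVector wmc,
                       double t_max, double bin_width) {
  const int n = ptr.size() - 1;
  std::vector<int> status(n, 0);
  std::vector<int> inf_list;              // currently infected nodes
  std::vector<int> inf_pos(n, -1);        // position in inf_list
  std::vector<int> ns_h(n, 0), ns_c(n, 0); // susceptible neighbours by class

  auto count_sus = [&](int v) {
    ns_h[v] = 0; ns_c[v] = 0;
    for (int e = ptr[v]; e < ptr[v + 1]; ++e)
      if (status[adj[e]] == 0) {
        if (cls[e] == 0) ++ns_h[v]; else ++ns_c[v];
      }
  };

  std::vector<double> ev_time; std::vector<int> ev_type, ev_node;
  auto infect = [&](int v, double t) {
    status[v] = 1;
    inf_pos[v] = inf_list.size();
    inf_list.push_back(v);
    count_sus(v);
    for (int e = ptr[v]; e < ptr[v + 1]; ++e) {
      int u = adj[e];
      if (status[u] == 1) { if (cls[e] == 0) --ns_h[u]; else --ns_c[u]; }
    }
    ev_time.push_back(t); ev_type.push_back(0); ev_node.push_back(v);
  };

  for (int i = 0; i < init_infected.size(); ++i)
    infect(init_infected[i], 0.0);

  double t = 0.0;
  const int nw = wstart.size();
  auto mults = [&](double tt, double &mh, double &mc, double &next_bd) {
    mh = 1.0; mc = 1.0; next_bd = t_max;
    for (int w = 0; w < nw; ++w) {
      if (tt >= wstart[w] && tt < wend[w]) { mh = wmh[w]; mc = wmc[w]; }
      if (wstart[w] > tt) next_bd = std::min(next_bd, wstart[w]);
      if (wend[w] > tt) next_bd = std::min(next_bd, wend[w]);
    }
  };

  while (!inf_list.empty() && t < t_max) {
    double mh, mc, next_bd;
    mults(t, mh, mc, next_bd);
    long tot_h = 0, tot_c = 0;
    for (int v : inf_list) { tot_h += ns_h[v]; tot_c += ns_c[v]; }
    double rh = beta_h * mh * tot_h, rc = beta_c * mc * tot_c;
    double rr = gamma * (double)inf_list.size();
    double R = rh + rc + rr;
    double dt = -std::log(unif_rand()) / R;
    if (t + dt > next_bd) { t = next_bd; continue; }
    t += dt;
    double u = unif_rand() * R;
    if (u < rr) {  // recovery
      int j = (int)(u / gamma);
      if (j >= (int)inf_list.size()) j = inf_list.size() - 1;
      int v = inf_list[j];
      status[v] = 2;
      int last = inf_list.back();
      inf_list[j] = last; inf_pos[last] = j;
      inf_list.pop_back(); inf_pos[v] = -1;
      ev_time.push_back(t); ev_type.push_back(1); ev_node.push_back(v);
    } else {     // transmission across a household or community edge
      int want_cls = (u < rr + rh) ? 0 : 1;
      double target = (want_cls == 0) ? (u - rr) / (beta_h * mh)
                                      : (u - rr - rh) / (beta_c * mc);
      int src = -1;
      double acc = 0.0;
      for (int v : inf_list) {
        acc += (want_cls == 0) ? ns_h[v] : ns_c[v];
        if (acc > target) { src = v; break; }
      }
      if (src < 0) src = inf_list.back();
      int cnt = (want_cls == 0) ? ns_h[src] : ns_c[src];
      int pick = (int)(unif_rand() * cnt);
      if (pick >= cnt) pick = cnt - 1;
      int tgt = -1, seen = 0;
      for (int e = ptr[src]; e < ptr[src + 1]; ++e) {
        int w = adj[e];
        if (cls[e] == want_cls && status[w] == 0) {
          if (seen == pick) { tgt = w; break; }
          ++seen;
        }
      }
      infect(tgt, t);
    }
  }

  // daily-binned trajectory
  int nb = (int)std::floor(t_max / bin_width) + 1;
  NumericVector bt(nb); IntegerVector bS(nb), bI(nb), bR(nb);
  {
    int cs = n, ci = 0, cr = 0;
    size_t ei = 0;
    for (int b = 0; b < nb; ++b) {
      double tb = b * bin_width;
      while (ei < ev_time.size() && ev_time[ei] <= tb) {
        if (ev_type[ei] == 0) { --cs; ++ci; } else { --ci; ++cr; }
        ++ei;
      }
      bt[b] = tb; bS[b] = cs; bI[b] = ci; bR[b] = cr;
    }
  }
  return List::create(
    _["events"] = DataFrame::create(
        _["time"] = ev_time, _["event_type"] = ev_type, _["node"] = ev_node),
    _["daily"] = DataFrame::create(
        _["time"] = bt, _["S"] = bS, _["I"] = bI, _["R"] = bR),
    _["final_size"] = (double)(std::count(status.begin(), status.end(), 2) +
                               std::count(status.begin(), status.end(), 1)));
}
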