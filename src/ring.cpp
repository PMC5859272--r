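#include <Rcpp.h>
using namespace Rcpp;

// Event-driven (Gillespie) dynamics on a ring of N stem-cell positions.
//
// Replacement events: every (cell, side) pair fires at rate lambda/2, so a
// crypt experiences N*lambda replacement events per day and each clone
// boundary is resolved at rate lambda.  At a boundary between an Apc-null
// cell and a non-null cell the winner is redrawn: the null cell's progeny
// takes the slot with probability `bias` regardless of which cell divided
// (this makes the contiguous-clone size walk step up with probability `bias`,
// matching the birth-death oracle).  Heterozygous-vs-wild-type boundaries use
// `het_bias` the same way; genotype ties resolve in favour of the divider.
//
// Border expulsion: each *position* listed in border_idx loses its occupant
// to the transit-amplifying zone at rate border_loss; the emptied slot is
// refilled by the progeny of a uniformly chosen centre cell (expelled cells
// do not re-enter the competition).

static inline int rint_below(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

static inline bool divider_wins(int ga, int gb, double bias, double het_bias) {
  if (ga == gb) return true;
  bool a_null = (ga == 2), b_null = (gb == 2);
  if (a_null != b_null) {
    bool null_wins = (unif_rand() < bias);
    return a_null ? null_wins : !null_wins;
  }
  bool a_het = (ga == 1);
  bool het_wins = (unif_rand() < het_bias);
  return a_het ? het_wins : !het_wins;
}

// [[Rcpp::export]]
List ring_gillespie_cpp(IntegerVector labels0, IntegerVector geno0,
                        IntegerVector border_idx0, IntegerVector centre_idx0,
                        double lambda, double bias, double het_bias,
                        double border_loss, NumericVector t_grid,
                        double t_start) {
  int N = labels0.size();
  std::vector<int> lab(labels0.begin(), labels0.end());
  std::vector<int> gen(geno0.begin(), geno0.end());
  std::vector<int> bidx(border_idx0.begin(), border_idx0.end()); // 0-based
  std::vector<int> cidx(centre_idx0.begin(), centre_idx0.end()); // 0-based
  int nb = bidx.size(), ncn = cidx.size();
  double R1 = N * lambda;
  double R2 = (border_loss > 0.0 && ncn > 0) ? nb * border_loss : 0.0;
  double Rtot = R1 + R2;
  int T = t_grid.size();
  IntegerMatrix labT(N, T), genT(N, T);
  double t = t_start;
  int g = 0;
  double events = 0;

  auto record_current = [&](int gi) {
    for (int i = 0; i < N; i++) { labT(i, gi) = lab[i]; genT(i, gi) = gen[i]; }
  };
  auto monoclonal = [&]() {
    for (int i = 1; i < N; i++)
      if (lab[i] != lab[0] || gen[i] != gen[0]) return false;
    return true;
  };

  long check = 0;
  while (g < T) {
    if (Rtot <= 0.0) { for (; g < T; g++) record_current(g); break; }
    if (((check++) & 63) == 0 && monoclonal()) {
      for (; g < T; g++) record_current(g);
      break;
    }
    double tnext = t + exp_rand() / Rtot;
    while (g < T && t_grid[g] < tnext) { record_current(g); g++; }
    if (g >= T) break;
    double u = unif_rand() * Rtot;
    if (u < R1) {
      int i = rint_below(N);
      int j = (unif_rand() < 0.5) ? (i + 1) % N : (i + N - 1) % N;
      if (divider_wins(gen[i], gen[j], bias, het_bias)) {
        lab[j] = lab[i]; gen[j] = gen[i];
      } else {
        lab[i] = lab[j]; gen[i] = gen[j];
      }
    } else {
      int k = bidx[rint_below(nb)];
      int j = cidx[rint_below(ncn)];
      lab[k] = lab[j]; gen[k] = gen[j];
    }
    events += 1;
    t = tnext;
  }
  return List::create(_["labels"] = labT, _["genotypes"] = genT,
                      _["events"] = events);
}

// Run until the focal clone (labels == focal_label) is lost or fixed over the
// whole ring, or until t_max.  outcome: 1 fixed, 0 lost, -1 censored.
// [[Rcpp::export]]
List ring_absorb_cpp(IntegerVector labels0, IntegerVector geno0,
                     IntegerVector border_idx0, IntegerVector centre_idx0,
                     double lambda, double bias, double het_bias,
                     double border_loss, int focal_label, double t_max) {
  int N = labels0.size();
  std::vector<int> lab(labels0.begin(), labels0.end());
  std::vector<int> gen(geno0.begin(), geno0.end());
  std::vector<int> bidx(border_idx0.begin(), border_idx0.end());
  std::vector<int> cidx(centre_idx0.begin(), centre_idx0.end());
  int nb = bidx.size(), ncn = cidx.size();
  double R1 = N * lambda;
  double R2 = (border_loss > 0.0 && ncn > 0) ? nb * border_loss : 0.0;
  double Rtot = R1 + R2;
  int cnt = 0;
  for (int i = 0; i < N; i++) if (lab[i] == focal_label) cnt++;
  double t = 0.0, events = 0;
  int outcome = (cnt == 0) ? 0 : (cnt == N ? 1 : -1);

  while (outcome == -1 && Rtot > 0.0) {
    t += exp_rand() / Rtot;
    if (t > t_max) { t = t_max; break; }
    double u = unif_rand() * Rtot;
    int winner, loser;
    if (u < R1) {
      int i = rint_below(N);
      int j = (unif_rand() < 0.5) ? (i + 1) % N : (i + N - 1) % N;
      if (divider_wins(gen[i], gen[j], bias, het_bias)) { winner = i; loser = j; }
      else { winner = j; loser = i; }
    } else {
      int k = bidx[rint_below(nb)];
      winner = cidx[rint_below(ncn)];
      loser = k;
    }
    bool was = (lab[loser] == focal_label);
    bool now = (lab[winner] == focal_label);
    lab[loser] = lab[winner]; gen[loser] = gen[winner];
    if (was && !now) cnt--;
    else if (!was && now) cnt++;
    events += 1;
    if (cnt == 0) outcome = 0;
    else if (cnt == N) outcome = 1;
  }
  return List::create(_["time"] = t, _["outcome"] = outcome,
                      _["events"] = events, _["size"] = cnt);
}
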