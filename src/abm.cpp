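// Daily step kernels of the bumblebee colony simulator. Entities (searching
// queens and colonies) are processed in a caller-supplied random order; all
// state vectors are modified in place, so R-level wrappers must duplicate
// before calling. Randomness goes through R's RNG, so runs are reproducible
// under set.seed().
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// entity states
static const int ST_DEAD = 0, ST_HIBERNATING = 1, ST_SEARCHING = 2,
                 ST_COLONY = 3;

// One foraging day. For each active entity, trips are allocated over
// patches with probability proportional to detection(distance) * stock;
// a trip's gross yield is capped by crop capacity, by what can be gathered
// at the patch's current nectar density within the trip's foraging time
// (slower on deep corollas and depleted patches), and by the stock left.
// Stocks are decremented by exactly the gross yield taken, so sugar is
// conserved. Returns an N x 2 matrix (gross, cost) per entity.
// [[Rcpp::export]]
NumericMatrix forage_day_cpp(NumericVector stock, NumericVector area,
                             NumericVector corolla, NumericMatrix det,
                             NumericMatrix dist, IntegerVector state,
                             NumericVector workers, IntegerVector order,
                             List cfg) {
  const int P = stock.size();
  const int N = state.size();
  const double crop = as<double>(cfg["crop_capacity_g"]);
  const double tpf = as<double>(cfg["trips_per_forager"]);
  const double qtrips = as<double>(cfg["queen_trips"]);
  const double gather_k = as<double>(cfg["gather_rate_coef"]);
  const double cor_scale = as<double>(cfg["corolla_scale_mm"]);
  const double speed = as<double>(cfg["flight_speed_m_min"]);
  const double fcost = as<double>(cfg["flight_cost_g_min"]);
  const double trip_min = as<double>(cfg["trip_minutes_max"]);

  NumericMatrix out(N, 2);
  std::vector<double> prob(P);
  std::vector<int> visits(P);
  RNGScope scope;

  for (int oi = 0; oi < order.size(); ++oi) {
    int e = order[oi] - 1;  // 1-based from R
    if (e < 0 || e >= N) stop("entity index out of range");
    int trips;
    if (state[e] == ST_SEARCHING) trips = (int)qtrips;
    else if (state[e] == ST_COLONY)
      trips = (int)std::ceil(std::max(workers[e], 1.0) * tpf);
    else continue;
    if (trips <= 0) continue;

    double wsum = 0.0;
    for (int i = 0; i < P; ++i) {
      double w = det(e, i) * stock[i];
      prob[i] = w > 0 ? w : 0.0;
      wsum += prob[i];
    }
    if (wsum <= 0.0) continue;  // nothing detectable: no trips made
    for (int i = 0; i < P; ++i) prob[i] /= wsum;
    rmultinom(trips, prob.data(), P, visits.data());

    double gross = 0.0, cost = 0.0;
    for (int i = 0; i < P; ++i) {
      int v = visits[i];
      if (v == 0) continue;
      double dens = area[i] > 0 ? stock[i] / area[i] : 0.0;
      double rate = gather_k * dens / (1.0 + corolla[i] / cor_scale);
      double per_trip = std::min(crop, rate * trip_min);
      double take = std::min((double)v * per_trip, stock[i]);
      double handle = rate > 0 ? (take / v) / rate : 0.0;
      double travel = 2.0 * dist(e, i) / speed;
      cost += v * fcost * (travel + handle);
      gross += take;
      stock[i] -= take;
      if (stock[i] < 0) stock[i] = 0;  // guard against roundoff
    }
    out(e, 0) = gross;
    out(e, 1) = cost;
  }
  return out;
}

// One colony-dynamics day, applied after foraging. Searching queens burn
// maintenance and found a colony once their store passes the founding
// threshold (or die when the store empties or the window closes). Colonies
// pay maintenance, mature brood, initiate new brood from surplus energy
// before the switch date and rear new queens after it, and die after a run
// of starvation days. Returns counters:
// c(founded, matured_workers, queens_produced, died).
// [[Rcpp::export]]
NumericVector colony_update_cpp(IntegerVector state, NumericVector energy,
                                NumericVector workers, NumericMatrix brood,
                                NumericVector newq, IntegerVector starv,
                                IntegerVector search_days,
                                NumericMatrix forage, int day, List cfg) {
  const int N = state.size();
  const int dev = brood.nrow();
  const double q_maint = as<double>(cfg["queen_maintenance_g"]);
  const double w_maint = as<double>(cfg["worker_maintenance_g"]);
  const double b_maint = as<double>(cfg["brood_maintenance_g"]);
  const double thresh = as<double>(cfg["founding_threshold_g"]);
  const int window = as<int>(cfg["founding_window_days"]);
  const double brood_cost = as<double>(cfg["brood_cost_g"]);
  const double invest = as<double>(cfg["brood_invest_frac"]);
  const double max_eggs = as<double>(cfg["max_eggs_per_day"]);
  const double max_workers = as<double>(cfg["max_workers"]);
  const int starv_max = as<int>(cfg["starvation_days"]);
  const int switch_day = as<int>(cfg["queen_switch_day"]);
  const double queen_cost = as<double>(cfg["queen_cost_g"]);
  const double qinvest = as<double>(cfg["queen_invest_frac"]);
  const double max_queens = as<double>(cfg["max_queens_per_day"]);

  double founded = 0, matured = 0, queens_prod = 0, died = 0;

  for (int e = 0; e < N; ++e) {
    double net = forage(e, 0) - forage(e, 1);
    if (state[e] == ST_SEARCHING) {
      energy[e] += net - q_maint;
      search_days[e] += 1;
      if (energy[e] >= thresh) {
        state[e] = ST_COLONY;
        workers[e] = 0;
        starv[e] = 0;
        founded += 1;
      } else if (energy[e] <= 0 || search_days[e] > window) {
        state[e] = ST_DEAD;
        energy[e] = 0;
        died += 1;
      }
    } else if (state[e] == ST_COLONY) {
      double broodsum = 0;
      for (int a = 0; a < dev; ++a) broodsum += brood(a, e);
      double maint = q_maint + workers[e] * w_maint + broodsum * b_maint;
      energy[e] += net - maint;
      if (energy[e] < 0) {
        energy[e] = 0;
        starv[e] += 1;
        if (starv[e] > starv_max) {
          state[e] = ST_DEAD;
          workers[e] = 0;
          for (int a = 0; a < dev; ++a) brood(a, e) = 0;
          died += 1;
        }
        continue;
      }
      starv[e] = 0;
      // brood matures into workers
      double m = brood(0, e);
      if (m > 0) {
        double room = max_workers - workers[e];
        double add = std::min(m, room);
        workers[e] += add;
        matured += add;
      }
      for (int a = 0; a + 1 < dev; ++a) brood(a, e) = brood(a + 1, e);
      brood(dev - 1, e) = 0;
      broodsum -= m;
      if (day < switch_day) {
        double cap = std::min(max_eggs,
                              max_workers - workers[e] - broodsum);
        double n = std::floor(std::min(energy[e] * invest / brood_cost, cap));
        if (n > 0) {
          energy[e] -= n * brood_cost;
          brood(dev - 1, e) += n;
        }
      } else {
        double nq = std::floor(std::min(energy[e] * qinvest / queen_cost,
                                        max_queens));
        if (nq > 0) {
          energy[e] -= nq * queen_cost;
          newq[e] += nq;
          queens_prod += nq;
        }
      }
    }
  }
  return NumericVector::create(founded, matured, queens_prod, died);
}
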