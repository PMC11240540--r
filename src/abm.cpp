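#include <Rcpp.h>
using namespace Rcpp;

// Lattice state codes shared with R (see STATE in the package).
static const int ST_EMPTY = 0;
static const int ST_TUMOR = 1;

// One simulation phase of the on-lattice tumor/stroma model.
//
// Asynchronous update: each step visits the cells alive at the start of the
// step in a fresh uniform random order.  Per visit the cell draws
// independent Bernoulli events:
//   - division with probability p_div (niche-dependent): a daughter is
//     placed on a uniformly chosen empty neighbour; skipped if none empty;
//   - death with probability p_die (drawn whether or not the cell divided,
//     so a cell can divide and die within the same 24 h step);
//   - migration with probability p_move, only if the cell neither divided
//     nor died, to a uniformly chosen empty neighbour.
// Stroma and excluded sites never change.  Daughters act from the next
// step.  Uses R's RNG, so results are reproducible under set.seed().
//
// state: integer matrix of lattice codes (copied, not modified in place)
// niche: logical vector, column-major, same length as state
// [[Rcpp::export]]
List abm_phase_cpp(IntegerMatrix state_, LogicalVector niche,
                   double p_div_out, double p_div_niche,
                   double p_die, double p_move,
                   int steps, bool moore) {
  IntegerMatrix state = clone(state_);
  const int nr = state.nrow(), nc = state.ncol(), n_sites = nr * nc;
  if ((int)niche.size() != n_sites)
    stop("niche map and grid dimensions disagree");

  std::vector<int> cells;
  cells.reserve(n_sites / 2);
  for (int k = 0; k < n_sites; ++k)
    if (state[k] == ST_TUMOR) cells.push_back(k);

  IntegerVector n_out(steps), div_out(steps), die_out(steps), mov_out(steps);
  const int ndirs = moore ? 8 : 4;
  const int drow[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dcol[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  std::vector<int> empties;
  empties.reserve(8);
  std::vector<int> next;

  for (int s = 0; s < steps; ++s) {
    const int ncell = (int)cells.size();
    // Fisher-Yates shuffle of the update order
    for (int i = ncell - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(cells[i], cells[j]);
    }
    next.clear();
    next.reserve(ncell + ncell / 4 + 8);
    int ndiv = 0, ndie = 0, nmov = 0;
    for (int i = 0; i < ncell; ++i) {
      int idx = cells[i];
      const int r = idx % nr, c = idx / nr;
      const double pd = niche[idx] ? p_div_niche : p_div_out;
      bool divided = false;
      if (pd > 0 && unif_rand() < pd) {
        empties.clear();
        for (int d = 0; d < ndirs; ++d) {
          const int rr = r + drow[d], cc = c + dcol[d];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          const int nidx = rr + cc * nr;
          if (state[nidx] == ST_EMPTY) empties.push_back(nidx);
        }
        if (!empties.empty()) {
          int pick = (int)(unif_rand() * empties.size());
          if (pick >= (int)empties.size()) pick = (int)empties.size() - 1;
          state[empties[pick]] = ST_TUMOR;
          next.push_back(empties[pick]);
          divided = true;
          ++ndiv;
        }
      }
      if (p_die > 0 && unif_rand() < p_die) {
        state[idx] = ST_EMPTY;
        ++ndie;
        continue;
      }
      if (!divided && p_move > 0 && unif_rand() < p_move) {
        empties.clear();
        for (int d = 0; d < ndirs; ++d) {
          const int rr = r + drow[d], cc = c + dcol[d];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          const int nidx = rr + cc * nr;
          if (state[nidx] == ST_EMPTY) empties.push_back(nidx);
        }
        if (!empties.empty()) {
          int pick = (int)(unif_rand() * empties.size());
          if (pick >= (int)empties.size()) pick = (int)empties.size() - 1;
          state[idx] = ST_EMPTY;
          state[empties[pick]] = ST_TUMOR;
          idx = empties[pick];
          ++nmov;
        }
      }
      next.push_back(idx);
    }
    cells.swap(next);
    n_out[s] = (int)cells.size();
    div_out[s] = ndiv;
    die_out[s] = ndie;
    mov_out[s] = nmov;
  }
  return List::create(_["state"] = state, _["n"] = n_out,
                      _["divisions"] = div_out, _["deaths"] = die_out,
                      _["moves"] = mov_out);
}
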