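// Nearest-neighbour minimum-free-energy folding of a single RNA strand.
//
// Reduced model: stacking energies for adjacent base pairs, loop-size
// penalties for hairpin / bulge / internal loops, affine multibranch-loop
// cost (offset + per-branch + per-unpaired), no dangling ends, no coaxial
// stacking, pseudoknots excluded, minimum hairpin loop of 3 nt. Energies are
// integer tenths of kcal/mol so the DP, the traceback re-scorer and the
// enumeration oracle agree exactly.
//
// Recursions are the textbook Zuker scheme: V(i,j) = best structure closed
// by pair (i,j); WM(i,j) = best multiloop segment with >= 1 branch;
// W(j) = best external-loop prefix. Interior loops are capped at 30
// unpaired nt (the usual search restriction; penalties beyond the cap are
// still defined for scoring).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>

using namespace Rcpp;

static const int INF = INT_MAX / 4;
static const int MINLOOP = 3;
static const int MAXILOOP = 30;

// Pair codes: AU=0, UA=1, GC=2, CG=3, GU=4, UG=5, -1 = not pairable.
static int pair_code(char a, char b) {
  if (a == 'A' && b == 'U') return 0;
  if (a == 'U' && b == 'A') return 1;
  if (a == 'G' && b == 'C') return 2;
  if (a == 'C' && b == 'G') return 3;
  if (a == 'G' && b == 'U') return 4;
  if (a == 'U' && b == 'G') return 5;
  return -1;
}

struct FoldParams {
  std::vector<int> stack;    // 6x6, row-major: stack[p1 * 6 + p2]
  std::vector<int> hairpin;  // indexed by loop size (0..n)
  std::vector<int> bulge;
  std::vector<int> internal_;
  int ml_offset, ml_branch, ml_unpaired;
};

struct FoldState {
  int n;
  std::string seq;
  std::vector<int> V, WM;
  std::vector<int> W;
  const FoldParams* par;
  int at(const std::vector<int>& m, int i, int j) const { return m[i * n + j]; }
};

static int interior_penalty(const FoldParams& par, int l1, int l2) {
  int sz = l1 + l2;
  if (l1 == 0 || l2 == 0) return par.bulge[sz];
  return par.internal_[sz];
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string seq,
                  IntegerVector stack6x6,
                  IntegerVector hairpin_pen,
                  IntegerVector bulge_pen,
                  IntegerVector internal_pen,
                  int ml_offset, int ml_branch, int ml_unpaired) {
  int n = seq.size();
  FoldParams par;
  par.stack.assign(stack6x6.begin(), stack6x6.end());
  par.hairpin.assign(hairpin_pen.begin(), hairpin_pen.end());
  par.bulge.assign(bulge_pen.begin(), bulge_pen.end());
  par.internal_.assign(internal_pen.begin(), internal_pen.end());
  par.ml_offset = ml_offset;
  par.ml_branch = ml_branch;
  par.ml_unpaired = ml_unpaired;

  std::vector<int> pc(n * n, -1);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      pc[i * n + j] = pair_code(seq[i], seq[j]);

  std::vector<int> V(n * n, INF), WM(n * n, INF);

  for (int span = MINLOOP + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // --- V(i,j)
      if (pc[i * n + j] >= 0) {
        int best = par.hairpin[j - i - 1];
        // stack
        if (j - i - 2 > MINLOOP && pc[(i + 1) * n + (j - 1)] >= 0 &&
            V[(i + 1) * n + (j - 1)] < INF) {
          int e = par.stack[pc[i * n + j] * 6 + pc[(i + 1) * n + (j - 1)]] +
                  V[(i + 1) * n + (j - 1)];
          if (e < best) best = e;
        }
        // bulge / internal loops (total unpaired 1..MAXILOOP)
        for (int k = i + 1; k <= std::min(i + 1 + MAXILOOP, j - 2); ++k) {
          int l1 = k - i - 1;
          int lmin = std::max(k + MINLOOP + 1, j - 1 - (MAXILOOP - l1));
          for (int l = j - 1; l >= lmin; --l) {
            int l2 = j - l - 1;
            if (l1 + l2 < 1) continue;
            if (V[k * n + l] >= INF) continue;
            int e = interior_penalty(par, l1, l2) + V[k * n + l];
            if (e < best) best = e;
          }
        }
        // multibranch loop
        for (int m = i + 1; m < j - 1; ++m) {
          if (WM[(i + 1) * n + m] < INF && WM[(m + 1) * n + (j - 1)] < INF) {
            int e = par.ml_offset + par.ml_branch +
                    WM[(i + 1) * n + m] + WM[(m + 1) * n + (j - 1)];
            if (e < best) best = e;
          }
        }
        V[i * n + j] = best;
      }
      // --- WM(i,j)
      int best = INF;
      if (V[i * n + j] < INF) best = V[i * n + j] + par.ml_branch;
      if (WM[(i + 1) * n + j] < INF)
        best = std::min(best, WM[(i + 1) * n + j] + par.ml_unpaired);
      if (WM[i * n + (j - 1)] < INF)
        best = std::min(best, WM[i * n + (j - 1)] + par.ml_unpaired);
      for (int k = i + 1; k <= j; ++k) {
        if (WM[i * n + (k - 1)] < INF && WM[k * n + j] < INF)
          best = std::min(best, WM[i * n + (k - 1)] + WM[k * n + j]);
      }
      WM[i * n + j] = best;
    }
  }

  // external loop
  std::vector<int> W(n + 1, 0);  // W[j+1] = best for prefix [0..j]
  for (int j = 0; j < n; ++j) {
    int best = W[j];  // j unpaired
    for (int k = 0; k + MINLOOP + 1 <= j; ++k) {
      if (V[k * n + j] < INF) best = std::min(best, W[k] + V[k * n + j]);
    }
    W[j + 1] = best;
  }
  int mfe = W[n];

  // ---- traceback (deterministic preference: unpaired first in W,
  //      hairpin > stack > interior > multiloop in V)
  std::string db(n, '.');
  std::vector<std::pair<std::pair<int,int>, int> > todo; // ((i,j), state)
  // state 0 = external suffix handled iteratively below, 1 = V, 2 = WM
  {
    int j = n - 1;
    while (j >= 0) {
      if (W[j + 1] == W[j]) { --j; continue; }
      bool found = false;
      for (int k = 0; k + MINLOOP + 1 <= j && !found; ++k) {
        if (V[k * n + j] < INF && W[k] + V[k * n + j] == W[j + 1]) {
          todo.push_back(std::make_pair(std::make_pair(k, j), 1));
          j = k - 1;
          found = true;
        }
      }
      if (!found) --j; // defensive; should not happen
    }
  }
  while (!todo.empty()) {
    int i = todo.back().first.first;
    int j = todo.back().first.second;
    int state = todo.back().second;
    todo.pop_back();
    if (state == 1) {
      db[i] = '('; db[j] = ')';
      int target = V[i * n + j];
      if (target == par.hairpin[j - i - 1]) continue;
      bool done = false;
      if (j - i - 2 > MINLOOP && pc[(i + 1) * n + (j - 1)] >= 0 &&
          V[(i + 1) * n + (j - 1)] < INF &&
          par.stack[pc[i * n + j] * 6 + pc[(i + 1) * n + (j - 1)]] +
            V[(i + 1) * n + (j - 1)] == target) {
        todo.push_back(std::make_pair(std::make_pair(i + 1, j - 1), 1));
        done = true;
      }
      for (int k = i + 1; !done && k <= std::min(i + 1 + MAXILOOP, j - 2); ++k) {
        int l1 = k - i - 1;
        int lmin = std::max(k + MINLOOP + 1, j - 1 - (MAXILOOP - l1));
        for (int l = j - 1; !done && l >= lmin; --l) {
          int l2 = j - l - 1;
          if (l1 + l2 < 1 || V[k * n + l] >= INF) continue;
          if (interior_penalty(par, l1, l2) + V[k * n + l] == target) {
            todo.push_back(std::make_pair(std::make_pair(k, l), 1));
            done = true;
          }
        }
      }
      for (int m = i + 1; !done && m < j - 1; ++m) {
        if (WM[(i + 1) * n + m] < INF && WM[(m + 1) * n + (j - 1)] < INF &&
            par.ml_offset + par.ml_branch + WM[(i + 1) * n + m] +
              WM[(m + 1) * n + (j - 1)] == target) {
          todo.push_back(std::make_pair(std::make_pair(i + 1, m), 2));
          todo.push_back(std::make_pair(std::make_pair(m + 1, j - 1), 2));
          done = true;
        }
      }
    } else { // WM
      int target = WM[i * n + j];
      if (i + 1 <= j && WM[(i + 1) * n + j] < INF &&
          WM[(i + 1) * n + j] + par.ml_unpaired == target) {
        todo.push_back(std::make_pair(std::make_pair(i + 1, j), 2));
        continue;
      }
      if (i <= j - 1 && WM[i * n + (j - 1)] < INF &&
          WM[i * n + (j - 1)] + par.ml_unpaired == target) {
        todo.push_back(std::make_pair(std::make_pair(i, j - 1), 2));
        continue;
      }
      if (V[i * n + j] < INF && V[i * n + j] + par.ml_branch == target) {
        todo.push_back(std::make_pair(std::make_pair(i, j), 1));
        continue;
      }
      for (int k = i + 1; k <= j; ++k) {
        if (WM[i * n + (k - 1)] < INF && WM[k * n + j] < INF &&
            WM[i * n + (k - 1)] + WM[k * n + j] == target) {
          todo.push_back(std::make_pair(std::make_pair(i, k - 1), 2));
          todo.push_back(std::make_pair(std::make_pair(k, j), 2));
          break;
        }
      }
    }
  }

  return List::create(_["mfe_tenths"] = mfe, _["dot_bracket"] = db);
}
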