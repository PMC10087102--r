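// Duplex alignment core: position-weighted, wobble-aware local alignment of a
// short guide RNA against a target window, antiparallel orientation.
//
// The DP works on the reversed guide so that both strands advance 5'->3' in
// index space; reported guide positions are 1-based from the guide 5' end,
// target positions 1-based on the window. Gaps are modelled as bounded jumps
// between aligned columns (guide-side bulges up to max_guide_bulge nt,
// target-side loops up to max_target_loop nt); a jump of k unpaired
// nucleotides costs gap_open + gap_extend * (k - 1).

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

namespace {

const int PAIR_NONE = 0, PAIR_WC = 1, PAIR_WOBBLE = 2;

int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'U': return 3; case 'T': return 3;
    default: return -1;
  }
}

int pair_type(int g, int t) {
  if (g < 0 || t < 0) return PAIR_NONE;
  if ((g == 0 && t == 3) || (g == 3 && t == 0) ||
      (g == 1 && t == 2) || (g == 2 && t == 1)) return PAIR_WC;
  if ((g == 2 && t == 3) || (g == 3 && t == 2)) return PAIR_WOBBLE;
  return PAIR_NONE;
}

struct Params {
  double match_score, wobble_score, mismatch_penalty;
  double gap_open, gap_extend, seed_scale;
  int seed_lo, seed_hi, max_target_loop, max_guide_bulge;
};

Params read_params(const List& p) {
  Params q;
  q.match_score = as<double>(p["match_score"]);
  q.wobble_score = as<double>(p["wobble_score"]);
  q.mismatch_penalty = as<double>(p["mismatch_penalty"]);
  q.gap_open = as<double>(p["gap_open"]);
  q.gap_extend = as<double>(p["gap_extend"]);
  q.seed_scale = as<double>(p["seed_scale"]);
  IntegerVector sr = p["seed_range"];
  q.seed_lo = sr[0]; q.seed_hi = sr[1];
  q.max_target_loop = as<int>(p["max_target_loop"]);
  q.max_guide_bulge = as<int>(p["max_guide_bulge"]);
  return q;
}

// Score and pair type of aligning guide position gp (1-based, 5'->3')
// against target base t. Guide position 1 never pairs.
void column_score(int gp, int gbase, int tbase, const Params& q,
                  double& sc, int& type) {
  type = (gp == 1) ? PAIR_NONE : pair_type(gbase, tbase);
  switch (type) {
    case PAIR_WC: sc = q.match_score; break;
    case PAIR_WOBBLE: sc = q.wobble_score; break;
    default: sc = q.mismatch_penalty; break;
  }
  if (gp >= q.seed_lo && gp <= q.seed_hi) sc *= q.seed_scale;
}

double gap_cost(int k, const Params& q) {
  return q.gap_open + q.gap_extend * (k - 1);
}

std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

} // namespace

// Best local duplex alignment of `guide` (RNA, 5'->3') against `target`
// (RNA, 5'->3'). Returns R_NilValue when no column chain scores > 0.
// [[Rcpp::export(name = ".align_core")]]
SEXP align_core(std::string guide, std::string target, List params) {
  const Params q = read_params(params);
  const std::vector<int> g = encode(guide), t = encode(target);
  const int m = (int)g.size(), n = (int)t.size();
  if (m == 0 || n == 0) return R_NilValue;

  // S[i][j]: best alignment score ending with column (guide idx i, target j),
  // indices over the reversed guide (i = 1 is the guide 3' end).
  std::vector<std::vector<double> > S(m + 1, std::vector<double>(n + 1, 0.0));
  std::vector<std::vector<int> > bpi(m + 1, std::vector<int>(n + 1, 0)),
      bpj(m + 1, std::vector<int>(n + 1, 0));
  double best = 0.0; int bi = 0, bj = 0;

  for (int i = 1; i <= m; ++i) {
    const int gp = m - i + 1;                 // guide position, 1-based 5'->3'
    for (int j = 1; j <= n; ++j) {
      double sub; int type;
      column_score(gp, g[m - i], t[j - 1], q, sub, type);
      // Ties between predecessors resolve towards the later-examined
      // candidate (largest target-side jump), which anchors pairs at their
      // 5'-most target coordinate and keeps planted loops in register.
      double prev = 0.0; int pi = 0, pj = 0;
      if (S[i - 1][j - 1] > prev) { prev = S[i - 1][j - 1]; pi = i - 1; pj = j - 1; }
      for (int a = 1; a <= q.max_guide_bulge; ++a) {       // unpaired guide nts
        if (i - 1 - a < 0) break;
        double cand = S[i - 1 - a][j - 1] + gap_cost(a, q);
        if (cand > prev || (cand == prev && prev > 0.0)) {
          prev = cand; pi = i - 1 - a; pj = j - 1;
        }
      }
      for (int b = 1; b <= q.max_target_loop; ++b) {       // unpaired target nts
        if (j - 1 - b < 0) break;
        double cand = S[i - 1][j - 1 - b] + gap_cost(b, q);
        if (cand > prev || (cand == prev && prev > 0.0)) {
          prev = cand; pi = i - 1; pj = j - 1 - b;
        }
      }
      S[i][j] = prev + sub;
      bpi[i][j] = pi; bpj[i][j] = pj;
      if (S[i][j] > best) { best = S[i][j]; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) return R_NilValue;

  std::vector<int> gpos, tpos, ptype;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    const int gp = m - i + 1;
    double sub; int type;
    column_score(gp, g[m - i], t[j - 1], q, sub, type);
    gpos.push_back(gp); tpos.push_back(j); ptype.push_back(type);
    const int ni = bpi[i][j], nj = bpj[i][j];
    if (ni == 0 && nj == 0) break;
    i = ni; j = nj;
  }
  // Traceback walks towards the guide 3' end, so columns already come out
  // with guide positions increasing (and target positions decreasing).
  return List::create(_["score"] = best, _["guide_pos"] = wrap(gpos),
                      _["target_pos"] = wrap(tpos), _["pair_type"] = wrap(ptype));
}

namespace {

struct Brute {
  const std::vector<int>* g; const std::vector<int>* t;
  int m, n; Params q; double best;

  // Extend a chain whose last column is (i, j) [reversed-guide index, target
  // index], current score acc; runs = gap runs still allowed.
  void extend(int i, int j, double acc, int runs) {
    if (acc > best) best = acc;
    for (int a = 1; a <= q.max_guide_bulge + 1; ++a) {
      for (int b = 1; b <= q.max_target_loop + 1; ++b) {
        if (a > 1 && b > 1) continue;           // single-sided jumps only
        const int gap = (a > 1 ? a - 1 : (b > 1 ? b - 1 : 0));
        if (gap > 0 && runs == 0) continue;
        const int ni = i + a, nj = j + b;
        if (ni > m || nj > n) continue;
        double sub; int type;
        column_score(m - ni + 1, (*g)[m - ni], (*t)[nj - 1], q, sub, type);
        double cost = gap > 0 ? gap_cost(gap, q) : 0.0;
        extend(ni, nj, acc + cost + sub, runs - (gap > 0 ? 1 : 0));
      }
    }
  }
};

} // namespace

// Exhaustive enumeration of antiparallel column chains with at most
// `max_gap_runs` gap runs: the independent oracle for align_core on tiny
// inputs. Returns the maximum chain score (0 when nothing positive exists).
// [[Rcpp::export(name = ".align_brute_score")]]
double align_brute_score(std::string guide, std::string target, List params,
                         int max_gap_runs) {
  Brute br;
  const std::vector<int> g = encode(guide), t = encode(target);
  br.g = &g; br.t = &t;
  br.m = (int)g.size(); br.n = (int)t.size();
  br.q = read_params(params); br.best = 0.0;
  for (int i = 1; i <= br.m; ++i) {
    for (int j = 1; j <= br.n; ++j) {
      double sub; int type;
      column_score(br.m - i + 1, g[br.m - i], t[j - 1], br.q, sub, type);
      br.extend(i, j, sub, max_gap_runs);
    }
  }
  return br.best;
}
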