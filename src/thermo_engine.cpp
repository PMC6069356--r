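// Interval dynamic programming over pseudoknot-free secondary structures:
// partition functions (single strands and ordered multi-strand complexes with
// nick-aware loop scoring) and single-strand MFE with traceback. The scoring
// rules mirror the R-level loop decomposition exactly; the R test suite
// verifies the two routes against each other by exhaustive enumeration.
//
// Conventions: positions 0..N-1 along the strand concatenation; gap d lies
// between positions d and d+1; a loop containing an uncovered nick gap is an
// exterior loop with zero energy. Weights carry a per-base rescaling factor
// wp = exp(scale_g/kT) to keep magnitudes in double range; logs are
// un-rescaled on output.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  double kT;
  double stack[4][4];
  std::vector<double> hairpin, bulge, interior; // size-indexed, [0] = size 1
  double js;
  double ml_a, ml_b, ml_c;
  int min_hairpin, max_twoloop;
  double scale_g;
};

Model read_model(const List& params) {
  Model m;
  m.kT = as<double>(params["kT"]);
  NumericMatrix st = params["stack"];
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) m.stack[a][b] = st(a, b);
  m.hairpin = as<std::vector<double> >(params["hairpin"]);
  m.bulge = as<std::vector<double> >(params["bulge"]);
  m.interior = as<std::vector<double> >(params["interior"]);
  m.js = as<double>(params["js_coef"]);
  m.ml_a = as<double>(params["ml_a"]);
  m.ml_b = as<double>(params["ml_b"]);
  m.ml_c = as<double>(params["ml_c"]);
  m.min_hairpin = as<int>(params["min_hairpin"]);
  m.max_twoloop = as<int>(params["max_twoloop"]);
  m.scale_g = as<double>(params["scale_g"]);
  return m;
}

inline bool wc(int a, int b) { return a + b == 3; }

inline double size_pen(const std::vector<double>& tab, int u, double js) {
  int nmax = (int)tab.size();
  if (u <= nmax) return tab[u - 1];
  return tab[nmax - 1] + js * std::log((double)u / nmax);
}

inline double two_loop_energy(const Model& m, int u1, int u2, int bi, int bk) {
  if (u1 == 0 && u2 == 0) return m.stack[bi][bk];
  if (u1 == 0 || u2 == 0) {
    int u = u1 + u2;
    double g = size_pen(m.bulge, u, m.js);
    if (u == 1) g += m.stack[bi][bk];
    return g;
  }
  return size_pen(m.interior, u1 + u2, m.js);
}

class PartitionDP {
public:
  PartitionDP(const std::vector<int>& seq, const std::vector<int>& nick_gaps,
              const Model& m)
      : s(seq), m(m), N((int)seq.size()) {
    nick.assign(std::max(N - 1, 0), 0);
    for (size_t t = 0; t < nick_gaps.size(); ++t) nick[nick_gaps[t]] = 1;
    ncum.assign(N + 1, 0);
    for (int d = 0; d < N - 1; ++d) ncum[d + 1] = ncum[d] + nick[d];
    if (N >= 1) ncum[N] = ncum[N - 1];
    wp = std::exp(m.scale_g / m.kT);
    wpow.assign(N + 1, 1.0);
    for (int i = 1; i <= N; ++i) wpow[i] = wpow[i - 1] * wp;
    QB.assign((size_t)N * N, 0.0);
    FXv.assign((size_t)N * N, 0.0);
    QMv.assign((size_t)N * N, 0.0);
    Dv.assign((size_t)N * N, 0.0);
    CXv.assign((size_t)N * N, 0.0);
    run();
  }

  // log of the unconstrained (connected or not) partition function of the
  // subsequence [a, b], exterior loops free; rescaling removed.
  double logQ_range(int a, int b) const {
    double f = FX(a, b);
    return std::log(f) - (b - a + 1) * std::log(wp);
  }

  double qb(int i, int j) const { return QB[(size_t)i * N + j]; }

private:
  std::vector<int> s;
  Model m;
  int N;
  std::vector<int> nick, ncum;
  double wp;
  std::vector<double> wpow;
  std::vector<double> QB, FXv, QMv, Dv, CXv;

  inline bool nickAt(int d) const { return d >= 0 && d < N - 1 && nick[d]; }
  // any nick among gaps [x, y]
  inline bool nickIn(int x, int y) const {
    if (x > y) return false;
    if (x < 0) x = 0;
    if (y > N - 2) y = N - 2;
    if (x > y) return false;
    return ncum[y + 1] - ncum[x] > 0;
  }
  inline int firstNick(int x, int y) const {
    for (int d = std::max(x, 0); d <= std::min(y, N - 2); ++d)
      if (nick[d]) return d;
    return -1;
  }

  inline double FX(int a, int b) const {
    if (a > b) return 1.0;
    return FXv[(size_t)a * N + b];
  }
  inline double QM(int a, int b) const {
    if (a > b) return 0.0;
    return QMv[(size_t)a * N + b];
  }
  inline double DD(int a, int b) const {
    if (a > b) return 0.0;
    return Dv[(size_t)a * N + b];
  }
  inline double CX(int a, int b) const {
    if (a > b) return 1.0;
    return CXv[(size_t)a * N + b];
  }

  void run() {
    const double bw = std::exp(-m.ml_b / m.kT);     // per-branch multiloop weight
    const double cw = std::exp(-m.ml_c / m.kT) * wp; // per-unpaired multiloop weight (rescaled)
    const double closew = std::exp(-(m.ml_a + m.ml_b) / m.kT);
    for (int L = 1; L <= N; ++L) {
      // ---- QB for spans of length L
      if (L >= 2) {
        for (int i = 0; i + L - 1 < N; ++i) {
          int j = i + L - 1;
          if (!wc(s[i], s[j])) continue;
          double q = 0.0;
          bool edgeNick = nickAt(i) || nickAt(j - 1);
          bool anyNick = nickIn(i, j - 1);
          // hairpin
          if (!anyNick) {
            int u = j - i - 1;
            if (u >= m.min_hairpin)
              q += std::exp(-size_pen(m.hairpin, u, m.js) / m.kT) * wpow[j - i + 1];
          }
          // two-loop (stack / bulge / interior); loop gaps must be nick-free
          for (int u1 = 0; u1 <= m.max_twoloop; ++u1) {
            int k = i + 1 + u1;
            if (k >= j) break;
            if (nickAt(k - 1)) break; // gap k-1 exposed for this and larger u1
            for (int u2 = 0; u2 + u1 <= m.max_twoloop; ++u2) {
              int l = j - 1 - u2;
              if (l <= k) break;
              if (nickAt(l)) break; // gap l exposed for this and larger u2
              double qb_in = QB[(size_t)k * N + l];
              if (qb_in == 0.0) continue;
              double g = two_loop_energy(m, u1, u2, s[i], s[k]);
              q += std::exp(-g / m.kT) * wpow[u1 + u2 + 2] * qb_in;
            }
          }
          // multiloop closure (all nicks covered by inner branches)
          if (!nickAt(i) && !nickAt(j - 1)) {
            double d2 = DD(i + 1, j - 1);
            if (d2 > 0.0) q += closew * wpow[2] * d2;
          }
          // exterior-type closure (some nick exposed in the loop): energy 0
          if (anyNick) {
            if (edgeNick)
              q += wpow[2] * FX(i + 1, j - 1);
            else
              q += wpow[2] * (FX(i + 1, j - 1) - CX(i + 1, j - 1));
          }
          QB[(size_t)i * N + j] = q;
        }
      }
      // ---- region arrays for regions of length L
      for (int a = 0; a + L - 1 < N; ++a) {
        int b = a + L - 1;
        // FX: unconstrained exterior-style fill
        {
          double v = wp * FX(a + 1, b);
          for (int l = a + 1; l <= b; ++l) {
            double qb = QB[(size_t)a * N + l];
            if (qb > 0.0) v += qb * FX(l + 1, b);
          }
          FXv[(size_t)a * N + b] = v;
        }
        // QM: >=1 branch, nick gaps inside [a, b-1] covered by branches
        {
          double v = 0.0;
          if (a == b || !nickAt(a)) v += cw * QM(a + 1, b);
          for (int l = a + 1; l <= b; ++l) {
            double qb = QB[(size_t)a * N + l];
            if (qb == 0.0) continue;
            double tail = 0.0;
            if (!nickIn(l, b - 1)) {
              double u = b - l;
              tail += std::exp(-m.ml_c * u / m.kT) * wpow[(int)u];
            }
            if (l < b && !nickAt(l)) tail += QM(l + 1, b);
            v += qb * bw * tail;
          }
          QMv[(size_t)a * N + b] = v;
        }
        // D: >=2 branches, covered, used by multiloop closures
        {
          double v = 0.0;
          if (a == b || !nickAt(a)) v += cw * DD(a + 1, b);
          for (int l = a + 1; l <= b; ++l) {
            double qb = QB[(size_t)a * N + l];
            if (qb == 0.0) continue;
            if (l < b && !nickAt(l)) v += qb * bw * QM(l + 1, b);
          }
          Dv[(size_t)a * N + b] = v;
        }
        // CX: fill with every nick gap in [a, b-1] covered (weight-1 loops)
        {
          double v;
          int d = firstNick(a, b - 1);
          if (d < 0) {
            v = FXv[(size_t)a * N + b];
          } else {
            v = 0.0;
            for (int k = a; k <= d; ++k) {
              double fa = FX(a, k - 1);
              if (fa == 0.0) continue;
              for (int l = d + 1; l <= b; ++l) {
                double qb = QB[(size_t)k * N + l];
                if (qb == 0.0) continue;
                if (l < b && nickAt(l)) continue;
                v += fa * qb * CX(l + 1, b);
              }
            }
          }
          CXv[(size_t)a * N + b] = v;
        }
      }
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".dp_partition_ranges")]]
NumericMatrix dp_partition_ranges(List strand_codes, List params) {
  Model m = read_model(params);
  int ns = strand_codes.size();
  std::vector<int> seq;
  std::vector<int> nick_gaps;
  std::vector<int> start(ns), end(ns);
  for (int t = 0; t < ns; ++t) {
    IntegerVector v = strand_codes[t];
    start[t] = (int)seq.size();
    for (int q = 0; q < v.size(); ++q) seq.push_back(v[q]);
    end[t] = (int)seq.size() - 1;
    if (t < ns - 1) nick_gaps.push_back((int)seq.size() - 1);
  }
  PartitionDP dp(seq, nick_gaps, m);
  NumericMatrix out(ns, ns);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int p = 0; p < ns; ++p)
    for (int q = p; q < ns; ++q) out(p, q) = dp.logQ_range(start[p], end[q]);
  return out;
}

// ---------------- single-strand MFE ----------------

namespace {

const double INF = 1e30;

struct MfeDP {
  const std::vector<int>& s;
  const Model& m;
  int N;
  std::vector<double> EB, EM, ED;
  std::vector<double> EF; // suffix exterior minimum, EF[i] over [i, N-1]
  std::vector<std::pair<int, int> > pairs;

  MfeDP(const std::vector<int>& seq, const Model& mod) : s(seq), m(mod), N((int)seq.size()) {
    EB.assign((size_t)N * N, INF);
    EM.assign((size_t)N * N, INF);
    ED.assign((size_t)N * N, INF);
    EF.assign(N + 1, 0.0);
    fill();
    traceback();
  }

  inline double eb(int i, int j) const {
    if (i >= j) return INF;
    return EB[(size_t)i * N + j];
  }
  inline double em(int a, int b) const {
    if (a > b) return INF;
    return EM[(size_t)a * N + b];
  }
  inline double ed(int a, int b) const {
    if (a > b) return INF;
    return ED[(size_t)a * N + b];
  }

  void fill() {
    for (int L = 2; L <= N; ++L) {
      for (int i = 0; i + L - 1 < N; ++i) {
        int j = i + L - 1;
        // EB
        if (wc(s[i], s[j])) {
          double e = INF;
          int u = j - i - 1;
          if (u >= m.min_hairpin) e = std::min(e, size_pen(m.hairpin, u, m.js));
          for (int u1 = 0; u1 <= m.max_twoloop; ++u1) {
            int k = i + 1 + u1;
            if (k >= j) break;
            for (int u2 = 0; u2 + u1 <= m.max_twoloop; ++u2) {
              int l = j - 1 - u2;
              if (l <= k) break;
              double in = eb(k, l);
              if (in >= INF) continue;
              e = std::min(e, two_loop_energy(m, u1, u2, s[i], s[k]) + in);
            }
          }
          double d2 = ed(i + 1, j - 1);
          if (d2 < INF) e = std::min(e, m.ml_a + m.ml_b + d2);
          EB[(size_t)i * N + j] = e;
        }
      }
      for (int a = 0; a + L - 1 < N; ++a) {
        int b = a + L - 1;
        double vm = em(a + 1, b);
        if (vm < INF) vm += m.ml_c;
        double vd = ed(a + 1, b);
        if (vd < INF) vd += m.ml_c;
        for (int l = a + 1; l <= b; ++l) {
          double e1 = eb(a, l);
          if (e1 >= INF) continue;
          double tail = m.ml_c * (b - l);
          vm = std::min(vm, e1 + m.ml_b + tail);
          double rest = em(l + 1, b);
          if (rest < INF) {
            vm = std::min(vm, e1 + m.ml_b + rest);
            vd = std::min(vd, e1 + m.ml_b + rest);
          }
        }
        EM[(size_t)a * N + b] = vm;
        ED[(size_t)a * N + b] = vd;
      }
      // (EM/ED for length-1 regions handled by defaults: single unpaired base)
    }
    // length-1 EM/ED: no branch possible
    for (int a = 0; a < N; ++a) {
      EM[(size_t)a * N + a] = INF;
      ED[(size_t)a * N + a] = INF;
    }
    for (int i = N - 1; i >= 0; --i) {
      double v = EF[i + 1]; // i unpaired
      for (int l = i + 1; l < N; ++l) {
        double e1 = eb(i, l);
        if (e1 < INF) v = std::min(v, e1 + EF[l + 1]);
      }
      EF[i] = v;
    }
  }

  static inline bool close_to(double a, double b) { return std::fabs(a - b) <= 1e-7; }

  void traceback() {
    // exterior: prefer unpaired, then smallest partner
    int i = 0;
    while (i < N) {
      if (close_to(EF[i], EF[i + 1])) { ++i; continue; }
      bool found = false;
      for (int l = i + 1; l < N && !found; ++l) {
        double e1 = eb(i, l);
        if (e1 < INF && close_to(EF[i], e1 + EF[l + 1])) {
          trace_b(i, l);
          i = l + 1;
          found = true;
        }
      }
      if (!found) ++i; // defensive; should not happen
    }
  }

  void trace_b(int i, int j) {
    pairs.push_back(std::make_pair(i, j));
    double target = eb(i, j);
    int u = j - i - 1;
    if (u >= m.min_hairpin && close_to(target, size_pen(m.hairpin, u, m.js))) return;
    for (int u1 = 0; u1 <= m.max_twoloop; ++u1) {
      int k = i + 1 + u1;
      if (k >= j) break;
      for (int u2 = 0; u2 + u1 <= m.max_twoloop; ++u2) {
        int l = j - 1 - u2;
        if (l <= k) break;
        double in = eb(k, l);
        if (in >= INF) continue;
        if (close_to(target, two_loop_energy(m, u1, u2, s[i], s[k]) + in)) {
          trace_b(k, l);
          return;
        }
      }
    }
    trace_d(i + 1, j - 1);
  }

  void trace_d(int a, int b) { // >=2 branches
    double target = ed(a, b);
    if (a < b && ed(a + 1, b) < INF && close_to(target, m.ml_c + ed(a + 1, b))) {
      trace_d(a + 1, b);
      return;
    }
    for (int l = a + 1; l <= b; ++l) {
      double e1 = eb(a, l);
      if (e1 >= INF) continue;
      double rest = em(l + 1, b);
      if (rest < INF && close_to(target, e1 + m.ml_b + rest)) {
        trace_b(a, l);
        trace_m(l + 1, b);
        return;
      }
    }
  }

  void trace_m(int a, int b) { // >=1 branch
    double target = em(a, b);
    if (a < b && em(a + 1, b) < INF && close_to(target, m.ml_c + em(a + 1, b))) {
      trace_m(a + 1, b);
      return;
    }
    for (int l = a + 1; l <= b; ++l) {
      double e1 = eb(a, l);
      if (e1 >= INF) continue;
      if (close_to(target, e1 + m.ml_b + m.ml_c * (b - l))) {
        trace_b(a, l);
        return;
      }
      double rest = em(l + 1, b);
      if (rest < INF && close_to(target, e1 + m.ml_b + rest)) {
        trace_b(a, l);
        trace_m(l + 1, b);
        return;
      }
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".dp_mfe_single")]]
List dp_mfe_single(IntegerVector codes, List params) {
  Model m = read_model(params);
  std::vector<int> seq(codes.begin(), codes.end());
  MfeDP dp(seq, m);
  int np = (int)dp.pairs.size();
  IntegerMatrix pr(np, 2);
  for (int t = 0; t < np; ++t) {
    pr(t, 0) = dp.pairs[t].first + 1;
    pr(t, 1) = dp.pairs[t].second + 1;
  }
  return List::create(_["energy"] = dp.EF[0], _["pairs"] = pr);
}
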