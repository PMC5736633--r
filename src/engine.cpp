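// Fast engine for trial-by-trial likelihood replay and free-running
// simulation of the four candidate learning agents on the discretized
// triple-Y maze.  The R level owns all data structures and granular
// operations; this file mirrors their semantics exactly (one code path for
// forced-choice replay and free simulation, switched by `forced`).
//
// Action codes: 0 = F, 1 = L, 2 = R, 3 = U.
// Observation codes (= cell kind codes): 0 = corridor (I), 1 = dead end (u),
// 2 = Y intersection (Y).
// Models: 0 = model-based RL, 1 = model-free actor-critic (nmem 0 or 3),
// 2 = Bayesian path integration.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
#include <algorithm>
using namespace Rcpp;

static inline double wrap_pi(double a) {
  while (a <= -M_PI) a += 2.0 * M_PI;
  while (a >   M_PI) a -= 2.0 * M_PI;
  return a;
}

struct Maze {
  int n, start, goal;               // 0-based cells
  std::vector<double> x, y;
  std::vector<std::vector<int> > nb;
  std::vector<int> kind;            // 0 I, 1 u, 2 Y
  std::vector<int> guided;          // correct action path from start
  std::vector<char> onpath;         // cell lies on the direct start->goal path
  double start_heading;
};

static Maze parse_maze(List m) {
  Maze mz;
  NumericVector x = m["x"], y = m["y"];
  IntegerVector kind = m["kind"];
  List nb = m["nb"];
  mz.n = x.size();
  mz.x.assign(x.begin(), x.end());
  mz.y.assign(y.begin(), y.end());
  mz.kind.assign(kind.begin(), kind.end());
  mz.nb.resize(mz.n);
  for (int i = 0; i < mz.n; ++i) {
    IntegerVector v = nb[i];
    mz.nb[i].assign(v.begin(), v.end());
    for (size_t j = 0; j < mz.nb[i].size(); ++j) mz.nb[i][j] -= 1; // to 0-based
  }
  mz.start = as<int>(m["start"]) - 1;
  mz.goal  = as<int>(m["goal"]) - 1;
  IntegerVector g = m["guided"];
  mz.guided.assign(g.begin(), g.end());
  IntegerVector pth = m["path"];
  mz.onpath.assign(mz.n, 0);
  for (int i = 0; i < pth.size(); ++i) mz.onpath[pth[i] - 1] = 1;
  mz.start_heading = as<double>(m["start_heading"]);
  return mz;
}

// Available egocentric options at (cell c, heading h), canonical order
// F, L, R, U.  At a dead end only the reverse move is offered (or F when the
// heading already points at the single opening, i.e. the departure pose).
struct Opts {
  int nav;
  int act[4];
  int tgt[4];
};

static Opts options_at(const Maze& mz, int c, double h) {
  int tF = -1, tL = -1, tR = -1, tB = -1;
  for (size_t k = 0; k < mz.nb[c].size(); ++k) {
    int j = mz.nb[c][k];
    double ang = atan2(mz.y[j] - mz.y[c], mz.x[j] - mz.x[c]);
    double rel = wrap_pi(ang - h);
    if (std::fabs(rel) < M_PI / 4.0)                       tF = j;
    else if (rel >=  M_PI / 4.0 && rel <  3.0 * M_PI / 4.0) tL = j;
    else if (rel <= -M_PI / 4.0 && rel > -3.0 * M_PI / 4.0) tR = j;
    else                                                   tB = j;
  }
  Opts o; o.nav = 0;
  if (mz.kind[c] == 1) { // dead end: single neighbour
    if (tB >= 0) { o.act[0] = 3; o.tgt[0] = tB; }
    else         { o.act[0] = 0; o.tgt[0] = tF; }
    o.nav = 1;
    return o;
  }
  if (tF >= 0) { o.act[o.nav] = 0; o.tgt[o.nav] = tF; o.nav++; }
  if (tL >= 0) { o.act[o.nav] = 1; o.tgt[o.nav] = tL; o.nav++; }
  if (tR >= 0) { o.act[o.nav] = 2; o.tgt[o.nav] = tR; o.nav++; }
  if (tB < 0) stop("internal maze error: no reverse neighbour at cell %d", c + 1);
  o.act[o.nav] = 3; o.tgt[o.nav] = tB; o.nav++;
  return o;
}

// ---------------------------------------------------------------- agents

struct MBModel {
  std::vector<std::array<int, 4> > child;
  std::vector<std::array<double, 4> > T;
  std::vector<char> Rw;
  std::vector<double> V;
  std::vector<int> depth;
  int cur;

  void reset_all() {
    child.assign(1, std::array<int, 4>{{-1, -1, -1, -1}});
    T.assign(1, std::array<double, 4>{{0, 0, 0, 0}});
    Rw.assign(1, 0);
    V.assign(1, 0.0);
    depth.assign(1, 0);
    cur = 0;
  }
  void take(int a, double eta, bool rewarded) {
    if (child[cur][a] < 0) {
      child.push_back(std::array<int, 4>{{-1, -1, -1, -1}});
      T.push_back(std::array<double, 4>{{0, 0, 0, 0}});
      Rw.push_back(rewarded ? 1 : 0);
      V.push_back(0.0);
      depth.push_back(depth[cur] + 1);
      int m = (int)V.size() - 1;
      child[cur][a] = m;
      T[cur][a] = eta;
      cur = m;
    } else {
      T[cur][a] += eta * (1.0 - T[cur][a]);
      int m = child[cur][a];
      if (rewarded) Rw[m] = 1;
      cur = m;
    }
  }
  // Value iteration (deep nodes first: the graph is a tree, so one sweep in
  // reverse-depth order reaches the fixed point; the loop still checks).
  void value_iteration(double gamma, double tol) {
    int n = (int)V.size();
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return depth[a] > depth[b]; });
    for (int sweep = 0; sweep < 1000; ++sweep) {
      double mx = 0.0;
      for (int oi = 0; oi < n; ++oi) {
        int N = ord[oi];
        double best = Rw[N] ? 1.0 : 0.0;
        if (V[N] > best) best = V[N];
        for (int a = 0; a < 4; ++a) {
          int c2 = child[N][a];
          if (c2 >= 0) {
            double q = gamma * T[N][a] * V[c2];
            if (q > best) best = q;
          }
        }
        double d = best - V[N];
        if (d > mx) mx = d;
        V[N] = best;
      }
      if (mx < tol) break;
    }
  }
  void values(const Opts& o, double gamma, double* v) const {
    for (int k = 0; k < o.nav; ++k) {
      int a = o.act[k], c2 = child[cur][a];
      v[k] = (c2 >= 0) ? gamma * T[cur][a] * V[c2] : 0.0;
    }
  }
};

struct MFModel {
  int nmem, S;
  std::vector<double> V;
  std::vector<std::array<double, 4> > P;
  std::vector<int> mem; // most recent first, 4 = null token

  void reset_all() {
    S = 3;
    for (int i = 0; i < nmem; ++i) S *= 5;
    V.assign(S, 0.0);
    P.assign(S, std::array<double, 4>{{0, 0, 0, 0}});
    reset_trial();
  }
  void reset_trial() { mem.assign(nmem, 4); }
  int encode(int obs) const {
    int k = obs;
    for (int i = 0; i < nmem; ++i) k = k * 5 + mem[i];
    return k;
  }
  void push(int a) {
    if (nmem > 0) {
      for (int i = nmem - 1; i > 0; --i) mem[i] = mem[i - 1];
      mem[0] = a;
    }
  }
};

struct PIModel {
  int G, tstep;
  std::vector<double> gx, gy, pos, goal, cosA, sinA;

  void init_grid(NumericVector gxv, NumericVector gyv) {
    gx.assign(gxv.begin(), gxv.end());
    gy.assign(gyv.begin(), gyv.end());
    G = (int)gx.size();
    cosA.assign(G * G, 0.0);
    sinA.assign(G * G, 0.0);
    for (int i = 0; i < G; ++i)
      for (int j = 0; j < G; ++j) {
        if (i == j) continue;
        double a = atan2(gy[j] - gy[i], gx[j] - gx[i]);
        cosA[i * G + j] = cos(a);
        sinA[i * G + j] = sin(a);
      }
  }
  void reset_all() { goal.assign(G, 1.0 / G); }
  void set_delta(double x0, double y0) {
    pos.assign(G, 0.0);
    int best = 0;
    double bd = R_PosInf;
    for (int i = 0; i < G; ++i) {
      double d = (gx[i] - x0) * (gx[i] - x0) + (gy[i] - y0) * (gy[i] - y0);
      if (d < bd) { bd = d; best = i; }
    }
    pos[best] = 1.0;
  }
  void reset_phase(double x0, double y0) { tstep = 0; set_delta(x0, y0); }
  void propagate(double xc, double yc, double sigma0) {
    tstep += 1;
    double s = sigma0 * tstep;
    if (s <= 1e-9) { set_delta(xc, yc); return; }
    double tot = 0.0;
    for (int i = 0; i < G; ++i) {
      double d2 = (gx[i] - xc) * (gx[i] - xc) + (gy[i] - yc) * (gy[i] - yc);
      pos[i] = exp(-d2 / (2.0 * s * s));
      tot += pos[i];
    }
    if (tot <= 0.0) { set_delta(xc, yc); return; }
    for (int i = 0; i < G; ++i) pos[i] /= tot;
  }
  void update_goal(double eta) {
    for (int i = 0; i < G; ++i) goal[i] = (1.0 - eta) * goal[i] + eta * pos[i];
  }
  // P(Dir = alpha_k): every ordered grid pair (Pos, Goal), Pos != Goal, is
  // assigned to the nearest candidate direction; normalized over candidates.
  void dir_values(const Maze& mz, int c, const Opts& o, double* v) const {
    double ca[4], sa[4];
    for (int k = 0; k < o.nav; ++k) {
      double al = atan2(mz.y[o.tgt[k]] - mz.y[c], mz.x[o.tgt[k]] - mz.x[c]);
      ca[k] = cos(al);
      sa[k] = sin(al);
    }
    double acc[4] = {0, 0, 0, 0};
    double tot = 0.0;
    for (int i = 0; i < G; ++i) {
      double pi_ = pos[i];
      if (pi_ <= 1e-9) continue; // negligible mass: total error < G * 1e-9
      for (int j = 0; j < G; ++j) {
        if (j == i) continue;
        double w = pi_ * goal[j];
        if (w <= 0.0) continue;
        int bk = 0;
        double bc = -2.0;
        for (int k = 0; k < o.nav; ++k) {
          double cc = ca[k] * cosA[i * G + j] + sa[k] * sinA[i * G + j];
          if (cc > bc) { bc = cc; bk = k; }
        }
        acc[bk] += w;
        tot += w;
      }
    }
    if (tot > 0.0)
      for (int k = 0; k < o.nav; ++k) v[k] = acc[k] / tot;
    else
      for (int k = 0; k < o.nav; ++k) v[k] = 1.0 / o.nav;
  }
};

// stable softmax over the available options
static void softmax_opts(const double* v, int nav, double beta, double* p) {
  double vmax = v[0];
  for (int k = 1; k < nav; ++k) if (v[k] > vmax) vmax = v[k];
  double s = 0.0;
  for (int k = 0; k < nav; ++k) { p[k] = exp(beta * (v[k] - vmax)); s += p[k]; }
  for (int k = 0; k < nav; ++k) p[k] /= s;
}

// ------------------------------------------------------------------ run

// model: 0 mb, 1 mf, 2 pi.  par: (eta, beta, gamma, sigma0).
// forced_: when given, a list of trials (each list(actions = 0-based codes,
// guided = logical)) replayed with teacher forcing; log p(d^t) accumulated
// over non-guided steps.  Otherwise n_agents agents run the full protocol
// freely (one uniform from R's RNG per decision with >= 2 options).
// [[Rcpp::export]]
List engine_run(int model, int nmem, NumericVector par, List mazeL, List protoL,
                Nullable<List> forced_ = R_NilValue, int n_agents = 1,
                bool return_actions = false,
                Nullable<List> gridL = R_NilValue) {
  Maze mz = parse_maze(mazeL);
  double eta = par[0], beta = par[1], gamma = par[2], sigma0 = par[3];
  int tps = as<int>(protoL["trials_per_session"]);
  int spd = as<int>(protoL["sessions_per_day"]);
  int days = as<int>(protoL["max_days"]);
  int cap = as<int>(protoL["trial_cap_steps"]);
  int n_trials = tps * spd * days;

  bool replay = forced_.isNotNull();
  List forced;
  if (replay) { forced = forced_.get(); n_agents = 1; n_trials = forced.size(); }

  MBModel mb;
  MFModel mf; mf.nmem = nmem;
  PIModel pi;
  if (model == 2) {
    if (gridL.isNull()) stop("path-integration model needs a grid");
    List g = gridL.get();
    pi.init_grid(g["gx"], g["gy"]);
  }

  RNGScope scope;

  NumericMatrix steps_out(n_agents, n_trials);
  LogicalMatrix success_out(n_agents, n_trials);
  LogicalMatrix offpath_out(n_agents, n_trials);
  double loglik = 0.0;
  int ndec = 0;
  List agent_actions(return_actions ? n_agents : 0);

  for (int ag = 0; ag < n_agents; ++ag) {
    if (model == 0) mb.reset_all();
    else if (model == 1) mf.reset_all();
    else pi.reset_all();

    List trial_actions(return_actions ? n_trials : 0);

    for (int tr = 0; tr < n_trials; ++tr) {
      // trial start
      if (model == 0) { mb.cur = 0; mb.value_iteration(gamma, 1e-6); }
      else if (model == 1) mf.reset_trial();
      else pi.reset_phase(mz.x[mz.start], mz.y[mz.start]);

      int c = mz.start;
      double h = mz.start_heading;
      bool guided_phase = false, reached = false, offpath = false;
      int free_steps = 0, guided_idx = 0, rec_idx = 0;
      IntegerVector fa;
      LogicalVector fg;
      if (replay) {
        List t = forced[tr];
        fa = t["actions"];
        fg = t["guided"];
      }
      std::vector<int> acts_rec;
      std::vector<int> guided_rec;

      while (true) {
        if (replay) {
          if (rec_idx >= fa.size()) break; // recorded trial exhausted
          if (fg[rec_idx] && !guided_phase) {
            // recorded teleport: back to departure, guided to the goal
            guided_phase = true;
            c = mz.start; h = mz.start_heading;
            if (model == 0) mb.cur = 0;
            else if (model == 1) mf.reset_trial();
            else pi.reset_phase(mz.x[mz.start], mz.y[mz.start]);
          }
        }

        Opts o = options_at(mz, c, h);
        double v[4], p[4];
        int s_cur = -1;
        if (model == 0) mb.values(o, gamma, v);
        else if (model == 1) {
          s_cur = mf.encode(mz.kind[c]);
          for (int k = 0; k < o.nav; ++k) v[k] = mf.P[s_cur][o.act[k]];
        } else pi.dir_values(mz, c, o, v);
        softmax_opts(v, o.nav, beta, p);

        // choose the action
        int a, ki = -1;
        if (replay) {
          a = fa[rec_idx];
          for (int k = 0; k < o.nav; ++k) if (o.act[k] == a) ki = k;
          if (ki < 0)
            stop("decision not available at trial %d, step %d", tr + 1, rec_idx + 1);
          if (!fg[rec_idx]) {
            double pa = p[ki];
            if (pa < 1e-12) pa = 1e-12;
            loglik += log(pa);
            ndec += 1;
          }
          rec_idx += 1;
        } else if (guided_phase) {
          a = mz.guided[guided_idx++];
          for (int k = 0; k < o.nav; ++k) if (o.act[k] == a) ki = k;
          if (ki < 0) stop("guided action unavailable (maze inconsistency)");
        } else {
          if (o.nav == 1) ki = 0;
          else {
            double u = unif_rand(), cum = 0.0;
            ki = o.nav - 1;
            for (int k = 0; k < o.nav; ++k) {
              cum += p[k];
              if (u <= cum) { ki = k; break; }
            }
          }
          a = o.act[ki];
        }
        if (ki < 0) stop("internal error: chosen action not available");

        if (return_actions) {
          acts_rec.push_back(a);
          guided_rec.push_back(guided_phase ? 1 : 0);
        }

        // move
        int tgt = o.tgt[ki];
        h = atan2(mz.y[tgt] - mz.y[c], mz.x[tgt] - mz.x[c]);
        c = tgt;
        if (!guided_phase && !mz.onpath[c]) offpath = true;
        reached = (c == mz.goal);
        double r = reached ? 1.0 : 0.0;

        // learn
        if (model == 0) mb.take(a, eta, reached);
        else if (model == 1) {
          mf.push(a);
          int s2 = mf.encode(mz.kind[c]);
          double delta = r + (reached ? 0.0 : gamma * mf.V[s2]) - mf.V[s_cur];
          mf.V[s_cur] += eta * delta;
          mf.P[s_cur][a] += eta * delta;
        } else {
          pi.propagate(mz.x[c], mz.y[c], sigma0);
          if (reached) pi.update_goal(eta);
        }

        if (!guided_phase) free_steps += 1;
        if (reached) break;

        if (!replay && !guided_phase && free_steps >= cap) {
          guided_phase = true;
          guided_idx = 0;
          c = mz.start; h = mz.start_heading;
          if (model == 0) mb.cur = 0;
          else if (model == 1) mf.reset_trial();
          else pi.reset_phase(mz.x[mz.start], mz.y[mz.start]);
        }
      }

      bool free_success = reached && !guided_phase;
      steps_out(ag, tr) = free_steps;
      success_out(ag, tr) = free_success;
      offpath_out(ag, tr) = offpath;
      if (return_actions) {
        trial_actions[tr] = List::create(
          _["actions"] = IntegerVector(acts_rec.begin(), acts_rec.end()),
          _["guided"] = LogicalVector(guided_rec.begin(), guided_rec.end()));
      }
    }
    if (return_actions) agent_actions[ag] = trial_actions;
  }

  if (replay)
    return List::create(_["loglik"] = loglik, _["n_decisions"] = ndec);
  List out = List::create(_["steps"] = steps_out, _["success"] = success_out,
                          _["offpath"] = offpath_out);
  if (return_actions) out["actions"] = agent_actions;
  return out;
}
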