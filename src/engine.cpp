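// Agent-based engine for the two-species gut community model.
//
// Active agents (bacteria) search for food, move, convert substrate
// particles into product particles, divide and die; passive particles
// (polysaccharides, SCFAs, toxins, antibiotic) are advected along the gut,
// jitter laterally, are absorbed at the wall (SCFAs, via saturable MCT
// transport) and excreted at the outlet. All randomness comes from R's RNG
// stream so a run is fully reproducible from set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

enum Kind { K_PS = 0, K_PSGUT, K_ACE, K_PRO, K_BUT, K_TOX1, K_TOX2, K_ANT };
static const int NKIND = 8;

// ledger causes (cumulative quanta per kind)
enum Cause { C_INJ = 0, C_PROD, C_CONS, C_ABSW, C_EXCR, C_DECAY,
             C_UPTK, C_REL };
static const int NCAUSE = 8;

struct Par {
  double k_ps_ace_1, k_ps_ace_2, k_psgut_ace_1, k_psgut_ace_2;
  double k_ps_pro_1, k_ps_pro_2, k_ace_but_1, k_ace_but_2;
  double k_antitoxin1, k_antitoxin2;
  double sens_tox1[2], sens_tox2[2], sens_ant[2];
  double k_gut_out, k_intake, k_ps_mucus, k_trans_mct;
  double km_mct[3];            // acetate, propionate, butyrate
  double km_conv_ace, km_conv_pro, km_conv_but;
  double R_search, speed, eat_period, eat_n, contact, division_threshold;
  double L, D, dt, quantum, jitter;
  int conc_nx, conc_ny;
  double conc_per_quantum;
  int ace_owner;               // type performing the acetate conversion
  bool fb[7];
  double fb1_pct;
  double fb2_thr; int fb2_source;
  double fb3_thr, fb4_thr, fb5_thr, fb6_thr, fb7_thr, gut_toxin_rate;
  double fb7_rate;
  int fb4_dir;                 // 0: propionate - butyrate; 1: butyrate - propionate
  double tox_disp;
  double k_ant_intake, ant_start, ant_days, ant_gavdur;
  int ant_per_day; bool ant_continuous;
  double Rc, alpha;
};

struct Bact {
  int type;                 // 1 or 2
  double x, y;
  double hunger, starvlim;  // hours
  double energy;            // quanta since last division
  double acc_ant;           // absorbed antibiotic quanta
  double acc_tox1, acc_tox2;
  bool resistant, alive;
};

struct World {
  Par p;
  std::vector<Bact> bact;
  std::vector<double> px, py;
  std::vector<int> pkind;
  std::vector<char> palive;
  long ndead_particles = 0;
  double clock = 0.0, next_meal = 0.0;
  double mucus_acc = 0.0, ant_acc = 0.0;
  double fb_acc[7] = {0, 0, 0, 0, 0, 0, 0};
  double ledger[NKIND][NCAUSE] = {{0}};
  double births[2] = {0, 0};
  double d_starv[2] = {0, 0}, d_tox[2] = {0, 0}, d_drug[2] = {0, 0};
  double fb_events[7] = {0, 0, 0, 0, 0, 0, 0};
  double kcount[NKIND] = {0};   // live particle counts per kind
  // neighbor grid (cell size = search radius)
  double gs; int gnx, gny;
  std::vector<int> ghead, gnext;
  // concentration grid
  std::vector<double> ccount;   // NKIND * (conc_nx*conc_ny)
};

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// positive-argument modulus (avoids libm fmod)
static inline double pmod(double x, double y) {
  return x - std::floor(x / y) * y;
}

static inline double reflect(double v, double lo, double hi) {
  // single reflection suffices for steps much smaller than the domain
  if (v < lo) v = 2 * lo - v;
  if (v > hi) v = 2 * hi - v;
  return clampd(v, lo, hi);
}

static void add_particle(World &w, int kind, double x, double y, int cause) {
  w.px.push_back(x);
  w.py.push_back(y);
  w.pkind.push_back(kind);
  w.palive.push_back(1);
  w.kcount[kind] += 1;
  w.ledger[kind][cause] += 1;
}

static void kill_particle(World &w, int i, int cause) {
  w.palive[i] = 0;
  w.kcount[w.pkind[i]] -= 1;
  w.ledger[w.pkind[i]][cause] += 1;
  w.ndead_particles++;
}

static void compact_particles(World &w) {
  size_t j = 0;
  for (size_t i = 0; i < w.px.size(); ++i) {
    if (w.palive[i]) {
      w.px[j] = w.px[i]; w.py[j] = w.py[i];
      w.pkind[j] = w.pkind[i]; w.palive[j] = 1;
      ++j;
    }
  }
  w.px.resize(j); w.py.resize(j); w.pkind.resize(j); w.palive.resize(j);
  w.ndead_particles = 0;
}

static void build_neighbor_grid(World &w) {
  const int ncell = w.gnx * w.gny;
  w.ghead.assign(ncell, -1);
  w.gnext.assign(w.px.size(), -1);
  for (int i = 0; i < (int)w.px.size(); ++i) {
    if (!w.palive[i]) continue;
    int cx = (int)(w.px[i] / w.gs); if (cx >= w.gnx) cx = w.gnx - 1;
    int cy = (int)(w.py[i] / w.gs); if (cy >= w.gny) cy = w.gny - 1;
    int c = cy * w.gnx + cx;
    w.gnext[i] = w.ghead[c];
    w.ghead[c] = i;
  }
}

static void build_conc_grid(World &w) {
  const int ncell = w.p.conc_nx * w.p.conc_ny;
  w.ccount.assign((size_t)NKIND * ncell, 0.0);
  for (size_t i = 0; i < w.px.size(); ++i) {
    if (!w.palive[i]) continue;
    int cx = (int)(w.px[i] / w.p.L * w.p.conc_nx);
    if (cx >= w.p.conc_nx) cx = w.p.conc_nx - 1;
    int cy = (int)(w.py[i] / w.p.D * w.p.conc_ny);
    if (cy >= w.p.conc_ny) cy = w.p.conc_ny - 1;
    w.ccount[(size_t)w.pkind[i] * ncell + cy * w.p.conc_nx + cx] += 1;
  }
}

static inline int conc_cell(const World &w, double x, double y) {
  int cx = (int)(x / w.p.L * w.p.conc_nx);
  if (cx >= w.p.conc_nx) cx = w.p.conc_nx - 1;
  if (cx < 0) cx = 0;
  int cy = (int)(y / w.p.D * w.p.conc_ny);
  if (cy >= w.p.conc_ny) cy = w.p.conc_ny - 1;
  if (cy < 0) cy = 0;
  return cy * w.p.conc_nx + cx;
}

static inline double conc_mM(const World &w, int kind, int cell) {
  const int ncell = w.p.conc_nx * w.p.conc_ny;
  return w.ccount[(size_t)kind * ncell + cell] * w.p.quantum *
         w.p.conc_per_quantum;
}

// wall position draw: thin band along one of the two walls
static void wall_position(const World &w, double &x, double &y) {
  x = unif_rand() * w.p.L;
  double band = w.p.D / 20.0;
  y = (unif_rand() < 0.5) ? unif_rand() * band
                          : w.p.D - unif_rand() * band;
}

static void inlet_position(const World &w, double &x, double &y) {
  x = unif_rand() * 0.02 * w.p.L;
  y = w.p.D / 5.0 + unif_rand() * 3.0 * w.p.D / 5.0;  // lumen
}

// ---- scheduled entry ------------------------------------------------------

static void entry_phase(World &w) {
  const Par &p = w.p;
  // periodic meal
  if (p.k_intake > 0 && w.clock >= w.next_meal - 1e-9) {
    int n = (int)std::lround(p.k_intake * p.eat_period / p.quantum);
    for (int i = 0; i < n; ++i) {
      double x, y; inlet_position(w, x, y);
      add_particle(w, K_PS, x, y, C_INJ);
    }
    w.next_meal += p.eat_period;
  }
  // continuous host polysaccharide (mucus) production at the walls
  w.mucus_acc += p.k_ps_mucus * p.dt / p.quantum;
  while (w.mucus_acc >= 1.0) {
    double x, y; wall_position(w, x, y);
    add_particle(w, K_PSGUT, x, y, C_INJ);
    w.mucus_acc -= 1.0;
  }
  // antibiotic gavage windows
  if (p.k_ant_intake > 0) {
    double t = w.clock - p.ant_start;
    bool in_course = t >= 0 &&
      (p.ant_continuous || t < p.ant_days * 24.0);
    if (in_course) {
      double day_t = pmod(t, 24.0);
      double gap = 24.0 / p.ant_per_day;
      double within = pmod(day_t, gap);
      if (within < p.ant_gavdur) {
        w.ant_acc += p.k_ant_intake * p.dt / p.quantum;
        while (w.ant_acc >= 1.0) {
          double x, y; inlet_position(w, x, y);
          add_particle(w, K_ANT, x, y, C_INJ);
          w.ant_acc -= 1.0;
        }
      }
    }
  }
}

// ---- gut-mediated feedbacks ----------------------------------------------

static void gut_feedback_phase(World &w, double n1, double n2,
                               bool &fb2_active) {
  const Par &p = w.p;
  fb2_active = false;
  if (p.fb[1]) {  // FB2: bacterial co-emission, condition evaluated here
    if (p.fb2_source == 2)
      fb2_active = (n1 - n2) > p.fb2_thr;
    else
      fb2_active = (n2 - n1) > p.fb2_thr;
  }
  struct Rule { int idx; bool cond; int kind; };
  double nbut = w.kcount[K_BUT], npro = w.kcount[K_PRO];
  double fb4_diff = p.fb4_dir ? (nbut - npro) : (npro - nbut);
  Rule rules[] = {
    {2, (n2 - n1) > p.fb3_thr, K_TOX1},        // FB3: gut toxin vs type 2
    {3, fb4_diff > p.fb4_thr, K_TOX1},         // FB4: SCFA imbalance
    {4, nbut > p.fb5_thr, K_TOX2},             // FB5: toxin vs type 1
    {5, npro > p.fb6_thr, K_TOX1},             // FB6: toxin vs type 2
    {6, nbut < p.fb7_thr, K_PSGUT}             // FB7: feed type 1
  };
  for (const Rule &r : rules) {
    if (!p.fb[r.idx]) continue;
    if (r.cond) {
      w.fb_acc[r.idx] += (r.idx == 6) ? p.fb7_rate : p.gut_toxin_rate;
      while (w.fb_acc[r.idx] >= 1.0) {
        double x, y; wall_position(w, x, y);
        add_particle(w, r.kind, x, y, C_PROD);
        w.fb_acc[r.idx] -= 1.0;
        w.fb_events[r.idx] += 1;
      }
    } else {
      w.fb_acc[r.idx] = 0.0;
    }
  }
}

// ---- bacterial phase ------------------------------------------------------

struct Reaction { int sub, prod; double k, km; bool fb1_branch; };

static void reactions_for(const World &w, const Bact &b,
                          std::vector<Reaction> &out) {
  const Par &p = w.p;
  out.clear();
  if (b.type == 1) {
    if (p.k_ps_ace_1 > 0)
      out.push_back({K_PS, K_ACE, p.k_ps_ace_1, p.km_conv_ace, false});
    if (p.k_psgut_ace_1 > 0)
      out.push_back({K_PSGUT, K_ACE, p.k_psgut_ace_1, p.km_conv_ace, false});
    if (p.k_ps_pro_1 > 0)
      out.push_back({K_PS, K_PRO, p.k_ps_pro_1, p.km_conv_pro, false});
  } else {
    if (p.k_ps_ace_2 > 0)
      out.push_back({K_PS, K_ACE, p.k_ps_ace_2, p.km_conv_ace, false});
    if (p.k_psgut_ace_2 > 0)
      out.push_back({K_PSGUT, K_ACE, p.k_psgut_ace_2, p.km_conv_ace, false});
    if (p.k_ps_pro_2 > 0)
      out.push_back({K_PS, K_PRO, p.k_ps_pro_2, p.km_conv_pro, false});
  }
  // the acetate conversion belongs to the configured consumer type; under
  // FB1 a fraction of that flux is diverted to the self-lethal toxin
  if (b.type == p.ace_owner) {
    double k = std::max(p.k_ace_but_1, p.k_ace_but_2);
    if (k > 0)
      out.push_back({K_ACE, K_BUT, k, p.km_conv_but, p.fb[0]});
  }
}

static bool edible_kind(const World &w, const Bact &b, int kind) {
  const Par &p = w.p;
  if (kind == K_TOX1 && b.type == 1) return true;   // detoxifier food
  if (kind == K_TOX2 && b.type == 2) return true;
  if (b.type == 1) {
    if (kind == K_PS) return p.k_ps_ace_1 > 0 || p.k_ps_pro_1 > 0;
    if (kind == K_PSGUT) return p.k_psgut_ace_1 > 0;
  } else {
    if (kind == K_PS) return p.k_ps_ace_2 > 0 || p.k_ps_pro_2 > 0;
    if (kind == K_PSGUT) return p.k_psgut_ace_2 > 0;
  }
  if (kind == K_ACE)
    return b.type == p.ace_owner &&
           std::max(p.k_ace_but_1, p.k_ace_but_2) > 0;
  return false;
}

static void bacterium_die(World &w, Bact &b, double *cause_tally) {
  b.alive = false;
  cause_tally[b.type - 1] += 1;
  // accumulated drug dissolves back into the gut at the death position
  int n = (int)std::floor(b.acc_ant + 1e-9);
  for (int i = 0; i < n; ++i)
    add_particle(w, K_ANT, b.x, b.y, C_REL);
  w.ledger[K_ANT][C_REL] += (b.acc_ant - n);  // fractional remainder (none in practice)
  b.acc_ant = 0;
}

static void bacterial_phase(World &w, bool fb2_active) {
  const Par &p = w.p;
  const double contact2 = p.contact * p.contact;
  const double R2 = p.R_search * p.R_search;

  // randomized update order over bacteria alive at tick start
  std::vector<int> order;
  order.reserve(w.bact.size());
  for (int i = 0; i < (int)w.bact.size(); ++i)
    if (w.bact[i].alive) order.push_back(i);
  for (int i = (int)order.size() - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(order[i], order[j]);
  }

  std::vector<int> contact_idx[NKIND];
  std::vector<Reaction> rxns;

  for (int bi : order) {
    Bact &b = w.bact[bi];
    if (!b.alive) continue;

    // starvation clock
    b.hunger += p.dt;
    if (b.hunger > b.starvlim) {
      bacterium_die(w, b, w.d_starv);
      continue;
    }

    // neighborhood scan: contact lists and nearest edible within R
    for (int k = 0; k < NKIND; ++k) contact_idx[k].clear();
    double best_d2 = R2 * 4; int best_i = -1;
    int cx = (int)(b.x / w.gs); if (cx >= w.gnx) cx = w.gnx - 1;
    int cy = (int)(b.y / w.gs); if (cy >= w.gny) cy = w.gny - 1;
    for (int dy = -1; dy <= 1; ++dy) {
      int yy = cy + dy; if (yy < 0 || yy >= w.gny) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = cx + dx; if (xx < 0 || xx >= w.gnx) continue;
        for (int i = w.ghead[yy * w.gnx + xx]; i >= 0; i = w.gnext[i]) {
          if (!w.palive[i]) continue;
          double ddx = w.px[i] - b.x, ddy = w.py[i] - b.y;
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 <= contact2) contact_idx[w.pkind[i]].push_back(i);
          if (d2 <= R2 && d2 < best_d2 && edible_kind(w, b, w.pkind[i])) {
            best_d2 = d2; best_i = i;
          }
        }
      }
    }

    // toxin contact: detoxifier consumes as nutrient, sensitive accumulates
    for (int tk = K_TOX1; tk <= K_TOX2; ++tk) {
      if (contact_idx[tk].empty()) continue;
      bool detox = (tk == K_TOX1 && b.type == 1) ||
                   (tk == K_TOX2 && b.type == 2);
      double thr = (tk == K_TOX1) ? p.sens_tox1[b.type - 1]
                                  : p.sens_tox2[b.type - 1];
      if (detox) {
        for (int i : contact_idx[tk]) {
          kill_particle(w, i, C_CONS);
          b.energy += 1;
        }
        b.hunger = 0;
      } else if (R_finite(thr)) {
        double &acc = (tk == K_TOX1) ? b.acc_tox1 : b.acc_tox2;
        for (int i : contact_idx[tk]) {
          kill_particle(w, i, C_CONS);
          acc += 1;
        }
        if (acc >= thr) { bacterium_die(w, b, w.d_tox); }
      }
      if (!b.alive) break;
    }
    if (!b.alive) continue;

    // antibiotic diffusion into the cell
    if (!contact_idx[K_ANT].empty()) {
      for (int i : contact_idx[K_ANT]) {
        kill_particle(w, i, C_UPTK);
        b.acc_ant += 1;
      }
      double thr = p.sens_ant[b.type - 1];
      if (!b.resistant && R_finite(thr) && b.acc_ant >= thr) {
        bacterium_die(w, b, w.d_drug);
        continue;
      }
    }

    // division (threshold is in mmol so behavior is quantum-invariant)
    if (b.energy * p.quantum >= p.division_threshold) {
      double C_local = (double)contact_idx[K_ANT].size();
      // contact antibiotic was just absorbed; use the accumulated load as
      // the local concentration signal as well
      C_local += b.acc_ant;
      double pmut = 0.0;
      if (p.alpha > 0)
        pmut = std::min(1.0, p.alpha * C_local / p.Rc);
      Bact d1 = b, d2 = b;
      for (Bact *d : {&d1, &d2}) {
        d->energy = 0; d->hunger = 0;
        d->acc_tox1 = 0; d->acc_tox2 = 0;
        d->starvlim = unif_rand() * p.eat_n * p.eat_period;
        d->x = reflect(d->x + (unif_rand() * 2 - 1) * p.contact, 0, p.L);
        d->y = reflect(d->y + (unif_rand() * 2 - 1) * p.contact, 0, p.D);
        if (!d->resistant && pmut > 0 && unif_rand() < pmut)
          d->resistant = true;
      }
      d2.acc_ant = 0;          // absorbed drug load stays with one daughter
      int btype = b.type;
      b = d1;                  // assign before push_back: it may reallocate
      w.bact.push_back(d2);
      w.births[btype - 1] += 1;
      continue;
    }

    // feeding: conversion of contact substrate
    reactions_for(w, b, rxns);
    bool converted = false;
    int cell = conc_cell(w, b.x, b.y);
    for (const Reaction &r : rxns) {
      std::vector<int> &avail = contact_idx[r.sub];
      if (avail.empty()) continue;
      // purge entries consumed by an earlier reaction this tick
      double S = conc_mM(w, r.sub, cell);
      double rate = 100.0 * r.k * S / (r.km + S);
      if (b.resistant) rate /= p.Rc;   // fitness cost of resistance
      double mean = rate * p.dt / p.quantum;
      int n = (mean > 0) ? (int)::Rf_rpois(mean) : 0;
      int got = 0;
      for (int i : avail) {
        if (got >= n) break;
        if (!w.palive[i]) continue;
        kill_particle(w, i, C_CONS);
        ++got;
      }
      if (got == 0) continue;
      converted = true;
      for (int q = 0; q < got; ++q) {
        int prod = r.prod;
        if (r.fb1_branch && unif_rand() * 100.0 < p.fb1_pct) {
          // toxin-antitoxin branch: self-lethal toxin instead of butyrate
          prod = (p.ace_owner == 2) ? K_TOX1 : K_TOX2;
          w.fb_events[0] += 1;
        }
        if (prod == K_TOX1 || prod == K_TOX2) {
          // toxins diffuse into the surrounding medium before acting
          double ang = unif_rand() * 2 * M_PI;
          double rad = std::sqrt(unif_rand()) * p.tox_disp;
          add_particle(w, prod,
                       reflect(b.x + std::cos(ang) * rad, 0, p.L),
                       reflect(b.y + std::sin(ang) * rad, 0, p.D), C_PROD);
        } else {
          add_particle(w, prod, b.x, b.y, C_PROD);
        }
        if (fb2_active && b.type == p.fb2_source) {
          // toxin co-emitted with the conversion products
          double ang = unif_rand() * 2 * M_PI;
          double rad = std::sqrt(unif_rand()) * p.tox_disp;
          add_particle(w, (p.fb2_source == 2) ? K_TOX2 : K_TOX1,
                       reflect(b.x + std::cos(ang) * rad, 0, p.L),
                       reflect(b.y + std::sin(ang) * rad, 0, p.D), C_PROD);
          w.fb_events[1] += 1;
        }
      }
      b.energy += got;
      b.hunger = 0;
    }
    if (converted) continue;

    // movement: directed toward nearest food in search radius, else random
    double step = p.speed * p.dt;
    double nx, ny;
    if (best_i >= 0 && best_d2 <= R2) {
      double d = std::sqrt(best_d2);
      if (d <= step) { nx = w.px[best_i]; ny = w.py[best_i]; }
      else {
        nx = b.x + (w.px[best_i] - b.x) / d * step;
        ny = b.y + (w.py[best_i] - b.y) / d * step;
      }
    } else {
      double ang = unif_rand() * 2 * M_PI;
      nx = b.x + std::cos(ang) * step;
      ny = b.y + std::sin(ang) * step;
    }
    b.x = reflect(nx, 0, p.L);
    b.y = reflect(ny, 0, p.D);
  }
}

// ---- particle transport ---------------------------------------------------

static void transport_phase(World &w) {
  const Par &p = w.p;
  build_conc_grid(w);   // post-consumption field for absorption
  const int ncell = p.conc_nx * p.conc_ny;
  const double mucin_lo = p.D / 5.0, mucin_hi = 4.0 * p.D / 5.0;
  const double pdec1 = 1.0 - std::exp(-p.k_antitoxin1 * p.dt);
  const double pdec2 = 1.0 - std::exp(-p.k_antitoxin2 * p.dt);

  for (int i = 0; i < (int)w.px.size(); ++i) {
    if (!w.palive[i]) continue;
    int kind = w.pkind[i];

    // spontaneous toxin degradation
    if (kind == K_TOX1 && pdec1 > 0 && unif_rand() < pdec1) {
      kill_particle(w, i, C_DECAY); continue;
    }
    if (kind == K_TOX2 && pdec2 > 0 && unif_rand() < pdec2) {
      kill_particle(w, i, C_DECAY); continue;
    }

    // wall absorption of SCFAs (saturable competitive MCT transport)
    if (kind >= K_ACE && kind <= K_BUT &&
        (w.py[i] < mucin_lo || w.py[i] > mucin_hi)) {
      int cell = conc_cell(w, w.px[i], w.py[i]);
      double conc[3] = {conc_mM(w, K_ACE, cell), conc_mM(w, K_PRO, cell),
                        conc_mM(w, K_BUT, cell)};
      double denom = 1.0 + conc[0] / p.km_mct[0] + conc[1] / p.km_mct[1] +
                     conc[2] / p.km_mct[2];
      double rate = p.k_trans_mct * (conc[kind - K_ACE] /
                                     p.km_mct[kind - K_ACE]) / denom;
      double pool = w.ccount[(size_t)kind * ncell + cell] * p.quantum;
      if (pool > 0) {
        double prob = std::min(1.0, rate * p.dt / pool);
        if (unif_rand() < prob) { kill_particle(w, i, C_ABSW); continue; }
      }
    }

    // advection along the gut with the wall-adherent velocity profile
    double frac = 1.0 - std::fabs(w.py[i] - p.D / 2.0) * 2.0 / p.D;
    double v = p.k_gut_out * p.L * frac * frac;
    w.px[i] += v * p.dt;
    // lateral jitter, reflecting at the walls
    w.py[i] = reflect(w.py[i] + (unif_rand() * 2 - 1) * p.jitter, 0, p.D);
    if (w.px[i] > p.L) { kill_particle(w, i, C_EXCR); continue; }
  }
  if (w.ndead_particles > (long)w.px.size() / 2) compact_particles(w);
}

// ---- parameter unpacking --------------------------------------------------

static Par unpack(const List &pl) {
  Par p;
  p.k_ps_ace_1 = pl["k_ps_to_acetate_1"]; p.k_ps_ace_2 = pl["k_ps_to_acetate_2"];
  p.k_psgut_ace_1 = pl["k_psgut_to_acetate_1"];
  p.k_psgut_ace_2 = pl["k_psgut_to_acetate_2"];
  p.k_ps_pro_1 = pl["k_ps_to_propionate_1"]; p.k_ps_pro_2 = pl["k_ps_to_propionate_2"];
  p.k_ace_but_1 = pl["k_acetate_to_butyrate_1"];
  p.k_ace_but_2 = pl["k_acetate_to_butyrate_2"];
  p.k_antitoxin1 = pl["k_antitoxin1"]; p.k_antitoxin2 = pl["k_antitoxin2"];
  p.sens_tox1[0] = pl["sensitive_toxin1_1"]; p.sens_tox1[1] = pl["sensitive_toxin1_2"];
  p.sens_tox2[0] = pl["sensitive_toxin2_1"]; p.sens_tox2[1] = pl["sensitive_toxin2_2"];
  p.sens_ant[0] = pl["sensitive_antibiotic_1"]; p.sens_ant[1] = pl["sensitive_antibiotic_2"];
  p.k_gut_out = pl["k_gut_out"]; p.k_intake = pl["k_intake"];
  p.k_ps_mucus = pl["k_ps_mucus"]; p.k_trans_mct = pl["k_trans_mct"];
  p.km_mct[0] = pl["km_acetate_mct"]; p.km_mct[1] = pl["km_propionate_mct"];
  p.km_mct[2] = pl["km_butyrate_mct"];
  p.km_conv_ace = pl["km_acetate_conv"]; p.km_conv_pro = pl["km_propionate_conv"];
  p.km_conv_but = pl["km_butyrate_conv"];
  p.R_search = pl["search_radius_R"]; p.speed = pl["bacterial_speed"];
  p.eat_period = pl["eat_period"]; p.eat_n = pl["eat_range_multiplier_n"];
  p.contact = pl["contact_radius"]; p.division_threshold = pl["division_threshold"];
  p.L = pl["gut_length_L"]; p.D = pl["gut_width_D"];
  p.dt = pl["tick_hours"]; p.quantum = pl["particle_quantum"];
  p.jitter = pl["jitter_step"];
  p.conc_nx = pl["conc_grid_nx"]; p.conc_ny = pl["conc_grid_ny"];
  p.conc_per_quantum = pl["conc_per_quantum"];
  CharacterVector fbs = pl["feedbacks_enabled"];
  for (int i = 0; i < 7; ++i) p.fb[i] = false;
  for (int i = 0; i < fbs.size(); ++i) {
    std::string s = as<std::string>(fbs[i]);
    int idx = (s.size() >= 3) ? s[2] - '0' : 0;
    if (idx >= 1 && idx <= 7) p.fb[idx - 1] = true;
  }
  p.ace_owner = (int)as<double>(pl["acetate_consumer_type"]);
  p.fb1_pct = pl["fb1_toxin_percentage"];
  p.fb2_thr = pl["fb2_abundance_threshold"];
  p.fb2_source = (int)as<double>(pl["fb2_source_type"]);
  p.fb3_thr = pl["fb3_abundance_threshold"];
  p.fb4_thr = pl["fb4_scfa_difference_threshold"];
  p.fb4_dir = (as<std::string>(pl["fb4_difference"]) == "but-pro") ? 1 : 0;
  p.fb5_thr = pl["fb5_butyrate_threshold"];
  p.fb6_thr = pl["fb6_propionate_threshold"];
  p.fb7_thr = pl["fb7_butyrate_threshold"];
  p.gut_toxin_rate = pl["gut_toxin_rate"];
  p.fb7_rate = pl["fb7_ps_rate"];
  p.tox_disp = pl["toxin_dispersal_radius"];
  p.k_ant_intake = pl["k_ant_intake"];
  p.ant_per_day = (int)as<double>(pl["ant_gavages_per_day"]);
  p.ant_days = pl["ant_course_days"];
  p.ant_start = pl["ant_course_start"];
  p.ant_gavdur = pl["ant_gavage_duration"];
  p.ant_continuous = as<bool>(pl["ant_continuous"]);
  p.Rc = pl["retardation_constant_Rc"];
  p.alpha = pl["mutation_rate_scale_alpha"];
  return p;
}

// ---- recording ------------------------------------------------------------

static const char *kind_names[NKIND] = {
  "ps", "ps_gut", "acetate", "propionate", "butyrate", "toxin1", "toxin2",
  "antibiotic"};
static const char *cause_names[NCAUSE] = {
  "injected", "produced", "consumed", "wall_absorbed", "excreted", "decayed",
  "uptaken", "released"};

static CharacterVector traj_colnames() {
  std::vector<std::string> nm = {
    "tick", "hours", "n1_sens", "n1_res", "n2_sens", "n2_res",
    "births_1", "births_2", "deaths_starvation_1", "deaths_starvation_2",
    "deaths_toxin_1", "deaths_toxin_2", "deaths_antibiotic_1",
    "deaths_antibiotic_2", "drug_in_bacteria"};
  for (int k = 0; k < NKIND; ++k) nm.push_back(kind_names[k]);
  for (int k = 0; k < NKIND; ++k)
    for (int c = 0; c < NCAUSE; ++c)
      nm.push_back(std::string("led_") + kind_names[k] + "_" + cause_names[c]);
  for (int f = 1; f <= 7; ++f)
    nm.push_back("fb" + std::to_string(f) + "_events");
  return wrap(nm);
}

static void record_row(const World &w, double tick, std::vector<double> &out) {
  double n1s = 0, n1r = 0, n2s = 0, n2r = 0, drug_in = 0;
  for (const Bact &b : w.bact) {
    if (!b.alive) continue;
    drug_in += b.acc_ant;
    if (b.type == 1) { if (b.resistant) n1r += 1; else n1s += 1; }
    else             { if (b.resistant) n2r += 1; else n2s += 1; }
  }
  out.insert(out.end(), {tick, w.clock, n1s, n1r, n2s, n2r,
                         w.births[0], w.births[1],
                         w.d_starv[0], w.d_starv[1], w.d_tox[0], w.d_tox[1],
                         w.d_drug[0], w.d_drug[1], drug_in});
  for (int k = 0; k < NKIND; ++k) out.push_back(w.kcount[k]);
  for (int k = 0; k < NKIND; ++k)
    for (int c = 0; c < NCAUSE; ++c) out.push_back(w.ledger[k][c]);
  for (int f = 0; f < 7; ++f) out.push_back(w.fb_events[f]);
}

static DataFrame bacteria_table(const World &w) {
  std::vector<double> type, x, y, energy, hunger, starvlim, acc_ant;
  std::vector<int> resistant;
  for (const Bact &b : w.bact) {
    if (!b.alive) continue;
    type.push_back(b.type); x.push_back(b.x); y.push_back(b.y);
    energy.push_back(b.energy); hunger.push_back(b.hunger);
    starvlim.push_back(b.starvlim); acc_ant.push_back(b.acc_ant);
    resistant.push_back(b.resistant ? 1 : 0);
  }
  return DataFrame::create(
    _["type"] = type, _["x"] = x, _["y"] = y, _["resistant"] = resistant,
    _["energy"] = energy, _["hunger"] = hunger,
    _["starvation_limit"] = starvlim, _["accumulated_antibiotic"] = acc_ant);
}

static DataFrame particle_table(const World &w) {
  std::vector<std::string> kind;
  std::vector<double> x, y;
  for (size_t i = 0; i < w.px.size(); ++i) {
    if (!w.palive[i]) continue;
    kind.push_back(kind_names[w.pkind[i]]);
    x.push_back(w.px[i]); y.push_back(w.py[i]);
  }
  return DataFrame::create(_["kind"] = kind, _["x"] = x, _["y"] = y);
}

// [[Rcpp::export(name = ".abm_run")]]
List abm_run(List params, int ticks, int record_every = 1,
             int snapshot_every = 0, bool snapshot_particles = false) {
  World w;
  w.p = unpack(params);
  const Par &p = w.p;

  w.gs = std::max(p.R_search, p.contact);
  w.gnx = std::max(1, (int)std::ceil(p.L / w.gs));
  w.gny = std::max(1, (int)std::ceil(p.D / w.gs));

  // initial agents at uniform-random positions; the first
  // round(fraction * n) of each type start resistant
  double res_frac = as<double>(params["initial_resistant_fraction"]);
  auto init_b = [&](int type, int n) {
    int n_res = (int)std::lround(res_frac * n);
    for (int i = 0; i < n; ++i) {
      Bact b;
      b.type = type;
      b.x = unif_rand() * p.L; b.y = unif_rand() * p.D;
      b.hunger = 0; b.starvlim = unif_rand() * p.eat_n * p.eat_period;
      b.energy = 0; b.acc_ant = 0; b.acc_tox1 = 0; b.acc_tox2 = 0;
      b.resistant = (i < n_res); b.alive = true;
      w.bact.push_back(b);
    }
  };
  init_b(1, (int)as<double>(params["initial_bacteria_1"]));
  init_b(2, (int)as<double>(params["initial_bacteria_2"]));
  auto init_p = [&](int kind, int n) {
    for (int i = 0; i < n; ++i)
      add_particle(w, kind, unif_rand() * p.L, unif_rand() * p.D, C_INJ);
  };
  init_p(K_PS, (int)as<double>(params["initial_ps"]));
  init_p(K_ACE, (int)as<double>(params["initial_acetate"]));
  init_p(K_PRO, (int)as<double>(params["initial_propionate"]));
  init_p(K_BUT, (int)as<double>(params["initial_butyrate"]));

  std::vector<double> traj;
  record_row(w, 0, traj);
  List snapshots;
  std::vector<double> snap_ticks;

  for (int t = 1; t <= ticks; ++t) {
    entry_phase(w);
    double n1 = 0, n2 = 0;
    for (const Bact &b : w.bact)
      if (b.alive) { if (b.type == 1) n1 += 1; else n2 += 1; }
    bool fb2_active = false;
    gut_feedback_phase(w, n1, n2, fb2_active);
    build_neighbor_grid(w);
    build_conc_grid(w);
    bacterial_phase(w, fb2_active);
    transport_phase(w);
    w.clock += p.dt;
    if (t % record_every == 0 || t == ticks)
      record_row(w, t, traj);
    if (snapshot_every > 0 && t % snapshot_every == 0) {
      snapshots.push_back(bacteria_table(w));
      snap_ticks.push_back(t);
    }
    if (t % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  CharacterVector cn = traj_colnames();
  int ncol = cn.size();
  int nrow = (int)traj.size() / ncol;
  NumericMatrix tm(nrow, ncol);
  for (int r = 0; r < nrow; ++r)
    for (int c = 0; c < ncol; ++c)
      tm(r, c) = traj[(size_t)r * ncol + c];
  colnames(tm) = cn;

  List out = List::create(
    _["trajectory"] = tm,
    _["final_bacteria"] = bacteria_table(w),
    _["snapshots"] = snapshots,
    _["snapshot_ticks"] = wrap(snap_ticks));
  if (snapshot_particles) out["final_particles"] = particle_table(w);
  return out;
}

// ---- segregation index (grid-bucket neighbor search) ----------------------

// [[Rcpp::export(name = ".seg_fractions")]]
NumericVector seg_fractions(NumericVector x, NumericVector y,
                            IntegerVector type, double r) {
  int n = x.size();
  NumericVector out(n, NA_REAL);
  if (n == 0) return out;
  double xmin = Rcpp::min(x), ymin = Rcpp::min(y);
  double xmax = Rcpp::max(x), ymax = Rcpp::max(y);
  double gs = r > 0 ? r : 1.0;
  int gnx = std::max(1, (int)std::floor((xmax - xmin) / gs) + 1);
  int gny = std::max(1, (int)std::floor((ymax - ymin) / gs) + 1);
  std::vector<int> head((size_t)gnx * gny, -1), nxt(n, -1);
  auto cellof = [&](double xi, double yi) {
    int cx = (int)((xi - xmin) / gs); if (cx >= gnx) cx = gnx - 1;
    int cy = (int)((yi - ymin) / gs); if (cy >= gny) cy = gny - 1;
    return cy * gnx + cx;
  };
  for (int i = 0; i < n; ++i) {
    int c = cellof(x[i], y[i]);
    nxt[i] = head[c]; head[c] = i;
  }
  double r2 = r * r;
  for (int i = 0; i < n; ++i) {
    int cx = (int)((x[i] - xmin) / gs); if (cx >= gnx) cx = gnx - 1;
    int cy = (int)((y[i] - ymin) / gs); if (cy >= gny) cy = gny - 1;
    int same = 0, tot = 0;
    for (int dy = -1; dy <= 1; ++dy) {
      int yy = cy + dy; if (yy < 0 || yy >= gny) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = cx + dx; if (xx < 0 || xx >= gnx) continue;
        for (int j = head[yy * gnx + xx]; j >= 0; j = nxt[j]) {
          if (j == i) continue;
          double ddx = x[j] - x[i], ddy = y[j] - y[i];
          if (ddx * ddx + ddy * ddy <= r2) {
            ++tot;
            if (type[j] == type[i]) ++same;
          }
        }
      }
    }
    if (tot > 0) out[i] = (double)same / tot;
  }
  return out;
}
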