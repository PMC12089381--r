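// Coarse-grained Langevin/Monte-Carlo engine.
//
// Units: nm, ps, amu, kJ/mol (1 kJ/mol == 1 amu nm^2 ps^-2), so the
// thermal energy at temperature T is R*T with R = 0.00831446 kJ/(mol K).
//
// The integrator is a BAOAB Langevin splitting for free beads and an
// analogous translation + principal-axis rotation scheme for rigid groups.
// Pair interactions: Ashbaugh-Hatch (hydropathy-scaled LJ), screened
// Coulomb (Yukawa) and an optional cation-pi 12-6 well, all under cubic
// periodic boundaries with minimum-image distances.  Directly bonded pairs
// and pairs within the same rigid group are excluded from non-bonded terms.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double GASCONST = 0.00831446; // kJ/(mol K)

struct PairParams {
  arma::vec sigma, lambda, charge, mass;
  arma::mat cpi;             // per-type-pair cation-pi well depth (kJ/mol)
  double eps_ah, cut_ah, cut_yk, debye, kcoul; // kcoul = 138.935458/dielectric
  double folded_scale;
  double bond_k, bond_r0;
};

struct Topology {
  arma::ivec type;           // per bead, 0-based into param vectors
  arma::ivec rigid;          // 0 = free, >=1 rigid group id
  arma::imat bonds;          // M x 2, 0-based
  std::vector<std::vector<int>> excl; // bonded partners per bead
  int n;
};

static inline double min_image(double d, double box) {
  return d - box * std::round(d / box);
}

// cheap variant for wrapped coordinates (|d| < 1.5 box)
static inline double mi_wrapped(double d, double box, double hbox) {
  if (d > hbox) return d - box;
  if (d < -hbox) return d + box;
  return d;
}

// U and dU/dr for the Ashbaugh-Hatch term; lambda already folded-scaled.
static inline void ah_term(double r, double sig, double lam, double eps,
                           double cut, double &u, double &dudr) {
  u = 0.0; dudr = 0.0;
  if (r >= cut || eps == 0.0) return;
  double sr = sig / r;
  double s6 = sr * sr; s6 = s6 * s6 * s6;
  double s12 = s6 * s6;
  double ulj = 4.0 * eps * (s12 - s6);
  double flj = 24.0 * eps * (s6 - 2.0 * s12) / r; // dU_LJ/dr
  double rmin = std::pow(2.0, 1.0 / 6.0) * sig;
  if (r <= rmin) { u = ulj + (1.0 - lam) * eps; dudr = flj; }
  else           { u = lam * ulj;               dudr = lam * flj; }
}

static inline void lj_term(double r, double sig, double eps, double cut,
                           double &u, double &dudr) {
  u = 0.0; dudr = 0.0;
  if (r >= cut || eps == 0.0) return;
  double sr = sig / r;
  double s6 = sr * sr; s6 = s6 * s6 * s6;
  double s12 = s6 * s6;
  u = 4.0 * eps * (s12 - s6);
  dudr = 24.0 * eps * (s6 - 2.0 * s12) / r;
}

static inline void yk_term(double r, double qq, double kcoul, double debye,
                           double cut, double &u, double &dudr) {
  u = 0.0; dudr = 0.0;
  if (r >= cut || qq == 0.0) return;
  u = kcoul * qq * std::exp(-r / debye) / r;
  dudr = -u * (1.0 / debye + 1.0 / r);
}

// Full non-bonded pair energy (AH + Yukawa + cation-pi) for beads i,j.
static double pair_energy(int i, int j, const arma::mat &pos, double box,
                          const Topology &top, const PairParams &pp,
                          int type_i_override = -1) {
  int ti = (type_i_override >= 0) ? type_i_override : (int)top.type[i];
  int tj = (int)top.type[j];
  double dx = min_image(pos(i,0) - pos(j,0), box);
  double dy = min_image(pos(i,1) - pos(j,1), box);
  double dz = min_image(pos(i,2) - pos(j,2), box);
  double r = std::sqrt(dx*dx + dy*dy + dz*dz);
  double sig = 0.5 * (pp.sigma[ti] + pp.sigma[tj]);
  double lam = 0.5 * (pp.lambda[ti] + pp.lambda[tj]);
  double scale = (top.rigid[i] > 0 || top.rigid[j] > 0) ? pp.folded_scale : 1.0;
  double u, du, utot = 0.0;
  ah_term(r, sig, scale * lam, pp.eps_ah, pp.cut_ah, u, du); utot += u;
  yk_term(r, pp.charge[ti] * pp.charge[tj], pp.kcoul, pp.debye, pp.cut_yk, u, du);
  utot += u;
  double ec = pp.cpi((arma::uword)ti, (arma::uword)tj);
  if (ec != 0.0) { lj_term(r, sig, scale * ec, pp.cut_ah, u, du); utot += u; }
  return utot;
}

static bool excluded(const Topology &top, int i, int j) {
  if (top.rigid[i] > 0 && top.rigid[i] == top.rigid[j]) return true;
  for (int b : top.excl[i]) if (b == j) return true;
  return false;
}

// Forces + component energies in one pass.  The pair loop is the hot path:
// coordinates are hoisted per i-bead, exclusions are the (at most two)
// bonded neighbours checked as scalars, and far pairs exit on r^2.
static void compute_forces(const arma::mat &pos, double box,
                           const Topology &top, const PairParams &pp,
                           arma::mat &force, double *e_ah, double *e_yk,
                           double *e_cpi, double *e_bond) {
  force.zeros();
  double eah = 0, eyk = 0, ecp = 0, ebd = 0;
  double cut = std::max(pp.cut_ah, pp.cut_yk);
  double cut2 = cut * cut;
  double hbox = 0.5 * box;
  int n = top.n;
  const double *px = pos.colptr(0), *py = pos.colptr(1), *pz = pos.colptr(2);
  double *fx = force.colptr(0), *fy = force.colptr(1), *fz = force.colptr(2);
  for (int i = 0; i < n - 1; ++i) {
    int ti = (int)top.type[i];
    double xi = px[i], yi = py[i], zi = pz[i];
    int ri = (int)top.rigid[i];
    int e0 = top.excl[i].size() > 0 ? top.excl[i][0] : -1;
    int e1 = top.excl[i].size() > 1 ? top.excl[i][1] : -1;
    double fxi = 0, fyi = 0, fzi = 0;
    for (int j = i + 1; j < n; ++j) {
      double dx = mi_wrapped(xi - px[j], box, hbox);
      double dy = mi_wrapped(yi - py[j], box, hbox);
      double dz = mi_wrapped(zi - pz[j], box, hbox);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 >= cut2) continue;
      if (j == e0 || j == e1) continue;
      if (ri > 0 && ri == top.rigid[j]) continue;
      double r = std::sqrt(r2);
      int tj = (int)top.type[j];
      double sig = 0.5 * (pp.sigma[ti] + pp.sigma[tj]);
      double lam = 0.5 * (pp.lambda[ti] + pp.lambda[tj]);
      double scale = (ri > 0 || top.rigid[j] > 0) ? pp.folded_scale : 1.0;
      double u, du, dudr = 0.0;
      ah_term(r, sig, scale * lam, pp.eps_ah, pp.cut_ah, u, du);
      eah += u; dudr += du;
      double qq = pp.charge[ti] * pp.charge[tj];
      if (qq != 0.0) {
        yk_term(r, qq, pp.kcoul, pp.debye, pp.cut_yk, u, du);
        eyk += u; dudr += du;
      }
      double ec = pp.cpi((arma::uword)ti, (arma::uword)tj);
      if (ec != 0.0) { lj_term(r, sig, scale * ec, pp.cut_ah, u, du); ecp += u; dudr += du; }
      if (dudr != 0.0) {
        double fr = -dudr / r;
        fxi += fr * dx; fyi += fr * dy; fzi += fr * dz;
        fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
      }
    }
    fx[i] += fxi; fy[i] += fyi; fz[i] += fzi;
  }
  for (arma::uword b = 0; b < (arma::uword)top.bonds.n_rows; ++b) {
    int i = top.bonds(b,0), j = top.bonds(b,1);
    if (top.rigid[i] > 0 && top.rigid[i] == top.rigid[j]) continue;
    double dx = min_image(pos(i,0) - pos(j,0), box);
    double dy = min_image(pos(i,1) - pos(j,1), box);
    double dz = min_image(pos(i,2) - pos(j,2), box);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dr = r - pp.bond_r0;
    ebd += 0.5 * pp.bond_k * dr * dr;
    double fr = -pp.bond_k * dr / r;
    force(i,0) += fr * dx; force(i,1) += fr * dy; force(i,2) += fr * dz;
    force(j,0) -= fr * dx; force(j,1) -= fr * dy; force(j,2) -= fr * dz;
  }
  if (e_ah) { *e_ah = eah; *e_yk = eyk; *e_cpi = ecp; *e_bond = ebd; }
}

// ---- quaternion helpers (w, x, y, z), body->lab rotation --------------------

static arma::mat33 quat_to_mat(const arma::vec4 &q) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  arma::mat33 R;
  R(0,0) = 1 - 2*(y*y + z*z); R(0,1) = 2*(x*y - w*z);   R(0,2) = 2*(x*z + w*y);
  R(1,0) = 2*(x*y + w*z);     R(1,1) = 1 - 2*(x*x+z*z); R(1,2) = 2*(y*z - w*x);
  R(2,0) = 2*(x*z - w*y);     R(2,1) = 2*(y*z + w*x);   R(2,2) = 1 - 2*(x*x+y*y);
  return R;
}

static arma::vec4 quat_mult(const arma::vec4 &a, const arma::vec4 &b) {
  arma::vec4 q;
  q[0] = a[0]*b[0] - a[1]*b[1] - a[2]*b[2] - a[3]*b[3];
  q[1] = a[0]*b[1] + a[1]*b[0] + a[2]*b[3] - a[3]*b[2];
  q[2] = a[0]*b[2] - a[1]*b[3] + a[2]*b[0] + a[3]*b[1];
  q[3] = a[0]*b[3] + a[1]*b[2] - a[2]*b[1] + a[3]*b[0];
  return q;
}

static arma::vec4 quat_from_mat(const arma::mat33 &R) {
  arma::vec4 q;
  double tr = R(0,0) + R(1,1) + R(2,2);
  if (tr > 0) {
    double s = std::sqrt(tr + 1.0) * 2;
    q[0] = 0.25 * s;
    q[1] = (R(2,1) - R(1,2)) / s;
    q[2] = (R(0,2) - R(2,0)) / s;
    q[3] = (R(1,0) - R(0,1)) / s;
  } else if (R(0,0) > R(1,1) && R(0,0) > R(2,2)) {
    double s = std::sqrt(1.0 + R(0,0) - R(1,1) - R(2,2)) * 2;
    q[0] = (R(2,1) - R(1,2)) / s; q[1] = 0.25 * s;
    q[2] = (R(0,1) + R(1,0)) / s; q[3] = (R(0,2) + R(2,0)) / s;
  } else if (R(1,1) > R(2,2)) {
    double s = std::sqrt(1.0 + R(1,1) - R(0,0) - R(2,2)) * 2;
    q[0] = (R(0,2) - R(2,0)) / s; q[1] = (R(0,1) + R(1,0)) / s;
    q[2] = 0.25 * s;              q[3] = (R(1,2) + R(2,1)) / s;
  } else {
    double s = std::sqrt(1.0 + R(2,2) - R(0,0) - R(1,1)) * 2;
    q[0] = (R(1,0) - R(0,1)) / s; q[1] = (R(0,2) + R(2,0)) / s;
    q[2] = (R(1,2) + R(2,1)) / s; q[3] = 0.25 * s;
  }
  return arma::normalise(q);
}

// Rotate quaternion by body-frame angular velocity w over time h.
static void quat_advance(arma::vec4 &q, const arma::vec3 &w, double h) {
  double wn = arma::norm(w);
  if (wn < 1e-300) return;
  double half = 0.5 * wn * h;
  arma::vec3 ax = w / wn;
  arma::vec4 dq;
  dq[0] = std::cos(half);
  double s = std::sin(half);
  dq[1] = s * ax[0]; dq[2] = s * ax[1]; dq[3] = s * ax[2];
  q = quat_mult(q, dq);       // body-frame rotation composes on the right
  q = arma::normalise(q);
}

struct RigidBody {
  std::vector<int> members;
  arma::mat body;     // 3 x m principal-frame coordinates
  arma::vec3 I;       // principal moments (amu nm^2)
  double M;
  arma::vec3 c, V, w; // center, velocity, body-frame angular velocity
  arma::vec4 q;
};

struct EventRec { double t; int kind, site; double dU, prob; int acc; };
// kind: 0 contact, 1 phospho_attempt, 2 phospho_accept, 3 dephospho_accept,
//       4 reservoir_attempt, 5 reservoir_accept

// [[Rcpp::export]]
List cpp_run_simulation(arma::mat pos, Nullable<NumericMatrix> vel_,
                        IntegerVector type, IntegerVector rigid,
                        IntegerMatrix bonds, List par, List config,
                        IntegerVector phossites, IntegerVector ser_type,
                        IntegerVector pser_type, IntegerVector chem0,
                        IntegerVector active_site, IntegerVector feature_beads) {
  Topology top;
  top.n = pos.n_rows;
  top.type = arma::ivec(top.n);
  top.rigid = arma::ivec(top.n);
  for (int i = 0; i < top.n; ++i) { top.type[i] = type[i]; top.rigid[i] = rigid[i]; }
  top.bonds.set_size(bonds.nrow(), 2);
  top.excl.assign(top.n, {});
  for (int b = 0; b < bonds.nrow(); ++b) {
    top.bonds(b,0) = bonds(b,0); top.bonds(b,1) = bonds(b,1);
    top.excl[bonds(b,0)].push_back(bonds(b,1));
    top.excl[bonds(b,1)].push_back(bonds(b,0));
  }
  for (int i = 0; i < top.n; ++i)
    if (top.excl[i].size() > 2)
      stop("bead %d has more than two bonds; linear chains expected", i + 1);

  PairParams pp;
  pp.mass   = as<arma::vec>(par["mass"]);
  pp.sigma  = as<arma::vec>(par["sigma"]);
  pp.lambda = as<arma::vec>(par["lambda"]);
  pp.charge = as<arma::vec>(par["charge"]);
  pp.cpi    = as<arma::mat>(par["cpi"]);
  pp.eps_ah = par["eps_ah"]; pp.cut_ah = par["cut_ah"];
  pp.cut_yk = par["cut_yk"]; pp.debye = par["debye"];
  pp.kcoul  = par["kcoul"];  pp.folded_scale = par["folded_scale"];
  pp.bond_k = par["bond_k"]; pp.bond_r0 = par["bond_r0"];

  double dt   = config["dt"];
  double Tref = config["temperature"];
  double gamma  = config["friction"];
  double gammar = config["rot_friction"];
  double box  = config["box"];
  long   n_steps = (long)as<double>(config["n_steps"]);
  int    mc_interval = config["mc_interval"];
  bool   mc_enabled  = config["mc_enabled"];
  double contact_cut = config["contact_cutoff"];
  double resv_dist   = config["reservoir_distance"];
  double dmu         = config["dmu_p"];
  bool   resv        = config["reservoir_enabled"];
  int    resv_every   = config["reservoir_interval"]; // in MC checks
  int    phos_every   = config["phospho_interval"];    // in MC checks
  int    frame_stride = config["frame_stride"];
  int    pos_stride   = config["pos_stride"]; // 0 = never
  unsigned long seed  = (unsigned long)as<double>(config["seed"]);

  double kT = GASCONST * Tref;
  double beta = (kT > 0) ? 1.0 / kT : R_PosInf;

  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  int nsite = phossites.size();
  std::vector<int> chem(nsite);
  for (int s = 0; s < nsite; ++s) {
    chem[s] = chem0[s];
    top.type[phossites[s]] = chem[s] ? pser_type[s] : ser_type[s];
  }

  // --- rigid-body setup ---
  int ngroup = 0;
  for (int i = 0; i < top.n; ++i) ngroup = std::max(ngroup, (int)top.rigid[i]);
  std::vector<RigidBody> bodies(ngroup);
  for (int g = 0; g < ngroup; ++g) {
    RigidBody &B = bodies[g];
    for (int i = 0; i < top.n; ++i) if (top.rigid[i] == g + 1) B.members.push_back(i);
    if ((int)B.members.size() < 2)
      stop("rigid group %d has fewer than 2 beads", g + 1);
    B.M = 0; B.c.zeros();
    for (int i : B.members) {
      double m = pp.mass[top.type[i]];
      B.M += m;
      B.c += m * arma::vec3({pos(i,0), pos(i,1), pos(i,2)});
    }
    B.c /= B.M;
    arma::mat33 Iten(arma::fill::zeros);
    for (int i : B.members) {
      arma::vec3 d = arma::vec3({pos(i,0), pos(i,1), pos(i,2)}) - B.c;
      double m = pp.mass[top.type[i]];
      Iten += m * (arma::dot(d,d) * arma::eye(3,3) - d * d.t());
    }
    arma::vec eval; arma::mat evec;
    arma::eig_sym(eval, evec, Iten);
    if (eval[0] < 1e-8 * eval[2])
      stop("degenerate (collinear) rigid group %d rejected at setup", g + 1);
    if (arma::det(evec) < 0) evec.col(0) *= -1.0;
    B.I = eval;
    B.q = quat_from_mat(evec);
    B.body.set_size(3, B.members.size());
    for (size_t k = 0; k < B.members.size(); ++k) {
      int i = B.members[k];
      arma::vec3 d = arma::vec3({pos(i,0), pos(i,1), pos(i,2)}) - B.c;
      B.body.col(k) = evec.t() * d;
    }
    B.V.zeros(); B.w.zeros();
  }

  // --- velocities ---
  arma::mat vel(top.n, 3, arma::fill::zeros);
  bool have_vel = vel_.isNotNull();
  if (have_vel) {
    NumericMatrix v(vel_);
    for (int i = 0; i < top.n; ++i)
      for (int k = 0; k < 3; ++k) vel(i,k) = v(i,k);
  } else if (Tref > 0) {
    for (int i = 0; i < top.n; ++i) {
      if (top.rigid[i] > 0) continue;
      double sd = std::sqrt(kT / pp.mass[top.type[i]]);
      for (int k = 0; k < 3; ++k) vel(i,k) = sd * gauss(rng);
    }
    for (auto &B : bodies) {
      double sdv = std::sqrt(kT / B.M);
      for (int k = 0; k < 3; ++k) {
        B.V[k] = sdv * gauss(rng);
        B.w[k] = std::sqrt(kT / B.I[k]) * gauss(rng);
      }
    }
  }

  auto sync_bodies = [&]() {
    for (auto &B : bodies) {
      arma::mat33 R = quat_to_mat(B.q);
      for (size_t k = 0; k < B.members.size(); ++k) {
        arma::vec3 r = B.c + R * B.body.col(k);
        int i = B.members[k];
        pos(i,0) = r[0]; pos(i,1) = r[1]; pos(i,2) = r[2];
      }
    }
  };
  sync_bodies();

  arma::mat force(top.n, 3);
  double e_ah, e_yk, e_cpi, e_bond;
  compute_forces(pos, box, top, pp, force, &e_ah, &e_yk, &e_cpi, &e_bond);

  double c1  = (gamma  > 0) ? std::exp(-gamma  * dt) : 1.0;
  double c1r = (gammar > 0) ? std::exp(-gammar * dt) : 1.0;
  double c2  = std::sqrt(std::max(0.0, 1.0 - c1  * c1 ) * kT);
  double c2r = std::sqrt(std::max(0.0, 1.0 - c1r * c1r) * kT);

  // --- output buffers ---
  long n_frames = n_steps / frame_stride + 1;
  NumericVector f_time(n_frames);
  IntegerMatrix f_chem(n_frames, nsite);
  NumericMatrix f_sdist(n_frames, nsite);
  int nfeat = feature_beads.size();
  NumericMatrix f_feat(n_frames, nfeat);
  NumericVector f_energy(n_frames);
  std::vector<double> pbuf;
  std::vector<EventRec> events;
  std::vector<int> prev_contact(nsite, 0);
  long n_checks = 0;

  // criterion distance: max of the three active-site distances
  auto site_crit_dist = [&](int s) {
    int b = phossites[s];
    double dmax = 0, dmin = R_PosInf;
    for (int a = 0; a < active_site.size(); ++a) {
      int ab = active_site[a];
      double dx = min_image(pos(b,0) - pos(ab,0), box);
      double dy = min_image(pos(b,1) - pos(ab,1), box);
      double dz = min_image(pos(b,2) - pos(ab,2), box);
      double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      dmax = std::max(dmax, d); dmin = std::min(dmin, d);
    }
    return std::pair<double,double>(dmax, dmin);
  };
  auto feat_dist = [&](int b) {
    double dmin = R_PosInf;
    for (int a = 0; a < active_site.size(); ++a) {
      int ab = active_site[a];
      double dx = min_image(pos(b,0) - pos(ab,0), box);
      double dy = min_image(pos(b,1) - pos(ab,1), box);
      double dz = min_image(pos(b,2) - pos(ab,2), box);
      dmin = std::min(dmin, std::sqrt(dx*dx + dy*dy + dz*dz));
    }
    return dmin;
  };
  auto site_energy = [&](int s, int as_type) {
    int b = phossites[s];
    double u = 0;
    for (int j = 0; j < top.n; ++j) {
      if (j == b || excluded(top, b, j)) continue;
      u += pair_energy(b, j, pos, box, top, pp, as_type);
    }
    return u;
  };
  auto record_frame = [&](long idx, double tns) {
    f_time[idx] = tns;
    for (int s = 0; s < nsite; ++s) {
      f_chem(idx, s) = chem[s];
      f_sdist(idx, s) = site_crit_dist(s).first;
    }
    for (int k = 0; k < nfeat; ++k) f_feat(idx, k) = feat_dist(feature_beads[k]);
    compute_forces(pos, box, top, pp, force, &e_ah, &e_yk, &e_cpi, &e_bond);
    f_energy[idx] = e_ah + e_yk + e_cpi + e_bond;
    if (!std::isfinite(f_energy[idx]) || !pos.is_finite())
      stop("non-finite coordinates/energy at t = %g ns: integration unstable "
           "(reduce dt or check initial overlaps)", tns);
  };
  record_frame(0, 0.0);

  long frame_idx = 1;
  for (long step = 1; step <= n_steps; ++step) {
    // B
    for (int i = 0; i < top.n; ++i) {
      if (top.rigid[i] > 0) continue;
      double m = pp.mass[top.type[i]];
      for (int k = 0; k < 3; ++k) vel(i,k) += 0.5 * dt * force(i,k) / m;
    }
    for (auto &B : bodies) {
      arma::vec3 F(arma::fill::zeros), tau(arma::fill::zeros);
      arma::mat33 R = quat_to_mat(B.q);
      for (size_t k = 0; k < B.members.size(); ++k) {
        int i = B.members[k];
        arma::vec3 f = {force(i,0), force(i,1), force(i,2)};
        F += f;
        tau += arma::cross(R * B.body.col(k), f);
      }
      arma::vec3 tau_b = R.t() * tau;
      B.V += 0.5 * dt * F / B.M;
      for (int k = 0; k < 3; ++k) B.w[k] += 0.5 * dt * tau_b[k] / B.I[k];
    }
    // A  O  A
    for (int i = 0; i < top.n; ++i) {
      if (top.rigid[i] > 0) continue;
      double m = pp.mass[top.type[i]];
      double sd = c2 / std::sqrt(m);
      for (int k = 0; k < 3; ++k) {
        pos(i,k) += 0.5 * dt * vel(i,k);
        vel(i,k) = c1 * vel(i,k) + sd * gauss(rng);
        pos(i,k) += 0.5 * dt * vel(i,k);
        if (pos(i,k) >= box) pos(i,k) -= box;
        else if (pos(i,k) < 0) pos(i,k) += box;
      }
    }
    for (auto &B : bodies) {
      B.c += 0.5 * dt * B.V;
      quat_advance(B.q, B.w, 0.5 * dt);
      double sdv = c2 / std::sqrt(B.M);
      for (int k = 0; k < 3; ++k) {
        B.V[k] = c1 * B.V[k] + sdv * gauss(rng);
        B.w[k] = c1r * B.w[k] + (c2r / std::sqrt(B.I[k])) * gauss(rng);
      }
      B.c += 0.5 * dt * B.V;
      for (int k = 0; k < 3; ++k) {
        if (B.c[k] >= box) B.c[k] -= box;
        else if (B.c[k] < 0) B.c[k] += box;
      }
      quat_advance(B.q, B.w, 0.5 * dt);
    }
    sync_bodies();
    // force + B
    compute_forces(pos, box, top, pp, force, nullptr, nullptr, nullptr, nullptr);
    for (int i = 0; i < top.n; ++i) {
      if (top.rigid[i] > 0) continue;
      double m = pp.mass[top.type[i]];
      for (int k = 0; k < 3; ++k) vel(i,k) += 0.5 * dt * force(i,k) / m;
    }
    for (auto &B : bodies) {
      arma::vec3 F(arma::fill::zeros), tau(arma::fill::zeros);
      arma::mat33 R = quat_to_mat(B.q);
      for (size_t k = 0; k < B.members.size(); ++k) {
        int i = B.members[k];
        arma::vec3 f = {force(i,0), force(i,1), force(i,2)};
        F += f;
        tau += arma::cross(R * B.body.col(k), f);
      }
      arma::vec3 tau_b = R.t() * tau;
      B.V += 0.5 * dt * F / B.M;
      for (int k = 0; k < 3; ++k) B.w[k] += 0.5 * dt * tau_b[k] / B.I[k];
    }

    // --- MC block every mc_interval steps ---
    if (mc_enabled && step % mc_interval == 0) {
      ++n_checks;
      double tns = step * dt / 1000.0;
      // contact detection: all three distances < cutoff; closest site only
      int best = -1; double best_mean = R_PosInf;
      for (int s = 0; s < nsite; ++s) {
        int b = phossites[s];
        double dsum = 0; bool ok = true;
        for (int a = 0; a < active_site.size(); ++a) {
          int ab = active_site[a];
          double dx = min_image(pos(b,0) - pos(ab,0), box);
          double dy = min_image(pos(b,1) - pos(ab,1), box);
          double dz = min_image(pos(b,2) - pos(ab,2), box);
          double d = std::sqrt(dx*dx + dy*dy + dz*dz);
          if (d >= contact_cut) { ok = false; break; }
          dsum += d;
        }
        if (ok) {
          if (!prev_contact[s])
            events.push_back({tns, 0, s, NA_REAL, NA_REAL, 1});
          prev_contact[s] = 1;
          double dmean = dsum / active_site.size();
          if (dmean < best_mean) { best_mean = dmean; best = s; }
        } else prev_contact[s] = 0;
      }
      if (best >= 0 && (n_checks % phos_every) == 0) {
        int s = best, b = phossites[s];
        double u_ser = site_energy(s, ser_type[s]);
        double u_pser = site_energy(s, pser_type[s]);
        double dU = u_pser - u_ser;   // Ser -> pSer convention
        double lnA = chem[s] ? (beta * dU + beta * dmu)    // pSer -> Ser
                             : (-beta * dU - beta * dmu);  // Ser -> pSer
        double A = std::min(1.0, std::exp(lnA));
        events.push_back({tns, 1, s, dU, A, 0});
        if (unif(rng) < A) {
          chem[s] = 1 - chem[s];
          top.type[b] = chem[s] ? pser_type[s] : ser_type[s];
          events.back().acc = 1;
          events.push_back({tns, chem[s] ? 2 : 3, s, dU, A, 1});
          compute_forces(pos, box, top, pp, force, nullptr, nullptr, nullptr, nullptr);
        }
      }
      if (resv && (n_checks % resv_every) == 0) {
        for (int s = 0; s < nsite; ++s) {
          auto dd = site_crit_dist(s);
          if (dd.second <= resv_dist) continue; // all three must exceed
          int b = phossites[s];
          int tgt = chem[s] ? ser_type[s] : pser_type[s];
          double dU = site_energy(s, tgt) - site_energy(s, top.type[b]);
          double A = std::min(1.0, std::exp(-beta * dU));
          events.push_back({step * dt / 1000.0, 4, s, dU, A, 0});
          if (unif(rng) < A) {
            chem[s] = 1 - chem[s];
            top.type[b] = tgt;
            events.back().acc = 1;
            events.push_back({step * dt / 1000.0, 5, s, dU, A, 1});
            compute_forces(pos, box, top, pp, force, nullptr, nullptr, nullptr, nullptr);
          }
        }
      }
    }

    if (step % frame_stride == 0 && frame_idx < n_frames)
      record_frame(frame_idx++, step * dt / 1000.0);
    if (pos_stride > 0 && step % pos_stride == 0) {
      for (int i = 0; i < top.n; ++i)
        for (int k = 0; k < 3; ++k) {
          double x = pos(i,k) - box * std::floor(pos(i,k) / box);
          pbuf.push_back(x);
        }
    }
    if (step % 200000 == 0) Rcpp::checkUserInterrupt();
  }

  int ne = events.size();
  NumericVector ev_t(ne), ev_dU(ne), ev_p(ne);
  IntegerVector ev_k(ne), ev_s(ne), ev_a(ne);
  for (int e = 0; e < ne; ++e) {
    ev_t[e] = events[e].t; ev_k[e] = events[e].kind;
    ev_s[e] = events[e].site + 1; ev_dU[e] = events[e].dU;
    ev_p[e] = events[e].prob; ev_a[e] = events[e].acc;
  }
  NumericMatrix pos_out(top.n, 3), vel_out(top.n, 3);
  for (int i = 0; i < top.n; ++i)
    for (int k = 0; k < 3; ++k) {
      pos_out(i,k) = pos(i,k) - box * std::floor(pos(i,k) / box);
      vel_out(i,k) = vel(i,k);
    }
  List frames = List::create(_["time"] = f_time, _["chem"] = f_chem,
                             _["site_dist"] = f_sdist, _["features"] = f_feat,
                             _["energy"] = f_energy);
  List ev = List::create(_["time"] = ev_t, _["kind"] = ev_k, _["site"] = ev_s,
                         _["dU"] = ev_dU, _["prob"] = ev_p, _["accepted"] = ev_a);
  List out = List::create(_["frames"] = frames, _["events"] = ev,
                          _["final_pos"] = pos_out, _["final_vel"] = vel_out,
                          _["final_chem"] = IntegerVector(chem.begin(), chem.end()),
                          _["n_checks"] = (double)n_checks);
  if (pos_stride > 0) {
    long npf = pbuf.size() / (3L * top.n);
    NumericVector pv(pbuf.begin(), pbuf.end());
    pv.attr("dim") = IntegerVector::create(3, top.n, npf);
    out["positions"] = pv;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Energy queries used by the analysis modules and by bookkeeping tests.

static Topology make_topology(const arma::mat &pos, IntegerVector type,
                              IntegerVector rigid, IntegerMatrix bonds) {
  Topology top;
  top.n = pos.n_rows;
  top.type = arma::ivec(top.n);
  top.rigid = arma::ivec(top.n);
  for (int i = 0; i < top.n; ++i) { top.type[i] = type[i]; top.rigid[i] = rigid[i]; }
  top.bonds.set_size(bonds.nrow(), 2);
  top.excl.assign(top.n, {});
  for (int b = 0; b < bonds.nrow(); ++b) {
    top.bonds(b,0) = bonds(b,0); top.bonds(b,1) = bonds(b,1);
    top.excl[bonds(b,0)].push_back(bonds(b,1));
    top.excl[bonds(b,1)].push_back(bonds(b,0));
  }
  for (int i = 0; i < top.n; ++i)
    if (top.excl[i].size() > 2)
      stop("bead %d has more than two bonds; linear chains expected", i + 1);
  return top;
}

static PairParams make_pp(List par) {
  PairParams pp;
  pp.mass   = as<arma::vec>(par["mass"]);
  pp.sigma  = as<arma::vec>(par["sigma"]);
  pp.lambda = as<arma::vec>(par["lambda"]);
  pp.charge = as<arma::vec>(par["charge"]);
  pp.cpi    = as<arma::mat>(par["cpi"]);
  pp.eps_ah = par["eps_ah"]; pp.cut_ah = par["cut_ah"];
  pp.cut_yk = par["cut_yk"]; pp.debye = par["debye"];
  pp.kcoul  = par["kcoul"];  pp.folded_scale = par["folded_scale"];
  pp.bond_k = par["bond_k"]; pp.bond_r0 = par["bond_r0"];
  return pp;
}

// [[Rcpp::export]]
List cpp_total_energy(arma::mat pos, IntegerVector type, IntegerVector rigid,
                      IntegerMatrix bonds, List par, double box) {
  Topology top = make_topology(pos, type, rigid, bonds);
  PairParams pp = make_pp(par);
  arma::mat force(top.n, 3);
  double e_ah, e_yk, e_cpi, e_bond;
  compute_forces(pos, box, top, pp, force, &e_ah, &e_yk, &e_cpi, &e_bond);
  return List::create(_["total"] = e_ah + e_yk + e_cpi + e_bond,
                      _["ah"] = e_ah, _["yukawa"] = e_yk,
                      _["cation_pi"] = e_cpi, _["bond"] = e_bond,
                      _["force"] = wrap(force));
}

// Interaction energy of bead `site` (0-based) with all non-excluded partners,
// with its type overridden to `as_type`.
// [[Rcpp::export]]
double cpp_site_energy(arma::mat pos, IntegerVector type, IntegerVector rigid,
                       IntegerMatrix bonds, List par, double box,
                       int site, int as_type) {
  Topology top = make_topology(pos, type, rigid, bonds);
  PairParams pp = make_pp(par);
  double u = 0;
  for (int j = 0; j < top.n; ++j) {
    if (j == site || excluded(top, site, j)) continue;
    u += pair_energy(site, j, pos, box, top, pp, as_type);
  }
  return u;
}

// Per-group-residue decomposition of group-partner interaction energy into
// AH / Yukawa / cation-pi terms.  Each (group, partner) pair is attributed in
// full to the group residue; sets must be disjoint.
// [[Rcpp::export]]
NumericMatrix cpp_energy_decomposition(arma::mat pos, IntegerVector type,
                                       IntegerVector rigid, IntegerMatrix bonds,
                                       List par, double box,
                                       IntegerVector group, IntegerVector partner) {
  Topology top = make_topology(pos, type, rigid, bonds);
  PairParams pp = make_pp(par);
  NumericMatrix out(group.size(), 3);
  for (int gi = 0; gi < group.size(); ++gi) {
    int i = group[gi];
    int ti = (int)top.type[i];
    for (int pj = 0; pj < partner.size(); ++pj) {
      int j = partner[pj];
      if (i == j) stop("group and partner sets overlap");
      if (excluded(top, i, j)) continue;
      int tj = (int)top.type[j];
      double dx = min_image(pos(i,0) - pos(j,0), box);
      double dy = min_image(pos(i,1) - pos(j,1), box);
      double dz = min_image(pos(i,2) - pos(j,2), box);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      double sig = 0.5 * (pp.sigma[ti] + pp.sigma[tj]);
      double lam = 0.5 * (pp.lambda[ti] + pp.lambda[tj]);
      double scale = (top.rigid[i] > 0 || top.rigid[j] > 0) ? pp.folded_scale : 1.0;
      double u, du;
      ah_term(r, sig, scale * lam, pp.eps_ah, pp.cut_ah, u, du);
      out(gi,0) += u;
      yk_term(r, pp.charge[ti] * pp.charge[tj], pp.kcoul, pp.debye, pp.cut_yk, u, du);
      out(gi,1) += u;
      double ec = pp.cpi((arma::uword)ti, (arma::uword)tj);
      if (ec != 0.0) { lj_term(r, sig, scale * ec, pp.cut_ah, u, du); out(gi,2) += u; }
    }
  }
  return out;
}
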