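// Analytic geometry of three overlapping ellipses and the hill-climbing
// optimizer core. All areas are exact (up to floating point): boundary
// intersection points come from the pair's resultant quartic (companion
// matrix eigenvalues + Newton refinement) and region areas from the
// arc-segment integral 1/2 * int(x dy - y dx) over the region boundary.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double DEDUP_TOL = 1e-9;     // in unit-circle frame
static const double TANGENT_TOL = 1e-8;   // |cross| of unit gradients
static const double REGION_FLOOR = 1e-12; // fraction of total area
static const double GOOD_EPS = 1e-6;      // diagError threshold

struct Ell {
  double cx, cy, a, b, th, ct, st;
  Ell(double cx_, double cy_, double a_, double b_, double th_)
    : cx(cx_), cy(cy_), a(a_), b(b_), th(th_), ct(std::cos(th_)), st(std::sin(th_)) {}
  // implicit conic Axx x^2 + Axy xy + Ayy y^2 + Bx x + By y + C, interior < 0
  void conic(double &Axx, double &Axy, double &Ayy,
             double &Bx, double &By, double &C) const {
    double ia2 = 1.0 / (a * a), ib2 = 1.0 / (b * b);
    double A2 = ct * ct * ia2 + st * st * ib2;
    double B2 = 2.0 * ct * st * (ia2 - ib2);
    double C2 = st * st * ia2 + ct * ct * ib2;
    Axx = A2;
    Axy = B2;
    Ayy = C2;
    Bx = -2.0 * A2 * cx - B2 * cy;
    By = -B2 * cx - 2.0 * C2 * cy;
    C = A2 * cx * cx + B2 * cx * cy + C2 * cy * cy - 1.0;
  }
  double implicit_at(double x, double y) const {
    double u = ct * (x - cx) + st * (y - cy);
    double v = -st * (x - cx) + ct * (y - cy);
    return (u * u) / (a * a) + (v * v) / (b * b) - 1.0;
  }
  bool inside(double x, double y) const { return implicit_at(x, y) < 0.0; }
  // containment tests use a tolerant predicate so the coincident-boundary
  // limit counts as inside
  bool inside_tol(double x, double y) const { return implicit_at(x, y) <= 1e-12; }
  // boundary point at parametric angle t (counter-clockwise)
  void point_at(double t, double &x, double &y) const {
    double u = a * std::cos(t), v = b * std::sin(t);
    x = cx + ct * u - st * v;
    y = cy + st * u + ct * v;
  }
  double param_of(double x, double y) const {
    double u = ct * (x - cx) + st * (y - cy);
    double v = -st * (x - cx) + ct * (y - cy);
    return std::atan2(v / b, u / a);
  }
  double area() const { return M_PI * a * b; }
};

// real roots of c4 x^4 + c3 x^3 + c2 x^2 + c1 x + c0 via companion eigenvalues
static void poly_real_roots(double c4, double c3, double c2, double c1, double c0,
                            std::vector<double> &roots) {
  double coef[5] = {c0, c1, c2, c3, c4};
  int deg = 4;
  double scale = 0.0;
  for (int i = 0; i <= 4; ++i) scale = std::max(scale, std::fabs(coef[i]));
  if (scale == 0.0) return;
  while (deg > 0 && std::fabs(coef[deg]) < 1e-14 * scale) --deg;
  if (deg == 0) return;
  if (deg == 1) {
    roots.push_back(-coef[0] / coef[1]);
    return;
  }
  arma::mat Cm(deg, deg, arma::fill::zeros);
  for (int i = 0; i < deg; ++i) Cm(0, i) = -coef[deg - 1 - i] / coef[deg];
  for (int i = 1; i < deg; ++i) Cm(i, i - 1) = 1.0;
  arma::cx_vec ev;
  if (!arma::eig_gen(ev, Cm)) return;
  for (arma::uword i = 0; i < ev.n_elem; ++i) {
    double re = ev(i).real(), im = ev(i).imag();
    // repeated roots perturb into conjugate pairs with imaginary parts of
    // order sqrt(machine eps); keep near-real candidates and let the Newton
    // refinement plus the residual check weed out spurious ones
    if (std::fabs(im) < 1e-4 * (1.0 + std::fabs(re))) roots.push_back(re);
  }
}

struct IsectPoint {
  double x, y;
  bool tangential;
};

// transversal + tangential boundary intersection points of two ellipses
static void intersect_pair(const Ell &e1, const Ell &e2, std::vector<IsectPoint> &out) {
  // map e1 to the unit circle: orig = c1 + M p, M = R(th1) diag(a1,b1)
  double m00 = e1.a * e1.ct, m01 = -e1.b * e1.st;
  double m10 = e1.a * e1.st, m11 = e1.b * e1.ct;
  double Axx, Axy, Ayy, Bx, By, C;
  e2.conic(Axx, Axy, Ayy, Bx, By, C);
  // conic of e2 in the unit frame
  double A00 = Axx, A01 = 0.5 * Axy, A11 = Ayy;
  // A' = M^T A M
  double AM00 = A00 * m00 + A01 * m10, AM01 = A00 * m01 + A01 * m11;
  double AM10 = A01 * m00 + A11 * m10, AM11 = A01 * m01 + A11 * m11;
  double Ap00 = m00 * AM00 + m10 * AM10;
  double Ap01 = m00 * AM01 + m10 * AM11;
  double Ap11 = m01 * AM01 + m11 * AM11;
  // b' = M^T (2 A t + b), t = centre of e1
  double w0 = 2.0 * (A00 * e1.cx + A01 * e1.cy) + Bx;
  double w1 = 2.0 * (A01 * e1.cx + A11 * e1.cy) + By;
  double bp0 = m00 * w0 + m10 * w1;
  double bp1 = m01 * w0 + m11 * w1;
  double cp = A00 * e1.cx * e1.cx + 2.0 * A01 * e1.cx * e1.cy + A11 * e1.cy * e1.cy +
              Bx * e1.cx + By * e1.cy + C;
  // unit-frame conic: AA x^2 + BB xy + CC y^2 + DD x + EE y + FF
  double AA = Ap00, BB = 2.0 * Ap01, CC = Ap11, DD = bp0, EE = bp1, FF = cp;
  // eliminate y against x^2 + y^2 = 1:
  // (a2 x^2 + a1 x + a0)^2 + (x^2 - 1)(b1 x + b0)^2 = 0
  double a2 = AA - CC, a1 = DD, a0 = CC + FF, b1c = BB, b0c = EE;
  double c4 = a2 * a2 + b1c * b1c;
  double c3 = 2.0 * a2 * a1 + 2.0 * b1c * b0c;
  double c2 = a1 * a1 + 2.0 * a2 * a0 + b0c * b0c - b1c * b1c;
  double c1 = 2.0 * a1 * a0 - 2.0 * b1c * b0c;
  double c0 = a0 * a0 - b0c * b0c;
  std::vector<double> xs;
  poly_real_roots(c4, c3, c2, c1, c0, xs);

  std::vector<std::pair<double, double>> cand;
  for (double x : xs) {
    if (x < -1.0 - 1e-7 || x > 1.0 + 1e-7) continue;
    double xc = std::max(-1.0, std::min(1.0, x));
    double denom = b1c * xc + b0c;
    double yabs = std::sqrt(std::max(0.0, 1.0 - xc * xc));
    if (std::fabs(denom) > 1e-10) {
      double y = -(a2 * xc * xc + a1 * xc + a0) / denom;
      cand.push_back({xc, y});
    } else {
      cand.push_back({xc, yabs});
      cand.push_back({xc, -yabs});
    }
  }
  // Newton refinement on F1 = x^2 + y^2 - 1, F2 = unit-frame conic
  std::vector<std::pair<double, double>> pts;
  for (auto &p : cand) {
    double x = p.first, y = p.second;
    bool ok = true;
    for (int it = 0; it < 12; ++it) {
      double F1 = x * x + y * y - 1.0;
      double F2 = AA * x * x + BB * x * y + CC * y * y + DD * x + EE * y + FF;
      if (std::fabs(F1) < 1e-14 && std::fabs(F2) < 1e-13 * (1.0 + std::fabs(FF))) break;
      double J00 = 2.0 * x, J01 = 2.0 * y;
      double J10 = 2.0 * AA * x + BB * y + DD, J11 = BB * x + 2.0 * CC * y + EE;
      double det = J00 * J11 - J01 * J10;
      if (std::fabs(det) < 1e-14) break;
      double dx = (F1 * J11 - F2 * J01) / det;
      double dy = (J00 * F2 - J10 * F1) / det;
      x -= dx;
      y -= dy;
      if (!std::isfinite(x) || !std::isfinite(y)) { ok = false; break; }
    }
    if (!ok) continue;
    double F1 = x * x + y * y - 1.0;
    double F2 = AA * x * x + BB * x * y + CC * y * y + DD * x + EE * y + FF;
    double fscale = std::fabs(AA) + std::fabs(BB) + std::fabs(CC) +
                    std::fabs(DD) + std::fabs(EE) + std::fabs(FF);
    if (std::fabs(F1) > 1e-8 || std::fabs(F2) > 1e-7 * (1.0 + fscale)) continue;
    bool dup = false;
    for (auto &q : pts)
      if (std::fabs(q.first - x) < DEDUP_TOL && std::fabs(q.second - y) < DEDUP_TOL) dup = true;
    if (!dup) pts.push_back({x, y});
  }
  // back to the original frame; classify transversality by gradient angle
  double A1xx, A1xy, A1yy, B1x, B1y, C1;
  e1.conic(A1xx, A1xy, A1yy, B1x, B1y, C1);
  for (auto &p : pts) {
    double ox = e1.cx + m00 * p.first + m01 * p.second;
    double oy = e1.cy + m10 * p.first + m11 * p.second;
    double g1x = 2.0 * A1xx * ox + A1xy * oy + B1x;
    double g1y = A1xy * ox + 2.0 * A1yy * oy + B1y;
    double g2x = 2.0 * Axx * ox + Axy * oy + Bx;
    double g2y = Axy * ox + 2.0 * Ayy * oy + By;
    double n1 = std::hypot(g1x, g1y), n2 = std::hypot(g2x, g2y);
    bool tang = true;
    if (n1 > 0 && n2 > 0) {
      double cross = (g1x * g2y - g1y * g2x) / (n1 * n2);
      tang = std::fabs(cross) < TANGENT_TOL;
    }
    out.push_back({ox, oy, tang});
  }
}

// Green's theorem contribution of the boundary arc of `e` from t1 to t2 (ccw)
static double arc_contrib(const Ell &e, double t1, double t2) {
  if (t2 < t1) t2 += 2.0 * M_PI;
  double dt = t2 - t1;
  double u1 = e.a * std::cos(t1), v1 = e.b * std::sin(t1);
  double u2 = e.a * std::cos(t2), v2 = e.b * std::sin(t2);
  double p1 = e.ct * u1 - e.st * v1, q1 = e.st * u1 + e.ct * v1;
  double p2 = e.ct * u2 - e.st * v2, q2 = e.st * u2 + e.ct * v2;
  return 0.5 * (e.a * e.b * dt + e.cx * (q2 - q1) - e.cy * (p2 - p1));
}

// overlap area of two ellipses (containment and disjointness included)
static double pair_area(const Ell &e1, const Ell &e2) {
  std::vector<IsectPoint> pts;
  intersect_pair(e1, e2, pts);
  std::vector<std::pair<double, double>> tr;
  for (auto &p : pts)
    if (!p.tangential) tr.push_back({p.x, p.y});
  if (tr.size() < 2) {
    double x0, y0;
    e1.point_at(0.0, x0, y0);
    if (e2.inside_tol(x0, y0)) return std::min(e1.area(), e2.area());
    e2.point_at(0.0, x0, y0);
    if (e1.inside_tol(x0, y0)) return e2.area();
    return 0.0;
  }
  double total = 0.0;
  const Ell *self[2] = {&e1, &e2};
  const Ell *other[2] = {&e2, &e1};
  for (int k = 0; k < 2; ++k) {
    std::vector<double> ang;
    for (auto &p : tr) ang.push_back(self[k]->param_of(p.first, p.second));
    std::sort(ang.begin(), ang.end());
    size_t n = ang.size();
    for (size_t i = 0; i < n; ++i) {
      double t1 = ang[i];
      double t2 = (i + 1 < n) ? ang[i + 1] : ang[0] + 2.0 * M_PI;
      double tm = 0.5 * (t1 + t2);
      double xm, ym;
      self[k]->point_at(tm, xm, ym);
      if (other[k]->inside(xm, ym)) total += arc_contrib(*self[k], t1, t2);
    }
  }
  return std::max(total, 0.0);
}

// area of e1 ∩ e2 ∩ e3
static double triple_area(const Ell &e1, const Ell &e2, const Ell &e3) {
  const Ell *E[3] = {&e1, &e2, &e3};
  // angles of all boundary intersection points, per ellipse
  std::vector<double> ang[3];
  int pair_i[3] = {0, 0, 1}, pair_j[3] = {1, 2, 2};
  for (int p = 0; p < 3; ++p) {
    std::vector<IsectPoint> pts;
    intersect_pair(*E[pair_i[p]], *E[pair_j[p]], pts);
    for (auto &q : pts) {
      if (q.tangential) continue;
      ang[pair_i[p]].push_back(E[pair_i[p]]->param_of(q.x, q.y));
      ang[pair_j[p]].push_back(E[pair_j[p]]->param_of(q.x, q.y));
    }
  }
  // a curve with no boundary intersection points at all either lies wholly
  // inside the other two (its full boundary bounds the triple region) or
  // contributes nothing; when several such curves are nested/coincident
  // only the smallest (ties by index) is the region boundary
  bool whole[3] = {false, false, false};
  for (int k = 0; k < 3; ++k) {
    if (!ang[k].empty()) continue;
    double x0, y0;
    E[k]->point_at(0.0, x0, y0);
    whole[k] = E[(k + 1) % 3]->inside_tol(x0, y0) &&
               E[(k + 2) % 3]->inside_tol(x0, y0);
  }
  int whole_pick = -1;
  for (int k = 0; k < 3; ++k)
    if (whole[k] && (whole_pick < 0 || E[k]->area() < E[whole_pick]->area()))
      whole_pick = k;
  double total = 0.0;
  if (whole_pick >= 0) total += E[whole_pick]->area();
  for (int k = 0; k < 3; ++k) {
    const Ell *oa = E[(k + 1) % 3], *ob = E[(k + 2) % 3];
    if (ang[k].empty()) continue;
    std::sort(ang[k].begin(), ang[k].end());
    size_t n = ang[k].size();
    for (size_t i = 0; i < n; ++i) {
      double t1 = ang[k][i];
      double t2 = (i + 1 < n) ? ang[k][i + 1] : ang[k][0] + 2.0 * M_PI;
      double tm = 0.5 * (t1 + t2);
      double xm, ym;
      E[k]->point_at(tm, xm, ym);
      if (oa->inside(xm, ym) && ob->inside(xm, ym)) total += arc_contrib(*E[k], t1, t2);
    }
  }
  return std::max(total, 0.0);
}

static Ell ell_from_row(const double *E, int i) {
  // column-major 3x5: cx, cy, s1, s2, theta
  return Ell(E[i], E[3 + i], E[6 + i], E[9 + i], E[12 + i]);
}

struct RegionResult {
  double areas[7]; // a, b, c, ab, ac, bc, abc
  int npts[3];     // transversal counts for ab, ac, bc
  bool tang[3];
  bool consistent;
};

static void region_areas_core(const Ell &ea, const Ell &eb, const Ell &ec, RegionResult &r) {
  const Ell *E[3] = {&ea, &eb, &ec};
  int pi[3] = {0, 0, 1}, pj[3] = {1, 2, 2};
  for (int p = 0; p < 3; ++p) {
    std::vector<IsectPoint> pts;
    intersect_pair(*E[pi[p]], *E[pj[p]], pts);
    int nt = 0;
    bool tg = false;
    for (auto &q : pts) {
      if (q.tangential) tg = true; else ++nt;
    }
    r.npts[p] = nt;
    r.tang[p] = tg;
  }
  double Aa = ea.area(), Ab = eb.area(), Ac = ec.area();
  double Iab = pair_area(ea, eb), Iac = pair_area(ea, ec), Ibc = pair_area(eb, ec);
  double T = triple_area(ea, eb, ec);
  double raw[7] = {Aa - Iab - Iac + T, Ab - Iab - Ibc + T, Ac - Iac - Ibc + T,
                   Iab - T, Iac - T, Ibc - T, T};
  double tol = 1e-9 * (Aa + Ab + Ac);
  r.consistent = true;
  for (int i = 0; i < 7; ++i) {
    if (raw[i] < 0) {
      if (raw[i] < -tol) r.consistent = false;
      raw[i] = 0.0;
    }
    r.areas[i] = raw[i];
  }
}

// valid 3-Venn topology: every pair crosses transversally in exactly two
// points (so the arrangement has 6 vertices, 12 edges and, being connected,
// exactly 8 faces) and all seven signature areas are positive, which then
// pins one face per signature: no region can be split.
static bool topology_valid(const RegionResult &r, int &reason) {
  for (int p = 0; p < 3; ++p) {
    if (r.tang[p] || r.npts[p] != 2) { reason = 1; return false; }
  }
  if (!r.consistent) { reason = 3; return false; }
  double tot = 0.0;
  for (int i = 0; i < 7; ++i) tot += r.areas[i];
  if (tot <= 0) { reason = 2; return false; }
  for (int i = 0; i < 7; ++i)
    if (r.areas[i] <= REGION_FLOOR * tot) { reason = 2; return false; }
  reason = 0;
  return true;
}

static double diag_error_core(const double *A, const double *w) {
  double sa = 0.0, sw = 0.0;
  for (int i = 0; i < 7; ++i) { sa += A[i]; sw += w[i]; }
  double m = 0.0;
  for (int i = 0; i < 7; ++i)
    m = std::max(m, std::fabs(A[i] / sa - w[i] / sw));
  return m;
}

static double cost_f6_core(const double *A, const double *wp) {
  double s = 0.0;
  for (int i = 0; i < 7; ++i) {
    if (A[i] <= 0.0) return R_PosInf;
    double d = wp[i] - A[i];
    s += d * d / A[i];
  }
  return s / 7.0;
}

// [[Rcpp::export(name = ".ell_intersect_cpp")]]
List ell_intersect_cpp(NumericVector e1, NumericVector e2) {
  Ell a(e1[0], e1[1], e1[2], e1[3], e1[4]);
  Ell b(e2[0], e2[1], e2[2], e2[3], e2[4]);
  std::vector<IsectPoint> pts;
  intersect_pair(a, b, pts);
  NumericMatrix P(pts.size(), 2);
  LogicalVector tang(pts.size());
  for (size_t i = 0; i < pts.size(); ++i) {
    P(i, 0) = pts[i].x;
    P(i, 1) = pts[i].y;
    tang[i] = pts[i].tangential;
  }
  return List::create(_["points"] = P, _["tangential"] = tang);
}

// [[Rcpp::export(name = ".pair_area_cpp")]]
double pair_area_cpp(NumericVector e1, NumericVector e2) {
  Ell a(e1[0], e1[1], e1[2], e1[3], e1[4]);
  Ell b(e2[0], e2[1], e2[2], e2[3], e2[4]);
  return pair_area(a, b);
}

// [[Rcpp::export(name = ".triple_area_cpp")]]
double triple_area_cpp(NumericVector e1, NumericVector e2, NumericVector e3) {
  Ell a(e1[0], e1[1], e1[2], e1[3], e1[4]);
  Ell b(e2[0], e2[1], e2[2], e2[3], e2[4]);
  Ell c(e3[0], e3[1], e3[2], e3[3], e3[4]);
  return triple_area(a, b, c);
}

// [[Rcpp::export(name = ".region_areas_cpp")]]
List region_areas_cpp(NumericMatrix E) {
  RegionResult r;
  region_areas_core(ell_from_row(E.begin(), 0), ell_from_row(E.begin(), 1),
                    ell_from_row(E.begin(), 2), r);
  int reason = 0;
  bool valid = topology_valid(r, reason);
  NumericVector A(7);
  for (int i = 0; i < 7; ++i) A[i] = r.areas[i];
  IntegerVector np(3);
  LogicalVector tg(3);
  for (int i = 0; i < 3; ++i) { np[i] = r.npts[i]; tg[i] = r.tang[i]; }
  return List::create(_["areas"] = A, _["valid"] = valid, _["reason"] = reason,
                      _["pair_points"] = np, _["tangential"] = tg,
                      _["consistent"] = r.consistent);
}

// [[Rcpp::export(name = ".diag_error_cpp")]]
double diag_error_cpp(NumericVector areas, NumericVector w) {
  return diag_error_core(areas.begin(), w.begin());
}

struct DiagState {
  Ell e[3];
  DiagState(const NumericMatrix &E)
    : e{ell_from_row(E.begin(), 0), ell_from_row(E.begin(), 1), ell_from_row(E.begin(), 2)} {}
};

static double eval_cost(const Ell e[3], const double *wp, double *diag_err,
                        const double *w) {
  RegionResult r;
  region_areas_core(e[0], e[1], e[2], r);
  int reason;
  if (!topology_valid(r, reason)) {
    if (diag_err) *diag_err = NA_REAL;
    return R_PosInf;
  }
  if (diag_err) *diag_err = diag_error_core(r.areas, w);
  return cost_f6_core(r.areas, wp);
}

static bool is_good_state(const Ell e[3], const double *w, double *diag_err) {
  RegionResult r;
  region_areas_core(e[0], e[1], e[2], r);
  int reason;
  bool valid = topology_valid(r, reason);
  double de = valid ? diag_error_core(r.areas, w) : NA_REAL;
  if (diag_err) *diag_err = de;
  return valid && de <= GOOD_EPS;
}

static double canon_theta(double th) {
  th -= M_PI * std::floor(th / M_PI);
  if (th >= M_PI) th -= M_PI; // guard against round-off at the boundary
  if (th < 0) th = 0.0;
  return th;
}

// Hill climb: greedy sequential acceptance in fixed order (ellipse a,b,c;
// centres, then semi-axes, then rotations), halving cooling schedule,
// termination when all three step parameters fall to eps = 1e-6.
// [[Rcpp::export(name = ".hill_climb_cpp")]]
List hill_climb_cpp(NumericMatrix E0, NumericVector w, NumericVector wp,
                    double p_gamma, double p_ab, double p_theta,
                    bool circles, bool audit, int max_iter) {
  Ell cur[3] = {ell_from_row(E0.begin(), 0), ell_from_row(E0.begin(), 1),
                ell_from_row(E0.begin(), 2)};
  const double eps = 1e-6;
  double de0;
  if (is_good_state(cur, w.begin(), &de0)) {
    NumericMatrix Eout(3, 5);
    for (int i = 0; i < 3; ++i) {
      Eout(i, 0) = cur[i].cx; Eout(i, 1) = cur[i].cy; Eout(i, 2) = cur[i].a;
      Eout(i, 3) = cur[i].b; Eout(i, 4) = cur[i].th;
    }
    return List::create(_["diagram"] = Eout, _["iterations"] = 0,
                        _["accurate"] = true, _["diag_error"] = de0,
                        _["cost"] = eval_cost(cur, wp.begin(), nullptr, w.begin()),
                        _["audit"] = R_NilValue);
  }
  double cur_cost = eval_cost(cur, wp.begin(), nullptr, w.begin());
  std::vector<double> audit_rows; // iter, ell, class, cost_before, cost_after
  int iter = 0;
  bool accurate = false;
  while (true) {
    ++iter;
    bool ch_c = false, ch_s = false, ch_r = false;
    for (int i = 0; i < 3; ++i) {
      // centres: E, W, N, S, NE, NW, SE, SW
      const double dx[8] = {1, -1, 0, 0, 1, -1, 1, -1};
      const double dy[8] = {0, 0, 1, -1, 1, 1, -1, -1};
      for (int k = 0; k < 8; ++k) {
        Ell cand[3] = {cur[0], cur[1], cur[2]};
        cand[i].cx = cur[i].cx + dx[k] * p_gamma;
        cand[i].cy = cur[i].cy + dy[k] * p_gamma;
        double c = eval_cost(cand, wp.begin(), nullptr, w.begin());
        if (c < cur_cost) {
          if (audit) {
            audit_rows.push_back(iter); audit_rows.push_back(i + 1);
            audit_rows.push_back(1); audit_rows.push_back(cur_cost);
            audit_rows.push_back(c);
          }
          cur[i] = cand[i];
          cur_cost = c;
          ch_c = true;
        }
      }
      // semi-axes
      double f1[8], f2[8];
      int nax;
      if (circles) {
        nax = 2;
        f1[0] = f2[0] = 1.0 + p_ab;
        f1[1] = f2[1] = 1.0 - p_ab;
      } else {
        nax = 8;
        const double g1[8] = {1 + p_ab, 1 - p_ab, 1, 1, 1 + p_ab, 1 - p_ab, 1 + p_ab, 1 - p_ab};
        const double g2[8] = {1, 1, 1 + p_ab, 1 - p_ab, 1 + p_ab, 1 - p_ab, 1 - p_ab, 1 + p_ab};
        for (int k = 0; k < 8; ++k) { f1[k] = g1[k]; f2[k] = g2[k]; }
      }
      for (int k = 0; k < nax; ++k) {
        Ell cand[3] = {cur[0], cur[1], cur[2]};
        cand[i].a = cur[i].a * f1[k];
        cand[i].b = cur[i].b * f2[k];
        double c = eval_cost(cand, wp.begin(), nullptr, w.begin());
        if (c < cur_cost) {
          if (audit) {
            audit_rows.push_back(iter); audit_rows.push_back(i + 1);
            audit_rows.push_back(2); audit_rows.push_back(cur_cost);
            audit_rows.push_back(c);
          }
          cur[i] = cand[i];
          cur_cost = c;
          ch_s = true;
        }
      }
      // rotations (skipped for circles)
      if (!circles) {
        for (int k = 0; k < 2; ++k) {
          Ell cand[3] = {cur[0], cur[1], cur[2]};
          double th = canon_theta(cur[i].th + (k == 0 ? p_theta : -p_theta));
          cand[i] = Ell(cur[i].cx, cur[i].cy, cur[i].a, cur[i].b, th);
          double c = eval_cost(cand, wp.begin(), nullptr, w.begin());
          if (c < cur_cost) {
            if (audit) {
              audit_rows.push_back(iter); audit_rows.push_back(i + 1);
              audit_rows.push_back(3); audit_rows.push_back(cur_cost);
              audit_rows.push_back(c);
            }
            cur[i] = cand[i];
            cur_cost = c;
            ch_r = true;
          }
        }
      }
    }
    if (!ch_c) p_gamma *= 0.5;
    if (!ch_s) p_ab *= 0.5;
    if (!ch_r) p_theta *= 0.5;
    if (p_gamma <= eps && p_ab <= eps && p_theta <= eps) {
      accurate = false;
      break;
    }
    if (is_good_state(cur, w.begin(), nullptr)) {
      accurate = true;
      break;
    }
    if (iter >= max_iter) {
      accurate = false;
      break;
    }
  }
  double de_final;
  is_good_state(cur, w.begin(), &de_final);
  NumericMatrix Eout(3, 5);
  for (int i = 0; i < 3; ++i) {
    Eout(i, 0) = cur[i].cx; Eout(i, 1) = cur[i].cy; Eout(i, 2) = cur[i].a;
    Eout(i, 3) = cur[i].b; Eout(i, 4) = cur[i].th;
  }
  SEXP audit_out = R_NilValue;
  if (audit) {
    size_t nr = audit_rows.size() / 5;
    NumericMatrix Am(nr, 5);
    for (size_t r = 0; r < nr; ++r)
      for (int c = 0; c < 5; ++c) Am(r, c) = audit_rows[r * 5 + c];
    colnames(Am) = CharacterVector::create("iteration", "ellipse", "move_class",
                                           "cost_before", "cost_after");
    audit_out = Am;
  }
  return List::create(_["diagram"] = Eout, _["iterations"] = iter,
                      _["accurate"] = accurate, _["diag_error"] = de_final,
                      _["cost"] = cur_cost, _["audit"] = audit_out);
}
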