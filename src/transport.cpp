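// Lagrangian gas-tracer engine: Poiseuille advection with RK4 and
// sub-stepped random-walk molecular diffusion inside a branching network
// of cylinders and trumpet sections.
//
// Units: mm, ms, mm^3; flows in mm^3/ms (numerically equal to ml/s).
// All randomness uses R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Geom {
  IntegerVector parent, child1, child2, compOf, isTrumpet;
  NumericVector len;
  IntegerVector profOff, profN;
  NumericVector profEnd, profR, profA;   // piecewise profile per element
};

Geom unpackGeom(const List& g) {
  Geom G;
  G.parent = g["parent"];     G.child1 = g["child1"];
  G.child2 = g["child2"];     G.compOf = g["compOf"];
  G.isTrumpet = g["isTrumpet"];
  G.len = g["len"];
  G.profOff = g["profOff"];   G.profN = g["profN"];
  G.profEnd = g["profEnd"];   G.profR = g["profR"];
  G.profA = g["profA"];
  return G;
}

// piece index of axial position z within element e
inline int pieceAt(const Geom& G, int e, double z) {
  int off = G.profOff[e], n = G.profN[e];
  for (int p = 0; p < n - 1; ++p)
    if (z <= G.profEnd[off + p]) return off + p;
  return off + n - 1;
}
inline double localR(const Geom& G, int e, double z) {
  return G.profR[pieceAt(G, e, z)];
}
inline double localA(const Geom& G, int e, double z) {
  return G.profA[pieceAt(G, e, z)];
}
// area of an element at one of its ends (junction side)
inline double endArea(const Geom& G, int e, bool distal) {
  int off = G.profOff[e], n = G.profN[e];
  return G.profA[distal ? off + n - 1 : off];
}

// periodic linear interpolation of element flow
inline double flowAt(const NumericMatrix& Q, const NumericVector& qt,
                     double period, int e, double t) {
  int nT = qt.size();
  if (nT == 1) return Q(e, 0);
  double tt = t - period * std::floor(t / period);  // periodic wrap
  if (tt < 0) tt += period;
  if (tt >= period) tt = 0;
  // find interval: qt ascending within [0, period)
  int lo = 0, hi = nT;  // last index with qt[i] <= tt
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (qt[mid] <= tt) lo = mid; else hi = mid;
  }
  int nxt = (lo + 1) % nT;
  double t1 = qt[lo];
  double t2 = (lo + 1 < nT) ? qt[lo + 1] : qt[0] + period;
  double f = (t2 > t1) ? (tt - t1) / (t2 - t1) : 0.0;
  return (1 - f) * Q(e, lo) + f * Q(e, nxt);
}

// axial velocity at (z, rrel): parabolic profile on the local mean Q/A
inline double axialVel(const Geom& G, const NumericMatrix& Q,
                       const NumericVector& qt, double period,
                       int e, double z, double rrel, double t) {
  double L = G.len[e];
  double zc = z < 0 ? 0 : (z > L ? L : z);
  double A = localA(G, e, zc);
  return 2.0 * flowAt(Q, qt, period, e, t) / A * (1.0 - rrel * rrel);
}

inline double unif() { return R::unif_rand(); }

// uniform direction on the sphere
inline void randDir(double& dx, double& dy, double& dz) {
  double c = 2.0 * unif() - 1.0;
  double phi = 2.0 * M_PI * unif();
  double s = std::sqrt(std::max(0.0, 1.0 - c * c));
  dx = s * std::cos(phi);
  dy = s * std::sin(phi);
  dz = c;
}

} // namespace

// One advection step of length dt for every tracer.
// status: 0 in-airway, 1 expired at the trachea opening, 2 absorbed into
// a terminal compartment (compartment index in comp).
// [[Rcpp::export]]
List cpp_advect(IntegerVector elem, NumericVector z, NumericVector rrel,
                NumericVector theta, List geomList, NumericMatrix Q,
                NumericVector qtimes, double period, double t0, double dt) {
  Geom G = unpackGeom(geomList);
  int n = elem.size();
  IntegerVector el = clone(elem);
  NumericVector zz = clone(z), rr = clone(rrel), th = clone(theta);
  IntegerVector status(n), comp(n, -1);
  int held = 0;

  for (int i = 0; i < n; ++i) {
    int e = el[i] - 1;               // 0-based element
    double zi = zz[i], ri = rr[i];
    double remaining = dt, tcur = t0;
    for (int iter = 0; iter < 200 && remaining > 1e-12; ++iter) {
      double L = G.len[e];
      // RK4 over the remaining step inside the current element
      double h = remaining;
      double k1 = axialVel(G, Q, qtimes, period, e, zi, ri, tcur);
      double k2 = axialVel(G, Q, qtimes, period, e, zi + 0.5 * h * k1, ri,
                           tcur + 0.5 * h);
      double k3 = axialVel(G, Q, qtimes, period, e, zi + 0.5 * h * k2, ri,
                           tcur + 0.5 * h);
      double k4 = axialVel(G, Q, qtimes, period, e, zi + h * k3, ri,
                           tcur + h);
      double znew = zi + h / 6.0 * (k1 + 2 * k2 + 2 * k3 + k4);
      if (znew >= 0 && znew <= L) {
        zi = znew; tcur += h; remaining = 0; break;
      }
      // crossed an end: linear estimate of the crossing fraction
      double bound = znew < 0 ? 0.0 : L;
      double f = (bound - zi) / (znew - zi);
      if (f < 0) f = 0;
      if (f > 1) f = 1;
      tcur += f * h;
      remaining = h * (1 - f);
      zi = bound;
      if (znew < 0) {                      // proximal exit
        if (G.parent[e] < 0) {             // trachea opening
          status[i] = 1; remaining = 0; break;
        }
        int p = G.parent[e];
        if (G.child2[p] < 0) {             // trumpet -> terminal cylinder
          e = p; zi = G.len[e];
          continue;
        }
        int sib = (G.child1[p] == e) ? G.child2[p] : G.child1[p];
        double qp = flowAt(Q, qtimes, period, p, tcur);
        double qs = flowAt(Q, qtimes, period, sib, tcur);
        double wp = qp < 0 ? -qp : 0.0;    // parent carries flow away
        double ws = qs > 0 ? qs : 0.0;     // sibling carries flow away
        if (wp + ws <= 0) { ++held; remaining = 0; break; }
        if (unif() < wp / (wp + ws)) { e = p; zi = G.len[e]; }
        else { e = sib; zi = 0.0; }
        th[i] = 2.0 * M_PI * unif();       // azimuth randomized on routing
      } else {                             // distal exit
        if (G.compOf[e] >= 0) {            // trumpet end: acinus
          status[i] = 2; comp[i] = G.compOf[e]; remaining = 0; break;
        }
        if (G.child1[e] < 0) {             // sealed end: hold
          ++held; remaining = 0; break;
        }
        if (G.child2[e] < 0) {             // terminal cylinder -> trumpet
          e = G.child1[e]; zi = 0.0;
          continue;
        }
        int c1 = G.child1[e], c2 = G.child2[e];
        double q1 = flowAt(Q, qtimes, period, c1, tcur);
        double q2 = flowAt(Q, qtimes, period, c2, tcur);
        double w1 = q1 > 0 ? q1 : 0.0, w2 = q2 > 0 ? q2 : 0.0;
        if (w1 + w2 <= 0) { ++held; remaining = 0; break; }
        e = (unif() < w1 / (w1 + w2)) ? c1 : c2;
        zi = 0.0;
        th[i] = 2.0 * M_PI * unif();
      }
    }
    el[i] = e + 1; zz[i] = zi; rr[i] = ri;
  }
  return List::create(_["elem"] = el, _["z"] = zz, _["rrel"] = rr,
                      _["theta"] = th, _["status"] = status,
                      _["comp"] = comp, _["held"] = held);
}

// One diffusion step (subSteps random-walk sub-steps of variance 6*D*tau
// each) for every tracer. relabel[i] = 1 when the tracer crossed the
// trachea opening by diffusion and was replaced by a mirrored fresh-gas
// tracer (the caller flips its type to B and counts one expiration + one
// injection). A diffusive crossing into a terminal compartment is an
// exchange: the tracer joins the tally and one tracer sampled in
// proportion to the tally contents returns at the mirrored position
// (bidirectional diffusive flux across the acinar mouth, zero net
// volume); type and the tallies are updated in place.
// [[Rcpp::export]]
List cpp_diffuse(IntegerVector elem, NumericVector z, NumericVector rrel,
                 NumericVector theta, IntegerVector type,
                 NumericVector tallyA, NumericVector tallyB,
                 List geomList, double D, double dt,
                 int subSteps, int maxRetries) {
  Geom G = unpackGeom(geomList);
  int n = elem.size();
  IntegerVector el = clone(elem);
  NumericVector zz = clone(z), rr = clone(rrel), th = clone(theta);
  IntegerVector tp = clone(type);
  NumericVector tA = clone(tallyA), tB = clone(tallyB);
  IntegerVector status(n), comp(n, -1), relabel(n);
  int forfeited = 0, exchanged = 0;
  if (D <= 0 || subSteps < 1)
    return List::create(_["elem"] = el, _["z"] = zz, _["rrel"] = rr,
                        _["theta"] = th, _["type"] = tp,
                        _["tallyA"] = tA, _["tallyB"] = tB,
                        _["status"] = status,
                        _["comp"] = comp, _["relabel"] = relabel,
                        _["forfeited"] = 0, _["exchanged"] = 0);
  double tau = dt / subSteps;
  double sigma = std::sqrt(6.0 * D * tau);

  for (int i = 0; i < n; ++i) {
    int e = el[i] - 1;
    double R0 = localR(G, e, zz[i]);
    double x = rr[i] * R0 * std::cos(th[i]);
    double y = rr[i] * R0 * std::sin(th[i]);
    double zi = zz[i];
    bool done = false;

    for (int s = 0; s < subSteps && !done; ++s) {
      double ell = std::fabs(R::norm_rand()) * sigma;
      double dx, dy, dz;
      randDir(dx, dy, dz);
      int retries = 0;
      while (ell > 1e-14) {
        double L = G.len[e];
        double R = localR(G, e, zi);
        double px = x + dx * ell, py = y + dy * ell, pz = zi + dz * ell;
        // first crossing: wall (radial) or axial end
        double fwall = 2.0, fax = 2.0;
        double a = (dx * dx + dy * dy) * ell * ell;
        if (a > 0) {
          double b = 2.0 * ell * (x * dx + y * dy);
          double c = x * x + y * y - R * R;
          double disc = b * b - 4.0 * a * c;
          if (disc >= 0) {
            double f = (-b + std::sqrt(disc)) / (2.0 * a);
            if (f >= 0 && f <= 1) fwall = f;
          }
        }
        if (pz < 0)      fax = (0.0 - zi) / (dz * ell);
        else if (pz > L) fax = (L - zi) / (dz * ell);
        if (fwall > 1 && fax > 1) {        // move stays inside
          x = px; y = py; zi = pz; ell = 0; break;
        }
        if (fwall <= fax) {                // wall collision
          x += dx * ell * fwall; y += dy * ell * fwall;
          zi += dz * ell * fwall;
          double rn = std::sqrt(x * x + y * y);
          if (rn > 0) {                    // nudge just inside the wall
            double sc = (R * (1.0 - 1e-9)) / rn;
            if (sc < 1.0) { x *= sc; y *= sc; }
          }
          ell *= (1.0 - fwall);
          // direction randomly reset, restricted to the interior
          // half-space at the collision point
          randDir(dx, dy, dz);
          double rn2 = std::sqrt(x * x + y * y);
          if (rn2 > 0 && (dx * x + dy * y) / rn2 > 0) { dx = -dx; dy = -dy; }
          if (++retries > maxRetries) { ++forfeited; ell = 0; break; }
          continue;
        }
        // axial crossing
        x += dx * ell * fax; y += dy * ell * fax; zi += dz * ell * fax;
        ell *= (1.0 - fax);
        bool proximal = dz < 0;
        if (proximal) {
          if (G.parent[e] < 0) {
            // trachea opening: fresh-gas reservoir. Reflect and relabel:
            // the exiting tracer is expired and replaced by an incoming
            // Type B tracer at the mirrored position.
            dz = -dz; zi = 1e-12;
            relabel[i] = 1;
            continue;
          }
          int p = G.parent[e];
          if (G.child2[p] < 0) {           // trumpet -> terminal cylinder
            double rrelKeep = std::sqrt(x * x + y * y) / R;
            e = p;
            double Rn = localR(G, e, G.len[e]);
            double rnew = std::min(rrelKeep, 1.0 - 1e-9) * Rn;
            double ang = std::atan2(y, x);
            x = rnew * std::cos(ang); y = rnew * std::sin(ang);
            zi = G.len[e] - 1e-12;
            continue;
          }
          // bifurcation: route among the three airways by area ratio
          int sib = (G.child1[p] == e) ? G.child2[p] : G.child1[p];
          double aSelf = endArea(G, e, false);
          double aPar  = endArea(G, p, true);
          double aSib  = endArea(G, sib, false);
          double u = unif() * (aSelf + aPar + aSib);
          int chosen; bool atDistal;
          if (u < aSelf)              { chosen = e;   atDistal = false; }
          else if (u < aSelf + aPar)  { chosen = p;   atDistal = true;  }
          else                        { chosen = sib; atDistal = false; }
          double rrelKeep = std::sqrt(x * x + y * y) / R;
          e = chosen;
          zi = atDistal ? G.len[e] - 1e-12 : 1e-12;
          double Rn = localR(G, e, zi);
          double rnew = std::min(rrelKeep, 1.0 - 1e-9) * Rn;
          double ang = 2.0 * M_PI * unif();
          x = rnew * std::cos(ang); y = rnew * std::sin(ang);
          randDir(dx, dy, dz);
          continue;
        } else {                           // distal crossing
          if (G.compOf[e] >= 0) {          // acinar mouth: diffusive
            int c = G.compOf[e];           // exchange with the tally
            if (tp[i] == 1) tA[c] += 1; else tB[c] += 1;
            double tot = tA[c] + tB[c];
            int newtp = (unif() < tA[c] / tot) ? 1 : 2;
            if (newtp == 1) tA[c] -= 1; else tB[c] -= 1;
            if (newtp != tp[i]) ++exchanged;
            tp[i] = newtp;
            dz = -dz; zi = G.len[e] - 1e-12;
            continue;
          }
          if (G.child1[e] < 0) {           // sealed end: reflect
            dz = -dz; zi = G.len[e] - 1e-12;
            if (++retries > maxRetries) { ++forfeited; ell = 0; break; }
            continue;
          }
          if (G.child2[e] < 0) {           // terminal cylinder -> trumpet
            double rrelKeep = std::sqrt(x * x + y * y) / R;
            e = G.child1[e];
            double Rn = localR(G, e, 0.0);
            double rnew = std::min(rrelKeep, 1.0 - 1e-9) * Rn;
            double ang = std::atan2(y, x);
            x = rnew * std::cos(ang); y = rnew * std::sin(ang);
            zi = 1e-12;
            continue;
          }
          int c1 = G.child1[e], c2 = G.child2[e];
          double aSelf = endArea(G, e, true);
          double a1 = endArea(G, c1, false);
          double a2 = endArea(G, c2, false);
          double u = unif() * (aSelf + a1 + a2);
          int chosen; bool atDistal;
          if (u < aSelf)           { chosen = e;  atDistal = true;  }
          else if (u < aSelf + a1) { chosen = c1; atDistal = false; }
          else                     { chosen = c2; atDistal = false; }
          double rrelKeep = std::sqrt(x * x + y * y) / R;
          e = chosen;
          zi = atDistal ? G.len[e] - 1e-12 : 1e-12;
          double Rn = localR(G, e, zi);
          double rnew = std::min(rrelKeep, 1.0 - 1e-9) * Rn;
          double ang = 2.0 * M_PI * unif();
          x = rnew * std::cos(ang); y = rnew * std::sin(ang);
          randDir(dx, dy, dz);
          continue;
        }
      }
    }
    if (status[i] == 0 || status[i] == 2) {
      double R = localR(G, e, std::min(std::max(zi, 0.0), G.len[e]));
      double rn = std::sqrt(x * x + y * y);
      el[i] = e + 1;
      zz[i] = std::min(std::max(zi, 0.0), G.len[e]);
      rr[i] = std::min(rn / R, 1.0);
      th[i] = std::atan2(y, x);
    }
  }
  return List::create(_["elem"] = el, _["z"] = zz, _["rrel"] = rr,
                      _["theta"] = th, _["type"] = tp,
                      _["tallyA"] = tA, _["tallyB"] = tB,
                      _["status"] = status,
                      _["comp"] = comp, _["relabel"] = relabel,
                      _["forfeited"] = forfeited,
                      _["exchanged"] = exchanged);
}
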