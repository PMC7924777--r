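// Incremental simulation core: occupancy, neighborhood compositions,
// sample-class membership with O(1) swap-removal, and the SSA / tau-leap
// event loops.  All randomness flows through R's RNG so set.seed() governs
// reproducibility.  Species are coded 0 = open site, 1..L = species.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

class IPSCore {
public:
  int n;           // number of sites
  int L;           // number of occupied species types
  int D;           // nominal max neighbors (channel count driver)
  int nClass;
  int nChan;

  // neighbor lists, CSR layout
  std::vector<int> nbrOff;   // size n+1
  std::vector<int> nbrIdx;

  std::vector<int> occ;      // size n, 0..L
  std::vector<int> comp;     // size n*(L+1): comp[s*(L+1)+k] = # neighbors of s with species k

  // sample classes: partner = -1 for on-site classes
  std::vector<int> clCenter, clPartner, clJ;
  std::vector<int> pairBase;               // (L+1)*(L+1): class id of j=1, or -1
  std::vector<int> onsiteCl;               // (L+1): class id or -1
  std::vector< std::vector<int> > partnersOf; // per center code: partner codes with classes

  std::vector< std::vector<int> > members; // per class, member sites
  std::vector<int> pos;                    // nClass*n: index into members, or -1

  // channels
  std::vector<int> chClass, chType;        // chType: 0 pairwise, 1 on-site
  std::vector<double> chRate;              // per-particle rate (j*k or k)
  std::vector<int> chCenter, chPartner;    // reactant codes (partner -1 for on-site)
  std::vector<int> chPc, chPn;             // product codes (pn -1 for on-site)
  std::vector<int> chJ;                    // neighbor count (0 for on-site)

  std::vector<double> lam;
  std::vector<int> affectedBuf;
  std::vector<int> pop;                    // size L+1, pop[0] = open sites
  double t;
  double nEvents;

  IPSCore(const List& graph, int L_, int D_, const List& classes,
          const List& channels)
    : L(L_), D(D_) {
    List nb = graph["neighbors"];
    n = nb.size();
    nbrOff.resize(n + 1);
    nbrOff[0] = 0;
    for (int s = 0; s < n; ++s) {
      IntegerVector v = nb[s];
      nbrOff[s + 1] = nbrOff[s] + v.size();
    }
    nbrIdx.resize(nbrOff[n]);
    for (int s = 0; s < n; ++s) {
      IntegerVector v = nb[s];
      for (int i = 0; i < v.size(); ++i)
        nbrIdx[nbrOff[s] + i] = v[i] - 1;   // R is 1-based
    }

    IntegerVector cc = classes["center"], cp = classes["partner"], cj = classes["j"];
    nClass = cc.size();
    clCenter.assign(cc.begin(), cc.end());
    clPartner.assign(cp.begin(), cp.end());
    clJ.assign(cj.begin(), cj.end());
    pairBase.assign((L + 1) * (L + 1), -1);
    onsiteCl.assign(L + 1, -1);
    partnersOf.assign(L + 1, std::vector<int>());
    for (int c = 0; c < nClass; ++c) {
      if (clPartner[c] < 0) {
        onsiteCl[clCenter[c]] = c;
      } else if (clJ[c] == 1) {
        pairBase[clCenter[c] * (L + 1) + clPartner[c]] = c;
        partnersOf[clCenter[c]].push_back(clPartner[c]);
      }
    }

    IntegerVector hc = channels["class"], ht = channels["type"],
      hce = channels["center"], hpa = channels["partner"],
      hpc = channels["pc"], hpn = channels["pn"], hj = channels["j"];
    NumericVector hr = channels["rate"];
    nChan = hc.size();
    chClass.assign(hc.begin(), hc.end());
    chType.assign(ht.begin(), ht.end());
    chRate.assign(hr.begin(), hr.end());
    chCenter.assign(hce.begin(), hce.end());
    chPartner.assign(hpa.begin(), hpa.end());
    chPc.assign(hpc.begin(), hpc.end());
    chPn.assign(hpn.begin(), hpn.end());
    chJ.assign(hj.begin(), hj.end());

    occ.assign(n, 0);
    comp.assign((size_t)n * (L + 1), 0);
    members.assign(nClass, std::vector<int>());
    pos.assign((size_t)nClass * n, -1);
    lam.assign(nChan, 0.0);
    pop.assign(L + 1, 0);
    t = 0.0;
    nEvents = 0.0;
  }

  inline int deg(int s) const { return nbrOff[s + 1] - nbrOff[s]; }

  void addToClasses(int s) {
    int a = occ[s];
    int c = onsiteCl[a];
    if (c >= 0) {
      pos[(size_t)c * n + s] = members[c].size();
      members[c].push_back(s);
    }
    const std::vector<int>& ps = partnersOf[a];
    for (size_t i = 0; i < ps.size(); ++i) {
      int b = ps[i];
      int j = comp[(size_t)s * (L + 1) + b];
      if (j >= 1) {
        int cb = pairBase[a * (L + 1) + b] + (j - 1);
        pos[(size_t)cb * n + s] = members[cb].size();
        members[cb].push_back(s);
      }
    }
  }

  void removeOne(int c, int s) {
    int i = pos[(size_t)c * n + s];
    int last = members[c].back();
    members[c][i] = last;
    pos[(size_t)c * n + last] = i;
    members[c].pop_back();
    pos[(size_t)c * n + s] = -1;
  }

  void removeFromClasses(int s) {
    int a = occ[s];
    int c = onsiteCl[a];
    if (c >= 0) removeOne(c, s);
    const std::vector<int>& ps = partnersOf[a];
    for (size_t i = 0; i < ps.size(); ++i) {
      int b = ps[i];
      int j = comp[(size_t)s * (L + 1) + b];
      if (j >= 1) removeOne(pairBase[a * (L + 1) + b] + (j - 1), s);
    }
  }

  // full (re)initialization from an occupancy vector: the "global update"
  void reset(const IntegerVector& occupancy, double t0) {
    if ((int)occupancy.size() != n) stop("occupancy length != number of sites");
    std::fill(comp.begin(), comp.end(), 0);
    std::fill(pos.begin(), pos.end(), -1);
    std::fill(pop.begin(), pop.end(), 0);
    for (int c = 0; c < nClass; ++c) members[c].clear();
    for (int s = 0; s < n; ++s) {
      int a = occupancy[s];
      if (a < 0 || a > L) stop("occupancy code out of range at site %d", s + 1);
      occ[s] = a;
      pop[a]++;
    }
    for (int s = 0; s < n; ++s)
      for (int i = nbrOff[s]; i < nbrOff[s + 1]; ++i)
        comp[(size_t)s * (L + 1) + occ[nbrIdx[i]]]++;
    for (int s = 0; s < n; ++s) addToClasses(s);
    t = t0;
    nEvents = 0.0;
  }

  double lambda0() {
    double s = 0.0;
    for (int r = 0; r < nChan; ++r) {
      lam[r] = chRate[r] * members[chClass[r]].size();
      s += lam[r];
    }
    return s;
  }

  // core local update: change occupancy at 1 or 2 sites, refreshing
  // compositions and memberships only for the changed sites and neighbors
  void applyChange(int u, int newU, int v, int newV) {
    affectedBuf.clear();   // up to 2 changed sites + their neighbors
    std::vector<int>& affected = affectedBuf;
    int na = 0;
    int changed[2];
    int newOcc[2];
    int nc = 0;
    if (newU != occ[u]) { changed[nc] = u; newOcc[nc] = newU; ++nc; }
    if (v >= 0 && newV != occ[v]) { changed[nc] = v; newOcc[nc] = newV; ++nc; }
    if (nc == 0) return;
    for (int k = 0; k < nc; ++k) {
      int s = changed[k];
      bool seen = false;
      for (int q = 0; q < na; ++q) if (affected[q] == s) { seen = true; break; }
      if (!seen) { affected.push_back(s); ++na; }
      for (int i = nbrOff[s]; i < nbrOff[s + 1]; ++i) {
        int x = nbrIdx[i];
        seen = false;
        for (int q = 0; q < na; ++q) if (affected[q] == x) { seen = true; break; }
        if (!seen) { affected.push_back(x); ++na; }
      }
    }
    for (int q = 0; q < na; ++q) removeFromClasses(affected[q]);
    for (int k = 0; k < nc; ++k) {
      int s = changed[k], a = occ[s], b = newOcc[k];
      occ[s] = b;
      pop[a]--; pop[b]++;
      for (int i = nbrOff[s]; i < nbrOff[s + 1]; ++i) {
        int x = nbrIdx[i];
        comp[(size_t)x * (L + 1) + a]--;
        comp[(size_t)x * (L + 1) + b]++;
      }
    }
    for (int q = 0; q < na; ++q) addToClasses(affected[q]);
  }

  // apply a specific event; center/nbr are 0-based; nbr = -1 for on-site
  void applyEvent(int r, int center, int nbr) {
    int c = chClass[r];
    if (occ[center] != clCenter[c])
      stop("center site is not a member of the channel's class (occupancy mismatch)");
    if (chType[r] == 0) {
      if (clPartner[c] < 0) stop("internal error: pairwise channel with on-site class");
      if (comp[(size_t)center * (L + 1) + clPartner[c]] != clJ[c])
        stop("center site is not a member of the channel's class (neighbor count mismatch)");
      if (nbr < 0) stop("pairwise event requires a neighbor site");
      bool adj = false;
      for (int i = nbrOff[center]; i < nbrOff[center + 1]; ++i)
        if (nbrIdx[i] == nbr) { adj = true; break; }
      if (!adj) stop("neighbor site is not adjacent to the center site");
      if (occ[nbr] != chPartner[r])
        stop("neighbor site does not hold the required reactant");
      applyChange(center, chPc[r], nbr, chPn[r]);
    } else {
      if (nbr >= 0) stop("on-site event takes no neighbor site");
      applyChange(center, chPc[r], -1, 0);
    }
    nEvents += 1.0;
  }

  // sample center uniformly from the class, and (pairwise) the partner
  // uniformly among the j qualifying neighbors; returns (center, nbr)
  void fire(int r, int& centerOut, int& nbrOut, int& oldC, int& oldN) {
    int c = chClass[r];
    int m = members[c].size();
    if (m == 0) stop("cannot fire channel %d: its sample class is empty", r + 1);
    int idx = (int)(unif_rand() * m);
    if (idx >= m) idx = m - 1;
    int center = members[c][idx];
    int nbr = -1;
    if (chType[r] == 0) {
      int b = chPartner[r];
      int j = comp[(size_t)center * (L + 1) + b];
      int pick = (int)(unif_rand() * j);
      if (pick >= j) pick = j - 1;
      int seen = 0;
      for (int i = nbrOff[center]; i < nbrOff[center + 1]; ++i) {
        int x = nbrIdx[i];
        if (occ[x] == b) {
          if (seen == pick) { nbr = x; break; }
          ++seen;
        }
      }
    }
    oldC = occ[center];
    oldN = (nbr >= 0) ? occ[nbr] : NA_INTEGER;
    applyEvent(r, center, nbr);
    centerOut = center;
    nbrOut = nbr;
  }
};

// [[Rcpp::export(name = ".ips_core_new")]]
SEXP ips_core_new(List graph, int L, int D, List classes, List channels,
                  IntegerVector occupancy, double t0) {
  XPtr<IPSCore> p(new IPSCore(graph, L, D, classes, channels), true);
  p->reset(occupancy, t0);
  return p;
}

// [[Rcpp::export(name = ".ips_core_reset")]]
void ips_core_reset(SEXP ptr, IntegerVector occupancy, double t0) {
  XPtr<IPSCore> p(ptr);
  p->reset(occupancy, t0);
}

// [[Rcpp::export(name = ".ips_core_lambda")]]
NumericVector ips_core_lambda(SEXP ptr) {
  XPtr<IPSCore> p(ptr);
  p->lambda0();
  return NumericVector(p->lam.begin(), p->lam.end());
}

// [[Rcpp::export(name = ".ips_core_snapshot")]]
List ips_core_snapshot(SEXP ptr) {
  XPtr<IPSCore> p(ptr);
  double l0 = p->lambda0();
  IntegerMatrix compM(p->L + 1, p->n);
  for (int s = 0; s < p->n; ++s)
    for (int k = 0; k <= p->L; ++k)
      compM(k, s) = p->comp[(size_t)s * (p->L + 1) + k];
  List mem(p->nClass);
  for (int c = 0; c < p->nClass; ++c) {
    IntegerVector v(p->members[c].size());
    for (size_t i = 0; i < p->members[c].size(); ++i) v[i] = p->members[c][i] + 1;
    mem[c] = v;
  }
  return List::create(
    _["occupancy"] = IntegerVector(p->occ.begin(), p->occ.end()),
    _["composition"] = compM,
    _["members"] = mem,
    _["classSizes"] = [&]{ IntegerVector z(p->nClass);
      for (int c = 0; c < p->nClass; ++c) z[c] = p->members[c].size(); return z; }(),
    _["lambda"] = NumericVector(p->lam.begin(), p->lam.end()),
    _["lambda0"] = l0,
    _["populations"] = IntegerVector(p->pop.begin(), p->pop.end()),
    _["t"] = p->t,
    _["nEvents"] = p->nEvents);
}

// [[Rcpp::export(name = ".ips_core_apply")]]
List ips_core_apply(SEXP ptr, int channel, int center, int nbr, double dt) {
  XPtr<IPSCore> p(ptr);
  if (channel < 1 || channel > p->nChan) stop("channel index out of range");
  int oldC = p->occ[center - 1];
  int oldN = (nbr >= 1) ? p->occ[nbr - 1] : NA_INTEGER;
  p->t += dt;
  p->applyEvent(channel - 1, center - 1, nbr >= 1 ? nbr - 1 : -1);
  return List::create(_["t"] = p->t, _["channel"] = channel,
                      _["center"] = center, _["neighbor"] = nbr >= 1 ? nbr : NA_INTEGER,
                      _["oldCenter"] = oldC, _["oldNeighbor"] = oldN,
                      _["newCenter"] = p->occ[center - 1],
                      _["newNeighbor"] = nbr >= 1 ? p->occ[nbr - 1] : NA_INTEGER);
}

// [[Rcpp::export(name = ".ips_core_fire")]]
List ips_core_fire(SEXP ptr, int channel, double dt) {
  XPtr<IPSCore> p(ptr);
  if (channel < 1 || channel > p->nChan) stop("channel index out of range");
  GetRNGstate();
  int center = -1, nbr = -1, oldC = NA_INTEGER, oldN = NA_INTEGER;
  p->t += dt;
  p->fire(channel - 1, center, nbr, oldC, oldN);
  PutRNGstate();
  return List::create(_["t"] = p->t, _["channel"] = channel,
                      _["center"] = center + 1,
                      _["neighbor"] = nbr >= 0 ? nbr + 1 : NA_INTEGER,
                      _["oldCenter"] = oldC, _["oldNeighbor"] = oldN,
                      _["newCenter"] = p->occ[center],
                      _["newNeighbor"] = nbr >= 0 ? p->occ[nbr] : NA_INTEGER);
}

static void recordGrid(const IPSCore& p, const NumericVector& saveTimes,
                       int& nextSave, double upTo, IntegerMatrix& popOut) {
  while (nextSave < saveTimes.size() && saveTimes[nextSave] <= upTo) {
    for (int k = 0; k <= p.L; ++k) popOut(nextSave, k) = p.pop[k];
    ++nextSave;
  }
}

// Direct SSA loop: sample_time, select_channel, fire, repeat.
// Populations are recorded at the saveTimes grid by carrying the last
// state forward.  Stops at t > tFinal, maxEvents, or lambda0 == 0.
// [[Rcpp::export(name = ".ips_run_ssa")]]
List ips_run_ssa(SEXP ptr, double tFinal, double maxEvents,
                 NumericVector saveTimes, bool recordEvents) {
  XPtr<IPSCore> p(ptr);
  IntegerMatrix popOut(saveTimes.size(), p->L + 1);
  int nextSave = 0;
  std::vector<double> evT;
  std::vector<int> evChan, evCenter, evNbr;
  std::string status = "t_final";
  double nev = 0.0;
  GetRNGstate();
  for (;;) {
    double l0 = p->lambda0();
    if (l0 <= 0.0) {
      status = "absorbed";
      recordGrid(*p, saveTimes, nextSave, R_PosInf, popOut);
      break;
    }
    double u1;
    do { u1 = unif_rand(); } while (u1 <= 0.0);
    double T = -std::log(u1) / l0;
    if (p->t + T > tFinal) {
      recordGrid(*p, saveTimes, nextSave, tFinal, popOut);
      p->t = tFinal;
      break;
    }
    double u2;
    do { u2 = unif_rand(); } while (u2 <= 0.0);
    double target = u2 * l0, cum = 0.0;
    int r = -1;
    for (int k = 0; k < p->nChan; ++k) {
      cum += p->lam[k];
      if (target <= cum) { r = k; break; }
    }
    if (r < 0) r = p->nChan - 1;
    recordGrid(*p, saveTimes, nextSave, p->t + T, popOut);
    p->t += T;
    int center = -1, nbr = -1, oldC, oldN;
    p->fire(r, center, nbr, oldC, oldN);
    nev += 1.0;
    if (recordEvents) {
      evT.push_back(p->t);
      evChan.push_back(r + 1);
      evCenter.push_back(center + 1);
      evNbr.push_back(nbr >= 0 ? nbr + 1 : NA_INTEGER);
    }
    if (nev >= maxEvents) {
      status = "max_events";
      recordGrid(*p, saveTimes, nextSave, p->t, popOut);
      break;
    }
  }
  PutRNGstate();
  List events = R_NilValue;
  if (recordEvents)
    events = List::create(_["t"] = NumericVector(evT.begin(), evT.end()),
                          _["channel"] = IntegerVector(evChan.begin(), evChan.end()),
                          _["center"] = IntegerVector(evCenter.begin(), evCenter.end()),
                          _["neighbor"] = IntegerVector(evNbr.begin(), evNbr.end()));
  return List::create(_["populations"] = popOut, _["nSaved"] = nextSave,
                      _["status"] = status, _["nEvents"] = nev,
                      _["t"] = p->t, _["events"] = events);
}

// Tau-leaping with shuffled sequential firing.  Per leap, a Poisson number
// of events is drawn for each channel from the leap-start propensities; the
// combined event list is shuffled (Fisher-Yates) and applied sequentially.
// Events whose sample class is empty at application time are skipped.
// [[Rcpp::export(name = ".ips_run_tau")]]
List ips_run_tau(SEXP ptr, double tau, double tFinal, double maxEvents,
                 NumericVector saveTimes, bool shuffle) {
  XPtr<IPSCore> p(ptr);
  IntegerMatrix popOut(saveTimes.size(), p->L + 1);
  int nextSave = 0;
  std::string status = "t_final";
  double nev = 0.0, skipped = 0.0;
  std::vector<int> queue;
  GetRNGstate();
  for (;;) {
    double l0 = p->lambda0();
    if (l0 <= 0.0) {
      status = "absorbed";
      recordGrid(*p, saveTimes, nextSave, R_PosInf, popOut);
      break;
    }
    if (p->t + tau > tFinal) {
      recordGrid(*p, saveTimes, nextSave, tFinal, popOut);
      p->t = tFinal;
      break;
    }
    queue.clear();
    for (int r = 0; r < p->nChan; ++r) {
      int k = (int)R::rpois(p->lam[r] * tau);
      for (int i = 0; i < k; ++i) queue.push_back(r);
    }
    if (shuffle) {
      for (int i = (int)queue.size() - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(queue[i], queue[j]);
      }
    }
    recordGrid(*p, saveTimes, nextSave, p->t + tau, popOut);
    p->t += tau;
    for (size_t q = 0; q < queue.size(); ++q) {
      int r = queue[q];
      if (p->members[p->chClass[r]].empty()) {
        skipped += 1.0;
        continue;
      }
      int center = -1, nbr = -1, oldC, oldN;
      p->fire(r, center, nbr, oldC, oldN);
      nev += 1.0;
    }
    if (nev >= maxEvents) {
      status = "max_events";
      recordGrid(*p, saveTimes, nextSave, p->t, popOut);
      break;
    }
  }
  PutRNGstate();
  return List::create(_["populations"] = popOut, _["nSaved"] = nextSave,
                      _["status"] = status, _["nEvents"] = nev,
                      _["skipped"] = skipped, _["t"] = p->t,
                      _["events"] = R_NilValue);
}
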