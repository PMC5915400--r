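#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Integer codes shared with the R side:
// matingType: 0 empty, 1 P, 2 M
// strategy:   0 none, 1 switcher, 2 non-switcher
// switchPhase: 0 not applicable, 1 will switch, 2 will not switch
// All randomness goes through R's RNG (unif_rand) so set.seed() in R makes
// every simulation reproducible.

static inline int randInt(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// Moore neighbourhood of column-major site index parts (r, c) on an L x L grid.
static int mooreNeighbours(int r, int c, int L, bool torus, int* out) {
  int n = 0;
  for (int dr = -1; dr <= 1; ++dr) {
    for (int dc = -1; dc <= 1; ++dc) {
      if (dr == 0 && dc == 0) continue;
      int rr = r + dr, cc = c + dc;
      if (torus) {
        rr = (rr + L) % L;
        cc = (cc + L) % L;
      } else if (rr < 0 || rr >= L || cc < 0 || cc >= L) {
        continue;
      }
      out[n++] = rr + cc * L;
    }
  }
  return n;
}

// Asexual growth. Each round visits the sites occupied at the start of the
// round in a fresh random order; a cell with at least one empty Moore
// neighbour divides with probability R * (1 - s if switcher) * (c if
// intraclonal origin). Division places one resulting cell at the old site and
// one at a uniformly chosen empty neighbour; which of the two carries the
// switched mating type (for a will-switch mother) is decided by a fair coin,
// which also absorbs the mother-or-daughter migration coin (the two cells are
// otherwise identical in clone id and intraclonal flag).
// [[Rcpp::export]]
List cpp_grow(IntegerMatrix matingType, IntegerMatrix strategy,
              IntegerMatrix switchPhase, IntegerMatrix cloneId,
              IntegerMatrix intraclonal,
              double R, double s, double cIntra, bool torus,
              double maxRounds, double roundCap, bool bernoulliPhase) {
  IntegerMatrix mt = clone(matingType), st = clone(strategy),
                ph = clone(switchPhase), cl = clone(cloneId),
                ic = clone(intraclonal);
  int L = mt.nrow();
  int N = L * L;
  std::vector<int> occ;
  occ.reserve(N);
  int nEmpty = 0;
  for (int i = 0; i < N; ++i) {
    if (mt[i] != 0) occ.push_back(i); else ++nEmpty;
  }
  if (occ.empty()) stop("growth requires at least one occupied site");

  int rounds = 0;
  int nbr[8], emptyNbr[8];
  double totalDivisions = 0;

  while (nEmpty > 0 && rounds < maxRounds) {
    if (rounds >= roundCap)
      stop("growth failed to fill the grid within the round safeguard; "
           "the effective division probability is degenerate");
    ++rounds;
    int nOcc = (int)occ.size();
    std::vector<int> order(occ.begin(), occ.end());
    for (int i = nOcc - 1; i > 0; --i) {
      int j = randInt(i + 1);
      std::swap(order[i], order[j]);
    }
    for (int k = 0; k < nOcc; ++k) {
      int i = order[k];
      int n = mooreNeighbours(i % L, i / L, L, torus, nbr);
      int ne = 0;
      for (int q = 0; q < n; ++q)
        if (mt[nbr[q]] == 0) emptyNbr[ne++] = nbr[q];
      if (ne == 0) continue;
      double p = R;
      if (st[i] == 1) p *= (1.0 - s);
      if (ic[i] == 1) p *= cIntra;
      if (unif_rand() >= p) continue;
      int target = emptyNbr[randInt(ne)];

      int typeHome, typeAway, phHome, phAway;
      if (st[i] == 2) {
        typeHome = typeAway = mt[i];
        phHome = phAway = 0;
      } else {
        int tSame = mt[i], tOpp = (mt[i] == 1) ? 2 : 1;
        if (ph[i] == 1) {
          // will-switch mother: exactly one resulting cell switches and
          // becomes unswitchable for one division; the other keeps the type
          // and remains competent
          if (unif_rand() < 0.5) {
            typeHome = tOpp;  phHome = 2;
            typeAway = tSame; phAway = 1;
          } else {
            typeHome = tSame; phHome = 1;
            typeAway = tOpp;  phAway = 2;
          }
        } else {
          // won't-switch mother: one resulting cell acquires competence
          typeHome = typeAway = tSame;
          if (unif_rand() < 0.5) { phHome = 1; phAway = 2; }
          else                   { phHome = 2; phAway = 1; }
        }
        if (bernoulliPhase) {
          // sensitivity variant: phases redrawn i.i.d. Bernoulli(1/2)
          phHome = (unif_rand() < 0.5) ? 1 : 2;
          phAway = (unif_rand() < 0.5) ? 1 : 2;
        }
      }
      st[target] = st[i];
      cl[target] = cl[i];
      ic[target] = ic[i];
      mt[i] = typeHome;      ph[i] = phHome;
      mt[target] = typeAway; ph[target] = phAway;
      occ.push_back(target);
      --nEmpty;
      totalDivisions += 1;
    }
  }

  return List::create(_["matingType"] = mt, _["strategy"] = st,
                      _["switchPhase"] = ph, _["cloneId"] = cl,
                      _["intraclonal"] = ic, _["rounds"] = rounds,
                      _["filled"] = (nEmpty == 0),
                      _["divisions"] = totalDivisions);
}

// Mating. Unmated cells are visited in a uniformly random order; each mates
// with a uniformly chosen eligible partner (moore: unmated opposite-type
// Moore neighbour; global: any unmated opposite-type cell). Because
// eligibility only ever shrinks, one pass reaches the fixed point; the outer
// loop re-checks until a pass produces no mating.
// [[Rcpp::export]]
List cpp_mate(IntegerMatrix matingType, IntegerMatrix strategy,
              IntegerMatrix cloneId, bool global, bool torus) {
  int L = matingType.nrow();
  int N = L * L;
  IntegerMatrix mated(L, L);
  const IntegerMatrix& mt = matingType;
  std::vector<int> za, zb;

  if (!global) {
    int nbr[8], cand[8];
    bool changed = true;
    while (changed) {
      changed = false;
      std::vector<int> unm;
      for (int i = 0; i < N; ++i)
        if (mt[i] != 0 && !mated[i]) unm.push_back(i);
      for (int i = (int)unm.size() - 1; i > 0; --i) {
        int j = randInt(i + 1);
        std::swap(unm[i], unm[j]);
      }
      for (size_t k = 0; k < unm.size(); ++k) {
        int i = unm[k];
        if (mated[i]) continue;
        int want = (mt[i] == 1) ? 2 : 1;
        int n = mooreNeighbours(i % L, i / L, L, torus, nbr);
        int nc = 0;
        for (int q = 0; q < n; ++q) {
          int j2 = nbr[q];
          if (mt[j2] == want && !mated[j2]) cand[nc++] = j2;
        }
        if (nc == 0) continue;
        int j2 = cand[randInt(nc)];
        mated[i] = 1;
        mated[j2] = 1;
        za.push_back(i);
        zb.push_back(j2);
        changed = true;
      }
    }
  } else {
    std::vector<int> listP, listM;
    std::vector<int> pos(N, -1);
    std::vector<int> order;
    for (int i = 0; i < N; ++i) {
      if (mt[i] == 1) { pos[i] = (int)listP.size(); listP.push_back(i); }
      else if (mt[i] == 2) { pos[i] = (int)listM.size(); listM.push_back(i); }
      if (mt[i] != 0) order.push_back(i);
    }
    for (int i = (int)order.size() - 1; i > 0; --i) {
      int j = randInt(i + 1);
      std::swap(order[i], order[j]);
    }
    for (size_t k = 0; k < order.size(); ++k) {
      int i = order[k];
      if (mated[i]) continue;
      std::vector<int>& own = (mt[i] == 1) ? listP : listM;
      std::vector<int>& other = (mt[i] == 1) ? listM : listP;
      if (other.empty()) continue;
      int j2 = other[randInt((int)other.size())];
      mated[i] = 1;
      mated[j2] = 1;
      // swap-pop removal keeps partner choice uniform among the unmated
      int p = pos[i];
      own[p] = own.back(); pos[own.back()] = p; own.pop_back(); pos[i] = -1;
      p = pos[j2];
      other[p] = other.back(); pos[other.back()] = p; other.pop_back(); pos[j2] = -1;
      za.push_back(i);
      zb.push_back(j2);
    }
  }

  int nz = (int)za.size();
  IntegerVector siteA(nz), siteB(nz), stratA(nz), stratB(nz), clA(nz), clB(nz);
  LogicalVector intra(nz);
  for (int k = 0; k < nz; ++k) {
    siteA[k] = za[k] + 1;
    siteB[k] = zb[k] + 1;
    stratA[k] = strategy[za[k]];
    stratB[k] = strategy[zb[k]];
    clA[k] = cloneId[za[k]];
    clB[k] = cloneId[zb[k]];
    intra[k] = cloneId[za[k]] == cloneId[zb[k]];
  }
  return List::create(_["mated"] = mated, _["siteA"] = siteA,
                      _["siteB"] = siteB, _["strategyA"] = stratA,
                      _["strategyB"] = stratB, _["cloneA"] = clA,
                      _["cloneB"] = clB, _["intraclonal"] = intra);
}
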