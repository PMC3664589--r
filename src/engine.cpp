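// Per-minute Monte Carlo engine for enzymatic cellulose hydrolysis.
//
// The substrate is a set of microfibrils (MF), each a bundle of elementary
// fibrils (EF) of 36 parallel glucose chains. Units are stored in one flat
// 0-based array; each chain occupies a contiguous run [start, start+dp).
// Axial index 0 is the reducing end of every chain (parallel-chain cellulose
// I-beta), so within any fragment the reducing end sits at the lower axial
// index and the non-reducing end at the higher one.
//
// All randomness comes from R's RNG stream (unif_rand), so set.seed() on the
// R side makes whole trajectories bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

static inline double ru() { return unif_rand(); }

// enzyme class codes (keep in sync with R/enzyme.R)
enum EnzClass {
  EG_NONPROC_CBM = 1, EG_NONPROC_NOCBM = 2, EG_PROC_CBM = 3,
  CBH1_PROC = 4, CBH1_NONPROC = 5, CBH2_PROC = 6, CBH2_NONPROC = 7,
  BG = 8
};

static inline bool isEG(int c)   { return c >= 1 && c <= 3; }
static inline bool isCBH1(int c) { return c == 4 || c == 5; }
static inline bool isCBH2(int c) { return c == 6 || c == 7; }

struct EnzP {
  int cls;
  double nMax;        // event budget per minute (N_hi_max)
  int footprint;      // contiguous unblocked surface units needed to bind
  int minDp;          // no action below this chain length
  int prefDp;         // CBH chain-length preference threshold (0 = none)
  double pLong;       // acceptance scale above prefDp: p = pLong * prefDp/len
  double pCryst;      // EG acceptance multiplier for crystalline bonds
  double pBuried;     // acceptance on EF-surface-not-MF-surface chains
  double pGlucEnd;    // EG acceptance for glucose-producing terminal cuts
  double pDesAm, pDesCr; // processive desorption per cleavage
  double pSol;        // CBH acceptance on soluble DP 5-6 oligomers
  double pBgG2, pBgOligo; // BG acceptance on cellobiose / DP 3-6
  double nNb, nNp, nInhG, nInhG2; // counter increments
};

// outcome tally columns
enum { T_PROD = 0, T_NB = 1, T_NP = 2, T_INH = 3 };

class Engine {
public:
  int nUnits, nChains, nMf;
  const int *cStart, *cDp, *cMf, *cBelow; // chain-level (cMf 1-based)
  const int *cDepth;
  const int *cMfSurf;
  std::vector<int> chainOf;
  std::vector<uint8_t> cryst, removed, broken, surf;
  std::vector<int> blockStamp;
  std::vector<std::vector<int> > surfList; // per MF, uids of surface units
  std::vector<int> posInList;
  std::vector<long long> NR, NNR;          // insoluble fragment ends per MF
  std::vector<std::array<long long, 7> > pool; // [mf][dp 1..6]
  long long insol, crystInsol, fragsN;
  long long solub; // glucose units moved to the soluble pool
  int minuteNow;
  std::vector<EnzP> enz;
  std::vector<std::array<long long, 4> > tally;

  void init(const IntegerVector& chainStart, const IntegerVector& chainDp,
            const IntegerVector& chainMf, const IntegerVector& chainBelow,
            const IntegerVector& chainMfSurf, const IntegerVector& chainDepth,
            const RawVector& crystal, int nMf_, const NumericMatrix& initPool) {
    nChains = chainStart.size();
    nMf = nMf_;
    cStart = INTEGER(chainStart); cDp = INTEGER(chainDp);
    cMf = INTEGER(chainMf); cBelow = INTEGER(chainBelow);
    cMfSurf = INTEGER(chainMfSurf); cDepth = INTEGER(chainDepth);
    nUnits = crystal.size();
    cryst.assign(nUnits, 0);
    for (int i = 0; i < nUnits; ++i) cryst[i] = RAW(crystal)[i];
    removed.assign(nUnits, 0);
    broken.assign(nUnits, 0);
    surf.assign(nUnits, 0);
    blockStamp.assign(nUnits, -1);
    chainOf.assign(nUnits, 0);
    posInList.assign(nUnits, -1);
    surfList.assign(nMf, std::vector<int>());
    NR.assign(nMf, 0); NNR.assign(nMf, 0);
    pool.assign(nMf, std::array<long long, 7>());
    for (int j = 0; j < nMf; ++j)
      for (int d = 0; d < 7; ++d) pool[j][d] = 0;
    if (initPool.nrow() == nMf && initPool.ncol() == 6)
      for (int j = 0; j < nMf; ++j)
        for (int d = 1; d <= 6; ++d) pool[j][d] = (long long) initPool(j, d - 1);
    insol = nUnits;
    crystInsol = 0;
    for (int i = 0; i < nUnits; ++i) if (cryst[i]) crystInsol++;
    fragsN = nChains;
    solub = 0;
    minuteNow = 0;
    for (int c = 0; c < nChains; ++c) {
      int mf = cMf[c] - 1;
      NR[mf]++; NNR[mf]++;
      for (int x = cStart[c]; x < cStart[c] + cDp[c]; ++x) chainOf[x] = c;
      if (cDepth[c] == 0) {
        for (int x = cStart[c]; x < cStart[c] + cDp[c]; ++x) {
          surf[x] = 1;
          posInList[x] = (int) surfList[mf].size();
          surfList[mf].push_back(x);
        }
      }
    }
  }

  inline int chainS(int u) const { return cStart[chainOf[u]]; }
  inline int chainE(int u) const { int c = chainOf[u]; return cStart[c] + cDp[c] - 1; }

  void pushSurf(int v) {
    int mf = cMf[chainOf[v]] - 1;
    surf[v] = 1;
    posInList[v] = (int) surfList[mf].size();
    surfList[mf].push_back(v);
  }

  void popSurf(int x) {
    int mf = cMf[chainOf[x]] - 1;
    std::vector<int>& L = surfList[mf];
    int p = posInList[x];
    int last = L.back();
    L[p] = last;
    posInList[last] = p;
    L.pop_back();
    posInList[x] = -1;
    surf[x] = 0;
  }

  void removeUnit(int x) {
    removed[x] = 1;
    insol--; solub++;
    if (cryst[x]) crystInsol--;
    if (surf[x]) popSurf(x);
    // expose the chain segment directly beneath
    int c = chainOf[x];
    int bl = cBelow[c];
    if (bl >= 0) {
      int v = cStart[bl] + (x - cStart[c]);
      if (!removed[v] && !surf[v]) pushSurf(v);
    }
  }

  // fragment [a,b] with DP <= 6 leaves the lattice for the soluble pool
  void solubilizeFrag(int a, int b, int mf) {
    int len = b - a + 1;
    pool[mf][len]++;
    NR[mf]--; NNR[mf]--; fragsN--;
    for (int x = a; x < b; ++x) broken[x] = 1;
    for (int x = a; x <= b; ++x) removeUnit(x);
  }

  inline int findRight(int u) const {
    int x = u, ce = chainE(u);
    while (x < ce && !broken[x]) x++;
    return x;
  }
  inline int findLeft(int u) const {
    int x = u, cs = chainS(u);
    while (x > cs && !broken[x - 1]) x--;
    return x;
  }

  // internal cleavage of bond (cut, cut+1); both sides re-evaluated for
  // solubilization; censuses and end counts updated
  void cleaveInternal(int cut, int mf) {
    broken[cut] = 1;
    fragsN++; NR[mf]++; NNR[mf]++;
    int cs = chainS(cut), ce = chainE(cut);
    // left side [a..cut]
    int a = cut, l = 1;
    while (a > cs && !broken[a - 1] && l < 8) { a--; l++; }
    if (l <= 6) solubilizeFrag(a, cut, mf);
    // right side [cut+1..b]
    int b = cut + 1; l = 1;
    while (b < ce && !broken[b] && l < 8) { b++; l++; }
    if (l <= 6) solubilizeFrag(cut + 1, b, mf);
  }

  void blockWindow(int u, int f) {
    int cs = chainS(u), ce = chainE(u);
    int lo = u - f / 2, hi = u + (f - 1) / 2;
    if (lo < cs) lo = cs;
    if (hi > ce) hi = ce;
    for (int x = lo; x <= hi; ++x) blockStamp[x] = minuteNow;
  }

  // processive cellobiose release from the reducing end of fragment [u,b].
  // Counter cost 1 per cleavage. Remaining DP <= 6 is solubilized.
  void runReducing(int u, int b, const EnzP& e, double& counter, double limit,
                   int mf, bool processive, std::array<long long, 4>& tl) {
    int pos = u, len = b - u + 1;
    while (len >= e.minDp) {
      broken[pos] = 1;
      if (pos + 1 < chainE(pos)) broken[pos + 1] = 1;
      removeUnit(pos); removeUnit(pos + 1);
      pool[mf][2]++;
      counter += 1.0; tl[T_PROD]++;
      pos += 2; len -= 2;
      if (!processive || counter >= limit) break;
      if (len >= e.minDp) {
        double pd = cryst[pos] ? e.pDesCr : e.pDesAm;
        if (pd > 0 && ru() < pd) break;
      }
    }
    if (len >= 1 && len <= 6) solubilizeFrag(pos, pos + len - 1, mf);
  }

  // mirror image: release from the non-reducing end of fragment [a,u]
  void runNonReducing(int u, int a, const EnzP& e, double& counter, double limit,
                      int mf, bool processive, std::array<long long, 4>& tl) {
    int pos = u, len = pos - a + 1;
    while (len >= e.minDp) {
      broken[pos - 1] = 1;
      if (pos - 2 >= chainS(pos)) broken[pos - 2] = 1;
      removeUnit(pos - 1); removeUnit(pos);
      pool[mf][2]++;
      counter += 1.0; tl[T_PROD]++;
      pos -= 2; len -= 2;
      if (!processive || counter >= limit) break;
      if (len >= e.minDp) {
        double pd = cryst[pos] ? e.pDesCr : e.pDesAm;
        if (pd > 0 && ru() < pd) break;
      }
    }
    if (len >= 1 && len <= 6) solubilizeFrag(pos - len + 1, pos, mf);
  }

  // ---- per-class attempts on an insoluble surface unit ----

  void attemptEG(int u, const EnzP& e, double& counter, double limit, int mf,
                 std::array<long long, 4>& tl) {
    if (blockStamp[u] == minuteNow) { counter += e.nNb; tl[T_NB]++; return; }
    int c = chainOf[u];
    if (!cMfSurf[c] && ru() >= e.pBuried) { counter += e.nNb; tl[T_NB]++; return; }
    // footprint: e.footprint contiguous unblocked surface units around target
    int cs = cStart[c], ce = cs + cDp[c] - 1;
    int cnt = 1, x = u, y = u;
    while (cnt < e.footprint && x > cs && !broken[x - 1] && surf[x - 1] &&
           blockStamp[x - 1] != minuteNow) { x--; cnt++; }
    while (cnt < e.footprint && y < ce && !broken[y] && surf[y + 1] &&
           blockStamp[y + 1] != minuteNow) { y++; cnt++; }
    if (cnt < e.footprint) { counter += e.nNb; tl[T_NB]++; return; }
    // bond to the right of the target, or the left bond at a fragment end
    int cut;
    if (u == ce || broken[u]) cut = u - 1; else cut = u;
    double p = 1.0;
    if (cryst[u]) p *= e.pCryst;
    bool termL = (cut == cs) || broken[cut - 1];
    bool termR = (cut + 1 == ce) || broken[cut + 1];
    if (termL || termR) p *= e.pGlucEnd;
    if (ru() >= p) { counter += e.nNp; tl[T_NP]++; return; }
    blockWindow(u, e.footprint);
    cleaveInternal(cut, mf);
    counter += 1.0; tl[T_PROD]++;
    if (e.cls == EG_PROC_CBM && counter < limit) {
      // processive endoglucanase slides from the fresh cut, either direction
      if (ru() < 0.5) {
        if (!removed[cut + 1]) {
          int b = findRight(cut + 1);
          runReducing(cut + 1, b, e, counter, limit, mf, true, tl);
        }
      } else {
        if (!removed[cut]) {
          int a = findLeft(cut);
          runNonReducing(cut, a, e, counter, limit, mf, true, tl);
        }
      }
    }
  }

  void attemptCBH1(int u, const EnzP& e, double& counter, double limit, int mf,
                   std::array<long long, 4>& tl) {
    if (blockStamp[u] == minuteNow) { counter += e.nNb; tl[T_NB]++; return; }
    int c = chainOf[u];
    int cs = cStart[c];
    bool isR = (u == cs) || broken[u - 1];
    if (!isR) { counter += e.nNb; tl[T_NB]++; return; }
    if (!cMfSurf[c] && ru() >= e.pBuried) { counter += e.nNb; tl[T_NB]++; return; }
    int b = findRight(u);
    int len = b - u + 1;
    if (len < e.footprint) { counter += e.nNb; tl[T_NB]++; return; }
    for (int x = u; x < u + e.footprint; ++x)
      if (!surf[x] || blockStamp[x] == minuteNow) { counter += e.nNb; tl[T_NB]++; return; }
    if (e.prefDp > 0 && len > e.prefDp &&
        ru() >= e.pLong * (double) e.prefDp / (double) len) {
      counter += e.nNp; tl[T_NP]++; return;
    }
    blockWindow(u + e.footprint / 2, e.footprint);
    runReducing(u, b, e, counter, limit, mf, e.cls == CBH1_PROC, tl);
  }

  void attemptCBH2(int u, const EnzP& e, double& counter, double limit, int mf,
                   std::array<long long, 4>& tl) {
    if (blockStamp[u] == minuteNow) { counter += e.nNb; tl[T_NB]++; return; }
    int c = chainOf[u];
    int ce = cStart[c] + cDp[c] - 1;
    bool isNR = (u == ce) || broken[u];
    if (!isNR) { counter += e.nNb; tl[T_NB]++; return; }
    if (!cMfSurf[c] && ru() >= e.pBuried) { counter += e.nNb; tl[T_NB]++; return; }
    int a = findLeft(u);
    int len = u - a + 1;
    if (len < e.footprint) { counter += e.nNb; tl[T_NB]++; return; }
    for (int x = u - e.footprint + 1; x <= u; ++x)
      if (!surf[x] || blockStamp[x] == minuteNow) { counter += e.nNb; tl[T_NB]++; return; }
    if (e.prefDp > 0 && len > e.prefDp &&
        ru() >= e.pLong * (double) e.prefDp / (double) len) {
      counter += e.nNp; tl[T_NP]++; return;
    }
    blockWindow(u - e.footprint / 2, e.footprint);
    runNonReducing(u, a, e, counter, limit, mf, e.cls == CBH2_PROC, tl);
  }

  // ---- soluble-pool interactions for EG / CBH targets ----

  void solubleEG(int d, const EnzP& e, double& counter, int mf,
                 std::array<long long, 4>& tl) {
    if (d == 1) { counter += e.nInhG; tl[T_INH]++; return; }
    if (d == 2) { counter += e.nInhG2; tl[T_INH]++; return; }
    if (d < e.minDp) { counter += e.nNb; tl[T_NB]++; return; }
    // uniform bond in a soluble DP-5/6 oligomer; terminal cuts make glucose
    int k = 1 + (int) (ru() * (d - 1));
    if (k > d - 1) k = d - 1;
    double p = 1.0;
    if (k == 1 || k == d - 1) p *= e.pGlucEnd;
    if (ru() >= p) { counter += e.nNp; tl[T_NP]++; return; }
    pool[mf][d]--; pool[mf][k]++; pool[mf][d - k]++;
    counter += 1.0; tl[T_PROD]++;
  }

  void solubleCBH(int d, const EnzP& e, double& counter, int mf, bool fromNR,
                  std::array<long long, 4>& tl) {
    if (d == 1) { counter += e.nInhG; tl[T_INH]++; return; }
    if (d == 2) { counter += e.nInhG2; tl[T_INH]++; return; }
    if (d < e.minDp) { counter += e.nNb; tl[T_NB]++; return; }
    if (ru() >= e.pSol) { counter += e.nNp; tl[T_NP]++; return; }
    (void) fromNR; // products are symmetric: G2 + G(d-2)
    pool[mf][d]--; pool[mf][2]++; pool[mf][d - 2]++;
    counter += 1.0; tl[T_PROD]++;
  }

  void attemptBG(int d, const EnzP& e, double& counter, int mf,
                 std::array<long long, 4>& tl) {
    if (d == 1) { counter += e.nInhG; tl[T_INH]++; return; }
    if (d == 2) {
      if (ru() < e.pBgG2) {
        pool[mf][2]--; pool[mf][1] += 2;
        counter += 1.0; tl[T_PROD]++;
      } else { counter += e.nNp; tl[T_NP]++; }
      return;
    }
    if (ru() < e.pBgOligo) {
      pool[mf][d]--; pool[mf][d - 1]++; pool[mf][1]++;
      counter += 1.0; tl[T_PROD]++;
    } else { counter += e.nNp; tl[T_NP]++; }
  }

  inline long long poolSum(int mf) const {
    long long s = 0;
    for (int d = 1; d <= 6; ++d) s += pool[mf][d];
    return s;
  }

  // spend one (enzyme, MF) minute budget
  void spendBudget(int ei, int mf, double limit) {
    const EnzP& e = enz[ei];
    std::array<long long, 4>& tl = tally[ei];
    double counter = 0.0;
    while (counter < limit) {
      if (e.cls == BG) {
        long long L = poolSum(mf);
        if (L <= 0) break;
        long long r = (long long) (ru() * (double) L);
        if (r >= L) r = L - 1;
        int d = 1;
        while (r >= pool[mf][d]) { r -= pool[mf][d]; d++; }
        attemptBG(d, e, counter, mf, tl);
      } else {
        long long Ns = (long long) surfList[mf].size();
        long long L = Ns + poolSum(mf);
        if (L <= 0) break;
        long long r = (long long) (ru() * (double) L);
        if (r >= L) r = L - 1;
        if (r < Ns) {
          int u = surfList[mf][(size_t) r];
          if (isEG(e.cls)) attemptEG(u, e, counter, limit, mf, tl);
          else if (isCBH1(e.cls)) attemptCBH1(u, e, counter, limit, mf, tl);
          else attemptCBH2(u, e, counter, limit, mf, tl);
        } else {
          r -= Ns;
          int d = 1;
          while (r >= pool[mf][d]) { r -= pool[mf][d]; d++; }
          if (isEG(e.cls)) solubleEG(d, e, counter, mf, tl);
          else solubleCBH(d, e, counter, mf, !isCBH1(e.cls), tl);
        }
      }
    }
  }
};

// [[Rcpp::export(name = ".cpp_run_engine")]]
List cpp_run_engine(IntegerVector chainStart, IntegerVector chainDp,
                    IntegerVector chainMf, IntegerVector chainBelow,
                    IntegerVector chainMfSurf, IntegerVector chainDepth,
                    RawVector crystalline, int nMf,
                    NumericMatrix enzymeParams, int durationMin,
                    int recordInterval, NumericMatrix initPool) {
  Engine eng;
  eng.init(chainStart, chainDp, chainMf, chainBelow, chainMfSurf, chainDepth,
           crystalline, nMf, initPool);

  int nEnz = enzymeParams.nrow();
  eng.enz.resize(nEnz);
  for (int i = 0; i < nEnz; ++i) {
    EnzP& e = eng.enz[i];
    e.cls = (int) enzymeParams(i, 0);
    e.nMax = enzymeParams(i, 1);
    e.footprint = (int) enzymeParams(i, 2);
    e.minDp = (int) enzymeParams(i, 3);
    e.prefDp = (int) enzymeParams(i, 4);
    e.pLong = enzymeParams(i, 5);
    e.pCryst = enzymeParams(i, 6);
    e.pBuried = enzymeParams(i, 7);
    e.pGlucEnd = enzymeParams(i, 8);
    e.pDesAm = enzymeParams(i, 9);
    e.pDesCr = enzymeParams(i, 10);
    e.pSol = enzymeParams(i, 11);
    e.pBgG2 = enzymeParams(i, 12);
    e.pBgOligo = enzymeParams(i, 13);
    e.nNb = enzymeParams(i, 14);
    e.nNp = enzymeParams(i, 15);
    e.nInhG = enzymeParams(i, 16);
    e.nInhG2 = enzymeParams(i, 17);
  }
  eng.tally.assign(nEnz, std::array<long long, 4>());
  for (int i = 0; i < nEnz; ++i) for (int k = 0; k < 4; ++k) eng.tally[i][k] = 0;

  // trajectory storage
  int nRec = 2 + durationMin / std::max(1, recordInterval) + 1;
  NumericMatrix traj(nRec, 11);
  int rec = 0;
  colnames(traj) = CharacterVector::create(
    "minute", "nGlu", "nG2", "nG3", "nG4", "nG5", "nG6",
    "insolubleUnits", "crystallineInsoluble", "fragments", "solubilizedUnits");
  long long poolTot[7];

  struct Work { int ei, mf; double limit; };
  std::vector<Work> works;
  works.reserve((size_t) nEnz * nMf);

  for (int minute = 0; minute <= durationMin; ++minute) {
    if (minute > 0) {
      eng.minuteNow = minute;
      works.clear();
      for (int i = 0; i < nEnz; ++i) {
        const EnzP& e = eng.enz[i];
        double denom = 0.0;
        std::vector<double> w((size_t) nMf, 0.0);
        for (int j = 0; j < nMf; ++j) {
          double wj;
          if (isEG(e.cls)) wj = (double) eng.surfList[j].size();
          else if (isCBH1(e.cls)) wj = (double) eng.NR[j];
          else if (isCBH2(e.cls)) wj = (double) eng.NNR[j];
          else wj = (double) eng.poolSum(j);
          w[j] = wj; denom += wj;
        }
        if (denom <= 0.0) continue;
        for (int j = 0; j < nMf; ++j) {
          double share = e.nMax * w[j] / denom;
          double lim = std::floor(share);
          if (ru() < share - lim) lim += 1.0;
          if (lim > 0.0) works.push_back(Work{ i, j, lim });
        }
      }
      // randomize the order of (enzyme, MF) work units within the minute
      for (int k = (int) works.size() - 1; k > 0; --k) {
        int m = (int) (ru() * (k + 1));
        if (m > k) m = k;
        std::swap(works[(size_t) k], works[(size_t) m]);
      }
      for (size_t k = 0; k < works.size(); ++k)
        eng.spendBudget(works[k].ei, works[k].mf, works[k].limit);
    }
    bool atRecord = (minute % std::max(1, recordInterval) == 0) ||
      minute == durationMin;
    if (atRecord && rec < nRec) {
      for (int d = 1; d <= 6; ++d) {
        poolTot[d] = 0;
        for (int j = 0; j < nMf; ++j) poolTot[d] += eng.pool[j][d];
      }
      traj(rec, 0) = minute;
      for (int d = 1; d <= 6; ++d) traj(rec, d) = (double) poolTot[d];
      traj(rec, 7) = (double) eng.insol;
      traj(rec, 8) = (double) eng.crystInsol;
      traj(rec, 9) = (double) eng.fragsN;
      traj(rec, 10) = (double) eng.solub;
      rec++;
    }
  }
  traj = traj(Range(0, rec - 1), _);

  NumericMatrix poolByMf(nMf, 6);
  for (int j = 0; j < nMf; ++j)
    for (int d = 1; d <= 6; ++d) poolByMf(j, d - 1) = (double) eng.pool[j][d];

  NumericMatrix tallies(nEnz, 4);
  colnames(tallies) = CharacterVector::create(
    "productive", "noBinding", "nonProductive", "inhibited");
  for (int i = 0; i < nEnz; ++i)
    for (int k = 0; k < 4; ++k) tallies(i, k) = (double) eng.tally[i][k];

  NumericMatrix census(nMf, 4);
  colnames(census) = CharacterVector::create("nS", "nR", "nNR", "nSL");
  for (int j = 0; j < nMf; ++j) {
    census(j, 0) = (double) eng.surfList[j].size();
    census(j, 1) = (double) eng.NR[j];
    census(j, 2) = (double) eng.NNR[j];
    census(j, 3) = (double) eng.poolSum(j);
  }

  RawVector remOut(eng.nUnits), brkOut(eng.nUnits), surfOut(eng.nUnits);
  for (int i = 0; i < eng.nUnits; ++i) {
    RAW(remOut)[i] = eng.removed[i];
    RAW(brkOut)[i] = eng.broken[i];
    RAW(surfOut)[i] = eng.surf[i];
  }

  return List::create(
    _["trajectory"] = traj,
    _["poolByMf"] = poolByMf,
    _["tallies"] = tallies,
    _["census"] = census,
    _["removed"] = remOut,
    _["broken"] = brkOut,
    _["surface"] = surfOut);
}
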