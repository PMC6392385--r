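#include <Rcpp.h>
#include <vector>
#include <cstring>
#include <cmath>
#include <climits>
using namespace Rcpp;

// Demes are indexed 0 = LW, 1 = ML, 2 = HG throughout.
// Bases are indexed 0 = A, 1 = C, 2 = G, 3 = T; >= 4 means missing/ambiguous.

struct Event {
  int type;     // 0 = split (all src lineages -> tgt), 1 = admixture
  double time;  // generations before present
  int src, tgt, tgt2;
  double r;     // admixture: lineage goes to tgt with prob r, else tgt2
};

// ---------------------------------------------------------------------------
// Structured Kingman coalescent with split/admixture events.
// Waiting time to coalescence among k lineages in a haploid deme of size N is
// exponential with rate k(k-1)/(2N) generations^-1.
// Node ids: tips 0..ntot-1 (grouped by deme), internal ntot..2*ntot-2,
// created in increasing time order, so parent id > child id always.
static bool sim_genealogy_core(const int ntip[3], const double N[3],
                               const std::vector<Event>& evs,
                               std::vector<int>& parent,
                               std::vector<double>& ntime) {
  const int ntot = ntip[0] + ntip[1] + ntip[2];
  const int nmax = 2 * ntot - 1;
  parent.assign(nmax, -1);
  ntime.assign(nmax, 0.0);
  std::vector<int> deme(nmax, -1);
  std::vector<int> act;
  act.reserve(ntot);
  int id = 0;
  for (int d = 0; d < 3; ++d)
    for (int k = 0; k < ntip[d]; ++k) { deme[id] = d; act.push_back(id); ++id; }
  int nxt = ntot;
  double t = 0.0;
  size_t ei = 0;
  std::vector<int> buf(ntot);

  while ((int)act.size() > 1) {
    int cnt[3] = {0, 0, 0};
    for (size_t a = 0; a < act.size(); ++a) cnt[deme[act[a]]]++;
    double rate[3], R = 0.0;
    for (int d = 0; d < 3; ++d) {
      rate[d] = cnt[d] > 1 ? cnt[d] * (cnt[d] - 1.0) / (2.0 * N[d]) : 0.0;
      R += rate[d];
    }
    const double tEv = (ei < evs.size()) ? evs[ei].time : R_PosInf;
    const double dt = (R > 0.0) ? R::exp_rand() / R : R_PosInf;
    if (t + dt < tEv) {
      t += dt;
      double u = R::unif_rand() * R;
      int d = 0;
      double acc = rate[0];
      while (u > acc && d < 2) { ++d; acc += rate[d]; }
      int nb = 0;
      for (size_t a = 0; a < act.size(); ++a)
        if (deme[act[a]] == d) buf[nb++] = (int)a;
      int i1 = (int)(R::unif_rand() * nb); if (i1 >= nb) i1 = nb - 1;
      int i2 = (int)(R::unif_rand() * (nb - 1)); if (i2 >= nb - 1) i2 = nb - 2;
      if (i2 >= i1) ++i2;
      const int pa = buf[i1], pb = buf[i2];
      parent[act[pa]] = nxt;
      parent[act[pb]] = nxt;
      ntime[nxt] = t;
      deme[nxt] = d;
      act[pa] = nxt;
      act[pb] = act.back();
      act.pop_back();
      ++nxt;
    } else {
      if (!R_FINITE(tEv)) return false;  // lineages stranded in isolated demes
      if (tEv > t) t = tEv;  // never step backward if events arrive unsorted
      const Event& e = evs[ei];
      for (size_t a = 0; a < act.size(); ++a) {
        if (deme[act[a]] != e.src) continue;
        if (e.type == 0) deme[act[a]] = e.tgt;
        else deme[act[a]] = (R::unif_rand() < e.r) ? e.tgt : e.tgt2;
      }
      ++ei;
    }
  }
  return true;
}

// ---------------------------------------------------------------------------
// HKY85 transition probability matrix, exact closed form (TN93 family with
// equal transition rates). d is the expected number of substitutions per site
// (mu * branch length in generations); the rate matrix is normalised so the
// stationary flux is one substitution per unit d.
static void hky_pmat(double d, double kappa, const double* pi, double P[4][4]) {
  const double piR = pi[0] + pi[2], piY = pi[1] + pi[3];
  const double m = 2.0 * kappa * (pi[0] * pi[2] + pi[1] * pi[3]) + 2.0 * piR * piY;
  const double s = (m > 0.0 && d > 0.0) ? d / m : 0.0;
  const double eb = std::exp(-s);
  const double eR = std::exp(-s * (piR * kappa + piY));
  const double eY = std::exp(-s * (piY * kappa + piR));
  for (int i = 0; i < 4; ++i) {
    const bool iPur = (i == 0 || i == 2);
    for (int j = 0; j < 4; ++j) {
      const bool jPur = (j == 0 || j == 2);
      if (iPur != jPur) { P[i][j] = pi[j] * (1.0 - eb); continue; }
      const double piS = iPur ? piR : piY;
      const double piO = iPur ? piY : piR;
      const double ec = iPur ? eR : eY;
      if (i == j)
        P[i][j] = pi[j] + pi[j] * (piO / piS) * eb + ((piS - pi[j]) / piS) * ec;
      else
        P[i][j] = pi[j] + pi[j] * (piO / piS) * eb - (pi[j] / piS) * ec;
    }
  }
}

static void evolve_core(const std::vector<int>& parent,
                        const std::vector<double>& ntime,
                        int ntot, int L, double mu, double kappa,
                        const double pi[4], std::vector<unsigned char>& seqs) {
  const int nmax = 2 * ntot - 1, root = nmax - 1;
  seqs.assign((size_t)nmax * L, 0);
  double cpi[4] = {pi[0], pi[0] + pi[1], pi[0] + pi[1] + pi[2], 1.0};
  unsigned char* rs = &seqs[(size_t)root * L];
  for (int s = 0; s < L; ++s) {
    const double u = R::unif_rand();
    int b = 0;
    while (u > cpi[b] && b < 3) ++b;
    rs[s] = (unsigned char)b;
  }
  double C[4][4], P[4][4];
  for (int v = nmax - 2; v >= 0; --v) {
    const double d = mu * (ntime[parent[v]] - ntime[v]);
    const unsigned char* ps = &seqs[(size_t)parent[v] * L];
    unsigned char* vs = &seqs[(size_t)v * L];
    if (d <= 0.0) { std::memcpy(vs, ps, L); continue; }
    hky_pmat(d, kappa, pi, P);
    for (int i = 0; i < 4; ++i) {
      C[i][0] = P[i][0];
      for (int j = 1; j < 3; ++j) C[i][j] = C[i][j - 1] + P[i][j];
      C[i][3] = 1.0;
    }
    for (int s = 0; s < L; ++s) {
      const double u = R::unif_rand();
      const double* c = C[ps[s]];
      int b = 0;
      while (u > c[b] && b < 3) ++b;
      vs[s] = (unsigned char)b;
    }
  }
}

// ---------------------------------------------------------------------------
// Summary statistics. Stat order (33 entries), groups LW, ML, HG then pairs
// LW-ML, LW-HG, ML-HG:
//  per group: nhap, segsites, pi_mean, pi_var, tajd, private, rarest (7 x 3)
//  per pair:  nhap, segsites, pi_mean, fst                          (4 x 3)
static double tajimas_d_from(int n, int S, double pimean) {
  if (n < 2 || S <= 0) return 0.0;
  double a1 = 0.0, a2 = 0.0;
  for (int i = 1; i < n; ++i) { a1 += 1.0 / i; a2 += 1.0 / ((double)i * i); }
  const double b1 = (n + 1.0) / (3.0 * (n - 1.0));
  const double b2 = 2.0 * (n * (double)n + n + 3.0) / (9.0 * n * (n - 1.0));
  const double c1 = b1 - 1.0 / a1;
  const double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  const double e1 = c1 / a1;
  const double e2 = c2 / (a1 * a1 + a2);
  const double den = std::sqrt(e1 * S + e2 * (double)S * (S - 1.0));
  if (den <= 0.0) return 0.0;
  return (pimean - S / a1) / den;
}

static void sumstats_core(const unsigned char* seqs, int ntot, int L,
                          const int gsz[3], double* out) {
  const int goff[3] = {0, gsz[0], gsz[0] + gsz[1]};
  // pairwise difference counts and exact-identity flags over all tip pairs
  std::vector<int> diff((size_t)ntot * ntot, 0);
  std::vector<unsigned char> same((size_t)ntot * ntot, 0);
  for (int i = 0; i < ntot; ++i) {
    const unsigned char* si = seqs + (size_t)i * L;
    for (int j = i + 1; j < ntot; ++j) {
      const unsigned char* sj = seqs + (size_t)j * L;
      int nd = 0;
      bool eq = true;
      for (int s = 0; s < L; ++s) {
        const unsigned char a = si[s], b = sj[s];
        if (a != b) { eq = false; if (a < 4 && b < 4) ++nd; }
      }
      diff[(size_t)i * ntot + j] = nd;
      diff[(size_t)j * ntot + i] = nd;
      same[(size_t)i * ntot + j] = eq;
      same[(size_t)j * ntot + i] = eq;
    }
  }
  // per-group per-site base counts
  std::vector<int> cnt(3 * (size_t)L * 4, 0);
  for (int g = 0; g < 3; ++g)
    for (int k = 0; k < gsz[g]; ++k) {
      const unsigned char* si = seqs + (size_t)(goff[g] + k) * L;
      int* cg = &cnt[(size_t)g * L * 4];
      for (int s = 0; s < L; ++s)
        if (si[s] < 4) cg[(size_t)s * 4 + si[s]]++;
    }
  auto nstates = [&](int g, int s) {
    const int* c = &cnt[((size_t)g * L + s) * 4];
    int k = 0;
    for (int b = 0; b < 4; ++b) if (c[b] > 0) ++k;
    return k;
  };

  double gmean[3] = {0, 0, 0};
  int p = 0;
  for (int g = 0; g < 3; ++g) {
    const int n = gsz[g], o = goff[g];
    // haplotypes: rows with no identical earlier row in the group
    int nh = 0;
    for (int i = 0; i < n; ++i) {
      bool uniq = true;
      for (int j = 0; j < i; ++j)
        if (same[(size_t)(o + i) * ntot + (o + j)]) { uniq = false; break; }
      if (uniq) ++nh;
    }
    // segregating sites, private sites, rarest-allele mean
    int S = 0, priv = 0;
    double rar = 0.0;
    for (int s = 0; s < L; ++s) {
      if (nstates(g, s) < 2) continue;
      ++S;
      const int* c = &cnt[((size_t)g * L + s) * 4];
      int mn = INT_MAX;
      for (int b = 0; b < 4; ++b) if (c[b] > 0 && c[b] < mn) mn = c[b];
      rar += mn;
      // private: monomorphic over the union of the other two groups
      int ost = 0;
      for (int b = 0; b < 4; ++b) {
        int tot = 0;
        for (int g2 = 0; g2 < 3; ++g2)
          if (g2 != g) tot += cnt[((size_t)g2 * L + s) * 4 + b];
        if (tot > 0) ++ost;
      }
      if (ost <= 1) ++priv;
    }
    rar = S > 0 ? rar / S : 0.0;
    // pairwise moments
    double sum = 0.0, sum2 = 0.0;
    const long np = (long)n * (n - 1) / 2;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        const double d = diff[(size_t)(o + i) * ntot + (o + j)];
        sum += d;
        sum2 += d * d;
      }
    const double mean = np > 0 ? sum / np : 0.0;
    const double var = np > 0 ? sum2 / np - mean * mean : 0.0;
    gmean[g] = mean;
    out[p++] = nh;
    out[p++] = S;
    out[p++] = mean;
    out[p++] = var >= 0.0 ? var : 0.0;
    out[p++] = tajimas_d_from(n, S, mean);
    out[p++] = priv;
    out[p++] = rar;
  }

  const int pa[3] = {0, 0, 1}, pb[3] = {1, 2, 2};
  for (int q = 0; q < 3; ++q) {
    const int ga = pa[q], gb = pb[q];
    const int na = gsz[ga], nb = gsz[gb], oa = goff[ga], ob = goff[gb];
    // pooled haplotypes
    int nh = 0;
    std::vector<int> rows;
    rows.reserve(na + nb);
    for (int k = 0; k < na; ++k) rows.push_back(oa + k);
    for (int k = 0; k < nb; ++k) rows.push_back(ob + k);
    for (size_t i = 0; i < rows.size(); ++i) {
      bool uniq = true;
      for (size_t j = 0; j < i; ++j)
        if (same[(size_t)rows[i] * ntot + rows[j]]) { uniq = false; break; }
      if (uniq) ++nh;
    }
    // pooled segregating sites
    int S = 0;
    for (int s = 0; s < L; ++s) {
      int ost = 0;
      for (int b = 0; b < 4; ++b)
        if (cnt[((size_t)ga * L + s) * 4 + b] + cnt[((size_t)gb * L + s) * 4 + b] > 0) ++ost;
      if (ost >= 2) ++S;
    }
    // pooled mean pairwise differences and HSM FST
    double sumW = 0.0;
    for (int i = 0; i < na; ++i)
      for (int j = i + 1; j < na; ++j) sumW += diff[(size_t)(oa + i) * ntot + (oa + j)];
    for (int i = 0; i < nb; ++i)
      for (int j = i + 1; j < nb; ++j) sumW += diff[(size_t)(ob + i) * ntot + (ob + j)];
    double sumB = 0.0;
    for (int i = 0; i < na; ++i)
      for (int j = 0; j < nb; ++j) sumB += diff[(size_t)(oa + i) * ntot + (ob + j)];
    const long npool = (long)(na + nb) * (na + nb - 1) / 2;
    const double meanPool = npool > 0 ? (sumW + sumB) / npool : 0.0;
    const double Hw = 0.5 * (gmean[ga] + gmean[gb]);
    const double Hb = (na > 0 && nb > 0) ? sumB / ((double)na * nb) : 0.0;
    const double fst = Hb > 0.0 ? 1.0 - Hw / Hb : 0.0;
    out[p++] = nh;
    out[p++] = S;
    out[p++] = meanPool;
    out[p++] = fst;
  }
}

static std::vector<Event> events_from_matrix(const NumericMatrix& ev) {
  std::vector<Event> out;
  for (int i = 0; i < ev.nrow(); ++i) {
    Event e;
    e.type = (int)ev(i, 0);
    e.time = ev(i, 1);
    e.src = (int)ev(i, 2);
    e.tgt = (int)ev(i, 3);
    e.tgt2 = (int)ev(i, 4);
    e.r = ev(i, 5);
    out.push_back(e);
  }
  return out;
}

// [[Rcpp::export]]
List sim_genealogy_cpp(IntegerVector n_tip, NumericVector N, NumericMatrix events) {
  int ntip[3] = {n_tip[0], n_tip[1], n_tip[2]};
  double Nv[3] = {N[0], N[1], N[2]};
  std::vector<Event> evs = events_from_matrix(events);
  std::vector<int> parent;
  std::vector<double> ntime;
  if (!sim_genealogy_core(ntip, Nv, evs, parent, ntime))
    stop("scenario leaves lineages in demes with no common ancestor");
  return List::create(_["parent"] = wrap(parent), _["node_time"] = wrap(ntime));
}

// [[Rcpp::export]]
IntegerMatrix evolve_sequences_cpp(IntegerVector parent, NumericVector node_time,
                                   int n_tip, double mu, double kappa,
                                   NumericVector base_freq, int n_sites) {
  const int nmax = parent.size();
  if (nmax != 2 * n_tip - 1) stop("parent vector inconsistent with tip count");
  std::vector<int> par(parent.begin(), parent.end());
  std::vector<double> tim(node_time.begin(), node_time.end());
  double pi[4] = {base_freq[0], base_freq[1], base_freq[2], base_freq[3]};
  std::vector<unsigned char> seqs;
  evolve_core(par, tim, n_tip, n_sites, mu, kappa, pi, seqs);
  IntegerMatrix out(n_tip, n_sites);
  for (int i = 0; i < n_tip; ++i)
    for (int s = 0; s < n_sites; ++s) out(i, s) = seqs[(size_t)i * n_sites + s];
  return out;
}

// [[Rcpp::export]]
NumericVector sumstats_cpp(IntegerMatrix seqs, IntegerVector group_sizes) {
  const int ntot = seqs.nrow(), L = seqs.ncol();
  int gsz[3] = {group_sizes[0], group_sizes[1], group_sizes[2]};
  if (gsz[0] + gsz[1] + gsz[2] != ntot) stop("group sizes do not sum to row count");
  std::vector<unsigned char> s((size_t)ntot * L);
  for (int i = 0; i < ntot; ++i)
    for (int c = 0; c < L; ++c) {
      int v = seqs(i, c);
      s[(size_t)i * L + c] = (unsigned char)(v >= 0 && v < 4 ? v : 4);
    }
  NumericVector out(33);
  sumstats_core(&s[0], ntot, L, gsz, REAL(out));
  return out;
}

// [[Rcpp::export]]
NumericMatrix abc_batch_cpp(List templates, IntegerVector scen, NumericMatrix params,
                            IntegerVector n_tip, int n_sites, NumericVector base_freq) {
  // params columns: N_LW, N_ML, N_HG, t1, t2, r, mu, kappa
  const int nsim = params.nrow();
  int ntip[3] = {n_tip[0], n_tip[1], n_tip[2]};
  const int ntot = ntip[0] + ntip[1] + ntip[2];
  double pi[4] = {base_freq[0], base_freq[1], base_freq[2], base_freq[3]};
  // parse templates (per scenario): cols type, tcode(1->t1, 2->t2), src, tgt, tgt2, use_r
  std::vector<std::vector<std::vector<double> > > tpl(templates.size());
  for (int k = 0; k < templates.size(); ++k) {
    NumericMatrix m = templates[k];
    for (int i = 0; i < m.nrow(); ++i) {
      std::vector<double> row(6);
      for (int j = 0; j < 6; ++j) row[j] = m(i, j);
      tpl[k].push_back(row);
    }
  }
  NumericMatrix out(nsim, 33);
  std::vector<int> parent;
  std::vector<double> ntime;
  std::vector<unsigned char> seqs;
  for (int i = 0; i < nsim; ++i) {
    if ((i & 255) == 0) Rcpp::checkUserInterrupt();
    const int sc = scen[i] - 1;
    if (sc < 0 || sc >= (int)tpl.size()) stop("scenario id out of range");
    const double t1 = params(i, 3), t2 = params(i, 4), r = params(i, 5);
    double N[3] = {params(i, 0), params(i, 1), params(i, 2)};
    std::vector<Event> evs;
    for (size_t k = 0; k < tpl[sc].size(); ++k) {
      const std::vector<double>& row = tpl[sc][k];
      Event e;
      e.type = (int)row[0];
      e.time = (row[1] == 1.0) ? t1 : t2;
      e.src = (int)row[2];
      e.tgt = (int)row[3];
      e.tgt2 = (int)row[4];
      e.r = row[5] != 0.0 ? r : 0.0;
      evs.push_back(e);
    }
    if (!sim_genealogy_core(ntip, N, evs, parent, ntime))
      stop("scenario leaves lineages in demes with no common ancestor");
    evolve_core(parent, ntime, ntot, n_sites, params(i, 6), params(i, 7), pi, seqs);
    double buf[33];
    sumstats_core(&seqs[0], ntot, n_sites, ntip, buf);
    for (int j = 0; j < 33; ++j) out(i, j) = buf[j];  // NumericMatrix is column-major
  }
  return out;
}
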