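#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Forward-time offspring construction: recombination with a Poisson number
// of crossovers per chromosome, supergene inviability, per-copy effect
// inheritance, and mutation. Uses R's RNG throughout so set.seed() governs
// the stream.
//
// Layout: haplotypes are COLUMNS. state is (n_chrom * L) x (2 * N); columns
// 2i, 2i+1 (0-based) are individual i's haplotypes. effc/effp are
// (n_qtl_trait) x (2 * N) matrices of the effects carried by each QTL copy,
// rows ordered as the architecture's QTL table for that trait.
//
// Allele states are assumed to be in {0, 1}: the initial draw is Bernoulli
// and mutation re-draws among the states currently segregating at a locus,
// so no other state can ever arise.

// Build one gamete from parent p into output column `ocol`.
// Returns false if a crossover falls strictly inside the supergene region
// (the zygote using this gamete is inviable and discarded, not redrawn).
static bool make_gamete(const IntegerMatrix& state,
                        const NumericMatrix& effc, const NumericMatrix& effp,
                        const IntegerVector& qtlc_loc, const IntegerVector& qtlp_loc,
                        int p, int n_chrom, int L, double recomb_rate,
                        int sg_chrom, int sg_start, int sg_end,
                        IntegerMatrix& out_state,
                        NumericMatrix& out_effc, NumericMatrix& out_effp,
                        int ocol, std::vector<int>& src_buf) {
  const int h0 = 2 * p, h1 = 2 * p + 1;
  std::vector<int> bp;
  for (int chr = 0; chr < n_chrom; ++chr) {
    const int base = chr * L;
    int k = (int) R::rpois(recomb_rate);
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    if (k == 0) {
      const int* src = &state(base, cur ? h1 : h0);
      int* dst = &out_state(base, ocol);
      std::copy(src, src + L, dst);
      std::fill(src_buf.begin() + base, src_buf.begin() + base + L, cur);
    } else {
      bp.clear();
      for (int j = 0; j < k; ++j) {
        int b = (int) (unif_rand() * L);
        if (b >= L) b = L - 1;
        if (chr == sg_chrom && b > sg_start && b < sg_end) return false;
        bp.push_back(b);
      }
      std::sort(bp.begin(), bp.end());
      int bi = 0;
      const int* s0 = &state(base, h0);
      const int* s1 = &state(base, h1);
      int* dst = &out_state(base, ocol);
      for (int l = 0; l < L; ++l) {
        while (bi < k && bp[bi] == l) { cur ^= 1; ++bi; }
        dst[l] = cur ? s1[l] : s0[l];
        src_buf[base + l] = cur;
      }
    }
  }
  for (int q = 0; q < qtlc_loc.size(); ++q) {
    const int hap = src_buf[qtlc_loc[q]];
    out_effc(q, ocol) = effc(q, hap ? h1 : h0);
  }
  for (int q = 0; q < qtlp_loc.size(); ++q) {
    const int hap = src_buf[qtlp_loc[q]];
    out_effp(q, ocol) = effp(q, hap ? h1 : h0);
  }
  return true;
}

// [[Rcpp::export]]
List cpp_make_offspring(IntegerMatrix state, NumericMatrix effc,
                        NumericMatrix effp, IntegerVector sire,
                        IntegerVector dam, int n_chrom, int L,
                        IntegerVector qtlc_loc, IntegerVector qtlp_loc,
                        double recomb_rate, int sg_chrom, int sg_start,
                        int sg_end, double mu, double sigma_mu) {
  const int n_off = sire.size();
  const int Lg = n_chrom * L;
  IntegerMatrix out_state(Lg, 2 * n_off);
  NumericMatrix out_effc(std::max((int) qtlc_loc.size(), 1), 2 * n_off);
  NumericMatrix out_effp(std::max((int) qtlp_loc.size(), 1), 2 * n_off);
  LogicalVector viable(n_off);
  IntegerVector n_mut(n_off);
  std::vector<int> src_buf(Lg);

  // which allele states segregate at each locus in the parental population
  std::vector<unsigned char> has0(Lg, 0), has1(Lg, 0);
  if (mu > 0) {
    for (int c = 0; c < state.ncol(); ++c) {
      const int* col = &state(0, c);
      for (int l = 0; l < Lg; ++l) {
        if (col[l]) has1[l] = 1; else has0[l] = 1;
      }
    }
  }
  // locus -> QTL row lookup, per trait
  std::vector<int> qrow_c(Lg, -1), qrow_p(Lg, -1);
  for (int q = 0; q < qtlc_loc.size(); ++q) qrow_c[qtlc_loc[q]] = q;
  for (int q = 0; q < qtlp_loc.size(); ++q) qrow_p[qtlp_loc[q]] = q;

  const double mut_mean = 2.0 * mu * L * n_chrom;
  for (int o = 0; o < n_off; ++o) {
    bool ok = make_gamete(state, effc, effp, qtlc_loc, qtlp_loc, sire[o],
                          n_chrom, L, recomb_rate, sg_chrom, sg_start, sg_end,
                          out_state, out_effc, out_effp, 2 * o, src_buf);
    if (ok) {
      ok = make_gamete(state, effc, effp, qtlc_loc, qtlp_loc, dam[o],
                       n_chrom, L, recomb_rate, sg_chrom, sg_start, sg_end,
                       out_state, out_effc, out_effp, 2 * o + 1, src_buf);
    }
    viable[o] = ok;
    if (!ok || mu <= 0) continue;
    int k = (int) R::rpois(mut_mean);
    n_mut[o] = k;
    for (int j = 0; j < k; ++j) {
      const int hap = (unif_rand() < 0.5) ? 0 : 1;
      int l = (int) (unif_rand() * Lg);
      if (l >= Lg) l = Lg - 1;
      const int col = 2 * o + hap;
      if (has0[l] && has1[l]) {
        out_state(l, col) = (unif_rand() < 0.5) ? 0 : 1;
      } else {
        out_state(l, col) = has1[l] ? 1 : 0;
      }
      if (qrow_c[l] >= 0) out_effc(qrow_c[l], col) += R::rnorm(0.0, sigma_mu);
      if (qrow_p[l] >= 0) out_effp(qrow_p[l], col) += R::rnorm(0.0, sigma_mu);
    }
  }
  return List::create(_["state"] = out_state, _["eff_c"] = out_effc,
                      _["eff_p"] = out_effp, _["viable"] = viable,
                      _["n_mut"] = n_mut);
}
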