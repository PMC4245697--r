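#include <Rcpp.h>
using namespace Rcpp;

// Mixing weights omega[j | snp genotype k] for the LD-based QTL mixture:
// haplotype frequencies from (p, q, D), joint genotype probabilities under
// random union of gametes, normalised by the SNP genotype marginals.
// k, j indexed 0..2 with order (MM, Mm, mm) and (AA, Aa, aa).
static void omega_given_snp(double p, double q, double D, double omega[3][3]) {
  double p11 = p * q + D;
  double p10 = p * (1.0 - q) - D;
  double p01 = (1.0 - p) * q - D;
  double p00 = (1.0 - p) * (1.0 - q) + D;
  if (p11 < 0) p11 = 0; if (p10 < 0) p10 = 0;
  if (p01 < 0) p01 = 0; if (p00 < 0) p00 = 0;
  double joint[3][3] = {
    {p11 * p11,        2 * p11 * p10,                  p10 * p10},
    {2 * p11 * p01,    2 * (p11 * p00 + p10 * p01),    2 * p10 * p00},
    {p01 * p01,        2 * p01 * p00,                  p00 * p00}
  };
  for (int k = 0; k < 3; ++k) {
    double marg = joint[k][0] + joint[k][1] + joint[k][2];
    for (int j = 0; j < 3; ++j)
      omega[k][j] = (marg > 0) ? joint[k][j] / marg : 0.0;
  }
}

// One EM fit of the three-component normal mixture with SNP-structured
// mixing weights. snp: genotype class 0=MM, 1=Mm, 2=mm. p is fixed at the
// observed SNP major-allele frequency; (q, D) are updated by an
// expected-haplotype-count M-step with the double-heterozygote phase split
// proportional to p11*p00 vs p10*p01 and the row constraint p11 + p10 = p.
// [[Rcpp::export(name = ".em_core")]]
List em_core(NumericVector y, IntegerVector snp, double p,
             NumericVector mu0, double sigma0, double q0, double D0,
             double tol, int max_iter) {
  const int n = y.size();
  const double LOG2PI = 1.8378770664093453;
  double mu[3] = {mu0[0], mu0[1], mu0[2]};
  double sigma = sigma0, q = q0, D = D0;

  NumericMatrix post(n, 3);
  NumericVector ll_trace(max_iter);
  double ll_prev = R_NegInf, ll = R_NegInf;
  int iter = 0;
  bool converged = false;
  double omega[3][3];

  for (iter = 0; iter < max_iter; ++iter) {
    omega_given_snp(p, q, D, omega);
    double p11 = p * q + D, p10 = p * (1.0 - q) - D;
    double p01 = (1.0 - p) * q - D, p00 = (1.0 - p) * (1.0 - q) + D;

    // E-step: responsibilities over QTL genotypes, and observed loglik
    ll = 0.0;
    double s2 = sigma * sigma;
    double sw[3] = {0, 0, 0}, swy[3] = {0, 0, 0};
    // expected haplotype counts
    double c11 = 0, c10 = 0, c01 = 0, c00 = 0;
    // phase split for (Mm, Aa): probability the two haplotypes are MA + ma
    double wphase = p11 * p00 + p10 * p01;
    double rphase = (wphase > 0) ? (p11 * p00) / wphase : 0.5;

    for (int i = 0; i < n; ++i) {
      int k = snp[i];
      double d[3], m = R_NegInf;
      for (int j = 0; j < 3; ++j) {
        double z = (y[i] - mu[j]) / sigma;
        d[j] = (omega[k][j] > 0)
          ? std::log(omega[k][j]) - 0.5 * (LOG2PI + z * z) - std::log(sigma)
          : R_NegInf;
        if (d[j] > m) m = d[j];
      }
      double tot = 0.0;
      for (int j = 0; j < 3; ++j) {
        d[j] = (d[j] == R_NegInf) ? 0.0 : std::exp(d[j] - m);
        tot += d[j];
      }
      ll += m + std::log(tot);
      for (int j = 0; j < 3; ++j) {
        double pij = d[j] / tot;
        post(i, j) = pij;
        sw[j] += pij;
        swy[j] += pij * y[i];
      }
      // haplotype count contributions given SNP genotype k and QTL j
      double pAA = post(i, 0), pAa = post(i, 1), paa = post(i, 2);
      if (k == 0) {            // MM: two M haplotypes
        c11 += 2 * pAA + pAa;
        c10 += pAa + 2 * paa;
      } else if (k == 2) {     // mm: two m haplotypes
        c01 += 2 * pAA + pAa;
        c00 += pAa + 2 * paa;
      } else {                 // Mm
        c11 += pAA + rphase * pAa;
        c01 += pAA + (1.0 - rphase) * pAa;
        c10 += paa + (1.0 - rphase) * pAa;
        c00 += paa + rphase * pAa;
      }
    }
    ll_trace[iter] = ll;

    // convergence on relative loglik change
    if (iter > 0) {
      double denom = std::fabs(ll_prev) + 1e-12;
      if (std::fabs(ll - ll_prev) / denom < tol) { converged = true; break; }
    }
    ll_prev = ll;

    // M-step: means and common sigma by responsibility-weighted moments
    double newmu[3];
    for (int j = 0; j < 3; ++j)
      newmu[j] = (sw[j] > 1e-12) ? swy[j] / sw[j] : mu[j];
    double ss = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < 3; ++j) {
        double r = y[i] - newmu[j];
        ss += post(i, j) * r * r;
      }
    for (int j = 0; j < 3; ++j) mu[j] = newmu[j];
    sigma = std::sqrt(ss / n);
    if (sigma < 1e-10) sigma = 1e-10;

    // M-step for (q, D): row-constrained haplotype frequency update
    double denM = c11 + c10, denm = c01 + c00;
    double np11 = (denM > 0) ? p * c11 / denM : p * q;
    double np01 = (denm > 0) ? (1.0 - p) * c01 / denm : (1.0 - p) * q;
    double nq = np11 + np01;
    if (nq < 1e-9) nq = 1e-9;
    if (nq > 1.0 - 1e-9) nq = 1.0 - 1e-9;
    double nD = np11 - p * nq;
    // keep D strictly inside the Frechet interval
    double lo = std::max(-p * nq, -(1.0 - p) * (1.0 - nq)) + 1e-9;
    double hi = std::min(p * (1.0 - nq), (1.0 - p) * nq) - 1e-9;
    if (nD < lo) nD = lo;
    if (nD > hi) nD = hi;
    q = nq; D = nD;
    (void) s2;
  }

  int n_iter = converged ? iter + 1 : max_iter;
  return List::create(
    _["mu"] = NumericVector::create(mu[0], mu[1], mu[2]),
    _["sigma"] = sigma, _["q"] = q, _["D"] = D,
    _["loglik"] = ll,
    _["loglik_trace"] = ll_trace[Range(0, n_iter - 1)],
    _["posteriors"] = post,
    _["n_iter"] = n_iter,
    _["converged"] = converged);
}
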