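#include <Rcpp.h>
using namespace Rcpp;

// Bivariate standard normal CDF Phi2(h, k; r) = P(X <= h, Y <= k).
// Genz (2004) adaptation of the Drezner-Wesolowsky algorithm, double precision;
// absolute accuracy ~5e-16 for |r| < 0.925 and ~1e-14 otherwise.
static const double GW[3][10] = {
    {0.1713244923791704, 0.3607615730481386, 0.4679139345726910,
     0, 0, 0, 0, 0, 0, 0},
    {0.04717533638651183, 0.1069393259953184, 0.1600783285433462,
     0.2031674267230659, 0.2334925365383548, 0.2491470458134028,
     0, 0, 0, 0},
    {0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
     0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
     0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
     0.1527533871307259}};
static const double GX[3][10] = {
    {-0.9324695142031522, -0.6612093864662645, -0.2386191860831969,
     0, 0, 0, 0, 0, 0, 0},
    {-0.9815606342467192, -0.9041172563704749, -0.7699026741943047,
     -0.5873179542866175, -0.3678314989981802, -0.1252334085114689,
     0, 0, 0, 0},
    {-0.9931285991850949, -0.9639719272779138, -0.9122344282513259,
     -0.8391169718222188, -0.7463319064601508, -0.6360536807265150,
     -0.5108670019508271, -0.3737060887154195, -0.2277858511416451,
     -0.07652652113349734}};

static double phid(double x) { return R::pnorm(x, 0.0, 1.0, 1, 0); }

// P(X > dh, Y > dk) for standard bivariate normal with correlation r.
static double bvnd(double dh, double dk, double r) {
    const double twopi = 6.283185307179586;
    int ng, lg;
    if (std::fabs(r) < 0.3) { ng = 0; lg = 3; }
    else if (std::fabs(r) < 0.75) { ng = 1; lg = 6; }
    else { ng = 2; lg = 10; }
    double h = dh, k = dk, hk = h * k, bvn = 0.0;
    if (std::fabs(r) < 0.925) {
        if (std::fabs(r) > 0) {
            double hs = (h * h + k * k) / 2.0, asr = std::asin(r);
            for (int i = 0; i < lg; i++) {
                for (int is = -1; is <= 1; is += 2) {
                    double sn = std::sin(asr * (is * GX[ng][i] + 1.0) / 2.0);
                    bvn += GW[ng][i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
                }
            }
            bvn = bvn * asr / (2.0 * twopi);
        }
        bvn += phid(-h) * phid(-k);
    } else {
        if (r < 0) { k = -k; hk = -hk; }
        if (std::fabs(r) < 1) {
            double as = (1.0 - r) * (1.0 + r), a = std::sqrt(as);
            double bs = (h - k) * (h - k);
            double c = (4.0 - hk) / 8.0, d = (12.0 - hk) / 16.0;
            double asr = -(bs / as + hk) / 2.0;
            if (asr > -100.0)
                bvn = a * std::exp(asr) *
                      (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
                       c * d * as * as / 5.0);
            if (-hk < 100.0) {
                double b = std::sqrt(bs);
                bvn -= std::exp(-hk / 2.0) * std::sqrt(twopi) * phid(-b / a) * b *
                       (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
            }
            a /= 2.0;
            for (int i = 0; i < lg; i++) {
                for (int is = -1; is <= 1; is += 2) {
                    double x = a * (is * GX[ng][i] + 1.0);
                    double xs = x * x, rs = std::sqrt(1.0 - xs);
                    asr = -(bs / xs + hk) / 2.0;
                    if (asr > -100.0)
                        bvn += a * GW[ng][i] * std::exp(asr) *
                               (std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs -
                                (1.0 + c * xs * (1.0 + d * xs)));
                }
            }
            bvn = -bvn / twopi;
        }
        if (r > 0) bvn += phid(-std::max(h, k));
        else {
            bvn = -bvn;
            if (k > h) bvn += phid(k) - phid(h);
        }
    }
    return bvn;
}

// CDF with infinite-limit handling.
static double cdf2(double h, double k, double r) {
    if (h == R_NegInf || k == R_NegInf) return 0.0;
    if (h == R_PosInf && k == R_PosInf) return 1.0;
    if (h == R_PosInf) return phid(k);
    if (k == R_PosInf) return phid(h);
    double p = bvnd(-h, -k, r);
    if (p < 0.0) p = 0.0;
    if (p > 1.0) p = 1.0;
    return p;
}

//' Bivariate standard normal distribution function
//'
//' @param h,k upper limits (recycled to common length)
//' @param r correlation in (-1, 1)
//' @return vector of probabilities P(X <= h, Y <= k)
//' @keywords internal
// [[Rcpp::export]]
NumericVector pbvn_cpp(NumericVector h, NumericVector k, double r) {
    R_xlen_t n = std::max(h.size(), k.size());
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; i++)
        out[i] = cdf2(h[i % h.size()], k[i % k.size()], r);
    return out;
}

// Rectangle probability P(a1 < X <= b1, a2 < Y <= b2).
static double rect2(double a1, double b1, double a2, double b2, double r) {
    double p = cdf2(b1, b2, r) - cdf2(a1, b2, r) - cdf2(b1, a2, r) +
               cdf2(a1, a2, r);
    if (p < 0.0) p = 0.0;
    return p;
}

// Negative log-likelihood of the latent-variable model.
// par: (a0,a1,a2, b0,b1,b2, g1, p0,p1, t1..t4, s1,s2, r12,r13,r14,r23,r24,r34)
// dat columns: treat, y10, y20, Y1, Y2, Y3 (1..5), Y4 (0/1)
// Caller guarantees the implied 4x4 covariance is positive definite.
// [[Rcpp::export]]
double negloglik_cpp(NumericVector par, NumericMatrix dat) {
    const double a0 = par[0], a1 = par[1], a2 = par[2];
    const double b0 = par[3], b1 = par[4], b2 = par[5];
    const double g1 = par[6], p0 = par[7], p1 = par[8];
    double tau[6] = {R_NegInf, par[9], par[10], par[11], par[12], R_PosInf};
    const double s1 = par[13], s2 = par[14];
    const double r12 = par[15], r13 = par[16], r14 = par[17];
    const double r23 = par[18], r24 = par[19], r34 = par[20];

    const double om = 1.0 - r12 * r12;
    // conditional (on Y1, Y2) moments of the latent pair: Schur complement of
    // the upper 2x2 block of Sigma
    const double c31 = (r13 - r12 * r23) / (s1 * om);
    const double c32 = (r23 - r12 * r13) / (s2 * om);
    const double c41 = (r14 - r12 * r24) / (s1 * om);
    const double c42 = (r24 - r12 * r14) / (s2 * om);
    const double v3 = 1.0 - (r13 * r13 - 2.0 * r12 * r13 * r23 + r23 * r23) / om;
    const double v4 = 1.0 - (r14 * r14 - 2.0 * r12 * r14 * r24 + r24 * r24) / om;
    const double c34 = r34 - (r13 * r14 + r23 * r24 -
                              r12 * (r13 * r24 + r14 * r23)) / om;
    if (v3 <= 0.0 || v4 <= 0.0) return 1e10;
    const double sd3 = std::sqrt(v3), sd4 = std::sqrt(v4);
    double rc = c34 / (sd3 * sd4);
    if (rc > 0.999999) rc = 0.999999;
    if (rc < -0.999999) rc = -0.999999;

    const double ldet = std::log(s1) + std::log(s2) + 0.5 * std::log(om);
    const double l2pi = 1.837877066409345; // log(2*pi)

    const int n = dat.nrow();
    double nll = 0.0;
    for (int i = 0; i < n; i++) {
        const double t = dat(i, 0), y10 = dat(i, 1), y20 = dat(i, 2);
        const double Y1 = dat(i, 3), Y2 = dat(i, 4);
        const int w = (int)dat(i, 5); // 1..5
        const int k = (int)dat(i, 6); // 0/1
        const double mu1 = a0 + a1 * t + a2 * y10;
        const double mu2 = b0 + b1 * t + b2 * y20;
        const double mu3 = g1 * t;
        const double mu4 = p0 + p1 * t;
        const double z1 = (Y1 - mu1) / s1, z2 = (Y2 - mu2) / s2;
        // log bivariate normal density of (Y1, Y2)
        const double q = (z1 * z1 - 2.0 * r12 * z1 * z2 + z2 * z2) / om;
        nll -= -l2pi - ldet - q / 2.0;
        // conditional cell probability for the observed (Y3, Y4)
        const double m3 = mu3 + c31 * (Y1 - mu1) + c32 * (Y2 - mu2);
        const double m4 = mu4 + c41 * (Y1 - mu1) + c42 * (Y2 - mu2);
        const double lo3 = (tau[w - 1] - m3) / sd3;
        const double hi3 = (tau[w] - m3) / sd3;
        const double lo4 = (k == 0) ? R_NegInf : (0.0 - m4) / sd4;
        const double hi4 = (k == 0) ? (0.0 - m4) / sd4 : R_PosInf;
        double pcell = rect2(lo3, hi3, lo4, hi4, rc);
        if (pcell < 1e-300) pcell = 1e-300;
        nll -= std::log(pcell);
    }
    return nll;
}

// Orthant probabilities P(X <= b) for X ~ N(mu_i, Sigma), vectorised over rows
// of mu and b. L is the lower Cholesky factor of Sigma. Separation-of-variables
// quadrature: the two outer coordinates are integrated with Gauss-Legendre
// nodes (xn, wn on (0,1)); the inner pair reduces to a bivariate normal CDF.
// [[Rcpp::export]]
NumericVector mvn4_cdf_cpp(NumericMatrix mu, NumericMatrix b, NumericMatrix L,
                           NumericVector xn, NumericVector wn) {
    const int n = mu.nrow(), K = xn.size();
    const double l11 = L(0, 0), l21 = L(1, 0), l22 = L(1, 1);
    const double l31 = L(2, 0), l32 = L(2, 1), l33 = L(2, 2);
    const double l41 = L(3, 0), l42 = L(3, 1), l43 = L(3, 2), l44 = L(3, 3);
    const double s = std::sqrt(l43 * l43 + l44 * l44);
    double rc = l43 / s;
    if (rc > 0.999999) rc = 0.999999;
    if (rc < -0.999999) rc = -0.999999;
    const double BIG = 8.5;
    NumericVector out(n);
    for (int i = 0; i < n; i++) {
        double b1 = b(i, 0) - mu(i, 0), b2 = b(i, 1) - mu(i, 1);
        double b3 = b(i, 2) - mu(i, 2), b4 = b(i, 3) - mu(i, 3);
        if (b1 == R_NegInf || b2 == R_NegInf || b3 == R_NegInf ||
            b4 == R_NegInf) { out[i] = 0.0; continue; }
        double e1 = b1 / l11;
        if (e1 > BIG) e1 = BIG;
        if (e1 < -BIG) { out[i] = 0.0; continue; }
        const double p1 = phid(e1);
        double acc1 = 0.0;
        for (int ii = 0; ii < K; ii++) {
            const double z1 = R::qnorm(xn[ii] * p1, 0.0, 1.0, 1, 0);
            double e2 = (b2 - l21 * z1) / l22;
            if (e2 > BIG) e2 = BIG;
            if (e2 < -BIG) continue;
            const double p2 = phid(e2);
            double acc2 = 0.0;
            for (int jj = 0; jj < K; jj++) {
                const double z2 = R::qnorm(xn[jj] * p2, 0.0, 1.0, 1, 0);
                double f3 = (b3 - l31 * z1 - l32 * z2) / l33;
                double g4 = (b4 - l41 * z1 - l42 * z2) / s;
                if (f3 > BIG) f3 = BIG;
                if (g4 > BIG) g4 = BIG;
                if (f3 < -BIG || g4 < -BIG) continue;
                acc2 += wn[jj] * cdf2(f3, g4, rc);
            }
            acc1 += wn[ii] * p2 * acc2;
        }
        out[i] = p1 * acc1;
    }
    return out;
}
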