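/* Brownian-dynamics photon-trace simulator.
 *
 * Particles take independent Gaussian steps (sd = sqrt(2 D dt) per axis)
 * in a periodic box centred on a 3D Gaussian detection profile; each time
 * bin emits Poisson counts with mean
 *   dt * sum_i brightness_i * exp(-2 x^2/r^2 - 2 y^2/r^2 - 2 z^2/z_ax^2).
 *
 * Uses a self-contained xoshiro256++ generator (seeded via splitmix64) so
 * traces are bit-reproducible from the config seed alone, independent of
 * R's RNG state.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>
#include <stdint.h>

typedef struct { uint64_t s[4]; } xo_state;

static uint64_t splitmix64(uint64_t *x) {
    uint64_t z = (*x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
}

static void xo_seed(xo_state *st, uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) st->s[i] = splitmix64(&x);
}

static inline uint64_t rotl(const uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
}

static inline uint64_t xo_next(xo_state *st) {
    uint64_t *s = st->s;
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
}

/* uniform in [0, 1) */
static inline double xo_unif(xo_state *st) {
    return (xo_next(st) >> 11) * 0x1.0p-53;
}

/* standard normal, Marsaglia polar with one cached spare */
static int have_spare = 0;
static double spare_val = 0.0;

static double xo_norm(xo_state *st) {
    if (have_spare) { have_spare = 0; return spare_val; }
    double u, v, s;
    do {
        u = 2.0 * xo_unif(st) - 1.0;
        v = 2.0 * xo_unif(st) - 1.0;
        s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = sqrt(-2.0 * log(s) / s);
    spare_val = v * f;
    have_spare = 1;
    return u * f;
}

/* Poisson draw; inversion for small mean, normal approximation above 50
 * (bin means here are far below that in practice). */
static int xo_pois(xo_state *st, double lambda) {
    if (lambda <= 0.0) return 0;
    if (lambda < 50.0) {
        double L = exp(-lambda), p = 1.0;
        int k = 0;
        do { k++; p *= xo_unif(st); } while (p > L);
        return k - 1;
    }
    double v = lambda + sqrt(lambda) * xo_norm(st);
    return v < 0 ? 0 : (int)(v + 0.5);
}

static inline double wrap(double x, double L) {
    if (x >= 0.5 * L) return x - L;
    if (x < -0.5 * L) return x + L;
    return x;
}

SEXP C_brownian_trace(SEXP box, SEXP d_um2_s, SEXP brightness, SEXP dt_,
                      SEXP n_bins_, SEXP r_um_, SEXP z_um_, SEXP seed_,
                      SEXP init_pos) {
    const double *L = REAL(box);
    const int np = LENGTH(d_um2_s);
    const double *D = REAL(d_um2_s);
    const double *bri = REAL(brightness);
    const double dt = REAL(dt_)[0];
    const int n_bins = INTEGER(n_bins_)[0];
    const double r = REAL(r_um_)[0], zax = REAL(z_um_)[0];
    const double inv_r2 = 2.0 / (r * r), inv_z2 = 2.0 / (zax * zax);

    xo_state st;
    xo_seed(&st, (uint64_t)INTEGER(seed_)[0]);
    have_spare = 0;

    double *px = (double *) R_alloc(np, sizeof(double));
    double *py = (double *) R_alloc(np, sizeof(double));
    double *pz = (double *) R_alloc(np, sizeof(double));
    double *sd = (double *) R_alloc(np, sizeof(double));
    double *bdt = (double *) R_alloc(np, sizeof(double));

    if (init_pos != R_NilValue) {
        const double *ip = REAL(init_pos); /* row-major x,y,z per particle */
        for (int i = 0; i < np; i++) {
            px[i] = ip[3 * i];
            py[i] = ip[3 * i + 1];
            pz[i] = ip[3 * i + 2];
        }
    } else {
        for (int i = 0; i < np; i++) {
            px[i] = (xo_unif(&st) - 0.5) * L[0];
            py[i] = (xo_unif(&st) - 0.5) * L[1];
            pz[i] = (xo_unif(&st) - 0.5) * L[2];
        }
    }
    for (int i = 0; i < np; i++) {
        sd[i] = sqrt(2.0 * D[i] * dt);
        bdt[i] = bri[i] * dt;
    }

    SEXP counts = PROTECT(allocVector(INTSXP, n_bins));
    int *cnt = INTEGER(counts);

    for (int b = 0; b < n_bins; b++) {
        double lambda = 0.0;
        for (int i = 0; i < np; i++) {
            if (sd[i] > 0.0) {
                px[i] = wrap(px[i] + sd[i] * xo_norm(&st), L[0]);
                py[i] = wrap(py[i] + sd[i] * xo_norm(&st), L[1]);
                pz[i] = wrap(pz[i] + sd[i] * xo_norm(&st), L[2]);
            }
            if (bdt[i] > 0.0) {
                double q = (px[i] * px[i] + py[i] * py[i]) * inv_r2
                         + pz[i] * pz[i] * inv_z2;
                if (q < 30.0) lambda += bdt[i] * exp(-q);
            }
        }
        cnt[b] = xo_pois(&st, lambda);
        if ((b & 0xFFFFF) == 0) R_CheckUserInterrupt();
    }

    UNPROTECT(1);
    return counts;
}
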