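/* Right-hand side of the spherically symmetric poro-elastic pressure
 * equation, discretised by conservative finite volumes on a logarithmic
 * radial grid.  Compiled model for deSolve (lsoda, banded Jacobian).
 *
 *   dp/dt = (K / Vcell_i) * (flux_in - flux_out)
 *   flux at a face (outward positive) = -(k/mu) * phi_face * dp/dr * 4 pi r_f^2
 *   phi = phi0 + (p - p0)/K, clamped to [eps, 1]
 *
 * Inner face: prescribed volumetric inflow Q(t) (a deSolve forcing).
 * Outer face: Dirichlet p = p0 through a half-cell gradient.
 *
 * Parameter vector layout (padded to PP_MAXPAR on the R side):
 *   [0] n cells   [1] k/mu      [2] K         [3] phi0
 *   [4] p0        [5] linearised flag (1 = use phi0 mobility)
 *   [6] eps clamp [7] 1/(r_outer - r_center_n)
 *   [8 .. 8+n]            face areas 4 pi r_f^2          (n + 1 values)
 *   [8+n+1 .. 8+2n+1]     cell volumes                   (n values)
 *   [.. + n-1]            1/dr between adjacent centres  (n - 1 values)
 */

#include <R.h>
#include <math.h>

#define PP_MAXN   2048
#define PP_MAXPAR (8 + 3 * PP_MAXN + 2)

static double pp_par[PP_MAXPAR];
static double pp_forc[1]; /* Q(t), m^3/s */

void pp_initmod(void (*odeparms)(int *, double *))
{
    int n = PP_MAXPAR;
    odeparms(&n, pp_par);
}

void pp_initforc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, pp_forc);
}

void pp_derivs(int *neq, double *t, double *p, double *dp,
               double *yout, int *ip)
{
    int n = (int) pp_par[0];
    double kmu  = pp_par[1];
    double K    = pp_par[2];
    double phi0 = pp_par[3];
    double p0   = pp_par[4];
    int lin     = pp_par[5] > 0.5;
    double eps  = pp_par[6];
    double hout = pp_par[7];
    double *A   = pp_par + 8;              /* n + 1 faces */
    double *V   = pp_par + 8 + n + 1;      /* n cells     */
    double *H   = pp_par + 8 + 2 * n + 1;  /* n - 1 gaps  */
    double Q    = pp_forc[0];

    double phim1, flux_prev, flux;
    int i;

    /* mobility porosity of cell 0 */
    phim1 = lin ? phi0 : phi0 + (p[0] - p0) / K;
    if (phim1 < eps) phim1 = eps;
    if (phim1 > 1.0) phim1 = 1.0;

    flux_prev = Q; /* outward flux through the inner face */

    for (i = 0; i < n; i++) {
        double phii = phim1;
        if (i < n - 1) {
            double phin = lin ? phi0 : phi0 + (p[i + 1] - p0) / K;
            if (phin < eps) phin = eps;
            if (phin > 1.0) phin = 1.0;
            flux = -kmu * 0.5 * (phii + phin) *
                   (p[i + 1] - p[i]) * H[i] * A[i + 1];
            phim1 = phin;
        } else {
            /* outer Dirichlet p = p0 through half-cell distance */
            flux = -kmu * phii * (p0 - p[i]) * hout * A[n];
        }
        dp[i] = K * (flux_prev - flux) / V[i];
        flux_prev = flux;
    }
}
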