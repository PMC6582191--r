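/* Compiled right-hand side of the coupled substrate/biomass batch ODEs,
 * in the form deSolve expects from a dll-resident model:
 *
 *   dS/dt = -(1/Y) * mu(S, X) * X
 *   dX/dt = ( mu(S, X) - kd ) * X
 *
 * Parameter slots (see R/models.R, .kin_parms_vector):
 *   0 mu_max  1 Ks  2 Y  3 kd  4 model_id  5 extra
 * `extra` is the single model-specific parameter: n (Moser, Heijnen),
 * Ksx (Contois), A (Dabes), L (Powell); unused otherwise.
 */
#include <R.h>
#include <math.h>

static double parms[6];

void kinfit_init(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, parms);
}

static double growth_mu(double S, double X)
{
    double mu_max = parms[0], Ks = parms[1], extra = parms[5];
    int id = (int) parms[4];

    if (S <= 0.0)
        return 0.0;

    switch (id) {
    case 1:                     /* Monod */
        return mu_max * S / (Ks + S);
    case 2:                     /* Tessier */
        return mu_max * (1.0 - exp(-S / Ks));
    case 3:                     /* Contois: extra = Ksx */
        return mu_max * S / (extra * X + S);
    case 4:                     /* Blackman */
        return mu_max * (S >= Ks ? 1.0 : S / Ks);
    case 5: {                   /* Dabes: S = A mu + Ks mu/(mu_max - mu) */
        double A = extra;
        double q = S + A * mu_max + Ks;
        double disc = q * q - 4.0 * A * S * mu_max;
        if (disc < 0.0) disc = 0.0;
        return (q - sqrt(disc)) / (2.0 * A);
    }
    case 6: {                   /* Powell: extra = L */
        double L = extra;
        double q = S + Ks + L;
        double disc = q * q - 4.0 * L * S;
        if (disc < 0.0) disc = 0.0;
        return mu_max * (q - sqrt(disc)) / (2.0 * L);
    }
    case 7: {                   /* Moser: extra = n */
        double Sn = pow(S, extra);
        return mu_max * Sn / (Ks + Sn);
    }
    case 8: {                   /* Heijnen (Hill form): extra = n */
        double Sn = pow(S, extra);
        double Kn = pow(Ks, extra);
        return mu_max * Sn / (Kn + Sn);
    }
    }
    return NA_REAL;
}

void kinfit_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double S = y[0] > 0.0 ? y[0] : 0.0;
    double X = y[1] > 0.0 ? y[1] : 0.0;
    double mu = growth_mu(S, X);

    ydot[0] = -mu * X / parms[2];
    ydot[1] = (mu - parms[3]) * X;
}
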