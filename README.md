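# larvconn

Biophysical larval dispersal, zone-to-zone connectivity, and zero-inflated
bycatch abundance modelling for island sea-urchin populations.

`larvconn` is for marine ecologists and fishery scientists studying whether
an island population of a long-lived planktonic disperser is self-seeding.
It implements three linked stages around a six-zone island system
(`RC_A` ... `RC_F`):

1. **Passive Lagrangian transport** on gridded ocean velocity fields
   (CF-style NetCDF, CMEMS dialect): particles obey
   *dx/dt = u, dy/dt = v, dz/dt = w*, integrated by classical fourth-order
   Runge-Kutta, *y(n+1) = y(n) + (1/6)(k1 + 2k2 + 2k3 + k4)*, with a 120-s
   step, 122-day horizon, 6-hourly snapshots, trilinear-in-space /
   linear-in-time velocity interpolation with land-weight renormalization,
   and absorbing beach/exit fates. The default release is the full study
   design: 6000 particles/day x 92 days (552,000 particles), 0-80 m.
2. **Connectivity and retention**: each particle recruits to the first zone
   it occupies during its 110-120-day age window (115 +/- 5 d larval
   duration). The release-zone x recruitment-zone count matrix yields the
   retention fraction (recruits / released), per-zone source contributions
   (row shares), and sink proportions (column shares).
3. **Bycatch abundance**: urchin counts per lobster-trap haul modelled on
   year, month, zone, depth stratum, and lobster size class with
   log-link count GLMs — Poisson, NB2 (*Var = lambda + lambda^2/phi*), and
   their zero-inflated forms, e.g. ZINB:
   *P(0) = pi + (1-pi) NB(0; lambda, phi)* — fitted by analytic-gradient
   maximum likelihood and compared by AIC over simple (m1-m5) and
   cumulative (M1-M5) predictor ladders.

Synthetic generators (background flow + anticyclonic Rankine recirculation
around a circular island; ZINB trap-haul tables) make the whole pipeline
runnable and testable at desk scale with no external data.

## Worked example

A desk-scale run on the retention preset — a 22-km anticyclonic
recirculation cell around a 4-km island with weak background flow — using a
reduced release (20 particles/day x 2 days):

```r
library(larvconn)

fld  <- make_flow_field(retention_scenario(), retention_grid())
zs   <- retention_zones()
rel  <- build_release(release_schedule(20, 2, seed = 42), zs)
traj <- advect(rel, fld)
rec  <- recruit(traj, zs, window_days = c(110, 120))
m    <- connectivity_matrix(rec, rel$release_zone, zone_ids = zs$ids)
m
#> <connectivity_matrix> (rows = release zone, cols = recruitment zone)
#>        recruitment
#> release RC_A RC_B RC_C RC_D RC_E RC_F
#>    RC_A    0    0    0    0    2    9
#>    RC_B    9    0    0    1    0    0
#>    RC_C    0    1    0    0    0    0
#>    RC_D    0    2    4    0    0    0
#>    RC_E    0    0    1    5    0    0
#>    RC_F    0    0    0    1    5    0
#>   recruited 40 of 40 released (100.00%); window 110-120 days
```

All 40 particles stay in the closed recirculation and recruit; the
off-diagonal structure (A feeds F, F feeds E, ...) is the counterclockwise
— Southern-Hemisphere anticyclonic — rotation carrying larvae to
neighbouring zones over their 4-month drift. `retention_fraction(m)` is
100 here; the full preset (1000 particles) retains ~98%, and doubling the
background flow erodes it to ~95%.

The abundance stage on a synthetic trap table whose only real effect is a
zone effect:

```r
tab <- make_trap_table(catch_scenario(n = 4000, phi = 1.2, pi = 0.35,
                                      beta = c("zoneRC_C" = 0.6), seed = 1))
fit <- fit_count_model(urchin_count ~ zone, tab, family = "zinb")
fit
#> <count_fit> ZINB model: urchin_count ~ zone
#>   n = 4000, df = 8, logLik = -6364.80, AIC = 12745.6
#>   dispersion phi = 1.0442
#>   zero-inflation pi = 0.3137
#>   coefficients (log link):
#> (Intercept)    zoneRC_B    zoneRC_C    zoneRC_D    zoneRC_E    zoneRC_F
#>      0.6072      0.0929      0.5862      0.0159      0.0254      0.0174
```

The fit recovers the generating parameters (intercept log 2 = 0.69,
RC_C effect 0.6, phi 1.2, pi 0.35) within sampling error, and
`model_selection(tab, abundance_ladders()$cumulative, family = "zinb")`
ranks M3 (year + month + zone) first on this table — the smallest candidate
containing the one real effect.

See `vignettes/larval-connectivity.Rmd` for the full model description,
parameter defaults, and design rationale.

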