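---
title: "Statistical optimization of nanoparticle formulations with slnopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical optimization of nanoparticle formulations with slnopt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slnopt)
```

## The problem

Formulating a drug into solid lipid nanoparticles (SLNs) means choosing the
masses of a solid lipid, a surfactant and the drug so that the resulting
dispersion has small particles, a narrow size distribution, and high drug
encapsulation and loading. Screening every combination is wasteful, so the
standard quality-by-design route is response surface methodology: run a small
designed experiment, fit a quadratic model per quality attribute, and find
the factor settings that best compromise between competing goals.

`slnopt` implements that pipeline end to end for three-factor studies, using
the published cannabidiol (CBD) SLN study it ships as a fixture
(`cbd_sln_design()`): glyceryl monostearate (A, 1.5–2.5 g), polysorbate 80
(B, 0.6–1.0 g) and methanolic CBD (C, 10–20 mg), with responses particle
size Y1 (nm), polydispersity index Y2, encapsulation efficiency Y3 (%) and
drug loading Y4 (%).

## Design and model

A three-factor Box–Behnken design (BBD) places 12 runs at the midpoints of
the cube edges — each factor pair at $(\pm 1, \pm 1)$ with the third factor
at its center — plus replicated center points. Factors are handled in coded
units, $x = (\text{actual} - \text{center})/\text{half range}$, so that
every linear and interaction column is exactly orthogonal and coefficient
magnitudes are directly comparable. `bbd_design()` emits the canonical run
order (blocks AB, AC, BC, then centers); randomized order is available but
never the default, so design tables diff cleanly.

Each response is modelled as the quadratic polynomial

$$ y = \beta_0 + \sum_i \beta_i x_i + \sum_{i<j} \beta_{ij} x_i x_j +
   \sum_i \beta_{ii} x_i^2 + \varepsilon, $$

fit by ordinary least squares (`fit_rsm()`). The ANOVA uses partial
(type-III) sums of squares per term — on the orthogonal BBD columns these
coincide with sequential sums of squares. Replicated center points allow the
residual to be split into lack-of-fit and pure error; `pure_error()` sums
squared deviations within replicate groups. Model quality is summarized by
$R^2$, adjusted $R^2$, the PRESS-based predicted $R^2$
($\mathrm{PRESS} = \sum_i (e_i/(1-h_{ii}))^2$, which can be negative), and
adequate precision $(\max\hat y - \min\hat y)/\sqrt{p\,\mathrm{MSE}/n}$, the
signal-to-noise definition used by Design-Expert, whose reports this package
mirrors.

### Model reduction

`reduce_model()` performs backward elimination from the full quadratic:
repeatedly drop the non-significant term with the largest partial-F p-value
(> `alpha`, default 0.05) and refit. Hierarchy enforcement is on by default:
a main effect is protected while any retained interaction or quadratic term
depends on it. This matches how the published reduced equations are
structured, and on the packaged design it reproduces them exactly — the
encapsulation-efficiency model collapses to the linear terms only, and the
drug-loading model retains $\{A, B, C, AC, BC, A^2\}$.

Two caveats a user should know. First, refitting from a *rounded* published
design table reproduces most printed coefficients to well under 1% but not
all: the encapsulation-efficiency equation's B and C coefficients differ
noticeably (−2.10 vs −2.47, +3.45 vs +3.10), which is expected when the
original fit used unrounded raw data. The package reports what the data
given to it imply and does not force agreement. Second, because every
spurious term survives elimination with roughly the type-I error rate,
"tiny noise" does not mean certain recovery of a true model — about
$1 - 0.95^6 \approx 26\%$ of linear-truth datasets retain at least one
extra term at $\alpha = 0.05$. The test suite asserts the achievable
property (true terms always retained, spurious retention at the type-I
rate), not perfection.

## Desirability optimization

Each goal maps a predicted response to $d \in [0,1]$ by the Derringer–Suich
ramps (`desirability()`): for minimization $d = 1$ at or below the lower
anchor, 0 at or above the upper anchor, linear (raised to a weight) between;
maximization mirrored; plus `target` and `in_range` forms and optional hard
constraints (a predicted size above 200 nm forces $d = 0$). The overall
desirability is the importance-weighted geometric mean
$D = (\prod d_i^{w_i})^{1/\sum w_i}$.

Anchors default to the observed response range and all importances to 1 —
the same defaults as the commercial software used in such studies — because
published papers state the goals ("minimize", "maximize") but rarely the
anchors. `optimize_desirability()` maximizes $D$ over the coded cube
$[-1,1]^3$ deterministically: a $21^3$ lattice is scored, the best 8 points
seed Nelder–Mead polishes with coordinates projected onto the cube, and the
best polished point wins. Nelder–Mead was chosen over gradient methods
because the clamped ramps make $D$ piecewise-smooth with flat plateaus. Ties
in $D$ (within $10^{-9}$) are broken by the smaller predicted value of the
first minimize-type goal — for this study, the smaller predicted particle
size. On the packaged study the optimum lands at roughly A = 1.57 g,
B = 0.62 g with the drug amount pinned at its upper bound (C = 20 mg),
in agreement with the published optimum (1.60 g, 0.62 g, 20 mg); the A/B
coordinates are anchor-sensitive and only reproduce approximately from a
rounded table, whereas the boundary optimum in C is robust.

Confirmation runs are judged with single-observation prediction intervals
(`predict_interval()`), $\hat y \pm t_{\nu}\, s \sqrt{1 + x_0'(X'X)^{-1}x_0}$,
and the signed percent error
$(\text{observed} - \text{predicted})/\text{predicted} \times 100$
(`percent_error()`), rounded only at presentation.

## Release kinetics

Dialysis-bag release experiments withdraw an aliquot $V_e$ at each timepoint
and replace it with fresh medium, so `cumulative_release()` adds the removed
drug back: $CR_n = (V_e \sum_{i<n} C_i + V_o C_n)/m \times 100$.

`fit_kinetic()` fits five standard models on the untransformed cumulative
percents by Levenberg–Marquardt least squares, with starting values from the
linearized regressions (log–log for Korsmeyer–Peppas):

| model | form | parameters |
|---|---|---|
| zero-order | $F = K_0 t$ | $K_0$ |
| first-order | $F = 100(1 - e^{-K_1 t})$ | $K_1$ |
| Higuchi | $F = K_H \sqrt t$ | $K_H$ |
| Korsmeyer–Peppas | $F = K_{KP} t^n$ | $K_{KP}, n$ |
| Hixson–Crowell | $F = 100 - (100^{1/3} - K_{HC} t)^3$ | $K_{HC}$ |

First-order and Hixson–Crowell are anchored at complete release
($F_\infty = 100\%$) so each carries a single rate constant, matching the
one-parameter entries such studies report. Points at $t = 0$ are excluded
(the linearizations are undefined there; release at time zero is zero by
definition). Model comparison uses $R^2$, the unweighted
$\mathrm{AIC} = n \ln \mathrm{SSR} + 2p$ and the model selection criterion
$\mathrm{MSC} = \ln(\mathrm{SST}/\mathrm{SSR}) - 2p/n$; this AIC form is the
one used by the DDsolver spreadsheet common in dissolution work (an AIC near
37 at $R^2 \approx 0.994$ is consistent with it, unlike the
$n\ln(\mathrm{SSR}/n)$ form). `select_model()` ranks by MSC descending —
identical to AIC ascending at fixed $n$ — breaking near-ties toward fewer
parameters. The Korsmeyer–Peppas exponent is classified by the standard
thresholds (quasi-Fickian $n < 0.45$, Fickian $n = 0.45$, anomalous
$0.45 < n < 0.89$, case-II $n = 0.89$, super case-II above), with equality
judged at $10^{-9}$.

## Formulation and assay arithmetic

Encapsulation efficiency $\mathrm{EE} = (W_t - W_s)/W_t \times 100$ and drug
loading $\mathrm{DL} = (W_t - W_s)/W_{np} \times 100$ satisfy
$\mathrm{EE} \cdot W_t = \mathrm{DL} \cdot W_{np}$ exactly and are invariant
to the shared mass unit. `colloidal_checks()` applies the field's acceptance
rules — PDI ≤ 0.3 acceptable for lipid carriers, PDI > 0.7 aggregation-prone
(ISO guidance), $|\zeta| \geq 30$ mV electrostatically stabilized — with
inclusive comparisons and configurable thresholds.

Plate assays are normalized to the stimulated, untreated control
(`percent_of_control()`); percent inhibition is $100 - \text{level}$. Fold
potency is defined as the ratio of residual levels (77%/62% → 1.24 ≈
1.2-fold): this is the only definition consistent with how such comparisons
are reported, and the alternative ratio of inhibitions (38/23 → 1.65) is
deliberately rejected. Replicates are summarized as mean ± SD with a Welch
t-test against the control as a convenience; multi-group ANOVA with post hoc
comparisons is out of scope.

## Synthetic data

The generators in `gen_rsm_dataset()`, `gen_release_curve()` and
`gen_assay_plate()` emulate exactly the statistical structure the analysis
stages assume: Gaussian noise around a known quadratic surface, Gaussian
noise on a kinetic release profile (optionally back-converted to the aliquot
concentrations a sampling-with-replacement experiment would measure, so the
cumulative correction round-trips exactly at zero noise), and lognormal
replicate noise around known percent-of-control levels. Default noise scales
mirror the replicate scatter of the packaged study (a few nm on size, a few
tenths of a percent on loading); they are defaults, not facts about any real
instrument. Every generator takes an explicit seed, saves and restores the
global RNG stream, and is a pure function of its arguments.

What passing tests on these generators show — and do not show: they verify
the estimators (OLS recovery, prediction-interval coverage at the nominal
95%, unbiased coefficient and exponent recovery), but real release data have
autocorrelated errors, real plates have edge effects and drift, and real
response surfaces are only locally quadratic. The generators make the
pipeline testable, not the laboratory redundant.

## Numerical choices and problem sizes

- Coding round-off from decimal actual levels is snapped at 12 decimal
  places when reading CSVs, so coded settings are exactly ±1/0.
- Rank deficiency is detected by QR before fitting and reported with the
  names of the collinear terms; constant responses yield zero slopes with
  NaN F statistics and a warning rather than an error.
- The optimizer's lattice (21 per dimension) and 8 polish starts make the
  search deterministic; a denser exhaustive grid is used as an oracle in the
  tests, not in production.
- Statistical property tests use 1000 replicates for prediction-interval
  coverage, 500 for coefficient bias, 200 for exponent recovery, and 40 for
  elimination behaviour — sizes at which the binomial/Monte-Carlo error of
  each check is well inside its asserted band.

## Limitations

Only three-factor Box–Behnken designs are generated (central-composite,
Plackett–Burman and larger designs are out of scope), responses are fit
untransformed (no Box–Cox), release models beyond the five above (Weibull,
Peppas–Sahlin) are not included, and ELISA standard-curve quantitation is
not attempted. Exact reproduction of every printed coefficient from a
rounded published table is not possible in principle; the package documents
where refits differ rather than adjusting toward printed values.
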