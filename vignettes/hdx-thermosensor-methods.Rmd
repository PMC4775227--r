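---
title: "Models and methods: bimodal HDX-MS deconvolution and thermosensor analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: bimodal HDX-MS deconvolution and thermosensor analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxtherm)
```

# The scientific problem

Some transcription factors sense temperature directly: a thermolabile
structural element unfolds within a narrow temperature window, triggering
oligomerization and DNA binding. Hydrogen–deuterium exchange mass
spectrometry (HDX-MS) resolves this because an unfolding event in the EX1
regime exchanges many backbone amides at once, so the isotope envelope of an
affected peptide becomes **bimodal**: a light, low-exchanging subpopulation
(still folded) and a heavy, high-exchanging subpopulation (unfolded or
solvent-exposed) coexist in one spectrum. The fraction of molecules in the
heavy envelope, followed across pre-incubation temperature or heat-shock
time, is the raw signal from which transition midpoints, rate constants,
activation energies and finally a concentration-dependent activation
*setpoint* are derived.

`hdxtherm` implements that chain of analyses, plus a synthetic-data
generator that emulates each dataset's statistical structure, so the whole
pipeline is testable end to end without any deposited raw spectra.

# Two-Gaussian envelope deconvolution

An observed isotope cluster is a set of discrete peaks at m/z positions
$\mu_i$ with intensities $I_i$. The bimodal model is a sum of two Gaussian
peaks with one shared width:

$$
I(\mu) = \frac{A_1}{\sigma\sqrt{2\pi}}
  e^{-\frac{1}{2}\left(\frac{\mu-\bar\mu_1}{\sigma}\right)^2}
 + \frac{A_2}{\sigma\sqrt{2\pi}}
  e^{-\frac{1}{2}\left(\frac{\mu-\bar\mu_2}{\sigma}\right)^2},
$$

where $A_{1/2}$ are the areas of the low/high-exchanging envelopes,
$\bar\mu_{1/2}$ their centroids and $\sigma$ the common width. All spectra of
one temperature or time series are fitted **globally**: $\bar\mu_1$,
$\bar\mu_2$ and $\sigma$ are shared across the series, the areas are free per
spectrum and constrained non-negative ([`fit_bimodal_series()`]). The
constraint $\bar\mu_1 < \bar\mu_2$ is built into the parameterization
($\bar\mu_2 = \bar\mu_1 + \Delta\mu$, $\Delta\mu > 0$), so "high-exchanging"
always refers to the heavier centroid. Fitting uses only the observed
discrete peak positions — isotope envelopes *are* discrete — with
Levenberg–Marquardt least squares (`minpack.lm::nls.lm`), relative SSE
tolerance $10^{-10}$, at most 500 iterations, and up to 3 jittered restarts.

Initialization matters for a mixture fit: $\bar\mu_1$ starts at the
intensity-weighted centroid of the lowest-condition spectrum (or an
unexchanged control when present), $\bar\mu_2$ at that of the
highest-condition spectrum (or a fully deuterated control), $\sigma$ at the
RMS width of the lowest-condition spectrum, and each spectrum's areas at the
best of an 11-point fraction grid. Control spectra inform initialization
only; they are excluded from the global fit itself. If a series is
effectively unimodal (one component below 2 % of the area in every
spectrum), the unused centroid is reported as **unidentifiable** rather than
returned as an arbitrary number.

## Per-peak intensity attribution

After the fit, each observed peak intensity is attributed to the two
subpopulations in proportion to the fitted component densities at that
peak's position:

$$
I^{\text{low}}_i = I_i\,
  \frac{g_1(\mu_i)}{g_1(\mu_i) + g_2(\mu_i)},\qquad
g_k(\mu) = A_k\,\varphi(\mu;\bar\mu_k,\sigma).
$$

This is the unique attribution rule that conserves the observed intensity of
every peak exactly and reduces to the components themselves in the
noise-free limit. The high-exchanging fraction is the intensity-sum ratio
$f_{\text{high}} = \sum_i I^{\text{high}}_i / \sum_i I_i$. Peaks beyond both
tails (both densities numerically zero) are split 50/50 with a warning; by
construction they carry negligible intensity. Centroid-level deuterium
uptake uses the standard two-point back-exchange correction against
unexchanged and fully deuterated controls
([`centroid_uptake()`]): it is the only correction compatible with having
exactly those two controls.

# Transition, kinetics and Arrhenius models

Fraction-versus-temperature data are fitted with the two-state transition

$$
F(T) = f_0 + (f_{\max}-f_0)\,
 \frac{e^{x}}{1+e^{x}},\qquad
 x = \frac{(T-T_m)\,\Delta H}{R\,T\,T_m},
$$

with $T$ in Kelvin internally (interfaces speak °C; the conversion is the
exact offset 273.15) and $R = 8.314462618$ J mol⁻¹ K⁻¹. Because the
underlying transition is kinetically controlled and irreversible, $\Delta H$
is reported strictly as an **apparent steepness parameter** — the fit is
used to locate the midpoint $T_m$, not to extract a thermodynamic enthalpy,
and every report labels it so. Falling transitions (e.g. a protected region
losing its high-exchanging fraction) are fitted with $f_{\max} < f_0$ rather
than by re-orienting the data, which keeps reports in the raw orientation.
Plateaus may be fixed (`f0_fixed`, `fmax_fixed`), including the 0–100
convention for percent-scale data. Points with standard errors are weighted
$1/\mathrm{se}^2$.

Time courses are fitted with a single exponential
$f(t) = f_\infty + (f_0 - f_\infty)e^{-kt}$, with the orientation inferred
from the data and plateaus free (the generator's laws pin them at 0/1, but
free plateaus are the safer default for real data, where burst phases and
incomplete conversion are common). The rate is initialized by a coarse
log-grid on $k$ with the plateaus solved linearly at each candidate — the
model is linear in the plateaus given $k$ — then refined.

Arrhenius analysis is ordinary least squares of $\ln k$ on $1/T$ with
$E_a = -R \cdot \text{slope}$; for two points this reduces exactly to
$E_a = R\,T_1 T_2 \ln(k_2/k_1)/(T_2-T_1)$, which the tests use as a closed
form cross-check.

# DNA-binding equilibrium with fractional activity

Binding of active trimer $P$ to labelled DNA $D$ with dissociation constant
$K_D$ follows the exact two-species quadratic solution; the bound fraction is
evaluated in the conjugate form

$$
f_b = \frac{2P}{P+D+K_D+\sqrt{(P+D+K_D)^2-4PD}},
$$

which avoids catastrophic cancellation at saturation and yields the
hyperbolic limit $P/(P+K_D)$ continuously as $D \to 0$. "Fractional
activity" enters as $P = a_c \times$ (theoretical trimer concentration),
where the theoretical trimer concentration is the monomer concentration
divided by 3 tracked through the dilution series, and $a_c$ is one free
activity per condition. Anisotropy is
$r = r_{\min} + (r_{\max}-r_{\min})\,f_b$.

All dilution series are fitted **globally** with shared $K_D$, $r_{\min}$,
$r_{\max}$ — assuming all binding-competent trimers bind the probe
identically — and per-condition $a_c \in [0,1]$. Keeping $a_c$ constant
along a dilution series encodes the observation that trimers do not
dissociate upon dilution; the assumption is recorded verbatim in every fit
report. The fit parameterizes $\log K_D$ (well-scaled across decades) and
initializes each $a_c$ from its titration's half-maximal point
($a \cdot P_{\text{mid}} \approx D/2 + K_D$); five multi-starts on $K_D$
guard against the $K_D$–activity trade-off valley, which is shallow when the
binding is nearly stoichiometric ($K_D \ll D$). Activities that converge
onto a bound (0 or 1) are flagged and their curvature-based standard errors
suppressed. Trimer–DNA stoichiometry is 1:1 on the three-HSE probe; the data
cannot distinguish multi-site binding at this resolution.

# The monomer–dimer setpoint model

Dimerization $2M \rightleftharpoons D$ with
$K_{\text{dim}} = [M]^2/[D]$ (monomer-unit concentrations) has the exact
solution $[M] = 2c/(\sqrt{1+8c/K_{\text{dim}}}+1)$ — again the
cancellation-free form — with conservation $[M]+2[D]=c$ exact. The **dimer
fraction** is taken as the fraction of monomer units in dimers, $2[D]/c$:
this convention gives the clean anchor that the fraction is exactly $1/2$ at
$c = K_{\text{dim}}$, so the midpoint of the concentration–$T_m$ curve sits
at $K_{\text{dim}}$. The alternative molecule-fraction convention
($[D]/([M]+[D])$, $1/3$ at $c=K_{\text{dim}}$) is available via
`convention = "molecules"`; under either convention the published
physiological $T_m$ window (47–53 °C for 10–130 nM) is reproduced only to
within about 1 °C, and we do not force agreement.

Assuming the dimer fraction determines the midpoint,

$$
T_m(c) = T_{m,M} + \frac{2[D]}{c}\,(T_{m,D}-T_{m,M}),
$$

bounded in $[T_{m,D},\,T_{m,M}]$ and monotone non-increasing in $c$ when the
dimer is the less stable species. `fit_dimer_model()` fits the three
parameters by unweighted least squares (HX-derived and binding-derived
$T_m$ points enter equally; nothing in the data motivates a weighting). Two
flags qualify the estimates: a **low-concentration caveat** when no point
lies below $K_{\text{dim}}/3$ — the fit is most sensitive exactly where data
are scarcest, and the extrapolated $T_{m,M}$ inherits roughly three times
the per-point noise — and a **Kd-unidentifiable** flag when the sampled
concentrations miss the transition region entirely (every point > 90 % or
< 10 % dimer). `simulate_variants()` evaluates the curve under parameter
overrides (e.g. a lowered $K_{\text{dim}}$, or lowered $K_{\text{dim}}$ plus
destabilized dimer, emulating a chaperone's effect), and
`cellular_setpoint()` does the concentration arithmetic
$c = \text{mass fraction} \times \text{total protein} \times 10^6 / M_w$
(nM, with mg/ml and kDa) plus a nuclear enrichment factor.

# What the synthetic generator emulates — and what it does not

The generator produces isotope clusters on the grid
$\mathtt{mz\_start} + i\,\times$ 1.00336 Da/charge (a symmetric compromise
between ¹³C and ²H isotopologue spacings; generator and fitter share
whatever spacing the data carry, so the choice only affects synthesis).
Noise-free intensities are the mixture density at each peak times the grid
spacing, so peak intensities sum to the total envelope area; additive
Gaussian noise scaled to the maximum peak intensity (default
`noise_rel = 0.02`, chosen once as visually representative scatter for
well-behaved envelopes) is truncated at zero. Natural isotopic fine
structure of the undeuterated peptide is *not* modelled: the low-exchanging
Gaussian subsumes it, exactly as the two-Gaussian analysis model does.
Charge-state envelopes beyond one declared charge, retention-time effects
and vendor formats are out of scope.

Default study conditions mirror the experiments: 7 pre-incubation
temperatures (30–42 °C) for thermal series with midpoint 36.15 °C and an
apparent steepness of $3.5\times10^5$ J mol⁻¹ (a 10–90 % window of roughly
10 °C); the measured time grid 10–1000 s with rates 0.0028–0.018 s⁻¹ for
kinetics; four pre-incubation concentrations (100 nM–5 µM, theoretical
trimer = monomer/3) serially 2-fold diluted 12 times against 10 nM probe
with $K_D$ = 1.10 nM for binding; and $T_m$ data at 50–5000 nM from the
model (330 nM, 53 °C, 33 °C) with 0.3 °C noise. Seeds are explicit
everywhere and never global state: the same seed and scenario give
bit-identical output.

Passing recovery tests on these data show that the estimators are correct
and well-conditioned *for the assumed noise model* (additive Gaussian,
independent across peaks). Real spectra have heteroscedastic shot noise,
baseline chemistry, overlapping peptides and imperfect peak picking; the
tests say nothing about robustness to those.

# Numerical and design choices

* **Problem sizes.** Recovery studies use 20 seeds per setting — enough to
  estimate a median or a 95 % exceedance over seeds while keeping the whole
  suite in seconds.
* **Transition recovery design.** The recovery study for $T_m$ runs the full
  pipeline (2 % intensity noise → global deconvolution → transition fit)
  with the plateaus fixed at the generating law's 0 and 1, mirroring the
  constrained-fit variant used for percent-scale data in the source
  experiments. With all four parameters free and noise applied directly to
  the fraction points at sd 0.02, the midpoint's sampling error exceeds
  0.3 °C in roughly a quarter of seeds — an information limit of the
  7-point design, not an estimator defect — so the constrained pipeline
  design is the honest setting in which sub-0.3 °C recovery is achievable.
* **Unimodal degeneracy.** When a series is effectively single-component,
  the initialization keeps the observed centroid on the low component, so
  the empty component (flagged unidentifiable) is always the high one — a
  tie-break, since labels are arbitrary for unimodal data.
* **Binding recovery margins.** Under the four-condition design the global
  $K_D$ carries ~25 % sampling CV; the recovery bands (20 % on $K_D$,
  0.05 on activities, medians over seeds) sit close to the Fisher
  information limit, and the multi-start initialization is what keeps the
  optimizer reliably at the global minimum.
* **Report hygiene.** Every JSON report echoes the conventions in force
  (fraction scale, °C interfaces, nM concentrations, unit-fraction dimer
  convention, "apparent" ΔH labelling); non-finite numeric fields are
  nulled and flagged rather than silently serialized.
* **Replicates.** Independent experiments are treated independently:
  aggregation happens at the fraction/uptake level (mean ± SEM, quadrature
  propagation for differences), never by pooling spectra across
  experiments.

# Known limitations

Two-component mixtures only — a third population (e.g. partially unfolded
intermediate) would bias both centroids. No peak picking from profile-mode
data. The setpoint model maps equilibrium dimer fraction to $T_m$
phenomenologically; it does not simulate the time-resolved
activation scheme. $K_D$ estimates from nearly stoichiometric titrations
and $T_{m,M}$ extrapolations from concentration grids that start above
$K_{\text{dim}}/3$ carry the wide uncertainties their flags advertise.
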