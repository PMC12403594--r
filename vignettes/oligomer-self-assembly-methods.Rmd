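---
title: "Methods: characterizing finite protein self-assembly by scattering and diffusional sizing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing finite protein self-assembly by scattering and diffusional sizing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoscatter)
```

## The scientific problem

Small heat-shock proteins such as αB-crystallin self-assemble into finite
oligomers rather than growing without bound. Characterizing that
self-assembly means answering four questions: how many monomers per
assembly (the aggregation number $N$), what shape and size the assembly
has, how large it appears hydrodynamically, and at what concentration
assembly sets in. No single instrument answers all four, so this package
implements the joint analysis of four techniques — static light scattering
(SLS), small-angle X-ray scattering (SAXS), dynamic light scattering (DLS)
and microfluidic diffusional sizing (MDS) — together with a
closed-association equilibrium model that ties the dilute-regime behavior
together. A seeded synthetic-data module emulates each instrument so that
every estimator in the package can be validated by parameter recovery
without access to an instrument.

## Dynamic light scattering

A goniometer records the intensity–intensity correlation function
$g^{(2)}(q,\tau)$ at angles $\theta$, with scattering vector
$q = 4\pi n \sin(\theta/2)/\lambda$. For a single diffusing species the
Siegert relation gives

$$g^{(2)}(\tau) = 1 + \beta e^{-2\Gamma\tau}, \qquad \Gamma = q^2 D,$$

with $\beta \lesssim 1$ an instrument coherence factor. `fit_monoexponential()`
fits this in linear $g^2$ space with uniform weights (initialized by a
log-linear regression of $\log(g^2-1)$ on $\tau$); lags whose model
amplitude has decayed below $10^{-3}\beta$ are excluded so that baseline
noise does not bias the fit. `fit_gamma_vs_q2()` then regresses $\Gamma$
on $q^2$. Because free diffusion admits no intercept, the through-origin
slope is the headline diffusion coefficient; the free-intercept fit is
reported as a diagnostic only. Finally the Stokes–Einstein relation
$R_H = k_B T / 6\pi\eta D$ converts $D$ to a hydrodynamic radius.

Whether to fit $g^{(2)}$ directly or the field correlation
$g^{(1)} = \sqrt{(g^{(2)}-1)/\beta}$ is an open choice; this package fixes
$g^{(2)}$-space fitting, which avoids taking square roots of noisy,
possibly negative baseline values. Cumulant expansions beyond first order
and regularized inverse-Laplace size distributions are out of scope: the
data this pipeline targets are single-exponential.

## Static light scattering

Scattered count rates are placed on absolute scale by toluene calibration,

$$\Delta R = \frac{I_s - I_b}{I_t}\, R_t \left(\frac{n_b}{n_t}\right)^2,$$

with $R_t = 1.148\times10^{-5}\,\mathrm{cm}^{-1}$ at 25 °C, $n_b = 1.33$,
$n_t = 1.49$. Each concentration's $\Delta R(q)$ is extrapolated to $q = 0$
by a linear fit in $q^2$ (for particles with $qR \ll 1$ the slope is
consistent with zero). For monodisperse assemblies of $N$ monomers the
forward ratio is linear in mass concentration,

$$\Delta R(0) = K_{\mathrm{opt}}\, c\, N M_w, \qquad
K_{\mathrm{opt}} = \frac{4\pi^2 n_b^2 (dn/dc)^2}{N_A \lambda^4},$$

so the through-origin slope of $\Delta R(0)$ vs $c$ yields $N$. This is
the standard Rayleigh–Debye dilute-solution form; because any
constant-factor convention error would cancel in synthetic round trips
but not against real data, $K_{\mathrm{opt}}$ is overridable in the
configuration. The fit is unweighted and through the origin (linearity of
$\Delta R(0)$ in $c$ — i.e. concentration-independent $N$ — is itself the
scientific observation; a free-intercept fit is reported as a linearity
diagnostic). $dn/dc$ defaults to 0.185 mL/g, the conventional protein
value, and must be reviewed when absolute $N$ values matter. Zimm-type
second-virial analysis and structure-factor corrections are deliberately
out of scope: the solutions are treated as ideal-dilute.

## Small-angle X-ray scattering

The SAXS module fits the homogeneous-sphere model

$$I(q) = I(0)\left[\frac{3(\sin qR - qR\cos qR)}{(qR)^3}\right]^2 + I_{\mathrm{int}},$$

where $I_{\mathrm{int}}$ is a small flat term from the internal structure
of the assembly and its constituent protein molecules. Numerically the
bracket is evaluated by series for $qR < 10^{-2}$ so the $q\to 0$ limit is
exact. The squared form factor oscillates, which creates local minima in
$R$; `fit_sphere()` therefore multi-starts on a 2–15 nm grid in 0.5 nm
steps, profiling out the two linear intensity parameters at each grid
radius by weighted linear least squares before a Levenberg–Marquardt
polish. Weights are $1/\sigma^2$ when uncertainties are present, else
$1/I$ (Poisson-like) — the choice matters little for the radius but keeps
the reduced $\chi^2$ interpretable. The default fit range $q \le 2.5$
nm$^{-1}$ covers the first two oscillations of a 6 nm sphere while
excluding the high-$q$ region where a real protein assembly's diffuse
interface departs from the sharp-boundary model. A curve with no
form-factor signal above the flat background leaves $R$ unidentifiable
and raises a fit-failure condition instead of returning a number.

The real-space view is the pair-distance distribution function. For a
homogeneous sphere it is analytic: with $x = r/R$,
$p(r) \propto x^2(1 - \tfrac{3}{4}x + \tfrac{1}{16}x^3)$ on $[0, 2R]$,
peaking at $r \approx 1.05R$ (`sphere_pddf()`, normalized to unit
maximum). From data, `estimate_pddf()` performs a regularized indirect
Fourier transform: $p$ is represented on a 101-point $r$ grid with
endpoints pinned to zero, and estimated by nonnegative least squares
against the forward model $I(q) = 4\pi\sum_j p(r_j)\,\mathrm{sinc}(qr_j)\,\Delta r$
with a second-difference smoothness penalty. The penalty weight is scaled
by the ratio of design-matrix to penalty-matrix norms so it is
dimensionless; by default it is chosen by an L-curve-style scan (the
largest penalty whose $\chi^2$ stays within 50% of the scan minimum),
which favors the smoothest $p(r)$ the data do not reject. A reduced
$\chi^2$ above 10 sets a misfit flag — the typical signature of an assumed
$d_{max}$ smaller than the particle. Note that regularization broadens the
estimated $p(r)$ slightly near its support edge, so a data-derived
$d_{max}$ can exceed the geometric $2R$ by of order one grid step; the
package reports both and does not reconcile them.

The volume fraction of protein inside the assembly,
$f = N M_w / (N_A \rho \tfrac{4}{3}\pi R^3)$ with $\rho = 1.4$ g/mL,
links the SLS aggregation number to the SAXS radius; $f \approx 0.5$
indicates an assembly that is roughly half water, which is compatible
with the homogeneous-sphere description as long as the internal contrast
variations stay below SAXS sensitivity.

## The closed association model and diffusional sizing

Below micromolar concentrations, light scattering runs out of signal and
microfluidic diffusional sizing takes over: a fluorescently labelled
dilution series reports the average hydrodynamic radius down to ~1 nM.
The observed behavior — a low plateau near 5 nm, a rise around a few nM,
and a high plateau near 7 nm — is modeled by closed association: subunits
(dimers, the irreducible associating unit; monomer–dimer equilibrium is
deliberately not modeled) associate into a single preferred $N$-mer with
one association constant

$$K = \frac{c_N}{c_s^N}, \qquad c = m\,(c_s + N c_N),$$

with $m = 2$ monomers per subunit and all concentrations in nM (so $K$
carries units nM$^{-(N-1)}$). `solve_speciation()` finds $c_s$ by Newton
iteration on $\log c_s$ with log-sum-exp guarding, which keeps the mass
balance below $10^{-12}$ relative across at least eight decades of
concentration without overflow.

For a bimodal mixture the radius read out by a mass-transport experiment
is the mass-weighted harmonic mean

$$\langle R_H \rangle = \left(\frac{w_s}{R_{H,s}} + \frac{w_N}{R_{H,N}}\right)^{-1},$$

because diffusion coefficients, not radii, average linearly over mass.
The weighting scheme is isolated in `mean_hydrodynamic_radius()` so an
arithmetic-mean variant could be swapped in if a different instrument
response demanded it. The onset of assembly is operationalized as the
total concentration at which the oligomer mass fraction reaches 10% — a
threshold parameter, since a closed-form critical concentration depends
on convention; the analytic scale $(1/K)^{1/(N-1)}$ is reported alongside.
At $K = 10^{-4}$ nM$^{-8}$, $N = 9$, this gives an onset near 4 nM.

`fit_association_constant()` fits $\log_{10} K$ (for conditioning) by
least squares of the model curve against replicate-averaged radii,
profiling the objective over a $\log_{10}K$ grid so the flatness of the
fit is visible — with only a 2 nm contrast between the 5 nm subunit and
7 nm oligomer, $K$ is an order-of-magnitude estimate, not a precision
measurement. Data whose radii span less than 10% of that contrast lie on
a single plateau and are flagged unidentifiable with a one-sided bound.

Dilute samples lose protein to surfaces. `correct_concentrations()`
implements the internal correction: a linear regression of
replicate-averaged fluorescence intensity on nominal concentration over
the loss-free 1–8 μM window, inverted to re-estimate the concentration of
every sample below that window. The corrected concentration inherits the
calibration intercept's uncertainty, which at nM concentrations can
exceed the value itself; non-positive corrected concentrations are
excluded from the $K$ fit, and the plateau pooling (`pool_plateau()`,
pooled mean and SD over all replicates in a window) selects samples by
nominal concentration for the same reason.

## The synthetic-data module

Each generator emulates one instrument at the study conditions and
records its ground truth:

* `gen_dls()` — per-angle Siegert correlograms on a log-spaced
  10⁻⁶–1 s lag grid (200 points, a typical correlator span), 60–140° in
  5° steps, $\beta = 0.9$, additive Gaussian noise on $g^2$ (default SD
  10⁻³).
* `gen_sls()` — the six-concentration series 10, 22, 34, 46, 58, 69 μM,
  converted from the forward Rayleigh model to raw sample/buffer/toluene
  count rates with 2% multiplicative Gaussian noise on the excess counts.
* `gen_saxs()` — the sphere model on 200 log-spaced points over
  0.05–3 nm⁻¹ with 2% multiplicative noise and a matching σ column.
* `gen_mds()` — the sixteen-point 1 nM–8 μM dilution series in
  triplicate: radii on the closed-association curve plus 0.3 nm additive
  noise (the magnitude implied by the reported plateau SDs), intensities
  proportional to the true concentration with 0.2% multiplicative noise
  (instrument intensity readouts are far more precise than the nM-scale
  inverse regression built on them), and an optional adsorption loss —
  a fixed fraction removed below a concentration threshold — so the
  concentration correction is exercised end to end.

Noise is Gaussian throughout — multiplicative for intensities, additive
for $g^2$ and radii — a deliberate simplification. The generators do not
emulate correlator afterpulsing, beam smearing, detector dead time,
polydispersity, or slow drifts; passing recovery tests therefore
demonstrates that the estimators invert their stated models at realistic
noise levels, not that they are robust to every instrument artifact in
real data. The named presets `day0` (aggregation number 24, the
freshly-prepared state), `day7` (aggregation number 18, the equilibrium
reached after about a week, with hydrodynamic radius 7.4 nm), `sphere`
(radius 6 nm) and `paper_mds` ($K = 10^{-4}$ nM$^{-8}$, $N = 9$, radii
5/7 nm) encode the study conditions used as ground truth by the test
suite and the acceptance script.

## Numerical choices and degenerate inputs

* Boltzmann constant $1.38\times10^{-23}$ J/K and Avogadro's number
  $6.022\times10^{23}$ mol$^{-1}$ at the precision conventional in this
  field, so worked examples reproduce published arithmetic exactly.
* Water viscosity at 25 °C defaults to $8.872\times10^{-4}$ Pa s
  (standard tabulated value); temperature defaults to 298.15 K. Both are
  configuration parameters; no temperature-dependent viscosity model is
  included.
* Unit conventions: nM (monomer) in the association module, g/mL in the
  SLS optics, nm for $q^{-1}$ and radii; conversions are explicit through
  the monomer molar mass, never implicit.
* Degenerate inputs raise conditions of class `os_fit_failure`
  (flat correlograms, non-positive regression slopes, background-only
  SAXS curves, failed calibrations) and are distinguishable from
  precondition violations, which are plain errors.
* Problem sizes in the validation suite — 100-seed recovery batches for
  the aggregation number and association constant, 30-seed batches for
  noise-scaling checks — were chosen so the whole suite demonstrates
  unbiased recovery in well under a minute per batch on a single core.

## Known limitations

* The aggregation number is only as accurate as $dn/dc$ and the optical
  constant convention; both are exposed in the configuration for exactly
  that reason.
* The sphere model cannot detect a small central cavity or distinguish a
  diffuse interface from mild polydispersity; the package reports the
  model fit and its residuals, not a unique structure.
* The closed association model assumes a single oligomeric state;
  isodesmic ladders and assembly kinetics (the week-long equilibration)
  are out of scope — only the equilibrium state is modeled.
* The concentration correction presumes fluorescence intensity linear in
  concentration across the full series; quenching or labelling
  stoichiometry effects would violate this silently.
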