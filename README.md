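# oligoscatter

Multi-technique characterization of finite protein self-assembly —
oligomer size, shape and association equilibrium — for small heat-shock
proteins such as αB-crystallin, which assemble into discrete ~18-mer
oligomers instead of growing indefinitely. The package is aimed at
scattering and biophysics labs that need a reproducible, scriptable
alternative to instrument-vendor analysis for four complementary
measurements:

* **Static light scattering (SLS).** Toluene-calibrated excess Rayleigh
  ratios, ΔR = ((I_s − I_b)/I_t)·R_t·(n_b/n_t)², extrapolated to q = 0 and
  fitted through the origin against mass concentration; for monodisperse
  assemblies ΔR(0) = K_opt·c·N·M_w, so the slope yields the aggregation
  number N.
* **Dynamic light scattering (DLS).** Mono-exponential (Siegert) fits
  g² = 1 + β·exp(−2Γτ) per angle, a through-origin regression of Γ = q²D
  on q², and the Stokes–Einstein conversion R_H = k_BT/6πηD.
* **Small-angle X-ray scattering (SAXS).** Homogeneous-sphere form-factor
  fits with a flat internal-structure term, the analytic sphere
  pair-distance distribution p(r) ∝ x²(1 − ¾x + x³/16) with x = r/R, a
  regularized indirect-Fourier-transform p(r) estimate from data, and the
  protein volume fraction f = N·M_w/(N_A·ρ·(4/3)πR³).
* **Microfluidic diffusional sizing (MDS) + closed association model.**
  Mass-action speciation for dimeric subunits associating into a single
  N-mer (K = c_N/c_s^N, c = 2(c_s + N·c_N)), the bimodal mass-weighted
  mean radius ⟨R_H⟩ = 1/(w_s/R_Hs + w_N/R_HN), the onset concentration of
  assembly, association-constant fitting, and the surface-adsorption
  concentration correction for dilute samples.

A seeded synthetic-data module (`gen_dls()`, `gen_sls()`, `gen_saxs()`,
`gen_mds()`, presets in `os_preset()`) emulates each instrument with known
ground truth, so the entire pipeline is testable by parameter recovery
without any external data.

## Worked example

Generate one synthetic dataset per modality at the equilibrium ("day 7")
conditions and run the full pipeline:

```r
library(oligoscatter)
tmp <- tempdir()
write_table(gen_sls(n_agg = 18, noise_frac = 0.02, seed = 1, day = "day7")$data,
            file.path(tmp, "sls.csv"), "sls")
write_table(gen_dls(r_h_nm = 7.4, noise_sd = 1e-3, seed = 1)$data,
            file.path(tmp, "dls.csv"), "dls")
write_saxs(gen_saxs(radius = 6, noise_frac = 0.02, seed = 1)$data,
           file.path(tmp, "saxs.dat"))
write_table(gen_mds(seed = 1)$data, file.path(tmp, "mds.csv"), "mds")

report <- run_pipeline(list(sls = file.path(tmp, "sls.csv"),
                            dls = file.path(tmp, "dls.csv"),
                            saxs = file.path(tmp, "saxs.dat"),
                            mds = file.path(tmp, "mds.csv")))
print(report)
```

```
Multi-technique self-assembly analysis report
  SLS aggregation number by day:
  day    N_raw N_rounded     slope      stderr
 day7 18.22705        18 0.0762494 0.004815522
  DLS hydrodynamic radius: 7.40 nm
  SAXS sphere radius: 6.00 nm (d_max = 13.0 nm)
  MDS: log10K = -5.53, onset = 6.30 nM, plateaus 5.04 / 7.02 nm
  Protein volume fraction in assembly: 0.47
```

Reading the report: the SLS slope recovers the generating aggregation
number (N = 18) to within its standard error; DLS returns the 7.4 nm
hydrodynamic radius of the generating particle; the SAXS fit recovers the
6 nm sphere radius; the MDS section shows the two plateaus (~5 nm
subunits at nM concentrations, ~7 nm oligomers above ~1 μM) and an
order-of-magnitude estimate of the association constant — with only 2 nm
of contrast between subunit and oligomer, log₁₀K is deliberately reported
together with its objective profile (`report$mds$fit$profile`) so its
flatness is visible. The volume fraction 0.47 (≈0.5) says the 18-mer
modeled as a 6 nm sphere is roughly half protein, half water.

The methods vignette
(`vignettes/oligomer-self-assembly-methods.Rmd`) documents the models,
parameter defaults, numerical choices and the limits of what synthetic
recovery can demonstrate.

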