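# chainflow

Simulation of rotating magnetic nanochain-enhanced lateral flow
immunoassays (LFAs) in R.

Lateral flow tests are cheap and fast but often not sensitive enough
for low-abundance biomarkers: in a rapid format, antibody-antigen
binding is starved by diffusion. Anisotropic magnetic nanochains
(~1 um rods of assembled nanoparticles) driven by a rotating magnetic
field act as micro-stirrers that convectively feed antigen to their
functionalised surfaces, and - inside a nitrocellulose strip -
accumulate on the test line where captured chains magnetically recruit
further flowing chains. chainflow implements the two coupled
reaction-transport models behind this enhancement strategy, for people
who want to audit, rerun or adapt them: biosensor modellers, assay
developers, and anyone reviewing the published figures.

## The models

**Microscale capture model.** Steady creeping flow around nine
rigidly rotating nanochains in a 15 um square domain (staggered-grid
finite volumes with a grad-div penalty; the Stokes problem is linear
in the rotation rate, so one factorised solve serves every
frequency), coupled to transient antigen transport

∂c/∂t + u·∇c = D∇²c,  J_wall = k_on · c · Γ_max · (1 − c/K_D),

with K_D = k_off/k_on, solved implicitly to t = 360 s. The headline
metric is the antigen removal percentage over the square domain, as a
function of rotation frequency (0-20 Hz).

**Membrane transport and cooperative capture model.** A 7 mm strip
(3 mm + 1 mm test line + 3 mm) wets by a Lucas-Washburn front
x_front = sqrt(2 k P_cap (t+0.1)/(η ε)); Darcy flow
∇·((k_eff/η)∇p) = 0 carries mobile nanochains (c) past immobilised
antibodies (c2) forming complexes (c3):

R_c3 = k_on c·c2 − k_off c3 + k_recruit c·c3,

where the k_recruit term is the phenomenological cooperative
recruitment channel. Outcomes: total test-line complex, antibody
saturation margin, and an upstream/downstream asymmetry index of the
capture pattern.

Also included: the capture-efficiency data analysis used with the
supernatant-depletion experiment (efficiency = (C0−Cs)/C0 × 100 and
fold improvement), a strict YAML configuration format, fixture
generation, CSV/VTK export, and a CLI (`exec/chainflow` in the
installed package).

## Worked example

```r
library(chainflow)

p <- micro_params()         # the published microscale parameter set
sw <- frequency_sweep(p, freqs = c(0, 1, 3, 10), seed = 1,
                      resolution = "coarse")
as.data.frame(sw)[, 1:4]
#>   freq_hz removal_pct residual_ng_ml wall_mode
#> 1       0       29.82         0.7022    uptake
#> 2       1       29.82         0.7022    uptake
#> 3       3       29.82         0.7022    uptake
#> 4      10       29.82         0.7021    uptake
```

After 360 s the chains have removed ~29.8 % of the antigen (residual
0.70 ng/mL of the initial 1 ng/mL). The static value sits within the
published 27.9 %; the flat frequency response is a property of the
published rate constants - uptake is reaction-limited, so stirring
cannot add capture (the methods vignette quantifies this).

```r
mp <- membrane_params()
h <- simulate_membrane_assay(mp, N_Abs = 600, k_recruit = 7e4,
                             output_times = c(0, 180, 360))
summary(h)
#> Membrane assay: N_Abs 600, k_recruit 7e+04, quasistatic coupling, dt 1 s
#>   t = 360 s: test-line complex 4.938e-12, min free antibody 8.89e-06 mol/m^3
#>   asymmetry index +0.107; nanochain mass audit error 2.3e-14
```

With cooperative recruitment on, capture skews towards the upstream
edge of the test line (asymmetry +0.107 versus +0.036 with
`k_recruit = 0`), while the test line stays far from saturation
(minimum free antibody 8.9e-6 of the initial 1e-5 mol/m^3).

```r
df <- data.frame(condition = rep(c("rotating", "static"), each = 3),
                 replicate = rep(1:3, 2), C0_ng_ml = 1,
                 Cs_ng_ml = c(0.59, 0.48, 0.37, 0.94, 0.84, 0.74))
capture_summary(df)
#> Capture efficiency by condition (mean +/- sd over replicates):
#>   rotating      52.0 +/- 11.0 %  (n = 3)
#>   static        16.0 +/- 10.0 %  (n = 3)
#>   fold improvement rotating vs static: 3.25
```

## Learn more

The methods vignette (`vignettes/chainflow-methods.Rmd`) documents
the governing equations, discretisations, tolerances, the wall
flux-convention question, and every place where the implementation
had to decide something the published description left open.
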