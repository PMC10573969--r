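---
title: "A fiber-content-based viscoelastic creep model of the periodontal ligament"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A fiber-content-based viscoelastic creep model of the periodontal ligament}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdlcreep)
```

## The problem

The periodontal ligament (PDL) is the thin soft-tissue layer anchoring a
tooth root in its bony socket. It transmits chewing and orthodontic forces,
and its mechanical response is strongly time-dependent: under a constant
load the tissue keeps deforming (creep). The PDL is mostly collagen fiber
bundles embedded in a hydrated matrix, and how much collagen a region
contains is a major determinant of how stiffly it resists deformation.

`pdlcreep` implements an analysis chain for nano-indentation creep tests on
PDL performed with a flat cylindrical punch: a constant-rate ramp to a peak
load, a long constant-load hold during which the tissue creeps, and an
elastic unload. The chain recovers (i) nonlinear viscoelastic parameters
from the hold stage, (ii) the reduced elastic modulus from the unload, and
(iii) the collagen area fraction from Masson-stained histology, with seeded
synthetic generators standing in for cadaveric specimens.

## The constitutive model

### Linear skeleton

The tissue is idealized as a collagen fiber spring of modulus $E_{tf}$ in
parallel with a Maxwell branch for the matrix (spring $E_m$ in series with
a dashpot $\eta$). Solving this three-element solid under a unit step
stress gives the creep compliance

$$D(t) = \frac{1}{E_{tf}} - \frac{E_m}{E_{tf}(E_{tf}+E_m)}
  \exp\!\left(-\frac{E_{tf}E_m\,t}{\eta\,(E_{tf}+E_m)}\right),$$

which runs from the glassy value $1/(E_{tf}+E_m)$ at $t=0$ (both springs
carry load) to the equilibrium $1/E_{tf}$ (the relaxed matrix sheds its
share). `creep_compliance()` evaluates this form; the test suite verifies
it against an independent numerical integration of the underlying ODE to
$10^{-8}$ relative error.

The loading of interest is a step: the ramp lasts 6 s against a 200 s
hold, so the hold-stage response is analysed as if the full load were
applied instantaneously. General (hereditary-integral) load histories are
out of scope.

### Kelvin–Voigt reparameterization and the nonlinear form

Matching a first-order generalized Kelvin–Voigt compliance
$D'(t) = D_0' + D_1'(1-e^{-t/\tau_1})$ to the model yields

$$D_0' = \frac{2E_m+E_{tf}}{E_{tf}(E_{tf}+E_m)},\quad
  D_1' = -\frac{E_m}{E_{tf}(E_{tf}+E_m)},\quad
  \tau_1 = \frac{\eta\,(E_{tf}+E_m)}{E_{tf}E_m},$$

with the exact identity $D_0' + D_1' = 1/E_{tf}$. The hold-stage strain is
then written in Schapery form, multiplying the compliance terms by
dimensionless factors that track collagen fiber content:

$$\varepsilon(t) = g_0\,D_0'\,\sigma_0
  \;-\; g_1 g_2\,\lvert D_1'\rvert\,(1-e^{-t/\tau_1})\,\sigma_0 .$$

Two deliberate modelling quirks deserve note, because they are properties
of the fitted form rather than bugs:

* **$D_0'$ is not the instantaneous SLS compliance.** The matched $D_0'$
  above differs from $1/(E_{tf}+E_m)$. The nonlinear strain response uses
  the matched $D_0'$ because the published parameter tables this package
  round-trips presuppose exactly that form; the linear `creep_compliance()`
  is kept as a separate, internally consistent operation.
* **The sign structure can exceed the linear equilibrium.** With
  $g_0=g_1=1,\ g_2=-1$ the long-time strain is
  $(3E_m+E_{tf})/(E_{tf}(E_{tf}+E_m))\,\sigma_0$, larger than the linear
  solid's $1/E_{tf}$. This is documented behaviour of the sign convention.

The transient factor $g_1$ is determined from rebound strains
(`g1_from_strains()`): creep tissue that fully rebounds on unloading gives
$g_1 = 1$, the default throughout. The Schapery stress-dependence exponent
($\alpha_\sigma$) is taken as 1 — reduced time equals physical time — since
the fitted strain law contains no such factor; the hook is left to future
extension rather than exposed as a live parameter.

## Identifiability and the fitting procedure

A single hold-stage curve identifies only three combinations:

$$\varepsilon(t) = A + B\,(1-e^{-t/\tau}),\qquad
A = g_0 D_0' \sigma_0,\quad B = -g_1 g_2 |D_1'| \sigma_0,\quad \tau=\tau_1 .$$

$E_{tf}$, $E_m$ and $\sigma_0$ are never separately observable from one
curve, so `creep_context()` fixes them — by default at the normalization
$E_{tf}=E_m=\sigma_0=1$, $g_1=1$, which makes recovered $(g_0, g_2, \eta)$
directly comparable with parameter tables published under the same
convention. Users with measured moduli or a known contact stress can
substitute them; the reduced-space mapping is a bijection either way
(`reduced_from_full()` / `schapery_from_reduced()`).

`fit_creep()` minimizes the residual sum of squares in the reduced
$(A, B, \tau)$ space with bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`), which avoids dragging the degenerate
$(E_{tf}, E_m)$ directions through the optimizer. Numerical choices:

* initial guesses $A=\varepsilon_1$, $B=\varepsilon_n-\varepsilon_1$,
  $\tau = \text{span}/3$;
* bounds $\tau \in [10^{-9}, 10^{6}\cdot\text{span}]$; $A$, $B$ free;
* cost tolerance $10^{-10}$, step tolerance $10^{-12}$, at most 1000
  iterations;
* non-convergence is flagged in the result, never raised;
* a zero-variance (flat) curve short-circuits: $g_2=0$, $g_0$ from the
  level, $R^2$ reported as missing;
* fits with decreasing strain ($B<0$) are allowed but flagged as outside
  the creep regime.

$R^2$ is computed on the hold stage only, matching how such experiments
are reported; the loading phase is excluded.

On noiseless self-generated curves all three parameters are recovered to
better than $10^{-6}$ relative error and $R^2 = 1$ to float tolerance.
Worth knowing: under the normalized context $\tau_1 = 2\eta$, so the
regional parameter table's viscosities (192–371 MPa·s) imply retardation
times of roughly 380–740 s observed through a 200 s window. The
exponential is therefore only partially resolved, and at 1 % of the curve
range of Gaussian noise the apex-region set with $\tau \approx 741$ s sits
essentially at the Cramér–Rao identifiability floor for a 5 % median error
on $\eta$ — simulation medians land within a fraction of a percentage
point of that bound on either side, depending on the noise seeds. This is
a property of the experimental design (hold length versus retardation
time), not of the optimizer, which matches a global profiled grid search
on the same data.

## Indentation processing

`segment_record()` splits a record at the first sample reaching
$P \ge P_{\text{peak}}(1-\text{tol})$ (tol = 1 % of peak), spans the hold
time from there, and leaves the remainder as unload. Strain is depth
divided by local PDL thickness (`strain_from_displacement()`), measured by
default from total depth including the loading-phase penetration, with a
hold-onset-relative convention available; the hold clock is re-zeroed for
fitting. Replicate curves are averaged pointwise after linear interpolation
onto the first curve's grid, without extrapolation.

For the unload, the punch is a flat cylinder: contact area is constant, so
the Oliver–Pharr stiffness relation reduces to $E^* = S/(2R)$ with $S$ the
unloading slope $dP/dh$. The Berkovich-style area-function machinery would
be wrong here and is deliberately absent. $S$ is a linear fit to the top
50 % of the unloading curve by load (fraction configurable; the choice is
ours since no standard fraction exists for this geometry). Units: with $S$
in mN/µm and $R$ in µm, $E^*$ in MPa is $1000\,S/(2R)$ — e.g.
$S = 1.016$ mN/µm on a 100 µm punch gives $E^* = 5.08$ MPa.

Published per-region moduli cannot be regenerated at desk scale — they
require the cadaveric specimens and unprinted per-sample thicknesses — so
the package validates this stage by round trips on synthetic elastic
unloads with known $E^*$, recovered to better than 1 %.

## Collagen fiber content

`segment_collagen()` classifies pixels of a Masson-trichrome image: the
stain renders collagen blue/green and muscle/cytoplasm red, so the default
rule is a hue window in HSV space (hue $\in [0.45, 0.75]$ of the color
circle, saturation $\ge 0.15$). The thresholds are package defaults, not a
community standard — any reported $V_f$ should state them. The fiber
content of an ROI is the exact pixel ratio
$V_f = 100\cdot\text{collagen px}/\text{ROI px}$ (`measure_vf()`), and
per-region values are arithmetic means over slices (`summarize_region()`),
reproducing the built-in per-slice reference table's averages exactly.
ROIs are 0-based, half-open rectangles or polygons rasterized at pixel
centers.

## What the synthetic generators emulate — and what they do not

`generate_indentation_record()` reproduces the bench protocol: 0.5 mN/s
ramp to 3 mN (6 s), 200 s hold sampled at 1 Hz (201 hold points), optional
linear unload. Depth during the ramp is modeled quasi-statically through
the instantaneous term only ($\varepsilon = g_0 D_0' \sigma(t)$) — only
the hold stage is fitted, so ramp realism is secondary. The default unload
slope makes the tissue rebound fully to zero depth at zero load,
consistent with the $g_1 = 1$ assumption; the implied $E^*$ is recorded in
the ground truth. Noise is i.i.d. Gaussian on depth with standard
deviation `noise_sd × thickness` and no drift term. Default thickness is
200 µm, the protocol's minimum usable thickness. A warning is raised when
$\tau_1 \ge 5\times$ the hold time, where fitting cannot resolve the
exponential.

`generate_masson_image()` draws curvilinear fiber bundles (quadratic
Bézier strokes of seeded geometry) until the collagen area reaches the
target fraction, then adjusts the mask boundary pixelwise so the
ground-truth fraction matches the target to quantization. Collagen is
rendered in Masson-blue hues and background in red, with mild seeded color
jitter.

These generators make every pipeline stage testable without histology or
indentation hardware, but they are idealizations: real records carry
thermal drift, machine compliance and adhesion effects; real sections have
stain batch variation, partial-volume pixels at fiber boundaries, nuclei
and vessels in third colors, and fiber orientation structure. Passing
round trips therefore demonstrate correctness of the analysis chain, not
robustness to instrument artifacts the generators deliberately omit.

`generate_study()` composes the full design — 3 regions × 2 planes × 5
indentation points and 5 slices × 3 regions of stained images — with
per-region-and-plane material parameters drawn from the built-in table
`pdl_creep_parameters` (the table does not state which member of each
regional pair is transverse versus longitudinal; the study assigns the
first to transverse as a synthesis convention, asserting nothing about the
original samples) and per-slice collagen targets from `pdl_fiber_content`.

## The pipeline

`run_pipeline()` chains generate (or load) → segment → strain → fit →
modulus → fiber content → report, writing three CSV tables and a JSON
manifest (seed, config, config hash, stage log). Every stage is
deterministic given the config, so reruns are bit-identical. Configs are
plain lists or YAML/JSON files validated against the known keys; unknown
keys are rejected rather than ignored. The package deliberately ships no
shell executable: it is a library, and the exported functions plus
`run_pipeline()` are its interface.

## Design notes

* The package is organised around one fitting function returning a classed
  object (`creep_fit`) with the standard modelling methods (`coef`,
  `predict`, `residuals`, `simulate`, `plot`, ...), in base R. A formula
  interface was considered and rejected: the model's predictor is a single
  time axis with a fixed physical meaning, so `fit_creep(curve, context)`
  on a `creep_curve` is clearer than `strain ~ time` sugar.
* Units are fixed throughout — time s, force mN, length µm, stress
  MPa (kPa only at the force/area entry point), strain dimensionless —
  with conversions confined to the two contact points
  (`stress_from_load()`, `reduced_modulus_flat_punch()`).
* Problem sizes in the tests (201-point hold curves; 200 noise replicates
  per parameter set; 1024² px images for fraction checks, 256² for
  texture checks) were chosen as the smallest sizes that exercise the
  claims they verify.

## Known limitations

The model treats the PDL as transversely isotropic and ignores fluid–solid
coupling; anisotropy beyond that, poroelastic flow, and finite-element use
of the constitutive law are out of scope. Only step loading is supported.
$E_{tf}$, $E_m$, $\sigma_0$ are fixed, not fitted — joint estimation from
one curve is ill-posed by construction. The collagen segmentation rule is
a simple color threshold; stain-normalization across batches and fiber
orientation analysis are not provided.
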