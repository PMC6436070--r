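---
title: "A porous-media model of myocardial contrast-agent perfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A porous-media model of myocardial contrast-agent perfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfusim)
```

## The problem

Contrast-enhanced cardiac MRI infers myocardial perfusion from the
spatiotemporal dynamics of a gadolinium-based contrast agent (CA).  Two
protocols are complementary: *first pass* (FP) follows the bolus for about
50 s — hypoperfused regions stay dark — while *late enhancement* (LE) images
the heart about 10 min after injection, when fibrotic infarct scar retains
the CA and appears bright.  `perfusim` simulates both protocols on a 2D
short-axis slice, treating the myocardium as a porous medium, so that
anatomical causes (a coronary stenosis, a fibrotic scar) can be linked to
the functional signal-intensity (SI) curves a scanner would record.

## Model

### Flow

Blood flow in the intravascular domain $\Omega_i$ is incompressible Darcy
flow,

$$\nabla\cdot\vec v = 0, \qquad \vec v = -\mathbf K \nabla p,$$

with Dirichlet pressures on the epicardial rim $\Gamma_o$ ($p_o = 2.0$ kPa,
reduced on a stenosis arc) and the endocardial rim $\Gamma_i$ ($p_i = 0$).
A coronary stenosis is represented purely by the lowered epicardial boundary
pressure on a 30° arc: 1.4 kPa for a 30% stenosis, 0.4 kPa for 80%.

The permeability tensor $\mathbf K(x,y)$ is anisotropic and heterogeneous.
A transmural weight $w$ solves the Laplace equation with $w = 0$ on
$\Gamma_o$ and $w = 1$ on $\Gamma_i$; the second preferential direction is
$\vec e_t = \nabla w / |\nabla w|$ (transmural) and the first, $\vec e_l$,
its 90° rotation (parallel to the surfaces, following the micro-vascular
orientation).  Permeabilities blend linearly so the subendocardium is twice
as permeable as the subepicardium:

$$K_l = K_1(1-w) + 2K_1 w, \qquad K_t = K_2(1-w) + 2K_2 w,$$

with $K_1 = 1.5$, $K_2 = 0.75\ \mathrm{mm^2\,kPa^{-1}\,s^{-1}}$.  The printed
tensor formula $\mathbf K = K_l \mathbf I + (K_t - K_l)\,\vec e_l \vec
e_l^{\,T}$ assigns eigenvalue $K_t$ to $\vec e_l$, contradicting the stated
meaning of $K_l$ as "the permeability along $\vec e_l$"; the package defaults
to the stated meaning, $\mathbf K = K_l \vec e_l \vec e_l^{\,T} + K_t \vec
e_t \vec e_t^{\,T}$, and exposes the literal form behind
`assemble_tensor(form = "literal")`.  Both are symmetric positive definite
with eigenvalues $\{K_l, K_t\}$.  (A related inconsistency — the text says
$K_1 \approx 10.8\,K_2$ while the declared parameter set has $K_1/K_2 = 2$ —
is resolved in favour of the declared set; the ratio is configurable.)

### Contrast-agent transport

Three concentrations live on the slice: intravascular $C_i$, interstitial
$C_e$ and fibrotic $C_f$ (supported on the scar region $\Omega_f$ only).
With porosity $\phi$ (intravascular volume fraction), interstitial fraction
$\lambda$ of the extravascular space, and fibrotic fraction $\lambda_f$ of
the interstitium:

$$\frac{\partial(\phi C_i)}{\partial t}
  + \nabla\cdot(\vec v C_i) - \phi\,\nabla\cdot(D_i \nabla C_i) + f = 0,$$

$$\frac{\partial((1{-}\phi)\lambda C_e)}{\partial t}
  - (1{-}\phi)\lambda\,\nabla\cdot(D_e \nabla C_e) - f
  + (1{-}\phi)\lambda k_e C_e + g = 0,$$

$$\frac{\partial((1{-}\phi)\lambda\lambda_f C_f)}{\partial t}
  + (1{-}\phi)\lambda\lambda_f k_f C_f - g = 0,$$

where the endothelial transfer is a one-way valve,
$f = P\,(C_i - C_e)$ if $C_i > C_e$ and $0$ otherwise (Gd-DTPA leaks out of
the capillaries but is not pumped back), and the sortion term
$g = (1{-}\phi)\lambda\lambda_f k_{ef} C_e$ models trapping of interstitial
CA in the fibrotic network.  $k_e C_e$ and $k_f C_f$ are venous washout
sinks.  The porosity/fraction factors are kept exactly where the model
states them; in particular the advection term uses the superficial Darcy
velocity without dividing by $\phi$, so the concentration front physically
travels at $|\vec v|/\phi$ — this matters for the stability bound below.

The epicardial influx is a prescribed advective flux $\vec v\,Q(t)$ with

$$Q(t) = \frac{1}{\sigma\sqrt{2\pi}}
  e^{-\frac12\left(\frac{t-t_{peak}}{\sigma}\right)^2} + X(t),$$

$\sigma = 7$ s, $t_{peak} = 25$ s.  (The source prints the exponent without
the square; since it is described as a Gaussian bolus, the package
implements the true Gaussian.)  Diffusive fluxes vanish on all external
faces; the endocardial faces are advective outflow — the venous drain of the
simplified two-domain circuit.

### Recirculation

$X(t)$ is the feedback of a 1D recirculation line: the intravascular average
$C_L(t) = \int_{\Omega_i} C_i \,\mathrm d\Omega / |\Omega_i|$ enters at the
left boundary of a line of length $L$ and is advected
($v_{out} = 1$ mm/s), dispersed ($D_{out} = 0.05$ mm²/s) and eliminated
($k = 0.02$ s⁻¹, the kidneys) before the outlet value $C_R$ re-enters the
epicardial influx.  The loop produces the secondary SI peaks ("oscillatory
decay") seen clinically; with the loop off the post-peak decay is monotone.
$L$ is not prescribed by the model source; the default $L = 25$ mm gives a
loop transit time $L/v_{out} = 25$ s, consistent with the inter-pass spacing
of clinical first-pass curves.  $X$ is applied uniformly over $\Gamma_o$
(no spatial recipe is given for it).

### Signal intensity

An ROI signal is the volume-fraction weighted sum

$$SI = \sum_{\text{ROI}} \left[\phi C_i + (1{-}\phi)\lambda C_e +
  (1{-}\phi)\lambda\lambda_f C_f\right] h^2,$$

reported with its intravascular/extravascular/fibrosis breakdown.  The
weighting makes the ROI signal commensurate with the conserved CA mass of
the transport system; concentrations are in arbitrary units and no
SI-to-concentration MR conversion is attempted (a stated non-goal of the
model).  Comparisons to clinical curves are by shape and ordering.

## Numerics

* **Discretization.** Cell-centered finite volumes on the raster grid
  (square cells of edge $h$; reference $h = 0.5$ mm, about 10,000 cells).
  Face transmissibilities use the harmonic mean of the normal tensor
  component; tensor cross-terms are discretized with centered tangential
  differences and moved to the right-hand side (deferred correction), which
  keeps the core matrix an M-matrix so the Jacobi iteration applies and the
  discrete maximum principle holds.  The model source does not say how
  cross-terms were treated on the pixel grid; deferred correction is this
  package's choice.
* **Pressure solver.** Jacobi iteration (the reference method) to a relative
  residual of $10^{-8}$ in the max norm, cross-terms refreshed every sweep.
  A sparse direct solve wrapped in a Picard loop (`method = "direct"`) meets
  the same residual contract and is used where speed matters (tests, sweep
  reuse).  Dirichlet values are imposed at boundary faces (half-cell
  distance), preserving second-order accuracy — verified by manufactured
  solutions (observed order ≈ 2 for axis-aligned anisotropy).
* **Advection.** TOPUS, the third-order polynomial upwind scheme, in
  normalized variables: $\hat\phi_f = 2\hat\phi^4 - 3\hat\phi^3 + 2\hat\phi$
  inside $[0,1]$, first-order upwind outside (and where the far-upwind
  stencil is truncated), satisfying the convection-boundedness criterion.
  Step profiles advect without new extrema.
* **Time integration.** Explicit Euler with
  `dt = 0.25 * min(phi h / max|u|, h^2/(4 max D), 1 / max(P/phi, k_e, k_f,
  k_ef))`, fixed per run and re-checked every step (any negative
  concentration beyond $-10^{-12}$ raises a diagnostic).  The porosity
  factors are required: without them the printed equations are advanced at
  an effective CFL number of $1/\phi = 10$ and blow up within a second.
  The 1D recirculation line is sub-stepped to its own explicit bound.
* **Mass budget.** The discrete update conserves
  $\sum[\phi C_i + (1{-}\phi)\lambda C_e + (1{-}\phi)\lambda\lambda_f C_f]h^2$
  up to boundary fluxes and the venous sinks *exactly* (the exchange $f$ and
  sortion $g$ cancel pairwise); the running budget closes to machine
  precision and is asserted below 0.5% in the tests.
* **Degenerate inputs.** Where $|\nabla w| < 10^{-12}$ (constant patches of
  the transmural weight) fiber directions are copied from the nearest
  non-degenerate cell; a cell contacting both OUTSIDE and CAVITY (wall one
  cell thick) is pinned to $w = 1/2$.  ROI construction takes the $N$
  nearest myocardial cells to a subendocardial seed, ties broken by cell
  index, so the published ROI areas (70 and 55 mm² at $h = 0.5$ mm) are met
  exactly.

## The phantom and what it does and does not emulate

No patient data ships with the package.  `make_annulus_phantom()` builds an
annular myocardium (outer radius 34 mm, inner 19 mm) whose area matches the
segmented slice the model was demonstrated on (≈ 2,500 mm², ≈ 10,000 cells
at $h = 0.5$ mm), with the stenosis arc on the right (angle 0), a
subendocardial fibrosis sector facing it, the diseased ROI (55 mm²) inside
that sector and the remote ROI (70 mm²) diametrically opposite.  The
stenosis arc half-width defaults to 15° (the source shows the arc only
graphically) and is configurable, as is a cosine taper of the arc pressure
(default abrupt).

The phantom reproduces the published geometry's *scale and topology*, not
its shape: there are no papillary muscles and the rims are perfect circles
up to rasterization (the boundaries stay pixel-based and non-smooth, as in
the reference workflow).  Consequences: quantities tied to scale and
boundary conditions (pressure ranges, transmural drops, SI orderings, pass
timing) transfer; exact pressure contours and ROI-shape-dependent details do
not.  Passing tests therefore certify the solver contracts and the
qualitative clinical contrasts, not patient-specific accuracy.

## Scenarios and published contrasts

```{r presets}
scenario_config("infarct")
```

The three presets differ only in the stenosis pressure and the infarct
transport column (`k_e = 0.0009`, `P = 0.025`, `k_f = 7e-4`, `k_ef = 1.0`,
`lambda = 1.0`, `lambda_f = 0.5`, `D = 1e-7`).  Where the running text and
the declared parameter table disagree ($k_e$, $t_{peak}$, the recirculation
$v$ and $k$), the declared table wins; everything stays configurable.

A short coarsened run shows the first-pass contrast (a full-resolution run
uses `h = 0.5`; the coarse grid keeps this vignette fast while every
qualitative feature survives):

```{r run, eval = FALSE}
res <- run_scenario(scenario_config("ischemia", h = 1, t_end = 200))
res
plot(res$series$t, res$series$SI_remote, type = "l",
     xlab = "t (s)", ylab = "SI (a.u.)")
lines(res$series$t, res$series$SI_diseased, col = 2)
```

The diseased ROI peaks later and lower than the remote ROI during first
pass; with the recirculation loop active both curves show a second pass
about 25 s after the first; at late enhancement the infarct preset flips the
ordering (the scar retains CA while the remote tissue washes out, the
intravascular component being gone within about two minutes).

### Sensitivity sweeps

`sweep_parameter()` varies one of $\lambda, P, k_e, k_f, \lambda_f$ or the stenosis
pressure while pinning everything else to the supplied configuration
(conventionally the infarct column).  Transport parameters are varied
*inside the diseased ROI only* by default — the convention of the published
sensitivity analyses, which state that parameters were varied in that region
and kept constant elsewhere.  This locality matters: raising $\lambda$
globally lowers the diseased-ROI uptake (the wide-open exchange valve drains
$C_i$ upstream before it arrives), reversing the expected direction, whereas
the ROI-local sweep reproduces it (more interstitial space, more CA held,
higher peak and late value).

## Problem sizes used by the checks

The test suite runs the Darcy-only checks at the reference resolution
($h = 0.5$ mm, ≈ 10,000 cells) and the time-dependent scenario checks on
coarsened phantoms ($h = 1$ mm for the 200 s and 600 s horizons, $h = 1.5$
mm for short property runs); these sizes were chosen so the whole suite
completes in about a minute while every published contrast remains
resolvable.  The acceptance script runs the pressure pipeline at the full
reference resolution with the Jacobi reference solver.

## Known limitations

* 2D, non-contracting (end-diastolic) myocardium; no poroelastic coupling.
* One intravascular compartment (no arterial/capillary/venous hierarchy,
  no discrete arterial tree).
* The recirculation line is a single-phase caricature of the systemic
  circulation; only transit delay, dispersion and first-order elimination
  are represented.
* Concentrations are in arbitrary units; no MR signal conversion.
* The transport parameters are uniform scalars per scenario (per-cell
  overrides exist for the sweep mechanism); fibrosis locality enters through
  the scar mask, not through spatially resolved parameter maps.
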