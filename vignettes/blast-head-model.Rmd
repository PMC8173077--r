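---
title: "A desk-scale plane-strain model of blast loading on a gyrified head phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A desk-scale plane-strain model of blast loading on a gyrified head phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model world

`headblast` simulates the transient response of an idealized human head to a
free-field blast wave, at a scale a laptop can run, with the intracranial
mechanical *interfaces* — skull–CSF–cortex, sulcal CSF, ventricle walls,
vessel lumina — resolved explicitly. The motivating hypothesis is that blast
TBI is an injury of material interfaces: cavitation in CSF and blood, and
strain-rate focusing in the adjacent tissue (subpial, perivascular,
periventricular), are the model's primary outputs.

The model world is **two-dimensional plane strain**: an axial mid-plane
slice of the head, extruded conceptually to infinity. All reported fields
are per unit out-of-plane thickness. This choice trades the 3D wave physics
of a real head (axial focusing, skull curvature out of plane) for meshes of
a few thousand rather than millions of elements; patterns and interface
phenomenology are comparable, absolute magnitudes are not.

## The phantom

`build_head_geometry()` generates a conformal all-quadrilateral mesh from a
parametric description:

* an elliptical brain (defaults 140 x 170 mm) with a periodic gyral
  boundary: Gaussian sulcal dips of depth 12 mm and full width 8 mm, eight
  gyri per hemisphere;
* a constant-thickness gray-matter ribbon (3 mm) following the gyral
  boundary;
* CSF filling the sulci and the 2.5 mm skull–brain gap;
* a 7 mm elastic skull shell;
* paired ventricles as closed CSF-filled cavities in the white matter;
* optional circular vessel channels (0.6, 0.8, 1.2, 1.6 mm diameter) at six
  depths, each lumen wrapped in a five-element wall band whose total radial
  thickness is 10% of the vessel diameter.

The absolute dimensions are **generator defaults chosen once** to match
typical adult axial proportions; the source anatomy for this class of model
is usually an MRI-derived drawing, and no published absolute dimensions
exist to copy. The sulcal width default (8 mm) is wider than a live sulcus;
it is the narrowest shape whose walls stay meshable by the terrain-following
polar grid without near-degenerate quadrilaterals (sulcal wall slope enters
the element shear directly). Ventricles are modeled as closed internal
cavities; whether they communicate with the outer CSF in the source anatomy
is not documented, and a closed cavity is the conservative choice for
confinement-driven cavitation.

The mesh is a structured polar multi-block layout: rings for skull, CSF and
gray (each at least `min_elements_through_thin_layers = 5` through the
thickness — the resolution contract), white-matter rings blending into a
central Coons-patch core, and vessels embedded by local patch remeshing
(an O-grid replacing a rectangular block of background cells, with the
lumen center snapped to the patch centroid; successive depths along a ray
are staggered laterally by a few millimetres so the patches stay disjoint).
Everything is deterministic given the parameters; `seed` only drives the
optional boundary jitter, which is off by default.

Sheared cells on sulcal walls are the known weak point of the
terrain-following parameterization: aspect ratios above 10 are reported
with a warning rather than an error, matching the generator's contract.

## Blast loading

The Eulerian air domain that a coupled hydrocode would use exists only to
deliver a calibrated Friedlander load to the skull, so it is replaced by an
analytically prescribed boundary traction:

* incident waveform \(p(t) = P_{peak}(1 - t/t_d)\,e^{-b t/t_d}\) with
  \(t_d = 1\) ms and decay constant \(b = 1\) by default (the decay constant
  of the source profile is not published; it is exposed in the scenario);
* a planar front sweeping the skull at the ideal-gas shock speed
  \(U = c_0\sqrt{1 + \frac{\gamma+1}{2\gamma} \Delta P_i / P_0}\);
* reflection amplification on each exterior face from the ideal-gas
  Rankine–Hugoniot relation
  \(\Delta P_r = 2\Delta P_i + (\gamma+1)\Delta P_i^2 /
  ((\gamma-1)\Delta P_i + 2\gamma P_0)\), interpolated in the incidence
  cosine between face-on and side-on; faces facing away from the front
  receive side-on loading (diffraction is not modeled — a stated
  approximation);
* the wall scenario adds an image source: the front mirrored across a
  reflecting surface 6.3 cm from the side of the head at 26.5 degrees off
  the blast direction, carrying the wall-reflected amplitude. A Mach stem is
  not resolved; the image source is its first-order surrogate.
* the negative phase is kept and floored at \(-P_0\) (absolute vacuum).

## Materials

| region | model | parameters |
|---|---|---|
| skull | corotational linear elastic | rho 1.21 g/cm^3, E 2000 MPa, nu 0.40 |
| gray/white | Tillotson-Brundage volumetric + Prony shear | rho 1.04, A 2.18e6 kPa, B 13.25e6 kPa, cutoff -300 kPa; white G0 33.2, Ginf 7.8 kPa; gray 27.6 / 6.4 kPa; beta 40 1/s |
| CSF / blood | same EOS, no deviatoric strength | cutoff -200 kPa |

Decisions behind the realization:

* **Reduced Tillotson form.** Only the bulk coefficients A and B are
  tabulated for brain tissue; the full Tillotson energy-dependent terms and
  expanded-state branch are not. At loads of a few hundred kPa,
  \(|\mu| \ll 1\) and the energy terms are negligible, so the compressed
  branch \(P = A\mu + B\mu^2\) with linear tension and the cavitation floor
  is used.
* **Cavitation** is a minimum-pressure model: when the trial pressure falls
  below the cutoff the element pressure is pinned there and the element
  flagged; rebound clears the flag as soon as the trial pressure recovers,
  and cavitation history never alters the instantaneous response.
  Post-inception bubble dynamics (growth, collapse, microjetting) are out of
  scope, so cavitated elements are markers of inception, and near-cavitation
  strains/strain rates should be read as conservative.
* **Prony shear** uses the standard identification of the tabulated
  "short-term" and "long-term" moduli with
  \(G(t) = G_\infty + (G_0-G_\infty)e^{-\beta t}\), advanced by the exact
  exponential integrator (unconditionally stable, exact for
  piecewise-constant strain rate).
* **Skull** "hyperelastic" is realized as corotational (Jaumann) linear
  elasticity from (E, nu); skull strains stay well below 1% at these loads.
* Units are SI internally (Pa, m, s); configuration files carry the field's
  units (kPa, ms, mm) in their key names and are converted on load — mixed
  kPa/MPa/GPa tables are the dominant failure mode in this literature.

## Solver

Explicit central-difference Lagrangian dynamics on the conformal mesh, all
interfaces tied (merged nodes; no sliding or contact is described for the
monolithic source meshes this emulates). Plane-strain bilinear quads with
2x2 Gauss integration of the deviatoric term and mean-dilatation (B-bar)
treatment of the volumetric term — brain K/G is ~1e5, so full integration
would lock; CSF behaves as a contained fluid. Lumped (row-sum) masses; CFL
time step `cfl_factor * min(area / longest_edge / c)` with a default factor
of 0.5.

Standard artificial bulk viscosity (linear 0.06, quadratic 1.5) acts in
compression. Strengthless fluid zones additionally carry a small artificial
*deviatoric* viscosity (~0.1 rho h c): a Lagrangian fluid element has
nothing else resisting distortion, and without it the CSF layer tangles
under the 500 kPa scenario. Its dissipation is charged to the viscous term
of the energy ledger. The ledger (external work vs kinetic + internal +
viscous) uses trapezoidal stress power against the raw velocity-gradient
increments and closes to ~0.1% on the study runs; 2% is the acceptance
bound.

Strain is incremental small strain accumulated on the current configuration
(updated Lagrangian). This is adequate below ~20% strain; cavitating fluid
zones can exceed it locally, which is a documented limitation shared with
the strain measures the output metrics are defined on.

## Output metrics

Per element, running maxima of |shear strain|, |dilatational strain| and
their per-step rates, plus cavitation flags and max/min pressure. "Shear
strain" is read as the largest in-plane principal shear
\((\varepsilon_1-\varepsilon_2)/2\) of the accumulated tensor — the source
figures never define their scalar; rates divide per-step increments by the
step, matching explicit-code convention, and are reported in 1/s.

Interface bands (`classify_interface_bands()`) label tissue within a
band width (default 1 mm, configurable — no published definition exists) of
CSF (subpial), vessels (perivascular), ventricles (periventricular) and the
gray–white interface, with precedence vessel > ventricle > pial >
gray-white. Vessel summaries report cavitated lumen area and fraction and
the wall-band strain-rate maximum per vessel. The pattern report flags
sulcal and ventricular cavitation and a coup/contrecoup asymmetry index
along the blast direction through the mesh centroid.

## Problem sizes and what the tests show

The package's own test matrix runs the full study scenarios on a coarse
phantom (5 mm nominal elements, 5 gyri per side, 10 mm sulci; about 3,000
elements, ~60,000 steps for 6 ms) — sizes chosen so the whole matrix runs
on one CPU in minutes. The vascular check embeds a single 0.6 mm channel
near the loaded crown and runs the first 1.4 ms. At these sizes the model
reproduces the qualitative pattern structure: CSF-layer cavitation
enveloping the brain, cavitation reaching into sulci, ventricular
cavitation growing with overpressure, near-identical cavitation maps when
brain shear moduli are divided by 10, reduced cortical strain with a
stiffer skull, and perivascular strain rates above 1e3 1/s beside a 0.6 mm
lumen. Passing these checks demonstrates internal consistency and pattern
reproduction at desk scale — not quantitative agreement with any 3D
simulation or with tissue-level injury data, and not convergence of local
extrema (strain-rate maxima near tiny elements are resolution-dependent in
any shock-physics code).

Verification is layered beneath those pattern checks: closed-form oracles
(Friedlander impulse and zero crossing, Rankine–Hugoniot limits, Prony
relaxation curve, EOS clamp values, sound speeds), bar-propagation wave
speeds within 2%, mirror-symmetry of a symmetric run to 1e-6, an energy
ledger within 2%, bitwise equality of a wall scenario with the reflector
removed, and mesh self-convergence of a mid-brain pressure probe within
10% under element-size halving.

## Known limitations

* 2D plane strain; no out-of-plane physics, no skull curvature in the
  third dimension.
* No diffraction around the head; shadow-side loading is side-on by
  construction.
* No bubble dynamics after cavitation inception, no tissue damage or
  failure, no rate-dependent shear moduli, no anisotropy.
* Lagrangian CSF relies on artificial deviatoric viscosity for mesh
  integrity; extreme distortion (>500 kPa, long runs) remains the
  mesh-robustness boundary.
* Quantitative field values are comparable across configurations of this
  model, not across codes: the time integrator, viscosity settings and
  interface treatment of the 3D simulations this emulates are not public.
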