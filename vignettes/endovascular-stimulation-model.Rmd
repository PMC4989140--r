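---
title: "Modeling endovascular electrical stimulation of a large artery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling endovascular electrical stimulation of a large artery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arteryfield)
```

## The problem

Short electrical pulses applied to a blood vessel elicit vasoconstriction,
a candidate technique for controlling non-compressible hemorrhage. When the
vessel cannot be surgically exposed, the electrodes can instead be
introduced *endovascularly* via catheter. `arteryfield` simulates this
situation for a large artery (modeled on the porcine abdominal aorta): it
computes the electric field a pulse train produces on the arterial wall for
several electrode configurations, scores each configuration by field
strength, homogeneity and localization, finds the inter-electrode distance
that optimizes those scores, and checks thermal safety by solving the
transient Pennes bioheat equation for the full stimulation session.

Three configurations are compared:

1. **Endovascular bipolar** — square 1 mm electrodes on the vessel axis,
   alternating between the pulse potential $V_p$ and ground. With an odd
   electrode count the center electrode is active and the flanks are
   returns.
2. **Endovascular active, extravascular return** — all endovascular
   electrodes active; two circular 3 mm return electrodes sit in the muscle
   1.5 mm outside the wall, one above and one below the vessel at the
   active group's axial midpoint.
3. **Remote ground** — endovascular active electrodes against a grounded
   15 × 150 mm plate 40 cm from the vessel, the arrangement used by
   electro-surgical grounding pads.

## Electrical model

During a pulse plateau the field obeys the electro-quasistatic conduction
equation

$$\nabla \cdot (\sigma \nabla \phi) = 0,
\qquad \mathbf{E} = -\nabla \phi,$$

with Dirichlet conditions on the electrode footprints ($\phi = V_p$ or $0$)
and insulating outer boundaries ($\mathbf{n} \cdot \mathbf{J} = 0$). The
charge-relaxation times $\varepsilon/\sigma$ of blood, wall and muscle are
of order microseconds, four orders of magnitude below the 10 ms pulse
duration, so the stationary resistive solution is exact for the plateau and
the permittivities in the material table are carried but unused.
Electrodes are 304 stainless steel, which conducts about $10^7$ times
better than tissue; they are therefore represented as equipotential
(Dirichlet) regions rather than resolved conductors.

The domain is a planar rectangle (unit depth): a 12 mm vessel strip — a
9 mm blood lumen between two 1.5 mm wall layers — centered in a
700 × 200 mm muscle block, the vessel running along the long axis. The
vessel strip is 250 mm long so that its ends are far from the stimulated
section. Two readings of the published geometry are possible (12 mm lumen
inside the walls, or 12 mm overall); we adopt the overall reading because
it reproduces the reference wall-field values to a few percent, whereas
the 12 mm-lumen reading underestimates them by 25–30 %. For the
remote-ground configuration the block is extended upward so its top edge
carries the return plate, 40 cm above the wall.

### Discretization

The equation is discretized with a 5-point finite-volume stencil on a
rectilinear tensor-product grid: uniform 0.25 mm cells across the vessel
and around the electrode group, geometrically coarsened (growth ratio 1.4,
capped at 12 mm) into the far muscle. Interfaces between blood, wall and
muscle fall exactly on cell faces, and face conductances use
distance-weighted harmonic means, which reproduce the series-resistor
composition of layered media exactly — a two-layer slab fixture solves to
$10^{-12}$ relative error. The reduced system is symmetric positive
definite and solved by sparse Cholesky factorization; a residual check at
$10^{-10}$ guards the solve. On a 50 × 50-scale toy problem the sparse path
agrees with a dense plain-loop reference assembly to $10^{-8}$.

The field magnitude is evaluated from *face current fluxes*
($E = J_{\text{face}}/\sigma$, averaged per cell) rather than raw potential
differences, which keeps the normal field consistent with current
continuity across the blood–wall interface where $\sigma$ jumps by a factor
2.8. Refining the spacing from 0.5 mm to the default 0.25 mm changes the
wall-averaged field at the 4-electrode optimum by 2.1 %; the default
resolves the 1.5 mm wall with six cells.

## Wall metrics

All three decision metrics are computed on a region of interest covering
the upper wall through its full 1.5 mm thickness over a 50 mm axial window
centered on the electrode group:

* **mean field** — area-weighted mean of $|\mathbf{E}|$ (V/m), linear in
  $V_p$;
* **homogeneity** — area-weighted standard deviation over the mean,
  in percent (scale-invariant);
* **localization value (LV)** — mean wall field divided by the mean field
  over the muscle directly above the wall, same axial window, extending
  from the wall to the edge of the geometry (~100 mm for the default
  block). Scale-invariant; values well above 1 mean the stimulus targets
  the wall rather than surrounding muscle.

Two conventions here were genuinely open. The standard deviation is taken
area-weighted over the full 2-D ROI (not over the thickness-averaged axial
profile); this matches seven of the nine published homogeneity values
within ~5 %. The tissue ROI follows the published verbal definition ("to
the edge of the geometry") rather than a fixed 100 mm: the two coincide on
the default block, and for the extended remote-ground domain only the
to-the-edge reading reproduces the published localization values (3.77 vs
3.8 computed here for one electrode). A fixed ROI height remains available
as a parameter and warns when it exceeds the domain.

## Distance optimization

`run_sweep()` re-solves the model over a grid of inter-electrode distances
(default 1–50 mm in 1 mm steps — wider than the published 1–20 mm scan
because several reported optima lie at 25–45 mm) and `find_optimum()`
returns the arg-max of the mean field, the arg-min of the normalized STD,
or the arg-max of LV, with ties broken toward the smaller distance. The
pipeline contains no randomness: repeated sweeps are bit-identical. In the
bipolar scheme the field and homogeneity optima coincide only for four
electrodes (near 13 mm); with two or three electrodes they fall at clearly
different distances, which is the basis for preferring the 4-electrode
configuration.

## Thermal model

Joule heating deposits $p = \sigma |\mathbf{E}|^2$ (W/m³) while a pulse is
on. Temperature follows the Pennes bioheat equation

$$\rho c_p \frac{\partial T}{\partial t} =
\nabla \cdot (k \nabla T) + w_b c_b \rho_b (T_a - T) + q''' + p,$$

with the perfusion sink $w_b = 58.34\ \mathrm{s^{-1}}$ acting in the lumen
blood only (scaled by a perfusion factor of 1, 0.1 or 0.01 to emulate
progressive constriction), blood properties $c_b, \rho_b$ from the material
table, arterial temperature $T_a = 310.15$ K, and zero total heat flux on
the outer boundaries (the body interior is at steady state).

The solver advances the *temperature rise* $\theta = T - 310.15$ K: by
linearity the equilibrated baseline — including the metabolic source
$q''' = 33{,}800$ W/m³ and the arterial-temperature term — cancels, and
$\theta$ responds to the pulse-gated Joule source alone. This implements
baseline equilibration exactly, guarantees $T \ge 310.15$ K (all sources
are non-negative), and makes the reported rise independent of how the
unpulsed tissue reached its steady state. The metabolic term can still be
applied explicitly (`include_metabolic = TRUE`) to study the unequilibrated
problem; whether metabolic heat belongs in the blood domain as well is
moot under the rise formulation.

Time stepping is backward Euler — unconditionally stable, which matters for
the 22,000 steps of a 40 s session at 50 Hz — with 1 ms steps during the
10 ms pulses and up to 10 ms steps between pulses. The two step sizes each
get one sparse Cholesky factorization, cached and reused, so a step costs
one triangular solve. Halving both step sizes changes the session maximum
rise by under 2 %, and on an insulated test box the discrete enthalpy gain
equals the integrated Joule input to rounding error (backward Euler
conserves the discrete energy balance exactly under zero-flux boundaries).
The conduction field is solved once per configuration and reused for every
pulse: conductivities are temperature-independent, so the electro-thermal
coupling is one-way. The thermal safety number quoted throughout is the
maximum of the wall-ROI temperature rise over the whole session for the
worst case — 50 Hz repetition, 1 % perfusion — computed here as 1.6 K
(published: 1.2 K), with rises growing in repetition rate and falling as
perfusion recovers.

## Verification fixtures

The package carries its own oracle cases, generated in code
(`make_parallel_plate()`, `make_layered_slab()`, `make_lumped_thermal()`,
`paper_configs()`): uniform-field capacitor slabs, two-conductivity series
slabs, and single-cell Pennes scenarios with closed-form exponential or
ramp trajectories. Every fixture's expected value is computable without the
main solvers, and the test suite feeds each one through the full pipeline.
These fixtures emulate idealized laboratory conditions — uniform media,
exact interfaces, lumped thermal balance. Passing them validates the
numerics; it does not validate the anatomical idealizations (planar
geometry, homogeneous single-layer wall, no flow convection), so agreement
with measurements on real vessels is only as good as those assumptions.

## Problem sizes and defaults

| Quantity | Default | Note |
|---|---|---|
| fine grid spacing | 0.25 mm | 6 cells across the wall; ~28k–90k cells |
| coarsening ratio / cap | 1.4 / 12 mm | far-muscle cells |
| pulse | 40 V, 10 ms | field metrics scale linearly in $V_p$ |
| repetition rates | 1, 10, 50 Hz | duty cycles 1–50 % |
| session | 40 s | 40–2000 pulses |
| dt (pulse / gap) | 1 ms / 10 ms | backward Euler |
| perfusion | 58.34 s⁻¹ × {1, 0.1, 0.01} | lumen only |

Unit tests run on a reduced muscle block (160 × 80 mm) at 0.5 mm spacing;
the optimum-structure check sweeps 1–45 mm in 2 mm steps. The full-size
runs (0.25 mm spacing, 1 mm sweep steps, 40 s worst-case session) are
exercised by the acceptance script, `scripts/acceptance.R`.

## Known limitations

* Planar 2-D geometry with unit depth: no vessel curvature, no
  axisymmetry; absolute currents are per meter of depth.
* Single-layer wall; no intima/media/adventitia distinction, no
  electrode–electrolyte interface impedance, no electroporation-induced
  conductivity change.
* Perfusion is a distributed heat sink, not convective transport; heated
  blood is not advected downstream.
* The published far-field geometry is internally inconsistent (a
  200 × 700 mm muscle block cannot contain a 250 mm vessel as stated), so
  remote-ground (scheme 3) wall fields carry the largest reproduction
  uncertainty — about 13 % below the published values here, with
  localization values matching to 1 %.
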