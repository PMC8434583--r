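---
title: "Designing tripolar concentric ring electrodes under the finite dimensions model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing tripolar concentric ring electrodes under the finite dimensions model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringlap)
library(dplyr)
```

## The problem

Concentric ring electrodes (CREs) record, at a single sensor, enough spatial
information to estimate the surface Laplacian of the potential — the second
spatial derivative that sharpens the blurred scalp or body-surface image of
underlying dipole sources. A tripolar CRE (TCRE) has three recording
surfaces: a central disc and two concentric rings.

Classically these electrodes were analysed with a *negligible dimensions
model* (a point disc and zero-width rings). The *finite dimensions model*
(FDM) used here instead divides the electrode radius into nine equal
intervals and lets the disc radius, each ring's width, and each inter-ring
gap occupy whole intervals. A TCRE geometry is then an integer boundary
tuple `(disc, a1, b1, a2, b2)` with `b2 = 9` (or 6, or any chosen outer
radius), written compactly as `disc|a1-b1|a2-b2`. This makes electrode
design a finite combinatorial problem: every admissible geometry can be
enumerated and ranked.

## From circle averages to estimation weights

The potential averaged over a circle of radius $r h$ around the electrode
centre ($h$ = one interval in physical units) has the Taylor expansion

$$\bar v(rh) = v_0 + \frac{(rh)^2}{4}\,\nabla^2 v
  + \sum_{k\ge 2} \frac{(rh)^{2k}}{(2k)!\,/\,(2\,k!\,\cdots)}\,(\text{higher terms}),$$

in which every term carries an even power $r^{2k}$. Each recording surface
averages the circles it covers — the disc of radius $d$ covers circles
$r = 0,\dots,d$ (including the centre point), a ring $[a,b]$ covers
$r = a,\dots,b$ — so the *moment* of a surface at order $k$ is the mean of
$r^{2k}$ over its circles, an exact rational number. Bipolar differences
(ring minus disc) cancel the centre potential, leaving difference moments
$D_{j,k}$.

For a TCRE the two weights $(w_1, w_2)$ solve the exact linear system

$$w_1 D_{1,2} + w_2 D_{2,2} = 0, \qquad w_1 D_{1,1} + w_2 D_{2,1} = 4,$$

cancelling the 4th-order truncation term (twice the number of rings is the
highest order that can be cancelled) and normalising the leading term —
whose circle-average coefficient is $r^2/4$ — to contribute exactly one
unit of the Laplacian. The lowest surviving term has order 6; its absolute
coefficient

$$c_6 = \frac{\left|\,w_1 D_{1,3} + w_2 D_{2,3}\right|}{2 \cdot 6!}
      = \frac{\left|\,w_1 D_{1,3} + w_2 D_{2,3}\right|}{1440}$$

is the figure of merit: the ratio of two configurations' $c_6$ values
predicts the ratio of their Laplacian estimation errors.

```{r weights}
w <- solve_weights(named_config("OPTIMAL"))
tidy(w)
glance(w)
```

All of this is carried out in exact rational arithmetic; floating point
appears only at rendering and in the mesh validation. The package ships its
own vectorised rational class on integer-valued doubles (exact below
$2^{53}$, with overflow guards); for radii up to 12 all intermediates stay
many orders of magnitude below the bound, and additions use
least-common-multiple denominators to keep them small. Decimal renderings
round half away from zero — 3 decimals for coefficients, 2 for percentages
— by digit-wise long division on the exact fraction, so table output is
reproducible bit for bit at any magnitude.

## Exhaustive ranking

For outer radius $R$ every strictly increasing boundary tuple is
admissible; there are $\binom{R-1}{4}$ of them (1 at radius 5, 5 at radius
6, 70 at radius 9). Ranking is by exact coefficient; percentage increases
over the optimum are formed from the exact coefficient *ratio* before
rounding, because rounding the two coefficients first drifts in the last
printed digit. Ties would break lexicographically on the boundary tuple;
none occur for radii 5–12.

```{r ranking}
rank_configs(enumerate_configs(9)) |>
  select(rank, label, coefficient_3dp, pct_increase) |>
  filter(rank %in% c(1, 15, 30, 70))
```

The optimal radius-9 geometry `1|2-3|4-9` keeps every surface minimal and
at minimal distance except the outer ring, which absorbs all remaining
area. The previously used constant (CIRD, `1|4-5|8-9`) and linearly
increasing (LIIRD, `1|3-4|8-9`) inter-ring-distance designs rank 30th and
15th, with coefficient increases of 213.01% and 99.33%. `cre_principles()`
checks the five ordering principles (minimal disc, wide outer ring, outer
gap placement, …) on the full enumeration of any radius.

## Dipole-field validation

The analytic ranking is validated against the closed-form field of a unit
current dipole at depth $z$ below a measurement plane, oriented along $+Z$,
in a homogeneous medium of conductivity $\sigma = 7.14$ (entered in mS/cm;
with distances in cm and a unit moment, potentials read as volts). The
reference "analytical Laplacian" is the closed-form second derivative

$$\nabla v = \frac{3}{4\pi\sigma}\left[
  \frac{5 (z_p - z)^2\,(\bar r_p-\bar r)\cdot\bar p}{|\bar r_p-\bar r|^7}
  - \frac{(\bar r_p-\bar r)\cdot\bar p + 2 (z_p - z) p_z}{|\bar r_p-\bar r|^5}
\right],$$

which on the axis reduces to $6/(4\pi\sigma z^4)$ (0.825 mV/cm² at 3 cm).

**Sign convention.** For the source-free half-space the potential is
harmonic, so this quantity equals $\partial^2 v/\partial z^2 =
-\nabla^2_{xy} v$: the field's customary Laplacian sign, under which a
superficial source produces a positive peak. The package keeps both views
explicit. `laplacian_estimate()` is the plain finite-difference estimator
of the *tangential* Laplacian (ring-minus-disc differences; it returns
exactly $+4$ for $v = x^2+y^2$), while the mesh layer's `estimate_map()`
negates it so estimate and analytical maps are directly comparable (the
same quadratic field maps to $-4$ there). Mixing the two conventions is
the single easiest way to get nonsense (∼200% relative error) out of this
comparison.

The mesh is 700 × 700 nodes at spacing 0.25/9 cm (≈ 0.278 mm, ≈ 19.4 cm
side). That spacing is exactly one ninth of a 0.5 cm electrode's interval,
so every tested diameter 0.5, 1.0, …, 5.0 cm yields a whole number of grid
steps per interval (1–10) and all circle sample points fall on nodes. The
dipole sits under node (350, 350), putting a node exactly on-axis; a
half-step sub-grid offset is available via `mesh_spec(dipole_offset = 0.5)`
and changes the measures by well under 0.01 percentage points. Circle
potentials on the mesh are 4-point means (the four axis-aligned nodes);
with 4-point sampling the estimator is exact for polynomial fields of total
degree ≤ 3 and for $x^2+y^2$, versus degree ≤ 5 with true circle averages.
Estimates exist wherever all sample points fit on the mesh: a centred
square of side $700 - 18\,s$ nodes for $s$ steps per interval (682 for
0.5 cm, 520 for 5 cm).

Four measures compare each estimate map $\hat L$ with the analytical map
$L$ over the valid region:

* **Max amplitude** $\max|\hat L|$ (sensitivity);
* **NSG**, the normalized spatial gradient at the dipole node: the mean
  over four cross-shaped displacements of $d = 0.5$ cm (18 grid steps) of
  $|L_0 - L_d|/L_0$, with the signed centre value in the denominator
  (spatial resolution);
* **RE** $= \sqrt{\sum (L-\hat L)^2 / \sum L^2}$ (total error);
* **NME** $= \max|L-\hat L| / \max|L|$ (worst-case error, normalised); the
  unnormalised maximum error is also reported.

`measure_sweep()` runs the full grid of configurations × diameters
(0.5–5 cm) × depths (1–10 cm) and `increase_summary()` condenses it into
per-depth means and standard deviations of the RE/NME increases of CIRD
and LIIRD over the optimal design. The standard deviation is the
*population* form (divisor $n$ = 10 diameters): with sample SDs every
tabulated deviation is high by exactly $\sqrt{10/9}$, so the population
form is the one the reference values follow. `median_increase()` takes the
median over depths of the per-depth means — at depth 10 cm the mesh-based
increases (≈ 211.4% and 98.7% for RE) converge to the analytic coefficient
ratios (213.01% and 99.33%), closing the loop between the exact and
simulated layers.

## Numerical and design choices

* **Surface potential model**: unweighted mean over the covered integer
  circles' potentials, disc including the centre. This is the only
  averaging rule consistent with the published weight fractions, all three
  of which the solver reproduces exactly.
* **Coefficient normalisation**: divisor $2\,(2k)!$ at order $2k$ (1440 at
  order 6). The constant is immaterial for ranking — only ratios matter —
  but fixes the rendered coefficients to the reference tables bit for bit.
  For more than two rings the solver generalises (cancel orders
  $2..n$, normalise order 1, coefficient at order $2(n+1)$), but the
  normalising constant beyond tripolar is an extrapolation of the same
  rule, not independently confirmed.
* **Degenerate inputs**: non-increasing boundaries are rejected naming the
  offending pair; a singular moment system (not reachable from valid
  strictly increasing geometries) reports the moment matrix; an
  electrode too large for its mesh, a mesh-misaligned diameter, and a zero
  NSG denominator are each explicit errors.
* **Problem sizes**: unit tests exercise the mesh code on 41- and 81-node
  meshes, which cover every code path of the 700-node production mesh; the
  full-mesh sweep (3 configurations × 10 diameters × 10 depths) is run
  once in the validation tests and takes on the order of half a minute.

## Limitations

* The dipole model is a homogeneous half-space evaluated on a plane; no
  multi-layer tissue models, no boundary (image-charge) corrections, no
  tilted or off-centre dipoles in the shipped sweeps.
* The validation mesh discretises circle averages with 4 points; that is
  the convention of the reference results, not a quadrature refinement.
* Exact arithmetic is bounded by $2^{53}$; operations that would exceed it
  fail loudly rather than silently losing precision. Radii well beyond 12
  may require a big-integer backend.
* Geometries are integer-interval only; continuous boundaries and
  area-weighted (rather than circle-averaged) surface potentials are out
  of scope.
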