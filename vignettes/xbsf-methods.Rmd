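---
title: "Halogen-bond scoring with xbsf: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Halogen-bond scoring with xbsf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xbsf)
```

## The interaction and the model

A halogen bond is the short, directional contact C–X···A between a
carbon-bonded halogen X (Cl, Br or I) and an electron donor A (here O, N
or S). It exists because the halogen's electron density is anisotropic:
along the extension of the C–X bond sits the σ-hole, a patch of positive
electrostatic potential, while the equatorial belt stays negative. Two
geometric consequences drive the scoring model:

1. the attraction is strongest at a linear C–X···A angle
   (Θ = 180°) and vanishes once the acceptor sees net negative charge;
2. the halogen is *polar-flattened* — its effective radius is smaller
   along the σ-hole axis than sideways — so near-linear contacts sit at
   shorter X···A distances than bent ones.

`xbsf` scores each candidate interaction as

$$E = W \, \Phi(\Theta) \, D(r, \Theta)$$

and a complex as the sum over all (donor site, acceptor) pairs.

**Angle factor.** The effective σ-hole charge at angle Θ is modelled as
$Z_{X,\Theta} = A\cos(\nu\alpha) + B$ with $\alpha = 180° - \Theta$, and

$$\Phi = Z_{X,\Theta} / Z_{X,180} \ \text{for } \Theta_0 \le \Theta \le 180°,
  \qquad \Phi = 0 \text{ otherwise.}$$

$\Theta_0$ is the electroneutral angle at which the surface charge
changes sign: 146° for Cl, 126° for Br, 122° for I. The published
account of this model states $\Theta_0$ but not the calibrated
$(A, B, \nu)$ coefficients, which live in cited external work. The
package therefore defaults to the minimal model consistent with all
stated anchors: $\nu = 1$, $A = 1$ and $B = -\cos(180° - \Theta_0)$, i.e.
the cosine shifted so the charge is exactly zero at $\Theta_0$, giving
the closed form

$$\Phi(\Theta) = \frac{\cos(180°-\Theta) - \cos(180°-\Theta_0)}
                      {1 - \cos(180°-\Theta_0)}.$$

This reproduces the reference value Φ(177.8°, I) = 0.998 and pins
Φ(180°) = 1 and Φ(Θ₀) = 0 exactly. Users who hold calibrated
coefficients can override them per halogen
(`xbsf_params(charge = list(I = list(A = ..., B = ..., nu = ...)))` or
via the YAML config); the normalization and the Θ₀ clamp are applied
identically in either case.

**Distance factor.** With vdW radii $r_X$ (Cl 1.8, Br 2.02, I 2.2 Å)
and $r_A$ (O 1.7, N 1.8 Å), the signed overlap is
$d = r_{XA} - (r_X + r_A)$. Then D = 1 for $d \le -\delta$, D = 0 for
$d \ge 0$, linear in between. The saturation depth δ is tabulated per
halogen and per 15° angle range:

| halogen | 165–180° | 150–165° | 135–150° |
|---------|---------:|---------:|---------:|
| Cl      | 0.25 Å   | 0.15 Å   | —        |
| Br      | 0.45 Å   | 0.35 Å   | 0.25 Å   |
| I       | 0.55 Å   | 0.45 Å   | 0.35 Å   |

δ shrinking with angle *toward* 180° would be flattening along the
equator; here δ grows toward 180°, i.e. deeper tolerated overlap along
the σ-hole axis, which is exactly the polar-flattening signature mined
from crystal-contact distance histograms (the `mine_contacts()` /
`bin_contacts()` pair reproduces that survey methodology on any input
set: contacts binned by 15° increments from 135° to 180° against
distance).

**Weights.** W is the per-halogen energy-well depth: Cl −0.265,
Br −0.32, I −0.4. Acceptors are equally weighted, so O, N and S carry no
extra parameter. Because E = W·Φ·D with Φ, D ∈ [0, 1], every interaction
energy lies in [W, 0] and a ligand without Cl/Br/I scores exactly zero.

## Parameters that matter, and their defaults

* **Covalent C–X cutoffs** (donor detection): carbon within 2.1 / 2.2 /
  2.4 Å for Cl / Br / I — typical C–X bond lengths (1.79 / 1.94 /
  2.13 Å) plus slack. Prepared docking files carry no connectivity
  records, so bonds must be inferred; the nearest in-cutoff carbon wins,
  ties broken by lowest serial. Fluorine is never a donor.
* **Sulfur radius**: 2.0 Å. The published radii table covers the atoms
  of the C–X···O worked example (Cl, Br, I, O, N) but not S; 2.0 Å is
  the conventional value and is exposed as
  `xbsf_params(sulfur_radius = )`.
* **δ below the lowest tabulated range**: the table starts at 135° for
  Br/I and at 150° for Cl, while Φ stays positive down to Θ₀ (146° for
  Cl, 126°/122° for Br/I). Default `delta_extension = "extend"` carries
  the halogen's lowest tabulated δ downward, so D remains defined and
  continuous in distance wherever Φ > 0; zeroing D there
  (`"zero"`) would contradict the nonzero angle factor, but is available
  as a config switch. In that region Φ is small, so the choice moves
  totals very little.
* **Waters and cofactors**: water oxygens (HOH/WAT/H2O) are parsed but
  excluded from acceptors unless `include_waters = TRUE`, mirroring
  receptor preparation that strips waters. HETATM O/N/S in the receptor
  (cofactors) count as acceptors by default — they are part of the
  prepared receptor file — and can be excluded with
  `include_hetatm = FALSE`.
* **Mining windows**: `max_distance = 4.5` Å and `min_theta = 120°`
  cover the whole region where the scoring terms can be nonzero
  (the largest radii sum is 4.2 Å, the smallest Θ₀ 122°) with margin for
  surveying; they are survey defaults, not scoring cutoffs — the scoring
  function's own support is implied by Φ and D themselves.
* **Grid box**: size per axis = ligand extent + 15 Å total padding;
  center = extent midpoint, optionally shifted per axis by an
  independent draw from {−2.5, 0, +2.5} Å under a user seed. The
  sign-symmetric draw is a choice (the protocol this reproduces states
  "any, all, or none of the directions by 2.5 Å" without a sign
  convention); the magnitude and the padding are fixed by that protocol.
* **Pose RMSD**: heavy atoms only, in place (no superposition — docked
  poses already live in the receptor frame), no symmetry correction,
  atoms matched by name order. `match = "element"` switches to an
  optimal per-element assignment (shortest-augmenting-path solver) for
  pose writers that reorder atoms.

## Numerical choices

* Angles are computed from clamped arccosines; Φ and D are clamped to
  [0, 1] against rounding at the anchors.
* The zero-overlap boundary d = 0 is snapped at |d| < 1e-9 Å so that a
  distance exactly equal to the radii sum scores 0 in floating point.
* δ-bin boundaries are half-open ([165°, 180°] closed at the top,
  [150°, 165°), [135°, 150°)), so every angle maps to exactly one bin.
  D therefore steps discontinuously by the δ-table increment when Θ
  crosses 150° or 165° at fixed distance; the table is implemented
  literally, with no smoothing across bins. Scores rounded for display
  carry full precision internally.
* Reported Φ/D/score values are displayed to 3 decimals; all arithmetic
  keeps full double precision.
* Seeded utilities (grid-box shift, fixtures, pose sets) draw under a
  locally restored RNG state, so they are bitwise reproducible per seed
  and never perturb the caller's RNG stream.

## What the synthetic fixtures do and do not show

`make_complex()` places a C–X bond and an acceptor at an exactly
requested (distance, Θ) geometry, plus decoy carbons ≥ 6 Å away; the
measured geometry matches the request to 1e-6 before file rounding and
to 1e-3 Å / 0.05° after a PDB write/parse round trip (3-decimal
coordinates). `make_pose_set()` adds rigid perturbations: each
non-reference pose is translated by exactly the requested magnitude in a
random direction and rotated ≤ 15° about its centroid, so displacement
statistics are controlled and deterministic per seed.

These fixtures are geometric probes, not chemistry: no bond orders,
protonation, realistic ligand topology, conformational strain, or
crystallographic noise. Tests built on them establish that the geometric
detection, the term evaluation and the bookkeeping are correct — they do
not establish docking accuracy on real complexes, which depends on the
engine and the benchmark set and is out of scope here. For the same
reason the package rescoring is reported as the standalone halogen-bond
term; combining it with (or substituting it into) a docking engine's
other terms is left to the user.

Problem sizes used by the shipped test suite — a 10^5-point property
grid over (Θ, r), 50 random fixture complexes against an
exhaustive-pair oracle, 200 synthetic contacts against a brute-force
histogram tally — were chosen to exercise every code path and bin while
keeping the suite fast enough to run on every check.

## Known limitations

* Donor inference is distance-based; exotic C–X bond lengths outside
  the cutoffs would be missed, and non-carbon-bonded halogens are
  (correctly) never donors.
* π-system acceptors are not modelled — acceptors are O/N/S atoms only.
* The element-from-name fallback used when a PDB file lacks the element
  column can misread unusual metal names (e.g. calcium named "CA" in a
  HETATM record without an element column); prepared files normally
  carry either the element column or an AutoDock type.
* The δ table's printed integer ranges leave its behavior between Θ₀
  and the lowest range, and any smoothing at bin boundaries,
  undetermined; both are resolved by explicit, documented defaults
  (`extend`, no smoothing) rather than by guessing hidden behavior.
* One published reference value is internally inconsistent at the last
  digit: with Φ and D rounded to three decimals (0.998, 0.992) their
  product is 0.990016, while the quoted pre-weight score is 0.99014 and
  the full-precision product is 0.9912. Comparisons against that value
  use a ±0.002 band rather than exact match.
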