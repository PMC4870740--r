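# xbsf

Empirical halogen-bond scoring for protein–ligand complexes.

Most docking scoring functions treat a carbon-bonded halogen as a plain
van der Waals sphere, so a close C–X···A contact (X = Cl, Br, I;
A = O, N, S) is penalized as steric repulsion even when it is in fact an
attractive halogen bond through the halogen's σ-hole — the patch of
positive electrostatic potential on the distal end of the C–X axis.
`xbsf` implements an empirical halogen-bond term that can be used to
rescore docked poses or crystal complexes independently of any docking
engine, together with the supporting utilities such a study needs:
structure parsing (PDB and multi-MODEL PDBQT pose files), contact-geometry
mining, grid-box construction and in-place pose RMSD.

## The scoring function

Each candidate C–X···A interaction is scored as

    E = W · Φ(Θ) · D(r, Θ)

* **W** — per-halogen energy-well weight: Cl −0.265, Br −0.32, I −0.4.
* **Φ(Θ)** — angle factor. The effective σ-hole charge is modelled as
  `Z = A·cos(να) + B` with `α = 180° − Θ`; Φ is the charge normalized by
  its value at the linear geometry, `Φ = Z_Θ / Z_180`, clamped to zero
  below the halogen's electroneutral angle Θ₀ (Cl 146°, Br 126°, I 122°),
  where the surface charge changes sign. Φ(180°) = 1 and Φ(Θ₀) = 0
  exactly.
* **D(r, Θ)** — distance factor on the signed van der Waals overlap
  `d = r(X···A) − (r_X + r_A)`: D = 1 when `d ≤ −δ`, 0 when `d ≥ 0`,
  linear in between. The saturation depth δ depends on the halogen *and*
  on the angle range (165–180°, 150–165°, 135–150°), shrinking toward the
  σ-hole axis — this encodes the polar flattening of the halogen's
  aspherical shape, read off from surveyed crystal-contact distance
  distributions.

All acceptors (O, N, S) are equally weighted; a non-halogenated ligand
scores exactly zero. Parameters ship as editable YAML
(`write_xbsf_params()` / `read_xbsf_params()`).

## Worked example

The canonical test geometry is a C–I···O contact with an I···O distance
of 3.354 Å and a C–I···O angle of 177.8° (as found between an
iodophenyl inhibitor and a backbone carbonyl oxygen of MEK1):

```r
library(xbsf)
cx <- make_complex(halogen = "I", acceptor = "O",
                   distance = 3.354, theta = 177.8)
score_complex(cx$protein, cx$ligand)
#> XBSF halogen-bond score: 1 interaction, total energy -0.3965
#>  hal_element hal_serial acc_resname acc_resno acc_name distance theta   phi
#>            I          2         GLY         1        O    3.354 177.8 0.998
#>   dfac pre_weight energy
#>  0.993      0.991 -0.396
```

The angle factor Φ is 0.998 (almost perfectly linear), the distance
factor D is 0.993 (overlap 0.546 Å, just short of the 0.55 Å saturation
depth for iodine near 180°), the pre-weight score Φ·D is 0.991, and the
energy is W·Φ·D = −0.4 × 0.991 = −0.396.

Other entry points:

```r
g <- compute_grid_box(cx$ligand, seed = 11)   # padded, seeded-shift grid box
recs <- mine_contacts(list(cx))               # contact-geometry records
bin_contacts(recs, "I", "O")                  # 15-degree-binned histogram
ps <- make_pose_set(n_poses = 5, perturbation = 2, seed = 1)
rescore_poses(ps$protein, ps$poses, reference = ps$poses[[1]])
```

A thin command-line front end lives at `inst/cli/xbsf.R`
(`score`, `rescore`, `gridbox`, `mine`, `rmsd`, `fixture` subcommands).

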