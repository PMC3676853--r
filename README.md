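# enmconf

Elastic network analysis of two-domain protein conformer pairs in R.

Hinge-bending proteins — the bacterial periplasmic binding proteins are the
textbook case — are crystallized in an open (ligand-free) and a closed
(ligand-bound) form that differ by a rigid rotation of one domain relative
to the other. `enmconf` is for structural bioinformaticians who want to
analyse such pairs with coarse-grained elastic network models: predict
B-factors, locate the hinge, find the kinetically hot residues, map which
parts of the structure move as rigid blocks, and measure the inter-domain
rotation angle.

## What it computes

Working on one node per residue (Cα only), with uniform springs inside a
cutoff *r<sub>c</sub>*:

- **GNM** — the Kirchhoff (graph Laplacian) matrix Γ with Γ<sub>ij</sub> =
  −1 for contacts (R<sub>ij</sub> ≤ r<sub>c</sub>, default 7.3 Å);
  fluctuations ⟨ΔR<sub>i</sub>·ΔR<sub>j</sub>⟩ =
  (3k<sub>B</sub>T/γ)[Γ⁻¹]<sub>ij</sub>; B-factors B<sub>i</sub> =
  (8π²/3)⟨ΔR<sub>i</sub>²⟩; per-mode profiles λ<sub>k</sub>⁻¹[u<sub>k</sub>]<sub>i</sub>²;
  normalized cross-correlations C<sub>ij</sub> ∈ [−1, 1].
- **ANM** — the 3N×3N Hessian with superelements
  H<sub>ij</sub> = −(r<sub>j</sub>−r<sub>i</sub>)(r<sub>j</sub>−r<sub>i</sub>)ᵀ/d<sub>ij</sub>²
  (default cutoff 15 Å); fluctuation magnitudes *and* directions per mode.
- **Derived analyses** — least-squares k<sub>B</sub>T/γ fitting against
  experimental B-factors with Pearson correlation; hinge residues as
  near-zero minima of the slowest GNM mode; hot residues as peaks of the
  fastest-10-mode average (at 7.3 and 9 Å) with contact numbers;
  difference-distance maps with a ±1.5 Å classification;
  slowest-mode fluctuation differences; and the inter-domain rotation
  angle by two-stage Kabsch superposition (fixed domain, then moving
  domain; θ from the aligned rotation matrix).
- **Synthetic ground truth** — two-domain dumbbell generators with known
  linkers, rotation angles, and noise-corrupted B-factor columns, so the
  whole pipeline is testable end-to-end without any structure downloads.

Structures are read from PDB files (Cα atoms, experimental B-factor
column, altloc/chain/model handling) via `read_calpha()`; everything is
exportable as per-residue CSV tables, dense or sparse matrix text, and
summary JSON.

## Worked example

```r
library(enmconf)

# synthetic open/closed pair: 40+40-residue domains, 5-residue linker,
# domain B rotated 41.3 deg, B-factors at kBT/gamma = 5.64 A^2 + 5% noise
pair <- make_conformer_pair(seed = 1, angle_deg = 41.3)
open <- pair$open
open$exp_bfactor <- as.numeric(synth_bfactors(open, scale = 5.64,
                                              noise_sd_fraction = 0.05, seed = 1))

g <- enm_decompose(build_kirchhoff(open, 7.3))
fit_scale(gnm_msf(g), open$exp_bfactor)
#> B-factor scale fit: kBT/gamma = 5.667 A^2, Pearson r = 0.976 (n = 85)

find_hinges(gnm_mode_msf(g, 1))
#> hinge residues (1): 43

rotation_angle(open, pair$closed,
               fixed_domain = pair$labels$domain_a,
               moving_domain = pair$labels$domain_b)
#> inter-domain rotation: 41.300 deg (fixed-domain rmsd 0.000 A)
```

The fitted scale recovers the generating 5.64 Å² to within the noise, the
hinge lands inside the labelled linker (residues 41–45), and the rotation
angle recovers the generator's 41.3° exactly. For real structures,
substitute `read_calpha("1abc.pdb", chain = "A")` and the deposited
B-factor column is used automatically.

The same pipeline is packaged as a four-step analysis under `analysis/`
(generate → GNM → ANM → compare), each step writing its tables under
`results/` and printing what it found:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_gnm.R
Rscript analysis/03_anm.R
Rscript analysis/04_compare.R
```

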