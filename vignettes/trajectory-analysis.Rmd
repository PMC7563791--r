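---
title: "Conformational substates and interface complementarity from protein-complex trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational substates and interface complementarity from protein-complex trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajmd)
```

## Scope and model

trajmd characterises molecular-dynamics trajectories of protein--protein
complexes -- the motivating system being the adenylyl-cyclase (AC5)
catalytic core, whose pseudo-symmetric C1 and C2 domains carry
G-protein-binding grooves -- through five families of observables:

1. **Superposition-based observables.** Every RMSD in the package is the
   minimised (Kabsch) rigid-body RMSD. A frame is least-squares fitted on a
   *fit selection* and measured on a *measure selection*; the two are
   independent so that, for instance, one domain can be fitted while the
   displacement of the other is measured. The average structure is the fixed
   point of iteratively fitting all frames to the running mean (tolerance
   1e-4 Å, below the PDB coordinate precision of 1e-3 Å; at most 50
   iterations, with a warning on non-convergence). RMSF is the per-atom RMS
   fluctuation about that average after fitting, averaged over backbone
   atoms within each residue; for isotropic per-coordinate noise of
   standard deviation σ the expected value is σ√3, which the tests use as a
   closed form. Mass weighting is off by default (an optional `weights`
   argument exists): plain coordinate RMSD is the convention for
   backbone-level substate analysis.

2. **GROMOS conformational clustering.** On the matrix of pairwise fitted
   RMSDs (backbone atoms by default), the frame with the most neighbours
   within the cutoff (default 1.5 Å) seeds a cluster; it and its neighbours
   are removed and the scan repeats. Ties on neighbour count are broken
   toward the lowest frame index -- the published algorithm leaves this
   open, and determinism is required for reproducible runs. Clusters are
   then filtered by *dwell time* (member count × frame interval): clusters
   strictly below the threshold (default 100 ns) are discarded, so a
   cluster sitting exactly at the threshold is retained. Two notions of
   "central structure" exist: the greedy centre (most neighbours) and the
   medoid (minimum summed RMSD to co-members). Both are reported;
   `representative_structure()` returns the medoid by default as the
   stricter geometric reading. The full RMSD matrix is held in memory,
   which caps trajectories at 20,000 frames (a documented error suggests
   striding beyond that).

3. **Interface complementarity.** Solvent-accessible surface area uses a
   slice-based Lee--Richards integration: each atom's sphere is expanded by
   the probe radius (default 1.4 Å), cut into z-slabs (default 0.1 Å; the
   slab count per atom is rounded so the slabs span the sphere exactly,
   making an isolated sphere exact), and on each slab the accessible arc of
   the atom's circle is accumulated. ΔASA = ASA(A) + ASA(B) − ASA(AB), and
   the single-sided interface area is ΔASA/2, the convention under which
   published gap indices for protein complexes fall in the
   few-Å range. Gap volume follows the SURFNET construction: for
   every inter-chain heavy-atom pair, a sphere is grown midway between the
   atomic surfaces (skipped if its initial radius exceeds 5 Å), shrunk in
   0.1 Å steps away from the most-penetrating third atom (at most 50
   steps; the exact published shrink rule is not specified, so this
   simple deterministic rule is used), and discarded below 1 Å; the union
   of retained spheres is integrated on a 0.5 Å cubic grid. The gap index
   is gap volume / interface area; when the chains bury no area it is
   undefined and reported as NA rather than a number. Hydrogens are
   excluded throughout and Chothia-style united-atom radii (C 1.87, N
   1.65, O 1.40, S 1.85, P 1.90, H 1.00, default 1.80 Å) are assigned at
   load time; the radii table is a parameter, since published gap-index
   ranges depend on the radii set shared between the surface and gap
   computations. A Shrake--Rupley point quadrature
   (`shrake_rupley_sasa()`) is shipped as an algorithmically independent
   backend; the validation battery requires the two to agree within 1% on
   random structures, and the union-of-spheres grid volume to agree with
   Monte-Carlo integration within 5%.

4. **Helix geometry.** The inter-helix angle α and centre distance d of the
   groove-forming helix pairs (defaults: C1 408--420 vs 468--475, C2
   910--918 vs 978--988, author numbering) are computed per frame. The
   axis is seeded with the principal (SVD) direction of the Cα cloud and
   refined by a least-squares cylinder fit (minimising the spread of
   Cα-to-axis distances), which is exact on ideal helices even for
   non-integer numbers of turns -- the raw principal direction alone is
   biased by up to ~2° at typical helix lengths because the residue phase
   does not average out of the cross-covariance. The direction is oriented
   N→C, so antiparallel pairs report near 180° and small directional
   changes keep their sign. The helix "centre" is the Cα centroid.
   Angles are computed per frame and then summarised (mean, SD); computing
   on an average structure instead is possible but conflates fluctuation
   with structure change.

5. **Contacts and monitors.** A residue pair across the chain partition is
   a contact when any heavy-atom pair is within the cutoff (default 5 Å).
   The cell-list implementation is required by its tests to reproduce the
   brute-force enumeration exactly. Conserved-contact fractions are taken
   against a reference frame (default the first production frame, i.e. the
   docked pose after equilibration). Residue persistence is the fraction
   of frames in which a residue participates in at least one interface
   pair; the persistent-residue list uses a strict threshold (default
   0.8), so exactly 80% presence does not qualify. Named atom-pair
   monitors (e.g. active-site lysine/arginine to ATP phosphate oxygens,
   aspartates to Mg²⁺) are plain per-frame Euclidean distances.

## The synthetic-data generators

Real microsecond trajectories of these systems are not redistributable, so
the package carries generators that plant every property the analysis
modules are supposed to recover:

- `make_ideal_helix()` -- exact helical lattice (rise 1.5 Å, twist 100°,
  Cα radius 2.3 Å) with stub backbone atoms; the fitted axis must recover
  the construction direction.
- `make_helix_pair()` -- two helices whose constructed axes subtend exactly
  the requested angle with centroids at exactly the requested separation.
- `make_two_chain_complex()` -- two corrugated, interdigitated atom slabs
  seated at van der Waals tangency and pulled apart rigidly by a planted
  distance. The corrugation matters: for flat surfaces all buried area
  vanishes once the surface separation exceeds twice the probe radius
  (2.8 Å), whereas rough, nested surfaces -- like real interfaces -- keep a
  defined interface over the separations the monotonicity checks sweep.
- `make_multistate_trajectory()` -- frames visiting states in contiguous
  blocks (so the dwell-time filter is exercised meaningfully, unlike
  i.i.d. labels) with isotropic Gaussian coordinate noise; planted labels
  are returned for recovery scoring.
- `make_random_structure()` -- seeded rejection-sampled packings, used as
  oracle fodder.

All generators restore the global RNG state and are byte-deterministic
under their seed.

What the generators do *not* emulate: force-field energetics, correlated
(non-isotropic) fluctuations, side-chain packing, solvent, and ligand
chemistry. Passing the recovery battery therefore demonstrates the
*analysis* pipeline is correct and deterministic, not that any biological
conclusion about a particular system would be reproduced.

## Numerical choices

- Lee--Richards slab thickness 0.1 Å: error is roughly linear in the
  thickness; 0.1 Å keeps random-structure totals within ~0.1% of the
  10,000-point quadrature while costing a few tenths of a second for
  50-atom structures.
- Gap-volume grid 0.5 Å (3--5% accuracy); halving the spacing changes
  random-fixture volumes by under 3%.
- Kabsch reflections are corrected via the sign of det(U)det(V); point
  sets with collinear geometry raise an error rather than returning an
  arbitrary rotation.
- Degenerate helix fits (no dominant principal direction, e.g. a flat
  ring of Cα) raise an error rather than picking a direction by floating
  point accident.
- Cluster ids are assigned by size rank; equal-size ties keep formation
  order, and all tie-breaks are toward lower frame indices.
- The pipeline validates every selection and monitor against the topology
  before creating any output (fail-fast), skips
  floor(equilibration_ns/dt_ns) leading frames before any stage runs, and
  writes each stage's CSV as soon as the stage completes so a late failure
  preserves earlier results.

## Validation problem sizes

The shipped test-and-validation battery uses: 100 random 50-atom
structures for the SASA cross-check, 20 random sphere sets with 10⁶
Monte-Carlo points for the union-volume cross-check, 100 random ≤12-frame
trajectories against a brute-force clustering oracle plus a 200-frame
planted two-substate trajectory, 50 random 10-point instances against a
rotation-grid superposition oracle, a 10°--170° helix-angle sweep, 100
random two-chain fixtures for contact-map exactness, and a 2000-frame
noise trajectory for the RMSF closed form. These sizes make the oracle
comparisons tight (sampling error well under the tolerances) while keeping
the whole battery in the minutes range on one CPU.

## Worked example

```{r example, eval = FALSE}
# a two-state complex trajectory with planted substates
cx  <- make_two_chain_complex(25, surface_gap = 0.5, seed = 11)
bent <- set_coords(cx, coords(cx) + 0.8 * outer(sin(seq_len(n_atoms(cx)) / 4),
                                                c(1, -0.9, 0.8)))
tw  <- make_multistate_trajectory(list(cx, bent), c(0.5, 0.5), 12,
                                  noise_sigma = 0.05, dt_ns = 50, seed = 12)

bundle <- run_analysis(list(dt_ns = 50, seed = 1, output_dir = tempfile(),
                            chains_a = "A", chains_b = "B"),
                       trajectory = tw$trajectory)
bundle$tables$cluster_summary
head(bundle$tables$interface)
```

## Known limitations

- PDB only (fixed-column, multi-model for trajectories); no XTC/DCD/mmCIF.
  Insertion codes are rejected on input.
- Author residue numbering is used verbatim; mapping between alternative
  numbering schemes for the same protein is configuration, not code.
- Gap spheres are grown only between the two chain sets; rim cavities and
  intra-chain voids are not counted.
- The contact criterion is purely geometric; no hydrogen-bond angles or
  salt-bridge typing.
- SASA and gap volume are the costly stages; the pipeline therefore
  evaluates interface reports at a configurable frame stride (default
  every 10th frame).
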