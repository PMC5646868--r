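---
title: "Methods: Monte Carlo ligand migration and path conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo ligand migration and path conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligapath)
```

## The problem

Vanillyl alcohol oxidase (VAO) and its relatives eugenol oxidase (EUGO)
and *p*-cresol methylhydroxylase (PCMH) are flavoenzymes whose active
site is buried at the interface of a FAD-binding domain and a cap
domain, with no channel to bulk solvent visible in the crystal
structures. How phenolic substrates, products and the co-ligands
dioxygen and hydrogen peroxide travel between the active site and the
solvent is therefore a sampling problem: one needs an unbiased way of
exploring the protein energy landscape along rigid-body ligand motions,
plus analyses that turn the resulting trajectories into interpretable
path descriptions, and a sequence-level statistic that asks whether the
residues lining those paths are under selective pressure across the
enzyme subfamilies.

`ligapath` implements that computational pipeline: a Monte Carlo
migration explorer over a pluggable energy oracle, trajectory
statistics (RMSF, atom contacts, binding-energy/distance profiles, path
assignment, exit detection, dimer symmetry mapping), structure-derived
residue classifications (solvent accessibility, subunit interface), and
an alignment-column conservation statistic for three-subfamily
comparisons.

## The migration explorer

A ligand state is a rigid-body pose: the centroid translation, a unit
quaternion orientation, and the ligand atoms in a local frame. One
Monte Carlo move perturbs the pose with a translation of magnitude
uniform in a configured range along a random unit direction, and a
rotation about a random axis by an angle uniform in a configured range,
then applies a Metropolis filter at temperature `kT`:

$$P(\text{accept}) = \min\!\big(1, e^{-\Delta E / kT}\big).$$

Defaults follow the published protocol: exit moves draw translations
from 0.75–1.75 Å and rotations from 0.05–0.25 rad; entry moves use
larger translations (1.25–2.5 Å) whose direction is kept for three
consecutive steps; a small-ligand preset (dioxygen / peroxide scale)
uses 0.5–1.5 Å and 0.1–0.3 rad.

Two population-level devices drive the exploration:

* **Spawning (exit mode).** The reaction coordinate is the distance of
  the ligand centroid from a fixed point in the active-site void (the
  spawning point). At a fixed cadence the population best is found and
  any trajectory lagging it by more than 4 Å is reset to a copy of the
  best state. The best value is re-evaluated at every filter pass, so
  the population optimum can only improve.
* **Adaptive epochs (entry mode).** Trajectories start from six
  positions on a sphere enclosing the receptor. Every 12 steps the
  accepted ligand positions are leader-clustered and new initial
  conditions are drawn from the cluster leaders with probability
  proportional to the inverse cluster population, pushing the search
  toward sparsely visited regions.

Backbone flexibility enters through anisotropic network model (ANM)
moves: the standard elastic-network Hessian over C-alpha atoms
(pairwise springs below a cutoff, uniform force constant) is
eigendecomposed once; a connected network has exactly six zero
eigenvalues (rigid-body motion), and proposals displace the backbone
along one of the six lowest internal modes, scaled to a configured
maximum step.

A trajectory ends when the minimum ligand–receptor heavy-atom distance
exceeds 8 Å for three consecutive accepted frames ("left the protein"),
or at the step budget.

### The energy oracle

The original study evaluated moves with a molecular-mechanics force
field and implicit solvent inside a proprietary engine; those energies
are engine-specific (even across versions of the same engine they
differ by an order of magnitude) and are meaningful only qualitatively.
`ligapath` therefore defines the energy as a contract — two functions,
`total_energy(lig_xyz, receptor_xyz)` used by the Metropolis filter and
`binding_energy(lig_xyz, receptor_xyz)` reported in profiles — and
makes no claim about absolute scales. Any scoring function can be
plugged in; the synthetic system ships an analytic one. Consequences:

* `kT` defaults to 1 in oracle units (the study never states its
  simulation temperature);
* binding-energy/distance profiles are comparable within one oracle
  only;
* published step counts (tens to hundreds of engine steps per exit) do
  not transfer; only qualitative features (wells near the site, rising
  profile toward bulk, percentage of trajectories escaping) do.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `trans_range` | 0.75–1.75 Å (exit) / 1.25–2.5 Å (entry) / 0.5–1.5 Å (small) | translation magnitude range |
| `rot_range` | 0.05–0.25 rad (0.1–0.3 small) | rotation angle range |
| `persistence` | 1 (exit), 3 (entry) | steps a translation direction is kept |
| `temperature` | 1 | Metropolis kT, oracle units |
| `spawning_range` | 4 Å | allowed lag behind the population best |
| `spawn_cadence` | 5 steps | how often the spawning filter runs |
| `adaptive$epoch_length` | 12 steps | entry-mode epoch length |
| `adaptive$cluster_radius` | 2 Å | leader-clustering radius |
| `anm` | off; cutoff 15 Å, 6 modes, step 0.5 Å | backbone move settings |
| `exit_threshold` | 8 Å | minimum heavy-atom distance counting as "outside" |

The spawning cadence, the 8 Å exit threshold with its 3-frame
persistence, and the 2 Å cluster radius are this package's own
numerical choices — the source protocol leaves them unspecified ("the
ligand exited the protein completely" has no printed number). All are
configurable; the defaults were fixed once against the synthetic system
and not tuned per experiment.

## Trajectory statistics

* **RMSF.** Per residue,
  $\mathrm{RMSF}_i = \sqrt{\langle \lVert r_i(t) - \langle r_i\rangle \rVert^2 \rangle_t}$
  over the representative atom (C-alpha; the source does not state an
  atom selection, and an all-atom series can be passed instead).
  Isotropic Gaussian jitter of standard deviation $\sigma$ per axis
  gives $\mathrm{RMSF} = \sigma\sqrt{3}$, which the synthetic generator
  uses as planted truth. Analyses use accepted frames only, and by
  convention only residues of the chain carrying the ligand.
* **Contacts.** A contact is an atom pair (protein heavy atom, ligand
  atom) at distance strictly below 2.7 Å; per-residue counts omit
  zero-count residues. The strict inequality is deliberate: the
  criterion is printed as "smaller than".
* **Interface.** A residue is at the subunit interface when any heavy
  atom lies within 4 Å (inclusive — printed as "within") of another
  chain. Hydrogens never count: the package works on heavy atoms
  throughout, since crystal structures carry no reliable hydrogens and
  the published criteria do not state a hydrogen convention. This is a
  documented possible source of off-by-a-few discrepancies against
  counts computed on prepared (protonated) systems.
* **Surface.** Shrake–Rupley SASA on a deterministic golden-section
  sphere lattice (960 points/atom, probe 1.4 Å, Bondi radii), residue
  relative accessibility against the Tien et al. (2013) theoretical
  maxima, surface at ≥ 30%. The original surface list used a different
  tool's internal reference values; near-threshold residues can differ.
* **Energy–distance profiles.** Frames are binned on a signed
  coordinate: positive distance to the own-subunit reference point,
  negative distance to the partner subunit's when the ligand is nearer
  that one (tie → positive). Per-bin minima trace the qualitative
  energy profile along a path.
* **Path assignment.** Each frame is labelled with the path definition
  whose residue set collects the largest contact count within a ±5
  frame window; ties and zero-contact frames stay unlabelled. A
  trajectory visiting one path keeps its name; several, a
  `"mixed: a->b"` label. The shipped path residue sets
  (`vao_path_residues()`: cap 25, FAD 36, subunit interface 53, re-side
  22 residues) are reconstructions — the published record names only
  each path's most flexible/contacted members plus the set sizes — and
  are user-overridable via TSV.
* **Symmetry.** The dimer map is the Kabsch superposition of chain A
  C-alphas onto chain B; on an exact two-fold dimer it is an involution
  and transports poses, paths and analyses between subunits.

## The conservation statistic

Sequences are compared per alignment column against a designated query
(the VAO structure's sequence, 560 positions; query-gap columns are
excluded). Residues are grouped into six BLOSUM62-derived similarity
sets — {W,Y,F}, {M,I,L,V}, {H,R,K}, {N,D,Q,E}, {S,T,P,A,G}, {C} — and a
column's score is the fraction of records in its most populated group.
Within one subfamily alignment a position is *similar* at ≥ 50% and
*conserved* strictly above 90%.

For the merged three-subfamily alignment the package's default reading
is **per-subfamily agreement**: a position is similar when all three
subfamilies share one identical dominant group, each at ≥ 50%, and
conserved when additionally each exceeds 90%; otherwise dissimilar. A
dissimilar position is **PCMH-unlike** when VAO-like and EUGO-like
sequences share a dominant group (each ≥ 50%) but the PCMH-like
subfamily's dominant group differs or falls below 50%. The pooled
alternative (score the merged column as one population) is retained as
an option, but with VAO+EUGO contributing 238 of 268 records a pooled
reading makes PCMH-unlikeness nearly unattainable, which contradicts
the reported ~25% of positions being PCMH-unlike; hence the
per-subfamily default.

Two more conventions are deliberately explicit because the source is
silent on them and the headline percentages are sensitive to both:

* **Gap policy.** By default gaps count in the denominator and belong
  to no group (a gap-heavy column cannot be similar); `gap_policy =
  "exclude"` drops them. Both are first-class options and the
  reference-data check in the test suite evaluates both.
* **Boundaries.** Similar is inclusive at 0.50; conserved is strict at
  0.90 ("above 90%"). Group ties break to the alphabetically first
  group name and are flagged.

Anchor filtering removes records lacking the covalent FAD anchor
(His422 in VAO numbering, His390 in EUGO, Tyr384 in PCMH) before
analysis; the published subfamily alignments are already filtered, so
re-filtering removes nothing.

## The synthetic study system

`make_toy_receptor()` builds the system all statistical guarantees are
tested on: a C2-symmetric two-chain pseudo-protein (4 heavy atoms per
pseudo-residue, standard residue names so SASA references resolve) with
a buried site per chain, one channel from each site to bulk solvent
(truth path "cap") and one connecting the two sites through the
subunit interface (truth path "subunit_interface"), plus a two-atom
FAD stand-in per chain. The analytic oracle is

$$E(p) = -D\sum_{s \in \{A,B\}} e^{-\lVert p - s\rVert^2/2w^2}
 + k_\perp d_\perp(p)^2 + \sum_{\text{atoms}} k_r (r_c - d)^2_{\,d<r_c},$$

a Gaussian well of depth $D = 2$ (kT units) and width $w = 1.5$ Å at
each site, a harmonic restraint ($k_\perp = 0.3$) on the perpendicular
distance to the channel centerline, and a soft-core repulsion from
receptor atoms within $r_c = 1.8$ Å; the bulk plateau is zero. The
channel lining is at 2.4 Å radius, so a centred ligand atom contacts
lining atoms under the strict 2.7 Å criterion while staying clear of
the steric core; a spec whose centerline intersects the cores is
refused at generation time.

What the toy emulates: a buried minimum, continuous channels with a
monotone approach to the well, C2 dimer symmetry, plantable contacts,
fluctuations and exits, and subfamily alignments with exactly known
per-column categories (at the study's 121/117/30 subfamily sizes by
default, with the anchor column all-His). What it does not emulate:
real protein geometry or energetics, side-chain motion, solvent, or
any absolute energy scale. Passing tests therefore demonstrate the
correctness of the algorithms and statistics, not the biological
conclusions on VAO — those require the published structure and
alignments as inputs (see `inst/extdata/real/README.md`).

## Numerical choices and degenerate inputs

* SASA uses a deterministic lattice — no RNG — so results are
  bit-reproducible; unknown elements or residue types are errors, not
  silent defaults.
* Alternate locations resolve to highest occupancy, ties to file
  order; waters and hydrogens are dropped at parse time.
* ANM rejects disconnected networks (reporting the component count)
  rather than silently returning spurious near-zero modes; rigid-body
  modes are identified by a relative eigenvalue tolerance of 1e-8.
* The ligand "centre of mass" is the unweighted heavy-atom centroid
  (C/N/O masses are near-uniform); a mass-weighted centroid is
  available via the `weights` argument.
* Exploration RNG is stream-per-trajectory (`seed + trajectory
  index`), so results are reproducible regardless of population-level
  interleaving; identical seed and config give byte-identical
  trajectory files.
* All-gap columns have no dominant group and fraction 0; they are
  dissimilar under every policy.

## Problem sizes

The shipped tests and the acceptance script run the explorer at 20
trajectories × 500 steps on the toy receptor (seconds on one core),
RMSF recovery at 10⁴ frames, Metropolis calibration at 10⁵ draws, and
conservation on synthetic alignments up to the full 560 positions ×
268 records. These sizes were chosen to make every statistical check
sharp (3-sigma bands, ±2% tolerances) while keeping a full run
interactive; all of them are parameters, not limits.

## Known limitations

* No all-atom force field, solvent model, side-chain sampling or QM
  charges: energies come from the caller's oracle.
* Path-set defaults are reconstructions (see above), not the exact
  published membership, which is not available in machine-readable
  form.
* The random 58-residue control group used in published summaries is
  irreproducible (no seed was published); `default_residue_groups()`
  ships a fixed arbitrary stand-in and marks it as such.
* mmCIF input, hydrogen placement, pKa prediction and missing-loop
  modelling are out of scope; the PDB reader expects a prepared
  assembly.
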