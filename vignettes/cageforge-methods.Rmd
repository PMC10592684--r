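---
title: "cageforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cageforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Two-component symmetric protein assemblies — here tetrahedral cages built
from two different C3 trimers (the T:{C3}{C3} architecture, stoichiometry
A12B12) — are designed by placing each trimer's 3-fold axis on a body
diagonal of a cube and searching the four remaining rigid-body degrees of
freedom: rotation about and translation along each component's own axis.
`cageforge` implements the fragment-based route to that search: instead of
scoring raw shape complementarity, candidate interfaces are detected and
scored by how well pairs of 5-residue surface fragments reproduce tertiary
motifs observed in a database of structurally clustered fragment pairs.
The same fragment observations then drive sequence preferences
(position-specific amino-acid profiles) and a metric suite used to triage
and rank poses.

# The fragment model

**Fragment typing.** A surface residue is typed by the backbone RMSD of
its 5-residue window (residue +/- 2; terminal residues are untypeable)
against single-fragment type representatives; the minimal-RMSD type below
the database threshold wins, with ties broken to the lowest type id.
Surface exposure is gated on relative side-chain accessibility (see
*Numerical choices*).

**Ghost fragments.** For each typed fragment and each database cluster
whose mapped type matches, the cluster's paired-fragment representative is
placed by superposing the mapped representative onto the observed
fragment. Placements clashing with the source oligomer's backbone or
C-beta atoms (any heavy atom within 2.1 Å) are discarded. The optional
continuous-ghost constraint additionally requires a ghost to co-locate
(within the 1 Å match threshold) with a ghost from a *different* source
residue of the same component — e.g. residues i and i+4 of one helix.

**Observations and the match score.** In a posed arrangement, a ghost of
component A and a typed surface fragment of component B form an
observation when their direct (superposition-free) backbone RMSD is below
the 1 Å match threshold. Each observation is scored

$$m = \frac{1}{1 + (\mathrm{RMSD}_{frag}/\mathrm{RMSD}_{cluster})^2},$$

which is 1 at a perfect match and 0.5 when the observation deviates
exactly as much as an average cluster member.

**Interaction weights.** Each cluster position carries a weight
$t_r \in [0,1]$: the mean, over cluster members, of the fraction of the
residue's side-chain heavy atoms in contact with the opposite fragment.
Glycine contributes 0 by convention.

**Fragment profile.** Per residue, covering observations contribute their
cluster's amino-acid distribution at the matching position, scaled by
$m_F t_F$ and normalized by $\sum_F m_F t_F$. Rows without observations
(or with all-zero weights) carry no information and are excluded from all
losses. The evolutionary profile is parsed from hhm profile-HMM files
($v \mapsto 2^{-v/1000}$, `*` = 0, rows renormalized). The tertiary
profile blends the two with an effective fragment weight
$\alpha' = \alpha\,\min(1, \bar m/m_{t})\,\min(1, \bar t/t_{t})$, where
$\alpha = 0.5$ is the maximum fragment weight and the min-terms shrink it
in proportion to the quality discrepancy. The proportional-shrinkage form
of $\alpha'$ is this package's own reading — the source procedure states
only that the weight is reduced "by the proportion of the discrepancy"
without a formula.

# Docking

The four DOF are enumerated on a grid (rotations periodic over 120° with
the endpoint excluded; translations inclusive). A grid sample becomes a
candidate when at least `minimum_matched` (default 3) ghost/fragment
overlaps pass the initial-z gate. Candidates are grouped by a 6-D
transform hash of the relative transform — three translation bins plus
three z-y-z Euler-angle bins — and each group's best member is locally
optimized: a 3^4 neighbourhood search that halves its step whenever a
round improves the objective by less than 5 % (relative) and stops below
the minimum step. Final poses must retain `minimum_matched` observations
with $m \ge$ `match_value` (default 0.5).

Two deliberate design choices here:

* **Optimization objective.** The optimizer maximizes the *total*
  Nanohedra score, not the per-residue normalized form. The normalized
  (mean) form rewards shedding observations: a pose keeping only its two
  best-matching fragments out-scores the true optimum that keeps four,
  then fails the minimum-matched filter. The total is the stated
  optimization target of the underlying procedure; normalization is a
  reporting step.
* **initial-z gate.** The semantics of the upstream `initial-z-value`
  parameter are internal to the cited software. Here the coarse search
  keeps an overlap when its RMSD is at most
  `initial_z * RMSD_cluster` (capped by the 1 Å match threshold), i.e.
  z = 1 admits overlaps at least as good as an average cluster member —
  equivalently $m \ge 0.5$. This is a documented stand-in, exposed
  alongside `match_value`.

**Nanohedra score.** Each observation contributes $m$ to both of its
central residues; per-residue sums are capped at 2 and the normalized
score divides the capped total by the number of distinct central fragment
residues, so the normalized score is bounded by 2 and attains it exactly
when every central residue saturates. The cap-and-divide rule is declared
here (the exact accumulation internals live in the cited prior scorer);
it reproduces the printed maximum of 2 for all inputs, which the test
suite checks on 10,000 randomized observation sets.

**Scoring scope.** Observations are evaluated between the principal A–B
trimer pair — the cage's unique heterotypic interface; the full 24-chain
assembly (one chain per entity expanded under the 12 tetrahedral
rotations, each trimer's own C3 being a subgroup) is used for symmetry
checks, the spike ratio and output.

# Interface metrics

* **SASA/BSA.** Shrake–Rupley quadrature (960 points per atom by
  default; 240 for bulk metric sweeps) with radii C 1.7, N 1.55, O 1.52,
  S 1.8 Å and probe 1.4 Å. BSA = SASA(separated components, no
  repacking) − SASA(complex), reported positive, split into polar
  (N/O/S) and apolar (C) atom sums that partition the total exactly.
  The source text's subtraction order would yield negative burial; the
  conventional positive difference is used.
* **Residue classes.** Interface residues (nonzero per-residue BSA) are
  core / rim / support by relative SASA (Tien et al. theoretical maxima)
  at the 25 % threshold — rim: exposed in the complex; core: buried in
  the complex but exposed in the monomer; support: already buried in the
  monomer. The threshold value comes from the cited classification, not
  the source text.
* **Composition similarity.** Measured class counts against the
  size-expected linear fits (core = 0.01·BSA + 0.6, rim = 0.01·BSA −
  2.5, support = 0.006·BSA + 5), averaging
  $1 - |R_{exp} - R_{meas}|/R_{exp}$ with per-class terms floored at 0
  (so gross excess cannot push the mean negative); classes with
  non-positive expectation (tiny interfaces) are skipped.
* **Secondary structure.** Three-state phi/psi windows (helix:
  φ ∈ (−100, −30), ψ ∈ (−80, −5); strand: φ < −40, ψ > 45 or < −160);
  chain breaks and termini are coil. A Stride-style file, when supplied,
  overrides the internal assignment verbatim. Interface SS percentages
  use the interface residue count as denominator.
* **Hydrogen bonds.** Geometric stand-in for the physics-based term the
  source used: donor–acceptor heavy atoms within 3.5 Å and a
  donor-H⋯acceptor angle above 120°, with the backbone amide H placed
  geometrically; buried (SASA < 0.1 Å²) unsatisfied donors/acceptors are
  counted in complex minus unbound states, per 1,000 Å² of BSA.
* **Collapse sites.** Hydrophobic collapse index over the set FMILYVW
  with a uniform 9-residue centered window (window truncated at termini;
  the window size is a parameter — the defining reference does not print
  it); new collapse sites are positions exceeding 0.48 in the designed
  but not the reference sequence.
* **Spike ratio.** 1 − (smaller / larger component center-of-mass
  distance from the cage center): 0 for equidistant components, 0.5 when
  one sits twice as far out.
* **C-beta separation.** Percent of interface residues whose *minimum*
  cross-interface C-beta distance (C-alpha for glycine) exceeds 8 Å; the
  minimum-distance reading is a declared choice.

# Selection

Metric columns are min–max normalized over the rows considered
(lower-is-better columns flipped; constant columns, including any
single-row table, normalize to 0.5 — z-scores would be the alternative,
but min–max keeps weighted sums in [0, 1]). Scores are weighted sums;
both published weight schemes ship as validated built-ins (pose scheme
0.3/0.4/0.1/0.2; design scheme 0.25/0.15/0.2/0.15/0.1/0.15). Filter
cascades are conjunctive with a per-filter attrition log; externally
computed quantities (shape complementarity, energies, inference scores)
enter as supplied columns and are never computed here.

# The synthetic test bed

`make_helical_trimer()` builds ideal-geometry three-helix C3 trimers
(NeRF construction, φ = −57°, ψ = −47°, bonds N–CA 1.458, CA–C 1.525,
C–N 1.329 Å; CB at ideal tetrahedral geometry; glycine/proline excluded
so every residue carries a CB). Backbones are seed-independent; sequences
derive from the seed. `make_docking_scenario()` places two such trimers
at random axial rotations, pushes them out along their body diagonals to
a 4 Å clearance, and registers the fragment-pair geometry realized at
that pose as clusters of a toy database (members carry σ = 0.45 Å
Gaussian noise on the paired fragment, giving cluster RMSDs near 0.7 Å, a
realistic tightness for orientation-resolved clusters); the planted
transform is therefore the global optimum by construction, and the
scenario ships a machine-readable truth record. The emitted search window
spans the full 120° rotation period and ±1.5 Å around the contact
distance its own construction targeted.

What a green docking test establishes: grid search + hash clustering +
grid optimization recover a planted global optimum in a smooth,
noise-free landscape with one basin per planted cluster. What it does
not: robustness to flexible backbones, surface water, false-positive
motifs, or the scale of a real fragment database mined from the PDB —
none of which the synthetic world contains. Docking tests use a 4°/0.5 Å
coarse grid rather than the 3°/1 Å production default because the 1 Å
match tolerance of the planted clusters requires sub-Ångström
translation sampling; this is a grid-scale choice, not a threshold
change.

# Numerical choices

* Natural logarithms everywhere (losses in nats); thresholds quoted for
  profile losses are interpreted on that scale.
* ε = 1e-9 additive smoothing inside logarithms, so one-hot rows give
  finite losses; Gibbs' inequality then holds up to ε slack.
* RMSD_cluster floored at 0.01 Å in the match score so singleton
  clusters cannot divide by zero.
* Eq-style side-chain contacts use a 4.5 Å heavy-atom criterion, each
  atom counted at most once per member (the source prints no distance).
* Euler convention for the 6-D hash: intrinsic z-y-z, angles
  canonicalized to [0, 360), gimbal lock resolved deterministically with
  γ = 0. Any fixed convention suffices since only binning equality
  matters; the source does not state its convention.
* Surface-exposure gate: side-chain SASA relative to the summed
  free-sphere areas of the same atoms, > 10 %. This self-contained
  reference stays meaningful for the CB-only side chains of the
  synthetic structures; Gly–X–Gly reference states would be the
  full-atom alternative.
* Kabsch superposition rejects < 3 points and collinear inputs;
  reflections are excluded via the determinant correction.

# Known limitations

* No flexible-backbone or sequence-design stages: physics-based
  refinement, neural-network inference and MSA construction are consumed
  as inputs, never run.
* The PDB writer emits single-character chain ids only (the full cage's
  24 chains fit; larger assemblies would not).
* Pure-R geometry: fine for the fixture scale (≤ a few thousand atoms);
  a production fragment database over full PDB surfaces would need
  compiled neighbour search.
* lDDT is computed globally over all within-radius pairs rather than
  per-residue-then-averaged; the two agree at the extremes that the
  tests pin (identity, rigid motion, random structures).
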