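# cageforge

Fragment-based design tools for two-component tetrahedral protein cages.

`cageforge` is for structural-bioinformatics work on symmetric protein
assemblies: it implements the fragment-observation route to docking two
C3 trimers into the tetrahedral **T:{C3}{C3}** architecture (four copies
of each trimer, stoichiometry A12B12, 3-fold axes on cube body
diagonals), plus the profile and interface-metric machinery used to
triage and rank the resulting poses. Everything is testable end-to-end on
deterministic synthetic structures generated by the package itself.

## What it computes

Candidate interfaces are detected as **fragment observations**: a
5-residue surface fragment of one component that lands (within 1 Å
backbone RMSD, no superposition) on a **ghost fragment** — a hypothetical
partner placement implied by the other component's surface and a database
of structurally clustered fragment pairs. Each observation is scored

    m = 1 / (1 + (RMSD_frag / RMSD_cluster)^2)

and each cluster position carries an interaction weight `t_r`, the mean
fraction of side-chain atoms contacting the opposite fragment. Per
residue, observations combine into the **fragment profile**

    P_aa = sum_F f_aa^F * (m_F t_F) / sum_F m_F t_F,

which blends with an hhm-derived evolutionary profile into the tertiary
profile (maximum fragment weight alpha = 0.5). Poses accumulate a
**Nanohedra score** over central fragment residues whose normalized form
is bounded by 2; docking proceeds by grid enumeration of the four
symmetry degrees of freedom, 6-D transform-hash clustering, and local
grid optimization with a 5 % relative-improvement stop. The metric suite
covers Shrake-Rupley SASA and buried surface area, Levy core/rim/support
classes and the composition similarity

    1/3 * sum_R (1 - |R_expected - R_measured| / R_expected),

secondary-structure fractions, geometric hydrogen bonds and
buried-unsatisfied density, hydrophobic-collapse sites (set FMILYVW,
threshold 0.48), the spike ratio, and C-beta separation statistics.
Weighted min-max selection schemes and filter cascades reproduce both
published ranking schemes. See `vignettes/cageforge-methods.Rmd` for the
full model description and design notes.

## Worked example

Dock a planted synthetic scenario and recover its ground-truth transform:

```r
library(cageforge)

scen <- make_docking_scenario(seed = 7)
scen$planted$dof
#>     rot_a   trans_a     rot_b   trans_b
#> 118.66912  21.50000  47.72945  21.50000

poses <- dock(scen$oligA, scen$oligB, scen$db, scen$entry,
              dock_params(rot_step = 4, trans_step = 0.5,
                          trans_range = scen$search$trans_range))
poses[[1]]
#> cage_pose: rot (118.50, 48.50) deg, trans (21.50, 21.50) A, 4 obs, score 0.993

round(poses[[1]]$dof - scen$planted$dof, 3)
#>   rot_a trans_a   rot_b trans_b
#>  -0.169   0.000   0.771   0.000
```

The four degrees of freedom are the rotation about and translation along
each trimer's own 3-fold axis; the top pose lands within a fraction of a
degree / a quarter Ångström of the planted transform, recovering all
four planted fragment pairs with match scores near 1 (normalized
Nanohedra score 0.993 of the theoretical maximum 2 — one observation per
residue, each nearly perfect). `pose_metrics(poses[[1]])` then returns
the flat metric record (BSA and its hydrophobic fraction, residue-class
counts, composition similarity, spike ratio — 0 here because both
trimers sit at the same axial distance, and so on), and
`run_pipeline(run_config(out = "run", seed = 7))` chains
dock → profile → metrics → selection with a manifest of per-stage counts.

A command-line front end is installed with the package
(`inst/cli/cageforge`): `cageforge dock A.pdb B.pdb --db db/ --out run/`,
plus `convert`, `expand --symmetry {C3,T}`, `db build/inspect`,
`fragments`, `metrics`, `select`, `fixtures`, and `pipeline`.

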