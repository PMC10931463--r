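---
title: "Models and methods behind lassofold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lassofold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lassofold)
```

lassofold simulates the folding of a coarse-grained protein, optionally in
the presence of a generic small-molecule ligand and a simplified ribosome,
and analyses the resulting trajectories for *non-covalent lasso
entanglements*: topologies in which a backbone loop closed by a native
contact is threaded by another segment of the same chain.  This vignette
explains the models, the conventions, the tunable parameters, and the
choices made where the design was genuinely open.

## The coarse-grained protein model

Each residue is one bead at its Calpha position.  Bead masses are the
standard average residue masses; bead radii come from the Zamyatnin (1972)
residue volumes as equal-volume sphere radii (`aa_bead_params()`); charges
are +1 for Lys/Arg and -1 for Asp/Glu.  The potential is a structure-based
(Go) model biased toward a native reference structure:

* **Virtual bonds**: harmonic, `K_b (b - b0)^2` with `K_b = 50`
  kcal/mol/A^2 and `b0` the native Calpha-Calpha distance.
* **Angles**: harmonic about native values, `K_angle = 30` kcal/mol/rad^2.
* **Dihedrals**: the standard double well
  `K1 [1 - cos(phi - phi0)] + K3 [1 - cos 3(phi - phi0)]` about native
  values with `K1 = 1.0`, `K3 = 0.5` kcal/mol.
* **Native contacts** (pairs with sequence separation `j > i + 3` and
  native distance <= 8 A): the 12-10-6 well
  `eps [13 s^12 - 18 s^10 + 4 s^6]`, `s = R/r`, with `R` the native
  distance and depth `eps_contact = 1.0` kcal/mol by default.  This form
  has its minimum of exactly `-eps` at the native distance and a small
  desolvation-like barrier of `0.1427 eps` near `1.4485 R`.
* **Non-native pairs**: the same 12-10-6 form with the very weak per-bead
  depth `eps_i = 0.000132` kcal/mol (geometric-mean combination) and
  `R_ij = R_i + R_j`.  At this depth the term is effectively a soft
  excluded volume that only repels below ~3.5 A.

A 20 A cutoff with a C1 cubic switching ramp over the last 2 A applies to
all 12-10-6 terms.  Electrostatics are off by default (the ligand carries
no charge; protein charges are carried on the beads for users who want to
add a screened term downstream).

Only the bead geometry and these functional forms are asserted by the test
suite; the parameter values above are the package's documented defaults
(`ff_params()`), chosen to be typical of Calpha Go models, and every
headline check is property-based (energy conservation, equipartition,
two-state folding, monotonicity), not tied to a specific parameterization.

### A note on the combination rule

The weak-pair combination is written in the sources this model follows as
a literal product `eps_ij = eps_i * eps_j`, which for `eps_i ~ 1e-4` gives
a physically negligible `~1.7e-8` kcal/mol and is dimensionally odd.  The
package defaults to the geometric mean `sqrt(eps_i eps_j)` (which
reproduces `eps_i` for identical beads) and exposes the literal product
behind `ff_params(combine_eps = "product")`.

## The generic nine-site ligand

The generic ligand is an octahedral arrangement of 9 beads parameterized
by the median principal-axis dimensions of a population of small-molecule
drugs: 11.46 x 6.11 x 3.35 A by default, total mass 388.46 Da shared
equally across sites.  The long axis carries four sites which, with the
central site, evenly divide `[-a/2, a/2]`; the other axes carry two sites
at their half-extents.  Bonds (harmonic, `K_b = 50` kcal/mol/A^2 at the
ideal-geometry lengths) form a star from the centre to all peripheral
sites plus the two outer long-axis links, which keeps the body near-rigid
without angle terms; non-bonded site pairs interact through the weak
12-10-6 term (`eps_i = 0.000132` kcal/mol, `R_i = 3.415358` A — treated as
a *radius*, consistent with `R_ij = R_i + R_j`; the package's own residue
radius table has median ~3.41 A, which supports that reading).  Sites
carry no charge.

`principal_dimensions()` measures molecule extents by eigen-decomposing
the unit-weight coordinate covariance tensor and taking max-minus-min
projections per axis; mass weighting is available but off by default
because the survey it emulates is geometric.

## Protein-ligand and ribosome-ligand interactions

Binding-site pairs — a set of (residue, site) pairs with per-pair `R_ij`
chosen to reproduce a predefined pose (`design_binding_site()` derives
them from pose distances) — use the 12-6 well `eps [s^12 - 2 s^6]` with no
cutoff, so a dissociated ligand still feels the site.  All other
protein-ligand pairs use the weak 12-10-6 term.  The well depth `eps_bind`
of the binding pairs is the quantity scanned by `run_affinity_scan()`.

The ribosome is a deliberately simple static wall: the solid half-space
`x >= x_wall` (default 160 A) minus a cylindrical exit tunnel of radius
`r_tunnel` (default 7.5 A) about the x axis.  Protein beads feel a
harmonic penalty on penetration of the wall surface by their bead radius;
ligand sites interact with the same surface through the weak 12-10-6 form.
Both act on the *continuous signed distance* to the solid region —
a branch-discontinuous wall (plane term plus separate radial term) injects
energy whenever a bead crosses the plane at intermediate radius and was
rejected for exactly that reason.

A flat-bottom spherical restraint keeps the ligand near the action:
`K_sp (d - d0)^2` outside radius `d0`, zero inside, with `K_sp = 0.1`
kcal/mol/A^2.  Co-translationally `d` is each ligand site's distance to
the fixed centre `(160, 0, 0)` with `d0 = 100` A; post-translationally it
is the ligand-COM to protein-COM distance with `d0 = 200` A.

## Langevin dynamics

Propagation uses the BAOAB splitting with a 15 fs step and collision
frequency 0.05 ps^-1 at 310 K by default.  Units are kcal/mol, Angstrom,
Da and ps (1 kcal/mol = 418.4 Da A^2/ps^2, kB = 0.0019872041 kcal/mol/K).
With zero friction the scheme reduces to velocity Verlet; a 10-bead
harmonic chain drifts by less than 0.01 kcal/mol over 1e5 steps.

Two kinetic-energy estimators are reported per saved frame: the full-step
KE (`ekin`, the natural quantity for energy-conservation checks) and the
thermostat-midpoint KE (`ekin_mid`, the average of the kinetic energy just
before and just after the O substep).  The full-step estimator carries the
well-known `O((omega dt)^2)` bias (~2% for the stiffest bond at 15 fs);
the midpoint estimator samples the Maxwell-Boltzmann distribution to ~0.1%
and is what equipartition checks should use.

Trajectories are bit-reproducible for a given `(seed, config, initial
state)` on one platform; Gaussian noise comes from R's RNG so a single
`set.seed()` governs everything.  Integration aborts, naming the step, if
the potential energy becomes non-finite or exceeds 1e12 kcal/mol (the
latter guard catches exploding-but-finite trajectories).

### Nascent-chain elongation

`elongate_nascent_chain()` grows the chain against the ribosome wall, one
residue per dwell-time entry: the current C-terminal bead is harmonically
tethered at the tunnel-exit anchor during each dwell; at each insertion
the whole chain is translocated rigidly one virtual-bond length down the
tunnel axis (a rigid shift changes no internal energy) and the new bead
appears at the vacated C-terminal position.  A short displacement-capped
steepest-descent minimization (`minimize_energy()`) then relaxes the new
angle/dihedral terms before dynamics resume.  Insertion schemes that
re-tether an existing bead at a displaced anchor dump >100 kcal/mol per
residue and were rejected as numerically unstable.  The per-codon dwell
schedule is user-supplied.

## Entanglement analysis

* `compute_Q()` — the fraction of native contacts between residue sets I
  and J formed in a frame; a contact is formed when its distance does not
  exceed 1.2x its native distance (both the 8 A map cutoff and the 1.2x
  factor are inclusive).
* `discrete_gauss_linking()` — the midpoint/segment-vector discretization
  of the Gauss double integral over all segment pairs of two curves.  For
  closed polygons it converges to the integer topological linking number
  (|g| of an ideal Hopf link at 200 segments per circle is 1.000 +/- 0.001).
* `contact_linking()` — for a contact `(i, j)`, the loop is the backbone
  polyline `i..j` closed by a straight virtual segment; partial linking
  numbers `g_N`, `g_C` are computed against the N-/C-tails with 5 residues
  excluded next to each anchor (configurable), and the total `g` is the
  partial of maximal magnitude, sign preserved.  Comparisons use
  nearest-integer rounded values; raw values are also reported.  The
  "crossing residue" is reported only as the tail bead whose segment
  midpoint is nearest the loop centroid — an explicitly approximate
  heuristic.
* `compute_entanglement_fractions()` — with N the total number of native
  contacts, `G_gain` (`G_loss`) is the fraction of native contacts that
  are *formed* in the frame with rounded `|g|` above (below) the rounded
  native value, and `G` the fraction formed with any change of rounded
  `g`, which also counts chirality flips.  An unfolded frame therefore has
  all three equal to zero: the definitions are conjunctions with contact
  formation.
* `native_entanglement_formed()` — trailing-window averages (100 saved
  frames by default) against the thresholds `G < 0.02` (full-length mode)
  or `G_gain < 0.002` (nascent mode).
* `binding_detected()` — shortest ligand-site to protein-bead distance no
  greater than 8 A (inclusive).

## Pathways, scans and statistics

Frames are assigned to metastable states by nearest centroid in
normalized (G, Q) order-parameter space (`assign_states()`, ties to the
lowest index); centroids are user-supplied or built by a simple surrogate
(`build_state_model()`: local minima of `-ln P` on a 2D histogram).  The
state decomposition is therefore artifact-defined.  `extract_pathway()`
collapses consecutive repeats and then erases loops left to right — a
revisit truncates the route back to the first visit — so a route never
repeats a state.

`classify_threading_path()` distinguishes the two formation mechanisms of
a lasso: the entanglement exists at the first frame `t*` where the loop
contact is formed *and* the thread's rounded linking is nonzero; the
loop-closure and thread-positioning events are the first frames from which
each condition holds uninterrupted through `t*`; wrap (`Path1`) when the
thread was in place no later than the loop closed, pierce (`Path2`)
otherwise, with ties favouring wrap.

`run_affinity_scan()` sweeps the binding well depth over
`{0, 0.5, 1.0, 1.5, 2.0}` kcal/mol with 10 independent runs per point and
scores each run by (a) `P_Native`: formation of the native entanglement at
the end of the run, and (b) `P_Binding`: ligand binding at the end.
Binding can be scored on the literal final frame (`binding_score =
"final"`) or as the majority status over the trailing 20 saved frames
(`"window"`); the window rule parallels the trailing-window average used
for the entanglement criterion and removes the pure coin-flip noise of
sampling a reversibly bound ligand at a single instant.  `select_epsilon()`
implements the two published selection rules: the smallest depth with
`P_Native >= 0.5` and `0.5 < P_Binding < 1.0`, or the smallest with
`P_Native = 1`.

All interval estimates (pathway probabilities, binding traces, scan
probabilities) are seeded percentile bootstraps resampling whole
trajectories (10,000 resamples for pathway probabilities, 500-1,000
elsewhere).

## Synthetic fixtures and what they do (and do not) show

All test inputs are generated in code, deterministically given a seed:

* `make_hopf_link()` — two orthogonal circles, true linking +/-1 (or 0
  when separated); the oracle for the linking estimator.
* `make_lasso_chain()` — a planar contact-closed loop with a tail that
  either pierces perpendicularly through the centroid (rounded |g| = 1 by
  construction) or runs away in-plane (|g| = 0).
* `make_miniprotein()` — a 16-bead beta-hairpin (two strands 5 A apart
  with a slight out-of-plane zigzag to avoid collinear degeneracies) and a
  two-helix bundle.  The hairpin's melting temperature under the default
  force field is ~520 K (characterized by a Q(T) scan); two-state tests
  run at 260 K (mean Q > 0.99) and 1040 K (mean Q ~ 0.05, with a 7.5 fs
  step because hot unfolded chains cross the weak excluded-volume cores
  too quickly for 15 fs).
* `toy_binding_system()` — the frozen desk-scale binding system: the
  hairpin with the generic ligand docked flat against strand 1 (site
  residues 2, 4, 6; pose-derived pair distances within 8 A), a 25 A
  COM-COM restraint, random initial placement with 5 A clearance, and
  600 ps runs.  Its design spans the capture transition across the
  standard depth grid: `P_Binding` goes from ~0 at depth 0 to 1 at 1.5-2
  kcal/mol with Spearman rho >= 0.95 across independent seed sets.
* `make_drug_table()` — ellipsoidal point clouds with known generating
  extents (axis extremes included, so the extents are exact) for the
  dimension-recovery checks.
* `make_discrete_traj()` — random state sequences with a reference
  loop-erased route computed by an independent cut-first-cycle algorithm.

These fixtures validate the machinery — estimators, integrators,
bookkeeping, statistics — at desk scale.  They do not emulate the size,
contact order, or entanglement complexity of real multi-domain proteins,
the atomistic ribosome surface, codon-specific translation kinetics, or
the ~2 microsecond, thousand-trajectory ensembles needed for quantitative
folding yields of real systems; passing tests therefore demonstrate
correctness of the method, not biological predictions for any particular
protein.

## Numerical choices and degenerate inputs

* Tolerances: contact cutoffs and the 1.2x formation factor are inclusive;
  the equality in the `P_Native = 1` selection rule is tested to 1e-12.
* Degenerate dihedrals (collinear triples) contribute zero force and are
  skipped; angle forces guard `sin(theta)` away from zero.
* Coincident consecutive curve points are rejected by the linking
  estimator; tails shorter than two beads contribute zero partial linking.
* `place_ligand_randomly()` resamples until all ligand sites clear the
  protein by `min_dist` (default 2 A; the binding toy uses 5 A because a
  site that starts deep inside a steep 12-6 well at high `eps_bind`
  destabilizes a 15 fs step) and fails after 1,000 attempts.
* Problem sizes used by the shipped checks: 10-50-bead chains; 1e5 steps
  for conservation, 1e6 for equipartition, 2e6 (two beads) for the bond
  variance; 50 runs x 40,000 steps for the affinity scan; 1,000 random
  discrete trajectories for the loop-erasure oracle.

## Known limitations

* The protein force field is a documented generic Calpha Go model, not
  the exact parameter set of any published cotranslational pipeline;
  quantitative folding temperatures and rates are fixture-specific.
* The ribosome is a geometric occluder with an idealized straight tunnel.
* The surrogate state model is a histogram heuristic; its labels will not
  match any published metastable-state numbering.
* Crossing-residue identification is a labelled approximation (segment
  midpoint nearest the loop centroid), not a minimal-surface piercing
  computation.
* DCD output carries no time axis beyond a constant interval; XYZ is the
  authoritative text format and the only one supporting growing chains.
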