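---
title: "Methods: designing amyloid-fibril capping miniproteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: designing amyloid-fibril capping miniproteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, parameters and numerical choices behind
`fibrilcap`. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The design problem

An amyloid fibril is a stack of β-strand-rich monomer layers related by a
screw operator: layer *k+1* is layer *k* rotated by a twist (degrees) about
the fibril axis and translated by a rise (Å) along it. In the cross-β
regime the rise is ~4.7–4.8 Å — the spacing of a backbone hydrogen bond
between stacked strands. At a fibril tip the top layer's backbone amides
and carbonyls have no partner layer, so a row of hydrogen-bond donors and
acceptors dangles. Growth proceeds by templating the next monomer onto the
tip; a capping design competes for exactly that position. Its β-strand
mimics the native stacking (satisfying the dangling hydrogen bonds), and
its folded body sterically blocks the subsequent layer.

The pipeline therefore needs: (i) the fibril's screw operator and the
coordinates of the *virtual next layer*; (ii) candidate binding sites on
the tip; (iii) a library of small stable scaffolds presenting a graftable
β-strand; (iv) a placement rule (motif grafting); and (v) a scoring funnel
that rewards hydrogen-bond satisfaction, interface contact, and favorable
interface composition.

## Fibril geometry

**Screw fitting.** `fit_screw_symmetry()` superposes the backbone
(N, CA, C, O only — side chains are excluded so rotamer noise cannot bias
the fit) of one layer onto the next by the Kabsch algorithm (SVD, proper
rotation enforced), then decomposes the rigid transform into axis, twist
and rise. Three numerical regimes are distinguished:

- *Near-noiseless data* (superposition rmsd < 1e-4 Å): the exact
  decomposition — axis from the antisymmetric part of the rotation (or its
  eigenvector at angles near 180°), rise as the axial component of the
  translation, axis point as the minimum-norm solution of
  (I − R)p = t_perp.
- *Noisy data at small twist* (rmsd above 1e-4, twist < 5°, |t| > 0.5 Å):
  the axis of a ~1° rotation is ill-determined — its extraction amplifies
  coordinate noise into large rise errors — while the translation direction
  deviates from the true axis only by ~twist·r/rise (r = lateral offset of
  the layer centroid from the axis; < 0.001 rad for a typical fibril).
  Here the translation direction is used as the axis, and the twist is the
  rotation angle about that axis, atan2((a·u)/2, (tr R − 1)/2) with a the
  antisymmetric 3-vector of R.
- *Near-zero twist* (< 0.1°): translation direction again, with twist sign
  taken from the projection of the antisymmetric part.

The axis is always oriented so the rise is non-negative (the operator maps
a layer "up" to its neighbor); which physical end is called "plus" is then
a frame convention (largest axial projection), and because fibril polarity
is generally unknown, every site-facing function takes an explicit
`end = "plus"/"minus"` argument and the pipeline targets both by default.

**Consensus operator.** A fibril offers one operator measurement per
consecutive layer pair. `consensus_symmetry()` averages rise and twist over
all pairs of a protofilament. The information floor of a single pair is
σ·sqrt(2/N) on the rise (N backbone atoms per layer); for the default
synthetic fibril (25 residues/layer, 100 atoms) at σ = 0.1 Å that is
~0.015 Å, so pooling the five pairs of a six-layer stack is what makes
recovery to ±0.05 Å robust rather than marginal.

**Protofilament grouping.** Chains are grouped by sequence identity, the
axis is taken from the screw fit of the closest stacking-compatible pair
(|twist| ≤ 30°, rmsd ≤ 2 Å, rise > 0.5 Å — a C2 partner fails the twist
test), and protofilaments are separated by single-linkage clustering of
the chains' lateral (off-axis) centroid positions with a 5 Å cut. Layers
are ordered by axial projection. Grouping is invariant to chain order in
the input file.

**Secondary structure.** Per-residue H/E/L labels come from φ/ψ basins
(H: φ ∈ (−100°, −30°), ψ ∈ (−80°, −5°); E: φ ∈ (−180°, −90°),
ψ ∈ (90°, 180°] ∪ [−180°, −170°)), smoothed so runs shorter than 4 (H) or
3 (E) become loop. Terminal residues with undefined dihedrals are loop.
This is deliberately simple and testable; hydrogen-bond-pattern (DSSP-
style) assignment is not attempted. One consequence: assigned strand runs
are eroded by up to one residue at junctions, so enumerated sites sit
strictly inside true strands.

## Scaffolds

**Topology classes.** One α-helix plus two or three β-strands, all
orderings: EEEH, EEH, EEHE, EHE, EHEE, HEE, HEEE. All-strand topologies
are excluded (they do not make consistently stable miniproteins without
the helix), as is cysteine anywhere in a design (the targets are largely
intracellular; disulfides would not survive the reducing cytosol).

**Blueprints.** An ordered list of (element kind, length) with totals
constrained to 35–50 residues. Defaults: helix 12, strands 7, loops 4/5/4.

**Backbone construction.** Helix and strand elements use ideal dihedrals
(−57°, −47°) and (−139°, +135°) with standard peptide bond geometry,
built by internal-to-Cartesian chaining (the inner loop is compiled C++).
Loop conformations are initialized from canonical two-residue β-turn
templates (types I, II, I′, II′) padded with extended/α/PPII flanks and
±15° jitter, then refined by a short simulated annealing in loop torsion
space (600 steps, geometric temperature schedule 1.5 → 0.02) that
minimizes a compactness + steric objective: quadratic penalty above a
radius-of-gyration target and quadratic overlap penalty below a 2.7 Å
non-bonded floor. A candidate is *accepted* only if its radius of gyration
is at most 3.0·N^0.34 Å and no non-bonded backbone heavy-atom pair is
closer than 2.0 Å; up to 25 independent annealing restarts are tried.
Blind resampling of loop torsions from Ramachandran bins was tried first
and could not reach the acceptance region at workable rates (compact
candidates were ~0.6% of draws and essentially all of them clashed); the
annealed builder accepts most restarts for every class. Everything is
deterministic given (blueprint, seed): each restart derives its own RNG
stream from the seed, and the seed is recorded in the scaffold.

**Initial sequence.** Burial = number of CA atoms within 10 Å (excluding
±2 sequence neighbors). Buried positions (count ≥ 12) draw from
{A,V,L,I,F,M,W}, exposed ones from {D,E,K,R,N,Q,S,T}; loop positions with
positive φ get glycine; cysteine is never assigned. This produces the
hydrophobic-core/polar-shell organization that stabilizes miniproteins
without disulfides.

## Docking

**Sites.** Candidate binding sites are residue windows (default 6, minimum
4) lying wholly inside β-strand runs of the tip layer: every sliding
window, or one site per strand. The published site counts for real
fibrils are structure-specific outcomes of this enumeration, not inputs.

**Grafting.** For a chosen scaffold strand element, every window-length
stretch is superposed (N, CA, C, O) onto the corresponding backbone of the
virtual next layer restricted to the site window; the whole scaffold moves
by the fitted transform. Both parallel and antiparallel placements are
tried (antiparallel = reversed residue order); the lower-rmsd,
clash-passing orientation wins; equal-rmsd stretches break ties by lowest
start index. The stored transform is the single source of placement:
re-applying it to the unposed scaffold reproduces the pose exactly.

**Clashes.** Hard clash: heavy-atom pair < 2.5 Å. Soft clash: pair ≥
2.5 Å but closer than 0.8 × the sum of van der Waals radii (C 1.7, N 1.55,
O 1.52, S 1.8 Å). Computed with a cell-list grid whose result is
contractually identical to the all-pairs scan (tested against a
brute-force oracle). Poses with any hard clash are rejected.

## Scoring funnel

**Hydrogen bonds.** Amide hydrogens are rebuilt geometrically (1.01 Å from
N, in the peptide plane, anti to the preceding C′ — the bisector
construction); input-file hydrogens are ignored everywhere, so the rebuild
is the single source of truth. A bond requires N···O ≤ 3.5 Å and an
N–H···O angle ≥ 120°; each donor keeps its closest acceptor (ties: lower
residue index); prolines and chain-initial residues cannot donate.

**Tip satisfaction.** The *inventory* of a site is the set of tip-window
donors/acceptors whose ideal-next-monomer partner also lies inside the
window. (Window-edge residues can bond one position past the window;
those bonds belong to the neighboring site and no window-length capper
could satisfy them — including them would make the perfect capper's
hb_unsat nonzero by construction.) Satisfaction is recounted with the
posed scaffold in place; `hb_satisfied + hb_unsat` equals the inventory
size for every pose of a given site.

**Interface atoms.** Scaffold heavy atoms within 5.0 Å (closed boundary)
of any fibril heavy atom.

**Binding-energy surrogate (ddg).** A residue-level contact potential:
for every inter-molecular residue pair whose Cβ–Cβ distance (virtual Cβ
from backbone geometry; CA for glycine) is ≤ 8 Å, add the packaged 20×20
table entry. The table (`contact_potential_v1.tsv`) is built from a
hydrophobicity product (Kyte–Doolittle scaled to [0, 1], prefactor −3) plus
a ±0.5 charge-pair term — the additive structure characteristic of
knowledge-based contact potentials. It is shipped as a versioned data file
precisely so it can be swapped; the package claims rank-ordering utility
for design triage, not physical energies. There is no surrogate for an
all-atom total score: scaffold quality is filtered by propensity, clash
and compactness instead, and the ranking report header says so.

**Residue propensity (p_aa_p).** Each residue's (φ, ψ) maps to one of five
coarse Ramachandran bins (αR, β, αL, PPII, other); the score is the mean
over scorable residues of log P(aa | bin) from the packaged table, which
encodes the uncontroversial preferences (glycine in αL, β-branched
residues in β strands, proline in PPII). The mean (rather than a
per-residue threshold) is a deliberate choice. Terminal residues are
skipped; a chain with no scorable residue returns NA with a warning.

**Centroid side chains.** For mutation rescoring and optimization safety,
side chains are single pseudo-atoms 2.4 Å from CA along the CA→Cβ
direction (glycine: none) with residue-specific radii (A 1.7 … R 3.2 Å,
packaged). Soft centroid clashes use the same 0.8 × radius-sum rule as
atoms; *hard* centroid clash means deep penetration, < 1.8 Å to a heavy
atom, not the 2.5 Å atom-pair cutoff — an in-register stacked side chain
points its centroid ~2.3 Å above the next layer's CA, which is a native
contact, not an overlap. Because the radius table is monotone in residue
size and centroid positions are fixed by the backbone, mutating any
position to a larger residue can only add soft clashes — which is what
makes steric negative controls (small→large substitutions at interface
positions) expressible without rotamers.

**Greedy interface optimization.** Mutable positions default to scaffold
residues with interface atoms. Sweeps run in fixed order (lowest index
first); at each position the 19 non-cysteine residues are tried and the
best strict ddg improvement without a hard centroid clash is accepted;
the loop stops when a full sweep changes nothing (cap: 10 sweeps). Because
the surrogate is a sum of independent per-position contributions over
inter-molecular pairs, each position's 20 contributions are precomputed
and a candidate evaluation is O(1); the result is bit-identical to full
recomputation (tested), and single-position optimization equals the
exhaustive 19-way minimum by construction. The reported trajectory is
monotone non-increasing.

**Ranking.** Hard filters first — no hard clashes, hb_unsat ≤ 2,
interface_atoms ≥ 40 (both configurable; no published numeric cutoffs
exist for them) — then sort by ddg ascending, ties by hb_satisfied
descending, then by design id: a deterministic total order invariant to
input order. A lexicographic filter-then-sort was chosen over a weighted
composite because no relative weighting of the metrics is published;
the scheme is labeled as a choice in the report.

## Kinetics

Thioflavin-T traces are fitted to the 4-parameter logistic
baseline + amplitude/(1 + exp(−rate·(t − t50))) by Levenberg–Marquardt
least squares with five starts (t50 at the 25/40/50/60/75% time quantiles,
graded rate guesses) and box constraints (amplitude ≥ 0, rate > 0); the
best SSE wins. **Lag time is defined as t50 − 2/rate** — the intercept of
the tangent at the midpoint with the baseline — because the term is used
in the field without a standard formula; a threshold-crossing alternative
can be configured but the default is fixed. A trace counts as aggregated
only if the fitted amplitude exceeds 3× the baseline noise, estimated as
the MAD of the fit residuals over the first quartile of points (raw-signal
MAD misfires when the transition starts early). `lag_ratio()` returns
treated/control lag, with `Inf` as the sentinel when either condition
never aggregates — complete inhibition is stronger than any finite ratio.
Replicates are fitted independently and summarized as mean ± SD.

Saturation binding uses the one-site model bmax·c/(K + c) with positivity
constraints; fewer than 5 concentrations is an error, and a range narrower
than one order of magnitude warns and flags a wide confidence interval.

## What the synthetic fixtures do and do not emulate

`make_ideal_fibril()` builds each layer from rigidly placed ideal strands
(default two strands of 12 and 10 residues, antiparallel, 9 Å apart,
joined by a 3-residue interpolated arc), oriented so carbonyls alternate
along the stacking axis, and stacks layers by an exact screw operator
(defaults rise 4.75 Å, twist −1.2° — inside the cross-β regime). The
strand lengths are chosen to be representative of amyloid-core β-arch
segments; real disease cores are this size or larger. Stacked layers form
genuine backbone hydrogen bonds (N···O ≈ 2.9 Å) because the strand pleat
is aligned with the axis. Two-protofilament fibrils add a C2 copy about
the axis. Sequences alternate A/V so sequence-dependent scores are
well-defined. Optional Gaussian coordinate noise perturbs only the emitted
model; the ground truth (operator, labels, held-out next layer) stays
exact, so recovery tests never compare against hard-coded numbers.

What is *not* emulated: real disease polymorph folds and sequences,
steric-zipper side-chain interdigitation (layers are backbone-only),
chemically continuous loop geometry (the arc residues are placed, not
built, so loop bond lengths at junctions are approximate — irrelevant to
strand grafting and scoring, which never touch loop interiors), non-screw
packings (e.g. 2₁ symmetry with flipped layers), and cryo-EM maps. Passing
tests therefore demonstrate correctness of the geometry, scoring and
recovery machinery under idealized conditions — not predictive accuracy on
real fibril structures.

The kinetic fixtures are clean logistic/hyperbolic curves with Gaussian
noise. Study-design defaults were chosen once for identifiability at the
fixed noise levels: the fourfold lag pair uses lags 16 h vs 4 h (t50 17/5
h, rate 2 /h, 6-minute sampling over 28 h, triplicates) — a slow pair with
a lag-2 h control whose transition starts almost immediately is
ill-conditioned for any fitter; the binding design is an 11-concentration
series (25–3200 nM) densified around the expected half-saturation, in
quadruplicate, where the Fisher standard error of the half-saturation at
σ = 0.03 is ~3.8%. Real plate-reader data add baseline drift, evaporation
and secondary-nucleation shape deviations that these fixtures do not
model.

## Problem sizes

The shipped tests and the acceptance script run on desk-scale instances:
six-layer fibrils of 25-residue layers, scaffold libraries of a few per
class (the `--n-scaffolds` option of the CLI scales this; production-scale
libraries are thousands per class), 20-seed noise recovery, 50-instance
oracle-equivalence suites, a 100-case optimization contract suite, and
50-seed kinetics recoveries.

## Known limitations

- The ddg surrogate is residue-level; it cannot capture rotamer-specific
  packing or electrostatics beyond a coarse charge-pair term.
- Antiparallel grafting reverses residue order but keeps atom names, so
  its rmsd is conservative (real antiparallel pairing swaps N/C roles);
  parallel placements — the native stacking mode — are unaffected.
- Backbone-only clash filtering plus the centroid model can miss
  side-chain-level clashes a rotamer model would catch, and vice versa
  can be conservative for long flexible side chains.
- The screw fit assumes a single operator per protofilament; polymorphs
  with alternating operators or flipped layers are out of scope.
- `group_layers()` assumes the structure is given in a frame where the
  fibril is near the origin (true of deposited structures); the
  noisy-data axis heuristic relies on the translation dominating the
  in-plane component.
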