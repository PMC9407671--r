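# fibrilcap

Structure-based design of miniprotein inhibitors that cap the growing ends
of amyloid fibrils.

Amyloid fibrils (tau, α-synuclein, amyloid-β, ...) are stacks of
β-strand-rich monomer layers related by a screw operator: each layer is the
previous one rotated by a twist angle about the fibril axis and translated
by an axial rise (~4.7–4.8 Å in the cross-β regime). A fibril grows by
templating the next monomer onto its open tip, where a row of backbone
hydrogen-bond donors and acceptors dangles unsatisfied. A *capping
inhibitor* is a small designed protein that occupies the position of the
next monomer: one of its β-strands stacks onto the tip exactly as the next
layer would — satisfying the dangling hydrogen bonds — while its folded
body blocks any further addition.

`fibrilcap` implements the computational pipeline for designing such
cappers, plus the kinetics statistics used to quantify inhibition:

- **Structure I/O** — PDB/mmCIF in and out, through a uniform
  chain→residue→atom model (`read_structure()`, `write_structure()`).
- **Fibril geometry** — protofilament grouping (`group_layers()`), screw
  symmetry inference (`fit_screw_symmetry()`, `consensus_symmetry()`), the
  virtual next layer a capper must occupy (`virtual_next_layer()`), and
  dihedral-based secondary structure (`assign_secondary_structure()`).
- **Scaffolds** — the seven miniprotein topology classes with one α-helix
  and two or three β-strands (HEE, EHE, EEH, HEEE, EHEE, EEHE, EEEH;
  `enumerate_topology_classes()`), 35–50-residue idealized backbones built
  from blueprints (`build_scaffold()`), and burial-based starting sequences
  (hydrophobic core, polar exterior, never cysteine — the designs must fold
  in the reducing cytosol).
- **Docking** — tip binding-site enumeration over β-strand windows
  (`enumerate_sites()`) and β-strand motif grafting by backbone
  superposition onto the virtual next layer (`graft_scaffold()`), with
  hard/soft steric-clash filtering (`clash_counts()`).
- **Funnel scoring** — hydrogen-bond satisfaction at the capped tip
  (`tip_hbond_satisfaction()`), interface atom counts, a residue
  contact-potential binding-energy surrogate (`ddg_surrogate()`), the
  dihedral residue propensity p_aa_p (`paap_score()`), greedy interface
  sequence optimization (`optimize_interface_sequence()`), point-mutation
  rescoring for steric negative controls (`mutate_and_rescore()`), and
  deterministic funnel ranking (`rank_designs()`).
- **Kinetics** — 4-parameter logistic fits of thioflavin-T aggregation
  traces with lag time t50 − 2/rate (`fit_tht_curve()`), lag-time ratios
  between conditions (`lag_ratio()`), and one-site saturation-binding fits
  (`fit_saturation_binding()`).
- **Synthetic fixtures** — idealized fibrils with exact known rise/twist,
  strand layout and held-out next layer (`make_ideal_fibril()`), perfect
  complementary cappers (`make_complementary_capper()`), and noisy
  kinetic/binding datasets with recorded ground truth — so the whole
  pipeline is testable with no downloads.

The whole design funnel is wired together by `design_cappers()`, and a thin
command-line interface (`inst/scripts/fibrilcap`) exposes `fixtures`,
`design`, `kinetics` and `binding` subcommands.

## Worked example

Generate an ideal two-strand fibril (rise 4.75 Å, twist −1.2°, six
layers), infer its geometry, and cap its plus end:

```r
library(fibrilcap)

fx <- make_ideal_fibril(fibril_spec(rise = 4.75, twist = -1.2, n_layers = 6))
assembly <- group_layers(fx$model)
assembly
#> fibril_assembly: 1 protofilament(s)
#>   pf 1: 6 layers [A,B,C,D,E,F], rise 4.750 A, twist -1.200 deg
consensus_symmetry(assembly)
#> screw_symmetry: rise 4.750 A, twist -1.200 deg (fit rmsd 3.46e-15)
```

The inferred operator reproduces the generator's rise and twist to machine
precision. Enumerate 6-residue binding sites on the plus-end strands and
graft a complementary capper onto the first one:

```r
sites <- enumerate_sites(assembly, protofilament = 1, end = "plus", window = 6)
nrow(sites)
#> [1] 9
capper <- make_complementary_capper(sites[1, ], assembly, body_class = "EEH",
                                    seed = 5)
pose <- graft_scaffold(capper, strand_choice = 1, site = sites[1, ],
                       assembly = assembly)
pose
#> docked_pose: capper_EEH_site1 -> site 1 (plus end, pf 1), parallel,
#>   graft rmsd 1.6e-15 A, clashes 0 hard / 0 soft
score_pose(pose, assembly)[, c("hb_satisfied", "hb_unsat", "interface_atoms", "ddg")]
#>   hb_satisfied hb_unsat interface_atoms      ddg
#> 1            5        0              40 -15.5601
```

The capper's strand occupies the virtual next layer exactly (graft rmsd
~1e-15 Å), re-forms all five dangling backbone hydrogen bonds of the site
window (`hb_unsat = 0`), and buries 40 heavy atoms in the interface. The
`ddg` column is the contact-potential surrogate (dimensionless; lower =
better); `optimize_interface_sequence()` improves it further by greedy
single-position sweeps.

Fit synthetic aggregation and binding data (truth: t50 = 20 h, rate =
0.5/h so lag = 16 h; half-saturation 150 nM):

```r
tht <- make_tht_dataset(params = list(baseline = 0.1, amplitude = 1,
                                      t50 = 20, rate = 0.5),
                        noise_sd = 0.02, n_replicates = 3, seed = 1)
fit_tht_replicates(tht$traces)$summary[, c("n", "t50_mean", "lag_mean", "lag_sd")]
#>   n t50_mean lag_mean     lag_sd
#> 1 3 20.06758 16.11129 0.09333385

bnd <- make_binding_dataset(seed = 1)
fit_saturation_binding(bnd$data$conc, bnd$data$signal)
#> binding_fit: bmax 1.03, half-saturation 160.4 nM
```

## Command line

```sh
inst/scripts/fibrilcap fixtures --out fx --seed 3
inst/scripts/fibrilcap design --structure fx/fibril.pdb --out designs --end plus
inst/scripts/fibrilcap kinetics --traces fx/tht_traces.csv --out kinetics.json
inst/scripts/fibrilcap binding --curve fx/binding_curve.csv --out binding.json
```

`design` writes a ranked TSV of designs (funnel filters: no hard clashes,
few unsatisfied tip hydrogen bonds, enough interface atoms; then sorted by
the binding-energy surrogate) plus a JSON score report.

## Scope

The package deliberately replaces the heavy machinery of the original
design practice with transparent, testable counterparts: idealized-dihedral
backbone construction instead of fragment assembly, a residue-level contact
potential instead of all-atom binding energies, and a centroid side-chain
model instead of rotamers. It claims rank-ordering utility for design
triage, not physical energies. Molecular-dynamics stability filtering,
ab initio structure prediction and sequence-novelty checks are out of
scope, as are all wet-lab assays.
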