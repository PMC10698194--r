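---
title: "Designing thioether-macrocyclized peptide-small molecule conjugates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing thioether-macrocyclized peptide-small molecule conjugates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lariatforge)
```

## The design problem

Small-molecule opioid ligands reach deep into the orthosteric pocket of their
receptor but make few selectivity-determining contacts; peptides make rich
contacts with the extracellular vestibule (the ECL2/ECL3 loops and the tops
of TM6/TM7) but rarely reach the orthosteric site. `lariatforge` implements a
desk-scale version of a conjugate-design strategy that joins the two: a rigid
small-molecule *anchor* with a free amine sits in the orthosteric pocket, and
a lariat-shaped peptide — a 5–6 residue macrocycle closed by a thioether
between a Cys side-chain sulfur and the bromoacetylated N-terminus, with the
C-terminus left free — is conjugated to the amine so that the ring engages
the extracellular loops.

The pipeline runs six stages: (1) measure the pocket, (2) enumerate and rank
dipeptide extensions off the anchor amine, (3) sample a library of closed
macrocycle backbones and cluster it, (4) graft cluster representatives onto
the extension by rigid-body superposition, (5) design ring sequences under a
simplified score function, and (6) filter on interface metrics, loop
contacts, and diversity. Each stage is an exported function; `run_pipeline()`
chains them and returns a `filter_report` whose survivor sets are nested by
construction.

## Macrocycle sampling and ring closure

Backbones are built from internal coordinates at ideal geometry (N–CA 1.458,
CA–C 1.525, C–N 1.329, C=O 1.231 Å; standard amide angles) by the NeRF
construction (`place_atom()`). Per-residue (φ, ψ) are drawn from a declared
Ramachandran prior: a three-component Gaussian mixture centred at the
α-helical (−63°, −41°), β (−120°, 130°) and left-handed (60°, 40°) basins
with weights 0.45/0.45/0.10 and σ = 20°, sign-mirrored for D residues; ω is
trans (180° ± 5°) with a 5% cis fraction. Each residue is D with probability
0.5 by default — the design campaign mixes chirality freely, and the prior
is mirror-symmetric, so this is the least-informative choice.

The thioether bridge is modeled explicitly: a bromoacetyl-derived unit
(carbonyl C "CL", its O "OL", methylene "CM") acylates the N-terminus, and
ring closure means the last residue's Sγ meets CM. Closure targets are the
Sγ–CH2 bond (1.81 ± 0.2 Å) and the C–S–C angle at sulfur (100° ± 15°); the
CH2–C(=O) (1.52 Å) and C(=O)–N (1.33 Å) bonds are ideal by construction.
`close_ring()` runs cyclic coordinate descent over the φ/ψ torsions of the
last three residues plus the Cys χ1: per torsion, a 5° grid line search with
a 0.25° local refinement, iterated up to 200 sweeps. Two numerical details
matter in practice:

* the line search is evaluated in closed form (Rodrigues rotation of only
  the two objective atoms), so a sweep costs microseconds, and
* a sweep that fails to improve the closure objective by more than 1e-8
  terminates the search early — an infeasible chain (e.g. a fully extended
  ring with its ends tens of Å apart) fails in a few sweeps rather than
  burning the full budget.

Failure is a value: the returned backbone carries `closure$success = FALSE`
with its residuals. `sample_backbones()` only emits backbones whose closure
residuals *re-measured from coordinates* pass tolerance, and is byte-stable
under its seed (the RNG state is saved and restored around every seeded
operation in the package).

## Torsion bins, H-bond fingerprints, clustering

The clustering key has two parts. The torsion-bin string assigns one letter
per ring residue from a five-letter alphabet partitioning the (φ, ψ, ω)
torus: `O` whenever |ω| < 90° (cis-like), otherwise `A` (φ < 0, ψ ∈ [−75,
50)), `B` (φ < 0, ψ outside), `G` (φ ≥ 0, ψ ∈ [−100, 100)), `E` (φ ≥ 0, ψ
outside); φ = 180° is treated as −180°. These boundaries are this package's
declaration of the standard torsion-bin alphabet — they are a design choice,
not a reconstruction of any external tool's table.

The H-bond fingerprint is the set of ordered backbone (donor residue,
acceptor residue) pairs whose N–H···O geometry passes the shared
`hbond_criterion()` (below). Amide hydrogens are built onto every backbone N
precisely so that the donor–H–acceptor convention applies. Clustering is
exact grouping on (bin string, fingerprint); the representative is the
*medoid* under superposed ring-backbone RMSD, chosen because the
representative must be score-independent at this stage. With random torsion
sampling most keys are unique — the funnel's breadth comes from the library,
its depth from the later stages.

## Anchor extension and grafting

Position 1 of the extension is a fixed D-Phe (standing in for the aromatic
group removed from the parent ligand); position 2 sweeps all 20 amino acids
minus glycine and cysteine in both L and D forms — 36 identities. Extension
backbone torsions are sampled on a 30° grid (10–15 samples per identity by
default), scored as extension-internal energy plus extension–receptor
interaction, and the best sample per identity is refined by coordinate
descent (±5/10/15° per torsion). Ranking is ascending by score with
lexicographic tie-breaks, keeping 4 by default.

Grafting superposes the C, N, O, CA, CB atoms of the macrocycle's C-terminal
Cys onto a temporary ideal-geometry pseudo-Cys frame built at the tail's
N-terminus (`extension_graft_frame()`), using Kabsch superposition with
reflections excluded. Models with alignment RMSD above 0.75 Å are rejected
(chirality-mismatched frames reject themselves: the mirrored CB alone costs
≈1.1 Å). After superposition a rigid *translation* snaps the terminal
carbonyl C exactly onto the frame C, so the amide-link invariant (C–N 1.33 ±
0.2 Å) holds for every accepted model by construction; the recorded RMSD is
the pre-snap Kabsch value. The clash screen counts non-bonded heavy-atom
pairs with distance below `r_i + r_j − 0.4 Å` (pairs within two covalent
bonds of the link excluded) and passes at ≤ 5 clashes; both thresholds are
this package's defaults for "minimal clashes".

## The score function and sequence design

The score function is deliberately small and fully declared — it replaces a
production design energy and makes no claim of reproducing one:

$$E = \sum_{pairs} \left[ w_{atr}\,LJ_{atr}(r) + w_{rep}\,LJ_{rep}(r) +
w_{elec}\,\frac{q_i q_j}{4 r \cdot r} \right] - w_{hb}\,N_{hbond}$$

with `LJ(r) = ε[(r₀/r)¹² − 2(r₀/r)⁶]`, ε = 0.2, `r₀ = r_i + r_j` (vdW
radii), split at r₀ into attractive and repulsive branches; a
distance-dependent dielectric ε(r) = 4r; a 10 Å pair cutoff; and −1 per
hydrogen bond under the shared criterion. Default weights are (1.0, 0.55,
1.0, 0.7). Charges come from a minimal per-atom-type table (amide N +0.35,
carbonyl C +0.45, O −0.50, side-chain values per identity). Pairs within one
residue, or within two covalent bonds across residues, are excluded.
Covalent bonds are inferred by covalent radii *and* a chemical-pattern
filter (amide C–N, bromoacetyl CL–N, thioether Sγ–CH2, X–H): without the
filter, a steric clash between unrelated polar atoms can masquerade as a
bond and silently delete its repulsion.

Side chains are coarse: beyond CB, each identity carries at most two
pseudo-atoms (a CG-like carbon and a terminal functional-group atom whose
radius, charge and donor/acceptor flags encode the chemistry; aromatic
terminal atoms are inflated to stand in for the ring). Rotamers live on a
−60/60/180° χ grid, at most 9 per identity, mirrored for D.

`design_sequence()` anneals over (identity, rotamer) moves with Metropolis
acceptance and a geometric temperature schedule from T = 3.0 to 0.3 over
50 × n_positions moves per round (3 rounds by default; the pipeline uses 1).
Move energies are evaluated incrementally (only the swapped side chain's
interactions are recomputed), and the incremental ΔE is tested against full
recomputation in the suite. The chirality of a position is restricted by its
torsion bin: positive-φ bins admit D only, negative-φ bins L only, cis bins
either. The bridge Cys and the anchor-proximal D-Phe are never designable.
The returned state is the best visited, so the reported trace is monotone
non-increasing; on exhaustively enumerable instances (≤ 27 states) the
annealer finds the enumerated optimum in ≥ 95 of 100 seeded runs.

## Interface metrics

* **SASA** — Shrake–Rupley quadrature on Fibonacci sphere points (default
  240/atom; < 32 refused), probe 1.4 Å, hydrogens ignored. Agreement with a
  Monte-Carlo rejection-sampling oracle is within 2%. Because the point grid
  has a fixed orientation per atom, areas are rigid-motion invariant only to
  ~1% at default point counts (energies are invariant to 1e-6).
* **Interface area** — `SASA(receptor) + SASA(conjugate) − SASA(complex)`,
  reported **un-halved** (conventions differ across tools; this one is
  declared).
* **ΔΔG** — `E(complex) − E(receptor) − E(conjugate)` under rigid
  separation, no repacking.
* **Shape complementarity** — the Lawrence–Colman statistic on explicit dot
  surfaces: vdW-surface dots with outward radial normals (5 dots/Å²); for
  each interface-zone dot (nearest partner dot within 1.5 Å) the local score
  is `(n_a · −n_b)·exp(−0.5 d²)`; Sc is the mean of the two directional
  medians. Registered parallel plates give Sc → 1, orthogonal plates ≈ 0.
* **Contact molecular surface** — area-weighted sum of conjugate dots whose
  nearest receptor dot is within 1.5 Å; monotone in the cutoff.
* **Buried unsatisfied polars** — polar heavy atoms with per-atom SASA below
  0.01 Å² and no partner under the H-bond criterion.
* **Pocket volume** — probe-accessible grid flood fill (0.5 Å cells,
  6-connectivity) from a seed point; a flood reaching the bounding-box shell
  flags an open pocket and caps the volume. The tool reports volume in Å³ —
  for a spherical test cavity it recovers the analytic volume within ~6%
  (voxelization bias is positive at 0.5 Å).

For speed, Sc and contact-surface dots are generated only for atoms within
8 Å of the other partner; this cannot change the result because both
statistics only consume dots within 1.5–2.5 Å of the partner surface.

## The funnel

`percentile_filter()` interprets "top 10%" as the favorable-side
nearest-rank 0.9-quantile, inclusive at ties, applied *jointly*: a design
survives only if it is favorable on every listed metric. The default metric
list is the three headline metrics (ΔΔG lower-better, Sc higher-better,
interface area higher-better); all six computed metrics are exposed for
custom specs. With independent uniform metrics the joint survival fraction
is ≈ 10⁻³, which the suite checks by Monte Carlo. When a `target_count` is
given, q is relaxed jointly by binary search — on desk-scale tables (tens of
rows) the strict triple cut is usually harsher than the target, and the
recorded `q` documents the relaxation. The loop-contact filter requires at
least one peptide heavy atom within 4.5 Å (inclusive) of an annotated ECL2
or ECL3 heavy atom. Diversity selection is greedy max-min under a declared
mixture distance (0.5 sequence Hamming + 0.3 bin-string Hamming + 0.2
Jaccard distance of loop-contact sets), seeded at the best-ΔΔG design; the
"visual inspection" step of a real campaign is a human step and is not
simulated.

## Ensemble validation statistics

`hbond_criterion()` holds the shared definition: donor–acceptor heavy-atom
distance ≤ 3.5 Å and angle ≥ 135°. The angle vertex is ambiguous in common
usage, so both conventions are exposed: with an explicit hydrogen the
donor–H–acceptor angle is used (the default); without one, the
antecedent-heavy-atom–donor–acceptor angle. `contact_fraction()` counts a
residue as contacting in a frame when any heavy atom is within 4.5 Å
(inclusive) of any ligand heavy atom; the profile is the per-residue
fraction of frames. `ca_distance_table()` reports ensemble means against a
reference structure with the *population* standard deviation — the ensemble
is treated as a fixed object to describe, not a sample to infer from.
`kmeans_rmsd()` clusters flattened ligand heavy-atom coordinates (frames
pre-superposed on the receptor) with `stats::kmeans` under multiple random
restarts, keeping the best within-cluster sum of squares; the representative
is the frame nearest the largest cluster's centroid. Multi-restart
Hartigan–Wong was chosen over hand-rolling a k-means++ seeding: the
contract that matters — best inertia over n_init restarts, deterministic
under the seed — is identical, and the standard implementation is better
tested than anything bespoke.

## Pharmacology

`fit_logistic3()` fits `y = Emax / (1 + 10^(logEC50 − x))` with the bottom
fixed at 0 and Hill slope fixed at 1, by a deterministic grid over logEC50
(the conditionally optimal Emax has a closed form) followed by Nelder–Mead.
It recovers noiseless parameters to 1e-6 and holds median |logEC50| error
below 0.1 under 5% Gaussian noise. `cheng_prusoff()` is
`Ki = IC50 / (1 + L/Kd)`. `schild_fit()` regresses `log10(DR − 1)` on
`log10 B` (B in molar), rejecting DR ≤ 1 points with a warning; pA2 is the
negative of the x-intercept, i.e. `intercept/slope` of the unconstrained
fit, and `Kb = 10^(−pA2)`. The slope is *not* constrained to 1, so a
measured slope and a pA2 can be reported side by side. A rendered-formula
variant of the dose-ratio expression that divides EC50s differently is not
implemented: only the standard Gaddum/Schild form is self-consistent with
pA2-to-affinity conversion (pA2 9.1 ↔ 0.79 nM, pA2 7.9 ↔ 12.6 nM).
Reporting conventions: affinities to 2 significant figures, fold
selectivities to the nearest ten with a "~" prefix.

## What the synthetic fixtures do and do not emulate

`make_toy_pocket()` builds a closed spherical shell of carbon pseudo-atoms
(Fibonacci lattice, ~2.4 Å spacing) whose probe-accessible interior has a
requested radius (default 13.5 Å), with two shell patches near the mouth
axis annotated ECL2/ECL3. `make_toy_anchor()` is a ten-atom rigid cluster
with a free amine pointing at the mouth. The geometry was chosen once so
that grafted conjugates fit the cavity with a discriminating clash screen
(roughly a quarter of grafts pass) and a discriminating loop filter (a
minority-to-majority fraction of survivors contact the patches, depending on
extension). `make_toy_ensemble()` adds i.i.d. Gaussian coordinate noise per
frame.

These fixtures emulate *geometry only*: a closed cavity, a posed anchor,
loop-adjacent patches, thermal jitter. They do not emulate receptor
electrostatics, side-chain packing of a real binding site, membrane context,
or correlated conformational motion. A green test suite therefore
demonstrates that the algorithms are correct on inputs with known structure
— closure residuals, funnel nesting, optimizer optimality, statistical
recovery — not that the score function would rank real KOR ligands
correctly. That limitation is intrinsic to replacing a production energy
function with a declared one.

## Problem sizes and determinism

The default study conditions are ring size 6, 200 sampled backbones, 4 kept
extensions, a 36-design cap into sequence design (lowest-clash models kept),
one annealing round per design, q = 0.9 with target 20 survivors, and 6
final picks (the synthesis-set size of the funnel's design; the examples use
3). These sizes make the full funnel a minutes-scale computation on
one core while leaving every stage's filter discriminating; they are set in
`pipeline_config()` and can be raised freely. Every randomized operation
takes an explicit seed and restores the caller's RNG state; two runs from
one configuration produce identical tables, logs and selections.

## Known limitations

* Backbones are rigid after grafting: there is no relax step, so the clash
  screen and the link-snap translation carry the burden a relax protocol
  would share.
* Side chains are 1–2 pseudo-atoms; hydrogen bonds from side chains use the
  antecedent-angle convention because no side-chain hydrogens are built.
* The percentile filter's nearest-rank inclusive rule admits slightly more
  than (1−q) per metric on small tables — by design, so ties never drop a
  design that is indistinguishable from a survivor.
* PDB I/O covers ATOM/HETATM/MODEL records (via bio3d); mmCIF, assemblies
  and maps are out of scope.
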