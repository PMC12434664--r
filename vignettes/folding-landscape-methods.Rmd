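---
title: "Methods: coarse-grained RNA folding landscapes with explicit divalent ions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained RNA folding landscapes with explicit divalent ions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldscape)
```

`foldscape` studies how a small structured RNA folds in the presence of
divalent counterions, at desk scale: every stage of the analysis — model
building, sampling, landscape projection, ion statistics, free-energy
reconstruction — is implemented as tested package code, and the bundled
reference systems are generated programmatically so that every downstream
quantity has an exactly known ground truth. This vignette is the package's
account of its science: the model, the tunable parameters, what the
synthetic systems do and do not emulate, and the numerical choices made
where the design was genuinely open.

## The coarse-grained model

Each nucleotide is reduced to three beads at the mass-weighted centers of
its phosphate group, sugar, and base. The atom-to-group table is fixed:
the phosphate group holds P, OP1/OP2 (and O1P/O2P spellings), OP3 and O5';
the sugar holds C1'–C5', O4', O2' and O3' (O3' belongs to the sugar it is
bonded to, never to the downstream phosphate); the base holds the ring and
exocyclic atoms. A 5'-terminal residue lacking a phosphate carries its P
bead at the center of mass of the O5' group, so every residue contributes
exactly three beads and bead indexing is uniform.

Native contacts are all bead pairs closer than a cutoff (default 7 Å,
strict `<`) in the reference conformation and at least 3 residues apart in
sequence. A distance-cutoff map at CG resolution is used deliberately:
shadow-style atomistic contact maps require atomistic detail the CG model
does not carry, and the downstream analyses depend only on having a
well-defined contact basis for *Q*. Both the cutoff and the separation are
arguments of `native_contacts()`.

The fraction of native contacts is the hard count
*Q* = |{(i,j): r_ij < λ·r_ij^nat}| / N_c with λ = 1.2, the standard
structure-based-model convention; λ is configurable and recorded in the
output metadata. The same λ rule, applied to base-bead distances, defines
when an annotated base pair or stack is "formed" — at CG resolution there
are no hydrogen-bond geometries to test, so formation is a distance
criterion and Leontis–Westhof class labels are carried as annotation only.

## The surrogate simulator

The sampling engine is a structure-based (Gō-like) model with explicit
divalent ions:

* harmonic bonds between consecutive beads and harmonic angles on
  consecutive triples, both at their native values (k_bond = 100 ε/Å²,
  k_angle = 20 ε/rad²);
* a Gaussian well of depth ε_c = 1 (the energy unit) and width 0.6 Å at
  each native-contact distance, over a purely repulsive WCA core;
* WCA-style excluded volume for all remaining nonbonded pairs (bead radius
  1.6 Å; hydrated-ion radius 3.5 Å — the model has no explicit water, so
  the hydration shell enters only through this radius). Excluded-volume
  diameters are capped at 95% of a pair's native separation so the native
  structure is exactly the minimum of the bonded-plus-contact terms;
* Debye–Hückel electrostatics over charged sites: −1 per P bead, +2 per
  ion, prefactor 7.1 ε·Å (a Bjerrum length of ~7 Å when the reference
  thermal energy is one reduced unit), screening length 10 Å by default
  (the implicit monovalent salt), interaction cutoff 4λ_D. Dynamic
  counterion-condensation variables are intentionally absent: implicit
  monovalent salt enters only through the fixed Debye length, which is the
  stated scope of the surrogate.

Integration is BAOAB Langevin with timestep 0.001 τ_R, unit masses and a
drag coefficient of 1 τ_R⁻¹. The RNG is an in-engine mt19937_64 with an
explicit Box–Muller transform, so a (config, seed) pair reproduces a
trajectory bit-for-bit regardless of compiler library details. Ions are
wrapped into the periodic box each step and interact through the
minimum-image convention; the RNA is never wrapped. The default box is
15 nm — ion sampling at desk scale — with larger boxes accepted through
`box_edge_nm`. Non-finite energies abort with the step index.

**Temperature calibration.** Temperatures are multiples of a reduced
reference with k_B = 1; the surrogate's folding temperature was calibrated
once by a temperature scan of the bundled 52-nt system and frozen:
`temperature_folded()` = 0.5 keeps a native-started run folded (median
*Q* ≈ 0.98 over the second half of a 60k-step run with 20 Mg²⁺), and
`temperature_unfolded()` = 2.5 unfolds it (median *Q* ≈ 0.27). These two
values, not any external temperature scale, define the folded/unfolded
study conditions everywhere in the package.

**Umbrella sampling.** The bias ½k_Q(Q_smooth − Q₀)² uses the
differentiable contact fraction Q_smooth = (1/N_c) Σ 1/(1 + e^{β(r − λr^nat)})
with β = 5 Å⁻¹ and λ = 1.2, because the hard count has no gradient; hard
*Q* remains the reporting coordinate, and the bias energy recorded per
frame refers to Q_smooth. `umbrella_series()` runs windows from high to
low Q₀, seeding each start from the previous window's final frame — a
slow-pulling-style protocol that keeps adjacent windows overlapping — with
a per-window equilibration segment that is discarded. Spring constants are
a compromise between confinement and overlap; with the 12-nt demo system
(18 contacts, so *Q* is quantized in steps of 1/18) k_Q = 20 keeps all
adjacent windows connected, which is why the demo pipeline uses a softer
spring than the 52-nt analyses (k_Q = 50).

## Landscape projection

The dissimilarity between two conformations is δ = 1 − q_w with
q_w = (1/N_p) Σ exp[−(r_ij^k − r_ij^l)²/(2σ_ij²)] over bead pairs, and
σ_ij = σ₀·|Δn|^ε (σ₀ = 3 Å, ε = 0.15) where Δn is the residue-index
separation. Intra-residue bead pairs are excluded from the pair set: the
width rule vanishes at Δn = 0, which would make those terms singular, so
exclusion is the only self-consistent reading; N_p is the size of the
included set. δ depends only on internal distances and is therefore
rigid-motion invariant.

The 2D projection is the force scheme: seeded random initial layout; each
sweep visits every point once as a pivot (pivot order reshuffled per
sweep) and moves every other point along the pivot→point direction by
`step_fraction × (δ_target − d_current)`; defaults are 100 sweeps and
step fraction 1/8, both configurable — the projection literature leaves
them free, and these values converge on all bundled systems while keeping
the normalized stress Σ(δ−d)²/Σδ² non-increasing. δ is scaled by its
maximum before projection (its natural range is already [0,1]; scaling by
the maximum preserves the zero of identical conformations, which a
min–max rescale would not).

Density on the embedding is a product-Gaussian KDE with per-axis Scott's
rule bandwidths h_j = sd_j·n^(−1/6), evaluated at the sample points.
Region selection is programmatic — polygon (a TSV of vertices reproduces a
manual lasso workflow) or density quantile — and the local conformational
signature of a region is its dRMSD medoid: the member frame minimizing the
mean dRMSD to the others (ties to the lowest frame index), returned with
its nearest neighbours by dRMSD.

## Ion analytics

The Mg–phosphate RDF is shell-normalized against the ideal-gas density of
the same ions in the box; its first minimum after the first peak (located
on a 5-point running mean) is the package's default coordination cutoff,
replicating the practice of reading the cutoff off the RDF. Occupancy is
the number of ions strictly within the cutoff of each P bead
(minimum-image); ties at exactly the cutoff are excluded, and an ion near
two phosphates counts once for each — these are coordination counts, not
a partition. Occupancy along *Q* uses bins of width 0.05, left-closed,
with *Q* = 1 in the top bin and empty bins reported as missing rather than
zero. The bridging map is the per-frame probability that at least one ion
is simultaneously within the cutoff of two phosphates at least `min_sep`
residues apart ("nonlocal" defaults to 4 residues; an ion-count average is
a possible alternative reading, but the at-least-one convention is
implemented and documented). Excess ions per state are the mean count of
distinct ions within the cutoff of any phosphate minus the ideal-bulk
expectation for the union volume of the phosphate spheres, the union
estimated by seeded Monte Carlo per frame.

## WHAM and states

`wham_solve()` is the standard self-consistent iteration on the per-window
offsets, converged when max|Δf_w| < 10⁻⁷ (default grid: 50 bins on [0,1];
iteration cap 10⁵). Window supports that do not overlap are reported as
disconnected components with a warning, since their relative offsets are
then arbitrary. F(Q) = −kT ln P(Q) is shifted to minimum zero; unsampled
bins are missing, not zero. State labels follow the Q thresholds
0.4 / 0.55 / 0.85 (U, PO, PF, F) with left-closed intervals — a boundary
value belongs to the higher state; the thresholds themselves are
arguments.

## The synthetic systems, and what passing tests show

The bundled references are generated from idealized geometry and labelled
synthetic. The 52-nt system winds the chain on a solenoid so that residues
one turn (10 residues) apart are in contact — a compact, self-avoiding
fold with nonlocal contacts, including the 28–38 phosphate pair used by
the ion-bridge analyses — and its sequence carries the riboswitch residue
identities at the positions the analyses name. The 12-nt hairpin is a
five-pair stem with a two-residue loop. The morph generator interpolates
linearly from the native fold to an extended chain, adds Gaussian noise,
and can script ions: a bridging ion placed (deterministically) at a point
within the cutoff of exactly the two target phosphates, present in a
Bernoulli-sampled fraction of frames, and site ions parked 1.5 Å from
chosen phosphates only above a Q threshold.

These systems emulate the *structure* of the analysis problem — compact
native folds, nonlocal contacts, unfolded-to-folded ensembles, designed
ion signals — not real RNA energetics: there is no base-pairing
specificity, no sequence-dependent stability, no inner-sphere ion
chemistry, and the morph path is a geometric interpolation rather than a
Boltzmann ensemble. Passing tests therefore demonstrate that the
machinery recovers designed ground truth and obeys its invariants, not
that any particular real RNA folds a particular way. One consequence
worth noting: along the full morph path *Q* collapses to zero early
(nonlocal contacts break at small unfolding) while stacks decay late, so
guards that correlate interaction formation with *Q* are evaluated in the
partially folded regime (unfold fraction ≤ 0.12) where both quantities
actually vary.

## Numerical choices and limitations

* Strict `<` at every distance threshold (contacts, occupancy, bridge);
  boundary ties are excluded and documented.
* Deterministic orderings everywhere a set is enumerated (contacts are
  lexicographic in (i, j)); medoid ties break to the lowest frame index.
* The demo analyses run at deliberately small problem sizes — tens of
  thousands of integrator steps, hundreds of frames, nine umbrella
  windows — chosen so the full suite and the acceptance script complete
  in minutes; the window count, run lengths and frame counts are all
  configuration, and the same drivers scale up unchanged.
* WHAM consistency under window duplication is exact only when the
  duplicated window is the entire data set; with several finite-sample
  windows the reweighting shifts F(Q) within sampling error, which is how
  the tests assert it.
* The P bead of the 5'-terminal residue carries the phosphate charge even
  though it represents the O5' group; at one site in 52 this is a
  negligible simplification of the charge model.
* `load_structure()` reads standard fixed-column PDB ATOM records (first
  alternate location kept, heteroatoms separated); mmCIF and modified
  nucleotides are out of scope.
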