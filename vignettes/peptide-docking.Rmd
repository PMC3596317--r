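---
title: "Ensemble rigid-body protein-peptide docking by conformational selection"
author: "PepDock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble rigid-body protein-peptide docking by conformational selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Peptides that bind protein domains (MHC grooves, SH3 and PDZ domains, and
many signalling motifs) are short, flexible, and frequently disordered in
isolation. Docking them rigidly from a single conformation fails whenever
the bound conformation differs from the guess. PepDock implements the
conformational-selection strategy for the rigid-body stage of
information-driven docking: instead of one starting structure, the peptide
enters the docking as an ensemble of three canonical conformations —
ideal extended, alpha-helix and polyproline II — each sampled equally, and
the scoring function is left to select the conformer(s) compatible with
the receptor. The package covers everything needed to run and evaluate
that stage on a desk machine: conformer construction, restraint
generation, rigid-body sampling and minimization under a composite score,
peptide-adapted CAPRI quality assessment, RMSD clustering with
cluster-level ranking, and a deterministic generator of toy
receptor-peptide complexes for testing.

Induced fit — the flexible refinement that follows the rigid stage in a
full docking protocol (semi-flexible simulated annealing and solvated
refinement) — is deliberately out of scope: this toolkit stops after
rigid-body sampling, selection and assessment.

## Canonical conformers

`buildPeptide()` constructs peptides by sequential internal-coordinate
(NeRF) chain extension with fixed bond geometry (N-CA 1.458, CA-C 1.525,
C-N 1.329 Å; angles 111.2°, 116.2°, 121.7°; all omega = 180°). The three
templates are:

| template | phi (deg) | psi (deg) | per-residue extension |
|----------|-----------|-----------|-----------------------|
| extended | -139      | -135      | ~3.43 Å               |
| helix    | -57       | -47       | ~1.6 Å                |
| ppii     | -78       | 149       | ~3.1 Å                |

The builder is exact: measured interior phi/psi equal the template to
numerical precision, which the tests exploit as a round-trip invariant.
Only the backbone plus CB is built. Side chains beyond CB are not modelled
— the rigid-body stage operates on a reduced representation, and all
energies are parameterized per element. This is a documented divergence
from all-atom protocols; it makes poly-alanine-like fixtures the natural
test regime. CB placement uses the improper dihedral N-C-CA-CB = -122.6°,
which reproduces the L-configuration observed in crystal structures
(about -124° ± 3°). Proline gets no ring closure: its phi is set like any
other residue, a known simplification that matters only for PPII-heavy
proline sequences.

An ideal extended poly-alanine extends ~3.46 Å per residue (end-to-end CA
distance divided by n-1). Because the exact value depends on the bond
geometry chosen, the package asserts it to ±0.15 Å. The classification
cutoff for "extended" peptides is 80% of that ideal value, 2.8 Å per
residue, stored as `EXTENDED_CUTOFF`.

## Classification rules

`classifyPeptide()` applies, in fixed order: helix if more than half the
residues are helical, else extended if the per-residue extension is at
least 2.8 Å, else disordered. The precedence had to be fixed somewhere;
helix-first is the safer order because a helical peptide essentially never
extends past 2.8 Å/residue, while the reverse misclassification would be
possible. The 2.8 Å comparison is inclusive (>=): the choice is
measure-zero in practice but is frozen here for determinism.

Secondary-structure programs are unreliable on very short chains, so helix
assignment uses a dihedral-window rule instead: a residue is helical iff
phi in [-100, -30] and psi in [-80, -5] and it belongs to a run of at
least four consecutive such residues (the minimum length of one helical
turn). Users who prefer DSSP/STRIDE output can pass a per-residue string
via the `ss` argument, which bypasses the window rule.

Docking difficulty compares the bound peptide with its ideal extended
build: easy (backbone RMSD <= 4 Å), medium (4-8 Å], difficult (> 8 Å),
upper bounds inclusive. A PPII decamer classifies as extended under these
rules (extension ~3.1 >= 2.8), which the tests assert at length 10.

## Restraints and the composite score

The binding site is defined broadly, on purpose: all receptor residues
with any heavy atom within 5 Å of the peptide in the reference complex
become *active*; all peptide residues are *passive*. The resulting active
surface is considerably larger than the true interface (the tests check
it exceeds half the buried area), which drives poses to the right region
without dictating the exact pocket.

Each active residue contributes one ambiguous interaction restraint. Its
effective distance pools every heavy-atom pair between the residue and the
entire passive molecule, d_eff = (sum d^-6)^(-1/6), and the energy is a
flat-bottom quadratic k·max(0, d_eff - 2.0)² with k = 50 kcal/mol/Å².
Neither the upper bound nor k is printed in the protocols this mirrors;
both are recorded assumptions, exposed in `dockingParams()`.

The rigid-body score is the weighted sum

```
total = 0.01 E_rest + 0.01 E_vdw + 1.0 E_elec + 1.0 E_desol - 0.01 BSA
```

with BSA = SASA(receptor) + SASA(peptide) - SASA(complex). The weights are
frozen in `SCORE_WEIGHTS` and are not a tuning surface. The component
forms, by contrast, are this package's own simplified stand-ins, since a
reduced-representation model cannot reuse a full force field:

* `vdwEnergy()`: intermolecular 12-6 Lennard-Jones, per-element
  sigma/epsilon, truncated and shifted at 8.5 Å;
* `elecEnergy()`: Coulomb with relative dielectric 10, same truncation;
  unit charges sit on the CB of Asp/Glu/Lys/Arg and on terminal N/C when
  termini are flagged charged;
* `desolvationEnergy()`: per-atom atomic-solvation parameters times the
  SASA change on complexation (carbon and sulfur burial favourable,
  nitrogen/oxygen burial mildly unfavourable);
* SASA by an internal Shrake-Rupley implementation (probe 1.4 Å, 960
  dots/atom for reporting; radii C 1.70, N 1.55, O 1.52, S 1.80 Å).
  Relative accessibility references come from extended Gly-X-Gly
  tripeptides built by the package itself, so the 40% accessibility rule
  is self-consistent with this SASA implementation rather than an external
  table.

All numeric parameters live in one editable table, `dockingParams()`,
serializable as a flat key = value file.

## Rigid-body sampling and minimization

`samplePoses()` places each conformer at a random orientation on a sphere
of radius (receptor radius + peptide radius + 3 Å), slides it towards the
receptor centre until van der Waals contact (a cheap approach phase that
skips the SASA terms), evaluates both the start and its 180°-rotated
counterpart, and minimizes the better one with Nelder-Mead over the six
rigid degrees of freedom (150 iterations, then a fresh-simplex restart of
100 — restarts matter because the simplex collapses early in 6D; the
budget is configurable through `dockingParams()`).
Poses whose minimization fails are kept with their start score and
flagged. Every pose draws its own RNG substream from (seed, pose index),
so results are bitwise reproducible and independent of how many poses are
requested.

During minimization the SASA terms use 92 dots/atom: BSA is then accurate
to a few percent, which is well below the score differences that matter at
this stage, and the evaluation stays around a millisecond. A kernel-level
shortcut makes this affordable: receptor atoms whose spheres cannot touch
any peptide atom keep their precomputed free-receptor SASA, so only the
interface is recomputed per evaluation.

`selectTop()` sorts ascending by total score with a stable model-id
tie-break. `selectionStats()` reports, for a selection, each conformer's
fraction and enrichment factor EF = fraction × k (k = ensemble size): a
selection containing 60% helix-origin poses in a 3-member ensemble has
EF(helix) = 1.80, uniform selection has EF = 1 everywhere, and EFs always
sum to k.

## Assessment and clustering

Quality follows the peptide-adapted CAPRI convention, all computed against
a reference complex whose interface (both-sided, 10 Å) is defined once and
reused: i-RMSD (backbone of the pooled two-molecule interface, fitted on
those same atoms), l-RMSD (peptide backbone after fitting on all receptor
backbone), l-i-RMSD (peptide interface after fitting on the receptor
interface), and Fnat (fraction of native residue-residue contacts at a 5 Å
heavy-atom cutoff — the conventional CAPRI definition, adopted here since
no tighter one is standard for peptides). Classes cut at i-RMSD <= 1 Å
(high / sub-angstrom) and <= 2 Å (near-native), boundaries inclusive.
Including the peptide interface atoms in the i-RMSD superposition follows
the CAPRI standard; it is the one place where conventions genuinely
diverge, so the fit set is documented here rather than configurable.

Clustering uses the neighbour-counting (Daura-style) algorithm on the
matrix of pairwise peptide-backbone RMSDs after fitting each pair on the
receptor interface backbone — the interface-ligand metric that suits small
peptide interfaces, with a 5.0 Å cutoff rather than the larger values used
for protein-protein complexes. The minimum cluster size of 4 is forced by
the ranking rule: a cluster scores as the mean of its four best members,
and a cluster counts as near-native only if one of those top four members
is acceptable. Ties break on the representative's model id, making the
clustering deterministic and permutation-invariant.

## The synthetic fixtures

`makeComplex()` builds poly-alanine lattice receptors: a slab with a
groove sized to the extended conformer of the chosen peptide (walls 11 Å
apart, floor 3.5 Å below the peptide, end caps that close the groove so
the native register is unique), or a convex patch on which the peptide
lies exposed. Residue orientations are drawn deterministically from the
seed, so fixtures are bit-reproducible. The groove geometry was chosen so
that the native placement is clash-free while the helical conformer cannot
enter; a shallow floor prevents any conformer from wedging below the
native plane and out-burying it. If the peptide sequence contains charged
residues, a complementary charged residue is placed beneath each native
side-chain position, giving the groove chemical specificity in addition to
shape. `makeDecoySet()` perturbs the reference peptide rigidly with
magnitudes calibrated by bisection to land in planned i-RMSD strata, which
gives the assessment and clustering modules models with known labels.

What the fixtures do *not* emulate: real protein folds, connected receptor
chains, side chains beyond CB, bound-unbound receptor differences, and
crystallographic noise. Passing tests therefore demonstrate the internal
consistency and the qualitative selection behaviour of the protocol, not
benchmark-level success rates on real complexes — reproducing those
requires the full flexible-refinement stages that are out of scope here.

## Problem sizes and runtime choices

The shipped tests run the complete pipeline (restraints, three-conformer
ensemble, 50 poses per conformer, top 30, assessment, clustering) on the
groove fixture across ten seeds, and a lighter selection experiment (20
poses per conformer, top 6 per seed, pooled over ten seeds) for the
enrichment check. These sizes were chosen as the smallest pools in which
the selection statistics are stable; they complete in minutes on a single
core. The full-scale protocol mirrored by the defaults (2000 poses per
conformer, top 400) is available through the same parameters.

## Known limitations

* No flexible refinement: models come out of rigid-body minimization
  with possible residual clashes (the vdW weight at this stage is 0.01
  precisely so that near-native but imperfect poses survive selection).
* Reduced representation: per-element parameters, CB-only side chains,
  no hydrogens; energies are internally consistent but not transferable
  to all-atom force fields.
* The electrostatic term can reward interpenetrating opposite charges
  under the low vdW weight; with the neutral default fixtures this does
  not affect the shipped benchmarks.
* Residue correspondence between model and reference is by author
  numbering; an alignment-based remapping is available only insofar as
  the caller renumbers inputs.
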