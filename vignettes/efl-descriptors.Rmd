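---
title: "Descriptors of elementary functional loops: model, objective function and grafting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptors of elementary functional loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efloop)
```

## The model

Soluble proteins are built from closed loops of a preferred 25-35 residue
size, and many elementary biochemical activities -- phosphate binding,
metal coordination, redox chemistry -- are carried by such *elementary
functional loops* (EFLs) with recognizable sequence signatures (the
Walker-A `GxxGxG` P-loop, the glycine-rich `GxGxxG` dinucleotide-binding
loop, the `DxDxD` EF-hand). The same elementary function recurs across
unrelated folds, so a useful description of an EFL must pool, per residue
position, everything that varies across its structural realizations:

* **sequence** -- a position-specific frequency profile $w_{i,k}$ over the
  20 amino acids, with additive pseudocounts;
* **backbone geometry** -- a Gaussian-mixture model of the $(\phi,\psi)$
  dihedral pair at each position, fitted by EM with the number of
  components chosen by BIC;
* **packing** -- the number of van der Waals contacts (heavy-atom pairs
  within 5 Å) of the position's residue, counted separately inside the
  loop and against the rest of the fold;
* **hydrogen bonding** -- donor and acceptor counts under a distance-only
  geometric criterion (donor-acceptor heavy atoms within 3.5 Å), again
  split intra/external, summarized by a half-normal fit to their spread.

`assemble_descriptor()` is the fitting function: it takes a list of
30-position loop instances (`extract_loop_features()` output) and returns
an S3 `efl_descriptor` with `print`, `summary`, `coef`, `plot` and
`predict` methods. Everything downstream -- scoring, window scanning,
grafting -- consumes this object.

Intra-loop and loop-to-fold interactions are stored separately (the
distinction matters biologically: strands interact with the fold, helix
caps with themselves), but the scoring formula below compares pooled
totals, one count per feature per position.

## Deriving descriptors from sequence and structure collections

Derivation starts from a gapless alignment of 30-residue seed fragments.
`build_pssm()` turns it into a profile with frequencies
$(c_{i,k} + \alpha\,b_k)/(n_i + \alpha)$ (pseudocount $\alpha$, background
$b$, uniform by default). `iterate_profile()` then runs a hard-assignment
expectation-maximization-style expansion: scan the database
(`scan_database()`, summed log-odds in bits over every window,
non-overlapping matches greedily best-first), pool the matched segments
with the seeds, rebuild the profile, and repeat until the matched set is
stable or the max-norm frequency change falls below `tol`. The original
derivation pipeline scanned UniRef; here the database is any FASTA the
user supplies, which keeps the algorithm intact at desk scale. The
converged profile is matched against chain sequences of a structure
collection (`match_structures()`) and every qualifying window becomes a
loop instance via feature extraction.

Convergence criteria, threshold, pseudocount scheme and background model
are deliberately exposed as configuration (`efl_config()`); none of them
is prescribed by the method itself, and the defaults (threshold 10 bits,
pseudocount 1, uniform background) are ordinary choices for profile
searches of this width.

## The objective function

A candidate loop is scored against a descriptor with

$$F \;=\; \sum_{i=1}^{N}\sum_{j\in\{a,d,v,hA,hD\}} W_i^P\, W_{ij}^F\, S_{ij},$$

maximized over candidate realizations. The per-feature similarities
$S_{ij}\in[0,1]$ are:

* $S_{i,a}$ -- the profile-weighted expected BLOSUM62 log-odds
  $\sum_k w_{i,k} B(a_i,k)$, min-max rescaled to $[0,1]$ by the matrix's
  global extrema ($-4$ and $11$) so all features share a scale. A
  consensus-residue comparison is available via `seq_mode`.
* $S_{i,d} = 1 - \mathrm{erf}\!\left(\sum_k r_k\, D_k^{\top} C_k D_k\right)$,
  where $D_k$ is the wrap-aware displacement from component $k$'s mean,
  normalized per dimension by the median absolute displacement of the
  training points, and $C_k = \Lambda_k r_k$ combines the component
  precision $\Lambda_k = \sigma_k^{-2}$ with the point's posterior
  responsibility $r_k$. At a component mean the score is exactly
  $1-\mathrm{erf}(0)=1$; it decreases monotonically along any ray and
  tends to 0 far from all components. The absolute scale of the erf
  argument is a design choice (no canonical units exist for the mixed
  normalizer/precision product); the package fixes it by the median
  normalizer with a 1-degree floor and a 1-degree² variance floor, which
  places typical in-family displacements in the upper half of the score
  range.
* $S_{i,v}, S_{i,hA}, S_{i,hD} = 1 - |x-y|/\max(x,y)$ (and $1$ when both
  counts are zero): the count-mismatch ratio turned into a similarity so
  that, like every other feature, the best fit maximizes it. The
  reference $y$ is the rounded mean of the descriptor's pooled counts,
  or the target structure's own count in pairwise (grafting) mode.

Positions with missing data (chain breaks, unresolved backbone) score a
neutral 0.5 on every feature, so absent coordinates neither reward nor
punish a candidate.

### Feature weights and the direction of "conservation"

The position weight $W_i^P = \sum_j W_{ij}^F / \sum_{i,j} W_{ij}^F$
normalizes to 1 over the loop. The sequence weight $W_{i,a}^F$ is the
summed frequency of the two most frequent residues. For the dihedral and
count features the weight is the half-normal scale
$\hat\sigma = \sqrt{\mathrm{mean}(x^2)}$ fitted to the feature's spread
(displacement magnitudes for dihedrals, $|x-\bar x|$ for counts), each
multiplied by a per-feature scalar factor (default 1) that exists to
balance the features' numeric ranges.

There is a genuine ambiguity here: a weight *equal to* the spread rewards
variable positions, while the weighting is meant to express conservation.
The package implements the spread itself as the default and offers
`invert_spread_weights = TRUE`, which uses the bounded transform
$1/(1+\hat\sigma) \in (0,1]$ -- the same scale as the sequence weight, so
no feature can dominate through units alone. The recovery experiments
below use the conservation direction, the reading consistent with the
weights' purpose: under spread-as-weight, positions whose counts never
vary (spread 0, weight 0 -- or, inverted without a bound, an arbitrarily
large weight) are exactly the positions a conservation-seeking search
should trust most, so the bounded conservation form is what the
experiments exercise.

## Finding and grafting the best realization

Given a target window, `score_position_matrix()` scores every provenance
loop of the descriptor at every position: where the target's own features
are defined they serve as the pairwise reference (the native structure is
assumed the best fit, so candidate segments are compared against it);
disordered target positions are invalid for seeding and fall back to the
descriptor's distributions. `find_seed_segment()` locates the 7-residue
window (half a typical signature) with the highest cumulative score over
valid positions; ties prefer the smaller start, then the lexicographically
smaller source. `extend_and_merge()` grows the seed one position at a time
from whichever end offers the higher score, keeping the current source
unless another is strictly better (an optional hysteresis margin limits
fragmentation; the default margin 0 switches freely, which is what makes
recombinant loops from several sources possible). Invalid positions are
filled best-effort. The plan always covers all N positions with
non-overlapping segments.

`graft_loop()` places each segment by least-squares (Kabsch)
superposition on backbone anchors: the three backbone atoms (N, CA, C) of
the residue immediately flanking the segment on each side -- scaffold
flank residues at the window edges, the target's native junction residue
at internal segment boundaries. Anchoring on the residues adjacent to each
junction keeps the peptide geometry at the seams tight; using whole
flanking stretches instead distributes the source/target shape mismatch
into the junctions, which measurably degrades C-N distances. Side chains
ride along unchanged; there is no repacking, minimization or backbone
relaxation -- the report instead lists every junction's CA-CA and C-N
distances and the count of heavy-atom clashes (< 2 Å) against the retained
scaffold, which is what a downstream design tool needs to decide whether
refinement is required. Grafting a structure's own native window back is
an exact fixed point (coordinate drift at machine precision).

## Synthetic families: what they emulate and what they do not

All tests run on generated inputs:

* `build_peptide()` constructs ideal-geometry backbones (N-CA 1.458 Å,
  CA-C 1.525 Å, C-N 1.329 Å, trans peptide, standard angles) realizing
  requested torsions exactly, so dihedral extraction has a closed-loop
  oracle (round-trip error is ~1e-13 degrees).
* `generate_motif_family()` plants a motif window -- fixed signature
  letters, uniform letters elsewhere, template torsions plus Gaussian
  jitter -- inside random-coil flanks. The default spec emulates a
  beta-loop-alpha phosphate-binding loop with a `GxGxxG`-signature core.
* `sample_sequences()` draws database sequences position-wise from a
  profile inside uniform flanks.

These fixtures give controlled conservation, known true offsets and exact
determinism per seed. They do **not** emulate side-chain packing, real
Ramachandran correlations between neighbouring residues, solvent, ligands
or the redundancy structure of real sequence databases. Passing the
recovery experiments therefore demonstrates that the statistics,
weighting and search behave correctly -- not that the descriptor scale is
calibrated for PDB-derived families, whose contact-count distributions
are broader and whose profile thresholds need choosing per family.

## Study conditions and numerical choices

The recovery experiment used by the test-suite and `scripts/acceptance.R`
assembles a descriptor from 30 planted-motif structures (torsion jitter
5°, 25-residue flanks, 80-residue chains) and scans 20 held-out members;
the true window is required to outscore at least 95% of the other windows
of its chain. Graft-geometry experiments use a helical family at 2°
jitter -- the structurally conserved regime in which within-family
grafting is meaningful. These sizes keep the full pipeline comfortably
inside an interactive session while leaving dozens of competing windows
per chain.

Numerical conventions worth knowing:

* all windows and offsets are 1-based inclusive residue ranks within a
  chain, the R convention, including `ProfileMatch` offsets and the
  command-line `--offset`;
* dihedral clustering re-centres angles on their circular mean per
  dimension before EM, so clusters straddling ±180° are handled; variance
  floor 1 deg², median-normalizer floor 1 deg;
* altloc conflicts keep the highest occupancy (ties prefer altloc A);
  waters are dropped; non-water HETATM groups are ligands and are
  excluded from all feature counts; only the first MODEL is read;
  nonstandard residues with a standard parent (MSE, SEC, ...) map to the
  parent letter, others to `X`;
* contact exclusion: pairs within one residue or between residues whose
  author numbers differ by one (or share a number across an insertion
  code) are covalent neighbourhood, not contacts;
* equal window scores in a scan resolve to the smaller offset; equal
  seed-segment scores to the smaller start, then the smaller source id;
  extension ties between the two ends grow toward the C-terminus.

## Limitations

Loop length is fixed: replacement is N-for-N, with no insertions or
deletions in the realization. H-bonds are distance-only -- no angular
term, no hydrogen placement, no energy. There is no statistical
significance attached to F, no ligand-geometry scoring, and no coupling
to a design suite for repacking or minimization; the graft report is the
hand-off point. The EM-like profile expansion is a hard-assignment
approximation and can lock onto a poor basin if the seed alignment is
unrepresentative -- the `unconverged-empty` flag reports the degenerate
case rather than guessing.

## A worked call sequence

```{r example, eval = FALSE}
fam <- generate_motif_family(motif_spec(n_members = 20, seed = 1))
loops <- lapply(1:15, function(k) {
  extract_loop_features(fam$structures[[k]], "A", fam$offsets[k], 30)
})
d <- assemble_descriptor(loops, efl_config(invert_spread_weights = TRUE),
                         name = "GxGxxG-demo")
summary(d)

# where does the descriptor fit best in a held-out structure?
predict(d, fam$structures[[20]], "A")

# plan and perform a graft into that window
psm <- score_position_matrix(fam$structures[[20]], "A", fam$offsets[20], d)
plan <- extend_and_merge(psm)
lib <- setNames(fam$structures, sapply(fam$structures, `[[`, "id"))
graft <- graft_loop(fam$structures[[20]], plan, lib)
graft$junctions
```
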