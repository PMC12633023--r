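---
title: "Interface-adjacent pocket screening: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface-adjacent pocket screening: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iapScreen)
```

## The problem

Molecular glues stabilize a protein--protein interaction by binding in a
pocket at or beside the interface, contacting residues of both partners.
`iapScreen` implements the structural-bioinformatics side of finding such
molecules: it mines solved dimers for ligands bound in interface-adjacent
pockets (IAPs), turns ligand-bearing pockets into a template library, and
screens a target dimer by aligning its interface-adjacent pockets against
that library, transferring each matching template's ligand pose into the
target frame, and attaching a calibrated binding-precision estimate to every
prediction. The package makes no attempt to predict quaternary structure;
externally predicted complexes are consumed as ordinary structure files with
`provenance = "predicted"`.

## Mining rules

Two residue-level rules drive the mining stage, both counted on distinct
residues at a minimum heavy-atom distance cutoff:

* **Dimer rule** — a two-chain structure counts as a genuine dimer when each
  chain contributes at least 5 residues to the inter-chain interface
  (`qualifiesAsDimer`).
* **IAP-ligand rule** — a bound ligand is classified as interface-bridging
  (`"iap"`) when it contacts at least 5 distinct residues on *each* chain
  (`classifyLigand`); ligands meeting the threshold on exactly one chain are
  `"single_chain"`, all others `"non_binder"`. Waters are never classified;
  single-atom metal ions are classified but tallied separately.

The contact cutoff defaults to 4.5 Å, the standard heavy-atom contact
criterion; the mining literature that motivates the 5-residue thresholds
does not define "interacting" operationally, so the cutoff is exposed as a
parameter everywhere. Hydrogens are ignored throughout (most deposited
structures lack them and all rules are residue-level). For alternate
locations only the highest-occupancy conformer is kept, ties broken by
altloc identifier; selenomethionine and similar covalently linked modified
residues always stay in the polymer. No symmetry expansion is performed: the
deposited coordinates are used as-is, and the assembly policy is only
recorded on the model.

## Pocket detection

`detectPockets` is a grid method in the LIGSITE family, used here as a
documented, deterministic cavity detector. Polymer heavy atoms are
rasterized onto a cubic grid (default spacing 1.0 Å) with per-element van
der Waals radii; an empty cell is a cavity cell when scan lines hit protein
on both sides in at least 5 of 7 direction pairs (3 axes + 4 body
diagonals), and pockets are maximal 6-connected sets of cavity cells.
Pocket volume is the cell count times the cell volume; lining residues are
those with a heavy atom within `probeRadius + spacing` (default 2.4 Å) of a
member cell. Bound ligands and waters are excluded from rasterization, so a
pocket is found whether or not it is currently occupied.

Two derived predicates use the pockets:

* the **library filter** (at least 10 lining residues and 100 Å³) selects
  pockets worth templating;
* **interface adjacency**: a pocket is interface-adjacent when its lining
  contains at least one interface residue from each chain. This residue-level
  reading ties adjacency directly to the interface definition; a
  centroid-distance criterion was considered and rejected because it needs an
  arbitrary distance scale and can misclassify large elongated pockets.

## Pocket alignment, similarity score and p-value

`alignPockets` performs iterative rigid alignment of two pockets'
lining-residue representative atoms (Cα). Seeds are rigid superpositions of
pairs of consecutive lining-residue triples (capped deterministically, the
most promising refined further); each seed is refined by reassigning
mutual-nearest neighbours under a distance gate of twice the score scale
`d0` and re-superposing until the correspondence reaches a fixed point. The
similarity score is

$$ S \;=\; \frac{1}{L_{\min}} \sum_{i=1}^{L} \frac{1}{1 + (d_i/d_0)^2},
\qquad d_0 = 0.3\,L_{\min}^{1/3} + 0.4\ \text{Å}, $$

with $L_{\min}$ the smaller lining-residue count, so a pocket aligned to
itself scores exactly 1 and partial matches are penalized through the
$1/L_{\min}$ normalization. The size scaling follows the TM-score family,
but with constants tightened for pocket-sized residue sets: with the
protein-length constants (≈3 Å at 60 residues) unrelated pockets saturate
the kernel and the null and homolog score distributions overlap too much to
support a useful significance estimate. The tightened scale puts typical
unrelated-pocket matches near $d_0$ and genuine homologs (sub-Å matches)
well above it.

Significance comes from an empirical null (`fitNullModel`): scores of
randomly drawn unrelated pocket pairs are collected per aligned-length bin
(5–15, 16–30, >30) and summarized semiparametrically. Within the observed
score range, `pocketPvalue` uses a linearly interpolated empirical CDF, so
null p-values are uniform essentially by construction rather than by the
goodness of a parametric fit; beyond the largest observed score, a Gumbel
(extreme-value) distribution fitted to the bin's scores supplies the upper
tail, rescaled to continue the empirical CDF. A pure Gumbel fit was tried
first and rejected: its mid-range misfit varies from draw to draw and can
push the Kolmogorov–Smirnov distance of fresh null p-values from uniform
above 0.1, while the semiparametric form keeps it at the level of sampling
noise. The default calibration draws 10,000 pairs with a fixed seed; bins
with too few observations fall back to the pooled sample and fit.
Validation checks that p-values of fresh unrelated pairs are empirically
uniform (Kolmogorov–Smirnov statistic below 0.1 at n = 1000) and that
planted remote homologs score p < 0.05.

Global sequence identity (`globalSequenceIdentity`) is computed with
Needleman–Wunsch (BLOSUM62, gap open 11 / extend 1, via Biostrings), with
identical aligned positions divided by the alignment length including gaps.
Identity cutoffs apply to the *maximum* identity between any template chain
and either target chain — a template is only "remote" if it is remote from
both partners.

## Pose transfer, clashes and binding precision

A passing alignment's rigid transform maps the template's ligand
coordinates into the target frame (`transferPose`); atom identities are
untouched. Steric plausibility is a hard count of ligand/protein heavy-atom
pairs closer than 1.5 Å (`stericClashCount`); more than 5 such clashes
disqualifies a pose (precision 0). Pose accuracy against a reference is
summarized as the Euclidean distance between unweighted heavy-atom centers
of mass (`comDeviation`); the all-atom-RMSD-after-superposition alternative
was noted and not adopted, since the center-of-mass reading matches how the
benchmark metric is defined here.

The binding-precision estimate is a transparent calibration table
(`CalibrationTable`): empirical positive fractions in (score, p-value) bins,
made monotone (non-decreasing in score, non-increasing in p-value) by
count-weighted isotonic pooling, with empty bins inheriting a
monotone-consistent lower bound. The shipped default table was built by
`scripts/build_calibration.R` from a synthetic labeled set in which
positives are remote-homolog pocket matches (correct pose transfer by
construction) and negatives are unrelated pocket pairs; users with assay
data can substitute their own table via `readCalibrationTable`. This
estimator deliberately replaces a trained affinity model with an auditable
lookup: the package documents exactly what the numbers mean — the fraction
of matches with these features that were true in the calibration set — and
nothing more.

`screenTarget` composes the pipeline: detect interface-adjacent pockets,
align each against every library pocket, filter by p-value (default 0.05,
inclusive) and template identity, transfer poses, count clashes, estimate
precision, group poses by ligand code and rank by precision, then p-value,
then identity, then code — fully deterministic. `runBenchmark` wraps the
screen for targets with known native ligands (self-entries excluded from
the library per target) and reports recall, mean precision and mean
center-of-mass deviation per (p cutoff, identity cutoff) condition.

## Ligand chemistry

`pathFingerprint` hashes all linear atom/bond paths of up to 7 bonds (each
path read in its lexicographically smaller direction) into a 2048-bit
vector with a versioned FNV-1a hash — the folded path-fingerprint design of
the Daylight family. The exact hashing parameters of the original toolkit
are not public, so the scheme identifier is stored on every fingerprint to
keep runs comparable. `tanimoto` is plain bit-set similarity, and
`thresholdCluster` is Butina leader clustering at a similarity threshold
(default 0.8): fingerprints are ordered by neighbour count, leaders absorb
their unassigned neighbours, and each cluster's centroid is the member with
the highest mean within-cluster similarity. Molecular graphs come from SDF
or SMILES component dictionaries via ChemmineR/ChemmineOB; 3-letter codes
alone carry no graph.

## The synthetic-structure generator

All validation rests on `makeDimerFixture` and its relatives, which emit
structures whose ground truth is known by construction:

* **Open mode** plants exact counts: two parallel idealized Cα traces
  (3.8 Å spacing, dummy side-chain centroids) with exactly the requested
  number of inter-chain residue contacts at 4.0 Å, and a ligand contacting
  exactly the requested number of distinct residues on each chain. Geometry
  is arranged so each planted interaction is the only one within the
  cutoff; generator-internal brute-force measurement re-verifies every
  emitted file.
* **Enclosure mode** builds a closed cavity at the chain–chain seam: a wall
  shell of multi-atom residues on a jittered lattice, split between the two
  chains at mid-height, with sub-boxes and carved notches for shape
  diversity and the ligand planted inside. Contact counts here are measured,
  not planted; the mode guarantees an interface-adjacent, library-passing
  pocket hosting an IAP-classified ligand.
* `makeCavityFixture` samples wall atoms exactly one van der Waals radius
  outside a box, so the enclosed void *is* the box and the volume truth is
  analytic (the 0.3 Å sampling step leaves ≈0.02 Å of boundary
  uncertainty).
* `makeHomolog` applies residue deletions, sequence mutations, Gaussian
  coordinate noise and a rigid motion, returning the residue mapping and
  transform as truth.
* `makeFingerprintBlobs` plants fingerprint clusters in disjoint bit ranges
  with guaranteed within/between similarity bounds.

`makeBenchmarkSet` assembles the screening benchmark: 50 diverse-shape
interface-cavity targets, each with a remote-homolog template (mutation
rate 0.78, coordinate noise 0.5 Å, 5% deletions, random rigid motion). The
generator redraws a homolog (fresh mutation seed) until its measured
identity to both target chains is at most 0.29, so the emitted set actually
satisfies its stated ≈25% remote-homolog condition — at the wall-residue
sequence lengths involved (60–120 residues), raw mutation sampling leaves
the realized identity with a standard deviation of several percent, and
without the redraw a third of "remote" templates would land above a 30%
identity cutoff by chance.

What the fixtures do *not* emulate: real secondary structure and side-chain
packing, crystallographic artefacts (symmetry contacts, disorder), chemically
realistic ligand geometry, and the long-tailed shape distribution of real
pockets. Passing the synthetic benchmark therefore demonstrates that the
machinery is correct and well-calibrated under its stated model — planted
signals are recovered through the full pipeline at the advertised
thresholds — not that screening performance on deposited structures will
match these numbers.

## Numerical choices and degenerate inputs

* Superposition is Kabsch (SVD) with a proper-rotation correction; fewer
  than 3 pairs or collinear inputs are an error rather than a silently
  arbitrary rotation. The test suite cross-checks against an independent
  quaternion (Horn) implementation.
* All ranking ties break deterministically (aligned length then RMSD for
  alignments; precision, p-value, identity, ligand code for predictions;
  code order for cluster centroids). Two runs with the same inputs and seeds
  are byte-identical.
* Grid detection on a model with 3 or fewer atoms returns an empty pocket
  list, not an error; screens of targets without interface-adjacent pockets
  return an empty prediction list carrying a reason attribute.
* p-values are clamped away from 0 so they remain in (0, 1]; features
  outside the calibration table clamp to edge bins.
* Validation problem sizes (chosen once as part of the study design): null
  model fitted on 1,500 pairs over 40 pockets and checked on 1,000 fresh
  pairs drawn from a separate pool of 60 pockets (a larger fresh pool keeps
  pair correlations from sharing pockets small); benchmark of 50 targets;
  calibration set of 30 positives / 80 negatives. The fraction of null
  pairs at p ≥ 0.05 is judged as consistency with the nominal 95% level
  within binomial sampling error, since under exactly uniform p-values the
  observed fraction fluctuates symmetrically around 0.95.

## Known limitations

Only bridging (interface-adjacent) glue mechanisms are modelled — allosteric
glues that act by exposing new surfaces are out of scope by design. Pockets
are treated as rigid; plastic pocket matching is not attempted. The
precision estimate is only as good as its calibration set, and the shipped
default is synthetic. Covalent linkage of ligands is not detected, and the
mining stage takes deposited coordinates at face value (no re-refinement,
no symmetry expansion).
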