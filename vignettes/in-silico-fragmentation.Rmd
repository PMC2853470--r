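---
title: "In silico fragmentation and candidate ranking: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico fragmentation and candidate ranking: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragrank)
```

## The identification problem

Given a tandem-MS peak list and the precursor mass of an unknown small
molecule, the question is which structure in a compound library the
spectrum belongs to. Instead of predicting a spectrum mechanistically,
`fragrank` enumerates all *topological* fragments of every candidate of
matching mass and scores the candidates by how well their fragments
explain the measured peaks. This vignette documents the models, the
tunable parameters, the synthetic-data design, and the numerical choices.

## The molecular graph

A molecule is a connected heavy-atom graph. Hydrogens are not vertices:
each heavy atom carries an attached-hydrogen count, because individual
hydrogen atoms are not considered during fragmentation (hydrogen motion
is handled separately by the neutral-loss rules, and matching compensates
with the ±proton step). Input structures (SMILES, InChI, SDF/MOL) are
normalized through Open Babel — explicit hydrogens, kekulized bonds —
and collapsed onto this representation. A bond is *in a ring* iff it lies
on a cycle (equivalently, iff it is not a bridge); ring membership is
re-perceived inside every fragment, since a ring bond of the parent can
become acyclic in a child.

## Fragment enumeration

One **cleavage event** is either the removal of a single acyclic bond
(producing two components) or the joint removal of an unordered pair of
in-ring bonds whose removal disconnects the current fragment. Ring pairs
are *not* restricted to one smallest ring: in fused systems any
disconnecting pair of ring bonds counts, and a connectivity test decides
validity. Each event advances the tree depth by one; `max_depth`
(default 2) bounds the number of successive events. This "one ring-pair
cut = one depth level" convention was an open choice; it matches the
interpretation that a depth-two tree reaches fragments created by two
dissociation steps, whichever kind each step is.

Finding the valid ring pairs by testing all bond pairs would dominate the
runtime. Instead, each fragment is analysed once against a BFS spanning
tree: a non-tree bond *covers* the tree bonds on the path between its
endpoints; a tree bond with empty cover is a bridge; `{tree bond, its
unique covering non-tree bond}` and pairs of tree bonds with identical
nonempty cover sets are exactly the 2-edge cuts. Only those few valid
cuts are then materialized by a component search.

**Pruning and redundancy.** Fragments below `min_mass` are dropped, and
since fragment mass only decreases along the tree, they are never
expanded either. The search itself deduplicates by *atom-index subset* —
lossless, because identical subsets have identical futures — while the
**reported** set is deduplicated under the configured redundancy mode:

* `molecular_formula` (default): fragments with equal elemental
  composition are one fragment; among duplicates the one with the lowest
  cumulative bond dissociation energy is kept (it is the more plausible
  route);
* `atom_id`: fragments are duplicates iff they are the same atom set of
  the parent (this misses equal substructures at different positions);
* `isomorphism`: canonical labelled-graph comparison (elements, H counts,
  charges, bond orders; orders encoded by subdividing each bond with a
  coloured dummy vertex for the canonical-labelling backend).

Separating search-level from report-level deduplication makes the output
provably equal to a brute-force enumeration of all connected subgraphs
reachable by at most `max_depth` cleavage events (the property the test
suite checks against an independent oracle); deduplicating the search by
formula instead could silently lose formulas whose only cheap
representative has a different child set than the kept one.

**Bond dissociation energies.** Each bond type (unordered element pair +
bond order) maps to a standard literature enthalpy (kJ/mol) from a
bundled, user-replaceable table; unlisted pairs fall back to a default of
348 kJ/mol (the C–C single-bond value) with a one-time warning. A
fragment's cumulative BDE is the sum over all bonds cleaved along its
path; where several routes reach the same fragment the cheapest is kept.

## Neutral-loss rearrangements

Some common losses — water above all — are not substructures: an OH group
and a hydrogen leave from *different* positions. Five bundled rules
(H₂O 18.0106, HCN 27.0109, NH₃ 17.0266, CH₂O 30.0106 in both ion modes,
HCOOH 46.0055 positive-only) each name a heavy-atom motif, a loss
formula, and a maximum topological distance (3 bonds) between the motif's
attachment atom and the donor hydrogen. The motifs are defined
structurally (OH = terminal oxygen with hydrogen; NH₂ = terminal nitrogen
with ≥2 H; CN = terminal nitrogen on a carbon; COH = carbon bearing a
terminal oxygen; COOH = carbon bearing two terminal oxygens) in one
registry that users can extend. Applying a rule removes the motif atoms
and the donor hydrogen; a removal that would disconnect the heavy-atom
graph is skipped; derived structures are deduplicated by formula and
enter the fragmentation queue as roots of their own trees. By default
rules apply only to the intact candidate: applying them to every fragment
multiplies the fragment count and demonstrably lowers the positive
predictive value (`ppv_study()` reproduces this ordering), so that mode
is available but off.

## Matching and scoring

Measured peaks are singly charged ions. A neutral fragment of mass *m*
is compared to a peak at *m* + 1.00728 Da in positive mode (displayed as
1.007) or *m* − 1.00728 Da in negative mode; a fragment with nonzero net
formal charge is compared at its mass as-is, with a penalty added to its
cumulative BDE (default: the largest value in the BDE table, so an
intrinsic charge is never cheaper than a cleavage). The error window is
`mzabs + mzppm·10⁻⁶·m` — the relative term models instrument accuracy,
the absolute term absorbs the low-mass regime where ppm alone is too
strict. Matching is interleaved with generation level by level; each peak
is explained at most once, by the lowest-effective-BDE fragment among
those within tolerance at the level where it is first reached (ties:
heavier fragment, then a fixed lexicographic key), and explaining the
smallest unexplained peak raises the minimum-mass cutoff.

The candidate score is

$$S_i = \frac{w_i}{\max_j w_j} \;-\; \frac{e_i}{2\,\max_j e_j},$$

with \(w_i = \sum_{\text{explained peaks}} \mathrm{int}^{0.6}\cdot
\mathrm{mz}^{3}\) (exponents m = 0.6, n = 3) and \(e_i\) the arithmetic
mean of the cumulative BDEs of candidate *i*'s explaining fragments.
The first term lies in [0, 1], the second in [0, 0.5], so
\(S_i \in [-0.5, 1]\). Candidates explaining nothing score 0; if no
candidate explains anything all scores are 0; if all BDE means are zero
the penalty term vanishes. The exact printed form of the published score
is not available in the source text; this reconstruction follows the two
stated normalizations and the stated direction of the BDE penalty, and is
isolated in `candidate_scores()` should a different form be preferred.

**Ranks.** The worst-case rank of a candidate counts every candidate
scoring at least as high, itself included — a ten-way tie at the top is
rank 10 for all of them. Within each identical-score group, candidates
with fingerprint Tanimoto similarity ≥ 0.95 collapse into one cluster by
single linkage ("collapsed into one cluster" reads as transitive closure;
complete linkage is available as an option), and the same pessimistic
convention over clusters gives the cluster rank, which can never exceed
the worst-case rank.

**Fingerprints.** The fingerprint hashes all linear heavy-atom paths of
up to 5 atoms (element and bond-order strings, read in their smaller
direction) into 1024 bits. It sees only connectivity, never
stereochemistry — deliberately, since MS cannot distinguish stereoisomers
and the clustering step exists precisely to collapse them. Any
connectivity-only fingerprint satisfies the ≥ 0.95 stereoisomer-collapse
property; the path family, length and width are configurable.

## Synthetic fixtures: what they emulate, and what not

Everything is generated offline and deterministically from seeds.

* **Toy molecules.** 30 structures spanning chains, rings, aromatics and
  C/H/N/O/S, each with an independently computed reference formula and
  monoisotopic mass frozen into the table. At least 20 of them yield six
  or more distinct depth-2 fragments above 30 Da (`fragmentable_toys()`),
  which is what a six-peak simulated spectrum requires.
* **Simulated spectra.** `n_peaks` = 6 by default, sampled from the
  molecule's own depth-2 fragment set with probability ∝ mass³ (the
  heaviest fragment always included), protonated, with optional Gaussian
  m/z noise (default 0) and log-uniform intensities over two decades
  (100–10000). The mass³ law mirrors the scoring model's view that
  high-mass peaks are the characteristic ones and the small-neutral-loss
  dominance of real CID spectra; uniform sampling would overweight small
  generic formulas (CH₂O and the like) that carry no structural
  information.
* **Isomer libraries** (`make_isomer_library()`): the target plus random
  connected structures over the target's own atom multiset with matching
  per-atom valences — exact isomers, emulating a high-accuracy exact-mass
  hit list such as a handful of structures sharing C₁₅H₁₂O₅.
* **Decoy libraries** (`make_decoy_library()`): the target plus random
  structures realizing CHNOS formulas enumerated within a low-accuracy
  search window (mzabs 0.01 Da + 50 ppm) around the target's neutral
  mass, excluding the target's own formula. Heteroatom–heteroatom bonds
  are avoided when a carbon partner exists, because peroxide- and
  hydrazine-like linkages are all but absent from compound libraries and
  their anomalously low bond energies would give synthetic decoys
  systematically cheaper fragment routes than any real candidate.

What passing the recovery study shows — and what it does not: with
zero-noise spectra and formula-distinct decoys, the true molecule is
recovered at worst-case rank 1; this validates the machinery (matching,
scoring, ranking, clustering) end to end. It does *not* predict
real-database performance. Against large libraries dominated by exact
isomers, ties at the top are expected and structurally unavoidable — an
isomer can reach the same fragment formulas, sometimes through cheaper
bonds — which is precisely why the pessimistic rank convention and the
similarity clustering exist. Sugar-like molecules, whose fragment
formulas are maximally generic, are the worst case.

## Numerical choices and degenerate inputs

* Monoisotopic masses throughout, from a bundled IUPAC/CODATA table;
  proton mass stored as 1.00728 Da.
* Composite spectra: peaks from different collision energies within
  0.01 Th merge to the group-mean m/z with the maximum intensity;
  chains of close peaks are clustered greedily in ascending m/z, which
  is deterministic and agrees with the pairwise rule on well-separated
  data. Merging is idempotent.
* The 75% quantile in rank summaries uses linear interpolation
  (`stats::quantile` type 7).
* Deterministic ordering everywhere: fragments sort by mass descending,
  then formula, then atom-subset key; dedup ties resolve by lower BDE,
  lower depth, then key.
* Degenerate inputs: a single-atom molecule has no cleavable bonds and an
  empty fragment set; an empty spectrum is a valid object but matching
  against it is an error; two all-zero fingerprints compare as similarity
  0 with a warning; candidates explaining no peak stay in the ranked
  output with score 0.
* Study sizes: the test suite runs the recovery study at its full size
  (20 molecules × 100 decoys, a few minutes on one core) and the PPV
  study, whose magnitudes are database-dependent anyway, as a scaled-down
  ordering check over 8 molecules at depths 2 and 3.

## Known limitations

* No mechanistic fragmentation chemistry: no charge-site modelling, no
  intensity prediction, no fragmentation-tree likelihoods.
* Single charges and ±H ions only; no Na⁺/K⁺ adducts, no isotope peaks.
* Stereochemistry is intentionally invisible end to end.
* Live compound-database retrieval is out of scope; the candidate-library
  interface is local, and a remote wrapper would implement the same
  contract.
* The BDE penalty uses average bond enthalpies, not structure-specific
  energies; it is a plausibility heuristic, not thermochemistry.
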