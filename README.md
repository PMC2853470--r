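# fragrank

Identification of small molecules from tandem mass spectra, without
spectral reference libraries.

Tandem MS fragment peaks carry structural information, but measured
reference spectra cover only a small part of chemical space. `fragrank`
takes the complementary route: candidate structures of matching precursor
mass are retrieved from a local compound library, fragmented *in silico*
by systematic bond disconnection, and ranked by how well their fragments
explain the measured peaks. The package is aimed at metabolomics and
small-molecule MS workflows where a precursor mass and an MS/MS peak list
are available and the question is *which* library structure the spectrum
belongs to.

## Method

**Fragmentation.** Every candidate is fragmented breadth-first: each
acyclic bond cleavage splits a fragment into its two connected
components; inside ring systems two ring bonds are cleaved simultaneously.
Hydrogens travel with their heavy atom. The tree is grown to a maximum
depth (default 2 cleavage events), fragments below a minimum-mass cutoff
are pruned, and redundant fragments are eliminated — by molecular formula
(default), by atom-index set, or by full labelled-graph isomorphism —
keeping, among duplicates, the fragment requiring the lowest cumulative
bond dissociation energy (BDE). Neutral-loss rules (H₂O, HCN, NH₃, CH₂O
in both ion modes; HCOOH in positive mode) handle rearrangements that
pure bond disconnection cannot reach: a pattern group and a donor
hydrogen within topological distance 3 are removed together.

**Matching.** A neutral fragment of mass *m* is matched to a measured
peak at *m* + 1.007 Da (positive mode) or *m* − 1.007 Da (negative mode);
intrinsically charged fragments match at their mass as-is with a BDE
penalty. The error window is `mzabs + mzppm · 10⁻⁶ · m`. Each peak is
explained at most once; explaining the smallest unexplained peak raises
the minimum-mass cutoff dynamically.

**Scoring.** Candidate *i* receives

  S_i = w_i / max(w) − e_i / (2 · max(e)),   S_i ∈ [−0.5, 1]

where w_i = Σ intensity^0.6 · mz³ over the peaks candidate *i* explains
(heavy, intense peaks are the characteristic ones) and e_i is the mean
cumulative BDE of its explaining fragments (energetically implausible
fragments are penalized). Ranks are reported pessimistically: with ties,
the correct candidate tied with nine others gets rank 10. Tied candidates
with fingerprint Tanimoto similarity ≥ 0.95 — typically stereoisomers,
indistinguishable by MS — collapse into one cluster, giving a *cluster
rank*.

## Worked example

Simulate a spectrum of naringenin (C₁₅H₁₂O₅, monoisotopic mass
272.068 Da), search a 15-structure isomer library at 10 ppm, and rank:

```r
library(fragrank)

toys <- toy_molecule_set()
nar  <- toys$mol[[match("naringenin", toys$name)]]

spec <- simulate_spectrum(nar, n_peaks = 6, mass_noise_sd = 0, seed = 17)
lib  <- make_isomer_library(nar, n = 14, seed = 17)
hits <- search_by_mass(lib, 272.068, ppm = 10)   # all 15 structures
res  <- rank_candidates(hits, spec,
                        params = match_params(mzabs = 0, mzppm = 10))
res[, c("id", "n_peaks_explained", "score", "rank", "cluster_rank")]
#>           id n_peaks_explained     score rank cluster_rank
#> 1 naringenin                 6 0.7596591    1            1
#> 2  ISOMER008                 5 0.5863648    2            2
#> 3  ISOMER001                 3 0.5238874    3            3
#> ...
```

The true structure explains all six peaks and ranks first; the nearest
isomer explains five. `glance(res)` summarizes the run (15 candidates,
12 tied-rank clusters, top score 0.76), `tidy(res)` returns the long
fragment–peak match table, and `autoplot(spec)` / `autoplot(res)` draw
the spectrum and the ranked score plot.

A thin command-line wrapper with `run`, `merge`, `fragment`, `simulate`
and `evaluate` subcommands ships in `inst/cli/fragrank.R`.

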