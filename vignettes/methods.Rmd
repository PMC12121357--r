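---
title: "Methods: ASV biogeography and under-ice community structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ASV biogeography and under-ice community structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`asvbiogeo` implements the community-analysis computations used to study
microbial eukaryote (18S rRNA V4) communities sampled from landfast Arctic
sea ice and the water column beneath it across an under-ice phytoplankton
bloom: matching study amplicon sequence variants (ASVs) to a global
reference occurrence corpus, classifying their latitudinal biogeography,
and quantifying community differences across substrates (ice/water), size
fractions and bloom stages with Bray–Curtis dissimilarity, ANOSIM and
indicator-value (IndVal) statistics. Because real sequencing data and the
full global reference corpus are large external resources, the package
ships a synthetic-data generator with planted ground truth; every claim the
test suite makes is a claim about recovering that truth or about agreement
with independent oracles.

# The synthetic study

`simulate_study()` emulates the field design: six depth layers (bottom
0–3 cm ice `ICE_0`, 3–10 cm ice `ICE_1`, four water depths
`WATER_1..WATER_4`), three sequential size fractions (pico 0.2–3 µm, nano
3–20 µm, micro 20–100 µm) and nine sampling dates between 2016-05-01 and
2016-07-18, spanning the three bloom stages (snow-covered stage I to
2016-06-03, snow-melt stage II to 2016-06-15, ice-melt stage III to
2016-07-18; boundary dates belong to the later stage). Stage I samples are
the "dark phase", stages II–III the "light phase". Both stage-boundary
dates are in the default grid so the half-open intervals are exercised.

Counts follow a log-normal/multinomial compositional model. Each taxon
draws a base abundance from a log-normal with `sigma_log = 1.5` on the log
scale — enough spread to reproduce the strong dominance/rarity structure of
amplicon communities without modelling any ecology. Sample totals are
Poisson around `library_size` (default 50 000 reads) and split
multinomially. Planted indicator taxa have their expected abundance
multiplied by `affinity_effect` (default 8) in their preferred substrate
(ice or water) or bloom phase (dark or light). Affinities are planted among
the most abundant photosynthetic taxa: substrate specialists in these
systems are the community dominants, and the indicator screen only examines
top-abundance ASVs, so rare planted indicators would be untestable by
construction.

Taxonomy strings are drawn from a fixed catalogue of real lineages
(diatoms, mamiellophytes, haptophytes, cryptophytes, pelagophytes,
bolidophytes, plus heterotrophic ciliates, syndinians and labyrinthulids
and mixed-mode dinoflagellates), weighted so roughly three quarters of taxa
are photosynthetic. The companion trophic lookup
(`default_trophic_lookup()`) mixes class-level and genus-level entries so
the deepest-rank matching rule in `filter_photosynthetic()` is genuinely
exercised.

Microdiversity is planted as `ecotype_pairs` sequence pairs differing at
exactly one internal base (positions restricted to the middle half of the
amplicon), mirroring ice/pelagic ecotype pairs observed in cryptophytes.
Such pairs must never co-cluster: exact-identity matching treats a single
mismatch as a different variant.

# The synthetic reference corpus

`simulate_reference()` builds a scaled-down analogue of a global
metabarcoding occurrence database: `n_ref_samples` (default 400) reference
samples with latitudes drawn per `zone_mix` (default 30% polar, 45%
temperate, 25% tropical) across eight dataset identifiers. A fraction
`ref_fraction` (default 0.85) of study taxa have one reference counterpart
each — an exact copy, a truncation (5–20 nt off each end) or a flank
extension of the study sequence — so overlap clustering faces all three
match geometries. Ecotype-pair members always get exact copies: a
truncation could remove the single diagnostic base and merge the pair
artificially.

Each reference-represented taxon occurs in samples of its true zone with
probability `ref_presence = 0.8` and elsewhere with probability
`stray_rate = 0.005`. The stray default models contamination-level
out-of-zone detections (about one expected stray per taxon in a 300-sample
corpus); per-sample stray probabilities of a few percent would make
out-of-zone records scale linearly with corpus size, which is not what
zone-restricted taxa look like in curated occurrence databases. One polar
station is re-occupied ~25 times within a single dataset, centred on a
0.1° grid point with ±0.02° jitter, to exercise geographic deduplication.

Study-only taxa (no reference counterpart) and taxa with fewer than five
deduplicated occurrences have planted label "unallocated".

# Sequence clustering into cASVs

Two sequences match (`overlap_match()`) when one is an exact substring of
the other, or a suffix of one equals a prefix of the other over at least
`min_overlap` nucleotides with zero mismatches. Matching is gapless:
denoised amplicons of one locus differ by primer trimming, not indels. The
default `min_overlap = 100` nt prevents spurious short-overlap joins
between unrelated sequences; the relation is symmetric and reflexive but
not transitive, which is why clustering semantics matter.

`cluster_asvs()` first merges reference–reference matches by connected
components, then assigns each study ASV to the cluster of a matching
reference sequence. A study ASV matching several reference clusters joins
the best-sampled one, where a cluster's weight is the summed study reads of
*all* study ASVs matching it — a definition chosen because it is invariant
to input order (assigning by previously-joined members would not be); ties
break by lexicographically smallest cluster id. Study ASVs with no
reference match become singleton cASVs. Whether a reference database's own
clustering merges reference variants transitively is not observable from
here; connected components is the conservative choice and is pinned by a
brute-force all-pairs + union-find oracle in the tests.

The implementation prunes the all-pairs matching with an exact-substring
anchor screen (any qualifying match implies one sequence contains the
other's first-`min_overlap` or last-`min_overlap` substring), which is a
pure optimisation: candidate pairs are re-verified with the full rule.

# Biogeographical classification

Occurrences are deduplicated within (cASV, dataset, 0.1°-rounded latitude
and longitude): repeated samplings of one station — typical of time-series
datasets — count once. The 0.1° default (~11 km) absorbs GPS jitter at a
re-occupied station without merging distinct stations; the retained record
is the lexicographically smallest sample id, making output independent of
row order. The five-occurrence floor is applied *after* deduplication, so a
30-visit time series at one station contributes one occurrence toward it.

Latitudes bin into polar (|lat| ≥ 66), temperate (23 ≤ |lat| < 66) and
tropical (|lat| < 23); boundary values go poleward (66 is polar, 23
temperate). Categories follow occupancy rules evaluated in order:
unallocated below five occurrences; polar, temperate or tropical when one
zone holds ≥ 90% of occurrences; polar-temperate or temperate-tropical when
the zone pair holds ≥ 90%; cosmopolitan when all three zones are occupied
with no dominance. Single-zone rules are evaluated before the two-zone
combinations — otherwise a 100%-temperate profile would be labelled
polar-temperate, contradicting the meaning of the categories. All 90%
comparisons are non-strict (≥), and combined-zone shares are computed from
summed counts rather than by adding single-zone fractions, so a 9-of-10
profile hits the boundary exactly in floating point. A polar + tropical
mixture with an empty temperate band satisfies no rule; it is reported
unallocated with a warning (it cannot occur under the planted truth, but
real corpora could produce it). Within "polar", Arctic and Antarctic are
deliberately not distinguished.

# Community structure

Species-level relative abundances divide aggregated counts by per-sample
totals; all-zero samples yield all-zero rows plus a warning rather than
NaN. Key taxa are the smallest prefix of species, ranked by total reads
(ties by name), whose cumulative share reaches the coverage target
(default 75%).

Bray–Curtis dissimilarity, d(a,b) = 1 − 2·Σmin(aᵢ,bᵢ)/(Σaᵢ+Σbᵢ), is
computed by `vegan::vegdist()` behind `bray_curtis()`; pairs of all-zero
samples are undefined and set to 0 with a warning. ANOSIM is implemented
in-package: with all off-diagonal dissimilarities ranked (ties averaged),
R = (mean between-group rank − mean within-group rank) / (n(n−1)/4), the
standard normalisation that puts R in [−1, 1] with R = 1 at complete
separation. The permutation p-value is one-sided,
p = (#{permuted R ≥ observed} + 1)/(n_permutations + 1), never below
1/(n_permutations + 1), and seed-reproducible. The test suite cross-checks
the statistic against `vegan::anosim` on random communities.

# Indicator analysis

The "default IndVal" is interpreted as the group-size-corrected form:
specificity A = (mean abundance in the target group) / (sum of group mean
abundances), fidelity B = fraction of target-group samples where the ASV is
present, statistic √(A·B). Group means rather than pooled sums keep A
unbiased under unequal group sizes (ice and water have different sample
counts). Abundances entering A are per-sample relative abundances, since
library sizes differ; the statistic is invariant to global rescaling. An
ASV absent everywhere has undefined A and is reported with statistic 0 and
a flag.

The permutation test permutes group labels uniformly (no stratification)
and recomputes the *best-group* statistic each time, so the p-value
accounts for selecting the most-associated group; equality of permuted and
observed statistics is accepted within 1e-12 so a constant taxon attains
p = 1 exactly. The screen takes the 20 most abundant photosynthetic ASVs
(per comparison: substrate, then phase), stars raw p-values at
0.05/0.01/0.001, and emits a Holm-adjusted column for reference without
using it for the flags, matching how such screens are conventionally
reported.

One behaviour of relative-abundance indicators is worth knowing:
compositional coupling. Boosting some taxa in light-phase samples
depresses every other taxon's *relative* abundance there, so abundant
neutral taxa can legitimately test as dark-phase-associated. This is a
property of compositional data, not an artefact of the implementation, and
the type-I simulation (no planted effects anywhere) confirms the test holds
its nominal size when the null is actually true.

# Problem sizes and numerical choices

Routine validation uses deliberately scaled-down corpora: ~40–60 taxa and
150–300 reference samples in the unit and recovery tests, 1000 null ASVs at
999 permutations for the type-I study, 100 replicate datasets for the power
study, and the full default configuration (150 taxa, 400 reference samples,
9999 permutations) for the workflow scripts. These sizes were chosen as the
smallest at which the statistical claims are meaningful — binomial error on
a 5% rate at n = 1000 is ±1.8 percentage points at 99% confidence — while
keeping any single study re-runnable in minutes on a laptop.

Determinism is treated as a contract: the generator is a pure function of
its configuration (study and reference draw from independent sub-streams
derived from the master seed), every permutation test takes an explicit
seed, and output files carry a provenance header (package version,
configuration hash, seed) but no timestamps, so a rerun reproduces every
artifact byte for byte.

# What passing tests do and do not show

The generator plants clean, strong structure: single-zone biogeography
labels, single-taxon affinities with an 8-fold effect, one reference
variant per taxon, no sequencing error, no chimeras, no environmental
covariates. Passing recovery tests therefore demonstrates that the
*computations* are correct and well-calibrated, not that real communities
yield such clean signals: real reference corpora have uneven geographic
coverage, real effect sizes vary, and real taxa may have genuinely
intermediate distributions that the ≥ 90% rules split on sampling noise.
The unallocated category absorbs exactly the cases the rules cannot
support, which is the conservative behaviour wanted in practice.
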