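# asvbiogeo

Community analysis of 18S rRNA V4 amplicon sequence variants (ASVs) from
Arctic sea ice and the under-ice water column: where do the members of a
sympagic / under-ice-bloom community occur globally, and which of them are
indicators of a substrate (ice vs water) or bloom phase (dark vs light)?

The package is aimed at microbial ecologists working with
metabarcoding-derived ASV tables who want to reproduce, test or adapt this
style of analysis. It implements:

- **cASV clustering** — study ASVs are matched to a global reference
  occurrence corpus by 100% identity over their overlap region (exact
  substring, or suffix/prefix overlap ≥ 100 nt with zero mismatches), so
  variants trimmed to different primer boundaries merge while
  single-base-pair ecotypes stay apart.
- **Biogeographical classification** — reference occurrences are
  deduplicated by geographical point (within dataset, 0.1°), binned into
  latitudinal zones (polar |lat| ≥ 66°, temperate 23–66°, tropical < 23°),
  and each cASV gets a category by occupancy rules: one zone ≥ 90% →
  polar / temperate / tropical; a zone pair ≥ 90% → polar-temperate /
  temperate-tropical; all three zones occupied → cosmopolitan; fewer than
  5 occurrences (or no reference match) → unallocated.
- **Community structure** — bloom-stage assignment from sampling dates,
  photosynthetic filtering via a trophic-mode lookup, species-level
  relative abundances, minimal key-taxa sets covering 75% of reads,
  Bray–Curtis dissimilarity d(a,b) = 1 − 2·Σmin(aᵢ,bᵢ)/(Σaᵢ+Σbᵢ), and
  ANOSIM, R = (r̄_between − r̄_within)/(n(n−1)/4) with a one-sided
  permutation p.
- **Indicator analysis** — group-size-corrected IndVal: specificity
  A = mean abundance in the target group over the sum of group means,
  fidelity B = presence fraction in the target group, statistic √(A·B),
  tested by label permutation (default 9999 permutations).
- **Synthetic data with planted truth** — a generator that emulates the
  study design (2 ice layers + 4 water depths × 3 size fractions × 3 bloom
  stages) and a global reference corpus, with planted biogeography labels,
  indicator taxa and single-mismatch ecotype pairs, so every stage can be
  validated against known ground truth.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the
default synthetic configuration (150 ASVs, 162 samples, 400-sample
reference corpus, seed 1), writing tables under `results/run/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_cluster.R
Rscript analysis/03_biogeography.R
Rscript analysis/04_community.R
Rscript analysis/05_indicators.R
Rscript analysis/06_report.R
```

which prints, stage by stage:

```
simulated 150 study ASVs over 162 samples (126 with reference counterparts)
reference corpus: 400 samples, 14297 occurrence records
planted: 3 ecotype pairs; affinities: dark=6, ice=13, light=7, none=111, water=13

150 study ASVs -> 150 cASVs (126 matched to the reference, 24 study-only)

cASV categories:
      polar   temperate    tropical unallocated
         41          52          33          24
planted zone labels recovered: 100.0% (126/126 eligible taxa)

110 of 150 ASVs are photosynthetic/mixotrophic
14 species jointly hold 75.4% of the photosynthetic reads
ANOSIM substrate      R =  1.000  p = 0.0001
ANOSIM size_fraction  R = -0.012  p = 0.9759
ANOSIM phase          R =  0.501  p = 0.0001
ANOSIM stage_ice      R =  0.655  p = 0.0001
ANOSIM stage_water    R =  0.688  p = 0.0001

screened 20 ASVs x 2 comparisons at 9999 permutations
substrate: 5 ice, 8 water
phase: 2 dark, 6 light
19 flagged associations coincide with planted affinities
```

Reading the output: every planted latitudinal label was recovered by the
clustering + classification chain (the 24 study-only cASVs are correctly
unallocated); communities separate perfectly by substrate (ANOSIM R = 1 —
the planted 8-fold ice/water effects dominate) and strongly by bloom stage
within each substrate, while size fraction — to which no effect was
planted — shows R ≈ 0; and the indicator screen flags substrate/phase
associations that overwhelmingly coincide with the planted affinities.
Equivalent function-level access: `run_pipeline(run_config(seed = 1))`.

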