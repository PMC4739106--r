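# codhoming

Genetic assignment and philopatry testing for tagged Atlantic cod.

Atlantic cod (*Gadus morhua*) in the eastern North Sea–Skagerrak–Kattegat
area show weak but stable genetic structure between the North Sea/western
Skagerrak and Kattegat spawning regions, while their pelagic larvae drift
freely between them. Whether adults actively migrate back to the
population they belong to — philopatry — is the question this package's
pipeline answers from three data streams: microsatellite genotypes of
spawning reference samples, genotypes of archival-tagged fish, and the
tags' daily longitude geolocations. It is aimed at population geneticists
and fish ecologists who want the full inference chain — population
structure, individual assignment, behaviour classification, exact
independence test — as small composable functions on tibbles.

## What it computes

* **Genotype I/O**: Genepop reader/writer (2/3-digit dialects), locus-panel
  subsetting, sample pooling, track and metadata CSVs.
* **Population structure**: allele frequencies; observed and Nei's
  unbiased expected heterozygosity and allele counts (Table-2-style
  panels); a per-allele Hardy–Weinberg screen using F_IS = 1 − Ho/He and
  X² = n·F_IS² with df = 1 (the literal n·F_IS form is a switch);
  Weir–Cockerham θ with multilocus ratio-of-sums combination
  θ = Σa / Σ(a+b+c); individual-permutation significance with
  p = (1 + #{θ* ≥ θ})/(R+1); pairwise θ matrices; year-class stability;
  classical MDS of pairwise θ (negative cells clamped to zero).
* **Assignment**: pooled-reference allele counts; Rannala–Mountain-style
  Dirichlet posterior-predictive genotype likelihoods (frequency criterion
  as a switch); leave-one-out self-assignment; Monte-Carlo exclusion test
  (rank of the fish's likelihood among simulated genotypes, +1-corrected);
  reference-subsampling robustness.
* **Behaviour**: validation of daily longitude series (a new location
  needs ≥3 consecutive estimates departing >1° from the current valid
  longitude), days at liberty (>30 strict filter), and classification
  into the five behavioural groups (Skagerrak→North Sea, Kattegat→North
  Sea, Skagerrak→Kattegat, nonmigratory Skagerrak/Kattegat) via the
  west-of-10°E rule and a configurable Skagerrak/Kattegat boundary.
* **Philopatry**: the migration-direction × assignment 2×2 table; Fisher's
  exact test by direct hypergeometric enumeration; **Boschloo's
  unconditional exact test** — Fisher's p as statistic, maximised over the
  common success probability on a ≥1001-point grid with refinement,
  treating the two direction groups (n₁ = 3, n₂ = 32 in the study) as
  fixed binomial samples.
* **Synthetic data**: a Balding–Nichols generator (population frequencies
  ~ Dirichlet(p⁰(1−F)/F)) for references, tagged cohorts with known
  origins and a philopatry probability φ, and noisy daily-longitude tracks
  — so the entire pipeline runs and is tested with no external data.
* **Pipeline**: `run_pipeline()` drives every stage from one config (R
  list or YAML) and writes diversity, pairwise-θ, MDS, assignment,
  contingency and subsampling tables plus a JSON run report, all
  byte-reproducible for a fixed seed.

## Worked example

The packaged example config simulates two reference pools (n = 120 each,
F_ST target 0.02, 12 loci × 15 alleles) and 40 tagged fish at φ = 0.9,
then runs the whole chain:

```r
library(codhoming)
cfg <- system.file("extdata", "example_config.yaml", package = "codhoming")
run <- run_pipeline(cfg)
run
#> codhoming pipeline run
#>   reference: Kattegat (n=120), NorthSea_WSkagerrak (n=120)
#>   global theta = 0.0260 (P = 0.005)
#>   philopatry: Boschloo P = 0.0288 (Fisher statistic 0.07692)
```

The global 8-locus θ of 0.026 (permutation P = 0.005 at 199 reps) recovers
the simulated divergence; self-assignment sends 96% of Kattegat and 93% of
North Sea/W Skagerrak reference fish home:

```r
run$self_assignment$summary
#> # A tibble: 2 × 6
#>   group                   n n_Kattegat n_NorthSea_WSkagerrak prop_Kattegat prop_NorthSea_WSkagerrak
#> 1 Kattegat              120        115                     5        0.958                  0.0417
#> 2 NorthSea_WSkagerrak   120          8                   112        0.0667                 0.933
```

Of the 40 tagged fish, 13 were directional migrants; migration direction
and genetic assignment are not independent (one-sided Boschloo P = 0.029,
embedded Fisher statistic 0.077) — the simulated philopatry is recovered:

```r
run$contingency
#>                      direction
#> assigned              towardsKattegat towardsNorthSea
#>   Kattegat                          2               2
#>   NorthSea_WSkagerrak               0               9
tidy(run$boschloo)
#> # A tibble: 1 × 5
#>   method   sided      p fisher_p pi_argmax
#> 1 boschloo one   0.0288   0.0769     0.271
```

The same functions work directly on data frames, e.g. the published
contingency table of the 35 migrating study fish:

```r
tab <- matrix(c(3, 0, 12, 20), nrow = 2,
              dimnames = list(c("Kattegat", "NorthSea_WSkagerrak"),
                              c("towardsKattegat", "towardsNorthSea")))
boschloo_test(tab)$p
#> [1] 0.03098441
```

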