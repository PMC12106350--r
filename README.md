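# queenline

Colony genetic structure inference for multi-queen ants from
codominant microsatellite genotypes.

Social insect colonies often contain several mated queens whose
reproductive roles — who actually lays the eggs, who was replaced by a
daughter, who walked in from another nest — cannot be observed
directly. Under **haplodiploidy** (daughters carry their father's
single allele plus one maternal allele at every locus) and
**monandry** (one mate per queen, so one mother defines one
full-sister brood), those roles can be reconstructed from
microsatellite genotypes of sampled workers and collected queens.
`queenline` implements that reconstruction as a tested, reproducible
pipeline for researchers studying queen turnover, functional monogyny
and social parasitism in ants and other haplodiploid systems.

## What it computes

* **Minimal sibship partition** — the smallest number of monandrous
  mother queens explaining a colony's offspring genotypes, by branch
  and bound over set partitions with exact per-locus parental
  inference (`min_sibship_partition()`, `infer_parents()`); all
  minimal solutions are enumerated and irreducible ambiguity is
  flagged rather than resolved arbitrarily.
* **Queen matching and typing** — reconstructed mothers are compared
  with collected queens; queens become type 1 (former mother, inferred
  only), 2a (developed ovaries, mother of sampled offspring), 2b
  (developed ovaries, no sampled offspring) or 3 (undeveloped
  ovaries), and nests become type A (one contributor ever), B
  (several contributors present) or C (several contributors, at most
  one present).
* **Queller–Goodnight relatedness** — symmetrized ratio-of-sums
  pairwise estimates and unbiased pooled group means, with queen-pair
  category labels (1–1, 1–2, …, 3–3) ready for downstream
  distribution tests.
* **Breeder-detection power** — the exact probability that `n`
  sampled workers reveal all `k` breeders with contribution fractions
  `p`, by multinomial inclusion–exclusion
  (`detection_probability()`): for 8 workers, 99.2% for two equal
  breeders, 90.0% for a 75/25 split, 88.3% for three equal breeders.
* **Truth-tracked simulation** — a generator of synthetic colonies
  (queen turnover, co-breeding, unrelated adoptees, rare triploid
  brood, the 8-locus panel with 5–23 alleles per locus) whose full
  pedigree is retained, so every inference stage is testable without
  any external data.

## Worked example

```r
library(queenline)

ds <- generate_dataset(sim_config(n_colonies = 8, seed = 11))
ds$table
#> <genotype_table> 124 individuals, 8 colonies, 8 loci
#>   queens: 60, workers: 64, triploid: 0, low coverage (<7 loci): 0

freqs  <- estimate_allele_frequencies(ds$table)
recons <- reconstruct_colonies(ds$table, freqs = freqs)
recons[["c06"]]
#> <colony_reconstruction> c06: minimum 3 sibship(s), 1 reconstructed
#>   mother(s), 0 extra queen(s)

classes <- classify_colonies(recons, ds$table)
classes$summary[, c("colony_id", "nest_type", "n_type1", "n_type2a",
                    "n_type2b", "n_type3", "extra_queens")]
#>   colony_id nest_type n_type1 n_type2a n_type2b n_type3 extra_queens
#> 1       c01         C       0        0        1       1            2
#> 2       c02         A       0        1        0       4            0
#> 3       c03         B       0        2        1       4            0
#> 4       c04         C       0        0        1       5            2
#> 5       c05         A       0        1        0       6            0
#> 6       c06         C       1        1        0      13            0
#> 7       c07         A       0        1        0       6            0
#> 8       c08         B       0        2        0      10            0
```

Reading the output: colony c06 needed three mothers for its sampled
offspring; one reconstructed mother matched no collected queen — a
former mother (type 1) whose daughters are still in the nest — while
one collected queen with developed ovaries was matched as a current
egg-layer (2a), and the remaining 13 collected queens are non-layers
(type 3). Two or more queens contributed but at most one is present,
so the nest is type C, the turnover signature. Colonies c02, c05 and
c07 are single-contributor type A nests; c01 and c04 carry
contributor counts only through small sibships (anonymous "extra"
queens).

Relatedness by queen-pair category and detection power:

```r
pairs <- pairwise_queen_relatedness(classes$queens, freqs)
aggregate(r ~ category, pairs, function(x) round(median(x), 3))
#>   category     r
#> 1      1-2 0.293
#> 2      1-3 0.289
#> 3      2-2 0.404
#> 4      2-3 0.477
#> 5      3-3 0.498

detection_probability(c(0.5, 0.5), n = 8)   # 0.9921875
detection_probability(c(0.75, 0.25), n = 8) # 0.8998718
detection_probability(rep(1, 3) / 3, n = 8) # 0.8834019
```

`run_pipeline(run_config(...))` chains simulate → reconstruct →
classify → relatedness into one run directory (`data.csv`,
`recon.json`, `classes.csv`, `pairs.csv`, `report.json`), and
`recovery_study()` measures truth recovery across scenario grids. A
thin command-line wrapper lives at `inst/scripts/queenline.R`
(subcommands `simulate`, `convert`, `run`, `power`).

## Scope

Input is a tidy genotype CSV (one row per individual × locus; see
`read_genotype_table()`). Marker quality control (null alleles,
stutter, Hardy–Weinberg checks) is assumed done upstream —
`export_genepop()` writes the standard input for such tools — and
downstream hypothesis tests on the emitted tables (dip tests,
rank-sum comparisons, (G)LMs) are deliberately left to standard
statistical software. See the methods vignette
(`vignettes/colony-structure-methods.Rmd`) for the model, design
decisions and limitations.
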