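---
title: "Inferring multi-queen colony structure from microsatellites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring multi-queen colony structure from microsatellites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(queenline)
```

## The inference problem

Many ants keep several mated queens per nest, yet in some species only
one of them lays eggs (functional monogyny), queens are replaced by
their own daughters (serial turnover), and nests occasionally adopt
unrelated queens. None of this is visible from a census: it must be
read out of codominant marker genotypes. `queenline` implements that
readout for microsatellite data under two biological assumptions that
hold for the study system it targets:

* **haplodiploidy** — females are diploid, males haploid, so every
  daughter carries her father's single allele at every locus plus one
  of her mother's two alleles;
* **monandry** — each queen mates once, so one mother defines one
  full-sister brood ("sibship") and all of its members share the
  paternal allele wherever it can be distinguished.

Given the genotypes of a colony's sampled workers and collected
queens, the pipeline answers four questions: how many mothers are
*required* to explain the genotypes; which collected queens are those
mothers, relatives of them, or strangers; what that implies for the
colony's social organization; and how likely the worker sample was to
reveal every breeder in the first place.

## Parental solutions at one locus

For a candidate sibship the per-locus inference enumerates every
(mother pair, father allele) combination consistent with all members.
Internally a solution set is stored as pairs $(f, R)$ where $f$ is
the father allele and $R$ the set of maternal alleles the members
*demonstrate* ($|R| \le 2$); when $|R| = 1$ the mother's second
allele is unconstrained and is reported as such. Adding a member can
only delete solutions or grow $R$, which makes the representation
exact under incremental updates — the property the partition search
relies on. A locus typed in no member imposes no constraint, and
(following the least-assumption rule) a locus missing in one member
constrains only the others.

Two honest ambiguities deserve note, because they are properties of
the data, not of the algorithm. If every member shows the same
heterozygous genotype $\{a, c\}$, the mother may be $\{a,c\}$,
$\{a,a\}$ or $\{c,c\}$; and if the mother is homozygous the offspring
pattern $\{m, f\}$ admits three readings. With three or more members,
eight loci and realistic allele numbers these cases are common enough
that demanding a *uniquely* determined mother genotype at every locus
is a strong condition — the package therefore distinguishes carefully
between what offspring alone determine and what a collected queen's
own genotype resolves (below).

## Minimal sibship partitions

The number of queens needed to explain a colony is the minimal number
of blocks in a partition of its offspring into compatible sibships.
Collected queens enter the offspring pool too: they may be daughters
of other queens. The search is branch and bound over set partitions
in restricted-growth order, with individuals visited
most-constrained-first, a pairwise-compatibility prefilter, and exact
per-locus solution filtering at every step; *all* block-minimal
partitions are returned. For small instances an exhaustive enumerator
over every set partition (pruning only provably infeasible blocks,
which is sound because adding a member never restores compatibility)
serves as the oracle; the test suite checks the two agree on hundreds
of random colonies of up to 10 offspring, where the exhaustive side
of the comparison is itself validated against a completely unpruned
enumeration at small sizes.

Block count alone is not the biological objective, though. A mother
and any single daughter share an allele at every locus, so a
block-minimal partition can always be rearranged to seat a collected
mother as the "sister" of one of her own workers. These rearrangements
tie on block count but differ in how many *queens* they require once
matching is done. `reconstruct_colony()` therefore evaluates every
block-minimal partition — reliability rule, queen matching,
extra-queen accounting — and reports the one minimizing the net
number of identified contributors. A colony is flagged ambiguous only
when several contributor-minimal partitions disagree structurally,
mirroring the practice of excluding colonies that two independent
readings cannot reconcile, while keeping the flag rare enough to be
informative.

## Reliability, matching, and queen accounting

A mother genotype is *emitted* (as a virtual, type-1 queen if nobody
matches it) only from sibships with at least `min_offspring = 3`
members and a uniquely determined mother pair at every typed locus.
Smaller or ambiguous sibships are recorded solely as the minimum
number of additional queens required.

Collected queens are matched against the per-locus *alternative*
mother-pair sets of every sibship with three or more members: a queen
matches when her genotype is among the alternatives at each locus
constrained by the offspring and typed in her. Where the offspring
determine the mother uniquely this is plain identity; where they do
not, the queen's own genotype supplies the missing information — the
inferred-versus-actual comparison that motivates collecting queens at
all. A queen can never claim the sibship she is a member of. Queens
that match nothing are relatives of a reconstructed mother when their
maximal Queller–Goodnight relatedness to one reaches
`threshold = 0.25`, unrelated when below, and unresolved when typed at
fewer than 7 of 8 loci or when there is nothing to compare against.

Extra-queen accounting then applies three exclusions, each of which
prevents a phantom contributor: a sibship claimed by a matched
developed-ovary queen is her contribution, not an anonymous extra; a
block consisting solely of queens already matched as mothers is
explained by motherhood; and a lone collected queen in her own
singleton block is nobody's sampled offspring — her parents need not
be colony breeders at all (this is where adopted queens and turnover
survivors land, and counting them would push nearly every multi-queen
nest into the multiple-contributor classes).

Queen types follow: **1** former mother (emitted, unmatched), **2a**
collected, developed ovaries, matched; **2b** collected, developed
ovaries, no sampled offspring; **3** undeveloped ovaries regardless of
relatedness. Nest types: **A** exactly one contributor ever; **B**
two or more contributors still present; **C** two or more
contributors with at most one present. Contributors are types 1 and
2a plus the anonymous extras, which by construction can never be
"present".

## Relatedness

Pairwise relatedness uses the Queller–Goodnight moment estimator in
its symmetrized ratio-of-sums form: per-locus numerator and
denominator terms are computed with each individual as focal, grouped
per locus (which makes the estimate bit-identical under argument
swap), summed over loci, and divided once. Undefined denominators
propagate as missing, never as zero. An independent term-by-term
transcription of the published formula is kept in the test suite and
must agree with the production implementation to 10⁻¹².

Group summaries (`qg_mean_relatedness()`) pool numerators and
denominators over all pairs before the single division — the
estimator's own aggregate form. The distinction matters: with eight
loci the average of per-pair *ratios* is biased low by roughly 0.005
for close kin, several Monte-Carlo standard errors at 10,000 pairs,
whereas the pooled form is unbiased. The package's calibration checks
(full sisters 0.75, mother–daughter 0.5, strangers 0) use the pooled
form with allele frequencies estimated from the analyzed individuals
themselves, as an empirical study would.

Triploid offspring of diploid-male matings are collapsed to the two
smallest distinct alleles (configurable to the two largest; discarded
call counts are reported) for frequency estimation, matching and
relatedness. For the partition search, however, three-allele loci are
treated as uninformative: the haploid-father decomposition simply
does not apply there, and collapsing first can discard the shared
paternal allele and inflate the minimal queen count — treating the
locus as missing preserves the guarantee that the reconstructed
minimum never exceeds the true number of parental groups.

## Breeder-detection power

With contribution fractions $p_1, \dots, p_k$ and $n$ sampled
workers, the probability that every breeder is represented by at
least one worker is the inclusion–exclusion sum
$P = \sum_{S \subseteq \{1..k\}} (-1)^{|S|} (1 - \sum_{i \in S} p_i)^n$;
for a general threshold $m$ an exact truncated-multinomial
convolution is used, and the two routes must agree at $m = 1$. At the
package defaults ($n = 8$) this reproduces the design numbers for an
8-worker sample: 99.2% for two equal breeders, 90.0% for a 75/25
pair, 88.3% for three equal breeders. The analytic model ignores
genotypic indistinguishability between breeders; the simulation
pipeline measures that empirically, which is why recovery fractions
sit below the detection bound when marker diversity is poor.

## The synthetic-colony generator

`generate_dataset()` emulates the sampling design the analysis
expects: 33 colonies, 2–15 collected queens each (a truncated
geometric with median 4), 8 genotyped workers per colony, and an
8-locus panel with 5, 22, 12, 4, 23, 14, 8 and 5 alleles under flat
Dirichlet frequencies. Each colony has a founding queen and her
haploid mate; with probability `prob_queen_turnover` (default 0.6)
the founder is absent at sampling and one or more daughters breed
with independent mates; with `prob_multiple_breeders` (0.35) several
queens contribute, with symmetric-Dirichlet weights (skew
configurable, e.g. the 75/25 power scenario); non-breeding queen
slots are filled by native daughters (undeveloped ovaries) or, with
`prob_unrelated_adoptee` (0.15), by unrelated adoptees carrying their
own mitochondrial label; with `prob_triploid_brood` (0.03, about one
colony per study) a brood is sired by a diploid male. The turnover,
adoption and co-breeding rates are free parameters of the generator —
the study system provides no estimates — chosen once to produce a
realistic mixture of nest types; they are study conditions, not
tuning knobs. Every dataset carries a full truth record (pedigree,
breeder set, true queen and nest types) for recovery studies.

What the generator does *not* emulate: genotyping error and allele
dropout, null alleles and stutter, mutation, population structure
among colonies, polyandry, male offspring, and multi-year dynamics.
Passing recovery tests on synthetic data therefore demonstrates the
correctness of the inference machinery under the stated model, not
robustness to scoring artefacts — marker quality control is assumed
to have happened upstream (the GenePop export exists to feed such
checks).

## Numerical choices and scales

Determinism: every stochastic entry point takes or derives from a
single seed, and the pipeline writes byte-identical outputs under
identical configuration — the test suite checks this by hashing run
directories. Packed-integer encoding of per-locus solution sets keeps
the search allocation-free in the hot path; allele sizes are
validated below 2¹⁶ to make the packing exact. Exhaustive
enumeration is capped at 10 offspring (Bell(10) = 115,975
partitions). The calibration checks in the test suite use 10,000
pairs for the relatedness anchors, 200 random colonies for the
search-oracle comparison, and two 15-colony datasets for recovery —
sizes chosen so the whole suite stays comfortably desk-scale.

## Known limitations

* Identifiability, not the algorithm, limits queen typing: a
  homozygous mother's sibship cannot be uniquely reconstructed from
  offspring alone, so virtual (type-1) mothers are only emitted where
  the data genuinely pin them down; elsewhere contributors appear as
  anonymous extras. The recovery study's confusion matrices quantify
  this honestly.
* Two genuinely interchangeable minimal partitions (a worker
  compatible with both matrilines) are reported as ambiguity, as they
  should be; rates rise as marker diversity falls.
* The extra-queen rules are parsimony conventions. A lone queen block
  could in reality be the sole survivor of an unsampled sibship; the
  package prefers the reading that invents no unseen breeder.
* Relatedness categories for virtual queens use reconstructed
  genotypes, which at ambiguous loci are partially unknown; pairs are
  flagged `virtual` so downstream analyses can separate them.
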