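---
title: "Two successive screens: the olive self-incompatibility model behind oliveSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two successive screens: the olive self-incompatibility model behind oliveSI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oliveSI)
```

## The model and its assumptions

Olive self-incompatibility is sporophytic at two loci acting in sequence.

**Stigma screen (di-allelic).** Two alleles, S1 and S2; S2 is dominant in
the stigma and the S2S2 homozygote does not occur, so the population splits
into exactly two groups: G1 (S1S2, stigma and pollen phenotype S2) and G2
(S1S1, phenotype S1). Rejection is phenotype matching — pollen germinates
only on a stigma of the other group. Selfing, and any within-group cross,
is stopped here.

**Ovary screen (poly-allelic).** Six alleles R1–R6. Female-side all six are
codominant: an ovary presents both alleles of its pair. Pollen-side they
obey the transitive dominance hierarchy R6 > R2 > R1 = R3 = R5 > R4, and a
plant's pollen (uniform, because determination is sporophytic) expresses
only the non-dominated allele(s) of its diploid pair. A pollen tube that
reached the ovary is rejected if its expressed set intersects the host
pair. This single intersection rule reproduces every published worked
cross we encode, including the reciprocal asymmetries caused by dominance
masking (Manzanilla R1R2 pollen is {R2}, so its R1 is invisible to an R1R3
host, but not vice versa).

Verdicts are coded `1-1`, `1-0`, `0-0` for (germination, fruit); `0-1` is
unconstructible by design — the ovary screen is only evaluated after the
stigma screen passes, and olive lacks parthenocarpic fruit.

Counting consequences the package exposes directly:
`enumerate_female_genotypes()` gives the 20 admissible pairs (21 unordered
pairs minus R6R6; the five homozygotes R1R1–R5R5 are admissible, R4R4
merely unobserved), `enumerate_pollen_classes()` the 9 dominance images
(six singletons plus {R1,R3}, {R1,R5}, {R3,R5}), and
`compatibility_matrix()` the 180-cell product. The stigma screen is kept
out of the matrix because it depends only on the two groups.

**Assumptions inherited from the model.** The two loci assort
independently (the packaged frequency panel shows all six R alleles in both
groups); pollen phenotype depends only on the parent genotype; rejection is
categorical, not quantitative; and andromonoecy (hermaphrodite and
male-only flowers on one tree) is ignored.

## Degradation of S-determinants

Categorical screens cannot explain the observed partial self-fertility or
late fruit set. The degradation mechanism (`dsd_config()`) supposes that
some determinants are short-lived:

| parameter | default | meaning |
|---|---|---|
| `onset_day` | 3 | days after pollen deposition when loss can begin |
| `full_day` | 5 | day by which short-lived determinants are gone (deterministic mode) |
| `ovule_access_day_max` | 10 | last day a tube can still fertilize |
| `short_lived` | R2, R4, R5, R6 | degradable determinants; R1, R3 are stable |
| `dsi_degradable` | TRUE | the stigma determinant degrades on the same schedule |
| `rates` | 0.5/day short-lived, 0 stable | per-day loss hazards, stochastic mode |

The 3-, 5- and 10-day values are the published pollen-tube timings: fruit
set from nominally incompatible pairs appears 3–5 days after pollination,
and tubes keep making headway to ovules for 5–10 days. Degradation acts on
*both* sides of the interaction, and the rejection test at day *d* uses the
two effective sets. The stigma determinant must be degradable, otherwise no
selfing could exist at all.

Under the defaults a genotype selfs exactly when its expressed pollen class
contains no stable allele: pollen determinants are a subset of the ovary
pair, so after degradation the shared residue is the pollen class's stable
part. Hence R2R3 (pollen {R2}) selfs from day 5, while R1R3 and R1R4 never
self — matching the published lists of never-self-fertile pairs. Two
published partial selfers, Salonenque (R3R5) and Leccino (R1R5), retain a
stable allele in their own pollen class and are therefore predicted
self-sterile by the strict rule; the source record does not resolve this,
and the supported reading is a small nonzero stochastic rate for R1/R3
(`dsd_config(mode = "stochastic", rates = list(R1 = 0.05, R3 = 0.05))`)
rather than silently reclassifying the alleles. A per-group onset
difference (G1 vs G2 hosts) has been hinted at in field data; the
configuration keeps a single schedule for both, which the packaged
reference outcomes do not contradict.

**Numerical choices.** Time is whole days from each grain's deposition
(flower age is not tracked separately; each pollen encounter carries its
own clock). Deterministic mode is an all-or-none step at `full_day` —
chosen for testability and because the data constrain only the 3–5-day
window, not a curve shape. Stochastic mode draws a geometric loss day per
determinant copy with per-day hazard starting at `onset_day`; with hazards
at 1 it reproduces the deterministic day-10 outcomes, with hazards at 0 it
reproduces `mode = "off"`. The predicate functions `selfing_possible()` and
`late_cross_possible()` always use the deterministic schedule; stochastic
leakage is sampled per grain in the simulator, where it belongs.

## The orchard simulator

`simulate_season()` is deliberately minimal: each flower opens on a uniform
day of its variety's bloom window, stays receptive for `receptive_days`
(default 6) and receives a Poisson number of grains per day (default mean
5) drawn from the pollen cloud — planting proportions restricted to the
varieties in bloom that day. Each grain fertilizes at deposition day plus
its earliest screen-passing day; one ovule per flower and the earliest
fertilization wins (ties resolved by draw order). There is no spatial
dispersal kernel, no wind or insect vector, no ovule competition, and
paternity is simulator ground truth rather than marker inference. Fruit
whose winning grain was not statically `1-1` is counted as a degradation
event — the quantity a grower would read as "compatible pollen was
insufficient", and the simulator-level counterpart of the
paternity-paradox diagnostic `diagnose_paternity()`, which flags a
host/father pair whenever exactly one screen accepts it.

The packaged paternity reference table carries three rows flagged
`anomaly`: one where the printed stigma verdict contradicts the stated
groups of both parents (Grossane × Frantoio/Petit Ribier), one where the
printed ovary verdict contradicts the host's own stated allele pair
(Cayon × Picholine/Arbequina), and one where a father's printed group
contradicts its deciphering elsewhere (Amellau). The model's computed
verdicts are kept as the coherent reading and the flagged rows are
excluded from exact comparisons. Reference varieties whose pairs were
never published are packaged with `source = "inferred"` genotypes, chosen
as the minimal assignment consistent with their printed group and
diagnosis rows.

## Genotype inference

`consistent_assignments()` mechanizes the by-hand genotype attribution
from diallel tables: exhaustive search over (group, pair) candidates with
record-by-record pruning. `fruit` demands `1-1` (or, with `allow_dsd`, a
degradation-rescuable cross), `no_fruit` forbids `1-1`, and pollen-test
rows constrain only the stigma screen. A configurable `fruit_threshold`
lets a trickle of fruit from an incompatible pair (selfing, contamination)
be read as `no_fruit`, since the sources reason with exactly such a
quantitative threshold. Results are deduplicated up to relabeling within
the codominant class {R1, R3, R5}, the only symmetry the records cannot
break. Two search engines sit behind the interface: depth-first with early
stop when a `limit` is given (also used by `min_alleles()`), and a
vectorized prefix join for full enumeration, guarded by `max_states`
because mostly-`no_fruit` tables (weak constraints) can have consistent
sets far beyond what is worth materializing.

One structural point the search makes visible: under a single-locus class
model *no* number of classes can explain the intransitive
Picholine/Cayon/Tanche pattern (incompatibility is an equivalence
relation there), while the two-screen model explains it with two ovary
alleles. Conversely a *fully* compatible triple is impossible under two
stigma groups — three varieties cannot be pairwise in different groups —
unless degradation-rescued fruit is admitted.

## What the synthetic generator does and does not emulate

`generate_fixture()` draws panels from the packaged deciphered-variety
frequencies (or uniformly, or from an explicit list) and derives complete
diallel records from the model's own verdicts, optionally dropping rows
(`record_completeness`) and injecting degradation-driven false `fruit`
rows for rescuable crosses (`dsd_noise`, flip probability `noise_rate`
0.5). It emulates the *structure* of literature cross tables — including
their paradoxical fruit reports — but not their messiness: no synonym
confusion between local variety names, no misrecorded hosts, no bag
leakage by foreign pollen, no quantitative fruit counts with observation
error. Tests passing on these fixtures therefore validate the logic of
screens, degradation and inference, not robustness to the recording errors
of century-old field data.

Problem sizes used by the test-suite and the acceptance script — 40×40
genotype pairs for oracle equivalence, 4–6-variety diallels at 50 seeds
for generate-and-recover, 50–200 flowers per simulated variety — were
chosen as the smallest sizes at which every property is exercised with
unambiguous outcomes. The recovery property is tiered: where the full
consistent set is enumerable the generating assignment must be a member
(up to relabeling); for weakly constrained diallels whose consistent set
exceeds the enumeration guard, the generator must have zero violations
and the search must still return a sound witness.

## Known limitations

- Verdicts are categorical; the model predicts no fruit-set percentages.
- The allele universe is fixed at six (the minimum that explains the
  published 102-variety cross data); a seventh allele dominating R6 would
  require extending the dominance ranks.
- Degradation kinetics are a step (or geometric) abstraction of an
  unmeasured molecular process; only the 3–5-day onset window and the
  10-day ovule-access bound are data-driven.
- The inference engine reasons categorically — no likelihood over fruit
  counts, no error model — and is bounded at eight varieties for
  exhaustive search; larger panels should be checked against candidate
  assignments instead.
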