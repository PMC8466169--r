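# oliveSI

Self-incompatibility modeling for the olive tree (*Olea europaea* L.).

Olive varieties routinely refuse their own pollen, yet pollen tests and
fruit-set tests on the same variety pairs have contradicted each other for a
century, paternity tests keep naming "incompatible" fathers, and bagged
inflorescences of supposedly self-incompatible varieties still set the odd
fruit. `oliveSI` implements the two-locus sporophytic model that reconciles
these observations, and builds the practical tooling around it: cross
prediction, orchard pollination simulation, paternity-paradox diagnosis, and
S-genotype inference from diallel cross tables.

## The model

Two screens act in succession on every pollination:

1. **Di-allelic screen (DSI), at the stigma.** One S-locus with two alleles,
   S1 and S2, S2 dominant in the stigma and S2S2 non-existent; every variety
   is either G1 (S1S2) or G2 (S1S1). G1 stigmas and G1 pollen both present
   S2 (G2 both present S1), so pollen *germinates* only on a host of the
   other group.
2. **Poly-allelic screen (PASI), at the ovary.** A second S-locus with six
   alleles R1–R6 under the pollen-side dominance hierarchy

   R6 > R2 > R1 = R3 = R5 > R4

   Pollen (sporophytically determined, hence uniform per plant) expresses
   the non-dominated allele(s) of its parent's pair — nine possible pollen
   classes; the ovary expresses both alleles codominantly. A pollen tube is
   rejected at the ovary if it shares any expressed determinant with the
   host pair. Twenty female genotypes (R6R6 excluded) × nine pollen classes
   give the 180-cell compatibility matrix.

A cross is coded `1-1` (germination, then fruit), `1-0` (germination, no
fruit — the source of the classic pollen-test/fruit-test disagreement), or
`0-0`; `0-1` cannot occur. Because pollen expression is filtered by
dominance while ovary expression is not, reciprocal crosses can differ
(asymmetry: Manzanilla × Arbequina sets no fruit, Arbequina × Manzanilla
does).

**Degradation of S-determinants (DS-D).** Determinants of R2, R4, R5 and R6
(and, by necessity, the stigma S-determinant) degrade three to five days
after pollination, while pollen tubes can still reach ovules up to about ten
days. This turns strict incompatibility into time-dependent leakage: a
variety selfs exactly when its expressed pollen class contains no stable
allele (R2R3 selfs from day 5; R1R3 and R1R4 never do), and it explains why
paternity tests sometimes identify fathers that one screen rejects — which
is itself a usable field signal that compatible pollen was lacking.

## Worked example

```r
library(oliveSI)

tanche    <- variety_genotype("Tanche",    "G2", "R2R3")
picholine <- variety_genotype("Picholine", "G1", "R1R3")
cayon     <- variety_genotype("Cayon",     "G1", "R1R4")

dssm_verdict(tanche, picholine)
#> <cross> Tanche x Picholine : 1-0  (stigma pass, ovary reject)
dssm_verdict(tanche, cayon)
#> <cross> Tanche x Cayon : 1-1  (stigma pass, ovary pass)
dssm_verdict(picholine, cayon)
#> <cross> Picholine x Cayon : 0-0  (stigma reject)
```

This is the classic intransitive triple: Picholine and Cayon are mutually
incompatible (same stigma group), Picholine cannot pollinate Tanche (their
pollen/ovary sets share R3), yet Cayon pollinates Tanche freely — a pattern
no single two-class grouping can produce, and the argument for two loci.

```r
mate_availability(tanche, reference_panel_frequencies())
#> [1] 0.2462
```

Drawing a pollen donor at random from the 65 deciphered reference varieties,
Tanche has only a 25% chance of full compatibility — far from the 50% a
two-group model would suggest, which is why pollinizer choice matters.

```r
selfing_possible(tanche)
#> $possible: TRUE     $earliest_day: 5
diagnose_paternity(ref_variety("Aglandau"), ref_variety("Frantoio"))
#> <paternity> host Aglandau, father Frantoio
#>   stigma screen: Accept | ovary screen: Reject | degradation involved: Yes
#>   compatible pollen insufficient - plant suitable pollinizers
```

Tanche (pollen class {R2}, short-lived) becomes self-fertile once
degradation completes at day 5. The Aglandau embryo fathered by Frantoio
passed the stigma screen but not the ovary screen: only degradation can
explain it, so the orchard lacked compatible pollen.

A command-line front end ships in `exec/dssm` (`dssm help` lists the
`predict`, `matrix`, `availability`, `selfing`, `simulate`, `diagnose`,
`infer` and `fixtures` subcommands); orchard files are YAML (see
`inst/extdata/orchard_example.yaml`), panels and cross tables plain CSV.

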