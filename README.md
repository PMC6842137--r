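# synloss

Synteny-confirmed screening for genes of a reference species that are lost
in one predefined set of species and retained in another.

## The problem

Some evolutionary gains come from losing genes.  Given an *upper* fraction
of species carrying a property of interest (e.g. unusually long lifespans
relative to body mass) and a *lower* fraction lacking it, every
protein-coding gene of a reference species from the lower fraction can be
screened for the pattern "lost in the upper species, present in the lower
species".  Because orthology inference is noisy and assemblies imperfect,
`synloss` never trusts an ortholog table alone: a gene *X* counts as
present in a target species only when

1. the target carries a candidate counterpart *X′* (an ortholog of any
   type, optionally extended by paralogs of orthologs), **and**
2. at least *w* neighbouring reference genes *Y* within *r* of *X*
   ("witnesses") have counterparts *Y′* within *r′* of *X′* —
   local synteny at the Mbp scale of topologically associated domains.

Failing either condition makes the gene *lost* in that species.  Gene
selection over species sets is written in a small Boolean predicate
language, e.g. the classic four-set screen with compulsory species:

```
absent_in(COMPULSORY_UPPER, 3) and absent_in(UPPER_GLIRES, 1)
  and absent_in(UPPER_PRIMATES, 2) and present_in(LOWER_GLIRES, 2)
  and present_in(LOWER_PRIMATES, 2) and present_in(REFERENCE, 1)
```

meaning: lost in all compulsory upper species, in at least *m* = 1 upper
glires and *n* = 2 upper primates, while retained in at least *p* = 2 lower
glires, *q* = 2 lower primates and the reference.  Several orthology
sources can vote on each gene's verdict ("2 of 3"), and each hit carries
the maximal thresholds (*m*,*n*,*p*,*q*)<sub>max</sub> at which it would
still be found, whose sum *S* = *m* + *n* + *p* + *q* is a quality index
for ranking predictions.

For longevity screens, fractions are built from the longevity quotient
*LQ* = MRLS / (4.88 · *m*<sup>0.153</sup>) × 100%, the maximum reported
lifespan relative to the allometric expectation for adult body mass *m*
in grams.

## Worked example

Screen a deterministic synthetic data set (32 species, 40 reference genes,
5 planted losses) with the classic thresholds:

```r
library(synloss)
fix <- generateFixture(fixtureSpec(
  upperCounts = c(glires = 3L, primates = 7L),
  lowerCounts = c(glires = 11L, primates = 10L),
  nContigs = 2L, genesPerContig = 20L,
  plantedLosses = lapply(c(3L, 11L, 22L, 30L, 37L), function(i)
    list(gene = i, species = c(sprintf("upper_glires_%02d", 1:3),
                               sprintf("upper_primates_%02d", 1:7)))),
  seed = 42L))
res <- screenGenes(
  fix$genomes, fix$refSpecies, fix$source,
  paste("absent_in(UPPER_GLIRES, 1) and absent_in(UPPER_PRIMATES, 2)",
        "and present_in(LOWER_GLIRES, 2) and present_in(LOWER_PRIMATES, 2)",
        "and present_in(REFERENCE, 1)"),
  fixtureSets(fix), presenceParams())
screenHits(res)[, 1:8]
#>          gene_id postprocessing m_max n_max p_max q_max s_index seq_region
#> 1 reference_g003                    3     7    11    10      31      ctg01
#> 2 reference_g011                    3     7    11    10      31      ctg01
#> 3 reference_g022                    3     7    11    10      31      ctg02
#> 4 reference_g030                    3     7    11    10      31      ctg02
#> 5 reference_g037                    3     7    11    10      31      ctg02
```

Exactly the five planted genes are recovered; each is lost in all
3 + 7 upper species and retained in all 11 + 10 lower species, hence the
extreme maximal thresholds and quality index 31.  `writeResults(res,
"hits.tsv")` emits the tab-separated report (one ortholog column per
species, optional witness blocks).

Longevity utilities work the same way from the shipped life-history table:

```r
computeLQ(30, 874, round = TRUE)
#> [1] 218
lh <- readLifeHistory(system.file("extdata",
  "euarchontoglires_life_history.tsv", package = "synloss"))
partitionFractions(lh,
  groupSpec("primates", lh$species[lh$group == "primates"], 220, 190))
#> $upper  # 7 primates with LQ > 220%
#> [1] "homo_sapiens" "cebus_capucinus_imitator" "nomascus_leucogenys" ...
#> $lower  # 10 primates with LQ < 190%
#> [1] "colobus_angolensis_palliatus" "mandrillus_leucophaeus" ...
```

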