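# electroDGE

Differential expression and phenotype-consistent gene sets for
electric-organ transcriptomes.

## What this solves

*Paramormyrops* electric fishes diverge rapidly in their electric organ
discharges (EODs) along three axes — **duration** (long/short),
**complexity** (biphasic/triphasic) and **polarity** (small/large
electrocyte stalk penetrations; defined only for triphasic animals).
Given gene-level RNA-seq counts from electric organs of operational
taxonomic units (OTUs) that differ in these features, the package asks
which genes are consistently up-regulated in each phenotype, while
controlling for the fact that any two OTUs also differ in phylogeny and
OTU-specific quirks.

The pipeline:

1. **Pairwise differential expression** for every OTU pair: TMM
   normalization, conditional-maximum-likelihood dispersion estimation
   (common + tagwise shrinkage), and the negative-binomial exact test.
   A gene is a DEG when |log₂FC| > 2 and Benjamini–Hochberg FDR < 0.001.
2. **Set A** — union of DEGs over all comparisons.
3. **Set A′** — DEGs of the three *informative* comparisons (the OTU pair
   contrasting exactly one feature at minimal phylogenetic distance),
   relabeled from OTUs to phenotypes.
4. **Set B** — phenotype-consistency filter on Set A: on linear TMM-CPM,
   group-mean ratio > 4 and mean difference larger than both within-group
   standard deviations.
5. **Set C = A′ ∩ B** per (feature, phenotype): the headline gene lists.
6. **GO enrichment** (Fisher/hypergeometric, nodeSize = 10, p ≤ 0.02) with
   elim-style DAG decorrelation, per ontology domain, on every
   up-regulated list.

A negative-binomial simulator (`simulateCounts()`) reproduces the
11-sample, five-OTU study design with planted phenotype-linked genes,
OTU-specific confounders and nulls, so every stage is testable without
sequencing data, and `runRecoveryStudy()` measures sensitivity and
false-discovery proportions against the simulation truth.

## Worked example

```r
library(electroDGE)

cfg <- pipelineConfig(outdir = "eod-run", seed = 1)
out <- runPipeline(cfg)
out$bundle$family
#> GeneSetFamily: |Set A| = 350
#>   complexity|biphasic    A'=  51 B=  52 C=  46
#>   complexity|triphasic   A'=  99 B=  86 C=  82
#>   duration|long          A'=  49 B=  91 C=  45
#>   duration|short         A'=  57 B=  62 C=  57
#>   polarity|large         A'=  48 B=  53 C=  47
#>   polarity|small         A'=  47 B=  50 C=  41
```

Of 4000 simulated genes, 350 are differentially expressed in at least one
of the ten pairwise comparisons (Set A).  Each (feature, phenotype) key
then narrows to the genes both statistically supported in the cleanest
single-feature contrast (A′) and consistently four-fold up across all
replicates sharing the phenotype (B).
`eod-run/` contains the DEG and MA table per comparison, the per-key gene
lists with centred log₂ expression values, the GO enrichment table and a
JSON manifest; re-running with the same seed reproduces every file
byte-for-byte.  (The intersection C — e.g. 57 genes up in short-EOD
animals — is the candidate list for that phenotype.)

```r
rec <- runRecoveryStudy(cfg, nSeeds = 10)
rec$summary
#>      feature medianSensitivity   medianFdp medianStrictKeyFdp medianSetCSize
#> 1 complexity             0.930 0.003649635         0.30734801            133
#> 2   duration             0.925 0.060006001         0.06000600             99
#> 3   polarity             0.830 0.056513410         0.05651341             89
```

With 50 planted 8-fold genes per (feature, phenotype), Set C recovers
83–93% of them, and fewer than 6% of its calls are not phenotype-linked
at all.  The larger `strictKeyFdp` for complexity reflects genuinely
nested phenotypes (polarity groups are a subset of triphasic samples), not
noise — see the methods vignette.

A thin command-line wrapper lives at `inst/scripts/run-pipeline.R`
(`run`, `simulate`, `recover` subcommands).

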