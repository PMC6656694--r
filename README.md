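# CytoMonitor

Standardized mass-cytometry (CyTOF) immune monitoring in R: from raw
per-event ion counts to disease-associated immune signatures, around a
fixed 33-antibody reference panel.

Clinical immune-monitoring studies need the same questions answered for
every sample: is the instrument signal stable, which events are intact
live leukocytes, what is the frequency of every immune population, do two
runs of the same sample agree, and which populations differ between
patient groups? CytoMonitor packages that whole chain as tested,
reproducible functions, aimed at computational teams analyzing CyTOF
immunophenotyping panels (PBMC or bone-marrow-transplant monitoring) who
want an auditable, scriptable alternative to manual per-sample analysis.

The workflow:

1. **Bead normalization** — spiked-in EQ calibration beads are detected
   (positive in all five bead metals, DNA-negative) and per-time-window
   correction factors `f(w) = median_c(reference_c / median_{w,c})` undo
   acquisition-time sensitivity drift.
2. **Debarcoding** — pooled samples are deconvolved from k-of-n palladium
   barcode patterns with a within-event separation cutoff.
3. **Transforms** — `asinh(x/5)`, then per-channel division by the 99.5th
   percentile.
4. **Pre-gating** — non-beads, DNA⁺, singlets, live, CD45⁺,
   CD235ab/CD61⁻, non-neutrophils, with a per-stage attrition report.
5. **Hierarchical gating** — a declarative marker-sign tree (Treg =
   CD25^high CD127^low FoxP3⁺, classical monocytes = CD14⁺CD16⁻, ...)
   assigns every pre-gated event to a population.
6. **Clustering + annotation** — a batch self-organizing map with
   metaclustering; each metacluster median profile is scored against the
   population definitions (fraction of sign clauses on the correct side of
   their cutoff) and labeled with the deepest definition scoring ≥ 0.9
   along its whole ancestor chain, with recursive within-lineage
   subclustering for subset resolution.
7. **Statistics** — antigen-coverage QC (number of positive antigens per
   cell), cross-run regression and sample clustering, bootstrap SEM of
   medians (1000 resamples), precision/recall/F1/MCC label agreement, and
   per-population differential abundance via a negative-binomial GLM with
   log-total offset, moment dispersion shrunk to the cohort median, Wald
   test and BH FDR.

A synthetic-data generator (`simulateSample()`, `simulateReplicatePair()`,
`simulateCohort()`, `simulateBarcodedPool()`) emulates the assay — arcsinh
-scale expression modes, beads, dead cells, doublets, drift, barcodes,
logit-normal cohort dispersion — with full ground truth, so every stage of
the pipeline is testable without instrument data. FCS 3.0/3.1 files are
read and written natively (`readFCS()`, `writeFCS()`).

## Worked example

Simulate a PBMC sample, pre-gate it, gate it, and check coverage:

```r
library(CytoMonitor)

cfg <- simConfig(50000, seed = 42,
                 templates = populationTemplates("pbmc_default"),
                 beadFraction = 0.05, doubletRate = 0.02,
                 deadFraction = 0.03)
sim  <- simulateSample(cfg)
cuts <- defaultCutoffs()
tr   <- arcsinhTransform(beadNormalize(sim$matrix)$matrix)
pg   <- pregate(tr, cuts)
pg$attrition
#>             stage events_in events_out fraction_removed
#> 1       non-beads     50000      47546      0.049080000
#> 2            DNA+     47546      47546      0.000000000
#> 3        singlets     47546      46559      0.020758844
#> 4            live     46559      45236      0.028415559
#> 5           CD45+     45236      45236      0.000000000
#> 6   CD235ab/CD61-     45236      45186      0.001105314
#> 7 non-neutrophils     45186      45186      0.000000000
```

The attrition report mirrors the generator settings: ~5% beads, ~2%
doublets, ~3% dead cells. Gating and coverage on the pre-gated events:

```r
res <- applyGating(tr[pg$mask], gatingTree(lineageTable("pbmc_core")), cuts)
leafAssignedFraction(res)
#> [1] 0.9987385
antigenCoverage(tr[pg$mask], cuts, k = 4)$fraction_ge_k
#> [1] 1
head(sort(leafFrequencies(res), decreasing = TRUE), 3)
#> Classical monocytes         CD4 T naive CD56low CD16+ NK cells
#>              0.1528              0.1087                 0.1001
```

99.87% of pre-gated cells reach a lineage leaf (the assay's guarantee is
≥ 98.4%), every live cell carries ≥ 4 positive antigens (guarantee:
≥ 99.8% of cells), and the leaf frequencies recover the simulation's
composition (classical monocytes were simulated at 15%, naive CD4 T cells
at 11%, CD56^low NK cells at 10%).

The cohort pipeline — 28 post-transplant samples, clustering, annotation
and GvHD differential abundance — runs from one configuration:

```r
man <- runPipeline(list(nSamples = 28, nEvents = 20000, seed = 1,
                        outDir = "bmt_run"))
pipelineReport(man)
```

which writes frequency tables, the differential-abundance table (log2 fold
change, p, BH FDR per population) and a JSON manifest with seeds and
checksums; re-running the same configuration reproduces identical files.

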