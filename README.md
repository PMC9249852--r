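# ParalogOccupancy

Paralogous transcription factors — Hox proteins are the canonical case —
bind nearly identical DNA motifs in vitro yet drive different programs in
vivo, partly because heterodimerization with cofactors (Exd/Pbx-class
partners) creates latent binding specificities. This package implements the
computational core of a ChIP-seq/SELEX workflow for dissecting that
phenomenon: it detects loci bound preferentially by one of two paralogs in
matched tissues, orders the paralog-specific loci by how much their binding
depends on a cofactor interaction (using a wild-type versus
interaction-motif-mutant contrast), and connects the classes to sequence
via position-specific affinity model (PSAM) scanning and a simplified
SELEX-to-PSAM fitter.

It is aimed at regulatory-genomics analysts who have replicate peak sets,
coverage tracks and per-locus fragment counts in hand (read mapping and
peak calling are upstream, out of scope) and want a tested, deterministic
pipeline from those inputs to classified, dependency-ordered loci.

## What it computes

- **Affinity tracks.** A PSAM assigns window `s` the relative affinity
  `exp(Σ_i β_mono[i, s_i] + Σ_i β_di[i, (s_i, s_i+1)])`, consensus = 1.
  Tracks are built in a fixed order: strand-summed affinities at every
  offset, normalization to the genomic maximum, thresholding at 1e-4, and a
  left-anchored windowed maximum of width k.
- **Consensus loci and occupancy.** Peaks are re-centered to summit ± 250 bp,
  merged across replicate sets with membership bookkeeping, and scored as
  the sum of per-base signal over the 100-bp window centered on the peak
  (± 50 bp); samples are made comparable with a scaling factor that
  equalizes mean signal at common loci. Peak-centered matrices use ± 1 kb
  windows in 20-bp bins (100 bins).
- **Differential occupancy.** A negative-binomial Wald test on normalized
  counts (log2FC with a 0.5 pseudocount; variance `(1/μ + α)/n` by the
  delta method; pooled method-of-moments dispersion) with
  Benjamini–Hochberg correction. Loci are *differential* when called in
  ≥ 2 of 4 experiments with FDR < 0.05, *common* when called in ≥ 3 of 4
  with raw p > 0.1; accessibility uses the two-step FDR < 0.05 then
  |log2FC| > 1 rule.
- **Cofactor dependency.** Loci are split by the sign of the WT-vs-mutant
  log2FC, the WT>mut class sorted by FDR ascending, the WT<mut class
  descending, and concatenated; boundaries from overlap with the
  WT>mut-differential and WT≈mut-common classes yield high-confidence
  dependent / ambiguous / independent labels.
- **SELEX fitting.** Canonical k-mer enrichment between an unselected (R0)
  and one selected (R1) round seeds a single-mode mononucleotide PSAM that
  is refined by maximum likelihood under a linear selection model, with the
  R0 sample as Monte-Carlo partition function.
- **Synthetic data.** A generator plants monomer, composite-dimer
  (overlapping half-sites) and spaced-dimer motif instances with known
  occupancy classes into a random genome and emulates the full 2×2 ChIP
  design (counts, triangular-kernel coverage, per-replicate peak-call
  dropout) plus SELEX read sets, so every stage is testable against planted
  truth.

## Worked example

```r
library(ParalogOccupancy)

cfg <- RunConfig(stages = c("simulate", "scan", "quantify", "classify",
                            "dependency", "report"),
                 outDir = "run1", seed = 1L,
                 plan = SimulationPlan(seed = 1L))
res <- runPipeline(cfg)

table(res$differential$class_label)
#> differential_A_gt_B differential_A_lt_B              common        unclassified
#>                  94                   0                  93                  13

attr(res$ordering, "iDep"); attr(res$ordering, "iInd")
#> [1] 38
#> [1] 40
```

The default plan plants 100 shared and 100 condition-A-specific loci (40
cofactor-dependent, 40 cofactor-independent, 20 other) with a log2 fold
change of 2 at mean depth 200. In the run above, 94 loci are recovered as
A-specific (91 of the planted 100, plus 3 shared-locus false calls), and
the dependency ordering places ranks 1–38 in the high-confidence dependent
block (`iDep`) and ranks 40 onward in the independent block (`iInd`):
planted dependent loci land at or before rank 38, planted independent loci
after rank 40. Outputs (occupancy tables, differential records, the
dependency ordering, affinity bedGraphs, run log) are written under
`run1/`.

Scanning and motif tables work standalone:

```r
psams <- makePsamSet(seed = 1)
genome <- makeGenome(5e4, gc = 0.42, seed = 1)
track <- buildAffinityTrack(genome, psams$composite)   # threshold 1e-4
topMotifs(genome[[1]], psams$monomer, n = 10)          # ten strongest motifs
```

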