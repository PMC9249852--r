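---
title: "Models and methods: paralog-specific occupancy and its cofactor decomposition"
author: "ParalogOccupancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the design choices that were genuinely open,
and what the synthetic study does and does not demonstrate. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The scientific setting

Two paralogous transcription factors with near-identical monomer motifs
can occupy different genomic sites in vivo. One documented route to such
paralog-specific binding is latent specificity: heterodimerization with a
cofactor (an Exd/Pbx-class homeodomain partner) changes the preferred
sequence, so sites read out the dimer motif grammar rather than the
monomer one. Two grammars matter here: *composite* dimer sites, where the
two half-sites partially overlap, and *spaced* dimer sites, two monomer
half-sites separated by a short, nearly neutral spacer. The package's
pipeline quantifies paralog-specific occupancy from a replicated ChIP
design, orders the specific loci by cofactor dependency using a wild-type
versus interaction-motif-mutant contrast, and ties classes back to
sequence with PSAM affinity scanning and SELEX model fitting.

## PSAMs and affinity tracks

A position-specific affinity model stores per-position, per-base
log-affinity parameters (optionally per-adjacent-position dinucleotide
corrections). The relative affinity of window $s$ is

$$a(s) = \exp\Big(\sum_i \beta^{mono}_{i,s_i} + \sum_i \beta^{di}_{i,(s_i,s_{i+1})}\Big),$$

with each $\beta^{mono}$ row shifted so its maximum is exactly 0; the
mononucleotide consensus then has affinity 1. Row shifts multiply every
window affinity by a common factor and are removed again by track
normalization, which is why `readPSAM` may renormalize a parameter file
without changing any downstream result (a property the tests check).

Genome tracks are built in a frozen order: (1) affinities at every offset,
summed across both strands; (2) division by the global maximum over all
contigs; (3) zeroing of values below the threshold (default `1e-4`);
(4) a windowed maximum of window length $k$ to smooth local
position-specific variation. Two choices here were open and are worth
recording:

- **Anchoring.** The windowed maximum is *left-anchored* (the value at
  position $i$ covers $[i, i+k)$), with truncated windows at the right
  edge, so a track has exactly the contig's length. Centered anchoring
  would shift features by $k/2$; nothing downstream depends on the choice
  as long as it is consistent, and the track metadata records it.
- **Multi-mode files.** When a model file declares several modes, modes
  are scored separately and their raw affinities summed before
  normalization, matching the additive-occupancy reading of the model
  family. Single-mode files are the common case.

Windows containing N score 0 (a conservative choice; such windows are
simply unscorable). Motif tables (`topMotifs`, default 10 rows) score
strands separately so each reported hit has a defined orientation, and
break ties by offset, then + strand first.

## Loci, occupancy scores and matrices

Consensus loci re-center every peak to summit ± 250 bp (501 bp),
merge overlapping windows across replicate peak sets, and keep loci backed
by at least `minOverlap` sets. Open details fixed here: a summitless peak
falls back to its interval midpoint (floored, and logged), and a merged
locus's center is the floor of the mean of contributing summits —
deterministic and symmetric.

The occupancy score of a locus is the sum of per-base signal over the
100-bp window `[center - 50, center + 50)`. The window is half-open so it
contains exactly 100 bases; "50 bp upstream to 50 bp downstream" is
ambiguous by one base and this convention resolves it. Cross-sample
comparability uses a scaling factor equalizing mean scores over the common
loci — the package's count-space normalization (below) makes the same
assumption in the same place. Peak-centered matrices cut ± 1 kb windows
into 20-bp bins (exactly 100 bins); bins truncated by a contig edge
average the bases that exist.

Promoter (TSS) annotation uses the strand-aware window −1 kb to +100 bp
around the transcription start; the TTS window mirrors it (−100 bp to
+1 kb downstream). The precedence TSS > TTS > exon > intron > intergenic
is declared, not inferred from any external annotator, and every locus
receives exactly one label.

## The count model and its calibration

Testing uses a negative-binomial model, variance $\mu + \alpha\mu^2$. The
per-locus Wald statistic compares log mean normalized counts between
conditions with delta-method variance $(1/\tilde\mu + \alpha)/n$ per
condition, where $\tilde\mu$ includes the 0.5 pseudocount that also keeps
the log2 fold change finite at zero counts. p-values are two-sided normal;
FDR is Benjamini–Hochberg.

Two statistical choices deserve their rationale:

- **Dispersion.** With two replicates per condition, per-locus
  method-of-moments estimates $\hat\alpha = \max(0,(s^2-m)/m^2)$ are so
  noisy that plugging them (even 50/50-shrunk toward a common value) into
  the Wald denominator couples the estimated variance to the observed mean
  difference and inflates the empirical type-I error to roughly twice
  nominal. The test therefore uses a *pooled* moment estimator,
  $\hat\alpha_{common} = \max\big(0, (\overline{s^2} - \overline{m}) /
  \overline{m^2}\big)$ over all loci and conditions, which is close to
  unbiased at these replicate numbers; the per-locus and shrunk estimates
  are still computed and returned as diagnostics. The test suite verifies
  the resulting calibration (empirical type-I error within [0.04, 0.065]
  at nominal 0.05 on 10,000 null loci) and dispersion recovery
  (a planted $\alpha = 0.2$ recovered within [0.15, 0.25]).
- **Normalization.** Median-of-ratios factors assume most loci are
  non-differential. The paralog contrast violates that assumption
  aggressively — half the locus universe can be differential in one
  direction — and the median then falls between the null and changed
  clusters, manufacturing false calls among shared loci. The default
  contrast normalization (`nullModeSizeFactors`) therefore estimates
  within-condition factors by median-of-ratios (replicates share
  expectations, so that step is unbiased) and the between-condition offset
  from the per-locus log-ratio density, shifting the local mode nearest
  zero to zero. This is the count-space analogue of equalizing mean signal
  at common loci, and it assumes only that *some* coherent cluster of
  unchanged loci exists. Plain median-of-ratios and unit factors remain
  available as options, and `computeSizeFactors` itself is unchanged
  median-of-ratios.

Classification applies the printed rules verbatim: differential =
membership ≥ 2 of 4 and FDR < 0.05 (sign splits A>B from A<B); common =
membership ≥ 3 of 4 and raw p > 0.1; a locus meeting both is differential.
No fold-change floor is applied to ChIP classes (the accessibility rule,
FDR < 0.05 then |log2FC| > 1, is separate and two-step). The raw-p common
rule is deliberate: it asks for absence of evidence of change among
well-supported loci.

## Dependency ordering and confidence boundaries

The WT-vs-mutant contrast is evaluated *at the paralog-specific loci being
ordered*, not over the whole locus universe: the multiplicity correction
then matches the question asked of those loci (over the full universe,
where dependent loci are a small minority, the BH cutoff tightens and
sensitivity drops for no inferential gain). Loci are split by the sign of
the WT-vs-mutant log2FC (an exact zero joins the positive class, logged),
the WT>mut class is sorted by FDR ascending, the WT<mut class descending,
and the blocks concatenated — most-dependent first, most-confidently
independent last. Ties break by genomic coordinate.

High-confidence boundaries come from overlap (≥ 1 bp) with two reference
classes from the same contrast: the last ordered locus overlapping the
WT>mut differential class closes the *dependent* block, the first
overlapping the WT≈mut common class opens the *independent* block, and
the ranks between are *ambiguous*. If the boundaries cross, the zone is
flagged "conflict" and the run continues with a warning rather than
failing.

## SELEX: what is fitted and what is not

The fitter is deliberately a single-mode, mononucleotide-only maximum
likelihood fit from one selection round. The selection model is linear
(probability of selection ∝ the additive occupancy weight
$w(s) = \sum_{\text{offsets, strands}} a(\text{window})$), i.e. the
low-occupancy limit; saturation is not identifiable at this scale. The
objective

$$\mathcal{L} = \sum_{s \in R1} \log w_\theta(s) - |R1| \log\Big(\tfrac{1}{|R0|}\sum_{s' \in R0} w_\theta(s')\Big)$$

uses the R0 sample as a Monte-Carlo partition function, and the fit
carries a weak L2 (ridge) penalty on the parameters. Both the penalty and
the optimizer deserve their rationale:

- **Why ridge.** The likelihood is nearly flat along read-composition-like
  parameter directions: reweighting every window of a read by its base
  content moves the selected and unselected samples almost identically, so
  those directions are weakly identified and finite-sample noise can carry
  a null fit (R1 drawn from the R0 distribution) to parameter magnitudes
  of 0.4–0.7 at next to no likelihood cost — a control fit with R1 set to
  the very same reads as R0, where the optimum is provably flat, confirms
  the parameters wander freely. The penalty (standard in this
  binding-model family) resolves the degeneracy toward the minimum-norm
  solution. Its weight (default 100) was calibrated once so that null fits
  at the simulated read depths stay near flat (max |beta| well below 0.1
  at 10^5 reads) while planted-model recovery is untouched (Pearson r
  above 0.99 at 5 × 10^4 reads) — both quantities are recomputed by the
  acceptance script; because the likelihood term grows with read count
  and the penalty does not, its bias on well-identified parameters
  vanishes as reads grow.
- **Why quasi-Newton.** Log-linear binding parameters are severely
  ill-conditioned — deep penalties have exponentially small gradients —
  and plain or diagonally preconditioned gradient ascent crawls for
  hundreds of iterations without converging on the degenerate directions.
  The fit therefore uses full-batch L-BFGS with the analytic gradient
  (observed minus partition-function-expected base counts), which
  converges in tens of evaluations; the accepted-objective trace is
  non-decreasing, and iteration stops at a penalized-likelihood gain below
  1e-6 or 500 iterations.

The seed comes from canonical k-mer enrichment: top k-mer as consensus,
other bases at the log-odds of their column frequency against the
consensus base among the top 100 genuinely enriched k-mers (at least
1.5-fold; orientation-matched, capped at 0, floored at −6). The
enrichment cutoff matters: without it, a null enrichment table seeds the
fit with top-100 ranking noise instead of the near-flat model it should.
Multi-mode growth, shift symmetries, dinucleotide terms and Markov R0
bias correction are out of scope by design, and the fit report says so.

A fitted PSAM can converge in either orientation; comparisons against a
reference model score both the fitted matrix and its reverse complement
and keep the better, which is the standard motif-comparison convention.

## The synthetic study

The generator emulates the study design end to end: a 2-condition ×
2-replicate ChIP with matched inputs plus a mutant contrast in condition
A. Defaults are the study conditions used by the acceptance checks and
were chosen once: 100 shared, 40 cofactor-dependent, 40
cofactor-independent and 20 other condition-A-specific loci; planted
log2FC 2 (so the A/B mean ratio at specific loci is ~4 before sampling);
mean bound depth 200; NB dispersion 0.1; background depth 10 (kept well
below the bound signal so the planted fold change, not the background,
dominates the contrast); GC 0.42, a fly-like euchromatic value. Dependent
sites collapse to background in the mutant (the dimer contributes no
binding without the interaction); independent and other sites are
preserved; condition B carries the graded $2^{-\text{effect}}$ occupancy.

Counts are drawn directly from the NB means — the simulated libraries are
depth-matched, so the correct size factors are exactly 1 and the
normalization above must *recover* them rather than being told. Coverage
uses a triangular kernel of half-width 250 bp with area equal to the
count, which makes the 100-bp locus score a closed form
($0.36 \times$ mean count $+ 0.4 \times$ background) that the tests check
exactly. Per-replicate peak calling is emulated by a logistic on the
count, `plogis(slope (count - 3 x background))` with slope 0.05, so
weakly-bound loci genuinely drop out of individual replicates and the
membership rules are exercised. SELEX selection uses rejection sampling
with acceptance $w(s)/w_{max}$, exactly the linear model the fitter
assumes.

What passing does and does not show: recovery on this generator
demonstrates internal consistency of the pipeline under its own
assumptions — NB counts, independent loci, clean triangular pileup,
depth-matched libraries, motif instances planted on a uniform background.
Real ChIP data add fragment-length structure, GC and mappability bias,
copy-number effects, correlated replicates and peak-caller artifacts, none
of which the generator models; conclusions about real-data performance
need real data.

## Numerical and scale choices

Problem sizes were picked so the whole suite runs comfortably on a single
CPU: the default synthetic genome is 460 kb (200 loci at 2-kb spacing),
oracle-equivalence checks use ≤ 1 kb genomes with $k \le 10$, calibration
uses 10,000 null loci, and SELEX recovery uses 5 × 10⁴ reads (null check
10⁵). Exact-equivalence tests compare bit-for-bit against naive
enumeration oracles computed in the same floating-point order; statistical
checks run under fixed seeds with bands stated in the tests. Degenerate
inputs have defined behavior throughout: all-N genomes error ("no scorable
window"), empty shared-locus sets error, zero-variance correlation inputs
error, and conflicting dependency boundaries warn and continue.

## Known limitations

- The Wald test is asymptotic; with 2 replicates its calibration relies on
  the pooled dispersion being appropriate genome-wide. Strongly
  locus-dependent dispersion would need more replicates or a different
  test.
- Null-mode normalization requires an identifiable unchanged cluster; it
  will follow the wrong mode if *every* locus changes, or if changed and
  unchanged clusters are closer than the sampling noise.
- The SELEX fitter's linear selection model ignores saturation and
  multi-round effects; fitted parameters are interpretable as relative
  affinities only in the low-occupancy regime.
- Interval machinery assumes peaks and loci are small relative to contigs;
  loci within 1 kb of a contig edge get truncated windows (logged), not
  reflected padding.
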