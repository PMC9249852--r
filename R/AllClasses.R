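#' @import methods
#' @importFrom S4Vectors isConstant metadata metadata<-
NULL

DNA_BASES4 <- c("A", "C", "G", "T")
DINUCS <- as.vector(outer(DNA_BASES4, DNA_BASES4, function(a, b) paste0(a, b)))

#' Position-specific affinity model (PSAM)
#'
#' A PSAM assigns every k-mer a relative binding affinity
#' \eqn{exp(\sum_i \beta_{mono}[i, b_i] + \sum_i \beta_{di}[i, (b_i, b_{i+1})])}.
#' Mononucleotide parameters are kept on the natural-log scale and
#' renormalized so that the per-position maximum is exactly 0; the
#' mononucleotide consensus sequence therefore has relative affinity 1
#' whenever dinucleotide terms are absent.
#'
#' @slot k motif length in bp.
#' @slot betaMono k x 4 numeric matrix, columns A,C,G,T, per-position max 0.
#' @slot betaDi (k-1) x 16 numeric matrix of dinucleotide corrections
#'   (columns AA, CA, GA, TA, AC, ...), or NULL.
#' @slot modeId character label for the binding mode.
#' @export
setClass("PSAM", representation(
  k = "integer",
  betaMono = "matrix",
  betaDi = "ANY",
  modeId = "character"
))

setValidity("PSAM", function(object) {
  msg <- character()
  k <- object@k
  bm <- object@betaMono
  if (length(k) != 1L || is.na(k) || k < 1L) {
    msg <- c(msg, "k must be a single positive integer")
  }
  if (!is.numeric(bm) || nrow(bm) != k || ncol(bm) != 4L) {
    msg <- c(msg, "betaMono must be a numeric k x 4 matrix")
  } else {
    if (!identical(colnames(bm), DNA_BASES4)) {
      msg <- c(msg, "betaMono columns must be named A,C,G,T")
    }
    if (any(!is.finite(bm))) msg <- c(msg, "betaMono must be finite")
    rowmax <- apply(bm, 1L, max)
    if (any(abs(rowmax) > 1e-8)) {
      msg <- c(msg, "betaMono rows must have maximum 0 (renormalize)")
    }
  }
  bd <- object@betaDi
  if (!is.null(bd)) {
    if (!is.numeric(bd) || nrow(bd) != k - 1L || ncol(bd) != 16L) {
      msg <- c(msg, "betaDi must be a numeric (k-1) x 16 matrix or NULL")
    } else if (any(!is.finite(bd))) {
      msg <- c(msg, "betaDi must be finite")
    }
  }
  if (length(object@modeId) != 1L) msg <- c(msg, "modeId must be length 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PSAM
#'
#' @param betaMono k x 4 numeric matrix of mononucleotide log-affinity
#'   parameters (columns in A,C,G,T order; a character consensus sequence is
#'   also accepted, see Details).
#' @param betaDi optional (k-1) x 16 dinucleotide correction matrix.
#' @param modeId label for the binding mode.
#' @param normalize if TRUE (default), shift each mononucleotide row so its
#'   maximum is exactly 0. Shifts rescale all window affinities by a common
#'   factor and therefore leave normalized affinity tracks unchanged.
#' @return a \linkS4class{PSAM} object.
#' @export
PSAM <- function(betaMono, betaDi = NULL, modeId = "mode1", normalize = TRUE) {
  betaMono <- as.matrix(betaMono)
  if (is.null(colnames(betaMono))) colnames(betaMono) <- DNA_BASES4
  betaMono <- betaMono[, DNA_BASES4, drop = FALSE]
  if (normalize) betaMono <- betaMono - apply(betaMono, 1L, max)
  if (!is.null(betaDi)) {
    betaDi <- as.matrix(betaDi)
    if (is.null(colnames(betaDi))) colnames(betaDi) <- DINUCS
    betaDi <- betaDi[, DINUCS, drop = FALSE]
  }
  new("PSAM", k = nrow(betaMono), betaMono = betaMono, betaDi = betaDi,
      modeId = as.character(modeId))
}

#' @describeIn PSAM motif length in bp
#' @param x,object a PSAM
#' @export
psamLength <- function(x) x@k

#' @describeIn PSAM mononucleotide parameter matrix
#' @export
betaMono <- function(x) x@betaMono

#' @describeIn PSAM dinucleotide parameter matrix (or NULL)
#' @export
betaDi <- function(x) x@betaDi

#' @describeIn PSAM binding-mode label
#' @export
modeId <- function(x) x@modeId

#' @describeIn PSAM mononucleotide consensus sequence (ties resolved in
#'   A,C,G,T order)
#' @export
consensusSequence <- function(x) {
  paste(DNA_BASES4[apply(x@betaMono, 1L, which.max)], collapse = "")
}

setMethod("show", "PSAM", function(object) {
  cat("PSAM object\n")
  cat("  mode:     ", object@modeId, "\n", sep = "")
  cat("  k:        ", object@k, " bp\n", sep = "")
  cat("  consensus:", consensusSequence(object), "\n")
  cat("  dinucleotide terms:", if (is.null(object@betaDi)) "absent" else "present", "\n")
})

#' Genome-wide normalized affinity track
#'
#' Holds, per contig, the strand-summed relative affinities after
#' normalization to the genomic maximum, thresholding, and a windowed-maximum
#' smoothing of window length k. Values are run-length encoded.
#'
#' @slot values an \link[IRanges]{RleList}-like list of per-contig Rle vectors.
#' @slot k PSAM length that produced the track (also the smoothing window).
#' @slot threshold normalized affinities below this were zeroed.
#' @slot anchor windowed-maximum anchoring convention ("left").
#' @slot rawMax pre-normalization genomic maximum (strand-summed affinity).
#' @export
setClass("AffinityTrack", representation(
  values = "ANY",
  k = "integer",
  threshold = "numeric",
  anchor = "character",
  rawMax = "numeric"
))

setValidity("AffinityTrack", function(object) {
  msg <- character()
  if (length(object@values) == 0L) msg <- c(msg, "track has no contigs")
  if (is.null(names(object@values))) msg <- c(msg, "contigs must be named")
  if (!identical(object@anchor, "left")) msg <- c(msg, "anchor must be 'left'")
  if (object@threshold < 0) msg <- c(msg, "threshold must be >= 0")
  if (object@rawMax <= 0) msg <- c(msg, "rawMax must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn AffinityTrack per-contig Rle values
#' @param x an AffinityTrack
#' @export
trackValues <- function(x) x@values

#' @describeIn AffinityTrack threshold applied after normalization
#' @export
trackThreshold <- function(x) x@threshold

#' @describeIn AffinityTrack pre-normalization genomic maximum
#' @export
trackRawMax <- function(x) x@rawMax

setMethod("show", "AffinityTrack", function(object) {
  n <- sum(vapply(object@values, length, 1L))
  mx <- max(vapply(object@values, function(v) max(as.numeric(stats::na.omit(S4Vectors::runValue(v)))), 1.0))
  cat("AffinityTrack over", length(object@values), "contig(s),", n, "positions\n")
  cat("  k =", object@k, " threshold =", object@threshold,
      " anchor =", object@anchor, "\n")
  cat("  raw genomic maximum =", signif(object@rawMax, 6),
      " normalized maximum =", signif(mx, 6), "\n")
})

#' One-round SELEX read set
#'
#' @slot reads a \link[Biostrings]{DNAStringSet} of variable-region reads,
#'   all the same width (16 bp for monomer designs, 24 bp for dimer designs).
#' @slot round "R0" (unselected library) or "R1" (one selection round).
#' @slot fixedFlanks length-2 character vector of constant flank sequences.
#' @export
setClass("SelexReadSet", representation(
  reads = "ANY",
  round = "character",
  fixedFlanks = "character"
))

setValidity("SelexReadSet", function(object) {
  msg <- character()
  if (!is(object@reads, "DNAStringSet")) msg <- c(msg, "reads must be a DNAStringSet")
  else {
    w <- Biostrings::width(object@reads)
    if (length(w) && length(unique(w)) != 1L) {
      msg <- c(msg, "all reads must have identical variable length")
    }
    af <- Biostrings::alphabetFrequency(object@reads, collapse = TRUE)
    bad <- sum(af) - sum(af[DNA_BASES4])
    if (bad > 0) msg <- c(msg, "reads must use alphabet {A,C,G,T}")
  }
  if (!object@round %in% c("R0", "R1")) msg <- c(msg, "round must be R0 or R1")
  if (length(object@fixedFlanks) != 2L) msg <- c(msg, "fixedFlanks must be length 2")
  if (length(msg)) msg else TRUE
})

#' Construct a SelexReadSet
#' @param reads DNAStringSet or character vector of equal-length reads.
#' @param round "R0" or "R1".
#' @param fixedFlanks length-2 character vector of constant flanks.
#' @return a \linkS4class{SelexReadSet}.
#' @export
SelexReadSet <- function(reads, round = c("R0", "R1"), fixedFlanks = c("", "")) {
  round <- match.arg(round)
  if (!is(reads, "DNAStringSet")) reads <- Biostrings::DNAStringSet(reads)
  new("SelexReadSet", reads = reads, round = round, fixedFlanks = fixedFlanks)
}

#' @describeIn SelexReadSet the reads
#' @param x a SelexReadSet
#' @export
selexReads <- function(x) x@reads

#' @describeIn SelexReadSet variable-region length in bp
#' @export
variableLength <- function(x) {
  if (length(x@reads) == 0L) return(NA_integer_)
  Biostrings::width(x@reads)[1L]
}

#' @describeIn SelexReadSet selection round ("R0"/"R1")
#' @export
selexRound <- function(x) x@round

setMethod("show", "SelexReadSet", function(object) {
  cat("SelexReadSet:", length(object@reads), "reads, round", object@round,
      ", variable length", variableLength(object), "bp\n")
})

setMethod("length", "SelexReadSet", function(x) length(x@reads))

#' Simulation plan for the synthetic study design
#'
#' Describes a 2-condition x 2-replicate ChIP design with matched inputs and
#' a WT-vs-cofactor-interaction-mutant contrast in condition A. Default
#' values are the study conditions used throughout the test suite: 100
#' shared loci, 40 cofactor-dependent and 40 cofactor-independent
#' condition-A-specific loci, 20 other condition-A-specific loci, a planted
#' log2 fold change of 2, mean bound-locus depth 200, NB dispersion 0.1 and
#' background depth 10.
#'
#' @slot genomeLength genome length in bp.
#' @slot gc GC fraction of the random background sequence.
#' @slot nShared,nDependent,nIndependent,nOther planted locus counts per class.
#' @slot effectLog2fc planted log2 fold change of occupancy between conditions.
#' @slot meanDepth expected ChIP count at a fully bound locus.
#' @slot dispersion negative-binomial dispersion alpha (var = mu + alpha mu^2).
#' @slot inputDepth expected background (input) count per locus.
#' @slot peakDetectSlope logistic steepness for per-replicate peak-call emulation.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationPlan", representation(
  genomeLength = "integer", gc = "numeric",
  nShared = "integer", nDependent = "integer",
  nIndependent = "integer", nOther = "integer",
  effectLog2fc = "numeric", meanDepth = "numeric", dispersion = "numeric",
  inputDepth = "numeric", peakDetectSlope = "numeric", seed = "integer"
))

setValidity("SimulationPlan", function(object) {
  msg <- character()
  if (object@genomeLength < 1L) msg <- c(msg, "genomeLength must be >= 1")
  if (object@gc <= 0 || object@gc >= 1) msg <- c(msg, "gc must be in (0,1)")
  counts <- c(object@nShared, object@nDependent, object@nIndependent, object@nOther)
  if (any(counts < 0L)) msg <- c(msg, "locus counts must be >= 0")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be > 0")
  if (object@inputDepth < 0) msg <- c(msg, "inputDepth must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationPlan
#'
#' @param genomeLength,gc,nShared,nDependent,nIndependent,nOther,effectLog2fc
#'   see the class documentation.
#' @param meanDepth,dispersion,inputDepth,peakDetectSlope,seed see the class
#'   documentation.
#' @return a \linkS4class{SimulationPlan}.
#' @export
SimulationPlan <- function(genomeLength = 460000L, gc = 0.42,
                           nShared = 100L, nDependent = 40L,
                           nIndependent = 40L, nOther = 20L,
                           effectLog2fc = 2, meanDepth = 200,
                           dispersion = 0.1, inputDepth = 10,
                           peakDetectSlope = 0.05, seed = 1L) {
  new("SimulationPlan",
      genomeLength = as.integer(genomeLength), gc = gc,
      nShared = as.integer(nShared), nDependent = as.integer(nDependent),
      nIndependent = as.integer(nIndependent), nOther = as.integer(nOther),
      effectLog2fc = effectLog2fc, meanDepth = meanDepth,
      dispersion = dispersion, inputDepth = inputDepth,
      peakDetectSlope = peakDetectSlope, seed = as.integer(seed))
}

setMethod("show", "SimulationPlan", function(object) {
  cat("SimulationPlan:", object@genomeLength, "bp genome, GC", object@gc, "\n")
  cat("  loci: shared", object@nShared, "| cofactor-dependent", object@nDependent,
      "| cofactor-independent", object@nIndependent, "| other", object@nOther, "\n")
  cat("  effect log2fc", object@effectLog2fc, "| depth", object@meanDepth,
      "| dispersion", object@dispersion, "| input", object@inputDepth, "\n")
  cat("  seed", object@seed, "\n")
})

#' Run configuration for the full pipeline
#'
#' Aggregates every tunable parameter of the analysis, all defaulting to the
#' documented values: affinity threshold 1e-4, 50-bp occupancy flank, 250-bp
#' summit half-width, 1-kb/20-bp signal matrices, FDR < 0.05 for
#' differential loci, raw p > 0.1 for common loci, peak-set membership of at
#' least 2 (differential) and 3 (common) out of 4, |log2FC| > 1 for
#' differential accessibility, and 10-row strongest-motif tables.
#'
#' @slot stages character vector of pipeline stages to run, in order.
#' @slot outDir output directory.
#' @slot seed integer RNG seed used by every stochastic stage.
#' @slot plan a \linkS4class{SimulationPlan} (used by the simulate stage).
#' @slot affinityThreshold,flank,summitHalfwidth,matrixHalfwidth,matrixBinsize
#'   numeric parameters, see description.
#' @slot fdrDifferential,pCommon,minOverlapDifferential,minOverlapCommon
#'   classification thresholds, see description.
#' @slot lfcAccessibility,topNMotifs,selexReadCount,selexK further parameters.
#' @slot inputs named list of input file paths for stages that read data
#'   instead of simulating it.
#' @export
setClass("RunConfig", representation(
  stages = "character", outDir = "character", seed = "integer",
  plan = "SimulationPlan",
  affinityThreshold = "numeric", flank = "integer",
  summitHalfwidth = "integer", matrixHalfwidth = "integer",
  matrixBinsize = "integer", fdrDifferential = "numeric",
  pCommon = "numeric", minOverlapDifferential = "integer",
  minOverlapCommon = "integer", lfcAccessibility = "numeric",
  topNMotifs = "integer", selexReadCount = "integer", selexK = "integer",
  inputs = "list"
))

PIPELINE_STAGES <- c("simulate", "scan", "quantify", "classify",
                     "dependency", "selex-fit", "report")

setValidity("RunConfig", function(object) {
  msg <- character()
  if (!all(object@stages %in% PIPELINE_STAGES)) {
    msg <- c(msg, paste("stages must be among:", paste(PIPELINE_STAGES, collapse = ", ")))
  }
  if (object@affinityThreshold < 0 || object@affinityThreshold >= 1) {
    msg <- c(msg, "affinityThreshold must be in [0,1)")
  }
  if (object@flank < 1L) msg <- c(msg, "flank must be >= 1")
  if (object@summitHalfwidth < 1L) msg <- c(msg, "summitHalfwidth must be >= 1")
  if (object@matrixBinsize < 1L ||
      (2L * object@matrixHalfwidth) %% object@matrixBinsize != 0L) {
    msg <- c(msg, "matrixBinsize must divide 2*matrixHalfwidth")
  }
  for (p in c("fdrDifferential", "pCommon")) {
    v <- slot(object, p)
    if (v <= 0 || v >= 1) msg <- c(msg, paste(p, "must be in (0,1)"))
  }
  if (object@minOverlapDifferential < 1L) msg <- c(msg, "minOverlapDifferential must be >= 1")
  if (object@minOverlapCommon < 1L) msg <- c(msg, "minOverlapCommon must be >= 1")
  if (object@lfcAccessibility < 0) msg <- c(msg, "lfcAccessibility must be >= 0")
  if (object@topNMotifs < 1L) msg <- c(msg, "topNMotifs must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a RunConfig
#'
#' @param stages pipeline stages to run (default: all).
#' @param outDir output directory.
#' @param seed RNG seed.
#' @param plan a \linkS4class{SimulationPlan}.
#' @param affinityThreshold,flank,summitHalfwidth,matrixHalfwidth,matrixBinsize
#'   numeric parameters (see class documentation for defaults).
#' @param fdrDifferential,pCommon,minOverlapDifferential,minOverlapCommon
#'   classification thresholds.
#' @param lfcAccessibility,topNMotifs,selexReadCount,selexK further parameters.
#' @param inputs named list of input paths (for non-simulated runs).
#' @return a \linkS4class{RunConfig}.
#' @export
RunConfig <- function(stages = PIPELINE_STAGES, outDir = tempfile("run"),
                      seed = 1L, plan = SimulationPlan(seed = seed),
                      affinityThreshold = 1e-4, flank = 50L,
                      summitHalfwidth = 250L, matrixHalfwidth = 1000L,
                      matrixBinsize = 20L, fdrDifferential = 0.05,
                      pCommon = 0.1, minOverlapDifferential = 2L,
                      minOverlapCommon = 3L, lfcAccessibility = 1.0,
                      topNMotifs = 10L, selexReadCount = 20000L, selexK = 7L,
                      inputs = list()) {
  new("RunConfig", stages = stages, outDir = outDir, seed = as.integer(seed),
      plan = plan, affinityThreshold = affinityThreshold,
      flank = as.integer(flank), summitHalfwidth = as.integer(summitHalfwidth),
      matrixHalfwidth = as.integer(matrixHalfwidth),
      matrixBinsize = as.integer(matrixBinsize),
      fdrDifferential = fdrDifferential, pCommon = pCommon,
      minOverlapDifferential = as.integer(minOverlapDifferential),
      minOverlapCommon = as.integer(minOverlapCommon),
      lfcAccessibility = lfcAccessibility, topNMotifs = as.integer(topNMotifs),
      selexReadCount = as.integer(selexReadCount), selexK = as.integer(selexK),
      inputs = inputs)
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig\n")
  cat("  stages:", paste(object@stages, collapse = " -> "), "\n")
  cat("  seed:", object@seed, " outDir:", object@outDir, "\n")
  cat("  affinity threshold", object@affinityThreshold,
      "| flank", object@flank, "bp | summit halfwidth", object@summitHalfwidth, "bp\n")
  cat("  matrix", 2L * object@matrixHalfwidth, "bp /", object@matrixBinsize,
      "bp bins | FDR<", object@fdrDifferential, "| p>", object@pCommon,
      "| minOverlap", object@minOverlapDifferential, "/", object@minOverlapCommon, "\n")
})
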