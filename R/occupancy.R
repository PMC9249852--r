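# Consensus loci, per-locus occupancy scores, cross-sample scaling,
# peak-centered signal matrices and genomic-context annotation.

# 1-based peak center: summit when present, else interval midpoint (floor of
# the 0-based midpoint).
peakCenters <- function(peaks, warnMissing = TRUE) {
  summit <- mcols(peaks)$summit
  if (is.null(summit)) summit <- rep(NA_integer_, length(peaks))
  missing <- is.na(summit)
  if (any(missing) && warnMissing) {
    message(sum(missing), " peak(s) lack a summit; using interval midpoints")
  }
  mid0 <- (start(peaks) - 1L + end(peaks)) %/% 2L  # floor of 0-based midpoint
  ifelse(missing, mid0 + 1L, as.integer(summit))
}

#' Build consensus loci from replicate peak sets
#'
#' Each peak is re-centered to a 501-bp window around its summit (summit
#' +/- 250 bp); overlapping re-centered windows across all sets are merged
#' into one locus whose center is the floor of the mean of the contributing
#' summits. A membership indicator records which peak sets contributed, and
#' loci are retained only when at least \code{minOverlap} sets did. Peaks
#' without summits fall back to interval midpoints (logged).
#'
#' @param peakSets list of >= 2 GRanges as returned by \code{\link{readPeaks}}.
#' @param minOverlap minimum number of contributing peak sets (default 2).
#' @param summitHalfwidth re-centering half-width in bp (default 250).
#' @return a GRanges of merged loci with mcols \code{locus_id},
#'   \code{center} (1-based), \code{n_members}, and a logical membership
#'   matrix column \code{membership} (loci x peak sets).
#' @export
consensusLoci <- function(peakSets, minOverlap = 2L, summitHalfwidth = 250L) {
  if (!is.list(peakSets) || length(peakSets) < 2L) {
    stop("need a list of at least 2 peak sets")
  }
  nset <- length(peakSets)
  centers <- lapply(peakSets, peakCenters)
  recentered <- lapply(seq_len(nset), function(i) {
    p <- peakSets[[i]]
    if (length(p) == 0L) return(GRanges())
    GRanges(seqnames(p),
            IRanges(start = pmax(1L, centers[[i]] - summitHalfwidth),
                    end = centers[[i]] + summitHalfwidth),
            set = i, summit = centers[[i]])
  })
  pool <- suppressWarnings(do.call(c, recentered))
  if (length(pool) == 0L) return(GRanges())
  merged <- reduce(pool, ignore.strand = TRUE)
  hits <- findOverlaps(pool, merged, ignore.strand = TRUE)
  byLocus <- split(queryHits(hits), subjectHits(hits))
  membership <- matrix(FALSE, nrow = length(merged), ncol = nset)
  center <- integer(length(merged))
  for (j in seq_along(merged)) {
    idx <- byLocus[[as.character(j)]]
    membership[j, unique(pool$set[idx])] <- TRUE
    center[j] <- floor(mean(pool$summit[idx]))
  }
  keep <- rowSums(membership) >= minOverlap
  merged <- merged[keep]
  if (length(merged) == 0L) {
    mcols(merged)$locus_id <- character()
    mcols(merged)$center <- integer()
    mcols(merged)$n_members <- integer()
    mcols(merged)$membership <- membership[0L, , drop = FALSE]
    return(merged)
  }
  mcols(merged)$locus_id <- paste0("locus_", seq_along(merged))
  mcols(merged)$center <- center[keep]
  mcols(merged)$n_members <- rowSums(membership)[keep]
  mcols(merged)$membership <- membership[keep, , drop = FALSE]
  merged
}

#' Union loci across peak sets (background universes)
#'
#' Identical machinery to \code{\link{consensusLoci}}; used to build the
#' "called in at least m of n ChIP or ATAC experiments" universes that feed
#' no FDR rule. Mixed ChIP and ATAC peak sets are accepted.
#'
#' @inheritParams consensusLoci
#' @return as \code{\link{consensusLoci}}.
#' @export
unionLoci <- function(peakSets, minOverlap = 2L, summitHalfwidth = 250L) {
  consensusLoci(peakSets, minOverlap = minOverlap,
                summitHalfwidth = summitHalfwidth)
}

#' Occupancy score of a locus: the 100-bp window sum
#'
#' Sums the per-base signal over the half-open window
#' [center - flank, center + flank) in 0-based terms - exactly
#' \code{2 * flank} bases (100 by default), from 50 bp upstream to 50 bp
#' downstream of the peak center.
#'
#' @param track an RleList coverage track (see \code{\link{readCoverage}}).
#' @param contig contig name.
#' @param center 1-based peak center.
#' @param flank half-width in bp (default 50).
#' @return the window sum; windows truncated at contig edges sum the
#'   available bases (with a warning).
#' @export
locusScore <- function(track, contig, center, flank = 50L) {
  v <- track[[contig]]
  if (is.null(v)) stop("contig not in track: ", contig)
  n <- length(v)
  if (center < 1L || center > n) stop("center outside contig ", contig)
  s <- center - flank
  e <- center + flank - 1L
  if (s < 1L || e > n) {
    warning("locus window truncated at contig edge")
    s <- max(1L, s); e <- min(n, e)
  }
  sum(as.numeric(S4Vectors::window(v, start = s, end = e)))
}

#' Scores for many loci against one track
#' @param loci GRanges with a \code{center} mcol (from \code{\link{consensusLoci}}).
#' @param track an RleList coverage track.
#' @param flank half-width in bp.
#' @return numeric vector of locus scores, named by locus_id.
#' @export
locusScores <- function(loci, track, flank = 50L) {
  out <- vapply(seq_along(loci), function(i) {
    locusScore(track, as.character(seqnames(loci))[i],
               mcols(loci)$center[i], flank = flank)
  }, 1.0)
  names(out) <- mcols(loci)$locus_id
  out
}

#' Cross-sample scaling factor from shared loci
#'
#' Returns \code{mean(scoresA[shared]) / mean(scoresB[shared])}; multiplying
#' sample B's scores by the factor makes the two means equal exactly. This
#' is the normalization that puts two ChIP data sets on a common scale using
#' the loci they occupy equally.
#'
#' @param scoresA,scoresB named numeric score vectors.
#' @param sharedIds locus ids of the shared ("common") loci.
#' @return a positive scalar.
#' @export
scalingFactor <- function(scoresA, scoresB, sharedIds) {
  if (length(sharedIds) == 0L) stop("shared locus set is empty")
  a <- scoresA[sharedIds]; b <- scoresB[sharedIds]
  if (anyNA(a) || anyNA(b)) stop("shared ids missing from score vectors")
  mb <- mean(b)
  if (mb <= 0) stop("mean score of sample B over shared loci is not positive")
  mean(a) / mb
}

#' Peak-centered signal matrix
#'
#' For each locus the window [center - halfwidth, center + halfwidth) is cut
#' into bins of \code{binsize} bp and each bin takes the mean per-base
#' signal; with the 1-kb half-width and 20-bp bins this yields exactly 100
#' columns. Rows keep the input locus order. Bins truncated by a contig edge
#' average the available bases; rows entirely off-contig are zero (logged).
#'
#' @param loci GRanges with \code{center} mcols.
#' @param track an RleList coverage track.
#' @param halfwidth window half-width in bp (default 1000).
#' @param binsize bin size in bp (default 20; must divide 2*halfwidth).
#' @return numeric matrix, loci x bins, rownames = locus_id.
#' @export
signalMatrix <- function(loci, track, halfwidth = 1000L, binsize = 20L) {
  if ((2L * halfwidth) %% binsize != 0L) stop("binsize must divide 2*halfwidth")
  nbin <- (2L * halfwidth) %/% binsize
  out <- matrix(0, nrow = length(loci), ncol = nbin)
  rownames(out) <- mcols(loci)$locus_id
  for (i in seq_along(loci)) {
    ctg <- as.character(seqnames(loci))[i]
    v <- track[[ctg]]
    if (is.null(v)) stop("contig not in track: ", ctg)
    n <- length(v)
    c1 <- mcols(loci)$center[i]
    ws <- c1 - halfwidth          # 1-based start of the window
    if (ws > n || ws + 2L * halfwidth - 1L < 1L) {
      message("locus ", rownames(out)[i], " entirely off contig; zero row")
      next
    }
    for (b in seq_len(nbin)) {
      bs <- ws + (b - 1L) * binsize
      be <- bs + binsize - 1L
      s <- max(1L, bs); e <- min(n, be)
      if (s <= e) {
        out[i, b] <- mean(as.numeric(S4Vectors::window(v, start = s, end = e)))
      }
    }
  }
  out
}

#' Annotate loci by genomic context
#'
#' Classifies each locus center with precedence TSS > TTS > exon > intron >
#' intergenic. The promoter (TSS) window is strand-aware
#' [TSS - 1000, TSS + 100] (0-based, upstream negative); the TTS window
#' mirrors it as [TTS - 100, TTS + 1000]. Intron means inside a gene body
#' but not in an exon.
#'
#' @param loci GRanges with \code{center} mcols (1-based centers).
#' @param genes gene table from \code{\link{readGeneAnnotation}}.
#' @return factor of labels (TSS, TTS, exon, intron, intergenic), one per
#'   locus.
#' @export
annotateLoci <- function(loci, genes) {
  labels <- factor(rep("intergenic", length(loci)),
                   levels = c("TSS", "TTS", "exon", "intron", "intergenic"))
  if (length(loci) == 0L) return(labels)
  centers0 <- mcols(loci)$center - 1L   # 0-based center positions
  contigs <- as.character(seqnames(loci))
  for (i in seq_along(loci)) {
    c0 <- centers0[i]
    g <- genes[genes$contig == contigs[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    plus <- g$strand == "+"
    tssLo <- ifelse(plus, g$tss - 1000L, g$tss - 100L)
    tssHi <- ifelse(plus, g$tss + 100L, g$tss + 1000L)
    ttsLo <- ifelse(plus, g$tts - 100L, g$tts - 1000L)
    ttsHi <- ifelse(plus, g$tts + 1000L, g$tts + 100L)
    if (any(c0 >= tssLo & c0 <= tssHi)) { labels[i] <- "TSS"; next }
    if (any(c0 >= ttsLo & c0 <= ttsHi)) { labels[i] <- "TTS"; next }
    inBody <- c0 >= g$start & c0 < g$end
    if (any(inBody)) {
      inExon <- vapply(which(inBody), function(j) {
        ex <- g$exons[[j]]
        any(c0 >= ex[, 1L] & c0 < ex[, 2L])
      }, TRUE)
      labels[i] <- if (any(inExon)) "exon" else "intron"
    }
  }
  labels
}

#' Pearson correlation between two locus score vectors
#'
#' Thin wrapper around \code{stats::cor.test} (the standard product-moment
#' coefficient), with explicit errors for degenerate input.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the correlation coefficient.
#' @export
pearsonCor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  unname(stats::cor.test(x, y, method = "pearson")$estimate)
}
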