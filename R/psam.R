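# PSAM scanning: relative affinities at every genome offset, strand-summed,
# normalized to the genomic maximum, thresholded, windowed-maximum smoothed.

# Encode a sequence as integer codes 1..4 (A,C,G,T); N and anything else -> NA.
encodeSequence <- function(seq) {
  if (is(seq, "DNAString") || is(seq, "DNAStringSet")) seq <- as.character(seq)
  codes <- match(strsplit(toupper(seq), "")[[1L]], DNA_BASES4)
  codes
}

# Reverse-complement a PSAM: scoring a window on the minus strand equals
# scoring the forward window with the reverse-complemented model.
psamRevComp <- function(psam) {
  k <- psam@k
  comp <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G in A,C,G,T order
  bm <- psam@betaMono[k:1, comp, drop = FALSE]
  colnames(bm) <- DNA_BASES4
  bd <- NULL
  if (!is.null(psam@betaDi) && k >= 2L) {
    # di column index for (b1,b2) is b1 + 4*(b2-1); rc maps position i to
    # k-i and pair (b1,b2) to (comp b2, comp b1)
    idx <- integer(16L)
    for (b1 in 1:4) for (b2 in 1:4) {
      idx[b1 + 4L * (b2 - 1L)] <- comp[b2] + 4L * (comp[b1] - 1L)
    }
    bd <- psam@betaDi[(k - 1L):1L, idx, drop = FALSE]
    colnames(bd) <- DINUCS
  }
  new("PSAM", k = k, betaMono = bm, betaDi = bd, modeId = psam@modeId)
}

# Vectorized per-offset log-scores of a forward-strand scan. codes: integer
# codes of the full sequence. Returns numeric of length n-k+1 with NA where
# any window base is N.
scanLogScores <- function(codes, psam) {
  n <- length(codes)
  k <- psam@k
  nw <- n - k + 1L
  sc <- numeric(nw)
  bm <- psam@betaMono
  for (i in seq_len(k)) {
    row <- unname(bm[i, ])
    sc <- sc + row[codes[i:(nw + i - 1L)]]
  }
  if (!is.null(psam@betaDi) && k >= 2L) {
    bd <- psam@betaDi
    for (i in seq_len(k - 1L)) {
      b1 <- codes[i:(nw + i - 1L)]
      b2 <- codes[(i + 1L):(nw + i)]
      row <- unname(bd[i, ])
      sc <- sc + row[b1 + 4L * (b2 - 1L)]
    }
  }
  sc
}

#' Relative affinity of a single k-mer window
#'
#' Returns \eqn{exp(\sum_i \beta_{mono}[i,b_i] + \sum_i \beta_{di}[i,(b_i,b_{i+1})])}.
#' Under the per-position max-0 convention the mononucleotide consensus
#' scores exactly 1 when dinucleotide terms are absent. A window containing
#' N scores 0. On the minus strand the reverse complement of the window is
#' scored.
#'
#' @param window a k-mer (character or DNAString).
#' @param psam a \linkS4class{PSAM}.
#' @param strand "+" or "-".
#' @return a relative affinity in [0, 1] (mono-only models).
#' @export
relativeAffinity <- function(window, psam, strand = "+") {
  codes <- encodeSequence(window)
  if (length(codes) != psam@k) {
    stop("window length ", length(codes), " does not match PSAM k = ", psam@k)
  }
  model <- if (strand == "-") psamRevComp(psam) else psam
  sc <- scanLogScores(codes, model)
  if (is.na(sc)) 0 else exp(sc)
}

#' Scan a sequence: strand-summed raw affinities at every offset
#'
#' Entry j is the relative affinity of the window starting at offset j on
#' the plus strand plus the affinity of its reverse complement (the minus
#' strand at the same offset). Windows containing N contribute 0.
#'
#' @param seq a contig sequence (character or DNAString).
#' @param psam a \linkS4class{PSAM}.
#' @param contig contig name used in error messages.
#' @return numeric vector of length \code{length(seq) - k + 1}.
#' @export
scanSequence <- function(seq, psam, contig = "sequence") {
  codes <- encodeSequence(seq)
  if (length(codes) < psam@k) {
    stop("contig '", contig, "' is shorter (", length(codes),
         " bp) than PSAM k = ", psam@k)
  }
  fwd <- exp(scanLogScores(codes, psam))
  rev <- exp(scanLogScores(codes, psamRevComp(psam)))
  out <- fwd + rev
  out[is.na(out)] <- 0
  out
}

#' Left-anchored windowed maximum
#'
#' \code{out[i] = max(values[i .. min(i + k, n) - 1])}: each position takes
#' the maximum over the window of length k starting there, with truncated
#' windows at the right edge, so the output has the input's length.
#'
#' @param values numeric vector.
#' @param k window length (>= 1).
#' @param anchor anchoring convention; only "left" is implemented.
#' @return numeric vector of \code{length(values)}.
#' @export
windowedMax <- function(values, k, anchor = "left") {
  if (k < 1L) stop("window length k must be >= 1")
  anchor <- match.arg(anchor, "left")
  n <- length(values)
  if (n == 0L || k == 1L) return(values)
  out <- values
  for (s in seq_len(min(k - 1L, n - 1L))) {
    out <- pmax(out, c(values[-seq_len(s)], rep(-Inf, s)))
  }
  out
}

#' Build a genome-wide normalized affinity track
#'
#' The pipeline runs in this fixed order: (1) strand-summed relative
#' affinity at every offset of every contig; (2) division of all values by
#' the global maximum across contigs; (3) zeroing of normalized values below
#' \code{threshold}; (4) left-anchored windowed maximum with window length
#' k. The pre-normalization maximum is retained in the track metadata.
#'
#' @param genome a DNAStringSet.
#' @param psam a \linkS4class{PSAM}, or a list of PSAMs treated as modes of
#'   one model whose raw affinities are summed before normalization.
#' @param threshold normalized affinities below this are set to 0
#'   (default 1e-4).
#' @return an \linkS4class{AffinityTrack}. Per-offset values are padded with
#'   trailing zeros so each contig's track has the contig's full length.
#' @export
buildAffinityTrack <- function(genome, psam, threshold = 1e-4) {
  if (length(genome) == 0L) stop("genome is empty")
  psams <- if (is.list(psam)) psam else list(psam)
  k <- psams[[1L]]@k
  if (!all(vapply(psams, function(p) p@k, 1L) == k)) {
    stop("all modes of a multi-mode model must share k")
  }
  raw <- lapply(seq_along(genome), function(ci) {
    seq <- genome[[ci]]
    v <- scanSequence(seq, psams[[1L]], contig = names(genome)[ci])
    for (p in psams[-1L]) v <- v + scanSequence(seq, p, contig = names(genome)[ci])
    v
  })
  names(raw) <- names(genome)
  rawMax <- max(vapply(raw, function(v) if (length(v)) max(v) else 0, 1.0))
  if (rawMax <= 0) stop("no scorable window: all windows score 0")
  lens <- width(genome)
  vals <- lapply(seq_along(raw), function(ci) {
    v <- raw[[ci]] / rawMax
    v[v < threshold] <- 0
    v <- windowedMax(v, k)
    # pad to full contig length: the last k-1 positions start no window
    c(v, numeric(lens[ci] - length(v)))
  })
  names(vals) <- names(genome)
  new("AffinityTrack",
      values = RleList(lapply(vals, Rle), compress = FALSE),
      k = k, threshold = threshold, anchor = "left", rawMax = rawMax)
}

#' Table of the strongest motif matches in a sequence
#'
#' Scores every offset on both strands separately (per-strand, not
#' strand-summed, so each hit has a defined strand), normalizes to
#' \code{normalizeTo} (by default the sequence maximum; pass an
#' \linkS4class{AffinityTrack}'s \code{trackRawMax} companion value to
#' normalize to the genome maximum), sorts by affinity descending with ties
#' broken by (offset, + strand first), and returns the first n hits.
#'
#' @param seq sequence to scan.
#' @param psam a \linkS4class{PSAM}.
#' @param n number of hits to return (default 10; fewer if fewer exist).
#' @param normalizeTo raw affinity corresponding to 1.0; default NULL means
#'   the per-strand maximum of this sequence.
#' @param contig contig label for the output table.
#' @return data.frame with columns contig, offset (0-based window start),
#'   strand, relative_affinity.
#' @export
topMotifs <- function(seq, psam, n = 10L, normalizeTo = NULL, contig = "seq") {
  codes <- encodeSequence(seq)
  if (length(codes) < psam@k) stop("sequence shorter than PSAM k")
  fwd <- exp(scanLogScores(codes, psam))
  rev <- exp(scanLogScores(codes, psamRevComp(psam)))
  fwd[is.na(fwd)] <- 0
  rev[is.na(rev)] <- 0
  nm <- if (is.null(normalizeTo)) max(fwd, rev) else normalizeTo
  if (nm <= 0) stop("no scorable window in sequence")
  nw <- length(fwd)
  df <- data.frame(
    contig = contig,
    offset = c(seq_len(nw), seq_len(nw)) - 1L,
    strand = rep(c("+", "-"), each = nw),
    relative_affinity = c(fwd, rev) / nm,
    stringsAsFactors = FALSE
  )
  ord <- order(-df$relative_affinity, df$offset, df$strand)
  df <- df[ord, , drop = FALSE][seq_len(min(n, nrow(df))), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Extract an affinity-track value window around a position
#' @param track an \linkS4class{AffinityTrack}.
#' @param contig contig name.
#' @param start1,end1 1-based inclusive window.
#' @return numeric vector of values.
#' @export
trackWindow <- function(track, contig, start1, end1) {
  v <- track@values[[contig]]
  if (is.null(v)) stop("contig not in track: ", contig)
  as.numeric(S4Vectors::window(v, start = start1, end = end1))
}

#' Export an affinity track as bedGraph (4 decimal places, runs merged)
#' @param track an \linkS4class{AffinityTrack}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeAffinityTrack <- function(track, path) {
  writeCoverage(track@values, path, digits = 4L)
  invisible(path)
}
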