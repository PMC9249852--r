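# Cofactor-dependency ordering: loci are split by the sign of the
# WT-vs-mutant log2 fold change, the WT>mut class is sorted by FDR
# ascending, the WT<mut class by FDR descending, and the two blocks are
# concatenated; high-confidence dependent/independent labels come from
# overlap with reference locus classes.

#' Order loci by cofactor dependency
#'
#' @param loci GRanges of the loci to order (with \code{locus_id} mcols).
#' @param wtVsMut data.frame with locus_id, log2fc, fdr from the
#'   WT-vs-cofactor-interaction-mutant contrast; every locus must appear.
#' @return data.frame ordered by decreasing inferred dependency, with
#'   columns rank, locus_id, sign ("WT_gt_mut"/"WT_lt_mut"), fdr, contig,
#'   start, end. Loci with log2fc exactly 0 join the positive class
#'   (logged). Ties within a class break by (contig, start).
#' @export
dependencySort <- function(loci, wtVsMut) {
  ids <- mcols(loci)$locus_id
  m <- match(ids, wtVsMut$locus_id)
  if (anyNA(m)) stop("every locus needs a WT-vs-mutant record")
  lfc <- wtVsMut$log2fc[m]
  fdr <- wtVsMut$fdr[m]
  if (any(lfc == 0)) {
    message(sum(lfc == 0), " locus/loci with log2fc exactly 0 assigned to the WT>mut class")
  }
  pos <- lfc >= 0
  df <- data.frame(locus_id = ids,
                   sign = ifelse(pos, "WT_gt_mut", "WT_lt_mut"),
                   fdr = fdr,
                   contig = as.character(seqnames(loci)),
                   start = start(loci), end = end(loci),
                   stringsAsFactors = FALSE)
  op <- order(df$fdr[pos], df$contig[pos], df$start[pos])
  on <- order(-df$fdr[!pos], df$contig[!pos], df$start[!pos])
  out <- rbind(df[pos, , drop = FALSE][op, ], df[!pos, , drop = FALSE][on, ])
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", "locus_id", "sign", "fdr", "contig", "start", "end")]
}

#' High-confidence dependency boundaries and labels
#'
#' The last ordered locus overlapping (>= 1 bp) the reference dependent
#' class sets the dependent boundary \code{iDep}; the first ordered locus
#' overlapping the reference independent class sets \code{iInd}. Ranks
#' 1..iDep are labeled dependent, iInd..n independent, and the ranks in
#' between ambiguous. When the boundaries cross (iDep >= iInd) the loci
#' between them are flagged "conflict" and the run continues with a
#' warning.
#'
#' @param ordering data.frame from \code{\link{dependencySort}}.
#' @param dependentRef GRanges of the reference WT>mut differential class.
#' @param independentRef GRanges of the reference WT~mut common class.
#' @return the ordering with added \code{label} column (dependent /
#'   ambiguous / independent / conflict) plus attributes \code{iDep} and
#'   \code{iInd}.
#' @export
confidenceBoundaries <- function(ordering, dependentRef, independentRef) {
  gr <- GRanges(ordering$contig,
                IRanges(start = ordering$start, end = ordering$end))
  ovDep <- overlapsAnyRef(gr, dependentRef)
  ovInd <- overlapsAnyRef(gr, independentRef)
  n <- nrow(ordering)
  iDep <- if (any(ovDep)) max(which(ovDep)) else 0L
  iInd <- if (any(ovInd)) min(which(ovInd)) else n + 1L
  label <- rep("ambiguous", n)
  if (iDep >= iInd) {
    warning("dependency boundaries conflict (iDep >= iInd); flagging overlap zone")
    if (iInd <= n) label[iInd:n] <- "independent"
    if (iDep >= 1L) label[seq_len(iDep)] <- "dependent"
    label[iInd:iDep] <- "conflict"
  } else {
    if (iDep >= 1L) label[seq_len(iDep)] <- "dependent"
    if (iInd <= n) label[iInd:n] <- "independent"
  }
  ordering$label <- label
  attr(ordering, "iDep") <- iDep
  attr(ordering, "iInd") <- iInd
  ordering
}

overlapsAnyRef <- function(gr, ref) {
  if (is.null(ref) || length(ref) == 0L) return(rep(FALSE, length(gr)))
  IRanges::overlapsAny(gr, ref, minoverlap = 1L, ignore.strand = TRUE)
}
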