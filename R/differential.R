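# Count-based differential occupancy: median-of-ratios normalization,
# method-of-moments NB dispersion with shrinkage, a delta-method Wald test,
# Benjamini-Hochberg correction, and the membership-based locus
# classification rules.

#' Assemble a ChIP count container
#'
#' @param counts loci x samples integer matrix (rownames = locus ids).
#' @param condition character/factor of per-sample conditions.
#' @param replicate per-sample replicate labels.
#' @param isInput logical; TRUE for matched input (control) samples, which
#'   are carried along but excluded from testing.
#' @return a \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{counts} and colData columns condition, replicate, is_input.
#' @export
makeCountMatrix <- function(counts, condition, replicate, isInput = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(isInput)) isInput <- rep(FALSE, ncol(counts))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(condition = as.character(condition),
                                   replicate = as.character(replicate),
                                   is_input = isInput))
}

#' Write a count container as TSV with metadata header lines
#'
#' Emits \code{#condition}, \code{#replicate} and \code{#is_input} header
#' lines followed by a locus_id column and one column per sample.
#'
#' @param se SummarizedExperiment from \code{\link{makeCountMatrix}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeCountMatrix <- function(se, path) {
  cd <- SummarizedExperiment::colData(se)
  cm <- SummarizedExperiment::assay(se, "counts")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#condition\t", paste(cd$condition, collapse = "\t")),
               paste0("#replicate\t", paste(cd$replicate, collapse = "\t")),
               paste0("#is_input\t", paste(cd$is_input, collapse = "\t")),
               paste(c("locus_id", colnames(cm)), collapse = "\t")), con)
  writeLines(apply(cbind(rownames(cm), cm), 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a count container written by \code{\link{writeCountMatrix}}
#' @param path TSV path.
#' @return a SummarizedExperiment.
#' @export
readCountMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  getMeta <- function(key) {
    row <- meta[startsWith(meta, paste0("#", key, "\t"))]
    if (length(row) != 1L) stop("count matrix lacks #", key, " header")
    strsplit(row, "\t", fixed = TRUE)[[1L]][-1L]
  }
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t", check.names = FALSE)
  cm <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(cm) <- tab[[1L]]
  makeCountMatrix(cm, condition = getMeta("condition"),
                  replicate = getMeta("replicate"),
                  isInput = as.logical(getMeta("is_input")))
}

#' Median-of-ratios size factors
#'
#' Per-sample factors computed against the per-locus geometric-mean
#' reference over loci with all-positive counts, then renormalized to
#' geometric mean 1. When no locus has all-positive counts the function
#' falls back to total-count factors (logged).
#'
#' @param counts loci x samples numeric matrix.
#' @return positive numeric vector, one factor per sample.
#' @export
computeSizeFactors <- function(counts) {
  counts <- as.matrix(counts)
  allpos <- rowSums(counts <= 0) == 0L
  if (any(allpos)) {
    sub <- counts[allpos, , drop = FALSE]
    ref <- exp(rowMeans(log(sub)))
    sf <- apply(sub / ref, 2L, stats::median)
  } else {
    message("no all-positive locus; falling back to total-count size factors")
    sf <- colSums(counts)
  }
  if (any(sf <= 0)) stop("non-positive size factor")
  sf / exp(mean(log(sf)))
}

#' Method-of-moments NB dispersion estimates
#'
#' On normalized counts, each locus and condition yields the clipped
#' moment estimate \code{alpha = max(0, (s^2 - m) / m^2)}; per-locus
#' estimates average the conditions. The common dispersion pools moments
#' across all loci and conditions,
#' \code{alpha_common = max(0, (mean(s^2) - mean(m)) / mean(m^2))}, which
#' is unbiased at these replicate numbers where clipped-and-averaged
#' per-locus values are not. Per-locus values shrunk half-way toward the
#' common one are returned for diagnostics; with two replicates per
#' condition they remain far too noisy to plug into a Wald test (their
#' sampling error is correlated with the observed mean difference and
#' inflates the type-I error), so \code{\link{nbWaldTest}} defaults to the
#' common value.
#'
#' @param counts loci x samples count matrix (ChIP samples only).
#' @param condition per-sample condition labels (>= 2 replicates each).
#' @param sizeFactors per-sample size factors.
#' @return list with \code{common} (pooled-moment common dispersion),
#'   \code{perLocus} (50/50-shrunk per-locus dispersions) and \code{raw}
#'   (unshrunk per-locus estimates).
#' @export
estimateDispersion <- function(counts, condition, sizeFactors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(counts)
  norm <- sweep(counts, 2L, sizeFactors, "/")
  conds <- unique(as.character(condition))
  m2 <- s2all <- mall <- NULL
  perCond <- sapply(conds, function(cc) {
    sub <- norm[, condition == cc, drop = FALSE]
    if (ncol(sub) < 2L) stop("need >= 2 replicates per condition")
    m <- rowMeans(sub)
    s2 <- apply(sub, 1L, stats::var)
    mall <<- c(mall, m); s2all <<- c(s2all, s2); m2 <<- c(m2, m^2)
    a <- (s2 - m) / m^2
    a[!is.finite(a)] <- 0
    pmax(0, a)
  })
  raw <- rowMeans(perCond)
  common <- max(0, (mean(s2all) - mean(mall)) / mean(m2))
  list(common = common, perLocus = 0.5 * common + 0.5 * raw, raw = raw)
}

#' Negative-binomial Wald test for two-condition differential occupancy
#'
#' log2 fold change is \code{log2((meanA + 0.5) / (meanB + 0.5))} on
#' normalized counts (the 0.5 pseudocount avoids infinities at zero
#' counts). The two-sided p-value comes from a Wald test of the log-mean
#' difference whose variance is the delta-method propagation of the NB
#' variance \code{mu + alpha mu^2} of a replicate mean:
#' \code{var(log mean) = (1/mu + alpha) / n}.
#'
#' @param counts loci x samples count matrix (ChIP samples only).
#' @param condition per-sample condition labels; exactly two conditions.
#' @param contrast length-2 character: (A, B); log2fc is A over B.
#' @param sizeFactors optional per-sample size factors.
#' @param dispersion optional per-locus dispersions; estimated when NULL.
#' @return data.frame with columns locus_id, log2fc, p.
#' @export
nbWaldTest <- function(counts, condition, contrast = NULL,
                       sizeFactors = NULL, dispersion = NULL) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  conds <- unique(condition)
  if (length(conds) != 2L) stop("exactly two conditions required")
  if (is.null(contrast)) contrast <- conds
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(counts)
  if (is.null(dispersion)) {
    dispersion <- estimateDispersion(counts, condition, sizeFactors)$common
  }
  if (any(dispersion < 0)) stop("dispersion must be >= 0")
  norm <- sweep(counts, 2L, sizeFactors, "/")
  selA <- condition == contrast[1L]
  selB <- condition == contrast[2L]
  nA <- sum(selA); nB <- sum(selB)
  mA <- rowMeans(norm[, selA, drop = FALSE]) + 0.5
  mB <- rowMeans(norm[, selB, drop = FALSE]) + 0.5
  log2fc <- log2(mA / mB)
  se <- sqrt((1 / mA + dispersion) / nA + (1 / mB + dispersion) / nB)
  z <- (log(mA) - log(mB)) / se
  p <- 2 * stats::pnorm(-abs(z))
  ids <- rownames(counts)
  if (is.null(ids)) ids <- paste0("locus_", seq_len(nrow(counts)))
  data.frame(locus_id = ids, log2fc = unname(log2fc), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up BH with the monotone cumulative minimum, mapped back to the input
#' order. Equivalent to \code{p.adjust(method = "BH")}, exposed with the
#' package's input validation.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return FDR values in the input order.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Null-anchored size factors for a two-condition contrast
#'
#' Replicates within each condition share expectations, so within-condition
#' factors come from unbiased median-of-ratios. The between-condition
#' offset cannot be estimated that way when differential occupancy is
#' pervasive and one-directional (the median then falls between the null
#' and the changed cluster), so it is taken from the per-locus log2
#' mean-ratio density: the local mode nearest zero is assumed to be the
#' unchanged-loci cluster and is shifted to zero. Factors are returned with
#' geometric mean 1.
#'
#' @param counts loci x samples count matrix (ChIP samples of the contrast).
#' @param condition per-sample condition labels (two conditions).
#' @return positive per-sample factors, geometric mean 1.
#' @export
nullModeSizeFactors <- function(counts, condition) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  conds <- unique(condition)
  if (length(conds) != 2L) stop("exactly two conditions required")
  sf <- rep(1, ncol(counts))
  for (cc in conds) {
    sel <- condition == cc
    if (sum(sel) > 1L) sf[sel] <- computeSizeFactors(counts[, sel, drop = FALSE])
  }
  norm <- sweep(counts, 2L, sf, "/")
  mA <- rowMeans(norm[, condition == conds[1L], drop = FALSE]) + 0.5
  mB <- rowMeans(norm[, condition == conds[2L], drop = FALSE]) + 0.5
  M <- log2(mA / mB)
  d <- stats::density(M)
  pk <- which(diff(sign(diff(d$y))) == -2L) + 1L
  pk <- pk[d$y[pk] >= 0.25 * max(d$y)]
  offset <- if (length(pk)) d$x[pk[which.min(abs(d$x[pk]))]] else 0
  # shifting the B condition by 2^offset moves the null cluster to M = 0
  sf[condition == conds[2L]] <- sf[condition == conds[2L]] / 2^offset
  sf / exp(mean(log(sf)))
}

#' Full differential-occupancy records for a two-condition contrast
#'
#' Runs size-factor normalization, dispersion estimation, the NB Wald test
#' and BH adjustment over the ChIP (non-input) samples of a count
#' container. The default normalization is null-anchored
#' (\code{\link{nullModeSizeFactors}}), which stays calibrated when a large
#' one-directional fraction of loci is differential - the regime
#' paralog-specific binding creates; \code{"median-ratio"} applies plain
#' \code{\link{computeSizeFactors}} and \code{"none"} unit factors.
#'
#' @param se SummarizedExperiment from \code{\link{makeCountMatrix}}.
#' @param contrast length-2 character (A, B); log2fc is A over B.
#' @param normalization one of "null-mode", "median-ratio", "none".
#' @return data.frame with locus_id, log2fc, p, fdr.
#' @export
differentialOccupancy <- function(se, contrast,
                                  normalization = c("null-mode",
                                                    "median-ratio", "none")) {
  normalization <- match.arg(normalization)
  cd <- SummarizedExperiment::colData(se)
  keep <- !cd$is_input & cd$condition %in% contrast
  counts <- SummarizedExperiment::assay(se, "counts")[, keep, drop = FALSE]
  condition <- cd$condition[keep]
  sf <- switch(normalization,
               "null-mode" = nullModeSizeFactors(counts, condition),
               "median-ratio" = computeSizeFactors(counts),
               "none" = rep(1, ncol(counts)))
  res <- nbWaldTest(counts, condition, contrast = contrast, sizeFactors = sf)
  res$fdr <- bhAdjust(res$p)
  res
}

#' Classify loci as paralog-differential, common or unclassified
#'
#' A locus is differential when it was called a peak in at least
#' \code{mDiff} of the input experiments and has FDR below \code{fdrLt}
#' (the sign of log2fc splits A>B from A<B); it is common when called in at
#' least \code{mCommon} experiments with raw p above \code{pGt}. A locus
#' meeting both rules is differential (precedence); everything else is
#' unclassified.
#'
#' @param diff data.frame from \code{\link{differentialOccupancy}}.
#' @param nMembers per-locus membership counts (same order as \code{diff}).
#' @param fdrLt FDR threshold for differential loci (default 0.05).
#' @param pGt raw-p threshold for common loci (default 0.1).
#' @param mDiff,mCommon minimum peak-set memberships (defaults 2 and 3).
#' @return factor with levels differential_A_gt_B, differential_A_lt_B,
#'   common, unclassified.
#' @export
classifyParalogLoci <- function(diff, nMembers, fdrLt = 0.05, pGt = 0.1,
                                mDiff = 2L, mCommon = 3L) {
  if (length(nMembers) != nrow(diff)) stop("nMembers must match diff rows")
  lev <- c("differential_A_gt_B", "differential_A_lt_B", "common", "unclassified")
  lab <- rep("unclassified", nrow(diff))
  isCommon <- nMembers >= mCommon & diff$p > pGt
  lab[isCommon] <- "common"
  isDiff <- nMembers >= mDiff & diff$fdr < fdrLt
  lab[isDiff & diff$log2fc >= 0] <- "differential_A_gt_B"
  lab[isDiff & diff$log2fc < 0] <- "differential_A_lt_B"
  factor(lab, levels = lev)
}

#' Two-step differential-accessibility flags
#'
#' Step 1 keeps loci with FDR below \code{fdrLt}; step 2 reports, among
#' step-1 survivors, those with |log2fc| above \code{lfcGt}. The step-1
#' survivor count is logged.
#'
#' @param diff data.frame with log2fc and fdr columns.
#' @param fdrLt FDR threshold (default 0.05).
#' @param lfcGt absolute log2 fold-change threshold (default 1).
#' @return logical vector of flags.
#' @export
classifyAccessibility <- function(diff, fdrLt = 0.05, lfcGt = 1.0) {
  step1 <- diff$fdr < fdrLt
  message(sum(step1), " loci pass the FDR step")
  step1 & abs(diff$log2fc) > lfcGt
}
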