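# One-round SELEX analysis: canonical k-mer enrichment, additive read
# weights under a PSAM, a seeded mononucleotide PSAM and a single-mode
# ridge-penalized maximum-likelihood fit (L-BFGS, analytic gradient).

# Integer code matrix (reads x positions) for a DNAStringSet of equal-width
# reads; used by the fitter and the simulator's weight computations.
encodeReads <- function(reads) {
  if (is(reads, "SelexReadSet")) reads <- reads@reads
  chars <- as.matrix(reads)
  m <- matrix(match(chars, DNA_BASES4), nrow = nrow(chars))
  if (anyNA(m)) stop("reads must use alphabet {A,C,G,T}")
  m
}

# Window log-scores for every read: returns an (nReads x nWindows) matrix
# covering all offsets on both strands (forward windows first).
readWindowScores <- function(codes, psam) {
  L <- ncol(codes)
  k <- psam@k
  if (L < k) stop("reads shorter than PSAM k")
  nw <- L - k + 1L
  score1 <- function(model) {
    bm <- model@betaMono
    out <- matrix(0, nrow = nrow(codes), ncol = nw)
    for (j in seq_len(nw)) {
      s <- numeric(nrow(codes))
      for (i in seq_len(k)) s <- s + unname(bm[i, ])[codes[, j + i - 1L]]
      out[, j] <- s
    }
    out
  }
  cbind(score1(psam), score1(psamRevComp(psam)))
}

# Additive occupancy weight w(s) for every read (sum over offsets and strands).
readWeights <- function(codes, psam) {
  rowSums(exp(readWindowScores(codes, psam)))
}

#' Additive occupancy weight of one read under a PSAM
#'
#' \code{w(s)} is the sum of the relative affinities of every window of the
#' read on both strands - identically \code{sum(scanSequence(seq, psam))}.
#' This is the selection weight assumed by the fitter's linear
#' (non-saturating) selection model.
#'
#' @param seq a read (character or DNAString).
#' @param psam a \linkS4class{PSAM}.
#' @return a positive scalar.
#' @export
predictedReadWeight <- function(seq, psam) {
  sum(scanSequence(seq, psam))
}

canonicalKmers <- function(kmers) {
  rc <- as.character(reverseComplement(DNAStringSet(kmers)))
  ifelse(kmers <= rc, kmers, rc)
}

#' Canonical k-mer enrichment between SELEX rounds
#'
#' Counts k-mers over all read offsets on both strands, collapsing each
#' k-mer with its reverse complement onto the lexicographically smaller
#' representative. Enrichment is \code{(freqR1 + eps) / (freqR0 + eps)}
#' with \code{eps = 1 / (total windows across both rounds)}, so a k-mer
#' absent from both rounds has enrichment exactly 1.
#'
#' @param r0,r1 \linkS4class{SelexReadSet}s for the unselected and selected
#'   rounds.
#' @param k k-mer length (<= variable length).
#' @return data.frame sorted by enrichment descending with columns kmer,
#'   freq_R0, freq_R1, enrichment.
#' @export
kmerEnrichment <- function(r0, r1, k) {
  vl <- variableLength(r0)
  if (k > vl) stop("k exceeds the variable length (", vl, " bp)")
  countRound <- function(rs) {
    fwd <- oligonucleotideFrequency(rs@reads, width = k, simplify.as = "collapse")
    rc <- fwd[as.character(reverseComplement(DNAStringSet(names(fwd))))]
    both <- fwd + rc   # windows on both strands
    tot <- sum(both)
    list(counts = both, total = tot)
  }
  c0 <- countRound(r0); c1 <- countRound(r1)
  eps <- 1 / (c0$total + c1$total)
  f0 <- c0$counts / c0$total
  f1 <- c1$counts / c1$total
  kmers <- names(f0)
  canon <- canonicalKmers(kmers)
  keep <- kmers == canon
  df <- data.frame(kmer = kmers[keep],
                   freq_R0 = unname(f0[keep]),
                   freq_R1 = unname(f1[keep]),
                   stringsAsFactors = FALSE)
  df$enrichment <- (df$freq_R1 + eps) / (df$freq_R0 + eps)
  df <- df[order(-df$enrichment, df$kmer), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Seed PSAM from a k-mer enrichment table
#'
#' The top-enriched k-mer becomes the consensus (beta 0); every other base
#' at each position starts at the log-odds of its column frequency against
#' the consensus base's frequency among the top 100 genuinely enriched
#' k-mers (enrichment at least 1.5-fold) aligned ungapped to the consensus
#' (each k-mer taken in whichever orientation matches the consensus
#' better), capped at 0 and floored at -6, under the per-position max-0
#' convention.
#' A uniform (null) enrichment table has no k-mer above the cutoff and
#' seeds a flat model - ranking noise must not imprint spurious structure
#' on the starting point.
#'
#' @param enrichment data.frame from \code{\link{kmerEnrichment}}.
#' @param k motif length (must equal the table's k-mer length).
#' @return a \linkS4class{PSAM}.
#' @export
seedPSAM <- function(enrichment, k) {
  if (nrow(enrichment) == 0L) stop("empty enrichment table")
  if (nchar(enrichment$kmer[1L]) != k) stop("table k-mer length != k")
  consensus <- enrichment$kmer[1L]
  consCodes <- encodeSequence(consensus)
  # only genuinely enriched k-mers inform the seed; a uniform (null) table
  # has none above the 1.5-fold cutoff and seeds a flat model
  informative <- enrichment$kmer[enrichment$enrichment >= 1.5]
  if (length(informative) == 0L) {
    beta <- matrix(0, nrow = k, ncol = 4L, dimnames = list(NULL, DNA_BASES4))
    return(PSAM(beta, modeId = "seed", normalize = TRUE))
  }
  top <- utils::head(informative, 100L)
  rc <- as.character(reverseComplement(DNAStringSet(top)))
  matches <- function(a) {
    vapply(a, function(s) sum(encodeSequence(s) == consCodes), 1L)
  }
  oriented <- ifelse(matches(top) >= matches(rc), top, rc)
  codeMat <- do.call(rbind, lapply(oriented, encodeSequence))
  freq <- sapply(seq_len(k), function(i) {
    tabulate(codeMat[, i], nbins = 4L) / nrow(codeMat)
  })  # 4 x k
  # log-odds of each base against the consensus base at its position,
  # capped at 0 so the top-enriched k-mer is the seed consensus by
  # construction, and floored at -6
  consFreq <- freq[cbind(consCodes, seq_len(k))]
  beta <- t(log(sweep(freq, 2L, consFreq, "/")))
  beta <- pmin(beta, 0)
  beta[!is.finite(beta)] <- -6
  beta <- pmax(beta, -6)
  beta[cbind(seq_len(k), consCodes)] <- 0
  colnames(beta) <- DNA_BASES4
  PSAM(beta, modeId = "seed", normalize = TRUE)
}

# Expected base counts at each PSAM position under the per-read window
# posteriors P (nReads x nWindows). Shared by the R1 and R0 gradient terms.
expectedBaseCounts <- function(codes, psam, P) {
  k <- psam@k
  L <- ncol(codes)
  nw <- L - k + 1L
  comp <- c(4L, 3L, 2L, 1L)
  G <- matrix(0, nrow = k, ncol = 4L)
  for (j in seq_len(nw)) {
    for (i in seq_len(k)) {
      # forward window j: PSAM position i reads base at column j+i-1
      b <- codes[, j + i - 1L]
      G[i, ] <- G[i, ] + rowsum4(P[, j], b)
      # reverse window j: PSAM position i reads the complement of the base
      # at column j + k - i
      br <- comp[codes[, j + k - i]]
      G[i, ] <- G[i, ] + rowsum4(P[, nw + j], br)
    }
  }
  G
}

rowsum4 <- function(x, g) {
  out <- numeric(4L)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

#' Single-mode maximum-likelihood PSAM fit from one-round SELEX reads
#'
#' Maximizes \deqn{\sum_{s \in R1} \log w_\theta(s) - |R1| \log\left(
#' \frac{1}{|R0|} \sum_{s' \in R0} w_\theta(s')\right)} minus the ridge
#' penalty over mononucleotide parameters with full-batch L-BFGS and the
#' analytic gradient (observed minus partition-function-expected base
#' counts); the R0 sample is the Monte-Carlo estimate of the partition
#' function, and quasi-Newton curvature handles the severe
#' ill-conditioning of log-linear binding parameters. The returned model
#' is renormalized to the per-position max-0 convention (a
#' likelihood-neutral shift). Iteration stops at a penalized
#' log-likelihood gain below \code{tol} or after \code{maxit} iterations.
#'
#' The objective carries a weak L2 (ridge) penalty \code{ridge *
#' sum(beta^2)}. The likelihood is nearly flat along read-composition-like
#' parameter directions (reweighting every window of a read by its base
#' content moves the selected and unselected samples almost identically),
#' so the unpenalized maximum is weakly identified there and finite-sample
#' noise can carry a null fit far from zero at next to no likelihood cost;
#' the penalty - standard in this binding-model family - resolves that
#' degeneracy toward the minimum-norm solution while its scale stays
#' independent of read count, so its bias on well-identified parameters
#' vanishes as reads grow.
#'
#' @param r0,r1 \linkS4class{SelexReadSet}s.
#' @param k motif length.
#' @param seedModel starting \linkS4class{PSAM}; when NULL a seed is built
#'   from the k-mer enrichment table.
#' @param maxit maximum accepted iterations (default 500).
#' @param tol penalized log-likelihood convergence tolerance (default 1e-6).
#' @param ridge L2 penalty weight on the mononucleotide parameters
#'   (default 100; 0 disables). The default suppresses the
#'   weakly-identified null displacement at the read depths this package
#'   simulates while leaving well-identified parameters essentially
#'   untouched, since the likelihood term grows with read count and the
#'   penalty does not.
#' @return list with \code{psam} (the fitted model), \code{logLik} (the
#'   unpenalized log-likelihood), \code{penalizedLogLik},
#'   \code{iterations}, \code{converged}, and \code{trace} (accepted
#'   penalized log-likelihood sequence, non-decreasing by construction).
#' @export
fitPSAM <- function(r0, r1, k, seedModel = NULL, maxit = 500L, tol = 1e-6,
                    ridge = 100) {
  k <- as.integer(k)
  if (length(r0) == 0L || length(r1) == 0L) stop("R0 and R1 must be non-empty")
  if (is.null(seedModel)) {
    seedModel <- seedPSAM(kmerEnrichment(r0, r1, k), k)
  }
  if (seedModel@k != k) stop("seed model k mismatch")
  codes1 <- encodeReads(r1)
  codes0 <- encodeReads(r0)
  k4 <- k * 4L
  N1 <- nrow(codes1)

  # joint penalized objective and gradient at a raw parameter vector,
  # memoized so optim's separate fn/gr calls cost one scan per point
  cache <- new.env(parent = emptyenv())
  evalAt <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$val)
    bm <- matrix(par, nrow = k, dimnames = list(NULL, DNA_BASES4))
    # the likelihood is invariant to per-position shifts, so the raw
    # (unnormalized) matrix can be scored directly; the penalty on the raw
    # parameters breaks both the shift and the noise-plateau degeneracies
    # toward the minimum-norm point
    rawPsam <- new("PSAM", k = k, betaMono = bm - apply(bm, 1L, max),
                   betaDi = NULL, modeId = "fit")
    shift <- sum(apply(bm, 1L, max))
    E1 <- exp(readWindowScores(codes1, rawPsam) + shift)
    E0 <- exp(readWindowScores(codes0, rawPsam) + shift)
    w1 <- rowSums(E1); w0 <- rowSums(E0)
    if (any(!is.finite(w1)) || any(!is.finite(w0)) || any(w1 <= 0)) {
      stop("non-finite likelihood; largest |parameter| = ", max(abs(par)))
    }
    ll <- sum(log(w1)) - N1 * log(mean(w0))
    G1 <- expectedBaseCounts(codes1, rawPsam, E1 / w1)
    G0 <- expectedBaseCounts(codes0, rawPsam, E0 / sum(w0)) * N1
    val <- list(pll = ll - ridge * sum(bm^2), ll = ll,
                grad = as.vector(G1 - G0 - 2 * ridge * bm))
    cache$par <- par
    cache$val <- val
    val
  }

  trace <- numeric()
  best <- -Inf
  fn <- function(par) {
    v <- evalAt(par)
    if (v$pll > best) {
      best <<- v$pll
      trace <<- c(trace, v$pll)
    }
    -v$pll
  }
  gr <- function(par) -evalAt(par)$grad
  opt <- stats::optim(as.vector(seedModel@betaMono), fn = fn, gr = gr,
                      method = "L-BFGS-B", lower = -10, upper = 5,
                      control = list(maxit = maxit,
                                     factr = max(tol, 1e-9) / .Machine$double.eps))
  final <- evalAt(opt$par)
  psam <- PSAM(matrix(opt$par, nrow = k, dimnames = list(NULL, DNA_BASES4)),
               modeId = "fit", normalize = TRUE)
  list(psam = psam, logLik = final$ll, penalizedLogLik = final$pll,
       iterations = opt$counts[["function"]],
       converged = opt$convergence == 0L, trace = trace)
}
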