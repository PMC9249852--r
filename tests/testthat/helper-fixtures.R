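# Shared fixture builders: everything is generated in code at test time.

suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(SummarizedExperiment)
})

# a deterministic random DNA string (no N)
randomSeq <- function(n, seed = 1L) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

namedGenome <- function(seqs) {
  g <- DNAStringSet(seqs)
  if (is.null(names(g))) names(g) <- paste0("chr", seq_along(g))
  g
}

# a small PSAM with seeded penalties in [-3, -0.5]
randomPSAM <- function(k, seed = 1L, di = FALSE) {
  withr::with_seed(seed, {
    bm <- matrix(-runif(4L * k, 0.5, 3), nrow = k)
    bd <- if (di && k >= 2L) matrix(-runif(16L * (k - 1L), 0, 1), nrow = k - 1L)
  })
  PSAM(bm, if (di) bd else NULL)
}

# brute-force relative affinity of one window (independent oracle)
oracleWindowAffinity <- function(window, psam, strand = "+") {
  bases <- c("A", "C", "G", "T")
  s <- strsplit(window, "")[[1L]]
  if (strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    s <- rev(unname(comp[s]))
  }
  if (any(s == "N")) return(0)
  idx <- match(s, bases)
  tot <- 0
  for (i in seq_along(idx)) tot <- tot + betaMono(psam)[i, idx[i]]
  bd <- betaDi(psam)
  if (!is.null(bd)) {
    for (i in seq_len(length(idx) - 1L)) {
      tot <- tot + bd[i, idx[i] + 4L * (idx[i + 1L] - 1L)]
    }
  }
  unname(exp(tot))
}

# brute-force strand-summed scan (independent oracle)
oracleScan <- function(seqchr, psam) {
  k <- psamLength(psam)
  n <- nchar(seqchr)
  vapply(seq_len(n - k + 1L), function(j) {
    w <- substr(seqchr, j, j + k - 1L)
    oracleWindowAffinity(w, psam, "+") + oracleWindowAffinity(w, psam, "-")
  }, 1.0)
}

# brute-force normalized/thresholded/window-maxed track (independent oracle)
oracleAffinityTrack <- function(genome, psam, threshold = 1e-4) {
  raw <- lapply(seq_along(genome), function(i) {
    oracleScan(as.character(genome[[i]]), psam)
  })
  mx <- max(unlist(raw))
  k <- psamLength(psam)
  lapply(seq_along(raw), function(ci) {
    v <- raw[[ci]] / mx
    v[v < threshold] <- 0
    n <- length(v)
    out <- vapply(seq_len(n), function(i) max(v[i:min(i + k - 1L, n)]), 1.0)
    c(out, numeric(width(genome)[ci] - n))
  })
}

# tiny GTF writer
writeTestGTF <- function(path, rows) {
  lines <- vapply(rows, function(r) {
    paste(r$contig, "test", r$type, r$start, r$end, ".", r$strand, ".",
          sprintf('gene_id "%s";', r$gene), sep = "\t")
  }, "")
  writeLines(lines, path)
}

# peak GRanges builder (1-based coordinates, summit 1-based or NA)
peakGR <- function(contig, start1, end1, summit = NA_integer_) {
  gr <- GRanges(contig, IRanges(start = start1, end = end1))
  mcols(gr)$summit <- as.integer(summit)
  mcols(gr)$score <- rep(1, length(gr))
  mcols(gr)$name <- paste0("p", seq_along(gr))
  gr
}
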