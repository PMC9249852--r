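test_that("PSAM construction normalizes and validates", {
  p <- PSAM(rbind(c(0, -1, -2, -3), c(-1, -1, -1, 0)))
  expect_s4_class(p, "PSAM")
  expect_equal(psamLength(p), 2L)
  expect_equal(consensusSequence(p), "AT")
  # normalization shifts any row to max 0
  p2 <- PSAM(rbind(c(2, 1, 0, -1), c(-1, -1, -1, 0)))
  expect_equal(apply(betaMono(p2), 1, max), rep(0, 2))
  expect_error(new("PSAM", k = 2L, betaMono = matrix(1, 2, 4,
                   dimnames = list(NULL, c("A", "C", "G", "T"))),
                   betaDi = NULL, modeId = "x"),
               "maximum 0")
})

test_that("relative affinity matches brute-force enumeration on both strands", {
  p <- PSAM(rbind(c(0, -1, -2, -3), c(-1, -1, -1, 0)))
  # exhaustive oracle over all 16 dinucleotides
  bases <- c("A", "C", "G", "T")
  all2 <- as.vector(outer(bases, bases, paste0))
  got <- vapply(all2, relativeAffinity, 1.0, psam = p)
  want <- vapply(all2, oracleWindowAffinity, 1.0, psam = p)
  expect_equal(got, want)
  expect_equal(unname(got["CT"]), exp(-1))
  expect_equal(max(got), 1.0)         # consensus AT scores 1
  expect_equal(names(which.max(got)), "AT")
  # minus strand scores the reverse complement
  expect_equal(relativeAffinity("AG", p, "-"), relativeAffinity("CT", p, "+"))
  expect_equal(relativeAffinity("AG", p, "-"), exp(-1))

  # identity model scores 1 everywhere
  pid <- PSAM(matrix(0, 3, 4))
  expect_equal(relativeAffinity("GGT", pid), 1.0)
  expect_error(relativeAffinity("A", p), "does not match")
})

test_that("dinucleotide parameters enter the window score", {
  p <- randomPSAM(4, seed = 11, di = TRUE)
  w <- "ACGT"
  expect_equal(relativeAffinity(w, p), oracleWindowAffinity(w, p))
  expect_equal(relativeAffinity(w, p, "-"), oracleWindowAffinity(w, p, "-"))
})

test_that("scanSequence sums both strands at every offset", {
  p <- PSAM(rbind(c(0, -1, -2, -3), c(-1, -1, -1, 0)))
  s <- "ACGTT"
  got <- scanSequence(s, p)
  expect_length(got, 4L)
  expect_equal(got, oracleScan(s, p))

  # palindromic model: every entry is twice the forward affinity
  ppal <- PSAM(rbind(c(0, -2, -2, -1), c(-1, -2, -2, 0)))  # consensus AT
  s2 <- randomSeq(40, 13)
  fwd <- vapply(1:39, function(j) {
    oracleWindowAffinity(substr(s2, j, j + 1), ppal, "+")
  }, 1.0)
  expect_equal(scanSequence(s2, ppal), 2 * fwd)

  expect_equal(scanSequence("NNNN", p), rep(0, 3))
  expect_error(scanSequence("A", p, contig = "tiny"), "tiny")
})

test_that("windowedMax is the left-anchored sliding maximum", {
  expect_equal(windowedMax(c(3, 1, 2), 1), c(3, 1, 2))
  expect_equal(windowedMax(c(0, 0.2, 0.5, 0.1), 2), c(0.2, 0.5, 0.5, 0.1))
  v <- withr::with_seed(21, runif(100))
  naive <- vapply(seq_along(v), function(i) max(v[i:min(i + 6, 100)]), 1.0)
  expect_equal(windowedMax(v, 7), naive, tolerance = 0)
  expect_error(windowedMax(v, 0), ">= 1")
})

test_that("affinity tracks follow the normalize-threshold-windowmax order", {
  p <- randomPSAM(7, seed = 31)
  cons <- consensusSequence(p)
  bg <- randomSeq(200, 32)
  seqchr <- paste0(substr(bg, 1, 80), cons, substr(bg, 88, 200))
  genome <- namedGenome(seqchr)
  tr <- buildAffinityTrack(genome, p)
  vals <- as.numeric(trackValues(tr)[[1]])
  # planted consensus dominates: normalized max 1 at the planted window
  expect_equal(max(vals), 1.0)
  expect_equal(vals[81], 1.0)   # 0-based offset 80 -> index 81
  # threshold rule: every value is 0 or >= threshold
  expect_true(all(vals == 0 | vals >= trackThreshold(tr)))
  # end-to-end equality with the naive enumeration oracle, bit-exact
  expect_equal(vals, oracleAffinityTrack(genome, p)[[1]], tolerance = 0)

  expect_error(buildAffinityTrack(namedGenome("NNNNNNNNNN"), p), "no scorable")
})

test_that("multi-contig scans normalize to the global maximum", {
  p <- randomPSAM(5, seed = 41)
  genome <- namedGenome(c(randomSeq(150, 42), randomSeq(90, 43)))
  tr <- buildAffinityTrack(genome, p)
  allv <- unlist(lapply(trackValues(tr), as.numeric))
  expect_equal(max(allv), 1.0)
  want <- oracleAffinityTrack(genome, p)
  expect_equal(as.numeric(trackValues(tr)[[1]]), want[[1]], tolerance = 0)
  expect_equal(as.numeric(trackValues(tr)[[2]]), want[[2]], tolerance = 0)
})

test_that("strand involution: scanning the reverse complement mirrors the scan", {
  p <- randomPSAM(6, seed = 51)
  s <- randomSeq(120, 52)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(scanSequence(rc, p), rev(scanSequence(s, p)))
})

test_that("mono-parameter shifts leave the normalized track unchanged", {
  p <- randomPSAM(5, seed = 61)
  genome <- namedGenome(randomSeq(300, 62))
  bm <- betaMono(p)
  bm[3, ] <- bm[3, ] + 1.7   # constant shift at one position
  pShift <- PSAM(bm, modeId = modeId(p))  # construction renormalizes
  expect_equal(betaMono(pShift), betaMono(p))
  expect_equal(trackValues(buildAffinityTrack(genome, p)),
               trackValues(buildAffinityTrack(genome, pShift)))
})

test_that("multi-mode models sum mode affinities before normalization", {
  p1 <- randomPSAM(4, seed = 71)
  p2 <- randomPSAM(4, seed = 72)
  genome <- namedGenome(randomSeq(100, 73))
  tr <- buildAffinityTrack(genome, list(p1, p2))
  raw <- oracleScan(as.character(genome[[1]]), p1) +
    oracleScan(as.character(genome[[1]]), p2)
  v <- raw / max(raw)
  v[v < 1e-4] <- 0
  n <- length(v)
  want <- vapply(seq_len(n), function(i) max(v[i:min(i + 3, n)]), 1.0)
  expect_equal(as.numeric(trackValues(tr)[[1]]),
               c(want, numeric(3)), tolerance = 0)
})

test_that("topMotifs returns per-strand hits sorted with declared tie-breaks", {
  p <- randomPSAM(7, seed = 81)
  cons <- consensusSequence(p)
  s <- paste0(substr(randomSeq(30, 82), 1, 10), cons, substr(randomSeq(30, 83), 1, 13))
  hits <- topMotifs(s, p, n = 5)
  expect_equal(hits$offset[1], 10L)       # 0-based planted offset
  expect_equal(hits$relative_affinity[1], 1.0)
  expect_equal(hits$strand[1], "+")

  # n = 10 rows on a short sequence with k = 2
  p2 <- PSAM(rbind(c(0, -1, -2, -3), c(-1, -1, -1, 0)))
  expect_equal(nrow(topMotifs(randomSeq(30, 84), p2, n = 10)), 10L)

  # full list equals the exhaustive enumerate-score-sort oracle
  s3 <- randomSeq(20, 85)
  got <- topMotifs(s3, p2, n = 100)
  nw <- 19L
  df <- data.frame(offset = rep(0:(nw - 1L), 2L),
                   strand = rep(c("+", "-"), each = nw))
  df$affinity <- vapply(seq_len(nrow(df)), function(i) {
    oracleWindowAffinity(substr(s3, df$offset[i] + 1L, df$offset[i] + 2L),
                         p2, df$strand[i])
  }, 1.0)
  df$affinity <- df$affinity / max(df$affinity)
  df <- df[order(-df$affinity, df$offset, df$strand), ]
  expect_equal(got$offset, df$offset)
  expect_equal(got$strand, df$strand)
  expect_equal(got$relative_affinity, df$affinity)
})

test_that("affinity tracks export as 4-decimal run-merged bedGraph", {
  p <- randomPSAM(5, seed = 91)
  genome <- namedGenome(randomSeq(150, 92))
  tr <- buildAffinityTrack(genome, p)
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeAffinityTrack(tr, f)
  back <- readCoverage(f, genome)
  expect_equal(as.numeric(back[[1]]),
               round(as.numeric(trackValues(tr)[[1]]), 4))
})
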