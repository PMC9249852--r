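test_that("FASTA reading enforces the {A,C,G,T,N} alphabet and round-trips", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT"), f)
  g <- readGenome(f)
  expect_equal(length(g), 1L)
  expect_equal(unname(Biostrings::width(g)), 4L)
  expect_equal(as.character(g[[1L]]), "ACGT")

  # lowercase is uppercased, N allowed
  writeLines(c(">c1 description", "acgtn"), f)
  g2 <- readGenome(f)
  expect_equal(as.character(g2[[1L]]), "ACGTN")
  expect_equal(names(g2), "c1")

  # round trip preserves sequence content
  g3 <- namedGenome(c(randomSeq(137, 3), randomSeq(71, 4)))
  out <- withr::local_tempfile(fileext = ".fa")
  writeGenome(g3, out)
  back <- readGenome(out)
  expect_equal(as.character(back), as.character(g3))

  writeLines(c(">chr1", "ACXT"), f)
  expect_error(readGenome(f), "line 2")
  writeLines(c(">chr1", "ACGU"), f)
  expect_error(readGenome(f), "line 2")
  writeLines(c("ACGT"), f)
  expect_error(readGenome(f), "header")
})

test_that("peak readers map BED and narrowPeak coordinates and summits", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", f)
  p <- readPeaks(f, "BED")
  expect_equal(start(p), 101L)   # 0-based half-open [100,200) -> 1-based [101,200]
  expect_equal(end(p), 200L)
  expect_true(is.na(mcols(p)$summit))

  np <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(paste(c("chr1", 100, 200, "pk1", 0, ".", 5.5, -1, -1, 50),
                   collapse = "\t"), np)
  p2 <- readPeaks(np, "narrowPeak")
  expect_equal(mcols(p2)$summit, start(p2) + 50L)  # absolute summit

  writeLines(paste(c("chr1", 100, 200, "pk1", 0, ".", 5.5, -1, -1, -1),
                   collapse = "\t"), np)
  expect_true(is.na(mcols(readPeaks(np, "narrowPeak"))$summit))

  writeLines("chr1\t200\t100", f)
  expect_error(readPeaks(f, "BED"), "start >= end")
  writeLines("chr1\t10.5\t100", f)
  expect_error(readPeaks(f, "BED"), "non-integer")
})

test_that("peak writer round-trips through both dialects", {
  pk <- peakGR("chr2", c(101L, 501L), c(300L, 700L), summit = c(150L, NA))
  for (d in c("BED", "narrowPeak")) {
    f <- withr::local_tempfile()
    writePeaks(pk, f, d)
    back <- readPeaks(f, d)
    expect_equal(start(back), start(pk))
    expect_equal(end(back), end(pk))
    if (d == "narrowPeak") {
      expect_equal(mcols(back)$summit, mcols(pk)$summit)
    }
  }
})

test_that("bedGraph expands to dense per-base coverage with zero fill", {
  genome <- namedGenome("ACGTAC")  # 6 bp
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t4\t2.5", f)
  tr <- readCoverage(f, genome)
  expect_equal(as.numeric(tr[["chr1"]]), c(2.5, 2.5, 2.5, 2.5, 0, 0))

  writeLines(character(), f)
  expect_equal(as.numeric(readCoverage(f, genome)[["chr1"]]), rep(0, 6))

  writeLines(c("chr1\t0\t4\t1", "chr1\t2\t5\t2"), f)
  expect_error(readCoverage(f, genome), "overlapping")
  writeLines("chr1\t0\t9\t1", f)
  expect_error(readCoverage(f, genome), "beyond contig")
})

test_that("coverage writer merges runs and round-trips exactly", {
  genome <- namedGenome(randomSeq(50, 5))
  vals <- withr::with_seed(8, {
    v <- numeric(50)
    v[6:15] <- 3.25
    v[20:29] <- runif(10)
    v
  })
  tr <- RleList(chr1 = Rle(vals), compress = FALSE)
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeCoverage(tr, f)
  back <- readCoverage(f, genome)
  expect_identical(as.numeric(back[["chr1"]]), vals)
  # run-length encoding merged: the constant block is a single line
  lines <- readLines(f)
  expect_true(any(grepl("^chr1\t5\t15\t3.25$", lines)))
})

test_that("GTF genes convert to 0-based strand-aware TSS/TTS", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeTestGTF(f, list(
    list(contig = "chr1", type = "gene", start = 1001, end = 2000,
         strand = "+", gene = "gplus"),
    list(contig = "chr1", type = "exon", start = 1001, end = 1200,
         strand = "+", gene = "gplus"),
    list(contig = "chr1", type = "exon", start = 1800, end = 2000,
         strand = "+", gene = "gplus"),
    list(contig = "chr1", type = "gene", start = 1001, end = 2000,
         strand = "-", gene = "gminus")))
  gt <- readGeneAnnotation(f)
  expect_equal(gt$tss[gt$gene_id == "gplus"], 1000L)
  expect_equal(gt$tts[gt$gene_id == "gplus"], 1999L)
  expect_equal(gt$tss[gt$gene_id == "gminus"], 1999L)
  expect_equal(gt$tts[gt$gene_id == "gminus"], 1000L)
  ex <- gt$exons[[which(gt$gene_id == "gplus")]]
  expect_equal(nrow(ex), 2L)
  expect_true(all(diff(ex[, 1L]) > 0))  # sorted

  writeTestGTF(f, list(list(contig = "chr1", type = "gene", start = 1,
                            end = 10, strand = ".", gene = "gx")))
  expect_error(readGeneAnnotation(f), "strand")
})

test_that("PSAM files round-trip and renormalize shifted parameters", {
  p <- randomPSAM(5, seed = 2, di = TRUE)
  f <- withr::local_tempfile(fileext = ".psam")
  writePSAM(p, f)
  back <- readPSAM(f)
  expect_equal(betaMono(back), betaMono(p))
  expect_equal(betaDi(back), betaDi(p))
  expect_equal(modeId(back), modeId(p))

  # a file whose per-position max is not 0 is shifted on read, leaving
  # normalized window affinities unchanged up to a global factor
  raw <- betaMono(p) + 0.7
  shifted <- withr::local_tempfile()
  writeLines(c("k\t5", "mode\tshifted", ">mono",
               apply(raw, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))),
             shifted)
  pShift <- readPSAM(shifted)
  expect_equal(apply(betaMono(pShift), 1, max), rep(0, 5))
  w <- randomSeq(5, 9)
  expect_equal(relativeAffinity(w, pShift),
               relativeAffinity(w, PSAM(betaMono(p), modeId = "x")))

  writeLines(c("k\t2", "mode\tm", ">mono", "0\t-1\t-2", "0\t-1\t-2"), shifted)
  expect_error(readPSAM(shifted), "4 columns")
})

test_that("count matrix TSV round-trips with sample metadata", {
  cm <- withr::with_seed(3, matrix(rpois(40, 50), nrow = 10,
                                   dimnames = list(paste0("locus_", 1:10),
                                                   c("A_1", "A_2", "B_1", "B_2"))))
  se <- makeCountMatrix(cm, condition = c("A", "A", "B", "B"),
                        replicate = c("r1", "r2", "r1", "r2"),
                        isInput = c(FALSE, FALSE, FALSE, TRUE))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCountMatrix(se, f)
  back <- readCountMatrix(f)
  expect_equal(assay(back, "counts"), assay(se, "counts"))
  expect_equal(colData(back)$condition, colData(se)$condition)
  expect_equal(colData(back)$is_input, colData(se)$is_input)
})

test_that("YAML run configs apply defaults and reject unknown keys", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 5", "plan:", "  nShared: 10", "  seed: 5"), f)
  cfg <- readRunConfig(f)
  expect_s4_class(cfg, "RunConfig")
  expect_equal(cfg@seed, 5L)
  expect_equal(cfg@plan@nShared, 10L)
  expect_equal(cfg@affinityThreshold, 1e-4)
  expect_equal(cfg@flank, 50L)
  expect_equal(cfg@summitHalfwidth, 250L)
  expect_equal(cfg@matrixHalfwidth, 1000L)
  expect_equal(cfg@matrixBinsize, 20L)
  expect_equal(cfg@fdrDifferential, 0.05)
  expect_equal(cfg@pCommon, 0.1)
  expect_equal(cfg@minOverlapDifferential, 2L)
  expect_equal(cfg@minOverlapCommon, 3L)
  expect_equal(cfg@lfcAccessibility, 1.0)
  expect_equal(cfg@topNMotifs, 10L)

  writeLines("sead: 5", f)
  expect_error(readRunConfig(f), "unknown config key")
})
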