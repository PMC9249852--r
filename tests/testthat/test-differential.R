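test_that("median-of-ratios size factors match the closed forms", {
  m <- matrix(rep(c(10, 20, 400), 3), ncol = 3)
  expect_equal(computeSizeFactors(m), rep(1, 3))   # identical columns

  m2 <- cbind(m[, 1:2], m[, 3] * 2)                # one column doubled
  sf <- computeSizeFactors(m2)
  expect_equal(sf[3] / sf[1], 2)
  expect_equal(exp(mean(log(sf))), 1)              # geometric mean 1

  # random matrix against a naive reimplementation
  cm <- withr::with_seed(9, matrix(rpois(200, 80) + 1, ncol = 4))
  got <- computeSizeFactors(cm)
  ref <- exp(rowMeans(log(cm)))
  want <- apply(cm / ref, 2, median)
  want <- want / exp(mean(log(want)))
  expect_equal(got, want)

  zer <- rbind(c(0, 5, 5, 0), c(3, 0, 1, 2))       # no all-positive locus
  expect_message(computeSizeFactors(zer), "total-count")
})

test_that("dispersion estimates recover known generators", {
  cond <- c("A", "A", "B", "B")
  # Poisson counts: common dispersion is near zero
  cnt0 <- withr::with_seed(101, matrix(rpois(2000 * 4, 100), ncol = 4))
  d0 <- estimateDispersion(cnt0, cond, rep(1, 4))
  expect_lte(d0$common, 0.02)

  # NB alpha = 0.2 at mean 200: pooled-moment recovery
  cnt <- withr::with_seed(102, matrix(rnbinom(2000 * 4, mu = 200, size = 5),
                                      ncol = 4))
  d <- estimateDispersion(cnt, cond, rep(1, 4))
  expect_gte(d$common, 0.15)
  expect_lte(d$common, 0.25)

  # identical replicates: every raw per-locus estimate is 0
  same <- matrix(rep(c(5, 50, 500), 4), ncol = 4)
  expect_equal(unname(estimateDispersion(same, cond, rep(1, 4))$raw), rep(0, 3))
})

test_that("the NB Wald test is calibrated, antisymmetric and recovers effects", {
  cond <- c("A", "A", "B", "B")
  # antisymmetry: swapping conditions negates log2fc and keeps p
  cnt <- withr::with_seed(103, matrix(rnbinom(400, mu = 150, size = 10), ncol = 4))
  rAB <- nbWaldTest(cnt, cond, contrast = c("A", "B"), sizeFactors = rep(1, 4))
  rBA <- nbWaldTest(cnt, cond, contrast = c("B", "A"), sizeFactors = rep(1, 4))
  expect_equal(rAB$log2fc, -rBA$log2fc)
  expect_equal(rAB$p, rBA$p)

  # true 4-fold change at mean 500, alpha = 0.05: median log2fc within 2 +/- 0.2
  eff <- withr::with_seed(104, cbind(
    matrix(rnbinom(3000 * 2, mu = 500, size = 20), ncol = 2),
    matrix(rnbinom(3000 * 2, mu = 125, size = 20), ncol = 2)))
  re <- nbWaldTest(eff, cond, contrast = c("A", "B"), sizeFactors = rep(1, 4))
  expect_lt(abs(median(re$log2fc) - 2), 0.2)

  expect_error(nbWaldTest(cnt, cond, sizeFactors = rep(1, 4),
                          dispersion = rep(-0.1, nrow(cnt))), ">= 0")
  expect_error(nbWaldTest(cnt, rep("A", 4)), "two conditions")
})

test_that("empirical type-I error is near nominal under the null", {
  cnt <- withr::with_seed(105, matrix(rnbinom(10000 * 4, mu = 200, size = 10),
                                      ncol = 4))
  rownames(cnt) <- paste0("locus_", seq_len(nrow(cnt)))
  res <- nbWaldTest(cnt, c("A", "A", "B", "B"), contrast = c("A", "B"),
                    sizeFactors = rep(1, 4))
  frac <- mean(res$p < 0.05)
  expect_gte(frac, 0.04)
  expect_lte(frac, 0.065)
})

test_that("Benjamini-Hochberg adjustment equals the naive step-up", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  p <- withr::with_seed(106, runif(100)^2)
  got <- bhAdjust(p)
  # naive step-up oracle
  o <- order(p)
  n <- length(p)
  stepup <- p[o] * n / seq_len(n)
  stepup <- rev(cummin(rev(stepup)))
  want <- numeric(n); want[o] <- pmin(stepup, 1)
  expect_equal(got, want)

  # permutation invariance (up to re-ordering back)
  perm <- withr::with_seed(107, sample(n))
  expect_equal(bhAdjust(p[perm]), got[perm])

  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("null-mode size factors undo depth shifts without chasing real change", {
  cond <- c("A", "A", "B", "B")
  # pervasive one-directional change: half the loci 4-fold up in A
  cnt <- withr::with_seed(108, {
    mu <- cbind(rep(c(200, 800), each = 100), rep(c(200, 800), each = 100),
                rep(200, 200), rep(200, 200))
    matrix(rnbinom(length(mu), mu = mu, size = 10), ncol = 4)
  })
  sf <- nullModeSizeFactors(cnt, cond)
  # the null cluster anchors the offset: A/B factor ratio stays near 1
  expect_lt(abs(log2(mean(sf[1:2]) / mean(sf[3:4]))), 0.15)
  # while plain median-of-ratios is dragged toward the changed cluster
  sfPlain <- computeSizeFactors(cnt)
  expect_gt(abs(log2(mean(sfPlain[1:2]) / mean(sfPlain[3:4]))), 0.4)

  # a genuine global depth shift is removed
  cnt2 <- withr::with_seed(109, {
    mu <- matrix(200, nrow = 300, ncol = 4)
    m <- matrix(rnbinom(length(mu), mu = mu, size = 10), ncol = 4)
    m[, 3:4] <- matrix(rnbinom(600, mu = 400, size = 10), ncol = 2)
    m
  })
  sf2 <- nullModeSizeFactors(cnt2, cond)
  expect_lt(abs(log2(mean(sf2[3:4]) / mean(sf2[1:2])) - 1), 0.2)
})

test_that("paralog locus classification applies the printed rules", {
  diffd <- data.frame(
    locus_id = paste0("locus_", 1:5),
    log2fc = c(1.3, -0.9, 0.05, 2.0, -1.5),
    p = c(0.001, 0.004, 0.5, 0.05, 0.2),
    fdr = c(0.01, 0.03, 0.8, 0.2, 0.4))
  members <- c(2L, 4L, 3L, 2L, 1L)
  lab <- classifyParalogLoci(diffd, members)
  expect_equal(as.character(lab),
               c("differential_A_gt_B",  # membership 2/4, fdr 0.01, +lfc
                 "differential_A_lt_B",  # negative sign splits the class
                 "common",               # membership 3/4, p > 0.1
                 "unclassified",         # fails both rules
                 "unclassified"))        # membership too low for either

  # a locus meeting both rules is differential (precedence)
  both <- data.frame(locus_id = "locus_1", log2fc = 1, p = 0.2, fdr = 0.01)
  expect_equal(as.character(classifyParalogLoci(both, 4L)),
               "differential_A_gt_B")
})

test_that("condition-label swaps exchange the two differential classes exactly", {
  plan <- SimulationPlan(nShared = 30L, nDependent = 10L, nIndependent = 10L,
                         nOther = 5L, genomeLength = 120000L, seed = 11L)
  g <- makeGenome(plan@genomeLength, plan@gc, seed = 11L)
  pl <- plantSites(g, makePsamSet(11L), plan)
  chip <- simulateChip(pl$truth, plan, pl$genome)
  dAB <- differentialOccupancy(chip$counts, c("A", "B"))
  dBA <- differentialOccupancy(chip$counts, c("B", "A"))
  members <- rep(4L, nrow(dAB))
  labAB <- table(classifyParalogLoci(dAB, members))
  labBA <- table(classifyParalogLoci(dBA, members))
  expect_equal(unname(labAB["differential_A_gt_B"]),
               unname(labBA["differential_A_lt_B"]))
  expect_equal(unname(labAB["differential_A_lt_B"]),
               unname(labBA["differential_A_gt_B"]))
})

test_that("differential accessibility uses the two-step rule", {
  diffd <- data.frame(locus_id = paste0("l", 1:3),
                      log2fc = c(0.8, -1.5, 3.0),
                      p = c(0.001, 0.001, 0.1),
                      fdr = c(0.01, 0.01, 0.2))
  expect_message(flags <- classifyAccessibility(diffd), "pass the FDR step")
  expect_equal(flags, c(FALSE, TRUE, FALSE))
})
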