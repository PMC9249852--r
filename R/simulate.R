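# Synthetic study generator: random genomes, a monomer/composite-dimer/
# spaced-dimer PSAM set, planted binding loci with known class labels, a
# 2-condition x 2-replicate ChIP design with matched inputs plus a
# WT-vs-cofactor-interaction-mutant contrast, and one-round SELEX reads.

#' Random genome sequence
#'
#' i.i.d. bases with P(G) + P(C) = gc (split equally) and P(A) = P(T);
#' deterministic given the seed.
#'
#' @param length genome length in bp (>= 1).
#' @param gc GC fraction in (0, 1).
#' @param seed integer seed.
#' @param name contig name.
#' @return a single-contig \link[Biostrings]{DNAStringSet}.
#' @export
makeGenome <- function(length, gc = 0.42, seed = 1L, name = "chrS") {
  if (length < 1L) stop("length must be >= 1")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- withSeed(seed, sample(DNA_BASES4, length, replace = TRUE, prob = probs))
  genome <- DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- name
  genome
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Construct the planted motif-model set
#'
#' Three models sharing one AT-rich 7-bp monomer consensus:
#' \itemize{
#'   \item \code{monomer}: the 7-bp model itself;
#'   \item \code{composite}: a 12-bp dimer model whose two 7-bp half-sites
#'     overlap by 2 bp, the first half-site being the monomer consensus
#'     (the overlapping-half-site dimer grammar);
#'   \item \code{spaced}: two 6-bp half-site blocks separated by a 4-bp
#'     near-neutral spacer (every spacer parameter >= -0.2), the
#'     spaced-dimer grammar.
#' }
#' Off-consensus penalties are drawn uniformly from [-4.5, -2] per position
#' and base, deterministically from the seed.
#'
#' @param seed integer seed.
#' @return named list of \linkS4class{PSAM}s: monomer, composite, spaced.
#' @export
makePsamSet <- function(seed = 1L) {
  withSeed(seed, {
    monoCons <- "TAATTAT"   # AT-rich homeodomain-like consensus
    # partner half-site starts with the monomer's last 2 bp, so the two
    # 7-bp half-sites of the composite overlap by exactly 2 bp
    partnerCons <- paste0(substr(monoCons, 6L, 7L), "TGACG")  # 7 bp
    compositeCons <- paste0(monoCons, substr(partnerCons, 3L, 7L))  # 12 bp
    half1 <- substr(monoCons, 1L, 6L)
    half2 <- "TGTCGG"
    spacerLen <- 4L

    penalties <- function(consensus) {
      k <- nchar(consensus)
      beta <- matrix(-stats::runif(4L * k, 2, 4.5), nrow = k,
                     dimnames = list(NULL, DNA_BASES4))
      beta[cbind(seq_len(k), encodeSequence(consensus))] <- 0
      beta
    }
    monomer <- PSAM(penalties(monoCons), modeId = "monomer")
    composite <- PSAM(penalties(compositeCons), modeId = "composite_dimer")

    spacedCons <- paste0(half1, strrep("A", spacerLen), half2)
    betaSp <- penalties(spacedCons)
    spIdx <- nchar(half1) + seq_len(spacerLen)
    betaSp[spIdx, ] <- matrix(-stats::runif(4L * spacerLen, 0, 0.2),
                              nrow = spacerLen)
    betaSp[cbind(spIdx, encodeSequence(substr(spacedCons, spIdx[1L],
                                              spIdx[spacerLen])))] <- 0
    spaced <- PSAM(betaSp, modeId = "spaced_dimer")
    list(monomer = monomer, composite = composite, spaced = spaced)
  })
}

#' Plant binding sites in a genome according to a simulation plan
#'
#' Loci are placed on a regular grid with at least 2 kb spacing and the
#' genome sequence is overwritten with the planted site:
#' \itemize{
#'   \item \code{shared}: monomer consensus, bound in both conditions;
#'   \item \code{specific_cofactor_dependent}: composite-dimer consensus,
#'     bound only in condition A, occupancy collapsing in the
#'     interaction-mutant sample;
#'   \item \code{specific_cofactor_independent}: monomer consensus plus an
#'     adjacent partner half-site (a spaced-dimer arrangement), bound only
#'     in condition A, occupancy preserved in the mutant;
#'   \item \code{specific_other}: a lone monomer site, condition-A-only,
#'     with neither dimer signature, preserved in the mutant.
#' }
#'
#' @param genome single-contig DNAStringSet (from \code{\link{makeGenome}}).
#' @param psams model set from \code{\link{makePsamSet}}.
#' @param plan a \linkS4class{SimulationPlan}.
#' @return list with \code{genome} (sites planted), \code{truth} (the
#'   ground-truth table: locus_id, class, contig, center [1-based],
#'   site_offset [0-based], site_strand, motif_type, occupancy_A,
#'   occupancy_B, occupancy_Amut) and \code{loci} (a GRanges of the planted
#'   501-bp loci with \code{center} mcols).
#' @export
plantSites <- function(genome, psams, plan) {
  classes <- c(rep("shared", plan@nShared),
               rep("specific_cofactor_dependent", plan@nDependent),
               rep("specific_cofactor_independent", plan@nIndependent),
               rep("specific_other", plan@nOther))
  n <- length(classes)
  contig <- names(genome)[1L]
  L <- width(genome)[1L]
  if (n == 0L) {
    truth <- data.frame(locus_id = character(), class = character(),
                        contig = character(), center = integer(),
                        site_offset = integer(), site_strand = character(),
                        motif_type = character(), occupancy_A = numeric(),
                        occupancy_B = numeric(), occupancy_Amut = numeric(),
                        stringsAsFactors = FALSE)
    return(list(genome = genome, truth = truth, loci = GRanges()))
  }
  spacing <- 2000L
  margin <- 1200L
  required <- 2L * margin + (n - 1L) * spacing
  if (L < required) {
    stop("genome too short: need at least ", required, " bp for ", n, " loci")
  }
  centers <- margin + spacing * (seq_len(n) - 1L) + 1L   # 1-based
  classes <- withSeed(plan@seed + 101L, sample(classes))  # shuffle class order
  seqchr <- as.character(genome[[1L]])
  monoCons <- consensusSequence(psams$monomer)
  compCons <- consensusSequence(psams$composite)
  spacedCons <- consensusSequence(psams$spaced)
  siteFor <- function(cls) {
    switch(cls,
           shared = monoCons,
           specific_cofactor_dependent = compCons,
           specific_cofactor_independent = spacedCons,
           specific_other = monoCons)
  }
  # condition B carries the planted graded effect (A/B fold = 2^effect);
  # in the interaction mutant a cofactor-dependent site loses its
  # dimer-mediated binding entirely and collapses to background
  occFor <- function(cls) {
    e <- 2^(-plan@effectLog2fc)
    switch(cls,
           shared = c(A = 1, B = 1, Amut = 1),
           specific_cofactor_dependent = c(A = 1, B = e, Amut = 0),
           specific_cofactor_independent = c(A = 1, B = e, Amut = 1),
           specific_other = c(A = 1, B = e, Amut = 1))
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    site <- siteFor(classes[i])
    w <- nchar(site)
    s1 <- centers[i] - w %/% 2L          # 1-based site start
    substr(seqchr, s1, s1 + w - 1L) <- site
    occ <- occFor(classes[i])
    rows[[i]] <- data.frame(
      locus_id = paste0("locus_", i), class = classes[i], contig = contig,
      center = centers[i], site_offset = s1 - 1L, site_strand = "+",
      motif_type = switch(classes[i],
                          shared = "monomer",
                          specific_cofactor_dependent = "composite_dimer",
                          specific_cofactor_independent = "spaced_dimer",
                          specific_other = "monomer"),
      occupancy_A = unname(occ["A"]), occupancy_B = unname(occ["B"]),
      occupancy_Amut = unname(occ["Amut"]), stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  genome2 <- DNAStringSet(seqchr)
  names(genome2) <- contig
  loci <- GRanges(contig, IRanges(start = pmax(1L, centers - 250L),
                                  end = pmin(L, centers + 250L)))
  mcols(loci)$locus_id <- truth$locus_id
  mcols(loci)$center <- centers
  list(genome = genome2, truth = truth, loci = loci)
}

#' Simulate the replicated ChIP experiment from a truth table
#'
#' Per locus and ChIP sample the count is NB with mean
#' \code{inputDepth + occupancy * meanDepth} (occupancy already carries the
#' planted condition effect) and dispersion alpha; matched inputs are NB
#' with mean \code{inputDepth}. Coverage tracks add, per locus, a
#' triangular kernel of half-width 250 bp with unit area scaled to the
#' count (so the 100-bp locus score is the closed-form 0.36 x count)
#' plus a flat background of \code{inputDepth / 250} per base. Per-replicate
#' peak sets include a locus with probability
#' \code{plogis(peakDetectSlope * (count - 3 * inputDepth))}, emulating
#' replicate-level peak-caller dropout; summits jitter around the planted
#' center (sd 10 bp).
#'
#' @param truth truth table from \code{\link{plantSites}}.
#' @param plan the \linkS4class{SimulationPlan}.
#' @param genome the planted genome (contig lengths for the tracks).
#' @return list with \code{counts} (a SummarizedExperiment: samples
#'   A_rep1/2, B_rep1/2, Amut_rep1/2 and matched inputs), \code{tracks}
#'   (named list of RleList coverage tracks for A, B, Amut: replicate
#'   averages), and \code{peaks} (named list of per-replicate GRanges peak
#'   sets: A_rep1, A_rep2, B_rep1, B_rep2, Amut_rep1, Amut_rep2).
#' @export
simulateChip <- function(truth, plan, genome) {
  n <- nrow(truth)
  groups <- c(A = "occupancy_A", B = "occupancy_B", Amut = "occupancy_Amut")
  lens <- contigLengths(genome)
  withSeed(plan@seed + 202L, {
    rnb <- function(mu) {
      if (plan@dispersion > 0) {
        stats::rnbinom(length(mu), mu = mu, size = 1 / plan@dispersion)
      } else stats::rpois(length(mu), mu)
    }
    counts <- list(); tracks <- list(); peaks <- list()
    for (g in names(groups)) {
      occ <- truth[[groups[[g]]]]
      mu <- plan@inputDepth + occ * plan@meanDepth
      groupTrack <- lapply(lens, function(L) numeric(L))
      for (r in 1:2) {
        cnt <- rnb(mu)
        counts[[paste0(g, "_rep", r)]] <- cnt
        counts[[paste0("input_", g, "_rep", r)]] <-
          rnb(rep(plan@inputDepth, n))
        # triangular pileup, half-width 250, area = count
        for (i in seq_len(n)) {
          ctr <- truth$center[i]
          d <- -249:249
          pos <- ctr + d
          ok <- pos >= 1L & pos <= lens[[truth$contig[i]]]
          kern <- (1 - abs(d) / 250) / 250
          groupTrack[[truth$contig[i]]][pos[ok]] <-
            groupTrack[[truth$contig[i]]][pos[ok]] + cnt[i] * kern[ok] / 2
        }
        pdet <- stats::plogis(plan@peakDetectSlope * (cnt - 3 * plan@inputDepth))
        called <- stats::runif(n) < pdet
        jitter <- as.integer(round(stats::rnorm(n, 0, 10)))
        summit <- pmin(pmax(truth$center + jitter, 1L), lens[truth$contig])
        pk <- GRanges(truth$contig[called],
                      IRanges(start = pmax(1L, summit[called] - 200L),
                              end = pmin(lens[truth$contig[called]],
                                         summit[called] + 200L)))
        mcols(pk)$summit <- summit[called]
        mcols(pk)$score <- cnt[called]
        mcols(pk)$name <- truth$locus_id[called]
        peaks[[paste0(g, "_rep", r)]] <- pk
      }
      flat <- plan@inputDepth / 250
      tracks[[g]] <- RleList(lapply(groupTrack, function(v) Rle(v + flat)),
                             compress = FALSE)
    }
    cm <- do.call(cbind, counts)
    rownames(cm) <- truth$locus_id
    cond <- sub("^(input_)?([ABmut]+)_rep[12]$", "\\2", colnames(cm))
    se <- makeCountMatrix(cm,
                          condition = cond,
                          replicate = sub("^.*_(rep[12])$", "\\1", colnames(cm)),
                          isInput = startsWith(colnames(cm), "input_"))
    list(counts = se, tracks = tracks, peaks = peaks)
  })
}

#' Simulate one-round SELEX read sets from a PSAM
#'
#' R0 reads are uniform random sequences of the variable length. R1 reads
#' are drawn by rejection sampling with acceptance probability
#' \code{w(s) / wMax} (capped at 1), where \code{w} is the additive
#' occupancy weight and \code{wMax} the maximum weight in a seeded
#' calibration sample of 10,000 reads - exactly the linear selection model
#' assumed by \code{\link{fitPSAM}}.
#'
#' @param psam the selecting \linkS4class{PSAM}.
#' @param nReads reads per round (a warning below 1000).
#' @param variableLength read length in bp (16 for monomer designs, 24 for
#'   dimer designs); must be >= k.
#' @param seed integer seed.
#' @return list with elements \code{r0} and \code{r1}
#'   (\linkS4class{SelexReadSet}s).
#' @export
simulateSelex <- function(psam, nReads, variableLength = 16L, seed = 1L) {
  if (variableLength < psam@k) stop("variableLength must be >= k")
  if (nReads < 1000L) warning("fewer than 1000 reads gives unstable fits")
  withSeed(seed, {
    randomCodes <- function(m) {
      matrix(sample.int(4L, m * variableLength, replace = TRUE), nrow = m)
    }
    codesToSet <- function(codes, round) {
      seqs <- apply(codes, 1L, function(r) paste(DNA_BASES4[r], collapse = ""))
      SelexReadSet(DNAStringSet(seqs), round = round)
    }
    calib <- randomCodes(10000L)
    wMax <- max(readWeights(calib, psam))
    r0codes <- randomCodes(nReads)
    accepted <- matrix(integer(), nrow = 0, ncol = variableLength)
    while (nrow(accepted) < nReads) {
      prop <- randomCodes(max(4L * nReads, 200000L))
      w <- readWeights(prop, psam)
      keep <- stats::runif(nrow(prop)) < pmin(1, w / wMax)
      accepted <- rbind(accepted, prop[keep, , drop = FALSE])
    }
    list(r0 = codesToSet(r0codes, "R0"),
         r1 = codesToSet(accepted[seq_len(nReads), , drop = FALSE], "R1"))
  })
}
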