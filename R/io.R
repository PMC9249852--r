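#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement width alphabetFrequency oligonucleotideFrequency
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols
#'   "mcols<-" reduce findOverlaps
#' @importFrom IRanges IRanges RleList
#' @importFrom S4Vectors Rle runValue runLength queryHits subjectHits
NULL

#' Read a genome FASTA file
#'
#' Sequences are uppercased and restricted to the alphabet {A,C,G,T,N}; any
#' other letter (including U) is a parse error that names the offending line.
#'
#' @param path path to a FASTA file.
#' @return a \link[Biostrings]{DNAStringSet}, one element per record, named
#'   by the first whitespace-delimited token of each header.
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) stop("FASTA parse error at line 1: empty file")
  first <- nonempty[1L]
  if (!startsWith(lines[first], ">")) {
    stop("FASTA parse error at line ", first, ": expected '>' header")
  }
  headers <- startsWith(lines, ">")
  bad <- which(!headers & grepl("[^ACGTNacgtn]", lines) & nzchar(trimws(lines)))
  if (length(bad)) {
    stop("FASTA parse error at line ", bad[1L],
         ": sequence letters must be in {A,C,G,T,N}")
  }
  seqs <- readDNAStringSet(path)
  seqs <- DNAStringSet(toupper(as.character(seqs)))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  empty <- which(width(seqs) == 0L)
  if (length(empty)) stop("FASTA record '", names(seqs)[empty[1L]], "' is empty")
  if (anyDuplicated(names(seqs))) stop("duplicate contig names in FASTA")
  seqs
}

#' Write a genome FASTA file
#' @param genome a DNAStringSet.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeGenome <- function(genome, path) {
  writeXStringSet(genome, filepath = path, width = 70L)
  invisible(path)
}

#' Read a peak file (BED or narrowPeak)
#'
#' BED coordinates (0-based half-open) are converted to the 1-based closed
#' GRanges convention. For narrowPeak input, column 10 holds the summit
#' offset from the interval start; offset -1 means "no summit" and yields an
#' NA summit. Summits are stored 1-based in \code{mcols(x)$summit}.
#'
#' @param path path to the peak file.
#' @param dialect "BED" or "narrowPeak".
#' @return a GRanges with metadata columns \code{summit} (1-based position or
#'   NA) and \code{score}.
#' @export
readPeaks <- function(path, dialect = c("BED", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("peak file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  ncolmin <- if (dialect == "narrowPeak") 10L else 3L
  if (ncol(raw) < ncolmin) {
    stop(dialect, " parse error: expected at least ", ncolmin, " columns")
  }
  s <- suppressWarnings(as.numeric(raw[[2L]]))
  e <- suppressWarnings(as.numeric(raw[[3L]]))
  if (any(is.na(s)) || any(is.na(e)) || any(s != floor(s)) || any(e != floor(e))) {
    stop(dialect, " parse error: non-integer coordinates")
  }
  if (any(s >= e)) {
    stop(dialect, " record error: start >= end at record ", which(s >= e)[1L])
  }
  strand <- if (ncol(raw) >= 6L) raw[[6L]] else rep(".", nrow(raw))
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(raw[[1L]], IRanges(start = s + 1L, end = e), strand = strand)
  mcols(gr)$name <- if (ncol(raw) >= 4L) raw[[4L]] else rep(NA_character_, nrow(raw))
  score <- if (ncol(raw) >= 5L) suppressWarnings(as.numeric(raw[[5L]])) else rep(NA_real_, nrow(raw))
  mcols(gr)$score <- score
  if (dialect == "narrowPeak") {
    off <- suppressWarnings(as.integer(raw[[10L]]))
    if (any(is.na(off))) stop("narrowPeak parse error: non-integer summit offset")
    summit <- ifelse(off < 0L, NA_integer_, as.integer(start(gr)) + off)
    mcols(gr)$summit <- summit
  } else {
    mcols(gr)$summit <- rep(NA_integer_, length(gr))
  }
  gr
}

#' Write peaks as BED6 or narrowPeak
#' @param peaks GRanges with optional \code{summit} and \code{score} mcols.
#' @param path output path.
#' @param dialect "BED" or "narrowPeak".
#' @return invisibly, the path.
#' @export
writePeaks <- function(peaks, path, dialect = c("BED", "narrowPeak")) {
  dialect <- match.arg(dialect)
  n <- length(peaks)
  name <- mcols(peaks)$name
  if (is.null(name)) name <- paste0("peak_", seq_len(n))
  score <- mcols(peaks)$score
  if (is.null(score)) score <- rep(0, n)
  score[is.na(score)] <- 0
  strand <- as.character(strand(peaks))
  strand[strand == "*"] <- "."
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks),
                   name = name, score = score, strand = strand)
  if (dialect == "narrowPeak") {
    summit <- mcols(peaks)$summit
    if (is.null(summit)) summit <- rep(NA_integer_, n)
    off <- ifelse(is.na(summit), -1L, as.integer(summit) - start(peaks))
    df$signalValue <- 0
    df$pValue <- -1
    df$qValue <- -1
    df$peak <- off
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage file into a dense per-base track
#'
#' @param path path to a bedGraph file (0-based half-open intervals,
#'   non-overlapping per contig).
#' @param genome a DNAStringSet (or named integer vector of contig lengths)
#'   defining contig names and lengths; uncovered positions are 0.
#' @return an \link[IRanges]{RleList} with one run-length-encoded numeric
#'   vector per contig, each of the contig's full length.
#' @export
readCoverage <- function(path, genome) {
  lens <- contigLengths(genome)
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(track|#|browser)", lines)]
  tracks <- lapply(lens, function(L) numeric(L))
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 4L)) stop("bedGraph parse error at data line ", which(nf < 4L)[1L])
    m <- matrix(unlist(lapply(parts, `[`, 1:4)), ncol = 4L, byrow = TRUE)
    chrom <- m[, 1L]
    s <- as.integer(m[, 2L]); e <- as.integer(m[, 3L])
    v <- as.numeric(m[, 4L])
    if (any(is.na(s)) || any(is.na(e)) || any(is.na(v))) {
      stop("bedGraph parse error: malformed numeric field")
    }
    unknown <- !chrom %in% names(lens)
    if (any(unknown)) stop("bedGraph contig not in genome: ", chrom[unknown][1L])
    if (any(e > lens[chrom])) {
      stop("bedGraph interval beyond contig length on ", chrom[which(e > lens[chrom])[1L]])
    }
    if (any(v < 0)) stop("bedGraph values must be >= 0")
    for (ctg in unique(chrom)) {
      sel <- chrom == ctg
      o <- order(s[sel])
      ss <- s[sel][o]; ee <- e[sel][o]; vv <- v[sel][o]
      if (any(ss[-1L] < ee[-length(ee)])) {
        stop("bedGraph overlapping intervals on contig ", ctg)
      }
      for (i in seq_along(ss)) tracks[[ctg]][(ss[i] + 1L):ee[i]] <- vv[i]
    }
  }
  RleList(lapply(tracks, Rle), compress = FALSE)
}

#' Write a coverage track (or affinity track values) as bedGraph
#'
#' Runs of equal values are merged into single intervals; zero runs are
#' omitted, so reading the file back against the same genome reproduces the
#' track exactly.
#'
#' @param track an RleList (or list of numeric/Rle vectors) keyed by contig.
#' @param path output path.
#' @param digits if non-NULL, round values to this many decimal places
#'   before run-merging (affinity tracks are exported with \code{digits = 4}).
#' @return invisibly, the path.
#' @export
writeCoverage <- function(track, path, digits = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in names(track)) {
    v <- track[[ctg]]
    if (!is(v, "Rle")) v <- Rle(as.numeric(v))
    if (!is.null(digits)) v <- Rle(round(as.numeric(v), digits))
    rv <- runValue(v); rl <- runLength(v)
    ends <- cumsum(rl)
    starts <- ends - rl
    keep <- rv != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%.17g", ctg, starts[keep], ends[keep], rv[keep]), con)
    }
  }
  invisible(path)
}

contigLengths <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    stats::setNames(width(genome), names(genome))
  } else if (is.numeric(genome) && !is.null(names(genome))) {
    stats::setNames(as.integer(genome), names(genome))
  } else stop("genome must be a DNAStringSet or a named length vector")
}

#' Read gene models from a GTF file
#'
#' GTF coordinates are 1-based inclusive; this reader is the only place in
#' the package where that convention is converted. The returned transcription
#' start/termination sites are 0-based genome positions: for a + strand gene
#' TSS = GTF start - 1, for a - strand gene TSS = GTF end - 1.
#'
#' @param path path to a GTF file containing \code{gene} and/or \code{exon}
#'   features with \code{gene_id} attributes.
#' @return a data.frame with columns \code{gene_id}, \code{contig},
#'   \code{strand}, \code{tss}, \code{tts} (0-based positions), \code{start},
#'   \code{end} (0-based half-open gene body) and a list-column \code{exons}
#'   of per-gene 0-based half-open exon coordinate matrices, exons sorted by
#'   start.
#' @export
readGeneAnnotation <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0L) stop("GTF contains no features")
  if (is.null(mcols(gr)$gene_id)) stop("GTF features lack gene_id attributes")
  types <- as.character(mcols(gr)$type)
  gid <- as.character(mcols(gr)$gene_id)
  keep <- types %in% c("gene", "exon")
  gr <- gr[keep]; types <- types[keep]; gid <- gid[keep]
  genes <- unique(gid)
  rows <- lapply(genes, function(g) {
    sub <- gr[gid == g]
    st <- unique(as.character(strand(sub)))
    if (length(st) != 1L || !st %in% c("+", "-")) {
      stop("gene ", g, " lacks a consistent +/- strand")
    }
    gstart1 <- min(start(sub)); gend1 <- max(end(sub))
    ex <- sub[types[gid == g] == "exon"]
    if (length(ex) == 0L) ex <- sub  # gene-only record: body as single exon
    exo <- cbind(start = start(ex) - 1L, end = end(ex))
    exo <- exo[order(exo[, 1L]), , drop = FALSE]
    tss <- if (st == "+") gstart1 - 1L else gend1 - 1L
    tts <- if (st == "+") gend1 - 1L else gstart1 - 1L
    list(gene_id = g, contig = as.character(seqnames(sub))[1L], strand = st,
         tss = tss, tts = tts, start = gstart1 - 1L, end = gend1, exons = exo)
  })
  data.frame(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    contig = vapply(rows, `[[`, "", "contig"),
    strand = vapply(rows, `[[`, "", "strand"),
    tss = vapply(rows, `[[`, 0L, "tss"),
    tts = vapply(rows, `[[`, 0L, "tts"),
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "end"),
    exons = I(lapply(rows, `[[`, "exons")),
    stringsAsFactors = FALSE
  )
}

#' Read a PSAM parameter file
#'
#' The text format has a header (\code{k <tab> <length>},
#' \code{mode <tab> <label>}), a \code{>mono} section of k tab-separated
#' rows with 4 columns (A, C, G, T), and an optional \code{>di} section of
#' k-1 rows with 16 columns (AA, CA, GA, TA, AC, ...). On read the
#' mononucleotide rows are renormalized to per-position maximum 0; this
#' shift rescales all window affinities by a common factor and is removed by
#' track normalization.
#'
#' @param path path to the PSAM file.
#' @return a \linkS4class{PSAM}.
#' @export
readPSAM <- function(path) {
  if (!file.exists(path)) stop("PSAM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  kv <- strsplit(lines[1:2], "\t", fixed = TRUE)
  if (length(lines) < 4L || kv[[1L]][1L] != "k" || kv[[2L]][1L] != "mode") {
    stop("PSAM parse error: expected 'k' and 'mode' header lines")
  }
  k <- as.integer(kv[[1L]][2L])
  mode <- kv[[2L]][2L]
  body <- lines[-(1:2)]
  monoAt <- which(body == ">mono")
  diAt <- which(body == ">di")
  if (length(monoAt) != 1L) stop("PSAM parse error: missing '>mono' section")
  monoEnd <- if (length(diAt)) diAt - 1L else length(body)
  monoRows <- body[(monoAt + 1L):monoEnd]
  if (length(monoRows) != k) {
    stop("PSAM parse error: expected ", k, " mono rows, found ", length(monoRows))
  }
  parseRows <- function(rows, ncolExp, what) {
    sp <- strsplit(rows, "\t", fixed = TRUE)
    if (any(lengths(sp) != ncolExp)) {
      stop("PSAM parse error: ", what, " rows must have ", ncolExp, " columns")
    }
    m <- matrix(as.numeric(unlist(sp)), ncol = ncolExp, byrow = TRUE)
    if (any(is.na(m))) stop("PSAM parse error: non-numeric ", what, " value")
    m
  }
  bm <- parseRows(monoRows, 4L, "mono")
  colnames(bm) <- DNA_BASES4
  bd <- NULL
  if (length(diAt)) {
    diRows <- body[(diAt + 1L):length(body)]
    if (length(diRows) != k - 1L) {
      stop("PSAM parse error: expected ", k - 1L, " di rows, found ", length(diRows))
    }
    bd <- parseRows(diRows, 16L, "di")
    colnames(bd) <- DINUCS
  }
  PSAM(bm, bd, modeId = mode, normalize = TRUE)
}

#' Write a PSAM parameter file
#' @param psam a \linkS4class{PSAM}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePSAM <- function(psam, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("k\t", psam@k), paste0("mode\t", psam@modeId), ">mono"), con)
  writeLines(apply(psam@betaMono, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t")), con)
  if (!is.null(psam@betaDi)) {
    writeLines(">di", con)
    writeLines(apply(psam@betaDi, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t")), con)
  }
  invisible(path)
}

#' Read SELEX reads from FASTA or FASTQ
#' @param path read file; format inferred from the first character
#'   ('@' = FASTQ, '>' = FASTA). Qualities are ignored.
#' @param round "R0" or "R1".
#' @return a \linkS4class{SelexReadSet}.
#' @export
readSelexReads <- function(path, round = c("R0", "R1")) {
  round <- match.arg(round)
  first <- substr(readLines(path, n = 1L), 1L, 1L)
  fmt <- if (first == "@") "fastq" else "fasta"
  reads <- readDNAStringSet(path, format = fmt)
  SelexReadSet(reads, round = round)
}

#' Write SELEX reads as FASTA
#' @param readset a \linkS4class{SelexReadSet}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSelexReads <- function(readset, path) {
  reads <- readset@reads
  if (is.null(names(reads))) {
    names(reads) <- paste0(readset@round, "_", seq_along(reads))
  }
  writeXStringSet(reads, filepath = path, width = 200L)
  invisible(path)
}
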