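#' Construct a per-gene signal track
#'
#' Carrier for strand-aware per-base read-end counts over one gene.
#' `counts[1]` is the TSS-proximal base in gene orientation.
#'
#' @param gene_id Gene identifier.
#' @param counts Nonnegative integer vector of length `n` (gene length).
#' @param library_size Total qualifying read (fragment) ends in the whole
#'   library; must be at least `sum(counts)`.
#' @param upstream Optional vector of counts over the region immediately
#'   upstream of the TSS, ordered 5' to 3' so that `c(upstream, counts)` is
#'   contiguous in gene orientation. Used by [pause_index()].
#' @return A `signal_track` object.
#' @export
signal_track <- function(gene_id, counts, library_size, upstream = NULL) {
  counts <- as.numeric(counts)
  stopifnot(all(counts >= 0), library_size >= sum(counts))
  structure(list(gene_id = gene_id, counts = counts,
                 library_size = as.numeric(library_size),
                 upstream = if (!is.null(upstream)) as.numeric(upstream)),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %s: %d bases, %g counts, library %g\n",
              x$gene_id, length(x$counts), sum(x$counts), x$library_size))
  invisible(x)
}

# Cache of per-BAM library sizes, keyed by path + filters.
.library_size_cache <- new.env(parent = emptyenv())

#' Total qualifying read ends in a BAM file
#'
#' Counts primary mapped reads (or, for paired data, properly paired first
#' mates, i.e. fragments) passing the MAPQ threshold, genome-wide. The
#' result is cached per file so repeated [load_signal()] calls do not
#' re-scan the BAM.
#'
#' @param bam Path to an indexed BAM file.
#' @param mapq Minimum mapping quality (default 10).
#' @param paired Count properly paired fragments instead of single reads.
#' @return Integer count.
#' @export
bam_library_size <- function(bam, mapq = 10, paired = FALSE) {
  key <- paste(normalizePath(bam), mapq, paired, sep = "|")
  if (!is.null(.library_size_cache[[key]])) return(.library_size_cache[[key]])
  flag <- if (paired) {
    Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                           isSecondaryAlignment = FALSE,
                           isProperPair = TRUE, isFirstMateRead = TRUE)
  } else {
    Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                           isSecondaryAlignment = FALSE)
  }
  n <- Rsamtools::countBam(
    bam, param = Rsamtools::ScanBamParam(flag = flag, mapqFilter = mapq)
  )$records
  .library_size_cache[[key]] <- n
  n
}

#' Extract a strand-aware per-base signal track from a BAM file
#'
#' Each qualifying read (single-end) or properly paired fragment
#' (paired-end) contributes one count at one base of the gene. The default
#' `end = "three_prime"` places it at the 3'-most aligned base in gene
#' orientation, where run-on assays map the polymerase active site;
#' `"five_prime"` uses the 5'-most base and `"full_overlap"` increments
#' every overlapped base. A read counts toward a gene only when its
#' alignment strand (for pairs: the strand of the first mate) equals the
#' gene strand. Reads below `mapq` are excluded.
#'
#' @param bam Path to an indexed BAM file.
#' @param gene A [gene_model()].
#' @param mapq Minimum mapping quality (default 10).
#' @param end Counting convention; see Details.
#' @param paired Treat the library as paired-end (count fragments).
#' @param upstream_flank Also extract this many bases immediately upstream
#'   of the TSS into the track's `upstream` field (default 0).
#' @return A [signal_track()] whose `counts` has length `gene$n`, index 1
#'   at the TSS.
#' @export
load_signal <- function(bam, gene, mapq = 10,
                        end = c("three_prime", "five_prime", "full_overlap"),
                        paired = FALSE, upstream_flank = 0) {
  end <- match.arg(end)
  if (!file.exists(bam)) stop("BAM file not found: ", bam)
  bai <- paste0(bam, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM index (.bai) not found for: ", bam)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!gene$chrom %in% names(hdr))
    stop("chromosome '", gene$chrom, "' absent from BAM header of ", bam)

  # Genomic window to fetch: gene plus optional upstream flank.
  win_start <- gene$start  # 0-based
  win_end <- gene$end
  if (upstream_flank > 0) {
    if (gene$strand == "+") win_start <- max(0, gene$start - upstream_flank)
    else win_end <- gene$end + upstream_flank
  }
  which <- GenomicRanges::GRanges(
    gene$chrom, IRanges::IRanges(win_start + 1, win_end))
  flag <- if (paired) {
    Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                           isSecondaryAlignment = FALSE, isProperPair = TRUE)
  } else {
    Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                           isSecondaryAlignment = FALSE)
  }
  param <- Rsamtools::ScanBamParam(which = which, flag = flag,
                                   mapqFilter = mapq)
  rng <- if (paired) {
    galp <- GenomicAlignments::readGAlignmentPairs(bam, param = param)
    GenomicRanges::granges(galp)   # strandMode 1: fragment strand = mate 1
  } else {
    GenomicRanges::granges(GenomicAlignments::readGAlignments(bam,
                                                              param = param))
  }
  rng <- rng[as.character(GenomicRanges::strand(rng)) == gene$strand]

  flank <- if (upstream_flank > 0) upstream_flank else 0
  total_len <- gene$n + flank
  counts_ext <- numeric(total_len)
  # Extended gene-relative index: 1 = TSS - flank, flank + 1 = TSS.
  ext_index <- function(pos) {
    if (gene$strand == "+") pos - gene$start + flank
    else gene$end - pos + 1 + flank
  }
  if (end == "full_overlap") {
    if (length(rng) > 0) {
      s <- pmax(GenomicRanges::start(rng), win_start + 1)
      e <- pmin(GenomicRanges::end(rng), win_end)
      for (i in seq_along(s)) {
        idx <- ext_index(s[i]:e[i])
        counts_ext[idx] <- counts_ext[idx] + 1
      }
    }
  } else {
    pos <- if (end == "three_prime") {
      ifelse(as.character(GenomicRanges::strand(rng)) == "+",
             GenomicRanges::end(rng), GenomicRanges::start(rng))
    } else {
      ifelse(as.character(GenomicRanges::strand(rng)) == "+",
             GenomicRanges::start(rng), GenomicRanges::end(rng))
    }
    pos <- pos[pos >= win_start + 1 & pos <= win_end]
    if (length(pos) > 0)
      counts_ext <- tabulate(ext_index(pos), nbins = total_len)
  }
  signal_track(
    gene$gene_id,
    counts = counts_ext[(flank + 1):total_len],
    library_size = bam_library_size(bam, mapq = mapq, paired = paired),
    upstream = if (flank > 0) counts_ext[seq_len(flank)]
  )
}

#' Fragments per kilobase per million (FPKM)
#'
#' @param track A [signal_track()].
#' @param gene The matching [gene_model()].
#' @return `sum(counts) / ((n/1000) * (library_size/1e6))`.
#' @export
compute_fpkm <- function(track, gene) {
  if (track$library_size <= 0) stop("library_size must be positive")
  stopifnot(gene$n > 0)
  sum(track$counts) / ((gene$n / 1000) * (track$library_size / 1e6))
}

#' Filter genes by length and reference expression
#'
#' Keeps genes at least `min_length` bp long whose FPKM in the untreated
#' reference strictly exceeds `min_fpkm`. The defaults (40 kb, FPKM 1)
#' restrict rate inference to long, clearly expressed genes where a
#' depleted/intact transition can exist and be measured.
#'
#' @param genes List of [gene_model()] objects.
#' @param reference_tracks Named list of [signal_track()]s from the
#'   reference library, one per gene.
#' @param min_length Minimum gene length in bp (default 40000).
#' @param min_fpkm Reference FPKM must be strictly greater (default 1).
#' @return The surviving subset of `genes`, with the per-gene reference
#'   FPKM attached as attribute `"reference_fpkm"`.
#' @export
filter_genes <- function(genes, reference_tracks, min_length = 40000,
                         min_fpkm = 1) {
  ids <- vapply(genes, `[[`, "", "gene_id")
  if (!all(ids %in% names(reference_tracks)))
    stop("every gene needs a reference track")
  fpkm <- vapply(seq_along(genes), function(i)
    compute_fpkm(reference_tracks[[ids[i]]], genes[[i]]), 0)
  keep <- vapply(genes, `[[`, 0, "n") >= min_length & fpkm > min_fpkm
  out <- genes[keep]
  attr(out, "reference_fpkm") <- stats::setNames(fpkm[keep], ids[keep])
  out
}

#' Write a signal track as bedGraph
#'
#' Four-column bedGraph (0-based half-open) in genomic orientation, with
#' zero runs omitted.
#'
#' @param track A [signal_track()].
#' @param gene The matching [gene_model()].
#' @param path Output file.
#' @export
write_bedgraph <- function(track, gene, path) {
  v <- track$counts
  if (gene$strand == "-") v <- rev(v)   # genomic orientation
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  df <- data.frame(chrom = gene$chrom, start = gene$start + starts[keep],
                   end = gene$start + ends[keep], value = r$values[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a small BAM fixture from a read table
#'
#' Internal test/fixture helper: writes a SAM file describing single-end
#' reads and converts it to a coordinate-sorted, indexed BAM.
#'
#' @param reads `data.frame` with columns `qname`, `flag`, `chrom`, `pos`
#'   (1-based leftmost), `mapq`, `cigar`.
#' @param seqlengths Named integer vector of chromosome lengths.
#' @param path Output BAM path (`.bam`).
#' @return The BAM path, invisibly.
#' @export
write_fixture_bam <- function(reads, seqlengths, path) {
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                  reads$qname, as.integer(reads$flag), reads$chrom,
                  as.integer(reads$pos), as.integer(reads$mapq), reads$cigar)
  writeLines(c(hdr, body), sam)
  dest <- sub("\\.bam$", "", path)
  Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  invisible(path)
}
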