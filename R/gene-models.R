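#' Construct a gene model
#'
#' A gene model is the coordinate frame for all per-gene signal: a genomic
#' interval with a strand and a set of exons. Genomic coordinates follow the
#' BED convention (0-based, half-open); gene-relative coordinates used
#' elsewhere in the package are 1-based with base 1 at the TSS, i.e. at
#' `start` for `+` genes and at `end - 1` for `-` genes.
#'
#' @param gene_id Character scalar identifier.
#' @param chrom Chromosome name.
#' @param start,end Genomic interval, 0-based half-open; `end > start`.
#' @param strand `"+"` or `"-"`.
#' @param exons Optional two-column matrix (start, end) of exon intervals in
#'   the same convention; overlapping records are merged and the result is
#'   sorted. `NULL` means a single exon spanning the gene.
#' @return An object of class `gene_model` with fields `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `exons` and length `n = end - start`.
#' @export
gene_model <- function(gene_id, chrom, start, end, strand, exons = NULL) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (!isTRUE(end > start))
    stop("gene '", gene_id, "': end must be greater than start")
  if (!(is.character(strand) && length(strand) == 1L && strand %in% c("+", "-")))
    stop("gene '", gene_id, "': strand must be '+' or '-'")
  if (is.null(exons)) {
    exons <- matrix(c(start, end), ncol = 2L)
  } else {
    exons <- matrix(as.numeric(exons), ncol = 2L)
    if (any(exons[, 2] <= exons[, 1]))
      stop("gene '", gene_id, "': exon end must exceed exon start")
    if (any(exons[, 1] < start) || any(exons[, 2] > end))
      stop("gene '", gene_id, "': exons must lie within the gene interval")
    exons <- merge_intervals(exons)
  }
  colnames(exons) <- c("start", "end")
  structure(
    list(gene_id = gene_id, chrom = as.character(chrom), start = start,
         end = end, strand = strand, exons = exons, n = end - start),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) n=%d bp, %d exon(s)\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand, x$n,
              nrow(x$exons)))
  invisible(x)
}

# Sort intervals and merge overlapping/contiguous-overlap ones.
merge_intervals <- function(x) {
  x <- x[order(x[, 1], x[, 2]), , drop = FALSE]
  if (nrow(x) <= 1L) return(x)
  out <- x[1L, , drop = FALSE]
  for (i in seq.int(2L, nrow(x))) {
    j <- nrow(out)
    if (x[i, 1] < out[j, 2]) {            # strict overlap under half-open coords
      out[j, 2] <- max(out[j, 2], x[i, 2])
    } else {
      out <- rbind(out, x[i, , drop = FALSE])
    }
  }
  out
}

#' Map gene-relative positions to genomic positions
#'
#' Gene-relative base `i` (1-based, 1 = TSS) maps to the 1-based genomic
#' position `start + i` on `+` genes and `end - i + 1` on `-` genes.
#'
#' @param gene A [gene_model()].
#' @param i Vector of gene-relative 1-based positions.
#' @return 1-based genomic positions.
#' @export
gene_to_genomic <- function(gene, i) {
  stopifnot(all(i >= 1L), all(i <= gene$n))
  if (gene$strand == "+") gene$start + i else gene$end - i + 1
}

#' Map 1-based genomic positions to gene-relative positions
#'
#' Inverse of [gene_to_genomic()].
#'
#' @inheritParams gene_to_genomic
#' @param pos 1-based genomic positions within the gene.
#' @return Gene-relative 1-based positions.
#' @export
genomic_to_gene <- function(gene, pos) {
  i <- if (gene$strand == "+") pos - gene$start else gene$end - pos + 1
  stopifnot(all(i >= 1L), all(i <= gene$n))
  i
}

#' Read gene models from BED or GTF
#'
#' BED6 records become single-exon genes spanning the record; BED12 records
#' take their exons from the block fields. In GTF input, `exon` features are
#' grouped by `gene_id` and their intervals merged, so two transcripts of one
#' gene yield the union of their exons. Records on strands other than
#' `+`/`-` are rejected.
#'
#' @param path Path to the gene-model file.
#' @param format `"auto"` (by extension), `"bed"` or `"gtf"`.
#' @return A named list of [gene_model()] objects.
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff)(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "bed"
  }
  if (format == "bed") read_bed_models(path) else read_gtf_models(path)
}

read_bed_models <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  genes <- vector("list", length(lines))
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[[ln]], "\t")[[1]]
    if (length(f) < 6L)
      stop("BED parse error at line ", ln, ": need at least 6 fields, got ",
           length(f))
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end) || end <= start)
      stop("BED parse error at line ", ln, ": bad interval '", f[2], "-",
           f[3], "'")
    if (!f[6] %in% c("+", "-"))
      stop("BED parse error at line ", ln, ": unrecognized strand '", f[6],
           "'")
    exons <- NULL
    if (length(f) >= 12L) {
      nblock <- as.integer(f[10])
      sizes <- as.numeric(strsplit(f[11], ",")[[1]])
      starts <- as.numeric(strsplit(f[12], ",")[[1]])
      if (length(sizes) != nblock || length(starts) != nblock)
        stop("BED parse error at line ", ln,
             ": blockCount disagrees with block lists")
      exons <- cbind(start + starts, start + starts + sizes)
    }
    genes[[ln]] <- gene_model(f[4], f[1], start, end, f[6], exons)
  }
  stats::setNames(genes, vapply(genes, `[[`, "", "gene_id"))
}

read_gtf_models <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("GTF parse error: ",
                                          conditionMessage(e)))
  ex <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(ex) == 0L) return(list())
  if (any(!as.character(GenomicRanges::strand(ex)) %in% c("+", "-")))
    stop("GTF contains exon features on unrecognized strands")
  by_gene <- split(ex, S4Vectors::mcols(ex)$gene_id)
  genes <- lapply(names(by_gene), function(gid) {
    g <- GenomicRanges::reduce(by_gene[[gid]])
    chrom <- as.character(GenomicRanges::seqnames(g))[1]
    strand <- as.character(GenomicRanges::strand(g))[1]
    # GTF is 1-based inclusive; convert to 0-based half-open.
    exons <- cbind(GenomicRanges::start(g) - 1, GenomicRanges::end(g))
    gene_model(gid, chrom, min(exons[, 1]), max(exons[, 2]), strand, exons)
  })
  stats::setNames(genes, vapply(genes, `[[`, "", "gene_id"))
}
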