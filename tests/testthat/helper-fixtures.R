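# Fixture builders shared by the test files. Everything is generated in
# code at test time; nothing binary ships with the package.

# A plain gene with uniform or supplied counts.
toy_gene <- function(id = "g1", n = 8000, strand = "+", start = 1000,
                     chrom = "chrT", exons = NULL) {
  gene_model(id, chrom, start, start + n, strand, exons)
}

toy_track <- function(gene, counts = NULL, library_size = NULL,
                      upstream = NULL) {
  if (is.null(counts)) counts <- rep(1, gene$n)
  if (is.null(library_size)) library_size <- max(sum(counts), 1)
  signal_track(gene$gene_id, counts, library_size, upstream = upstream)
}

# Step tracks: treatment depleted (rate near zero) up to `truth`, intact
# beyond; reference uniform. Deterministic given a seed.
step_tracks <- function(gene, truth, base_rate = 0.5, difference = 0.02,
                        depth = 1, seed = 1) {
  set.seed(seed)
  n <- gene$n
  ref <- rpois(n, base_rate)
  trt <- c(rpois(truth, base_rate * depth * difference),
           rpois(n - truth, base_rate * depth))
  list(treatment = signal_track(gene$gene_id, trt, max(sum(trt), 1)),
       reference = signal_track(gene$gene_id, ref, max(sum(ref), 1)))
}

# Brute-force split score: for each pointer, within-segment sums of
# squared deviations computed directly. Independent oracle for ss_scan.
brute_force_ss <- function(values) {
  L <- length(values)
  sapply(seq_len(L), function(p) {
    a <- values[1:p]
    b <- if (p < L) values[(p + 1):L] else numeric(0)
    ssd <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
    ssd(a) + ssd(b)
  })
}

# Write a BED12 file for a list of gene-like rows.
write_bed12 <- function(lines, path) {
  writeLines(lines, path)
  path
}

# One read per count: emits a single-end BAM whose three_prime per-base
# track over `gene` equals `counts` exactly. Reads are 1M matches at the
# corresponding genomic base, on the gene's strand.
counts_to_bam <- function(gene, counts, path, mapq = 30) {
  pos <- rep(seq_along(counts), counts)          # gene-relative bases
  gpos <- if (gene$strand == "+") gene$start + pos else gene$end - pos + 1
  flag <- if (gene$strand == "+") 0L else 16L
  reads <- data.frame(
    qname = sprintf("r%06d", seq_along(gpos)), flag = flag,
    chrom = gene$chrom, pos = gpos, mapq = mapq, cigar = "1M")
  write_fixture_bam(reads, stats::setNames(gene$end + 1000, gene$chrom),
                    path)
  path
}
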