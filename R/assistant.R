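# Assistant transcription-dynamics statistics: pause index, metagene
# compression and capping, GC content, k-mer enrichment, exon density,
# rate-quantile gene clustering.

#' Promoter-proximal pause index
#'
#' The ratio of polymerase read density in the promoter window (TSS plus
#' or minus `promoter_halfwidth`) to the gene-body density (promoter end
#' to TTS). The upstream half of the promoter lies outside the gene, so it
#' is read from the track's `upstream` field (see [load_signal()]'s
#' `upstream_flank`) or from `upstream_counts`. The gene is excluded (no
#' value) when its promoter window or body overlaps another gene's
#' interval, since overlapping signal cannot be attributed.
#'
#' @param track A [signal_track()] over the gene.
#' @param gene The [gene_model()].
#' @param promoter_halfwidth Half-width of the promoter window in bp
#'   (default 1000).
#' @param all_genes Optional list of [gene_model()]s used for the overlap
#'   exclusion (the gene itself is ignored).
#' @param upstream_counts Counts over the `promoter_halfwidth` bases
#'   upstream of the TSS, 5' to 3'; defaults to `track$upstream`.
#' @return List with `value` (promoter density / body density, `NA` when
#'   excluded or the body is empty), `excluded`, `zero_body`.
#' @export
pause_index <- function(track, gene, promoter_halfwidth = 1000,
                        all_genes = list(), upstream_counts = NULL) {
  hw <- promoter_halfwidth
  stopifnot(gene$n > hw)
  if (is.null(upstream_counts)) upstream_counts <- track$upstream
  if (is.null(upstream_counts) && hw > 0)
    stop("no upstream signal: supply upstream_counts or load the track ",
         "with upstream_flank = promoter_halfwidth")
  if (length(upstream_counts) != hw)
    stop("upstream_counts must have length promoter_halfwidth")

  # Genomic promoter/body intervals (0-based half-open) for the exclusion.
  tss <- if (gene$strand == "+") gene$start else gene$end
  prom <- if (gene$strand == "+") c(tss - hw, tss + hw)
          else c(tss - hw, tss + hw)
  body <- if (gene$strand == "+") c(tss + hw, gene$end)
          else c(gene$start, tss - hw)
  overlaps <- function(a, g) g$chrom == gene$chrom &&
    a[1] < g$end && g$start < a[2]
  excluded <- FALSE
  for (g in all_genes) {
    if (identical(g$gene_id, gene$gene_id)) next
    if (overlaps(prom, g) || overlaps(body, g)) { excluded <- TRUE; break }
  }
  if (excluded)
    return(list(value = NA_real_, excluded = TRUE, zero_body = FALSE))

  prom_counts <- sum(upstream_counts) + sum(track$counts[seq_len(hw)])
  body_counts <- sum(track$counts[(hw + 1L):gene$n])
  prom_density <- prom_counts / (2 * hw)
  body_density <- body_counts / (gene$n - hw)
  if (body_density == 0)
    return(list(value = NA_real_, excluded = FALSE, zero_body = TRUE))
  list(value = prom_density / body_density, excluded = FALSE,
       zero_body = FALSE)
}

#' Compress gene tracks to a common metagene length
#'
#' Each gene's TSS-to-TTS fragments-per-million (FPM) profile is resampled
#' to `target_length` positions by proportional coordinate mapping with
#' mean aggregation, so genes of different lengths align. To tame outlier
#' positions, values above the `cap_quantile` quantile of the whole matrix
#' are reduced to that quantile.
#'
#' @param tracks List of [signal_track()]s.
#' @param target_length Number of compressed positions (default 2000).
#' @param cap_quantile Capping quantile in (0, 1] (default 0.99).
#' @return A `metagene_matrix`: list with `gene_ids`, `positions`, `fpm`
#'   (genes x positions matrix, capped), `cap_value`, `cap_quantile`, and
#'   `curve` (column means, the metagene profile).
#' @export
compress_metagene <- function(tracks, target_length = 2000,
                              cap_quantile = 0.99) {
  stopifnot(target_length >= 1, cap_quantile > 0, cap_quantile <= 1,
            length(tracks) > 0)
  L <- target_length
  fpm <- t(vapply(tracks, function(tr) {
    n <- length(tr$counts)
    stopifnot(n > 0)
    v <- tr$counts / tr$library_size * 1e6
    if (n == L) return(v)
    # output position j covers bases floor((j-1)n/L)+1 .. floor(jn/L);
    # when n < L some windows are empty and take the covering base.
    lo <- floor((seq_len(L) - 1) * n / L) + 1
    hi <- floor(seq_len(L) * n / L)
    hi <- pmax(hi, lo)
    cs <- c(0, cumsum(v))
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }, numeric(L)))
  cap <- stats::quantile(fpm, cap_quantile, names = FALSE)
  fpm_capped <- pmin(fpm, cap)
  structure(list(gene_ids = vapply(tracks, `[[`, "", "gene_id"),
                 positions = seq_len(L), fpm = fpm_capped,
                 cap_value = cap, cap_quantile = cap_quantile,
                 curve = colMeans(fpm_capped)),
            class = "metagene_matrix")
}

#' GC content of a nucleotide sequence
#'
#' `(G + C) / (A + C + G + T)`; ambiguous bases (N) are excluded from the
#' denominator. Case-insensitive.
#'
#' @param sequence Character scalar or `Biostrings::DNAString`.
#' @return Fraction in `[0, 1]`, or `NA_real_` when no unambiguous base
#'   is present.
#' @export
gc_content <- function(sequence) {
  s <- toupper(as.character(sequence))
  stopifnot(nchar(s) > 0)
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(s),
                                        c("A", "C", "G", "T"))
  denom <- sum(counts)
  if (denom == 0) return(NA_real_)
  unname((counts["C"] + counts["G"]) / denom)
}

#' k-mer frequency enrichment between two sequence sets
#'
#' Counts overlapping k-mer windows on the sense strand of each set,
#' converts to pseudocount-smoothed frequencies
#' `(count + pc) / (windows + pc * 4^k)`, and returns the per-k-mer
#' frequency ratio `set_a / set_b`, sorted descending — the ordering used
#' to rank motifs enriched in one gene cluster over another.
#'
#' @param set_a,set_b Character vectors (or `DNAStringSet`s) of sequences.
#' @param k k-mer width (default 6).
#' @param pseudocount Smoothing pseudocount (default 1).
#' @return `data.frame` with columns `kmer`, `freq_a`, `freq_b`, `ratio`,
#'   sorted by decreasing ratio.
#' @export
kmer_ratio <- function(set_a, set_b, k = 6, pseudocount = 1) {
  stopifnot(k >= 1)
  count_set <- function(seqs) {
    if (length(seqs) == 0L) stop("empty sequence set")
    ss <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
    colSums(Biostrings::oligonucleotideFrequency(ss, width = k))
  }
  ca <- count_set(set_a); cb <- count_set(set_b)
  fa <- (ca + pseudocount) / (sum(ca) + pseudocount * 4^k)
  fb <- (cb + pseudocount) / (sum(cb) + pseudocount * 4^k)
  out <- data.frame(kmer = names(ca), freq_a = unname(fa),
                    freq_b = unname(fb), ratio = unname(fa / fb),
                    stringsAsFactors = FALSE)
  out[order(-out$ratio, out$kmer), , drop = FALSE]
}

#' Exon density of a gene
#'
#' Number of (merged) exons per kilobase of gene length.
#'
#' @param gene A [gene_model()]; exons are merged at construction.
#' @return Exons per kb.
#' @export
exon_density <- function(gene) {
  nrow(gene$exons) * 1000 / gene$n
}

#' Split genes into slow/fast clusters at a rate quantile
#'
#' Cluster 1 holds genes with rates strictly below the `q` quantile,
#' cluster 2 the rest. Per-gene statistics of the two clusters are
#' conventionally compared with a two-sided rank-sum test
#' ([compare_clusters()]).
#'
#' @param rates Named numeric vector of per-gene rates.
#' @param q Quantile in (0, 1) (default 0.5, the median split).
#' @return List with `quantile1`, `quantile2` (character vectors of gene
#'   ids) and `cutoff`.
#' @export
quantile_split <- function(rates, q = 0.5) {
  stopifnot(length(rates) >= 2, q > 0, q < 1)
  cutoff <- stats::quantile(rates, q, names = FALSE)
  lo <- rates < cutoff
  if (!any(lo) || all(lo))
    warning("one rate cluster is empty (tied rates?)")
  list(quantile1 = names(rates)[lo], quantile2 = names(rates)[!lo],
       cutoff = cutoff)
}

#' Two-sided rank-sum comparison of a statistic between clusters
#'
#' @param values Named numeric vector of a per-gene statistic.
#' @param split A [quantile_split()] result.
#' @return List with the two cluster medians and the two-sided
#'   Mann-Whitney p-value.
#' @export
compare_clusters <- function(values, split) {
  a <- values[split$quantile1]; b <- values[split$quantile2]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  p <- if (length(a) && length(b))
    suppressWarnings(stats::wilcox.test(a, b)$p.value) else NA_real_
  list(median1 = stats::median(a), median2 = stats::median(b), p_value = p)
}
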