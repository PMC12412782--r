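# Poisson count simulator and evaluation harness for transition-point
# callers. The generator emulates a drug-block nascent-RNA experiment: a
# reference track with roughly uniform gene-body coverage and a treatment
# track read-depleted up to a per-gene transition point.

#' Simulation configuration
#'
#' @param n_genes Number of genes (default 150, the scale of a filtered
#'   long-gene set in a typical run-on experiment).
#' @param gene_length_range Gene length range in bp (default 40-60 kb,
#'   matching the 40 kb length filter used for rate inference).
#' @param base_rate Expected reference reads per base (default 0.5).
#' @param distance Depleted-region length as a fraction of the gene
#'   (default 0.5); the true transition base is `round(distance * n)`.
#' @param difference Expected depleted/intact signal ratio in `[0, 1]`
#'   (default 0.02: a near-complete block).
#' @param depth Treatment intact-region depth multiplier relative to the
#'   reference (default 1).
#' @param window_num Bin number the dataset is intended to be analyzed
#'   with (default 40); carried along for bookkeeping.
#' @param seed Integer seed; identical configs give identical datasets.
#' @param negative Generate a negative dataset: treatment drawn at intact
#'   depth everywhere, no transition point in truth.
#' @param overdispersion If `> 0`, draw counts from a negative binomial
#'   with this dispersion (`size = 1/overdispersion`) instead of Poisson.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 150, gene_length_range = c(40000, 60000),
                       base_rate = 0.5, distance = 0.5, difference = 0.02,
                       depth = 1, window_num = 40, seed = 1,
                       negative = FALSE, overdispersion = 0) {
  stopifnot(n_genes >= 1, length(gene_length_range) == 2,
            gene_length_range[1] >= 2,
            gene_length_range[2] >= gene_length_range[1],
            base_rate > 0, distance > 0, distance <= 1,
            difference >= 0, difference <= 1, depth > 0, window_num >= 2,
            overdispersion >= 0)
  structure(list(n_genes = as.integer(n_genes),
                 gene_length_range = as.integer(gene_length_range),
                 base_rate = base_rate, distance = distance,
                 difference = difference, depth = depth,
                 window_num = as.integer(window_num),
                 seed = as.integer(seed), negative = isTRUE(negative),
                 overdispersion = overdispersion),
            class = "sim_config")
}

draw_counts <- function(n, mu, overdispersion) {
  if (overdispersion > 0)
    stats::rnbinom(n, size = 1 / overdispersion, mu = mu)
  else
    stats::rpois(n, mu)
}

#' Simulate a drug-block nascent-RNA dataset
#'
#' Per gene: length uniform over `gene_length_range`; reference counts
#' Poisson(`base_rate`) per base; treatment counts
#' Poisson(`base_rate * depth * difference`) up to the true transition
#' base `round(distance * n)` and Poisson(`base_rate * depth`) beyond.
#' In negative mode the treatment is drawn at intact depth everywhere and
#' the truth table is absent. Library sizes are the total simulated counts
#' per condition (a self-contained universe), so FPKM filters apply
#' meaningfully. Deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `sim_dataset`: list with `genes` (named list of
#'   [gene_model()]s laid head-to-tail on one synthetic chromosome),
#'   `treatment_tracks`, `reference_tracks` (named lists of
#'   [signal_track()]s) and `truth` (named vector of true transition
#'   bases, `NULL` in negative mode), plus the `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  lens <- sample.int(config$gene_length_range[2] -
                       config$gene_length_range[1] + 1L, ng,
                     replace = TRUE) + config$gene_length_range[1] - 1L
  ids <- sprintf("sim_gene_%03d", seq_len(ng))
  gap <- 10000L
  starts <- cumsum(c(0L, lens[-ng] + gap))
  strands <- rep(c("+", "-"), length.out = ng)
  genes <- lapply(seq_len(ng), function(i)
    gene_model(ids[i], "chrSim", starts[i], starts[i] + lens[i],
               strands[i]))
  names(genes) <- ids
  truth <- if (config$negative) NULL else
    stats::setNames(floor(config$distance * lens + 0.5), ids)  # ties up
  ref_counts <- lapply(lens, function(n)
    draw_counts(n, config$base_rate, config$overdispersion))
  trt_counts <- lapply(seq_len(ng), function(i) {
    n <- lens[i]
    intact_mu <- config$base_rate * config$depth
    if (config$negative) return(draw_counts(n, intact_mu,
                                            config$overdispersion))
    tb <- truth[i]
    c(draw_counts(tb, intact_mu * config$difference,
                  config$overdispersion),
      draw_counts(n - tb, intact_mu, config$overdispersion))
  })
  ref_lib <- sum(vapply(ref_counts, sum, 0))
  trt_lib <- sum(vapply(trt_counts, sum, 0))
  reference_tracks <- stats::setNames(lapply(seq_len(ng), function(i)
    signal_track(ids[i], ref_counts[[i]], ref_lib)), ids)
  treatment_tracks <- stats::setNames(lapply(seq_len(ng), function(i)
    signal_track(ids[i], trt_counts[[i]], trt_lib)), ids)
  structure(list(genes = genes, treatment_tracks = treatment_tracks,
                 reference_tracks = reference_tracks, truth = truth,
                 config = config),
            class = "sim_dataset")
}

#' Score transition calls against simulation truth
#'
#' A positive-mode gene is counted correct when its call is significant
#' and the inferred base lies within `tolerance` bp of the true one;
#' accuracy is the correct fraction out of all simulated genes (a
#' non-significant call on a positive gene counts as incorrect). In
#' negative mode the false-positive rate is the fraction of genes called
#' significant.
#'
#' @param calls A result table from [infer_rates()].
#' @param dataset The [simulate_dataset()] output the calls were made on.
#' @param tolerance Maximum |inferred - true| in bp (default 50).
#' @return An `accuracy_report`: list with `n_genes`, `n_called`,
#'   `n_correct`, `accuracy`, `false_positive_rate` (negative mode only)
#'   and `deltas` (signed bp errors, positive-mode genes with a call).
#' @export
evaluate_accuracy <- function(calls, dataset, tolerance = 50) {
  stopifnot(inherits(dataset, "sim_dataset"))
  ids <- names(dataset$genes)
  if (!all(calls$gene_id %in% ids))
    stop("calls contain genes absent from the dataset")
  n_genes <- length(ids)
  n_called <- sum(calls$significant)
  if (dataset$config$negative) {
    return(structure(list(n_genes = n_genes, n_called = n_called,
                          n_correct = NA_integer_, accuracy = NA_real_,
                          false_positive_rate = n_called / n_genes,
                          deltas = NULL),
                     class = "accuracy_report"))
  }
  truth <- dataset$truth[calls$gene_id]
  delta <- calls$transition_base - truth
  correct <- calls$significant & !is.na(delta) & abs(delta) <= tolerance
  structure(list(n_genes = n_genes, n_called = n_called,
                 n_correct = sum(correct),
                 accuracy = sum(correct) / n_genes,
                 false_positive_rate = NA_real_,
                 deltas = stats::setNames(delta, calls$gene_id)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  if (is.na(x$accuracy))
    cat(sprintf("<accuracy_report> negative mode: %d/%d significant, FPR = %.4g\n",
                x$n_called, x$n_genes, x$false_positive_rate))
  else
    cat(sprintf("<accuracy_report> %d/%d correct (accuracy %.3f), %d significant\n",
                x$n_correct, x$n_genes, x$accuracy, x$n_called))
  invisible(x)
}

#' Run the simulator/caller over a parameter sweep
#'
#' Regenerates a dataset per swept value (all other parameters fixed at
#' `base_config`; the seed is offset per level so levels are independent),
#' runs the chosen method and scores it, returning one accuracy per value.
#'
#' @param base_config A [sim_config()].
#' @param sweep Named list of length 1: the parameter to sweep (one of
#'   `distance`, `difference`, `depth`, `window_num`) and its values.
#' @param method `"lss"` or `"hmm"`.
#' @param treatment_minutes Block time used for rate reporting.
#' @param tolerance Scoring tolerance in bp (default 50).
#' @return `data.frame` with columns `parameter`, `value`, `accuracy`,
#'   `n_called`, `false_positive_rate`.
#' @export
accuracy_grid <- function(base_config, sweep, method = "lss",
                          treatment_minutes = 15, tolerance = 50) {
  stopifnot(is.list(sweep), length(sweep) == 1L)
  par <- names(sweep)
  stopifnot(par %in% c("distance", "difference", "depth", "window_num"))
  vals <- sweep[[1L]]
  rows <- lapply(seq_along(vals), function(i) {
    cfg <- base_config
    cfg[[par]] <- vals[i]
    cfg$seed <- base_config$seed + (i - 1L) * 1000L
    ds <- simulate_dataset(cfg)
    rc <- rate_config(window_num = cfg$window_num,
                      treatment_minutes = treatment_minutes,
                      method = method)
    calls <- infer_rates(ds$genes, ds$treatment_tracks,
                         ds$reference_tracks, rc)
    rep <- evaluate_accuracy(calls, ds, tolerance = tolerance)
    data.frame(parameter = par, value = vals[i],
               accuracy = rep$accuracy, n_called = rep$n_called,
               false_positive_rate = rep$false_positive_rate)
  })
  do.call(rbind, rows)
}

#' Write a simulated dataset to disk
#'
#' Emits one bedGraph per track per condition plus a tab-separated truth
#' table (`gene_id`, `n`, `truth_base`; `truth_base` `NA` in negative
#' mode) and a BED6 gene-model file.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(dataset$genes)
  for (id in ids) {
    g <- dataset$genes[[id]]
    write_bedgraph(dataset$reference_tracks[[id]], g,
                   file.path(dir, paste0(id, ".reference.bedgraph")))
    write_bedgraph(dataset$treatment_tracks[[id]], g,
                   file.path(dir, paste0(id, ".treatment.bedgraph")))
  }
  truth <- data.frame(
    gene_id = ids,
    n = vapply(dataset$genes, `[[`, 0, "n"),
    truth_base = if (is.null(dataset$truth)) NA_integer_
                 else unname(dataset$truth[ids]))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bed <- vapply(dataset$genes, function(g)
    sprintf("%s\t%d\t%d\t%s\t0\t%s", g$chrom, g$start, g$end, g$gene_id,
            g$strand), "")
  writeLines(unname(bed), file.path(dir, "genes.bed"))
  invisible(dir)
}
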