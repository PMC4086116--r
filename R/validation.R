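# Evaluation harness: decoy spiking, leave-one-out over a target list,
# ROC/AUC from planted-target ranks, and category-ablation comparisons.
#
# One master seed spawns per-run substreams (sample.int of run seeds), so
# every experiment is bit-reproducible, decoys are sampled without
# replacement within a run and independently across runs.

#' ROC summary from planted-target ranks
#'
#' For a planted target ranked among `list_size` candidates over repeated
#' runs: sensitivity at cutoff `c` is the fraction of runs with rank <= c,
#' specificity is the fraction of decoys below the cutoff,
#' `(list_size - c) / (list_size - 1)`. The AUC is computed in closed
#' (Mann-Whitney) form, `mean((list_size - rank) / (list_size - 1))` --
#' the probability that the planted target outranks a random decoy -- so
#' that a rank of 1 in every run gives exactly 1, the worst rank gives
#' exactly 0, and AUC(ranks) + AUC(reversed ranks) = 1.
#'
#' @param ranks integer vector of planted-target ranks, each in
#'   `[1, list_size]`
#' @param list_size candidate list length (>= 2)
#' @return object of class `roc_result`: list with `ranks`, `list_size`,
#'   `auc`, `curve` (data.frame cutoff, sensitivity, specificity, fpr)
#' @export
roc_from_ranks <- function(ranks, list_size) {
  stopifnot(is_count(list_size), list_size >= 2)
  ranks <- as.integer(ranks)
  if (!length(ranks)) stop_mr("no ranks supplied")
  if (any(is.na(ranks)) || any(ranks < 1) || any(ranks > list_size)) {
    stop_mr("ranks must lie in [1, %d]", list_size)
  }
  cutoffs <- seq_len(list_size)
  sens <- vapply(cutoffs, function(c) mean(ranks <= c), numeric(1))
  spec <- (list_size - cutoffs) / (list_size - 1)
  auc <- mean((list_size - ranks) / (list_size - 1))
  structure(list(ranks = ranks, list_size = list_size, auc = auc,
                 curve = data.frame(cutoff = cutoffs, sensitivity = sens,
                                    specificity = spec, fpr = 1 - spec)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: %d runs, list size %d, AUC %.3f, median rank %g>\n",
              length(x$ranks), x$list_size, x$auc, stats::median(x$ranks)))
  invisible(x)
}

derive_run_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Decoy-spiking validation of a planted miR-gene pair
#'
#' Repeats the full prioritization pipeline `n_runs` times. Each run mixes
#' the planted miR with `n_decoy_mirs` miRs sampled from `decoy_mir_pool`
#' and the planted target gene with `n_decoy_genes` genes sampled from
#' `decoy_gene_pool` (both without replacement), ranks the assembled test
#' gene list against the corpus, scores the candidate miRs training-free,
#' and records the planted miR's and gene's ranks.
#'
#' @param corpus an `annotation_corpus`
#' @param compendium an `interaction_compendium`
#' @param target_mir,target_gene the planted pair
#' @param decoy_mir_pool,decoy_gene_pool pools to sample decoys from; the
#'   planted ids are removed from them first, and each pool must then hold
#'   at least the requested number of decoys
#' @param n_decoy_mirs,n_decoy_genes decoys per run (defaults 19 and 99)
#' @param n_runs number of runs (default 100)
#' @param seed master seed
#' @param alpha top-fraction cutoff for miR scoring (default 0.4)
#' @param ... further arguments passed to [rank_genes()]
#' @return list of class `spike_result`: `mir_roc` and `gene_roc`
#'   (`roc_result`s), `seed`, `design`
#' @export
spike_validation <- function(corpus, compendium, target_mir, target_gene,
                             decoy_mir_pool, decoy_gene_pool,
                             n_decoy_mirs = 19, n_decoy_genes = 99,
                             n_runs = 100, seed = 1, alpha = 0.4, ...) {
  target_mir <- normalize_mir_ids(target_mir)
  target_gene <- toupper(trimws(target_gene))
  decoy_mir_pool <- setdiff(normalize_mir_ids(decoy_mir_pool), target_mir)
  decoy_gene_pool <- setdiff(toupper(trimws(as_gene_vector(decoy_gene_pool))), target_gene)
  if (length(decoy_mir_pool) < n_decoy_mirs) {
    stop_mr("decoy miR pool (%d) smaller than design (%d)", length(decoy_mir_pool), n_decoy_mirs)
  }
  if (length(decoy_gene_pool) < n_decoy_genes) {
    stop_mr("decoy gene pool (%d) smaller than design (%d)", length(decoy_gene_pool), n_decoy_genes)
  }
  run_seeds <- derive_run_seeds(seed, n_runs)
  mir_ranks <- integer(n_runs)
  gene_ranks <- integer(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    mirs <- c(target_mir, sample(decoy_mir_pool, n_decoy_mirs))
    test <- c(target_gene, sample(decoy_gene_pool, n_decoy_genes))
    gt <- rank_genes(test, corpus, ...)
    mt <- score_mirs_eq1(mirs, gt, compendium, alpha = alpha)
    mir_ranks[r] <- mt$rank[mt$mir == target_mir]
    gene_ranks[r] <- gt$rank[gt$gene == target_gene]
  }
  structure(list(mir_roc = roc_from_ranks(mir_ranks, n_decoy_mirs + 1L),
                 gene_roc = roc_from_ranks(gene_ranks, n_decoy_genes + 1L),
                 seed = seed, run_seeds = run_seeds,
                 design = list(n_decoy_mirs = n_decoy_mirs,
                               n_decoy_genes = n_decoy_genes, n_runs = n_runs,
                               alpha = alpha)),
            class = "spike_result")
}

#' @export
print.spike_result <- function(x, ...) {
  cat(sprintf("<spike_result: %d runs | miR AUC %.3f | gene AUC %.3f>\n",
              x$design$n_runs, x$mir_roc$auc, x$gene_roc$auc))
  invisible(x)
}

#' Leave-one-out validation over a miR's target list
#'
#' For each gene of `target_genes` in turn: the remaining targets form the
#' training set, the held-out gene is mixed with `n_decoy_genes` decoys
#' into a test list, genes are ranked with the training context (and
#' interactome when `ppi_edges` is given), the miR is mixed with
#' `n_decoy_mirs` candidates and scored in training-dependent mode, and
#' both ranks are recorded. Training genes are scored through the same
#' ranking pipeline.
#'
#' @param corpus an `annotation_corpus`
#' @param compendium an `interaction_compendium`
#' @param mir the miR whose targets are analyzed
#' @param target_genes its known target genes (length >= 2)
#' @param decoy_gene_pool,decoy_mir_pool decoy pools (targets/mir removed)
#' @param n_decoy_mirs,n_decoy_genes decoys per experiment (19 and 99)
#' @param seed master seed
#' @param alpha top-fraction cutoff (default 0.4)
#' @param ppi_edges optional interactome edge table
#' @param ... further arguments passed to [rank_genes()]
#' @return list of class `loocv_result`: `mir_roc`, `gene_roc`,
#'   `frac_top10`, `frac_top20` (fraction of experiments with the miR in
#'   the top 10% / 20% of the candidate list), `n_experiments`
#' @export
loocv_validation <- function(corpus, compendium, mir, target_genes,
                             decoy_gene_pool, decoy_mir_pool,
                             n_decoy_mirs = 19, n_decoy_genes = 99,
                             seed = 1, alpha = 0.4, ppi_edges = NULL, ...) {
  mir <- normalize_mir_ids(mir)
  target_genes <- unique(toupper(trimws(as_gene_vector(target_genes))))
  if (length(target_genes) < 2) stop_mr("need at least two target genes for leave-one-out")
  decoy_gene_pool <- setdiff(toupper(trimws(as_gene_vector(decoy_gene_pool))), target_genes)
  decoy_mir_pool <- setdiff(normalize_mir_ids(decoy_mir_pool), mir)
  if (length(decoy_gene_pool) < n_decoy_genes) stop_mr("decoy gene pool too small")
  if (length(decoy_mir_pool) < n_decoy_mirs) stop_mr("decoy miR pool too small")
  run_seeds <- derive_run_seeds(seed, length(target_genes))
  list_size_mir <- n_decoy_mirs + 1L
  mir_ranks <- integer(length(target_genes))
  gene_ranks <- integer(length(target_genes))
  for (i in seq_along(target_genes)) {
    set.seed(run_seeds[i])
    held <- target_genes[i]
    train <- setdiff(target_genes, held)
    test <- c(held, sample(decoy_gene_pool, n_decoy_genes))
    mirs <- c(mir, sample(decoy_mir_pool, n_decoy_mirs))
    gt <- rank_genes(test, corpus, training = train, ppi_edges = ppi_edges, ...)
    tt <- rank_genes(train, corpus, ...)
    mt <- score_mirs_eq2(mirs, gt, tt, compendium, alpha = alpha)
    mir_ranks[i] <- mt$rank[mt$mir == mir]
    gene_ranks[i] <- gt$rank[gt$gene == held]
  }
  structure(list(mir_roc = roc_from_ranks(mir_ranks, list_size_mir),
                 gene_roc = roc_from_ranks(gene_ranks, n_decoy_genes + 1L),
                 frac_top10 = mean(mir_ranks <= ceiling(0.1 * list_size_mir)),
                 frac_top20 = mean(mir_ranks <= ceiling(0.2 * list_size_mir)),
                 n_experiments = length(target_genes),
                 seed = seed),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result: %d experiments | miR AUC %.3f | top10%% %.0f%% | top20%% %.0f%%>\n",
              x$n_experiments, x$mir_roc$auc, 100 * x$frac_top10, 100 * x$frac_top20))
  invisible(x)
}

#' Category-ablation comparison
#'
#' Reruns [spike_validation()] with the corpus restricted to each given
#' category subset, under the same master seed, so differences between
#' subsets reflect only the annotation features used.
#'
#' @param subsets named list of character vectors of category names
#' @param corpus an `annotation_corpus`
#' @param ... all remaining arguments forwarded to [spike_validation()]
#' @return named list of `spike_result`s, one per subset
#' @export
ablation_validation <- function(subsets, corpus, ...) {
  if (!length(subsets)) stop_mr("no category subsets given")
  if (is.null(names(subsets)) || any(!nzchar(names(subsets)))) {
    names(subsets) <- vapply(subsets, paste, character(1), collapse = "+")
  }
  # validate every subset before any computation
  restricted <- lapply(subsets, restrict_categories, corpus = corpus)
  lapply(restricted, function(cr) spike_validation(corpus = cr, ...))
}

#' Export a validation result as TSV + JSON
#'
#' Writes the per-run ranks and the ROC curve points as TSV and a JSON
#' summary (AUCs, design, seed) next to them.
#'
#' @param result a `spike_result` or `loocv_result`
#' @param prefix output path prefix (files `<prefix>_ranks.tsv`,
#'   `<prefix>_curve.tsv`, `<prefix>_summary.json`)
#' @return character vector of paths, invisibly
#' @export
write_validation_report <- function(result, prefix) {
  stopifnot(inherits(result, c("spike_result", "loocv_result")))
  ranks <- data.frame(run = seq_along(result$mir_roc$ranks),
                      mir_rank = result$mir_roc$ranks,
                      gene_rank = result$gene_roc$ranks)
  p1 <- paste0(prefix, "_ranks.tsv")
  utils::write.table(ranks, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- paste0(prefix, "_curve.tsv")
  utils::write.table(result$mir_roc$curve, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  p3 <- paste0(prefix, "_summary.json")
  summ <- list(mir_auc = result$mir_roc$auc, gene_auc = result$gene_roc$auc,
               seed = result$seed)
  if (inherits(result, "loocv_result")) {
    summ$frac_top10 <- result$frac_top10
    summ$frac_top20 <- result$frac_top20
    summ$n_experiments <- result$n_experiments
  } else {
    summ$design <- result$design
  }
  jsonlite::write_json(summ, p3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(p1, p2, p3))
}
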