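# Pipeline orchestration: compendium -> enrichment -> gene ranking ->
# (interactome if a training set is given) -> miR ranking (training-free
# or training-dependent per training presence) -> optional expression
# integration. Every output directory contains the exact configuration
# and seed needed to regenerate it.

#' Build a validated run configuration
#'
#' Paths are file/directory locations; everything else is a method
#' parameter with the package default. Unknown fields abort, so typos in
#' config files fail loudly.
#'
#' @param corpus_dir directory of `*.gmt` files (one category each)
#' @param sources list of interaction sources; each element is a list with
#'   `path`, `name`, and optionally `experimental`, `mir_col`, `gene_col`
#' @param test_genes path to the test gene list
#' @param training_genes optional path to a training gene list
#' @param expression optional path to an expression table
#' @param ppi_edges optional path to a two-column PPI edge TSV
#' @param id_map optional path to an identifier mapping table
#' @param mirs optional path to a candidate miR list (one id per line);
#'   defaults to every miR in the compendium
#' @param alpha top-fraction cutoff in (0, 1], default 0.4
#' @param beta HITS back probability in \[0, 1\], default 0.5
#' @param correction `"bonferroni"` or `"fdr_bh"`
#' @param alpha_sig significance level on adjusted p-values (default 0.05)
#' @param sig_filter,sig_level concept participation rule, see
#'   [category_scores()] (default `"none"`: every concept contributes,
#'   weighted by its reciprocal p-value)
#' @param fusion_weight annotation weight in score fusion, default 0.5
#' @param damping,tol,max_iter propagation parameters
#' @param seed integer seed recorded in the run manifest
#' @param out_dir output directory
#' @return validated configuration list of class `run_config`
#' @export
run_config <- function(corpus_dir, sources, test_genes,
                       training_genes = NULL, expression = NULL,
                       ppi_edges = NULL, id_map = NULL, mirs = NULL,
                       alpha = 0.4, beta = 0.5,
                       correction = "bonferroni", alpha_sig = 0.05,
                       sig_filter = "none", sig_level = 0.05,
                       fusion_weight = 0.5, damping = 0.85,
                       tol = 1e-8, max_iter = 1000,
                       seed = 1, out_dir = "mirrank_run") {
  cfg <- list(corpus_dir = corpus_dir, sources = sources, test_genes = test_genes,
              training_genes = training_genes, expression = expression,
              ppi_edges = ppi_edges, id_map = id_map, mirs = mirs,
              alpha = alpha, beta = beta, correction = correction,
              alpha_sig = alpha_sig, sig_filter = sig_filter,
              sig_level = sig_level, fusion_weight = fusion_weight,
              damping = damping, tol = tol, max_iter = max_iter,
              seed = as.integer(seed), out_dir = out_dir)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  known <- c("corpus_dir", "sources", "test_genes", "training_genes", "expression",
             "ppi_edges", "id_map", "mirs", "alpha", "beta", "correction",
             "alpha_sig", "sig_filter", "sig_level", "fusion_weight", "damping",
             "tol", "max_iter", "seed", "out_dir")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop_mr("unknown config field(s): %s", paste(extra, collapse = ", "))
  for (f in c("corpus_dir", "test_genes")) {
    if (is.null(cfg[[f]])) stop_mr("config field '%s' is required", f)
  }
  if (!length(cfg$sources)) stop_mr("config needs at least one interaction source")
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha > 1) stop_mr("alpha must be in (0, 1]")
  if (!is.numeric(cfg$beta) || cfg$beta < 0 || cfg$beta > 1) stop_mr("beta must be in [0, 1]")
  if (!cfg$correction %in% c("bonferroni", "fdr_bh")) stop_mr("correction must be bonferroni or fdr_bh")
  if (!cfg$sig_filter %in% c("none", "nominal", "adjusted")) stop_mr("sig_filter must be none, nominal or adjusted")
  if (!is.numeric(cfg$fusion_weight) || cfg$fusion_weight < 0 || cfg$fusion_weight > 1) {
    stop_mr("fusion_weight must be in [0, 1]")
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Fields mirror the arguments of [run_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file path
#' @return a validated `run_config`
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_mr("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    p <- as.character(p)
    if (anyNA(p)) stop_mr("invalid path in config file %s", path)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  for (f in c("corpus_dir", "test_genes", "training_genes", "expression",
              "ppi_edges", "id_map", "mirs")) {
    raw[[f]] <- resolve(raw[[f]])
  }
  if (!is.null(raw$sources)) {
    raw$sources <- lapply(raw$sources, function(s) { s$path <- resolve(s$path); s })
  }
  do.call(run_config, raw)
}

#' Execute the full prioritization pipeline
#'
#' Reads all configured inputs, ranks genes and miRs, optionally
#' integrates expression, and writes `enrichment.tsv`, `gene_ranks.tsv`,
#' `mir_ranks.tsv`, `network.gml` and `run_manifest.json` (the verbatim
#' configuration plus seed) into the output directory. Identical
#' configuration and seed produce byte-identical outputs. On error,
#' partial outputs are removed and the error is re-raised with the failed
#' stage named.
#'
#' @param config a `run_config` (or path to a YAML config)
#' @return invisible list with the in-memory results (`gene_table`,
#'   `mir_table`, `enrichment`, `paths`)
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- "setup"
  result <- tryCatch({
    set.seed(config$seed)
    stage <- "annotation_io"
    id_map <- if (!is.null(config$id_map)) read_id_map(config$id_map) else NULL
    corpus <- read_corpus_dir(config$corpus_dir, id_map = id_map)
    test <- read_gene_list(config$test_genes, id_map = id_map, label = "test")
    training <- if (!is.null(config$training_genes)) {
      read_gene_list(config$training_genes, id_map = id_map, label = "training")
    }
    expression <- if (!is.null(config$expression)) {
      read_expression_table(config$expression, id_map = id_map)
    }
    ppi <- if (!is.null(config$ppi_edges)) {
      utils::read.delim(config$ppi_edges, stringsAsFactors = FALSE)
    }
    stage <- "target_compendium"
    comp <- union_compendium(lapply(config$sources, function(s) {
      read_interaction_source(s$path, s$name,
                              experimental = isTRUE(s$experimental),
                              mir_col = s$mir_col %||% "mir",
                              gene_col = s$gene_col %||% "gene",
                              id_map = id_map)
    }))
    mirs <- if (!is.null(config$mirs)) {
      normalize_mir_ids(readLines(config$mirs, warn = FALSE))
    } else compendium_mirs(comp)
    mirs <- mirs[nzchar(mirs)]
    stage <- "gene_rank"
    gt <- rank_genes(test, corpus,
                     training = training,
                     ppi_edges = if (!is.null(training)) ppi else NULL,
                     method = config$correction, alpha_sig = config$alpha_sig,
                     sig_filter = config$sig_filter, sig_level = config$sig_level,
                     damping = config$damping, tol = config$tol,
                     max_iter = config$max_iter, beta = config$beta,
                     fusion_weight = config$fusion_weight)
    enr <- attr(gt, "enrichment")
    stage <- "mir_rank"
    mt <- if (!is.null(training)) {
      tt <- rank_genes(training, corpus,
                       method = config$correction, alpha_sig = config$alpha_sig,
                       sig_filter = config$sig_filter, sig_level = config$sig_level,
                       damping = config$damping, tol = config$tol,
                       max_iter = config$max_iter)
      score_mirs_eq2(mirs, gt, tt, comp, alpha = config$alpha)
    } else {
      score_mirs_eq1(mirs, gt, comp, alpha = config$alpha)
    }
    stage <- "expression_integration"
    if (!is.null(expression)) {
      gt_out <- if (any(expression$id %in% gt$gene)) {
        integrate_expression(gt, expression)
      } else gt
      # only integrate the miR table when the profile actually covers miRs
      mt_out <- if (any(expression$id %in% mt$mir)) {
        integrate_expression(mt, expression)
      } else mt
    } else {
      gt_out <- gt
      mt_out <- mt
    }
    stage <- "outputs"
    p_enr <- file.path(out_dir, "enrichment.tsv")
    write_enrichment_tsv(enr, p_enr); written <- c(written, p_enr)
    p_gene <- file.path(out_dir, "gene_ranks.tsv")
    write_ranked_tsv(as.data.frame(gt_out), p_gene, score_col = NULL); written <- c(written, p_gene)
    p_mir <- file.path(out_dir, "mir_ranks.tsv")
    write_ranked_tsv(as.data.frame(mt_out), p_mir, score_col = NULL); written <- c(written, p_mir)
    p_gml <- file.path(out_dir, "network.gml")
    net <- pipeline_network(enr, gt, mt, comp, ppi)
    write_network_gml(net$nodes, net$edges, p_gml); written <- c(written, p_gml)
    p_man <- file.path(out_dir, "run_manifest.json")
    jsonlite::write_json(
      list(config = unclass(config), seed = config$seed,
           n_test_genes = nrow(gt), n_candidate_mirs = nrow(mt),
           converged = isTRUE(attr(gt, "converged"))),
      p_man, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, p_man)
    list(gene_table = gt_out, mir_table = mt_out, enrichment = enr,
         paths = stats::setNames(written, c("enrichment", "gene_ranks", "mir_ranks",
                                            "network", "manifest")))
  }, error = function(e) {
    unlink(written)
    stop_mr("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(result)
}

# Tripartite (concept - mRNA - miR) network for export, with PPI edges
# among test genes when available. Node scores: concepts carry 1/p_raw,
# genes their final score, miRs their significance score.
pipeline_network <- function(enr, gene_table, mir_table, compendium, ppi = NULL) {
  rec <- sig_records(enr, "nominal",
                     sig_level = max(attr(enr, "alpha_sig") %||% 0.05, 0.05))
  genes <- gene_table$gene
  nodes <- rbind(
    if (nrow(rec)) data.frame(id = rec$concept_id, type = "concept",
                              score = 1 / rec$p_raw, stringsAsFactors = FALSE),
    data.frame(id = genes, type = "mRNA", score = gene_table$final,
               stringsAsFactors = FALSE),
    data.frame(id = mir_table$mir, type = "miR", score = mir_table$sig,
               stringsAsFactors = FALSE)
  )
  ann <- if (nrow(rec)) do.call(rbind, lapply(seq_len(nrow(rec)), function(i) {
    hit <- intersect(rec$members_hit[[i]], genes)
    if (!length(hit)) return(NULL)
    data.frame(src = hit, dst = rec$concept_id[i], kind = "annotation",
               stringsAsFactors = FALSE)
  }))
  reg <- compendium$interactions[compendium$interactions$gene %in% genes &
                                   compendium$interactions$mir %in% mir_table$mir, ]
  reg <- if (nrow(reg)) data.frame(src = reg$mir, dst = reg$gene, kind = "regulation",
                                   stringsAsFactors = FALSE)
  pp <- NULL
  if (!is.null(ppi) && nrow(ppi)) {
    keep <- toupper(ppi[[1]]) %in% genes & toupper(ppi[[2]]) %in% genes
    if (any(keep)) pp <- data.frame(src = toupper(ppi[keep, 1]),
                                    dst = toupper(ppi[keep, 2]),
                                    kind = "ppi", stringsAsFactors = FALSE)
  }
  edges <- rbind(ann, reg, pp)
  if (is.null(edges)) edges <- data.frame(src = character(), dst = character(),
                                          kind = character(), stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}
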