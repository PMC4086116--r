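# Scoring and ranking of test genes.
#
# Per category, a gene's significance is the sum of reciprocal raw
# p-values of the enriched concepts it belongs to. These per-category
# scores are then propagated across heterogeneous categories on the
# bipartite gene-concept graph until convergence, producing a single
# combined score per gene. When a training gene set and a protein
# interaction network are available, an interactome score is computed by
# HITS with priors (teleport probability beta back to the training
# "root" set) and fused with the combined annotation score.
#
# Which concepts participate in scoring is controlled by `sig_filter`.
# The default ("none") lets every concept a gene hits contribute, weighted
# by its reciprocal p-value -- the nominal significance IS the weight, so
# weak concepts contribute next to nothing while a hard gate would starve
# near-null query lists of signal entirely. "nominal" and "adjusted"
# apply a hard cutoff at `sig_level` on the raw or corrected p-value.

sig_records <- function(enr, sig_filter = c("none", "nominal", "adjusted"),
                        sig_level = 0.05) {
  sig_filter <- match.arg(sig_filter)
  keep <- switch(sig_filter,
                 none = rep(TRUE, nrow(enr)),
                 nominal = enr$p_raw <= sig_level,
                 adjusted = enr$p_adj <= sig_level)
  as.data.frame(enr)[keep, , drop = FALSE]
}

#' Per-category reciprocal-p gene scores
#'
#' `score(g, c)` is the sum of `1 / p_raw` over the enriched concepts of
#' category `c` that contain `g` and pass the participation filter. Genes
#' hitting no such concept score 0.
#'
#' @param enr an `enrichment_result` computed on the same gene list
#' @param genes a `gene_list` or character vector
#' @param sig_filter concept participation rule: `"none"` (default; every
#'   concept contributes, weighted by its reciprocal p), `"nominal"` (raw
#'   p must pass `sig_level`) or `"adjusted"` (corrected p must pass)
#' @param sig_level significance level for the gated filters (default 0.05)
#' @return numeric matrix genes x categories (all corpus categories seen in
#'   `enr`), with attribute `"records"` holding the participating concept
#'   rows
#' @export
category_scores <- function(enr, genes, sig_filter = c("none", "nominal", "adjusted"),
                            sig_level = 0.05) {
  stopifnot(inherits(enr, "enrichment_result"))
  genes <- unique(as_gene_vector(genes))
  cats <- unique(as.data.frame(enr)$category)
  M <- matrix(0, nrow = length(genes), ncol = length(cats),
              dimnames = list(genes, cats))
  rec <- sig_records(enr, sig_filter, sig_level)
  if (nrow(rec)) {
    for (i in seq_len(nrow(rec))) {
      hit <- intersect(rec$members_hit[[i]], genes)
      if (length(hit)) M[hit, rec$category[i]] <- M[hit, rec$category[i]] + 1 / rec$p_raw[i]
    }
  }
  attr(M, "records") <- rec
  M
}

#' Propagate gene scores across annotation categories to convergence
#'
#' Iterative propagation on the bipartite gene-concept graph restricted to
#' the participating concepts. Each iteration: (i) every concept takes the
#' mean combined score of its member genes; (ii) every gene collects, per
#' category, the reciprocal-p-weighted sum of its concepts' scores (weights
#' normalized to 1 within each category) and averages across categories;
#' (iii) the new combined score is `damping * propagated +
#' (1 - damping) * initial`, renormalized to total mass 1. The initial
#' vector is the cross-category mean of the column-normalized per-category
#' scores. With a single category there is nothing to propagate across and
#' the normalized category score is returned directly.
#'
#' @param cat_scores matrix from [category_scores()] (with its `"records"`
#'   attribute), or any gene x category score matrix plus `records`
#' @param records participating concept rows (data.frame with category,
#'   p_raw, members_hit); defaults to the attribute on `cat_scores`
#' @param damping weight of the propagated signal vs the initial scores,
#'   default 0.85
#' @param tol convergence tolerance on the max per-gene change, default 1e-8
#' @param max_iter iteration cap, default 1000 (a warning is raised and the
#'   current scores returned with `converged = FALSE` if reached)
#' @param trace if TRUE, attach the per-iteration total mass as attribute
#'   `"mass"`
#' @return named numeric vector of combined scores summing to 1, with
#'   attributes `converged` (logical) and `iterations`
#' @export
propagate <- function(cat_scores, records = attr(cat_scores, "records"),
                      damping = 0.85, tol = 1e-8, max_iter = 1000, trace = FALSE) {
  stopifnot(is.matrix(cat_scores), damping >= 0, damping <= 1, tol > 0)
  genes <- rownames(cat_scores)
  if (is.null(records) || !nrow(records)) stop_mr("no participating concepts to propagate")
  active <- intersect(colnames(cat_scores), unique(records$category))
  active <- active[colSums(cat_scores[, active, drop = FALSE]) > 0]
  if (!length(active)) stop_mr("no category carries a nonzero score")
  S <- cat_scores[, active, drop = FALSE]
  S_hat <- sweep(S, 2, colSums(S), "/")
  if (length(active) == 1L) {
    s <- norm1(S_hat[, 1])
    names(s) <- genes
    attr(s, "converged") <- TRUE
    attr(s, "iterations") <- 1L
    if (trace) attr(s, "mass") <- sum(s)
    return(s)
  }
  # per-category incidence (genes x concepts) and concept weights
  ops <- lapply(active, function(cat) {
    rc <- records[records$category == cat, , drop = FALSE]
    B <- matrix(FALSE, length(genes), nrow(rc), dimnames = list(genes, rc$concept_id))
    for (j in seq_len(nrow(rc))) {
      hit <- intersect(rc$members_hit[[j]], genes)
      B[hit, j] <- TRUE
    }
    keep <- colSums(B) > 0
    B <- B[, keep, drop = FALSE]
    w <- (1 / rc$p_raw[keep])
    list(B = B * 1, w = w / sum(w), msize = colSums(B))
  })
  init <- rowMeans(S_hat)
  s <- norm1(init)
  mass <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    D <- vapply(ops, function(op) {
      u <- as.vector(crossprod(op$B, s)) / op$msize   # concept <- mean member score
      as.vector(op$B %*% (op$w * u))                  # gene <- weighted concept scores
    }, numeric(length(genes)))
    s_new <- norm1(damping * rowMeans(D) + (1 - damping) * init)
    if (trace) mass <- c(mass, sum(s_new))
    delta <- max(abs(s_new - s))
    s <- s_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warn_mr("propagation did not converge in %d iterations", max_iter)
  names(s) <- genes
  attr(s, "converged") <- converged
  attr(s, "iterations") <- iter
  if (trace) attr(s, "mass") <- mass
  s
}

#' HITS with priors on a protein interaction network
#'
#' Hub/authority iteration biased toward a root (training) gene set: at
#' each step a fraction `beta` of the mass teleports back to the uniform
#' prior over root genes. Edges are treated as bidirectional. With
#' `beta = 1` the result is exactly the prior; with `beta = 0` it reduces
#' to standard HITS (up to normalization).
#'
#' @param edges two-column data.frame or matrix of undirected edges
#' @param root `gene_list` or character vector of root (training) genes;
#'   must intersect the graph
#' @param beta back probability in \[0, 1\], default 0.5
#' @param tol convergence tolerance, default 1e-8
#' @param max_iter iteration cap, default 1000
#' @param score which score to return, `"authority"` (default) or `"hub"`
#' @return named numeric vector over graph nodes summing to 1, with
#'   attributes `converged`, `iterations` and the companion score vector
#'   as `"other"`
#' @export
hits_with_priors <- function(edges, root, beta = 0.5, tol = 1e-8,
                             max_iter = 1000, score = c("authority", "hub")) {
  score <- match.arg(score)
  stopifnot(beta >= 0, beta <= 1)
  edges <- as.data.frame(edges)[, 1:2]
  names(edges) <- c("from", "to")
  edges$from <- toupper(trimws(as.character(edges$from)))
  edges$to <- toupper(trimws(as.character(edges$to)))
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  if (!nrow(edges)) stop_mr("empty interaction graph")
  nodes <- sort(unique(c(edges$from, edges$to)))
  root <- intersect(unique(normalize_gene_ids(as_gene_vector(root))), nodes)
  if (!length(root)) stop_mr("root set does not intersect the interaction graph")
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  idx <- cbind(match(edges$from, nodes), match(edges$to, nodes))
  A[idx] <- 1
  A[idx[, 2:1, drop = FALSE]] <- 1
  prior <- stats::setNames(numeric(length(nodes)), nodes)
  prior[root] <- 1 / length(root)
  a <- h <- prior
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    a_new <- (1 - beta) * norm1_or(as.vector(A %*% h), prior) + beta * prior
    h_new <- (1 - beta) * norm1_or(as.vector(A %*% a_new), prior) + beta * prior
    delta <- max(abs(a_new - a), abs(h_new - h))
    a <- stats::setNames(a_new, nodes)
    h <- stats::setNames(h_new, nodes)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warn_mr("HITS with priors did not converge in %d iterations", max_iter)
  out <- if (score == "authority") a else h
  attr(out, "other") <- if (score == "authority") h else a
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iter
  out
}

#' Fuse annotation and interactome scores into a final gene ranking
#'
#' Each signal is rescaled by its maximum before the weighted linear
#' combination `final = weight * combined + (1 - weight) * interactome`.
#' Without an interactome signal the final score is the combined score.
#' Ranks are assigned by final score descending, gene id ascending on
#' ties.
#'
#' @param combined named numeric vector of combined annotation scores
#' @param interactome optional named numeric vector (genes absent from it
#'   score 0)
#' @param weight weight of the annotation signal, default 0.5
#' @return data.frame of class `gene_score_table` with columns gene,
#'   combined, interactome, final, rank
#' @export
fuse_and_rank <- function(combined, interactome = NULL, weight = 0.5) {
  stopifnot(weight >= 0, weight <= 1)
  genes <- names(combined)
  if (is.null(genes)) stop_mr("combined scores must be named by gene")
  rescale <- function(x) if (length(x) && max(x) > 0) x / max(x) else x
  if (is.null(interactome)) {
    inter <- rep(NA_real_, length(genes))
    final <- unname(combined)
  } else {
    inter <- unname(interactome[genes])
    inter[is.na(inter)] <- 0
    final <- weight * rescale(unname(combined)) + (1 - weight) * rescale(inter)
  }
  out <- data.frame(gene = genes, combined = unname(combined),
                    interactome = inter, final = final,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$final, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("gene_score_table", "data.frame")
  out
}

#' Rank a test gene list by biological-context relevance
#'
#' End-to-end gene prioritization: enrichment of the test list against the
#' corpus, reciprocal-p category scores, cross-category propagation, and
#' (when both a training set and a protein interaction network are given)
#' HITS-with-priors interactome scores fused in.
#'
#' When no concept passes the participation filter (possible for small or
#' incoherent lists), all genes receive score 0 and rank by identifier;
#' this keeps decoy-resampling experiments well defined.
#'
#' @param test `gene_list` or character vector of test genes
#' @param corpus an `annotation_corpus`
#' @param training optional `gene_list`/character vector of training genes
#' @param ppi_edges optional two-column edge table of the interactome
#' @param method,alpha_sig,min_size,max_size,background passed to [enrich()]
#' @param sig_filter,sig_level concept participation rule, see
#'   [category_scores()]
#' @param damping,tol,max_iter propagation parameters, see [propagate()]
#' @param beta back probability for [hits_with_priors()]
#' @param fusion_weight weight of the annotation signal in [fuse_and_rank()]
#' @return `gene_score_table` with per-category score columns
#'   (`cat_<name>`) prepended, plus attributes `enrichment` (the
#'   `enrichment_result`) and `converged`
#' @export
rank_genes <- function(test, corpus, training = NULL, ppi_edges = NULL,
                       method = "bonferroni", alpha_sig = 0.05,
                       min_size = 2, max_size = 2000, background = NULL,
                       sig_filter = "none", sig_level = 0.05,
                       damping = 0.85, tol = 1e-8, max_iter = 1000,
                       beta = 0.5, fusion_weight = 0.5) {
  genes <- unique(as_gene_vector(test))
  enr <- enrich(genes, corpus, method = method, alpha_sig = alpha_sig,
                min_size = min_size, max_size = max_size, background = background)
  cs <- category_scores(enr, genes, sig_filter = sig_filter, sig_level = sig_level)
  rec <- attr(cs, "records")
  if (!nrow(rec) || all(cs == 0)) {
    message("rank_genes: no concept passed the participation filter; all scores 0")
    combined <- stats::setNames(numeric(length(genes)), genes)
    converged <- TRUE
  } else {
    combined <- propagate(cs, rec, damping = damping, tol = tol, max_iter = max_iter)
    converged <- attr(combined, "converged")
  }
  interactome <- NULL
  if (!is.null(training) && !is.null(ppi_edges)) {
    hits <- hits_with_priors(ppi_edges, root = training, beta = beta,
                             tol = tol, max_iter = max_iter)
    interactome <- hits
    converged <- converged && attr(hits, "converged")
  }
  tab <- fuse_and_rank(stats::setNames(as.numeric(combined), names(combined)),
                       interactome = interactome, weight = fusion_weight)
  cs_df <- as.data.frame(cs[tab$gene, , drop = FALSE])
  names(cs_df) <- paste0("cat_", colnames(cs))
  out <- cbind(tab["gene"], cs_df, tab[setdiff(names(tab), "gene")])
  rownames(out) <- NULL
  class(out) <- c("gene_score_table", "data.frame")
  attr(out, "enrichment") <- enr
  attr(out, "converged") <- converged
  out
}
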