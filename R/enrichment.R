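# Gene-set over-representation analysis: hypergeometric upper-tail tests
# per concept, corrected per annotation category (Bonferroni or
# Benjamini-Hochberg step-up). Correction is applied within each category
# independently so that large categories cannot swamp small ones.

#' Upper-tail hypergeometric p-value
#'
#' P(X >= k) where X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` members of a `K`-gene concept when sampling `n` genes
#' without replacement from a background of `N`. Returns 1 when `k = 0`.
#' All arguments are vectorized and recycled.
#'
#' @param k overlap count
#' @param K concept size
#' @param n query size
#' @param N background size
#' @return p-value(s) in (0, 1]
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  v <- suppressWarnings(cbind(k, K, n, N))
  k <- v[, 1]; K <- v[, 2]; n <- v[, 3]; N <- v[, 4]
  if (any(is.na(v))) stop_mr("hypergeom_pvalue: NA argument")
  if (any(K > N) || any(n > N)) stop_mr("hypergeom_pvalue: need K <= N and n <= N")
  if (any(k < 0) || any(k > pmin(K, n))) stop_mr("hypergeom_pvalue: need 0 <= k <= min(K, n)")
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p[k == 0] <- 1
  unname(p)
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, p * m)`) or Benjamini-Hochberg step-up (`fdr_bh`).
#' `m` defaults to `length(p)` but may be larger when only a subset of the
#' tested family is passed in (untested members count against the family
#' size).
#'
#' @param p numeric vector of raw p-values in (0, 1]
#' @param method `"bonferroni"` or `"fdr_bh"`
#' @param m family size, default `length(p)`
#' @return adjusted p-values, same length and order as `p`
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "fdr_bh"), m = length(p)) {
  method <- match.arg(method)
  if (!length(p)) return(numeric())
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) stop_mr("p-values must lie in (0, 1]")
  if (m < length(p)) stop_mr("family size m cannot be smaller than length(p)")
  stats::p.adjust(p, method = switch(method, bonferroni = "bonferroni", fdr_bh = "BH"), n = m)
}

#' Gene-set enrichment of a gene list against an annotation corpus
#'
#' For every concept with at least one query member (and size within
#' `[min_size, max_size]`), computes the hypergeometric upper-tail p-value
#' and an adjusted p-value corrected within the concept's category. The
#' background for a category defaults to the union of its concepts'
#' members; `background` overrides this for all categories. Query genes
#' outside the corpus background are dropped with a warning; an empty
#' intersection aborts.
#'
#' @param genes a `gene_list` or character vector of normalized gene ids
#' @param corpus an `annotation_corpus`
#' @param method correction method, see [adjust_pvalues()]
#' @param alpha_sig significance level applied to adjusted p-values for
#'   the `significant` flag (default 0.05)
#' @param min_size,max_size concept size filter applied before testing
#'   (defaults 2 and 2000)
#' @param background optional character vector overriding the per-category
#'   background universe
#' @param p_floor lower floor applied to raw p-values so downstream
#'   reciprocals stay finite (default 1e-300)
#' @return data.frame of class `enrichment_result` with one row per
#'   concept: category, concept_id, name, k, K, n, N, p_raw, p_adj,
#'   significant, members_hit (list column), sorted by p_raw within
#'   category
#' @export
enrich <- function(genes, corpus, method = c("bonferroni", "fdr_bh"),
                   alpha_sig = 0.05, min_size = 2, max_size = 2000,
                   background = NULL, p_floor = 1e-300) {
  method <- match.arg(method)
  stopifnot(inherits(corpus, "annotation_corpus"))
  q_all <- unique(as_gene_vector(genes))
  inside <- intersect(q_all, corpus$background)
  if (!length(inside)) stop_mr("query gene list does not intersect the corpus background")
  if (length(inside) < length(q_all)) {
    warn_mr("%d query gene(s) outside the corpus background dropped",
            length(q_all) - length(inside))
  }
  rows <- list()
  for (cat in names(corpus$categories)) {
    concepts <- corpus$categories[[cat]]
    if (!length(concepts)) next
    universe <- if (is.null(background)) {
      unique(unlist(lapply(concepts, `[[`, "members"), use.names = FALSE))
    } else unique(background)
    q <- intersect(inside, universe)
    N <- length(universe)
    n <- length(q)
    if (!n) next
    sizes <- lengths(lapply(concepts, `[[`, "members"))
    eligible <- names(concepts)[sizes >= min_size & sizes <= max_size]
    m_family <- length(eligible)
    if (!m_family) next
    hits <- lapply(concepts[eligible], function(co) intersect(co$members, q))
    kk <- lengths(hits)
    keep <- kk >= 1L
    if (!any(keep)) next
    cid <- eligible[keep]
    K <- sizes[match(cid, names(concepts))]
    k <- kk[keep]
    p_raw <- pmax(hypergeom_pvalue(k, K, n, N), p_floor)
    p_adj <- adjust_pvalues(p_raw, method, m = m_family)
    rows[[cat]] <- data.frame(
      category = cat,
      concept_id = cid,
      name = vapply(concepts[cid], `[[`, character(1), "name"),
      k = as.integer(k), K = as.integer(K), n = as.integer(n), N = as.integer(N),
      p_raw = p_raw, p_adj = pmin(p_adj, 1),
      significant = p_adj <= alpha_sig,
      stringsAsFactors = FALSE, row.names = NULL
    )
    rows[[cat]]$members_hit <- unname(hits[cid])
    ord <- order(rows[[cat]]$p_raw, rows[[cat]]$concept_id)
    rows[[cat]] <- rows[[cat]][ord, , drop = FALSE]
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(category = character(), concept_id = character(), name = character(),
               k = integer(), K = integer(), n = integer(), N = integer(),
               p_raw = numeric(), p_adj = numeric(), significant = logical(),
               members_hit = I(list()), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "query") <- sort(inside)
  attr(out, "method") <- method
  attr(out, "alpha_sig") <- alpha_sig
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Export an enrichment result as TSV
#'
#' Rows are written in their stored order (by p_raw within category);
#' `members_hit` is semicolon-joined.
#'
#' @param enr an `enrichment_result`
#' @param path output path
#' @return the path, invisibly
#' @export
write_enrichment_tsv <- function(enr, path) {
  write_ranked_tsv(as.data.frame(enr), path, score_col = NULL)
}
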