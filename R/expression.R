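# Integration of enrichment-derived significance with expression
# profiles. Each entity (gene or miR) gets a three-component vector --
# enrichment score, expression level, |log2 fold change| -- each rescaled
# to [0, 1] by its cohort maximum, and the overall score is the Euclidean
# (L2) norm of that vector. With no expression data the integration is a
# no-op on the ranking.

#' Build per-entity significance vectors
#'
#' Components are rescaled by dividing by the cohort maximum (so the
#' largest value maps to 1). Fold changes are transformed to
#' `|log2 FC|` by default, treating up- and down-regulation
#' symmetrically; `"signed"` uses `log2 FC` clamped below at 0, `"raw"`
#' uses the value as given. Entities absent from the expression table get
#' 0 for the expression components; an all-zero component is dropped (kept
#' as zeros) with a warning.
#'
#' @param scores named numeric vector of final entity scores (>= 0)
#' @param expression optional data.frame from [read_expression_table()]
#' @param fc_transform `"abs_log2"` (default), `"signed"` or `"raw"`
#' @return data.frame: id, sig_enrichment, sig_expression,
#'   sig_fold_change, overall
#' @export
significance_vectors <- function(scores, expression = NULL,
                                 fc_transform = c("abs_log2", "signed", "raw")) {
  fc_transform <- match.arg(fc_transform)
  ids <- names(scores)
  if (is.null(ids)) stop_mr("scores must be named by entity id")
  rescale <- function(x, label) {
    x[is.na(x)] <- 0
    if (any(x < 0)) stop_mr("negative %s values; check the transform", label)
    mx <- max(x)
    if (mx == 0) {
      if (length(x)) warn_mr("all-zero %s component dropped", label)
      return(x)
    }
    x / mx
  }
  enr <- rescale(as.numeric(scores), "enrichment")
  expr <- fc <- numeric(length(ids))
  if (!is.null(expression) && nrow(expression)) {
    m <- match(ids, expression$id)
    ev <- expression$expression_level[m]
    expr <- rescale(pmax(ev, 0), "expression level")
    fv <- expression$fold_change[m]
    fv <- switch(fc_transform,
                 abs_log2 = abs(log2(ifelse(is.na(fv) | fv <= 0, 1, fv))),
                 signed = pmax(log2(ifelse(is.na(fv) | fv <= 0, 1, fv)), 0),
                 raw = ifelse(is.na(fv), 0, fv))
    fc <- rescale(fv, "fold change")
  }
  data.frame(id = ids,
             sig_enrichment = enr,
             sig_expression = expr,
             sig_fold_change = fc,
             overall = sqrt(enr^2 + expr^2 + fc^2),
             stringsAsFactors = FALSE)
}

#' Euclidean overall score of a significance vector
#'
#' The L2 norm of the component vector; monotone nondecreasing in every
#' component, bounded by `sqrt(3)` when all components are in `[0, 1]`.
#'
#' @param v numeric vector of components, or a data.frame/matrix with one
#'   vector per row
#' @return numeric score(s)
#' @export
overall_score <- function(v) {
  if (is.data.frame(v)) v <- as.matrix(v[vapply(v, is.numeric, logical(1))])
  if (is.matrix(v)) sqrt(rowSums(v^2)) else sqrt(sum(v^2))
}

#' Re-rank a score table by expression-integrated overall score
#'
#' Builds significance vectors for the table's entities and re-ranks by
#' the Euclidean overall score (ties broken by id). With `expression =
#' NULL` the ranking equals the input ranking exactly.
#'
#' @param table a `gene_score_table` or `mir_score_table`
#' @param expression optional expression table
#' @param id_col,score_col columns holding entity id and score (defaults
#'   inferred from the table class)
#' @param fc_transform see [significance_vectors()]
#' @return the table with sig_* and overall columns appended, re-ranked by
#'   `overall`
#' @export
integrate_expression <- function(table, expression = NULL,
                                 id_col = NULL, score_col = NULL,
                                 fc_transform = "abs_log2") {
  if (is.null(id_col)) id_col <- if ("mir" %in% names(table)) "mir" else "gene"
  if (is.null(score_col)) score_col <- if ("mir" %in% names(table)) "sig" else "final"
  stopifnot(id_col %in% names(table), score_col %in% names(table))
  sv <- significance_vectors(stats::setNames(table[[score_col]], table[[id_col]]),
                             expression, fc_transform = fc_transform)
  out <- cbind(table, sv[match(table[[id_col]], sv$id),
                         c("sig_enrichment", "sig_expression", "sig_fold_change", "overall")])
  out <- out[order(-out$overall, out[[id_col]]), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
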