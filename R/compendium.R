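# Candidate miR -> mRNA interaction compendium: the union of several
# prediction/validation sources with per-pair provenance. Because overlap
# between prediction algorithms is low, the candidate set is the plain
# union of all sources; source membership and an experimental flag are
# carried as metadata only (no extra weight downstream).

#' Normalize miR identifiers
#'
#' Lowercases and trims; optionally strips a three-letter species prefix
#' (e.g. `hsa-`). Arms (-5p/-3p) are deliberately not collapsed, since
#' they are distinct regulators.
#'
#' @param x character vector of miR identifiers
#' @param strip_species drop a leading `xxx-` species prefix
#' @return normalized identifiers
#' @export
normalize_mir_ids <- function(x, strip_species = FALSE) {
  x <- tolower(trimws(as.character(x)))
  if (strip_species) x <- sub("^[a-z]{3}-(?=mir|let)", "", x, perl = TRUE)
  x
}

#' Load one miR-target source table
#'
#' Tab-separated with a header; the miR and gene column names are
#' configurable. Within-source duplicate pairs are collapsed.
#'
#' @param path file path
#' @param source_name registry name for this source
#' @param experimental is this source experimentally validated evidence?
#' @param mir_col,gene_col column names holding the miR and gene ids
#' @param id_map optional identifier map for genes
#' @param strip_species passed to [normalize_mir_ids()]
#' @return object of class `interaction_source`: list with `name`,
#'   `experimental`, `pairs` (data.frame mir, gene)
#' @export
read_interaction_source <- function(path, source_name,
                                    experimental = FALSE,
                                    mir_col = "mir", gene_col = "gene",
                                    id_map = NULL, strip_species = FALSE) {
  if (!file.exists(path)) stop_mr("interaction source not found: %s", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!mir_col %in% names(tab)) stop_mr("column '%s' absent from %s", mir_col, path)
  if (!gene_col %in% names(tab)) stop_mr("column '%s' absent from %s", gene_col, path)
  pairs <- data.frame(
    mir = normalize_mir_ids(tab[[mir_col]], strip_species),
    gene = normalize_gene_ids(tab[[gene_col]], id_map),
    stringsAsFactors = FALSE
  )
  pairs <- pairs[nzchar(pairs$mir) & nzchar(pairs$gene), , drop = FALSE]
  pairs <- unique(pairs)
  if (!nrow(pairs)) warn_mr("interaction source '%s' is empty", source_name)
  interaction_source(pairs, source_name, experimental)
}

#' Build an interaction source from pairs already in memory
#'
#' @param pairs data.frame with columns `mir`, `gene`
#' @inheritParams read_interaction_source
#' @export
interaction_source <- function(pairs, source_name, experimental = FALSE) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs)) {
    pairs <- unique(data.frame(mir = normalize_mir_ids(pairs$mir),
                               gene = toupper(trimws(pairs$gene)),
                               stringsAsFactors = FALSE))
    pairs <- pairs[order(pairs$mir, pairs$gene), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(name = source_name, experimental = isTRUE(experimental), pairs = pairs),
            class = "interaction_source")
}

#' Union several sources into an interaction compendium
#'
#' The compendium is the set union of all (miR, gene) pairs. Each pair
#' records every contributing source; `validated` is TRUE iff any
#' contributing source is experimental. The result is independent of the
#' order in which sources are supplied.
#'
#' @param sources list of `interaction_source` objects
#' @return object of class `interaction_compendium`: list with
#'   `interactions` (data.frame mir, gene, sources, validated) and
#'   `registry` (data.frame source, experimental)
#' @export
union_compendium <- function(sources) {
  if (inherits(sources, "interaction_source")) sources <- list(sources)
  if (!length(sources)) stop_mr("need at least one source")
  stopifnot(all(vapply(sources, inherits, logical(1), "interaction_source")))
  nms <- vapply(sources, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop_mr("duplicate source names")
  registry <- data.frame(source = nms,
                         experimental = vapply(sources, `[[`, logical(1), "experimental"),
                         stringsAsFactors = FALSE)
  registry <- registry[order(registry$source), , drop = FALSE]
  rownames(registry) <- NULL
  all_pairs <- do.call(rbind, lapply(sources, function(s) {
    if (!nrow(s$pairs)) return(NULL)
    cbind(s$pairs, src = s$name, exp = s$experimental)
  }))
  if (is.null(all_pairs) || !nrow(all_pairs)) {
    interactions <- data.frame(mir = character(), gene = character(),
                               sources = character(), validated = logical(),
                               stringsAsFactors = FALSE)
  } else {
    key <- paste(all_pairs$mir, all_pairs$gene, sep = "\r")
    src_by <- split(all_pairs$src, key)
    exp_by <- split(all_pairs$exp, key)
    keys <- sort(names(src_by))
    parts <- strsplit(keys, "\r", fixed = TRUE)
    interactions <- data.frame(
      mir = vapply(parts, `[[`, character(1), 1),
      gene = vapply(parts, `[[`, character(1), 2),
      sources = vapply(src_by[keys], function(v) paste(sort(unique(v)), collapse = ";"), character(1)),
      validated = vapply(exp_by[keys], any, logical(1)),
      stringsAsFactors = FALSE
    )
    interactions <- interactions[order(interactions$mir, interactions$gene), , drop = FALSE]
    rownames(interactions) <- NULL
  }
  structure(list(interactions = interactions, registry = registry),
            class = "interaction_compendium")
}

#' @export
print.interaction_compendium <- function(x, ...) {
  cat(sprintf("<interaction_compendium: %d interactions, %d miRs, %d genes, %d sources>\n",
              nrow(x$interactions), length(unique(x$interactions$mir)),
              length(unique(x$interactions$gene)), nrow(x$registry)))
  invisible(x)
}

#' Targets of a miR in a compendium
#'
#' Unknown miRs yield the empty set (not an error). When `restrict_to` is
#' given the result is intersected with it.
#'
#' @param compendium an `interaction_compendium`
#' @param mir a miR identifier (normalized internally)
#' @param restrict_to optional `gene_list` or character vector
#' @return sorted character vector of gene ids
#' @export
targets_of <- function(compendium, mir, restrict_to = NULL) {
  stopifnot(inherits(compendium, "interaction_compendium"))
  mir <- normalize_mir_ids(mir)
  tg <- compendium$interactions$gene[compendium$interactions$mir == mir]
  if (!is.null(restrict_to)) tg <- intersect(tg, as_gene_vector(restrict_to))
  sort(unique(tg))
}

#' All miR identifiers in a compendium
#' @param compendium an `interaction_compendium`
#' @return sorted character vector
#' @export
compendium_mirs <- function(compendium) {
  sort(unique(compendium$interactions$mir))
}

#' Persist / load a compendium as a single TSV
#'
#' Columns: mir, gene, sources (semicolon-joined), validated.
#'
#' @param compendium an `interaction_compendium`
#' @param path file path
#' @return `write_compendium`: the path invisibly; `read_compendium`: an
#'   `interaction_compendium`
#' @export
write_compendium <- function(compendium, path) {
  utils::write.table(compendium$interactions, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_compendium
#' @export
read_compendium <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mir", "gene", "sources", "validated")
  if (!all(need %in% names(tab))) stop_mr("compendium TSV needs columns: %s", paste(need, collapse = ", "))
  src_names <- sort(unique(unlist(strsplit(tab$sources, ";", fixed = TRUE))))
  # experimental flag per source: a source is experimental if every pair it
  # contributes is validated and it appears in some validated pair
  exp_flag <- vapply(src_names, function(s) {
    hit <- grepl(paste0("(^|;)", s, "($|;)"), tab$sources)
    all(tab$validated[hit]) && any(hit)
  }, logical(1))
  interactions <- tab[order(tab$mir, tab$gene), need, drop = FALSE]
  rownames(interactions) <- NULL
  structure(list(interactions = interactions,
                 registry = data.frame(source = src_names, experimental = exp_flag,
                                       stringsAsFactors = FALSE)),
            class = "interaction_compendium")
}
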