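# Readers and writers for the external file formats, plus identifier
# normalization into a single internal gene namespace.
#
# The internal namespace is the (HGNC-style) gene symbol, uppercased.
# Numeric identifiers (Entrez style) are resolved through a user-supplied
# two-column mapping table; there are no live lookups.

#' Read a two-column identifier mapping table
#'
#' Maps alternative identifiers (typically Entrez IDs) onto the internal
#' symbol namespace. The file is tab-separated with two columns,
#' `from` and `to`; a header line is detected and skipped if the first
#' field is literally "from".
#'
#' @param path file path
#' @return named character vector: `names` are the source identifiers
#'   (uppercased), values the target symbols (uppercased)
#' @export
read_id_map <- function(path) {
  if (!file.exists(path)) stop_mr("id map file not found: %s", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE, colClasses = "character",
                           quote = "", comment.char = "#", blank.lines.skip = TRUE)
  if (ncol(tab) < 2L) stop_mr("id map must have at least two tab-separated columns")
  if (nrow(tab) > 0L && tolower(tab[1, 1]) == "from") tab <- tab[-1, , drop = FALSE]
  map <- toupper(trimws(tab[[2]]))
  names(map) <- toupper(trimws(tab[[1]]))
  map[!duplicated(names(map))]
}

#' Normalize gene identifiers into the internal namespace
#'
#' Trims whitespace, maps identifiers found in `id_map`, and uppercases.
#' The operation is idempotent: applying it twice equals applying it once.
#'
#' @param x character vector of identifiers
#' @param id_map optional named vector from [read_id_map()]
#' @return character vector of normalized identifiers
#' @export
normalize_gene_ids <- function(x, id_map = NULL) {
  x <- toupper(trimws(as.character(x)))
  if (!is.null(id_map) && length(id_map)) {
    hit <- match(x, names(id_map))
    x[!is.na(hit)] <- unname(id_map[hit[!is.na(hit)]])
  }
  x
}

#' Read a plain-text gene list
#'
#' One identifier per line; lines starting with `#` and blank lines are
#' ignored. Numeric identifiers must be resolvable through `id_map`;
#' unresolvable ones are dropped with a warning unless their fraction
#' exceeds `max_unresolved`, which aborts (a guard against e.g.
#' wrong-species input). Duplicates after normalization are dropped with a
#' warning.
#'
#' @param path file path
#' @param id_map optional named vector from [read_id_map()]
#' @param label list label (defaults to the file name)
#' @param max_unresolved maximum tolerated fraction of unresolvable
#'   identifiers, default 0.5
#' @return object of class `gene_list`: list with `genes` (ordered,
#'   deduplicated character vector), `label`, `unresolved`
#' @export
read_gene_list <- function(path, id_map = NULL, label = basename(path),
                           max_unresolved = 0.5) {
  if (!file.exists(path)) stop_mr("gene list file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop_mr("empty gene list: %s", path)
  gene_list(lines, label = label, id_map = id_map, max_unresolved = max_unresolved)
}

#' Construct a gene list from identifiers already in memory
#'
#' Same normalization and tolerance rules as [read_gene_list()].
#'
#' @inheritParams read_gene_list
#' @param ids character vector of identifiers
#' @export
gene_list <- function(ids, label = "genes", id_map = NULL, max_unresolved = 0.5) {
  ids <- trimws(as.character(ids))
  ids <- ids[nzchar(ids)]
  if (!length(ids)) stop_mr("empty gene list")
  # numeric-only identifiers are Entrez style and must be mapped
  numeric_id <- grepl("^[0-9]+$", ids)
  resolvable <- !numeric_id | toupper(ids) %in% names(id_map %||% character())
  n_bad <- sum(!resolvable)
  if (n_bad / length(ids) > max_unresolved) {
    stop_mr("%d of %d identifiers unresolvable (> %.0f%% tolerated)",
            n_bad, length(ids), 100 * max_unresolved)
  }
  if (n_bad > 0) {
    warn_mr("dropped %d unresolvable identifier(s): %s", n_bad,
            paste(utils::head(ids[!resolvable], 5), collapse = ", "))
  }
  genes <- normalize_gene_ids(ids[resolvable], id_map)
  if (anyDuplicated(genes)) {
    warn_mr("dropped %d duplicate identifier(s) in gene list '%s'",
            sum(duplicated(genes)), label)
    genes <- genes[!duplicated(genes)]
  }
  structure(list(genes = genes, label = label,
                 unresolved = ids[!resolvable]),
            class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("<gene_list '%s': %d genes>\n", x$label, length(x$genes)))
  invisible(x)
}

# accept either a gene_list or a plain character vector everywhere
as_gene_vector <- function(x) {
  if (inherits(x, "gene_list")) x$genes else as.character(x)
}

#' Read one annotation category from a GMT file
#'
#' Standard GMT dialect: tab-separated lines
#' `concept-id <TAB> concept-name <TAB> member genes...`. Concepts with no
#' members are dropped with a warning; duplicate concept ids abort; a line
#' with fewer than two fields is malformed.
#'
#' @param path file path
#' @param category category name, defaults to the file name without
#'   extension
#' @param id_map optional identifier map applied to members
#' @return a corpus fragment: list with `category` and `concepts` (named
#'   list of `list(name, members)`)
#' @export
read_gmt <- function(path, category = sub("\\.gmt$", "", basename(path)),
                     id_map = NULL) {
  if (!file.exists(path)) stop_mr("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  concepts <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L) stop_mr("malformed GMT line %d in %s (need >= 2 fields)", i, path)
    cid <- trimws(fields[1])
    if (cid %in% names(concepts)) stop_mr("duplicate concept '%s' at line %d in %s", cid, i, path)
    members <- unique(normalize_gene_ids(fields[-(1:2)], id_map))
    members <- members[nzchar(members)]
    if (!length(members)) {
      warn_mr("concept '%s' (line %d) has no members; dropped", cid, i)
      next
    }
    concepts[[cid]] <- list(name = trimws(fields[2]), members = members)
  }
  structure(list(category = category, concepts = concepts), class = "corpus_fragment")
}

#' Write one annotation category as a GMT file
#'
#' @param fragment a corpus fragment as returned by [read_gmt()]
#' @param path output path
#' @return the path, invisibly
#' @export
write_gmt <- function(fragment, path) {
  lines <- vapply(names(fragment$concepts), function(cid) {
    co <- fragment$concepts[[cid]]
    paste(c(cid, co$name, co$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble an annotation corpus from category fragments
#'
#' The corpus holds concept -> gene memberships partitioned into named
#' categories; the background universe is the union of all members.
#'
#' @param fragments list of fragments from [read_gmt()] (or built in code)
#' @return object of class `annotation_corpus`: list with `categories`
#'   (category -> named list of `list(name, members)`) and `background`
#' @export
annotation_corpus <- function(fragments) {
  if (inherits(fragments, "corpus_fragment")) fragments <- list(fragments)
  cats <- list()
  for (fr in fragments) {
    if (is.null(fr$category) || !nzchar(fr$category)) stop_mr("fragment without category name")
    if (fr$category %in% names(cats)) stop_mr("duplicate category '%s'", fr$category)
    cats[[fr$category]] <- fr$concepts
  }
  background <- sort(unique(unlist(lapply(cats, function(co)
    unlist(lapply(co, `[[`, "members"), use.names = FALSE)), use.names = FALSE)))
  structure(list(categories = cats, background = background),
            class = "annotation_corpus")
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf("<annotation_corpus: %d categories, %d concepts, %d background genes>\n",
              length(x$categories), sum(lengths(x$categories)), length(x$background)))
  invisible(x)
}

#' Read every `*.gmt` file in a directory as one corpus
#'
#' Category names are the file names without extension.
#'
#' @param dir directory containing GMT files
#' @param id_map optional identifier map
#' @return an `annotation_corpus`
#' @export
read_corpus_dir <- function(dir, id_map = NULL) {
  files <- sort(list.files(dir, pattern = "\\.gmt$", full.names = TRUE))
  if (!length(files)) stop_mr("no .gmt files in %s", dir)
  annotation_corpus(lapply(files, read_gmt, id_map = id_map))
}

#' Restrict a corpus to a subset of categories
#'
#' @param corpus an `annotation_corpus`
#' @param categories character vector of category names to keep
#' @return an `annotation_corpus` containing only those categories
#' @export
restrict_categories <- function(corpus, categories) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  if (!length(categories)) stop_mr("empty category subset")
  unknown <- setdiff(categories, names(corpus$categories))
  if (length(unknown)) stop_mr("unknown categories: %s", paste(unknown, collapse = ", "))
  cats <- corpus$categories[categories]
  out <- corpus
  out$categories <- cats
  out$background <- sort(unique(unlist(lapply(cats, function(co)
    unlist(lapply(co, `[[`, "members"), use.names = FALSE)), use.names = FALSE)))
  out
}

#' Read an expression table
#'
#' Tab-separated with a header; the first column holds identifiers, and at
#' least one of the columns `Expression level` and `Fold change`
#' (case-insensitive match) must be present. Duplicate identifiers keep the
#' row with the largest absolute fold change (largest expression level when
#' no fold-change column exists).
#'
#' Identifiers containing "mir" (any case) are treated as miR ids and kept
#' lowercase; everything else is gene-normalized through `id_map`.
#'
#' @param path file path
#' @param id_map optional identifier map for gene rows
#' @return data.frame with columns `id`, `expression_level`, `fold_change`
#'   (absent measurements are `NA`)
#' @export
read_expression_table <- function(path, id_map = NULL) {
  if (!file.exists(path)) stop_mr("expression table not found: %s", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_mr("expression table needs an identifier column plus a value column")
  low <- tolower(trimws(names(tab)))
  expr_col <- which(low == "expression level")[1]
  fc_col <- which(low == "fold change")[1]
  if (is.na(expr_col) && is.na(fc_col)) {
    stop_mr("expression table must contain an 'Expression level' and/or 'Fold change' column")
  }
  ids <- trimws(as.character(tab[[1]]))
  is_mir <- grepl("mir", ids, ignore.case = TRUE)
  ids[!is_mir] <- normalize_gene_ids(ids[!is_mir], id_map)
  ids[is_mir] <- normalize_mir_ids(ids[is_mir])
  out <- data.frame(
    id = ids,
    expression_level = if (!is.na(expr_col)) as.numeric(tab[[expr_col]]) else NA_real_,
    fold_change = if (!is.na(fc_col)) as.numeric(tab[[fc_col]]) else NA_real_,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$id)) {
    pref <- if (!is.na(fc_col)) abs(out$fold_change) else out$expression_level
    pref[is.na(pref)] <- -Inf
    out <- out[order(out$id, -pref), , drop = FALSE]
    n_dup <- sum(duplicated(out$id))
    out <- out[!duplicated(out$id), , drop = FALSE]
    warn_mr("expression table: resolved %d duplicate identifier(s) keeping the %s",
            n_dup, if (!is.na(fc_col)) "largest |fold change|" else "largest expression level")
  }
  rownames(out) <- NULL
  out[order(out$id), , drop = FALSE]
}

#' Write a typed score network in GML format
#'
#' Nodes carry `id`, `type` (one of miR, mRNA, concept, interaction) and
#' `score`; edges carry `src`, `dst`, `kind`. The file is readable by
#' Cytoscape and round-trips through [read_network_gml()].
#'
#' @param nodes data.frame with columns `id`, `type`, `score`
#' @param edges data.frame with columns `src`, `dst`, `kind`
#' @param path output path
#' @return the path, invisibly
#' @export
write_network_gml <- function(nodes, edges, path) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  need_n <- c("id", "type", "score"); need_e <- c("src", "dst", "kind")
  if (!all(need_n %in% names(nodes))) stop_mr("nodes need columns: %s", paste(need_n, collapse = ", "))
  if (!all(need_e %in% names(edges))) stop_mr("edges need columns: %s", paste(need_e, collapse = ", "))
  if (anyDuplicated(nodes$id)) stop_mr("duplicate node ids")
  unknown <- setdiff(c(edges$src, edges$dst), nodes$id)
  if (length(unknown)) stop_mr("edge references unknown node(s): %s",
                               paste(utils::head(unknown, 5), collapse = ", "))
  vdf <- data.frame(name = as.character(nodes$id), type = as.character(nodes$type),
                    score = as.numeric(nodes$score), stringsAsFactors = FALSE)
  edf <- data.frame(from = as.character(edges$src), to = as.character(edges$dst),
                    kind = as.character(edges$kind), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  igraph::write_graph(g, path, format = "gml")
  invisible(path)
}

#' Read a network written by [write_network_gml()]
#'
#' @param path GML file path
#' @return list with `nodes` (id, type, score) and `edges` (src, dst, kind)
#' @export
read_network_gml <- function(path) {
  if (!file.exists(path)) stop_mr("GML file not found: %s", path)
  g <- igraph::read_graph(path, format = "gml")
  nodes <- data.frame(
    id = igraph::vertex_attr(g, "name"),
    type = igraph::vertex_attr(g, "type"),
    score = as.numeric(igraph::vertex_attr(g, "score")),
    stringsAsFactors = FALSE
  )
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- data.frame(
    src = if (nrow(el)) el[, 1] else character(),
    dst = if (nrow(el)) el[, 2] else character(),
    kind = igraph::edge_attr(g, "kind") %||% character(),
    stringsAsFactors = FALSE
  )
  list(nodes = nodes[order(nodes$id), , drop = FALSE], edges = edges)
}
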