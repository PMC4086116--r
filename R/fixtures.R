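# Synthetic corpora, interaction compendia, PPI graphs and expression
# tables with planted, parameterized signal.
#
# The generator emulates the structure the ranking engine exploits: a
# functional module of genes that are densely co-annotated (shared
# concepts across every category), planted miRs whose target sets are
# drawn from that module, and decoy miRs whose target sets are drawn like
# a background miR's. Degree balance is deliberate: outside the signal
# concepts every gene carries (nearly) the same annotation degree, and
# every miR carries the same module-target quota at signal strength 0, so
# that a planted miR with no signal is statistically exchangeable with
# the decoys.

#' Specification of a synthetic fixture
#'
#' @param n_genes number of genes in the universe (default 200)
#' @param categories annotation category names (default the four core
#'   categories: GO_BP, Pathway, MousePhenotype, Coexpression)
#' @param n_concepts_per_category concepts per category (default 30)
#' @param concept_size_range inclusive size range for sampled concepts
#'   (default c(10, 20))
#' @param signal_concepts_per_category how many concepts per category are
#'   drawn from the signal module (default 12)
#' @param module_size size of the planted functional module (default 30)
#' @param n_mirs number of miRs (default 20)
#' @param targets_per_mir targets per miR (default 20)
#' @param planted_mir_count how many miRs are planted (default 1)
#' @param signal_strength in \[0, 1\]: fraction of a planted miR's targets
#'   forced into the signal module; the remaining fraction is drawn like a
#'   decoy's, so 0 makes planted and decoy miRs indistinguishable
#' @param expression_noise_sd Gaussian noise sd on the synthetic
#'   expression table (default 0.25)
#' @param rng_seed master seed; all substreams derive from it
#' @return object of class `fixture_spec`
#' @export
fixture_spec <- function(n_genes = 200,
                         categories = c("GO_BP", "Pathway", "MousePhenotype", "Coexpression"),
                         n_concepts_per_category = 30,
                         concept_size_range = c(10, 20),
                         signal_concepts_per_category = 12,
                         module_size = 30,
                         n_mirs = 20,
                         targets_per_mir = 20,
                         planted_mir_count = 1,
                         signal_strength = 0.8,
                         expression_noise_sd = 0.25,
                         rng_seed = 1) {
  stopifnot(is_count(n_genes), is_count(n_concepts_per_category),
            is_count(module_size), is_count(n_mirs), is_count(targets_per_mir),
            is_count(planted_mir_count), length(categories) >= 1,
            length(concept_size_range) == 2,
            concept_size_range[1] >= 2,
            concept_size_range[2] >= concept_size_range[1],
            signal_concepts_per_category >= 0,
            signal_concepts_per_category <= n_concepts_per_category,
            signal_strength >= 0, signal_strength <= 1,
            expression_noise_sd >= 0,
            module_size <= n_genes, targets_per_mir <= n_genes,
            planted_mir_count <= n_mirs,
            concept_size_range[2] <= module_size)
  structure(list(n_genes = n_genes, categories = categories,
                 n_concepts_per_category = n_concepts_per_category,
                 concept_size_range = concept_size_range,
                 signal_concepts_per_category = signal_concepts_per_category,
                 module_size = module_size, n_mirs = n_mirs,
                 targets_per_mir = targets_per_mir,
                 planted_mir_count = planted_mir_count,
                 signal_strength = signal_strength,
                 expression_noise_sd = expression_noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "fixture_spec")
}

# substream seeds derived once from the master seed (documented order:
# corpus, compendium, expression, ppi)
fixture_substreams <- function(spec) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$rng_seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 4),
                  c("corpus", "compendium", "expression", "ppi"))
}

# Draw `length(sizes)` sets from `pool` with near-equal element usage:
# concatenated random permutations chopped into chunks. Within-chunk
# duplicates (possible at permutation boundaries) are replaced by unused
# pool elements.
balanced_sets <- function(pool, sizes) {
  total <- sum(sizes)
  n_perm <- ceiling(total / length(pool))
  seq_pool <- unlist(lapply(seq_len(n_perm), function(i) sample(pool)))
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  lapply(seq_along(sizes), function(i) {
    chunk <- seq_pool[starts[i]:ends[i]]
    dup <- duplicated(chunk)
    if (any(dup)) chunk[dup] <- sample(setdiff(pool, chunk), sum(dup))
    sort(chunk)
  })
}

#' Generate a synthetic annotation corpus with a planted module
#'
#' Every category contains `signal_concepts_per_category` concepts drawn
#' from the module and the rest drawn from the whole universe, with
#' near-balanced gene degrees within each group. Deterministic under the
#' spec's seed.
#'
#' @param spec a `fixture_spec`
#' @return an `annotation_corpus` with attributes `module` (the module
#'   gene ids) and `signal_concepts` (concept ids drawn from the module)
#' @export
make_corpus <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  seeds <- fixture_substreams(spec)
  set.seed(seeds[["corpus"]])
  genes <- sprintf("G%0*d", nchar(as.character(spec$n_genes)), seq_len(spec$n_genes))
  module <- sort(sample(genes, spec$module_size))
  rng <- spec$concept_size_range
  draw_sizes <- function(n) rng[1] + sample.int(rng[2] - rng[1] + 1L, n, replace = TRUE) - 1L
  frags <- list()
  signal_ids <- character(0)
  for (cat in spec$categories) {
    n_sig <- spec$signal_concepts_per_category
    n_bg <- spec$n_concepts_per_category - n_sig
    sizes_sig <- if (n_sig) draw_sizes(n_sig) else integer(0)
    sizes_bg <- if (n_bg) draw_sizes(n_bg) else integer(0)
    members <- c(if (n_sig) balanced_sets(module, sizes_sig),
                 if (n_bg) balanced_sets(genes, sizes_bg))
    ids <- sprintf("%s_C%03d", cat, seq_len(spec$n_concepts_per_category))
    concepts <- stats::setNames(lapply(seq_along(ids), function(i) {
      list(name = sprintf("synthetic concept %d of %s", i, cat), members = members[[i]])
    }), ids)
    if (n_sig) signal_ids <- c(signal_ids, ids[seq_len(n_sig)])
    frags[[cat]] <- structure(list(category = cat, concepts = concepts),
                              class = "corpus_fragment")
  }
  # guarantee full coverage: attach any never-sampled gene to a background
  # concept so background == universe
  corpus <- annotation_corpus(frags)
  missing <- setdiff(genes, corpus$background)
  if (length(missing)) {
    cat1 <- spec$categories[1]
    bg_ids <- setdiff(names(corpus$categories[[cat1]]), signal_ids)
    for (i in seq_along(missing)) {
      cid <- bg_ids[1 + (i - 1) %% length(bg_ids)]
      corpus$categories[[cat1]][[cid]]$members <-
        sort(c(corpus$categories[[cat1]][[cid]]$members, missing[i]))
    }
    corpus$background <- sort(unique(c(corpus$background, missing)))
  }
  attr(corpus, "module") <- module
  attr(corpus, "signal_concepts") <- signal_ids
  attr(corpus, "genes") <- genes
  corpus
}

#' Generate a synthetic interaction compendium with planted miRs
#'
#' Planted miRs draw `round(t * (s + (1 - s) * m/N))` of their `t` targets
#' from the module of size `m` in a universe of `N` genes (so signal
#' strength `s = 0` reproduces the decoy quota exactly and `s = 1` places
#' every target in the module); decoy miRs draw the baseline quota
#' `round(t * m/N)` from the module and the rest uniformly outside it.
#' Interactions are split across two predicted sources and one
#' experimental source to exercise provenance handling.
#'
#' @param spec a `fixture_spec`
#' @param corpus the corpus from [make_corpus()] (provides the module)
#' @return an `interaction_compendium` with attributes `planted_mirs` and
#'   `manifest` (data.frame of planted miR-gene pairs)
#' @export
make_compendium <- function(spec, corpus) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(corpus, "annotation_corpus"))
  seeds <- fixture_substreams(spec)
  set.seed(seeds[["compendium"]])
  genes <- attr(corpus, "genes") %||% corpus$background
  module <- attr(corpus, "module")
  nonmodule <- setdiff(genes, module)
  mirs <- sprintf("mir-%0*d", nchar(as.character(spec$n_mirs)), seq_len(spec$n_mirs))
  planted <- sort(sample(mirs, spec$planted_mir_count))
  t <- spec$targets_per_mir
  base_quota <- round(t * length(module) / length(genes))
  planted_quota <- round(t * (spec$signal_strength + (1 - spec$signal_strength) *
                                length(module) / length(genes)))
  pairs <- do.call(rbind, lapply(mirs, function(m) {
    quota <- if (m %in% planted) planted_quota else base_quota
    quota <- min(quota, length(module))
    tg <- c(sample(module, quota), sample(nonmodule, t - quota))
    data.frame(mir = m, gene = tg, stringsAsFactors = FALSE)
  }))
  # provenance: every pair is in predA and/or predB; ~10% also curated
  in_a <- stats::runif(nrow(pairs)) < 0.7
  in_b <- !in_a | stats::runif(nrow(pairs)) < 0.5
  in_cur <- stats::runif(nrow(pairs)) < 0.1
  comp <- union_compendium(list(
    interaction_source(pairs[in_a, ], "predA"),
    interaction_source(pairs[in_b, ], "predB"),
    interaction_source(pairs[in_cur, ], "curated", experimental = TRUE)
  ))
  manifest <- pairs[pairs$mir %in% planted, , drop = FALSE]
  manifest <- manifest[order(manifest$mir, manifest$gene), , drop = FALSE]
  rownames(manifest) <- NULL
  attr(comp, "planted_mirs") <- planted
  attr(comp, "manifest") <- manifest
  comp
}

#' Generate a synthetic expression table
#'
#' Signal genes get elevated expression level and fold change; everything
#' else sits at baseline. Gaussian noise with sd
#' `spec$expression_noise_sd` is added on the log2 scale of the fold
#' change and directly on the expression level.
#'
#' @param spec a `fixture_spec`
#' @param signal_genes character vector of elevated genes (typically the
#'   corpus module)
#' @param entities optional full id vector (defaults to the fixture genes)
#' @return expression table data.frame (id, expression_level, fold_change)
#' @export
make_expression <- function(spec, signal_genes, entities = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  seeds <- fixture_substreams(spec)
  set.seed(seeds[["expression"]])
  if (is.null(entities)) {
    entities <- sprintf("G%0*d", nchar(as.character(spec$n_genes)), seq_len(spec$n_genes))
  }
  is_sig <- entities %in% signal_genes
  sd <- spec$expression_noise_sd
  expr <- pmax(2 + 6 * is_sig + stats::rnorm(length(entities), 0, sd), 0)
  fc <- 2^(2 * is_sig + stats::rnorm(length(entities), 0, sd))
  data.frame(id = entities, expression_level = expr, fold_change = fc,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic protein-protein interaction graph
#'
#' Module genes are densely wired among themselves (edge probability 0.3);
#' the rest of the universe receives sparse random edges (about two per
#' gene), so the module is recoverable as a high-connectivity island.
#'
#' @param spec a `fixture_spec`
#' @param corpus the corpus from [make_corpus()]
#' @return two-column data.frame of undirected edges (from, to)
#' @export
make_ppi <- function(spec, corpus) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(corpus, "annotation_corpus"))
  seeds <- fixture_substreams(spec)
  set.seed(seeds[["ppi"]])
  genes <- attr(corpus, "genes") %||% corpus$background
  module <- attr(corpus, "module")
  mod_pairs <- t(utils::combn(module, 2))
  keep <- stats::runif(nrow(mod_pairs)) < 0.3
  bg_from <- sample(genes, 2 * length(genes), replace = TRUE)
  bg_to <- sample(genes, 2 * length(genes), replace = TRUE)
  edges <- rbind(
    data.frame(from = mod_pairs[keep, 1], to = mod_pairs[keep, 2], stringsAsFactors = FALSE),
    data.frame(from = bg_from, to = bg_to, stringsAsFactors = FALSE)
  )
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  key <- ifelse(edges$from < edges$to, paste(edges$from, edges$to),
                paste(edges$to, edges$from))
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Write a complete fixture bundle to disk
#'
#' Emits the same formats the readers consume: one GMT per category, one
#' TSV per interaction source, the unioned compendium TSV, the module as
#' a training gene list, an expression table, a PPI edge table and a JSON
#' manifest of the planted truth.
#'
#' @param spec a `fixture_spec`
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_fixture_bundle <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- make_corpus(spec)
  comp <- make_compendium(spec, corpus)
  expr <- make_expression(spec, attr(corpus, "module"))
  ppi <- make_ppi(spec, corpus)
  for (cat in names(corpus$categories)) {
    write_gmt(structure(list(category = cat, concepts = corpus$categories[[cat]]),
                        class = "corpus_fragment"),
              file.path(dir, paste0(cat, ".gmt")))
  }
  write_compendium(comp, file.path(dir, "compendium.tsv"))
  writeLines(attr(corpus, "module"), file.path(dir, "training_genes.txt"))
  writeLines(attr(corpus, "genes") %||% corpus$background, file.path(dir, "all_genes.txt"))
  utils::write.table(
    data.frame(id = expr$id, `Expression level` = expr$expression_level,
               `Fold change` = expr$fold_change, check.names = FALSE),
    file.path(dir, "expression.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ppi, file.path(dir, "ppi_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(spec = unclass(spec),
         module = attr(corpus, "module"),
         planted_mirs = attr(comp, "planted_mirs"),
         manifest = attr(comp, "manifest")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
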