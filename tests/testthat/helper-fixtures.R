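# Shared helpers: tiny in-code corpora/compendia and temp-file writers.

write_tmp <- function(lines, ext = ".txt", dir = NULL) {
  path <- tempfile(fileext = ext, tmpdir = dir %||% tempdir())
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# corpus with two categories over genes A..J; concept memberships chosen by
# hand so expected overlaps are easy to enumerate
toy_corpus <- function() {
  frag1 <- structure(list(category = "CatX", concepts = list(
    X1 = list(name = "x one", members = c("A", "B", "C")),
    X2 = list(name = "x two", members = c("C", "D", "E", "F")),
    X3 = list(name = "x three", members = c("G", "H"))
  )), class = "corpus_fragment")
  frag2 <- structure(list(category = "CatY", concepts = list(
    Y1 = list(name = "y one", members = c("A", "C", "E", "G", "I")),
    Y2 = list(name = "y two", members = c("B", "D", "F", "H", "J"))
  )), class = "corpus_fragment")
  annotation_corpus(list(frag1, frag2))
}

toy_compendium <- function() {
  union_compendium(list(
    interaction_source(data.frame(mir = c("mir-1", "mir-1", "mir-2"),
                                  gene = c("A", "C", "D")), "srcA"),
    interaction_source(data.frame(mir = c("mir-1", "mir-3"),
                                  gene = c("C", "J")), "srcB", experimental = TRUE)
  ))
}

# a gene score table with known final scores/ranks, bypassing the pipeline
toy_gene_table <- function(genes, finals) {
  fuse_and_rank(stats::setNames(finals, genes))
}

# default fixture trio under a given master seed
default_fixture <- function(seed = 1, ...) {
  spec <- fixture_spec(rng_seed = seed, ...)
  corpus <- make_corpus(spec)
  comp <- make_compendium(spec, corpus)
  list(spec = spec, corpus = corpus, comp = comp,
       module = attr(corpus, "module"),
       planted = attr(comp, "planted_mirs"),
       manifest = attr(comp, "manifest"))
}
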