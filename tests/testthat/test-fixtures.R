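test_that("corpus generation is deterministic, sized and fully covering", {
  spec <- fixture_spec(rng_seed = 4)
  c1 <- make_corpus(spec)
  c2 <- make_corpus(spec)
  expect_identical(c1, c2)
  expect_length(c1$background, spec$n_genes)
  expect_named(c1$categories, spec$categories)
  expect_true(all(lengths(c1$categories) == spec$n_concepts_per_category))
  # background equals the union of all members (corpus invariant)
  all_members <- unlist(lapply(c1$categories, function(co)
    lapply(co, `[[`, "members")), use.names = FALSE)
  expect_setequal(c1$background, unique(all_members))
  # signal concepts draw only module genes
  module <- attr(c1, "module")
  for (cid in attr(c1, "signal_concepts")) {
    cat <- sub("_C[0-9]+$", "", cid)
    expect_true(all(c1$categories[[cat]][[cid]]$members %in% module))
  }
  # byte-identical GMT output under a fixed seed
  d1 <- tempfile(); d2 <- tempfile()
  write_fixture_bundle(spec, d1)
  write_fixture_bundle(spec, d2)
  f <- "GO_BP.gmt"
  expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("fixed concept sizes are honored", {
  spec <- fixture_spec(concept_size_range = c(5, 5), module_size = 10,
                       n_genes = 50, n_concepts_per_category = 6,
                       signal_concepts_per_category = 2,
                       n_mirs = 5, targets_per_mir = 5, rng_seed = 2)
  cr <- make_corpus(spec)
  sizes <- unlist(lapply(cr$categories, function(co) lapply(co, function(x) length(x$members))))
  # all concepts exactly size 5, except background concepts that absorbed
  # never-sampled genes for full coverage
  expect_true(all(sizes >= 5))
  expect_gte(mean(sizes == 5), 0.5)
})

test_that("compendium planting follows the signal-strength quota", {
  spec1 <- fixture_spec(signal_strength = 1, rng_seed = 3)
  cr <- make_corpus(spec1)
  module <- attr(cr, "module")
  cp1 <- make_compendium(spec1, cr)
  planted <- attr(cp1, "planted_mirs")
  # signal 1: every planted target inside the module
  for (m in planted) expect_true(all(targets_of(cp1, m) %in% module))

  # signal 0: planted module quota equals the decoy quota exactly
  spec0 <- fixture_spec(signal_strength = 0, rng_seed = 3)
  cp0 <- make_compendium(spec0, make_corpus(spec0))
  quotas <- vapply(compendium_mirs(cp0), function(m)
    sum(targets_of(cp0, m) %in% module), integer(1))
  expect_true(all(quotas == round(spec0$targets_per_mir * spec0$module_size / spec0$n_genes)))

  # manifest pairs are contained in the compendium
  man <- attr(cp1, "manifest")
  key_all <- paste(cp1$interactions$mir, cp1$interactions$gene)
  expect_true(all(paste(man$mir, man$gene) %in% key_all))
  # every miR has the configured number of targets
  expect_true(all(vapply(compendium_mirs(cp1), function(m)
    length(targets_of(cp1, m)), integer(1)) == spec1$targets_per_mir))
})

test_that("expression generator separates signal from baseline", {
  spec <- fixture_spec(expression_noise_sd = 0, rng_seed = 5)
  cr <- make_corpus(spec)
  module <- attr(cr, "module")
  ex <- make_expression(spec, module)
  sig <- ex$id %in% module
  # exact two-level table at zero noise
  expect_length(unique(ex$expression_level[sig]), 1)
  expect_length(unique(ex$expression_level[!sig]), 1)
  expect_gt(mean(ex$expression_level[sig]), mean(ex$expression_level[!sig]))
  expect_gt(mean(log2(ex$fold_change[sig])), mean(log2(ex$fold_change[!sig])))
  expect_identical(ex, make_expression(spec, module))
})

test_that("ppi generator wires the module densely and round-trips via bundle", {
  spec <- fixture_spec(rng_seed = 6)
  cr <- make_corpus(spec)
  module <- attr(cr, "module")
  ppi <- make_ppi(spec, cr)
  in_mod <- ppi$from %in% module & ppi$to %in% module
  n_mod_possible <- choose(length(module), 2)
  n_out <- length(cr$background) - length(module)
  expect_gt(mean(in_mod) * nrow(ppi) / n_mod_possible,
            sum(!in_mod) / (choose(n_out, 2)))  # denser inside the module

  dir <- tempfile()
  write_fixture_bundle(spec, dir)
  # the written formats round-trip through the package readers
  corpus2 <- read_corpus_dir(dir)  # categories come back in file-name order
  expect_setequal(names(corpus2$categories), names(cr$categories))
  for (cat in names(cr$categories)) {
    expect_identical(names(corpus2$categories[[cat]]), names(cr$categories[[cat]]))
  }
  comp2 <- read_compendium(file.path(dir, "compendium.tsv"))
  expect_identical(comp2$interactions, make_compendium(spec, cr)$interactions)
  tl <- read_gene_list(file.path(dir, "training_genes.txt"))
  expect_identical(tl$genes, module)
  ex2 <- read_expression_table(file.path(dir, "expression.tsv"))
  expect_equal(nrow(ex2), spec$n_genes)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  expect_identical(man$planted_mirs, attr(make_compendium(spec, cr), "planted_mirs"))
})

test_that("gene degrees are balanced outside the signal concepts", {
  spec <- fixture_spec(rng_seed = 9)
  cr <- make_corpus(spec)
  module <- attr(cr, "module")
  sig_ids <- attr(cr, "signal_concepts")
  deg <- setNames(numeric(length(cr$background)), cr$background)
  for (cat in names(cr$categories)) {
    for (cid in names(cr$categories[[cat]])) {
      if (cid %in% sig_ids) next
      m <- cr$categories[[cat]][[cid]]$members
      deg[m] <- deg[m] + 1
    }
  }
  # permutation-chop assignment keeps background degrees within +-2 of the
  # mean apart from the few coverage-fix insertions
  expect_lte(stats::sd(deg), 1.5)
})
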