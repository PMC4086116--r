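test_that("ROC endpoints, symmetry and uniform-rank behavior", {
  r1 <- roc_from_ranks(rep(1L, 30), 20)
  expect_equal(r1$auc, 1.0)
  expect_equal(roc_from_ranks(rep(20L, 30), 20)$auc, 0.0)
  # reversal symmetry on arbitrary rank vectors
  set.seed(4)
  for (i in 1:20) {
    L <- sample(5:50, 1)
    ranks <- sample(L, sample(1:40, 1), replace = TRUE)
    expect_equal(roc_from_ranks(ranks, L)$auc +
                   roc_from_ranks(L + 1L - ranks, L)$auc, 1.0, tolerance = 1e-12)
  }
  # curve anchors: cutoff 1 has fpr 0; cutoff L has fpr 1 and sensitivity 1
  cv <- r1$curve
  expect_equal(cv$fpr[1], 0)
  expect_equal(cv$fpr[nrow(cv)], 1)
  expect_equal(cv$sensitivity[nrow(cv)], 1)
  expect_error(roc_from_ranks(c(1, 25), 20), "ranks must lie")
  expect_error(roc_from_ranks(integer(0), 20), "no ranks")
})

test_that("spike harness is seed-deterministic and guards its pools", {
  fx <- default_fixture(2)
  pm <- fx$planted[1]
  pg <- intersect(fx$manifest$gene[fx$manifest$mir == pm], fx$module)[1]
  pool_m <- setdiff(compendium_mirs(fx$comp), pm)
  a <- spike_validation(fx$corpus, fx$comp, pm, pg, pool_m, fx$corpus$background,
                        n_runs = 5, seed = 99)
  b <- spike_validation(fx$corpus, fx$comp, pm, pg, pool_m, fx$corpus$background,
                        n_runs = 5, seed = 99)
  expect_identical(a$mir_roc$ranks, b$mir_roc$ranks)
  expect_identical(a$gene_roc$ranks, b$gene_roc$ranks)
  c <- spike_validation(fx$corpus, fx$comp, pm, pg, pool_m, fx$corpus$background,
                        n_runs = 5, seed = 100)
  expect_false(identical(a$mir_roc$ranks, c$mir_roc$ranks) &&
                 identical(a$gene_roc$ranks, c$gene_roc$ranks))

  expect_error(spike_validation(fx$corpus, fx$comp, pm, pg, pool_m[1:10],
                                fx$corpus$background, n_runs = 2),
               "decoy miR pool")
  expect_error(spike_validation(fx$corpus, fx$comp, pm, pg, pool_m,
                                fx$corpus$background[1:50], n_runs = 2),
               "decoy gene pool")
})

test_that("a dominant planted miR ranks first in every spike run", {
  # planted-dominance limit: the planted miR targets every gene in the
  # universe, decoys target genes outside it (so they never score)
  fx <- default_fixture(10, n_mirs = 8)
  genes <- fx$corpus$background
  pairs <- rbind(
    data.frame(mir = "mir-p", gene = genes),
    do.call(rbind, lapply(1:6, function(i)
      data.frame(mir = paste0("mir-d", i), gene = paste0("ZZ", 1:5))))
  )
  comp <- union_compendium(list(interaction_source(pairs, "s")))
  res <- spike_validation(fx$corpus, comp, "mir-p", genes[1],
                          decoy_mir_pool = paste0("mir-d", 1:6),
                          decoy_gene_pool = genes,
                          n_decoy_mirs = 4, n_decoy_genes = 20,
                          n_runs = 8, seed = 3)
  expect_true(all(res$mir_roc$ranks == 1))
  expect_equal(res$mir_roc$auc, 1.0)
})

test_that("leave-one-out harness mirrors the held-out design and its error paths", {
  fx <- default_fixture(6)
  pm <- fx$planted[1]
  targets <- targets_of(fx$comp, pm)
  lo <- loocv_validation(fx$corpus, fx$comp, pm, targets[1:6],
                         decoy_gene_pool = fx$corpus$background,
                         decoy_mir_pool = setdiff(compendium_mirs(fx$comp), pm),
                         n_decoy_genes = 60, n_decoy_mirs = 19, seed = 21)
  expect_equal(lo$n_experiments, 6)
  expect_length(lo$mir_roc$ranks, 6)
  expect_length(lo$gene_roc$ranks, 6)
  expect_gte(lo$frac_top20, lo$frac_top10)
  expect_error(loocv_validation(fx$corpus, fx$comp, pm, targets[1],
                                fx$corpus$background,
                                setdiff(compendium_mirs(fx$comp), pm)),
               "at least two")
})

test_that("ablation reruns are seed-aligned and reject unknown categories", {
  fx <- default_fixture(8)
  pm <- fx$planted[1]
  pg <- intersect(fx$manifest$gene[fx$manifest$mir == pm], fx$module)[1]
  cats <- names(fx$corpus$categories)
  res <- suppressWarnings(ablation_validation(
    list(all = cats, first = cats[1]),
    corpus = fx$corpus, compendium = fx$comp,
    target_mir = pm, target_gene = pg,
    decoy_mir_pool = setdiff(compendium_mirs(fx$comp), pm),
    decoy_gene_pool = fx$corpus$background,
    n_runs = 5, seed = 31))
  expect_named(res, c("all", "first"))
  # identical master seed -> identical per-run decoy draws
  expect_identical(res$all$run_seeds, res$first$run_seeds)
  expect_error(ablation_validation(list(), corpus = fx$corpus), "no category")
  expect_error(ablation_validation(list(bad = "NotACategory"),
                                   corpus = fx$corpus, compendium = fx$comp,
                                   target_mir = pm, target_gene = pg,
                                   decoy_mir_pool = setdiff(compendium_mirs(fx$comp), pm),
                                   decoy_gene_pool = fx$corpus$background,
                                   n_runs = 1, seed = 1),
               "unknown categories")
})

test_that("planted signal is recovered: planted ranks beat decoy expectation", {
  fx <- default_fixture(12)
  pm <- fx$planted[1]
  pg <- intersect(fx$manifest$gene[fx$manifest$mir == pm], fx$module)[1]
  res <- spike_validation(fx$corpus, fx$comp, pm, pg,
                          setdiff(compendium_mirs(fx$comp), pm),
                          fx$corpus$background, n_runs = 30, seed = 55)
  # planted median rank strictly better than the uniform-decoy median (10.5)
  expect_lt(median(res$mir_roc$ranks), 10.5)
  expect_lt(wilcox.test(res$mir_roc$ranks, mu = 10.5, alternative = "less",
                        exact = FALSE)$p.value, 0.001)
})

test_that("validation reports serialize ranks, curve and summary", {
  fx <- default_fixture(2)
  pm <- fx$planted[1]
  pg <- fx$manifest$gene[fx$manifest$mir == pm][1]
  res <- spike_validation(fx$corpus, fx$comp, pm, pg,
                          setdiff(compendium_mirs(fx$comp), pm),
                          fx$corpus$background, n_runs = 3, seed = 5)
  prefix <- file.path(tempdir(), "valreport")
  paths <- write_validation_report(res, prefix)
  expect_true(all(file.exists(paths)))
  summ <- jsonlite::read_json(paths[3])
  expect_equal(summ$mir_auc, res$mir_roc$auc)
  ranks <- read.delim(paths[1])
  expect_equal(ranks$mir_rank, res$mir_roc$ranks)
})
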