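# Dense reference implementation of the propagation operator, coded
# independently of the package internals: builds the full gene x gene
# linear map and iterates the same normalized affine recursion.
propagate_oracle <- function(cat_scores, records, damping = 0.85,
                             tol = 1e-9, max_iter = 5000) {
  genes <- rownames(cat_scores)
  cats <- intersect(colnames(cat_scores), unique(records$category))
  cats <- cats[colSums(cat_scores[, cats, drop = FALSE]) > 0]
  S <- sweep(cat_scores[, cats, drop = FALSE], 2,
             colSums(cat_scores[, cats, drop = FALSE]), "/")
  if (length(cats) == 1L) return(S[, 1] / sum(S[, 1]))
  M <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  for (cat in cats) {
    rc <- records[records$category == cat, , drop = FALSE]
    w <- (1 / rc$p_raw) / sum(1 / rc$p_raw)
    for (j in seq_len(nrow(rc))) {
      hit <- intersect(rc$members_hit[[j]], genes)
      if (!length(hit)) next
      M[hit, hit] <- M[hit, hit] + w[j] / (length(cats) * length(hit))
    }
  }
  init <- rowMeans(S)
  s <- init / sum(init)
  for (i in seq_len(max_iter)) {
    s_new <- damping * as.vector(M %*% s) + (1 - damping) * init
    s_new <- s_new / sum(s_new)
    if (max(abs(s_new - s)) < tol) return(s_new)
    s <- s_new
  }
  s
}

test_that("category scores are reciprocal-p sums over participating concepts", {
  corpus <- toy_corpus()
  enr <- enrich(c("A", "B", "C", "D"), corpus)
  cs <- category_scores(enr, c("A", "B", "C", "D"))
  # every concept participates under the default rule; check A by hand:
  # CatX concepts containing A among hits: X1 only
  px1 <- enr$p_raw[enr$concept_id == "X1"]
  expect_equal(unname(cs["A", "CatX"]), 1 / px1)
  # symmetry: genes with identical concept memberships score identically
  expect_equal(cs["A", ], cs["B", ])  # A and B both only in X1 / Y1 vs Y2?
  # gated filter: a gene hitting no passing concept scores zero
  cs_gated <- category_scores(enr, c("A", "B", "C", "D"),
                              sig_filter = "nominal", sig_level = 1e-9)
  expect_true(all(cs_gated == 0))
})

test_that("propagation fixed point matches the dense oracle on toy graphs", {
  corpus <- toy_corpus()
  genes <- c("A", "B", "C", "D", "E")
  enr <- enrich(genes, corpus)
  cs <- category_scores(enr, genes)
  s <- propagate(cs, damping = 0.85, tol = 1e-12)
  expect_true(attr(s, "converged"))
  expect_equal(sum(s), 1, tolerance = 1e-12)
  o <- propagate_oracle(cs, attr(cs, "records"), damping = 0.85, tol = 1e-12)
  expect_equal(unname(s), unname(o[names(s)]), tolerance = 1e-9, ignore_attr = TRUE)

  # randomized corpora: oracle equivalence and mass conservation
  set.seed(7)
  for (rep in 1:5) {
    spec <- fixture_spec(n_genes = 40, module_size = 10,
                         concept_size_range = c(3, 8),
                         n_concepts_per_category = 8,
                         signal_concepts_per_category = 3,
                         n_mirs = 5, targets_per_mir = 8, rng_seed = rep)
    cr <- make_corpus(spec)
    q <- sample(cr$background, 20)
    en <- suppressWarnings(enrich(q, cr))
    cm <- category_scores(en, intersect(q, cr$background))
    s2 <- propagate(cm, tol = 1e-12, trace = TRUE)
    expect_true(attr(s2, "converged"))
    expect_equal(unname(attr(s2, "mass")), rep(1, length(attr(s2, "mass"))),
                 tolerance = 1e-12)
    o2 <- propagate_oracle(cm, attr(cm, "records"), tol = 1e-12)
    expect_equal(unname(s2), unname(o2[names(s2)]), tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("propagation degenerate cases: single category and uniform annotations", {
  corpus <- toy_corpus()
  enr <- enrich(c("A", "B", "C"), restrict_categories(corpus, "CatX"))
  cs <- category_scores(enr, c("A", "B", "C"))
  s <- propagate(cs)
  expect_equal(attr(s, "iterations"), 1L)
  expect_equal(unname(s), unname(cs[, 1] / sum(cs[, 1])), ignore_attr = TRUE)

  # all genes identically annotated -> uniform scores
  frag <- structure(list(category = "C1", concepts = list(
    K1 = list(name = "k", members = c("A", "B", "C")),
    K2 = list(name = "k2", members = c("A", "B", "C", "D"))
  )), class = "corpus_fragment")
  frag2 <- structure(list(category = "C2", concepts = list(
    L1 = list(name = "l", members = c("A", "B", "C", "D"))
  )), class = "corpus_fragment")
  cr <- annotation_corpus(list(frag, frag2))
  en <- enrich(c("A", "B", "C"), cr)
  cm <- category_scores(en, c("A", "B", "C"))
  su <- propagate(cm)
  expect_equal(unname(su), rep(1 / 3, 3), tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(propagate(cm, records = cm_records <- attr(cm, "records")[0, ]),
               "no participating concepts")
})

test_that("HITS with priors: teleport limit, standard-HITS limit, oracle fixed point", {
  set.seed(5)
  edges <- data.frame(from = c("A", "A", "B", "C", "D"),
                      to = c("B", "C", "C", "D", "E"))
  root <- c("A", "B")

  # beta = 1: scores equal the prior exactly
  s1 <- hits_with_priors(edges, root, beta = 1)
  expect_equal(unname(s1[c("A", "B")]), c(0.5, 0.5))
  expect_equal(unname(s1[c("C", "D", "E")]), c(0, 0, 0))

  # beta = 0 reduces to standard HITS (igraph as independent reference)
  s0 <- hits_with_priors(edges, root, beta = 0, tol = 1e-14)
  g <- igraph::simplify(igraph::graph_from_data_frame(edges, directed = FALSE))
  ref <- igraph::hits_scores(g)$authority
  ref <- ref[names(s0)] / sum(ref)
  expect_equal(unname(s0), unname(ref), tolerance = 1e-6, ignore_attr = TRUE)

  # beta = 0.3: independently coded power iteration, random graphs 5-50 nodes
  hits_oracle <- function(edges, root, beta, iters = 20000) {
    nodes <- sort(unique(c(edges[[1]], edges[[2]])))
    A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    for (r in seq_len(nrow(edges))) {
      A[edges[r, 1], edges[r, 2]] <- 1
      A[edges[r, 2], edges[r, 1]] <- 1
    }
    prior <- setNames(ifelse(nodes %in% root, 1 / sum(nodes %in% root), 0), nodes)
    a <- h <- prior
    for (i in seq_len(iters)) {
      x <- as.vector(A %*% h); a <- (1 - beta) * x / sum(x) + beta * prior
      y <- as.vector(A %*% a); h <- (1 - beta) * y / sum(y) + beta * prior
    }
    setNames(a, nodes)
  }
  for (n in c(5, 20, 50)) {
    repeat {
      em <- cbind(sample(n, 3 * n, replace = TRUE), sample(n, 3 * n, replace = TRUE))
      em <- em[em[, 1] != em[, 2], , drop = FALSE]
      g <- igraph::graph_from_edgelist(em, directed = FALSE)
      if (igraph::is_connected(igraph::simplify(g)) && igraph::vcount(g) == n) break
    }
    ed <- data.frame(from = paste0("N", em[, 1]), to = paste0("N", em[, 2]))
    rt <- paste0("N", sample(n, max(2, n %/% 5)))
    got <- hits_with_priors(ed, rt, beta = 0.3, tol = 1e-14)
    want <- hits_oracle(ed, rt, beta = 0.3, iters = 3000)
    expect_equal(unname(got), unname(want[names(got)]), tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(sum(got), 1, tolerance = 1e-12)
    expect_true(all(got >= 0))
  }

  expect_error(hits_with_priors(edges, "ZZZ"), "root set")
})

test_that("HITS scores are invariant under node relabeling", {
  set.seed(9)
  edges <- data.frame(from = c("A", "B", "C", "C"), to = c("B", "C", "D", "A"))
  s <- hits_with_priors(edges, c("A", "D"), beta = 0.4, tol = 1e-13)
  relabel <- c(A = "W", B = "X", C = "Y", D = "Z")
  edges2 <- data.frame(from = unname(relabel[edges$from]),
                       to = unname(relabel[edges$to]))
  s2 <- hits_with_priors(edges2, c("W", "Z"), beta = 0.4, tol = 1e-13)
  expect_equal(unname(s[c("A", "B", "C", "D")]),
               unname(s2[c("W", "X", "Y", "Z")]), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("fusion and ranking: identity without interactome, weights, tiebreaks", {
  combined <- c(G1 = 1, G2 = 0)
  inter <- c(G1 = 0, G2 = 1)
  t_none <- fuse_and_rank(combined)
  expect_identical(t_none$gene[t_none$rank == 1], "G1")
  expect_true(all(is.na(t_none$interactome)))

  t_w1 <- fuse_and_rank(combined, inter, weight = 1)
  expect_identical(t_w1$gene, c("G1", "G2"))  # interactome ignored

  # perfect tie at weight 0.5 -> broken by gene id
  t_tie <- fuse_and_rank(combined, inter, weight = 0.5)
  expect_equal(t_tie$final, c(0.5, 0.5))
  expect_identical(t_tie$gene, c("G1", "G2"))
})

test_that("monotonicity: an extra concept containing a gene never lowers its score", {
  corpus <- toy_corpus()
  genes <- c("A", "B", "C", "D")
  enr <- enrich(genes, corpus)
  cs_before <- category_scores(enr, genes)
  # add a concept containing A to CatX and recompute
  corpus2 <- corpus
  corpus2$categories$CatX$X9 <- list(name = "extra", members = c("A", "D"))
  enr2 <- enrich(genes, corpus2)
  cs_after <- category_scores(enr2, genes)
  expect_gte(cs_after["A", "CatX"], cs_before["A", "CatX"])
})

test_that("rank_genes runs end to end and fuses interactome when training is given", {
  fx <- default_fixture(3)
  set.seed(1)
  test <- sample(fx$corpus$background, 50)
  gt <- rank_genes(test, fx$corpus)
  expect_s3_class(gt, "gene_score_table")
  expect_setequal(gt$gene, test)
  expect_identical(sort(gt$rank), 1:50)
  expect_true(attr(gt, "converged"))
  expect_true(all(is.na(gt$interactome)))

  ppi <- make_ppi(fx$spec, fx$corpus)
  gt2 <- rank_genes(test, fx$corpus, training = fx$module, ppi_edges = ppi)
  expect_false(all(is.na(gt2$interactome)))
  expect_true(all(gt2$final >= 0))
})
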