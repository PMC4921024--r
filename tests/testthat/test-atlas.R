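test_that("full-gene flagging requires bidirectional coverage above the cutoff", {
  genes <- make_genes(c("g1", "g2"), c(105, 400))
  cdds <- make_cdds(c("cddA", "cddB"), c(100, 300))
  hits <- dplyr::bind_rows(
    make_hit("g1", "cddA", 1, 100, 1, 100),     # 1.00 model, 0.952 gene
    make_hit("g2", "cddB", 1, 300, 1, 300)      # 1.00 model, 0.75 gene
  )
  out <- mark_full_gene_cdds(hits, genes, cdds)
  expect_true(out$is_full_gene[out$cdd_id == "cddA"])
  expect_false(out$is_full_gene[out$cdd_id == "cddB"])  # gene side too low

  # empty hit list yields no full-gene models
  none <- mark_full_gene_cdds(hits[0, ], genes, cdds)
  expect_false(any(none$is_full_gene))
})

test_that("full-gene flags match a brute-force per-hit scan and are monotone", {
  set.seed(11)
  genes <- make_genes(sprintf("g%02d", 1:20), sample(150:900, 20))
  cdds <- make_cdds(sprintf("c%02d", 1:15), sample(80:400, 15))
  hits <- purrr::map(1:20, function(i) {
    gl <- genes$length[i]
    h <- random_gene_hits(10, gl, cdds$cdd_id, gene_id = genes$gene_id[i])
    # clamp model coordinates to model length
    ml <- cdds$model_length[match(h$cdd_id, cdds$cdd_id)]
    h$cdd_end <- pmin(h$cdd_end, ml)
    h
  }) |> dplyr::bind_rows()

  t <- fusion_thresholds()
  flagged <- mark_full_gene_cdds(hits, genes, cdds, t)
  oracle <- oracle_full_gene(hits, genes, cdds, t$full_gene_coverage)
  expect_equal(stats::setNames(flagged$is_full_gene, flagged$cdd_id), oracle)

  # lowering the coverage threshold never unsets a flag
  looser <- mark_full_gene_cdds(hits, genes, cdds,
                                fusion_thresholds(full_gene_coverage = 0.7))
  expect_true(all(looser$is_full_gene[flagged$is_full_gene]))
})

test_that("model consolidation groups identical footprints and isolates strangers", {
  genes <- make_genes(sprintf("g%d", 1:5), rep(500, 5))
  cdds <- make_cdds(c("a", "b", "x", "y", "z"), c(210, 210, 110, 130, 90))
  hits <- dplyr::bind_rows(
    purrr::map(1:5, function(i) dplyr::bind_rows(
      make_hit(sprintf("g%d", i), "a", 50, 250),
      make_hit(sprintf("g%d", i), "b", 50, 250)
    )),
    make_hit("g1", "x", 300, 400),
    make_hit("g2", "y", 300, 420)
  )
  sets <- build_cdd_sets(hits, cdds)
  # partition property: every catalogue model exactly once
  expect_setequal(sets$cdd_id, cdds$cdd_id)
  expect_equal(anyDuplicated(sets$cdd_id), 0L)
  set_of <- stats::setNames(sets$set_id, sets$cdd_id)
  expect_equal(set_of[["a"]], set_of[["b"]])
  expect_equal(length(unique(set_of[c("x", "y", "z")])), 3)
  # mean set size times set count equals catalogue size
  acc <- catalogue_accounting(nrow(cdds), 0, dplyr::n_distinct(sets$set_id))
  expect_equal(acc$mean_set_size * acc$n_sets, nrow(cdds))
})

test_that("consolidation equals brute-force all-pairs similarity plus closure", {
  set.seed(23)
  n_cdd <- 50
  cdd_ids <- sprintf("c%02d", 1:n_cdd)
  genes <- make_genes(sprintf("g%02d", 1:30), rep(600, 30))
  cdds <- make_cdds(cdd_ids, sample(80:300, n_cdd, replace = TRUE))
  # half the models are planted as footprint clones of a partner
  rows <- list()
  for (g in genes$gene_id) {
    k <- sample(2:5, 1)
    picked <- sample(cdd_ids, k)
    for (cdd in picked) {
      s <- sample(1:400, 1); e <- s + sample(60:180, 1)
      rows[[length(rows) + 1]] <- make_hit(g, cdd, s, min(e, 600))
      if (runif(1) < 0.5) {
        clone <- sample(cdd_ids, 1)
        rows[[length(rows) + 1]] <- make_hit(g, clone, s, min(e, 600))
      }
    }
  }
  hits <- dplyr::bind_rows(rows)
  sets <- build_cdd_sets(hits, cdds, similarity_min = 0.5)

  sim <- matrix(0, n_cdd, n_cdd, dimnames = list(cdd_ids, cdd_ids))
  for (i in 1:(n_cdd - 1)) for (j in (i + 1):n_cdd) {
    sim[i, j] <- sim[j, i] <-
      oracle_cdd_similarity(hits, cdd_ids[i], cdd_ids[j])
  }
  comp <- oracle_components(sim, 0.5)
  set_of <- stats::setNames(sets$set_id, sets$cdd_id)[cdd_ids]
  # identical partitions: same co-membership for every pair
  for (i in 1:(n_cdd - 1)) for (j in (i + 1):n_cdd) {
    expect_equal(unname(set_of[i] == set_of[j]), comp[i] == comp[j])
  }
})

test_that("co-occurrence counts match brute-force enumeration over genes", {
  # a model alone on its genes co-occurs with nothing
  genes <- make_genes(c("g1", "g2", "g3"), rep(500, 3))
  cdds <- make_cdds(c("a", "b", "c"), c(100, 120, 140))
  hits <- dplyr::bind_rows(
    make_hit("g1", "a", 1, 100),
    make_hit("g2", "a", 1, 100),
    make_hit("g3", "b", 1, 120),
    make_hit("g3", "c", 200, 340)
  )
  sets <- build_cdd_sets(hits, cdds)
  idx <- build_cooccurrence_index(hits, sets)
  counts <- stats::setNames(idx$set_counts$n_cooccurring_sets,
                            idx$set_counts$cdd_id)
  expect_equal(unname(counts[["a"]]), 0L)
  expect_gte(counts[["b"]], 1L)
  expect_gte(counts[["c"]], 1L)

  # random dataset agrees with the oracle for every model
  set.seed(31)
  genes <- make_genes(sprintf("g%02d", 1:20), rep(800, 20))
  cdds <- make_cdds(sprintf("c%02d", 1:12), sample(60:200, 12))
  hits <- purrr::map(genes$gene_id, function(g) {
    random_gene_hits(sample(2:6, 1), 800, cdds$cdd_id, gene_id = g)
  }) |> dplyr::bind_rows()
  ml <- cdds$model_length[match(hits$cdd_id, cdds$cdd_id)]
  hits$cdd_end <- pmin(hits$cdd_end, ml)
  sets <- build_cdd_sets(hits, cdds)
  idx <- build_cooccurrence_index(hits, sets)
  for (cdd in cdds$cdd_id) {
    expect_equal(fusionscan:::cooccurrence_of(idx, cdd),
                 oracle_cooccurrence(hits, sets, cdd))
  }
})
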