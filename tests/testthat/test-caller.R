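default_t <- fusion_thresholds()

test_that("naive multi-domain detection matches a brute-force pair scan", {
  h_yes <- dplyr::bind_rows(make_hit("g", "a", 10, 190),
                            make_hit("g", "b", 350, 650))
  expect_true(naive_multidomain(h_yes))
  expect_false(naive_multidomain(make_hit("g", "a", 10, 190)))
  h_no <- dplyr::bind_rows(make_hit("g", "a", 10, 190),
                           make_hit("g", "b", 150, 400))
  expect_false(naive_multidomain(h_no))

  set.seed(41)
  for (rep in 1:30) {
    h <- random_gene_hits(12, 700, letters[1:6])
    brute <- FALSE
    for (i in 1:11) for (j in (i + 1):12) {
      lo <- which.min(c(h$gene_end[i], h$gene_end[j]))
      pair <- c(i, j)
      if (h$gene_start[pair[-lo]] > h$gene_end[pair[lo]]) brute <- TRUE
    }
    expect_equal(naive_multidomain(h), brute)
  }
})

test_that("partition selection keeps full-gene models above the coverage floor", {
  genes <- make_genes(c("gf", "p1", "p2"), c(700, 205, 310))
  cdds <- make_cdds(c("cddA", "cddB"), c(200, 300))
  parents <- dplyr::bind_rows(
    make_hit("p1", "cddA", 3, 202, 1, 200),
    make_hit("p2", "cddB", 6, 305, 1, 300)
  )
  own <- dplyr::bind_rows(
    make_hit("gf", "cddA", 10, 190, 1, 190),   # 95% of model
    make_hit("gf", "cddB", 350, 650, 1, 295)   # 98% of model
  )
  flagged <- mark_full_gene_cdds(dplyr::bind_rows(parents, own),
                                 genes, cdds, default_t)
  cand <- select_partition(genes[1, ], own, flagged, default_t)
  expect_s3_class(cand, "fusion_candidate")
  expect_equal(cand$selected$cdd_id, c("cddA", "cddB"))
  expect_equal(cand$gaps$start, 191L)
  expect_equal(cand$gaps$end, 349L)

  # dropping model coverage below half disqualifies the alignment
  own2 <- own
  own2$cdd_end[2] <- 140L   # 140/300 = 47% < 50%
  expect_null(select_partition(genes[1, ], own2, flagged, default_t))
})

test_that("partition cardinality equals the exhaustive maximum on random genes", {
  set.seed(53)
  cdds <- make_cdds(sprintf("c%02d", 1:8), rep(100, 8))
  cdds$is_full_gene <- TRUE
  gene <- make_genes("g", 900)
  for (rep in 1:25) {
    n <- sample(5:15, 1)
    h <- random_gene_hits(n, 900, cdds$cdd_id)
    h$cdd_end <- pmin(h$cdd_end, 100L)
    # keep everything eligible: full model coverage
    h$cdd_start <- 1L; h$cdd_end <- 100L
    cand <- select_partition(gene, h, cdds, default_t)
    got <- if (is.null(cand)) 0L else nrow(cand$selected)
    oracle <- oracle_max_disjoint(h$gene_start, h$gene_end)
    expect_equal(got, if (oracle >= 2) oracle else 0L)
    if (!is.null(cand)) {
      expect_true(all(diff(cand$selected$gene_start) > 0))
      expect_true(all(cand$selected$gene_start[-1] >
                        cand$selected$gene_end[-nrow(cand$selected)]))
    }
  }
})

test_that("criteria arithmetic matches the worked two-domain example", {
  d <- toy_dataset()
  atlas <- build_domain_atlas(d$genes, d$hits, d$cdds)
  gene <- d$genes[d$genes$gene_id == "g1", ]
  gh <- atlas$hits[atlas$hits$gene_id == "g1", ]
  cand <- select_partition(gene, gh, atlas$cdds, default_t)
  crit <- apply_criteria(cand, gene, gh, atlas$sets, atlas$cooccurrence,
                         default_t)
  expect_true(crit$pass_length)            # 700 > 600
  expect_equal(crit$combined_coverage, (181 + 300) / 700)
  expect_true(crit$pass_coverage)          # 68.7% >= 40%
  expect_equal(crit$gap_margin, (191 + 350) / 2)  # midpoint 270.5
  expect_true(crit$pass_gap_position)      # 270.5 >= 60 and >= 70
  expect_equal(crit$n_cdd_sets, 2L)
  expect_equal(crit$crossing_fraction, 0)
  expect_true(crit$verdict)

  # a protein of exactly the length floor fails: "must exceed"
  gene600 <- dplyr::mutate(gene, length = 600L)
  crit600 <- apply_criteria(cand, gene600, gh, atlas$sets,
                            atlas$cooccurrence, default_t)
  expect_false(crit600$pass_length)
  expect_false(crit600$verdict)
})

test_that("candidates whose models share one consolidated set are rejected", {
  genes <- make_genes(c("gf", "p1", "p2", "s1", "s2", "s3"),
                      c(700, 205, 205, 500, 500, 500))
  cdds <- make_cdds(c("twinA", "twinB"), c(200, 200))
  hits <- dplyr::bind_rows(
    make_hit("p1", "twinA", 3, 202, 1, 200),
    make_hit("p2", "twinB", 3, 202, 1, 200),
    # identical footprints on shared genes consolidate the twins
    make_hit("s1", "twinA", 100, 299, 1, 200),
    make_hit("s1", "twinB", 100, 299, 1, 200),
    make_hit("s2", "twinA", 150, 349, 1, 200),
    make_hit("s2", "twinB", 150, 349, 1, 200),
    make_hit("s3", "twinA", 120, 319, 1, 200),
    make_hit("s3", "twinB", 120, 319, 1, 200),
    # the candidate gene: twins at disjoint positions
    make_hit("gf", "twinA", 10, 209, 1, 200),
    make_hit("gf", "twinB", 350, 549, 1, 200)
  )
  calls <- call_fusions(genes, hits, cdds)
  row <- as_tibble(calls)[as_tibble(calls)$gene_id == "gf", ]
  expect_equal(row$stage_reached, "full_gene_candidate")
  expect_false(row$pass_distinct_sets)
})

test_that("the workflow is deterministic and stage counts are monotone", {
  co <- simulate_fusion_cohort(sim_config(genes_per_genome = 150, seed = 9))
  c1 <- call_fusions(co$genes, co$hits, co$cdds)
  c2 <- call_fusions(co$genes, co$hits, co$cdds)
  expect_identical(as.data.frame(c1), as.data.frame(c2))

  g <- glance(c1)
  expect_gte(g$n_naive, g$n_candidate)
  expect_gte(g$n_candidate, g$n_final)
  # every final fusion is also a naive multi-domain gene by construction
  expect_true(all(final_fusion_genes(c1) %in% c1$gene_id))
})

test_that("Rosetta-stone conditions are checked per selected domain", {
  d <- toy_dataset()
  atlas <- build_domain_atlas(d$genes, d$hits, d$cdds)
  gene <- d$genes[d$genes$gene_id == "g1", ]
  gh <- atlas$hits[atlas$hits$gene_id == "g1", ]
  cand <- select_partition(gene, gh, atlas$cdds, default_t)
  rs <- rosetta_stone_check(cand, atlas$hits, atlas$cdds, default_t)
  expect_equal(rs$cdd_id, c("cddA", "cddB"))
  # both models align alone to separate single-domain genes (g4, g5)
  expect_true(all(rs$standalone_elsewhere))
  expect_true(all(rs$identity_gt50))
  expect_true(all(rs$rosetta))

  # a model never occurring outside multi-domain genes fails condition (iii)
  no_parent <- atlas$hits[atlas$hits$gene_id != "g5", ]
  rs2 <- rosetta_stone_check(cand, no_parent, atlas$cdds, default_t)
  expect_false(rs2$standalone_elsewhere[rs2$cdd_id == "cddB"])

  # absent identity makes the check not evaluable, not false
  gh_na <- dplyr::mutate(gh, pct_identity = NA_real_)
  cand_na <- select_partition(gene, gh_na, atlas$cdds, default_t)
  rs3 <- rosetta_stone_check(cand_na, atlas$hits, atlas$cdds, default_t)
  expect_true(all(is.na(rs3$identity_gt50)))
  expect_true(all(is.na(rs3$rosetta)))
})
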