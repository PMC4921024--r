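toy_calls_final <- function(ids, genome = "gA", cdd_ids = NA_character_) {
  tibble::tibble(gene_id = ids, genome_id = genome,
                 stage_reached = "final_fusion", cdd_ids = cdd_ids)
}

test_that("adjacent-reaction detection finds the shared histidine intermediate", {
  rmap <- read_reaction_map(toy_path("toy_reaction_map.tsv"))
  genes <- make_genes("g1", 700, roles = list(
    c("Phosphoribosyl-ATP pyrophosphatase",
      "Phosphoribosyl-AMP cyclohydrolase")))
  calls <- toy_calls_final("g1")
  adj <- adjacent_reaction_fusions(calls, genes, rmap)
  expect_equal(nrow(adj), 1)
  expect_equal(adj$role_from, "Phosphoribosyl-ATP pyrophosphatase")
  expect_equal(adj$role_to, "Phosphoribosyl-AMP cyclohydrolase")
  expect_equal(adj$metabolites, "Phosphoribosyl-AMP")

  # fused roles with disjoint metabolite sets produce nothing
  genes2 <- make_genes("g2", 700, roles = list(
    c("Phosphoribosyl-ATP pyrophosphatase", "Cyclohexadienyl dehydratase")))
  adj2 <- adjacent_reaction_fusions(toy_calls_final("g2"), genes2, rmap)
  expect_equal(nrow(adj2), 0)

  # unknown roles are skipped with a count, not an error
  genes3 <- make_genes("g3", 700, roles = list(
    c("Phosphoribosyl-ATP pyrophosphatase", "unmapped role")))
  expect_message(
    adj3 <- adjacent_reaction_fusions(toy_calls_final("g3"), genes3, rmap),
    "absent from the reaction map")
  expect_equal(attr(adj3, "n_skipped_roles"), 1L)
})

test_that("adjacency matches brute-force product-substrate intersection", {
  set.seed(103)
  roles <- sprintf("role%02d", 1:8)
  mets <- sprintf("met%02d", 1:12)
  rr <- tibble::tibble(role = roles, reaction_id = sprintf("rxn%02d", 1:8))
  rp <- purrr::map(rr$reaction_id, function(r) {
    tibble::tibble(reaction_id = r,
                   metabolite = sample(mets, 4),
                   side = c("substrate", "substrate", "product", "product"))
  }) |> dplyr::bind_rows()
  rmap <- reaction_map(rr, rp)

  pairs <- combn(roles, 2)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    genes <- make_genes("gx", 700, roles = list(c(a, b)))
    adj <- adjacent_reaction_fusions(toy_calls_final("gx"), genes, rmap)
    prod_a <- rp$metabolite[rp$reaction_id == rr$reaction_id[rr$role == a] &
                              rp$side == "product"]
    sub_b <- rp$metabolite[rp$reaction_id == rr$reaction_id[rr$role == b] &
                             rp$side == "substrate"]
    prod_b <- rp$metabolite[rp$reaction_id == rr$reaction_id[rr$role == b] &
                              rp$side == "product"]
    sub_a <- rp$metabolite[rp$reaction_id == rr$reaction_id[rr$role == a] &
                             rp$side == "substrate"]
    expected_ab <- length(intersect(prod_a, sub_b)) > 0
    expected_ba <- length(intersect(prod_b, sub_a)) > 0
    expect_equal(any(adj$role_from == a & adj$role_to == b), expected_ab)
    expect_equal(any(adj$role_from == b & adj$role_to == a), expected_ba)
  }
})

test_that("reversible mode is symmetric under direction reversal", {
  rmap <- read_reaction_map(toy_path("toy_reaction_map.tsv"))
  genes <- make_genes("g1", 700, roles = list(
    c("Phosphoribosyl-ATP pyrophosphatase",
      "Phosphoribosyl-AMP cyclohydrolase")))
  adj <- adjacent_reaction_fusions(toy_calls_final("g1"), genes, rmap,
                                   reversible = TRUE)
  # both orientations emitted with the same shared metabolites
  expect_equal(nrow(adj), 2)
  expect_setequal(adj$role_from, unique(unlist(genes$roles)))
  expect_equal(unique(adj$metabolites), "Phosphoribosyl-AMP")
})

test_that("fusion variety counts distinct architectures once each", {
  domain_roles <- tibble::tibble(cdd_id = c("ribA", "ribB"),
                                 role = c("RibA role", "RibB role"))
  calls <- toy_calls_final(
    sprintf("g%02d", 1:40),
    cdd_ids = c(rep("ribA,partner1", 20), rep("ribA,partner2", 15),
                rep("partner3,ribA", 4), rep("ribB,partner1", 1)))
  pc <- tibble::tibble(cdd_id = c("partner1", "partner2"),
                       category = c("same_pathway", "other_metabolism"))
  v <- fusion_variety(calls, "RibA role", domain_roles, pc)
  expect_equal(v$variety, 3)       # 3 distinct partners despite 39 genes
  expect_equal(v$n_same_pathway, 1)
  expect_equal(v$n_other_metabolism, 1)
  expect_equal(v$n_unknown, 1)
  expect_equal(v$n_same_pathway + v$n_other_metabolism + v$n_unknown,
               v$variety)

  none <- fusion_variety(calls, "never fused role",
                         tibble::tibble(cdd_id = "zzz",
                                        role = "never fused role"))
  expect_equal(none$variety, 0)
})

test_that("fusion frequency is the fused share of a role's gene copies", {
  genes <- make_genes(sprintf("g%02d", 1:12), rep(700, 12),
                      roles = rep(list("thiC role"), 12))
  genes$genome_id <- rep(c("gn1", "gn2"), each = 6)
  calls <- toy_calls_final(c("g01", "g02", "g07"))
  f <- fusion_frequency(calls, genes, "thiC role")
  expect_equal(f$n_copies, 12)
  expect_equal(f$frequency, 0.25)

  # restricting the pool to fused-only genomes raises the share accordingly
  f2 <- fusion_frequency(calls, genes, "thiC role", genomes = "gn1")
  expect_equal(f2$frequency, 2 / 6)

  # all copies fused
  all_f <- fusion_frequency(toy_calls_final(genes$gene_id), genes, "thiC role")
  expect_equal(all_f$frequency, 1)

  # absent role reported as NA, not zero
  absent <- fusion_frequency(calls, genes, "missing role")
  expect_true(is.na(absent$frequency))
  expect_equal(absent$n_copies, 0)
})
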