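# interval helpers; coordinates are 1-based inclusive throughout
interval_length <- function(start, end) end - start + 1L

interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- interval_overlap(s1, e1, s2, e2)
  union <- interval_length(s1, e1) + interval_length(s2, e2) - inter
  inter / union
}

#' Flag domain models that represent entire genes
#'
#' A model is *full-gene* when at least one alignment covers more than
#' `full_gene_coverage` (default 90%) of **both** the model length and the
#' gene length — i.e. the domain stands for an entire standalone gene
#' somewhere in the database. Models without such a bidirectional alignment
#' are typically small sub-domains and are excluded from candidate
#' selection downstream.
#'
#' @param hits hit tibble, pre-filtered to E-value below the hit threshold.
#' @param genes gene tibble.
#' @param cdds catalogue tibble.
#' @param thresholds a [fusion_thresholds()] object.
#' @return The catalogue with `is_full_gene` filled in (logical).
#' @export
mark_full_gene_cdds <- function(hits, genes, cdds,
                                thresholds = fusion_thresholds()) {
  cov <- hits |>
    left_join(select(genes, "gene_id", gene_length = "length"),
              by = "gene_id") |>
    left_join(select(cdds, "cdd_id", "model_length"), by = "cdd_id") |>
    mutate(
      model_cov = interval_length(.data$cdd_start, .data$cdd_end) /
        .data$model_length,
      gene_cov = interval_length(.data$gene_start, .data$gene_end) /
        .data$gene_length
    ) |>
    filter(.data$model_cov > thresholds$full_gene_coverage,
           .data$gene_cov > thresholds$full_gene_coverage)
  cdds$is_full_gene <- cdds$cdd_id %in% cov$cdd_id
  cdds
}

#' Consolidate domain models with near-identical alignment footprints
#'
#' Redundant domain models (the same structural domain deposited several
#' times) align to essentially the same intervals on the same genes. Two
#' models are linked when the fraction of their jointly-hit genes on which
#' their alignments overlap with interval Jaccard at least
#' `interval_jaccard_min` is at least `similarity_min` of all genes either
#' model hits. Sets are the single-linkage connected components of this
#' link graph; models with no hits form singleton sets. The result is a
#' partition of the catalogue.
#'
#' @param hits hit tibble.
#' @param cdds catalogue tibble (defines the universe of models).
#' @param similarity_min minimum footprint-sharing fraction to link two
#'   models (default 0.5).
#' @param interval_jaccard_min minimum gene-interval Jaccard for two
#'   alignments on one gene to count as a shared footprint (default 0.8).
#' @return A tibble with columns `set_id`, `cdd_id`; every catalogue model
#'   appears exactly once.
#' @export
build_cdd_sets <- function(hits, cdds, similarity_min = 0.5,
                           interval_jaccard_min = 0.8) {
  edges <- cdd_similarity_edges(hits, interval_jaccard_min)
  edges <- edges[edges$similarity >= similarity_min, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[c("cdd_a", "cdd_b")], directed = FALSE,
    vertices = data.frame(name = cdds$cdd_id)
  )
  comp <- igraph::components(g)$membership
  # stable set ids: number components by their lexicographically first member
  first_member <- tapply(names(comp), comp, function(v) min(v))
  ord <- rank(first_member, ties.method = "first")
  width <- max(2L, nchar(as.character(length(first_member))))
  set_of <- sprintf(paste0("set%0", width, "d"), ord[as.character(comp)])
  tibble(set_id = set_of, cdd_id = names(comp)) |>
    arrange(.data$set_id, .data$cdd_id)
}

# All model pairs that share at least one gene, with footprint similarity:
# |genes where footprints match| / |genes hit by either model|.
cdd_similarity_edges <- function(hits, interval_jaccard_min) {
  genes_per_cdd <- hits |> distinct(.data$cdd_id, .data$gene_id) |>
    count(.data$cdd_id, name = "n_genes")
  pairs <- inner_join(
    select(hits, "gene_id", cdd_a = "cdd_id", s1 = "gene_start",
           e1 = "gene_end"),
    select(hits, "gene_id", cdd_b = "cdd_id", s2 = "gene_start",
           e2 = "gene_end"),
    by = "gene_id", relationship = "many-to-many"
  ) |>
    filter(.data$cdd_a < .data$cdd_b)
  if (nrow(pairs) == 0) {
    return(tibble(cdd_a = character(), cdd_b = character(),
                  similarity = numeric()))
  }
  pairs |>
    mutate(match = interval_jaccard(.data$s1, .data$e1, .data$s2, .data$e2) >=
             interval_jaccard_min) |>
    group_by(.data$cdd_a, .data$cdd_b) |>
    summarise(
      n_shared = n_distinct(.data$gene_id[.data$match]),
      n_cohit = n_distinct(.data$gene_id),
      .groups = "drop"
    ) |>
    left_join(rename(genes_per_cdd, cdd_a = "cdd_id", na = "n_genes"),
              by = "cdd_a") |>
    left_join(rename(genes_per_cdd, cdd_b = "cdd_id", nb = "n_genes"),
              by = "cdd_b") |>
    mutate(similarity = .data$n_shared /
             (.data$na + .data$nb - .data$n_cohit)) |>
    select("cdd_a", "cdd_b", "similarity")
}

#' Co-occurrence and pair-match index over domain models
#'
#' For every model, counts the number of *distinct model sets* (other than
#' its own) having a member hit on at least one gene the model also hits —
#' the promiscuity measure capped by the co-occurrence criterion. For every
#' unordered model pair, counts the distinct genes on which the two models
#' align with mutual gene-interval overlap of at least half the shorter
#' alignment — a proxy for the two domains being versions of one another,
#' capped by the pair-match criterion.
#'
#' @param hits hit tibble.
#' @param sets set partition from [build_cdd_sets()].
#' @return A list of class `cooccurrence_index`: `set_counts` (`cdd_id`,
#'   `n_cooccurring_sets`, one row per model in `sets`) and `pair_matches`
#'   (`cdd_a`, `cdd_b`, `n_genes`, only pairs with a positive count).
#' @export
build_cooccurrence_index <- function(hits, sets) {
  gh <- hits |> distinct(.data$gene_id, .data$cdd_id) |>
    left_join(sets, by = "cdd_id")
  if (any(is.na(gh$set_id))) {
    abort("hits refer to cdd_id(s) absent from the set partition")
  }
  gene_sets <- distinct(gh, .data$gene_id, other_set = .data$set_id)
  co <- gh |>
    inner_join(gene_sets, by = "gene_id", relationship = "many-to-many") |>
    filter(.data$other_set != .data$set_id) |>
    distinct(.data$cdd_id, .data$other_set) |>
    count(.data$cdd_id, name = "n_cooccurring_sets")
  set_counts <- sets |>
    select("cdd_id") |>
    left_join(co, by = "cdd_id") |>
    mutate(n_cooccurring_sets = coalesce(.data$n_cooccurring_sets, 0L))

  pm <- inner_join(
    select(hits, "gene_id", cdd_a = "cdd_id", s1 = "gene_start",
           e1 = "gene_end"),
    select(hits, "gene_id", cdd_b = "cdd_id", s2 = "gene_start",
           e2 = "gene_end"),
    by = "gene_id", relationship = "many-to-many"
  ) |>
    filter(.data$cdd_a < .data$cdd_b) |>
    mutate(
      ov = interval_overlap(.data$s1, .data$e1, .data$s2, .data$e2),
      shorter = pmin(interval_length(.data$s1, .data$e1),
                     interval_length(.data$s2, .data$e2))
    ) |>
    filter(.data$ov >= 0.5 * .data$shorter) |>
    distinct(.data$cdd_a, .data$cdd_b, .data$gene_id) |>
    count(.data$cdd_a, .data$cdd_b, name = "n_genes")

  structure(list(set_counts = set_counts, pair_matches = pm),
            class = "cooccurrence_index")
}

cooccurrence_of <- function(index, cdd_ids) {
  m <- match(cdd_ids, index$set_counts$cdd_id)
  out <- index$set_counts$n_cooccurring_sets[m]
  out[is.na(out)] <- 0L
  out
}

pair_matches_of <- function(index, cdd_a, cdd_b) {
  a <- pmin(cdd_a, cdd_b)
  b <- pmax(cdd_a, cdd_b)
  pm <- index$pair_matches
  key <- paste(pm$cdd_a, pm$cdd_b, sep = "\r")
  m <- match(paste(a, b, sep = "\r"), key)
  out <- pm$n_genes[m]
  out[is.na(out)] <- 0L
  out
}

#' Build the full domain atlas for a dataset
#'
#' Convenience wrapper that filters hits to the E-value threshold, flags
#' full-gene models, consolidates models into sets, and builds the
#' co-occurrence index.
#'
#' @inheritParams mark_full_gene_cdds
#' @param similarity_min passed to [build_cdd_sets()].
#' @return A list of class `domain_atlas`: `cdds` (flagged catalogue),
#'   `sets`, `cooccurrence`, `hits` (the E-value-filtered hits).
#' @export
build_domain_atlas <- function(genes, hits, cdds,
                               thresholds = fusion_thresholds(),
                               similarity_min = 0.5) {
  hits <- filter(hits, .data$e_value < thresholds$e_value_max)
  cdds <- mark_full_gene_cdds(hits, genes, cdds, thresholds)
  sets <- build_cdd_sets(hits, cdds, similarity_min = similarity_min)
  idx <- build_cooccurrence_index(hits, sets)
  structure(list(cdds = cdds, sets = sets, cooccurrence = idx, hits = hits),
            class = "domain_atlas")
}

#' Catalogue accounting
#'
#' Retention fraction of full-gene models and mean consolidated-set size,
#' the two bookkeeping ratios reported for a domain atlas.
#'
#' @param n_cdds total number of models in the catalogue.
#' @param n_full_gene number flagged full-gene.
#' @param n_sets number of consolidated sets.
#' @return A one-row tibble: `n_cdds`, `n_full_gene`, `retention_fraction`,
#'   `retention_pct`, `n_sets`, `mean_set_size`.
#' @export
catalogue_accounting <- function(n_cdds, n_full_gene, n_sets) {
  tibble(
    n_cdds = n_cdds,
    n_full_gene = n_full_gene,
    retention_fraction = n_full_gene / n_cdds,
    retention_pct = 100 * n_full_gene / n_cdds,
    n_sets = n_sets,
    mean_set_size = n_cdds / n_sets
  )
}

#' @export
glance.domain_atlas <- function(x, ...) {
  catalogue_accounting(
    n_cdds = nrow(x$cdds),
    n_full_gene = sum(x$cdds$is_full_gene, na.rm = TRUE),
    n_sets = n_distinct(x$sets$set_id)
  )
}

#' @export
print.domain_atlas <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<domain_atlas> %d models (%d full-gene, %.1f%%), %d sets (mean size %.2f)\n",
    g$n_cdds, g$n_full_gene, g$retention_pct, g$n_sets, g$mean_set_size))
  invisible(x)
}
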