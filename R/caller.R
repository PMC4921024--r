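# Two hits are compatible (non-overlapping) when the later one starts after
# the earlier one ends, modulo the configured overlap tolerance.
compatible_after <- function(end_i, start_j, tol) start_j > end_i - tol

#' Naive multi-domain test
#'
#' `TRUE` when a gene's hit list contains at least two pairwise
#' non-overlapping alignments to any domain models — the necessary (but far
#' from sufficient) condition for a gene to be a fusion.
#'
#' @param gene_hits tibble of one gene's hits, already filtered to the
#'   E-value threshold.
#' @param thresholds a [fusion_thresholds()] object (supplies the overlap
#'   tolerance).
#' @return A single logical.
#' @export
naive_multidomain <- function(gene_hits, thresholds = fusion_thresholds()) {
  n <- nrow(gene_hits)
  if (n < 2) return(FALSE)
  tol <- thresholds$overlap_tolerance
  i <- which.min(gene_hits$gene_end)
  any(compatible_after(gene_hits$gene_end[i], gene_hits$gene_start[-i], tol))
}

#' Select the maximal non-overlapping full-gene domain partition of a gene
#'
#' Among the gene's alignments to full-gene models that cover at least
#' `domain_coverage_min` of their model, finds a maximum-cardinality set of
#' pairwise non-overlapping alignments. Ties between equal-cardinality
#' solutions are broken by larger summed alignment length, then by
#' lexicographically smallest model-id sequence, so the selection is
#' deterministic. Returns `NULL` when fewer than two alignments can be
#' selected.
#'
#' @param gene one-row tibble for the gene (`gene_id`, `length`, ...).
#' @param gene_hits tibble of the gene's hits (E-value filtered).
#' @param cdds flagged catalogue (after [mark_full_gene_cdds()]).
#' @param thresholds a [fusion_thresholds()] object.
#' @return A list of class `fusion_candidate` with elements `gene_id`,
#'   `selected` (hit tibble in N-to-C order) and `gaps` (tibble
#'   `start`/`end`, the residue intervals between consecutive selected
#'   alignments), or `NULL`.
#' @export
select_partition <- function(gene, gene_hits, cdds,
                             thresholds = fusion_thresholds()) {
  elig <- gene_hits |>
    left_join(select(cdds, "cdd_id", "model_length", "is_full_gene"),
              by = "cdd_id") |>
    filter(
      !is.na(.data$is_full_gene), .data$is_full_gene,
      interval_length(.data$cdd_start, .data$cdd_end) / .data$model_length >=
        thresholds$domain_coverage_min
    ) |>
    arrange(.data$gene_end, .data$gene_start, .data$cdd_id, .data$cdd_start)
  n <- nrow(elig)
  if (n < 2) return(NULL)
  tol <- thresholds$overlap_tolerance

  # DP over hits sorted by end coordinate. Chains are compared by
  # (cardinality, summed alignment length, model-id sequence).
  len <- interval_length(elig$gene_start, elig$gene_end)
  best <- vector("list", n)
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$count != b$count) return(a$count > b$count)
    if (a$len != b$len) return(a$len > b$len)
    a$key < b$key
  }
  for (i in seq_len(n)) {
    cand <- list(count = 1L, len = len[i], key = elig$cdd_id[i], chain = i)
    if (i > 1) {
      for (j in seq_len(i - 1L)) {
        if (compatible_after(elig$gene_end[j], elig$gene_start[i], tol)) {
          ext <- list(
            count = best[[j]]$count + 1L,
            len = best[[j]]$len + len[i],
            key = paste(best[[j]]$key, elig$cdd_id[i], sep = ","),
            chain = c(best[[j]]$chain, i)
          )
          if (better(ext, cand)) cand <- ext
        }
      }
    }
    best[[i]] <- cand
  }
  top <- NULL
  for (i in seq_len(n)) if (better(best[[i]], top)) top <- best[[i]]
  if (top$count < 2L) return(NULL)

  selected <- elig[top$chain, setdiff(names(elig),
                                      c("model_length", "is_full_gene"))]
  k <- nrow(selected)
  gaps <- tibble(start = selected$gene_end[-k] + 1L,
                 end = selected$gene_start[-1] - 1L)
  structure(list(gene_id = gene$gene_id[[1]], selected = selected,
                 gaps = gaps),
            class = "fusion_candidate")
}

#' Evaluate the eight candidate-filter criteria
#'
#' Applies the eight filters that separate true fusions from multi-domain
#' false positives: (length) the protein must exceed
#' `min_protein_length` residues; (coverage) the selected alignments
#' together must cover at least `combined_coverage_min` of the gene;
#' (alignment length) every selected alignment must span at least
#' `min_alignment_length` residues; (gap position) every gap midpoint must
#' lie at least `min_gap_distance_residues` residues and
#' `min_gap_distance_fraction` of the gene length from both termini;
#' (distinct sets) the selected models must span at least two consolidated
#' sets; (crossing) fewer than `gap_crossing_fraction_max` of the gene's
#' alignments may cross a gap; (promiscuity) every selected model must
#' co-occur with fewer than `max_cooccurring_sets` sets; (pair similarity)
#' every selected model pair must have fewer than `max_pair_matches` pair
#' matches.
#'
#' @param candidate a `fusion_candidate` from [select_partition()].
#' @param gene one-row tibble for the gene.
#' @param gene_hits the gene's full E-value-filtered hit list (used by the
#'   gap-crossing criterion).
#' @param sets set partition from [build_cdd_sets()].
#' @param index co-occurrence index from [build_cooccurrence_index()].
#' @param thresholds a [fusion_thresholds()] object.
#' @return A one-row tibble of measured values, pass flags,
#'   `n_criteria_passed` and the overall `verdict`.
#' @export
apply_criteria <- function(candidate, gene, gene_hits, sets, index,
                           thresholds = fusion_thresholds()) {
  if (is.null(index)) abort("a co-occurrence index is required")
  t <- thresholds
  sel <- candidate$selected
  gaps <- candidate$gaps
  L <- gene$length[[1]]

  protein_length <- L
  pass_length <- L > t$min_protein_length

  aln_len <- interval_length(sel$gene_start, sel$gene_end)
  combined_coverage <- sum(aln_len) / L
  pass_coverage <- combined_coverage >= t$combined_coverage_min

  min_aln_length <- min(aln_len)
  pass_aln_length <- min_aln_length >= t$min_alignment_length

  mids <- (gaps$start + gaps$end) / 2
  gap_margin <- min(pmin(mids, L - mids))
  pass_gap_position <- gap_margin >= t$min_gap_distance_residues &&
    gap_margin >= t$min_gap_distance_fraction * L

  sel_sets <- sets$set_id[match(sel$cdd_id, sets$cdd_id)]
  n_cdd_sets <- n_distinct(sel_sets)
  pass_distinct_sets <- n_cdd_sets >= 2L

  crosses <- vapply(seq_len(nrow(gene_hits)), function(i) {
    any(gene_hits$gene_start[i] < gaps$start & gene_hits$gene_end[i] > gaps$end)
  }, logical(1))
  crossing_fraction <- if (nrow(gene_hits)) mean(crosses) else 0
  pass_crossing <- crossing_fraction < t$gap_crossing_fraction_max

  max_cooccurrence <- max(cooccurrence_of(index, unique(sel$cdd_id)))
  pass_promiscuity <- max_cooccurrence < t$max_cooccurring_sets

  cdd_u <- unique(sel$cdd_id)
  max_pair_matches <- if (length(cdd_u) >= 2) {
    pairs <- combn(cdd_u, 2)
    max(pair_matches_of(index, pairs[1, ], pairs[2, ]))
  } else 0L
  pass_pair_similarity <- max_pair_matches < t$max_pair_matches

  flags <- c(pass_length, pass_coverage, pass_aln_length, pass_gap_position,
             pass_distinct_sets, pass_crossing, pass_promiscuity,
             pass_pair_similarity)
  n_passed <- sum(flags)
  verdict <- switch(t$criteria_policy,
                    all = all(flags),
                    at_least_k = n_passed >= t$criteria_k)

  tibble(
    protein_length = as.integer(protein_length), pass_length = pass_length,
    combined_coverage = combined_coverage, pass_coverage = pass_coverage,
    min_aln_length = as.integer(min_aln_length),
    pass_aln_length = pass_aln_length,
    gap_margin = gap_margin, pass_gap_position = pass_gap_position,
    n_cdd_sets = as.integer(n_cdd_sets),
    pass_distinct_sets = pass_distinct_sets,
    crossing_fraction = crossing_fraction, pass_crossing = pass_crossing,
    max_cooccurrence = as.integer(max_cooccurrence),
    pass_promiscuity = pass_promiscuity,
    max_pair_matches = as.integer(max_pair_matches),
    pass_pair_similarity = pass_pair_similarity,
    n_criteria_passed = as.integer(n_passed), verdict = verdict
  )
}

new_fusion_calls <- function(df, thresholds = NULL, candidates = NULL) {
  structure(as_tibble(df),
            thresholds = thresholds,
            candidates = candidates,
            class = c("fusion_calls", class(as_tibble(df))))
}

empty_calls_row <- function() {
  tibble(
    protein_length = NA_integer_, pass_length = NA,
    combined_coverage = NA_real_, pass_coverage = NA,
    min_aln_length = NA_integer_, pass_aln_length = NA,
    gap_margin = NA_real_, pass_gap_position = NA,
    n_cdd_sets = NA_integer_, pass_distinct_sets = NA,
    crossing_fraction = NA_real_, pass_crossing = NA,
    max_cooccurrence = NA_integer_, pass_promiscuity = NA,
    max_pair_matches = NA_integer_, pass_pair_similarity = NA,
    n_criteria_passed = NA_integer_, verdict = FALSE
  )
}

#' Run the full fusion-detection workflow
#'
#' For every gene: keep hits below the E-value threshold; record the gene if
#' it has two or more non-overlapping alignments (naive multi-domain stage);
#' try to select a non-overlapping full-gene domain partition
#' ([select_partition()], candidate stage); and evaluate the eight filter
#' criteria ([apply_criteria()]). A gene with three or more disjoint
#' domains yields a single call with multiple gaps, not several pairwise
#' calls. The run is deterministic for a fixed input.
#'
#' @param genes gene tibble.
#' @param hits hit tibble (unfiltered; the E-value threshold is applied
#'   internally).
#' @param cdds catalogue tibble.
#' @param thresholds a [fusion_thresholds()] object.
#' @param atlas optional pre-built [build_domain_atlas()] result; built from
#'   the inputs when omitted.
#' @return A `fusion_calls` tibble with one row per gene passing the naive
#'   stage: identity, `stage_reached` (`naive_multidomain`,
#'   `full_gene_candidate` or `final_fusion`), the selected architecture
#'   (`cdd_ids`, `domain_starts`, `domain_ends` in N-to-C order), criterion
#'   values/flags and `verdict`. Candidate objects are attached as the
#'   `candidates` attribute; per-genome stage counts via [stage_summary()].
#' @export
call_fusions <- function(genes, hits, cdds, thresholds = fusion_thresholds(),
                         atlas = NULL) {
  if (is.null(atlas)) {
    atlas <- build_domain_atlas(genes, hits, cdds, thresholds = thresholds)
  }
  fhits <- atlas$hits
  by_gene <- split(fhits, fhits$gene_id)
  gene_idx <- match(names(by_gene), genes$gene_id)
  if (anyNA(gene_idx)) {
    abort(sprintf("hits refer to gene(s) absent from the gene table: %s",
                  paste(head(names(by_gene)[is.na(gene_idx)], 5),
                        collapse = ", ")))
  }

  rows <- vector("list", length(by_gene))
  cands <- list()
  for (k in seq_along(by_gene)) {
    gh <- by_gene[[k]]
    gene <- genes[gene_idx[k], ]
    if (!naive_multidomain(gh, thresholds)) next
    stage <- "naive_multidomain"
    cand <- select_partition(gene, gh, atlas$cdds, thresholds)
    if (is.null(cand)) {
      crit <- empty_calls_row()
      arch <- tibble(n_domains = NA_integer_, cdd_ids = NA_character_,
                     domain_starts = NA_character_,
                     domain_ends = NA_character_)
    } else {
      stage <- "full_gene_candidate"
      crit <- apply_criteria(cand, gene, gh, atlas$sets, atlas$cooccurrence,
                             thresholds)
      if (crit$verdict) stage <- "final_fusion"
      arch <- tibble(
        n_domains = nrow(cand$selected),
        cdd_ids = paste(cand$selected$cdd_id, collapse = ","),
        domain_starts = paste(cand$selected$gene_start, collapse = ","),
        domain_ends = paste(cand$selected$gene_end, collapse = ",")
      )
      cands[[gene$gene_id[[1]]]] <- cand
    }
    rows[[k]] <- bind_cols(
      tibble(gene_id = gene$gene_id[[1]], genome_id = gene$genome_id[[1]],
             stage_reached = stage),
      arch, crit
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows)) {
    df <- bind_rows(rows) |> arrange(.data$genome_id, .data$gene_id)
  } else {
    df <- bind_cols(
      tibble(gene_id = character(), genome_id = character(),
             stage_reached = character(), n_domains = integer(),
             cdd_ids = character(), domain_starts = character(),
             domain_ends = character()),
      empty_calls_row()[0, ]
    )
  }
  new_fusion_calls(df[, intersect(call_table_columns(), names(df))],
                   thresholds = thresholds, candidates = cands)
}

#' Per-genome stage accounting of a call set
#'
#' @param calls a `fusion_calls` tibble.
#' @return A tibble per genome: `n_naive`, `n_candidate`, `n_final`,
#'   `n_eliminated_stage2` (naive genes losing candidacy),
#'   `n_eliminated_criteria` (candidates failing the filters).
#' @export
stage_summary <- function(calls) {
  as_tibble(calls) |>
    group_by(.data$genome_id) |>
    summarise(
      n_naive = n(),
      n_candidate = sum(.data$stage_reached %in%
                          c("full_gene_candidate", "final_fusion")),
      n_final = sum(.data$stage_reached == "final_fusion"),
      .groups = "drop"
    ) |>
    mutate(n_eliminated_stage2 = .data$n_naive - .data$n_candidate,
           n_eliminated_criteria = .data$n_candidate - .data$n_final)
}

#' Stage accounting from raw counts
#'
#' @param n_naive genes passing the naive multi-domain stage.
#' @param n_candidate genes with a full-gene non-overlapping partition.
#' @param n_final genes passing all filter criteria.
#' @return A one-row tibble with the counts and the two elimination tallies.
#' @export
stage_accounting <- function(n_naive, n_candidate, n_final = NA_integer_) {
  tibble(n_naive = n_naive, n_candidate = n_candidate, n_final = n_final,
         n_eliminated_stage2 = n_naive - n_candidate,
         n_eliminated_criteria = n_candidate - n_final)
}

#' Final fusion gene ids of a call set
#'
#' @param calls a `fusion_calls` tibble.
#' @return Character vector of gene ids with `stage_reached == "final_fusion"`.
#' @export
final_fusion_genes <- function(calls) {
  calls$gene_id[calls$stage_reached == "final_fusion"]
}

#' Rosetta-stone validation of a candidate's domains
#'
#' Checks, per selected domain model, the three conditions that make a
#' multi-domain protein a *Rosetta stone*: (i) the selected alignment covers
#' the full model (at least `full_gene_coverage` of the model length);
#' (ii) the alignment identity exceeds 50%; (iii) the model also aligns
#' elsewhere as the *only* domain of some other gene — i.e. the domain
#' exists as an independent standalone protein. When `pct_identity` is
#' absent the identity condition, and hence the overall check, is reported
#' as `NA` (not evaluable) rather than failed.
#'
#' @param candidate a `fusion_candidate` from [select_partition()].
#' @param hits the full dataset hit tibble (E-value filtered).
#' @param cdds catalogue tibble.
#' @param thresholds a [fusion_thresholds()] object.
#' @return A tibble per selected model: `cdd_id`, `full_length`,
#'   `identity_gt50`, `standalone_elsewhere`, `rosetta`.
#' @export
rosetta_stone_check <- function(candidate, hits, cdds,
                                thresholds = fusion_thresholds()) {
  sel <- candidate$selected
  model_len <- cdds$model_length[match(sel$cdd_id, cdds$cdd_id)]
  full_length <- interval_length(sel$cdd_start, sel$cdd_end) / model_len >=
    thresholds$full_gene_coverage
  identity_gt50 <- ifelse(is.na(sel$pct_identity), NA,
                          sel$pct_identity > 50)
  cdds_per_gene <- hits |>
    group_by(.data$gene_id) |>
    summarise(n_cdds = n_distinct(.data$cdd_id),
              only_cdd = .data$cdd_id[1], .groups = "drop")
  single_domain <- cdds_per_gene |>
    filter(.data$n_cdds == 1L, .data$gene_id != candidate$gene_id)
  standalone <- sel$cdd_id %in% single_domain$only_cdd
  tibble(
    cdd_id = sel$cdd_id,
    full_length = full_length,
    identity_gt50 = identity_gt50,
    standalone_elsewhere = standalone,
    rosetta = full_length & identity_gt50 & standalone
  )
}

#' @export
glance.fusion_calls <- function(x, ...) {
  s <- stage_summary(x)
  tibble(
    n_genomes = nrow(s),
    n_naive = sum(s$n_naive),
    n_candidate = sum(s$n_candidate),
    n_final = sum(s$n_final),
    n_eliminated_stage2 = sum(s$n_eliminated_stage2),
    n_eliminated_criteria = sum(s$n_eliminated_criteria)
  )
}

#' @export
tidy.fusion_calls <- function(x, ...) {
  as_tibble(x)
}

#' @export
print.fusion_calls <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<fusion_calls> %d naive multi-domain gene(s), %d candidate(s), %d final fusion(s) across %d genome(s)\n",
    g$n_naive, g$n_candidate, g$n_final, g$n_genomes))
  print(as_tibble(x), ...)
  invisible(x)
}
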