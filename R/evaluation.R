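#' Score predicted fusions against a curated training set
#'
#' Compares final fusion calls with a curated truth table. Entries with
#' status `uncertain` are excluded from both numerator and denominator —
#' neither credited nor penalised; `rejected` entries are likewise outside
#' the truth set. The false-positive rate is defined as
#' `(n_predicted - n_captured) / n_predicted` within the scoped genome(s);
#' raw counts are returned alongside so alternative definitions can be
#' recomputed.
#'
#' @param calls a `fusion_calls` tibble (or anything with `gene_id` and
#'   `stage_reached` columns).
#' @param truth training tibble ([read_training_table()]).
#' @param genes optional gene tibble; when given, every truth gene must
#'   resolve against it.
#' @param genomes optional character vector restricting scoring to calls
#'   from these genomes.
#' @return A one-row tibble of class `fusion_eval`: `n_truth`,
#'   `n_captured`, `n_predicted`, `capture_fraction`, `fn_rate`, `fp_rate`.
#'   Per-source counts are attached as the `per_source` attribute.
#' @export
evaluate_calls <- function(calls, truth, genes = NULL, genomes = NULL) {
  if (!is.null(genes)) {
    missing <- setdiff(truth$gene_id, genes$gene_id)
    if (length(missing)) {
      abort(sprintf("truth gene(s) absent from gene table: %s",
                    paste(head(missing, 10), collapse = ", ")))
    }
  }
  calls <- as_tibble(calls)
  if (!is.null(genomes)) calls <- filter(calls, .data$genome_id %in% genomes)
  final <- calls$gene_id[calls$stage_reached == "final_fusion"]

  confirmed <- filter(truth, .data$status == "confirmed_fusion")
  if (nrow(confirmed) == 0) {
    abort("empty confirmed truth set: rates are undefined")
  }
  n_truth <- nrow(confirmed)
  n_captured <- sum(confirmed$gene_id %in% final)
  n_predicted <- length(final)
  capture <- n_captured / n_truth

  per_source <- confirmed |>
    mutate(captured = .data$gene_id %in% final) |>
    tidyr::unnest_longer("source", values_to = "source") |>
    group_by(.data$source) |>
    summarise(n_truth = n(), n_captured = sum(.data$captured),
              capture_fraction = mean(.data$captured), .groups = "drop")

  out <- tibble(
    n_truth = n_truth,
    n_captured = n_captured,
    n_predicted = n_predicted,
    capture_fraction = capture,
    fn_rate = 1 - capture,
    fp_rate = if (n_predicted > 0) (n_predicted - n_captured) / n_predicted
              else NA_real_
  )
  structure(out, per_source = per_source,
            class = c("fusion_eval", class(out)))
}

#' @export
glance.fusion_eval <- function(x, ...) as_tibble(x)

#' @export
tidy.fusion_eval <- function(x, ...) attr(x, "per_source")

#' Source-overlap accounting of a training set
#'
#' For every curation source: the total number of entries citing it and the
#' number citing it exclusively; plus pairwise intersection counts.
#'
#' @param truth training tibble with a `source` list-column.
#' @return A list: `per_source` tibble (`source`, `n_total`, `n_exclusive`)
#'   and `pairwise` tibble (`source_a`, `source_b`, `n_shared`).
#' @export
source_overlap <- function(truth) {
  long <- truth |>
    mutate(n_sources = lengths(.data$source)) |>
    tidyr::unnest_longer("source", values_to = "source")
  per_source <- long |>
    group_by(.data$source) |>
    summarise(n_total = n(), n_exclusive = sum(.data$n_sources == 1L),
              .groups = "drop")
  srcs <- sort(unique(long$source))
  pairwise <- if (length(srcs) >= 2) {
    pairs <- combn(srcs, 2)
    tibble(source_a = pairs[1, ], source_b = pairs[2, ]) |>
      mutate(n_shared = map2(.data$source_a, .data$source_b, function(a, b) {
        sum(vapply(truth$source, function(s) a %in% s && b %in% s,
                   logical(1)))
      }) |> unlist())
  } else {
    tibble(source_a = character(), source_b = character(),
           n_shared = integer())
  }
  list(per_source = per_source, pairwise = pairwise)
}

#' Functional-category distribution of confirmed fusions
#'
#' Counts confirmed training fusions per functional category and reports
#' percentages rounded half-up to integer precision (the exact fractions
#' are returned alongside).
#'
#' @param truth training tibble; only `confirmed_fusion` entries are used.
#' @param categories tibble with columns `gene_id`, `category` covering
#'   every confirmed gene.
#' @return A tibble per category: `category`, `n_genes`, `fraction`, `pct`.
#' @export
category_distribution <- function(truth, categories) {
  confirmed <- filter(truth, .data$status == "confirmed_fusion")
  m <- match(confirmed$gene_id, categories$gene_id)
  if (anyNA(m)) {
    abort(sprintf("uncategorized gene(s): %s",
                  paste(head(confirmed$gene_id[is.na(m)], 10),
                        collapse = ", ")))
  }
  tibble(gene_id = confirmed$gene_id,
         category = categories$category[m]) |>
    count(.data$category, name = "n_genes") |>
    mutate(fraction = .data$n_genes / sum(.data$n_genes),
           pct = round_half_up(100 * .data$fraction)) |>
    arrange(desc(.data$n_genes))
}
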