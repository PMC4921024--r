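#' Per-role fusion statistics across a cohort
#'
#' Counts, for every functional role, the gene-role pairs annotated with it
#' (a multi-role gene contributes to each of its roles), the genomes
#' containing it, and how many of its genes are final fusion calls.
#'
#' @param genes gene tibble with a `roles` list-column.
#' @param calls a `fusion_calls` tibble.
#' @return A tibble of class `role_fusion_stats`: `role`, `n_genes`,
#'   `n_genomes`, `n_fused`, `proportion`.
#' @export
role_fusion_stats <- function(genes, calls) {
  fused <- final_fusion_genes(calls)
  out <- genes |>
    select("gene_id", "genome_id", "roles") |>
    tidyr::unnest_longer("roles", values_to = "role") |>
    filter(!is.na(.data$role), nzchar(.data$role)) |>
    mutate(fused = .data$gene_id %in% fused) |>
    group_by(.data$role) |>
    summarise(n_genes = n(), n_genomes = n_distinct(.data$genome_id),
              n_fused = sum(.data$fused), .groups = "drop") |>
    mutate(proportion = .data$n_fused / .data$n_genes)
  structure(out, class = c("role_fusion_stats", class(out)))
}

#' Per-subsystem fusion statistics across a cohort
#'
#' Same accounting as [role_fusion_stats()], at subsystem granularity.
#' Subsystems with no member genes simply do not appear (no division by
#' zero).
#'
#' @inheritParams role_fusion_stats
#' @return A tibble: `subsystem`, `n_genes`, `n_genomes`, `n_fused`,
#'   `proportion`.
#' @export
subsystem_fusion_stats <- function(genes, calls) {
  fused <- final_fusion_genes(calls)
  genes |>
    select("gene_id", "genome_id", "subsystems") |>
    tidyr::unnest_longer("subsystems", values_to = "subsystem") |>
    filter(!is.na(.data$subsystem), nzchar(.data$subsystem)) |>
    mutate(fused = .data$gene_id %in% fused) |>
    group_by(.data$subsystem) |>
    summarise(n_genes = n(), n_genomes = n_distinct(.data$genome_id),
              n_fused = sum(.data$fused), .groups = "drop") |>
    mutate(proportion = .data$n_fused / .data$n_genes)
}

#' Filter roles to consistently annotated, specific descriptions
#'
#' Keeps roles propagated to at least `min_genomes` genomes whose name
#' contains none of the generic descriptor words *predicted*,
#' *hypothetical*, *putative*, *possible*, *probable* (case-insensitive,
#' whole-word).
#'
#' @param stats a role-statistics tibble with `role` and `n_genomes`
#'   columns.
#' @param min_genomes minimum genome propagation (default 10).
#' @return The filtered tibble.
#' @export
filter_roles <- function(stats, min_genomes = 10L) {
  generic <- "\\b(predicted|hypothetical|putative|possible|probable)\\b"
  filter(stats,
         .data$n_genomes >= min_genomes,
         !stringr::str_detect(tolower(.data$role), generic))
}

#' Implied flagging threshold for frequently fused roles
#'
#' The fused-gene proportion beyond which a role counts as frequently
#' fused: the cohort mean plus `z_min` standard deviations.
#'
#' @param mu cohort mean of per-role fused proportions.
#' @param sigma cohort standard deviation of those proportions.
#' @param z_min standardized-excess cutoff (default 2).
#' @return A single numeric proportion.
#' @export
fused_proportion_threshold <- function(mu, sigma, z_min = 2) {
  mu + z_min * sigma
}

#' Flag frequently fused roles
#'
#' A role (or subsystem) is *frequently fused* when its fused-gene
#' proportion exceeds the cohort mean by more than `z_min` cohort standard
#' deviations **and** a one-sided exact binomial test of `n_fused` out of
#' `n_genes` against the cohort mean gives `p < p_max`. When the cohort
#' proportions have zero spread no role can show a standardized excess, so
#' nothing is flagged (with a warning).
#'
#' @param stats a statistics tibble with `n_genes`, `n_fused`,
#'   `proportion` columns (from [role_fusion_stats()] or
#'   [subsystem_fusion_stats()], typically after [filter_roles()]).
#' @param z_min standardized-excess cutoff (default 2).
#' @param p_max significance cutoff for the binomial test (default 0.05).
#' @return `stats` with added columns `z`, `p`, `frequently_fused`, and
#'   attributes `mu`, `sigma`, `threshold` (the implied proportion
#'   `mu + z_min * sigma`).
#' @export
frequently_fused <- function(stats, z_min = 2, p_max = 0.05) {
  if (nrow(stats) < 2) {
    abort("degenerate cohort: need at least two roles to estimate spread")
  }
  mu <- mean(stats$proportion)
  sigma <- sd(stats$proportion)
  if (sigma == 0) {
    warn("cohort proportions have zero spread; no role can be flagged")
    out <- mutate(stats, z = NA_real_, p = NA_real_, frequently_fused = FALSE)
  } else {
    out <- stats |>
      mutate(
        z = (.data$proportion - mu) / sigma,
        p = map2(.data$n_fused, .data$n_genes, function(x, n) {
          binom.test(x, n, p = mu, alternative = "greater")$p.value
        }) |> unlist(),
        frequently_fused = .data$z > z_min & .data$p < p_max
      )
  }
  structure(out, mu = mu, sigma = sigma,
            threshold = fused_proportion_threshold(mu, sigma, z_min),
            class = unique(c("role_fusion_stats", class(out))))
}

#' @export
glance.role_fusion_stats <- function(x, ...) {
  tibble(
    n_roles = nrow(x),
    mu = attr(x, "mu") %||% mean(x$proportion),
    sigma = attr(x, "sigma") %||% sd(x$proportion),
    threshold = attr(x, "threshold") %||% NA_real_,
    n_frequently_fused = if ("frequently_fused" %in% names(x))
      sum(x$frequently_fused) else NA_integer_
  )
}

#' Fusion counts versus genome size
#'
#' Reports the pooled fused-gene fraction and the least-squares
#' through-origin slope of fusions against genes per genome; when fusion
#' prevalence is proportional to genome size the two agree.
#'
#' @param genome_counts tibble with columns `genome_id`, `n_genes`,
#'   `n_fused` (one row per genome; at least two genomes).
#' @return A one-row tibble: `n_genomes`, `overall_fraction`, `slope`.
#' @export
genome_proportionality <- function(genome_counts) {
  if (nrow(genome_counts) < 2) {
    abort("need at least two genomes to assess proportionality")
  }
  x <- genome_counts$n_genes
  y <- genome_counts$n_fused
  tibble(
    n_genomes = nrow(genome_counts),
    overall_fraction = sum(y) / sum(x),
    slope = sum(x * y) / sum(x^2)
  )
}

#' Per-genome gene and fusion counts
#'
#' @param genes gene tibble.
#' @param calls a `fusion_calls` tibble.
#' @return A tibble: `genome_id`, `n_genes`, `n_fused`.
#' @export
genome_fusion_counts <- function(genes, calls) {
  fused <- final_fusion_genes(calls)
  genes |>
    group_by(.data$genome_id) |>
    summarise(n_genes = n(), n_fused = sum(.data$gene_id %in% fused),
              .groups = "drop")
}
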