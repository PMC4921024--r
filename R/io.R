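# Multi-valued cells (roles, subsystems, sources) use semicolon separators.
split_multi <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(trimws(v))) return(character(0))
    trimws(strsplit(v, ";", fixed = TRUE)[[1]])
  })
}

join_multi <- function(x) {
  vapply(x, paste, character(1), collapse = ";")
}

require_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("%s: missing mandatory column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

read_tsv_quiet <- function(path, ...) {
  if (!file.exists(path)) abort(sprintf("cannot read file: %s", path))
  readr::read_tsv(path, ..., progress = FALSE, show_col_types = FALSE)
}

#' Read a gene annotation table
#'
#' Expects a TSV with header columns `gene_id`, `genome_id`, `length`,
#' `roles` and optionally `subsystems`; `roles` and `subsystems` cells hold
#' semicolon-separated lists. `length` is the protein length in amino-acid
#' residues.
#'
#' @param path path to the TSV file.
#' @return A tibble with one row per gene: `gene_id`, `genome_id`,
#'   `length` (integer), and list-columns `roles` and `subsystems`.
#' @export
read_gene_table <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  require_columns(df, c("gene_id", "genome_id", "length", "roles"), path)
  bad_len <- !grepl("^[0-9]+$", df$length)
  if (any(bad_len)) {
    abort(sprintf("%s: non-integer gene length for gene(s): %s", path,
                  paste(head(df$gene_id[bad_len], 5), collapse = ", ")))
  }
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup)) {
    abort(sprintf("%s: duplicated gene_id(s): %s", path,
                  paste(unique(dup), collapse = ", ")))
  }
  genes <- tibble(
    gene_id = df$gene_id,
    genome_id = df$genome_id,
    length = as.integer(df$length),
    roles = split_multi(df$roles),
    subsystems = if ("subsystems" %in% names(df)) split_multi(df$subsystems)
                 else rep(list(character(0)), nrow(df))
  )
  if (any(genes$length < 1)) {
    abort(sprintf("%s: gene length must be >= 1", path))
  }
  genes
}

#' Write a gene annotation table
#'
#' @param genes a gene tibble as returned by [read_gene_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  out <- tibble(
    gene_id = genes$gene_id,
    genome_id = genes$genome_id,
    length = genes$length,
    roles = join_multi(genes$roles),
    subsystems = join_multi(genes$subsystems)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a domain-model catalogue
#'
#' Expects a TSV with columns `cdd_id`, `model_length`, `description`.
#' The returned catalogue carries an `is_full_gene` column initialised to
#' `NA`; it is filled in by [mark_full_gene_cdds()].
#'
#' @param path path to the TSV file.
#' @return A tibble: `cdd_id`, `model_length`, `description`, `is_full_gene`.
#' @export
read_cdd_table <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  require_columns(df, c("cdd_id", "model_length"), path)
  if (any(!grepl("^[0-9]+$", df$model_length))) {
    abort(sprintf("%s: non-integer model_length", path))
  }
  dup <- df$cdd_id[duplicated(df$cdd_id)]
  if (length(dup)) {
    abort(sprintf("%s: duplicated cdd_id(s): %s", path,
                  paste(unique(dup), collapse = ", ")))
  }
  out <- tibble(
    cdd_id = df$cdd_id,
    model_length = as.integer(df$model_length),
    description = if ("description" %in% names(df)) df$description
                  else NA_character_,
    is_full_gene = NA
  )
  if (any(out$model_length < 1)) abort(sprintf("%s: model_length must be >= 1", path))
  out
}

#' @rdname read_cdd_table
#' @param cdds a catalogue tibble.
#' @export
write_cdd_table <- function(cdds, path) {
  readr::write_tsv(cdds[c("cdd_id", "model_length", "description")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a domain-hit table
#'
#' Reads alignments of domain models to genes from a BLAST-tabular-style TSV
#' with header columns `gene_id`, `cdd_id`, `gene_start`, `gene_end`,
#' `cdd_start`, `cdd_end`, `e_value` and optionally `pct_identity`. Columns
#' are located by name, so any column order is accepted. All coordinates are
#' 1-based inclusive; alignment length is always `end - start + 1`.
#'
#' Rows referring to unknown genes or models, or with coordinates exceeding
#' the gene or model length, or with inverted intervals, are dropped with a
#' reported count (real domain scans contain such edge artifacts); negative
#' or non-numeric coordinates are a format error.
#'
#' @param path path to the TSV file.
#' @param genes gene tibble ([read_gene_table()]).
#' @param cdds catalogue tibble ([read_cdd_table()]).
#' @return A tibble of retained hits with an `n_dropped` attribute.
#' @export
read_domain_hits <- function(path, genes, cdds) {
  df <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  require_columns(df, c("gene_id", "cdd_id", "gene_start", "gene_end",
                        "cdd_start", "cdd_end", "e_value"), path)
  num_cols <- c("gene_start", "gene_end", "cdd_start", "cdd_end", "e_value")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (any(is.na(v) & !is.na(df[[cc]]))) {
      abort(sprintf("%s: non-numeric value in column %s", path, cc))
    }
    if (any(v < 0, na.rm = TRUE)) {
      abort(sprintf("%s: negative value in column %s", path, cc))
    }
    df[[cc]] <- v
  }
  hits <- tibble(
    gene_id = df$gene_id,
    cdd_id = df$cdd_id,
    gene_start = as.integer(df$gene_start),
    gene_end = as.integer(df$gene_end),
    cdd_start = as.integer(df$cdd_start),
    cdd_end = as.integer(df$cdd_end),
    e_value = df$e_value,
    pct_identity = if ("pct_identity" %in% names(df))
      suppressWarnings(as.numeric(df$pct_identity)) else NA_real_
  )
  validate_hits(hits, genes, cdds)
}

# Shared invariant screen: returns retained hits with attr n_dropped.
validate_hits <- function(hits, genes, cdds) {
  hits <- hits |>
    left_join(select(genes, "gene_id", gene_length = "length"),
              by = "gene_id") |>
    left_join(select(cdds, "cdd_id", "model_length"), by = "cdd_id")
  ok <- !is.na(hits$gene_length) & !is.na(hits$model_length) &
    hits$gene_start >= 1L & hits$gene_start <= hits$gene_end &
    hits$gene_end <= hits$gene_length &
    hits$cdd_start >= 1L & hits$cdd_start <= hits$cdd_end &
    hits$cdd_end <= hits$model_length
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    inform(sprintf("dropped %d hit(s) failing coordinate or identity checks",
                   n_dropped))
  }
  out <- hits[ok, setdiff(names(hits), c("gene_length", "model_length"))]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' @rdname read_domain_hits
#' @param hits a hit tibble.
#' @export
write_domain_hits <- function(hits, path) {
  readr::write_tsv(as_tibble(hits), path, progress = FALSE)
  invisible(path)
}

#' Read a curated training-set table
#'
#' Expects a TSV with columns `gene_id`, `status` (one of
#' `confirmed_fusion`, `uncertain`, `rejected`) and `source`
#' (semicolon-separated subset of Enright, Serres, IMG, SEED, Bvitamin).
#'
#' @param path path to the TSV file.
#' @param genes optional gene tibble; when given, every training gene must
#'   resolve against it.
#' @return A tibble: `gene_id`, `status`, `source` (list-column).
#' @export
read_training_table <- function(path, genes = NULL) {
  df <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  require_columns(df, c("gene_id", "status", "source"), path)
  statuses <- c("confirmed_fusion", "uncertain", "rejected")
  bad <- setdiff(unique(df$status), statuses)
  if (length(bad)) {
    abort(sprintf("%s: unknown training status(es): %s", path,
                  paste(bad, collapse = ", ")))
  }
  out <- tibble(gene_id = df$gene_id, status = df$status,
                source = split_multi(df$source))
  if (!is.null(genes)) {
    missing <- setdiff(out$gene_id, genes$gene_id)
    if (length(missing)) {
      abort(sprintf("%s: training gene(s) absent from gene table: %s", path,
                    paste(head(missing, 10), collapse = ", ")))
    }
  }
  out
}

#' @rdname read_training_table
#' @param truth a training tibble.
#' @export
write_training_table <- function(truth, path) {
  out <- tibble(gene_id = truth$gene_id, status = truth$status,
                source = join_multi(truth$source))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# Scalar columns a fusion-call table is serialised with, in order.
call_table_columns <- function() {
  c("gene_id", "genome_id", "stage_reached", "n_domains", "cdd_ids",
    "domain_starts", "domain_ends",
    "protein_length", "pass_length",
    "combined_coverage", "pass_coverage",
    "min_aln_length", "pass_aln_length",
    "gap_margin", "pass_gap_position",
    "n_cdd_sets", "pass_distinct_sets",
    "crossing_fraction", "pass_crossing",
    "max_cooccurrence", "pass_promiscuity",
    "max_pair_matches", "pass_pair_similarity",
    "n_criteria_passed", "verdict")
}

#' Write or read a fusion-call table
#'
#' Serialises the result of [call_fusions()] to TSV: one row per gene that
#' passed the naive multi-domain stage, with the selected domain models in
#' N-to-C order, each criterion's measured value and pass flag, and the final
#' verdict. `read_fusion_calls()` restores an identical tibble, so the pair
#' is a lossless round trip.
#'
#' @param calls a fusion-call tibble ([call_fusions()]).
#' @param path file path.
#' @return `write_fusion_calls()` returns `path` invisibly;
#'   `read_fusion_calls()` returns a `fusion_calls` tibble.
#' @export
write_fusion_calls <- function(calls, path) {
  cols <- call_table_columns()
  out <- as_tibble(calls)[, cols]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_fusion_calls
#' @export
read_fusion_calls <- function(path) {
  col_spec <- readr::cols(
    gene_id = "c", genome_id = "c", stage_reached = "c",
    n_domains = "i", cdd_ids = "c", domain_starts = "c", domain_ends = "c",
    protein_length = "i", pass_length = "l",
    combined_coverage = "d", pass_coverage = "l",
    min_aln_length = "i", pass_aln_length = "l",
    gap_margin = "d", pass_gap_position = "l",
    n_cdd_sets = "i", pass_distinct_sets = "l",
    crossing_fraction = "d", pass_crossing = "l",
    max_cooccurrence = "i", pass_promiscuity = "l",
    max_pair_matches = "i", pass_pair_similarity = "l",
    n_criteria_passed = "i", verdict = "l"
  )
  df <- read_tsv_quiet(path, col_types = col_spec)
  require_columns(df, call_table_columns(), path)
  new_fusion_calls(df)
}

#' Read a reaction map
#'
#' The reaction map links functional roles to biochemical reactions and
#' reactions to their metabolites. Expected TSV columns: `role`,
#' `reaction_id`, `metabolite`, `side` (`substrate` or `product`), one row
#' per (role, reaction, metabolite, side).
#'
#' @param path path to the TSV file.
#' @return A list of class `reaction_map` with tibbles `role_reactions`
#'   (`role`, `reaction_id`) and `reaction_parts` (`reaction_id`,
#'   `metabolite`, `side`).
#' @export
read_reaction_map <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  require_columns(df, c("role", "reaction_id", "metabolite", "side"), path)
  bad <- setdiff(unique(df$side), c("substrate", "product"))
  if (length(bad)) {
    abort(sprintf("%s: side must be 'substrate' or 'product', got: %s",
                  path, paste(bad, collapse = ", ")))
  }
  reaction_map(
    role_reactions = distinct(df, .data$role, .data$reaction_id),
    reaction_parts = distinct(df, .data$reaction_id, .data$metabolite,
                              .data$side)
  )
}

#' Build a reaction map from tibbles
#'
#' @param role_reactions tibble with columns `role`, `reaction_id`.
#' @param reaction_parts tibble with columns `reaction_id`, `metabolite`,
#'   `side`.
#' @return A `reaction_map` list.
#' @export
reaction_map <- function(role_reactions, reaction_parts) {
  structure(list(role_reactions = as_tibble(role_reactions),
                 reaction_parts = as_tibble(reaction_parts)),
            class = "reaction_map")
}
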