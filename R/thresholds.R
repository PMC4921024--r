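#' Detection thresholds
#'
#' Bundles every numeric constant of the fusion-detection workflow into a
#' validated list. The defaults are the published operating point of the
#' detector: alignments with E-value below `1e-5` count as hits; a domain
#' model is *full-gene* when a single alignment covers more than 90% of both
#' the model and the gene; selected alignments must cover at least half of
#' their model; and the eight candidate-filter criteria use the 600-residue
#' protein length floor, 40% combined coverage, 50-residue minimum alignment
#' length, gap-position floors of 60 residues and 10% of gene length, the
#' distinct-set requirement, a 0.5 ceiling on the fraction of alignments
#' crossing a gap, and promiscuity ceilings of 1500 co-occurring sets and
#' 1000 pair matches.
#'
#' @param e_value_max hits must have E-value strictly below this (default 1e-5).
#' @param full_gene_coverage fraction of both model and gene a single
#'   alignment must exceed for the model to be flagged full-gene (default 0.90).
#' @param domain_coverage_min minimum fraction of its model a selected
#'   alignment must cover (default 0.50).
#' @param min_protein_length candidate proteins must be strictly longer than
#'   this many residues (default 600).
#' @param combined_coverage_min selected alignments together must cover at
#'   least this fraction of the gene (default 0.40).
#' @param min_alignment_length every selected alignment must span at least
#'   this many residues (default 50).
#' @param min_gap_distance_residues,min_gap_distance_fraction every gap
#'   midpoint must lie at least this many residues *and* this fraction of the
#'   gene length away from both termini (defaults 60 and 0.10).
#' @param max_cooccurring_sets each selected domain model must co-occur with
#'   strictly fewer than this many distinct model sets (default 1500).
#' @param max_pair_matches each selected model pair must have strictly fewer
#'   than this many pair matches (default 1000).
#' @param gap_crossing_fraction_max the fraction of the gene's alignments
#'   crossing a gap must be strictly below this (default 0.5).
#' @param overlap_tolerance residues by which two "non-overlapping"
#'   alignments may still overlap (default 0: strictly disjoint intervals).
#' @param criteria_policy `"all"` requires every criterion to pass;
#'   `"at_least_k"` requires at least `criteria_k` of the eight.
#' @param criteria_k number of criteria required under `"at_least_k"`.
#'
#' @return A named list of class `fusion_thresholds`.
#' @examples
#' t <- fusion_thresholds()
#' t$min_protein_length
#' @export
fusion_thresholds <- function(e_value_max = 1e-5,
                              full_gene_coverage = 0.90,
                              domain_coverage_min = 0.50,
                              min_protein_length = 600L,
                              combined_coverage_min = 0.40,
                              min_alignment_length = 50L,
                              min_gap_distance_residues = 60L,
                              min_gap_distance_fraction = 0.10,
                              max_cooccurring_sets = 1500L,
                              max_pair_matches = 1000L,
                              gap_crossing_fraction_max = 0.5,
                              overlap_tolerance = 0L,
                              criteria_policy = c("all", "at_least_k"),
                              criteria_k = 8L) {
  criteria_policy <- match.arg(criteria_policy)
  t <- list(
    e_value_max = as.numeric(e_value_max),
    full_gene_coverage = as.numeric(full_gene_coverage),
    domain_coverage_min = as.numeric(domain_coverage_min),
    min_protein_length = as.integer(min_protein_length),
    combined_coverage_min = as.numeric(combined_coverage_min),
    min_alignment_length = as.integer(min_alignment_length),
    min_gap_distance_residues = as.integer(min_gap_distance_residues),
    min_gap_distance_fraction = as.numeric(min_gap_distance_fraction),
    max_cooccurring_sets = as.integer(max_cooccurring_sets),
    max_pair_matches = as.integer(max_pair_matches),
    gap_crossing_fraction_max = as.numeric(gap_crossing_fraction_max),
    overlap_tolerance = as.integer(overlap_tolerance),
    criteria_policy = criteria_policy,
    criteria_k = as.integer(criteria_k)
  )
  validate_thresholds(t)
  structure(t, class = "fusion_thresholds")
}

validate_thresholds <- function(t) {
  frac <- c("full_gene_coverage", "domain_coverage_min",
            "combined_coverage_min", "min_gap_distance_fraction",
            "gap_crossing_fraction_max")
  for (f in frac) {
    v <- t[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v > 1) {
      abort(sprintf("threshold `%s` must be a fraction in (0, 1], got %s",
                    f, format(v)))
    }
  }
  counts <- c("min_protein_length", "min_alignment_length",
              "min_gap_distance_residues", "max_cooccurring_sets",
              "max_pair_matches", "overlap_tolerance", "criteria_k")
  for (f in counts) {
    v <- t[[f]]
    if (is.na(v) || v < 0) {
      abort(sprintf("threshold `%s` must be a non-negative count", f))
    }
  }
  if (is.na(t$e_value_max) || t$e_value_max < 0) {
    abort("threshold `e_value_max` must be non-negative")
  }
  invisible(t)
}

#' Read or write a threshold configuration file
#'
#' The configuration is a flat YAML mapping whose keys correspond 1:1 to the
#' arguments of [fusion_thresholds()]. Unknown keys are an error, so a typo
#' in a threshold name cannot silently fall back to a default.
#'
#' @param path file path.
#' @param thresholds a `fusion_thresholds` object.
#' @return `read_fusion_config()` returns a `fusion_thresholds` object;
#'   `write_fusion_config()` returns `path` invisibly.
#' @export
read_fusion_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(fusion_thresholds))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  do.call(fusion_thresholds, vals)
}

#' @rdname read_fusion_config
#' @export
write_fusion_config <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "fusion_thresholds"))
  yaml::write_yaml(unclass(thresholds), path)
  invisible(path)
}

#' @export
print.fusion_thresholds <- function(x, ...) {
  cat("<fusion_thresholds>\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
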