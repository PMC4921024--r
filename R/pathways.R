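role_metabolites <- function(rmap, role, side) {
  rxns <- rmap$role_reactions$reaction_id[rmap$role_reactions$role == role]
  parts <- rmap$reaction_parts
  unique(parts$metabolite[parts$reaction_id %in% rxns &
                            (parts$side == side)])
}

#' Fusions of roles catalyzing adjacent reactions
#'
#' Among final fusion calls whose genes carry two or more functional roles,
#' emits every ordered role pair (A, B) where some product of a reaction of
#' A is a substrate of a reaction of B — i.e. the fused gene joins two
#' neighboring steps of a metabolic pathway — together with the shared
#' metabolites. With `reversible = TRUE` reactions are treated as runnable
#' in either direction, so any metabolite common to the two roles'
#' reactions links them.
#'
#' @param calls a `fusion_calls` tibble.
#' @param genes gene tibble with a `roles` list-column.
#' @param rmap a `reaction_map` ([read_reaction_map()]).
#' @param reversible treat reactions as reversible (default `FALSE`).
#' @return A tibble: `gene_id`, `role_from`, `role_to`, `metabolites`
#'   (comma-joined shared metabolites, non-empty by construction). The
#'   number of role occurrences skipped because the role is absent from the
#'   map is attached as attribute `n_skipped_roles`.
#' @export
adjacent_reaction_fusions <- function(calls, genes, rmap,
                                      reversible = FALSE) {
  fused <- final_fusion_genes(calls)
  gtab <- genes[genes$gene_id %in% fused, c("gene_id", "roles")]
  known_roles <- unique(rmap$role_reactions$role)
  n_skipped <- 0L
  rows <- list()
  for (i in seq_len(nrow(gtab))) {
    roles <- unique(gtab$roles[[i]])
    n_skipped <- n_skipped + sum(!roles %in% known_roles)
    roles <- roles[roles %in% known_roles]
    if (length(roles) < 2) next
    pairs <- combn(roles, 2)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      for (dir in list(c(a, b), c(b, a))) {
        from <- dir[1]; to <- dir[2]
        shared <- if (reversible) {
          intersect(
            c(role_metabolites(rmap, from, "product"),
              role_metabolites(rmap, from, "substrate")),
            c(role_metabolites(rmap, to, "substrate"),
              role_metabolites(rmap, to, "product"))
          )
        } else {
          intersect(role_metabolites(rmap, from, "product"),
                    role_metabolites(rmap, to, "substrate"))
        }
        if (length(shared)) {
          rows[[length(rows) + 1L]] <- tibble(
            gene_id = gtab$gene_id[[i]], role_from = from, role_to = to,
            metabolites = paste(sort(shared), collapse = ",")
          )
        }
      }
    }
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(gene_id = character(), role_from = character(),
           role_to = character(), metabolites = character())
  if (n_skipped > 0) {
    inform(sprintf("%d role occurrence(s) absent from the reaction map",
                   n_skipped))
  }
  attr(out, "n_skipped_roles") <- n_skipped
  out
}

# Architectures (distinct partner-domain sets) of calls containing a model
# mapped to `role` via domain_roles (tibble cdd_id, role).
focus_call_partners <- function(calls, role, domain_roles) {
  focus_cdds <- domain_roles$cdd_id[domain_roles$role == role]
  calls <- as_tibble(calls)
  calls <- calls[calls$stage_reached == "final_fusion" &
                   !is.na(calls$cdd_ids), ]
  partners <- character(0)
  for (arch in calls$cdd_ids) {
    members <- strsplit(arch, ",", fixed = TRUE)[[1]]
    if (any(members %in% focus_cdds)) {
      partners <- c(partners, setdiff(members, focus_cdds))
    }
  }
  unique(partners)
}

#' Variety of fusion architectures a role participates in
#'
#' Counts the distinct binary fusion architectures — unordered (role,
#' partner-domain) pairs, each counted once however many genes carry it —
#' in which a focus role participates, split by partner category
#' (`same_pathway`, `other_metabolism`, `unknown`). Partners without a
#' category assignment fall in `unknown`; the category split always sums to
#' the total.
#'
#' @param calls a `fusion_calls` tibble.
#' @param role the focus functional role.
#' @param domain_roles tibble mapping `cdd_id` to `role` (which domain
#'   models carry which role).
#' @param partner_categories optional tibble `cdd_id`, `category` with
#'   categories among `same_pathway`, `other_metabolism`, `unknown`.
#' @return A one-row tibble: `role`, `variety`, `n_same_pathway`,
#'   `n_other_metabolism`, `n_unknown`.
#' @export
fusion_variety <- function(calls, role, domain_roles,
                           partner_categories = NULL) {
  partners <- focus_call_partners(calls, role, domain_roles)
  if (is.null(partner_categories)) {
    cat_of <- rep("unknown", length(partners))
  } else {
    m <- match(partners, partner_categories$cdd_id)
    cat_of <- ifelse(is.na(m), "unknown", partner_categories$category[m])
  }
  tibble(
    role = role,
    variety = length(partners),
    n_same_pathway = sum(cat_of == "same_pathway"),
    n_other_metabolism = sum(cat_of == "other_metabolism"),
    n_unknown = sum(cat_of == "unknown")
  )
}

#' Frequency with which a role's gene copies are fused
#'
#' Over a genome subset, the fraction of gene copies annotated with the
#' focus role that participate in a final fusion call. Every gene copy
#' counts once in numerator and denominator, so multi-copy genes weigh by
#' copy number. A role with no copies in the subset is reported as absent
#' (`NA`), not 0%.
#'
#' @param calls a `fusion_calls` tibble.
#' @param genes gene tibble.
#' @param role the focus functional role.
#' @param genomes optional character vector of genome ids delimiting the
#'   pool (default: all genomes in `genes`).
#' @return A one-row tibble: `role`, `n_copies`, `n_fused`, `frequency`.
#' @export
fusion_frequency <- function(calls, genes, role, genomes = NULL) {
  if (!is.null(genomes)) genes <- filter(genes, .data$genome_id %in% genomes)
  carriers <- genes[vapply(genes$roles, function(r) role %in% r,
                           logical(1)), ]
  fused <- final_fusion_genes(calls)
  n_copies <- nrow(carriers)
  n_fused <- sum(carriers$gene_id %in% fused)
  tibble(
    role = role,
    n_copies = n_copies,
    n_fused = n_fused,
    frequency = if (n_copies > 0) n_fused / n_copies else NA_real_
  )
}
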