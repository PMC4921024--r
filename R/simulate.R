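#' Synthetic-cohort configuration
#'
#' Parameters of the planted-truth fixture generator. The default cohort —
#' 2 genomes of 500 genes, 10% planted true fusions and 10% of each decoy
#' class, seed 42 — is the reference benchmarking condition used throughout
#' the package's tests. Decoy classes mirror the documented false-positive
#' taxonomy of domain-based fusion detection: multifunctional single-domain
#' proteins, genes hit only by small sub-domain models, and promiscuous
#' modular proteins reusing a small domain pool across many partners.
#'
#' @param n_genomes number of genomes (default 2).
#' @param genes_per_genome genes per genome (default 500).
#' @param fraction_true_fusions fraction of genes planted as true fusions
#'   (default 0.10).
#' @param fraction_multifunctional_single_domain fraction planted as
#'   single-domain proteins with extra overlapping partial alignments
#'   (default 0.10).
#' @param fraction_subdomain_decoys fraction planted with multiple disjoint
#'   alignments to sub-domain models that never reach bidirectional
#'   full-gene coverage anywhere (default 0.10).
#' @param fraction_promiscuous_multidomain fraction planted as short
#'   modular proteins built from the promiscuous pool (default 0.10).
#' @param n_standalone_cdds size of the standalone domain-model pool
#'   (default 60).
#' @param n_subdomain_cdds size of the sub-domain model pool (default 20).
#' @param n_promiscuous_domains size of the promiscuous model pool
#'   (default 8).
#' @param standalone_length_range,subdomain_length_range,promiscuous_length_range
#'   model length bounds (residues) for each pool.
#' @param fraction_triple fraction of planted fusions joining three domains
#'   instead of two (default 0.10).
#' @param coverage_noise_max maximum fraction of a model trimmed from each
#'   alignment end for fusion/decoy hits (default 0.03; 0 disables noise).
#' @param seed RNG seed (default 42).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genomes = 2L,
                       genes_per_genome = 500L,
                       fraction_true_fusions = 0.10,
                       fraction_multifunctional_single_domain = 0.10,
                       fraction_subdomain_decoys = 0.10,
                       fraction_promiscuous_multidomain = 0.10,
                       n_standalone_cdds = 60L,
                       n_subdomain_cdds = 20L,
                       n_promiscuous_domains = 8L,
                       standalone_length_range = c(150L, 450L),
                       subdomain_length_range = c(60L, 100L),
                       promiscuous_length_range = c(110L, 160L),
                       fraction_triple = 0.10,
                       coverage_noise_max = 0.03,
                       seed = 42L) {
  cfg <- list(
    n_genomes = as.integer(n_genomes),
    genes_per_genome = as.integer(genes_per_genome),
    fraction_true_fusions = fraction_true_fusions,
    fraction_multifunctional_single_domain =
      fraction_multifunctional_single_domain,
    fraction_subdomain_decoys = fraction_subdomain_decoys,
    fraction_promiscuous_multidomain = fraction_promiscuous_multidomain,
    n_standalone_cdds = as.integer(n_standalone_cdds),
    n_subdomain_cdds = as.integer(n_subdomain_cdds),
    n_promiscuous_domains = as.integer(n_promiscuous_domains),
    standalone_length_range = as.integer(standalone_length_range),
    subdomain_length_range = as.integer(subdomain_length_range),
    promiscuous_length_range = as.integer(promiscuous_length_range),
    fraction_triple = fraction_triple,
    coverage_noise_max = coverage_noise_max,
    seed = as.integer(seed)
  )
  fracs <- c(cfg$fraction_true_fusions,
             cfg$fraction_multifunctional_single_domain,
             cfg$fraction_subdomain_decoys,
             cfg$fraction_promiscuous_multidomain)
  if (any(fracs < 0) || any(fracs > 1) || sum(fracs) > 1) {
    abort("planted-class fractions must lie in [0,1] and sum to at most 1")
  }
  if (cfg$n_genomes < 1 || cfg$genes_per_genome < 1) {
    abort("cohort must contain at least one genome and one gene")
  }
  if (cfg$coverage_noise_max < 0 || cfg$coverage_noise_max > 0.2) {
    abort("coverage_noise_max must lie in [0, 0.2]")
  }
  structure(cfg, class = "sim_config")
}

rint <- function(n, lo, hi) lo + floor(runif(n) * (hi - lo + 1L))

sample_evalue <- function(n) 10^(-runif(n, 6, 50))

# trim an alignment's two ends by up to noise_max of the model length
trim_alignment <- function(model_len, noise_max) {
  if (noise_max <= 0) return(c(0L, 0L))
  c(floor(runif(1, 0, noise_max) * model_len),
    floor(runif(1, 0, noise_max) * model_len))
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Produces a gene table, domain-model catalogue, domain-hit table and truth
#' table emulating the inputs of the detection pipeline. Planted true
#' fusions carry two (occasionally three) disjoint near-full-model
#' alignments from distinct standalone models with centrally placed gaps,
#' long proteins and high combined coverage, so they satisfy all filter
#' criteria at the default thresholds; every standalone model also aligns
#' full-length to at least one single-domain gene, making it full-gene and
#' giving each fused domain an independent standalone occurrence.
#' Sub-domain decoys carry several disjoint alignments from models that
#' never reach bidirectional full-gene coverage anywhere; multifunctional
#' single-domain genes carry one full-length alignment plus an overlapping
#' partial alignment; promiscuous modular genes pair members of a small
#' promiscuous pool on short (under 600-residue) proteins. All sampling is
#' drawn from a single seeded stream in a fixed order, so output is
#' reproducible byte-for-byte for a fixed seed.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `fusion_cohort`: `genes`, `cdds`, `hits`,
#'   `truth` (tibble `gene_id`, `class`), `config`, and `n_resampled`
#'   (geometry draws rejected and redrawn).
#' @export
simulate_fusion_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_resampled <- 0L

  # --- model catalogue -------------------------------------------------
  sa_ids <- sprintf("scdd%04d", seq_len(cfg$n_standalone_cdds))
  sa_len <- rint(cfg$n_standalone_cdds, cfg$standalone_length_range[1],
                 cfg$standalone_length_range[2])
  sd_ids <- sprintf("dcdd%04d", seq_len(cfg$n_subdomain_cdds))
  sd_len <- rint(cfg$n_subdomain_cdds, cfg$subdomain_length_range[1],
                 cfg$subdomain_length_range[2])
  pr_ids <- sprintf("pcdd%04d", seq_len(cfg$n_promiscuous_domains))
  pr_len <- rint(cfg$n_promiscuous_domains, cfg$promiscuous_length_range[1],
                 cfg$promiscuous_length_range[2])
  cdds <- tibble(
    cdd_id = c(sa_ids, sd_ids, pr_ids),
    model_length = c(sa_len, sd_len, pr_len),
    description = c(sprintf("standalone domain model %d",
                            seq_along(sa_ids)),
                    sprintf("sub-domain model %d", seq_along(sd_ids)),
                    sprintf("promiscuous module model %d",
                            seq_along(pr_ids))),
    is_full_gene = NA
  )
  model_len_of <- stats::setNames(cdds$model_length, cdds$cdd_id)

  # --- class assignment ------------------------------------------------
  n_total <- cfg$n_genomes * cfg$genes_per_genome
  probs <- c(true_fusion = cfg$fraction_true_fusions,
             multifunctional_single_domain =
               cfg$fraction_multifunctional_single_domain,
             subdomain_decoy = cfg$fraction_subdomain_decoys,
             promiscuous_multidomain = cfg$fraction_promiscuous_multidomain)
  probs <- c(probs, single_domain = 1 - sum(probs))
  classes <- sample(names(probs), n_total, replace = TRUE, prob = probs)

  # round-robin parents: the first single-domain genes cycle through every
  # standalone and promiscuous model so each has a clean full-length parent
  parent_cycle <- c(sa_ids, pr_ids)
  single_idx <- which(classes == "single_domain")
  parent_of <- rep(NA_character_, n_total)
  k <- min(length(parent_cycle), length(single_idx))
  if (k > 0) parent_of[single_idx[seq_len(k)]] <- parent_cycle[seq_len(k)]
  fusion_pool <- if (k >= length(sa_ids)) sa_ids else
    sa_ids[seq_len(max(0L, k))]
  if (sum(classes == "true_fusion") > 0 && length(fusion_pool) < 3) {
    abort("cohort too small to give planted fusions standalone parents")
  }

  genome_ids <- sprintf("genome%02d", seq_len(cfg$n_genomes))
  gene_rows <- vector("list", n_total)
  hit_rows <- vector("list", n_total)
  truth_class <- character(n_total)

  fusion_roles <- stats::setNames(
    sprintf("role of %s", c(sa_ids, pr_ids)), c(sa_ids, pr_ids))

  g <- 0L
  for (gi in seq_len(cfg$n_genomes)) {
    for (j in seq_len(cfg$genes_per_genome)) {
      g <- g + 1L
      gene_id <- sprintf("G%02d_%04d", gi, j)
      cls <- classes[g]
      truth_class[g] <- cls
      noise <- cfg$coverage_noise_max

      if (cls == "single_domain") {
        cdd <- if (!is.na(parent_of[g])) parent_of[g] else
          sa_ids[rint(1, 1, length(sa_ids))]
        m <- model_len_of[[cdd]]
        L <- as.integer(round(m * runif(1, 1.00, 1.05)))
        off <- rint(1, 0, L - m)
        hit_rows[[g]] <- tibble(
          gene_id = gene_id, cdd_id = cdd,
          gene_start = off + 1L, gene_end = off + m,
          cdd_start = 1L, cdd_end = m,
          e_value = sample_evalue(1),
          pct_identity = round(runif(1, 55, 95), 1))
        roles <- list(unname(fusion_roles[cdd]) %||% "modular component")
      } else if (cls == "true_fusion") {
        kdom <- if (runif(1) < cfg$fraction_triple) 3L else 2L
        kdom <- min(kdom, length(fusion_pool))
        attempts <- 0L
        repeat {
          members <- fusion_pool[sample.int(length(fusion_pool), kdom)]
          if (sum(model_len_of[members]) >= 540L) break
          n_resampled <- n_resampled + 1L
          attempts <- attempts + 1L
          if (attempts >= 100L) {
            # infeasible pool: take the longest models available
            members <- fusion_pool[order(-model_len_of[fusion_pool])][
              seq_len(kdom)]
            break
          }
        }
        lens <- model_len_of[members]
        lead <- rint(1, 5, 20); tail_ <- rint(1, 5, 20)
        gaps <- rint(kdom - 1L, 70, 120)
        L <- as.integer(lead + sum(lens) + sum(gaps) + tail_)
        pos <- lead
        hr <- vector("list", kdom)
        for (d in seq_len(kdom)) {
          m <- lens[[d]]
          tr <- trim_alignment(m, noise)
          hr[[d]] <- tibble(
            gene_id = gene_id, cdd_id = members[d],
            gene_start = as.integer(pos + 1L + tr[1]),
            gene_end = as.integer(pos + m - tr[2]),
            cdd_start = as.integer(1L + tr[1]),
            cdd_end = as.integer(m - tr[2]),
            e_value = sample_evalue(1),
            pct_identity = round(runif(1, 55, 95), 1))
          pos <- pos + m + if (d < kdom) gaps[d] else 0L
        }
        hit_rows[[g]] <- bind_rows(hr)
        roles <- list(unname(fusion_roles[members]))
      } else if (cls == "multifunctional_single_domain") {
        cdd <- sa_ids[rint(1, 1, length(sa_ids))]
        m <- model_len_of[[cdd]]
        L <- as.integer(round(m * runif(1, 1.00, 1.05)))
        off <- rint(1, 0, L - m)
        main <- tibble(
          gene_id = gene_id, cdd_id = cdd,
          gene_start = off + 1L, gene_end = off + m,
          cdd_start = 1L, cdd_end = m,
          e_value = sample_evalue(1),
          pct_identity = round(runif(1, 55, 95), 1))
        other <- sa_ids[rint(1, 1, length(sa_ids))]
        m2 <- model_len_of[[other]]
        l2 <- min(m2, as.integer(round(0.6 * m)))
        off2 <- off + rint(1, 0, m - l2)
        extra <- tibble(
          gene_id = gene_id, cdd_id = other,
          gene_start = off2 + 1L, gene_end = off2 + l2,
          cdd_start = 1L, cdd_end = l2,
          e_value = sample_evalue(1),
          pct_identity = round(runif(1, 40, 70), 1))
        hit_rows[[g]] <- bind_rows(main, extra)
        roles <- list(paste(unname(fusion_roles[cdd]) %||% "enzyme",
                            "(multifunctional)"))
      } else if (cls == "subdomain_decoy") {
        kdom <- rint(1, 2, 3)
        members <- sd_ids[sample.int(length(sd_ids), kdom)]
        lens <- model_len_of[members]
        lead <- rint(1, 10, 40)
        gaps <- rint(kdom - 1L, 40, 80)
        need <- as.integer(lead + sum(lens) + sum(gaps) + 20L)
        L <- max(rint(1, 450, 900), need)
        pos <- lead
        hr <- vector("list", kdom)
        for (d in seq_len(kdom)) {
          m <- lens[[d]]
          tr <- trim_alignment(m, noise)
          hr[[d]] <- tibble(
            gene_id = gene_id, cdd_id = members[d],
            gene_start = as.integer(pos + 1L + tr[1]),
            gene_end = as.integer(pos + m - tr[2]),
            cdd_start = as.integer(1L + tr[1]),
            cdd_end = as.integer(m - tr[2]),
            e_value = sample_evalue(1),
            pct_identity = round(runif(1, 35, 70), 1))
          pos <- pos + m + if (d < kdom) gaps[d] else 0L
        }
        hit_rows[[g]] <- bind_rows(hr)
        roles <- list("uncharacterized multi-motif protein")
      } else { # promiscuous_multidomain
        hub <- pr_ids[rint(1, 1, length(pr_ids))]
        partner <- pr_ids[pr_ids != hub][rint(1, 1, length(pr_ids) - 1L)]
        members <- c(hub, partner)
        lens <- model_len_of[members]
        lead <- rint(1, 5, 15); tail_ <- rint(1, 5, 15)
        gap <- rint(1, 70, 120)
        L <- as.integer(lead + sum(lens) + gap + tail_ + rint(1, 0, 20))
        pos <- lead
        hr <- vector("list", 2L)
        for (d in 1:2) {
          m <- lens[[d]]
          tr <- trim_alignment(m, noise)
          hr[[d]] <- tibble(
            gene_id = gene_id, cdd_id = members[d],
            gene_start = as.integer(pos + 1L + tr[1]),
            gene_end = as.integer(pos + m - tr[2]),
            cdd_start = as.integer(1L + tr[1]),
            cdd_end = as.integer(m - tr[2]),
            e_value = sample_evalue(1),
            pct_identity = round(runif(1, 45, 85), 1))
          pos <- pos + m + if (d == 1) gap else 0L
        }
        hit_rows[[g]] <- bind_rows(hr)
        roles <- list(c("signal transduction module",
                        "ligand recognition module"))
      }

      gene_rows[[g]] <- tibble(
        gene_id = gene_id, genome_id = genome_ids[gi],
        length = as.integer(L), roles = roles,
        subsystems = list(character(0)))
    }
  }

  genes <- bind_rows(gene_rows)
  hits <- bind_rows(hit_rows)
  truth <- tibble(gene_id = genes$gene_id, class = truth_class)
  structure(list(genes = genes, cdds = cdds, hits = hits, truth = truth,
                 config = cfg, n_resampled = n_resampled),
            class = "fusion_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits the cohort in the pipeline's on-disk formats: `genes.tsv`,
#' `cdds.tsv`, `hits.tsv`, `truth.tsv`, and optionally a dummy protein
#' FASTA (random residues of the right lengths; no sequence-level realism).
#'
#' @param cohort a `fusion_cohort`.
#' @param dir output directory (created if needed).
#' @param fasta also write `proteins.fasta` (requires the Biostrings
#'   package; default `FALSE`).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir, fasta = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_table(cohort$genes, file.path(dir, "genes.tsv"))
  write_cdd_table(cohort$cdds, file.path(dir, "cdds.tsv"))
  write_domain_hits(cohort$hits, file.path(dir, "hits.tsv"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"),
                   progress = FALSE)
  if (isTRUE(fasta)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("writing FASTA requires the Biostrings package")
    }
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    seqs <- vapply(cohort$genes$length, function(L) {
      paste(sample(aas, L, replace = TRUE), collapse = "")
    }, character(1))
    x <- Biostrings::AAStringSet(stats::setNames(seqs,
                                                 cohort$genes$gene_id))
    Biostrings::writeXStringSet(x, file.path(dir, "proteins.fasta"))
  }
  invisible(dir)
}

#' Score pipeline calls against planted truth
#'
#' @param calls a `fusion_calls` tibble produced on a generated cohort.
#' @param truth the cohort's truth tibble (`gene_id`, `class`).
#' @return A one-row tibble: `n_planted`, `n_called`, `n_true_called`,
#'   `recall` (called planted fusions / planted fusions) and `precision`
#'   (called planted fusions / all final calls; `NaN` when nothing is
#'   called), plus `per_class`, a tibble of final-call counts per planted
#'   class, as an attribute.
#' @export
score_recovery <- function(calls, truth) {
  final <- final_fusion_genes(calls)
  planted <- truth$gene_id[truth$class == "true_fusion"]
  n_true_called <- sum(planted %in% final)
  per_class <- truth |>
    mutate(called = .data$gene_id %in% final) |>
    group_by(.data$class) |>
    summarise(n_planted = n(), n_called = sum(.data$called),
              .groups = "drop")
  out <- tibble(
    n_planted = length(planted),
    n_called = length(final),
    n_true_called = n_true_called,
    recall = if (length(planted) > 0) n_true_called / length(planted)
             else NA_real_,
    precision = n_true_called / length(final)
  )
  attr(out, "per_class") <- per_class
  out
}

#' @export
glance.fusion_cohort <- function(x, ...) {
  counts <- table(factor(x$truth$class,
                         levels = c("true_fusion",
                                    "multifunctional_single_domain",
                                    "subdomain_decoy",
                                    "promiscuous_multidomain",
                                    "single_domain")))
  bind_cols(tibble(n_genes = nrow(x$genes), n_cdds = nrow(x$cdds),
                   n_hits = nrow(x$hits)),
            as_tibble(as.list(counts)))
}

#' @export
print.fusion_cohort <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<fusion_cohort> %d genes, %d models, %d hits (%d planted fusions)\n",
    g$n_genes, g$n_cdds, g$n_hits, g$true_fusion))
  invisible(x)
}
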