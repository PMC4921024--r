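# Shared in-code fixtures and independent brute-force oracles.

toy_path <- function(file) {
  system.file("extdata", file, package = "fusionscan", mustWork = TRUE)
}

toy_dataset <- function() {
  genes <- read_gene_table(toy_path("toy_genes.tsv"))
  cdds <- read_cdd_table(toy_path("toy_cdds.tsv"))
  hits <- suppressMessages(
    read_domain_hits(toy_path("toy_hits.tsv"), genes, cdds))
  list(genes = genes, cdds = cdds, hits = hits)
}

make_genes <- function(ids, lengths, genome = "gA", roles = NULL) {
  tibble::tibble(
    gene_id = ids,
    genome_id = rep_len(genome, length(ids)),
    length = as.integer(lengths),
    roles = roles %||% rep(list(character(0)), length(ids)),
    subsystems = rep(list(character(0)), length(ids))
  )
}

make_cdds <- function(ids, lengths) {
  tibble::tibble(cdd_id = ids, model_length = as.integer(lengths),
                 description = ids, is_full_gene = NA)
}

make_hit <- function(gene_id, cdd_id, gene_start, gene_end,
                     cdd_start = 1L, cdd_end = gene_end - gene_start + 1L,
                     e_value = 1e-20, pct_identity = 75) {
  tibble::tibble(gene_id = gene_id, cdd_id = cdd_id,
                 gene_start = as.integer(gene_start),
                 gene_end = as.integer(gene_end),
                 cdd_start = as.integer(cdd_start),
                 cdd_end = as.integer(cdd_end),
                 e_value = e_value, pct_identity = pct_identity)
}

# random hits for one gene; intervals within [1, gene_len]
random_gene_hits <- function(n, gene_len, cdd_ids, gene_id = "g1") {
  starts <- sample.int(gene_len - 30L, n, replace = TRUE)
  lens <- sample(20:200, n, replace = TRUE)
  ends <- pmin(gene_len, starts + lens)
  tibble::tibble(
    gene_id = gene_id,
    cdd_id = sample(cdd_ids, n, replace = TRUE),
    gene_start = as.integer(starts), gene_end = as.integer(ends),
    cdd_start = 1L, cdd_end = as.integer(ends - starts + 1L),
    e_value = 10^-runif(n, 6, 40), pct_identity = round(runif(n, 40, 95), 1)
  )
}

# comparison helper: drop classes and bookkeeping attributes
plain <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "class", "row.names")]
  x
}

# ---- oracles --------------------------------------------------------------

# exhaustive maximum set of pairwise disjoint intervals (n <= ~15)
oracle_max_disjoint <- function(starts, ends, tol = 0L) {
  n <- length(starts)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) <= best) next
    ok <- TRUE
    if (length(idx) > 1) {
      ord <- idx[order(starts[idx], ends[idx])]
      for (k in 2:length(ord)) {
        if (!(starts[ord[k]] > ends[ord[k - 1]] - tol)) { ok <- FALSE; break }
      }
    }
    if (ok) best <- length(idx)
  }
  best
}

# brute-force single-linkage components over a similarity matrix
oracle_components <- function(sim, threshold) {
  n <- nrow(sim)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && sim[i, j] >= threshold && comp[i] != comp[j]) {
        old <- comp[j]; comp[comp == old] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# brute-force pairwise footprint similarity between two cdds
oracle_cdd_similarity <- function(hits, a, b, jaccard_min = 0.8) {
  ga <- unique(hits$gene_id[hits$cdd_id == a])
  gb <- unique(hits$gene_id[hits$cdd_id == b])
  if (length(ga) + length(gb) == 0) return(0)
  shared <- 0L
  for (g in intersect(ga, gb)) {
    ha <- hits[hits$cdd_id == a & hits$gene_id == g, ]
    hb <- hits[hits$cdd_id == b & hits$gene_id == g, ]
    match_found <- FALSE
    for (i in seq_len(nrow(ha))) for (j in seq_len(nrow(hb))) {
      inter <- max(0, min(ha$gene_end[i], hb$gene_end[j]) -
                     max(ha$gene_start[i], hb$gene_start[j]) + 1)
      uni <- (ha$gene_end[i] - ha$gene_start[i] + 1) +
        (hb$gene_end[j] - hb$gene_start[j] + 1) - inter
      if (inter / uni >= jaccard_min) match_found <- TRUE
    }
    if (match_found) shared <- shared + 1L
  }
  shared / length(union(ga, gb))
}

# brute-force co-occurring-set count for one cdd
oracle_cooccurrence <- function(hits, sets, cdd) {
  own <- sets$set_id[sets$cdd_id == cdd]
  my_genes <- unique(hits$gene_id[hits$cdd_id == cdd])
  seen <- character(0)
  for (g in my_genes) {
    cdds_on_g <- unique(hits$cdd_id[hits$gene_id == g])
    seen <- union(seen, sets$set_id[sets$cdd_id %in% cdds_on_g])
  }
  length(setdiff(seen, own))
}

# brute-force full-gene flag per cdd
oracle_full_gene <- function(hits, genes, cdds, coverage) {
  flags <- logical(nrow(cdds))
  names(flags) <- cdds$cdd_id
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    gl <- genes$length[genes$gene_id == h$gene_id]
    ml <- cdds$model_length[cdds$cdd_id == h$cdd_id]
    mc <- (h$cdd_end - h$cdd_start + 1) / ml
    gc <- (h$gene_end - h$gene_start + 1) / gl
    if (mc > coverage && gc > coverage) flags[h$cdd_id] <- TRUE
  }
  flags
}
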