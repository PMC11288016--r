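#' Classify genes as microbe-unique markers
#'
#' A gene is `unique` when its only surviving alignment is its self-hit.
#' A gene whose surviving hits include a different gene of the same genome
#' is `multi_copy` (duplicated genes are never primer candidates, since they
#' would skew copy-number quantification); a gene hitting any other genome
#' is `non_unique`. Classification is independent of hit-row order and of
#' input file order.
#'
#' @param hits Surviving hit data.frame (must include self-hits).
#' @param catalog A [CommunityCatalog-class] consistent with the hit ids.
#' @return A list with `calls` (data.frame: `gene_id`, `genome_id`,
#'   `status`, `n_cross_hits`, `n_paralog_hits`, `evidence` comma-separated
#'   `other|fident|qcov` triples) and `summary` (per target genome:
#'   `genome_id`, `n_unique`, `n_total`, `fraction_unique`, sorted by
#'   descending `n_unique` -- the ordering used by the unique-genes bar
#'   plot).
#' @export
classifyUnique <- function(hits, catalog) {
  stopifnot(is(catalog, "CommunityCatalog"))
  ids <- geneIds(catalog)
  unknown <- setdiff(unique(c(hits$query, hits$target)), ids)
  if (length(unknown))
    cpStop("hit table references unknown gene '%s'", unknown[1])
  gd <- catalog@geneData
  genome <- structure(as.character(gd$genome_id), names = ids)

  cross <- hits[hits$query != hits$target, , drop = FALSE]
  qg <- genome[cross$query]
  tg <- genome[cross$target]
  other_genome <- cross[qg != tg, , drop = FALSE]
  paralog <- cross[qg == tg, , drop = FALSE]

  n_cross <- table(factor(other_genome$query, levels = ids))
  n_para <- table(factor(paralog$query, levels = ids))
  status <- ifelse(n_cross > 0, "non_unique",
                   ifelse(n_para > 0, "multi_copy", "unique"))

  ev <- character(length(ids)); names(ev) <- ids
  if (nrow(cross)) {
    ev_str <- sprintf("%s|%.4f|%.4f", cross$target, cross$fident, cross$qcov)
    agg <- vapply(split(ev_str, factor(cross$query, levels = ids)),
                  paste, character(1), collapse = ",")
    ev[names(agg)] <- agg
  }

  calls <- data.frame(
    gene_id = ids, genome_id = unname(genome[ids]),
    status = unname(status[ids]),
    n_cross_hits = as.integer(n_cross[ids]),
    n_paralog_hits = as.integer(n_para[ids]),
    evidence = unname(ev[ids]), stringsAsFactors = FALSE
  )

  tg_ids <- targetGenomes(catalog)
  per <- lapply(tg_ids, function(g) {
    sub <- calls[calls$genome_id == g, , drop = FALSE]
    data.frame(genome_id = g, n_unique = sum(sub$status == "unique"),
               n_total = nrow(sub),
               fraction_unique = sum(sub$status == "unique") / nrow(sub),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, per)
  summary <- summary[order(-summary$n_unique, summary$genome_id,
                           method = "radix"), , drop = FALSE]
  rownames(summary) <- NULL
  list(calls = calls, summary = summary)
}

#' Classify genes as group-shared markers
#'
#' A gene of a group genome is `group_shared` when (a) it has at least one
#' surviving hit into every other genome of the group and (b) it has no
#' surviving hit to any genome outside the group (targets or non-targets).
#' Genes with outside-group hits are `excluded_ambiguous`; genes missing
#' from some group member are `non_unique`. Only hits from the gene itself
#' are consulted (no transitive partner-of-partner chaining), so the check
#' is per-gene and deterministic.
#'
#' @param hits Surviving hit data.frame (including self-hits).
#' @param catalog A [CommunityCatalog-class].
#' @param group Character vector of at least two target genome ids.
#' @return data.frame with `gene_id`, `genome_id`, `status`,
#'   `group_members_hit` (comma-separated genomes of the group covered,
#'   including the gene's own) and `n_outside_hits`, for every gene of a
#'   group genome.
#' @export
classifyGroup <- function(hits, catalog, group) {
  stopifnot(is(catalog, "CommunityCatalog"))
  tg <- targetGenomes(catalog)
  if (length(group) < 2L)
    cpStop("group mode needs at least two genomes (use unique mode for one)")
  unknown <- setdiff(group, tg)
  if (length(unknown))
    cpStop("group names unknown or non-target genome '%s'", unknown[1])
  ids <- geneIds(catalog)
  bad <- setdiff(unique(c(hits$query, hits$target)), ids)
  if (length(bad))
    cpStop("hit table references unknown gene '%s'", bad[1])
  genome <- structure(as.character(catalog@geneData$genome_id), names = ids)

  g_ids <- ids[genome[ids] %in% group]
  hg <- hits[hits$query %in% g_ids, , drop = FALSE]
  hit_genome <- genome[hg$target]

  calls <- lapply(g_ids, function(g) {
    own <- genome[[g]]
    th <- hit_genome[hg$query == g]
    covered <- union(own, intersect(unique(th), group))
    outside <- setdiff(unique(th), group)
    status <- if (length(outside)) "excluded_ambiguous"
      else if (setequal(covered, group)) "group_shared"
      else "non_unique"
    data.frame(gene_id = g, genome_id = own, status = status,
               group_members_hit = paste(sort(covered), collapse = ","),
               n_outside_hits = sum(th %in% outside),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Rank eligible marker genes for primer design
#'
#' Candidate genes are ordered by decreasing sequence length (longer genes
#' offer more primer placements), ties broken lexicographically by gene id.
#' Genes with more than `max_frac_n` ambiguous bases are dropped: ambiguity
#' codes break the thermodynamic model.
#'
#' @param calls Call data.frame from [classifyUnique()] or
#'   [classifyGroup()].
#' @param catalog A [CommunityCatalog-class].
#' @param eligible_status Status value(s) marking candidates
#'   (default `"unique"`; use `"group_shared"` for group mode).
#' @param max_frac_n Maximum tolerated fraction of N bases (default 0.05).
#' @return Named list over genomes (unique mode) or a single `group`
#'   element (group mode) of gene-id vectors in design order.
#' @export
rankCandidates <- function(calls, catalog, eligible_status = "unique",
                           max_frac_n = 0.05) {
  stopifnot(is(catalog, "CommunityCatalog"))
  gd <- catalog@geneData
  frac_n <- structure(gd$frac_n, names = as.character(gd$gene_id))
  len <- structure(gd$length, names = as.character(gd$gene_id))
  elig <- calls[calls$status %in% eligible_status &
                frac_n[calls$gene_id] <= max_frac_n, , drop = FALSE]
  ordGenes <- function(g) {
    g[order(-len[g], g, method = "radix")]
  }
  if (identical(eligible_status, "group_shared")) {
    return(list(group = ordGenes(elig$gene_id)))
  }
  res <- lapply(targetGenomes(catalog), function(g)
    ordGenes(elig$gene_id[elig$genome_id == g]))
  names(res) <- targetGenomes(catalog)
  res
}

#' Write the per-genome unique-gene summary TSV
#'
#' Backing data of the unique-genes bar plot: unique vs total gene counts
#' per target genome, sorted by descending unique count.
#'
#' @param summary Summary data.frame from [classifyUnique()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeUniqueGeneSummary <- function(summary, path) {
  df <- summary
  df$n_non_unique <- df$n_total - df$n_unique
  df$fraction_unique <- formatNum(df$fraction_unique, 4L)
  writeTsv(df[c("genome_id", "n_unique", "n_non_unique", "n_total",
                "fraction_unique")], path)
}
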