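#' @describeIn CommunityCatalog-class Community-unique gene identifiers.
#' @export
setMethod("geneIds", "CommunityCatalog", function(x)
  as.character(x@geneData$gene_id))

#' @describeIn CommunityCatalog-class Genome identifiers (sorted).
#' @export
setMethod("genomeIds", "CommunityCatalog", function(x) x@genomes)

#' @describeIn CommunityCatalog-class Genomes with role `target`.
#' @export
setMethod("targetGenomes", "CommunityCatalog", function(x) {
  gd <- x@geneData
  sort(unique(as.character(gd$genome_id[gd$role == "target"])))
})

#' @describeIn CommunityCatalog-class Genomes with role `nontarget`.
#' @export
setMethod("nontargetGenomes", "CommunityCatalog", function(x) {
  gd <- x@geneData
  sort(unique(as.character(gd$genome_id[gd$role == "nontarget"])))
})

#' @describeIn CommunityCatalog-class The CDS sequences (named DNAStringSet).
#' @export
setMethod("cdsSeqs", "CommunityCatalog", function(x) x@sequences)

#' @describeIn CommunityCatalog-class Per-gene metadata DataFrame.
#' @export
setMethod("geneData", "CommunityCatalog", function(x) x@geneData)

#' @describeIn CommunityCatalog-class Number of genes, or per-genome counts
#'   as a named vector when `byGenome = TRUE`.
#' @param byGenome Return per-genome counts instead of the total.
#' @export
setMethod("nGenes", "CommunityCatalog", function(x) length(x@sequences))

#' Per-genome gene counts
#' @param x A `CommunityCatalog`.
#' @return Named integer vector over genomes.
#' @export
genesByGenome <- function(x) {
  stopifnot(is(x, "CommunityCatalog"))
  tab <- table(factor(as.character(x@geneData$genome_id), levels = x@genomes))
  ids <- split(as.character(x@geneData$gene_id),
               factor(as.character(x@geneData$genome_id), levels = x@genomes))
  structure(as.integer(tab), names = x@genomes, ids = ids)
}

setMethod("show", "CommunityCatalog", function(object) {
  nt <- length(targetGenomes(object))
  nn <- length(nontargetGenomes(object))
  cat(sprintf("CommunityCatalog: %d genomes (%d target, %d non-target), %d CDSs\n",
              length(object@genomes), nt, nn, length(object@sequences)))
  cnt <- genesByGenome(object)
  shown <- utils::head(object@genomes, 8L)
  for (g in shown)
    cat(sprintf("  %-30s %5d genes [%s]\n", g, cnt[[g]],
                object@geneData$role[match(g, object@geneData$genome_id)]))
  if (length(object@genomes) > 8L)
    cat(sprintf("  ... and %d more genomes\n", length(object@genomes) - 8L))
  invisible(NULL)
})

setMethod("show", "StringencyParams", function(object) {
  cat(sprintf(paste0("StringencyParams: min_identity=%.3g min_aln_len=%g ",
                     "min_coverage=%.3g cov_mode=%s\n"),
              object@min_identity, object@min_aln_len, object@min_coverage,
              object@cov_mode))
  invisible(NULL)
})

setMethod("show", "DesignParams", function(object) {
  cat(sprintf("DesignParams: product %g-%g bp, primer %g/%g/%g nt, Tm %g/%g/%g C (pair dTm <= %g), GC %g/%g/%g%%, n_return=%g\n",
              object@product_min, object@product_max,
              object@primer_len_min, object@primer_len_opt,
              object@primer_len_max,
              object@tm_min, object@tm_opt, object@tm_max,
              object@max_pair_tm_diff,
              object@gc_min, object@gc_opt, object@gc_max, object@n_return))
  invisible(NULL)
})

#' Construct stringency parameters
#'
#' @param min_identity Minimum fraction identity for a hit to survive
#'   (default 0.3, the screen's default identity threshold).
#' @param min_aln_len Minimum alignment length in columns (default 0).
#' @param min_coverage Minimum aligned fraction of gene length (default 0).
#' @param cov_mode One of `"both"`, `"either"`, `"query"`, `"target"`.
#' @return A validated [StringencyParams-class] object.
#' @examples
#' stringencyParams(min_identity = 0.9)
#' @export
stringencyParams <- function(min_identity = 0.3, min_aln_len = 0,
                             min_coverage = 0, cov_mode = "both") {
  new("StringencyParams", min_identity = min_identity,
      min_aln_len = min_aln_len, min_coverage = min_coverage,
      cov_mode = cov_mode)
}

#' Construct thermodynamic conditions
#'
#' @param monovalent_mM,divalent_mM,dntp_mM,oligo_nM See
#'   [ThermoConditions-class].
#' @return A validated [ThermoConditions-class] object.
#' @export
thermoConditions <- function(monovalent_mM = 50, divalent_mM = 1.5,
                             dntp_mM = 0.6, oligo_nM = 250) {
  new("ThermoConditions", monovalent_mM = monovalent_mM,
      divalent_mM = divalent_mM, dntp_mM = dntp_mM, oligo_nM = oligo_nM)
}

#' Construct primer design parameters
#'
#' Defaults mirror common qPCR/ddPCR amplicon design: a 125-175 bp product,
#' 18-27 nt primers with 20 nt optimum, a 62 C optimal Tm with min/max at
#' opt -/+ 3, and at most 1.5 C Tm difference within a pair.
#'
#' @param product_min,product_max Amplicon size bounds in bp (125 / 175).
#' @param primer_len_min,primer_len_opt,primer_len_max Primer length in nt.
#' @param tm_opt Optimal melting temperature (deg C, default 62).
#' @param tm_min,tm_max Hard Tm bounds; default `tm_opt - 3` / `tm_opt + 3`.
#' @param max_pair_tm_diff Maximum |Tm difference| within a pair (1.5).
#' @param gc_min,gc_opt,gc_max GC bounds in percent (30 / 50 / 70).
#' @param max_polyx Longest allowed mononucleotide run (5).
#' @param n_return Pairs returned per target (5).
#' @param w_tm,w_size,w_gc,w_pair_diff Penalty weights (all 1).
#' @param max_self_any,max_self_end,max_hairpin Complementarity caps
#'   (8 / 3 / 8).
#' @param gc_clamp Require a G/C among the two 3'-terminal bases (TRUE).
#' @param conditions A [ThermoConditions-class] object.
#' @return A validated [DesignParams-class] object.
#' @examples
#' designParams(tm_opt = 60)
#' @export
designParams <- function(product_min = 125, product_max = 175,
                         primer_len_min = 18, primer_len_opt = 20,
                         primer_len_max = 27,
                         tm_opt = 62, tm_min = tm_opt - 3, tm_max = tm_opt + 3,
                         max_pair_tm_diff = 1.5,
                         gc_min = 30, gc_opt = 50, gc_max = 70,
                         max_polyx = 5, n_return = 5,
                         w_tm = 1, w_size = 1, w_gc = 1, w_pair_diff = 1,
                         max_self_any = 8, max_self_end = 3, max_hairpin = 8,
                         gc_clamp = TRUE,
                         conditions = thermoConditions()) {
  new("DesignParams",
      product_min = product_min, product_max = product_max,
      primer_len_min = primer_len_min, primer_len_opt = primer_len_opt,
      primer_len_max = primer_len_max,
      tm_min = tm_min, tm_opt = tm_opt, tm_max = tm_max,
      max_pair_tm_diff = max_pair_tm_diff,
      gc_min = gc_min, gc_opt = gc_opt, gc_max = gc_max,
      max_polyx = max_polyx, n_return = n_return,
      w_tm = w_tm, w_size = w_size, w_gc = w_gc, w_pair_diff = w_pair_diff,
      max_self_any = max_self_any, max_self_end = max_self_end,
      max_hairpin = max_hairpin, gc_clamp = gc_clamp,
      conditions = conditions)
}
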