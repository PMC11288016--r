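AVOGADRO <- 6.0221e23   # molecules per mole, as conventionally rounded
BP_MW <- 660            # g per mole per base pair of double-stranded DNA

#' Genomic copies per microliter from a gDNA concentration
#'
#' `copies/uL = X * 6.0221e23 / (N * 660) * 1e-9`, where `X` is the DNA
#' concentration in ng/uL and `N` the genome size in bp; the `1e-9` factor
#' converts nanograms to grams so the units cancel to molecules per
#' microliter.
#'
#' @param conc_ng_per_ul DNA concentration(s), ng/uL (>= 0).
#' @param genome_size_bp Genome size(s), bp (>= 1).
#' @return Genomic copies per microliter.
#' @examples
#' genomicCopies(1, 1e6)   # 912439.4
#' @export
genomicCopies <- function(conc_ng_per_ul, genome_size_bp) {
  if (any(conc_ng_per_ul < 0) || any(is.na(conc_ng_per_ul)))
    cpStop("concentration must be non-negative")
  if (any(genome_size_bp < 1) || any(is.na(genome_size_bp)))
    cpStop("genome size must be >= 1 bp")
  conc_ng_per_ul * AVOGADRO / (genome_size_bp * BP_MW) * 1e-9
}

#' Per-sample volumes for an equal-genomic-copy pool
#'
#' Volumes inversely proportional to each sample's copies/uL, scaled to the
#' total pool volume, so every member contributes the same number of
#' genomic copies.
#'
#' @param copies_per_ul Positive copies/uL per sample (named vector).
#' @param total_volume Total pool volume (same unit as the output).
#' @return Volumes summing to `total_volume`.
#' @examples
#' equalCopyPool(c(a = 2e6, b = 1e6), 30)   # 10 and 20
#' @export
equalCopyPool <- function(copies_per_ul, total_volume) {
  if (any(is.na(copies_per_ul)) || any(copies_per_ul <= 0))
    cpStop("equal-copy pooling is infeasible with zero-copy members")
  if (total_volume <= 0) cpStop("total volume must be positive")
  w <- 1 / copies_per_ul
  w / sum(w) * total_volume
}

#' Absolute counts to relative abundance
#'
#' Divides each member's copies/uL by the community total. Members named in
#' `drop` (e.g. one without a specific primer pair) are excluded from both
#' numerator and denominator, so the remaining fractions still sum to one.
#'
#' @param counts Named non-negative vector of copies/uL.
#' @param drop Optional member names to exclude.
#' @return Named fractions summing to 1.
#' @examples
#' absoluteToRelative(c(a = 100, b = 300))
#' @export
absoluteToRelative <- function(counts, drop = NULL) {
  if (!is.null(drop)) counts <- counts[setdiff(names(counts), drop)]
  if (any(is.na(counts)) || any(counts < 0))
    cpStop("counts must be non-negative")
  if (length(counts) == 0L || sum(counts) == 0)
    cpStop("composition undefined: no positive counts remain")
  counts / sum(counts)
}

#' Copy-number worksheet for a community pool
#'
#' Convenience wrapper: from per-sample concentration and genome size,
#' computes copies/uL, equal-copy pooling volumes and the relative
#' abundance the pool would have.
#'
#' @param samples data.frame with `sample_id`, `conc_ng_per_ul`,
#'   `genome_size_bp`.
#' @param total_volume Pool volume (default 30).
#' @return Input data.frame extended with `copies_per_ul`, `pool_volume`,
#'   `relative_abundance`.
#' @export
quantTable <- function(samples, total_volume = 30) {
  need <- c("sample_id", "conc_ng_per_ul", "genome_size_bp")
  if (!all(need %in% colnames(samples)))
    cpStop("samples must have columns: %s", paste(need, collapse = ", "))
  cp <- genomicCopies(samples$conc_ng_per_ul, samples$genome_size_bp)
  names(cp) <- samples$sample_id
  out <- samples
  out$copies_per_ul <- unname(cp)
  out$pool_volume <- unname(equalCopyPool(cp, total_volume))
  out$relative_abundance <- unname(absoluteToRelative(cp))
  out
}
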