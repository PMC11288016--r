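#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement DNAString
#' @useDynLib CommunityPrimers, .registration = TRUE
NULL

#' Community CDS catalog
#'
#' Holds every coding sequence of a defined microbial community, one
#' community-unique gene identifier per CDS, together with per-gene metadata
#' (source genome, header dialect, target/non-target role, fraction of
#' ambiguous bases).
#'
#' @slot sequences A [Biostrings::DNAStringSet] named by `gene_id`
#'   (`"<genome_id>|<original header token>"`).
#' @slot geneData A [S4Vectors::DataFrame] with one row per gene: `gene_id`,
#'   `genome_id`, `length`, `dialect` (`prokka`, `rast` or `ncbi`), `role`
#'   (`target` or `nontarget`) and `frac_n` (fraction of non-ACGT bases).
#' @slot genomes Character vector of genome identifiers, lexicographically
#'   ordered.
#' @slot files Named character vector mapping each genome to its source file.
#'
#' @seealso [buildCatalog()], [readCdsFasta()]
#' @export
setClass("CommunityCatalog",
  slots = c(
    sequences = "DNAStringSet",
    geneData  = "DataFrame",
    genomes   = "character",
    files     = "character"
  )
)

setValidity("CommunityCatalog", function(object) {
  gd <- object@geneData
  msg <- character()
  need <- c("gene_id", "genome_id", "length", "dialect", "role", "frac_n")
  if (!all(need %in% colnames(gd)))
    return(paste("geneData must have columns:", paste(need, collapse = ", ")))
  if (length(object@sequences) != nrow(gd))
    msg <- c(msg, "sequences and geneData disagree in length")
  if (anyDuplicated(gd$gene_id))
    msg <- c(msg, "gene_id values must be unique across the community")
  if (!identical(names(object@sequences), as.character(gd$gene_id)))
    msg <- c(msg, "sequence names must equal geneData$gene_id")
  if (length(object@sequences) &&
      !all(gd$length == Biostrings::width(object@sequences)))
    msg <- c(msg, "geneData$length must match sequence widths")
  if (!all(gd$genome_id %in% object@genomes))
    msg <- c(msg, "every gene must belong to a catalog genome")
  if (!all(gd$role %in% c("target", "nontarget")))
    msg <- c(msg, "role must be 'target' or 'nontarget'")
  if (is.unsorted(object@genomes))
    msg <- c(msg, "genomes must be lexicographically sorted")
  roles <- split(as.character(gd$role), as.character(gd$genome_id))
  if (any(vapply(roles, function(r) length(unique(r)) > 1L, logical(1))))
    msg <- c(msg, "a genome cannot be both target and nontarget")
  if (length(msg)) msg else TRUE
})

#' Stringency parameters for the homology screen
#'
#' Thresholds applied to reported all-vs-all alignments before marker
#' classification. Raising any of them discards hits and therefore can only
#' enlarge the set of genes called unique.
#'
#' @slot min_identity Minimum fraction identity (matches / alignment
#'   columns) in `[0, 1]`; default 0.3.
#' @slot min_aln_len Minimum alignment length in columns; default 0.
#' @slot min_coverage Minimum aligned fraction of gene length in `[0, 1]`;
#'   default 0.
#' @slot cov_mode Which side(s) must satisfy `min_coverage`: `"both"`
#'   (min of query and target coverage), `"either"` (max), `"query"` or
#'   `"target"`; default `"both"`.
#'
#' @seealso [stringencyParams()], [allVsAll()], [filterHits()]
#' @export
setClass("StringencyParams",
  slots = c(
    min_identity = "numeric",
    min_aln_len  = "numeric",
    min_coverage = "numeric",
    cov_mode     = "character"
  ),
  prototype = prototype(
    min_identity = 0.3, min_aln_len = 0, min_coverage = 0, cov_mode = "both"
  )
)

setValidity("StringencyParams", function(object) {
  msg <- character()
  for (s in c("min_identity", "min_coverage")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must be a single value in [0, 1]", s))
  }
  if (length(object@min_aln_len) != 1L || object@min_aln_len < 0)
    msg <- c(msg, "min_aln_len must be a single non-negative value")
  if (!object@cov_mode %in% c("both", "either", "query", "target"))
    msg <- c(msg, "cov_mode must be one of both/either/query/target")
  if (length(msg)) msg else TRUE
})

#' Thermodynamic reaction conditions
#'
#' Ionic and oligo concentrations entering the nearest-neighbor melting
#' temperature model. Defaults are the conventional PCR-buffer values used by
#' Primer3.
#'
#' @slot monovalent_mM Monovalent cation concentration (mM), default 50.
#' @slot divalent_mM Divalent (Mg2+) concentration (mM), default 1.5.
#' @slot dntp_mM Total dNTP concentration (mM, chelates Mg2+), default 0.6.
#' @slot oligo_nM Primer concentration (nM), default 250.
#'
#' @seealso [thermoConditions()], [meltingTemperature()]
#' @export
setClass("ThermoConditions",
  slots = c(
    monovalent_mM = "numeric",
    divalent_mM   = "numeric",
    dntp_mM       = "numeric",
    oligo_nM      = "numeric"
  ),
  prototype = prototype(
    monovalent_mM = 50, divalent_mM = 1.5, dntp_mM = 0.6, oligo_nM = 250
  )
)

setValidity("ThermoConditions", function(object) {
  v <- c(object@monovalent_mM, object@divalent_mM, object@dntp_mM,
         object@oligo_nM)
  if (length(v) != 4L || any(is.na(v)) || any(v < 0))
    "all concentrations must be single non-negative values"
  else TRUE
})

#' Primer design parameters
#'
#' Product-size, length, melting-temperature, GC and complementarity
#' constraints plus the penalty weights used to rank admissible primer pairs.
#'
#' @slot product_min,product_max Amplicon size bounds (bp).
#' @slot primer_len_min,primer_len_opt,primer_len_max Primer length (nt).
#' @slot tm_min,tm_opt,tm_max Melting temperature (deg C).
#' @slot max_pair_tm_diff Maximum |Tm(fwd) - Tm(rev)| (deg C).
#' @slot gc_min,gc_opt,gc_max GC content (percent).
#' @slot max_polyx Longest allowed mononucleotide run.
#' @slot n_return Number of pairs to return per target.
#' @slot w_tm,w_size,w_gc,w_pair_diff Penalty weights.
#' @slot max_self_any,max_self_end,max_hairpin Complementarity score caps.
#' @slot gc_clamp Require a G or C within the two 3'-terminal bases.
#' @slot conditions A [ThermoConditions-class] object.
#'
#' @seealso [designParams()], [designPairs()]
#' @export
setClass("DesignParams",
  slots = c(
    product_min = "numeric", product_max = "numeric",
    primer_len_min = "numeric", primer_len_opt = "numeric",
    primer_len_max = "numeric",
    tm_min = "numeric", tm_opt = "numeric", tm_max = "numeric",
    max_pair_tm_diff = "numeric",
    gc_min = "numeric", gc_opt = "numeric", gc_max = "numeric",
    max_polyx = "numeric", n_return = "numeric",
    w_tm = "numeric", w_size = "numeric", w_gc = "numeric",
    w_pair_diff = "numeric",
    max_self_any = "numeric", max_self_end = "numeric",
    max_hairpin = "numeric",
    gc_clamp = "logical",
    conditions = "ThermoConditions"
  )
)

setValidity("DesignParams", function(object) {
  msg <- character()
  trip <- function(lo, op, hi, what) {
    if (!(lo <= op && op <= hi))
      msg <<- c(msg, sprintf("%s: need min <= opt <= max", what))
  }
  trip(object@primer_len_min, object@primer_len_opt, object@primer_len_max,
       "primer length")
  trip(object@tm_min, object@tm_opt, object@tm_max, "tm")
  trip(object@gc_min, object@gc_opt, object@gc_max, "gc")
  if (object@product_min > object@product_max)
    msg <- c(msg, "product_min must not exceed product_max")
  if (object@product_min < 2 * object@primer_len_min)
    msg <- c(msg, "product_min must be at least twice primer_len_min")
  if (object@primer_len_min < 8 || object@primer_len_max > 36)
    msg <- c(msg, "primer lengths must lie in [8, 36]")
  if (object@n_return < 1)
    msg <- c(msg, "n_return must be >= 1")
  if (any(c(object@w_tm, object@w_size, object@w_gc, object@w_pair_diff) < 0))
    msg <- c(msg, "penalty weights must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Synthetic community plan
#'
#' A deterministic recipe for a synthetic CDS community with planted truth:
#' private (unique) genes, gene families shared across genomes at a
#' controlled identity, within-genome duplicates, and optionally a genome
#' whose entire gene complement is a near-identical copy of another genome's
#' (no unique genes by construction).
#'
#' @slot seed Integer RNG seed; the same seed yields byte-identical output.
#' @slot genomes Genome identifiers.
#' @slot n_private Private genes per genome.
#' @slot shared_families data.frame(`family`, `identity`) of gene families
#'   planted in every genome (or in `members` genomes when that column is a
#'   list) at the given pairwise identity to the family founder sequence.
#' @slot n_duplicated Genomes' count of private genes planted twice.
#' @slot subsumed Optional `list(genome=, donor=, identity=)` marking one
#'   genome as a mutated copy of another genome's gene set.
#' @slot len_range Gene length range (bp).
#' @slot gc GC fraction of generated sequence.
#' @slot dialect FASTA header dialect to emit (`prokka`, `rast`, `ncbi`).
#'
#' @seealso [communityPlan()], [generateCommunity()]
#' @export
setClass("CommunityPlan",
  slots = c(
    seed = "numeric",
    genomes = "character",
    n_private = "numeric",
    shared_families = "data.frame",
    n_duplicated = "numeric",
    subsumed = "list",
    len_range = "numeric",
    gc = "numeric",
    dialect = "character"
  )
)

setValidity("CommunityPlan", function(object) {
  msg <- character()
  if (!length(object@genomes) || anyDuplicated(object@genomes))
    msg <- c(msg, "genomes must be non-empty and unique")
  if (nrow(object@shared_families) &&
      (any(object@shared_families$identity <= 0) ||
       any(object@shared_families$identity > 1)))
    msg <- c(msg, "shared family identities must lie in (0, 1]")
  if (length(object@len_range) != 2L || object@len_range[1] < 50 ||
      object@len_range[1] > object@len_range[2])
    msg <- c(msg, "len_range must be c(lo, hi) with 50 <= lo <= hi")
  if (object@gc <= 0 || object@gc >= 1)
    msg <- c(msg, "gc must lie in (0, 1)")
  if (!object@dialect %in% c("prokka", "rast", "ncbi"))
    msg <- c(msg, "dialect must be prokka, rast or ncbi")
  if (length(msg)) msg else TRUE
})
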