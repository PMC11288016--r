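#' Validate a CDS filename and derive the genome identifier
#'
#' CDS files must be named `<genome_id>_cds*.fna`: the name must contain the
#' string `"_cds"` and carry the `.fna` extension. The genome identifier is
#' everything before the first `"_cds"`.
#'
#' @param path Path to (or name of) a CDS FASTA file.
#' @return The genome identifier as a single string.
#' @examples
#' validateCdsFilename("B_theta_VPI5482_cds.fna")
#' validateCdsFilename("B_thetaiotaomicron_VPI_5482_cds_from_genomic.fna")
#' @export
validateCdsFilename <- function(path) {
  fn <- basename(path)
  if (!grepl("\\.fna$", fn))
    cpStop("CDS filename '%s' must end with '.fna'", fn)
  if (!grepl("cds", fn, fixed = TRUE))
    cpStop("CDS filename '%s' must contain the string 'cds'", fn)
  if (!grepl("_cds", fn, fixed = TRUE))
    cpStop("CDS filename '%s' must contain '_cds' after the genome identifier",
           fn)
  gid <- sub("_cds.*$", "", fn)
  if (!nzchar(gid))
    cpStop("CDS filename '%s' has an empty genome identifier", fn)
  gid
}

# Header dialect: NCBI extracted CDS headers start with "lcl|" or carry
# "[locus_tag=...]"; RAST uses "fig|..." ids with a "_CDS_" infix; anything
# else is treated as Prokka-style "<locustag> <product>".
detectDialect <- function(headers) {
  if (any(startsWith(headers, "lcl|")) ||
      any(grepl("[locus_tag=", headers, fixed = TRUE)))
    return("ncbi")
  if (any(startsWith(headers, "fig|")) && any(grepl("_CDS_", headers)))
    return("rast")
  "prokka"
}

#' Read one CDS FASTA file into normalized records
#'
#' Parses a per-genome multi-FASTA of coding sequences, prepends the genome
#' identifier (derived from the filename) to the first whitespace-delimited
#' header token to form community-unique gene identifiers, uppercases the
#' sequence, converts IUPAC ambiguity codes other than A/C/G/T to `N`, and
#' records the detected header dialect.
#'
#' @param path CDS FASTA file; the name must pass [validateCdsFilename()].
#' @param role `"target"` or `"nontarget"`.
#' @return A [S4Vectors::DataFrame] with columns `gene_id`, `genome_id`,
#'   `length`, `dialect`, `role`, `frac_n` and a `seq` column of class
#'   [Biostrings::DNAStringSet].
#' @export
readCdsFasta <- function(path, role = c("target", "nontarget")) {
  role <- match.arg(role)
  gid <- validateCdsFilename(path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e)
      cpStop("failed to parse FASTA '%s': %s", basename(path),
             conditionMessage(e))
  )
  if (length(seqs) == 0L)
    cpStop("CDS file '%s' contains no sequences", basename(path))
  if (any(Biostrings::width(seqs) == 0L))
    cpStop("CDS file '%s' contains an empty sequence", basename(path))
  headers <- names(seqs)
  tokens <- vapply(strsplit(headers, "[ \t]+"), `[[`, character(1), 1L)
  if (anyDuplicated(tokens))
    cpStop("duplicate FASTA header token '%s' in '%s'",
           tokens[duplicated(tokens)][1], basename(path))
  dialect <- detectDialect(headers)
  # canonical alphabet {A,C,G,T,N}: other IUPAC codes become N
  chr <- toupper(as.character(seqs))
  chr <- gsub("[^ACGT]", "N", chr)
  nN <- nchar(chr) - nchar(gsub("N", "", chr, fixed = TRUE))
  out <- DataFrame(
    gene_id = paste0(gid, "|", tokens),
    genome_id = gid,
    length = unname(nchar(chr)),
    dialect = dialect,
    role = role,
    frac_n = unname(nN / nchar(chr))
  )
  sq <- Biostrings::DNAStringSet(chr)
  names(sq) <- out$gene_id
  out$seq <- sq
  out
}

#' Build the community catalog from CDS directories
#'
#' Reads every `*_cds*.fna` file from the target directory (and optionally a
#' non-target directory, used only for specificity checks), assigns
#' community-unique gene identifiers, and returns the combined catalog.
#' Genomes are ordered lexicographically so the catalog is independent of
#' file-listing order.
#'
#' @param target_dir Directory of target CDS FASTA files (at least one).
#' @param nontarget_dir Optional directory of non-target CDS FASTA files.
#' @param combined_fasta Optional path; when given, the normalized combined
#'   community FASTA (headers = gene ids) is written there.
#' @param manifest Optional path for a catalog manifest TSV
#'   (genome_id, role, n_genes, file).
#' @return A [CommunityCatalog-class] object.
#' @examples
#' \dontrun{
#' cat <- buildCatalog("cds/targets", "cds/nontargets")
#' }
#' @export
buildCatalog <- function(target_dir, nontarget_dir = NULL,
                         combined_fasta = NULL, manifest = NULL) {
  listCds <- function(d) {
    if (!dir.exists(d)) cpStop("directory '%s' does not exist", d)
    sort(list.files(d, pattern = "\\.fna$", full.names = TRUE))
  }
  tf <- listCds(target_dir)
  if (length(tf) == 0L)
    cpStop("target directory '%s' contains no .fna CDS files", target_dir)
  nf <- if (!is.null(nontarget_dir)) listCds(nontarget_dir) else character()

  files <- c(tf, nf)
  roles <- c(rep("target", length(tf)), rep("nontarget", length(nf)))
  gids <- vapply(files, validateCdsFilename, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(gids))
    cpStop("genome identifier '%s' occurs more than once across input files",
           gids[duplicated(gids)][1])

  ord <- order(gids, method = "radix")
  files <- files[ord]; roles <- roles[ord]; gids <- gids[ord]

  parts <- mapply(readCdsFasta, files, roles, SIMPLIFY = FALSE)
  gd <- do.call(rbind, parts)
  seqs <- gd$seq
  names(seqs) <- gd$gene_id
  gd$seq <- NULL
  rownames(gd) <- NULL
  if (anyDuplicated(gd$gene_id))
    cpStop("gene identifier collision across genomes: '%s'",
           gd$gene_id[duplicated(gd$gene_id)][1])

  obj <- new("CommunityCatalog", sequences = seqs, geneData = gd,
             genomes = gids, files = structure(files, names = gids))
  if (!is.null(combined_fasta)) writeCatalogFasta(obj, combined_fasta)
  if (!is.null(manifest)) writeCatalogManifest(obj, manifest)
  obj
}

#' Write the normalized combined community FASTA
#'
#' Headers are the community-unique gene identifiers; re-reading the file
#' reproduces the catalog sequences exactly.
#'
#' @param catalog A [CommunityCatalog-class].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
writeCatalogFasta <- function(catalog, path) {
  stopifnot(is(catalog, "CommunityCatalog"))
  Biostrings::writeXStringSet(catalog@sequences, filepath = path)
  invisible(path)
}

#' Write the catalog manifest TSV
#'
#' One row per genome: `genome_id`, `role`, `n_genes`, `file`.
#'
#' @inheritParams writeCatalogFasta
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeCatalogManifest <- function(catalog, path) {
  stopifnot(is(catalog, "CommunityCatalog"))
  gd <- catalog@geneData
  cnt <- genesByGenome(catalog)
  role <- vapply(catalog@genomes, function(g)
    as.character(gd$role[match(g, gd$genome_id)]), character(1))
  df <- data.frame(genome_id = catalog@genomes, role = role,
                   n_genes = as.integer(cnt),
                   file = basename(catalog@files[catalog@genomes]),
                   stringsAsFactors = FALSE)
  writeTsv(df, path)
}
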