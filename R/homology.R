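#' @importFrom data.table data.table setkey := .N .SD setorder rbindlist
#'   as.data.table setDF
NULL

HIT_COLS <- c("query", "target", "fident", "alnlen", "mismatch", "gapopen",
              "qstart", "qend", "tstart", "tend", "evalue", "bits",
              "qcov", "tcov")

# minimum raw alignment score (match +2) for the internal engine to report a
# hit; suppresses chance micro-alignments the way an E-value cutoff would.
MIN_REPORT_SCORE <- 40L

kmerTable <- function(seqs, k) {
  ids <- names(seqs)
  chr <- as.character(seqs)
  rbindlist(lapply(seq_along(chr), function(i) {
    s <- chr[[i]]
    L <- nchar(s)
    if (L < k) return(NULL)
    pos <- seq_len(L - k + 1L)
    data.table(gene = ids[i],
               pos = pos,
               kmer = substring(s, pos, pos + k - 1L))
  }))
}

#' Candidate gene pairs sharing an exact k-mer
#'
#' Seeding stage of the internal aligner: returns every unordered pair of
#' distinct genes that share at least one exact k-mer, on the plus strand or
#' (optionally) with one gene reverse-complemented. Any pair whose true
#' alignment contains an exact k-length match is guaranteed to be returned.
#'
#' @param catalog A [CommunityCatalog-class].
#' @param k K-mer length (default 13; must be >= 8).
#' @param both_strands Also seed against reverse complements (default TRUE).
#' @return data.frame with columns `gene1`, `gene2` (gene1 < gene2),
#'   `strand` (`+` or `-`), and the seed diagonal range `dmin`, `dmax`
#'   (target position minus query position) used to band the extension.
#' @export
kmerCandidatePairs <- function(catalog, k = 13L, both_strands = TRUE) {
  stopifnot(is(catalog, "CommunityCatalog"))
  if (k < 8) cpStop("k must be >= 8")
  if (nGenes(catalog) == 0L)
    return(data.frame(gene1 = character(), gene2 = character(),
                      strand = character(), dmin = integer(),
                      dmax = integer()))
  kt <- kmerTable(catalog@sequences, k)
  kt <- kt[!grepl("N", kmer, fixed = TRUE)]

  pairUp <- function(a, b, strand) {
    m <- merge(a, b, by = "kmer", allow.cartesian = TRUE, suffixes = c("1", "2"))
    m <- m[gene1 < gene2]
    if (nrow(m) == 0L)
      return(NULL)
    m[, d := pos2 - pos1]
    m[, .(dmin = min(d), dmax = max(d), strand = strand),
      by = .(gene1, gene2)]
  }
  out <- list(pairUp(kt, kt, "+"))
  if (both_strands) {
    rcseqs <- Biostrings::reverseComplement(catalog@sequences)
    ktrc <- kmerTable(rcseqs, k)
    ktrc <- ktrc[!grepl("N", kmer, fixed = TRUE)]
    out <- c(out, list(pairUp(kt, ktrc, "-")))
  }
  res <- rbindlist(out)
  if (is.null(res) || nrow(res) == 0L)
    return(data.frame(gene1 = character(), gene2 = character(),
                      strand = character(), dmin = integer(),
                      dmax = integer()))
  setorder(res, gene1, gene2, strand)
  setDF(res[, .(gene1, gene2, strand, dmin, dmax)])
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment with linear gap costs (defaults: match +2,
#' mismatch -3, gap -5 per base). With `band = NULL` the full dynamic
#' programming matrix is evaluated; a `band = c(dmin, dmax)` restricts the
#' search to diagonals `tpos - qpos` within the range (seeded extension).
#'
#' @param a,b Nucleotide sequences (character strings; `N` matches nothing).
#' @param match,mismatch,gap Scoring parameters (gap is the per-base cost).
#' @param band Optional diagonal range `c(dmin, dmax)`.
#' @return One-row data.frame: `score`, `fident` (matches / columns),
#'   `alnlen`, `mismatch`, `gapopen`, `qstart`, `qend`, `tstart`, `tend`
#'   (1-based inclusive), `qcov`, `tcov`.
#' @examples
#' localAlign("ACGTACGTACGT", "ACGTACGAACGT")
#' @export
localAlign <- function(a, b, match = 2L, mismatch = -3L, gap = 5L,
                       band = NULL) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) cpStop("sequences must be non-empty")
  if (is.null(band)) band <- c(-nchar(a), nchar(b))
  r <- cpp_local_align(a, b, as.integer(match), as.integer(mismatch),
                       as.integer(abs(gap)), as.integer(band[1]),
                       as.integer(band[2]))
  alnlen <- r$columns
  data.frame(
    score = r$score,
    fident = if (alnlen > 0) r$matches / alnlen else 0,
    alnlen = alnlen, mismatch = r$mismatches, gapopen = r$gapopens,
    qstart = r$qstart, qend = r$qend, tstart = r$tstart, tend = r$tend,
    qcov = if (alnlen > 0) (r$qend - r$qstart + 1L) / nchar(a) else 0,
    tcov = if (alnlen > 0) (r$tend - r$tstart + 1L) / nchar(b) else 0
  )
}

#' Filter alignment hits by stringency thresholds
#'
#' Drops rows failing `min_identity`, `min_aln_len` or the coverage rule of
#' the chosen coverage mode. Self-hits (query == target) always survive.
#'
#' @param hits Hit data.frame (see [allVsAll()]).
#' @param params A [StringencyParams-class].
#' @return The surviving rows.
#' @export
filterHits <- function(hits, params = stringencyParams()) {
  stopifnot(is(params, "StringencyParams"))
  cov <- switch(params@cov_mode,
    both = pmin(hits$qcov, hits$tcov),
    either = pmax(hits$qcov, hits$tcov),
    query = hits$qcov,
    target = hits$tcov)
  keep <- hits$fident >= params@min_identity &
    hits$alnlen >= params@min_aln_len &
    cov >= params@min_coverage
  hits[keep | hits$query == hits$target, , drop = FALSE]
}

#' All-vs-all homology screen over the community
#'
#' Aligns every CDS against every other CDS: k-mer seeded candidate pairs
#' are extended with a banded Smith-Waterman around the seed diagonals, both
#' orientations of each surviving pair are reported (mirrored query/target
#' roles), a self-hit is emitted for every gene, and rows failing the
#' stringency thresholds are dropped. Cross-genome CDS pairs are compared on
#' the plus strand by default, since CDS files are sense-strand.
#'
#' @param catalog A [CommunityCatalog-class].
#' @param params A [StringencyParams-class].
#' @param k Seed k-mer length (default 13).
#' @param band_width Half-width added around the seed diagonal range (32).
#' @param both_strands Also align reverse complements (default FALSE).
#' @return data.frame in hit-table column order (`query`, `target`,
#'   `fident`, `alnlen`, `mismatch`, `gapopen`, `qstart`, `qend`, `tstart`,
#'   `tend`, `evalue`, `bits`, `qcov`, `tcov`), sorted by query then
#'   descending score; `evalue` is `NA` (not computed by the internal
#'   engine) and `bits` carries the raw alignment score.
#' @export
allVsAll <- function(catalog, params = stringencyParams(), k = 13L,
                     band_width = 32L, both_strands = FALSE) {
  stopifnot(is(catalog, "CommunityCatalog"), is(params, "StringencyParams"))
  cand <- kmerCandidatePairs(catalog, k = k, both_strands = both_strands)
  chr <- as.character(catalog@sequences)
  lens <- nchar(chr)
  names(lens) <- names(chr)

  rows <- vector("list", nrow(cand))
  half <- as.integer(band_width %/% 2L)
  for (i in seq_len(nrow(cand))) {
    g1 <- cand$gene1[i]; g2 <- cand$gene2[i]
    s2 <- if (cand$strand[i] == "-") revComp(chr[[g2]]) else chr[[g2]]
    h <- localAlign(chr[[g1]], s2,
                    band = c(cand$dmin[i] - half, cand$dmax[i] + half))
    if (h$score < MIN_REPORT_SCORE) next
    if (cand$strand[i] == "-") {
      # report target coordinates on the original (plus) strand
      L2 <- lens[[g2]]
      ts <- L2 - h$tend + 1L; te <- L2 - h$tstart + 1L
      h$tstart <- ts; h$tend <- te
    }
    fwd <- data.frame(query = g1, target = g2, h, strand = cand$strand[i],
                      stringsAsFactors = FALSE)
    rev <- fwd
    rev$query <- g2; rev$target <- g1
    rev$qstart <- h$tstart; rev$qend <- h$tend
    rev$tstart <- h$qstart; rev$tend <- h$qend
    rev$qcov <- h$tcov; rev$tcov <- h$qcov
    rows[[i]] <- rbind(fwd, rev)
  }
  cross <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])

  self <- data.frame(
    query = names(chr), target = names(chr), score = 2L * lens,
    fident = 1, alnlen = lens, mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = lens, tstart = 1L, tend = lens,
    qcov = 1, tcov = 1, strand = "+", stringsAsFactors = FALSE
  )
  all <- rbind(self, if (!is.null(cross)) cross[colnames(self)])
  all <- filterHits(all, params)
  all$evalue <- NA_real_
  all$bits <- all$score
  all <- all[order(all$query, -all$bits, all$target, method = "radix"),
             c(HIT_COLS, "strand")]
  rownames(all) <- NULL
  all
}

#' Write a hit table TSV
#'
#' 14-column tab-separated hit table (MMseqs2 convention-compatible:
#' `query target fident alnlen mismatch gapopen qstart qend tstart tend
#' evalue bits` plus `qcov tcov`), coordinates 1-based inclusive.
#'
#' @param hits Hit data.frame from [allVsAll()] or [loadExternalHits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeHitTable <- function(hits, path) {
  df <- hits[HIT_COLS]
  df$fident <- formatNum(df$fident, 4L)
  df$qcov <- formatNum(df$qcov, 4L)
  df$tcov <- formatNum(df$tcov, 4L)
  df$evalue <- ifelse(is.na(df$evalue), "NA", format(df$evalue))
  writeTsv(df, path)
}

#' Read a hit table TSV written by [writeHitTable()]
#' @param path Hit table path.
#' @return Hit data.frame.
#' @export
readHitTable <- function(path) {
  df <- readTsv(path)
  missing <- setdiff(HIT_COLS, colnames(df))
  if (length(missing))
    cpStop("hit table '%s' lacks columns: %s", path,
           paste(missing, collapse = ", "))
  df
}

#' Load an external tabular alignment file
#'
#' Adapter for MMseqs2/BLAST outfmt-6 style tables with at least 12
#' whitespace- or tab-separated columns (`query target fident alnlen
#' mismatch gapopen qstart qend tstart tend evalue bits`). Identity is
#' accepted on either the 0-1 or the 0-100 scale (auto-detected: any value
#' above 1.5 switches the whole file to percent). Query/target coverage is
#' computed from the alignment coordinates and the catalog gene lengths.
#'
#' @param path External alignment file.
#' @param catalog A [CommunityCatalog-class] resolving every identifier.
#' @return Hit data.frame in the standard column order.
#' @export
loadExternalHits <- function(path, catalog) {
  stopifnot(is(catalog, "CommunityCatalog"))
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0L) cpStop("alignment file '%s' is empty", path)
  parts <- strsplit(trimws(raw), "[ \t]+")
  bad <- which(vapply(parts, length, integer(1)) < 12L)
  if (length(bad))
    cpStop("malformed alignment row at line %d of '%s' (fewer than 12 columns)",
           bad[1], path)
  m <- do.call(rbind, lapply(parts, `[`, 1:12))
  df <- data.frame(
    query = m[, 1], target = m[, 2],
    fident = as.numeric(m[, 3]), alnlen = as.integer(m[, 4]),
    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    tstart = as.integer(m[, 9]), tend = as.integer(m[, 10]),
    evalue = suppressWarnings(as.numeric(m[, 11])),
    bits = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  num_bad <- which(is.na(df$fident) | is.na(df$alnlen) | is.na(df$qstart) |
                   is.na(df$qend) | is.na(df$tstart) | is.na(df$tend))
  if (length(num_bad))
    cpStop("malformed alignment row at line %d of '%s'", num_bad[1], path)
  if (any(df$fident > 1.5)) df$fident <- df$fident / 100
  ids <- geneIds(catalog)
  unknown <- setdiff(unique(c(df$query, df$target)), ids)
  if (length(unknown))
    cpStop("alignment file names unknown gene '%s'", unknown[1])
  lens <- structure(Biostrings::width(catalog@sequences), names = ids)
  df$qcov <- (abs(df$qend - df$qstart) + 1L) / lens[df$query]
  df$tcov <- (abs(df$tend - df$tstart) + 1L) / lens[df$target]
  df$strand <- ifelse(df$tend >= df$tstart, "+", "-")
  rownames(df) <- NULL
  df[c(HIT_COLS, "strand")]
}
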