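# Window-level machinery: all candidate primer windows of a gene with
# O(1)-per-window thermodynamic sums via cumulative dinucleotide tables.

geneWindows <- function(gene_seq, params) {
  L <- nchar(gene_seq)
  p <- params
  lens <- seq(p@primer_len_min, p@primer_len_max)
  base <- strsplit(toupper(gene_seq), "")[[1]]
  is_acgt <- base %in% c("A", "C", "G", "T")
  is_gc <- base %in% c("G", "C")

  din <- paste0(base[-L], base[-1])
  dh <- unname(NN_DH[din]); dh[is.na(dh)] <- 0
  ds <- unname(NN_DS[din]); ds[is.na(ds)] <- 0
  CH <- c(0, cumsum(dh)); CS <- c(0, cumsum(ds))
  CG <- c(0, cumsum(is_gc))
  CBAD <- c(0, cumsum(!is_acgt))
  # positions where a mononucleotide run longer than max_polyx ends
  r <- rle(base)
  run_end <- cumsum(r$lengths)
  poly_end <- integer(0)
  w <- p@max_polyx + 1
  for (i in which(r$lengths >= w)) {
    s0 <- run_end[i] - r$lengths[i] + 1L
    poly_end <- c(poly_end, (s0 + w - 1L):run_end[i])
  }
  ispoly <- integer(L); ispoly[poly_end] <- 1L
  CP <- c(0, cumsum(ispoly))

  out <- lapply(lens, function(len) {
    if (L < len) return(NULL)
    s1 <- seq_len(L - len + 1L)
    e1 <- s1 + len - 1L
    data.frame(start1 = s1, end1 = e1, len = len)
  })
  wdf <- do.call(rbind, out)
  if (is.null(wdf)) return(NULL)
  s1 <- wdf$start1; e1 <- wdf$end1; len <- wdf$len

  wdf$has_bad <- (CBAD[e1 + 1L] - CBAD[s1]) > 0
  wdf$has_poly <- (CP[e1 + 1L] - CP[s1 + p@max_polyx]) > 0
  gc_n <- CG[e1 + 1L] - CG[s1]
  wdf$gc_pct <- 100 * gc_n / len
  dhw <- CH[e1] - CH[s1]
  dsw <- CS[e1] - CS[s1]
  ends_gc <- as.integer(is_gc[s1]) + as.integer(is_gc[e1])
  tm <- rep(NA_real_, nrow(wdf))
  okbase <- !wdf$has_bad
  tm[okbase] <- tmFromSums(dhw[okbase], dsw[okbase], gc_n[okbase] / len[okbase],
                           len[okbase], 2L - ends_gc[okbase], ends_gc[okbase],
                           p@conditions)
  wdf$tm_c <- tm
  # GC clamp: a fwd primer 3'-ends at end1; a rev primer (reverse complement
  # of the window) 3'-ends at the complement of start1
  wdf$clamp_fwd <- is_gc[e1] | is_gc[pmax(e1 - 1L, 1L)]
  wdf$clamp_rev <- is_gc[s1] | is_gc[pmin(s1 + 1L, L)]
  wdf
}

#' Enumerate geometry-admissible primer window pairs
#'
#' All (forward window, reverse window) combinations whose amplicon -- the
#' template segment from the forward primer start to the reverse primer end
#' (0-based half-open) -- lies within the product-size range. Windows with
#' non-ACGT bases or mononucleotide runs longer than `max_polyx` are
#' dropped.
#'
#' @param gene_seq Template sequence.
#' @param params A [DesignParams-class].
#' @return data.frame `fwd_start`, `fwd_len`, `rev_end`, `rev_len`,
#'   `amplicon_bp` (coordinates 0-based half-open); zero rows (with a
#'   `reason` attribute) when the gene is shorter than `product_min`.
#' @export
enumerateCandidates <- function(gene_seq, params = designParams()) {
  stopifnot(is(params, "DesignParams"))
  empty <- data.frame(fwd_start = integer(), fwd_len = integer(),
                      rev_end = integer(), rev_len = integer(),
                      amplicon_bp = integer())
  if (nchar(gene_seq) < params@product_min) {
    attr(empty, "reason") <- "gene shorter than product_min"
    return(empty)
  }
  wdf <- geneWindows(gene_seq, params)
  wdf <- wdf[!wdf$has_bad & !wdf$has_poly, , drop = FALSE]
  if (nrow(wdf) == 0L) return(empty)
  fw <- data.table::as.data.table(wdf[c("start1", "len")])
  rv <- data.table::as.data.table(wdf[c("end1", "len")])
  data.table::setnames(fw, c("fstart1", "flen"))
  data.table::setnames(rv, c("rend1", "rlen"))
  fw[, `:=`(amin = fstart1 + params@product_min - 1L,
            amax = fstart1 + params@product_max - 1L)]
  pairs <- fw[rv, on = .(amin <= rend1, amax >= rend1),
              .(fstart1 = x.fstart1, flen = x.flen,
                rend1 = i.rend1, rlen = i.rlen),
              nomatch = NULL, allow.cartesian = TRUE]
  pairs <- pairs[rend1 - rlen + 1L > fstart1 + flen - 1L]  # non-overlapping
  out <- data.frame(fwd_start = pairs$fstart1 - 1L, fwd_len = pairs$flen,
                    rev_end = pairs$rend1, rev_len = pairs$rlen)
  out$amplicon_bp <- out$rev_end - out$fwd_start
  out[order(out$fwd_start, out$rev_end, out$fwd_len, out$rev_len), ,
      drop = FALSE]
}

#' Score a primer oligo, or reject it
#'
#' Hard filters first (Tm window, GC window, poly-X, GC clamp, self/hairpin
#' complementarity caps); survivors receive the penalty
#' `w_tm |tm - tm_opt| + w_size |len - len_opt| + w_gc |gc - gc_opt| / 10`.
#'
#' @param oligo One-row data.frame from [oligoProfile()] (or an oligo
#'   sequence, which is profiled first).
#' @param params A [DesignParams-class].
#' @param clamp_ok Optional override for the GC-clamp check when the caller
#'   has already evaluated it on the template.
#' @return list(`penalty` = numeric or NA, `rejected` = NA or the violated
#'   rule).
#' @export
scorePrimer <- function(oligo, params = designParams(), clamp_ok = NULL) {
  stopifnot(is(params, "DesignParams"))
  if (is.character(oligo)) oligo <- oligoProfile(oligo, params@conditions)
  p <- params
  reject <- function(rule) list(penalty = NA_real_, rejected = rule)
  if (oligo$length < p@primer_len_min || oligo$length > p@primer_len_max)
    return(reject("length"))
  if (is.na(oligo$tm_c) || oligo$tm_c < p@tm_min || oligo$tm_c > p@tm_max)
    return(reject("tm"))
  if (oligo$gc_pct < p@gc_min || oligo$gc_pct > p@gc_max)
    return(reject("gc"))
  if (grepl(sprintf("(A{%d}|C{%d}|G{%d}|T{%d})", p@max_polyx + 1,
                    p@max_polyx + 1, p@max_polyx + 1, p@max_polyx + 1),
            oligo$seq))
    return(reject("polyx"))
  if (p@gc_clamp) {
    ok <- if (!is.null(clamp_ok)) clamp_ok
      else grepl("[GC]", substring(oligo$seq, oligo$length - 1L))
    if (!ok) return(reject("gc_clamp"))
  }
  if (oligo$self_any > p@max_self_any) return(reject("self_any"))
  if (oligo$self_end > p@max_self_end) return(reject("self_end"))
  if (oligo$hairpin > p@max_hairpin) return(reject("hairpin"))
  pen <- p@w_tm * abs(oligo$tm_c - p@tm_opt) +
    p@w_size * abs(oligo$length - p@primer_len_opt) +
    p@w_gc * abs(oligo$gc_pct - p@gc_opt) / 10
  list(penalty = pen, rejected = NA_character_)
}

emptyPairTable <- function() {
  data.frame(gene_id = character(), gene_seq = character(),
             pair_penalty = numeric(), amplicon_bp = integer(),
             fwd_seq = character(), rev_seq = character(),
             fwd_start = integer(), rev_end = integer(),
             fwd_len = integer(), rev_len = integer(),
             fwd_tm = numeric(), rev_tm = numeric(),
             fwd_gc = numeric(), rev_gc = numeric(),
             fwd_penalty = numeric(), rev_penalty = numeric(),
             conservation = character(), stringsAsFactors = FALSE)
}

#' Design ranked primer pairs on one candidate gene
#'
#' Enumerates every admissible pair of primer windows on the template,
#' applies the per-oligo hard filters and pair constraints (amplicon size,
#' maximum pair Tm difference, forward/reverse cross-dimer caps), and
#' returns the top `n_return` pairs by ascending pair penalty
#' `penalty_fwd + penalty_rev + w_pair_diff |Tm_fwd - Tm_rev|`, ties broken
#' by (fwd_start, rev_end). Identical (fwd_seq, rev_seq) duplicates are
#' removed. With `conservation_targets` (group mode), each primer pair is
#' exact-substring checked against every target's gene copies and the
#' result recorded as `exact_in_all_targets` or `mismatched`.
#'
#' @param gene_id Gene identifier used in the output rows.
#' @param gene_seq Template CDS sequence.
#' @param params A [DesignParams-class].
#' @param conservation_targets Optional named list (per target genome) of
#'   character vectors of that genome's candidate gene sequences.
#' @return data.frame of primer pair rows (possibly zero rows, with a
#'   `rejection_summary` attribute tabulating the rules that removed
#'   candidates).
#' @export
designPairs <- function(gene_id, gene_seq, params = designParams(),
                        conservation_targets = NULL) {
  stopifnot(is(params, "DesignParams"))
  p <- params
  gene_seq <- toupper(gene_seq)
  out <- emptyPairTable()
  if (nchar(gene_seq) < p@product_min) {
    attr(out, "rejection_summary") <- c(gene_too_short = 1L)
    return(out)
  }
  wdf <- geneWindows(gene_seq, p)
  rejections <- c(bad_base = sum(wdf$has_bad), polyx = sum(wdf$has_poly))
  wdf <- wdf[!wdf$has_bad & !wdf$has_poly, , drop = FALSE]
  rejections["tm"] <- sum(wdf$tm_c < p@tm_min | wdf$tm_c > p@tm_max)
  rejections["gc"] <- sum(wdf$gc_pct < p@gc_min | wdf$gc_pct > p@gc_max)
  wdf <- wdf[wdf$tm_c >= p@tm_min & wdf$tm_c <= p@tm_max &
             wdf$gc_pct >= p@gc_min & wdf$gc_pct <= p@gc_max, , drop = FALSE]

  pen0 <- p@w_tm * abs(wdf$tm_c - p@tm_opt) +
    p@w_size * abs(wdf$len - p@primer_len_opt) +
    p@w_gc * abs(wdf$gc_pct - p@gc_opt) / 10

  fwd <- wdf; fwd$penalty <- pen0
  rev <- wdf; rev$penalty <- pen0
  if (p@gc_clamp) {
    rejections["gc_clamp"] <- sum(!wdf$clamp_fwd) + sum(!wdf$clamp_rev)
    fwd <- fwd[fwd$clamp_fwd, , drop = FALSE]
    rev <- rev[rev$clamp_rev, , drop = FALSE]
  }

  # self-structure filters on the realized oligo sequences
  oligoOk <- function(df, orient) {
    if (nrow(df) == 0L) return(df)
    seqs <- substring(gene_seq, df$start1, df$end1)
    if (orient == "rev") seqs <- revComp(seqs)
    keep <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
      s <- seqs[i]
      keep[i] <- cpp_comp_score(s, s, FALSE, -1L) <= p@max_self_any &&
        cpp_comp_score(s, s, TRUE, -1L) <= p@max_self_end &&
        cpp_comp_score(s, s, FALSE, 3L) <= p@max_hairpin
    }
    rejections[paste0("self_structure_", orient)] <<- sum(!keep)
    df$oligo_seq <- seqs
    df[keep, , drop = FALSE]
  }
  fwd <- oligoOk(fwd, "fwd")
  rev <- oligoOk(rev, "rev")

  if (nrow(fwd) == 0L || nrow(rev) == 0L) {
    attr(out, "rejection_summary") <- rejections
    return(out)
  }

  fdt <- data.table::data.table(
    fstart1 = fwd$start1, fend1 = fwd$end1, flen = fwd$len,
    ftm = fwd$tm_c, fgc = fwd$gc_pct, fpen = fwd$penalty, fseq = fwd$oligo_seq)
  rdt <- data.table::data.table(
    rstart1 = rev$start1, rend1 = rev$end1, rlen = rev$len,
    rtm = rev$tm_c, rgc = rev$gc_pct, rpen = rev$penalty, rseq = rev$oligo_seq)
  fdt[, `:=`(amin = fstart1 + p@product_min - 1L,
             amax = fstart1 + p@product_max - 1L)]
  pairs <- fdt[rdt, on = .(amin <= rend1, amax >= rend1),
               .(fstart1 = x.fstart1, fend1 = x.fend1, flen = x.flen,
                 ftm = x.ftm, fgc = x.fgc, fpen = x.fpen, fseq = x.fseq,
                 rstart1 = i.rstart1, rend1 = i.rend1, rlen = i.rlen,
                 rtm = i.rtm, rgc = i.rgc, rpen = i.rpen, rseq = i.rseq),
               nomatch = NULL, allow.cartesian = TRUE]
  pairs <- pairs[rstart1 > fend1]                       # primers must not overlap
  rejections["pair_tm_diff"] <- sum(abs(pairs$ftm - pairs$rtm) >
                                      p@max_pair_tm_diff)
  pairs <- pairs[abs(ftm - rtm) <= p@max_pair_tm_diff]
  if (nrow(pairs) == 0L) {
    attr(out, "rejection_summary") <- rejections
    return(out)
  }
  pairs[, pair_penalty := fpen + rpen + p@w_pair_diff * abs(ftm - rtm)]
  data.table::setorder(pairs, pair_penalty, fstart1, rend1, flen, rlen)
  pairs <- unique(pairs, by = c("fseq", "rseq"))

  # walk in penalty order, keeping pairs that pass the cross-dimer filter
  acc <- list()
  ndrop_dimer <- 0L
  for (i in seq_len(nrow(pairs))) {
    if (length(acc) >= p@n_return) break
    row <- pairs[i]
    cross_any <- cpp_comp_score(row$fseq, row$rseq, FALSE, -1L)
    cross_end <- max(cpp_comp_score(row$fseq, row$rseq, TRUE, -1L),
                     cpp_comp_score(row$rseq, row$fseq, TRUE, -1L))
    if (cross_any > p@max_self_any || cross_end > p@max_self_end) {
      ndrop_dimer <- ndrop_dimer + 1L
      next
    }
    acc[[length(acc) + 1L]] <- row
  }
  rejections["cross_dimer"] <- ndrop_dimer
  if (length(acc) == 0L) {
    attr(out, "rejection_summary") <- rejections
    return(out)
  }
  sel <- data.table::rbindlist(acc)

  conservation <- "n/a"
  if (!is.null(conservation_targets)) {
    conservation <- vapply(seq_len(nrow(sel)), function(i) {
      f <- sel$fseq[i]; r <- revComp(sel$rseq[i])
      all_hit <- vapply(conservation_targets, function(copies)
        any(vapply(copies, function(cp)
          grepl(f, cp, fixed = TRUE) && grepl(r, cp, fixed = TRUE),
          logical(1))), logical(1))
      if (all(all_hit)) "exact_in_all_targets" else "mismatched"
    }, character(1))
  }

  res <- data.frame(
    gene_id = gene_id, gene_seq = gene_seq,
    pair_penalty = sel$pair_penalty,
    amplicon_bp = sel$rend1 - (sel$fstart1 - 1L),
    fwd_seq = sel$fseq, rev_seq = sel$rseq,
    fwd_start = sel$fstart1 - 1L, rev_end = sel$rend1,
    fwd_len = sel$flen, rev_len = sel$rlen,
    fwd_tm = sel$ftm, rev_tm = sel$rtm,
    fwd_gc = sel$fgc, rev_gc = sel$rgc,
    fwd_penalty = sel$fpen, rev_penalty = sel$rpen,
    conservation = conservation, stringsAsFactors = FALSE
  )
  attr(res, "rejection_summary") <- rejections
  res
}

#' Design primers across the whole community
#'
#' Walks each genome's (unique mode) or the group's (group mode) ranked
#' candidate genes in order, designing pairs per gene until `n_return`
#' pairs are accumulated or candidates are exhausted. Genomes with no
#' candidates produce a warning and no rows -- the expected outcome for a
#' member whose gene set is subsumed by a close relative.
#'
#' @param ranked Ranked candidate list from [rankCandidates()].
#' @param catalog A [CommunityCatalog-class].
#' @param params A [DesignParams-class].
#' @param mode `"unique"` or `"group"`.
#' @param group Group genome ids (group mode).
#' @return Primer table data.frame with a leading `genome_id` (or `group`)
#'   column; the `skipped` attribute names genomes that received no
#'   primers.
#' @export
designForCommunity <- function(ranked, catalog, params = designParams(),
                               mode = c("unique", "group"), group = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(catalog, "CommunityCatalog"))
  chr <- as.character(catalog@sequences)
  skipped <- character()

  designWalk <- function(genes, conservation_targets = NULL) {
    acc <- list()
    for (g in genes) {
      left <- params@n_return - sum(vapply(acc, nrow, integer(1)))
      if (left <= 0L) break
      pp <- params
      pp@n_return <- left
      res <- designPairs(g, chr[[g]], pp,
                         conservation_targets = conservation_targets)
      if (nrow(res)) acc[[length(acc) + 1L]] <- res
    }
    if (length(acc)) do.call(rbind, acc) else emptyPairTable()
  }

  if (mode == "unique") {
    out <- lapply(names(ranked), function(gm) {
      rows <- designWalk(ranked[[gm]])
      if (nrow(rows) == 0L) {
        warning(sprintf("no microbe-specific primers for genome '%s' (%s)",
                        gm, if (length(ranked[[gm]])) "no admissible pairs"
                            else "0 unique genes"), call. = FALSE)
        skipped <<- c(skipped, gm)
        return(NULL)
      }
      cbind(genome_id = gm, rows, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(res)) res <- cbind(genome_id = character(), emptyPairTable())
  } else {
    if (is.null(group)) cpStop("group mode requires 'group'")
    gd <- catalog@geneData
    cons <- lapply(group, function(gm)
      unname(chr[as.character(gd$gene_id[gd$genome_id == gm])]))
    names(cons) <- group
    rows <- designWalk(ranked$group, conservation_targets = cons)
    if (nrow(rows) == 0L) {
      warning("no group-specific primers could be designed", call. = FALSE)
      skipped <- paste(group, collapse = "+")
    }
    res <- cbind(group = paste(group, collapse = "+"), rows,
                 stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Write a primer table TSV
#'
#' Serializes the gene name and sequence, pair penalty, amplicon size,
#' forward/reverse primer sequence, length, GC content and melting
#' temperature per row (plus the conservation flag in group mode) with
#' fixed formatting, so identical inputs give byte-identical files.
#'
#' @param rows Primer table from [designForCommunity()] or [designPairs()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writePrimerTable <- function(rows, path) {
  df <- rows
  for (col in c("pair_penalty", "fwd_tm", "rev_tm", "fwd_gc", "rev_gc",
                "fwd_penalty", "rev_penalty"))
    if (col %in% colnames(df)) df[[col]] <- formatNum(df[[col]], 4L)
  if (all(is.na(df$conservation)) ||
      all(df$conservation == "n/a"))
    df$conservation <- NULL
  writeTsv(df, path)
}
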