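# independent exhaustive designer used as oracle on short genes: profiles
# every window with the per-oligo thermodynamic functions (not the engine's
# cumulative tables), then applies the documented rules to all window pairs
oracleDesign <- function(gene_seq, p) {
  L <- nchar(gene_seq)
  wins <- do.call(rbind, lapply(p@primer_len_min:p@primer_len_max,
    function(len) {
      if (L < len) return(NULL)
      s1 <- 1:(L - len + 1)
      data.frame(s1 = s1, e1 = s1 + len - 1, len = len,
                 seq = substring(gene_seq, s1, s1 + len - 1),
                 stringsAsFactors = FALSE)
    }))
  polyre <- sprintf("(A{%d}|C{%d}|G{%d}|T{%d})", p@max_polyx + 1,
                    p@max_polyx + 1, p@max_polyx + 1, p@max_polyx + 1)
  wins <- wins[!grepl("[^ACGT]", wins$seq) & !grepl(polyre, wins$seq), ]
  wins$tm <- meltingTemperature(wins$seq, p@conditions)
  wins$gc <- gcContent(wins$seq)
  ok_thermo <- wins$tm >= p@tm_min & wins$tm <= p@tm_max &
    wins$gc >= p@gc_min & wins$gc <= p@gc_max
  wins <- wins[ok_thermo, ]
  selfOk <- function(s) {
    unname(complementarityScores(s, s)["any"]) <= p@max_self_any &&
      unname(complementarityScores(s, s)["end"]) <= p@max_self_end &&
      hairpinScore(s) <= p@max_hairpin
  }
  pen <- function(tm, len, gc) {
    p@w_tm * abs(tm - p@tm_opt) + p@w_size * abs(len - p@primer_len_opt) +
      p@w_gc * abs(gc - p@gc_opt) / 10
  }
  clampOk <- function(s) grepl("[GC]", substr(s, nchar(s) - 1, nchar(s)))
  fw <- wins
  fw <- fw[(!p@gc_clamp | clampOk(fw$seq)) &
             vapply(fw$seq, selfOk, logical(1)), ]
  rv <- wins
  rv$seq <- revComp(rv$seq)
  rv <- rv[(!p@gc_clamp | clampOk(rv$seq)) &
             vapply(rv$seq, selfOk, logical(1)), ]
  rows <- list()
  for (i in seq_len(nrow(fw))) {
    js <- which(rv$e1 >= fw$s1[i] + p@product_min - 1 &
                rv$e1 <= fw$s1[i] + p@product_max - 1 &
                rv$s1 > fw$e1[i] &
                abs(rv$tm - fw$tm[i]) <= p@max_pair_tm_diff)
    for (j in js) {
      fseq <- fw$seq[i]; rseq <- rv$seq[j]
      ca <- unname(complementarityScores(fseq, rseq)["any"])
      ce <- max(unname(complementarityScores(fseq, rseq)["end"]),
                unname(complementarityScores(rseq, fseq)["end"]))
      if (ca > p@max_self_any || ce > p@max_self_end) next
      rows[[length(rows) + 1L]] <- data.frame(
        fwd_start = fw$s1[i] - 1L, rev_end = rv$e1[j],
        fwd_len = fw$len[i], rev_len = rv$len[j],
        fwd_seq = fseq, rev_seq = rseq,
        pair_penalty = pen(fw$tm[i], fw$len[i], fw$gc[i]) +
          pen(rv$tm[j], rv$len[j], rv$gc[j]) +
          p@w_pair_diff * abs(fw$tm[i] - rv$tm[j]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out <- out[order(out$pair_penalty, out$fwd_start, out$rev_end,
                   out$fwd_len, out$rev_len), ]
  out <- out[!duplicated(paste(out$fwd_seq, out$rev_seq)), ]
  utils::head(out, p@n_return)
}

test_that("window-pair enumeration obeys amplicon geometry and poly-X rules", {
  p <- designParams()
  short <- enumerateCandidates(randSeq(120), p)
  expect_equal(nrow(short), 0L)
  expect_match(attr(short, "reason"), "shorter")

  set.seed(71)
  g <- randSeq(175)
  cand <- enumerateCandidates(g, p)
  expect_gt(nrow(cand), 0)
  expect_true(all(cand$amplicon_bp >= 125 & cand$amplicon_bp <= 175))
  expect_true(all(cand$amplicon_bp ==
                  cand$rev_end - cand$fwd_start))

  # a forward window containing the whole 6-run is never used
  g2 <- paste0(substr(g, 1, 50), "AAAAAA", substr(g, 57, 175))
  cand2 <- enumerateCandidates(g2, p)
  contains_run <- cand2$fwd_start <= 50 &
    (cand2$fwd_start + cand2$fwd_len) >= 56
  expect_false(any(contains_run))
})

test_that("primer penalty follows the documented linear form", {
  p <- designParams()
  at_opt <- data.frame(seq = strrep("AC", 10), length = 20, tm_c = 62,
                       gc_pct = 50, self_any = 0, self_end = 0, hairpin = 0)
  expect_equal(scorePrimer(at_opt, p)$penalty, 0)
  off <- at_opt; off$tm_c <- 63.2
  expect_equal(scorePrimer(off, p)$penalty, 1.2)
  off2 <- at_opt; off2$seq <- strrep("AC", 11)
  off2$tm_c <- 61; off2$length <- 22; off2$gc_pct <- 45
  expect_equal(scorePrimer(off2, p)$penalty, 1 + 2 + 0.5)
  hot <- at_opt; hot$tm_c <- 66
  expect_identical(scorePrimer(hot, p)$rejected, "tm")
  dimer <- at_opt; dimer$self_any <- 9
  expect_identical(scorePrimer(dimer, p)$rejected, "self_any")
})

test_that("designed pairs satisfy every constraint and are recomputable", {
  set.seed(72)
  p <- designParams()
  found <- 0L
  for (i in 1:6) {
    g <- randSeq(500)
    tab <- designPairs("gene", g, p)
    if (nrow(tab) == 0L) next
    found <- found + nrow(tab)
    expect_true(all(tab$amplicon_bp >= 125 & tab$amplicon_bp <= 175))
    expect_true(all(abs(tab$fwd_tm - tab$rev_tm) <= 1.5))
    for (j in seq_len(nrow(tab))) {
      r <- tab[j, ]
      # coordinates anchor the sequences on the template
      expect_identical(substr(g, r$fwd_start + 1,
                              r$fwd_start + r$fwd_len), r$fwd_seq)
      expect_identical(substr(g, r$rev_end - r$rev_len + 1, r$rev_end),
                       revComp(r$rev_seq))
      # thermodynamic columns recompute exactly from the primer sequences
      expect_equal(r$fwd_tm, meltingTemperature(r$fwd_seq), tolerance = 1e-12)
      expect_equal(r$rev_tm, meltingTemperature(r$rev_seq), tolerance = 1e-12)
      expect_equal(r$fwd_gc, gcContent(r$fwd_seq), tolerance = 1e-12)
      expect_equal(r$amplicon_bp, r$rev_end - r$fwd_start)
      expect_equal(r$pair_penalty,
                   r$fwd_penalty + r$rev_penalty +
                     abs(r$fwd_tm - r$rev_tm), tolerance = 1e-12)
    }
  }
  expect_gt(found, 0)
})

test_that("the engine reproduces the exhaustive oracle on short genes", {
  set.seed(73)
  p <- designParams(n_return = 5)
  checked <- 0L
  for (i in 1:8) {
    g <- randSeq(sample(200:400, 1))
    mine <- designPairs("g", g, p)
    oracle <- oracleDesign(g, p)
    if (is.null(oracle)) {
      expect_equal(nrow(mine), 0L)
      next
    }
    checked <- checked + 1L
    expect_equal(nrow(mine), nrow(oracle))
    expect_identical(paste(mine$fwd_seq, mine$rev_seq),
                     paste(oracle$fwd_seq, oracle$rev_seq))
    expect_equal(mine$pair_penalty, oracle$pair_penalty, tolerance = 1e-9)
  }
  expect_gt(checked, 2)
})

test_that("shrinking the product-size range never adds pairs", {
  set.seed(74)
  g <- randSeq(600)
  wide <- designPairs("g", g, designParams(product_min = 100,
                                           product_max = 200,
                                           n_return = 100000))
  narrow <- designPairs("g", g, designParams(product_min = 125,
                                             product_max = 175,
                                             n_return = 100000))
  keyW <- paste(wide$fwd_seq, wide$rev_seq)
  keyN <- paste(narrow$fwd_seq, narrow$rev_seq)
  expect_true(all(keyN %in% keyW))
})

test_that("design is deterministic to the byte", {
  set.seed(75)
  g <- randSeq(450)
  f1 <- tempfile(); f2 <- tempfile()
  writePrimerTable(designPairs("g", g, designParams()), f1)
  writePrimerTable(designPairs("g", g, designParams()), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("group-mode conservation flags 3'-end mismatches in target copies", {
  set.seed(76)
  g <- randSeq(400)
  p <- designParams()
  tab <- designPairs("g", g, p,
                     conservation_targets = list(A = g, B = g))
  expect_gt(nrow(tab), 0)
  expect_true(all(tab$conservation == "exact_in_all_targets"))

  # mutate B's copy under the forward primer's 3' terminus
  r <- tab[1, ]
  pos <- r$fwd_start + r$fwd_len      # 1-based position of fwd 3' base
  mutated <- g
  substr(mutated, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                       substr(g, pos, pos))[1]
  tab2 <- designPairs("g", g, p,
                      conservation_targets = list(A = g, B = mutated))
  r2 <- tab2[tab2$fwd_seq == r$fwd_seq & tab2$rev_seq == r$rev_seq, ]
  if (nrow(r2)) expect_identical(r2$conservation[1], "mismatched")
})

test_that("community-level design covers every genome with candidates", {
  plan <- communityPlan(seed = 77, n_genomes = 4)
  dir <- tempfile(); generateCommunity(plan, dir)
  cat1 <- buildCatalog(dir)
  cls <- classifyUnique(allVsAll(cat1), cat1)
  ranked <- rankCandidates(cls$calls, cat1)
  tab <- designForCommunity(ranked, cat1, designParams())
  expect_setequal(unique(tab$genome_id), genomeIds(cat1))
  per <- table(tab$genome_id)
  expect_true(all(per >= 1 & per <= 5))

  # a subsumed genome gets a warning and no rows
  plan2 <- communityPlan(
    seed = 78, n_genomes = 3,
    shared_families = data.frame(family = character(), identity = numeric()),
    subsumed = list(genome = "GEN03", donor = "GEN01", identity = 0.999))
  dir2 <- tempfile(); generateCommunity(plan2, dir2)
  cat2 <- buildCatalog(dir2)
  cls2 <- classifyUnique(allVsAll(cat2), cat2)
  ranked2 <- rankCandidates(cls2$calls, cat2)
  warns <- capture_warnings(tab2 <- designForCommunity(ranked2, cat2,
                                                       designParams()))
  expect_true(any(grepl("GEN03", warns)))
  expect_false("GEN03" %in% tab2$genome_id)
  expect_true("GEN03" %in% attr(tab2, "skipped"))
})
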