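test_that("k-mer seeding finds identical, homologous and reverse-complement pairs", {
  set.seed(21)
  s <- randSeq(300)
  genomes <- list(
    A = c(a1 = s, a2 = randSeq(300)),
    B = c(b1 = s,                       # identical copy
          b2 = as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(randSeq(300)))))
  )
  genomes$B[["b3"]] <- revComp <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(genomes$A[["a2"]])))
  cat1 <- buildCatalog(writeCommunity(genomes))
  pairs <- kmerCandidatePairs(cat1, k = 13)
  key <- paste(pairs$gene1, pairs$gene2, pairs$strand)
  expect_true("A|a1 B|b1 +" %in% key)
  expect_true("A|a2 B|b3 -" %in% key)
  # unrelated random pair absent
  expect_false(any(pairs$gene1 == "A|a1" & pairs$gene2 == "B|b2"))
  expect_error(kmerCandidatePairs(cat1, k = 6), ">= 8")
})

test_that("local alignment recovers identity, coverage and planted mutations", {
  set.seed(22)
  a <- randSeq(300)
  h <- localAlign(a, a)
  expect_equal(h$fident, 1)
  expect_equal(h$alnlen, 300L)
  expect_equal(h$qcov, 1); expect_equal(h$tcov, 1)
  expect_equal(h$score, 600L)

  b <- mutateToIdentity(a, 0.99, seed = 3)
  h2 <- localAlign(a, b)
  expect_equal(h2$fident, 0.99, tolerance = 1e-9)
  expect_equal(h2$alnlen, 300L)

  # unrelated repeats: best local identity too weak to pass default screen
  h3 <- localAlign(strrep("ACGT", 50), strrep("TTAA", 50))
  expect_lt(h3$score, 40)
})

test_that("internal aligner matches the full Smith-Waterman oracle", {
  mat <- swOracleMatrix()
  for (i in 1:40) {
    set.seed(100 + i)
    L <- sample(100:400, 1)
    a <- randSeq(L)
    b <- mutateToIdentity(a, runif(1, 0.7, 1), seed = 200 + i)
    if (i %% 4 == 0) {
      cut <- sample(40:(L - 50), 1)
      b <- paste0(substr(b, 1, cut), substr(b, cut + sample(1:3, 1) + 1, L))
    }
    h <- localAlign(a, b)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 5)
    expect_identical(h$score, as.integer(Biostrings::score(pa)))
    # our traceback reconstructs the optimal score, hence is itself optimal
    m <- as.integer(round(h$fident * h$alnlen))
    gapcols <- h$alnlen - m - h$mismatch
    expect_identical(2L * m - 3L * h$mismatch - 5L * gapcols, h$score)
  }
})

test_that("all-vs-all reports self-hits, mirrored cross hits, and honors identity", {
  genes <- makeGenes(5, len = 350, seed = 31)
  cat1 <- buildCatalog(writeCommunity(list(Z = genes)))
  hits <- allVsAll(cat1)
  expect_equal(nrow(hits), 5L)
  expect_true(all(hits$query == hits$target))
  expect_true(all(hits$fident == 1 & hits$qcov == 1 & hits$tcov == 1))

  set.seed(32)
  s <- randSeq(400)
  cat2 <- buildCatalog(writeCommunity(list(
    A = c(a1 = s, a2 = randSeq(400)),
    B = c(b1 = mutateToIdentity(s, 0.95, seed = 7), b2 = randSeq(400)))))
  h95 <- allVsAll(cat2)
  cross <- h95[h95$query != h95$target, ]
  expect_equal(nrow(cross), 2L)   # both orientations of the one homolog pair
  expect_setequal(cross$query, c("A|a1", "B|b1"))
  expect_true(all(abs(cross$fident - 0.95) < 0.005))

  h99 <- allVsAll(cat2, stringencyParams(min_identity = 0.99))
  expect_equal(sum(h99$query != h99$target), 0L)
  expect_equal(sum(h99$query == h99$target), 4L)  # self-hits never filtered
})

test_that("hit filtering is symmetric and monotone in every threshold", {
  set.seed(33)
  s1 <- randSeq(500)
  cat1 <- buildCatalog(writeCommunity(list(
    A = c(a1 = s1, a2 = randSeq(300)),
    B = c(b1 = mutateToIdentity(s1, 0.9, seed = 8),
          b2 = paste0(randSeq(150), substr(s1, 100, 260))))))
  base <- allVsAll(cat1)
  crossKey <- function(h) {
    cr <- h[h$query != h$target, ]
    paste(cr$query, cr$target)
  }
  # symmetry under cov_mode both: mirrored hit survives iff original does
  for (p in list(stringencyParams(), stringencyParams(min_coverage = 0.5),
                 stringencyParams(min_identity = 0.8, min_coverage = 0.3))) {
    k <- crossKey(filterHits(base, p))
    swapped <- vapply(strsplit(k, " "), function(x)
      paste(x[2], x[1]), character(1))
    expect_setequal(k, swapped)
  }
  # monotonicity: raising any threshold never adds hits
  grid <- list(
    list(a = stringencyParams(0.3), b = stringencyParams(0.6)),
    list(a = stringencyParams(min_aln_len = 50),
         b = stringencyParams(min_aln_len = 200)),
    list(a = stringencyParams(min_coverage = 0.2),
         b = stringencyParams(min_coverage = 0.6)))
  for (g in grid) {
    expect_true(all(crossKey(filterHits(base, g$b)) %in%
                    crossKey(filterHits(base, g$a))))
  }
  # self-hits survive any threshold combination
  strict <- filterHits(base, stringencyParams(0.99, 1e4, 1))
  expect_true(all(geneIds(cat1) %in% strict$query[strict$query == strict$target]))
})

test_that("external hit tables parse, auto-scale identity and validate ids", {
  genes <- makeGenes(2, len = 300, seed = 41)
  cat1 <- buildCatalog(writeCommunity(list(G = genes)))
  g1 <- geneIds(cat1)[1]; g2 <- geneIds(cat1)[2]
  path <- tempfile()
  writeLines(c(
    sprintf("%s %s 1.000 300 0 0 1 300 1 300 1e-50 500", g1, g1),
    sprintf("%s %s 99.0 150 1 0 1 150 51 200 1e-20 200", g1, g2)), path)
  hits <- loadExternalHits(path, cat1)
  expect_equal(hits$qcov[1], 1)
  expect_equal(hits$fident[2], 0.99)   # percent scale auto-detected
  expect_equal(hits$tcov[2], 0.5)

  writeLines(sprintf("%s gX 1.0 10 0 0 1 10 1 10 1 20", g1), path)
  expect_error(loadExternalHits(path, cat1), "unknown gene 'gX'")
  writeLines("too few columns", path)
  expect_error(loadExternalHits(path, cat1), "line 1")
})
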