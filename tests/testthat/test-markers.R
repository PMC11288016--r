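makePlantedCommunity <- function(seed = 51, n_genomes = 3, n_private = 5) {
  plan <- communityPlan(
    seed = seed, n_genomes = n_genomes, n_private = n_private,
    shared_families = data.frame(family = "fam1", identity = 0.95))
  dir <- tempfile("planted"); mf <- generateCommunity(plan, dir)
  list(catalog = buildCatalog(dir), manifest = mf)
}

test_that("planted private genes are unique and shared genes are not", {
  fx <- makePlantedCommunity()
  hits <- allVsAll(fx$catalog)
  cls <- classifyUnique(hits, fx$catalog)
  expect_true(all(cls$summary$n_unique == 5))
  truthUnique <- fx$manifest$gene_id[fx$manifest$role == "private"]
  calledUnique <- cls$calls$gene_id[cls$calls$status == "unique"]
  expect_setequal(calledUnique, truthUnique)  # precision = recall = 1
  shared <- fx$manifest$gene_id[startsWith(fx$manifest$role, "shared")]
  expect_true(all(cls$calls$status[cls$calls$gene_id %in% shared] ==
                  "non_unique"))
  # partition: every gene gets exactly one call
  expect_setequal(cls$calls$gene_id, geneIds(fx$catalog))
  expect_false(anyDuplicated(cls$calls$gene_id) > 0)
})

test_that("a genome subsumed by a close relative has zero unique genes", {
  plan <- communityPlan(
    seed = 52, n_genomes = 3, n_private = 6,
    shared_families = data.frame(family = character(),
                                 identity = numeric()),
    subsumed = list(genome = "GEN03", donor = "GEN01", identity = 0.999))
  dir <- tempfile(); generateCommunity(plan, dir)
  cat1 <- buildCatalog(dir)
  cls <- classifyUnique(allVsAll(cat1), cat1)
  s <- cls$summary
  expect_equal(s$n_unique[s$genome_id == "GEN03"], 0L)
  expect_equal(s$n_unique[s$genome_id == "GEN01"], 0L)  # donor also covered
  expect_equal(s$n_unique[s$genome_id == "GEN02"], 6L)
  # summary ordered by descending unique count
  expect_true(!is.unsorted(rev(s$n_unique)))
})

test_that("within-genome duplicates are multi_copy, not unique", {
  plan <- communityPlan(
    seed = 53, n_genomes = 2, n_private = 3,
    shared_families = data.frame(family = character(), identity = numeric()),
    n_duplicated = 1)
  dir <- tempfile(); mf <- generateCommunity(plan, dir)
  cat1 <- buildCatalog(dir)
  cls <- classifyUnique(allVsAll(cat1), cat1)
  dup_ids <- mf$gene_id[mf$role == "duplicate"]
  expect_true(all(cls$calls$status[cls$calls$gene_id %in% dup_ids] ==
                  "multi_copy"))
  # the originals they duplicate are multi_copy too
  expect_equal(sum(cls$calls$status == "multi_copy"), 2L * length(dup_ids))
})

test_that("classification is invariant to hit-row order", {
  fx <- makePlantedCommunity(seed = 54)
  hits <- allVsAll(fx$catalog)
  set.seed(1)
  shuffled <- hits[sample.int(nrow(hits)), ]
  a <- classifyUnique(hits, fx$catalog)
  b <- classifyUnique(shuffled, fx$catalog)
  expect_identical(a$calls[c("gene_id", "status")],
                   b$calls[c("gene_id", "status")])
  expect_identical(a$summary, b$summary)
})

test_that("unique-gene count is non-decreasing in the identity threshold", {
  set.seed(55)
  base <- replicate(4, randSeq(500), simplify = FALSE)
  genomes <- list(
    A = c(a1 = base[[1]], a2 = base[[2]], a3 = base[[3]], a4 = base[[4]]),
    B = c(b1 = mutateToIdentity(base[[1]], 0.92, seed = 1),
          b2 = mutateToIdentity(base[[2]], 0.95, seed = 2),
          b3 = mutateToIdentity(base[[3]], 0.98, seed = 3),
          b4 = randSeq(500)))
  cat1 <- buildCatalog(writeCommunity(genomes))
  counts <- vapply(c(0.3, 0.6, 0.9, 0.99), function(p) {
    cls <- classifyUnique(allVsAll(cat1, stringencyParams(p)), cat1)
    sum(cls$summary$n_unique)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_lt(counts[1], counts[4])   # thresholds actually bite on this fixture
})

test_that("group-shared genes need every group member and no outsiders", {
  set.seed(56)
  fam <- randSeq(600)
  mk <- function(idt, seed) mutateToIdentity(fam, idt, seed = seed)
  genomes <- list(
    A = c(a1 = mk(0.97, 1), a2 = randSeq(400)),
    B = c(b1 = mk(0.97, 2), b2 = randSeq(400)),
    C = c(c1 = mk(0.97, 3), c2 = randSeq(400)),
    D = c(d1 = randSeq(400)))
  cat1 <- buildCatalog(writeCommunity(genomes))
  hits <- allVsAll(cat1)
  grp <- classifyGroup(hits, cat1, group = c("A", "B", "C"))
  shared <- grp$gene_id[grp$status == "group_shared"]
  expect_setequal(shared, c("A|a1", "B|b1", "C|c1"))
  # private genes of group members are not group markers
  expect_true(all(grp$status[grp$gene_id %in% c("A|a2", "B|b2", "C|c2")] ==
                  "non_unique"))

  # an outside-group homolog poisons every copy
  genomes$D <- c(d1 = genomes$D[["d1"]], d2 = mk(0.90, 4))
  cat2 <- buildCatalog(writeCommunity(genomes))
  grp2 <- classifyGroup(allVsAll(cat2), cat2, group = c("A", "B", "C"))
  expect_true(all(grp2$status[grp2$gene_id %in%
                              c("A|a1", "B|b1", "C|c1")] ==
                  "excluded_ambiguous"))

  expect_error(classifyGroup(hits, cat1, group = "A"), "at least two")
  expect_error(classifyGroup(hits, cat1, group = c("A", "Zz")), "unknown")
})

test_that("candidates are ranked by decreasing length with stable ties", {
  genomes <- list(G = c(g1 = randSeq(900), g2 = randSeq(1200),
                        g3 = randSeq(300), g4 = randSeq(900)))
  cat1 <- buildCatalog(writeCommunity(genomes))
  calls <- data.frame(
    gene_id = geneIds(cat1), genome_id = "G",
    status = "unique", stringsAsFactors = FALSE)
  ranked <- rankCandidates(calls, cat1)
  expect_identical(ranked$G, c("G|g2", "G|g1", "G|g4", "G|g3"))
  # no eligible genes -> empty vector, not an error
  calls$status <- "non_unique"
  expect_length(rankCandidates(calls, cat1)$G, 0L)
})
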