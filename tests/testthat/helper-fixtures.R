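# Fixture helpers: small communities built in code, written as temporary
# FASTA files so the I/O path is exercised.

randSeq <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# genomes: named list genome_id -> named character vector (token -> seq)
writeCommunity <- function(genomes, dir = tempfile("comm"),
                           suffix = "_cds.fna") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (g in names(genomes)) {
    seqs <- genomes[[g]]
    lines <- unlist(lapply(names(seqs), function(tok)
      c(paste0(">", tok), seqs[[tok]])))
    writeLines(lines, file.path(dir, paste0(g, suffix)))
  }
  dir
}

# deterministic unrelated gene set
makeGenes <- function(n, len = 400, gc = 0.5, seed = 1) {
  set.seed(seed)
  stats::setNames(
    vapply(seq_len(n), function(i) randSeq(len, gc), character(1)),
    sprintf("g%03d", seq_len(n)))
}

# brute-force antiparallel complementarity oracle (mirrors the documented
# scoring rule, implemented independently of the compiled path)
oracleCompScore <- function(a, b, anchor_end = FALSE, min_loop = -1L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  best <- 0L
  for (off in 0:(la + lb - 2)) {
    run <- 0L
    for (i in max(0, off - lb + 1):min(la - 1, off)) {
      j <- off - i
      if (min_loop >= 0 && j - i - 1 < min_loop) next
      run <- run + if (comp[[av[i + 1]]] == bv[j + 1]) 1L else -1L
      if (run < 0L) run <- 0L
      if (!anchor_end && run > best) best <- run
      if (anchor_end && i == la - 1 && run > best) best <- run
    }
  }
  best
}

swOracleMatrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                           baseOnly = TRUE)
}
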