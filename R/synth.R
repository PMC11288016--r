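# Deterministic RNG scope: run code under a seed without disturbing the
# caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

randomSeq <- function(len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

#' Construct a synthetic community plan
#'
#' The default plan is a ten-genome community in which every genome carries
#' five private (unique) genes and a copy of each of two community-wide
#' shared gene families at 95% identity to the family founder -- i.e. a
#' defined community whose members are clearly distinguishable, with the
#' shared families comfortably above a 0.3 identity screen. Gene lengths
#' are uniform in 400-800 bp at 50% GC, a realistic size range for
#' bacterial CDSs that leaves room for a 125-175 bp amplicon.
#'
#' @param seed Integer RNG seed (default 1).
#' @param n_genomes Number of genomes (default 10).
#' @param genomes Genome ids (default `sprintf("GEN%02d", ...)`).
#' @param n_private Private genes per genome (default 5).
#' @param shared_families data.frame(`family`, `identity`); default two
#'   all-member families at identity 0.95.
#' @param n_duplicated Per-genome count of private genes planted twice
#'   (default 0).
#' @param subsumed Optional `list(genome =, donor =, identity =)`: the
#'   genome's entire gene set becomes mutated copies of the donor's
#'   (no private genes), emulating a substrain with no unique genes.
#' @param len_range Gene length range, bp (default c(400, 800)).
#' @param gc GC fraction (default 0.5).
#' @param dialect Header dialect to emit (default `"prokka"`).
#' @return A validated [CommunityPlan-class] object.
#' @export
communityPlan <- function(seed = 1L, n_genomes = 10L,
                          genomes = sprintf("GEN%02d", seq_len(n_genomes)),
                          n_private = 5L,
                          shared_families = data.frame(
                            family = c("shared1", "shared2"),
                            identity = c(0.95, 0.95)),
                          n_duplicated = 0L, subsumed = list(),
                          len_range = c(400L, 800L), gc = 0.5,
                          dialect = "prokka") {
  new("CommunityPlan", seed = seed, genomes = genomes,
      n_private = n_private, shared_families = shared_families,
      n_duplicated = n_duplicated, subsumed = subsumed,
      len_range = len_range, gc = gc, dialect = dialect)
}

#' Mutate a sequence to an exact target identity
#'
#' Substitution-only mutant with exactly `round(len * (1 - identity))`
#' mismatches at positions drawn deterministically from the seed; each
#' mutated base becomes one of the three other bases.
#'
#' @param seq Sequence to mutate.
#' @param target_identity Identity in (0, 1].
#' @param seed RNG seed.
#' @return Mutated sequence of the same length.
#' @examples
#' s <- strrep("ACGT", 75)
#' m <- mutateToIdentity(s, 0.99, seed = 7)
#' sum(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])   # 3
#' @export
mutateToIdentity <- function(seq, target_identity, seed = 1L) {
  if (target_identity <= 0 || target_identity > 1)
    cpStop("target identity must lie in (0, 1]")
  L <- nchar(seq)
  nmut <- round(L * (1 - target_identity))
  if (nmut == 0L) return(seq)
  withSeed(seed, {
    pos <- sample.int(L, nmut)
    chars <- strsplit(seq, "")[[1]]
    for (i in pos) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
    paste(chars, collapse = "")
  })
}

formatHeader <- function(genome, idx, dialect) {
  tag <- sprintf("%s_%05d", genome, idx)
  switch(dialect,
    prokka = sprintf("%s hypothetical protein", tag),
    rast = sprintf("fig|123.%d.peg.%d_CDS_%d synthetic feature",
                   idx, idx, idx),
    ncbi = sprintf("lcl|%s_cds_%d [locus_tag=%s]", genome, idx, tag))
}

#' Generate a synthetic CDS community with planted truth
#'
#' Writes one `<genome>_cds.fna` file per genome of the plan and returns a
#' truth manifest mapping every gene to its planted role: `private` (unique
#' to its genome), `shared:<family>` (homolog family member at the planned
#' identity), `duplicate` (second copy of a private gene in the same
#' genome) or `homolog_of:<donor gene>` (subsumed-genome copies). The same
#' seed yields byte-identical files.
#'
#' @param plan A [CommunityPlan-class] object.
#' @param out_dir Output directory (created if needed).
#' @return data.frame manifest: `gene_id` (as the catalog will name it),
#'   `genome_id`, `role`, `family`, `identity`, `length`, invisibly also
#'   written to `out_dir/truth_manifest.tsv`.
#' @export
generateCommunity <- function(plan, out_dir) {
  stopifnot(is(plan, "CommunityPlan"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  sub <- plan@subsumed
  withSeed(plan@seed, {
    founders <- lapply(seq_len(nrow(plan@shared_families)), function(i)
      randomSeq(sample(seq(plan@len_range[1], plan@len_range[2]), 1L),
                plan@gc))
    names(founders) <- plan@shared_families$family

    manifest <- list()
    gene_bank <- list()   # per genome: named list token -> seq
    for (g in plan@genomes) {
      idx <- 0L
      genes <- list()     # token -> sequence
      headers <- character()
      addGene <- function(seqs, role, family = NA, identity = NA) {
        for (s in seqs) {
          idx <<- idx + 1L
          hdr <- formatHeader(g, idx, plan@dialect)
          tok <- strsplit(hdr, "[ \t]+")[[1]][1]
          genes[[tok]] <<- s
          headers <<- c(headers, hdr)
          manifest[[length(manifest) + 1L]] <<- data.frame(
            gene_id = paste0(g, "|", tok), genome_id = g, role = role,
            family = family, identity = identity, length = nchar(s),
            stringsAsFactors = FALSE)
        }
      }
      if (length(sub) && identical(g, sub$genome)) {
        donor <- gene_bank[[sub$donor]]
        if (is.null(donor))
          cpStop("subsumed donor '%s' must precede '%s' in the genome list",
                 sub$donor, g)
        for (tok in names(donor)) {
          m <- mutateToIdentity(donor[[tok]], sub$identity,
                                seed = sample.int(2^31 - 1L, 1L))
          addGene(list(m), role = paste0("homolog_of:", sub$donor, "|", tok),
                  identity = sub$identity)
        }
      } else {
        priv <- replicate(plan@n_private,
                          randomSeq(sample(seq(plan@len_range[1],
                                               plan@len_range[2]), 1L),
                                    plan@gc), simplify = FALSE)
        addGene(priv, role = "private")
        if (plan@n_duplicated > 0L) {
          ndup <- min(plan@n_duplicated, length(priv))
          addGene(priv[seq_len(ndup)], role = "duplicate")
        }
        for (i in seq_len(nrow(plan@shared_families))) {
          fam <- plan@shared_families$family[i]
          idt <- plan@shared_families$identity[i]
          m <- mutateToIdentity(founders[[fam]], idt,
                                seed = sample.int(2^31 - 1L, 1L))
          addGene(list(m), role = paste0("shared:", fam), family = fam,
                  identity = idt)
        }
      }
      gene_bank[[g]] <- genes

      lines <- unlist(lapply(seq_along(genes), function(i)
        c(paste0(">", headers[i]), genes[[i]])))
      con <- file(file.path(out_dir, paste0(g, "_cds.fna")), open = "wb")
      writeLines(lines, con = con, sep = "\n")
      close(con)
    }
    mf <- do.call(rbind, manifest)
    rownames(mf) <- NULL
    writeTsv(mf, file.path(out_dir, "truth_manifest.tsv"))
    mf
  })
}
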