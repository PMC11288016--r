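# CommunityPrimers

Taxon-specific PCR primer design for defined microbial communities.

Given one coding-sequence (CDS) FASTA file per genome, `CommunityPrimers`
finds genes carried by exactly one community member (or shared by a chosen
group of members and absent everywhere else) and designs PCR primer pairs
on them under thermodynamic and product-size constraints. Such primers let
you detect and absolutely quantify individual strains — down to substrains
that differ by only a handful of genes — by ordinary PCR, qPCR or droplet
digital PCR (ddPCR), without sequencing.

It is aimed at microbiome researchers working with defined consortia
(gnotobiotic communities, synthetic ecology experiments, strain libraries)
and at anyone who needs strain-resolved detection where 16S amplicons have
no discriminatory power.

## What it computes

1. **All-vs-all homology screen.** Every CDS is locally aligned against
   every other CDS with a k-mer-seeded, banded Smith–Waterman engine
   (match +2 / mismatch −3 / gap −5; exact-optimal on the tested range),
   or with an external MMseqs2-compatible hit table via an adapter. Hits
   are filtered by minimum fraction identity (default 0.3), alignment
   length, coverage and coverage mode.
2. **Marker classification.** A gene whose only surviving hit is its
   self-hit is *unique* (microbe-specific candidate); a gene hitting a
   different gene of its own genome is *multi-copy* (excluded — it would
   skew copy-number quantification); in group mode, a gene hitting every
   group genome and no outside genome is *group-shared*.
3. **Primer design.** Candidate genes are walked in decreasing length;
   every admissible primer-window pair (default: 18–27 nt primers,
   125–175 bp amplicon, Tm 62 ± 3 °C, pair ΔTm ≤ 1.5 °C, GC 30–70%,
   GC clamp, poly-X ≤ 5, dimer/hairpin caps) is scored by the penalty
   `w_tm·|Tm − Tm_opt| + w_size·|len − len_opt| + w_gc·|GC − GC_opt|/10`
   summed over the pair plus `w_pair·|ΔTm|`, and the best `n_return`
   pairs are reported. Melting temperatures use the unified
   nearest-neighbor model (SantaLucia 1998) with the Owczarzy 2008
   divalent salt correction at Tm = 1000·ΔH/(ΔS + R·ln(CT/4)) − 273.15.
4. **Quantification arithmetic.** Genomic copies/µL =
   X·6.0221×10²³/(N·660)·10⁻⁹ for X ng/µL and an N-bp genome;
   equal-genomic-copy pooling volumes; ddPCR absolute counts to relative
   abundance (with optional member drops).
5. **Synthetic communities.** A seeded generator plants private genes,
   shared gene families at exact target identities, duplicates and
   subsumed genomes, so every stage is testable against known truth.

## Worked example

Generate a three-genome synthetic community (five private genes plus two
community-wide shared gene families per genome), screen it, and design two
microbe-specific primer pairs per member:

```r
library(CommunityPrimers)

dir <- tempfile()
plan <- communityPlan(seed = 42, n_genomes = 3)
generateCommunity(plan, dir)

catalog <- buildCatalog(dir)
catalog
#> CommunityCatalog: 3 genomes (3 target, 0 non-target), 21 CDSs
#>   GEN01                              7 genes [target]
#>   GEN02                              7 genes [target]
#>   GEN03                              7 genes [target]

hits <- allVsAll(catalog)                   # min identity 0.3 by default
cls  <- classifyUnique(hits, catalog)
cls$summary
#>   genome_id n_unique n_total fraction_unique
#> 1     GEN01        5       7       0.7142857
#> 2     GEN02        5       7       0.7142857
#> 3     GEN03        5       7       0.7142857

tab <- designForCommunity(rankCandidates(cls$calls, catalog), catalog,
                          designParams(n_return = 2))
tab[, c("genome_id", "pair_penalty", "amplicon_bp",
        "fwd_seq", "rev_seq", "fwd_tm", "rev_tm")]
#>   genome_id pair_penalty amplicon_bp              fwd_seq              rev_seq   fwd_tm   rev_tm
#> 1     GEN01     1.119764         166 CGTTGCTCTACAGCTCCACA ATGAGTGATTTGCGTCCCGT 61.87477 61.69012
#> 2     GEN01     1.119764         163 TGCTCTACAGCTCCACAACG ATGAGTGATTTGCGTCCCGT 61.87477 61.69012
#> 3     GEN02     1.150644         134 GGATGCGCAGTATCCATCCA GAACGAATCAGCAGACGGGA 61.96731 61.92468
#> 4     GEN02     1.172692         139 AGCTGTGAAATGCCGGAAGA ATAGAAACCACTGGGCTGGG 61.71232 61.66365
#> 5     GEN03     0.694500         153 TTTACCAAAGCCAGCGTCGT CGAGCTTATTTCCGCTCCCA 62.09725 62.06749
#> 6     GEN03     0.940488         155 CGCACACCAATCTTGAAGCG TGAAAGGGGTGCGGTTTTGA 61.97425 62.19449
```

Each genome gets five unique genes (exactly the planted private genes; the
two shared families align across all members and are excluded). Every
emitted pair sits on a unique gene of its genome, amplifies a 125–175 bp
product, and holds both primers within 1.5 °C of each other near the
62 °C optimum; the penalty is the documented deviation sum, so row 5 —
penalty 0.69 — is the closest to ideal. For wet-lab pooling,
`genomicCopies(2.1, 4.2e6)` says a 2.1 ng/µL stock of a 4.2 Mbp genome
carries 456,219.7 copies/µL.

The same workflow runs from a shell:

```sh
community-primers align   --target-dir cds/ --out-dir out/
community-primers primers --hit-table out/hit_table.tsv \
                          --target-dir cds/ --out-dir out/
```

producing `hit_table.tsv`, `unique_genes.tsv` (the unique-genes bar-plot
data, sorted by descending unique count) and `UniquePrimerTable.tsv`
(`GroupPrimerTable.tsv` with `--mode group --group a,b,c`, including a
per-target conservation flag).

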