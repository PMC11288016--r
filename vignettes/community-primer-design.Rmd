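---
title: "Designing taxon-specific primers in defined microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing taxon-specific primers in defined microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CommunityPrimers)
```

## The problem

In a defined microbial community — a gnotobiotic consortium, a synthetic
community experiment, a strain library — one often needs to detect or
quantify a single member, or a chosen group of members, against the
background of everyone else. PCR with taxon-specific primers is the cheap,
sensitive way to do this, and droplet digital PCR (ddPCR) turns it into
absolute quantification. The hard part is finding genes on which such
primers can be placed: a *microbe-specific* primer pair must sit on a gene
with no homolog anywhere else in the community, and a *group-specific* pair
must sit on a gene shared by every intended target and absent from every
non-target.

`CommunityPrimers` automates this end to end. Starting from one
coding-sequence (CDS) FASTA file per genome, it (1) screens every CDS
against every other CDS for local homology, (2) classifies genes as unique,
group-shared, multi-copy or cross-reactive, (3) enumerates and ranks primer
pairs on the candidate genes under thermodynamic and size constraints, and
(4) provides the copy-number arithmetic needed to pool genomes at equal
genomic copies and to convert ddPCR absolute counts into relative
abundances.

## The homology screen

Marker discovery reduces to one question per gene: *which other genes does
it align to, at the chosen stringency?*

The screen is an all-vs-all local alignment of the community's CDSs. The
internal engine seeds candidate gene pairs with shared exact k-mers
(k = 13 by default; any pair whose true alignment contains an exact
13-mer is guaranteed to be considered) and extends each candidate with a
banded Smith–Waterman around the seed diagonals (half-width 16 on either
side of the outermost seeds). Scoring is linear-gap: match +2, mismatch
−3, gap −5 per base. On sequences where the band covers the whole matrix
this is exact Smith–Waterman, and the test suite verifies score-level
optimality against an independent full dynamic-programming implementation
(`Biostrings::pairwiseAlignment`).

Two numerical conventions matter downstream:

* **Identity** is matches divided by alignment columns (gap columns
  count), the convention of the common tabular alignment formats. One
  caveat the test suite makes explicit: when two different local
  alignments achieve the same optimal score (co-optima), their identities
  can legitimately differ — by up to one column's worth per column of
  difference in their extents. Our checks therefore assert exact score
  optimality, verify that the reported alignment *reconstructs* the
  optimal score from its own match/mismatch/gap counts, and bound the
  identity disagreement by that structural limit rather than asserting a
  unique identity value.
* **Reporting floor.** The engine only reports alignments with raw score
  ≥ 40 (a perfect ~20-mer). Alignment-based screens conventionally
  suppress chance micro-alignments with an E-value cutoff; this engine
  does not compute E-values (the column is emitted as `NA`), so a
  raw-score floor plays that role. Without it, a chance shared 13-mer
  between two unrelated genes would surface as a short `fident = 1.0`
  hit and spuriously destroy the uniqueness of a genuinely unique gene.

Cross-genome CDS pairs are compared on the plus strand by default, since
CDS files are sense-strand and homologous CDSs share the coding strand; a
`both_strands` option also scans reverse complements.

Reported hits then pass a stringency filter with four knobs: minimum
identity (default 0.3), minimum alignment length (0), minimum coverage
(0), and the coverage mode (`both`/`either`/`query`/`target`, default
`both` = min of query and target coverage). The filter is applied to
reported hits, which gives the thresholds a clean monotone meaning:
*raising* the identity threshold discards hits and can only *increase* the
number of genes called unique — along with the risk that those extra
"unique" genes are false positives, which is why the default is a
permissive 0.3. An adapter ingests external 12+-column tabular alignment
files (MMseqs2/BLAST outfmt-6 convention) in place of the internal engine,
with identity accepted on either the 0–1 or 0–100 scale (auto-detected).

## Marker classification

With surviving hits in hand, classification is a set of per-gene rules:

* **unique** — the gene's only surviving hit is its self-hit. These are
  the microbe-specific candidates.
* **multi_copy** — the gene hits a *different gene of its own genome*
  (and nothing elsewhere). Duplicated genes are deliberately ineligible:
  a primer on a two-copy gene doubles the apparent copy number in
  quantitative PCR.
* **non_unique** — the gene hits another genome.
* **group_shared** (group mode) — the gene has at least one surviving hit
  into *every* other genome of the user-defined group and none outside
  it. A hit to any outside genome makes it **excluded_ambiguous**.

The group rule is evaluated from each gene's own hits only; we do not
chase transitive partner-of-partner links, so the check is deterministic
and order-independent. It is also deliberately asymmetric (gene g of
genome A must hit B, C, ...; their reciprocal hits are not required),
which the symmetric default coverage mode makes moot in practice.
Non-target genomes participate only as exclusion evidence — they never
receive candidates.

Candidate genes are ranked by decreasing length (longer templates offer
more primer placements), ties broken lexicographically, and genes with
more than 5% ambiguous bases are dropped because `N`s have no
nearest-neighbor parameters. Per-genome unique/total counts are reported
in descending-unique order, the ordering used for the unique-genes bar
plot data: it makes community redundancy visible at a glance.

## Oligo thermodynamics

Melting temperatures come from the unified nearest-neighbor model
(SantaLucia 1998 parameter set): the duplex ΔH/ΔS is the sum of the
sixteen dinucleotide stacking terms plus terminal A/T (+2.3 kcal/mol,
+4.1 cal/mol/K per end) and G/C (+0.1, −2.8) initiation corrections, and

Tm = 1000·ΔH / (ΔS + R·ln(CT/4)) − 273.15

with CT the primer concentration (the CT/4 convention for
non-self-complementary duplexes). The result is then salt-corrected on
the 1/Tm scale with the Owczarzy 2008 divalent-cation formula, including
Mg²⁺ chelation by dNTPs and the fall-back to the monovalent-only 2004
formula when free Mg²⁺ is negligible. Default conditions are the
conventional PCR-buffer values: 50 mM monovalent, 1.5 mM Mg²⁺, 0.6 mM
dNTPs, 250 nM primer; all four are exposed via `thermoConditions()`
because published Tm targets rarely state them. The test suite holds this
implementation within 0.5 °C of an independent implementation of the same
published model (Biopython's `MeltingTemp`) over 1,000 random oligos; the
observed agreement is at the 10⁻⁶ °C level.

One numerical choice is worth stating: final Tm values are quantized to a
microdegree. The primer search computes window Tm from cumulative
dinucleotide tables (O(1) per window) while verification recomputes each
primer from scratch; quantization makes the two float summation orders
agree bit-for-bit, so penalty ties break identically everywhere and
outputs are byte-reproducible.

Dimer and hairpin propensity use the classic ungapped antiparallel
complementarity score: +1 per complementary pair, −1 otherwise, floored
at zero, maximized over all relative offsets (`any`), optionally anchored
at the 3′ terminus (`end`), and against the oligo itself with a minimum
loop of 3 for hairpins. These are alignment scores, not free energies —
a deliberate trade of physical fidelity for transparency and speed, in
the tradition of Primer3's `SELF_ANY`/`SELF_END`.

## Primer pair search

For each candidate gene, every window of 18–27 nt is profiled (Tm, GC,
mononucleotide runs) in O(1) per window via cumulative tables. Hard
filters remove windows with non-ACGT bases, runs longer than 5, Tm
outside [opt − 3, opt + 3] (optimum 62 °C by default), GC outside
30–70%, a missing G/C in the two 3′-terminal bases (the GC clamp,
configurable off), or self-complementarity above the caps
(any > 8, end > 3, hairpin > 8). Surviving forward and reverse windows
are paired under the amplicon constraint (125–175 bp by default — a
ddPCR-friendly product size), the pair Tm difference cap (1.5 °C), and a
forward/reverse cross-dimer check with the same caps.

Admissible pairs are ranked by the penalty

penalty = w_tm·|Tm − Tm_opt| + w_size·|len − len_opt| + w_gc·|GC − GC_opt|/10

per primer, summed over the pair plus w_pair·|ΔTm|, all weights 1 by
default. The functional form is deliberately simple and fully disclosed so
every table value can be recomputed from the primer sequences alone; the
test suite verifies the engine against an independent exhaustive
enumeration on short genes (identical top-n sets, identical order). Ties
break on (forward start, reverse end, lengths); identical sequence pairs
are deduplicated; the top `n_return` (default 5) are emitted.

At the community level, the designer walks each genome's ranked candidates
until `n_return` pairs accumulate. A genome with no candidates — the
expected outcome for a substrain whose gene set is entirely covered by a
close relative — produces a warning and an empty section, not an error.
In group mode, primers are designed on the group member with the longest
copy of the shared gene, and every primer is exact-substring-checked
against each target's copies: pairs are flagged `exact_in_all_targets`
or `mismatched`. Divergent copies are handled the way practitioners do it
— raise `n_return` and pool multiple pairs into a cocktail — rather than
by enforcing conservation, which would silently discard usable designs.

## Copy-number arithmetic

Genomic copies per µL from a gDNA concentration X (ng/µL) and genome size
N (bp):

copies/µL = X · 6.0221×10²³ / (N · 660) · 10⁻⁹

where 660 g/mol/bp is the mean double-stranded base-pair mass and the
10⁻⁹ converts nanograms to grams (the formula is sometimes typeset with
"×10⁹ ng/g" on the denominator's side — dimensionally the same
conversion; writing the unit cancellation out: ng · (molecules/mol) /
(bp · g/mol/bp) · g/ng = molecules). At 1 ng/µL and 1 Mbp this gives
912,439.4 copies/µL. Equal-copy pooling assigns volumes proportional to
1/(copies/µL), normalized to the pool volume; ddPCR counts convert to
relative abundance by dividing each member's copies/µL by the community
sum, with an option to drop members (e.g. one for which no specific
primer could be designed) from both numerator and denominator so the
remaining fractions still sum to one.

## The synthetic community generator

Validation needs communities where the truth is known. The generator
plants, per genome: private genes (unique by construction), copies of
community-wide gene families mutated to an exact target identity
(substitution-only, so planted identity is exact: `round(L·(1−identity))`
mismatches), optional within-genome duplicates, and optionally one genome
that is entirely a near-identical mutated copy of another (the
zero-unique-genes scenario). The default plan — ten genomes, five private
genes plus two all-member shared families at 0.95 identity, gene lengths
uniform in 400–800 bp at 50% GC — is a defined community of clearly
distinguishable members whose shared families sit comfortably above the
0.3 identity screen, with genes long enough to host a 125–175 bp
amplicon. Output is byte-identical for a fixed seed, in any of the three
supported FASTA header dialects.

What the generator does *not* emulate: real codon usage and GC skew,
operon structure, indel divergence (an indel mode exists for aligner
stress tests but planted identities are then approximate), mobile
elements, or contig-level assembly artifacts. Passing the planted-truth
tests therefore demonstrates that the classification logic is correct at
the stated stringencies — not that any particular real community will
yield unique genes, which depends on its actual gene-content overlap, as
the zero-unique-genes scenario illustrates.

## Problem sizes used in validation

The shipped test suite and the acceptance script run on: the default
ten-genome community (70 CDSs) for planted-truth recovery, primer
validity and end-to-end determinism; a three-genome community with one
subsumed member for the zero-unique-genes case; a two-genome fixture with
homologs at 0.92–0.995 identity for threshold monotonicity; 200 seeded
pairs of 120–500 bp for aligner optimality; and 1,000 random 18–27-mers
for the Tm cross-check. These sizes keep a full validation run in the
minutes range on one CPU while exercising every code path; the engines
themselves scale to communities in the low hundreds of genomes.

## Known limitations

* The internal aligner's k-mer seeding bounds sensitivity: homolog pairs
  below roughly 60–70% identity may lack a shared exact 13-mer over CDS
  lengths and be missed. For such communities, run an external
  aligner and load its tabular output via the adapter.
* Complementarity scores are not thermodynamic ΔG; strongly
  GC-skewed dimers can be under- or over-penalized relative to a
  partition-function model.
* Uniqueness is assessed at the gene level against the provided CDS
  catalog only — primers are not screened against whole genomes or
  against taxa absent from the input, so specificity in complex
  communities is only as good as the non-target list is complete.
* Multi-copy exclusion relies on duplicated genes appearing as separate
  CDS entries; collapsed repeats in fragmented assemblies will evade it.
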