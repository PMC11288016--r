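# Unified nearest-neighbor parameters (SantaLucia 1998 / Allawi & SantaLucia
# 1997): duplex propagation dH (kcal/mol) and dS (cal/mol/K) indexed by the
# 5'->3' dinucleotide of one strand, plus terminal initiation corrections.
NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
INIT_AT <- c(dh = 2.3, ds = 4.1)   # per terminal A/T base pair
INIT_GC <- c(dh = 0.1, ds = -2.8)  # per terminal G/C base pair
GAS_R <- 1.987                     # cal / (mol K)

#' GC content of oligonucleotides
#'
#' @param seq Character vector of A/C/G/T sequences.
#' @return Percent GC in `[0, 100]` (full precision; round on output).
#' @examples
#' gcContent(c("ATGC", "GGGG", "ATAT"))
#' @export
gcContent <- function(seq) {
  seq <- toupper(seq)
  if (any(!nzchar(seq)) || any(grepl("[^ACGT]", seq)))
    cpStop("gcContent needs non-empty sequences over A/C/G/T only")
  n <- nchar(seq)
  gc <- n - nchar(gsub("[GC]", "", seq))
  100 * gc / n
}

# Owczarzy et al. (2008) divalent-cation correction to 1/Tm, with Mg2+
# corrected for dNTP chelation; falls back to the Owczarzy (2004) monovalent
# formula when free Mg2+ is negligible relative to monovalent ions.
# Vectorized over fgc and nlen (the ionic decision tree is per-condition).
saltCorrection <- function(fgc, nlen, cond) {
  mon <- cond@monovalent_mM * 1e-3
  mg <- cond@divalent_mM * 1e-3
  if (cond@dntp_mM > 0) {
    dntps <- cond@dntp_mM * 1e-3
    ka <- 3e4
    mg <- (-(ka * dntps - ka * mg + 1) +
             sqrt((ka * dntps - ka * mg + 1)^2 + 4 * ka * mg)) / (2 * ka)
  }
  a <- 3.92; b <- -0.911; cc <- 6.26; d <- 1.42
  e <- -48.2; f <- 52.5; g <- 8.31
  if (mon > 0) {
    ratio <- sqrt(mg) / mon
    if (ratio < 0.22)
      return((4.29 * fgc - 3.95) * 1e-5 * log(mon) + 9.40e-6 * log(mon)^2)
    if (ratio < 6.0) {
      a <- 3.92 * (0.843 - 0.352 * sqrt(mon) * log(mon))
      d <- 1.42 * (1.279 - 4.03e-3 * log(mon) - 8.03e-3 * log(mon)^2)
      g <- 8.31 * (0.486 - 0.258 * log(mon) + 5.25e-3 * log(mon)^3)
    }
  }
  (a + b * log(mg) + fgc * (cc + d * log(mg)) +
     (1 / (2 * (nlen - 1))) * (e + f * log(mg) + g * log(mg)^2)) * 1e-5
}

tmFromSums <- function(dh, ds, fgc, nlen, ends_at, ends_gc, cond) {
  dh <- dh + INIT_AT["dh"] * ends_at + INIT_GC["dh"] * ends_gc
  ds <- ds + INIT_AT["ds"] * ends_at + INIT_GC["ds"] * ends_gc
  k <- cond@oligo_nM * 1e-9 / 4   # CT/4 for non-self-complementary duplexes
  tm <- 1000 * dh / (ds + GAS_R * log(k)) - 273.15
  corr <- saltCorrection(fgc, nlen, cond)
  tm <- 1 / (1 / (tm + 273.15) + corr) - 273.15
  # quantize to a microdegree: makes the value independent of float
  # summation order, so windowed and per-oligo computation paths agree
  # bit-for-bit and penalty ties break deterministically
  round(tm, 6L)
}

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature from the unified SantaLucia (1998)
#' nearest-neighbor dH/dS sums with terminal A/T and G/C initiation terms,
#' `Tm = 1000 dH / (dS + R ln(CT/4)) - 273.15`, followed by the Owczarzy
#' (2008) divalent-corrected salt adjustment of `1/Tm` (free Mg2+ after
#' dNTP chelation). Symmetric under reverse complement, as a duplex must be.
#'
#' @param seq Character vector of oligos, 8-36 nt over A/C/G/T.
#' @param cond A [ThermoConditions-class] object.
#' @return Melting temperature(s) in deg C.
#' @examples
#' meltingTemperature("AGCGTACCGTTGATCGCATA")
#' @export
meltingTemperature <- function(seq, cond = thermoConditions()) {
  stopifnot(is(cond, "ThermoConditions"))
  seq <- toupper(seq)
  n <- nchar(seq)
  if (any(n < 8 | n > 36))
    cpStop("oligo length must lie in [8, 36]")
  if (any(grepl("[^ACGT]", seq)))
    cpStop("oligos must contain only A/C/G/T")
  dinuc <- function(s) {
    substring(s, seq_len(nchar(s) - 1L), seq_len(nchar(s) - 1L) + 1L)
  }
  dh <- vapply(seq, function(s) sum(NN_DH[dinuc(s)]), numeric(1))
  ds <- vapply(seq, function(s) sum(NN_DS[dinuc(s)]), numeric(1))
  ends <- paste0(substring(seq, 1, 1), substring(seq, n, n))
  ends_at <- nchar(gsub("[GC]", "", ends))
  ends_gc <- 2L - ends_at
  fgc <- gcContent(seq) / 100
  unname(tmFromSums(dh, ds, fgc, n, ends_at, ends_gc, cond))
}

#' Primer3-style complementarity scores between two oligos
#'
#' Maximum ungapped antiparallel complementarity run-score over all relative
#' offsets (+1 per complementary pair, -1 otherwise, floored at zero). The
#' `end` score is the same quantity restricted to runs ending at the first
#' oligo's 3' terminus (the primer-extension-critical end).
#'
#' @param a,b Oligos, 8-36 nt.
#' @return Named integer vector `c(any = , end = )`.
#' @examples
#' complementarityScores("ACGTACGTAC", "GTACGTACGT")
#' @export
complementarityScores <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) < 8 || nchar(a) > 36 || nchar(b) < 8 || nchar(b) > 36)
    cpStop("oligos must be 8-36 nt")
  c(any = cpp_comp_score(a, b, FALSE, -1L),
    end = cpp_comp_score(a, b, TRUE, -1L))
}

#' Hairpin self-complementarity score of an oligo
#'
#' Self-complementarity with a minimum loop of `min_loop` unpaired bases
#' between the two arms of the fold.
#'
#' @param a Oligo, 8-36 nt.
#' @param min_loop Minimum loop length (default 3).
#' @return Integer score (larger is worse).
#' @export
hairpinScore <- function(a, min_loop = 3L) {
  a <- toupper(a)
  if (nchar(a) < 8 || nchar(a) > 36)
    cpStop("oligo must be 8-36 nt")
  cpp_comp_score(a, a, FALSE, as.integer(min_loop))
}

#' Thermodynamic profile of an oligo
#'
#' @param seq Oligo sequence (15-36 nt typical primer range accepted as
#'   8-36).
#' @param cond A [ThermoConditions-class].
#' @return One-row data.frame: `seq`, `length`, `tm_c`, `gc_pct`,
#'   `self_any`, `self_end`, `hairpin`.
#' @export
oligoProfile <- function(seq, cond = thermoConditions()) {
  seq <- toupper(seq)
  sc <- complementarityScores(seq, seq)
  data.frame(
    seq = seq, length = nchar(seq),
    tm_c = meltingTemperature(seq, cond),
    gc_pct = gcContent(seq),
    self_any = unname(sc["any"]), self_end = unname(sc["end"]),
    hairpin = hairpinScore(seq),
    stringsAsFactors = FALSE
  )
}
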