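# data.table non-standard evaluation symbols
utils::globalVariables(c(
  "kmer", "gene1", "gene2", "pos1", "pos2", "d", "fstart1", "flen",
  "rend1", "rlen", "amin", "amax", "ftm", "rtm", "fpen", "rpen",
  "pair_penalty", "rstart1", "fend1", "fseq", "rseq",
  "x.fstart1", "x.flen", "i.rend1", "i.rlen", "x.fend1", "x.ftm",
  "x.fgc", "x.fpen", "x.fseq", "i.rstart1", "i.rtm", "i.rgc",
  "i.rpen", "i.rseq", "."
))
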