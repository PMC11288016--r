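# Condition helpers: cpInputError for bad user input (CLI exit 2),
# plain errors for internal failures (CLI exit 1).

cpStop <- function(fmt, ..., class = "cpInputError") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# write a data.frame as a deterministic TSV (fixed number formatting,
# "\n" endings, no quoting)
writeTsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(colnames(df), collapse = "\t"),
             do.call(paste, c(lapply(df, function(col) {
               if (is.character(col) || is.factor(col)) as.character(col)
               else if (is.integer(col) || is.logical(col)) format(col)
               else formatNum(col)
             }), sep = "\t")))
  if (nrow(df) == 0L) lines <- lines[1]
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}

# fixed-precision numeric formatting so repeated runs are byte-identical
formatNum <- function(x, digits = 4L) {
  out <- ifelse(is.na(x), "NA",
                ifelse(x == round(x), format(round(x), scientific = FALSE),
                       formatC(x, digits = digits, format = "f")))
  as.character(out)
}

readTsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
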