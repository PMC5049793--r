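# In-code fixtures for the IO layer.

write_sumstats_file <- function(df, path = tempfile(fileext = ".tsv"),
                                col_names = NULL) {
  out <- df
  if (!is.null(col_names)) names(out) <- col_names
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# three well-formed records on two chromosomes
basic_records <- function() {
  data.frame(
    SNP = c("rs1", "rs2", "rs3"),
    CHR = c("2", "1", "1"),
    POS = c(500L, 100L, 900L),
    EA = c("A", "C", "G"),
    OA = c("G", "T", "A"),
    EAF = c(0.2, 0.4, 0.5),
    BETA = c(0.10, -0.05, 0.02),
    SE = c(0.05, 0.02, 0.01),
    P = c(0.0455, 0.0124, 0.0455),
    N = c(1000L, 1000L, 998L),
    stringsAsFactors = FALSE
  )
}

# two-panel record set on shared SNPs, optionally with allele swaps
two_panel_records <- function(flip_second = FALSE) {
  a <- basic_records()
  b <- a
  b$BETA <- a$BETA + c(0.01, -0.01, 0)
  if (flip_second) {
    b[, c("EA", "OA")] <- b[, c("OA", "EA")]
    b$BETA <- -b$BETA
    b$EAF <- 1 - b$EAF
  }
  list(a = a, b = b)
}

read_records <- function(df, ...) {
  path <- write_sumstats_file(df)
  on.exit(unlink(path))
  read_sumstats(path, ...)
}
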