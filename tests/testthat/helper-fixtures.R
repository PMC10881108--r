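# Small in-code fixture builders shared across test files.

# TTAA index with sites every `spacing` bp on one or more chromosomes.
uniform_ttaa <- function(lengths = c(chrT = 100000L), spacing = 250L) {
  TTAAIndex(lapply(lengths, function(L) seq(0L, L - 4L, by = spacing)))
}

# InsertionSet from bare positions on one chromosome.
iset <- function(positions, chrom = "chrT", reads = 1L, strand = "+",
                 barcode = NULL) {
  df <- data.frame(chrom = chrom, start = as.integer(positions),
                   end = as.integer(positions) + 4L, reads = reads,
                   strand = strand, stringsAsFactors = FALSE)
  if (!is.null(barcode)) df$barcode <- barcode
  InsertionSet(df)
}

# PeakSet from bare intervals.
pset <- function(chrom, start, end, pvalue = 0.001) {
  PeakSet(data.frame(chrom = chrom, start = as.integer(start),
                     end = as.integer(end),
                     center = as.integer((start + end) %/% 2),
                     n_exp = 10L, n_bkg = 0L, n_ttaa = 1L, lam = 1,
                     pvalue = pvalue, qvalue = pvalue,
                     stringsAsFactors = FALSE))
}

# Caller config that reports every candidate block with its raw p-value.
candidate_cfg <- function(...) {
  caller_config(min_insertions = 1L, pvalue_cutoff = 1,
                multiple_testing = "none", ...)
}

write_tmp <- function(lines, ext = ".qbed") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
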