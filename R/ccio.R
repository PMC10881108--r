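# File formats and core containers: qbed insertions, TTAA index, BED/bedGraph,
# gene tables. Coordinates are 0-based half-open (BED convention) throughout;
# an insertion's position for all downstream statistics is its `start`.

#' Construct an insertion set
#'
#' An `InsertionSet` is the central event stream of a Calling Cards analysis:
#' one row per transposon insertion, sorted by (chrom, start), with cached
#' per-chromosome and overall totals. All statistics downstream count
#' insertions (not reads); the read count is carried for plotting and export.
#'
#' @param records data.frame with columns `chrom`, `start`, `end`, `reads`,
#'   `strand` and optionally `barcode`.
#' @return An object of class `InsertionSet`: a list with elements `records`
#'   (sorted data.frame), `totals` (named integer vector per chromosome) and
#'   `total` (overall insertion count).
#' @export
InsertionSet <- function(records = NULL) {
  if (is.null(records) || nrow(records) == 0L) {
    records <- data.frame(chrom = character(), start = integer(),
                          end = integer(), reads = integer(),
                          strand = character(), stringsAsFactors = FALSE)
  }
  required <- c("chrom", "start", "end", "reads", "strand")
  missing <- setdiff(required, names(records))
  if (length(missing))
    stop("InsertionSet records lack column(s): ", paste(missing, collapse = ", "))
  if (nrow(records)) {
    if (any(!nzchar(records$chrom))) stop("empty chromosome name")
    if (any(records$start >= records$end))
      stop("insertion with start >= end")
    if (any(records$reads < 1L)) stop("insertion with reads < 1")
    bad <- !records$strand %in% c("+", "-", ".")
    if (any(bad)) stop("invalid strand value: ", records$strand[which(bad)[1L]])
    ord <- order(records$chrom, records$start, records$end, method = "radix")
    records <- records[ord, , drop = FALSE]
    rownames(records) <- NULL
  }
  totals <- if (nrow(records)) {
    tab <- table(records$chrom)
    structure(as.integer(tab), names = names(tab))
  } else {
    structure(integer(0), names = character(0))
  }
  structure(list(records = records, totals = totals,
                 total = nrow(records)),
            class = "InsertionSet")
}

#' @export
print.InsertionSet <- function(x, ...) {
  cat(sprintf("InsertionSet with %d insertions on %d chromosome(s)\n",
              x$total, length(x$totals)))
  if (x$total) {
    cat("  has barcodes:", "barcode" %in% names(x$records), "\n")
    print(utils::head(x$records, 5L))
    if (x$total > 5L) cat(sprintf("  ... and %d more\n", x$total - 5L))
  }
  invisible(x)
}

#' @export
length.InsertionSet <- function(x) x$total

#' Read a qbed file of transposon insertions
#'
#' qbed is a BED-derived tab-separated format with one insertion per line:
#' chromosome, start (0-based), end, read count, strand, and optionally a
#' cell barcode. Header lines beginning with `#` or `track` are skipped.
#' Gzipped files (`.gz`) are read transparently.
#'
#' @param path path to a qbed file (optionally gzipped).
#' @param has_barcode logical or NA; when NA (default) the barcode column is
#'   auto-detected from the column count.
#' @param dedup if TRUE, duplicate insertions by (chrom, start, barcode) are
#'   collapsed to one record (reads summed). Default FALSE: each line is an
#'   independent insertion event.
#' @return An [InsertionSet].
#' @export
read_qbed <- function(path, has_barcode = NA, dedup = FALSE) {
  lines <- read_text_lines(path)
  keep <- !startsWith(lines, "#") & !startsWith(lines, "track") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(InsertionSet())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (is.na(has_barcode)) {
    ncol_expect <- max(nf)
    if (!ncol_expect %in% c(5L, 6L))
      stop("qbed line ", line_no[which.max(nf)], ": expected 5 or 6 columns, got ",
           ncol_expect)
  } else {
    ncol_expect <- if (isTRUE(has_barcode)) 6L else 5L
  }
  bad <- which(nf != ncol_expect)
  if (length(bad))
    stop("qbed line ", line_no[bad[1L]], ": expected ", ncol_expect,
         " columns, got ", nf[bad[1L]])
  m <- matrix(unlist(fields, use.names = FALSE), ncol = ncol_expect, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  reads <- suppressWarnings(as.integer(m[, 4L]))
  bad <- which(is.na(start) | is.na(end) | is.na(reads) |
                 m[, 2L] != as.character(start) | m[, 3L] != as.character(end))
  if (length(bad))
    stop("qbed line ", line_no[bad[1L]], ": non-integer coordinates or reads")
  bad <- which(start >= end)
  if (length(bad))
    stop("qbed line ", line_no[bad[1L]], ": start >= end")
  bad <- which(reads < 1L)
  if (length(bad))
    stop("qbed line ", line_no[bad[1L]], ": reads < 1")
  rec <- data.frame(chrom = m[, 1L], start = start, end = end, reads = reads,
                    strand = m[, 5L], stringsAsFactors = FALSE)
  if (ncol_expect == 6L) rec$barcode <- m[, 6L]
  if (dedup) {
    key <- paste(rec$chrom, rec$start,
                 if (ncol_expect == 6L) rec$barcode else "", sep = "\r")
    first <- !duplicated(key)
    reads_sum <- tapply(rec$reads, key, sum)
    kept <- rec[first, , drop = FALSE]
    kept$reads <- as.integer(reads_sum[paste(kept$chrom, kept$start,
                                             if (ncol_expect == 6L) kept$barcode else "",
                                             sep = "\r")])
    rec <- kept
  }
  InsertionSet(rec)
}

#' Write an insertion set back to qbed
#'
#' Inverse of [read_qbed()]: the data lines round-trip byte-identically
#' (modulo header and original line order; records are written sorted).
#'
#' @param insertions an [InsertionSet].
#' @param path output path.
#' @export
write_qbed <- function(insertions, path) {
  stopifnot(inherits(insertions, "InsertionSet"))
  r <- insertions$records
  cols <- list(r$chrom, r$start, r$end, r$reads, r$strand)
  if ("barcode" %in% names(r)) cols <- c(cols, list(r$barcode))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

# ---------------------------------------------------------------------------
# TTAA index

#' Build a TTAA index from genome sequence
#'
#' The piggyBac transposase inserts exclusively at TTAA tetranucleotides, so
#' enrichment statistics must be corrected for local TTAA density. The index
#' records the 0-based start of every TTAA occurrence per chromosome,
#' scanning with a sliding window of width 4 and step 1 (all occurrences,
#' including any sharing bases, are reported). Matching is case-insensitive;
#' N never matches.
#'
#' @param x a named character vector of sequences, a
#'   [Biostrings::DNAStringSet], or a path to a FASTA file.
#' @return A `TTAAIndex`: list with `positions` (named list of strictly
#'   increasing integer vectors) and `total`.
#' @export
build_ttaa_index <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      grepl("\\.(fa|fasta|fna)(\\.gz)?$", x, ignore.case = TRUE)) {
    x <- Biostrings::readDNAStringSet(x)
    names(x) <- sub("\\s.*$", "", names(x))
  }
  if (is.character(x)) {
    if (is.null(names(x)) && length(x) == 1L) names(x) <- "seq1"
    bad <- grepl("[^ACGTNacgtn]", x)
    if (any(bad))
      stop("sequence '", names(x)[which(bad)[1L]],
           "' contains characters outside {A,C,G,T,N}")
    x <- Biostrings::DNAStringSet(toupper(x))
  }
  if (!methods::is(x, "DNAStringSet"))
    stop("x must be sequences (character/DNAStringSet) or a FASTA path")
  positions <- lapply(seq_along(x), function(i) {
    m <- Biostrings::matchPattern("TTAA", x[[i]], fixed = TRUE)
    as.integer(Biostrings::start(m)) - 1L   # 0-based
  })
  names(positions) <- names(x)
  TTAAIndex(positions)
}

#' Construct a TTAA index from explicit positions
#'
#' @param positions named list of 0-based TTAA start positions per chromosome.
#' @return A `TTAAIndex` object.
#' @export
TTAAIndex <- function(positions) {
  stopifnot(is.list(positions))
  positions <- lapply(positions, function(p) {
    p <- as.integer(sort(unique(p)))
    p
  })
  structure(list(positions = positions,
                 total = sum(lengths(positions))),
            class = "TTAAIndex")
}

#' @export
print.TTAAIndex <- function(x, ...) {
  cat(sprintf("TTAAIndex: %d sites on %d chromosome(s)\n",
              x$total, length(x$positions)))
  invisible(x)
}

#' Read a TTAA index from a BED file of TTAA positions
#'
#' @param path BED file whose `start` column gives 0-based TTAA starts.
#' @return A `TTAAIndex`.
#' @export
read_ttaa_bed <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") & nzchar(lines)]
  if (!length(lines)) return(TTAAIndex(list()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- vapply(f, `[`, "", 1L)
  start <- as.integer(vapply(f, `[`, "", 2L))
  TTAAIndex(split(start, chrom))
}

#' Count TTAA sites within a genomic interval
#'
#' Counts TTAA start positions `p` with `start <= p < end` (half-open) by
#' binary search against the sorted index.
#'
#' @param index a `TTAAIndex`.
#' @param chrom chromosome name.
#' @param start,end interval bounds (vectors recycled to common length).
#' @return Integer vector of counts. Querying a chromosome absent from the
#'   index returns 0 with a warning.
#' @export
count_ttaa <- function(index, chrom, start, end) {
  stopifnot(inherits(index, "TTAAIndex"))
  if (length(chrom) != 1L) stop("count_ttaa operates on a single chromosome")
  if (any(start > end)) stop("start > end")
  pos <- index$positions[[chrom]]
  if (is.null(pos)) {
    warning("chromosome '", chrom, "' not in TTAA index; returning 0")
    return(integer(length(start)))
  }
  count_in_ranges(pos, start, end)
}

# number of sorted values v with s <= v < e, vectorised over (s, e)
count_in_ranges <- function(sorted_pos, start, end) {
  if (!length(sorted_pos)) return(integer(length(start)))
  findInterval(end - 1L, sorted_pos) - findInterval(start - 1L, sorted_pos)
}

# ---------------------------------------------------------------------------
# BED / bedGraph / gene tables

#' Write a peak set to BED6
#'
#' Score is `-10 * log10(p)` rounded to integer and capped at 1000 (p = 0
#' maps to the cap); strand is `.`.
#'
#' @param peaks a `PeakSet` (see [call_cccaller()]).
#' @param path output path.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(inherits(peaks, "PeakSet"))
  if (nrow(peaks) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  score <- ifelse(peaks$pvalue <= 0, 1000,
                  pmin(1000, round(-10 * log10(peaks$pvalue))))
  lines <- paste(peaks$chrom, peaks$start, peaks$end,
                 paste0("peak_", seq_len(nrow(peaks))),
                 format(score, scientific = FALSE, trim = TRUE), ".",
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write the full per-peak statistics table as TSV
#'
#' Sidecar to [write_bed()] carrying n_exp, n_bkg, n_ttaa, lambda, p and q.
#'
#' @param peaks a `PeakSet`.
#' @param path output path.
#' @export
write_peak_tsv <- function(peaks, path) {
  stopifnot(inherits(peaks, "PeakSet"))
  utils::write.table(as.data.frame(peaks), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage file
#'
#' @param path 4-column bedGraph (chrom, start, end, value); gzip accepted.
#' @return data.frame with columns chrom, start, end, value.
#' @export
read_bedgraph <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      value = numeric()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 4L)) stop("bedGraph requires 4 columns")
  data.frame(chrom = vapply(f, `[`, "", 1L),
             start = as.integer(vapply(f, `[`, "", 2L)),
             end = as.integer(vapply(f, `[`, "", 3L)),
             value = as.numeric(vapply(f, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Read a gene table (BED6 or GTF/GFF)
#'
#' For GTF/GFF input only `gene` features are used and coordinates are
#' converted to 0-based half-open; gene names come from the `gene_name`
#' attribute, falling back to `gene_id`. BED input uses columns
#' chrom, start, end, name, (score,) strand.
#'
#' @param path gene annotation file; format detected from the extension.
#' @return data.frame of `GeneRecord`s: chrom, start, end, name, strand,
#'   sorted by (chrom, start).
#' @export
read_genes <- function(path) {
  if (grepl("\\.(gtf|gff3?|gff)(\\.gz)?$", path, ignore.case = TRUE)) {
    lines <- read_text_lines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    f <- f[lengths(f) >= 9L]
    feat <- vapply(f, `[`, "", 3L)
    f <- f[feat == "gene"]
    if (!length(f)) stop("no 'gene' features in ", path)
    attr9 <- vapply(f, `[`, "", 9L)
    name <- sub('.*gene_name[ =]"?([^";]+)"?.*', "\\1", attr9)
    noname <- !grepl("gene_name", attr9)
    name[noname] <- sub('.*gene_id[ =]"?([^";]+)"?.*', "\\1", attr9[noname])
    g <- data.frame(chrom = vapply(f, `[`, "", 1L),
                    start = as.integer(vapply(f, `[`, "", 4L)) - 1L,  # 1-based -> 0-based
                    end = as.integer(vapply(f, `[`, "", 5L)),
                    name = name,
                    strand = vapply(f, `[`, "", 7L),
                    stringsAsFactors = FALSE)
  } else {
    lines <- read_text_lines(path)
    lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(f) < 4L)) stop("gene BED requires at least 4 columns")
    g <- data.frame(chrom = vapply(f, `[`, "", 1L),
                    start = as.integer(vapply(f, `[`, "", 2L)),
                    end = as.integer(vapply(f, `[`, "", 3L)),
                    name = vapply(f, `[`, "", 4L),
                    strand = vapply(f, function(z) if (length(z) >= 6L) z[6L] else ".", ""),
                    stringsAsFactors = FALSE)
  }
  if (any(g$start >= g$end)) stop("gene with start >= end")
  g <- g[order(g$chrom, g$start, method = "radix"), , drop = FALSE]
  rownames(g) <- NULL
  g
}
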