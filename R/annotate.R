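# Peak annotation, peak-gene pairing, GWAS intersection, signal matrices and
# export helpers.

#' Annotate peaks with their two nearest genes
#'
#' Distance is edge-to-edge between the peak interval and the gene interval
#' (0 when they overlap). The two smallest-distance genes are reported; ties
#' are broken by (distance, gene start, gene name). A TSS-distance mode is
#' available behind a flag.
#'
#' @param peaks a `PeakSet`.
#' @param genes gene table from [read_genes()] (chrom, start, end, name,
#'   strand), sorted.
#' @param use_tss if TRUE, distance is measured to the transcription start
#'   site (strand-aware gene 5' end) instead of the gene body edges.
#' @return data.frame: peak, gene1, distance1, gene2, distance2. Peaks on a
#'   chromosome with no genes get the sentinel gene `"none"` and NA distance.
#' @export
annotate_peaks <- function(peaks, genes, use_tss = FALSE) {
  stopifnot(inherits(peaks, "PeakSet"))
  n <- nrow(peaks)
  out <- data.frame(peak = peak_ids(peaks),
                    gene1 = rep("none", n), distance1 = rep(NA_real_, n),
                    gene2 = rep("none", n), distance2 = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  for (chrom in unique(peaks$chrom)) {
    pk <- which(peaks$chrom == chrom)
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    if (!nrow(g)) next
    for (i in pk) {
      d <- if (use_tss) {
        tss <- ifelse(g$strand == "-", g$end - 1L, g$start)
        ifelse(tss >= peaks$start[i] & tss < peaks$end[i], 0,
               pmax(peaks$start[i] - tss, tss + 1L - peaks$end[i], 0))
      } else {
        pmax(peaks$start[i] - g$end, g$start - peaks$end[i], 0)
      }
      ord <- order(d, g$start, g$name)
      out$gene1[i] <- g$name[ord[1L]]
      out$distance1[i] <- d[ord[1L]]
      if (nrow(g) >= 2L) {
        out$gene2[i] <- g$name[ord[2L]]
        out$distance2[i] <- d[ord[2L]]
      }
    }
  }
  out
}

#' Pair differentially bound peaks with differentially expressed genes
#'
#' Retains (peak, gene) pairs where the peak passes the binding significance
#' threshold and one of its two annotated genes passes the expression
#' thresholds (typical choices: |log2FC| >= 3 and adjusted p <= 0.05). A
#' concordance flag marks pairs whose binding and expression changes point
#' the same way.
#'
#' @param diff a `DiffResult` data.frame (from [fisher_diff()],
#'   [binomial_diff()] or a strategy wrapper).
#' @param annot annotation table from [annotate_peaks()].
#' @param de_table differential-expression table with columns `gene`,
#'   `log2FoldChange`, `padj` (DESeq2-style names; remap with `columns`).
#' @param lfc_min minimum |gene log2 fold change|.
#' @param padj_max maximum gene adjusted p.
#' @param peak_padj_max maximum peak adjusted p for the binding side.
#' @param columns named mapping from required names (`gene`,
#'   `log2FoldChange`, `padj`) to the table's actual column names.
#' @return data.frame of pairs: peak, gene, gene_rank (1 nearest, 2 next),
#'   peak stats, gene_log2fc, gene_padj, concordant. The number of genes
#'   skipped because they are absent from `de_table` is attached as
#'   attribute `n_skipped`.
#' @export
pair_peak_gene <- function(diff, annot, de_table, lfc_min = 3,
                           padj_max = 0.05, peak_padj_max = 0.05,
                           columns = c(gene = "gene",
                                       log2FoldChange = "log2FoldChange",
                                       padj = "padj")) {
  need <- c("gene", "log2FoldChange", "padj")
  if (!all(need %in% names(columns)))
    stop("'columns' must map gene, log2FoldChange and padj")
  if (!all(columns[need] %in% names(de_table)))
    stop("de_table lacks column(s): ",
         paste(setdiff(columns[need], names(de_table)), collapse = ", "))
  de <- data.frame(gene = de_table[[columns[["gene"]]]],
                   log2fc = de_table[[columns[["log2FoldChange"]]]],
                   padj = de_table[[columns[["padj"]]]],
                   stringsAsFactors = FALSE)
  sig <- diff[!is.na(diff$padj) & diff$padj <= peak_padj_max, , drop = FALSE]
  n_skipped <- 0L
  rows <- list()
  for (i in seq_len(nrow(sig))) {
    a <- annot[annot$peak == sig$peak[i], , drop = FALSE]
    if (!nrow(a)) next
    for (rank in 1:2) {
      gene <- a[[paste0("gene", rank)]][1L]
      if (identical(gene, "none")) next
      j <- match(gene, de$gene)
      if (is.na(j)) { n_skipped <- n_skipped + 1L; next }
      if (abs(de$log2fc[j]) < lfc_min || is.na(de$padj[j]) ||
          de$padj[j] > padj_max) next
      rows[[length(rows) + 1L]] <- data.frame(
        peak = sig$peak[i], gene = gene, gene_rank = rank,
        peak_log2fc = sig$log2fc[i], peak_padj = sig$padj[i],
        gene_log2fc = de$log2fc[j], gene_padj = de$padj[j],
        concordant = sign(sig$log2fc[i]) == sign(de$log2fc[j]),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peak = character(), gene = character(), gene_rank = integer(),
               peak_log2fc = numeric(), peak_padj = numeric(),
               gene_log2fc = numeric(), gene_padj = numeric(),
               concordant = logical(), stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Intersect peaks with a GWAS catalog
#'
#' Reports every (peak, SNP) pair with `start <= pos < end` in stable
#' (peak, then catalog) order. Malformed catalog rows (non-integer position)
#' are skipped and counted in attribute `n_skipped`.
#'
#' @param peaks a `PeakSet`.
#' @param catalog data.frame with columns chrom, pos, trait, rsid, or a path
#'   to such a TSV (with header).
#' @return data.frame: peak, chrom, pos, trait, rsid.
#' @export
gwas_intersect <- function(peaks, catalog) {
  stopifnot(inherits(peaks, "PeakSet"))
  if (is.character(catalog))
    catalog <- utils::read.table(catalog, sep = "\t", header = TRUE,
                                 quote = "", comment.char = "",
                                 stringsAsFactors = FALSE)
  pos <- suppressWarnings(as.integer(catalog$pos))
  bad <- is.na(pos)
  catalog <- catalog[!bad, , drop = FALSE]
  pos <- pos[!bad]
  rows <- list()
  pid <- peak_ids(peaks)
  for (i in seq_len(nrow(peaks))) {
    hit <- which(catalog$chrom == peaks$chrom[i] &
                   pos >= peaks$start[i] & pos < peaks$end[i])
    if (length(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        peak = pid[i], chrom = catalog$chrom[hit], pos = pos[hit],
        trait = catalog$trait[hit], rsid = catalog$rsid[hit],
        stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peak = character(), chrom = character(), pos = integer(),
               trait = character(), rsid = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Signal around peaks from a coverage track
#'
#' Divides each peak's center +/- `flank` into `bins` equal bins and fills
#' each bin with the length-weighted mean of the bedGraph coverage (0 where
#' the track has no interval). Bins extending below position 0 are truncated
#' to the available span.
#'
#' @param peaks a `PeakSet`; the stored density center is used when present,
#'   else the interval midpoint.
#' @param coverage bedGraph data.frame from [read_bedgraph()] (non-overlapping
#'   intervals per chromosome), or a path.
#' @param flank half-width of the profiled region in bp.
#' @param bins number of bins (>= 1).
#' @return list with `matrix` (peaks x bins) and `profile` (column means).
#' @export
signal_matrix <- function(peaks, coverage, flank = 2000L, bins = 50L) {
  stopifnot(inherits(peaks, "PeakSet"), bins >= 1L)
  if (is.character(coverage)) coverage <- read_bedgraph(coverage)
  n <- nrow(peaks)
  mat <- matrix(0, nrow = n, ncol = bins,
                dimnames = list(peak_ids(peaks), NULL))
  centers <- ifelse(is.na(peaks$center), (peaks$start + peaks$end) %/% 2L,
                    peaks$center)
  for (i in seq_len(n)) {
    cov <- coverage[coverage$chrom == peaks$chrom[i], , drop = FALSE]
    edges <- seq(centers[i] - flank, centers[i] + flank, length.out = bins + 1L)
    for (b in seq_len(bins)) {
      s <- max(0, edges[b]); e <- max(0, edges[b + 1L])
      if (e <= s) { mat[i, b] <- 0; next }
      ov <- pmin(cov$end, e) - pmax(cov$start, s)
      ov[ov < 0] <- 0
      mat[i, b] <- sum(ov * cov$value) / (e - s)
    }
  }
  list(matrix = mat, profile = colMeans(mat))
}

# ---------------------------------------------------------------------------
# external-tool export

#' Export peak sequences for motif finding
#'
#' Writes a BED of the peak intervals and a FASTA of their sequences, ready
#' for an external motif finder (e.g. Homer, which is not wrapped here).
#'
#' @param peaks a `PeakSet`.
#' @param genome named character vector of chromosome sequences or a
#'   [Biostrings::DNAStringSet].
#' @param bed_path,fasta_path output paths.
#' @export
export_for_motif <- function(peaks, genome, bed_path, fasta_path) {
  write_bed(peaks, bed_path)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(toupper(genome))
  seqs <- vapply(seq_len(nrow(peaks)), function(i) {
    chrom <- peaks$chrom[i]
    if (!chrom %in% names(genome)) return(NA_character_)
    as.character(Biostrings::subseq(genome[[chrom]], peaks$start[i] + 1L,
                                    min(peaks$end[i], length(genome[[chrom]]))))
  }, character(1))
  keep <- !is.na(seqs)
  lines <- as.vector(rbind(paste0(">", peak_ids(peaks)[keep]), seqs[keep]))
  writeLines(lines, fasta_path)
  invisible(fasta_path)
}

#' Export browser-ready track files
#'
#' Writes a coordinate-sorted qbed and peak BED suitable for bgzip/tabix and
#' display in a genome browser.
#'
#' @param insertions an [InsertionSet].
#' @param peaks a `PeakSet`.
#' @param qbed_path,bed_path output paths.
#' @export
export_browser <- function(insertions, peaks, qbed_path, bed_path) {
  write_qbed(insertions, qbed_path)
  write_bed(peaks, bed_path)
  invisible(c(qbed_path, bed_path))
}
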