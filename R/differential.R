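# Cells-by-peaks / groups-by-peaks matrices and differential binding tests.
# All tested tables use insertion counts (not read counts, not cell counts).

#' Assign insertions to peaks and build a count matrix
#'
#' Each insertion is assigned to the unique peak whose half-open interval
#' contains its `start`; insertions falling outside all peaks are counted as
#' unassigned. Rows are cells (one row per barcode), groups (when `by` is a
#' barcode-to-group mapping) or samples (when `insertions` is a named list of
#' insertion sets); columns are peaks.
#'
#' @param insertions an [InsertionSet], or a named list of them (one per
#'   group/sample).
#' @param peaks a sorted, non-overlapping `PeakSet` (as produced by the
#'   callers).
#' @param by `"barcode"` for a cells-by-peaks matrix, or a named character
#'   vector mapping barcodes to group labels for a groups-by-peaks matrix.
#'   Ignored when `insertions` is a list.
#' @return A `PeakMatrix`: list with `counts` (sparse dgCMatrix, rows =
#'   cells/groups, columns = peaks), `row_meta`, `col_meta` (peak table) and
#'   `unassigned` (insertions outside all peaks, per row).
#' @export
assign_insertions <- function(insertions, peaks, by = "barcode") {
  stopifnot(inherits(peaks, "PeakSet"))
  if (inherits(insertions, "InsertionSet")) {
    if (identical(by, "barcode") || is.character(by) && !is.null(names(by))) {
      if (!"barcode" %in% names(insertions$records))
        stop("insertion records lack barcodes; supply a list of InsertionSets ",
             "or qbed files with a barcode column")
      labels <- insertions$records$barcode
      if (!identical(by, "barcode")) {
        mapped <- unname(by[labels])
        if (anyNA(mapped))
          stop("barcode(s) missing from the group mapping: ",
               paste(utils::head(unique(labels[is.na(mapped)]), 3L), collapse = ", "))
        labels <- mapped
      }
    } else stop("'by' must be \"barcode\" or a named barcode-to-group mapping")
    rec <- insertions$records
    row_labels <- labels
  } else if (is.list(insertions)) {
    if (is.null(names(insertions)) || any(!nzchar(names(insertions))))
      stop("list of insertion sets must be named by group")
    rec <- do.call(rbind, lapply(names(insertions), function(g) {
      r <- insertions[[g]]$records[, c("chrom", "start", "end", "reads", "strand")]
      r$.group <- g
      r
    }))
    row_labels <- rec$.group
  } else stop("insertions must be an InsertionSet or a named list of them")

  rows <- sort(unique(row_labels))
  ri <- match(row_labels, rows)
  peak_idx <- rep(NA_integer_, nrow(rec))
  for (chrom in unique(peaks$chrom)) {
    pk <- which(peaks$chrom == chrom)
    sel <- which(rec$chrom == chrom)
    if (!length(sel)) next
    fi <- findInterval(rec$start[sel], peaks$start[pk])
    hit <- fi >= 1L & rec$start[sel] < peaks$end[pk][pmax(fi, 1L)]
    peak_idx[sel[hit]] <- pk[fi[hit]]
  }
  assigned <- !is.na(peak_idx)
  counts <- Matrix::sparseMatrix(i = ri[assigned], j = peak_idx[assigned],
                                 x = 1, dims = c(length(rows), nrow(peaks)),
                                 dimnames = list(rows, peak_ids(peaks)))
  unassigned <- as.integer(tabulate(ri[!assigned], nbins = length(rows)))
  structure(list(counts = counts,
                 row_meta = data.frame(label = rows, row.names = rows,
                                       stringsAsFactors = FALSE),
                 col_meta = as.data.frame(peaks),
                 unassigned = stats::setNames(unassigned, rows)),
            class = "PeakMatrix")
}

peak_ids <- function(peaks) {
  if (!nrow(peaks)) return(character(0))
  paste0(peaks$chrom, ":", peaks$start, "-", peaks$end)
}

#' @export
print.PeakMatrix <- function(x, ...) {
  cat(sprintf("PeakMatrix: %d row(s) x %d peak(s), %d unassigned insertion(s)\n",
              nrow(x$counts), ncol(x$counts), sum(x$unassigned)))
  invisible(x)
}

#' Attach a cluster assignment to a cells-by-peaks matrix
#'
#' @param mat a `PeakMatrix` with one row per cell.
#' @param clusters named vector mapping barcodes to cluster labels.
#' @return The matrix with `row_meta$cluster` populated.
#' @export
set_clusters <- function(mat, clusters) {
  stopifnot(inherits(mat, "PeakMatrix"))
  cl <- unname(clusters[rownames(mat$counts)])
  if (anyNA(cl)) stop("cluster mapping missing for some barcodes")
  mat$row_meta$cluster <- cl
  mat
}

# sum matrix rows by a grouping label
group_counts <- function(mat, groups) {
  g <- factor(groups)
  agg <- matrix(0, nlevels(g), ncol(mat$counts),
                dimnames = list(levels(g), colnames(mat$counts)))
  for (l in levels(g))
    agg[l, ] <- Matrix::colSums(mat$counts[g == l, , drop = FALSE])
  agg
}

row_groups <- function(mat) {
  if (!is.null(mat$row_meta$cluster)) mat$row_meta$cluster
  else rownames(mat$counts)
}

# ---------------------------------------------------------------------------
# exact tests

# Two-sided Fisher exact p for 2x2 tables, vectorised over tables.
# Table [[a, b], [c, d]]; sums over hypergeometric outcomes whose probability
# does not exceed the observed one (relative tolerance 1e-7, as in
# stats::fisher.test).
fisher_twosided_p <- function(a, b, c, d) {
  n <- length(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]; m2 <- c[i] + d[i]; k <- a[i] + c[i]
    support <- max(0L, k - m2):min(k, m1)
    probs <- stats::dhyper(support, m1, m2, k)
    p_obs <- stats::dhyper(a[i], m1, m2, k)
    out[i] <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  pmin(out, 1)
}

#' Differential binding by Fisher's exact test
#'
#' For each peak, tests the 2x2 table
#' `[[n_in_a, total_a - n_in_a], [n_in_b, total_b - n_in_b]]` (insertion
#' counts) two-sided; the log2 fold change compares the library-normalised
#' rates with a pseudocount.
#'
#' @param mat a `PeakMatrix`.
#' @param group_a,group_b row-group labels to compare.
#' @param pseudocount added to each rate numerator for the fold change.
#' @return data.frame of `DiffResult`s: peak, counts, totals, log2fc,
#'   pvalue, padj, direction.
#' @export
fisher_diff <- function(mat, group_a, group_b, pseudocount = 0.5) {
  stopifnot(inherits(mat, "PeakMatrix"))
  g <- row_groups(mat)
  if (!group_a %in% g || !group_b %in% g)
    stop("group not found among matrix rows/clusters")
  agg <- group_counts(mat, g)
  na <- agg[group_a, ]; nb <- agg[group_b, ]
  ta <- sum(na) + sum(mat$unassigned[g == group_a])
  tb <- sum(nb) + sum(mat$unassigned[g == group_b])
  if (ta == 0 || tb == 0) stop("a group has zero total insertions")
  p <- fisher_twosided_p(na, ta - na, nb, tb - nb)
  lfc <- log2(((na + pseudocount) / ta) / ((nb + pseudocount) / tb))
  data.frame(peak = colnames(mat$counts),
             n_in = as.integer(na), n_out = as.integer(nb),
             group_total = ta, other_total = tb,
             log2fc = lfc, pvalue = p, padj = adjust_pvalues(p),
             direction = ifelse(lfc >= 0, group_a, group_b),
             stringsAsFactors = FALSE)
}

#' Differential binding by one-sided binomial test
#'
#' For each peak, tests `x = n_in` insertions from `group` out of the peak's
#' column total `n` against the null proportion `p0` = the group's share of
#' all insertions (or `background_fraction` when supplied); reports
#' `P(X >= x)`.
#'
#' @param mat a `PeakMatrix`.
#' @param group row-group label tested against the rest.
#' @param background_fraction optional null proportion in (0, 1).
#' @param pseudocount added to each rate numerator for the fold change.
#' @return data.frame of `DiffResult`s.
#' @export
binomial_diff <- function(mat, group, background_fraction = NULL,
                          pseudocount = 0.5) {
  stopifnot(inherits(mat, "PeakMatrix"))
  g <- row_groups(mat)
  if (!group %in% g) stop("group not found among matrix rows/clusters")
  agg <- group_counts(mat, g)
  x <- agg[group, ]
  n <- Matrix::colSums(mat$counts)
  tg <- sum(x) + sum(mat$unassigned[g == group])
  tall <- sum(mat$counts) + sum(mat$unassigned)
  p0 <- background_fraction %||% (tg / tall)
  if (p0 <= 0 || p0 >= 1) stop("null proportion p0 must lie in (0, 1)")
  tested <- n >= 1
  p <- rep(NA_real_, length(n))
  p[tested] <- stats::pbinom(x[tested] - 1, n[tested], p0, lower.tail = FALSE)
  lfc <- log2(((x + pseudocount) / tg) / ((n - x + pseudocount) / (tall - tg)))
  padj <- p
  padj[tested] <- adjust_pvalues(p[tested])
  data.frame(peak = colnames(mat$counts), group = group,
             n_in = as.integer(x), n_out = as.integer(n - x),
             group_total = tg, other_total = tall - tg,
             log2fc = lfc, pvalue = p, padj = padj,
             direction = ifelse(lfc >= 0, group, "rest"),
             stringsAsFactors = FALSE)
}

#' Rank cell-type specific peaks (one-vs-rest binomial per cluster)
#'
#' For every cluster, runs [binomial_diff()] one-vs-rest and ranks peaks by
#' p-value, then descending fold change, with ties broken by peak coordinate
#' for determinism.
#'
#' @param mat a `PeakMatrix` with clusters set ([set_clusters()]) or rows as
#'   groups.
#' @return Named list of ranked `DiffResult` data.frames, one per cluster.
#' @export
rank_peak_groups <- function(mat) {
  g <- row_groups(mat)
  out <- lapply(sort(unique(g)), function(cl) {
    d <- binomial_diff(mat, cl)
    d <- d[!is.na(d$pvalue), , drop = FALSE]
    d[order(d$pvalue, -d$log2fc, d$peak), , drop = FALSE]
  })
  names(out) <- sort(unique(g))
  out
}

# ---------------------------------------------------------------------------
# two differential strategies

#' Differential peaks from jointly called peaks
#'
#' Pools the insertions of all groups, calls one peak set on the joint data,
#' builds a groups-by-peaks matrix, and tests each peak with Fisher's exact
#' (two groups) or one-vs-rest binomial tests.
#'
#' @param exp_sets named list of [InsertionSet]s, one per group (>= 2).
#' @param ttaa a `TTAAIndex`.
#' @param cfg a [caller_config()].
#' @param bkg optional background [InsertionSet] for peak calling.
#' @param test `"fisher"` (two groups only) or `"binomial"`.
#' @param caller one of `"cccaller"`, `"maccs"`, `"blockify"`.
#' @return list with `peaks` (the joint `PeakSet`), `matrix` (`PeakMatrix`)
#'   and `results` (a `DiffResult` data.frame, or a named list for binomial
#'   one-vs-rest).
#' @export
diff_strategy_joint <- function(exp_sets, ttaa, cfg = caller_config(),
                                bkg = NULL, test = c("fisher", "binomial"),
                                caller = c("cccaller", "maccs", "blockify")) {
  test <- match.arg(test)
  caller <- match.arg(caller)
  check_groups(exp_sets)
  pooled <- InsertionSet(do.call(rbind, lapply(exp_sets, function(s)
    s$records[, c("chrom", "start", "end", "reads", "strand")])))
  call_fun <- switch(caller, cccaller = call_cccaller, maccs = call_maccs,
                     blockify = call_blockify)
  peaks <- call_fun(pooled, bkg, ttaa, cfg)
  mat <- assign_insertions(exp_sets, peaks)
  list(peaks = peaks, matrix = mat,
       results = run_diff_test(mat, exp_sets, test))
}

#' Differential peaks from separately called, merged peaks
#'
#' Calls peaks separately in each group, merges peaks that overlap by at
#' least 1 bp across groups into union intervals, and tests the union
#' intervals. This suppresses false positives caused by slightly shifted
#' peak centers between samples at the same bound region.
#'
#' @inheritParams diff_strategy_joint
#' @return As [diff_strategy_joint()]; `peaks` holds the union intervals.
#' @export
diff_strategy_separate <- function(exp_sets, ttaa, cfg = caller_config(),
                                   bkg = NULL, test = c("fisher", "binomial"),
                                   caller = c("cccaller", "maccs", "blockify")) {
  test <- match.arg(test)
  caller <- match.arg(caller)
  check_groups(exp_sets)
  call_fun <- switch(caller, cccaller = call_cccaller, maccs = call_maccs,
                     blockify = call_blockify)
  per_group <- lapply(exp_sets, function(s) call_fun(s, bkg, ttaa, cfg))
  all_peaks <- do.call(rbind, lapply(per_group, as.data.frame))
  if (is.null(all_peaks) || !nrow(all_peaks)) {
    empty <- PeakSet()
    return(list(peaks = empty, per_group = per_group,
                matrix = assign_insertions(exp_sets, empty),
                results = NULL))
  }
  gr <- GenomicRanges::GRanges(all_peaks$chrom,
                               IRanges::IRanges(all_peaks$start + 1L,
                                                all_peaks$end))
  un <- GenomicRanges::reduce(gr)
  union_df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(un)),
    start = GenomicRanges::start(un) - 1L,
    end = GenomicRanges::end(un),
    center = as.integer((GenomicRanges::start(un) - 1L +
                           GenomicRanges::end(un)) %/% 2L),
    n_exp = 0L, n_bkg = 0L, n_ttaa = 0L, lam = NA_real_,
    pvalue = 0, qvalue = 0, stringsAsFactors = FALSE)
  peaks <- PeakSet(union_df)
  mat <- assign_insertions(exp_sets, peaks)
  list(peaks = peaks, per_group = per_group, matrix = mat,
       results = run_diff_test(mat, exp_sets, test))
}

check_groups <- function(exp_sets) {
  if (!is.list(exp_sets) || length(exp_sets) < 2L || is.null(names(exp_sets)))
    stop("exp_sets must be a named list of >= 2 InsertionSets")
  empty <- vapply(exp_sets, function(s) s$total == 0L, logical(1))
  if (any(empty))
    stop("group(s) with no insertions: ",
         paste(names(exp_sets)[empty], collapse = ", "))
}

run_diff_test <- function(mat, exp_sets, test) {
  if (ncol(mat$counts) == 0L) return(NULL)
  if (test == "fisher") {
    if (length(exp_sets) != 2L)
      stop("fisher test supports exactly two groups; use binomial for more")
    fisher_diff(mat, names(exp_sets)[1L], names(exp_sets)[2L])
  } else {
    rank_peak_groups(mat)
  }
}

#' Export a differential result table for a volcano plot
#'
#' Writes a TSV of peak, log2 fold change and -log10 adjusted p.
#'
#' @param diff a `DiffResult` data.frame.
#' @param path output path.
#' @export
write_volcano_tsv <- function(diff, path) {
  out <- data.frame(peak = diff$peak, log2fc = diff$log2fc,
                    neg_log10_padj = -log10(pmax(diff$padj, 1e-300)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a peak matrix to MatrixMarket + TSV metadata
#'
#' Writes `counts.mtx`, `rows.tsv` and `peaks.tsv` into a directory; the
#' layout mirrors the common cells-by-features exchange format.
#'
#' @param mat a `PeakMatrix`.
#' @param dir output directory (created if needed).
#' @export
write_peak_matrix <- function(mat, dir) {
  stopifnot(inherits(mat, "PeakMatrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(mat$counts, "CsparseMatrix"),
                  file.path(dir, "counts.mtx"))
  utils::write.table(mat$row_meta, file.path(dir, "rows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(mat$col_meta, file.path(dir, "peaks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
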