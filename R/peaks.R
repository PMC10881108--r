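# Peak calling. All three callers (CCcaller, MACCs, Blockify) share one
# significance engine: the expected number of experiment insertions in a
# candidate interval under the null (lambda) is estimated either from a
# background insertion set or from the local insertion rate, always corrected
# for the TTAA content of the intervals involved, and the candidate is tested
# with a one-sided Poisson upper tail.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Peak caller configuration
#'
#' @param mode `"auto"` (background mode when a background set is supplied),
#'   `"with_background"` or `"background_free"`.
#' @param window sliding-window width in bp (MACCs) and the neighborhood
#'   width used to locate a candidate's density center.
#' @param step sliding-window step in bp; must be <= `window`.
#' @param maxbetween maximum gap in bp between consecutive insertions within
#'   one CCcaller candidate block.
#' @param lambda_windows radii (bp) of the flanking windows used to estimate
#'   the local null rate; the most conservative (largest) lambda wins.
#' @param min_insertions minimum experiment insertions for a candidate to be
#'   tested (5 is a typical bulk setting; 3 suits sparse single-cell data).
#' @param pvalue_cutoff significance threshold; defaults to 0.01 with a
#'   background and 1e-4 background-free.
#' @param pseudocount floor applied to background counts / lambda so that a
#'   zero background never yields a zero null mean.
#' @param multiple_testing `"BH"` (filter on Benjamini-Hochberg adjusted
#'   values; raw p reported alongside) or `"none"` (filter on raw p).
#' @param extend margin in bp added to each side of a called peak interval.
#' @return A `CallerConfig` list.
#' @export
caller_config <- function(mode = c("auto", "with_background", "background_free"),
                          window = 1000L, step = 500L, maxbetween = 2000L,
                          lambda_windows = c(1000L, 5000L, 10000L),
                          min_insertions = 5L, pvalue_cutoff = NULL,
                          pseudocount = 0.5,
                          multiple_testing = c("BH", "none"),
                          extend = 0L) {
  mode <- match.arg(mode)
  multiple_testing <- match.arg(multiple_testing)
  if (step > window) stop("step must be <= window")
  if (maxbetween <= 0) stop("maxbetween must be > 0")
  if (!length(lambda_windows)) stop("lambda_windows must be nonempty")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  structure(list(mode = mode, window = as.integer(window),
                 step = as.integer(step), maxbetween = as.integer(maxbetween),
                 lambda_windows = as.integer(sort(lambda_windows)),
                 min_insertions = as.integer(min_insertions),
                 pvalue_cutoff = pvalue_cutoff, pseudocount = pseudocount,
                 multiple_testing = multiple_testing,
                 extend = as.integer(extend)),
            class = "CallerConfig")
}

resolve_mode <- function(cfg, bkg) {
  has_bkg <- !is.null(bkg) && bkg$total > 0L
  if (!is.null(bkg) && bkg$total == 0L)
    warning("background set is empty; falling back to background-free mode")
  mode <- cfg$mode
  if (mode == "auto") mode <- if (has_bkg) "with_background" else "background_free"
  if (mode == "with_background" && !has_bkg)
    stop("with_background mode requires a nonempty background set; ",
         "use background_free mode instead")
  mode
}

resolve_cutoff <- function(cfg, mode) {
  cfg$pvalue_cutoff %||% if (mode == "with_background") 0.01 else 1e-4
}

#' Poisson upper-tail probability
#'
#' `P(X >= x)` for `X ~ Poisson(lam)`. At `lam = 0` the distribution is a
#' point mass at zero, so the tail is 1 for `x = 0` and 0 otherwise (callers
#' apply a pseudocount before reaching this degenerate case).
#'
#' @param x observed count (nonnegative integer, vectorised).
#' @param lam expected count under the null (nonnegative, vectorised).
#' @return `P(X >= x)`.
#' @export
poisson_upper_tail <- function(x, lam) {
  if (any(x < 0) || any(lam < 0)) stop("x and lam must be nonnegative")
  if (any(x != floor(x))) stop("x must be integer-valued")
  stats::ppois(x - 1, lam, lower.tail = FALSE)
}

#' Expected insertion count (lambda) for a candidate peak
#'
#' With a background set, each local estimate is
#' `max(n_bkg, pseudocount) * (total_exp / total_bkg) * (ttaa_peak / max(ttaa_local, 1))`,
#' evaluated over the peak itself and over each flanking lambda window that is
#' larger than the peak; the maximum (most conservative) estimate is kept.
#' Background-free, the local rate is taken from the experiment itself:
#' `(n_exp_window - n_exp_peak) * ttaa_peak / max(ttaa_window - ttaa_peak, 1)`
#' maximised over lambda windows and floored at the pseudocount.
#'
#' @param cfg a [caller_config()]; `cfg$mode` selects the formula (`auto`
#'   resolves to with-background when `total_bkg` is supplied).
#' @param ttaa_peak TTAA count under the candidate interval.
#' @param n_bkg_local background insertion counts over the peak and each
#'   lambda window (vector, peak first). With-background mode only.
#' @param ttaa_local TTAA counts parallel to `n_bkg_local`.
#' @param total_exp,total_bkg library sizes. `total_bkg = 0` is an error.
#' @param n_exp_peak experiment insertions in the candidate (background-free).
#' @param n_exp_windows experiment insertions in each lambda window
#'   (background-free).
#' @param ttaa_windows TTAA counts of each lambda window (background-free).
#' @return The Poisson mean `lam` (scalar).
#' @export
expected_count <- function(cfg, ttaa_peak,
                           n_bkg_local = NULL, ttaa_local = NULL,
                           total_exp = NULL, total_bkg = NULL,
                           n_exp_peak = NULL, n_exp_windows = NULL,
                           ttaa_windows = NULL) {
  mode <- cfg$mode
  if (mode == "auto")
    mode <- if (!is.null(total_bkg)) "with_background" else "background_free"
  pc <- cfg$pseudocount
  if (mode == "with_background") {
    if (is.null(total_bkg) || is.null(total_exp))
      stop("with_background mode requires total_exp and total_bkg")
    if (total_bkg == 0)
      stop("total background count is 0; use background_free mode")
    if (length(n_bkg_local) != length(ttaa_local))
      stop("n_bkg_local and ttaa_local must be parallel")
    lam <- pmax(n_bkg_local, pc) * (total_exp / total_bkg) *
      (ttaa_peak / pmax(ttaa_local, 1))
    max(lam)
  } else {
    if (is.null(n_exp_peak) || is.null(n_exp_windows) || is.null(ttaa_windows))
      stop("background_free mode requires n_exp_peak, n_exp_windows, ttaa_windows")
    lam <- (n_exp_windows - n_exp_peak) * ttaa_peak /
      pmax(ttaa_windows - ttaa_peak, 1)
    max(pc, lam)
  }
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return Adjusted values (clipped at 1), in the input order.
#' @export
adjust_pvalues <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(pvalues[o] * m / (m:1)))[ro]
}

# ---------------------------------------------------------------------------
# PeakSet container

peak_columns <- c("chrom", "start", "end", "center", "n_exp", "n_bkg",
                  "n_ttaa", "lam", "pvalue", "qvalue")

#' Construct a peak set
#'
#' @param df data.frame with columns chrom, start, end, center, n_exp, n_bkg,
#'   n_ttaa, lam, pvalue, qvalue.
#' @return A `PeakSet` (a classed, sorted data.frame).
#' @export
PeakSet <- function(df = NULL) {
  if (is.null(df) || nrow(df) == 0L) {
    df <- as.data.frame(stats::setNames(
      list(character(), integer(), integer(), integer(), integer(), integer(),
           integer(), numeric(), numeric(), numeric()), peak_columns))
  }
  missing <- setdiff(peak_columns, names(df))
  if (length(missing))
    stop("PeakSet lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(df)) {
    if (any(df$start >= df$end)) stop("peak with start >= end")
    if (any(df$pvalue < 0 | df$pvalue > 1)) stop("pvalue outside [0, 1]")
    df <- df[order(df$chrom, df$start, method = "radix"), peak_columns,
             drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("PeakSet", "data.frame")
  df
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet with %d peak(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

# ---------------------------------------------------------------------------
# shared candidate scoring

chrom_positions <- function(iset, chrom) {
  r <- iset$records
  r$start[r$chrom == chrom]   # already sorted
}

# leftmost insertion position maximizing the insertion count in a
# window-width neighborhood [p - w/2, p + w/2)
density_center <- function(pos, window) {
  h <- max(1L, window %/% 2L)
  cnt <- count_in_ranges(pos, pos - h, pos + h)
  pos[which.max(cnt)]
}

# Vectorised lambda for candidate intervals on one chromosome.
# cand: data.frame(start, end); returns data.frame(n_exp, n_bkg, n_ttaa, lam).
candidate_stats <- function(cand, exp_pos, bkg_pos, ttaa_pos, cfg, mode,
                            total_exp, total_bkg) {
  n <- nrow(cand)
  start <- cand$start; end <- cand$end
  mid <- (start + end) %/% 2L
  width <- end - start
  n_exp <- count_in_ranges(exp_pos, start, end)
  n_ttaa <- count_in_ranges(ttaa_pos, start, end)
  pc <- cfg$pseudocount
  if (mode == "with_background") {
    n_bkg <- count_in_ranges(bkg_pos, start, end)
    ratio <- total_exp / total_bkg
    lam <- pmax(n_bkg, pc) * ratio * (n_ttaa / pmax(n_ttaa, 1))
    for (r in cfg$lambda_windows) {
      use <- 2L * r > width
      if (!any(use)) next
      ws <- mid - r; we <- mid + r
      nb <- count_in_ranges(bkg_pos, ws, we)
      tw <- count_in_ranges(ttaa_pos, ws, we)
      lam_r <- pmax(nb, pc) * ratio * (n_ttaa / pmax(tw, 1))
      lam <- ifelse(use, pmax(lam, lam_r), lam)
    }
  } else {
    n_bkg <- integer(n)
    lam <- rep(pc, n)
    for (r in cfg$lambda_windows) {
      ws <- mid - r; we <- mid + r
      ne <- count_in_ranges(exp_pos, ws, we)
      tw <- count_in_ranges(ttaa_pos, ws, we)
      lam_r <- (ne - n_exp) * n_ttaa / pmax(tw - n_ttaa, 1)
      lam <- pmax(lam, lam_r)
    }
  }
  data.frame(n_exp = n_exp, n_bkg = n_bkg, n_ttaa = n_ttaa, lam = lam)
}

# Gather candidates across chromosomes, test those meeting min_insertions,
# BH-adjust, filter at the cutoff. cands: data.frame(chrom,start,end,center).
score_candidates <- function(cands, exp, bkg, ttaa, cfg, mode) {
  cutoff <- resolve_cutoff(cfg, mode)
  total_exp <- exp$total
  total_bkg <- if (mode == "with_background") bkg$total else NULL
  out <- vector("list", 0L)
  for (chrom in unique(cands$chrom)) {
    cc <- cands[cands$chrom == chrom, , drop = FALSE]
    st <- candidate_stats(cc, chrom_positions(exp, chrom),
                          if (mode == "with_background") chrom_positions(bkg, chrom) else NULL,
                          ttaa$positions[[chrom]], cfg, mode,
                          total_exp, total_bkg)
    out[[length(out) + 1L]] <- cbind(cc, st)
  }
  res <- do.call(rbind, out)
  res <- res[res$n_exp >= cfg$min_insertions, , drop = FALSE]
  if (!nrow(res)) return(PeakSet())
  res$pvalue <- poisson_upper_tail(res$n_exp, res$lam)
  res$qvalue <- adjust_pvalues(res$pvalue)
  crit <- if (cfg$multiple_testing == "BH") res$qvalue else res$pvalue
  res <- res[crit <= cutoff, , drop = FALSE]
  PeakSet(res)
}

drop_unindexed_chroms <- function(iset, ttaa) {
  chroms <- names(iset$totals)
  missing <- setdiff(chroms, names(ttaa$positions))
  if (length(missing))
    warning("dropping insertions on chromosome(s) absent from the TTAA index: ",
            paste(missing, collapse = ", "))
  setdiff(chroms, missing)
}

# ---------------------------------------------------------------------------
# CCcaller

#' Call peaks with the greedy gap-based method (CCcaller)
#'
#' Scans the sorted insertion positions of each chromosome left to right,
#' starting a candidate block at the first insertion and extending it while
#' the next insertion is within `maxbetween` bp; every insertion belongs to
#' exactly one candidate block. Blocks with at least `min_insertions`
#' experiment insertions are tested against the TTAA-corrected Poisson null
#' (see [expected_count()]) and significant blocks become peaks with interval
#' `[first insertion, last insertion + 4)` plus the `extend` margin.
#'
#' @param exp experiment [InsertionSet] (nonempty).
#' @param bkg optional background [InsertionSet] from an unfused transposase.
#' @param ttaa a `TTAAIndex` for the same assembly.
#' @param cfg a [caller_config()].
#' @return A `PeakSet`.
#' @export
call_cccaller <- function(exp, bkg = NULL, ttaa, cfg = caller_config()) {
  stopifnot(inherits(exp, "InsertionSet"), inherits(ttaa, "TTAAIndex"))
  if (exp$total == 0L) stop("experiment insertion set is empty")
  mode <- resolve_mode(cfg, bkg)
  chroms <- drop_unindexed_chroms(exp, ttaa)
  cands <- lapply(chroms, function(chrom) {
    p <- chrom_positions(exp, chrom)
    first_idx <- c(1L, which(diff(p) > cfg$maxbetween) + 1L)
    last_idx <- c(first_idx[-1L] - 1L, length(p))
    center <- vapply(seq_along(first_idx), function(k)
      density_center(p[first_idx[k]:last_idx[k]], cfg$window), numeric(1))
    data.frame(chrom = chrom,
               start = pmax(0L, p[first_idx] - cfg$extend),
               end = p[last_idx] + 4L + cfg$extend,
               center = as.integer(center), stringsAsFactors = FALSE)
  })
  cands <- do.call(rbind, cands)
  if (is.null(cands) || !nrow(cands)) return(PeakSet())
  score_candidates(cands, exp, bkg, ttaa, cfg, mode)
}

# ---------------------------------------------------------------------------
# MACCs

#' Call peaks with the sliding-window method (MACCs)
#'
#' Slides a window of `cfg$window` bp by `cfg$step` over each chromosome; a
#' window is provisionally enriched if its insertion count passes the Poisson
#' test at the cutoff against its own local expected count. Overlapping and
#' abutting enriched windows are merged into candidates; each candidate's
#' center is the insertion position maximising the insertion count in a
#' window-width neighborhood (ties broken leftmost), its interval is trimmed
#' to `[first, last insertion + 4)`, and the final p-value is recomputed on
#' the trimmed interval exactly as in [call_cccaller()].
#'
#' @inheritParams call_cccaller
#' @return A `PeakSet`.
#' @export
call_maccs <- function(exp, bkg = NULL, ttaa, cfg = caller_config()) {
  stopifnot(inherits(exp, "InsertionSet"), inherits(ttaa, "TTAAIndex"))
  if (exp$total == 0L) stop("experiment insertion set is empty")
  mode <- resolve_mode(cfg, bkg)
  cutoff <- resolve_cutoff(cfg, mode)
  chroms <- drop_unindexed_chroms(exp, ttaa)
  total_exp <- exp$total
  total_bkg <- if (mode == "with_background") bkg$total else NULL
  cands <- lapply(chroms, function(chrom) {
    p <- chrom_positions(exp, chrom)
    if (!length(p)) return(NULL)
    ws <- seq.int(from = (min(p) %/% cfg$step) * cfg$step, to = max(p),
                  by = cfg$step)
    win <- data.frame(start = as.integer(ws), end = as.integer(ws + cfg$window))
    win <- win[count_in_ranges(p, win$start, win$end) > 0L, , drop = FALSE]
    if (!nrow(win)) return(NULL)
    st <- candidate_stats(win, p,
                          if (mode == "with_background") chrom_positions(bkg, chrom) else NULL,
                          ttaa$positions[[chrom]], cfg, mode,
                          total_exp, total_bkg)
    pv <- poisson_upper_tail(st$n_exp, st$lam)
    win <- win[pv <= cutoff, , drop = FALSE]
    if (!nrow(win)) return(NULL)
    merged <- IRanges::reduce(IRanges::IRanges(win$start + 1L, win$end))
    ms <- IRanges::start(merged) - 1L
    me <- IRanges::end(merged)
    res <- lapply(seq_along(ms), function(i) {
      inside <- p[p >= ms[i] & p < me[i]]
      if (!length(inside)) return(NULL)
      data.frame(chrom = chrom,
                 start = pmax(0L, min(inside) - cfg$extend),
                 end = max(inside) + 4L + cfg$extend,
                 center = density_center(inside, cfg$window),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  cands <- do.call(rbind, cands)
  if (is.null(cands) || !nrow(cands)) return(PeakSet())
  score_candidates(cands, exp, bkg, ttaa, cfg, mode)
}

# ---------------------------------------------------------------------------
# Bayesian Blocks

# Scargle-style event-data segmentation on one chromosome.
# x: unique sorted positions, w: multiplicities. Returns data.frame of block
# index ranges (i, j) into x plus integer interval bounds.
bayesian_blocks_1d <- function(x, w, ncp_prior) {
  m <- length(x)
  if (m == 1L)
    return(data.frame(i = 1L, j = 1L, start = x, end = x + 4L))
  edges <- c(x[1L], (x[-m] + x[-1L]) / 2, x[m] + 4)
  cw <- c(0, cumsum(w))
  best <- numeric(m)
  last <- integer(m)
  for (R in seq_len(m)) {
    r <- seq_len(R)
    N <- cw[R + 1L] - cw[r]
    Tlen <- edges[R + 1L] - edges[r]
    fit <- N * (log(N) - log(Tlen)) - ncp_prior +
      c(0, best[seq_len(R - 1L)])
    last[R] <- which.max(fit)
    best[R] <- fit[last[R]]
  }
  # backtrack
  cp <- integer(0)
  R <- m
  while (R > 0L) {
    cp <- c(last[R], cp)
    R <- last[R] - 1L
  }
  i <- cp
  j <- c(cp[-1L] - 1L, m)
  data.frame(i = i, j = j,
             start = as.integer(floor(edges[i])),
             end = as.integer(ceiling(edges[j + 1L])))
}

scargle_ncp_prior <- function(n, p0 = 0.05) 4 - log(73.53 * p0 * n^(-0.478))

#' Call peaks by Bayesian-Blocks segmentation (Blockify-style)
#'
#' Segments the insertion positions of each chromosome with the Bayesian
#' Blocks dynamic program for event data (block fitness
#' `N * (log N - log T)` for `N` events in a block of length `T`, with a
#' change-point prior `ncp_prior`), then tests and filters the resulting
#' blocks with the same TTAA-corrected Poisson machinery as the other
#' callers.
#'
#' @inheritParams call_cccaller
#' @param p0 false-alarm probability used by the default change-point prior
#'   calibration `ncp_prior = 4 - log(73.53 * p0 * n^-0.478)`.
#' @param ncp_prior explicit change-point prior; overrides `p0`.
#' @return A `PeakSet`.
#' @export
call_blockify <- function(exp, bkg = NULL, ttaa, cfg = caller_config(),
                          p0 = 0.05, ncp_prior = NULL) {
  stopifnot(inherits(exp, "InsertionSet"), inherits(ttaa, "TTAAIndex"))
  if (exp$total == 0L) stop("experiment insertion set is empty")
  mode <- resolve_mode(cfg, bkg)
  chroms <- drop_unindexed_chroms(exp, ttaa)
  cands <- lapply(chroms, function(chrom) {
    p <- chrom_positions(exp, chrom)
    if (!length(p)) return(NULL)
    ux <- unique(p)
    w <- as.numeric(tabulate(match(p, ux)))
    ncp <- ncp_prior %||% scargle_ncp_prior(length(p), p0)
    blocks <- bayesian_blocks_1d(ux, w, ncp)
    center <- vapply(seq_len(nrow(blocks)), function(k) {
      inside <- p[p >= ux[blocks$i[k]] & p <= ux[blocks$j[k]]]
      density_center(inside, cfg$window)
    }, numeric(1))
    data.frame(chrom = chrom, start = blocks$start, end = blocks$end,
               center = as.integer(center), stringsAsFactors = FALSE)
  })
  cands <- do.call(rbind, cands)
  if (is.null(cands) || !nrow(cands)) return(PeakSet())
  score_candidates(cands, exp, bkg, ttaa, cfg, mode)
}
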