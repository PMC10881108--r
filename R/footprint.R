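# Footprint refinement. In yeast Calling Cards data a bound TF often
# protects its site: insertions pile up on both flanks but not at the site
# itself. A two-component 1-D Gaussian mixture fit to the insertion
# positions inside a peak localises the two flanking modes; the interval
# between them is the inferred binding site.

#' Fit a two-component Gaussian mixture footprint
#'
#' Deterministic EM on the 1-D insertion positions of one peak: means are
#' initialised at the 25th/75th percentile positions with equal weights and
#' the pooled standard deviation; component standard deviations are floored
#' at 1 bp to avoid singular point-mass components. The log-likelihood is
#' checked to be nondecreasing at every iteration. The inferred site is
#' `[mu1 + c * sd1, mu2 - c * sd2)` (c = 0 by default, i.e. the interval
#' between the two means); if the bounds cross, the site collapses to the
#' midpoint +/- 2 bp.
#'
#' @param positions insertion positions (bp) within one peak; at least `2 * k`
#'   and at least 2 distinct values.
#' @param k number of components (fixed at 2).
#' @param max_iter maximum EM iterations.
#' @param tol convergence threshold on the log-likelihood gain.
#' @param c_sd site-interval shrinkage in units of component sd.
#' @return A `FootprintFit`: list with `mu` (mu1 < mu2), `sd`, `weights`,
#'   `site_start`, `site_end`, `converged`, `loglik` (final value) and
#'   `loglik_trace`.
#' @export
fit_footprint <- function(positions, k = 2L, max_iter = 500L, tol = 1e-8,
                          c_sd = 0) {
  if (k != 2L) stop("only k = 2 components are supported")
  x <- as.numeric(positions)
  if (length(x) < 2L * k)
    stop("need at least ", 2L * k, " insertion positions; ",
         "skip footprinting for this peak")
  if (length(unique(x)) < 2L)
    stop("all insertion positions identical; footprint not identifiable")
  mu <- unname(stats::quantile(x, c(0.25, 0.75), type = 7))
  if (mu[1L] == mu[2L]) mu <- mu + c(-0.5, 0.5)
  sd0 <- max(stats::sd(x), 1)
  sds <- c(sd0, sd0)
  w <- c(0.5, 0.5)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- cbind(w[1L] * stats::dnorm(x, mu[1L], sds[1L]),
                  w[2L] * stats::dnorm(x, mu[2L], sds[2L]))
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    if (length(ll_trace) && ll < ll_old - 1e-8)
      stop("EM log-likelihood decreased (internal error)")
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.eps
    w <- nk / length(x)
    mu <- colSums(resp * x) / nk
    sds <- sqrt(pmax(colSums(resp * (outer(x, mu, "-"))^2) / nk, 1))
  }
  ord <- order(mu)
  mu <- mu[ord]; sds <- sds[ord]; w <- w[ord]
  site_start <- mu[1L] + c_sd * sds[1L]
  site_end <- mu[2L] - c_sd * sds[2L]
  if (site_start >= site_end) {
    mid <- mean(mu)
    site_start <- mid - 2
    site_end <- mid + 2
  }
  structure(list(mu = mu, sd = sds, weights = w,
                 site_start = site_start, site_end = site_end,
                 converged = converged, loglik = ll_trace[length(ll_trace)],
                 loglik_trace = ll_trace, n = length(x)),
            class = "FootprintFit")
}

#' @export
print.FootprintFit <- function(x, ...) {
  cat(sprintf(paste0("FootprintFit: mu = (%.1f, %.1f), sd = (%.1f, %.1f), ",
                     "site [%.0f, %.0f), %s\n"),
              x$mu[1L], x$mu[2L], x$sd[1L], x$sd[2L],
              x$site_start, x$site_end,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Footprint every peak in a peak set
#'
#' @param peaks a `PeakSet`.
#' @param exp the experiment [InsertionSet].
#' @param min_positions peaks with fewer insertions are skipped.
#' @param ... passed to [fit_footprint()].
#' @return data.frame with one row per footprinted peak: peak, mu1, mu2,
#'   sd1, sd2, site_start, site_end, converged, n.
#' @export
footprint_peaks <- function(peaks, exp, min_positions = 4L, ...) {
  stopifnot(inherits(peaks, "PeakSet"), inherits(exp, "InsertionSet"))
  rows <- list()
  pid <- peak_ids(peaks)
  for (i in seq_len(nrow(peaks))) {
    pos <- chrom_positions(exp, peaks$chrom[i])
    pos <- pos[pos >= peaks$start[i] & pos < peaks$end[i]]
    if (length(pos) < min_positions || length(unique(pos)) < 2L) next
    fit <- fit_footprint(pos, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      peak = pid[i], mu1 = fit$mu[1L], mu2 = fit$mu[2L],
      sd1 = fit$sd[1L], sd2 = fit$sd[2L],
      site_start = fit$site_start, site_end = fit$site_end,
      converged = fit$converged, n = fit$n, stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(peak = character(), mu1 = numeric(), mu2 = numeric(),
               sd1 = numeric(), sd2 = numeric(), site_start = numeric(),
               site_end = numeric(), converged = logical(), n = integer(),
               stringsAsFactors = FALSE)
}
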