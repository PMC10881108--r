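# Synthetic Calling Cards data with known ground truth. The generator
# emulates the two ingredients of real data: authentic peaks (directed
# insertions scattered around a bound site) and undirected background
# insertions, both restricted to TTAA tetranucleotide positions.

#' Simulation configuration
#'
#' Defaults describe a 1 Mb chromosome with a realistic TTAA density
#' (~1 site per 250 bp), 10 planted binding sites receiving on average 50
#' directed insertions each, and a sparse undirected background comparable
#' to bulk Calling Cards coverage.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param ttaa_density expected TTAA sites per bp (sites are placed by a
#'   seeded uniform process with the minimum 4 bp spacing).
#' @param n_true_peaks number of planted binding sites.
#' @param peak_width width (bp) of each true peak interval.
#' @param enrichment expected directed insertions per true peak (Poisson).
#' @param n_background number of undirected insertions in the experiment
#'   set; an independent background set of the same size is also drawn.
#' @param spread_sd standard deviation (bp) of directed insertion positions
#'   around each peak center before snapping to the nearest TTAA.
#' @param reads_p geometric parameter for per-insertion read counts
#'   (`reads = 1 + Geometric(reads_p)`).
#' @param n_cells number of cells (0 = bulk, 5-column qbed; > 0 emits
#'   barcodes).
#' @param n_clusters number of cell clusters (cells assigned round-robin).
#' @param activity_mask optional logical matrix (clusters x peaks); directed
#'   insertions at a peak only come from cells of active clusters.
#' @param centers optional list (per chromosome) of explicit peak centers,
#'   overriding random placement.
#' @param min_separation minimum distance (bp) between planted peak centers.
#' @param seed mandatory integer seed; all randomness derives from it.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(chrom_lengths = c(chrSim1 = 1e6),
                       ttaa_density = 0.004,
                       n_true_peaks = 10L, peak_width = 500L,
                       enrichment = 50, n_background = 200L,
                       spread_sd = 100, reads_p = 0.5,
                       n_cells = 0L, n_clusters = 1L,
                       activity_mask = NULL, centers = NULL,
                       min_separation = 20000L, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  if (any(c(n_true_peaks, n_background, n_cells) < 0))
    stop("counts must be >= 0")
  if (ttaa_density < 0 || ttaa_density > 0.25)
    stop("ttaa_density must lie in [0, 0.25]")
  structure(list(chrom_lengths = chrom_lengths, ttaa_density = ttaa_density,
                 n_true_peaks = as.integer(n_true_peaks),
                 peak_width = as.integer(peak_width),
                 enrichment = enrichment,
                 n_background = as.integer(n_background),
                 spread_sd = spread_sd, reads_p = reads_p,
                 n_cells = as.integer(n_cells),
                 n_clusters = as.integer(n_clusters),
                 activity_mask = activity_mask, centers = centers,
                 min_separation = as.integer(min_separation),
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Simulate TTAA positions for a synthetic genome
#'
#' Places TTAA sites by a seeded uniform process at the configured density
#' with the physical minimum spacing of 4 bp (sites cannot share bases with
#' identical sequence TTAA overlapping itself). The number of sites per
#' chromosome is Binomial(length, density).
#'
#' @param cfg a [sim_config()].
#' @return A `TTAAIndex`.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  positions <- lapply(cfg$chrom_lengths, function(L) {
    L <- as.integer(L)
    n <- stats::rbinom(1L, L, cfg$ttaa_density)
    if (n == 0L) return(integer(0))
    M <- L - 4L * n + 1L
    if (M < 1L) stop("ttaa_density too high for minimum 4 bp spacing")
    y <- sort(sample.int(M, n, replace = TRUE)) - 1L
    y + 4L * (seq_len(n) - 1L)
  })
  TTAAIndex(positions)
}

snap_nearest <- function(sorted_pos, x) {
  n <- length(sorted_pos)
  i <- findInterval(x, sorted_pos)
  left <- sorted_pos[pmax(i, 1L)]
  right <- sorted_pos[pmin(i + 1L, n)]
  out <- ifelse(i == 0L, right,
                ifelse(i >= n, left,
                       ifelse(x - left <= right - x, left, right)))
  as.integer(out)
}

#' Simulate Calling Cards insertions with known ground truth
#'
#' Background (undirected) insertions are drawn uniformly over TTAA
#' positions; directed insertions are drawn per planted peak as
#' Normal(center, spread_sd) and snapped to the nearest TTAA, so every
#' insertion lands exactly on a TTAA start. Read counts are
#' 1 + Geometric(reads_p). With `n_cells > 0`, each insertion carries a cell
#' barcode; directed insertions at a peak come only from cells of clusters
#' active for that peak.
#'
#' @param cfg a [sim_config()].
#' @param ttaa optional `TTAAIndex`; generated from `cfg` when NULL.
#' @return list with `exp` (experiment [InsertionSet] = directed +
#'   undirected), `bkg` (independent background [InsertionSet]), `ttaa`,
#'   and `truth` (a `GroundTruth`: `true_peaks` data.frame, per-insertion
#'   `labels` aligned with `exp$records`, and `cells`).
#' @export
simulate_insertions <- function(cfg, ttaa = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (is.null(ttaa)) ttaa <- simulate_genome(cfg)
  set.seed(cfg$seed + 1L)
  chroms <- names(cfg$chrom_lengths)
  half <- cfg$peak_width %/% 2L

  # plant peaks: centers on TTAAs, pairwise separated, away from edges
  true_peaks <- data.frame(chrom = character(), start = integer(),
                           end = integer(), center = integer(),
                           stringsAsFactors = FALSE)
  if (!is.null(cfg$centers)) {
    # explicit placement: plant exactly the requested centers, snapped to
    # the nearest TTAA
    for (chrom in names(cfg$centers)) {
      centers <- snap_nearest(ttaa$positions[[chrom]], cfg$centers[[chrom]])
      true_peaks <- rbind(true_peaks, data.frame(
        chrom = chrom, start = as.integer(centers - half),
        end = as.integer(centers + half), center = as.integer(centers),
        stringsAsFactors = FALSE))
    }
  } else if (cfg$n_true_peaks > 0L) {
    per_chrom <- table(factor(
      sample(chroms, cfg$n_true_peaks,
             replace = TRUE, prob = cfg$chrom_lengths / sum(cfg$chrom_lengths)),
      levels = chroms))
    for (chrom in chroms) {
      k <- per_chrom[[chrom]]
      if (!k) next
      pos <- ttaa$positions[[chrom]]
      margin <- half + 4 * cfg$spread_sd + 4
      eligible <- pos[pos > margin & pos < cfg$chrom_lengths[[chrom]] - margin]
      if (length(eligible) < k)
        stop("not enough TTAA sites on ", chrom, " to plant peaks")
      centers <- integer(0)
      for (tries in seq_len(1000L)) {
        cand <- sample(eligible, 1L)
        if (!length(centers) || min(abs(centers - cand)) >= cfg$min_separation)
          centers <- c(centers, cand)
        if (length(centers) == k) break
      }
      if (length(centers) < k)
        stop("could not place ", k, " separated peaks on ", chrom,
             " after bounded retries")
      true_peaks <- rbind(true_peaks, data.frame(
        chrom = chrom, start = as.integer(centers - half),
        end = as.integer(centers + half), center = as.integer(centers),
        stringsAsFactors = FALSE))
    }
  }
  if (nrow(true_peaks)) {
    true_peaks <- true_peaks[order(true_peaks$chrom, true_peaks$start), ,
                             drop = FALSE]
    rownames(true_peaks) <- NULL
    true_peaks$peak_id <- seq_len(nrow(true_peaks))
  }

  # cells and clusters
  cells <- NULL
  if (cfg$n_cells > 0L) {
    cells <- data.frame(
      barcode = sprintf("cell%05d", seq_len(cfg$n_cells)),
      cluster = paste0("cluster",
                       ((seq_len(cfg$n_cells) - 1L) %% cfg$n_clusters) + 1L),
      stringsAsFactors = FALSE)
  }
  mask <- cfg$activity_mask
  if (is.null(mask) && nrow(true_peaks) && cfg$n_clusters > 0L)
    mask <- matrix(TRUE, cfg$n_clusters, nrow(true_peaks))

  draw_uniform_bkg <- function(n) {
    chrom_of <- sample(chroms, n, replace = TRUE,
                       prob = lengths(ttaa$positions)[chroms])
    pos <- integer(n)
    for (chrom in chroms) {
      sel <- chrom_of == chrom
      if (any(sel))
        pos[sel] <- sample(ttaa$positions[[chrom]], sum(sel), replace = TRUE)
    }
    data.frame(chrom = chrom_of, start = pos, stringsAsFactors = FALSE)
  }

  # directed insertions
  directed <- NULL
  if (nrow(true_peaks)) {
    dl <- lapply(seq_len(nrow(true_peaks)), function(j) {
      nd <- stats::rpois(1L, cfg$enrichment)
      if (!nd) return(NULL)
      chrom <- true_peaks$chrom[j]
      raw <- stats::rnorm(nd, true_peaks$center[j], cfg$spread_sd)
      data.frame(chrom = chrom,
                 start = snap_nearest(ttaa$positions[[chrom]], raw),
                 origin = j, stringsAsFactors = FALSE)
    })
    directed <- do.call(rbind, dl)
  }
  undirected <- if (cfg$n_background > 0L) draw_uniform_bkg(cfg$n_background) else NULL
  if (!is.null(undirected) && nrow(undirected)) undirected$origin <- 0L

  exp_df <- rbind(directed, undirected)
  if (is.null(exp_df) || !nrow(exp_df)) stop("simulation produced no insertions")
  exp_df$end <- exp_df$start + 4L
  exp_df$reads <- 1L + stats::rgeom(nrow(exp_df), cfg$reads_p)
  exp_df$strand <- sample(c("+", "-"), nrow(exp_df), replace = TRUE)
  if (!is.null(cells)) {
    bc <- character(nrow(exp_df))
    for (i in seq_len(nrow(exp_df))) {
      j <- exp_df$origin[i]
      pool <- if (j > 0L && !is.null(mask)) {
        active <- paste0("cluster", which(mask[, j]))
        cells$barcode[cells$cluster %in% active]
      } else cells$barcode
      if (!length(pool)) pool <- cells$barcode
      bc[i] <- sample(pool, 1L)
    }
    exp_df$barcode <- bc
  }
  ord <- order(exp_df$chrom, exp_df$start, exp_df$end, method = "radix")
  exp_df <- exp_df[ord, , drop = FALSE]
  labels <- ifelse(exp_df$origin > 0L, "directed", "background")
  core <- c("chrom", "start", "end", "reads", "strand",
            if (!is.null(cells)) "barcode")
  exp <- InsertionSet(exp_df[, core, drop = FALSE])

  bkg_df <- draw_uniform_bkg(max(cfg$n_background, 1L))
  bkg_df$end <- bkg_df$start + 4L
  bkg_df$reads <- 1L + stats::rgeom(nrow(bkg_df), cfg$reads_p)
  bkg_df$strand <- sample(c("+", "-"), nrow(bkg_df), replace = TRUE)
  bkg <- InsertionSet(bkg_df)

  truth <- structure(list(true_peaks = true_peaks, labels = labels,
                          origin = exp_df$origin, cells = cells),
                     class = "GroundTruth")
  list(exp = exp, bkg = bkg, ttaa = ttaa, truth = truth)
}

#' Score called peaks against simulation ground truth
#'
#' A true peak is recovered when at least one called peak overlaps it by >= 1
#' bp; a called peak is a true positive when it overlaps any true interval.
#' With zero called peaks precision is reported as 1 with `zero_call = TRUE`.
#' Also reports the cumulative called peak length, the fraction of
#' experiment insertions under called peaks (when `exp` is given), and the
#' maximum number of true peaks spanned by one called peak (an over-merging
#' flag).
#'
#' @param called a `PeakSet`.
#' @param truth a `GroundTruth` from [simulate_insertions()].
#' @param exp optional experiment [InsertionSet] for the insertion-fraction
#'   statistic.
#' @return list: recall, precision, zero_call, n_called, n_true,
#'   cumulative_length, insertion_fraction, max_true_per_called.
#' @export
score_caller <- function(called, truth, exp = NULL) {
  stopifnot(inherits(called, "PeakSet"), inherits(truth, "GroundTruth"))
  tp <- truth$true_peaks
  n_true <- nrow(tp)
  n_called <- nrow(called)
  overlap <- matrix(FALSE, n_called, max(n_true, 1L))
  if (n_called && n_true) {
    for (i in seq_len(n_called)) {
      overlap[i, ] <- tp$chrom == called$chrom[i] &
        tp$start < called$end[i] & called$start[i] < tp$end
    }
  }
  recall <- if (n_true) mean(apply(overlap, 2L, any)[seq_len(n_true)]) else NA_real_
  precision <- if (n_called) mean(apply(overlap, 1L, any)) else 1
  insertion_fraction <- NA_real_
  if (!is.null(exp) && exp$total) {
    under <- 0L
    for (chrom in unique(called$chrom)) {
      pk <- called[called$chrom == chrom, , drop = FALSE]
      pos <- chrom_positions(exp, chrom)
      under <- under + sum(count_in_ranges(pos, pk$start, pk$end))
    }
    insertion_fraction <- under / exp$total
  }
  list(recall = recall, precision = precision, zero_call = n_called == 0L,
       n_called = n_called, n_true = n_true,
       cumulative_length = if (n_called) sum(called$end - called$start) else 0L,
       insertion_fraction = insertion_fraction,
       max_true_per_called = if (n_called && n_true) max(rowSums(overlap)) else 0L)
}

#' Write a simulated dataset to disk
#'
#' Writes `exp.qbed`, `bkg.qbed`, `ttaa.bed` and `truth.json` into a
#' directory.
#'
#' @param sim result of [simulate_insertions()].
#' @param dir output directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_qbed(sim$exp, file.path(dir, "exp.qbed"))
  write_qbed(sim$bkg, file.path(dir, "bkg.qbed"))
  ttaa_lines <- unlist(lapply(names(sim$ttaa$positions), function(chrom) {
    p <- sim$ttaa$positions[[chrom]]
    if (!length(p)) return(character(0))
    paste(chrom, p, p + 4L, sep = "\t")
  }))
  writeLines(ttaa_lines, file.path(dir, "ttaa.bed"))
  jsonlite::write_json(
    list(true_peaks = sim$truth$true_peaks,
         labels = sim$truth$labels,
         cells = sim$truth$cells),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
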