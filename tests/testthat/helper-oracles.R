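# Independent oracles (brute force / direct summation) used to pin expected
# values. These deliberately avoid the code paths they check.

# P(X >= x) for X ~ Poisson(lam) by direct series summation of the tail.
oracle_poisson_tail <- function(x, lam) {
  if (lam == 0) return(if (x == 0) 1 else 0)
  if (x == 0) return(1)
  term <- exp(x * log(lam) - lam - lgamma(x + 1))
  total <- term
  k <- x
  repeat {
    k <- k + 1
    term <- term * lam / k
    total <- total + term
    if (term < total * 1e-18 || k > x + 10000) break
  }
  min(total, 1)
}

# Two-sided Fisher exact p for [[a,b],[c,d]] by full hypergeometric
# enumeration with choose(); sums outcomes no more probable than observed
# (relative tolerance 1e-7, the conventional rule).
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  av <- max(0, k - m2):min(k, m1)
  probs <- choose(m1, av) * choose(m2, k - av) / choose(m1 + m2, k)
  p_obs <- probs[match(a, av)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# P(X >= x) for X ~ Binomial(n, p) by direct summation.
oracle_binom_tail <- function(x, n, p) {
  if (x <= 0) return(1)
  k <- x:n
  sum(choose(n, k) * p^k * (1 - p)^(n - k))
}

# Hand Benjamini-Hochberg: p * m / rank, cumulative minimum from the largest.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  pmin(q, 1)[order(o)]
}

# Brute-force optimal Bayesian-Blocks segmentation over all 2^(m-1)
# placements of change points between the m unique event positions, using
# the same Voronoi edges and fitness N*(log N - log T) - ncp per block.
oracle_bayesian_blocks <- function(x, w, ncp) {
  m <- length(x)
  edges <- if (m == 1) c(x, x + 4) else c(x[1], (x[-m] + x[-1]) / 2, x[m] + 4)
  score_seg <- function(bounds) {  # bounds: indexes of first cell of each block
    tot <- 0
    starts <- bounds
    ends <- c(bounds[-1] - 1L, m)
    for (b in seq_along(starts)) {
      N <- sum(w[starts[b]:ends[b]])
      Tlen <- edges[ends[b] + 1L] - edges[starts[b]]
      tot <- tot + N * (log(N) - log(Tlen)) - ncp
    }
    tot
  }
  best <- -Inf; best_bounds <- 1L
  if (m == 1) return(list(score = score_seg(1L), bounds = 1L))
  for (mask in 0:(2^(m - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(m - 2))) > 0) + 1L
    bounds <- c(1L, cuts)
    s <- score_seg(bounds)
    if (s > best) { best <- s; best_bounds <- bounds }
  }
  list(score = best, bounds = best_bounds)
}

# DP score of a segmentation returned by the package (for comparison with
# the brute-force optimum).
segmentation_score <- function(x, w, bounds, ncp) {
  oracle_seg <- function() {
    m <- length(x)
    edges <- if (m == 1) c(x, x + 4) else c(x[1], (x[-m] + x[-1]) / 2, x[m] + 4)
    starts <- bounds
    ends <- c(bounds[-1] - 1L, m)
    tot <- 0
    for (b in seq_along(starts)) {
      N <- sum(w[starts[b]:ends[b]])
      Tlen <- edges[ends[b] + 1L] - edges[starts[b]]
      tot <- tot + N * (log(N) - log(Tlen)) - ncp
    }
    tot
  }
  oracle_seg()
}
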