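# Independent oracles, coded without reference to the package internals.

# Brute-force tricube weighted least squares: Cleveland's LOESS evaluated
# point by point.  Neighbourhood = the floor(span * n) nearest points;
# weights tricube on distance scaled by the distance to the furthest
# included neighbour.
oracle_loess <- function(x, y, span, degree, at = x) {
  n <- length(x)
  q <- max(min(floor(n * span), n), degree + 1)
  vapply(at, function(x0) {
    d <- abs(x - x0)
    h <- sort(d)[q]
    if (h <= 0) h <- .Machine$double.eps
    w <- (1 - pmin(d / h, 1)^3)^3
    keep <- w > 0
    X <- outer(x[keep] - x0, 0:degree, `^`)
    fit <- lm.wfit(X, y[keep], w[keep])
    unname(fit$coefficients[1])
  }, numeric(1))
}

# Exhaustive semi-global alignment: minimal global edit distance of the
# pattern against every substring of the subject, by Levenshtein distance
# (adist) over all substrings.  O(m^2 n); tiny inputs only.
oracle_semiglobal <- function(pattern, subject) {
  m <- nchar(subject)
  best <- Inf
  n_best_ends <- 0L
  for (end in 1:m) {
    cand <- min(vapply(1:(end + 1), function(start) {
      if (start > end) {
        nchar(pattern)  # empty substring: delete nothing, insert all
      } else {
        adist(pattern, substr(subject, start, end))[1, 1]
      }
    }, numeric(1)))
    if (cand < best) {
      best <- cand
      n_best_ends <- 1L
    } else if (cand == best) {
      n_best_ends <- n_best_ends + 1L
    }
  }
  list(cost = best, n_best_ends = n_best_ends)
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(n1+n2, n1) labelings, on mid-ranks.
oracle_mw_exact <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2); N <- n1 + n2
  r <- rank(c(g1, g2))
  obs <- abs(sum(r[seq_len(n1)]) - n1 * (N + 1) / 2)
  combos <- combn(N, n1)
  sums <- colSums(matrix(r[combos], nrow = n1))
  mean(abs(sums - n1 * (N + 1) / 2) >= obs - 1e-9)
}

# Reverse complement without Biostrings.
oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(unname(map[strsplit(s, "")[[1]]])), collapse = "")
}
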