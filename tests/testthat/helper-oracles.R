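# Independent brute-force oracles and small test utilities.

# exhaustive least-squares single change-point: returns the breakpoint k
# (last index of the left segment) minimizing total SSE
oracle_one_breakpoint <- function(x, min_width = 3L) {
  n <- length(x)
  best <- list(k = NA_integer_, sse = Inf)
  for (k in seq(min_width, n - min_width)) {
    l <- x[1:k]; r <- x[(k + 1):n]
    sse <- sum((l - mean(l))^2) + sum((r - mean(r))^2)
    if (sse < best$sse) best <- list(k = k, sse = sse)
  }
  best$k
}

# exhaustive least-squares two change-points (k1 < k2); prefix sums make the
# O(n^2) scan cheap, but every split is still evaluated exactly
oracle_two_breakpoints <- function(x, min_width = 3L) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  css <- c(0, cumsum(x^2))
  sse_seg <- function(a, b) {  # SSE of x[a..b]
    s <- cs[b + 1] - cs[a]
    (css[b + 1] - css[a]) - s^2 / (b - a + 1)
  }
  best <- list(k = c(NA, NA), sse = Inf)
  for (k1 in seq(min_width, n - 2L * min_width)) {
    for (k2 in seq(k1 + min_width, n - min_width)) {
      sse <- sse_seg(1, k1) + sse_seg(k1 + 1, k2) + sse_seg(k2 + 1, n)
      if (sse < best$sse) best <- list(k = c(k1, k2), sse = sse)
    }
  }
  best$k
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_i * sum_j / n
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# planted per-bin integer copy state for a clone definition; NA for bins
# straddling a planted breakpoint (their state is undefined at bin
# resolution)
planted_bin_states <- function(bins, clone_def) {
  vapply(seq_len(nrow(bins)), function(i) {
    d <- clone_def[clone_def$chrom == bins$chrom[i] &
                     clone_def$end >= bins$start[i] &
                     clone_def$start <= bins$end[i], ]
    if (nrow(d) == 1L) as.numeric(d$state) else NA_real_
  }, numeric(1))
}
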