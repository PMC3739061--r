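# Independent oracles used to freeze expected values.

# Enumerate all set partitions of n items (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, mx) {
    if (length(labels) == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (l in seq_len(mx + 1)) rec(c(labels, l), max(mx, l))
  }
  rec(integer(0), 0L)
  out
}

# Exhaustive-enumeration modularity optimum (feasible for n <= 8).
best_partition_q <- function(g) {
  stopifnot(nrow(g$w) <= 9)
  best <- -Inf
  for (p in all_partitions(nrow(g$w))) {
    q <- modularity_q(g, p)
    if (q > best) best <- q
  }
  best
}

# Direct double-loop evaluation of weighted modularity (independent of the
# package's grouped-sum implementation).
naive_q <- function(w, assignment) {
  diag(w) <- 0
  k <- rowSums(w)
  m2 <- sum(w)
  q <- 0
  n <- nrow(w)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (assignment[i] == assignment[j]) {
        q <- q + w[i, j] - k[i] * k[j] / m2
      }
    }
  }
  q / m2
}
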