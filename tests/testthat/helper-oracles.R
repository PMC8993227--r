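# independent oracles kept deliberately naive: they re-derive expected
# values by brute force, never by calling the implementation's code path

# O(n^2) transitive-closure clustering: link every pair within `window`,
# then take connected components
oracle_cluster <- function(pos, window) {
  n <- length(pos)
  if (n == 0) return(integer(0))
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      linked <- which(abs(pos - pos[i]) <= window)
      target <- min(comp[linked], comp[i])
      if (any(comp[linked] != target) || comp[i] != target) {
        comp[linked] <- target
        comp[i] <- target
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp[order(pos)]))
}

# per-character internal-priming rule check on one window string
oracle_ip_artifact <- function(window, max_a = 7, run_a = 6) {
  ch <- strsplit(window, "")[[1]]
  is_a <- ch == "A"
  lead <- if (length(is_a) == 0 || !is_a[1]) 0 else {
    stop_at <- which(!is_a)
    if (length(stop_at) == 0) length(is_a) else stop_at[1] - 1
  }
  sum(is_a) >= max_a || lead >= run_a
}

# spreadsheet-style median-of-ratios recomputation (loops, no vectorized
# shortcuts shared with the implementation)
oracle_size_factors <- function(counts) {
  ok <- apply(counts, 1, function(r) all(r > 0))
  geo <- numeric(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    geo[i] <- prod(counts[i, ])^(1 / ncol(counts))
  }
  sf <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    sf[j] <- median(counts[ok, j] / geo[ok])
  }
  sf
}

# textbook Pearson chi-square on a 2 x k table
oracle_chisq <- function(tbl) {
  tot <- sum(tbl)
  stat <- 0
  for (i in seq_len(nrow(tbl))) {
    for (j in seq_len(ncol(tbl))) {
      e <- sum(tbl[i, ]) * sum(tbl[, j]) / tot
      stat <- stat + (tbl[i, j] - e)^2 / e
    }
  }
  stat
}

# Benjamini-Hochberg step-up, written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}
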