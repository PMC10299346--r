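# Independent oracles used to cross-check the package's implementations.
# Each is written as plainly as possible and shares no code with the package.

# mean over all sequence pairs of their per-effective-site difference
pi_bruteforce <- function(msa) {
  eff <- apply(msa, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- msa[, eff, drop = FALSE]
  L <- ncol(m)
  if (L == 0) return(NA_real_)
  d <- nrow(m)
  vals <- c()
  for (i in 1:(d - 1)) for (j in (i + 1):d) {
    vals <- c(vals, sum(m[i, ] != m[j, ]) / L)
  }
  mean(vals)
}

random_msa <- function(depth, len, gap_prob = 0.1, amb_prob = 0.05) {
  alphabet <- c("A", "C", "G", "T")
  m <- matrix(sample(alphabet, depth * len, replace = TRUE), nrow = depth)
  mask <- matrix(runif(depth * len) < gap_prob, nrow = depth)
  m[mask] <- "-"
  mask2 <- matrix(runif(depth * len) < amb_prob, nrow = depth)
  m[mask2 & !mask] <- "N"
  rownames(m) <- paste0("s", seq_len(depth))
  m
}

# longest monotone chain with rank-gap cap, memoised recursion over pairs
longest_chain_oracle <- function(ra, rb, max_gap) {
  n <- length(ra)
  memo <- rep(NA_integer_, n)
  follow <- function(i) {
    if (!is.na(memo[i])) return(memo[i])
    best <- 1L
    for (j in seq_len(n)) {
      if (ra[j] > ra[i] && rb[j] > rb[i] &&
          ra[j] - ra[i] - 1 <= max_gap && rb[j] - rb[i] - 1 <= max_gap) {
        best <- max(best, 1L + follow(j))
      }
    }
    memo[i] <<- best
    best
  }
  if (n == 0) return(0L)
  max(vapply(seq_len(n), follow, integer(1)))
}

# both orientations (second axis may run backwards)
longest_chain_oracle_2dir <- function(ra, rb, max_gap) {
  max(longest_chain_oracle(ra, rb, max_gap),
      longest_chain_oracle(ra, max(rb) + 1 - rb, max_gap))
}

# Gotoh affine-gap local alignment score; gap of length k costs open + k*ext
gotoh_local_score <- function(a, b, match = 1, mismatch = -1,
                              open = 5, ext = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    s <- if (a[i - 1] == b[j - 1]) match else mismatch
    M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                          Y[i - 1, j - 1]) + s)
    best <- max(best, M[i, j], X[i, j], Y[i, j])
  }
  best
}

# partition by reachability over an undirected edge list (no graph library)
transitive_closure_oracle <- function(nodes, edges_a, edges_b) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (k in seq_along(edges_a)) {
      ca <- comp[[edges_a[k]]]; cb <- comp[[edges_b[k]]]
      if (ca != cb) {
        comp[comp == max(ca, cb)] <- min(ca, cb)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# exhaustive hypergeometric upper-tail for a 2x2 over-representation test
hypergeom_tail_oracle <- function(a, set_size, annotated, universe) {
  ks <- a:min(set_size, annotated)
  sum(vapply(ks, function(k) {
    choose(annotated, k) * choose(universe - annotated, set_size - k) /
      choose(universe, set_size)
  }, numeric(1)))
}
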