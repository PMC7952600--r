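# Independent brute-force oracles, deliberately naive and separate from the
# package implementations.

hamming_str <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Naive simulation of the UMI adjacency rule: exhaustive pairwise Hamming
# scan, explicit edge matrix, step-by-step coverage bookkeeping.
naive_adjacency <- function(umis) {
  if (length(umis) == 0) return(0L)
  seqs <- names(umis)
  counts <- as.integer(umis)
  n <- length(seqs)
  edge <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && hamming_str(seqs[i], seqs[j]) == 1 &&
          counts[i] >= 2 * counts[j] - 1) {
        edge[i, j] <- TRUE
      }
    }
  }
  ord <- order(-counts, seqs)
  covered <- rep(FALSE, n)
  selected <- 0L
  for (i in ord) {
    if (covered[i]) next
    selected <- selected + 1L
    covered[i] <- TRUE
    covered[edge[i, ]] <- TRUE
  }
  selected
}

# random UMI set with frequent Hamming-1 adjacencies: mutations around a base
random_umi_set <- function(max_distinct = 12, len = 10) {
  bases <- c("A", "C", "G", "T")
  base <- paste(sample(bases, len, replace = TRUE), collapse = "")
  k <- sample.int(max_distinct, 1)
  seqs <- base
  while (length(seqs) < k) {
    s <- sample(seqs, 1)
    nmut <- sample(1:2, 1)
    for (m in seq_len(nmut)) {
      p <- sample.int(len, 1)
      substr(s, p, p) <- sample(bases, 1)
    }
    seqs <- unique(c(seqs, s))
  }
  counts <- sample.int(12, length(seqs), replace = TRUE)
  names(counts) <- seqs
  counts
}

# ARI by exhaustive pair enumeration (closed form over pair agreement counts)
naive_ari <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else if (!sa && sb) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  2 * (n11 * n00 - n10 * n01) /
    ((n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00))
}

# plug-in uncertainty coefficient computed with explicit loops
naive_uncertainty <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  hx <- 0
  for (px in rowSums(tab) / n) if (px > 0) hx <- hx - px * log(px)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      p <- tab[i, j] / n
      if (p > 0) {
        mi <- mi + p * log(p / ((sum(tab[i, ]) / n) * (sum(tab[, j]) / n)))
      }
    }
  }
  mi / hx
}

# expand a contingency table of counts into two label vectors
labels_from_table <- function(tab) {
  x <- integer(0); y <- integer(0)
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      x <- c(x, rep(i, tab[i, j]))
      y <- c(y, rep(j, tab[i, j]))
    }
  }
  list(x = x, y = y)
}
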