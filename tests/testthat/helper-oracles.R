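# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (per-position loops, recursive enumeration,
# pair counting) and never share code with the implementation they check.

# DRACH membership by explicit set lookup, one position at a time
drach_oracle <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  hits <- integer()
  if (n >= 5) {
    for (p in 3:(n - 2)) {          # 1-based central position
      ok <- chars[p - 2] %in% c("A", "G", "T") &&
        chars[p - 1] %in% c("A", "G") &&
        chars[p] == "A" &&
        chars[p + 1] == "C" &&
        chars[p + 2] %in% c("A", "C", "T")
      if (ok) hits <- c(hits, p - 1L)   # 0-based
    }
  }
  hits
}

# Exhaustive minimum over all pseudoknot-free structures (min hairpin loop
# 3) by plain recursion: position i is unpaired, or pairs with some k.
fold_oracle <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pair_e <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "")
    switch(key, CG = -3, AT = -2, GT = -1, 1)
  }
  rec <- function(i, j) {
    if (j - i < 4L) return(0)
    best <- rec(i + 1L, j)
    for (k in (i + 4L):j) {
      w <- pair_e(chars[i], chars[k])
      if (w > 0) next
      best <- min(best, w + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    best
  }
  rec(1L, length(chars))
}

# AUROC by counting concordant positive/negative pairs (ties = 1/2)
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# k-mer frequencies by a nested character loop, skipping k-mers with N
kmer_oracle <- function(window, k) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  kmers <- apply(expand.grid(rep(list(bases), k))[, k:1, drop = FALSE],
                 1, paste, collapse = "")
  counts <- stats::setNames(numeric(length(kmers)), sort(kmers))
  n_counted <- 0
  for (i in seq_len(length(chars) - k + 1)) {
    km <- paste(chars[i:(i + k - 1)], collapse = "")
    if (grepl("N", km, fixed = TRUE)) next
    counts[km] <- counts[km] + 1
    n_counted <- n_counted + 1
  }
  if (n_counted > 0) counts / n_counted else counts
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_seq_fixed <- function(n, seed = 1) {
  set.seed(seed)
  random_seq(n)
}
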