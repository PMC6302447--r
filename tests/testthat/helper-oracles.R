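# Independent brute-force oracles: deliberately naive re-derivations of each
# encoder/metric, kept free of any package internals beyond trivial helpers.

random_dna <- function(L, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

oracle_all_kmers <- function(k) {
  g <- expand.grid(rep(list(c("A", "C", "G", "T")), k), stringsAsFactors = FALSE)
  sort(do.call(paste0, g))
}

oracle_windows <- function(seq, k) {
  L <- nchar(seq)
  substring(seq, 1:(L - k + 1), k:L)
}

oracle_spectrum <- function(seq, k) {
  win <- oracle_windows(seq, k)
  km <- oracle_all_kmers(k)
  sapply(km, function(t) sum(win == t)) / length(win)
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

oracle_mismatch <- function(seq, k, m) {
  win <- oracle_windows(seq, k)
  km <- oracle_all_kmers(k)
  sapply(km, function(t) sum(vapply(win, oracle_hamming, numeric(1), b = t) <= m)) /
    length(win)
}

oracle_revckmer <- function(seq, k) {
  win <- oracle_windows(seq, k)
  canon <- function(x) {
    rc <- oracle_revcomp(x)
    if (x <= rc) x else rc
  }
  km <- oracle_all_kmers(k)
  classes <- sort(unique(vapply(km, canon, character(1))))
  wc <- vapply(win, canon, character(1))
  sapply(classes, function(cl) sum(wc == cl)) / length(win)
}

# direct double/triple-loop pseudo nucleotide composition
oracle_psenc <- function(seq, variant, lambda, w, props) {
  ord <- if (endsWith(variant, "DNC")) 2 else 3
  L <- nchar(seq)
  M <- L - ord + 1
  oligos <- substring(seq, 1:M, ord:L)
  types <- oracle_all_kmers(ord)
  f <- sapply(types, function(t) sum(oligos == t)) / M
  P <- props$values
  Np <- ncol(P)
  if (startsWith(variant, "PC")) {
    corr <- numeric(lambda)
    for (j in 1:lambda) {
      acc <- 0
      for (i in 1:(M - j)) {
        th <- 0
        for (u in 1:Np) th <- th + (P[oligos[i], u] - P[oligos[i + j], u])^2
        acc <- acc + th / Np
      }
      corr[j] <- acc / (M - j)
    }
  } else {
    corr <- numeric(0)
    for (j in 1:lambda) {
      for (u in 1:Np) {
        acc <- 0
        for (i in 1:(M - j)) acc <- acc + P[oligos[i], u] * P[oligos[i + j], u]
        corr <- c(corr, acc / (M - j))
      }
    }
  }
  unname(c(f, w * corr) / (1 + w * sum(corr)))
}

oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# linearly separable toy dataset: A-rich positives vs C-rich negatives
make_separable_dataset <- function(n_per_class = 20, L = 60, seed = 1) {
  set.seed(seed)
  gen <- function(p_main, main, other) {
    vapply(seq_len(n_per_class), function(i) {
      paste(sample(c(main, other), L, replace = TRUE, prob = c(p_main, 1 - p_main)),
            collapse = "")
    }, character(1))
  }
  pos <- gen(0.9, "A", "G")
  neg <- gen(0.9, "C", "G")
  names(pos) <- paste0("p", seq_len(n_per_class))
  names(neg) <- paste0("n", seq_len(n_per_class))
  labeled_dataset(c(pos, neg), rep(c(1L, 0L), each = n_per_class))
}
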