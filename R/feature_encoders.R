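#' All k-mers over A/C/G/T in lexicographic order
#'
#' @param k word length (>= 1).
#' @return character vector of length `4^k`, ordered A < C < G < T.
#' @export
kmer_strings <- function(k) {
  stopifnot(k >= 1)
  .cache_get(paste0("kmers_", k), function() mkAllStrings(DNA_BASES, k))
}

# k-mer count matrix (n sequences x 4^k), lexicographic columns
kmer_count_matrix <- function(seqs, k) {
  L <- nchar(seqs)
  if (any(L < k)) {
    stop(sprintf("sequence '%s' (length %d) shorter than k = %d",
                 names(seqs)[which(L < k)[1L]], min(L), k))
  }
  m <- oligonucleotideFrequency(DNAStringSet(seqs), width = k)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(m)))
  rownames(m) <- names(seqs)
  m
}

spectrum_matrix <- function(seqs, k, normalize = TRUE) {
  seqs <- validate_dna(seqs)
  cnt <- kmer_count_matrix(seqs, k)
  if (normalize) cnt <- cnt / (nchar(seqs) - k + 1)
  cnt
}

#' k-spectrum profile
#'
#' Frequencies of all `4^k` contiguous k-length subsequences: entry for
#' k-mer `t` is its count among the `L - k + 1` windows divided by the
#' window count, so entries sum to 1. Columns are lexicographic (A<C<G<T).
#'
#' @param seq a single DNA sequence (character).
#' @param k word length; requires `nchar(seq) >= k`.
#' @param normalize divide counts by the window count (default TRUE).
#' @return named numeric vector of length `4^k`.
#' @export
spectrum_profile <- function(seq, k, normalize = TRUE) {
  drop_row(spectrum_matrix(seq, k, normalize))
}

# sum counts over all 4 bases at 0-based position p (1 = leftmost);
# returns matrix of same shape, column t holding sum over values at p
position_marginal <- function(cnt, k, p) {
  v <- 4L^(k - p)
  idx <- 0:(ncol(cnt) - 1L)
  d <- (idx %/% v) %% 4L
  base <- idx - d * v
  out <- cnt[, base + 1L, drop = FALSE]
  for (b in 1:3) out <- out + cnt[, base + b * v + 1L, drop = FALSE]
  colnames(out) <- colnames(cnt)
  out
}

# Hamming-ball counts: ball[t] = sum of counts over all k-mers within
# Hamming distance m of t. Computed by Moebius-style inclusion-exclusion
# over position subsets: ball = sum over subsets T (|T| <= m) of
# alpha_{|T|} * M_T, where M_T marginalizes the count tensor over the
# positions in T and alpha_t = sum_{j=0}^{m-t} (-1)^j C(k-t, j).
hamming_ball_matrix <- function(cnt, k, m) {
  alpha <- vapply(0:m, function(t) {
    j <- 0:(m - t)
    sum((-1)^j * choose(k - t, j))
  }, numeric(1))
  ball <- alpha[1L] * cnt
  if (m >= 1L) {
    for (size in 1:m) {
      for (subset in as.data.frame(combn(k, size))) {
        M <- cnt
        for (p in subset) M <- position_marginal(M, k, p)
        ball <- ball + alpha[size + 1L] * M
      }
    }
  }
  ball
}

mismatch_matrix <- function(seqs, k, m, normalize = TRUE) {
  if (m < 0 || m >= k) stop(sprintf("mismatch profile needs 0 <= m < k (got k=%d, m=%d)", k, m))
  seqs <- validate_dna(seqs)
  cnt <- hamming_ball_matrix(kmer_count_matrix(seqs, k), k, m)
  if (normalize) cnt <- cnt / (nchar(seqs) - k + 1)
  cnt
}

#' (k,m)-mismatch profile
#'
#' Like the spectrum profile, but each window also credits every k-mer
#' within Hamming distance `m` of it (the exact match is the j = 0 term of
#' the mismatch sum). Entry for k-mer `t` = number of windows within
#' distance `m` of `t`, divided by the window count. `m = 0` reduces exactly
#' to [spectrum_profile()].
#'
#' @inheritParams spectrum_profile
#' @param m maximum mismatches, `0 <= m < k`.
#' @return named numeric vector of length `4^k`.
#' @export
mismatch_profile <- function(seq, k, m, normalize = TRUE) {
  drop_row(mismatch_matrix(seq, k, m, normalize))
}

# canonical class structure for reverse-complement k-mer collapsing
revckmer_classes <- function(k) {
  .cache_get(paste0("revc_", k), function() {
    km <- kmer_strings(k)
    rc <- revcomp(km)
    canon <- ifelse(km <= rc, km, rc)  # lexicographic minimum of the pair
    list(canon = canon, classes = sort(unique(canon)))
  })
}

revckmer_matrix <- function(seqs, k, normalize = TRUE) {
  seqs <- validate_dna(seqs)
  cnt <- kmer_count_matrix(seqs, k)
  cl <- revckmer_classes(k)
  collapsed <- t(rowsum(t(cnt), group = cl$canon))
  collapsed <- collapsed[, cl$classes, drop = FALSE]
  rownames(collapsed) <- names(seqs)
  if (normalize) collapsed <- collapsed / (nchar(seqs) - k + 1)
  collapsed
}

#' Reverse-complement k-mer profile (RevcKmer)
#'
#' Each window's k-mer is collapsed with its reverse complement into one
#' canonical class (the lexicographic minimum of the pair); frequencies are
#' reported per class. Dimension is `4^k / 2` for odd k and
#' `(4^k + 4^(k/2)) / 2` for even k (self-complementary k-mers form
#' singleton classes). The profile is invariant under reverse
#' complementation of the input sequence.
#'
#' @inheritParams spectrum_profile
#' @return named numeric vector over canonical k-mer classes.
#' @export
revc_kmer_profile <- function(seq, k, normalize = TRUE) {
  drop_row(revckmer_matrix(seq, k, normalize))
}

drop_row <- function(m) {
  if (nrow(m) != 1L) stop("expected a single sequence")
  setNames(as.numeric(m[1L, ]), colnames(m))
}

#' Pseudo nucleotide composition
#'
#' Extends di-/tri-nucleotide composition with `lambda` correlation factors
#' built from standardized physicochemical property values, capturing
#' sequence-order information up to lag `lambda`.
#'
#' Let `O_1..O_M` be the overlapping di- (`M = L-1`) or tri- (`M = L-2`)
#' nucleotides, `f_v` their frequencies over the 16/64 types, and `P_u(.)`
#' the standardized value of property `u`.
#'
#' * Parallel correlation (`PCPseDNC`, `PCPseTNC`): one factor per lag,
#'   `theta_j = mean_i mean_u (P_u(O_i) - P_u(O_{i+j}))^2`; the vector is
#'   `(f_v, w*theta_j) / (1 + w * sum(theta))`, dimension `base + lambda`,
#'   and the components sum to 1.
#' * Series correlation (`SCPseDNC`, `SCPseTNC`): one factor per (lag,
#'   property) pair, `tau_{j,u} = mean_i P_u(O_i) * P_u(O_{i+j})`, ordered
#'   lag-outer/property-inner, same denominator; dimension
#'   `base + N_p * lambda`.
#'
#' @param seq a single DNA sequence.
#' @param variant one of `"PCPseDNC"`, `"PCPseTNC"`, `"SCPseDNC"`, `"SCPseTNC"`.
#' @param lambda highest counted correlation lag; must satisfy
#'   `lambda <= L - 2` (di) or `lambda <= L - 3` (tri).
#' @param w pseudo-composition weight factor (> 0) balancing frequencies vs
#'   correlation factors; default 0.05.
#' @param props a [property_table()] matching the variant's alphabet;
#'   defaults to the shipped synthetic table.
#' @return named numeric vector.
#' @export
pse_nc <- function(seq, variant = c("PCPseDNC", "PCPseTNC", "SCPseDNC", "SCPseTNC"),
                   lambda, w = 0.05, props = NULL) {
  variant <- match.arg(variant)
  drop_row(psenc_matrix(seq, variant, lambda, w, props))
}

psenc_matrix <- function(seqs, variant, lambda, w = 0.05, props = NULL) {
  seqs <- validate_dna(seqs)
  parallel <- startsWith(variant, "PC")
  ord <- if (endsWith(variant, "DNC")) 2L else 3L
  alphabet <- if (ord == 2L) "di" else "tri"
  if (is.null(props)) props <- default_property_table(alphabet)
  stopifnot(inherits(props, "property_table"))
  if (props$alphabet != alphabet) {
    stop(sprintf("%s needs a %s-nucleotide property table (got %s)",
                 variant, alphabet, props$alphabet))
  }
  if (!props$standardized) props <- standardize_property_table(props)
  lambda <- as.integer(lambda)
  if (is.na(lambda) || lambda < 1L) stop("lambda must be an integer >= 1")
  if (w <= 0) stop("w must be > 0")
  Lmin <- min(nchar(seqs))
  if (lambda > Lmin - ord) {
    stop(sprintf("lambda = %d out of range for sequence length L = %d (%s allows lambda <= L - %d)",
                 lambda, Lmin, variant, ord))
  }
  P <- props$values
  Np <- ncol(P)
  oligo_levels <- kmer_strings(ord)
  corr_names <- if (parallel) {
    paste0("theta", seq_len(lambda))
  } else {
    as.vector(t(outer(seq_len(lambda), colnames(P),
                      function(j, u) paste0("tau", j, ".", u))))
  }
  out <- matrix(0, length(seqs), length(oligo_levels) + length(corr_names),
                dimnames = list(names(seqs), c(oligo_levels, corr_names)))
  for (s in seq_along(seqs)) {
    L <- nchar(seqs[s])
    M <- L - ord + 1L
    oligos <- substring(seqs[s], 1:M, ord:L)
    f <- tabulate(factor(oligos, levels = oligo_levels),
                  nbins = length(oligo_levels)) / M
    Pm <- P[oligos, , drop = FALSE]
    if (parallel) {
      corr <- vapply(seq_len(lambda), function(j) {
        d <- Pm[seq_len(M - j), , drop = FALSE] - Pm[(1L + j):M, , drop = FALSE]
        mean(rowMeans(d^2))
      }, numeric(1))
    } else {
      corr <- as.vector(vapply(seq_len(lambda), function(j) {
        colMeans(Pm[seq_len(M - j), , drop = FALSE] * Pm[(1L + j):M, , drop = FALSE])
      }, numeric(Np)))
    }
    out[s, ] <- c(f, w * corr) / (1 + w * sum(corr))
  }
  out
}
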