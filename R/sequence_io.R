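#' Validate DNA sequences
#'
#' Uppercases residues, maps RNA `U` to `T`, and rejects anything outside the
#' strict 4-letter alphabet `A/C/G/T`. Ambiguity codes such as `N` are
#' rejected rather than skipped: every encoder's dimension arithmetic assumes
#' exactly four symbols.
#'
#' @param seqs character vector of sequences; names are used as identifiers
#'   (unnamed input gets `seq1`, `seq2`, ...).
#' @return named character vector of validated sequences.
#' @export
validate_dna <- function(seqs) {
  if (!is.character(seqs)) stop("sequences must be a character vector")
  if (length(seqs) == 0L) return(setNames(character(0), character(0)))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    nm <- names(seqs)
    if (is.null(nm)) nm <- rep("", length(seqs))
    nm[!nzchar(nm)] <- paste0("seq", which(!nzchar(nm)))
    names(seqs) <- nm
  }
  out <- chartr("U", "T", toupper(seqs))
  bad <- grepl("[^ACGT]", out)
  if (any(bad)) {
    i <- which(bad)[1L]
    sym <- regmatches(out[i], regexpr("[^ACGT]", out[i]))
    stop(sprintf("record '%s': invalid residue '%s' (alphabet is A/C/G/T; U is mapped to T)",
                 names(out)[i], sym))
  }
  if (any(!nzchar(out))) {
    stop(sprintf("record '%s': empty sequence", names(out)[which(!nzchar(out))[1L]]))
  }
  out
}

#' Read a FASTA file of DNA sequences
#'
#' Records are validated with [validate_dna()]: case is normalized, `U`
#' becomes `T`, and ambiguity codes raise an error naming the record.
#' Identifiers are the first whitespace-delimited token of each header.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(readBStringSet(path),
                  error = function(e) stop(sprintf("malformed FASTA '%s': %s",
                                                   path, conditionMessage(e))))
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  validate_dna(seqs)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector over A/C/G/T.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- validate_dna(seqs)
  writeXStringSet(DNAStringSet(seqs), filepath = path)
  invisible(path)
}

#' Read a genomic interval table
#'
#' Tab-separated file with header columns `id`, `start`, `end`, `strand`.
#' Coordinates are 1-based and inclusive on both ends (NCBI convention);
#' strand is `+` or `-`.
#'
#' @param path TSV file path.
#' @return data.frame with columns id, start, end, strand.
#' @export
read_intervals <- function(path) {
  iv <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "start", "end", "strand")
  if (!all(need %in% names(iv))) {
    stop(sprintf("interval table must have columns %s", paste(need, collapse = ", ")))
  }
  iv$start <- as.integer(iv$start)
  iv$end <- as.integer(iv$end)
  validate_intervals(iv)
  iv[need]
}

validate_intervals <- function(iv) {
  if (any(iv$start < 1L) || any(iv$end < iv$start)) {
    bad <- which(iv$start < 1L | iv$end < iv$start)[1L]
    stop(sprintf("invalid interval %s: start=%d end=%d (need 1 <= start <= end)",
                 iv$id[bad], iv$start[bad], iv$end[bad]))
  }
  if (!all(iv$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  invisible(iv)
}

#' Extract interval sequences from a genome
#'
#' Coordinates are 1-based inclusive; a fragment has length `end - start + 1`.
#' Minus-strand intervals return the reverse complement of the extracted
#' fragment.
#'
#' @param genome single genome sequence (length-1 character vector).
#' @param intervals data.frame with columns id, start, end, strand
#'   (see [read_intervals()]).
#' @return named character vector of fragments, one per interval row.
#' @export
extract_intervals <- function(genome, intervals) {
  genome <- validate_dna(genome)
  if (length(genome) != 1L) stop("genome must be a single sequence")
  if (is.null(intervals$id)) intervals$id <- paste0("iv", seq_len(nrow(intervals)))
  validate_intervals(intervals)
  L <- nchar(genome)
  oob <- intervals$end > L
  if (any(oob)) {
    b <- which(oob)[1L]
    stop(sprintf("interval %s (%d-%d,%s) out of genome bounds (length %d)",
                 intervals$id[b], intervals$start[b], intervals$end[b],
                 intervals$strand[b], L))
  }
  frags <- substring(genome, intervals$start, intervals$end)
  minus <- intervals$strand == "-"
  if (any(minus)) frags[minus] <- revcomp(frags[minus])
  setNames(frags, intervals$id)
}

#' Uniformly shuffle the residues of sequences
#'
#' Fisher-Yates permutation of each sequence's residues; mono-nucleotide
#' composition is preserved exactly. This is the operation that turns genuine
#' genomic sequence into "pseudo" background with the same base content.
#'
#' @param seqs named character vector (one or more sequences).
#' @param seed integer seed; required, so every shuffle is reproducible.
#' @return named character vector of shuffled sequences.
#' @export
shuffle_residues <- function(seqs, seed) {
  if (missing(seed)) stop("shuffle_residues() requires an explicit seed")
  seqs <- validate_dna(seqs)
  set.seed(as.integer(seed))
  vapply(strsplit(seqs, "", fixed = TRUE),
         function(ch) paste(sample(ch), collapse = ""),
         character(1))
}

#' Remove exact duplicate sequences
#'
#' Keeps the first occurrence of each residue string, preserving order.
#' (Similarity-based redundancy removal can be plugged in via `key`.)
#'
#' @param seqs named character vector.
#' @param key optional function mapping a sequence to a deduplication key;
#'   defaults to identity (exact-string deduplication).
#' @return the deduplicated vector.
#' @export
deduplicate <- function(seqs, key = identity) {
  if (length(seqs) == 0L) return(seqs)
  seqs[!duplicated(vapply(unname(seqs), key, character(1)))]
}

#' Construct a labeled sRNA dataset
#'
#' @param sequences named character vector over A/C/G/T.
#' @param labels binary vector (1 = sRNA, 0 = pseudo-sRNA), one per sequence.
#' @param ratio optional descriptor of the positive:negative ratio.
#' @return an object of class `labeled_dataset` with elements `sequences`,
#'   `labels`, `ratio`.
#' @export
labeled_dataset <- function(sequences, labels, ratio = NULL) {
  sequences <- validate_dna(sequences)
  labels <- as.integer(labels)
  if (length(sequences) != length(labels)) {
    stop("sequences and labels must have equal length")
  }
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  structure(list(sequences = sequences, labels = labels, ratio = ratio),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d sequences (%d positive, %d negative)\n",
              length(x$sequences), sum(x$labels == 1L), sum(x$labels == 0L)))
  if (!is.null(x$ratio)) cat(sprintf("  ratio: %s\n", x$ratio))
  invisible(x)
}

#' Build a benchmark dataset with shuffle-derived negatives
#'
#' Positives are the interval sequences extracted from the genome, after
#' exact-duplicate removal. Negatives come from `ratio` independent
#' whole-genome shuffles, each re-extracted at the coordinates of the kept
#' positives — so negatives match positives in length and genomic base
#' context but carry no real signal, and `|negatives| = ratio * |positives|`.
#'
#' @param genome single genome sequence.
#' @param intervals interval data.frame (see [read_intervals()]).
#' @param ratio integer >= 1, negatives per positive.
#' @param seed integer seed controlling the genome shuffles.
#' @return a [labeled_dataset()] (positives first).
#' @export
build_benchmark <- function(genome, intervals, ratio = 1L, seed = 1L) {
  ratio <- as.integer(ratio)
  if (is.na(ratio) || ratio < 1L) stop("ratio must be an integer >= 1")
  genome <- validate_dna(genome)
  pos_all <- extract_intervals(genome, intervals)
  keep <- !duplicated(unname(pos_all))
  pos <- pos_all[keep]
  iv_kept <- intervals[keep, , drop = FALSE]
  set.seed(as.integer(seed))
  chars <- strsplit(unname(genome), "", fixed = TRUE)[[1L]]
  neg <- character(0)
  for (r in seq_len(ratio)) {
    shuffled <- paste(sample(chars), collapse = "")
    frag <- extract_intervals(setNames(shuffled, "shuffled"), iv_kept)
    names(frag) <- sprintf("pseudo_r%d_%s", r, names(frag))
    neg <- c(neg, frag)
  }
  labeled_dataset(c(pos, neg),
                  c(rep(1L, length(pos)), rep(0L, length(neg))),
                  ratio = sprintf("1:%d", ratio))
}

#' Write a labeled dataset to a directory
#'
#' Serializes as `pos.fa` + `neg.fa` plus a JSON manifest recording counts,
#' the ratio descriptor and any extra provenance fields.
#'
#' @param data a [labeled_dataset()].
#' @param dir output directory (created if needed).
#' @param ... extra fields stored in the manifest.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir, ...) {
  stopifnot(inherits(data, "labeled_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(data$sequences[data$labels == 1L], file.path(dir, "pos.fa"))
  write_fasta(data$sequences[data$labels == 0L], file.path(dir, "neg.fa"))
  manifest <- c(list(n_pos = sum(data$labels == 1L),
                     n_neg = sum(data$labels == 0L),
                     ratio = data$ratio), list(...))
  write_json(manifest, file.path(dir, "manifest.json"),
             auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `pos.fa` and `neg.fa`.
#' @return a [labeled_dataset()].
#' @export
read_dataset <- function(dir) {
  pos <- read_fasta(file.path(dir, "pos.fa"))
  neg <- read_fasta(file.path(dir, "neg.fa"))
  ratio <- NULL
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) ratio <- read_json(mf)$ratio
  labeled_dataset(c(pos, neg), c(rep(1L, length(pos)), rep(0L, length(neg))),
                  ratio = ratio)
}
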