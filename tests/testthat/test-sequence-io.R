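test_that("FASTA reading normalizes case, maps U to T, and rejects ambiguity codes", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1 some description", "acgt", ">s2", "ACGU"), f)
  seqs <- read_fasta(f)
  expect_identical(seqs, c(s1 = "ACGT", s2 = "ACGT"))

  writeLines(c(">bad", "ACGN"), f)
  expect_error(read_fasta(f), "bad.*'N'")
})

test_that("write_fasta / read_fasta round-trips identifiers and residues", {
  seqs <- setNames(vapply(1:5, function(i) random_dna(40 + i, seed = i), character(1)),
                   paste0("sq", 1:5))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)
})

test_that("interval extraction is 1-based inclusive with minus-strand reverse complement", {
  g <- c(genome = "ACGTACGT")
  iv <- data.frame(id = "a", start = 1, end = 4, strand = "+")
  expect_equal(unname(extract_intervals(g, iv)), "ACGT")
  expect_equal(unname(nchar(extract_intervals(g, iv))), iv$end - iv$start + 1)

  iv$strand <- "-"
  expect_equal(unname(extract_intervals(g, iv)), "ACGT")  # palindrome

  g2 <- c(genome = "AACCGGTT")
  iv2 <- data.frame(id = c("x", "y"), start = c(3, 1), end = c(6, 4),
                    strand = c("-", "-"))
  out <- extract_intervals(g2, iv2)
  expect_equal(unname(out["x"]), "CCGG")           # palindromic fragment
  expect_equal(unname(out["y"]), oracle_revcomp("AACC"))  # = "GGTT"

  bad <- data.frame(id = "z", start = 5, end = 99, strand = "+")
  expect_error(extract_intervals(g2, bad), "z.*out of genome bounds")
  expect_error(extract_intervals(g2, data.frame(id = "w", start = 4, end = 2,
                                                strand = "+")),
               "invalid interval")
})

test_that("shuffling preserves base counts exactly and is seed-deterministic", {
  expect_equal(unname(shuffle_residues(c(h = "AAAA"), seed = 3)), "AAAA")
  s <- c(q = random_dna(200, seed = 11))
  a <- shuffle_residues(s, seed = 7)
  b <- shuffle_residues(s, seed = 7)
  expect_identical(a, b)
  count_bases <- function(x) table(factor(strsplit(x, "")[[1]], c("A", "C", "G", "T")))
  expect_equal(count_bases(unname(a)), count_bases(unname(s)))
  expect_error(shuffle_residues(s), "seed")
})

test_that("deduplicate keeps the first occurrence in stable order", {
  expect_equal(unname(deduplicate(c(a = "ACGT", b = "ACGT", c = "AAAA"))),
               c("ACGT", "AAAA"))
  u <- c(a = "ACGT", b = "AAAA")
  expect_identical(deduplicate(u), u)
  expect_length(deduplicate(character(0)), 0)
})

test_that("build_benchmark sizes negatives as ratio x deduplicated positives", {
  g <- gen_random_genome(3000, seed = 21)
  iv <- data.frame(id = paste0("s", 1:8),
                   start = seq(1, 2200, length.out = 8),
                   end = seq(1, 2200, length.out = 8) + 59,
                   strand = rep(c("+", "-"), 4))
  iv$start <- as.integer(iv$start); iv$end <- as.integer(iv$end)
  # duplicate a coordinate row: the duplicated positive must be dropped
  iv <- rbind(iv, transform(iv[1, ], id = "dup"))
  for (r in c(1L, 3L, 5L)) {
    d <- build_benchmark(g, iv, ratio = r, seed = 5)
    expect_equal(sum(d$labels == 1L), 8)
    expect_equal(sum(d$labels == 0L), r * 8)
  }
  expect_error(build_benchmark(g, iv, ratio = 0), "ratio")
})

test_that("dataset directory serialization round-trips", {
  d <- make_separable_dataset(n_per_class = 6, L = 50, seed = 2)
  dir <- withr::local_tempdir()
  write_dataset(d, dir, seed = 42)
  d2 <- read_dataset(dir)
  expect_setequal(names(d2$sequences), names(d$sequences))
  expect_equal(sort(d2$sequences[d2$labels == 1L]),
               sort(d$sequences[d$labels == 1L]))
})

test_that("labeled_dataset validates lengths and labels", {
  expect_error(labeled_dataset(c(a = "ACGT"), c(1, 0)), "equal length")
  expect_error(labeled_dataset(c(a = "ACGT"), 2), "0/1")
})
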