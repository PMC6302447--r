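test_that("spectrum profile matches hand cases and sums to one", {
  expect_equal(spectrum_profile("AAAA", 2),
               setNames(c(1, rep(0, 15)), kmer_strings(2)))
  expect_equal(unname(spectrum_profile("ACGT", 1)), rep(0.25, 4))
  for (k in 1:5) {
    s <- random_dna(80, seed = k)
    expect_equal(sum(spectrum_profile(s, k)), 1, tolerance = 1e-12)
  }
  expect_error(spectrum_profile("ACG", 4), "shorter than k")
})

test_that("every encoder agrees with the naive enumeration oracle on short sequences", {
  di <- default_property_table("di")
  tri <- default_property_table("tri")
  for (seed in 1:4) {
    s <- random_dna(sample(20:30, 1), seed = seed)
    for (k in 1:5) {
      expect_equal(unname(spectrum_profile(s, k)), unname(oracle_spectrum(s, k)),
                   tolerance = 1e-12)
      expect_equal(unname(revc_kmer_profile(s, k)), unname(oracle_revckmer(s, k)),
                   tolerance = 1e-12)
    }
    for (k in 3:5) {
      for (m in c(1L, 2L)) {
        expect_equal(unname(mismatch_profile(s, k, m)),
                     unname(oracle_mismatch(s, k, m)), tolerance = 1e-12)
      }
    }
    for (variant in c("PCPseDNC", "SCPseDNC")) {
      expect_equal(unname(pse_nc(s, variant, lambda = 3, props = di)),
                   oracle_psenc(s, variant, 3, 0.05, di), tolerance = 1e-12)
    }
    for (variant in c("PCPseTNC", "SCPseTNC")) {
      expect_equal(unname(pse_nc(s, variant, lambda = 2, props = tri)),
                   oracle_psenc(s, variant, 2, 0.05, tri), tolerance = 1e-12)
    }
  }
})

test_that("pseudo-composition matches the direct-summation oracle on a toy two-property table", {
  km <- kmer_strings(2)
  set.seed(99)
  toy <- property_table(matrix(rnorm(32), 16, 2, dimnames = list(km, c("a", "b"))))
  s <- "ACGTACGT"
  expect_equal(unname(pse_nc(s, "PCPseDNC", lambda = 2, w = 0.05, props = toy)),
               oracle_psenc(s, "PCPseDNC", 2, 0.05, toy), tolerance = 1e-12)
  expect_equal(unname(pse_nc(s, "SCPseDNC", lambda = 2, w = 0.05, props = toy)),
               oracle_psenc(s, "SCPseDNC", 2, 0.05, toy), tolerance = 1e-12)
})

test_that("dimension identities hold across k and lambda", {
  s <- random_dna(120, seed = 8)
  for (k in 1:5) {
    expect_length(spectrum_profile(s, k), 4^k)
    if (k >= 2) expect_length(mismatch_profile(s, k, 1), 4^k)
    d_expect <- if (k %% 2 == 1) 4^k / 2 else (4^k + 4^(k / 2)) / 2
    expect_length(revc_kmer_profile(s, k), d_expect)
  }
  for (lam in c(1, 9, 15)) {
    expect_length(pse_nc(s, "PCPseDNC", lam), 16 + lam)
    expect_length(pse_nc(s, "PCPseTNC", lam), 64 + lam)
    expect_length(pse_nc(s, "SCPseDNC", lam), 16 + 6 * lam)
    expect_length(pse_nc(s, "SCPseTNC", lam), 64 + 12 * lam)
  }
  dims <- vapply(all_feature_specs(), function(sp) length(encode(s, sp)), numeric(1))
  expect_equal(unname(dims),
               c(4, 16, 64, 256, 1024, 64, 256, 1024,
                 2, 10, 32, 136, 512, 25, 65, 106, 76))
  expect_equal(unname(dims), vapply(all_feature_specs(), feature_dim, numeric(1),
                                    USE.NAMES = FALSE))
})

test_that("zero-mismatch profile degenerates to the spectrum profile", {
  for (seed in 1:10) {
    s <- random_dna(sample(45:120, 1), seed = seed)
    for (k in 3:5) {
      expect_equal(unname(mismatch_profile(s, k, 0)),
                   unname(spectrum_profile(s, k)), tolerance = 1e-12)
    }
  }
  expect_error(mismatch_profile("ACGTACG", 3, 3), "m < k")
})

test_that("single-window mismatch ball has exactly the Hamming-ball support", {
  v <- mismatch_profile("ACG", 3, 1)
  expect_equal(sum(v > 0), 10)      # ACG plus its 9 Hamming-1 neighbours
  expect_true(all(v[v > 0] == 1))
})

test_that("RevcKmer is invariant under reverse complementation", {
  expect_equal(revc_kmer_profile("AATT", 1), c(A = 1, C = 0))
  expect_equal(revc_kmer_profile("ACGT", 2)[c("AC", "CG")],
               c(AC = 2 / 3, CG = 1 / 3))
  for (seed in 1:20) {
    s <- random_dna(sample(20:80, 1), seed = seed)
    for (k in c(2, 3, 4)) {
      expect_equal(revc_kmer_profile(s, k),
                   revc_kmer_profile(oracle_revcomp(s), k))
    }
  }
})

test_that("frequency vectors and parallel pseudo-composition components sum to one", {
  for (seed in 1:5) {
    s <- random_dna(70, seed = seed)
    for (k in 1:5) {
      expect_equal(sum(spectrum_profile(s, k)), 1, tolerance = 1e-12)
      expect_equal(sum(revc_kmer_profile(s, k)), 1, tolerance = 1e-12)
    }
    expect_equal(sum(pse_nc(s, "PCPseDNC", 9)), 1, tolerance = 1e-9)
    expect_equal(sum(pse_nc(s, "PCPseTNC", 5)), 1, tolerance = 1e-9)
  }
})

test_that("homopolymer pseudo-composition collapses to the single dinucleotide", {
  v <- pse_nc(strrep("A", 50), "PCPseDNC", lambda = 10)
  expect_equal(unname(v["AA"]), 1)
  expect_equal(sum(v), 1)
  expect_true(all(v[names(v) != "AA"] == 0))  # theta_j = 0 at every lag
})

test_that("lambda bounds and property-table mismatches are rejected", {
  s <- random_dna(20, seed = 1)
  expect_error(pse_nc(s, "PCPseDNC", lambda = 19), "lambda = 19.*L = 20")
  expect_error(pse_nc(s, "PCPseTNC", lambda = 18), "lambda = 18")
  expect_error(pse_nc(s, "PCPseDNC", lambda = 2,
                      props = default_property_table("tri")),
               "di-nucleotide property table")
  expect_error(pse_nc(s, "PCPseDNC", lambda = 0), "lambda")
  expect_error(pse_nc(s, "PCPseDNC", lambda = 2, w = 0), "w must be")
})

test_that("all seventeen default specs accept minimum-length (45 nt) sequences", {
  s <- random_dna(45, seed = 77)
  for (sp in all_feature_specs()) {
    expect_length(encode(s, sp), feature_dim(sp))
  }
})

test_that("encode_matrix rows equal per-sequence encodings", {
  seqs <- setNames(vapply(1:6, function(i) random_dna(50 + i, seed = i),
                          character(1)), paste0("s", 1:6))
  for (idx in c("F2", "F6", "F12", "F14", "F17")) {
    m <- encode_matrix(seqs, idx)
    expect_equal(nrow(m), 6)
    for (i in seq_along(seqs)) {
      expect_equal(unname(m[i, ]), unname(encode(seqs[i], idx)),
                   tolerance = 1e-12)
    }
  }
})

test_that("group concatenation has the documented dimensions and a stable order", {
  s <- random_dna(60, seed = 4)
  dims <- c(SP = 1364, MP = 1344, RCK = 692, PNC = 272)
  for (g in names(dims)) {
    v1 <- group_concat(s, g)
    expect_length(v1, dims[[g]])
    expect_identical(names(v1), names(group_concat(s, g)))
  }
  expect_error(group_concat(s, "XX"), "unknown feature group")
  # F-index order: SP starts with F1 entries and ends with F5 entries
  nm <- names(group_concat(s, "SP"))
  expect_true(startsWith(nm[1], "F1."))
  expect_true(startsWith(nm[1364], "F5."))
})
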