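test_that("FASTA parsing returns records in order and validates residues", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">seq1 some description", "ACDEFG", ">seq2", "MKLV", "WY"),
             path)
  seqs <- read_fasta(path)
  expect_equal(seqs$id, c("seq1", "seq2"))
  expect_equal(seqs$sequence, c("ACDEFG", "MKLVWY"))

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "empty")

  noresidues <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", ""), noresidues)
  expect_error(read_fasta(noresidues), "empty sequence")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACD", ">a", "ACD"), dup)
  expect_error(read_fasta(dup), "duplicate")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDX"), bad)
  expect_error(read_fasta(bad), "illegal residue")
  expect_equal(read_fasta(bad, allow_ambiguity = TRUE)$sequence, "ACDX")
})

test_that("local alignment scores match hand-checked values", {
  p <- alignment_params()
  # all-diagonal path: A+C+D+E self-scores 4+9+6+5 under BLOSUM62
  expect_equal(sw_score("ACDE", "ACDE", p), 24)
  expect_equal(sw_score("A", "A", p), 4)
  # no positive-scoring residue pair => empty local alignment
  expect_equal(sw_score("A", "D", p), 0)
})

test_that("local alignment equals the brute-force DP oracle exactly", {
  p <- alignment_params()
  sub <- blosum62()
  withr::with_seed(7, {
    for (i in 1:60) {
      a <- random_aa_seq(sample(1:8, 1))
      b <- random_aa_seq(sample(1:8, 1))
      expect_equal(sw_score(a, b, p), sw_oracle(a, b, sub),
                   info = paste(a, b))
    }
  })
})

test_that("alignment score is symmetric and monotone under extension", {
  p <- alignment_params()
  withr::with_seed(11, {
    for (i in 1:20) {
      a <- random_aa_seq(sample(3:10, 1))
      b <- random_aa_seq(sample(3:10, 1))
      expect_equal(sw_score(a, b, p), sw_score(b, a, p))
      ext <- random_aa_seq(3)
      expect_gte(sw_score(paste0(a, ext), paste0(b, ext), p),
                 sw_score(a, b, p))
    }
  })
})

test_that("normalized similarity is 1 at identity, 0 when nothing aligns", {
  p <- alignment_params()
  expect_equal(normalized_similarity("MKWVTF", "MKWVTF", p), 1.0)
  expect_equal(normalized_similarity("A", "D", p), 0.0)
  withr::with_seed(3, {
    a <- random_aa_seq(12); b <- random_aa_seq(12)
    sub <- blosum62()
    expected <- sw_oracle(a, b, sub) /
      sqrt(sw_oracle(a, a, sub) * sw_oracle(b, b, sub))
    expect_equal(normalized_similarity(a, b, p), expected)
    expect_equal(normalized_similarity(a, b, p),
                 normalized_similarity(b, a, p))
  })
})

test_that("alignment parameter validation catches bad configurations", {
  expect_error(alignment_params(gap_open = 2, gap_extend = 5), "gap_extend")
  expect_error(alignment_params("NOTAMATRIX"), "unknown substitution")
  expect_error(sw_score("AC!E", "ACDE", alignment_params()), "residues")
})

test_that("protein descriptors follow panel order and mark identity", {
  sim <- tiny_sim()
  panel <- sim$panel
  p <- alignment_params()
  desc <- protein_descriptors(panel[3, c("id", "sequence")], panel, p)
  expect_equal(ncol(desc), nrow(panel) + 1)
  vals <- as.numeric(desc[1, -1])
  expect_equal(vals[3], 1.0)
  expect_true(all(vals >= 0 & vals <= 1))

  # permuting the panel permutes the descriptor identically
  perm <- sample(nrow(panel))
  desc_perm <- protein_descriptors(panel[3, c("id", "sequence")],
                                   panel[perm, ], p)
  expect_equal(as.numeric(desc_perm[1, -1]), vals[perm])
  expect_equal(names(desc_perm)[-1], paste0("P_", panel$id[perm]))

  # repeated calls are bit-identical
  expect_identical(desc,
                   protein_descriptors(panel[3, c("id", "sequence")],
                                       panel, p))
})
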