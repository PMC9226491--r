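test_that("generator config validates its inputs", {
  expect_error(synthetic_config(5, 9, seed = 1), ">= 10")
  expect_error(synthetic_config(5, 100), "seed")
  expect_error(synthetic_config(5, 100, aa_weights = c(Z = 1), seed = 1),
               "amino-acid")
  expect_error(synthetic_config(5, 100,
                                codon_weights = list(F = c(AAA = 1)),
                                seed = 1),
               "codon_weights")
})

test_that("all generated data pass validation with zero rejections", {
  sets <- list(
    generate_cds(synthetic_config(6, c(10, 50), seed = 1)),
    generate_bias_gradient(0.7, synthetic_config(4, 60, seed = 2)),
    generate_neutrality_dataset(0.5, 30, 2, c(20, 80),
                                synthetic_config(4, 120, seed = 3))
  )
  for (seqs in sets) {
    recs <- data.frame(id = vapply(seqs, function(s) s$id, character(1)),
                       description = "",
                       residues = vapply(seqs, cds_string, character(1)))
    out <- validate_fasta(recs)
    expect_true(all(out$report$accepted))
  }
})

test_that("identical seeds give byte-identical FASTA output", {
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(generate_cds(synthetic_config(5, c(20, 90), seed = 42)), f1)
  write_fasta(generate_cds(synthetic_config(5, c(20, 90), seed = 42)), f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- tempfile(fileext = ".fasta")
  write_fasta(generate_cds(synthetic_config(5, c(20, 90), seed = 43)), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("uniform codon weights give frequencies within 3 sd of expectation", {
  seqs <- generate_cds(synthetic_config(10, 1000, seed = 77))
  counts <- count_codons(seqs)
  n <- sum(counts)
  # expected frequency of codon j: P(aa) * 1/k = (1/20) / k
  for (aa in names(codon_families())) {
    fam <- codon_families()[[aa]]
    p <- (1 / 20) / length(fam)
    sd3 <- 3 * sqrt(p * (1 - p) * n)
    expect_true(all(abs(counts[fam] - n * p) <= sd3),
                label = paste("family", aa))
  }
})

test_that("bias gradient hits its analytic endpoints", {
  g1 <- generate_bias_gradient(1, synthetic_config(3, 100, seed = 5))
  for (s in g1) {
    aa_tab <- table(strsplit(translate_cds(s), "")[[1]])
    expect_length(aa_tab, 20L)           # every amino acid present
    expect_true(all(aa_tab >= 2L))       # at least twice
    expect_equal(effective_number_of_codons(count_codons(s)), 20)
  }
  g0 <- generate_bias_gradient(0, synthetic_config(1, 2000, seed = 6))
  nc0 <- effective_number_of_codons(count_codons(g0[[1]]))
  expect_gt(nc0, 55)  # near the unbiased ceiling at finite n
  expect_error(generate_bias_gradient(1, synthetic_config(1, 12, seed = 1)),
               "40 codons")
})

test_that("neutrality generator realises its per-gene targets within 3%", {
  seqs <- generate_neutrality_dataset(0.3, 35, 2, c(25, 85),
                                      synthetic_config(30, c(150, 400),
                                                       seed = 8))
  man <- attr(seqs, "manifest")
  expect_equal(nrow(man), 30L)
  expect_true(all(abs(man$target_gc3 - man$realized_gc3) <= 3))
  expect_true(all(abs(man$target_gc12 - man$realized_gc12) <= 3))
  # out-of-band deterministic targets error
  expect_error(
    generate_neutrality_dataset(1, 60, 0, c(30, 90),
                                synthetic_config(2, 100, seed = 1)),
    "achievable")
})

test_that("a generating slope of zero is recovered as near-zero", {
  seqs <- generate_neutrality_dataset(0, 50, 2, c(20, 80),
                                      synthetic_config(200, 300, seed = 303))
  man <- attr(seqs, "manifest")
  fit <- neutrality_fit(man$realized_gc3, man$realized_gc12)
  expect_lt(abs(fit$slope), 0.05)
})

test_that("dinucleotide depletion is synonymous-only and reaches its target", {
  s <- generate_cds(synthetic_config(1, 1000, seed = 9))[[1]]
  before <- dinucleotide_odds(s)[["CG"]]
  out <- deplete_dinucleotide(s, "CG", 0.5, seed = 4)
  expect_identical(translate_cds(out), translate_cds(s))
  expect_identical(length(out$codons), length(s$codons))
  achieved <- dinucleotide_odds(out)[["CG"]]
  expect_lte(achieved, 0.5)
  expect_lt(achieved, before)
  expect_equal(attr(out, "achieved_odds"), achieved, tolerance = 1e-9)
  expect_true(attr(out, "reached"))
  # target above current odds -> unchanged input
  noop <- deplete_dinucleotide(s, "CG", 10, seed = 4)
  expect_identical(noop$codons, s$codons)
  # unreachable target warns and reports best achieved: AA windows inside
  # lysine codons (AAA/AAG) cannot be removed by synonymous swaps
  lys <- codon_seq("lys", rep("AAA", 100))
  expect_warning(out2 <- deplete_dinucleotide(lys, "AA", 1e-6, seed = 4),
                 "not reached")
  expect_false(attr(out2, "reached"))
  expect_identical(translate_cds(out2), translate_cds(lys))
})
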