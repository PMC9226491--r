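test_that("hard-coded genetic code agrees with the Biostrings reference", {
  bs <- Biostrings::GENETIC_CODE
  for (codon in names(bs)) {
    expect_equal(unname(cubtools:::.GENETIC_CODE[codon]), unname(bs[codon]))
  }
  expect_length(sense_codons(), 61L)
  k <- vapply(codon_families(), length, integer(1))
  expect_equal(sum(k == 2), 9L)  # 2-fold families
  expect_equal(sum(k == 3), 1L)  # Ile
  expect_equal(sum(k == 4), 5L)
  expect_equal(sum(k == 6), 3L)  # Leu, Ser, Arg kept intact
  expect_length(rscu_codons(), 59L)
})

test_that("codon counting is exact, additive and matches a brute tally", {
  counts <- count_codons(make_cds("TTTTTCTTT"))
  expect_equal(counts[["TTT"]], 2L)
  expect_equal(counts[["TTC"]], 1L)
  expect_equal(sum(counts), 3L)

  seqs <- generate_cds(synthetic_config(4, 50, seed = 12))
  pooled <- count_codons(seqs)
  per_seq <- Reduce(`+`, lapply(seqs, count_codons))
  expect_equal(pooled, per_seq)

  s <- generate_cds(synthetic_config(1, 1000, seed = 66))[[1]]
  tally <- table(factor(s$codons, levels = sense_codons()))
  expect_equal(unname(count_codons(s)), as.integer(tally))
})

test_that("RSCU values, family sums and representation calls are correct", {
  counts <- uniform_counts(0)
  counts["TTT"] <- 3L; counts["TTC"] <- 1L
  r <- rscu(counts)
  expect_equal(r[["TTT"]], 1.5)
  expect_equal(r[["TTC"]], 0.5)
  expect_true(all(is.na(r[setdiff(names(r), c("TTT", "TTC"))])))

  expect_true(all(abs(rscu(uniform_counts()) - 1) < 1e-12))

  # family sums equal degeneracy for all present families
  seqs <- generate_cds(synthetic_config(6, c(50, 200), seed = 8))
  for (s in seqs) {
    r <- rscu(count_codons(s))
    for (fam in codon_families()) {
      if (length(fam) < 2 || all(is.na(r[fam]))) next
      expect_equal(sum(r[fam]), length(fam), tolerance = 1e-9)
    }
  }

  cls <- classify_rscu(c(TTT = 4.73, TTC = 1.6, TTA = 0.6, TTG = 0.21,
                         CTT = NA_real_))
  expect_equal(unname(cls[1:4]), c("OVER", "NEITHER", "NEITHER", "UNDER"))
  expect_true(is.na(cls[["CTT"]]))
})

test_that("rare codon screen uses pooled frequencies below the threshold", {
  expect_error(rare_codons(uniform_counts(0)), "empty")
  # uniform usage: every codon at 1/61 > 1%
  expect_length(rare_codons(uniform_counts()), 0L)
  counts <- uniform_counts(100L)
  counts["TTA"] <- 0L  # absent codon is rare
  counts["CTA"] <- 10L # 10 / 6010 < 1%
  expect_setequal(rare_codons(counts), c("TTA", "CTA"))
})

test_that("CAI weights divide by the family maximum with 0.5-count smoothing", {
  ref <- uniform_counts(10)
  ref["TTT"] <- 60; ref["TTC"] <- 40
  w <- cai_weights(ref)
  expect_equal(w[["TTT"]], 1)
  expect_equal(w[["TTC"]], 2 / 3)
  # max-w codon of every family is exactly 1
  byfam <- vapply(codon_families()[nchar(names(codon_families())) > 0],
                  function(fam) if (length(fam) > 1) max(w[fam]) else 1,
                  numeric(1))
  expect_true(all(abs(byfam - 1) < 1e-12))
  # smoothing: zero count in a family with max 100 -> 0.5/100
  ref2 <- uniform_counts(10)
  ref2["GGG"] <- 100; ref2["GGA"] <- 0
  w2 <- cai_weights(ref2)
  expect_equal(w2[["GGA"]], 0.5 / 100)
  # entirely absent family errors
  ref3 <- uniform_counts(10)
  ref3[codon_families()$F] <- 0
  expect_error(cai_weights(ref3), "family")
})

test_that("CAI is the log-space geometric mean over degenerate families", {
  ref <- uniform_counts(10)
  ref["TTT"] <- 40; ref["TTC"] <- 60
  w <- cai_weights(ref)
  cai <- codon_adaptation_index(count_codons(make_cds("TTTTTC")), w)
  expect_equal(cai, sqrt(2 / 3), tolerance = 1e-12)
  # Met/Trp-only gene has no eligible codon
  expect_error(
    codon_adaptation_index(count_codons(make_cds("ATGTGG")), w), "degenerate")
  # Met and Trp are excluded from the mean
  with_met <- codon_adaptation_index(count_codons(make_cds("TTTTTCATG")), w)
  expect_equal(with_met, cai)
})

test_that("family homozygosity matches closed forms", {
  counts <- uniform_counts(0)
  counts["TTT"] <- 3L; counts["TTC"] <- 1L
  fh <- family_homozygosity(counts)
  expect_equal(fh$f_hat[fh$amino_acid == "F"], 0.5)
  expect_true(all(is.na(fh$f_hat[fh$amino_acid != "F"])))

  counts["TTT"] <- 5L; counts["TTC"] <- 0L  # single codon used
  expect_equal(family_homozygosity(counts)$f_hat[fh$amino_acid == "F"], 1)

  for (m in c(2L, 5L, 50L)) {  # uniform (m, m): (m-1)/(2m-1)
    counts["TTT"] <- m; counts["TTC"] <- m
    expect_equal(family_homozygosity(counts)$f_hat[fh$amino_acid == "F"],
                 (m - 1) / (2 * m - 1))
  }
  # probability convention: sum(p^2)
  expect_equal(
    family_homozygosity(counts, "probability")$f_hat[fh$amino_acid == "F"],
    0.5)
})

test_that("Nc spans [20, 61] with correct endpoints and classes", {
  expect_equal(effective_number_of_codons(single_codon_counts()), 20)
  expect_equal(
    effective_number_of_codons(uniform_counts(), convention = "probability"),
    61)
  expect_equal(nc_class(c(33.9, 35, 50, 59.9)),
               c("HIGH_BIAS", "MODERATE", "MODERATE", "LOW"))
  # missing required class errors with its name
  counts <- uniform_counts(0)
  counts["TTT"] <- 10L; counts["TTC"] <- 10L
  expect_error(effective_number_of_codons(counts), "degeneracy 4")
})

test_that("Nc is permutation invariant and count duplication keeps it in range", {
  s <- generate_cds(synthetic_config(1, 300, seed = 14))[[1]]
  counts <- count_codons(s)
  set.seed(2)
  perm <- codon_seq("p", sample(s$codons))
  expect_equal(effective_number_of_codons(count_codons(perm)),
               effective_number_of_codons(counts))
  for (mult in c(2L, 10L, 100L)) {
    nc <- effective_number_of_codons(counts * mult)
    expect_true(nc >= 20 && nc <= 61)
  }
})

test_that("Ile imputation uses the mean of the 2- and 4-fold class averages", {
  counts <- uniform_counts(6L)
  counts[codon_families()$I] <- 0L
  fh <- family_homozygosity(counts)
  f2 <- mean(fh$f_hat[fh$k == 2], na.rm = TRUE)
  f4 <- mean(fh$f_hat[fh$k == 4], na.rm = TRUE)
  f6 <- mean(fh$f_hat[fh$k == 6], na.rm = TRUE)
  expected <- 2 + 9 / f2 + 1 / ((f2 + f4) / 2) + 5 / f4 + 3 / f6
  expect_equal(effective_number_of_codons(counts), min(expected, 61))
})

test_that("ICDI endpoints, worked example and denominator modes hold", {
  expect_equal(intrinsic_codon_bias_index(uniform_counts()), 0)
  expect_equal(intrinsic_codon_bias_index(single_codon_counts()), 1)
  counts <- uniform_counts(0)
  counts["TTT"] <- 3L; counts["TTC"] <- 1L
  expect_equal(intrinsic_codon_bias_index(counts), 0.25)
  # fixed /18 denominator counts absent families as zero bias
  expect_equal(intrinsic_codon_bias_index(counts, families = "all18"),
               0.25 / 18)
  expect_error(intrinsic_codon_bias_index(count_codons(make_cds("ATGTGG"))),
               "ICDI undefined")
})

test_that("Nc decreases and ICDI increases along a bias gradient", {
  b_grid <- c(0, 0.25, 0.5, 0.75, 1)
  nc <- icdi <- numeric(length(b_grid))
  for (i in seq_along(b_grid)) {
    seqs <- generate_bias_gradient(b_grid[i],
                                   synthetic_config(40, 200, seed = 500 + i))
    pooled <- count_codons(seqs)
    nc[i] <- effective_number_of_codons(pooled)
    icdi[i] <- intrinsic_codon_bias_index(pooled)
  }
  expect_true(all(diff(nc) < 0))
  expect_true(all(diff(icdi) > 0))
  expect_true(all(nc >= 20 & nc <= 61))
  expect_true(all(icdi >= 0 & icdi <= 1))
})

test_that("ICDI and Nc rank-correlate strongly negatively across genes", {
  b_grid <- seq(0, 1, length.out = 50)
  idx <- do.call(rbind, lapply(seq_along(b_grid), function(i) {
    s <- generate_bias_gradient(b_grid[i],
                                synthetic_config(1, 300, seed = 900 + i))[[1]]
    counts <- count_codons(s)
    data.frame(nc = effective_number_of_codons(counts),
               icdi = intrinsic_codon_bias_index(counts))
  }))
  rho <- suppressWarnings(stats::cor(idx$nc, idx$icdi, method = "spearman"))
  expect_lt(rho, -0.9)
})

test_that("bias_indices assembles per-sequence indices with classes", {
  seqs <- generate_cds(synthetic_config(5, 150, seed = 3))
  tab <- bias_indices(seqs)
  expect_equal(nrow(tab), 5L)
  expect_true(all(tab$nc >= 20 & tab$nc <= 61))
  expect_true(all(tab$icdi >= 0 & tab$icdi <= 1))
  expect_true(all(tab$cai > 0 & tab$cai <= 1))
  expect_equal(tab$nc_class, nc_class(tab$nc))
})
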