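test_that("parity coordinates follow third-position ratios", {
  # third positions A, T, C, G once each -> exact centre
  expect_equal(unname(parity_point(make_cds("GCAGCTGCCGCG"))), c(0.5, 0.5))
  # third positions A, A, T, G
  pp <- parity_point(make_cds("GCAGCAGCTGCG"))
  expect_equal(pp[["x"]], 2 / 3)
  expect_equal(pp[["y"]], 1)
  # zero denominator -> NA coordinate
  pp2 <- parity_point(make_cds("GCAGCT"))
  expect_true(is.na(pp2[["y"]]))
  expect_equal(pp2[["x"]], 0.5)
})

test_that("neutrality fit recovers exact collinear parameters", {
  fit <- neutrality_fit(c(20, 50, 80), c(30, 45, 60))
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 20, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$mutation_pct, 50)
  expect_equal(fit$selection_pct, 50)
  expect_equal(fit$mutation_pct + fit$selection_pct, 100)

  # pure mutation limit: GC12 = GC3
  fit2 <- neutrality_fit(c(10, 40, 90), c(10, 40, 90))
  expect_equal(fit2$slope, 1, tolerance = 1e-12)
  expect_equal(fit2$selection_pct, 0, tolerance = 1e-9)

  # slope 0.1732 decomposes into 17.32% mutation / 82.68% selection
  gc3 <- c(30, 45, 60, 75)
  fit3 <- neutrality_fit(gc3, 0.1732 * gc3 + 39.18)
  expect_equal(fit3$mutation_pct, 17.32, tolerance = 1e-9)
  expect_equal(fit3$selection_pct, 82.68, tolerance = 1e-9)

  expect_error(neutrality_fit(c(50, 50, 50), c(1, 2, 3)), "degenerate")
  expect_error(neutrality_fit(c(1, 2), c(1, 2)), "at least 3")
})

test_that("expected ENc curve matches the closed form and its symmetry", {
  expect_equal(expected_enc(0), 31)
  expect_equal(expected_enc(0.5), 60.5)
  expect_equal(expected_enc(1), 32)
  s <- seq(0, 1, by = 0.05)
  expect_equal(expected_enc(s) - s, expected_enc(1 - s) - (1 - s),
               tolerance = 1e-12)
  expect_error(expected_enc(1.2), "0, 1")

  expect_equal(enc_gc3_deviation(60.5, 0.5), 0)
  expect_equal(enc_gc3_deviation(45, 0.5), 15.5)
  expect_equal(enc_gc3_deviation(61, 0.5), -0.5)
})

test_that("correlation matches hand values and a brute-force oracle", {
  expect_equal(correlate(1:10, 2 * (1:10) + 1)$r, 1, tolerance = 1e-12)
  expect_equal(correlate(c(1, 2, 3), c(1, 3, 2))$r, 0.5, tolerance = 1e-12)
  set.seed(7)
  x <- rnorm(40); y <- rnorm(40)
  res <- correlate(x, y)
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, brute, tolerance = 1e-12)
  expect_true(res$p >= 0 && res$p <= 1)
  expect_equal(res$n, 40L)
  expect_error(correlate(rep(1, 5), rnorm(5)), "zero variance")
  sp <- correlate(x, y, method = "spearman")
  expect_equal(sp$r, cor(x, y, method = "spearman"), tolerance = 1e-12)
})

test_that("OLS regression is exact on collinear input", {
  fit <- regress(c(0, 1, 2), c(1, 3, 5))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_error(regress(rep(2, 4), 1:4), "degenerate")
})

test_that("PCA on RSCU vectors reconstructs and orders variance", {
  seqs <- generate_cds(synthetic_config(12, c(100, 300), seed = 21))
  mat <- rscu_matrix(seqs)
  expect_equal(dim(mat), c(12L, 59L))
  pca <- pca_rscu(mat)
  expect_true(all(diff(pca$explained_pct) <= 1e-9))
  expect_lte(sum(pca$explained_pct), 100 + 1e-6)
  # reconstruction of the imputed, uncentred matrix
  imputed <- mat
  for (j in seq_len(ncol(imputed))) {
    nas <- is.na(imputed[, j])
    if (any(nas)) imputed[nas, j] <- mean(imputed[, j], na.rm = TRUE)
  }
  recon <- pca$scores %*% t(pca$loadings) +
    matrix(pca$center, nrow(mat), ncol(mat), byrow = TRUE)
  expect_equal(unname(recon), unname(imputed), tolerance = 1e-8)
  # components orthogonal
  gram <- crossprod(pca$loadings)
  expect_equal(unname(gram), diag(ncol(gram)), tolerance = 1e-8)
})

test_that("rank-1 RSCU variation loads entirely on PC1", {
  base <- rscu(count_codons(generate_cds(
    synthetic_config(1, 500, seed = 55))[[1]]))
  base[is.na(base)] <- 1
  direction <- seq(-0.1, 0.1, length.out = 59)
  mat <- t(sapply(seq(-1, 1, length.out = 6), function(a) base + a * direction))
  colnames(mat) <- rscu_codons()
  pca <- pca_rscu(mat)
  expect_equal(pca$explained_pct[1], 100, tolerance = 1e-9)
})

test_that("PCA sign convention and errors are deterministic", {
  seqs <- generate_cds(synthetic_config(5, 100, seed = 13))
  p1 <- pca_rscu(seqs); p2 <- pca_rscu(seqs)
  expect_identical(p1$scores, p2$scores)
  # largest-magnitude loading of each component is positive
  for (j in seq_len(ncol(p1$loadings))) {
    v <- p1$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_error(pca_rscu(seqs[1:2]), "at least 3")
})
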