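# Evolutionary-force diagnostics: PR2 parity, neutrality regression,
# expected ENc-GC3 curve, correlation/regression helpers, PCA on RSCU.

#' PR2 parity coordinates
#'
#' `x = A3/(A3 + T3)` (AT bias, abscissa) and `y = G3/(G3 + C3)` (GC bias,
#' ordinate), computed from third-codon-position content. Under parity rule 2
#' (no strand-asymmetric mutation/selection bias) both coordinates are 0.5.
#' A coordinate is `NA` when its denominator is zero.
#'
#' @param x A `composition_profile` from [positional_composition()] or a
#'   [codon_seq()].
#' @return Named numeric vector `c(x = , y = )`, both in [0, 1].
#' @export
parity_point <- function(x) {
  if (inherits(x, "codon_seq")) x <- positional_composition(x)
  stopifnot(inherits(x, "composition_profile"))
  cp <- x$counts_pos[, 3L]
  a <- cp[["A"]]; t <- cp[["T"]]; g <- cp[["G"]]; c <- cp[["C"]]
  c(
    x = if ((a + t) > 0) a / (a + t) else NA_real_,
    y = if ((g + c) > 0) g / (g + c) else NA_real_
  )
}

#' Neutrality-plot regression of GC12 on GC3
#'
#' Ordinary least squares of GC12 percent on GC3 percent across genes. The
#' slope estimates the fraction of GC12 variation attributable to directional
#' mutation pressure: `mutation_pct = slope * 100` and `selection_pct =
#' (1 - slope) * 100` (selection plus other constraints).
#'
#' @param gc3,gc12 Numeric vectors of per-gene GC3 and GC12 percents
#'   (equal length, n >= 3).
#' @return List: `slope`, `intercept`, `r2`, `mutation_pct`, `selection_pct`,
#'   `n`.
#' @export
neutrality_fit <- function(gc3, gc12) {
  stopifnot(length(gc3) == length(gc12))
  if (length(gc3) < 3L) stop("neutrality fit needs at least 3 genes")
  if (stats::var(gc3) == 0) stop("degenerate input: all GC3 values identical")
  fit <- stats::lm(gc12 ~ gc3)
  slope <- unname(stats::coef(fit)[2L])
  # R^2 from sums of squares (summary.lm warns on exact collinear input)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((gc12 - mean(gc12))^2)
  list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1L]),
    r2 = r2,
    mutation_pct = slope * 100,
    selection_pct = (1 - slope) * 100,
    n = length(gc3)
  )
}

#' Expected ENc under pure GC3 compositional constraint
#'
#' Wright's null curve `Nc = 2 + s + 29 / (s^2 + (1 - s)^2)` for a gene whose
#' only source of codon bias is its third-position GC content `s`. Genes
#' falling well below the curve are candidates for selection on codon choice.
#'
#' @param s GC3 as a fraction in [0, 1] (vectorised).
#' @return Expected Nc value(s).
#' @export
expected_enc <- function(s) {
  if (any(s < 0 | s > 1, na.rm = TRUE)) stop("GC3 fraction must be in [0, 1]")
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Deviation of observed Nc from the expected ENc-GC3 curve
#'
#' `deviation = expected_enc(s) - nc`; positive values place the gene below
#' the curve (a selection signal), negative values above it (possible for Nc
#' capped at 61).
#'
#' @param nc Observed Nc value(s).
#' @param s GC3 fraction(s) in [0, 1].
#' @return Numeric deviation(s).
#' @export
enc_gc3_deviation <- function(nc, s) expected_enc(s) - nc

#' Correlation with a two-sided p-value
#'
#' Pearson (default; p via the t transform) or Spearman correlation.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return List: `r`, `p`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("correlation needs at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in input vector; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = method, alternative = "two.sided",
                        exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), method = method)
}

#' Simple OLS regression
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return List: `slope`, `intercept`, `r2`, `n`.
#' @export
regress <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("regression needs at least 3 observations")
  if (stats::var(x) == 0) stop("degenerate predictor: zero variance")
  fit <- stats::lm(y ~ x)
  list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r2 = 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2),
    n = length(x)
  )
}

#' RSCU matrix of a data set
#'
#' @param sequences List of [codon_seq()] objects.
#' @return Numeric matrix, one row per sequence (rownames = ids), 59 columns
#'   (the codons of degenerate families); `NA` where a family is absent.
#' @export
rscu_matrix <- function(sequences) {
  m <- t(vapply(sequences, function(s) rscu(count_codons(s)),
                numeric(length(.RSCU_CODONS))))
  rownames(m) <- vapply(sequences, function(s) s$id, character(1))
  m
}

#' PCA on per-sequence RSCU vectors
#'
#' Column-mean-centred principal component analysis (no unit-variance
#' scaling: RSCU values already share a scale) of the n x 59 RSCU matrix.
#' `NA` entries (families absent from a gene) are imputed with the column
#' mean before centring, which keeps short genes in the analysis and leaves
#' the centred entry at zero. Component signs are fixed by forcing each
#' component's largest-magnitude loading positive, so results are
#' reproducible across platforms.
#'
#' @param mat Matrix from [rscu_matrix()] (>= 3 rows), or a list of
#'   [codon_seq()] objects.
#' @return List: `scores` (n x m), `loadings` (59 x m), `explained_pct`
#'   (non-increasing, sums to <= 100), `center` (column means used).
#' @export
pca_rscu <- function(mat) {
  if (is.list(mat) && !is.matrix(mat)) mat <- rscu_matrix(mat)
  if (nrow(mat) < 3L) stop("PCA needs at least 3 sequences")
  for (j in seq_len(ncol(mat))) {
    nas <- is.na(mat[, j])
    if (any(nas)) {
      mat[nas, j] <- if (all(nas)) 0 else mean(mat[, j], na.rm = TRUE)
    }
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2L, flip, `*`)
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  list(
    scores = scores,
    loadings = loadings,
    explained_pct = 100 * pc$sdev^2 / sum(pc$sdev^2),
    center = pc$center
  )
}
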