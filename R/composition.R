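# Nucleotide composition overall and by codon position, GC aggregates, skews.

.nt_counts <- function(chars) {
  tab <- table(factor(chars, levels = c("A", "C", "G", "T")))
  stats::setNames(as.integer(tab), names(tab))
}

#' Positional nucleotide composition of a coding sequence
#'
#' Computes the percent composition of A, C, G, T overall and at each codon
#' position (A1..G3), GC and AT percent, positional GC (GC1, GC2, GC3), AT3,
#' GC12 = (GC1 + GC2)/2 (the standard neutrality-plot convention) and the AT
#' and GC strand skews. Third-position percentages use raw third-position
#' content, not synonymous-only positions.
#'
#' @param cds A [codon_seq()] (terminal stop already stripped at validation).
#' @return An object of class `composition_profile`: a list with `pct`
#'   (named A/C/G/T percent), `pct_pos` (4 x 3 matrix, rows A/C/G/T, columns
#'   codon positions), `counts`, `counts_pos`, `gc`, `at`, `gc1`, `gc2`,
#'   `gc3`, `gc12`, `at3`, `skew_at`, `skew_gc`, `n_codons`.
#' @export
positional_composition <- function(cds) {
  stopifnot(inherits(cds, "codon_seq"))
  n <- length(cds$codons)
  pos_chars <- lapply(1:3, function(k) substr(cds$codons, k, k))
  counts_pos <- vapply(pos_chars, .nt_counts, integer(4))
  dimnames(counts_pos) <- list(c("A", "C", "G", "T"), paste0("pos", 1:3))
  counts <- rowSums(counts_pos)
  total <- 3L * n
  pct <- 100 * counts / total
  pct_pos <- 100 * counts_pos / n
  gc_k <- colSums(pct_pos[c("G", "C"), ])
  skews <- nucleotide_skews(counts)
  structure(list(
    id = cds$id,
    pct = pct,
    pct_pos = pct_pos,
    counts = counts,
    counts_pos = counts_pos,
    gc = sum(pct[c("G", "C")]),
    at = sum(pct[c("A", "T")]),
    gc1 = gc_k[[1L]], gc2 = gc_k[[2L]], gc3 = gc_k[[3L]],
    gc12 = (gc_k[[1L]] + gc_k[[2L]]) / 2,
    at3 = sum(pct_pos[c("A", "T"), 3L]),
    skew_at = skews[["skew_at"]],
    skew_gc = skews[["skew_gc"]],
    n_codons = n
  ), class = "composition_profile")
}

#' AT and GC strand skews
#'
#' `skew_at = (A - T)/(A + T)` and `skew_gc = (G - C)/(G + C)` on overall
#' nucleotide counts, with the convention that a zero denominator yields 0.
#'
#' @param x A `composition_profile` or a named count/percent vector with
#'   entries A, C, G, T.
#' @return Named numeric vector `c(skew_at = , skew_gc = )`, both in [-1, 1].
#' @export
nucleotide_skews <- function(x) {
  if (inherits(x, "composition_profile")) x <- x$counts
  a <- x[["A"]]; t <- x[["T"]]; g <- x[["G"]]; c <- x[["C"]]
  c(
    skew_at = if ((a + t) > 0) (a - t) / (a + t) else 0,
    skew_gc = if ((g + c) > 0) (g - c) / (g + c) else 0
  )
}

#' Per-sequence composition table
#'
#' One row per sequence with the column roles of a supplementary composition
#' table: overall percents, the twelve positional percents A1..T3, GC
#' aggregates and skews.
#'
#' @param sequences List of [codon_seq()] objects.
#' @return data.frame, one row per sequence.
#' @export
composition_table <- function(sequences) {
  rows <- lapply(sequences, function(s) {
    p <- positional_composition(s)
    pos <- as.vector(p$pct_pos)  # column-major: A1 C1 G1 T1 A2 ... T3
    names(pos) <- paste0(rep(c("A", "C", "G", "T"), 3L),
                         rep(1:3, each = 4L))
    cbind(
      data.frame(id = s$id, gene = s$gene, n_codons = p$n_codons,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(c(
        A = p$pct[["A"]], C = p$pct[["C"]], G = p$pct[["G"]], T = p$pct[["T"]],
        pos,
        GC = p$gc, AT = p$at, GC1 = p$gc1, GC2 = p$gc2, GC3 = p$gc3,
        GC12 = p$gc12, AT3 = p$at3,
        skew_at = p$skew_at, skew_gc = p$skew_gc
      )))
    )
  })
  do.call(rbind, rows)
}
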