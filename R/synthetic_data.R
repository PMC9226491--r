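# Seeded synthetic-CDS generators: free sampling, bias gradients, neutrality
# structure (controlled GC12-GC3 relationship) and dinucleotide depletion.

#' Synthetic data-set configuration
#'
#' @param n_genes Number of sequences to generate.
#' @param length_codons Codon count per gene: a single value or `c(min, max)`
#'   for per-gene uniform sampling. Must be >= 10.
#' @param aa_weights Optional named probability vector over the 20 amino
#'   acids (normalised internally); default uniform.
#' @param codon_weights Optional list mapping amino acids to named
#'   within-family codon probability vectors; default uniform per family.
#' @param seed Root seed (mandatory). Per-gene child seeds are derived
#'   deterministically from it (`(seed + i * 48271) mod (2^31 - 1)`), so a
#'   data set is reproducible gene by gene.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes, length_codons, aa_weights = NULL,
                             codon_weights = NULL, seed) {
  stopifnot(n_genes >= 1L, length(length_codons) %in% 1:2)
  if (any(length_codons < 10L)) stop("length_codons must be >= 10")
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (!is.null(aa_weights)) {
    if (is.null(names(aa_weights)) ||
        !all(names(aa_weights) %in% names(.FAMILIES))) {
      stop("aa_weights must be named with one-letter amino-acid codes")
    }
    if (sum(aa_weights) <= 0) stop("aa_weights must have positive mass")
  }
  if (!is.null(codon_weights)) {
    for (aa in names(codon_weights)) {
      cw <- codon_weights[[aa]]
      if (!all(names(cw) %in% .FAMILIES[[aa]]) || sum(cw) <= 0) {
        stop("invalid codon_weights for family ", aa)
      }
    }
  }
  structure(list(n_genes = as.integer(n_genes),
                 length_codons = as.integer(length_codons),
                 aa_weights = aa_weights, codon_weights = codon_weights,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

.child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + as.numeric(i) * 48271) %% 2147483647)
}

.gene_length <- function(config) {
  lc <- config$length_codons
  if (length(lc) == 1L) lc else sample(lc[1L]:lc[2L], 1L)
}

.sample_codons_for_aa <- function(aa_seq, codon_weights = NULL) {
  codons <- character(length(aa_seq))
  for (aa in unique(aa_seq)) {
    fam <- .FAMILIES[[aa]]
    idx <- which(aa_seq == aa)
    prob <- NULL
    if (!is.null(codon_weights) && !is.null(codon_weights[[aa]])) {
      w <- codon_weights[[aa]]
      prob <- stats::setNames(rep(0, length(fam)), fam)
      prob[names(w)] <- w
    }
    codons[idx] <- if (length(fam) == 1L) rep(fam, length(idx))
                   else sample(fam, length(idx), replace = TRUE, prob = prob)
  }
  codons
}

#' Generate coding sequences by codon sampling
#'
#' Each gene draws its amino-acid sequence from `aa_weights` and its codons
#' from the per-family `codon_weights` (uniform by default). Outputs are
#' valid coding sequences by construction (sense codons only), and an
#' identical seed reproduces identical sequences.
#'
#' @param config A [synthetic_config()].
#' @return List of [codon_seq()] objects with ids `syn_001`, `syn_002`, ...
#' @export
generate_cds <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  aas <- names(.FAMILIES)
  prob <- NULL
  if (!is.null(config$aa_weights)) {
    prob <- stats::setNames(rep(0, length(aas)), aas)
    prob[names(config$aa_weights)] <- config$aa_weights
  }
  lapply(seq_len(config$n_genes), function(i) {
    set.seed(.child_seed(config$seed, i))
    L <- .gene_length(config)
    aa_seq <- sample(aas, L, replace = TRUE, prob = prob)
    codon_seq(sprintf("syn_%03d", i),
              .sample_codons_for_aa(aa_seq, config$codon_weights))
  })
}

#' Generate sequences along a codon-bias gradient
#'
#' The within-family codon distribution is the interpolation
#' `(1 - b) * uniform + b * point mass` on one preferred codon per family, so
#' `b = 0` gives uniform synonymous usage (no bias; Nc of 61 under the
#' probability convention) and `b = 1` a single codon per family (maximal
#' bias; Nc of 20). With `ensure_coverage` every amino acid appears at least
#' twice (requires >= 40 codons), making Wright homozygosities defined for
#' all families.
#'
#' @param b Bias strength in [0, 1].
#' @param config A [synthetic_config()].
#' @param preferred Optional named vector (amino acid -> codon); default the
#'   alphabetically first codon of each family.
#' @param ensure_coverage Guarantee every amino acid occurs at least twice.
#' @return List of [codon_seq()] objects; attribute `b` records the strength.
#' @export
generate_bias_gradient <- function(b, config, preferred = NULL,
                                   ensure_coverage = TRUE) {
  stopifnot(inherits(config, "synthetic_config"), b >= 0, b <= 1)
  aas <- names(.FAMILIES)
  if (is.null(preferred)) {
    preferred <- vapply(.FAMILIES, `[`, character(1), 1L)
  }
  codon_weights <- lapply(stats::setNames(aas, aas), function(aa) {
    fam <- .FAMILIES[[aa]]
    w <- rep((1 - b) / length(fam), length(fam))
    names(w) <- fam
    w[preferred[[aa]]] <- w[preferred[[aa]]] + b
    w
  })
  out <- lapply(seq_len(config$n_genes), function(i) {
    set.seed(.child_seed(config$seed, i))
    L <- .gene_length(config)
    if (ensure_coverage) {
      if (L < 40L) stop("ensure_coverage needs at least 40 codons per gene")
      aa_seq <- sample(c(rep(aas, 2L), sample(aas, L - 40L, replace = TRUE)))
    } else {
      aa_seq <- sample(aas, L, replace = TRUE)
    }
    codon_seq(sprintf("syn_%03d", i),
              .sample_codons_for_aa(aa_seq, codon_weights))
  })
  attr(out, "b") <- b
  out
}

# amino-acid pools by GC12 contribution per codon (percent of first two
# positions), each with AT-ending and GC-ending synonymous choices, covering
# degeneracy classes 2, 3, 4 and 6
.NEUTRALITY_POOLS <- list(
  high = list(aas = c("A", "G", "P", "R"),
              at = list(A = c("GCA", "GCT"), G = c("GGA", "GGT"),
                        P = c("CCA", "CCT"), R = c("CGA", "CGT")),
              gc = list(A = c("GCC", "GCG"), G = c("GGC", "GGG"),
                        P = c("CCC", "CCG"), R = c("CGC", "CGG"))),
  mid = list(aas = c("L", "S", "H", "D"),
             at = list(L = c("CTA", "CTT"), S = c("TCA", "TCT"),
                       H = "CAT", D = "GAT"),
             gc = list(L = c("CTC", "CTG"), S = c("TCC", "TCG"),
                       H = "CAC", D = "GAC")),
  low = list(aas = c("K", "I", "F", "Y"),
             at = list(K = "AAA", I = c("ATA", "ATT"), F = "TTT", Y = "TAT"),
             gc = list(K = "AAG", I = "ATC", F = "TTC", Y = "TAC"))
)

.NEUTRALITY_MID_SHARE <- 0.3

#' Generate a data set with a prescribed GC12-GC3 relationship
#'
#' Gene i receives a target `GC3_i ~ Uniform(gc3_range)` and a target
#' `GC12_i = beta * GC3_i + intercept + Normal(0, noise_sd)`. Two knobs
#' realise the targets: GC12 through the amino-acid mixture (pools of
#' residues whose first two codon positions contribute 100%, 50% or 0% GC,
#' mixed to hit the target; the 50% pool holds a fixed 30% share) and GC3
#' through the choice of GC-ending versus AT-ending synonymous codons at an
#' exact number of positions. Realised values land within rounding error
#' (well inside +/-3%) of the targets. Achievable GC12 targets span
#' [15, 85]%; a deterministic target outside that band is an error, and
#' noise draws are clamped to it (the clamped value is recorded as the
#' target).
#'
#' @param beta Target slope in [0, 1].
#' @param intercept_pct Target intercept (percent GC12).
#' @param noise_sd_pct SD of the Gaussian noise on GC12 targets (percent).
#' @param gc3_range `c(lo, hi)` percent, inside [5, 95].
#' @param config A [synthetic_config()].
#' @return List of [codon_seq()] objects with attribute `manifest`: a
#'   data.frame (`id`, `length`, `target_gc3`, `target_gc12`,
#'   `realized_gc3`, `realized_gc12`).
#' @export
generate_neutrality_dataset <- function(beta, intercept_pct, noise_sd_pct,
                                        gc3_range, config) {
  stopifnot(inherits(config, "synthetic_config"),
            beta >= 0, beta <= 1, length(gc3_range) == 2L)
  if (gc3_range[1L] < 5 || gc3_range[2L] > 95 || diff(gc3_range) < 0) {
    stop("gc3_range must be an increasing interval inside [5, 95]")
  }
  m <- .NEUTRALITY_MID_SHARE
  band <- c(100 * m / 2, 100 * (1 - m / 2))
  det12 <- beta * gc3_range + intercept_pct
  if (any(det12 < band[1L] | det12 > band[2L])) {
    stop(sprintf("beta * GC3 + intercept falls outside the achievable GC12 range [%g, %g]",
                 band[1L], band[2L]))
  }
  pools <- .NEUTRALITY_POOLS
  seqs <- vector("list", config$n_genes)
  manifest <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    set.seed(.child_seed(config$seed, i))
    L <- .gene_length(config)
    gc3_t <- stats::runif(1L, gc3_range[1L], gc3_range[2L])
    gc12_t <- beta * gc3_t + intercept_pct + stats::rnorm(1L, 0, noise_sd_pct)
    gc12_t <- min(max(gc12_t, band[1L]), band[2L])
    n_mid <- round(m * L)
    n_high <- round(gc12_t / 100 * L - 0.5 * n_mid)
    n_high <- min(max(n_high, 0L), L - n_mid)
    n_low <- L - n_mid - n_high
    aa_seq <- c(sample(pools$high$aas, n_high, replace = TRUE),
                sample(pools$mid$aas, n_mid, replace = TRUE),
                sample(pools$low$aas, n_low, replace = TRUE))
    pool_of <- rep(c("high", "mid", "low"), c(n_high, n_mid, n_low))
    n_gc3 <- round(gc3_t / 100 * L)
    gc_end <- rep(FALSE, L)
    gc_end[sample.int(L, n_gc3)] <- TRUE
    codons <- character(L)
    for (j in seq_len(L)) {
      choices <- pools[[pool_of[j]]][[if (gc_end[j]) "gc" else "at"]][[aa_seq[j]]]
      codons[j] <- if (length(choices) == 1L) choices else sample(choices, 1L)
    }
    ord <- sample.int(L)
    s <- codon_seq(sprintf("syn_%03d", i), codons[ord])
    prof <- positional_composition(s)
    seqs[[i]] <- s
    manifest[[i]] <- data.frame(
      id = s$id, length = L, target_gc3 = gc3_t, target_gc12 = gc12_t,
      realized_gc3 = prof$gc3, realized_gc12 = prof$gc12,
      stringsAsFactors = FALSE
    )
  }
  attr(seqs, "manifest") <- do.call(rbind, manifest)
  seqs
}

.count_di_in <- function(str, xy) {
  n <- nchar(str)
  if (n < 2L) return(0L)
  sum(substring(str, 1:(n - 1L), 2:n) == xy)
}

#' Deplete a dinucleotide by synonymous codon swaps
#'
#' Greedy hill-climbing over single-codon synonymous replacements (so the
#' translation and length never change) until the odds ratio of the chosen
#' dinucleotide drops to `target_odds` or no single swap improves it further.
#' If the current odds ratio is already at or below the target the input is
#' returned unchanged.
#'
#' @param cds A [codon_seq()].
#' @param dinucleotide One of the 16 dinucleotides, e.g. `"CG"` or `"TA"`.
#' @param target_odds Desired odds ratio (below the current value).
#' @param seed Seed controlling the scan order.
#' @return A [codon_seq()] with attributes `achieved_odds` and `reached`
#'   (logical; a warning is raised when the target was not reachable).
#' @export
deplete_dinucleotide <- function(cds, dinucleotide, target_odds, seed = 1L) {
  stopifnot(inherits(cds, "codon_seq"),
            dinucleotide %in% .DINUCLEOTIDES, target_odds >= 0)
  x <- substr(dinucleotide, 1L, 1L)
  y <- substr(dinucleotide, 2L, 2L)
  codons <- cds$codons
  n <- length(codons)
  L <- 3L * n
  seqstr <- paste(codons, collapse = "")
  chars <- strsplit(seqstr, "", fixed = TRUE)[[1L]]
  mono <- .nt_counts(chars)
  n_xy <- .count_di_in(seqstr, dinucleotide)
  odds_of <- function(n_xy, mono) {
    expected <- (mono[[x]] / L) * (mono[[y]] / L)
    if (expected == 0) return(0)
    (n_xy / (L - 1L)) / expected
  }
  current <- odds_of(n_xy, mono)
  finish <- function(reached) {
    out <- codon_seq(cds$id, codons, gene = cds$gene)
    attr(out, "achieved_odds") <- current
    attr(out, "reached") <- reached
    if (!reached) {
      warning(sprintf("target odds %.3g for %s not reached; best achieved %.3g",
                      target_odds, dinucleotide, current))
    }
    out
  }
  if (current <= target_odds) return(finish(TRUE))
  set.seed(seed)
  context <- function(i, mid) {
    paste0(if (i > 1L) substr(codons[i - 1L], 3L, 3L) else "",
           mid,
           if (i < n) substr(codons[i + 1L], 1L, 1L) else "")
  }
  repeat {
    improved <- FALSE
    for (i in sample.int(n)) {
      old <- codons[i]
      fam <- .FAMILIES[[.GENETIC_CODE[[old]]]]
      alts <- setdiff(fam, old)
      if (length(alts) == 0L) next
      old_local <- .count_di_in(context(i, old), dinucleotide)
      old_counts <- .nt_counts(strsplit(old, "", fixed = TRUE)[[1L]])
      best_odds <- current
      best_alt <- NULL
      best_nxy <- n_xy
      best_mono <- mono
      for (alt in alts) {
        new_nxy <- n_xy - old_local + .count_di_in(context(i, alt), dinucleotide)
        new_mono <- mono - old_counts +
          .nt_counts(strsplit(alt, "", fixed = TRUE)[[1L]])
        cand <- odds_of(new_nxy, new_mono)
        if (cand < best_odds - 1e-12) {
          best_odds <- cand; best_alt <- alt
          best_nxy <- new_nxy; best_mono <- new_mono
        }
      }
      if (!is.null(best_alt)) {
        codons[i] <- best_alt
        n_xy <- best_nxy
        mono <- best_mono
        current <- best_odds
        improved <- TRUE
        if (current <= target_odds) return(finish(TRUE))
      }
    }
    if (!improved) break
  }
  finish(current <= target_odds)
}
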