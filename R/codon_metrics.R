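# Codon counting, RSCU, rare codons, CAI, Wright's ENc and ICDI.

#' Count sense codons
#'
#' @param x A [codon_seq()] or a list of them (counts are pooled over the
#'   list, so the data-set table is the sum of per-sequence tables).
#' @return Named integer vector over the 61 sense codons (alphabetical).
#' @export
count_codons <- function(x) {
  codons <- if (inherits(x, "codon_seq")) x$codons
            else unlist(lapply(x, function(s) s$codons), use.names = FALSE)
  tab <- table(factor(codons, levels = .SENSE_CODONS))
  stats::setNames(as.integer(tab), names(tab))
}

.check_counts <- function(counts) {
  if (is.null(names(counts)) || !all(.SENSE_CODONS %in% names(counts))) {
    stop("counts must be named over the 61 sense codons (see count_codons())")
  }
  counts[.SENSE_CODONS]
}

#' Relative synonymous codon usage
#'
#' For codon j of a synonymous family with total count `n_i` and degeneracy
#' `k_i`, `RSCU_j = x_j / (n_i / k_i)`: the observed count over the count
#' expected under equal synonymous usage. Families absent from the gene
#' (`n_i = 0`) yield `NA`. Within every present family the RSCU values sum to
#' the family degeneracy. Only the 59 codons of degenerate families carry an
#' RSCU value (Met and Trp have no synonymous choice).
#'
#' @param counts Codon counts from [count_codons()].
#' @return Named numeric vector over [rscu_codons()].
#' @export
rscu <- function(counts) {
  counts <- .check_counts(counts)
  out <- stats::setNames(rep(NA_real_, length(.RSCU_CODONS)), .RSCU_CODONS)
  for (aa in .DEGENERATE_AAS) {
    fam <- .FAMILIES[[aa]]
    n_i <- sum(counts[fam])
    if (n_i > 0L) out[fam] <- counts[fam] / (n_i / length(fam))
  }
  out
}

#' Classify RSCU values
#'
#' Codons with RSCU above 1.6 are called overrepresented and below 0.6
#' underrepresented (strict inequalities; the boundaries are NEITHER).
#'
#' @param rscu_vec Named vector from [rscu()].
#' @param over,under Thresholds.
#' @return Character vector with values `OVER`, `UNDER`, `NEITHER`, or `NA`.
#' @export
classify_rscu <- function(rscu_vec, over = 1.6, under = 0.6) {
  cls <- ifelse(is.na(rscu_vec), NA_character_,
                ifelse(rscu_vec > over, "OVER",
                       ifelse(rscu_vec < under, "UNDER", "NEITHER")))
  stats::setNames(cls, names(rscu_vec))
}

#' Rare codons of a pooled data set
#'
#' Codons whose frequency in the pooled codon-usage table falls below the
#' threshold (default 1%, i.e. fewer than 10 per 1,000 codons).
#'
#' @param counts Pooled codon counts from [count_codons()].
#' @param threshold Frequency threshold (fraction).
#' @return Character vector of rare codons (alphabetical).
#' @export
rare_codons <- function(counts, threshold = 0.01) {
  counts <- .check_counts(counts)
  total <- sum(counts)
  if (total == 0L) stop("empty codon usage table")
  names(counts)[counts / total < threshold]
}

#' Read a reference codon-usage table
#'
#' @param path TSV with two columns (codon, count or frequency); `#` lines
#'   are comments. Codons may use U or T; all 61 sense codons must appear.
#' @return Named numeric vector over the 61 sense codons.
#' @export
read_reference_usage <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (identical(tolower(tab[1L, 1L]), "codon")) tab <- tab[-1L, , drop = FALSE]
  codons <- chartr("Uu", "Tt", toupper(as.character(tab[[1L]])))
  vals <- as.numeric(tab[[2L]])
  keep <- codons %in% .SENSE_CODONS
  freq <- stats::setNames(vals[keep], codons[keep])
  missing <- setdiff(.SENSE_CODONS, names(freq))
  if (length(missing) > 0L) {
    stop("reference table lacks sense codon(s): ",
         paste(missing, collapse = ", "))
  }
  freq[.SENSE_CODONS]
}

#' Bundled human reference codon usage
#'
#' The Homo sapiens codon usage table distributed by the Kazusa codon usage
#' database (GenBank CUTG; 93,487 coding sequences, 40,662,582 codons),
#' expressed per 1,000 codons. See the bundled file's header for provenance.
#'
#' @return Named numeric vector over the 61 sense codons (per-1000 values).
#' @export
human_reference_usage <- function() {
  read_reference_usage(system.file("extdata", "human_codon_usage.tsv",
                                   package = "cubtools", mustWork = TRUE))
}

#' Relative adaptiveness weights for CAI
#'
#' Within each degenerate family, `w_j = f_j / max(f)` where `f` are the
#' reference frequencies. Zero reference entries are replaced by 0.5 counts
#' before normalisation (Sharp-Li smoothing) so every weight is positive.
#' Met, Trp and stop codons carry no weight.
#'
#' @param reference Named numeric vector over the 61 sense codons (counts,
#'   per-1000 frequencies, or any proportional scale).
#' @return Named numeric vector of weights in (0, 1] over [rscu_codons()];
#'   the most-used codon of every family has weight 1.
#' @export
cai_weights <- function(reference) {
  reference <- .check_counts(reference)
  w <- stats::setNames(rep(NA_real_, length(.RSCU_CODONS)), .RSCU_CODONS)
  for (aa in .DEGENERATE_AAS) {
    fam <- .FAMILIES[[aa]]
    f <- reference[fam]
    if (max(f) <= 0) {
      stop("reference usage absent for the entire ", aa, " family")
    }
    f[f == 0] <- 0.5
    w[fam] <- f / max(f)
  }
  w
}

#' Codon adaptation index
#'
#' The geometric mean of relative adaptiveness weights over all codon
#' occurrences in degenerate families (Met and Trp excluded, CAIcal
#' convention), accumulated in log space to avoid underflow. CAI lies in
#' (0, 1], with 1 attained exactly when the gene uses only maximal-weight
#' codons.
#'
#' @param counts Codon counts from [count_codons()].
#' @param weights Weights from [cai_weights()], or a raw reference usage
#'   vector over the 61 sense codons (weights are then derived).
#' @return CAI as a single numeric value.
#' @export
codon_adaptation_index <- function(counts, weights) {
  counts <- .check_counts(counts)
  if (!all(names(weights) %in% .RSCU_CODONS) ||
      length(weights) != length(.RSCU_CODONS)) {
    weights <- cai_weights(weights)
  }
  n_eligible <- sum(counts[.RSCU_CODONS])
  if (n_eligible == 0L) {
    stop("no codon from a degenerate family; CAI undefined")
  }
  exp(sum(counts[.RSCU_CODONS] * log(weights[.RSCU_CODONS])) / n_eligible)
}

#' Per-family codon homozygosity
#'
#' For each degenerate family with `n` codon occurrences and within-family
#' proportions `p`, Wright's unbiased homozygosity estimator is
#' `F_hat = (n * sum(p^2) - 1) / (n - 1)`, defined for `n >= 2`. The
#' probability convention `F = sum(p^2)` (defined for `n >= 1`) is available
#' for analytic work. Wright estimates that come out non-positive (possible
#' at very small `n`) are set to `NA` and excluded from class averages, the
#' usual guard in ENc implementations.
#'
#' @param counts Codon counts from [count_codons()].
#' @param convention `"wright"` (unbiased estimator) or `"probability"`.
#' @return data.frame with columns `amino_acid`, `k` (degeneracy), `n`
#'   (family count) and `f_hat` (`NA` where undefined).
#' @export
family_homozygosity <- function(counts, convention = c("wright", "probability")) {
  convention <- match.arg(convention)
  counts <- .check_counts(counts)
  rows <- lapply(.DEGENERATE_AAS, function(aa) {
    fam <- .FAMILIES[[aa]]
    n <- sum(counts[fam])
    f_hat <- NA_real_
    if (n >= 1L) {
      p <- counts[fam] / n
      sp2 <- sum(p^2)
      if (convention == "probability") {
        f_hat <- sp2
      } else if (n >= 2L) {
        f_hat <- (n * sp2 - 1) / (n - 1)
        if (f_hat <= 0) f_hat <- NA_real_
      }
    }
    data.frame(amino_acid = aa, k = length(fam), n = as.integer(n),
               f_hat = f_hat, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wright's effective number of codons (ENc)
#'
#' `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, where `Fk` is the mean homozygosity
#' over the families of degeneracy class k (9 two-fold, 1 three-fold, 5
#' four-fold, 3 six-fold families; six-fold families kept intact, CodonW
#' convention). If the single three-fold family (Ile) has no defined
#' homozygosity, `F3` is imputed as `(F2 + F4)/2`. The result is capped at 61
#' (sampling noise can push the raw sum above); values range from 20 (one
#' codon per amino acid, maximal bias) to 61 (uniform usage, no bias).
#'
#' @param x Codon counts from [count_codons()], a [codon_seq()], or a
#'   homozygosity data.frame from [family_homozygosity()].
#' @param convention Passed to [family_homozygosity()] when `x` is counts.
#' @return Nc as a single numeric value in [20, 61].
#' @export
effective_number_of_codons <- function(x, convention = c("wright", "probability")) {
  convention <- match.arg(convention)
  scores <- if (is.data.frame(x)) x
            else family_homozygosity(if (inherits(x, "codon_seq"))
                                       count_codons(x) else x,
                                     convention = convention)
  class_mean <- function(k) {
    f <- scores$f_hat[scores$k == k & !is.na(scores$f_hat)]
    if (length(f) == 0L) NA_real_ else mean(f)
  }
  f2 <- class_mean(2L); f3 <- class_mean(3L)
  f4 <- class_mean(4L); f6 <- class_mean(6L)
  for (cls in list(c(2, f2), c(4, f4), c(6, f6))) {
    if (is.na(cls[2L])) {
      stop("cannot compute Nc: no usable family of degeneracy ", cls[1L])
    }
  }
  if (is.na(f3)) f3 <- (f2 + f4) / 2
  nc <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  nc <- min(nc, 61)
  if (nc < 20 - 1e-9) stop("Nc below 20; homozygosity inputs are inconsistent")
  nc
}

#' Classify the degree of codon bias from Nc
#'
#' Nc below 35 indicates high codon preference, above 50 nearly random usage,
#' and the 35-50 band moderate bias.
#'
#' @param nc Numeric vector of Nc values.
#' @return Character vector: `HIGH_BIAS`, `MODERATE`, or `LOW`.
#' @export
nc_class <- function(nc) {
  ifelse(nc < 35, "HIGH_BIAS", ifelse(nc > 50, "LOW", "MODERATE"))
}

#' Intrinsic codon bias index (ICDI)
#'
#' Per degenerate family present in the gene, `S = sum((RSCU - 1)^2) /
#' (k * (k - 1))`; the ICDI is the mean of S over the families present
#' (`n >= 1`). It is 0 under exactly equal synonymous usage and 1 when every
#' family uses a single codon. With `families = "all18"` the sum is divided
#' by a fixed 18 and absent families contribute S = 0.
#'
#' @param x Codon counts from [count_codons()] or a [codon_seq()].
#' @param families `"present"` (default) or `"all18"`.
#' @return ICDI as a single numeric value in [0, 1].
#' @export
intrinsic_codon_bias_index <- function(x, families = c("present", "all18")) {
  families <- match.arg(families)
  counts <- .check_counts(if (inherits(x, "codon_seq")) count_codons(x) else x)
  r <- rscu(counts)
  s_vals <- vapply(.DEGENERATE_AAS, function(aa) {
    fam <- .FAMILIES[[aa]]
    if (sum(counts[fam]) == 0L) return(NA_real_)
    k <- length(fam)
    sum((r[fam] - 1)^2) / (k * (k - 1))
  }, numeric(1))
  present <- !is.na(s_vals)
  if (!any(present)) stop("no degenerate family present; ICDI undefined")
  if (families == "present") mean(s_vals[present]) else sum(s_vals[present]) / 18
}

#' Per-sequence codon-bias indices
#'
#' @param sequences List of [codon_seq()] objects.
#' @param reference Reference usage vector (61 sense codons) or weights from
#'   [cai_weights()]; defaults to the bundled human table.
#' @param convention Homozygosity convention for Nc.
#' @return data.frame: `id`, `gene`, `n_codons`, `nc`, `nc_class`, `icdi`,
#'   `cai`.
#' @export
bias_indices <- function(sequences, reference = human_reference_usage(),
                         convention = "wright") {
  w <- if (all(names(reference) %in% .RSCU_CODONS) &&
           length(reference) == length(.RSCU_CODONS)) reference
       else cai_weights(reference)
  rows <- lapply(sequences, function(s) {
    counts <- count_codons(s)
    data.frame(
      id = s$id, gene = s$gene, n_codons = length(s$codons),
      nc = effective_number_of_codons(counts, convention = convention),
      icdi = intrinsic_codon_bias_index(counts),
      cai = codon_adaptation_index(counts, w),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$nc_class <- nc_class(out$nc)
  out[, c("id", "gene", "n_codons", "nc", "nc_class", "icdi", "cai")]
}

#' RSCU table for a data set
#'
#' Mirrors a per-gene RSCU table: one row per codon of a degenerate family
#' with its amino acid, one column per sequence.
#'
#' @param sequences List of [codon_seq()] objects.
#' @return data.frame: `amino_acid`, `codon`, then one numeric column per
#'   sequence id.
#' @export
rscu_table <- function(sequences) {
  base <- data.frame(
    amino_acid = unname(.GENETIC_CODE[.RSCU_CODONS]),
    codon = .RSCU_CODONS,
    stringsAsFactors = FALSE
  )
  for (s in sequences) base[[s$id]] <- unname(rscu(count_codons(s)))
  base
}
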