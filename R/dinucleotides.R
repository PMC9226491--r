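# Dinucleotide odds ratios over the linear CDS and representation calls.

.DINUCLEOTIDES <- as.vector(t(outer(c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T"), paste0)))

#' Dinucleotide odds ratios of a coding sequence
#'
#' For each of the 16 dinucleotides XY, the odds ratio is the observed
#' dinucleotide frequency divided by the product of the mononucleotide
#' frequencies: `odds[XY] = f(XY) / (f(X) * f(Y))`. Dinucleotides are counted
#' over all `L - 1` overlapping windows of the linear sequence (across codon
#' junctions, non-circular); mononucleotide frequencies are taken over all
#' `L` nucleotides. The odds ratio is `NA` when `f(X) * f(Y) = 0`.
#'
#' @param x A [codon_seq()] or a nucleotide string of length >= 2.
#' @return Named numeric vector of 16 odds ratios, names AA..TT alphabetical.
#' @export
dinucleotide_odds <- function(x) {
  seqstr <- if (inherits(x, "codon_seq")) cds_string(x) else toupper(x)
  L <- nchar(seqstr)
  if (L < 2L) stop("sequence must be at least 2 nt for dinucleotide analysis")
  chars <- strsplit(seqstr, "", fixed = TRUE)[[1L]]
  di <- paste0(chars[-L], chars[-1L])
  f_di <- table(factor(di, levels = .DINUCLEOTIDES)) / (L - 1L)
  f_mono <- table(factor(chars, levels = c("A", "C", "G", "T"))) / L
  expected <- as.numeric(f_mono[substr(.DINUCLEOTIDES, 1L, 1L)]) *
    as.numeric(f_mono[substr(.DINUCLEOTIDES, 2L, 2L)])
  odds <- ifelse(expected > 0, as.numeric(f_di) / expected, NA_real_)
  stats::setNames(odds, .DINUCLEOTIDES)
}

#' Classify dinucleotide representation
#'
#' A dinucleotide is called underrepresented when its odds ratio is below
#' 0.78 and overrepresented when above 1.25 (strict inequalities; the
#' boundary values themselves are UNBIASED).
#'
#' @param odds Named numeric vector from [dinucleotide_odds()].
#' @param under,over Classification thresholds.
#' @return Character vector (same names) with values `UNDER`, `UNBIASED`,
#'   `OVER`, or `NA` where the odds ratio is `NA`.
#' @export
classify_dinucleotides <- function(odds, under = 0.78, over = 1.25) {
  cls <- ifelse(is.na(odds), NA_character_,
                ifelse(odds < under, "UNDER",
                       ifelse(odds > over, "OVER", "UNBIASED")))
  stats::setNames(cls, names(odds))
}

#' Dinucleotide odds-ratio table for a data set
#'
#' In `per-transcript` mode (the default) one row is produced per sequence.
#' In `per-gene` mode each gene's transcripts are concatenated in id order
#' and one row is produced per gene, mirroring a one-row-per-gene layout.
#'
#' @param sequences List of [codon_seq()] objects.
#' @param mode `"per-transcript"` or `"per-gene"`.
#' @return data.frame with an `id` column, 16 odds columns (AA..TT) and 16
#'   class columns (`class_AA`..`class_TT`).
#' @export
dinucleotide_table <- function(sequences, mode = c("per-transcript", "per-gene")) {
  mode <- match.arg(mode)
  units <- if (mode == "per-gene") {
    genes <- vapply(sequences, function(s)
      if (is.na(s$gene)) s$id else s$gene, character(1))
    ids <- vapply(sequences, function(s) s$id, character(1))
    lapply(split(seq_along(sequences), genes), function(idx) {
      idx <- idx[order(ids[idx])]
      list(id = genes[idx[1L]],
           seqstr = paste(vapply(sequences[idx], cds_string, character(1)),
                          collapse = ""))
    })
  } else {
    lapply(sequences, function(s) list(id = s$id, seqstr = cds_string(s)))
  }
  rows <- lapply(units, function(u) {
    odds <- dinucleotide_odds(u$seqstr)
    cls <- classify_dinucleotides(odds)
    names(cls) <- paste0("class_", names(cls))
    cbind(data.frame(id = u$id, stringsAsFactors = FALSE),
          as.data.frame(as.list(odds)),
          as.data.frame(as.list(cls), stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
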