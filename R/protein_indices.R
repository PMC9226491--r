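# Translation and protein physicochemical indices (GRAVY, aromaticity,
# aliphatic index, pI, instability index, charge-class percentages).

.AA_LETTERS <- sort(unique(unname(.GENETIC_CODE[.GENETIC_CODE != "*"])))

# resource tables are loaded once per session
.protein_tables <- new.env(parent = emptyenv())

.extdata <- function(file) {
  system.file("extdata", file, package = "cubtools", mustWork = TRUE)
}

.hydropathy <- function() {
  if (is.null(.protein_tables$kd)) {
    tab <- utils::read.delim(.extdata("kyte_doolittle.tsv"), comment.char = "#",
                             stringsAsFactors = FALSE)
    .protein_tables$kd <- stats::setNames(tab$hydropathy, tab$aa)
  }
  .protein_tables$kd
}

.diwv <- function() {
  if (is.null(.protein_tables$diwv)) {
    tab <- utils::read.delim(.extdata("diwv_instability.tsv"),
                             comment.char = "#", stringsAsFactors = FALSE,
                             check.names = FALSE)
    m <- as.matrix(tab[, -1L])
    rownames(m) <- tab$aa
    .protein_tables$diwv <- m
  }
  .protein_tables$diwv
}

.pka_default <- function() {
  if (is.null(.protein_tables$pka)) {
    .protein_tables$pka <- utils::read.delim(.extdata("pka_isoelectric.tsv"),
                                             comment.char = "#",
                                             stringsAsFactors = FALSE)
  }
  .protein_tables$pka
}

.check_peptide <- function(peptide, min_len = 1L) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  peptide <- toupper(peptide)
  if (nchar(peptide) < min_len) {
    stop("peptide must have at least ", min_len, " residue(s)")
  }
  chars <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  if (any(!(chars %in% .AA_LETTERS))) {
    stop("non-standard residue(s): ",
         paste(unique(chars[!(chars %in% .AA_LETTERS)]), collapse = ", "))
  }
  chars
}

#' Translate a coding sequence
#'
#' One residue per codon under the standard genetic code (stops are excluded
#' upstream by validation), so peptide length equals the codon count.
#'
#' @param cds A [codon_seq()].
#' @return Single amino-acid string over the 20 standard letters.
#' @export
translate_cds <- function(cds) {
  stopifnot(inherits(cds, "codon_seq"))
  paste(.GENETIC_CODE[cds$codons], collapse = "")
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues; typically in [-2, 2],
#' positive for more hydrophobic proteins.
#'
#' @param peptide Amino-acid string.
#' @return GRAVY value.
#' @export
gravy <- function(peptide) {
  chars <- .check_peptide(peptide)
  mean(.hydropathy()[chars])
}

#' Aromaticity
#'
#' Fraction of aromatic residues (Phe, Tyr, Trp), reported in [0, 1].
#'
#' @param peptide Amino-acid string.
#' @return Fraction of F + Y + W.
#' @export
aromaticity <- function(peptide) {
  chars <- .check_peptide(peptide)
  mean(chars %in% c("F", "Y", "W"))
}

#' Aliphatic index
#'
#' Relative volume occupied by aliphatic side chains:
#' `X(Ala) + 2.9 X(Val) + 3.9 (X(Ile) + X(Leu))` with X in mole percent.
#'
#' @param peptide Amino-acid string.
#' @return Aliphatic index (>= 0; 100 for poly-Ala, 290 for poly-Val).
#' @export
aliphatic_index <- function(peptide) {
  chars <- .check_peptide(peptide)
  x <- 100 * c(A = mean(chars == "A"), V = mean(chars == "V"),
               I = mean(chars == "I"), L = mean(chars == "L"))
  x[["A"]] + 2.9 * x[["V"]] + 3.9 * (x[["I"]] + x[["L"]])
}

.net_charge <- function(ph, counts, pka) {
  charge <- 0
  for (i in seq_len(nrow(pka))) {
    n <- switch(pka$site[i], Nterm = 1, Cterm = 1,
                counts[[pka$site[i]]] %||% 0)
    if (n == 0) next
    charge <- charge + if (pka$charge[i] > 0) {
      n / (1 + 10^(ph - pka$pka[i]))
    } else {
      -n / (1 + 10^(pka$pka[i] - ph))
    }
  }
  charge
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Isoelectric point
#'
#' The pH at which the Henderson-Hasselbalch net charge of the peptide (free
#' N- and C-termini plus the ionisable side chains D, E, C, Y, H, K, R) is
#' zero, found by bisection on [0, 14] to a residual `|charge| < tol`. The
#' bundled pKa set follows Bjellqvist/Expasy; an alternative set can be
#' supplied as a TSV of the same layout.
#'
#' @param peptide Amino-acid string.
#' @param pka Optional pKa table: a data.frame with columns `site`, `pka`,
#'   `charge`, or a path to such a TSV.
#' @param tol Charge tolerance for the bisection.
#' @return pH of zero net charge, in [0, 14].
#' @export
isoelectric_point <- function(peptide, pka = NULL, tol = 1e-4) {
  chars <- .check_peptide(peptide)
  if (is.null(pka)) {
    pka <- .pka_default()
  } else if (is.character(pka)) {
    pka <- utils::read.delim(pka, comment.char = "#", stringsAsFactors = FALSE)
  }
  counts <- as.list(table(chars))
  lo <- 0; hi <- 14
  # net charge decreases monotonically with pH; termini guarantee a crossing
  repeat {
    mid <- (lo + hi) / 2
    q <- .net_charge(mid, counts, pka)
    if (abs(q) < tol || (hi - lo) < 1e-12) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Instability index
#'
#' `(10 / L) * sum` of dipeptide instability weights (DIWV) over the L - 1
#' consecutive dipeptides. Values of 40 and above conventionally flag a
#' protein as unstable.
#'
#' @param peptide Amino-acid string of length >= 2.
#' @return Instability index value.
#' @export
instability_index <- function(peptide) {
  chars <- .check_peptide(peptide, min_len = 2L)
  m <- .diwv()
  L <- length(chars)
  idx <- cbind(match(chars[-L], rownames(m)), match(chars[-1L], colnames(m)))
  10 / L * sum(m[idx])
}

#' Charge-class and hydrophobic percentages
#'
#' Acidic = D, E; basic = R, K, H (histidine counted basic); neutral = the
#' remainder; hydrophobic = A, V, L, I, P, F, M, W (a documented convention;
#' tools differ on this set). All reported as percent of length, with
#' acidic + basic + neutral = 100.
#'
#' @param peptide Amino-acid string.
#' @return Named numeric vector: `pct_acidic`, `pct_basic`, `pct_neutral`,
#'   `pct_hydrophobic`.
#' @export
charge_classes <- function(peptide) {
  chars <- .check_peptide(peptide)
  acidic <- mean(chars %in% c("D", "E"))
  basic <- mean(chars %in% c("R", "K", "H"))
  c(
    pct_acidic = 100 * acidic,
    pct_basic = 100 * basic,
    pct_neutral = 100 * (1 - acidic - basic),
    pct_hydrophobic = 100 * mean(chars %in% c("A", "V", "L", "I",
                                              "P", "F", "M", "W"))
  )
}

#' Per-sequence protein index table
#'
#' Translates each coding sequence and computes all protein indices.
#'
#' @param sequences List of [codon_seq()] objects.
#' @return data.frame: `id`, `length`, `gravy`, `aromaticity`,
#'   `aliphatic_index`, `pi`, `instability`, `unstable` (instability >= 40),
#'   `pct_acidic`, `pct_basic`, `pct_neutral`, `pct_hydrophobic`.
#' @export
protein_table <- function(sequences) {
  rows <- lapply(sequences, function(s) {
    pep <- translate_cds(s)
    cc <- charge_classes(pep)
    inst <- instability_index(pep)
    data.frame(
      id = s$id, length = nchar(pep),
      gravy = gravy(pep), aromaticity = aromaticity(pep),
      aliphatic_index = aliphatic_index(pep),
      pi = isoelectric_point(pep),
      instability = inst, unstable = inst >= 40,
      pct_acidic = cc[["pct_acidic"]], pct_basic = cc[["pct_basic"]],
      pct_neutral = cc[["pct_neutral"]],
      pct_hydrophobic = cc[["pct_hydrophobic"]],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
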