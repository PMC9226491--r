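# Standard genetic code and synonymous-family structure used throughout.

.GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.SENSE_CODONS <- sort(names(.GENETIC_CODE)[.GENETIC_CODE != "*"])

# amino acid -> sorted synonymous codon set (20 families)
.FAMILIES <- split(.SENSE_CODONS, .GENETIC_CODE[.SENSE_CODONS])

# degeneracy per amino acid
.DEGENERACY <- vapply(.FAMILIES, length, integer(1))

# amino acids with >= 2 synonymous codons (18 of 20; Met and Trp excluded)
.DEGENERATE_AAS <- names(.DEGENERACY)[.DEGENERACY >= 2]

# the 59 codons of degenerate families (sense minus ATG and TGG)
.RSCU_CODONS <- sort(unlist(.FAMILIES[.DEGENERATE_AAS], use.names = FALSE))

#' Stop codons of the standard genetic code
#' @return Character vector `c("TAA", "TAG", "TGA")`.
#' @export
stop_codons <- function() .STOP_CODONS

#' The 61 sense codons of the standard genetic code
#' @return Character vector of sense codons in alphabetical order.
#' @export
sense_codons <- function() .SENSE_CODONS

#' Synonymous codon families
#'
#' The standard genetic code partitions the 61 sense codons into 20 families,
#' one per amino acid. Nine amino acids are 2-fold degenerate, isoleucine is
#' 3-fold, five are 4-fold and three (Leu, Ser, Arg) are 6-fold; 6-fold
#' families are kept intact rather than split 2+4, matching the CodonW
#' convention used for the effective number of codons.
#'
#' @return Named list mapping one-letter amino-acid codes to their codon sets.
#' @export
codon_families <- function() .FAMILIES

#' Codons entering RSCU and PCA vectors
#'
#' The 59 codons belonging to degenerate families: all sense codons except
#' ATG (Met) and TGG (Trp), whose usage carries no synonymous choice.
#'
#' @return Character vector of 59 codons, alphabetical.
#' @export
rscu_codons <- function() .RSCU_CODONS
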