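# Fixtures are built in code; no stored data files.

# "ATGAAA" or "ATG AAA" -> codon_seq
make_cds <- function(nt, id = "seq1", gene = NA_character_) {
  nt <- gsub("[ \n]", "", nt)
  n <- nchar(nt) %/% 3L
  codon_seq(id, substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n)),
            gene = gene)
}

# codon usage table with equal counts within every synonymous family
uniform_counts <- function(per_codon = 12L) {
  u <- stats::setNames(rep(0L, 61L), sense_codons())
  for (fam in codon_families()) u[fam] <- per_codon
  u
}

# all counts of each family on its first codon
single_codon_counts <- function(per_family = 24L) {
  u <- stats::setNames(rep(0L, 61L), sense_codons())
  for (fam in codon_families()) u[fam[1L]] <- per_family
  u
}

# random nucleotide string (iid uniform, not necessarily a valid CDS)
random_nt <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_peptide <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n, replace = TRUE),
        collapse = "")
}

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
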