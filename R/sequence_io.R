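# FASTA input, coding-sequence admission rules and dataset summary.

#' Read a multi-record FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()] that preserves record
#' order, uppercases residues and splits the header into an id (first
#' whitespace-delimited token) and a free-text description.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return A data.frame with columns `id`, `description`, `residues`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  head_lines <- readLines(path, n = 100L, warn = FALSE)
  nonblank <- which(nzchar(trimws(head_lines)))
  if (length(nonblank) == 0L) stop("malformed FASTA: file is empty: ", path)
  first <- head_lines[nonblank[1L]]
  if (!startsWith(first, ">")) {
    stop("malformed FASTA: sequence before first header at line ",
         nonblank[1L], " of ", path)
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  if (any(!nzchar(id))) stop("malformed FASTA: empty record id in ", path)
  description <- sub("^\\S+\\s*", "", headers)
  data.frame(
    id = id,
    description = description,
    residues = toupper(as.character(set)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Write sequences to FASTA
#'
#' @param x A data.frame with columns `id`, `residues` (and optionally
#'   `description`), or a list of coding sequences from [validate_fasta()] or
#'   the synthetic generators.
#' @param path Output path.
#' @param width Line width for wrapping; default 60.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- data.frame(
      id = vapply(x, function(s) s$id, character(1)),
      description = "",
      residues = vapply(x, cds_string, character(1)),
      stringsAsFactors = FALSE
    )
  }
  headers <- x$id
  if (!is.null(x$description)) {
    has_desc <- nzchar(x$description)
    headers[has_desc] <- paste(x$id[has_desc], x$description[has_desc])
  }
  set <- Biostrings::BStringSet(x$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a coding sequence object
#'
#' @param id Sequence identifier.
#' @param codons Character vector of 3-mers over A/C/G/T, no stop codons.
#' @param gene Optional gene symbol.
#' @return An object of class `codon_seq` with fields `id`, `gene`, `codons`.
#' @export
codon_seq <- function(id, codons, gene = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(codons), length(codons) >= 1L)
  if (!all(codons %in% .SENSE_CODONS)) {
    bad <- unique(codons[!(codons %in% .SENSE_CODONS)])
    stop("invalid codon(s) in '", id, "': ", paste(bad, collapse = ", "))
  }
  structure(list(id = id, gene = gene, codons = codons), class = "codon_seq")
}

#' @export
print.codon_seq <- function(x, ...) {
  cat(sprintf("<codon_seq> %s%s: %d codons (%d nt)\n", x$id,
              if (is.na(x$gene)) "" else paste0(" [", x$gene, "]"),
              length(x$codons), 3L * length(x$codons)))
  invisible(x)
}

#' Nucleotide string of a coding sequence
#' @param cds A `codon_seq`.
#' @return Single concatenated nucleotide string.
#' @export
cds_string <- function(cds) paste(cds$codons, collapse = "")

#' Length of a coding sequence in nucleotides
#' @param cds A `codon_seq`.
#' @return Integer, `3 * number of codons`.
#' @export
cds_length_nt <- function(cds) 3L * length(cds$codons)

#' Validate one sequence as an in-frame coding sequence
#'
#' Admission rules: the residue string must be non-empty, a multiple of three,
#' contain no base other than A, C, G or T (ambiguity codes such as R, Y or B
#' are rejected, as is the RNA letter U), and contain no internal stop codon
#' (TAA, TAG, TGA). A terminal stop codon is removed before the checks when
#' `strip_terminal_stop = TRUE` (the default), so stop codons never enter any
#' downstream statistic.
#'
#' @param residues Nucleotide string (case-insensitive).
#' @param id Sequence identifier used in the report.
#' @param strip_terminal_stop Remove a final TAA/TAG/TGA before validation.
#' @param gene Optional gene symbol attached to the accepted sequence.
#' @return A list with elements `cds` (a [codon_seq()] or `NULL`) and
#'   `report`: a list with `id`, `accepted`, and `reasons` (character vector
#'   of rejection codes among `NOT_MULTIPLE_OF_3`, `AMBIGUOUS_BASE`,
#'   `INTERNAL_STOP`, `EMPTY`; empty iff accepted).
#' @export
validate_cds <- function(residues, id = "seq", strip_terminal_stop = TRUE,
                         gene = NA_character_) {
  res <- toupper(residues)
  reasons <- character(0)
  if (nchar(res) == 0L) {
    return(list(cds = NULL,
                report = list(id = id, accepted = FALSE, reasons = "EMPTY")))
  }
  chars <- strsplit(res, "", fixed = TRUE)[[1L]]
  if (any(!(chars %in% c("A", "C", "G", "T")))) {
    reasons <- c(reasons, "AMBIGUOUS_BASE")
  }
  codons <- NULL
  if (nchar(res) %% 3L != 0L) {
    reasons <- c(reasons, "NOT_MULTIPLE_OF_3")
  } else {
    n <- nchar(res) %/% 3L
    codons <- substring(res, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    if (strip_terminal_stop && codons[n] %in% .STOP_CODONS) {
      codons <- codons[-n]
    }
    if (length(codons) == 0L) {
      reasons <- c(reasons, "EMPTY")
    } else if (any(codons %in% .STOP_CODONS)) {
      reasons <- c(reasons, "INTERNAL_STOP")
    }
  }
  accepted <- length(reasons) == 0L
  cds <- if (accepted) codon_seq(id, codons, gene = gene) else NULL
  list(cds = cds, report = list(id = id, accepted = accepted, reasons = reasons))
}

#' Read a two-column id-to-gene mapping
#' @param path TSV with columns `id`, `gene` (no header required; `#` lines
#'   are skipped).
#' @return Named character vector mapping id to gene symbol.
#' @export
read_gene_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("gene map must have two columns (id, gene)")
  if (identical(tolower(tab[1L, 1L]), "id")) tab <- tab[-1L, , drop = FALSE]
  stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' Validate every record of a FASTA data set
#'
#' Applies [validate_cds()] to each record. Sequence ids must be unique;
#' duplicates are a hard error to prevent silent double counting. The gene
#' symbol is taken from `gene_map` when supplied, otherwise from the first
#' token of the record description; it is never guessed from the id.
#'
#' @param records Data.frame from [read_fasta()] (columns `id`, `description`,
#'   `residues`).
#' @param strip_terminal_stop Passed to [validate_cds()].
#' @param gene_map Optional named character vector (id -> gene) or path to a
#'   two-column TSV.
#' @return List with `sequences` (list of accepted [codon_seq()] objects) and
#'   `report` (data.frame: `id`, `accepted`, `reasons` semicolon-joined).
#' @export
validate_fasta <- function(records, strip_terminal_stop = TRUE,
                           gene_map = NULL) {
  if (anyDuplicated(records$id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  }
  if (is.character(gene_map) && length(gene_map) == 1L && file.exists(gene_map)) {
    gene_map <- read_gene_map(gene_map)
  }
  out <- vector("list", nrow(records))
  rep_rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    gene <- NA_character_
    if (!is.null(gene_map) && records$id[i] %in% names(gene_map)) {
      gene <- unname(gene_map[records$id[i]])
    } else if (!is.null(records$description) && nzchar(records$description[i])) {
      gene <- sub("\\s.*$", "", records$description[i])
    }
    v <- validate_cds(records$residues[i], id = records$id[i],
                      strip_terminal_stop = strip_terminal_stop, gene = gene)
    out[[i]] <- v$cds
    rep_rows[[i]] <- data.frame(
      id = v$report$id, accepted = v$report$accepted,
      reasons = paste(v$report$reasons, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  list(
    sequences = Filter(Negate(is.null), out),
    report = do.call(rbind, rep_rows)
  )
}

#' Summarize a validated data set
#'
#' @param sequences List of [codon_seq()] objects.
#' @return List with `n_sequences`, `total_nt`, `total_codons`
#'   (`total_codons == total_nt / 3` exactly).
#' @export
summarize_dataset <- function(sequences) {
  n_codons <- vapply(sequences, function(s) length(s$codons), integer(1))
  list(
    n_sequences = length(sequences),
    total_nt = sum(3L * n_codons),
    total_codons = sum(n_codons)
  )
}
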