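# One-call orchestration writing the full analysis surface as plain text.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the full codon-usage report on a FASTA file
#'
#' Executes every analysis stage in dependency order: validation,
#' composition, dinucleotide odds ratios, RSCU, rare codons, bias indices
#' (Nc, ICDI, CAI), PR2 parity, neutrality regression, ENc-GC3 curve
#' deviations, PCA on RSCU vectors, protein indices and a correlation table,
#' and writes each as a TSV (plus `neutrality.json`, `summary.json` and
#' `run_config.json`) into `out_dir`. The pipeline is a pure function of its
#' inputs and options, so repeated runs produce byte-identical bundles.
#'
#' @param fasta Path to the input FASTA of coding sequences.
#' @param out_dir Output directory (created if needed).
#' @param reference Reference codon usage: path to a TSV or a named vector;
#'   default the bundled human table.
#' @param gene_map Optional id-to-gene TSV path or named vector.
#' @param strip_terminal_stop Passed to validation.
#' @param transcript_mode `"per-transcript"` or `"per-gene"` for the
#'   dinucleotide table.
#' @param rare_threshold Rare-codon frequency threshold (fraction).
#' @param seed Recorded in `run_config.json` (no stage is stochastic).
#' @return Invisibly, a list with the accepted sequences, the key result
#'   objects and the paths written.
#' @export
run_report <- function(fasta, out_dir, reference = NULL, gene_map = NULL,
                       strip_terminal_stop = TRUE,
                       transcript_mode = c("per-transcript", "per-gene"),
                       rare_threshold = 0.01, seed = NULL) {
  transcript_mode <- match.arg(transcript_mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- if (is.null(reference)) human_reference_usage()
         else if (is.character(reference)) read_reference_usage(reference)
         else reference

  records <- read_fasta(fasta)
  val <- validate_fasta(records, strip_terminal_stop = strip_terminal_stop,
                        gene_map = gene_map)
  .write_tsv(val$report, file.path(out_dir, "validation.tsv"))
  seqs <- val$sequences
  if (length(seqs) == 0L) stop("no sequence passed validation")
  message(sprintf("validate: %d/%d sequences accepted",
                  length(seqs), nrow(records)))

  comp <- composition_table(seqs)
  .write_tsv(comp, file.path(out_dir, "composition.tsv"))
  message(sprintf("composition: %d rows", nrow(comp)))

  dints <- dinucleotide_table(seqs, mode = transcript_mode)
  .write_tsv(dints, file.path(out_dir, "dinucleotides.tsv"))
  message(sprintf("dinucleotides (%s): %d rows", transcript_mode, nrow(dints)))

  rscu_tab <- rscu_table(seqs)
  .write_tsv(rscu_tab, file.path(out_dir, "rscu.tsv"))

  pooled <- count_codons(seqs)
  rare <- rare_codons(pooled, threshold = rare_threshold)

  idx <- bias_indices(seqs, reference = ref)
  .write_tsv(idx, file.path(out_dir, "indices.tsv"))
  message(sprintf("indices: %d rows", nrow(idx)))

  par_pts <- t(vapply(seqs, parity_point, numeric(2)))
  parity <- data.frame(id = idx$id, x = par_pts[, "x"], y = par_pts[, "y"],
                       stringsAsFactors = FALSE)
  .write_tsv(parity, file.path(out_dir, "parity.tsv"))

  neut <- NULL
  if (nrow(comp) >= 3L && stats::var(comp$GC3) > 0) {
    neut <- neutrality_fit(comp$GC3, comp$GC12)
    .write_json(neut, file.path(out_dir, "neutrality.json"))
  }

  enc_tab <- data.frame(
    id = idx$id, gc3 = comp$GC3, nc = idx$nc,
    expected = expected_enc(comp$GC3 / 100),
    deviation = enc_gc3_deviation(idx$nc, comp$GC3 / 100),
    stringsAsFactors = FALSE
  )
  .write_tsv(enc_tab, file.path(out_dir, "enc_gc3.tsv"))

  if (length(seqs) >= 3L) {
    pca <- pca_rscu(seqs)
    .write_tsv(data.frame(id = rownames(pca$scores), pca$scores,
                          stringsAsFactors = FALSE),
               file.path(out_dir, "pca_scores.tsv"))
    .write_tsv(data.frame(codon = rownames(pca$loadings), pca$loadings,
                          stringsAsFactors = FALSE),
               file.path(out_dir, "pca_loadings.tsv"))
    .write_tsv(data.frame(component = seq_along(pca$explained_pct),
                          explained_pct = pca$explained_pct),
               file.path(out_dir, "pca_scree.tsv"))
    message(sprintf("pca: PC1 %.2f%%, PC2 %.2f%%",
                    pca$explained_pct[1L], pca$explained_pct[2L]))
  }

  prot <- protein_table(seqs)
  .write_tsv(prot, file.path(out_dir, "protein.tsv"))

  corr <- .correlation_table(comp, idx, prot)
  .write_tsv(corr, file.path(out_dir, "correlations.tsv"))

  summ <- summarize_dataset(seqs)
  nc_tab <- table(factor(idx$nc_class,
                         levels = c("HIGH_BIAS", "MODERATE", "LOW")))
  summary_json <- list(
    n_sequences = summ$n_sequences,
    total_nt = summ$total_nt,
    total_codons = summ$total_codons,
    nc_class_pct = as.list(100 * as.numeric(nc_tab) / sum(nc_tab)) |>
      stats::setNames(names(nc_tab)),
    parity_mean = list(x = mean(parity$x, na.rm = TRUE),
                       y = mean(parity$y, na.rm = TRUE)),
    parity_sd = list(x = stats::sd(parity$x, na.rm = TRUE),
                     y = stats::sd(parity$y, na.rm = TRUE)),
    rare_codons = rare,
    cai_range = list(min = min(idx$cai), max = max(idx$cai)),
    nc_range = list(min = min(idx$nc), max = max(idx$nc)),
    icdi_mean = mean(idx$icdi)
  )
  .write_json(summary_json, file.path(out_dir, "summary.json"))

  .write_json(list(
    fasta = basename(fasta),
    strip_terminal_stop = strip_terminal_stop,
    transcript_mode = transcript_mode,
    rare_threshold = rare_threshold,
    seed = seed,
    reference = if (is.null(reference)) "bundled human (Kazusa/CUTG)"
                else if (is.character(reference)) basename(reference)
                else "user vector"
  ), file.path(out_dir, "run_config.json"))

  invisible(list(sequences = seqs, summary = summary_json, indices = idx,
                 composition = comp, neutrality = neut, out_dir = out_dir))
}

# correlations between the variable families this analysis pairs:
# Nc vs composition (overall and positional), Nc vs protein indices,
# CAI vs third-position content
.correlation_table <- function(comp, idx, prot) {
  comp_vars <- c("A", "T", "C", "G",
                 paste0(rep(c("A", "C", "G", "T"), 3L), rep(1:3, each = 4L)),
                 "GC", "GC3", "GC12")
  prot_vars <- c("gravy", "aromaticity", "aliphatic_index", "pi",
                 "instability", "pct_acidic", "pct_basic", "pct_neutral",
                 "pct_hydrophobic")
  pairs <- rbind(
    data.frame(x = "nc", y = comp_vars, frame_y = "comp"),
    data.frame(x = "nc", y = prot_vars, frame_y = "prot"),
    data.frame(x = "cai", y = c("A3", "T3", "G3", "C3"), frame_y = "comp")
  )
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    xv <- idx[[pairs$x[i]]]
    yv <- (if (pairs$frame_y[i] == "comp") comp else prot)[[pairs$y[i]]]
    res <- tryCatch(correlate(xv, yv), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(var_x = pairs$x[i], var_y = pairs$y[i], method = res$method,
               r = res$r, p = res$p, n = res$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    out <- data.frame(var_x = character(0), var_y = character(0),
                      method = character(0), r = numeric(0), p = numeric(0),
                      n = integer(0))
  }
  out
}
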