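# Small in-code fixtures shared across test files.

fixture_annotation <- function() {
  genes <- data.frame(
    gene_id = c("GENE1", "GENE2", "CTAG1", "LNC1"),
    biotype = c("protein_coding", "protein_coding", "protein_coding", "lncRNA"),
    is_cta = c(FALSE, FALSE, TRUE, FALSE),
    chrom = "chr1", start = c(0L, 300L, 600L, 900L),
    end = c(200L, 500L, 800L, 1100L),
    strand = c("+", "-", "+", "+"), stringsAsFactors = FALSE)
  eres <- data.frame(
    locus_id = c("L1HS_1", "ALU_1", "ERV_1"),
    chrom = "chr2", start = c(100L, 400L, 700L),
    end = c(300L, 600L, 900L), strand = c("+", "+", "-"),
    ere_class = c("LINE", "SINE", "LTR"),
    family = c("L1", "Alu", "ERVL"), stringsAsFactors = FALSE)
  list(genes = genes, eres = eres)
}

# Peptide table with explicit detection patterns; intensity 1000 where
# detected, NA where not.
fixture_peptides <- function(patterns_treated, patterns_control,
                             biotype = NULL) {
  n <- nrow(patterns_treated)
  if (is.null(biotype)) biotype <- rep("canonical", n)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- vapply(seq_len(n), function(i)
    paste(aa[((i + 0:8) %% 20) + 1], collapse = ""), character(1))
  tab <- data.frame(sequence = seqs, source_id = paste0("P", seq_len(n)),
                    biotype = biotype, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(patterns_treated)))
    tab[[paste0("trt_", j)]] <- ifelse(patterns_treated[, j] == 1, 1000, NA)
  for (j in seq_len(ncol(patterns_control)))
    tab[[paste0("ctrl_", j)]] <- ifelse(patterns_control[, j] == 1, 1000, NA)
  class(tab) <- c("peptide_table", "data.frame")
  tab
}

quick_config <- function(...) {
  # desk-scale config for fast unit tests
  defaults <- list(n_genes = 300, n_ere = 300, n_cta = 20, n_proteins = 60,
                   n_peptides = 300, cohort_n = 60, n_cohort_genes = 150,
                   n_cohort_ere = 40, n_autophagy_genes = 20)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
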