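#' ERE-derived fraction of the detected immunopeptidome
#'
#' Per condition, the fraction of detected peptides whose biotype is ERE,
#' plus the ratio between two conditions (first / second).
#'
#' @param peptides Peptide table with `biotype` and intensity columns.
#' @param condition_cols Named list of length 2 mapping condition name to
#'   intensity column names; a peptide counts as detected in a condition
#'   when it is detected in at least one of its replicates.
#' @return List with `fractions` (named, per condition), `counts`
#'   (ERE / total detected per condition) and `ratio`.
#' @export
ere_map_fraction <- function(peptides, condition_cols) {
  stopifnot(length(condition_cols) == 2L)
  res <- lapply(condition_cols, function(cols) {
    det <- rowSums(detection_matrix(peptides, cols)) > 0
    n_det <- sum(det)
    if (n_det == 0L) stop("no detected peptides in a condition")
    n_ere <- sum(det & peptides$biotype == "ERE")
    c(ere = n_ere, total = n_det, fraction = n_ere / n_det)
  })
  fr <- vapply(res, `[[`, numeric(1), "fraction")
  ratio <- if (fr[2] == 0) {
    if (fr[1] == 0) 0 else Inf
  } else fr[1] / fr[2]
  if (all(fr == 0)) ratio <- 0
  list(fractions = fr,
       counts = do.call(rbind, res),
       ratio = unname(ratio))
}

#' Run the full synthetic pipeline end to end
#'
#' Simulates an experiment, proteome, immunopeptidome and cohort from one
#' configuration, then runs every analysis stage: transcript and peptide
#' differential tests, direction summaries, common-element intersection
#' across simulated cell lines, ERE class enrichment, peptide feature
#' statistics, candidate-database integration, cohort ssGSEA correlation
#' and stratified pre-ranked GSEA. Identical config and seed give identical
#' reports.
#'
#' @param config A [sim_config()]; its `seed` drives every stage.
#' @param out_dir Optional directory to write stage tables and the report
#'   (JSON + text). NULL keeps everything in memory.
#' @param tau_lfc,tau_fdr Differential calling thresholds.
#' @param n_perm Permutations for the stratified GSEA.
#' @return List of class `ereflow_report`; element `summary` holds the
#'   headline numbers, the other elements the stage tables.
#' @export
run_end_to_end <- function(config = sim_config(), out_dir = NULL,
                           tau_lfc = 1, tau_fdr = 0.05, n_perm = 500) {
  if (tau_fdr <= 0 || tau_fdr > 1)
    stop("tau_fdr must lie in (0, 1]")
  exp1 <- simulate_experiment(config)
  prot <- simulate_proteome(config)
  pep <- simulate_immunopeptidome(config, prot, exp1)
  cohort <- simulate_cohort(config)

  # transcript differential expression
  lc <- log2_norm(exp1$counts)
  deg <- moderated_test(lc, exp1$counts$groups, reference = "control")
  deg <- call_de(deg, tau_lfc, tau_fdr)
  up_ere <- deg$feature_id[deg$direction == "up" &
                             deg$feature_id %in% exp1$annotation$eres$locus_id]
  enr <- if (length(up_ere) > 0)
    class_enrichment(up_ere, exp1$annotation$eres) else NULL

  # peptide differential abundance
  nr <- config$n_reps_per_group
  cond_cols <- list(control = paste0("ctrl_", seq_len(nr)),
                    treated = paste0("trt_", seq_len(nr)))
  imp <- impute_peptides(pep$peptides, cond_cols)
  grp <- rep(names(cond_cols), vapply(cond_cols, length, integer(1)))
  dem <- moderated_test(log2(imp$intensities + 1), grp,
                        reference = "control")
  dem <- call_de(dem, tau_lfc, tau_fdr)
  dem$source_id <- imp$peptides$source_id[match(dem$feature_id,
                                                imp$peptides$sequence)]
  dem$biotype <- imp$peptides$biotype[match(dem$feature_id,
                                            imp$peptides$sequence)]
  specific <- call_condition_specific(pep$peptides,
                                      cond_cols$treated, cond_cols$control)
  emf <- ere_map_fraction(pep$peptides,
                          list(treated = cond_cols$treated,
                               control = cond_cols$control))

  # peptide feature battery
  up_seq <- dem$feature_id[dem$direction == "up"]
  down_seq <- dem$feature_id[dem$direction == "down"]
  feat <- list(
    gravy_up = if (length(up_seq)) mean(gravy(up_seq)) else NA_real_,
    gravy_down = if (length(down_seq)) mean(gravy(down_seq)) else NA_real_,
    cterm = if (length(up_seq) && length(down_seq))
      cterm_association(up_seq, down_seq) else NULL)
  prot_dem <- dem[dem$source_id %in% names(prot$proteins), ]
  n_up_by_prot <- table(prot_dem$source_id[prot_dem$direction == "up"])
  comp <- tryCatch(
    composition_correlation(prot$proteins,
                            stats::setNames(as.integer(n_up_by_prot),
                                            names(n_up_by_prot))),
    error = function(e) NULL)

  # cohort: ERE metrics, ssGSEA correlation, stratified GSEA
  metrics <- ere_metrics(cohort$expression, cohort$ere_ids)
  gene_universe <- setdiff(rownames(cohort$expression), cohort$ere_ids)
  sets <- random_set_collection(gene_universe, n_sets = 100, set_size = 40,
                                seed = stage_seed(config$seed, 5L))
  sets[["AUTOPHAGY_SET"]] <- cohort$autophagy_genes
  es <- ssgsea_matrix(cohort$expression[gene_universe, ], sets)
  E_p <- cumulative_ere_cpm(cohort$expression, cohort$ere_ids)
  corr <- correlate_sets(es, E_p, tail = "negative")
  strat <- stratify(cohort$expression, cohort$ere_ids)
  gsea_res <- stratum_gsea(cohort, strat, sets[["AUTOPHAGY_SET"]],
                           stratum = "high", n_perm = n_perm,
                           seed = stage_seed(config$seed, 6L))

  auto_row <- corr[corr$set == "AUTOPHAGY_SET", ]
  summary <- list(
    n_deg_up = sum(deg$direction == "up"),
    n_deg_down = sum(deg$direction == "down"),
    deg_up_fraction = attr(deg, "n_up") /
      max(1, attr(deg, "n_up") + attr(deg, "n_down")),
    n_dem_up = sum(dem$direction == "up"),
    n_dem_down = sum(dem$direction == "down"),
    n_condition_specific = sum(specific),
    ere_map_fraction = as.list(emf$fractions),
    ere_map_ratio = emf$ratio,
    class_enrichment_ratio = if (!is.null(enr))
      stats::setNames(as.list(enr$ratio), enr$ere_class) else NULL,
    gravy_up = feat$gravy_up, gravy_down = feat$gravy_down,
    autophagy_spearman = auto_row$rho,
    autophagy_top_decile = isTRUE(auto_row$top_decile),
    stratified_nes = gsea_res$NES,
    median_split_sizes = as.list(attr(median_split(E_p), "sizes")),
    seed = config$seed)

  report <- structure(
    list(summary = summary, deg = deg, dem = dem,
         class_enrichment = enr, composition_correlation = comp,
         ere_metrics = metrics, set_correlation = corr,
         strata = strat, gsea = gsea_res, config = config),
    class = "ereflow_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Random gene-set collection
#' @param universe Gene ids to draw from.
#' @param n_sets,set_size Collection dimensions.
#' @param seed Integer seed.
#' @export
random_set_collection <- function(universe, n_sets = 100, set_size = 40,
                                  seed = 1) {
  with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i)
      sample(universe, min(set_size, length(universe))))
    names(sets) <- sprintf("RANDOM_SET_%03d", seq_len(n_sets))
    sets
  })
}

#' Pre-ranked GSEA of a gene set within one ERE stratum
#'
#' Ranks genes by the moderated t of CD8-high vs CD8-low samples within the
#' requested ERE stratum and runs [gsea_preranked()] on that ranking.
#'
#' @param cohort A `cohort_frame`.
#' @param strata Output of [stratify()].
#' @param gene_set Gene ids to test.
#' @param stratum `"high"` or `"low"` (the ERE axis).
#' @param n_perm,seed Permutation settings.
#' @return [gsea_preranked()] result.
#' @export
stratum_gsea <- function(cohort, strata, gene_set, stratum = "high",
                         n_perm = 500, seed = 1) {
  sel <- strata$ere_label == stratum
  sub <- cohort$expression[, sel, drop = FALSE]
  cd8 <- strata$cd8_label[sel]
  genes <- setdiff(rownames(sub), cohort$ere_ids)
  ranking <- moderated_test(log2(sub[genes, , drop = FALSE] + 1), cd8,
                            reference = "low")
  stat <- stats::setNames(ranking$t, ranking$feature_id)
  gsea_preranked(stat, gene_set, n_perm = n_perm, seed = seed)
}

#' Write a pipeline report
#'
#' Emits stage tables as TSV, the summary as JSON and a short human-readable
#' text rendering of the same numbers.
#'
#' @param report An `ereflow_report`.
#' @param dir Output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_differential(report$deg, file.path(dir, "deg.tsv"))
  write_differential(report$dem, file.path(dir, "dem.tsv"))
  for (nm in c("class_enrichment", "composition_correlation", "ere_metrics",
               "set_correlation", "strata")) {
    if (!is.null(report[[nm]]))
      utils::write.table(report[[nm]], file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  s <- report$summary
  txt <- c(
    sprintf("ereflow report (seed %d)", s$seed),
    sprintf("DEGs: %d up / %d down (up fraction %.3f)",
            s$n_deg_up, s$n_deg_down, s$deg_up_fraction),
    sprintf("DEMs: %d up / %d down; %d condition-specific",
            s$n_dem_up, s$n_dem_down, s$n_condition_specific),
    sprintf("ERE-MAP fraction treated/control: %.4f / %.4f (ratio %.2f)",
            s$ere_map_fraction$treated, s$ere_map_fraction$control,
            s$ere_map_ratio),
    sprintf("autophagy-set Spearman vs cumulative ERE cpm: %.3f (top decile: %s)",
            s$autophagy_spearman, s$autophagy_top_decile),
    sprintf("stratified GSEA NES (autophagy, ERE-high, CD8 high vs low): %.3f",
            s$stratified_nes))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}

#' @export
print.ereflow_report <- function(x, ...) {
  s <- x$summary
  cat("ereflow report (seed ", s$seed, ")\n", sep = "")
  cat("  DEGs up/down: ", s$n_deg_up, "/", s$n_deg_down, "\n", sep = "")
  cat("  DEMs up/down: ", s$n_dem_up, "/", s$n_dem_down, "\n", sep = "")
  cat("  ERE-MAP ratio: ", round(s$ere_map_ratio, 3), "\n", sep = "")
  invisible(x)
}
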