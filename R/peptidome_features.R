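# Kyte-Doolittle hydropathy values, the scale on which GRAVY is defined.
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# Default residue sets; all overridable through function arguments.
POLAR_SET <- c("S", "T", "N", "Q", "C", "Y", "H", "K", "R", "D", "E")
TRYPTIC_SET <- c("K", "R")
CHYMOTRYPTIC_SET <- c("F", "W", "Y", "L", "M")
AROMATIC_SET <- c("F", "W", "Y")
DNMT2_SET <- c("D", "G", "V")

residues <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(aa, AA20)
  if (length(bad) > 0L)
    stop("unknown residue(s): ", paste(unique(bad), collapse = ", "))
  aa
}

#' GRAVY index (grand average of hydropathy)
#'
#' Arithmetic mean of the Kyte-Doolittle hydropathy values of the residues;
#' scores > 0 indicate hydrophobic sequences.
#'
#' @param sequence Character scalar or vector over the 20-letter alphabet.
#' @return Numeric GRAVY value(s).
#' @export
gravy <- function(sequence) {
  if (length(sequence) > 1L) return(vapply(sequence, gravy, numeric(1)))
  mean(KYTE_DOOLITTLE[residues(sequence)])
}

fraction_of <- function(sequence, set) {
  aa <- residues(sequence)
  sum(aa %in% set) / length(aa)
}

#' Aromaticity: fraction of Phe, Trp and Tyr residues
#' @inheritParams gravy
#' @export
aromaticity <- function(sequence) {
  if (length(sequence) > 1L) return(vapply(sequence, aromaticity, numeric(1)))
  fraction_of(sequence, AROMATIC_SET)
}

#' DNMT2-target residue fraction: Asp, Gly and Val
#'
#' The fraction of residues whose tRNAs depend on DNMT2 methylation
#' (aspartate, glycine, valine).
#'
#' @inheritParams gravy
#' @export
dnmt2_fraction <- function(sequence) {
  if (length(sequence) > 1L)
    return(vapply(sequence, dnmt2_fraction, numeric(1)))
  fraction_of(sequence, DNMT2_SET)
}

#' Polar residue fraction
#' @inheritParams gravy
#' @param polar_set Residues counted as polar.
#' @export
polar_fraction <- function(sequence, polar_set = POLAR_SET) {
  if (length(sequence) > 1L)
    return(vapply(sequence, polar_fraction, numeric(1),
                  polar_set = polar_set))
  fraction_of(sequence, polar_set)
}

#' Per-residue frequency vector of a sequence
#' @inheritParams gravy
#' @return Named numeric vector over the 20 residues summing to 1.
#' @export
residue_frequencies <- function(sequence) {
  aa <- residues(sequence)
  f <- as.numeric(table(factor(aa, levels = AA20))) / length(aa)
  names(f) <- AA20
  f
}

#' C-terminal protease association of up vs down peptides
#'
#' Classifies each peptide by its final residue as tryptic (in `tryptic`),
#' chymotryptic (in `chymotryptic`) or excluded, builds the 2x2 table
#' (up/down x tryptic/chymotryptic), and runs a two-sided Fisher exact test.
#'
#' @param up_peptides,down_peptides Character vectors of peptide sequences.
#' @param tryptic,chymotryptic Disjoint C-terminal residue sets.
#' @return List with `table` (2x2), `odds_ratio` (conditional MLE), `p`.
#'   A zero margin gives p = 1 with a warning.
#' @export
cterm_association <- function(up_peptides, down_peptides,
                              tryptic = TRYPTIC_SET,
                              chymotryptic = CHYMOTRYPTIC_SET) {
  if (length(intersect(tryptic, chymotryptic)) > 0L)
    stop("tryptic and chymotryptic residue sets must be disjoint")
  classify <- function(peps) {
    last <- substring(peps, nchar(peps), nchar(peps))
    ifelse(last %in% tryptic, "tryptic",
           ifelse(last %in% chymotryptic, "chymotryptic", NA_character_))
  }
  cu <- classify(up_peptides); cd <- classify(down_peptides)
  tab <- rbind(up = c(tryptic = sum(cu == "tryptic", na.rm = TRUE),
                      chymotryptic = sum(cu == "chymotryptic", na.rm = TRUE)),
               down = c(tryptic = sum(cd == "tryptic", na.rm = TRUE),
                        chymotryptic = sum(cd == "chymotryptic", na.rm = TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in the 2x2 table; p set to 1")
    return(list(table = tab, odds_ratio = NA_real_, p = 1))
  }
  ft <- stats::fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Correlate residue composition with per-protein up-DEM counts
#'
#' For each of the 20 residues, Spearman correlation between the residue's
#' frequency across proteins and the number of upregulated DEMs attributed
#' to each protein, BH-adjusted across residues.
#'
#' @param protein_seqs Named character vector of protein sequences.
#' @param n_up Named integer vector of up-DEM counts (names matching
#'   `protein_seqs`); proteins absent get 0.
#' @return data.frame with residue, rho, p, q, ordered by decreasing rho;
#'   residues with constant frequency get NA.
#' @export
composition_correlation <- function(protein_seqs, n_up) {
  counts <- rep(0L, length(protein_seqs))
  names(counts) <- names(protein_seqs)
  common <- intersect(names(n_up), names(counts))
  counts[common] <- n_up[common]
  if (sum(counts > 0) < 10L)
    stop("need >= 10 proteins with at least one DEM")
  freq <- t(vapply(protein_seqs, residue_frequencies, numeric(20)))
  res <- lapply(AA20, function(a) {
    f <- freq[, a]
    if (stats::sd(f) == 0)
      return(data.frame(residue = a, rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(
      stats::cor.test(f, counts, method = "spearman", exact = FALSE))
    data.frame(residue = a, rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_fdr(out$p[ok])
  out[order(-out$rho, na.last = TRUE), , drop = FALSE]
}

#' Rank-sum comparison of two groups of values
#'
#' Mann-Whitney U with a two-sided p: exact when the smaller group has <= 8
#' observations and there are no ties, normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return List with `U` (statistic for group `a`), `p`, `method`.
#' @export
group_compare <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  exact <- min(length(a), length(b)) <= 8 &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal")
}

#' Per-protein feature table
#'
#' Residue-composition summaries plus up/down DEM counts for a set of source
#' proteins.
#'
#' @param protein_seqs Named character vector of protein sequences.
#' @param dem_table differential_table over peptides with a `source_id`
#'   column (or NULL for composition only).
#' @return data.frame with protein_id, gravy, aromaticity, dnmt2_fraction,
#'   polar_fraction, n_up, n_down.
#' @export
protein_features <- function(protein_seqs, dem_table = NULL) {
  out <- data.frame(
    protein_id = names(protein_seqs),
    gravy = gravy(protein_seqs),
    aromaticity = aromaticity(protein_seqs),
    dnmt2_fraction = dnmt2_fraction(protein_seqs),
    polar_fraction = polar_fraction(protein_seqs),
    n_up = 0L, n_down = 0L,
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(dem_table) && !is.null(dem_table$source_id)) {
    up <- table(dem_table$source_id[dem_table$direction == "up"])
    dn <- table(dem_table$source_id[dem_table$direction == "down"])
    out$n_up <- as.integer(up[out$protein_id]); out$n_up[is.na(out$n_up)] <- 0L
    out$n_down <- as.integer(dn[out$protein_id]); out$n_down[is.na(out$n_down)] <- 0L
  }
  out
}
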