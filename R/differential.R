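#' Construct a count matrix
#'
#' @param counts Non-negative integer matrix, features x samples, with row
#'   and column names.
#' @param groups Optional per-sample group labels (character or factor).
#' @return A `count_matrix` list with elements `counts`, `groups`,
#'   `lib_sizes` (column sums).
#' @export
count_matrix <- function(counts, groups = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have row (feature) and column (sample) names")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (!is.null(groups)) {
    if (length(groups) != ncol(counts))
      stop("groups length (", length(groups), ") != number of samples (",
           ncol(counts), ")")
    groups <- as.character(groups)
  }
  structure(list(counts = counts, groups = groups,
                 lib_sizes = colSums(counts)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  if (!is.null(x$groups))
    cat("groups:", paste(sprintf("%s(%d)", names(table(x$groups)),
                                 table(x$groups)), collapse = " "), "\n")
  invisible(x)
}

#' Counts per million
#'
#' cpm_fs = c_fs * 1e6 / L_s with L_s the library size (column sum). Every
#' column of the result sums to 1e6.
#'
#' @param x A [count_matrix()] or numeric matrix.
#' @return Matrix of cpm values.
#' @export
cpm <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  L <- colSums(counts)
  if (any(L <= 0)) {
    bad <- colnames(counts)[which(L <= 0)[1]]
    stop("zero library size for sample '", bad, "'")
  }
  sweep(counts, 2, L, "/") * 1e6
}

#' Log2 cpm with +1 offset
#' @param x A [count_matrix()] or matrix.
#' @export
log2_cpm <- function(x) log2(cpm(x) + 1)

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors robust to composition bias: the median over
#' features of the ratio between a sample's count and the feature's
#' geometric mean, computed on features with all-positive counts.
#'
#' @param x A [count_matrix()] or count matrix.
#' @return Named numeric vector of size factors (geometric mean 1).
#' @export
size_factors <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  keep <- rowSums(counts == 0) == 0
  if (sum(keep) < 10L)
    stop("too few features with all-positive counts for size factors")
  lg <- log(counts[keep, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- exp(apply(lg - ref, 2, stats::median))
  sf / exp(mean(log(sf)))
}

#' Composition-robust log2 normalized expression
#'
#' log2(count / size factor * 1e6 / median library size + 1): cpm-scale
#' values whose per-sample scaling uses median-of-ratios size factors, so
#' a handful of strongly induced features does not depress every other
#' feature. This is the input the differential engine expects for counts.
#'
#' @param x A [count_matrix()] or count matrix.
#' @return Numeric matrix of normalized log2 expression.
#' @export
log2_norm <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  sf <- size_factors(counts)
  med_lib <- stats::median(colSums(counts))
  log2(sweep(counts, 2, sf, "/") * 1e6 / med_lib + 1)
}

#' Fit empirical-Bayes variance-shrinkage hyperparameters
#'
#' Method-of-moments fit of the scaled-inverse-chi-squared prior
#' (prior df `d0`, prior variance `s0^2`) from the per-feature sample
#' variances: marginally s^2 / s0^2 ~ F(d, d0), whose first two moments give
#' d0 = (2d + 4Rd - 4) / (Rd - 2) with R = var(s^2)/mean(s^2)^2, and
#' s0^2 = mean(s^2) (d0 - 2) / d0. When the observed spread is at or below
#' the pure chi-squared expectation (Rd <= 2) the prior df is effectively
#' infinite and is capped at `d0_max` (complete pooling).
#'
#' @param s2 Vector of per-feature pooled variances.
#' @param d Residual degrees of freedom per feature.
#' @param d0_max Cap on the prior df.
#' @return List with `d0` and `s0_sq`.
#' @export
fit_shrinkage <- function(s2, d, d0_max = 1e6) {
  s2 <- s2[is.finite(s2)]
  if (length(s2) < 2L) stop("need >= 2 variances to fit the prior")
  m <- mean(s2)
  if (m <= 0) stop("variances are all zero; nothing to fit")
  R <- stats::var(s2) / m^2
  if (R * d <= 2) {
    d0 <- d0_max
  } else {
    d0 <- (2 * d + 4 * R * d - 4) / (R * d - 2)
    if (!is.finite(d0) || d0 <= 4 || d0 > d0_max) d0 <- min(max(d0, 4.01), d0_max)
  }
  s0_sq <- if (d0 > 2) m * (d0 - 2) / d0 else m
  list(d0 = d0, s0_sq = max(s0_sq, .Machine$double.eps))
}

#' Moderated two-group t-test
#'
#' Empirical-Bayes moderated t on a matrix of log2-scale values (log2-cpm for
#' transcripts, log2-intensity for peptides). Per feature, the pooled
#' variance s^2 (df d = n1 + n2 - 2) is shrunk towards the prior:
#' s~^2 = (d0 s0^2 + d s^2) / (d0 + d); t = (mean2 - mean1) /
#' (s~ sqrt(1/n1 + 1/n2)); two-sided p from a t distribution with d0 + d df.
#'
#' @param values Numeric matrix (features x samples), log2 scale.
#' @param groups Two-level per-sample labels; the contrast is
#'   `level2 - level1` in the order of `levels(factor(groups))` unless
#'   `reference` names the baseline.
#' @param model `"fit"` (default) to estimate (d0, s0^2) by
#'   [fit_shrinkage()], or a list with `d0` and `s0_sq`.
#' @param reference Optional baseline group label.
#' @return data.frame of class `differential_table` with columns feature_id,
#'   log2FC, t, p, q, direction (q and direction filled by [call_de()],
#'   which is applied with default thresholds).
#' @export
moderated_test <- function(values, groups, model = "fit", reference = NULL) {
  values <- as.matrix(values)
  groups <- as.character(groups)
  if (length(groups) != ncol(values))
    stop("groups length != number of columns")
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups required, got ", length(lev))
  if (!is.null(reference)) {
    if (!reference %in% lev) stop("reference '", reference, "' not a group")
    lev <- c(reference, setdiff(lev, reference))
  } else lev <- sort(lev)
  i1 <- which(groups == lev[1]); i2 <- which(groups == lev[2])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs >= 2 samples (got ", n1, " and ", n2, ")")
  m1 <- rowMeans(values[, i1, drop = FALSE])
  m2 <- rowMeans(values[, i2, drop = FALSE])
  v1 <- apply(values[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(values[, i2, drop = FALSE], 1, stats::var)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  if (identical(model, "fit")) model <- fit_shrinkage(s2, d)
  stopifnot(is.list(model), model$d0 >= 0, model$s0_sq > 0)
  s2_tilde <- (model$d0 * model$s0_sq + d * s2) / (model$d0 + d)
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  lfc <- m2 - m1
  tstat <- ifelse(se > 0, lfc / se, 0)
  df_total <- min(model$d0 + d, 1e6)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  tab <- data.frame(feature_id = rownames(values), log2FC = lfc, t = tstat,
                    p = p, stringsAsFactors = FALSE, row.names = NULL)
  attr(tab, "shrinkage") <- model
  attr(tab, "contrast") <- paste(lev[2], "vs", lev[1])
  call_de(tab)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: q_(i) = min_{j >= i} p_(j) m / j.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Vector of q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Call differential direction
#'
#' A feature is `up` when log2FC > tau_lfc and q < tau_fdr, `down` when
#' log2FC < -tau_lfc and q < tau_fdr, otherwise `ns`.
#'
#' @param table data.frame with columns log2FC and p (q recomputed via
#'   [bh_fdr()] if absent).
#' @param tau_lfc log2 fold-change threshold (default 1).
#' @param tau_fdr FDR threshold (default 0.05).
#' @return The table with columns q and direction, class
#'   `differential_table`; attribute `n_up`/`n_down` carry direction counts.
#' @export
call_de <- function(table, tau_lfc = 1, tau_fdr = 0.05) {
  if (is.null(table$q)) table$q <- bh_fdr(table$p)
  table$direction <- ifelse(table$q < tau_fdr & table$log2FC > tau_lfc, "up",
                     ifelse(table$q < tau_fdr & table$log2FC < -tau_lfc,
                            "down", "ns"))
  attr(table, "thresholds") <- c(tau_lfc = tau_lfc, tau_fdr = tau_fdr)
  attr(table, "n_up") <- sum(table$direction == "up")
  attr(table, "n_down") <- sum(table$direction == "down")
  if (!inherits(table, "differential_table"))
    class(table) <- c("differential_table", class(table))
  table
}

#' Summarize direction counts of one or more differential tables
#' @param ... differential_table objects (named).
#' @return data.frame with analysis, n_up, n_down, up_fraction.
#' @export
direction_summary <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) &&
      !inherits(tabs[[1]], "data.frame")) tabs <- tabs[[1]]
  if (is.null(names(tabs))) names(tabs) <- paste0("analysis", seq_along(tabs))
  out <- do.call(rbind, lapply(names(tabs), function(nm) {
    t <- tabs[[nm]]
    nu <- sum(t$direction == "up"); nd <- sum(t$direction == "down")
    data.frame(analysis = nm, n_up = nu, n_down = nd,
               up_fraction = if (nu + nd > 0) nu / (nu + nd) else NA_real_)
  }))
  out
}

#' Detection matrix of a peptide table
#' @param peptides Peptide table with intensity columns.
#' @param intensity_cols Names of the intensity columns.
#' @return Logical matrix peptides x replicates (TRUE = detected).
#' @keywords internal
detection_matrix <- function(peptides, intensity_cols) {
  !is.na(as.matrix(peptides[, intensity_cols, drop = FALSE]))
}

#' Filter and impute peptide intensities for testing
#'
#' Keeps peptides detected in at least `min_detected` replicates of at least
#' one condition; remaining missing intensities are imputed with half the
#' minimum observed intensity of that replicate column.
#'
#' @param peptides Peptide table.
#' @param condition_cols Named list mapping condition name to its intensity
#'   column names.
#' @param min_detected Minimum detections per condition to keep a peptide.
#' @return List with `peptides` (filtered), `intensities` (imputed numeric
#'   matrix, rows = sequences) and `kept` (logical over input rows).
#' @export
impute_peptides <- function(peptides, condition_cols, min_detected = 2) {
  all_cols <- unlist(condition_cols, use.names = FALSE)
  det_per_cond <- sapply(condition_cols, function(cols)
    rowSums(detection_matrix(peptides, cols)))
  kept <- apply(det_per_cond >= min_detected, 1, any)
  sub <- peptides[kept, , drop = FALSE]
  mat <- as.matrix(sub[, all_cols, drop = FALSE])
  mode(mat) <- "numeric"
  for (j in seq_len(ncol(mat))) {
    obs <- mat[, j][!is.na(mat[, j])]
    if (length(obs) == 0L) next
    mat[is.na(mat[, j]), j] <- min(obs) / 2
  }
  rownames(mat) <- sub$sequence
  list(peptides = sub, intensities = mat, kept = kept)
}

#' Flag condition-specific peptides
#'
#' A peptide is condition-specific when it is detected in every replicate of
#' the treated condition and in no replicate of the control condition.
#'
#' @param peptides Peptide table.
#' @param treated_cols Intensity column names of the treated condition.
#' @param control_cols Intensity column names of the control condition.
#' @return Logical vector over peptide rows.
#' @export
call_condition_specific <- function(peptides, treated_cols, control_cols) {
  miss <- setdiff(c(treated_cols, control_cols), names(peptides))
  if (length(miss) > 0L)
    stop("condition column(s) absent from table: ", paste(miss, collapse = ", "))
  dt <- detection_matrix(peptides, treated_cols)
  dc <- detection_matrix(peptides, control_cols)
  rowSums(dt) == length(treated_cols) & rowSums(dc) == 0L
}

#' Intersect direction calls across analyses
#'
#' @param tables List of differential_table objects (one per analysis).
#' @param direction `"up"` or `"down"`.
#' @return Character vector of feature ids called with that direction in
#'   every table.
#' @export
common_elements <- function(tables, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(tables) < 2L) stop("need >= 2 tables to intersect")
  sets <- lapply(tables, function(t) t$feature_id[t$direction == direction])
  Reduce(intersect, sets)
}

#' Pearson correlation between per-analysis DEM and DEG counts
#'
#' @param n_dems,n_degs Numeric vectors (one entry per analysis).
#' @return List with `r`, `p` and `n`; `r` is NA with a warning when either
#'   vector has zero variance.
#' @export
dem_deg_correlation <- function(n_dems, n_degs) {
  if (length(n_dems) != length(n_degs)) stop("length mismatch")
  if (length(n_dems) < 3L) stop("need >= 3 paired analyses")
  if (stats::sd(n_dems) == 0 || stats::sd(n_degs) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(n_dems)))
  }
  ct <- stats::cor.test(n_dems, n_degs, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(n_dems))
}

#' Write a differential table as TSV
#' @param table differential_table.
#' @param path Output path.
#' @export
write_differential <- function(table, path) {
  cols <- intersect(c("feature_id", "log2FC", "t", "p", "q", "direction"),
                    names(table))
  utils::write.table(table[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
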