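#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' Rank-based running-sum enrichment score for one sample: genes are ordered
#' by decreasing expression; each in-set gene at ordered position i carries
#' weight |r_i|^alpha where r_i is the gene's expression rank (largest
#' expression = rank n); ES = sum_i [P_in(i) - P_out(i)], with P_in the
#' running in-set weight fraction and P_out the running fraction of
#' out-of-set genes. The score depends on the expression values only through
#' their ranks.
#'
#' @param expr Named numeric vector of expression values for one sample.
#' @param gene_set Character vector of gene ids.
#' @param alpha Rank weight exponent (default 0.25).
#' @return Enrichment score (numeric scalar).
#' @export
ssgsea <- function(expr, gene_set, alpha = 0.25) {
  n <- length(expr)
  in_set <- names(expr) %in% gene_set
  k <- sum(in_set)
  if (k == 0L) stop("gene set does not intersect the measured genes")
  if (k == n) stop("gene set equals the universe; complement is empty")
  ord <- order(expr, decreasing = TRUE)
  # expression rank: largest value gets rank n
  r <- rank(expr, ties.method = "average")
  w <- abs(r[ord])^alpha
  ind <- in_set[ord]
  w_in <- w * ind
  P_in <- cumsum(w_in) / sum(w_in)
  P_out <- cumsum(!ind) / (n - k)
  sum(P_in - P_out)
}

#' ssGSEA score matrix for a gene-set collection
#'
#' @param expression Numeric matrix (genes x samples) with rownames.
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param alpha Rank weight exponent.
#' @return Matrix of ES, sets x samples.
#' @export
ssgsea_matrix <- function(expression, sets, alpha = 0.25) {
  genes <- rownames(expression)
  n <- length(genes)
  out <- matrix(NA_real_, nrow = length(sets), ncol = ncol(expression),
                dimnames = list(names(sets), colnames(expression)))
  set_ind <- lapply(sets, function(s) genes %in% s)
  for (j in seq_len(ncol(expression))) {
    x <- expression[, j]
    ord <- order(x, decreasing = TRUE)
    w_all <- abs(rank(x, ties.method = "average")[ord])^alpha
    for (i in seq_along(sets)) {
      ind <- set_ind[[i]][ord]
      k <- sum(ind)
      if (k == 0L || k == n) next
      w_in <- w_all * ind
      P_in <- cumsum(w_in) / sum(w_in)
      P_out <- cumsum(!ind) / (n - k)
      out[i, j] <- sum(P_in - P_out)
    }
  }
  out
}

#' Correlate per-sample gene-set scores with a covariate
#'
#' Spearman correlation of each set's ssGSEA score vector with a per-sample
#' covariate (e.g. cumulative ERE cpm), ranked by the correlation
#' coefficient; sets in the first `decile` of ranks on the requested tail
#' are flagged.
#'
#' @param scores ES matrix, sets x samples.
#' @param covariate Named numeric vector over the same samples.
#' @param tail `"negative"` (rank 1 = most negative rho) or `"positive"`.
#' @param decile Fraction of top ranks to flag (default 0.1).
#' @return data.frame with set, rho, p, rank, top_decile; constant-score
#'   sets are excluded with a warning.
#' @export
correlate_sets <- function(scores, covariate, tail = c("negative", "positive"),
                           decile = 0.1) {
  tail <- match.arg(tail)
  if (ncol(scores) < 4L) stop("need >= 4 samples")
  if (stats::sd(covariate) == 0) {
    warning("constant covariate; all correlations undefined")
    return(data.frame(set = rownames(scores), rho = NA_real_, p = NA_real_,
                      rank = NA_integer_, top_decile = NA))
  }
  keep <- apply(scores, 1, function(v) stats::sd(v) > 0 && !anyNA(v))
  if (any(!keep))
    warning(sum(!keep), " set(s) with constant or missing scores excluded")
  scores <- scores[keep, , drop = FALSE]
  res <- t(apply(scores, 1, function(v) {
    ct <- suppressWarnings(
      stats::cor.test(v, covariate, method = "spearman", exact = FALSE))
    c(rho = unname(ct$estimate), p = ct$p.value)
  }))
  rk <- if (tail == "negative") rank(res[, "rho"], ties.method = "first") else
    rank(-res[, "rho"], ties.method = "first")
  n_top <- ceiling(decile * nrow(res))
  data.frame(set = rownames(scores), rho = res[, "rho"], p = res[, "p"],
             rank = as.integer(rk), top_decile = rk <= n_top,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Weighted (p=1) GSEA running-sum ES for a sorted statistic.
# stat_sorted: decreasing; ind: logical in-set indicator along the sort.
gsea_es <- function(stat_sorted, ind) {
  nh <- sum(ind)
  n <- length(ind)
  w <- abs(stat_sorted) * ind
  denom <- sum(w)
  if (denom == 0) w_hit <- ind / nh else w_hit <- w / denom
  run <- cumsum(w_hit - (!ind) / (n - nh))
  unname(run[which.max(abs(run))])
}

#' Pre-ranked GSEA with permutation null
#'
#' Classical weighted (exponent 1) Kolmogorov-Smirnov-like running sum: genes
#' sorted by decreasing statistic; the ES is the maximal-magnitude deviation
#' of the running sum. The null distribution is obtained by gene-label
#' permutation (random sets of the same size); NES = ES divided by the mean
#' magnitude of same-sign null scores, and the permutation p is two-sided:
#' p = (1 + #\{|ES_null| >= |ES|\}) / (n_perm + 1).
#'
#' @param stats Named numeric vector of per-gene ranking statistics (no
#'   duplicated names).
#' @param gene_set Character vector of gene ids (>= 2 after intersection).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation null.
#' @return List with ES, NES, p, n_perm, seed, set_size.
#' @export
gsea_preranked <- function(stats, gene_set, n_perm = 1000, seed = 1) {
  if (anyDuplicated(names(stats))) stop("duplicated gene ids in stats")
  if (n_perm < 100) stop("n_perm must be >= 100")
  genes <- names(stats)
  set <- intersect(gene_set, genes)
  if (length(set) < 2L) stop("gene set has < 2 members after intersection")
  ord <- order(stats, decreasing = TRUE)
  s <- stats[ord]
  ind <- names(s) %in% set
  es <- gsea_es(s, ind)
  n <- length(s); k <- sum(ind)
  null_es <- numeric(n_perm)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    perm_ind <- logical(n)
    perm_ind[sample.int(n, k)] <- TRUE
    null_es[b] <- gsea_es(s, perm_ind)
  }
  same_sign <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same_sign) > 0) es / mean(abs(same_sign)) else NA_real_
  p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
  list(ES = es, NES = nes, p = p, n_perm = n_perm, seed = seed,
       set_size = k)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Hypergeometric over-representation test
#'
#' For each set, the upper-tail hypergeometric probability of observing at
#' least the seen overlap between the query list and the set within the
#' universe, BH-adjusted across sets. Fold enrichment is
#' (overlap/list size) / (set size in universe / universe size).
#'
#' @param gene_list Character vector (subset of `universe`).
#' @param universe Character vector of all measurable genes.
#' @param sets Named list of gene sets.
#' @return data.frame with set, overlap, set_size, fold_enrichment, p, q.
#' @export
overrepresentation <- function(gene_list, universe, sets) {
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  if (length(gene_list) == 0L) stop("empty gene list")
  extra <- setdiff(gene_list, universe)
  if (length(extra) > 0L)
    stop("gene list not contained in universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  N <- length(universe); n <- length(gene_list)
  res <- lapply(names(sets), function(nm) {
    K <- length(intersect(sets[[nm]], universe))
    k <- length(intersect(sets[[nm]], gene_list))
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fe <- if (K == 0L) NA_real_ else (k / n) / (K / N)
    data.frame(set = nm, overlap = k, set_size = K, fold_enrichment = fe,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Stratify a cohort on an ERE axis and a CD8 axis
#'
#' CD8 score = mean of log2(cpm + 1) of the marker rows (default CD8A and
#' CD8B); the ERE axis is the HE-ERE count (default) or the cumulative ERE
#' cpm. Both axes are median-split with the `>= median = high` convention,
#' yielding four strata.
#'
#' @param expression cpm matrix (features x samples).
#' @param ere_set ERE row ids.
#' @param cd8_markers Marker row ids (all must be present).
#' @param ere_axis `"he_ere"` or `"cumulative"`.
#' @return data.frame with sample, ere_score, cd8_score, ere_label,
#'   cd8_label, stratum; attribute `sizes` tabulates the four strata.
#' @export
stratify <- function(expression, ere_set, cd8_markers = c("CD8A", "CD8B"),
                     ere_axis = c("he_ere", "cumulative")) {
  ere_axis <- match.arg(ere_axis)
  miss <- setdiff(cd8_markers, rownames(expression))
  if (length(miss) > 0L)
    stop("missing marker row(s): ", paste(miss, collapse = ", "))
  cd8 <- colMeans(log2(expression[cd8_markers, , drop = FALSE] + 1))
  ere_score <- if (ere_axis == "he_ere") he_ere_count(expression, ere_set)
               else cumulative_ere_cpm(expression, ere_set)
  ere_lab <- median_split(ere_score)
  cd8_lab <- median_split(cd8)
  out <- data.frame(sample = colnames(expression),
                    ere_score = as.numeric(ere_score), cd8_score = cd8,
                    ere_label = as.character(ere_lab),
                    cd8_label = as.character(cd8_lab),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$stratum <- paste0("ERE-", out$ere_label, "/CD8-", out$cd8_label)
  attr(out, "sizes") <- table(out$stratum)
  out
}
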