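#' Assign a biotype to a feature or peptide from its sources
#'
#' Priority: any protein-coding (non-CTA) source makes the call `canonical`;
#' else a CTA-listed gene makes it `CTA`; else an ERE locus makes it `ERE`;
#' anything else is `other-noncanonical`. A peptide is thus ERE-derived only
#' when no canonical coding source explains it (conservative ERE calling).
#'
#' @param sources Character vector of source ids (genes and/or ERE loci), or
#'   a list of such vectors for vectorized use.
#' @param genes Gene annotation data.frame (gene_id, biotype, is_cta).
#' @param eres ERE annotation data.frame (locus_id).
#' @return Character biotype (or vector when `sources` is a list).
#' @export
assign_biotype <- function(sources, genes, eres) {
  if (is.list(sources))
    return(vapply(sources, assign_biotype, character(1),
                  genes = genes, eres = eres))
  sources <- unique(sources)
  unknown <- setdiff(sources, c(genes$gene_id, eres$locus_id))
  if (length(unknown) > 0L)
    stop("unresolvable source id(s): ", paste(unknown, collapse = ", "))
  g <- genes[match(sources, genes$gene_id), ]
  g <- g[!is.na(g$gene_id), , drop = FALSE]
  if (any(g$biotype == "protein_coding" & !g$is_cta)) return("canonical")
  if (any(g$is_cta)) return("CTA")
  if (any(sources %in% eres$locus_id)) return("ERE")
  "other-noncanonical"
}

#' ERE class enrichment against the genomic background
#'
#' Compares the class composition of a set of upregulated ERE loci with the
#' composition of the full annotation: expected e_k = b_k * n where b_k is
#' the background fraction of class k and n the number of observed loci.
#' Per-class two-sided binomial p of the observed count given (n, b_k),
#' computed by the tail-doubling rule: p = min(1, 2 min(P(X <= o), P(X >= o))).
#'
#' @param up_ere_ids Character vector of ERE locus ids.
#' @param eres Full ERE annotation data.frame (locus_id, ere_class).
#' @return data.frame with ere_class, observed, background_fraction,
#'   expected, ratio, p.
#' @export
class_enrichment <- function(up_ere_ids, eres) {
  if (length(up_ere_ids) == 0L) stop("nothing to test: empty up set")
  miss <- setdiff(up_ere_ids, eres$locus_id)
  if (length(miss) > 0L)
    stop("ids absent from annotation: ", paste(utils::head(miss, 5), collapse = ", "))
  bg <- table(factor(eres$ere_class, levels = ERE_CLASSES))
  b <- as.numeric(bg) / sum(bg)
  obs_class <- eres$ere_class[match(up_ere_ids, eres$locus_id)]
  o <- as.numeric(table(factor(obs_class, levels = ERE_CLASSES)))
  n <- sum(o)
  e <- b * n
  p <- vapply(seq_along(ERE_CLASSES), function(k) {
    if (b[k] == 0) return(NA_real_)
    lower <- stats::pbinom(o[k], n, b[k])
    upper <- stats::pbinom(o[k] - 1, n, b[k], lower.tail = FALSE)
    min(1, 2 * min(lower, upper))
  }, numeric(1))
  data.frame(ere_class = ERE_CLASSES, observed = o, background_fraction = b,
             expected = e, ratio = ifelse(e > 0, o / e, NA_real_), p = p,
             stringsAsFactors = FALSE)
}

#' Cumulative ERE cpm per sample
#'
#' E_p = sum over the ERE set of cpm in sample p.
#'
#' @param expression Numeric matrix (features x samples) on the cpm scale.
#' @param ere_set Character vector of ERE row ids; must all be present.
#' @return Named numeric vector, one value per sample.
#' @export
cumulative_ere_cpm <- function(expression, ere_set) {
  if (length(ere_set) == 0L) stop("empty ERE set")
  miss <- setdiff(ere_set, rownames(expression))
  if (length(miss) > 0L)
    stop("ERE row(s) missing from expression: ",
         paste(utils::head(miss, 10), collapse = ", "))
  colSums(expression[ere_set, , drop = FALSE])
}

#' Highly-expressed-ERE count per sample
#'
#' For each ERE e, the reference m_e is the median of its cpm over samples
#' with non-null (> 0) expression; H_p counts the EREs of the set whose
#' expression in sample p is strictly above m_e. EREs with zero expression
#' everywhere contribute 0 to every sample.
#'
#' @inheritParams cumulative_ere_cpm
#' @return Named integer vector, one count per sample.
#' @export
he_ere_count <- function(expression, ere_set) {
  if (length(ere_set) == 0L) stop("empty ERE set")
  if (ncol(expression) < 2L) stop("need >= 2 samples")
  miss <- setdiff(ere_set, rownames(expression))
  if (length(miss) > 0L)
    stop("ERE row(s) missing from expression: ",
         paste(utils::head(miss, 10), collapse = ", "))
  sub <- expression[ere_set, , drop = FALSE]
  H <- integer(ncol(expression))
  for (i in seq_len(nrow(sub))) {
    v <- sub[i, ]
    nz <- v[v > 0]
    if (length(nz) == 0L) next  # all-zero ERE: contributes nothing
    m <- stats::median(nz)
    H <- H + as.integer(v > m)
  }
  names(H) <- colnames(expression)
  H
}

#' Median split of per-sample scores
#'
#' Median is the middle order statistic (odd n) or the mean of the two middle
#' ones (even n); a sample is `high` iff its score >= median. On 437 distinct
#' scores this yields 219 high / 218 low.
#'
#' @param scores Named numeric vector (>= 2 values).
#' @return Character vector of `"high"`/`"low"` labels, named like `scores`;
#'   attribute `sizes` carries the group sizes and `median` the cut point.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2L) stop("need >= 2 samples")
  m <- stats::median(scores)
  if (all(scores == scores[1])) {
    warning("all scores identical; every sample labelled 'high'")
  }
  lab <- ifelse(scores >= m, "high", "low")
  names(lab) <- names(scores)
  attr(lab, "sizes") <- c(high = sum(lab == "high"), low = sum(lab == "low"))
  attr(lab, "median") <- m
  lab
}

#' Per-sample ERE metrics table
#'
#' Convenience wrapper computing E_p, H_p and the two median-split labels for
#' a cohort expression matrix.
#'
#' @param expression cpm matrix (features x samples).
#' @param ere_set ERE row ids.
#' @return data.frame with sample, cumulative_cpm, he_ere_count, ere_label
#'   (split on cumulative cpm), he_label (split on HE-ERE count).
#' @export
ere_metrics <- function(expression, ere_set) {
  E <- cumulative_ere_cpm(expression, ere_set)
  H <- he_ere_count(expression, ere_set)
  data.frame(sample = colnames(expression), cumulative_cpm = E,
             he_ere_count = H,
             ere_label = as.character(median_split(E)),
             he_label = as.character(median_split(H)),
             stringsAsFactors = FALSE, row.names = NULL)
}
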