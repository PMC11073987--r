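# Internal coordinate convention: 0-based half-open everywhere.
# GTF (1-based inclusive) is converted at the parser boundary and back on
# export; BED is stored as-is.

ERE_CLASSES <- c("LINE", "SINE", "LTR", "Other")
GENE_BIOTYPES <- c("protein_coding", "lncRNA", "ncRNA")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Genomic interval (0-based half-open)
#'
#' @param chrom Chromosome name.
#' @param start 0-based start.
#' @param end Exclusive end; must satisfy `start < end`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return A `genomic_interval` list.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  if (!strand %in% c("+", "-", "."))
    stop("invalid strand '", strand, "' (allowed: + - .)")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' Read gene (GTF) and ERE (BED6+2) annotation
#'
#' Genes come from a GTF file (1-based inclusive coordinates, converted to the
#' internal 0-based half-open convention); ERE loci come from a BED6+2 file
#' with columns chrom, start, end, locus_id, score, strand, ere_class, family.
#' ERE classes are restricted to LINE, SINE, LTR, Other.
#'
#' @param gtf_path Path to a GTF file with `gene` features carrying `gene_id`
#'   and `gene_biotype` attributes.
#' @param ere_bed_path Path to the ERE BED6+2 file.
#' @param cta_path Optional path to a plain-text file of cancer-testis gene
#'   ids, one per line; listed genes get `is_cta = TRUE`.
#' @return A list with elements `genes` (data.frame: gene_id, biotype, is_cta,
#'   chrom, start, end, strand) and `eres` (data.frame: locus_id, chrom,
#'   start, end, strand, ere_class, family).
#' @export
read_annotation <- function(gtf_path, ere_bed_path, cta_path = NULL) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0L) stop("no gene features in ", gtf_path)
  biotype <- as.character(gr$gene_biotype)
  bad <- !biotype %in% GENE_BIOTYPES
  if (any(bad))
    stop("unknown gene biotype(s): ", paste(unique(biotype[bad]), collapse = ", "),
         " (allowed: ", paste(GENE_BIOTYPES, collapse = ", "), ")")
  cta <- character(0)
  if (!is.null(cta_path)) cta <- read_id_list(cta_path)
  genes <- data.frame(
    gene_id = as.character(gr$gene_id),
    biotype = biotype,
    is_cta  = as.character(gr$gene_id) %in% cta,
    chrom   = as.character(GenomicRanges::seqnames(gr)),
    # GTF is 1-based inclusive; internal is 0-based half-open
    start   = GenomicRanges::start(gr) - 1L,
    end     = GenomicRanges::end(gr),
    strand  = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene_id in ", gtf_path)
  eres <- read_ere_bed(ere_bed_path)
  list(genes = genes, eres = eres)
}

#' Read an ERE BED6+2 annotation
#'
#' @param path BED6+2 file (0-based half-open; extra columns ere_class, family).
#' @return data.frame with locus_id, chrom, start, end, strand, ere_class, family.
#' @export
read_ere_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "locus_id",
                                         "score", "strand", "ere_class", "family"))
  bad_class <- !tab$ere_class %in% ERE_CLASSES
  if (any(bad_class)) {
    i <- which(bad_class)[1L]
    stop("line ", i, " of ", path, ": unknown ere_class '", tab$ere_class[i],
         "' (allowed: ", paste(ERE_CLASSES, collapse = ", "), ")")
  }
  bad_coord <- tab$start >= tab$end | tab$start < 0
  if (any(bad_coord)) {
    i <- which(bad_coord)[1L]
    stop("line ", i, " of ", path, ": invalid interval [", tab$start[i], ", ",
         tab$end[i], ")")
  }
  if (anyDuplicated(tab$locus_id)) stop("duplicated locus_id in ", path)
  data.frame(locus_id = tab$locus_id, chrom = tab$chrom,
             start = as.integer(tab$start), end = as.integer(tab$end),
             strand = tab$strand, ere_class = tab$ere_class,
             family = tab$family, stringsAsFactors = FALSE)
}

#' Write an ERE annotation as BED6+2
#' @param eres data.frame as returned by [read_ere_bed()].
#' @param path Output path.
#' @export
write_ere_bed <- function(eres, path) {
  out <- data.frame(eres$chrom, eres$start, eres$end, eres$locus_id,
                    0L, eres$strand, eres$ere_class, eres$family)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene models as GTF
#' @param genes data.frame as in [read_annotation()]'s `genes` element.
#' @param path Output path.
#' @export
write_gene_gtf <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    # internal 0-based half-open back to 1-based inclusive
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = ifelse(genes$strand == ".", "*", genes$strand))
  gr$type <- "gene"
  gr$source <- "ereflow"
  gr$gene_id <- genes$gene_id
  gr$gene_biotype <- genes$biotype
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Each line is set name, description, then one or more member ids,
#' tab-separated. Duplicate members within a line are collapsed.
#'
#' @param path GMT file path.
#' @return A named list of character vectors, class `gene_set_collection`,
#'   with the source path in attribute `source`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT parse error at line ", i, " of ", path,
           ": expected >= 3 tab-separated fields, got ", length(f))
    nms[i] <- f[1]
    sets[[i]] <- unique(f[-(1:2)])
  }
  if (anyDuplicated(nms)) stop("duplicated set names in ", path)
  names(sets) <- nms
  structure(sets, class = "gene_set_collection", source = path)
}

#' Write a gene-set collection as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], unique(sets[[i]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text id list (one id per line)
#' @param path File path.
#' @return Character vector of unique ids.
#' @export
read_id_list <- function(path) {
  ids <- readLines(path, warn = FALSE)
  unique(trimws(ids[nzchar(trimws(ids))]))
}

#' Read a feature-by-sample count table
#'
#' TSV with first column `feature_id` and remaining columns non-negative
#' integer counts. Every feature must resolve in the supplied annotation.
#'
#' @param path TSV path.
#' @param annotation Optional list with `genes` and `eres` elements (as from
#'   [read_annotation()]); when supplied, unresolvable feature ids are an error.
#' @param groups Optional character vector of per-sample group labels.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, annotation = NULL, groups = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("no features in ", path)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-integer or negative count at row '", rownames(counts)[bad[1, 1]],
         "', sample '", colnames(counts)[bad[1, 2]], "'")
  if (!is.null(annotation)) {
    known <- c(annotation$genes$gene_id, annotation$eres$locus_id)
    missing <- setdiff(rownames(counts), known)
    if (length(missing) > 0L)
      stop("feature id(s) absent from annotation: ",
           paste(utils::head(missing, 10), collapse = ", "))
  }
  count_matrix(counts, groups = groups)
}

#' Write a count matrix as TSV
#' @param x A [count_matrix()] or integer matrix.
#' @param path Output path.
#' @export
write_counts <- function(x, path) {
  counts <- if (inherits(x, "count_matrix")) x$counts else x
  tab <- data.frame(feature_id = rownames(counts), counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peptide intensity table
#'
#' CSV with columns `sequence`, `source_id`, `biotype`, then per-replicate
#' intensity columns; empty cells or NA mean not detected.
#'
#' @param path CSV path.
#' @return data.frame of class `peptide_table`.
#' @export
read_peptides <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sequence", "source_id", "biotype")
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0L)
    stop("peptide table missing column(s): ", paste(miss, collapse = ", "))
  lens <- nchar(tab$sequence)
  if (any(lens < 8L | lens > 11L))
    stop("peptide length outside 8-11 at row ", which(lens < 8L | lens > 11L)[1])
  class(tab) <- c("peptide_table", "data.frame")
  tab
}

#' Write a peptide table as CSV
#' @param peptides A peptide table data.frame.
#' @param path Output path.
#' @export
write_peptides <- function(peptides, path) {
  utils::write.csv(peptides, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write named sequences as FASTA
#' @param seqs Named character vector of sequences (protein or nucleotide).
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Convert a RepeatMasker-style table to the BED6+2 ERE dialect
#'
#' Convenience converter for tab-separated tables with columns chrom, start
#' (1-based), end, strand, repeat_name, class_family (e.g. "LINE/L1").
#' RepeatMasker releases differ in column layout; this reads the simple
#' tabular export, not the fixed-width .out.
#'
#' @param path Input table path.
#' @param out_bed Output BED6+2 path.
#' @export
repeatmasker_to_bed <- function(path, out_bed) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  cls <- sub("/.*$", "", tab$class_family)
  fam <- sub("^[^/]*/?", "", tab$class_family)
  cls[!cls %in% ERE_CLASSES] <- "Other"
  eres <- data.frame(
    locus_id = sprintf("%s_%d", tab$repeat_name, seq_len(nrow(tab))),
    chrom = tab$chrom, start = as.integer(tab$start) - 1L,
    end = as.integer(tab$end), strand = tab$strand,
    ere_class = cls, family = ifelse(nzchar(fam), fam, "unknown"),
    stringsAsFactors = FALSE)
  write_ere_bed(eres, out_bed)
}
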