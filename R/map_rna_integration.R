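GENETIC_CODE_1 <- Biostrings::GENETIC_CODE

#' Three-frame translation into stop-free fragments
#'
#' Translates a stranded transcript sequence in its three forward reading
#' frames with the standard genetic code. Codons containing N translate to X;
#' fragments are split at stop codons and at X so emitted fragments contain
#' only the 20 canonical residues. Trailing partial codons are dropped.
#'
#' @param sequence Nucleotide string over A, C, G, T, N.
#' @return List of three character vectors (one per frame) of stop-free
#'   peptide fragments; empty vectors where a frame has none.
#' @export
translate_three_frames <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  sequence <- toupper(sequence)
  bad <- setdiff(strsplit(sequence, "")[[1]], c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L)
    stop("invalid nucleotide(s): ", paste(unique(bad), collapse = ", "))
  lapply(translate_frames_full(sequence), function(prot) {
    frags <- strsplit(prot, "[*X]+")[[1]]
    frags[nzchar(frags)]
  })
}

# Full translation of the three frames, stops as '*', N-codons as 'X'.
translate_frames_full <- function(sequence) {
  sequence <- toupper(sequence)
  vapply(0:2, function(f) {
    s <- substring(sequence, f + 1L)
    n_codon <- nchar(s) %/% 3L
    if (n_codon == 0L) return("")
    codons <- substring(s, 3L * (seq_len(n_codon) - 1L) + 1L,
                        3L * seq_len(n_codon))
    aa <- GENETIC_CODE_1[codons]
    aa[is.na(aa)] <- "X"  # codons containing N
    paste(aa, collapse = "")
  }, character(1))
}

#' Build a candidate MAP database by three-frame translation
#'
#' Enumerates every 8-11-mer of every stop-free fragment of the three
#' reading frames of each sufficiently expressed transcript, recording the
#' source transcript, frame and offset. This is the in-silico database
#' against which detected MHC-I peptides are matched to their possible RNA
#' sources.
#'
#' @param transcripts Named character vector of transcript nucleotide
#'   sequences.
#' @param expression Named numeric vector of transcript expression (cpm).
#' @param min_cpm Transcripts below this expression are skipped.
#' @param lengths Peptide lengths to enumerate.
#' @return data.frame of class `candidate_db` with columns peptide, source,
#'   frame (1-3), offset (0-based within the frame's translation).
#' @export
build_candidate_db <- function(transcripts, expression, min_cpm = 0,
                               lengths = 8:11) {
  miss <- setdiff(names(transcripts), names(expression))
  if (length(miss) > 0L)
    stop("expression missing for transcript(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  keep <- names(transcripts)[expression[names(transcripts)] >= min_cpm]
  rows <- list()
  for (tx in keep) {
    prots <- translate_frames_full(transcripts[[tx]])
    for (f in 1:3) {
      prot <- prots[f]
      if (!nzchar(prot)) next
      m <- gregexpr("[^*X]+", prot)[[1]]
      if (m[1] == -1L) next
      frag_starts <- as.integer(m)
      frag_lens <- attr(m, "match.length")
      for (j in seq_along(frag_starts)) {
        frag <- substring(prot, frag_starts[j],
                          frag_starts[j] + frag_lens[j] - 1L)
        L <- frag_lens[j]
        for (k in lengths) {
          if (L < k) next
          starts <- seq_len(L - k + 1L)
          rows[[length(rows) + 1L]] <- data.frame(
            peptide = substring(frag, starts, starts + k - 1L),
            source = tx, frame = f,
            # 0-based offset within the full frame translation
            offset = frag_starts[j] - 1L + starts - 1L,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  db <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(peptide = character(0), source = character(0),
               frame = integer(0), offset = integer(0))
  db <- unique(db)
  class(db) <- c("candidate_db", "data.frame")
  db
}

#' Sources of a peptide in a candidate database
#' @param db candidate_db.
#' @param peptide Peptide sequence.
#' @return Character vector of source transcript ids (possibly empty).
#' @export
db_sources <- function(db, peptide) {
  unique(db$source[db$peptide == peptide])
}

#' Reads per hundred million (rphm)
#'
#' rphm = r * 1e8 / T, where r is the read count supporting the
#' peptide-coding region(s) and T the total read count of the context.
#'
#' @param r_total Supporting reads (>= 0).
#' @param total_reads Total reads of the context (> 0).
#' @return rphm value.
#' @export
rphm <- function(r_total, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be > 0")
  if (any(r_total < 0)) stop("r_total must be >= 0")
  r_total * 1e8 / total_reads
}

#' rphm of a peptide given per-source read support
#'
#' Sums read support over the peptide's sources in the database. A peptide
#' absent from the database gets rphm 0 and the `rna_absent` flag.
#'
#' @param peptide Peptide sequence.
#' @param db candidate_db.
#' @param read_support Named numeric vector of reads per source transcript.
#' @param total_reads Total reads of the context.
#' @return List with `rphm` and `rna_absent`.
#' @export
peptide_rphm <- function(peptide, db, read_support, total_reads) {
  src <- db_sources(db, peptide)
  if (length(src) == 0L)
    return(list(rphm = 0, rna_absent = TRUE))
  r <- sum(read_support[src], na.rm = TRUE)
  list(rphm = rphm(r, total_reads), rna_absent = FALSE)
}

#' RNA/peptide concordance classes
#'
#' Classes each differentially abundant peptide (DEM) by the differential
#' call of its best-supported source transcript: `rna_up`, `rna_down`,
#' `rna_unchanged`, or `rna_absent` when no database source exists. The
#' best-supported source is the one with maximal read support; ties break by
#' biotype priority canonical > CTA > ERE > other, then lexicographic id.
#' Also reports the rank-sum comparison of source-RNA log2 fold-changes
#' between up- and down-DEMs.
#'
#' @param dems differential_table over peptides (feature_id = sequence).
#' @param degs differential_table over transcripts.
#' @param db candidate_db.
#' @param read_support Named numeric vector of per-transcript read support.
#' @param biotype_of Optional named character vector transcript -> biotype
#'   (canonical/CTA/ERE/other-noncanonical) used for tie-breaks.
#' @return List with `classes` (data.frame sequence, direction, best_source,
#'   rna_class), `counts` (table DEM direction x rna class), and `fc_test`
#'   (rank-sum of source log2FC, up vs down DEMs; NULL when either side is
#'   empty).
#' @export
concordance <- function(dems, degs, db, read_support = NULL,
                        biotype_of = NULL) {
  prio <- c(canonical = 1, CTA = 2, ERE = 3, `other-noncanonical` = 4)
  pick_source <- function(srcs) {
    if (length(srcs) == 1L) return(srcs)
    sup <- if (is.null(read_support)) rep(0, length(srcs)) else
      ifelse(is.na(read_support[srcs]), 0, read_support[srcs])
    best <- srcs[sup == max(sup)]
    if (length(best) > 1L && !is.null(biotype_of)) {
      pr <- prio[biotype_of[best]]
      pr[is.na(pr)] <- 5
      best <- best[pr == min(pr)]
    }
    sort(best)[1]
  }
  deg_dir <- degs$direction
  names(deg_dir) <- degs$feature_id
  deg_lfc <- degs$log2FC
  names(deg_lfc) <- degs$feature_id
  res <- lapply(seq_len(nrow(dems)), function(i) {
    pep <- dems$feature_id[i]
    srcs <- db_sources(db, pep)
    if (length(srcs) == 0L)
      return(data.frame(sequence = pep, direction = dems$direction[i],
                        best_source = NA_character_, rna_class = "rna_absent",
                        source_log2FC = NA_real_, stringsAsFactors = FALSE))
    best <- pick_source(srcs)
    dir <- deg_dir[best]
    cls <- if (is.na(dir)) "rna_absent" else
      switch(dir, up = "rna_up", down = "rna_down", "rna_unchanged")
    data.frame(sequence = pep, direction = dems$direction[i],
               best_source = best, rna_class = cls,
               source_log2FC = unname(deg_lfc[best]),
               stringsAsFactors = FALSE)
  })
  classes <- do.call(rbind, res)
  counts <- table(DEM = classes$direction,
                  RNA = factor(classes$rna_class,
                               levels = c("rna_up", "rna_down",
                                          "rna_unchanged", "rna_absent")))
  up_fc <- classes$source_log2FC[classes$direction == "up" &
                                   !is.na(classes$source_log2FC)]
  dn_fc <- classes$source_log2FC[classes$direction == "down" &
                                   !is.na(classes$source_log2FC)]
  fc_test <- if (length(up_fc) > 0 && length(dn_fc) > 0)
    group_compare(up_fc, dn_fc) else NULL
  list(classes = classes, counts = counts, fc_test = fc_test)
}

#' Normal-tissue rphm screen
#'
#' Flags each peptide x context cell whose rphm exceeds the threshold
#' (strict inequality); a peptide is summarized "lowly or not expressed"
#' when no context is flagged.
#'
#' @param profile Numeric matrix of rphm values, peptides x contexts.
#' @param threshold rphm cut-off (default 8.55).
#' @return List with `flags` (logical matrix) and `lowly_expressed`
#'   (logical per peptide: no flagged context).
#' @export
tissue_screen <- function(profile, threshold = 8.55) {
  profile <- as.matrix(profile)
  flags <- profile > threshold
  list(flags = flags, lowly_expressed = rowSums(flags) == 0L)
}

#' Write a candidate database as TSV
#' @param db candidate_db.
#' @param path Output path.
#' @export
write_candidate_db <- function(db, path) {
  utils::write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
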