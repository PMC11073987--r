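test_that("three-frame translation splits at stops and handles N codons", {
  fr <- translate_three_frames("ATGGCC")
  expect_equal(fr[[1]], "MA")
  expect_equal(fr[[2]], "W")
  expect_equal(fr[[3]], "G")

  expect_length(translate_three_frames("TAA")[[1]], 0)

  # stop splits a frame into fragments
  fr2 <- translate_three_frames("ATGTAAATG")
  expect_equal(fr2[[1]], c("M", "M"))

  # N codon translates to X and is excluded from fragments
  fr3 <- translate_three_frames("ATGANTGCC")
  expect_equal(fr3[[1]], c("M", "A"))

  expect_identical(translate_three_frames("ATGGCCAAA"),
                   translate_three_frames("ATGGCCAAA"))
  expect_error(translate_three_frames(""), "empty")
  expect_error(translate_three_frames("ATGU"), "invalid nucleotide")
})

test_that("candidate database enumerates k-mer windows with source links", {
  # one transcript with a 10-aa stop-free frame-1 fragment; the other frames
  # are interrupted immediately (short fragments below 8 aa)
  tx <- paste0("ATG", "GCC", "GAT", "GAA", "TTT", "GGT", "CAT", "AAA",
               "CTG", "AAT", "TAA")
  frames <- translate_three_frames(tx)
  expect_equal(nchar(frames[[1]][1]), 10)
  expr <- c(T1 = 10)
  db <- build_candidate_db(c(T1 = tx), expr, min_cpm = 1)
  db1 <- db[db$frame == 1, ]
  long_frames <- sum(vapply(frames, function(f)
    sum(pmax(0, nchar(f) - 8 + 1) + pmax(0, nchar(f) - 9 + 1) +
        pmax(0, nchar(f) - 10 + 1) + pmax(0, nchar(f) - 11 + 1)),
    numeric(1)))
  expect_equal(nrow(db), long_frames)
  expect_equal(nrow(db1), 3 + 2 + 1)  # 8-, 9-, 10-mers of a 10-aa fragment

  # window-count identity for a single L-aa fragment
  L <- 10
  expect_equal(nrow(db1), sum(pmax(0, L - 8:11 + 1)))

  # below the expression floor the transcript contributes nothing
  expect_equal(nrow(build_candidate_db(c(T1 = tx), c(T1 = 0.1),
                                       min_cpm = 1)), 0)

  # a shared 8-mer lists both sources
  tx2 <- c(A = "GCTGATGAATTTGGTCATAAACTG", B = "GCTGATGAATTTGGTCATAAACTG")
  db2 <- build_candidate_db(tx2, c(A = 5, B = 5))
  shared <- db2$peptide[duplicated(db2$peptide)][1]
  expect_setequal(db_sources(db2, shared), c("A", "B"))
})

test_that("every emitted peptide is re-findable in its source translation", {
  set.seed(13)
  txs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = ""),
    character(1))
  names(txs) <- paste0("TX", 1:5)
  db <- build_candidate_db(txs, stats::setNames(rep(10, 5), names(txs)))
  expect_gt(nrow(db), 0)
  for (i in seq_len(nrow(db))) {
    frags <- translate_three_frames(txs[[db$source[i]]])[[db$frame[i]]]
    expect_true(any(grepl(db$peptide[i], frags, fixed = TRUE)),
                info = paste("peptide", db$peptide[i]))
  }
})

test_that("rphm is the stated read normalization and scales linearly", {
  expect_equal(rphm(171, 2e9), 8.55)
  expect_equal(rphm(0, 1e7), 0)
  expect_equal(rphm(2 * 171, 2e9), 2 * 8.55)
  expect_equal(rphm(171 * 3, 2e9 * 3), 8.55)  # proportional scaling
  expect_error(rphm(1, 0), "total_reads")
  expect_error(rphm(-1, 10), "r_total")
})

test_that("peptide rphm aggregates sources and flags absent peptides", {
  db <- build_candidate_db(
    c(A = "GCTGATGAATTTGGTCATAAACTGGGG", B = "GCTGATGAATTTGGTCATAAACTGGGG"),
    c(A = 5, B = 5))
  pep <- db$peptide[1]
  got <- peptide_rphm(pep, db, c(A = 100, B = 71), 2e9)
  expect_equal(got$rphm, 8.55)
  expect_false(got$rna_absent)
  miss <- peptide_rphm("WWWWWWWW", db, c(A = 100, B = 71), 2e9)
  expect_equal(miss$rphm, 0)
  expect_true(miss$rna_absent)
})

test_that("concordance classes DEMs by their best-supported source", {
  db <- data.frame(peptide = c("AAAAAAAK", "CCCCCCCK", "DDDDDDDK",
                               "AAAAAAAK"),
                   source = c("T_up", "T_ns", "T_down", "T_weak"),
                   frame = 1L, offset = 0L, stringsAsFactors = FALSE)
  class(db) <- c("candidate_db", "data.frame")
  degs <- data.frame(feature_id = c("T_up", "T_ns", "T_down", "T_weak"),
                     log2FC = c(3, 0.1, -3, 2.5), p = 0.01,
                     q = c(0.01, 0.9, 0.01, 0.01),
                     direction = c("up", "ns", "down", "up"),
                     stringsAsFactors = FALSE)
  dems <- data.frame(feature_id = c("AAAAAAAK", "CCCCCCCK", "DDDDDDDK",
                                    "EEEEEEEK"),
                     log2FC = c(2, 2, -2, 2), p = 0.01, q = 0.01,
                     direction = c("up", "up", "down", "up"),
                     stringsAsFactors = FALSE)
  res <- concordance(dems, degs, db,
                     read_support = c(T_up = 100, T_ns = 50, T_down = 10,
                                      T_weak = 1))
  cls <- res$classes
  expect_equal(cls$rna_class[cls$sequence == "AAAAAAAK"], "rna_up")
  expect_equal(cls$best_source[cls$sequence == "AAAAAAAK"], "T_up")
  expect_equal(cls$rna_class[cls$sequence == "CCCCCCCK"], "rna_unchanged")
  expect_equal(cls$rna_class[cls$sequence == "DDDDDDDK"], "rna_down")
  expect_equal(cls$rna_class[cls$sequence == "EEEEEEEK"], "rna_absent")
  expect_equal(unname(res$counts["up", "rna_up"]), 1L)
})

test_that("concordance recovers full and null RNA drive", {
  run_conc <- function(drive) {
    cfg <- sim_config(seed = 1, rna_drive = drive, lfc_mean = 3,
                      dispersion = 0.05, n_peptides = 1500,
                      frac_ere_peptides = 0)
    e <- simulate_experiment(cfg)
    pr <- simulate_proteome(cfg)
    pep <- simulate_immunopeptidome(cfg, pr, e)
    deg <- moderated_test(log2_norm(e$counts), e$counts$groups,
                          reference = "control")
    nr <- cfg$n_reps_per_group
    cc <- list(control = paste0("ctrl_", seq_len(nr)),
               treated = paste0("trt_", seq_len(nr)))
    imp <- impute_peptides(pep$peptides, cc)
    dem <- moderated_test(log2(imp$intensities + 1),
                          rep(names(cc), each = nr), reference = "control")
    db <- data.frame(peptide = imp$peptides$sequence,
                     source = imp$peptides$source_gene,
                     frame = 1L, offset = 0L, stringsAsFactors = FALSE)
    class(db) <- c("candidate_db", "data.frame")
    res <- concordance(dem, deg, db)
    cls <- res$classes
    up <- cls[cls$direction == "up", ]
    list(frac_rna_up = mean(up$rna_class == "rna_up"),
         deg_up_rate = mean(deg$direction == "up"))
  }
  full <- run_conc(1)
  expect_gte(full$frac_rna_up, 0.95)
  null <- run_conc(0)
  # under no drive the source of an up-DEM is no more often an up-DEG than
  # any feature is
  expect_lt(null$frac_rna_up, null$deg_up_rate + 0.05)
})

test_that("tissue screen applies the strict rphm threshold", {
  prof <- rbind(p1 = c(gtex = 8.6, blood = 0), p2 = c(gtex = 8.55, blood = 0),
                p3 = c(gtex = 0, blood = 0))
  ts <- tissue_screen(prof, threshold = 8.55)
  expect_true(ts$flags["p1", "gtex"])
  expect_false(ts$flags["p2", "gtex"])
  expect_equal(unname(ts$lowly_expressed), c(FALSE, TRUE, TRUE))
})
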