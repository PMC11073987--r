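test_that("cpm normalizes columns to one million", {
  m <- matrix(c(10L, 90L, 5L, 0L), 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  x <- cpm(count_matrix(m))
  expect_equal(unname(x[, "s1"]), c(1e5, 9e5))
  expect_equal(colSums(x), c(s1 = 1e6, s2 = 1e6))
  expect_equal(unname(cpm(matrix(42L, 1, 1,
    dimnames = list("f", "s")))[1, 1]), 1e6)
  m0 <- matrix(c(1L, 0L, 0L, 0L), 2,
               dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_error(cpm(m0), "s2")
})

test_that("moderated test reduces to the ordinary t at d0 = 0 and follows the
           shrinkage arithmetic", {
  set.seed(11)
  vals <- matrix(rnorm(5 * 6), 5,
                 dimnames = list(paste0("f", 1:5), paste0("s", 1:6)))
  grp <- rep(c("a", "b"), each = 3)
  tab <- moderated_test(vals, grp, model = list(d0 = 0, s0_sq = 1))
  for (i in 1:5) {
    tt <- t.test(vals[i, 4:6], vals[i, 1:3], var.equal = TRUE)
    expect_equal(tab$t[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(tab$p[i], tt$p.value, tolerance = 1e-12)
  }

  # s2 = 1 in both groups, prior (d0 = 2, s0^2 = 4), d = 4 -> s~^2 = 2
  v <- rbind(f1 = c(-1, 0, 1, 4, 5, 6))  # group variances exactly 1
  tab2 <- moderated_test(v, grp, model = list(d0 = 2, s0_sq = 4))
  s2_tilde <- (2 * 4 + 4 * 1) / (2 + 4)
  expect_equal(s2_tilde, 2)
  expect_equal(tab2$t, 5 / sqrt(s2_tilde * (2 / 3)), tolerance = 1e-12)

  # identical group means: log2FC 0, two-sided p at the symmetry point
  v0 <- rbind(f1 = c(1, 2, 3, 1, 2, 3))
  tab0 <- moderated_test(v0, grp, model = list(d0 = 0, s0_sq = 1))
  expect_equal(tab0$log2FC, 0)
  expect_gt(tab0$p, 0.999)
})

test_that("shrinkage fit recovers the prior on simulated variances", {
  set.seed(42)
  d <- 4; d0_true <- 8; s0_true <- 0.5
  sigma2 <- d0_true * s0_true / rchisq(20000, d0_true)
  s2 <- sigma2 * rchisq(20000, d) / d
  fit <- fit_shrinkage(s2, d)
  expect_equal(fit$d0, d0_true, tolerance = 0.25)
  expect_equal(fit$s0_sq, s0_true, tolerance = 0.05)
  # homogeneous variances: prior df effectively infinite
  s2h <- rchisq(5000, d) / d
  expect_gt(fit_shrinkage(s2h, d)$d0, 100)
})

test_that("BH q-values match the step-up oracle on all permutations", {
  p6 <- c(0.011, 0.2, 0.04, 0.9, 0.33, 0.0007)
  perms <- rbind(1:6)
  # all 720 permutations
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  for (i in seq_len(nrow(perms))) {
    p <- p6[perms[i, ]]
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("direction calling applies fold and FDR thresholds jointly", {
  tab <- data.frame(feature_id = c("a", "b", "c", "d"),
                    log2FC = c(1.5, 0.5, -2, -1.6),
                    p = c(0.001, 0.0001, 0.5, 0.002))
  tab$q <- c(0.01, 0.001, 0.2, 0.04)
  out <- call_de(tab)
  expect_equal(out$direction, c("up", "ns", "ns", "down"))
  expect_equal(attr(out, "n_up"), 1L)
  # significant but below the fold cutoff stays ns
  expect_equal(out$direction[out$feature_id == "b"], "ns")
})

test_that("condition-specific calling requires all treated, zero control", {
  trt <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 1, 1), c(0, 0, 0))
  ctl <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(0, 0, 0))
  pep <- fixture_peptides(trt, ctl)
  flag <- call_condition_specific(pep, paste0("trt_", 1:3), paste0("ctrl_", 1:3))
  expect_equal(flag, c(TRUE, FALSE, FALSE, FALSE))
  expect_error(call_condition_specific(pep, paste0("trt_", 1:3), "nope"),
               "nope")
})

test_that("common_elements intersects direction calls across analyses", {
  mk <- function(ids_up, all_ids) {
    data.frame(feature_id = all_ids,
               log2FC = ifelse(all_ids %in% ids_up, 2, 0),
               p = 0.5, q = ifelse(all_ids %in% ids_up, 0.01, 0.9),
               direction = ifelse(all_ids %in% ids_up, "up", "ns"))
  }
  ids <- LETTERS[1:6]
  t1 <- mk(c("A", "B", "C"), ids); t2 <- mk(c("B", "C", "D"), ids)
  expect_setequal(common_elements(list(t1, t2), "up"), c("B", "C"))
  t3 <- mk(character(0), ids)
  expect_length(common_elements(list(t1, t2, t3), "up"), 0)
  expect_error(common_elements(list(t1), "up"), ">= 2")
})

test_that("intersection recovers shared planted up-EREs across cell lines", {
  # four synthetic cell lines sharing 50 planted up-features at lfc 2
  set.seed(1)
  n_feat <- 800; n_shared <- 50
  ids <- sprintf("E%03d", seq_len(n_feat))
  shared <- ids[1:n_shared]
  base <- rlnorm(n_feat, log(200), 0.5)
  tabs <- lapply(1:4, function(line) {
    lfc <- ifelse(ids %in% shared, 2, 0)
    # each line also has private effects
    lfc[sample((n_shared + 1):n_feat, 30)] <- 2
    mu <- cbind(base, base, base, base * 2^lfc, base * 2^lfc, base * 2^lfc)
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 20), n_feat,
                     dimnames = list(ids, paste0("s", 1:6)))
    moderated_test(log2_norm(counts), rep(c("c", "t"), each = 3),
                   reference = "c")
  })
  hits <- common_elements(tabs, "up")
  expect_gte(length(intersect(hits, shared)), 45)
})

test_that("DEM-DEG count correlation matches hand-computed Pearson", {
  expect_equal(dem_deg_correlation(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(dem_deg_correlation(c(1, 2, 3), c(3, 2, 1))$r, -1)
  expect_equal(dem_deg_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))$r, 0.6)
  expect_warning(r0 <- dem_deg_correlation(c(1, 1, 1), c(1, 2, 3)),
                 "zero variance")
  expect_true(is.na(r0$r))
})

test_that("directionality summary reflects a planted 80% up fraction", {
  set.seed(3)
  n <- 2000; n_eff <- 200
  lfc <- numeric(n)
  lfc[1:160] <- 2; lfc[161:200] <- -2
  vals <- matrix(rnorm(n * 6, sd = 0.5), n) +
    outer(lfc, c(0, 0, 0, 1, 1, 1))
  rownames(vals) <- sprintf("f%04d", 1:n)
  colnames(vals) <- paste0("s", 1:6)
  tab <- moderated_test(vals, rep(c("c", "t"), each = 3), reference = "c")
  up_frac <- attr(tab, "n_up") / (attr(tab, "n_up") + attr(tab, "n_down"))
  expect_gte(up_frac, 0.7)
  expect_lte(up_frac, 0.9)
})

test_that("peptide imputation keeps >= 2 detections and fills half-minimum", {
  trt <- rbind(c(1, 1, 1), c(1, 0, 0), c(1, 1, 0))
  ctl <- rbind(c(1, 1, 1), c(0, 1, 0), c(0, 0, 0))
  pep <- fixture_peptides(trt, ctl)
  pep$trt_1 <- c(800, 600, 400)[c(1, 2, 3)] * ifelse(is.na(pep$trt_1), NA, 1)
  cc <- list(treated = paste0("trt_", 1:3), control = paste0("ctrl_", 1:3))
  imp <- impute_peptides(pep, cc, min_detected = 2)
  # peptide 2 detected once per condition -> dropped
  expect_equal(imp$kept, c(TRUE, FALSE, TRUE))
  # missing trt_3 of peptide 3 imputed with half the column minimum
  i3 <- which(rownames(imp$intensities) == pep$sequence[3])
  expect_equal(unname(imp$intensities[i3, "trt_3"]), 1000 / 2)
})

test_that("size factors undo composition bias at fixed sequencing depth", {
  # 50 of 500 features induced 8-fold; sequencing re-allocates a fixed read
  # budget, so every null feature loses depth in the treated samples
  set.seed(9)
  w <- rlnorm(500, log(100), 0.5)
  lfc <- c(rep(3, 50), rep(0, 450))
  depth <- 3e5
  draw <- function(weights) rmultinom(3, depth, weights / sum(weights))
  counts <- cbind(draw(w), draw(w * 2^lfc))
  dimnames(counts) <- list(sprintf("f%03d", 1:500), paste0("s", 1:6))
  raw <- log2_cpm(counts)
  nrm <- log2_norm(counts)
  null_raw <- rowMeans(raw[51:500, 4:6]) - rowMeans(raw[51:500, 1:3])
  null_nrm <- rowMeans(nrm[51:500, 4:6]) - rowMeans(nrm[51:500, 1:3])
  expect_lt(median(null_raw), -0.4)        # raw cpm shows the spurious drop
  expect_lt(abs(median(null_nrm)), 0.1)    # size factors remove it
})
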