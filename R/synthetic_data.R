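#' Simulation configuration
#'
#' Holds every knob of the synthetic-data generator. Defaults emulate the
#' study conditions the pipeline is designed for: negative-binomial counts
#' for a desk-scale transcriptome (2000 genes, 3000 ERE loci, 3 replicates
#' per group), hypomethylating-agent-style induction concentrated in LINE
#' and LTR loci and in a cancer-testis gene subset, a label-free
#' immunopeptidome whose fold-changes are only partially RNA-driven, and a
#' 437-sample cohort with a latent autophagy activity negatively coupled to
#' ERE expression and to CD8 T-cell abundance.
#'
#' @param seed Integer root seed; each generator stage derives its own
#'   stream from it.
#' @param n_genes,n_ere Numbers of genes and ERE loci.
#' @param class_mix Named fractions over LINE/SINE/LTR/Other summing to 1.
#' @param n_cta Number of cancer-testis genes (all planted upregulated).
#' @param frac_ere_up Fraction of LINE+LTR loci planted upregulated; SINE
#'   and Other loci never receive a planted effect.
#' @param lfc_mean,lfc_sd Planted log2 fold-change distribution.
#' @param dispersion Negative-binomial dispersion phi (variance
#'   mu + phi mu^2); 0 gives Poisson counts.
#' @param n_reps_per_group Replicates per condition.
#' @param n_proteins,protein_length Proteome size and protein length.
#' @param dgv_frac Fraction of proteins in the D/G/V-enriched subset.
#' @param dgv_enrichment Dirichlet enrichment factor for Asp and Gly in the
#'   enriched subset (Val gets half the excess).
#' @param dgv_dem_shift Extra independent up-shift (log2) for peptides from
#'   enriched proteins.
#' @param n_peptides Immunopeptidome size.
#' @param frac_ere_peptides Fraction of peptides drawn from ERE loci; these
#'   sit near the detection limit (low-abundance MAPs).
#' @param ere_pep_lfc Extra treatment log2 up-shift applied to ERE-derived
#'   peptides (0 = no shift; positive values emulate an autophagy-inhibited
#'   arm in which ERE MAP presentation is restored).
#' @param rna_drive Fraction a in [0,1] of peptide log2FC driven by the
#'   source RNA log2FC.
#' @param frac_pep_effect Fraction of peptides carrying a non-zero
#'   RNA-independent (post-translational) effect.
#' @param pep_effect_sd Log2 spread of that independent effect.
#' @param peptide_noise_sd Residual peptide log2FC noise.
#' @param rep_noise_sd Replicate-level log2-intensity noise (0.25 log2
#'   units, about an 18 percent CV, typical of label-free replicates).
#' @param detect_dropout_scale Multiplier of the logistic missing-not-at-
#'   random dropout probability; 0 disables missingness.
#' @param cohort_n Cohort size (>= 4).
#' @param n_cohort_genes,n_cohort_ere,n_autophagy_genes Cohort feature counts.
#' @param beta_autophagy Strength (>= 0) of the negative coupling between
#'   the latent autophagy activity and ERE expression.
#' @param beta_cd8 Strength of the negative coupling between autophagy
#'   activity and the latent CD8 abundance.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 2000, n_ere = 3000,
                       class_mix = c(LINE = 0.35, SINE = 0.45,
                                     LTR = 0.15, Other = 0.05),
                       n_cta = 100, frac_ere_up = 0.2,
                       lfc_mean = 2, lfc_sd = 0.5,
                       dispersion = 0.1, n_reps_per_group = 3,
                       n_proteins = 500, protein_length = 300,
                       dgv_frac = 0.2, dgv_enrichment = 3,
                       dgv_dem_shift = 1.5,
                       n_peptides = 2000, frac_ere_peptides = 0.008,
                       ere_pep_lfc = 0,
                       rna_drive = 0.3, frac_pep_effect = 0.25,
                       pep_effect_sd = 2, peptide_noise_sd = 0.25,
                       rep_noise_sd = 0.25,
                       detect_dropout_scale = 1,
                       cohort_n = 437, n_cohort_genes = 1000,
                       n_cohort_ere = 200, n_autophagy_genes = 50,
                       beta_autophagy = 1, beta_cd8 = 0.8) {
  cfg <- as.list(environment())
  fr <- c(frac_ere_up = frac_ere_up, dgv_frac = dgv_frac,
          rna_drive = rna_drive, frac_ere_peptides = frac_ere_peptides)
  if (any(fr < 0 | fr > 1))
    stop("fraction out of [0,1]: ",
         paste(names(fr)[fr < 0 | fr > 1], collapse = ", "))
  if (is.null(names(class_mix)) ||
      !setequal(names(class_mix), ERE_CLASSES))
    stop("class_mix must be named over ", paste(ERE_CLASSES, collapse = ", "))
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix must sum to 1 (got ", sum(class_mix), ")")
  if (any(class_mix < 0)) stop("class_mix fractions must be >= 0")
  if (cohort_n < 4) stop("cohort_n must be >= 4")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (detect_dropout_scale < 0) stop("detect_dropout_scale must be >= 0")
  if (beta_autophagy < 0) stop("beta_autophagy must be >= 0")
  if (n_cta > n_genes) stop("n_cta cannot exceed n_genes")
  structure(cfg, class = "sim_config")
}

#' Load a simulation configuration from YAML
#' @param path YAML file whose keys are [sim_config()] arguments.
#' @export
read_sim_config <- function(path) {
  args <- yaml::read_yaml(path)
  if (!is.null(args$class_mix)) args$class_mix <- unlist(args$class_mix)
  do.call(sim_config, args)
}

# Per-stage seed derivation from the root seed; keeps every stream below
# 2^31 and documented: stage k uses (seed + 77003 * k) mod (2^31 - 1).
stage_seed <- function(seed, stage) {
  (as.integer(seed) + 77003L * stage) %% 2147483647L
}

with_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  force(code)
}

rnb <- function(n, mu, phi) {
  if (phi == 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Simulate a two-group RNA-seq experiment (genes + ERE loci)
#'
#' Counts are negative binomial with variance mu + phi mu^2. Planted
#' upregulation (log2FC ~ Normal(lfc_mean, lfc_sd)) hits every
#' cancer-testis gene and a `frac_ere_up` fraction of LINE and LTR loci;
#' SINE and Other loci and non-CTA genes receive no effect. Deterministic
#' under a fixed seed.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (a [count_matrix()] with groups
#'   control/treated), `annotation` (genes + eres data.frames) and `truth`
#'   (per-feature true log2FC, CTA ids, planted ERE ids).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, 1L), {
    ng <- config$n_genes; ne <- config$n_ere
    gene_id <- sprintf("GENE%05d", seq_len(ng))
    biotype <- sample(GENE_BIOTYPES, ng, replace = TRUE,
                      prob = c(0.75, 0.15, 0.10))
    coding <- which(biotype == "protein_coding")
    cta_idx <- sort(sample(coding, min(config$n_cta, length(coding))))
    is_cta <- seq_len(ng) %in% cta_idx
    width <- sample(500:5000, ng, replace = TRUE)
    gstart <- cumsum(c(0L, width[-ng] + 1000L))
    genes <- data.frame(gene_id = gene_id, biotype = biotype, is_cta = is_cta,
                        chrom = "chr1", start = gstart, end = gstart + width,
                        strand = sample(c("+", "-"), ng, replace = TRUE),
                        stringsAsFactors = FALSE)
    cls <- sample(ERE_CLASSES, ne, replace = TRUE,
                  prob = config$class_mix[ERE_CLASSES])
    fam_of <- c(LINE = "L1", SINE = "Alu", LTR = "ERVL", Other = "misc")
    ewidth <- sample(300:6000, ne, replace = TRUE)
    estart <- cumsum(c(0L, ewidth[-ne] + 500L))
    eres <- data.frame(locus_id = sprintf("ERE%05d_%s", seq_len(ne), cls),
                       chrom = "chr2", start = estart, end = estart + ewidth,
                       strand = sample(c("+", "-"), ne, replace = TRUE),
                       ere_class = cls, family = fam_of[cls],
                       stringsAsFactors = FALSE)
    feature_id <- c(gene_id, eres$locus_id)
    nf <- ng + ne
    lfc <- stats::setNames(numeric(nf), feature_id)
    lfc[gene_id[cta_idx]] <- stats::rnorm(length(cta_idx),
                                          config$lfc_mean, config$lfc_sd)
    inducible <- which(cls %in% c("LINE", "LTR"))
    n_up <- round(config$frac_ere_up * length(inducible))
    up_ere <- if (n_up > 0) sort(sample(inducible, n_up)) else integer(0)
    lfc[eres$locus_id[up_ere]] <- stats::rnorm(n_up, config$lfc_mean,
                                               config$lfc_sd)
    base <- stats::rlnorm(nf, meanlog = log(50), sdlog = 1)
    nr <- config$n_reps_per_group
    groups <- rep(c("control", "treated"), each = nr)
    mu <- (base %o% rep(1, 2 * nr)) *
      2^(lfc %o% ifelse(groups == "treated", 1, 0))
    counts <- matrix(rnb(length(mu), mu, config$dispersion), nrow = nf,
                     dimnames = list(feature_id,
                                     paste0(rep(c("ctrl_", "trt_"), each = nr),
                                            rep(seq_len(nr), 2))))
    list(counts = count_matrix(counts, groups = groups),
         annotation = list(genes = genes, eres = eres),
         truth = list(log2FC = lfc, cta_ids = gene_id[cta_idx],
                      planted_ere = eres$locus_id[up_ere]))
  })
}

# Typical vertebrate amino-acid frequencies used as the Dirichlet centre.
AA_BACKGROUND <- c(A = .074, C = .025, D = .054, E = .054, F = .047,
                   G = .074, H = .026, I = .068, K = .058, L = .099,
                   M = .025, N = .045, P = .039, Q = .034, R = .052,
                   S = .057, T = .051, V = .073, W = .013, Y = .032)

#' Simulate a proteome with a D/G/V-enriched subset
#'
#' Per-protein residue frequencies are Dirichlet draws around typical
#' amino-acid frequencies; a `dgv_frac` subset has the Asp and Gly
#' concentrations multiplied by `dgv_enrichment` and Val by half the excess,
#' emulating proteins whose translation is most sensitive to loss of
#' DNMT2-dependent tRNA methylation.
#'
#' @param config A [sim_config()].
#' @return List with `proteins` (named character vector of sequences),
#'   `source_gene` (named map protein -> gene id) and `truth`
#'   (dgv_enriched logical per protein).
#' @export
simulate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$protein_length < 1) stop("protein_length must be >= 1")
  with_seed(stage_seed(config$seed, 2L), {
    np <- config$n_proteins
    enriched <- seq_len(np) <= round(config$dgv_frac * np)
    conc <- AA_BACKGROUND[AA20] * 60
    seqs <- character(np)
    for (i in seq_len(np)) {
      ci <- conc
      if (enriched[i]) {
        ci[c("D", "G")] <- ci[c("D", "G")] * config$dgv_enrichment
        ci["V"] <- ci["V"] * (1 + (config$dgv_enrichment - 1) / 2)
      }
      g <- stats::rgamma(20, shape = ci)
      f <- g / sum(g)
      seqs[i] <- paste(sample(AA20, config$protein_length, replace = TRUE,
                              prob = f), collapse = "")
    }
    names(seqs) <- sprintf("PROT%04d", seq_len(np))
    gene_ids <- sprintf("GENE%05d", ((seq_len(np) - 1L) %% config$n_genes) + 1L)
    names(gene_ids) <- names(seqs)
    list(proteins = seqs, source_gene = gene_ids,
         truth = list(dgv_enriched = stats::setNames(enriched, names(seqs))))
  })
}

#' Simulate an immunopeptidome with partial RNA drive and MNAR dropout
#'
#' Peptides are 8-11-mers cut from the simulated proteome (plus a small
#' fraction attributed to ERE loci). Each peptide's true log2 fold-change is
#' a * (source RNA log2FC) + (1 - a) * independent effect + noise, where the
#' independent effect of peptides from D/G/V-enriched proteins carries an
#' extra up-shift. Replicate intensities are log-normal; detection is
#' missing-not-at-random with dropout probability
#' detect_dropout_scale * plogis((c - log2 intensity) / 0.5), c the 10th
#' percentile of log2 intensities, so missingness concentrates at the
#' detection limit.
#'
#' @param config A [sim_config()].
#' @param proteome Output of [simulate_proteome()].
#' @param experiment Output of [simulate_experiment()] (same config).
#' @return List with `peptides` (peptide_table with intensity columns
#'   ctrl_i / trt_i) and `truth` (true peptide log2FC, rna_driven flag,
#'   rna component per peptide).
#' @export
simulate_immunopeptidome <- function(config, proteome, experiment) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, 3L), {
    np <- config$n_peptides
    a <- config$rna_drive
    n_ere_pep <- round(config$frac_ere_peptides * np)
    n_prot_pep <- np - n_ere_pep
    prot_idx <- sample(length(proteome$proteins), n_prot_pep, replace = TRUE)
    lens <- sample(8:11, np, replace = TRUE)
    seqs <- character(np)
    for (i in seq_len(n_prot_pep)) {
      s <- proteome$proteins[[prot_idx[i]]]
      start <- sample.int(nchar(s) - lens[i] + 1L, 1L)
      seqs[i] <- substring(s, start, start + lens[i] - 1L)
    }
    # ERE-attributed peptides: random sequences tagged to ERE loci
    eres <- experiment$annotation$eres
    ere_src <- if (n_ere_pep > 0)
      sample(eres$locus_id, n_ere_pep, replace = TRUE) else character(0)
    for (i in seq_len(n_ere_pep)) {
      seqs[n_prot_pep + i] <- paste(
        sample(AA20, lens[n_prot_pep + i], replace = TRUE,
               prob = AA_BACKGROUND[AA20]), collapse = "")
    }
    stopifnot(all(nchar(seqs) >= 8L & nchar(seqs) <= 11L))
    source_id <- c(names(proteome$proteins)[prot_idx], ere_src)
    source_gene <- c(proteome$source_gene[prot_idx], ere_src)
    cta_ids <- experiment$truth$cta_ids
    genes <- experiment$annotation$genes
    bio_of_gene <- ifelse(genes$gene_id %in% cta_ids, "CTA",
                   ifelse(genes$biotype == "protein_coding", "canonical",
                          "other-noncanonical"))
    names(bio_of_gene) <- genes$gene_id
    biotype <- c(unname(bio_of_gene[source_gene[seq_len(n_prot_pep)]]),
                 rep("ERE", n_ere_pep))
    rna_lfc <- experiment$truth$log2FC[source_gene]
    rna_lfc[is.na(rna_lfc)] <- 0
    enriched <- c(unname(proteome$truth$dgv_enriched[source_id[seq_len(n_prot_pep)]]),
                  rep(FALSE, n_ere_pep))
    has_effect <- stats::runif(np) < config$frac_pep_effect
    indep <- ifelse(has_effect, stats::rnorm(np, 0, config$pep_effect_sd), 0) +
      ifelse(enriched, config$dgv_dem_shift, 0)
    noise <- stats::rnorm(np, 0, config$peptide_noise_sd)
    pep_lfc <- a * rna_lfc + (1 - a) * indep + noise
    is_ere_pep <- seq_len(np) > n_prot_pep
    pep_lfc[is_ere_pep] <- pep_lfc[is_ere_pep] + config$ere_pep_lfc
    nr <- config$n_reps_per_group
    base <- stats::rnorm(np, 20, 2)
    # ERE MAPs are rare and low-abundance: place them near the detection limit
    base[is_ere_pep] <- stats::rnorm(sum(is_ere_pep), 17, 1)
    logI <- cbind(
      matrix(rep(base, nr), ncol = nr) +
        matrix(stats::rnorm(np * nr, 0, config$rep_noise_sd), ncol = nr),
      matrix(rep(base + pep_lfc, nr), ncol = nr) +
        matrix(stats::rnorm(np * nr, 0, config$rep_noise_sd), ncol = nr))
    colnames(logI) <- paste0(rep(c("ctrl_", "trt_"), each = nr),
                             rep(seq_len(nr), 2))
    # MNAR: dropout concentrated below the 10th intensity percentile, with
    # a logistic shoulder of 0.5 log2 units; detect_dropout_scale = 1 gives
    # ~8% missing values overall, typical of label-free replicates.
    cutoff <- stats::quantile(logI, 0.1)
    p_miss <- pmin(1, config$detect_dropout_scale *
                        stats::plogis((cutoff - logI) / 0.5))
    intens <- round(2^logI, 3)
    intens[stats::runif(length(logI)) < p_miss] <- NA
    tab <- data.frame(sequence = seqs, source_id = unname(source_id),
                      source_gene = unname(source_gene), biotype = biotype,
                      intens, stringsAsFactors = FALSE, check.names = FALSE)
    dup <- duplicated(tab$sequence)
    tab <- tab[!dup, , drop = FALSE]
    class(tab) <- c("peptide_table", "data.frame")
    truth <- list(log2FC = stats::setNames(pep_lfc[!dup], tab$sequence),
                  rna_component = stats::setNames((a * rna_lfc)[!dup],
                                                  tab$sequence),
                  rna_driven = stats::setNames(
                    (abs(a * rna_lfc) >= abs((1 - a) * indep))[!dup],
                    tab$sequence))
    list(peptides = tab, truth = truth)
  })
}

#' Simulate a patient cohort with latent autophagy and CD8 axes
#'
#' Each sample p carries a latent autophagy activity A_p ~ Normal(0, 1) and
#' a latent CD8 abundance C_p = -beta_cd8 A_p + Normal(0, 1). Autophagy-set
#' genes increase with A_p (log2-mean shift +A_p), ERE loci decrease with it
#' (shift -beta_autophagy A_p), and the CD8A/CD8B marker rows follow C_p.
#' Counts are negative binomial; the returned expression matrix is counts
#' scaled by a single cohort-wide factor to the cpm range (per-sample
#' sequencing-depth variation is not simulated) with a vanishing continuous
#' jitter so per-sample cumulative ERE scores are almost surely distinct.
#'
#' @param config A [sim_config()].
#' @return List of class `cohort_frame` with `expression` (cpm matrix),
#'   `samples`, `ere_ids`, `autophagy_genes` and `truth` (A and C latents).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$cohort_n < 4) stop("cohort_n must be >= 4")
  with_seed(stage_seed(config$seed, 4L), {
    n <- config$cohort_n
    samples <- sprintf("PT%04d", seq_len(n))
    A <- stats::rnorm(n)
    C <- -config$beta_cd8 * A + stats::rnorm(n)
    auto_genes <- sprintf("AUTOPHAGY%03d", seq_len(config$n_autophagy_genes))
    bg_genes <- sprintf("COHG%05d", seq_len(config$n_cohort_genes))
    ere_ids <- sprintf("COHERE%04d", seq_len(config$n_cohort_ere))
    feats <- c(auto_genes, bg_genes, c("CD8A", "CD8B"), ere_ids)
    base <- c(stats::rnorm(length(auto_genes), 6, 1),
              stats::rnorm(length(bg_genes), 6, 1.5),
              stats::rnorm(2, 6, 0.5),
              stats::rnorm(length(ere_ids), 3, 1))
    shift <- rbind(
      matrix(rep(A, each = length(auto_genes)), nrow = length(auto_genes)),
      matrix(0, nrow = length(bg_genes), ncol = n),
      matrix(rep(C, each = 2), nrow = 2),
      matrix(rep(-config$beta_autophagy * A, each = length(ere_ids)),
             nrow = length(ere_ids)))
    mu <- 2^(base + shift)
    counts <- matrix(rnb(length(mu), mu, config$dispersion),
                     nrow = length(feats),
                     dimnames = list(feats, samples))
    # one cohort-wide scale factor to the cpm range: per-sample depth
    # variation is not simulated, so planted couplings stay interpretable
    # (per-sample normalization would leak the autophagy-gene shifts into
    # every other feature's cpm)
    expr <- counts * (1e6 / stats::median(colSums(counts))) +
      matrix(stats::runif(length(mu)), nrow = length(feats)) * 1e-9
    structure(list(expression = expr, samples = samples, ere_ids = ere_ids,
                   autophagy_genes = auto_genes,
                   truth = list(A = stats::setNames(A, samples),
                                C = stats::setNames(C, samples))),
              class = "cohort_frame")
  })
}

#' Write simulated objects as the pipeline's external file formats
#'
#' @param experiment,proteome,immunopeptidome,cohort Outputs of the
#'   corresponding generators (any may be NULL to skip).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_simulation <- function(dir, experiment = NULL, proteome = NULL,
                             immunopeptidome = NULL, cohort = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (!is.null(experiment)) {
    paths["counts"] <- write_counts(experiment$counts,
                                    file.path(dir, "counts.tsv"))
    paths["gtf"] <- write_gene_gtf(experiment$annotation$genes,
                                   file.path(dir, "genes.gtf"))
    paths["ere_bed"] <- write_ere_bed(experiment$annotation$eres,
                                      file.path(dir, "eres.bed"))
    cta <- file.path(dir, "cta_ids.txt")
    writeLines(experiment$truth$cta_ids, cta)
    paths["cta"] <- cta
  }
  if (!is.null(proteome))
    paths["proteome"] <- write_fasta(proteome$proteins,
                                     file.path(dir, "proteome.fasta"))
  if (!is.null(immunopeptidome))
    paths["peptides"] <- write_peptides(immunopeptidome$peptides,
                                        file.path(dir, "peptides.csv"))
  if (!is.null(cohort)) {
    tab <- data.frame(feature_id = rownames(cohort$expression),
                      cohort$expression, check.names = FALSE)
    p <- file.path(dir, "cohort_cpm.tsv")
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["cohort"] <- p
  }
  paths
}
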