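# Synthetic-data generator: serum proteomics and metabolomics tables with
# planted group effects, plus a toy knowledge base (formulae, compounds,
# targets, pathways, diseases, drugs, networks) with controllable overlap
# structure. Everything is a deterministic function of the configuration
# seed, and every planted signal is reported in a ground-truth object so
# recall/FDR of the downstream calling can be measured.

#' Synthetic study configuration
#'
#' Parameters of the synthetic cohort and knowledge base. Defaults emulate
#' the scale of a serum DIA proteomics + dual metabolomics study of two
#' disease syndromes: 44/37/30 samples (syndrome A, syndrome B, healthy
#' controls), 388 quantified proteins with intensities spanning about six
#' orders of magnitude, 11 pooled-standard replicates, 1000 untargeted
#' metabolite features and 306 targeted metabolites in 10 chemical
#' categories, and planted differential-feature counts of 17/16/7
#' (syndrome-specific and shared proteins) and 90/115/110 (metabolites).
#'
#' @param seed integer; fully determines every generated table.
#' @param n_ccqs,n_qsbs,n_hc cohort group sizes.
#' @param n_proteins_identified,n_proteins_quantified protein counts; only
#'   quantified proteins enter the intensity table.
#' @param n_met_untargeted,n_met_targeted metabolite feature counts.
#' @param planted_dp_counts integer triple (ccqs-only, qsbs-only, shared)
#'   of planted differential proteins.
#' @param planted_dm_counts integer triple of planted untargeted
#'   differential metabolites.
#' @param planted_dm_targeted_counts integer triple of planted targeted
#'   differential metabolites.
#' @param effect_log2fc planted log2 shift of differential features.
#' @param cv_standard target coefficient of variation of the standard
#'   replicates (multiplicative noise).
#' @param missing_rate overall fraction of missing proteomics entries
#'   (missing-not-at-random; see Details).
#' @param n_standard number of standard-sample replicates.
#' @param sd_protein,sd_metabolite per-feature biological standard
#'   deviation on the log2 scale (scaled by a random factor in
#'   `[0.7, 1.3]` per feature).
#' @param kb_sizes named list of knowledge-base sizes and overlap
#'   structure; see [gen_knowledgebase()].
#'
#' @details Missingness follows a missing-not-at-random model: the dropout
#'   probability decreases with the feature's mean log-intensity through a
#'   logistic link, rescaled so the expected overall rate matches
#'   `missing_rate`. This mimics the intensity-dependent dropout of
#'   data-independent acquisition.
#'
#' @return A validated list of class `syn_config`.
#' @export
syn_config <- function(seed = 1L,
                       n_ccqs = 44L, n_qsbs = 37L, n_hc = 30L,
                       n_proteins_identified = 470L,
                       n_proteins_quantified = 388L,
                       n_met_untargeted = 1000L, n_met_targeted = 306L,
                       planted_dp_counts = c(ccqs = 17L, qsbs = 16L,
                                             shared = 7L),
                       planted_dm_counts = c(ccqs = 90L, qsbs = 115L,
                                             shared = 110L),
                       planted_dm_targeted_counts = c(ccqs = 20L,
                                                      qsbs = 25L,
                                                      shared = 15L),
                       effect_log2fc = 0.5,
                       cv_standard = 0.05,
                       missing_rate = 0.02,
                       n_standard = 11L,
                       sd_protein = 0.2,
                       sd_metabolite = 0.5,
                       kb_sizes = list()) {
  kb_default <- list(
    n_genes = 600L, compounds_per_herb = 8L,
    n_random_pathways = 8L, n_diseases = 12L, n_related_diseases = 5L,
    n_drugs = 40L, core_f1 = 60L, core_f2 = 50L, core_common = 40L,
    n_variants = 200L
  )
  kb_sizes <- utils::modifyList(kb_default, kb_sizes)
  cfg <- list(
    seed = as.integer(seed),
    n_ccqs = n_ccqs, n_qsbs = n_qsbs, n_hc = n_hc,
    n_proteins_identified = n_proteins_identified,
    n_proteins_quantified = n_proteins_quantified,
    n_met_untargeted = n_met_untargeted, n_met_targeted = n_met_targeted,
    planted_dp_counts = planted_dp_counts,
    planted_dm_counts = planted_dm_counts,
    planted_dm_targeted_counts = planted_dm_targeted_counts,
    effect_log2fc = effect_log2fc, cv_standard = cv_standard,
    missing_rate = missing_rate, n_standard = n_standard,
    sd_protein = sd_protein, sd_metabolite = sd_metabolite,
    kb_sizes = kb_sizes
  )
  counts <- c(n_ccqs, n_qsbs, n_hc, n_proteins_quantified,
              n_met_untargeted, n_met_targeted, n_standard)
  if (any(counts <= 0)) stop("all counts must be > 0")
  if (sum(planted_dp_counts) > n_proteins_quantified)
    stop("planted protein counts exceed the quantified feature count")
  if (sum(planted_dm_counts) > n_met_untargeted)
    stop("planted metabolite counts exceed the untargeted feature count")
  if (sum(planted_dm_targeted_counts) > n_met_targeted)
    stop("planted metabolite counts exceed the targeted feature count")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (kb_sizes$core_common > min(kb_sizes$core_f1, kb_sizes$core_f2))
    stop("core_common cannot exceed either syndrome core size")
  if (kb_sizes$n_genes < n_proteins_quantified)
    stop("gene universe must cover the quantified proteins")
  structure(cfg, class = "syn_config")
}

# the 10 metabolite chemical categories and their target proportions
.met_categories <- c(
  glycerophospholipid = 0.253, fatty_acyl = 0.233, amino_acid = 0.144,
  sphingolipid = 0.06, organic_acid = 0.06, carbohydrate = 0.05,
  benzenoid = 0.05, bile_acid = 0.05, carnitine = 0.05, other = 0.05
)

.gene_ids <- function(n) sprintf("G%04d", seq_len(n))
.met_u_ids <- function(n) sprintf("MU%04d", seq_len(n))
.met_t_ids <- function(n) sprintf("MT%03d", seq_len(n))

# Deterministic plan of every planted identifier; shared by all three
# generators so omics tables and knowledge base stay consistent.
.plan_truth <- function(cfg) {
  old <- .seeded_rng(cfg$seed)
  on.exit(.restore_rng(old))
  genes <- .gene_ids(cfg$kb_sizes$n_genes)
  prot_ids <- sort(sample(genes, cfg$n_proteins_quantified))
  ndp <- cfg$planted_dp_counts
  dp_all <- sample(prot_ids, sum(ndp))
  dp <- list(ccqs_only = dp_all[seq_len(ndp[1L])],
             qsbs_only = dp_all[ndp[1L] + seq_len(ndp[2L])],
             shared = dp_all[ndp[1L] + ndp[2L] + seq_len(ndp[3L])])
  dp_dir <- setNames(sample(c("up", "down"), sum(ndp), replace = TRUE,
                            prob = c(0.3, 0.7)), dp_all)
  mu_ids <- .met_u_ids(cfg$n_met_untargeted)
  ndm <- cfg$planted_dm_counts
  dm_all <- sample(mu_ids, sum(ndm))
  dm <- list(ccqs_only = dm_all[seq_len(ndm[1L])],
             qsbs_only = dm_all[ndm[1L] + seq_len(ndm[2L])],
             shared = dm_all[ndm[1L] + ndm[2L] + seq_len(ndm[3L])])
  dm_dir <- setNames(sample(c("up", "down"), sum(ndm), replace = TRUE),
                     dm_all)
  mt_ids <- .met_t_ids(cfg$n_met_targeted)
  ndt <- cfg$planted_dm_targeted_counts
  dt_all <- sample(mt_ids, sum(ndt))
  dmt <- list(ccqs_only = dt_all[seq_len(ndt[1L])],
              qsbs_only = dt_all[ndt[1L] + seq_len(ndt[2L])],
              shared = dt_all[ndt[1L] + ndt[2L] + seq_len(ndt[3L])])
  dmt_dir <- setNames(sample(c("up", "down"), sum(ndt), replace = TRUE),
                      dt_all)
  cat_u <- setNames(sample(names(.met_categories), cfg$n_met_untargeted,
                           replace = TRUE, prob = .met_categories), mu_ids)
  cat_t <- setNames(sample(names(.met_categories), cfg$n_met_targeted,
                           replace = TRUE, prob = .met_categories), mt_ids)
  structure(
    list(
      genes = genes, prot_ids = prot_ids,
      dp = dp, dp_direction = dp_dir,
      dm = dm, dm_direction = dm_dir,
      dm_targeted = dmt, dm_targeted_direction = dmt_dir,
      met_categories_untargeted = cat_u, met_categories_targeted = cat_t,
      panel_markers = list(
        ccqs_protein = sort(dp$ccqs_only)[seq_len(min(4L, ndp[1L]))],
        qsbs_protein = sort(dp$qsbs_only)[seq_len(min(5L, ndp[2L]))],
        ccqs_metabolite = sort(dm$ccqs_only)[seq_len(min(4L, ndm[1L]))],
        qsbs_metabolite = sort(dm$qsbs_only)[seq_len(min(4L, ndm[2L]))]
      )
    ),
    class = "ground_truth"
  )
}

#' Planted ground truth of a synthetic run
#'
#' Returns the planted differential-feature identifiers (with direction and
#' syndrome partition), the metabolite category assignment, and the planted
#' biomarker panel markers for a configuration. The same object is attached
#' to every generator's output, so downstream recall/FDR can be evaluated
#' without re-deriving the truth.
#'
#' @param cfg a [syn_config].
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "syn_config"))
  .plan_truth(cfg)
}

# per-feature planted log2 offsets for a sample group
.planted_offset <- function(ids, planted_sets, directions, effect, groups) {
  off <- setNames(rep(0, length(ids)), ids)
  hit <- intersect(ids, unlist(planted_sets[groups]))
  off[hit] <- ifelse(directions[hit] == "up", effect, -effect)
  off
}

.sample_ids <- function(cfg) {
  list(ccqs = sprintf("CCQS%02d", seq_len(cfg$n_ccqs)),
       qsbs = sprintf("QSBS%02d", seq_len(cfg$n_qsbs)),
       hc = sprintf("HC%02d", seq_len(cfg$n_hc)),
       std = sprintf("STD%02d", seq_len(cfg$n_standard)))
}

#' Generate the synthetic serum proteomics table
#'
#' Log-normal baseline intensities with feature means spanning about six
#' orders of magnitude; planted differential proteins are shifted by
#' `effect_log2fc` on the log2 scale in their syndrome group(s) (shared
#' proteins shift in both). Standard-sample replicates carry pure
#' multiplicative noise calibrated to `cv_standard`. Missingness is
#' applied to cohort samples only, preferentially to low-intensity
#' features (logistic link on mean log2 intensity), and every feature
#' retains at least one observed value.
#'
#' @param cfg a [syn_config].
#' @return List with `table` (an [omics_table]) and `truth`
#'   (a `ground_truth`).
#' @export
gen_proteomics <- function(cfg) {
  stopifnot(inherits(cfg, "syn_config"))
  truth <- .plan_truth(cfg)
  old <- .seeded_rng(cfg$seed + 1L)
  on.exit(.restore_rng(old))
  ids <- truth$prot_ids
  nf <- length(ids)
  mu <- setNames(runif(nf, 10, 30), ids)      # log2; ~6 decades of raw range
  sdf <- cfg$sd_protein * runif(nf, 0.7, 1.3)
  smp <- .sample_ids(cfg)
  grp_cols <- c(smp$ccqs, smp$qsbs, smp$hc)
  grp <- rep(c("CCQS", "QSBS", "HC"), c(cfg$n_ccqs, cfg$n_qsbs, cfg$n_hc))
  off_ccqs <- .planted_offset(ids, truth$dp, truth$dp_direction,
                              cfg$effect_log2fc, c("ccqs_only", "shared"))
  off_qsbs <- .planted_offset(ids, truth$dp, truth$dp_direction,
                              cfg$effect_log2fc, c("qsbs_only", "shared"))
  offset <- cbind(
    matrix(off_ccqs, nf, cfg$n_ccqs),
    matrix(off_qsbs, nf, cfg$n_qsbs),
    matrix(0, nf, cfg$n_hc)
  )
  log2x <- mu + offset + matrix(rnorm(nf * length(grp), 0, sdf),
                                nf, length(grp))
  # standard replicates: multiplicative noise with CV = cv_standard
  sdlog <- sqrt(log(1 + cfg$cv_standard^2))
  std <- matrix(2^mu, nf, cfg$n_standard) *
    exp(matrix(rnorm(nf * cfg$n_standard, 0, sdlog), nf, cfg$n_standard))
  x <- cbind(2^log2x, std)
  colnames(x) <- c(grp_cols, smp$std)
  rownames(x) <- ids
  # MNAR dropout on cohort columns: each cell goes missing with
  # probability plogis(-(log2 intensity - L) / tau), a soft detection
  # limit, with L solved so the expected overall rate matches the
  # configuration. Low-intensity features lose most values, as in DIA.
  if (cfg$missing_rate > 0) {
    tau <- 0.5
    L <- stats::uniroot(function(l)
      mean(plogis(-(log2x - l) / tau)) - cfg$missing_rate,
      range(log2x) + c(-5, 5))$root
    pm <- plogis(-(log2x - L) / tau)
    miss <- matrix(rbinom(length(pm), 1, pm), nf, length(grp)) == 1
    # keep at least one observed cohort value per feature
    all_gone <- rowSums(!miss) == 0
    miss[all_gone, 1L] <- FALSE
    xg <- x[, seq_along(grp), drop = FALSE]
    xg[miss] <- NA_real_
    x[, seq_along(grp)] <- xg
  }
  tab <- omics_table(x, c(grp, rep("STD", cfg$n_standard)))
  attr(tab, "n_identified") <- cfg$n_proteins_identified
  list(table = tab, truth = truth)
}

# shared machinery for the two metabolomics tables
.gen_met_table <- function(cfg, ids, categories, planted, directions,
                           mu_range, sd_feature, seed_offset) {
  old <- .seeded_rng(cfg$seed + seed_offset)
  on.exit(.restore_rng(old))
  nf <- length(ids)
  mu <- setNames(runif(nf, mu_range[1L], mu_range[2L]), ids)
  sdf <- sd_feature * runif(nf, 0.7, 1.3)
  smp <- .sample_ids(cfg)
  grp <- rep(c("CCQS", "QSBS", "HC"), c(cfg$n_ccqs, cfg$n_qsbs, cfg$n_hc))
  off_ccqs <- .planted_offset(ids, planted, directions,
                              cfg$effect_log2fc, c("ccqs_only", "shared"))
  off_qsbs <- .planted_offset(ids, planted, directions,
                              cfg$effect_log2fc, c("qsbs_only", "shared"))
  offset <- cbind(
    matrix(off_ccqs, nf, cfg$n_ccqs),
    matrix(off_qsbs, nf, cfg$n_qsbs),
    matrix(0, nf, cfg$n_hc)
  )
  x <- 2^(mu + offset + matrix(rnorm(nf * length(grp), 0, sdf),
                               nf, length(grp)))
  colnames(x) <- c(smp$ccqs, smp$qsbs, smp$hc)
  rownames(x) <- ids
  omics_table(x, grp,
              feature_meta = data.frame(id = ids,
                                        category = unname(categories[ids]),
                                        stringsAsFactors = FALSE))
}

#' Generate the synthetic metabolomics tables
#'
#' Untargeted features carry peak areas, targeted metabolites positive
#' concentrations; both tables carry chemical-category labels drawn from
#' the 10 configured categories (glycerophospholipids, fatty acyls and
#' amino acids dominating). Planted differential metabolites shift by
#' `effect_log2fc` between their syndrome group and controls.
#'
#' @param cfg a [syn_config].
#' @return List with `untargeted`, `targeted` (both [omics_table]) and
#'   `truth` (a `ground_truth`).
#' @export
gen_metabolomics <- function(cfg) {
  stopifnot(inherits(cfg, "syn_config"))
  truth <- .plan_truth(cfg)
  unt <- .gen_met_table(cfg, .met_u_ids(cfg$n_met_untargeted),
                        truth$met_categories_untargeted,
                        truth$dm, truth$dm_direction,
                        c(12, 26), cfg$sd_metabolite, 2L)
  tgt <- .gen_met_table(cfg, .met_t_ids(cfg$n_met_targeted),
                        truth$met_categories_targeted,
                        truth$dm_targeted, truth$dm_targeted_direction,
                        c(-2, 10), cfg$sd_metabolite, 3L)
  list(untargeted = unt, targeted = tgt, truth = truth)
}

# build a set overlapping `base` with Jaccard index ~ j_target; the pool
# cap only binds for near-zero targets, where the realized index stays
# far below the similarity thresholds
.overlap_set <- function(base, j_target, pool) {
  s <- max(1L, ceiling(length(base) * j_target) + 3L)
  extra <- max(0L, round(s / j_target) - length(base))
  extra <- min(extra, length(pool))
  c(sample(base, min(s, length(base))), sample(pool, extra))
}

#' Generate the synthetic knowledge base
#'
#' Builds six formulae (codes F1-1..F2-3, three per syndrome) with herb
#' counts 7/5/5/2/11/3, compound records whose activity attributes
#' straddle the filter thresholds (TCMSP-style OB/DL, ETCM-style gradings,
#' unconditional Q-markers), and compound-target assignments arranged so
#' that each syndrome's formula triple shares a known signature core
#' (`kb_sizes$core_f1`, `core_f2`, overlapping in `core_common` genes)
#' while formula-specific extra targets are drawn from disjoint pools.
#' Also generates pathway collections over genes, metabolites and mixed
#' ids (with one planted signal pathway per syndrome, named identically
#' across collections), disease gene/variant sets with controlled Jaccard
#' overlap to a query disease, ATC-coded drug records whose targets
#' overlap the signature partitions in a category-specific way, a
#' connected PPI network over the gene universe, and a metabolite-gene
#' association network wired so each syndrome's planted molecules form an
#' extractable subnetwork.
#'
#' @param cfg a [syn_config].
#' @return List of class `knowledge_base` with elements `formulae`,
#'   `compounds`, `targets`, `pathways` (lists `gene`, `metabolite`,
#'   `joint`), `diseases` (query + candidates), `drugs`, `ppi`, `metgene`,
#'   `signature_cores`, and `truth`.
#' @export
gen_knowledgebase <- function(cfg) {
  stopifnot(inherits(cfg, "syn_config"))
  truth <- .plan_truth(cfg)
  kb <- cfg$kb_sizes
  old <- .seeded_rng(cfg$seed + 4L)
  on.exit(.restore_rng(old))
  genes <- truth$genes

  ## formulae and herbs: per-formula herb counts fixed at 7/5/5/2/11/3
  ## (33 slots) over 26 distinct herbs, so some herbs recur across the
  ## formulae of one syndrome -- but never across a full syndrome triple,
  ## which keeps the signature intersections clean
  codes <- c("F1-1", "F1-2", "F1-3", "F2-1", "F2-2", "F2-3")
  syn <- rep(c("CCQS", "QSBS"), each = 3L)
  herbs <- sprintf("H%02d", 1:26)
  herb_assign <- list(
    "F1-1" = herbs[1:7],
    "F1-2" = herbs[8:12],
    "F1-3" = c(herbs[13:14], herbs[c(1, 2, 8)]),
    "F2-1" = herbs[15:16],
    "F2-2" = c(herbs[17:26], herbs[15]),
    "F2-3" = herbs[c(16, 17, 18)]
  )
  formulae <- data.frame(
    code = rep(codes, lengths(herb_assign)),
    syndrome = rep(syn, lengths(herb_assign)),
    herb = unlist(herb_assign, use.names = FALSE),
    stringsAsFactors = FALSE
  )

  ## compound records with attributes straddling the activity thresholds
  n_cmp <- kb$compounds_per_herb * length(herbs)
  compounds <- data.frame(
    compound = sprintf("CMP%04d", seq_len(n_cmp)),
    herb = rep(herbs, each = kb$compounds_per_herb),
    source = sample(c("tcmsp", "etcm", "qmarker"), n_cmp, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2)),
    stringsAsFactors = FALSE
  )
  compounds$OB <- ifelse(compounds$source == "tcmsp",
                         runif(n_cmp, 10, 60), NA_real_)
  compounds$DL <- ifelse(compounds$source == "tcmsp",
                         runif(n_cmp, 0.05, 0.5), NA_real_)
  compounds$grading <- ifelse(
    compounds$source == "etcm",
    sample(c("good", "moderate", "weak", "none"), n_cmp, replace = TRUE,
           prob = c(0.3, 0.3, 0.2, 0.2)),
    NA_character_)

  ## signature cores and disjoint formula-specific target pools
  core_f1 <- sample(genes, kb$core_f1)
  core_common <- core_f1[seq_len(kb$core_common)]
  core_f2 <- c(core_common,
               sample(setdiff(genes, core_f1),
                      kb$core_f2 - kb$core_common))
  rest <- setdiff(genes, union(core_f1, core_f2))
  pools <- split(sample(rest), rep_len(seq_along(codes), length(rest)))
  names(pools) <- codes

  active <- filter_active(compounds)
  # herbs appearing in exactly one formula; only their compounds receive
  # formula-specific pool targets, so herbs shared between two formulae
  # cannot smuggle pool genes into a third formula's target set
  herb_use <- unique(formulae[, c("code", "herb")])
  exclusive_herbs <- names(which(table(herb_use$herb) == 1L))
  target_rows <- list()
  for (i in seq_along(codes)) {
    code <- codes[i]
    f_herbs <- formulae$herb[formulae$code == code]
    f_active <- active$compound[active$herb %in% f_herbs]
    n_wt <- max(1L, round(0.8 * length(f_active)))
    with_t <- sample(f_active, n_wt)
    core <- if (syn[i] == "CCQS") core_f1 else core_f2
    pool <- pools[[code]]
    # every core gene is carried by at least one compound of the formula
    carrier <- sample(with_t, length(core), replace = TRUE)
    rows <- data.frame(compound = carrier, target = core,
                       stringsAsFactors = FALSE)
    excl_cmp <- active$compound[active$herb %in%
                                  intersect(f_herbs, exclusive_herbs)]
    for (cmp in with_t) {
      extra <- if (cmp %in% excl_cmp) sample(pool, sample(3:8, 1L))
               else character(0)
      some_core <- sample(core, sample(2:6, 1L))
      rows <- rbind(rows, data.frame(compound = cmp,
                                     target = c(extra, some_core),
                                     stringsAsFactors = FALSE))
    }
    target_rows[[code]] <- unique(rows)
  }
  targets <- do.call(rbind, target_rows)
  rownames(targets) <- NULL

  ## pathway collections; the planted signal pathway of each syndrome has
  ## the same term name in all three collections so cross-view consistency
  ## can match it
  # signal pathways are built from syndrome-specific planted molecules
  # only, so each one should enrich in exactly one syndrome's views
  dp_ccqs <- truth$dp$ccqs_only
  dp_qsbs <- truth$dp$qsbs_only
  dm_ccqs <- truth$dm$ccqs_only
  dm_qsbs <- truth$dm$qsbs_only
  mu_ids <- .met_u_ids(cfg$n_met_untargeted)
  rnd_sets <- function(prefix, universe, size) {
    out <- lapply(seq_len(kb$n_random_pathways), function(i)
      sample(universe, size))
    names(out) <- sprintf("%s_%02d", prefix, seq_along(out))
    out
  }
  pw_gene <- c(
    list(ccqs_signal = unique(c(sample(dp_ccqs, 12L), sample(genes, 5L))),
         qsbs_signal = unique(c(sample(dp_qsbs, 12L), sample(genes, 5L)))),
    rnd_sets("pw_gene", genes, 25L)
  )
  pw_met <- c(
    list(ccqs_signal = unique(c(sample(dm_ccqs, 15L), sample(mu_ids, 6L))),
         qsbs_signal = unique(c(sample(dm_qsbs, 15L), sample(mu_ids, 6L)))),
    rnd_sets("pw_met", mu_ids, 25L)
  )
  pw_joint <- c(
    list(ccqs_signal = unique(c(sample(dp_ccqs, 8L), sample(dm_ccqs, 10L),
                                sample(genes, 3L))),
         qsbs_signal = unique(c(sample(dp_qsbs, 8L), sample(dm_qsbs, 10L),
                                sample(genes, 3L)))),
    rnd_sets("pw_joint", c(genes, mu_ids), 25L)
  )

  ## disease gene/variant sets with controlled Jaccard overlap
  variants <- sprintf("V%04d", seq_len(kb$n_variants))
  chd <- list(genes = sample(genes, 80L), variants = sample(variants, 60L))
  gene_pool <- setdiff(genes, chd$genes)
  var_pool <- setdiff(variants, chd$variants)
  candidates <- list()
  for (i in seq_len(kb$n_diseases)) {
    related <- i <= kb$n_related_diseases
    jg <- if (related) runif(1, 0.28, 0.4) else runif(1, 0.03, 0.12)
    jv <- if (related) runif(1, 0.08, 0.2) else runif(1, 0.0, 0.03)
    g <- .overlap_set(chd$genes, jg, gene_pool)
    v <- if (jv > 0) .overlap_set(chd$variants, jv, var_pool)
         else sample(var_pool, 20L)
    candidates[[sprintf("disease_%02d", i)]] <-
      list(genes = unique(g), variants = unique(v), related = related)
  }

  ## ATC-coded drugs whose targets tie categories to signature partitions
  f1_spec <- setdiff(core_f1, core_common)
  f2_spec <- setdiff(core_f2, core_common)
  drug_specs <- data.frame(
    drug = sprintf("DRUG%02d", seq_len(kb$n_drugs)),
    atc = c(sprintf("C01AA%02d", 1:10), sprintf("A10BA%02d", 1:8),
            sprintf("A08AB%02d", 1:6), sprintf("B01AC%02d", 1:6),
            sprintf("N02BE%02d", seq_len(kb$n_drugs - 30L))),
    stringsAsFactors = FALSE
  )
  drug_rows <- lapply(seq_len(nrow(drug_specs)), function(i) {
    atc <- drug_specs$atc[i]
    tg <- if (startsWith(atc, "C"))
      c(sample(core_common, sample(3:6, 1L)), sample(rest, 2L))
    else if (startsWith(atc, "A10"))
      c(sample(f1_spec, sample(2:4, 1L)), sample(rest, 2L))
    else if (startsWith(atc, "A08") || startsWith(atc, "B01"))
      c(sample(f2_spec, sample(1:3, 1L)), sample(rest, 2L))
    else sample(rest, sample(2:5, 1L))
    data.frame(drug = drug_specs$drug[i], atc = atc, target = unique(tg),
               stringsAsFactors = FALSE)
  })
  drugs <- do.call(rbind, drug_rows)
  rownames(drugs) <- NULL

  ## connected PPI over the gene universe: random spanning tree + extras
  ng <- length(genes)
  tree <- data.frame(from = genes[vapply(2:ng, function(i)
    sample.int(i - 1L, 1L), integer(1L))], to = genes[2:ng])
  extra <- data.frame(from = genes[sample.int(ng, 1000L, replace = TRUE)],
                      to = genes[sample.int(ng, 1000L, replace = TRUE)])
  ed <- rbind(tree, extra)
  ed <- ed[ed$from != ed$to, ]
  key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  ed <- ed[!duplicated(key), ]
  ed$weight <- runif(nrow(ed), 0.1, 1)
  ppi <- molecular_network(ed, data.frame(id = genes, kind = "gene",
                                          stringsAsFactors = FALSE))

  ## metabolite-gene association network with extractable planted cores
  mg <- data.frame(
    from = mu_ids[sample.int(length(mu_ids), 1500L, replace = TRUE)],
    to = genes[sample.int(ng, 1500L, replace = TRUE)]
  )
  wire <- function(dms, dps, tgts) {
    s_dm <- sort(dms)[1:8]; s_dp <- sort(dps)[1:4]; s_tg <- sort(tgts)[1:5]
    direct <- data.frame(from = s_dm,
                         to = rep(c(s_dp, s_tg[1:4]), length.out = 8L))
    bridges <- sample(setdiff(genes, c(s_dp, s_tg)), 3L)
    br <- do.call(rbind, lapply(bridges, function(b)
      data.frame(from = sample(s_dm, 4L), to = b)))
    rbind(direct, br, data.frame(from = s_dm[1:2], to = s_tg[5]))
  }
  mg <- rbind(mg,
              wire(truth$dm$ccqs_only, truth$dp$ccqs_only, f1_spec),
              wire(truth$dm$qsbs_only, truth$dp$qsbs_only, f2_spec))
  mg <- mg[mg$from != mg$to, ]
  key <- paste(pmin(mg$from, mg$to), pmax(mg$from, mg$to))
  mg <- mg[!duplicated(key), ]
  mg$weight <- 1
  metgene <- molecular_network(
    mg,
    data.frame(id = c(genes, mu_ids),
               kind = rep(c("gene", "metabolite"),
                          c(ng, length(mu_ids))),
               stringsAsFactors = FALSE))

  structure(
    list(formulae = formulae, compounds = compounds, targets = targets,
         pathways = list(gene = pw_gene, metabolite = pw_met,
                         joint = pw_joint),
         diseases = list(query = chd, candidates = candidates),
         drugs = drugs, ppi = ppi, metgene = metgene,
         signature_cores = list(f1 = sort(core_f1), f2 = sort(core_f2),
                                common = sort(core_common),
                                f1_specific = sort(f1_spec),
                                f2_specific = sort(f2_spec)),
         truth = truth),
    class = "knowledge_base"
  )
}

#' Write a full synthetic run to plain-text files
#'
#' Serializes omics tables and sample metadata as TSV, pathway collections
#' as GMT, networks as SIF (+ weight and node-attribute TSVs), knowledge
#' tables as TSV, and the planted ground truth as a sidecar TSV.
#'
#' @param cfg a [syn_config].
#' @param outdir output directory (created if absent).
#' @return Invisibly, the output directory.
#' @export
write_syndata <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "syn_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(outdir, ...)
  prot <- gen_proteomics(cfg)
  met <- gen_metabolomics(cfg)
  kb <- gen_knowledgebase(cfg)
  write_omics_tsv(prot$table, fp("proteomics.tsv"), fp("proteomics_meta.tsv"))
  write_omics_tsv(met$untargeted, fp("met_untargeted.tsv"),
                  fp("met_untargeted_meta.tsv"))
  write_omics_tsv(met$targeted, fp("met_targeted.tsv"),
                  fp("met_targeted_meta.tsv"))
  write_gmt(kb$pathways$gene, fp("pathways_gene.gmt"))
  write_gmt(kb$pathways$metabolite, fp("pathways_met.gmt"))
  write_gmt(kb$pathways$joint, fp("pathways_joint.gmt"))
  write_gmt(lapply(kb$diseases$candidates, `[[`, "genes"),
            fp("disease_genes.gmt"))
  write_gmt(lapply(kb$diseases$candidates, `[[`, "variants"),
            fp("disease_variants.gmt"))
  write.table(kb$formulae, fp("formulae.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(kb$compounds, fp("compounds.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(kb$targets, fp("targets.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(kb$drugs, fp("drugs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_sif(kb$ppi, fp("ppi.sif"), fp("ppi_weights.tsv"),
            fp("ppi_nodes.tsv"))
  write_sif(kb$metgene, fp("metgene.sif"), fp("metgene_weights.tsv"),
            fp("metgene_nodes.tsv"))
  tr <- kb$truth
  truth_df <- rbind(
    data.frame(kind = "protein", partition = rep(names(tr$dp),
               lengths(tr$dp)), id = unlist(tr$dp)),
    data.frame(kind = "metabolite", partition = rep(names(tr$dm),
               lengths(tr$dm)), id = unlist(tr$dm)),
    data.frame(kind = "metabolite_targeted",
               partition = rep(names(tr$dm_targeted),
                               lengths(tr$dm_targeted)),
               id = unlist(tr$dm_targeted))
  )
  rownames(truth_df) <- NULL
  write.table(truth_df, fp("ground_truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(unclass(cfg), fp("config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(outdir)
}
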