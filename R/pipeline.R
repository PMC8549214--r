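# End-to-end orchestration: synthetic data -> differential omics ->
# network pharmacology -> graph analytics -> enrichment -> panels, with a
# consolidated machine-readable report.

#' Default analysis thresholds
#'
#' The thresholds used throughout the pipeline: fold change > 1.1 and
#' p < 0.05 for proteins, VIP > 1 with q < 0.05 (untargeted) or p < 0.05
#' (targeted) for metabolites, OB >= 30 and DL >= 0.18 for compound
#' activity, JIg > 0.2 and JIv > 0.05 for disease similarity, propagation
#' alpha 0.5 with 10 added genes, and the "high" clustering stringency.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(fc = 1.1, p = 0.05, vip = 1, fdr = 0.05,
       ob = 30, dl = 0.18, jig = 0.2, jiv = 0.05,
       alpha = 0.5, topk = 10L, stringency = "high",
       enrich_p = 0.05)
}

#' Reference clinical cohort summary
#'
#' Loads the cohort baseline table shipped with the package (group sizes,
#' demographics, comorbidity counts and clinical chemistry for two
#' syndrome groups and healthy controls) in the long format accepted by
#' [cohort_stats()].
#'
#' @return data.frame with columns `variable`, `type`, `group`, `n`,
#'   `mean`, `sd`, `events`.
#' @export
load_cohort_reference <- function() {
  read.delim(system.file("extdata", "cohort_summary.tsv",
                         package = "syndromics"))
}

# differential-metabolite calling for one syndrome on one table
.dm_stage <- function(table, syndrome, mode, thr, seed) {
  sub <- subset_samples(table, c(syndrome, "HC"))
  X <- t(log2(sub$intensity))
  y <- sub$samples$group
  model <- fit_oplsda(X, y, n_ortho = 1L)
  uni <- univariate_mwu_fdr(X, y)
  cats <- setNames(table$feature_meta$category, table$feature_meta$id)
  called <- call_dms(model$vip, uni, mode = mode, categories = cats,
                     vip_thresh = thr$vip, p_thresh = if (mode ==
                       "untargeted") thr$fdr else thr$p)
  q2 <- cross_validate_q2(X, y, n_ortho = 1L, seed = seed)
  list(model = model, called = called, Q2 = q2$Q2, R2Y = model$R2Y)
}

.recall_fdr <- function(called_ids, true_ids, universe_ids) {
  tp <- length(intersect(called_ids, true_ids))
  recall <- if (length(true_ids)) tp / length(true_ids) else NA_real_
  fdr <- if (length(called_ids))
    (length(called_ids) - tp) / length(called_ids) else 0
  list(recall = recall, fdr = fdr, n_called = length(called_ids))
}

#' Run the integrated multi-omics + network pharmacology pipeline
#'
#' Executes every stage on a self-contained synthetic study: generates the
#' omics tables and knowledge base, calls differential proteins and
#' metabolites per syndrome, aggregates formula targets and signature
#' partitions, maps related diseases and ATC drug-class overlaps, expands
#' the differential proteins on the PPI network by label propagation,
#' extracts the integrated metabolite-gene networks, runs
#' over-representation analysis in three views plus disease-term
#' clustering, evaluates the planted biomarker panels within and across
#' syndromes, and assembles everything into a JSON-serializable report.
#' All randomness derives from `cfg$seed`, so an identical configuration
#' reproduces the report byte for byte.
#'
#' @param cfg a [syn_config].
#' @param thresholds list as from [default_thresholds()].
#' @return A nested list (the report) with sections `config`, `cohort`,
#'   `proteomics`, `metabolomics`, `netpharm`, `networks`, `enrichment`,
#'   `consistency`, `panels`.
#' @export
run_pipeline <- function(cfg = syn_config(), thresholds = default_thresholds()) {
  stopifnot(inherits(cfg, "syn_config"))
  thr <- utils::modifyList(default_thresholds(), thresholds)
  prot <- gen_proteomics(cfg)
  met <- gen_metabolomics(cfg)
  kb <- gen_knowledgebase(cfg)
  truth <- prot$truth

  ## ---- cohort ----
  cohort <- load_cohort_reference()
  cohort_p <- cohort_stats(cohort)

  ## ---- proteomics ----
  imputed <- suppressWarnings(impute_missing(prot$table))
  cv <- qc_cv(imputed)
  corr <- qc_correlation(imputed)
  dp_ccqs <- diff_proteins(imputed, "CCQS", "HC", thr$fc, thr$p)
  dp_qsbs <- diff_proteins(imputed, "QSBS", "HC", thr$fc, thr$p)
  ids_ccqs <- dp_ccqs$id[dp_ccqs$significant]
  ids_qsbs <- dp_qsbs$id[dp_qsbs$significant]
  dp_venn <- venn_sets(ids_ccqs, ids_qsbs)
  dp_truth_ccqs <- c(truth$dp$ccqs_only, truth$dp$shared)
  dp_truth_qsbs <- c(truth$dp$qsbs_only, truth$dp$shared)
  proteomics <- list(
    n_quantified = nrow(imputed$intensity),
    cv_fraction_below_010 = cv$fraction_below,
    min_sample_correlation = min(corr[upper.tri(corr)], na.rm = TRUE),
    n_dp = list(CCQS = length(ids_ccqs), QSBS = length(ids_qsbs)),
    venn = lapply(dp_venn, length),
    dp_ids = list(CCQS = ids_ccqs, QSBS = ids_qsbs),
    eval = list(
      CCQS = .recall_fdr(ids_ccqs, dp_truth_ccqs, imputed$intensity),
      QSBS = .recall_fdr(ids_qsbs, dp_truth_qsbs, imputed$intensity))
  )

  ## ---- metabolomics ----
  met_res <- list()
  for (s in c("CCQS", "QSBS")) {
    met_res[[s]] <- list(
      untargeted = .dm_stage(met$untargeted, s, "untargeted", thr,
                             cfg$seed + 10L),
      targeted = .dm_stage(met$targeted, s, "targeted", thr,
                           cfg$seed + 11L))
  }
  dm_ids <- lapply(met_res, function(r)
    r$untargeted$called$results$id[r$untargeted$called$results$significant])
  dm_venn <- venn_sets(dm_ids$CCQS, dm_ids$QSBS)
  dm_truth <- list(CCQS = c(truth$dm$ccqs_only, truth$dm$shared),
                   QSBS = c(truth$dm$qsbs_only, truth$dm$shared))
  metabolomics <- list(
    n_dm = lapply(dm_ids, length),
    venn = lapply(dm_venn, length),
    Q2 = lapply(met_res, function(r) list(untargeted = r$untargeted$Q2,
                                          targeted = r$targeted$Q2)),
    R2Y = lapply(met_res, function(r) list(untargeted = r$untargeted$R2Y)),
    category_proportions = lapply(met_res, function(r)
      as.list(r$untargeted$called$category_proportions)),
    dm_ids = dm_ids,
    eval = list(
      CCQS = .recall_fdr(dm_ids$CCQS, dm_truth$CCQS, NULL),
      QSBS = .recall_fdr(dm_ids$QSBS, dm_truth$QSBS, NULL))
  )

  ## ---- network pharmacology ----
  active <- filter_active(kb$compounds, thr$ob, thr$dl)
  ftab <- lapply(unique(kb$formulae$code), function(code) {
    herbs <- kb$formulae$herb[kb$formulae$code == code]
    ft <- formula_targets(herbs, active, kb$targets)
    list(code = code, n_herbs = length(herbs), n_active = ft$n_active,
         n_active_with_targets = ft$n_active_with_targets,
         n_targets = ft$n_targets, targets = ft$targets)
  })
  names(ftab) <- unique(kb$formulae$code)
  sig_f1 <- signature_targets(ftab[["F1-1"]]$targets, ftab[["F1-2"]]$targets,
                              ftab[["F1-3"]]$targets)
  sig_f2 <- signature_targets(ftab[["F2-1"]]$targets, ftab[["F2-2"]]$targets,
                              ftab[["F2-3"]]$targets)
  sig_parts <- specific_signatures(sig_f1, sig_f2)
  dis <- disease_similarity(kb$diseases$query, kb$diseases$candidates,
                            thr$jig, thr$jiv)
  drug_overlap <- map_drug_overlap(sig_parts, kb$drugs)
  netpharm <- list(
    formula_table = lapply(ftab, function(f) f[c("code", "n_herbs",
      "n_active", "n_active_with_targets", "n_targets")]),
    n_signature = list(F1 = length(sig_f1), F2 = length(sig_f2)),
    partitions = lapply(sig_parts, length),
    related_diseases = dis$disease[dis$related],
    drug_overlap = drug_overlap$counts
  )

  ## ---- graph analytics ----
  networks <- list()
  for (s in c("CCQS", "QSBS")) {
    seeds <- intersect(proteomics$dp_ids[[s]], network_nodes(kb$ppi))
    prop <- label_propagate(kb$ppi, seeds, alpha = thr$alpha)
    exp <- expand_top_k(kb$ppi, prop, k = thr$topk)
    spec_targets <- if (s == "CCQS") sig_parts$f1_only else sig_parts$f2_only
    sub <- extract_metabolite_gene_network(
      kb$metgene, dm_ids[[s]], proteomics$dp_ids[[s]], spec_targets)
    networks[[s]] <- list(
      ppi_seeds = length(seeds),
      ppi_added = exp$added,
      metgene_nodes = nrow(sub$nodes),
      metgene_origin = as.list(table(sub$nodes$origin)),
      metgene_node_ids = sub$nodes$id,
      metgene_kinds = sub$nodes$kind)
  }

  ## ---- enrichment ----
  enr <- list(); hits <- list()
  disease_gene_sets <- lapply(kb$diseases$candidates, `[[`, "genes")
  for (s in c("CCQS", "QSBS")) {
    o_gene <- ora(proteomics$dp_ids[[s]], kb$pathways$gene)
    o_met <- ora(dm_ids[[s]], kb$pathways$metabolite)
    nodes <- networks[[s]]$metgene_node_ids
    kinds <- networks[[s]]$metgene_kinds
    o_joint <- joint_ora(nodes[kinds == "gene"],
                         nodes[kinds == "metabolite"],
                         kb$pathways$joint)
    o_dis <- ora(proteomics$dp_ids[[s]], disease_gene_sets)
    kap <- kappa_matrix(unique(unlist(disease_gene_sets)),
                        disease_gene_sets)
    clusters <- cluster_terms(o_dis, kap, thr$stringency)
    enr[[s]] <- list(
      gene = o_gene[o_gene$p < thr$enrich_p, ],
      metabolite = o_met[o_met$p < thr$enrich_p, ],
      joint = o_joint[o_joint$p < thr$enrich_p, ],
      disease_clusters = clusters)
    hits[[s]] <- list(proteomics = o_gene$term[o_gene$p < thr$enrich_p],
                      metabolomics = o_met$term[o_met$p < thr$enrich_p],
                      integrated = o_joint$term[o_joint$p < thr$enrich_p])
  }
  consistency <- cross_view_consistency(hits)

  ## ---- biomarker panels ----
  panels <- list()
  panel_defs <- list(
    CCQS_protein = list(tab = imputed, markers = truth$panel_markers$ccqs_protein,
                        own = "CCQS", other = "QSBS"),
    QSBS_protein = list(tab = imputed, markers = truth$panel_markers$qsbs_protein,
                        own = "QSBS", other = "CCQS"),
    CCQS_metabolite = list(tab = met$untargeted,
                           markers = truth$panel_markers$ccqs_metabolite,
                           own = "CCQS", other = "QSBS"),
    QSBS_metabolite = list(tab = met$untargeted,
                           markers = truth$panel_markers$qsbs_metabolite,
                           own = "QSBS", other = "CCQS"))
  for (nm in names(panel_defs)) {
    pd <- panel_defs[[nm]]
    own <- subset_samples(pd$tab, c(pd$own, "HC"))
    oth <- subset_samples(pd$tab, c(pd$other, "HC"))
    Xo <- t(log2(own$intensity)); Xc <- t(log2(oth$intensity))
    fit <- fit_panel(Xo, own$samples$group == pd$own, pd$markers)
    cross <- cross_apply(fit, Xc, oth$samples$group == pd$other)
    panels[[nm]] <- list(markers = pd$markers,
                         auc_own = fit$roc$auc, auc_cross = cross$auc,
                         separation = fit$separation)
  }

  list(
    config = c(unclass(cfg)[setdiff(names(unclass(cfg)), "kb_sizes")],
               list(thresholds = thr, schema_version = "1.0")),
    cohort = list(p_values = cohort_p),
    proteomics = proteomics[setdiff(names(proteomics), "dp_ids")],
    metabolomics = metabolomics[setdiff(names(metabolomics), "dm_ids")],
    netpharm = netpharm,
    networks = lapply(networks, function(n)
      n[setdiff(names(n), c("metgene_node_ids", "metgene_kinds"))]),
    enrichment = enr,
    consistency = consistency,
    panels = panels
  )
}

#' Serialize a pipeline report to JSON
#'
#' @param report list from [run_pipeline()].
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}
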