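# Network pharmacology over multi-herb formulae: activity filtering of
# compounds, per-formula target aggregation, signature-target set algebra,
# Jaccard disease similarity, and ATC-class drug-target overlap.

#' Filter active compounds
#'
#' Keeps a compound record according to its source database's activity
#' rule: TCMSP-style records pass with oral bioavailability OB >= 30 and
#' drug-likeness DL >= 0.18 (inclusive thresholds); ETCM-style records pass
#' with a druglikeness grading of good or moderate; quality-marker
#' (pharmacopeia Q-marker) compounds are active unconditionally. A compound
#' listed under several sources is kept if it passes under any of them.
#' TCMSP records missing OB or DL are rejected with a warning.
#'
#' @param compounds data.frame with columns `compound`, `herb`, `source`
#'   (`"tcmsp"`, `"etcm"`, `"qmarker"`), `OB`, `DL`, `grading`.
#' @param ob_thresh,dl_thresh activity thresholds (defaults 30 and 0.18).
#' @return The active subset of `compounds` (same columns). Idempotent.
#' @export
filter_active <- function(compounds, ob_thresh = 30, dl_thresh = 0.18) {
  compounds <- as.data.frame(compounds)
  need <- c("compound", "herb", "source")
  if (!all(need %in% names(compounds)))
    stop("compounds needs columns: ", paste(need, collapse = ", "))
  src <- compounds$source
  keep <- logical(nrow(compounds))
  is_t <- src == "tcmsp"
  bad <- is_t & (is.na(compounds$OB) | is.na(compounds$DL))
  if (any(bad))
    warning(sprintf("rejecting %d tcmsp record(s) missing OB/DL", sum(bad)))
  keep[is_t & !bad] <- compounds$OB[is_t & !bad] >= ob_thresh &
    compounds$DL[is_t & !bad] >= dl_thresh
  is_e <- src == "etcm"
  keep[is_e] <- compounds$grading[is_e] %in% c("good", "moderate")
  keep[src == "qmarker"] <- TRUE
  out <- compounds[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate putative targets of a formula
#'
#' Union of the target sets of a formula's active compounds, with the
#' bookkeeping counts used in formula summary tables: number of active
#' compounds, number of active compounds that have at least one target, and
#' number of distinct putative targets.
#'
#' @param herbs character vector of the formula's herb ids.
#' @param active data.frame of active compounds ([filter_active()] output).
#' @param targets data.frame with columns `compound`, `target`.
#' @return List with `targets` (character vector), `n_active`,
#'   `n_active_with_targets`, `n_targets`.
#' @export
formula_targets <- function(herbs, active, targets) {
  comp <- unique(active$compound[active$herb %in% herbs])
  tmap <- targets[targets$compound %in% comp, , drop = FALSE]
  with_t <- unique(tmap$compound)
  tset <- sort(unique(tmap$target))
  if (length(comp) == 0)
    warning("formula has no active compounds; empty target set")
  list(targets = tset,
       n_active = length(comp),
       n_active_with_targets = length(with_t),
       n_targets = length(tset))
}

#' Signature targets of a syndrome's formula triple
#'
#' The targets common to all three formulae prescribed for one syndrome:
#' the triple intersection of their putative target sets.
#'
#' @param t1,t2,t3 character vectors of target ids.
#' @return Character vector (sorted).
#' @export
signature_targets <- function(t1, t2, t3) {
  sort(intersect(intersect(unique(t1), unique(t2)), unique(t3)))
}

#' Partition two syndromes' signature targets
#'
#' Venn partition of the two signature sets into common and
#' syndrome-specific signature targets.
#'
#' @param sig_f1,sig_f2 character vectors of signature targets.
#' @return List with `common`, `f1_only`, `f2_only`.
#' @export
specific_signatures <- function(sig_f1, sig_f2) {
  v <- venn_sets(sig_f1, sig_f2)
  list(common = v$common, f1_only = v$a_only, f2_only = v$b_only)
}

#' Jaccard index of two sets
#'
#' `J(A, B) = |A ∩ B| / |A ∪ B|`; 0 when the union is empty.
#'
#' @param a,b character vectors.
#' @return Numeric in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Diseases similar to a query disease by shared genes and variants
#'
#' Computes, for every candidate disease, the Jaccard index of its gene set
#' (JIg) and of its variant set (JIv) with the query disease, and retains
#' candidates with `JIg > jig_thresh` and `JIv > jiv_thresh` (both strict,
#' combined conjunctively by default).
#'
#' @param query list with `genes` and `variants` character vectors.
#' @param candidates named list of such lists.
#' @param jig_thresh,jiv_thresh thresholds (defaults 0.2 and 0.05).
#' @param combine `"and"` (default) or `"or"`.
#' @return data.frame with columns `disease`, `JIg`, `JIv`, `related`,
#'   ordered by JIg descending.
#' @export
disease_similarity <- function(query, candidates, jig_thresh = 0.2,
                               jiv_thresh = 0.05,
                               combine = c("and", "or")) {
  combine <- match.arg(combine)
  if (length(query$genes) == 0 || length(query$variants) == 0)
    stop("query disease needs non-empty gene and variant sets")
  jig <- vapply(candidates, function(d) jaccard(query$genes, d$genes),
                numeric(1L))
  jiv <- vapply(candidates, function(d) jaccard(query$variants, d$variants),
                numeric(1L))
  rel <- if (combine == "and") jig > jig_thresh & jiv > jiv_thresh
         else jig > jig_thresh | jiv > jiv_thresh
  res <- data.frame(disease = names(candidates), JIg = jig, JIv = jiv,
                    related = rel, stringsAsFactors = FALSE)
  res <- res[order(-res$JIg, res$disease), ]
  rownames(res) <- NULL
  res
}

#' Assign a drug's ATC code to a configured category
#'
#' Case-insensitive longest-prefix match of the ATC code against the
#' configured prefixes; `NA` when no prefix matches.
#'
#' @param atc character vector of ATC codes.
#' @param prefixes character vector of category prefixes.
#' @return Character vector of matched prefixes (or `NA`).
#' @export
atc_category <- function(atc, prefixes = c("C", "A10", "A08", "B01")) {
  prefixes <- prefixes[order(-nchar(prefixes))]  # longest match wins
  vapply(toupper(atc), function(code) {
    hit <- prefixes[startsWith(code, toupper(prefixes))]
    if (length(hit)) hit[1L] else NA_character_
  }, character(1L), USE.NAMES = FALSE)
}

#' Overlap of signature-target partitions with ATC drug-class targets
#'
#' Maps each drug to an ATC category by longest-prefix match (drugs with no
#' matching prefix are excluded), then counts, for every
#' (signature partition x category) cell, the targets shared between the
#' partition and the pharmacological targets of the category's drugs, and
#' returns the bipartite target-drug edge list for the shared pairs.
#'
#' @param partitions named list of character vectors (e.g. `common`,
#'   `f1_only`, `f2_only`).
#' @param drugs data.frame with columns `drug`, `atc`, `target` (one row
#'   per drug-target pair).
#' @param atc_prefixes configured category prefixes.
#' @return List with `counts` (data.frame: partition, category,
#'   n_shared_targets), `edges` (data.frame: partition, category, target,
#'   drug) and `network` (a [molecular_network] over targets and drugs).
#' @export
map_drug_overlap <- function(partitions, drugs,
                             atc_prefixes = c("C", "A10", "A08", "B01")) {
  drugs <- as.data.frame(drugs)
  drugs$category <- atc_category(drugs$atc, atc_prefixes)
  dropped <- unique(drugs$drug[is.na(drugs$category)])
  if (length(dropped))
    message(sprintf("excluding %d drug(s) outside the configured ATC classes",
                    length(dropped)))
  drugs <- drugs[!is.na(drugs$category), , drop = FALSE]
  cells <- expand.grid(partition = names(partitions),
                       category = unique(drugs$category),
                       stringsAsFactors = FALSE)
  edges <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    part <- partitions[[cells$partition[i]]]
    d <- drugs[drugs$category == cells$category[i] &
                 drugs$target %in% part, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    data.frame(partition = cells$partition[i],
               category = cells$category[i],
               target = d$target, drug = d$drug,
               stringsAsFactors = FALSE)
  }))
  counts <- cells
  counts$n_shared_targets <- vapply(seq_len(nrow(cells)), function(i) {
    part <- partitions[[cells$partition[i]]]
    length(unique(drugs$target[drugs$category == cells$category[i] &
                                 drugs$target %in% part]))
  }, integer(1L))
  net <- if (!is.null(edges) && nrow(edges)) {
    nodes <- data.frame(
      id = c(unique(edges$target), unique(edges$drug)),
      kind = c(rep("gene", length(unique(edges$target))),
               rep("drug", length(unique(edges$drug)))),
      stringsAsFactors = FALSE)
    molecular_network(
      unique(data.frame(from = edges$target, to = edges$drug, weight = 1,
                        stringsAsFactors = FALSE)),
      nodes)
  } else NULL
  list(counts = counts, edges = edges, network = net,
       excluded_drugs = dropped)
}
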