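# Over-representation analysis and kappa-based functional annotation
# clustering.

#' Hypergeometric over-representation analysis
#'
#' Tests each annotation set for over-representation of the query list
#' within a universe: with `N` universe items, `K` of them in the term, and
#' a query of `n` universe items of which `k` hit the term, the p-value is
#' the hypergeometric upper tail `P(X >= k)` (equivalently the one-sided
#' Fisher exact test on the 2x2 table). Benjamini-Hochberg q-values are
#' computed across the tested terms and rows are ordered by
#' (p ascending, term ascending).
#'
#' @param query character vector of query ids.
#' @param sets named list of character vectors (annotation sets).
#' @param universe character vector of background ids; by default, every id
#'   annotated to at least one set.
#' @return data.frame with columns `term`, `k`, `K`, `n`, `N`, `percentage`
#'   (share of the query mapped to the term, in percent), `p`, `q`.
#' @export
ora <- function(query, sets, universe = NULL) {
  if (is.null(universe)) universe <- unique(unlist(sets))
  universe <- unique(universe)
  q_eff <- intersect(unique(query), universe)
  if (length(q_eff) == 0)
    stop("query has no overlap with the universe")
  n <- length(q_eff)
  N <- length(universe)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), universe)
    K <- length(members)
    k <- length(intersect(q_eff, members))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = nm, k = k, K = K, n = n, N = N,
               percentage = percentage(k, length(unique(query))),
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- p.adjust(res$p, "BH")
  res <- res[order(res$p, res$term), ]
  rownames(res) <- NULL
  res
}

#' Joint over-representation of genes and metabolites
#'
#' Single combined-query hypergeometric test per term: the gene and
#' metabolite queries are pooled into one id set and tested against
#' mixed-kind annotation sets over the combined universe. Gene and
#' metabolite identifier namespaces must be disjoint.
#'
#' @param genes,mets character vectors of query ids.
#' @param sets named list of mixed-kind annotation sets.
#' @param universe combined background; defaults to all annotated ids.
#' @return As [ora()].
#' @export
joint_ora <- function(genes, mets, sets, universe = NULL) {
  if (length(intersect(genes, mets)) > 0)
    stop("gene and metabolite id namespaces must be disjoint")
  ora(c(unique(genes), unique(mets)), sets, universe)
}

#' Mapped percentage of a query list
#'
#' `100 * k / n` rounded to two decimals, the "Percentage" column of
#' annotation reports.
#'
#' @param k_mapped number of query items mapped to the term.
#' @param n_input query list size.
#' @return Numeric percentage.
#' @export
percentage <- function(k_mapped, n_input) {
  if (any(n_input == 0)) stop("n_input must be > 0")
  if (any(k_mapped > n_input)) stop("k_mapped cannot exceed n_input")
  round(100 * k_mapped / n_input, 2)
}

#' Pairwise Cohen's kappa between annotation terms
#'
#' Agreement between two terms' binary membership profiles over a common
#' item set, from the 2x2 item-membership table:
#' `kappa = (Po - Pe) / (1 - Pe)`. When the chance agreement `Pe` is 1
#' (both terms annotate everything or nothing), kappa is defined as 0 with
#' a warning.
#'
#' @param items character vector of items (e.g. the pooled differential
#'   proteins) over which membership is profiled.
#' @param sets named list of >= 2 annotation sets.
#' @return Symmetric numeric matrix of kappa values with unit diagonal.
#' @export
kappa_matrix <- function(items, sets) {
  if (length(sets) < 2) stop("at least 2 terms are required")
  items <- unique(items)
  M <- vapply(sets, function(s) items %in% s, logical(length(items)))
  n <- length(items)
  K <- matrix(1, ncol(M), ncol(M), dimnames = list(colnames(M), colnames(M)))
  warned <- FALSE
  for (i in seq_len(ncol(M) - 1L)) for (j in (i + 1L):ncol(M)) {
    a <- M[, i]; b <- M[, j]
    po <- mean(a == b)
    pe <- mean(a) * mean(b) + (1 - mean(a)) * (1 - mean(b))
    kap <- if (pe == 1) { warned <- TRUE; 0 } else (po - pe) / (1 - pe)
    K[i, j] <- K[j, i] <- kap
  }
  if (warned)
    warning("kappa set to 0 for term pair(s) with degenerate profiles")
  K
}

# stringency presets for annotation clustering, mirroring the structure of
# the DAVID-style presets; "high" is the default used throughout
.stringency_presets <- list(
  high   = list(kappa_min = 0.85, min_partners = 3L, linkage = 0.5),
  medium = list(kappa_min = 0.50, min_partners = 3L, linkage = 0.5),
  low    = list(kappa_min = 0.35, min_partners = 2L, linkage = 0.5)
)

#' Cluster enriched terms by kappa similarity
#'
#' Greedy seed-and-merge clustering of annotation terms (the functional
#' annotation clustering idiom): terms with at least `min_partners` other
#' terms at kappa >= `kappa_min` seed initial groups (the seed plus its
#' qualifying partners); groups sharing at least a `linkage` fraction of
#' the smaller group's members are merged to a fixed point. Terms left
#' outside every group become singleton clusters. Each cluster's
#' enrichment score is `-log10` of the geometric mean of its member terms'
#' p-values, and clusters are ranked by score descending.
#'
#' @param enrichment data.frame with columns `term` and `p`
#'   (e.g. [ora()] output).
#' @param kappa symmetric kappa matrix over the same terms
#'   ([kappa_matrix()]).
#' @param stringency `"high"` (default), `"medium"` or `"low"`; or a list
#'   with elements `kappa_min`, `min_partners`, `linkage`.
#' @return data.frame with columns `rank`, `enrichment_score`, `n_terms`,
#'   `terms` (list column), ordered by score descending.
#' @export
cluster_terms <- function(enrichment, kappa, stringency = "high") {
  preset <- if (is.list(stringency)) stringency
            else .stringency_presets[[match.arg(stringency,
                                                names(.stringency_presets))]]
  terms <- enrichment$term
  if (!all(terms %in% rownames(kappa)))
    stop("kappa matrix must cover every enriched term")
  kap <- kappa[terms, terms, drop = FALSE]
  groups <- list()
  for (t in terms) {
    partners <- terms[terms != t & kap[t, terms] >= preset$kappa_min]
    if (length(partners) >= preset$min_partners)
      groups[[length(groups) + 1L]] <- c(t, partners)
  }
  # merge groups sharing >= linkage fraction of the smaller group
  merged <- TRUE
  while (merged && length(groups) > 1L) {
    merged <- FALSE
    for (i in seq_len(length(groups) - 1L)) {
      for (j in (i + 1L):length(groups)) {
        shared <- length(intersect(groups[[i]], groups[[j]]))
        if (shared / min(length(groups[[i]]), length(groups[[j]])) >=
            preset$linkage) {
          groups[[i]] <- union(groups[[i]], groups[[j]])
          groups[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
  }
  clustered <- unique(unlist(groups))
  singles <- setdiff(terms, clustered)
  groups <- c(groups, as.list(singles))
  pmap <- setNames(enrichment$p, enrichment$term)
  score <- vapply(groups, function(g) mean(-log10(pmap[g])), numeric(1L))
  ord <- order(-score)
  data.frame(
    rank = seq_along(ord),
    enrichment_score = score[ord],
    n_terms = vapply(groups[ord], length, integer(1L)),
    terms = I(lapply(groups[ord], sort)),
    stringsAsFactors = FALSE
  )
}

#' Cross-view consistency of enriched pathways
#'
#' Tabulates, for every pathway significant in at least one analysis view
#' (e.g. proteomics, metabolomics, integrated) of at least one syndrome,
#' its membership across views and syndromes, and flags pathways common to
#' both syndromes versus syndrome-specific ones.
#'
#' @param hits nested named list: `hits[[syndrome]][[view]]` is a character
#'   vector of significant terms.
#' @return data.frame with one row per (term, syndrome): logical column
#'   per view, `n_views`, and a per-term `syndrome_flag`
#'   (`"both"` or `"<syndrome>-specific"`).
#' @export
cross_view_consistency <- function(hits) {
  syndromes <- names(hits)
  views <- unique(unlist(lapply(hits, names)))
  rows <- do.call(rbind, lapply(syndromes, function(s) {
    terms <- unique(unlist(hits[[s]]))
    if (length(terms) == 0) return(NULL)
    d <- data.frame(term = terms, syndrome = s, stringsAsFactors = FALSE)
    for (v in views) d[[v]] <- terms %in% hits[[s]][[v]]
    d
  }))
  if (is.null(rows)) return(rows)
  rows$n_views <- rowSums(rows[, views, drop = FALSE])
  by_syn <- lapply(syndromes, function(s)
    unique(rows$term[rows$syndrome == s]))
  names(by_syn) <- syndromes
  rows$syndrome_flag <- vapply(rows$term, function(t) {
    present <- syndromes[vapply(by_syn, function(x) t %in% x, logical(1L))]
    if (length(present) == length(syndromes) && length(syndromes) > 1L)
      "both" else paste0(present[1L], "-specific")
  }, character(1L))
  rows[order(rows$syndrome, -rows$n_views, rows$term), ]
}
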